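#' Build a channel adjacency graph by distance threshold
#'
#' Two channels are neighbours iff `0 < dist(i, j) <= distance_threshold`.
#' This is the spatial half of the channel-time connectivity used for cluster
#' enhancement: in channel-time space, two points are connected iff they share
#' a sample and their channels are neighbours, or share a channel and sit at
#' adjacent samples (no diagonal moves).
#'
#' @param layout a `sensor_layout`.
#' @param distance_threshold positive distance in the layout's units (head
#'   radii for unit-sphere layouts). See [calibrate_adjacency_threshold()].
#' @return a `channel_graph`: list with `n_channels`, `neighbors` (list of
#'   integer index vectors), `distance_threshold`, `channel_names`.
#' @export
build_adjacency <- function(layout, distance_threshold) {
  validate_sensor_layout(layout)
  stopifnot_scalar_number(distance_threshold, "distance_threshold", lower = 1e-12)
  d <- as.matrix(stats::dist(layout$positions))
  n <- nrow(d)
  adj <- d > 0 & d <= distance_threshold
  neighbors <- lapply(seq_len(n), function(i) which(adj[i, ]))
  structure(list(n_channels = n, neighbors = neighbors,
                 distance_threshold = distance_threshold,
                 channel_names = layout$channel_names),
            class = "channel_graph")
}

#' Pick an adjacency threshold by target mean degree
#'
#' Scans candidate thresholds (the sorted unique pairwise distances) and
#' returns the smallest one whose mean degree reaches `target_degree`. Dense
#' montages typically use neighbourhoods of ~5-8 channels.
#'
#' @param layout a `sensor_layout`.
#' @param target_degree desired mean number of neighbours (default 6).
#' @return the distance threshold (numeric scalar).
#' @export
calibrate_adjacency_threshold <- function(layout, target_degree = 6) {
  d <- as.matrix(stats::dist(layout$positions))
  n <- nrow(d)
  dv <- sort(d[upper.tri(d)])
  # mean degree after including the k smallest pairwise distances is 2k/n
  k <- ceiling(target_degree * n / 2)
  k <- min(k, length(dv))
  dv[k]
}

#' Per-channel degree statistics of a channel graph
#'
#' @param graph a `channel_graph`.
#' @return list with `degrees` (integer per channel), `min`, `mean`, `max`.
#' @export
neighborhood_degree_summary <- function(graph) {
  stopifnot(inherits(graph, "channel_graph"))
  deg <- vapply(graph$neighbors, length, integer(1))
  list(degrees = deg, min = min(deg), mean = mean(deg), max = max(deg))
}

#' Export a channel graph as a tab-separated edge list
#'
#' One line per undirected edge: `channel_a TAB channel_b`, each edge once.
#'
#' @param graph a `channel_graph`.
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  edges <- do.call(rbind, lapply(seq_len(graph$n_channels), function(i) {
    js <- graph$neighbors[[i]]
    js <- js[js > i]
    if (length(js)) cbind(graph$channel_names[i], graph$channel_names[js]) else NULL
  }))
  if (is.null(edges)) edges <- matrix(character(0), 0, 2)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
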