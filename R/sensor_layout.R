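#' Generate a scalp-like sensor layout
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper portion of the
#' unit sphere (a Fibonacci lattice restricted to z > -0.2, roughly the area a
#' dense EEG net covers), with a small seeded angular jitter so distinct seeds
#' give distinct but equally regular montages. Channels are named
#' `"E1".."E<n>"`, mirroring dense-net conventions.
#'
#' @param n_channels number of electrodes (>= 4).
#' @param seed integer seed controlling the jitter.
#' @param jitter_sd angular jitter (radians-scale displacement before
#'   re-normalisation); 0 gives the bare lattice.
#' @return a `sensor_layout`: list with `channel_names` and a `positions`
#'   matrix (`n_channels` x 3, rownames = channel names, unit-norm rows).
#' @export
generate_sensor_layout <- function(n_channels, seed = 1L, jitter_sd = 0.02) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 4) {
    stop("`n_channels` must be a single integer >= 4", call. = FALSE)
  }
  n <- as.integer(n_channels)
  z_cut <- -0.2

  # Fibonacci lattice over the full sphere; z descends uniformly, so the
  # first points generated are the top of the head. Grow the lattice until
  # exactly n points clear the z cut.
  m <- max(n, ceiling(n / ((1 - z_cut) / 2)))
  repeat {
    i <- seq_len(m)
    z <- 1 - 2 * (i - 0.5) / m
    keep <- z > z_cut
    if (sum(keep) >= n) break
    m <- m + 1L
  }
  golden <- pi * (3 - sqrt(5))
  i <- which(keep)[seq_len(n)]
  z <- 1 - 2 * (i - 0.5) / m
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (i - 1)
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)

  if (jitter_sd > 0) {
    pos <- with_seed(seed, pos + matrix(stats::rnorm(3L * n, sd = jitter_sd), n, 3L))
    pos <- pos / sqrt(rowSums(pos^2))
  }
  names_ <- paste0("E", seq_len(n))
  rownames(pos) <- names_
  layout <- list(channel_names = names_, positions = pos)
  class(layout) <- "sensor_layout"
  validate_sensor_layout(layout)
  layout
}

#' @keywords internal
validate_sensor_layout <- function(layout) {
  stopifnot(is.list(layout), !is.null(layout$channel_names), is.matrix(layout$positions))
  if (anyDuplicated(layout$channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (nrow(layout$positions) != length(layout$channel_names) || ncol(layout$positions) != 3L) {
    stop("positions must be an n x 3 matrix, one row per channel", call. = FALSE)
  }
  d <- as.matrix(stats::dist(layout$positions))
  diag(d) <- Inf
  if (any(d == 0)) stop("two channels share identical coordinates", call. = FALSE)
  invisible(layout)
}

#' Write / read electrode positions as plain text
#'
#' One line per channel: `name x y z` (the common .sfp/.xyz convention).
#'
#' @param layout a `sensor_layout`.
#' @param path file path.
#' @return `read_sensor_layout` returns a `sensor_layout`.
#' @export
write_sensor_layout <- function(layout, path) {
  validate_sensor_layout(layout)
  df <- data.frame(name = layout$channel_names,
                   layout$positions, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_layout
#' @export
read_sensor_layout <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("name", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$name
  layout <- list(channel_names = df$name, positions = pos)
  class(layout) <- "sensor_layout"
  validate_sensor_layout(layout)
  layout
}
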