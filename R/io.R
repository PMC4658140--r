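#' Persist an ERP dataset as plain text
#'
#' Writes one delimited numeric matrix (channels x samples) per
#' subject x condition cell, named `sub<ii>_<condition>.tsv`, plus a single
#' JSON metadata file (`dataset.json`) holding group labels, covariates, the
#' time axis, condition labels and channel names.
#'
#' @param dataset an `erp_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_erp_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "erp_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$data)
  for (s in seq_len(d[1])) for (cc in seq_len(d[2])) {
    m <- dataset$data[s, cc, , ]
    utils::write.table(m, file.path(dir, sprintf("sub%02d_%s.tsv", s,
                                                 dataset$condition_labels[cc])),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  meta <- list(n_subjects = d[1], groups = as.character(dataset$groups),
               condition_labels = dataset$condition_labels,
               channel_names = dataset$channel_names,
               time_axis = dataset$time_axis,
               covariates = dataset$covariates)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(dataset$layout)) {
    write_sensor_layout(dataset$layout, file.path(dir, "layout.sfp"))
  }
  invisible(dir)
}

#' @rdname write_erp_dataset
#' @param dir directory written by `write_erp_dataset`.
#' @export
read_erp_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"), simplifyVector = TRUE)
  n_sub <- meta$n_subjects
  n_cond <- length(meta$condition_labels)
  n_ch <- length(meta$channel_names)
  n_t <- length(meta$time_axis)
  arr <- array(NA_real_, dim = c(n_sub, n_cond, n_ch, n_t))
  for (s in seq_len(n_sub)) for (cc in seq_len(n_cond)) {
    f <- file.path(dir, sprintf("sub%02d_%s.tsv", s, meta$condition_labels[cc]))
    arr[s, cc, , ] <- as.matrix(utils::read.table(f, sep = "\t"))
  }
  layout_path <- file.path(dir, "layout.sfp")
  layout <- if (file.exists(layout_path)) read_sensor_layout(layout_path) else NULL
  covs <- as.data.frame(meta$covariates)
  if (!nrow(covs)) covs <- NULL
  erp_dataset(arr, meta$time_axis, factor(meta$groups, levels = unique(meta$groups)),
              meta$condition_labels, meta$channel_names, covs, layout)
}

#' Write a run manifest
#'
#' JSON record of the parameters and seeds sufficient to reproduce a stage's
#' outputs exactly, written beside them.
#'
#' @param path output JSON path.
#' @param stage short stage name.
#' @param params named list of parameters (must be JSON-serialisable).
#' @param seed the seed(s) used.
#' @export
write_manifest <- function(path, stage, params, seed) {
  jsonlite::write_json(
    list(stage = stage, params = params, seed = seed,
         package_version = as.character(utils::packageVersion("erptfce")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
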