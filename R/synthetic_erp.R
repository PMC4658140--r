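#' Specify an injected ERP effect
#'
#' Describes an additive mean shift applied to selected channels within a time
#' window, with a per-(group, condition) amplitude, so simulated datasets
#' carry a known ground truth for recovery tests.
#'
#' @param target_channels channel names receiving the effect.
#' @param window numeric length-2, time window in ms post-event (closed).
#' @param amplitude_by_cell numeric matrix of mean shifts in uV with one row
#'   per group and one column per condition (dimnames = group / condition
#'   labels), or a single number applied to every cell.
#' @param shape temporal envelope: `"hann"` (raised-cosine bump, 0 at the
#'   window edges, 1 at its centre) or `"boxcar"`.
#' @return an `effect_spec`.
#' @export
effect_spec <- function(target_channels, window, amplitude_by_cell, shape = c("hann", "boxcar")) {
  shape <- match.arg(shape)
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2]) {
    stop("`window` must be (start_ms, end_ms) with start < end", call. = FALSE)
  }
  if (!all(is.finite(unlist(amplitude_by_cell)))) {
    stop("effect amplitudes must be finite", call. = FALSE)
  }
  structure(list(target_channels = target_channels, window = as.numeric(window),
                 amplitude_by_cell = amplitude_by_cell, shape = shape),
            class = "effect_spec")
}

#' Noise model for simulated ERPs
#'
#' Gaussian noise with squared-exponential correlation across the scalp and
#' across time, plus a per-subject random amplitude offset. The kernels give
#' smooth topographies and waveforms, the structure cluster-enhancement
#' methods are designed for.
#'
#' @param sd noise standard deviation (uV).
#' @param spatial_lengthscale distance (same units as the layout, i.e. head
#'   radii) over which channel noise decorrelates.
#' @param temporal_lengthscale time (ms) over which sample noise decorrelates.
#' @param subject_sd standard deviation (uV) of the per-subject constant
#'   amplitude offset (between-subject variability).
#' @return a `noise_model`.
#' @export
noise_model <- function(sd = 2, spatial_lengthscale = 0.5, temporal_lengthscale = 40,
                        subject_sd = 1) {
  for (nm in c("sd", "spatial_lengthscale", "temporal_lengthscale")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop(sprintf("`%s` must be a positive scalar", nm), call. = FALSE)
    }
  }
  if (subject_sd < 0) stop("`subject_sd` must be >= 0", call. = FALSE)
  structure(list(sd = sd, spatial_lengthscale = spatial_lengthscale,
                 temporal_lengthscale = temporal_lengthscale, subject_sd = subject_sd),
            class = "noise_model")
}

# Cholesky factor of a squared-exponential correlation over pairwise distances.
se_chol <- function(d, lengthscale) {
  k <- exp(-(d / lengthscale)^2 / 2)
  diag(k) <- diag(k) + 1e-8
  t(chol(k))
}

#' Simulate an ERP dataset with known injected effects
#'
#' Generates per-subject, per-condition averaged ERPs as cell means implied by
#' `effects` plus spatially and temporally correlated Gaussian noise and a
#' per-subject offset. With all effect amplitudes zero the dataset is a valid
#' null: its distribution is exchangeable across groups and conditions.
#'
#' @param layout a `sensor_layout`.
#' @param group_sizes named integer vector, subjects per group (each >= 2).
#' @param condition_labels character vector of within-subject conditions.
#' @param effects list of [effect_spec()] objects (may be empty).
#' @param noise a [noise_model()].
#' @param time_axis sample times in ms relative to the event (evenly spaced).
#' @param seed integer seed; the simulation is bit-reproducible given it.
#' @param covariates optional data.frame of per-subject covariates (one row
#'   per subject, in subject order); if `NULL`, plausible `age` and `ess`
#'   columns are drawn.
#' @return an `erp_dataset`: list with `data` (subject x condition x channel x
#'   sample array, uV), `time_axis` (ms), `groups` (factor per subject),
#'   `condition_labels`, `channel_names`, `covariates`, `layout`.
#' @export
simulate_erp_dataset <- function(layout, group_sizes, condition_labels,
                                 effects = list(), noise = noise_model(),
                                 time_axis = seq(-200, 796, by = 4), seed = 1L,
                                 covariates = NULL) {
  validate_sensor_layout(layout)
  if (any(group_sizes < 2)) stop("every group needs >= 2 subjects", call. = FALSE)
  if (is.null(names(group_sizes))) names(group_sizes) <- paste0("G", seq_along(group_sizes))
  if (length(unique(diff(time_axis))) > 1L &&
      max(abs(diff(diff(time_axis)))) > 1e-9) {
    stop("`time_axis` must be evenly spaced", call. = FALSE)
  }
  if (any(diff(time_axis) <= 0)) stop("`time_axis` must be strictly increasing", call. = FALSE)
  condition_labels <- as.character(condition_labels)

  n_sub <- sum(group_sizes)
  n_cond <- length(condition_labels)
  n_ch <- length(layout$channel_names)
  n_t <- length(time_axis)
  groups <- factor(rep(names(group_sizes), group_sizes), levels = names(group_sizes))

  for (ef in effects) {
    if (!all(ef$target_channels %in% layout$channel_names)) {
      stop("effect targets channels absent from the layout", call. = FALSE)
    }
    if (ef$window[1] < min(time_axis) || ef$window[2] > max(time_axis)) {
      stop("effect window lies outside the epoch time axis", call. = FALSE)
    }
  }

  # Deterministic cell-mean signal implied by the effects.
  signal_arr <- array(0, dim = c(length(group_sizes), n_cond, n_ch, n_t))
  for (ef in effects) {
    ch_idx <- match(ef$target_channels, layout$channel_names)
    t_in <- which(time_axis >= ef$window[1] & time_axis <= ef$window[2])
    if (length(t_in) == 0L) next
    env <- if (ef$shape == "hann") {
      u <- (time_axis[t_in] - ef$window[1]) / diff(ef$window)
      (1 - cos(2 * pi * u)) / 2
    } else rep(1, length(t_in))
    amp <- ef$amplitude_by_cell
    if (length(amp) == 1L) {
      amp <- matrix(amp, length(group_sizes), n_cond,
                    dimnames = list(names(group_sizes), condition_labels))
    }
    for (g in seq_along(group_sizes)) for (cc in seq_len(n_cond)) {
      a <- amp[names(group_sizes)[g], condition_labels[cc]]
      if (a != 0) {
        signal_arr[g, cc, ch_idx, t_in] <- signal_arr[g, cc, ch_idx, t_in] +
          a * rep(env, each = length(ch_idx))
      }
    }
  }

  ls_sp <- se_chol(as.matrix(stats::dist(layout$positions)), noise$spatial_lengthscale)
  ls_tm <- se_chol(abs(outer(time_axis, time_axis, "-")), noise$temporal_lengthscale)

  dat <- with_seed(seed, {
    out <- array(0, dim = c(n_sub, n_cond, n_ch, n_t))
    subj_off <- stats::rnorm(n_sub, sd = noise$subject_sd)
    for (s in seq_len(n_sub)) {
      g <- as.integer(groups[s])
      for (cc in seq_len(n_cond)) {
        eps <- ls_sp %*% matrix(stats::rnorm(n_ch * n_t), n_ch, n_t) %*% t(ls_tm)
        out[s, cc, , ] <- signal_arr[g, cc, , ] + subj_off[s] + noise$sd * eps
      }
    }
    out
  })

  if (is.null(covariates)) {
    covariates <- with_seed(seed + 104729L, data.frame(
      age = round(stats::rnorm(n_sub, mean = 40, sd = 12), 1),
      ess = pmin(24, pmax(0, round(stats::rnorm(n_sub, mean = 8, sd = 4))))
    ))
  }
  if (nrow(covariates) != n_sub) stop("one covariate row per subject required", call. = FALSE)

  erp_dataset(dat, time_axis, groups, condition_labels,
              layout$channel_names, covariates, layout)
}

#' Construct and validate an ERP dataset
#'
#' @param data subject x condition x channel x sample array (uV).
#' @param time_axis sample times (ms), evenly spaced, strictly increasing.
#' @param groups factor of group labels, one per subject.
#' @param condition_labels condition names matching `dim(data)[2]`.
#' @param channel_names channel names matching `dim(data)[3]`.
#' @param covariates per-subject data.frame (may be empty).
#' @param layout optional `sensor_layout`.
#' @return an `erp_dataset`.
#' @export
erp_dataset <- function(data, time_axis, groups, condition_labels, channel_names,
                        covariates = NULL, layout = NULL) {
  stopifnot(length(dim(data)) == 4L)
  groups <- as.factor(groups)
  d <- dim(data)
  if (d[1] != length(groups)) stop("group label per subject required", call. = FALSE)
  if (d[2] != length(condition_labels)) stop("condition labels do not match data", call. = FALSE)
  if (d[3] != length(channel_names)) stop("channel names do not match data", call. = FALSE)
  if (d[4] != length(time_axis)) stop("time axis does not match data", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 subjects", call. = FALSE)
  if (any(diff(time_axis) <= 0)) stop("time axis must be strictly increasing", call. = FALSE)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(d[1]))
  structure(list(data = data, time_axis = as.numeric(time_axis), groups = groups,
                 condition_labels = as.character(condition_labels),
                 channel_names = as.character(channel_names),
                 covariates = covariates, layout = layout),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ERP dataset: %d subjects (%s) x %d conditions x %d channels x %d samples\n",
              d[1], paste(sprintf("%s=%d", levels(x$groups), table(x$groups)), collapse = ", "),
              d[2], d[3], d[4]))
  cat(sprintf("time: %g..%g ms, step %g ms\n", min(x$time_axis), max(x$time_axis),
              x$time_axis[2] - x$time_axis[1]))
  invisible(x)
}
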