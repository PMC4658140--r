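#' Band-pass filter a continuous recording
#'
#' Zero-phase Butterworth band-pass built from a high-pass and a low-pass
#' stage. The default 1-30 Hz band with 12 dB/octave high-pass and
#' 24 dB/octave low-pass slopes corresponds to Butterworth orders 2 and 4;
#' both stages are applied forward-backward so the passband phase is zero.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz high-pass cutoff (Hz).
#' @param high_hz low-pass cutoff (Hz).
#' @param low_slope_db_oct high-pass slope, a multiple of 6 (dB/octave).
#' @param high_slope_db_oct low-pass slope, a multiple of 6 (dB/octave).
#' @return the filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 1, high_hz = 30,
                            low_slope_db_oct = 12, high_slope_db_oct = 24) {
  stopifnot(inherits(rec, "eeg_recording"))
  ny <- rec$rate / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < ny)) {
    stop("cutoffs must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  hp <- signal::butter(max(1L, round(low_slope_db_oct / 6)), low_hz / ny, type = "high")
  lp <- signal::butter(max(1L, round(high_slope_db_oct / 6)), high_hz / ny, type = "low")
  rec$data <- t(apply(rec$data, 1, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  rec
}

#' Notch filter at the mains frequency
#'
#' Zero-phase Butterworth band-stop around `freq_hz` (default 50 Hz).
#'
#' @param rec an `eeg_recording`.
#' @param freq_hz centre of the stop band (Hz).
#' @param width_hz full width of the stop band (Hz).
#' @return the filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq_hz = 50, width_hz = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  ny <- rec$rate / 2
  if (freq_hz + width_hz / 2 >= ny || freq_hz - width_hz / 2 <= 0) {
    stop("notch band must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  bs <- signal::butter(2, c(freq_hz - width_hz / 2, freq_hz + width_hz / 2) / ny,
                       type = "stop")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bs, x)))
  rec
}

#' Downsample a continuous recording
#'
#' Anti-alias low-pass (zero-phase Butterworth at 80% of the new Nyquist)
#' followed by decimation. Integer rate ratios decimate exactly; non-integer
#' ratios are resampled onto the new time grid by interpolation of the
#' anti-aliased signal. Event markers are remapped to the nearest retained
#' sample.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz new sampling rate (<= current rate).
#' @return the downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_hz = 250) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_hz > rec$rate) stop("target rate exceeds the recording rate", call. = FALSE)
  if (target_hz == rec$rate) return(rec)
  aa <- signal::butter(8, 0.8 * (target_hz / 2) / (rec$rate / 2), type = "low")
  filtered <- t(apply(rec$data, 1, function(x) signal::filtfilt(aa, x)))
  q <- rec$rate / target_hz
  n <- ncol(filtered)
  if (abs(q - round(q)) < 1e-9) {
    idx <- seq(1L, n, by = as.integer(round(q)))
    newdata <- filtered[, idx, drop = FALSE]
  } else {
    old_t <- (seq_len(n) - 1) / rec$rate
    new_t <- seq(0, old_t[n], by = 1 / target_hz)
    newdata <- t(apply(filtered, 1, function(x) stats::approx(old_t, x, xout = new_t)$y))
  }
  ev <- rec$events
  if (nrow(ev)) ev$sample <- pmax(1L, pmin(ncol(newdata),
                                           as.integer(round((ev$sample - 1) / q)) + 1L))
  eeg_recording(newdata, target_hz, rec$channel_names, ev)
}

# Legendre polynomials P_1..P_nmax evaluated at x (vector), as length(x) x nmax.
legendre_table <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  out[, 1] <- p_cur
  if (nmax >= 2) for (n in 2:nmax) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    out[, n] <- p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out
}

# Spherical-spline kernel g(cos theta) of the Perrin formulation.
spline_g <- function(cosang, m = 4, nterms = 50) {
  n <- seq_len(nterms)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  p <- legendre_table(pmin(1, pmax(-1, as.numeric(cosang))), nterms)
  matrix(p %*% coef / (4 * pi), nrow = nrow(as.matrix(cosang)))
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed bad channels with spherical-spline estimates (Perrin
#' interpolation, order `m = 4`, ridge regularisation `1e-5`) from the
#' remaining channels, for a recording or an epoch matrix. Refuses when the
#' bad-channel fraction exceeds `max_fraction` (default 5/125, the cap a
#' careful lab imposes per participant).
#'
#' @param x channels x samples numeric matrix, or an `eeg_recording`.
#' @param layout the `sensor_layout` the rows of `x` correspond to.
#' @param bad_channels channel names to re-estimate.
#' @param max_fraction maximum tolerated fraction of bad channels.
#' @param m spline order.
#' @param reg ridge regularisation added to the spline system diagonal.
#' @return object of the same shape with bad channels replaced.
#' @export
interpolate_channels <- function(x, layout, bad_channels, max_fraction = 5 / 125,
                                 m = 4, reg = 1e-5) {
  is_rec <- inherits(x, "eeg_recording")
  dat <- if (is_rec) x$data else x
  stopifnot(is.matrix(dat), nrow(dat) == length(layout$channel_names))
  if (length(bad_channels) == 0L) return(x)
  if (!all(bad_channels %in% layout$channel_names)) {
    stop("bad channels not present in the layout", call. = FALSE)
  }
  n_ch <- length(layout$channel_names)
  if (length(bad_channels) / n_ch > max_fraction + 1e-12) {
    stop(sprintf("refusing to interpolate %d of %d channels (cap is %d)",
                 length(bad_channels), n_ch, floor(max_fraction * n_ch)), call. = FALSE)
  }
  bad <- match(bad_channels, layout$channel_names)
  good <- setdiff(seq_len(n_ch), bad)
  pos <- layout$positions / sqrt(rowSums(layout$positions^2))
  cos_gg <- tcrossprod(pos[good, , drop = FALSE])
  cos_bg <- tcrossprod(pos[bad, , drop = FALSE], pos[good, , drop = FALSE])
  g_gg <- spline_g(cos_gg, m = m)
  g_bg <- matrix(spline_g(cos_bg, m = m), nrow = length(bad))
  k <- length(good)
  # Perrin system with the constant term and a ridge on the data block
  a <- rbind(cbind(g_gg + diag(reg, k), rep(1, k)), c(rep(1, k), 0))
  rhs <- rbind(dat[good, , drop = FALSE], 0)
  sol <- solve(a, rhs)
  dat[bad, ] <- cbind(g_bg, 1) %*% sol
  if (is_rec) { x$data <- dat; x } else dat
}

#' Re-reference to the average of all electrodes
#'
#' Subtracts, at every sample, the mean over channels; afterwards the channel
#' mean is zero everywhere. Idempotent.
#'
#' @param x channels x samples matrix, or an `eeg_recording`.
#' @return same shape, average-referenced.
#' @export
rereference_average <- function(x) {
  is_rec <- inherits(x, "eeg_recording")
  dat <- if (is_rec) x$data else x
  if (nrow(dat) < 2) stop("average reference needs >= 2 channels", call. = FALSE)
  dat <- sweep(dat, 2, colMeans(dat))
  if (is_rec) { x$data <- dat; x } else dat
}

#' Semi-automatic rejection criteria
#'
#' Defaults follow standard amplitude-based screening: a maximal voltage step
#' of 25 uV/ms between adjacent samples, a maximal peak-to-peak difference of
#' 75 uV within any 200 ms sliding window, and an absolute amplitude bound of
#' +/-150 uV.
#'
#' @param max_step maximal voltage step (uV per ms).
#' @param max_window_diff maximal peak-to-peak difference (uV) in the window.
#' @param window_len sliding-window length (ms).
#' @param amp_low,amp_high absolute amplitude bounds (uV).
#' @return a `rejection_criteria`.
#' @export
rejection_criteria <- function(max_step = 25, max_window_diff = 75, window_len = 200,
                               amp_low = -150, amp_high = 150) {
  stopifnot(amp_low < amp_high, max_step > 0, max_window_diff > 0, window_len > 0)
  structure(list(max_step = max_step, max_window_diff = max_window_diff,
                 window_len = window_len, amp_low = amp_low, amp_high = amp_high),
            class = "rejection_criteria")
}

#' Screen one epoch against the rejection criteria
#'
#' @param epoch an `erp_epoch` (see [make_epochs()]), or a channels x samples
#'   matrix together with `dt_ms`.
#' @param criteria a [rejection_criteria()].
#' @param dt_ms sample interval in ms (taken from the epoch if omitted).
#' @return list with `rejected` (logical) and `rules` (subset of
#'   `c("step", "window", "amplitude")`).
#' @export
detect_artifacts <- function(epoch, criteria = rejection_criteria(), dt_ms = NULL) {
  dat <- if (inherits(epoch, "erp_epoch")) epoch$data else epoch
  if (is.null(dt_ms)) {
    if (!inherits(epoch, "erp_epoch")) stop("`dt_ms` required for bare matrices", call. = FALSE)
    dt_ms <- epoch$time_axis[2] - epoch$time_axis[1]
  }
  stopifnot(is.matrix(dat), ncol(dat) >= 2)
  rules <- character(0)

  if (max(abs(dat[, -1, drop = FALSE] - dat[, -ncol(dat), drop = FALSE])) / dt_ms >
      criteria$max_step) {
    rules <- c(rules, "step")
  }

  w <- min(ncol(dat), round(criteria$window_len / dt_ms) + 1L)
  worst <- 0
  for (s in seq_len(ncol(dat) - w + 1L)) {
    seg <- dat[, s:(s + w - 1L), drop = FALSE]
    worst <- max(worst, max(apply(seg, 1, max) - apply(seg, 1, min)))
    if (worst > criteria$max_window_diff) break
  }
  if (worst > criteria$max_window_diff) rules <- c(rules, "window")

  if (any(dat < criteria$amp_low | dat > criteria$amp_high)) {
    rules <- c(rules, "amplitude")
  }
  list(rejected = length(rules) > 0L, rules = rules)
}

#' Cut a continuous recording into event-locked epochs
#'
#' Each epoch spans the half-open window `[tmin_ms, tmax_ms)` around its event
#' and therefore holds exactly `round((tmax - tmin)/1000 * rate)` samples
#' (250 samples for the default -200..800 ms window at 250 Hz). Events too
#' close to a recording edge are skipped with a warning.
#'
#' @param rec an `eeg_recording` with events (or an explicit `events` table).
#' @param events optional data.frame (`sample`, `label`) overriding
#'   `rec$events`.
#' @param tmin_ms,tmax_ms epoch window relative to the event (ms).
#' @param subject_id identifier stored on every epoch.
#' @return list of `erp_epoch` objects (`data`, `time_axis`, `condition_label`,
#'   `subject_id`, `rejected`, `rules`).
#' @export
make_epochs <- function(rec, events = NULL, tmin_ms = -200, tmax_ms = 800,
                        subject_id = "S1") {
  stopifnot(inherits(rec, "eeg_recording"), tmin_ms < tmax_ms)
  if (is.null(events)) events <- rec$events
  if (!nrow(events)) stop("no events to epoch around", call. = FALSE)
  n_samp <- round((tmax_ms - tmin_ms) / 1000 * rec$rate)
  offset0 <- round(tmin_ms / 1000 * rec$rate)
  time_axis <- (offset0 + seq_len(n_samp) - 1L) / rec$rate * 1000
  n <- ncol(rec$data)
  out <- list()
  for (k in seq_len(nrow(events))) {
    idx <- events$sample[k] + offset0 + seq_len(n_samp) - 1L
    if (idx[1] < 1L || idx[n_samp] > n) {
      warning(sprintf("event %d ('%s') too close to the recording edge; epoch skipped",
                      k, events$label[k]), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(data = rec$data[, idx, drop = FALSE], time_axis = time_axis,
           condition_label = as.character(events$label[k]),
           subject_id = subject_id, rejected = FALSE, rules = character(0)),
      class = "erp_epoch")
  }
  out
}

#' Apply rejection criteria to a list of epochs
#'
#' @param epochs list of `erp_epoch`.
#' @param criteria a [rejection_criteria()].
#' @return the list with `rejected`/`rules` fields filled in.
#' @export
reject_epochs <- function(epochs, criteria = rejection_criteria()) {
  lapply(epochs, function(ep) {
    res <- detect_artifacts(ep, criteria)
    ep$rejected <- res$rejected
    ep$rules <- res$rules
    ep
  })
}

#' Write a rejection report
#'
#' TSV with one row per epoch: subject, epoch index, rejected flag, violated
#' rules (comma-separated).
#'
#' @param epochs list of screened `erp_epoch`.
#' @param path output file.
#' @export
write_rejection_report <- function(epochs, path) {
  df <- data.frame(
    subject = vapply(epochs, `[[`, "", "subject_id"),
    epoch = seq_along(epochs),
    condition = vapply(epochs, `[[`, "", "condition_label"),
    rejected = vapply(epochs, `[[`, FALSE, "rejected"),
    rules = vapply(epochs, function(e) paste(e$rules, collapse = ","), "")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average surviving epochs into an ERP dataset
#'
#' Arithmetic mean of the non-rejected epochs in every subject x condition
#' cell. An empty cell (all epochs rejected, or never recorded) is an error
#' naming the subject and condition.
#'
#' @param epochs list of screened `erp_epoch` across subjects and conditions.
#' @param channel_names channel names (rows of the epoch matrices).
#' @param groups named vector/factor mapping subject id to group label.
#' @param covariates optional data.frame with rownames = subject ids.
#' @param layout optional `sensor_layout` stored on the dataset.
#' @return an `erp_dataset`.
#' @export
average_epochs <- function(epochs, channel_names, groups, covariates = NULL,
                           layout = NULL) {
  stopifnot(length(epochs) > 0)
  subjects <- unique(vapply(epochs, `[[`, "", "subject_id"))
  conditions <- unique(vapply(epochs, `[[`, "", "condition_label"))
  time_axis <- epochs[[1]]$time_axis
  n_ch <- nrow(epochs[[1]]$data)
  stopifnot(n_ch == length(channel_names))
  arr <- array(NA_real_, dim = c(length(subjects), length(conditions), n_ch,
                                 length(time_axis)))
  for (si in seq_along(subjects)) for (ci in seq_along(conditions)) {
    keep <- Filter(function(e) {
      e$subject_id == subjects[si] && e$condition_label == conditions[ci] && !e$rejected
    }, epochs)
    if (length(keep) == 0L) {
      stop(sprintf("no surviving epochs for subject '%s', condition '%s'",
                   subjects[si], conditions[ci]), call. = FALSE)
    }
    arr[si, ci, , ] <- Reduce(`+`, lapply(keep, `[[`, "data")) / length(keep)
  }
  grp <- factor(unname(groups[subjects]))
  cov <- if (is.null(covariates)) NULL else covariates[subjects, , drop = FALSE]
  erp_dataset(arr, time_axis, grp, conditions, channel_names, cov, layout)
}
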