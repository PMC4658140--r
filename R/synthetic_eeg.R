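#' Construct a continuous EEG recording object
#'
#' @param data channels x samples matrix (uV).
#' @param rate sampling rate (Hz).
#' @param channel_names one name per row of `data`.
#' @param events data.frame with columns `sample` (1-based index) and `label`.
#' @return an `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names, events = NULL) {
  stopifnot(is.matrix(data), rate > 0, nrow(data) == length(channel_names))
  if (is.null(events)) events <- data.frame(sample = integer(0), label = character(0))
  stopifnot(all(c("sample", "label") %in% names(events)))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    stop("event samples outside the recording", call. = FALSE)
  }
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 events = events), class = "eeg_recording")
}

#' Simulate continuous EEG with injectable artifacts
#'
#' Baseline activity is spatially correlated, temporally smooth Gaussian noise
#' (squared-exponential correlation across channels, first-order
#' autoregressive smoothing across samples). On top of it, artifact waveforms
#' are injected at requested channels and times, and the ground truth is
#' returned alongside so rejection stages can be scored.
#'
#' Artifact types:
#' * `step` — an instantaneous DC jump of `amplitude` uV between two adjacent
#'   samples (violates a voltage-step criterion).
#' * `drift` — a linear ramp reaching `amplitude` uV over `duration_ms`.
#' * `out_of_range` — a smooth bump peaking at `amplitude` uV (violates an
#'   absolute amplitude bound when `|amplitude|` exceeds it).
#'
#' @param layout a `sensor_layout`.
#' @param duration_s recording length (s).
#' @param sampling_rate_hz sampling rate (> 0).
#' @param events data.frame with `time` (s) and `label`, or NULL.
#' @param artifacts data.frame with columns `type`, `channel`, `time` (s) and
#'   optionally `amplitude` (uV) and `duration_ms`, or NULL.
#' @param noise_sd baseline noise sd (uV).
#' @param spatial_lengthscale scalp decorrelation distance (head radii).
#' @param ar_coef temporal AR(1) smoothing coefficient in [0, 1).
#' @param seed integer seed.
#' @return an `eeg_recording` with an extra `artifact_truth` element.
#' @export
simulate_continuous_eeg <- function(layout, duration_s, sampling_rate_hz,
                                    events = NULL, artifacts = NULL,
                                    noise_sd = 3, spatial_lengthscale = 0.5,
                                    ar_coef = 0.95, seed = 1L) {
  validate_sensor_layout(layout)
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  stopifnot_scalar_number(duration_s, "duration_s", lower = 1e-9)
  n_ch <- length(layout$channel_names)
  n_t <- round(duration_s * sampling_rate_hz)

  if (!is.null(events) && nrow(events)) {
    if (any(events$time < 0 | events$time >= duration_s)) {
      stop("event times must lie within the recording", call. = FALSE)
    }
  }
  if (!is.null(artifacts) && nrow(artifacts)) {
    if (any(artifacts$time < 0 | artifacts$time >= duration_s)) {
      stop("artifact time outside the recording", call. = FALSE)
    }
    if (!all(artifacts$channel %in% layout$channel_names)) {
      stop("artifact channel absent from the layout", call. = FALSE)
    }
    if (!all(artifacts$type %in% c("step", "drift", "out_of_range"))) {
      stop("artifact type must be one of step/drift/out_of_range", call. = FALSE)
    }
    if (is.null(artifacts$amplitude)) {
      artifacts$amplitude <- c(step = 200, drift = 100, out_of_range = 160)[artifacts$type]
    }
    if (is.null(artifacts$duration_ms)) artifacts$duration_ms <- 400
  }

  ls_sp <- se_chol(as.matrix(stats::dist(layout$positions)), spatial_lengthscale)
  dat <- with_seed(seed, {
    innov <- ls_sp %*% matrix(stats::rnorm(n_ch * n_t), n_ch, n_t)
    x <- matrix(0, n_ch, n_t)
    x[, 1] <- innov[, 1]
    for (t in 2:n_t) x[, t] <- ar_coef * x[, t - 1] + sqrt(1 - ar_coef^2) * innov[, t]
    noise_sd * x
  })

  if (!is.null(artifacts) && nrow(artifacts)) {
    for (k in seq_len(nrow(artifacts))) {
      a <- artifacts[k, ]
      ch <- match(a$channel, layout$channel_names)
      s0 <- max(1L, round(a$time * sampling_rate_hz) + 1L)
      len <- max(2L, round(a$duration_ms / 1000 * sampling_rate_hz))
      s1 <- min(n_t, s0 + len - 1L)
      if (a$type == "step") {
        dat[ch, s0:n_t] <- dat[ch, s0:n_t] + a$amplitude
      } else if (a$type == "drift") {
        ramp <- seq(0, a$amplitude, length.out = s1 - s0 + 1L)
        dat[ch, s0:s1] <- dat[ch, s0:s1] + ramp
        if (s1 < n_t) dat[ch, (s1 + 1L):n_t] <- dat[ch, (s1 + 1L):n_t] + a$amplitude
      } else { # out_of_range: smooth bump peaking at `amplitude`
        u <- seq(0, 1, length.out = s1 - s0 + 1L)
        dat[ch, s0:s1] <- dat[ch, s0:s1] + a$amplitude * (1 - cos(2 * pi * u)) / 2
      }
    }
  }

  ev <- if (is.null(events) || !nrow(events)) NULL else {
    data.frame(sample = round(events$time * sampling_rate_hz) + 1L, label = events$label)
  }
  rec <- eeg_recording(dat, sampling_rate_hz, layout$channel_names, ev)
  rec$artifact_truth <- if (is.null(artifacts)) {
    data.frame(type = character(0), channel = character(0), time = numeric(0))
  } else artifacts
  rec
}
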