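#' Orthogonalize a covariate with respect to group
#'
#' Centers a subject-level covariate within each group by subtracting the
#' sub-group mean from the individual scores. The resulting construct carries
#' only within-group variability and is numerically orthogonal to every
#' group-indicator contrast, so it can enter a group ANCOVA without absorbing
#' between-group variance.
#'
#' @param values numeric vector, one value per subject.
#' @param groups group labels, one per subject.
#' @return numeric vector of group-centered values.
#' @export
orthogonalize_covariate <- function(values, groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- as.factor(groups)
  singletons <- names(which(table(groups) == 1L))
  if (length(singletons)) {
    message("group(s) with a single subject (construct set to 0): ",
            paste(singletons, collapse = ", "))
  }
  values - stats::ave(values, groups)
}

#' Region-of-interest specification
#'
#' @param channels non-empty channel names.
#' @param window `(start_ms, end_ms)`, closed interval, start < end.
#' @return a `roi_spec`.
#' @export
roi_spec <- function(channels, window) {
  stopifnot(length(channels) >= 1, length(window) == 2, window[1] < window[2])
  structure(list(channels = as.character(channels), window = as.numeric(window)),
            class = "roi_spec")
}

#' Average ERP amplitude over an ROI
#'
#' Arithmetic mean over the ROI channels and over every sample whose time
#' lies in the closed window `[start_ms, end_ms]` (closed so printed bounds
#' like 244-280 ms include their endpoints at 4 ms sampling).
#'
#' @param dataset an `erp_dataset`.
#' @param roi a [roi_spec()].
#' @return subjects x conditions numeric matrix of mean amplitudes (uV).
#' @export
roi_average <- function(dataset, roi) {
  stopifnot(inherits(dataset, "erp_dataset"), inherits(roi, "roi_spec"))
  ch <- match(roi$channels, dataset$channel_names)
  if (anyNA(ch)) {
    stop("ROI channels absent from the dataset: ",
         paste(roi$channels[is.na(ch)], collapse = ", "), call. = FALSE)
  }
  t_in <- which(dataset$time_axis >= roi$window[1] & dataset$time_axis <= roi$window[2])
  if (!length(t_in)) stop("ROI window contains no samples", call. = FALSE)
  sub <- dataset$data[, , ch, t_in, drop = FALSE]
  out <- apply(sub, c(1, 2), mean)
  dimnames(out) <- list(NULL, dataset$condition_labels)
  out
}

#' Per-subject cue-component amplitude
#'
#' ROI average over the central cue channels and window, collapsed across
#' conditions — the scalar marker of cue salience entered as an extra
#' predictor of feedback-stage amplitudes.
#'
#' @param dataset an `erp_dataset` of cue-locked ERPs.
#' @param roi a [roi_spec()] (e.g. the central channels, 200-230 ms).
#' @return numeric vector, one value per subject.
#' @export
cue_component_extract <- function(dataset, roi) {
  rowMeans(roi_average(dataset, roi))
}

#' Repeated-measures ANCOVA on an ROI scalar
#'
#' Mixed-design ANCOVA via the general linear model, in two strata:
#' between-subject effects (group and the subject-level covariates) are
#' tested on subject means across conditions; within-subject effects
#' (condition, condition x group) on orthonormal condition contrasts.
#' Covariates are subject-level constants, so they enter the between stratum
#' only; each fitted covariate costs one denominator df there (3 groups x 12
#' subjects: group df (2, 33) with no covariates, (2, 31) with two, (2, 30)
#' with three).
#'
#' @param dv subjects x conditions matrix of ROI amplitudes.
#' @param groups group labels, one per subject.
#' @param covariates optional data.frame / named list of subject-level
#'   covariates (should be group-orthogonalized; see
#'   [orthogonalize_covariate()]).
#' @param extra_covariates optional additional named covariates (e.g. a cue
#'   component amplitude), appended to the model.
#' @return an `ancova_result`: `effects` data.frame (effect, F, df_num,
#'   df_den, p) plus the between-stratum fit used by [planned_contrasts()].
#' @export
rm_ancova <- function(dv, groups, covariates = NULL, extra_covariates = NULL) {
  dv <- as.matrix(dv)
  groups <- droplevels(as.factor(groups))
  n_sub <- nrow(dv); n_cond <- ncol(dv); g <- nlevels(groups)
  stopifnot(n_sub == length(groups), n_cond >= 2, g >= 2)
  pieces <- Filter(Negate(is.null), list(covariates, extra_covariates))
  covs <- if (length(pieces)) do.call(cbind, lapply(pieces, as.data.frame)) else NULL
  if (!is.null(covs) && ncol(covs)) {
    if (nrow(covs) != n_sub) stop("one covariate value per subject required", call. = FALSE)
    if (anyNA(covs)) {
      stop("missing covariate value for subject(s): ",
           paste(which(apply(covs, 1, anyNA)), collapse = ", "), call. = FALSE)
    }
  }
  n_cov <- if (is.null(covs)) 0L else ncol(covs)

  # between stratum: subject means ~ group + covariates
  m <- rowMeans(dv)
  s_code <- stats::model.matrix(~groups, data.frame(groups = groups),
                                contrasts.arg = list(groups = stats::contr.sum))
  x_full <- if (n_cov) cbind(s_code, as.matrix(covs)) else s_code
  qrx <- qr(x_full)
  if (qrx$rank < ncol(x_full)) {
    stop("rank-deficient design: a covariate is collinear with group; ",
         "orthogonalize covariates within group first", call. = FALSE)
  }
  df_den_b <- n_sub - g - n_cov
  rss_full <- sum(qr.resid(qrx, m)^2)
  drop_ss <- function(cols) {
    x_red <- x_full[, setdiff(seq_len(ncol(x_full)), cols), drop = FALSE]
    sum(qr.resid(qr(x_red), m)^2) - rss_full
  }
  effects <- data.frame(effect = character(0), F = numeric(0), df_num = numeric(0),
                        df_den = numeric(0), p = numeric(0))
  add_eff <- function(name, ss, df1, df2) {
    f <- (ss / df1) / (rss_full / df2)
    rbind(effects, data.frame(effect = name, F = f, df_num = df1, df_den = df2,
                              p = stats::pf(f, df1, df2, lower.tail = FALSE)))
  }
  effects <- add_eff("group", drop_ss(2:g), g - 1, df_den_b)
  if (n_cov) for (j in seq_len(n_cov)) {
    effects <- add_eff(colnames(covs)[j], drop_ss(g + j), 1, df_den_b)
  }

  # within stratum: condition contrasts ~ group (covariates are subject
  # constants and cancel from within-subject differences up to their
  # interaction with condition, which this model omits)
  w <- stats::contr.helmert(n_cond)
  w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
  z <- dv %*% w
  xw <- s_code
  qrw <- qr(xw)
  rss_w <- sum(qr.resid(qrw, z)^2)
  df_den_w <- (n_sub - g) * (n_cond - 1L)
  ss_cond <- sum(qr.resid(qr(xw[, -1, drop = FALSE]), z)^2) - rss_w
  ss_int <- sum(qr.resid(qr(xw[, 1, drop = FALSE]), z)^2) - rss_w
  f_cond <- (ss_cond / (n_cond - 1L)) / (rss_w / df_den_w)
  f_int <- (ss_int / ((g - 1) * (n_cond - 1L))) / (rss_w / df_den_w)
  effects <- rbind(effects,
    data.frame(effect = "condition", F = f_cond, df_num = n_cond - 1L,
               df_den = df_den_w,
               p = stats::pf(f_cond, n_cond - 1L, df_den_w, lower.tail = FALSE)),
    data.frame(effect = "condition:group", F = f_int,
               df_num = (g - 1) * (n_cond - 1L), df_den = df_den_w,
               p = stats::pf(f_int, (g - 1) * (n_cond - 1L), df_den_w,
                             lower.tail = FALSE)))
  rownames(effects) <- NULL

  beta <- qr.coef(qrx, m)
  sigma2 <- rss_full / df_den_b
  xtx_inv <- chol2inv(qr.R(qrx))
  structure(list(effects = effects, groups = groups,
                 between = list(beta = beta, vcov = sigma2 * xtx_inv,
                                df = df_den_b, g = g, n_cov = n_cov)),
            class = "ancova_result")
}

#' Planned pairwise group contrasts
#'
#' Compares covariate-adjusted group means (evaluated at covariate value 0,
#' the group mean after orthogonalization) using the between-subject error
#' term of a fitted [rm_ancova()]. Two-sided p-values, no multiplicity
#' adjustment — these are planned contrasts.
#'
#' @param result an `ancova_result`.
#' @param pairs list of length-2 character vectors of group labels.
#' @return data.frame with `pair`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
planned_contrasts <- function(result, pairs) {
  stopifnot(inherits(result, "ancova_result"))
  lv <- levels(result$groups)
  g <- result$between$g
  # row of the sum-coded design giving group i's adjusted mean (covariates 0)
  mean_row <- function(i) {
    cm <- stats::contr.sum(g)
    c(1, cm[i, ], rep(0, result$between$n_cov))
  }
  out <- lapply(pairs, function(pr) {
    idx <- match(pr, lv)
    if (anyNA(idx)) stop("unknown group in contrast pair: ",
                         paste(pr[is.na(idx)], collapse = ", "), call. = FALSE)
    l <- mean_row(idx[1]) - mean_row(idx[2])
    est <- sum(l * result$between$beta)
    se <- sqrt(drop(t(l) %*% result$between$vcov %*% l))
    tv <- if (se > 0) est / se else 0
    data.frame(pair = paste(pr, collapse = " - "), estimate = est, se = se,
               t = tv, df = result$between$df,
               p = 2 * stats::pt(abs(tv), result$between$df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("Repeated-measures ANCOVA\n")
  eff <- x$effects
  eff$F <- round(eff$F, 3); eff$p <- signif(eff$p, 3)
  print(eff, row.names = FALSE)
  invisible(x)
}

#' Write ANCOVA effect and contrast tables
#'
#' @param result an `ancova_result`.
#' @param path TSV path for the effects table; contrasts (if given) go to
#'   `<path base>_contrasts.tsv`, and a JSON mirror of both beside them.
#' @param contrasts optional data.frame from [planned_contrasts()].
#' @export
write_ancova_result <- function(result, path, contrasts = NULL) {
  utils::write.table(result$effects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  base <- sub("\\.tsv$", "", path)
  if (!is.null(contrasts)) {
    utils::write.table(contrasts, paste0(base, "_contrasts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(effects = result$effects, contrasts = contrasts),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
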