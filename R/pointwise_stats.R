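#' @keywords internal
stat_map <- function(values, effect, df) {
  stopifnot(is.matrix(values))
  structure(list(values = values, effect = effect, df = df), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  pk <- which(x$values == max(x$values), arr.ind = TRUE)[1, ]
  cat(sprintf("StatMap [%s], %d x %d, df = (%g, %g), peak %.3f at (%d, %d)\n",
              x$effect, nrow(x$values), ncol(x$values), x$df[1], x$df[2],
              max(x$values), pk[1], pk[2]))
  invisible(x)
}

# residual sums of squares of Z (n x p) on the column space of X, per column
rss_on <- function(z, x) {
  if (is.null(x)) return(colSums(z^2))
  q <- qr.Q(qr(x))
  colSums((z - q %*% crossprod(q, z))^2)
}

# Internal engine: Y is subjects x conditions x points. Returns per-effect F
# vectors over points plus dfs. Balanced group sizes use closed-form sums of
# squares; unbalanced designs go through Type-III projections (sum-coded
# group design) on the two strata: subject means for the between stratum,
# orthonormal within-subject contrasts for the within stratum.
mixed_anova_engine <- function(y, groups) {
  dims <- dim(y)
  n_sub <- dims[1]; n_cond <- dims[2]; n_pt <- dims[3]
  g <- nlevels(groups)
  n_g <- tabulate(groups, nbins = g)
  balanced <- length(unique(n_g)) == 1L
  slice <- function(cc) {
    z <- y[, cc, , drop = FALSE]
    dim(z) <- c(n_sub, n_pt)
    z
  }

  msub <- Reduce(`+`, lapply(seq_len(n_cond), slice)) / n_cond
  gm_g <- rowsum(msub, groups) / n_g              # g x points
  gmean <- colSums(msub) / n_sub
  ss_s <- n_cond * colSums((msub - gm_g[as.integer(groups), , drop = FALSE])^2)
  df_s <- n_sub - g
  # single between factor: marginal (Type III) and sequential SS coincide
  ss_a <- n_cond * colSums(n_g * (gm_g - rep(gmean, each = g))^2)
  f_a <- (ss_a / (g - 1)) / (ss_s / df_s)

  if (n_cond >= 2L) {
    w <- stats::contr.helmert(n_cond)
    w <- sweep(w, 2, sqrt(colSums(w^2)), "/")     # orthonormal condition contrasts
    ss_b <- ss_ab <- ss_bs <- numeric(n_pt)
    if (!balanced) {
      s_code <- stats::model.matrix(
        ~groups, data.frame(groups = groups),
        contrasts.arg = list(groups = stats::contr.sum))[, -1, drop = FALSE]
      x_full <- cbind(1, s_code)
    }
    for (j in seq_len(n_cond - 1L)) {
      z <- Reduce(`+`, lapply(seq_len(n_cond), function(cc) w[cc, j] * slice(cc)))
      if (balanced) {
        zg <- rowsum(z, groups) / n_g
        zbar <- colSums(z) / n_sub
        ss_b <- ss_b + n_sub * zbar^2
        ss_ab <- ss_ab + colSums(n_g * (zg - rep(zbar, each = g))^2)
        ss_bs <- ss_bs + colSums((z - zg[as.integer(groups), , drop = FALSE])^2)
      } else {
        rss_full <- rss_on(z, x_full)
        ss_b <- ss_b + pmax(0, rss_on(z, s_code) - rss_full)
        ss_ab <- ss_ab + pmax(0, rss_on(z, matrix(1, n_sub, 1)) - rss_full)
        ss_bs <- ss_bs + rss_full
      }
    }
    df_bs <- (n_sub - g) * (n_cond - 1L)
    ms_err <- ss_bs / df_bs
    f_b <- (ss_b / (n_cond - 1L)) / ms_err
    f_ab <- (ss_ab / ((g - 1) * (n_cond - 1L))) / ms_err
  } else {
    f_b <- f_ab <- rep(NA_real_, n_pt)
    df_bs <- NA_integer_
  }

  # degenerate cells (zero effect SS over zero error SS) are no evidence: F = 0
  zap_nan <- function(f) { f[is.nan(f)] <- 0; f }
  list(
    group = list(f = zap_nan(f_a), df = c(g - 1, n_sub - g)),
    condition = list(f = zap_nan(f_b), df = c(n_cond - 1L, df_bs)),
    interaction = list(f = zap_nan(f_ab), df = c((g - 1) * (n_cond - 1L), df_bs))
  )
}

#' Mass-univariate mixed-design ANOVA over every channel-time point
#'
#' At each channel-sample pair, fits the standard two-way mixed ANOVA with a
#' between-subject group factor and a within-subject condition factor: group
#' is tested against subject-within-group mean squares (df `(g-1, N-g)`);
#' condition and the group x condition interaction against the
#' condition x subject-within-group error. Balanced designs use closed-form
#' sums of squares (the permutation loop evaluates this map millions of
#' times); unbalanced group sizes fall back to Type-III-equivalent
#' projections.
#'
#' @param dataset an `erp_dataset` where every subject has every condition.
#' @return list of three `stat_map`s: `group`, `condition`, `interaction`.
#' @export
mixed_anova_map <- function(dataset) {
  stopifnot(inherits(dataset, "erp_dataset"))
  d <- dim(dataset$data)
  if (any(is.na(dataset$data))) stop("missing cells in the ERP dataset", call. = FALSE)
  y <- array(dataset$data, dim = c(d[1], d[2], d[3] * d[4]))
  res <- mixed_anova_engine(y, dataset$groups)
  shape <- function(v) matrix(v, d[3], d[4],
                              dimnames = list(dataset$channel_names, NULL))
  list(
    group = stat_map(shape(res$group$f), "group", res$group$df),
    condition = stat_map(shape(res$condition$f), "condition", res$condition$df),
    interaction = stat_map(shape(res$interaction$f), "interaction", res$interaction$df)
  )
}

#' 2 x 2 mixed ANOVA map
#'
#' Convenience wrapper of [mixed_anova_map()] for a two-level between factor
#' and a two-level within factor (e.g. patient subgroup x feedback outcome).
#'
#' @param dataset an `erp_dataset` with exactly 2 groups and 2 conditions.
#' @return list of `stat_map`s as in [mixed_anova_map()].
#' @export
anova_map_2x2 <- function(dataset) {
  if (nlevels(dataset$groups) != 2L || length(dataset$condition_labels) != 2L) {
    stop("anova_map_2x2 requires 2 groups and 2 conditions", call. = FALSE)
  }
  mixed_anova_map(dataset)
}

#' Convert an F map to pointwise p-values
#'
#' Upper-tail probabilities from the F reference distribution with the map's
#' degrees of freedom (uncorrected; use the permutation machinery for
#' familywise control).
#'
#' @param fmap a `stat_map` holding F values.
#' @return a `stat_map` of probabilities.
#' @export
pointwise_p_map <- function(fmap) {
  stopifnot(inherits(fmap, "stat_map"))
  p <- stats::pf(fmap$values, fmap$df[1], fmap$df[2], lower.tail = FALSE)
  stat_map(p, paste0(fmap$effect, "_p"), fmap$df)
}

#' Export a statistic map as TSV plus a JSON header
#'
#' Rows are channels, columns sample times; the JSON sidecar records the
#' effect and degrees of freedom.
#'
#' @param map a `stat_map`.
#' @param path TSV path; the header is written to `<path>.json`.
#' @param time_axis optional column labels (ms).
#' @export
write_stat_map <- function(map, path, time_axis = NULL) {
  m <- map$values
  if (!is.null(time_axis)) colnames(m) <- time_axis
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = !is.null(time_axis),
                     row.names = !is.null(rownames(m)))
  jsonlite::write_json(list(effect = map$effect, df = map$df),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
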