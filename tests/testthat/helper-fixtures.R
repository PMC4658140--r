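# Shared fixtures: tiny layouts, graphs and datasets built in code.

tiny_layout <- function(n = 16, seed = 42) generate_sensor_layout(n, seed = seed)

tiny_graph <- function(layout = tiny_layout(), target_degree = 6) {
  build_adjacency(layout, calibrate_adjacency_threshold(layout, target_degree))
}

# a layout whose 4 channels sit at the corners of a unit square (flat, for
# hand-checkable adjacency)
square_layout <- function() {
  pos <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  rownames(pos) <- paste0("E", 1:4)
  structure(list(channel_names = paste0("E", 1:4), positions = pos),
            class = "sensor_layout")
}

# small null dataset on a reduced channel-time grid
null_dataset <- function(layout = tiny_layout(), group_sizes = c(HC = 12, NC = 12, PD = 12),
                         n_samples = 40, seed = 1) {
  simulate_erp_dataset(layout, group_sizes, c("gain", "loss"),
                       time_axis = seq(-200, by = 4, length.out = n_samples),
                       seed = seed)
}

# dataset built from an explicit array (for exact-arithmetic checks)
dataset_from_array <- function(arr, groups, conditions = NULL, time_axis = NULL) {
  d <- dim(arr)
  if (is.null(conditions)) conditions <- paste0("c", seq_len(d[2]))
  if (is.null(time_axis)) time_axis <- seq(0, by = 4, length.out = d[4])
  erp_dataset(arr, time_axis, groups, conditions, paste0("E", seq_len(d[3])))
}

# independent brute-force TFCE: loops thresholds and floods components in R
brute_force_tfce <- function(fmap, neighbors, E = 0.5, H = 2, n_steps = 100) {
  nch <- nrow(fmap); nt <- ncol(fmap)
  hmax <- max(fmap)
  out <- matrix(0, nch, nt)
  if (hmax <= 0) return(out)
  dh <- hmax / n_steps
  id <- function(ch, t) ch + (t - 1) * nch
  for (k in seq_len(n_steps)) {
    h <- hmax * k / n_steps
    supra <- fmap >= h
    seen <- matrix(FALSE, nch, nt)
    for (ch in seq_len(nch)) for (t in seq_len(nt)) {
      if (!supra[ch, t] || seen[ch, t]) next
      comp <- list(c(ch, t)); seen[ch, t] <- TRUE; queue <- list(c(ch, t))
      while (length(queue)) {
        u <- queue[[1]]; queue <- queue[-1]
        cand <- list()
        if (u[2] > 1) cand <- c(cand, list(c(u[1], u[2] - 1)))
        if (u[2] < nt) cand <- c(cand, list(c(u[1], u[2] + 1)))
        for (nb in neighbors[[u[1]]]) cand <- c(cand, list(c(nb, u[2])))
        for (v in cand) {
          if (supra[v[1], v[2]] && !seen[v[1], v[2]]) {
            seen[v[1], v[2]] <- TRUE
            comp <- c(comp, list(v)); queue <- c(queue, list(v))
          }
        }
      }
      add <- length(comp)^E * h^H * dh
      for (v in comp) out[v[1], v[2]] <- out[v[1], v[2]] + add
    }
  }
  out
}

# independent mixed-ANOVA oracle per point via base aov() with an Error term
aov_oracle_f <- function(y_sc, groups) {
  n_sub <- nrow(y_sc); n_cond <- ncol(y_sc)
  df <- data.frame(
    y = as.vector(y_sc),
    subject = factor(rep(seq_len(n_sub), n_cond)),
    cond = factor(rep(seq_len(n_cond), each = n_sub)),
    group = factor(rep(groups, n_cond))
  )
  fit <- summary(stats::aov(y ~ group * cond + Error(subject / cond), data = df))
  s1 <- fit[["Error: subject"]][[1]]
  s2 <- fit[["Error: subject:cond"]][[1]]
  c(group = s1["group", "F value"],
    condition = s2["cond", "F value"],
    interaction = s2["group:cond", "F value"])
}
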