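test_that("TFCE matches brute-force threshold sums on elementary maps", {
  lay <- square_layout()
  g <- build_adjacency(lay, 1.0)
  pars <- tfce_params(n_steps = 100)

  # all-zero map
  z <- matrix(0, 4, 3)
  expect_equal(tfce_enhance(z, g, pars)$values, z)

  # single isolated point of value v: extent 1 at every threshold
  v <- 3.7
  m <- matrix(0, 4, 3); m[1, 2] <- v
  dh <- v / 100
  hs <- dh * (1:100)
  closed <- sum(1^0.5 * hs^2 * dh)
  out <- tfce_enhance(m, g, pars)$values
  expect_equal(out[1, 2], closed, tolerance = 1e-10)
  expect_equal(sum(out), out[1, 2])  # all other points zero

  # constant map on a connected lattice: every point sees extent N
  cm <- matrix(2.5, 4, 3)
  n_pts <- 12
  dh2 <- 2.5 / 100
  closed2 <- n_pts^0.5 * sum((dh2 * (1:100))^2 * dh2)
  out2 <- tfce_enhance(cm, g, pars)$values
  expect_equal(max(abs(out2 - closed2)), 0, tolerance = 1e-10)

  # a random map against the independent R flood-fill implementation
  set.seed(31)
  rmap <- matrix(rexp(12), 4, 3)
  bf <- brute_force_tfce(rmap, g$neighbors, E = 0.5, H = 2, n_steps = 40)
  expect_equal(tfce_enhance(rmap, g, tfce_params(n_steps = 40))$values, bf,
               tolerance = 1e-10)

  neg <- matrix(0, 4, 3); neg[2, 2] <- -0.5
  expect_error(tfce_enhance(neg, g), "non-negative")
})

test_that("TFCE is monotone and equivariant under channel relabeling", {
  lay <- tiny_layout(8)
  g <- build_adjacency(lay, calibrate_adjacency_threshold(lay, 4))
  set.seed(5)
  b <- matrix(rexp(8 * 6), 8, 6)
  a <- b + matrix(runif(48, 0, 2), 8, 6)   # a >= b pointwise
  # monotonicity holds on a common threshold grid (the one set by max(a));
  # checked with an independent flood-fill over that explicit grid
  steps <- 80
  ta <- tfce_enhance(a, g, tfce_params(n_steps = steps))$values
  dh <- max(a) / steps
  grid_tfce <- function(m) {
    out <- 0 * m
    for (k in 1:steps) {
      h <- max(a) * k / steps
      supra <- m >= h
      if (!any(supra)) next
      lab <- matrix(0L, nrow(m), ncol(m)); nxt <- 0L
      for (ch in seq_len(nrow(m))) for (t in seq_len(ncol(m))) {
        if (!supra[ch, t] || lab[ch, t] > 0) next
        nxt <- nxt + 1L
        stack <- list(c(ch, t)); lab[ch, t] <- nxt
        while (length(stack)) {
          u <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          nbs <- list()
          if (u[2] > 1) nbs <- c(nbs, list(c(u[1], u[2] - 1)))
          if (u[2] < ncol(m)) nbs <- c(nbs, list(c(u[1], u[2] + 1)))
          for (nb in g$neighbors[[u[1]]]) nbs <- c(nbs, list(c(nb, u[2])))
          for (v in nbs) if (supra[v[1], v[2]] && lab[v[1], v[2]] == 0) {
            lab[v[1], v[2]] <- nxt; stack <- c(stack, list(v))
          }
        }
      }
      sizes <- tabulate(lab[lab > 0])
      out <- out + supra * (sizes[pmax(lab, 1)]^0.5 * h^2 * dh)
    }
    out
  }
  expect_true(all(grid_tfce(a) - grid_tfce(b) >= -1e-12))
  expect_equal(grid_tfce(a), ta, tolerance = 1e-10)

  # relabeling channels permutes the output identically
  perm <- sample(8)
  g2 <- g
  g2$neighbors <- lapply(g$neighbors[perm], function(v) match(v, perm))
  out1 <- tfce_enhance(b, g, tfce_params())$values
  out2 <- tfce_enhance(b[perm, ], g2, tfce_params())$values
  expect_equal(out2, out1[perm, ], tolerance = 1e-12)
})

test_that("two-step permutation preserves data and group sizes", {
  ds <- null_dataset(tiny_layout(5), group_sizes = c(A = 3, B = 4, C = 5),
                     n_samples = 8)
  p1 <- permute_labels(ds, seed = 9)
  expect_equal(table(p1$groups), table(ds$groups))
  # the multiset of subject x condition matrices is unchanged
  flat <- function(d) sort(round(as.vector(d$data), 10))
  expect_equal(flat(p1), flat(ds))
  expect_identical(permute_labels(ds, seed = 9)$data, p1$data)

  # two conditions: a given subject's condition labels swap with probability 1/2
  arr <- array(0, dim = c(2, 2, 1, 1))
  arr[1, , 1, 1] <- c(1, 2)
  arr[2, , 1, 1] <- c(5, 6)
  ds1 <- dataset_from_array(arr, factor(c("A", "A")))
  swaps <- vapply(1:2000, function(s) {
    d <- permute_labels(ds1, seed = s)$data
    slot <- if (d[1, 1, 1, 1] %in% c(1, 2)) 1 else 2  # where subject 1 landed
    d[slot, 1, 1, 1] == 2
  }, logical(1))
  expect_equal(mean(swaps), 0.5, tolerance = 0.05)
})

test_that("permutation p-values follow the +1 counting rule", {
  lay <- tiny_layout(5)
  g <- build_adjacency(lay, calibrate_adjacency_threshold(lay, 4))

  # a huge injected effect beats every null max: p = 1/(n+1)
  ef <- effect_spec(lay$channel_names[1:3], c(20, 60),
                    matrix(c(0, 0, 25, 25), 2, 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), c("x", "y"))))
  ds <- simulate_erp_dataset(lay, c(A = 6, B = 6), c("x", "y"),
                             effects = list(ef),
                             noise = noise_model(sd = 0.5, subject_sd = 0.2),
                             time_axis = seq(0, 76, by = 4), seed = 4)
  res <- tfce_permutation_test(ds, g, "group", config = perm_config(99, seed = 2))
  expect_equal(min(res$p_map$values), 1 / 100)
  expect_true(all(res$p_map$values > 0 & res$p_map$values <= 1))
  expect_equal(unname(res$significant_mask), unname(res$p_map$values <= 0.05))
  # p-map agrees with direct counting against the stored null distribution
  direct <- (1 + vapply(as.vector(res$observed_tfce$values),
                        function(o) sum(res$null_max_distribution >= o),
                        numeric(1))) / 100
  expect_equal(as.vector(res$p_map$values), direct)

  # identical subjects: every permutation reproduces the observed statistic
  arr <- array(rep(as.vector(matrix(rnorm(5 * 8), 5, 8)), each = 8),
               dim = c(4, 2, 5, 8))
  for (s in 1:4) for (cc in 1:2) arr[s, cc, , ] <- arr[1, 1, , ]
  ds_deg <- dataset_from_array(arr, factor(c("A", "A", "B", "B")))
  res_deg <- tfce_permutation_test(ds_deg, g, "group",
                                   config = perm_config(60, seed = 3))
  expect_true(all(res_deg$p_map$values == 1))

  # n_permutations = 1: p is either 1/2 or 1 everywhere
  res1 <- tfce_permutation_test(ds, g, "group", config = perm_config(1, seed = 5))
  expect_true(all(res1$p_map$values %in% c(0.5, 1)))
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration on 2x3 designs", {
  # 2 groups x 3 subjects, group effect: the exact null enumerates all
  # choose(6,3) = 20 group assignments (the within step cannot change
  # subject means). Oracle: independent F and TFCE implementations.
  lay <- tiny_layout(4)
  g <- build_adjacency(lay, calibrate_adjacency_threshold(lay, 3))
  set.seed(123)
  y <- array(rnorm(6 * 2 * 4 * 3, sd = 1), dim = c(6, 2, 4, 3))
  y[4:6, , 1:2, ] <- y[4:6, , 1:2, ] + 1.2   # a moderate group effect
  groups <- factor(rep(c("a", "b"), each = 3))
  ds <- dataset_from_array(y, groups)

  oneway_f <- function(msub, grp) {
    # msub: subjects x points; independent textbook one-way ANOVA
    apply(msub, 2, function(v) {
      m1 <- mean(v[grp == levels(grp)[1]]); m2 <- mean(v[grp == levels(grp)[2]])
      gm <- mean(v)
      ssb <- 3 * ((m1 - gm)^2 + (m2 - gm)^2)
      ssw <- sum((v[grp == levels(grp)[1]] - m1)^2) +
        sum((v[grp == levels(grp)[2]] - m2)^2)
      (ssb / 1) / (ssw / 4)
    })
  }
  msub <- apply(y, c(1, 3, 4), mean)          # subjects x channels x samples
  msub_flat <- matrix(msub, nrow = 6)
  tfce_of <- function(fvec) {
    brute_force_tfce(matrix(fvec, 4, 3), g$neighbors, n_steps = 100)
  }
  obs_tfce <- tfce_of(oneway_f(msub_flat, groups))
  combos <- utils::combn(6, 3)
  null_max <- apply(combos, 2, function(idx) {
    grp <- factor(ifelse(seq_len(6) %in% idx, "a", "b"))
    max(tfce_of(oneway_f(msub_flat, grp)))
  })
  peak <- which.max(obs_tfce)
  p_exact <- mean(null_max >= obs_tfce[peak])

  res <- tfce_permutation_test(ds, g, "group",
                               config = perm_config(999, seed = 11))
  p_mc <- min(res$p_map$values)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_mc - p_exact), 4 * se + 2 / 1000)
})

test_that("the optimized permutation null equals the label-permutation route", {
  lay <- tiny_layout(6)
  g <- build_adjacency(lay, calibrate_adjacency_threshold(lay, 4))
  ds <- null_dataset(lay, group_sizes = c(A = 4, B = 4, C = 4), n_samples = 10,
                     seed = 12)
  d <- dim(ds$data)
  y <- array(ds$data, dim = c(d[1], d[2], d[3] * d[4]))
  generic_null <- function(eff, seed, n) {
    erptfce:::with_seed(seed, vapply(seq_len(n), function(i) {
      perm <- erptfce:::draw_permutation(d[1], d[2])
      yp <- erptfce:::apply_permutation_y(y, perm)
      ds2 <- ds
      ds2$data <- array(yp, dim = d)
      max(tfce_enhance(mixed_anova_map(ds2)[[eff]], g)$values)
    }, numeric(1)))
  }
  for (eff in c("group", "condition", "interaction")) {
    res <- tfce_permutation_test(ds, g, eff, config = perm_config(25, seed = 9))
    expect_equal(res$null_max_distribution, generic_null(eff, 9, 25),
                 tolerance = 1e-10)
  }
})
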