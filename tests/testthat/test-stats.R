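random_table <- function(n = 12, effect = 0) {
  vals <- matrix(rnorm(n * 4), n, 4) + rnorm(n)   # subject offsets
  vals[, 1] <- vals[, 1] + effect
  colnames(vals) <- c("c11", "c12", "c21", "c22")
  condition_table(vals)
}

test_that("window_mean equals a double-loop oracle", {
  set.seed(1)
  erp <- mmnpipe:::new_erp(matrix(rnorm(4 * 100), 4, 100), 200, -0.05, 0.45,
                           c("a", "b", "c", "d"), "x", 5)
  expect_equal(window_mean(erp, c(0, 0.4), "b"),
               mean(erp$data[2, erp$times >= -1e-9 & erp$times < 0.4 - 1e-9]))
  const <- erp; const$data[] <- 3.25
  expect_equal(window_mean(const, c(0.135, 0.175), c("a", "c")), 3.25)
  acc <- 0; cnt <- 0
  for (ch in c("a", "d")) for (j in seq_along(erp$times)) {
    if (erp$times[j] >= 0.1 - 1e-9 && erp$times[j] < 0.3 - 1e-9) {
      acc <- acc + erp$data[match(ch, erp$channel_names), j]
      cnt <- cnt + 1
    }
  }
  expect_equal(window_mean(erp, c(0.1, 0.3), c("a", "d")), acc / cnt,
               tolerance = 1e-12)
  expect_error(window_mean(erp, c(0.9, 1), "a"), "config error")
  expect_error(window_mean(erp, c(0, 0.1), "zz"), "config error")
})

test_that("2x2 repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(42)
  for (i in 1:30) {
    tab <- random_table(n = sample(6:20, 1), effect = runif(1, 0, 2))
    res <- rm_anova_2x2(tab)
    oracle <- rm_anova_ss_oracle(tab$values)
    for (e in c("root", "suffix", "interaction"))
      expect_equal(res$F[res$effect == e], oracle[[e]], tolerance = 1e-8)
    expect_equal(res$df1, rep(1L, 3))
    expect_equal(res$df2, rep(nrow(tab$values) - 1L, 3))
  }
})

test_that("ANOVA agrees with aov's within-subject error stratum", {
  set.seed(13)
  tab <- random_table(n = 10, effect = 1)
  res <- rm_anova_2x2(tab)
  long <- data.frame(
    y = as.vector(tab$values),
    subj = factor(rep(seq_len(10), 4)),
    A = factor(rep(c("a1", "a1", "a2", "a2"), each = 10)),
    B = factor(rep(c("b1", "b2", "b1", "b2"), each = 10)))
  fit <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), data = long))
  f_aov <- c(fit[["Error: subj:A"]][[1]]["A", "F value"],
             fit[["Error: subj:B"]][[1]]["B", "F value"],
             fit[["Error: subj:A:B"]][[1]]["A:B", "F value"])
  expect_equal(res$F, f_aov, tolerance = 1e-8)
})

test_that("interaction F is exactly the squared paired t on contrasts", {
  set.seed(7)
  for (i in 1:20) {
    tab <- random_table(n = 9)
    v <- tab$values
    d <- (v[, 1] - v[, 2]) - (v[, 3] - v[, 4])
    tstat <- t.test(d)$statistic
    res <- rm_anova_2x2(tab)
    expect_equal(res$F[res$effect == "interaction"], unname(tstat^2),
                 tolerance = 1e-10)
  }
  # df reported as (1, 25) for 26 subjects
  res26 <- rm_anova_2x2(random_table(n = 26))
  expect_equal(res26$df2, rep(25L, 3))
  # zero contrast variance raises a degenerate-data error naming the effect
  flat <- condition_table(matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4))
  expect_error(rm_anova_2x2(flat), "degenerate-data.*root")
})

test_that("planned comparisons are squared paired t tests", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(planned_comparison(a, a + rnorm(5))$df2, 4L)
  expect_error(planned_comparison(a, a), "degenerate")
  set.seed(5)
  x <- rnorm(26); y <- rnorm(26)
  pc <- planned_comparison(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(pc$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(pc$p, tt$p.value, tolerance = 1e-10)
  expect_equal(pc$df2, 25L)
})

test_that("critical F thresholds reproduce the tabled values", {
  expect_equal(round(f_critical(0.05, 1, 25), 2), 4.24)
  expect_equal(round(f_critical(0.05, 1, 1e6), 2), 3.84)  # chi-square limit
  thr <- f_critical(0.01, 3, 17)
  expect_equal(pf(thr, 3, 17, lower.tail = FALSE), 0.01, tolerance = 1e-6)
  expect_error(f_critical(0, 1, 10), "config error")
  expect_error(f_critical(0.05, 1, 0), "config error")
})

test_that("volume conversion is node-exact and reproduces affine fields", {
  m <- small_montage()
  p <- project_to_plane(m, c(16, 16))
  mk_erps <- function(field) {
    erp <- mmnpipe:::new_erp(matrix(field, length(field), 3), 200, 0, 0.015,
                             p$channel, "c", 1)
    list(list(c11 = erp, c12 = erp, c21 = erp, c22 = erp))
  }
  vols <- erps_to_volumes(mk_erps(rep(4.5, length(p$channel))), p)
  expect_equal(unname(vols$data[1, 1, ]),
               rep(4.5, length(vols$vox_index)))   # constant field

  lin <- 0.5 + 2 * p$plane_cells[, 1]              # linear in grid x
  vl <- erps_to_volumes(mk_erps(lin), p)
  frame1 <- vl$data[1, 1, seq_len(nrow(vl$cells))]
  # electrode-bearing cells carry the channel value exactly
  key <- paste(vl$cells[, 1], vl$cells[, 2])
  at <- match(paste(p$cell[, 1], p$cell[, 2]), key)
  expect_equal(frame1[at], unname(lin))
  # all other in-hull voxels are affine in the cell-center coordinate
  other <- setdiff(seq_len(nrow(vl$cells)), at)
  expect_equal(frame1[other], 0.5 + 2 * vl$cells[other, 1],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("cluster labelling agrees with a flood-fill oracle", {
  m <- small_montage()
  p <- project_to_plane(m, c(16, 16))
  set.seed(99)
  for (i in 1:40) {
    dims <- c(sample(3:5, 1), sample(3:5, 1), sample(2:6, 1))
    arr <- array(runif(prod(dims)) < 0.45, dims)
    vox <- which(array(TRUE, dims)) - 1L
    lab <- label_clusters(as.vector(arr), vox, dims)
    oracle <- flood_fill_labels(arr)
    expect_true(same_partition(array(lab, dims), oracle))
  }
})

test_that("permutation p-values follow the printed counting convention", {
  null <- c(seq_len(965), rep(2000, 35))
  expect_equal(perm_p(1000, null), 0.035)
  expect_equal(perm_p(1000, null, "plus-one"), 36 / 1001)
  expect_equal(perm_p(5000, null), 0)            # heavier than every null
  expect_equal(perm_p(0, null), 1)
  # ties count toward the null
  expect_equal(perm_p(2000, null), 0.035)
})

test_that("cluster permutation recovers a planted effect and conserves mass", {
  m <- small_montage()
  p <- project_to_plane(m, c(16, 16))
  params <- gen_params()
  erps <- simulate_erp_cohort(14, params, m, p, tmin = 0, tmax = 0.4,
                              seed = 21)
  vols <- erps_to_volumes(erps, p)
  res <- cluster_permutation(vols, n_perm = 300, seed = 5)
  expect_s3_class(res, "mmn_cluster_result")
  expect_length(res$null_max_masses, 300)
  # mass conservation: cluster masses partition the suprathreshold F mass
  expect_equal(sum(res$clusters$mass),
               sum(res$f_map[res$f_map > res$f_threshold]),
               tolerance = 1e-9)
  top <- res$clusters[1, ]
  expect_lt(top$p, 0.05)
  expect_lt(top$t_min_ms, 175)
  expect_gt(top$t_max_ms, 135)

  # deterministic under a fixed seed
  res2 <- cluster_permutation(vols, n_perm = 300, seed = 5)
  expect_identical(res$null_max_masses, res2$null_max_masses)
  expect_identical(res$clusters, res2$clusters)

  # invariant to a subject-constant offset on all conditions
  vols2 <- vols
  for (s in seq_len(dim(vols$data)[1]))
    vols2$data[s, , ] <- vols2$data[s, , ] + s * 3
  res3 <- cluster_permutation(vols2, n_perm = 300, seed = 5)
  expect_equal(res3$clusters, res$clusters)
  # and to relabelling subjects (same flips applied to permuted order)
  vols4 <- vols
  perm <- c(7, 3, 1, 14, 2, 10, 4, 13, 5, 9, 6, 12, 8, 11)
  vols4$data <- vols4$data[perm, , ]
  res4 <- cluster_permutation(vols4, n_perm = 300, seed = 5)
  expect_equal(res4$clusters$mass, res$clusters$mass)
  expect_equal(res4$f_map, res$f_map)

  expect_error(cluster_permutation(vols, n_perm = 0), "config error")
})

test_that("an all-subthreshold map yields an empty, valid cluster list", {
  m <- small_montage()
  p <- project_to_plane(m, c(16, 16))
  quiet <- gen_params(noise_sd = 0.01, subject_amp_sd = 0.01,
                      mmn_amplitude = c(a = -1, b = -1, c = -1, d = -1))
  erps <- simulate_erp_cohort(8, quiet, m, p, tmin = 0, tmax = 0.2,
                              conditions = c("a", "b", "c", "d"), seed = 3)
  vols <- erps_to_volumes(erps, p)
  res <- cluster_permutation(vols, f_threshold = 1e9, n_perm = 50, seed = 2)
  expect_equal(nrow(res$clusters), 0L)
  expect_true(all(res$null_max_masses == 0))
})
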