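test_that("pooled two-sample t reproduces the printed IQ group comparisons", {
  # summaries are printed to 2 dp, so recomputed t values carry ~0.01 slop
  fsiq <- two_sample_t(53.21, 13.19, 19, 116.30, 13.37, 33)
  expect_equal(fsiq$t, -16.46, tolerance = 0.01 / 16.46)
  expect_identical(fsiq$df, 50)
  viq <- two_sample_t(54.42, 14.97, 19, 117.12, 13.51, 33)
  expect_equal(round(viq$t, 1), -15.5)
  expect_identical(viq$df, 50)
  nviq <- two_sample_t(56.42, 16.00, 19, 112.64, 15.58, 33)
  expect_equal(round(nviq$t, 2), -12.41)
  expect_true(all(c(fsiq$p, viq$p, nviq$p) < 0.001))
})

test_that("two_sample_t handles raw vectors, identical groups, and the Welch variant", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  ts <- two_sample_t(x = x, y = y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ts$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ts$p, ref$p.value, tolerance = 1e-12)
  expect_equal(two_sample_t(5, 2, 10, 5, 2, 10)$t, 0)
  tw <- two_sample_t(x = x, y = c(y, 10, -4), var_equal = FALSE)
  refw <- t.test(x, c(y, 10, -4))
  expect_equal(tw$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(tw$df, unname(refw$parameter), tolerance = 1e-10)
  expect_error(two_sample_t(1, 0, 5, 1, 0, 5), "zero variance")
})

test_that("bh_fdr matches the hand-evaluated step-up formula and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(1)
  for (i in 1:5) {
    p <- runif(40)^2
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("voxelwise GLM group t reduces to the two-sample t without covariate", {
  set.seed(2)
  n <- 20
  Y <- matrix(rnorm(n * 30), n, 30)
  grp <- rep(c("DS", "TD"), each = 10)
  fit <- voxelwise_group_glm(Y, grp)
  ref <- apply(Y, 2, function(y)
    two_sample_t(x = y[grp == "DS"], y = y[grp == "TD"])$t)
  expect_equal(fit$t, -ref, tolerance = 1e-10)  # contrast: level 2 - level 1
  expect_equal(fit$df, n - 2)
  # identical maps for all subjects: t = 0 everywhere
  Y0 <- matrix(rep(rnorm(30), each = n), n, 30)
  expect_true(all(voxelwise_group_glm(Y0, grp)$t == 0))
})

test_that("voxelwise GLM covariate handling: df, shift invariance, collinearity guard", {
  set.seed(3)
  n <- 24
  Y <- matrix(rnorm(n * 10), n, 10)
  grp <- rep(c("A", "B"), each = 12)
  cov <- rnorm(n)
  fit <- voxelwise_group_glm(Y, grp, cov)
  expect_equal(fit$df, n - 3)
  fit_shift <- voxelwise_group_glm(Y, grp, cov + 100)
  expect_equal(fit$t, fit_shift$t, tolerance = 1e-8)
  expect_error(voxelwise_group_glm(Y, grp, as.numeric(grp == "B")),
               "collinear")
  expect_error(voxelwise_group_glm(Y, grp, rep(2, n)), "constant")
})

test_that("voxelwise GLM holds its type-I error under a permutation null", {
  set.seed(4)
  reps <- 200
  n <- 24
  hits <- numeric(reps)
  for (r in seq_len(reps)) {
    Y <- matrix(rnorm(n * 50), n, 50)
    grp <- sample(rep(c("A", "B"), each = 12))
    cov <- rnorm(n)
    hits[r] <- mean(voxelwise_group_glm(Y, grp, cov)$p < 0.05)
  }
  rate <- mean(hits)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("define_rois applies the dual threshold, adjacency, and inclusive minimum size", {
  g <- c(8, 8, 4)
  tv <- array(0, g); pv <- array(1, g); qv <- array(1, g)
  # blob 1: 12-voxel face-connected box; blob 2: 5-voxel rod
  blob1 <- as.matrix(expand.grid(1:3, 1:2, 1:2))
  blob2 <- cbind(6:8, 6, 3)
  blob2 <- rbind(blob2, c(8, 7, 3), c(8, 8, 3))
  for (v in seq_len(nrow(blob1))) {
    tv[blob1[v, 1], blob1[v, 2], blob1[v, 3]] <- 6
    pv[blob1[v, 1], blob1[v, 2], blob1[v, 3]] <- 1e-6
    qv[blob1[v, 1], blob1[v, 2], blob1[v, 3]] <- 0.01
  }
  for (v in seq_len(nrow(blob2))) {
    tv[blob2[v, 1], blob2[v, 2], blob2[v, 3]] <- -7
    pv[blob2[v, 1], blob2[v, 2], blob2[v, 3]] <- 1e-6
    qv[blob2[v, 1], blob2[v, 2], blob2[v, 3]] <- 0.01
  }
  sm <- list(t_vol = tv, p_vol = pv, q_vol = qv)
  rs <- define_rois(sm, min_size = 10)
  expect_identical(nrow(rs$table), 1L)
  expect_identical(rs$table$size, 12L)
  expect_identical(rs$table$sign, 1)
  # both clusters kept at min_size = 5; ordered by |peak t| descending
  rs2 <- define_rois(sm, min_size = 5)
  expect_identical(nrow(rs2$table), 2L)
  expect_identical(rs2$table$size, c(5L, 12L))
  expect_identical(rs2$table$peak_t[1], -7)
  # empty suprathreshold set is an empty ROI set, not an error
  rs0 <- define_rois(list(t_vol = tv, p_vol = array(1, g),
                          q_vol = array(1, g)))
  expect_identical(nrow(rs0$table), 0L)
  # a 10-voxel rod is retained at min_size = 10 (boundary inclusive)
  tv3 <- array(0, g); pv3 <- array(1, g); qv3 <- array(1, g)
  tv3[1:8, 1, 1] <- 5; tv3[8, 2, 1] <- 5; tv3[8, 3, 1] <- 5
  pv3[tv3 != 0] <- 1e-6; qv3[tv3 != 0] <- 0.01
  rs3 <- define_rois(list(t_vol = tv3, p_vol = pv3, q_vol = qv3),
                     min_size = 10)
  expect_identical(rs3$table$size, 10L)
  # cluster sizes sum to the suprathreshold count of retained clusters
  expect_identical(sum(rs2$table$size), rs2$n_suprathreshold)
})

test_that("connected components respect the declared adjacency", {
  g <- c(3, 3, 1)
  m <- array(FALSE, g)
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE  # diagonal touch
  tv <- array(0, g); tv[m] <- 4
  pv <- array(1, g); pv[m] <- 1e-6
  qv <- array(1, g); qv[m] <- 0.01
  sm <- list(t_vol = tv, p_vol = pv, q_vol = qv)
  expect_identical(nrow(define_rois(sm, min_size = 2, adjacency = 6)$table), 0L)
  expect_identical(define_rois(sm, min_size = 2, adjacency = 18)$table$size, 2L)
  expect_identical(define_rois(sm, min_size = 2, adjacency = 26)$table$size, 2L)
})

test_that("define_rois tags clusters with the majority parcellation label", {
  g <- c(6, 2, 1)
  tv <- array(0, g); pv <- array(1, g); qv <- array(1, g)
  tv[1:4, 1, 1] <- 5; pv[1:4, 1, 1] <- 1e-6; qv[1:4, 1, 1] <- 0.01
  labs <- array(0L, g); labs[1:2, 1, 1] <- 2L; labs[3, 1, 1] <- 2L
  labs[4, 1, 1] <- 1L
  rs <- define_rois(list(t_vol = tv, p_vol = pv, q_vol = qv), min_size = 4,
                    parc = parcellation(labs))
  expect_identical(rs$table$network, 2L)
})

test_that("ROI-pair group tests form one BH family over all pairs", {
  set.seed(5)
  n_sub <- 14; n_roi <- 6
  grp <- rep(c("A", "B"), each = 7)
  arr <- array(0, c(n_roi, n_roi, n_sub))
  for (s in seq_len(n_sub)) {
    z <- matrix(rnorm(n_roi^2, sd = 0.2), n_roi, n_roi)
    z <- (z + t(z)) / 2
    if (grp[s] == "A") z <- z + 0.5   # uniform elevation in group A
    diag(z) <- 0
    arr[, , s] <- z
  }
  res <- roi_pair_group_tests(arr, grp)
  expect_equal(nrow(res$pairs), n_roi * (n_roi - 1) / 2)
  expect_equal(res$pairs$q, bh_fdr(res$pairs$p))
  expect_true(all(res$pairs$t < 0))  # contrast is B minus the elevated A
  expect_true(all(res$pairs$q < 0.05))
  expect_true(isSymmetric(res$t_matrix))
  # identical matrices across subjects: every t = 0, nothing significant
  arr0 <- array(rep(arr[, , 1], n_sub), c(n_roi, n_roi, n_sub))
  res0 <- roi_pair_group_tests(arr0, grp)
  expect_true(all(res0$pairs$t == 0))
  expect_false(any(res0$sig_matrix[upper.tri(res0$sig_matrix)]))
})

test_that("ancova reduces to the two-sample t without a covariate and reports F(1, n-4)", {
  set.seed(6)
  y <- rnorm(52)
  grp <- rep(c("DS", "TD"), c(19, 33))
  ts <- two_sample_t(x = y[grp == "DS"], y = y[grp == "TD"])
  a0 <- ancova(y, grp, rep(1, 52))
  expect_equal(unname(a0$F["group"]), ts$t^2, tolerance = 1e-8)
  expect_equal(unname(a0$p["group"]), ts$p, tolerance = 1e-10)
  a1 <- ancova(y, grp, rnorm(52))
  expect_identical(a1$df, c(1, 48))  # n = 52 gives the F(1, 48) shape
  expect_true(all(a1$F >= 0))
  expect_error(ancova(y, rep("DS", 52), rnorm(52)), "2 group levels")
})

test_that("ancova interaction holds its type-I error under the null", {
  set.seed(7)
  reps <- 500
  grp <- rep(c("A", "B"), c(19, 33))
  pint <- numeric(reps)
  for (r in seq_len(reps)) {
    y <- rnorm(52)
    cov <- rnorm(52)
    pint[r] <- ancova(y, grp, cov)$p["interaction"]
  }
  rate <- mean(pint < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
  # and the p values look uniform
  expect_gt(suppressWarnings(ks.test(pint, "punif"))$p.value, 0.01)
})

test_that("partial correlation equals the two-regression oracle with df = n - 3", {
  set.seed(8)
  x <- rnorm(6); cov <- rnorm(6)
  y <- 0.5 * x + 0.3 * cov + rnorm(6, sd = 0.1)
  pc <- partial_correlation(x, y, cov)
  expect_equal(pc$r, brute_partial_cor(x, y, cov), tolerance = 1e-12)
  expect_identical(pc$df, 3)
  # y = x with an independent covariate: r = 1
  x2 <- rnorm(20)
  expect_equal(partial_correlation(x2, x2, rnorm(20))$r, 1, tolerance = 1e-12)
  # n = 52 gives the r(49) df shape
  expect_identical(partial_correlation(rnorm(52), rnorm(52), rnorm(52))$df, 49)
  expect_error(partial_correlation(cov, rnorm(6), cov), "collinear")
})
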