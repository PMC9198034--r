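test_that("compute_fd matches the stated formula and conventions", {
  expect_identical(compute_fd(matrix(3, 10, 6)), 0)
  # one translation column stepping 0.3 mm at a single transition, 124 frames
  m <- matrix(0, 124, 6)
  m[60:124, 1] <- 0.3
  expect_equal(compute_fd(m), 0.3 / 123, tolerance = 1e-12)
  # rotations converted to arc length on a 50 mm sphere
  m2 <- matrix(0, 3, 6)
  m2[2:3, 4] <- 1  # one 1-degree step
  expect_equal(compute_fd(m2), (pi / 180 * 50) / 2, tolerance = 1e-12)
  expect_error(compute_fd(matrix(0, 1, 6)), "2 frames")
})

test_that("FD is shift-invariant and degree-1 homogeneous in increments", {
  set.seed(1)
  m <- apply(matrix(rnorm(50 * 6, sd = 0.05), 50, 6), 2, cumsum)
  fd <- compute_fd(m)
  expect_equal(compute_fd(sweep(m, 2, rnorm(6, 0, 10), "+")), fd)
  expect_equal(compute_fd(m * 3.7), fd * 3.7, tolerance = 1e-12)
  # sum-of-absolute-values variant bounds the euclidean one from above
  expect_gte(compute_fd(m, method = "sum_abs"), fd)
})

test_that("motion exclusion is strict at the threshold and reports all partitions", {
  fds <- c(a = 0.04, b = 0.29, c = 0.30, d = 0.35)
  part <- exclude_by_motion(fds, threshold = 0.30)
  expect_identical(part$retained$subject_id, c("a", "b"))
  expect_identical(part$excluded$subject_id, c("c", "d"))
  # empty cohort and all-below cases
  empty <- exclude_by_motion(numeric(0))
  expect_identical(nrow(empty$retained), 0L)
  expect_identical(nrow(empty$excluded), 0L)
  all_ok <- exclude_by_motion(c(x = 0.1, y = 0.2))
  expect_identical(nrow(all_ok$excluded), 0L)
  # missing FD is unevaluable, not dropped
  part2 <- exclude_by_motion(data.frame(subject_id = c("p", "q"),
                                        fd = c(0.1, NA)))
  expect_identical(part2$unevaluable$subject_id, "q")
})

test_that("gaussian smoothing: identity at fwhm 0, uniform frames unchanged, impulse matches the analytic kernel", {
  img <- random_image(c(7, 7, 5), 3, seed = 2)
  expect_identical(smooth_gaussian(img, 0), img)

  uni <- bold_image(array(rep(c(2, 5), each = 7 * 7 * 5), c(7, 7, 5, 2)))
  smu <- smooth_gaussian(uni, 6)
  expect_equal(smu$values, uni$values, tolerance = 1e-10)

  imp <- array(0, c(13, 13, 13, 2))
  imp[7, 7, 7, ] <- 1
  sm <- smooth_gaussian(bold_image(imp), 6)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3   # voxel units at 3 mm
  hw <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-hw):hw)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  # interior voxels: full kernel support inside the volume, no boundary
  # renormalization in play
  inner <- -2:2
  expected <- outer(outer(k1[inner + hw + 1], k1[inner + hw + 1]),
                    k1[inner + hw + 1])
  expect_equal(sm$values[inner + 7, inner + 7, inner + 7, 1], expected,
               tolerance = 1e-6)
})

test_that("local sphere average: own-voxel, uniform-field, and brute-force cases", {
  img <- random_image(c(4, 4, 1), 10, seed = 3)
  tis <- full_mask(c(4, 4, 1))
  # radius below voxel spacing on a tissue voxel returns that voxel's series
  tgt <- array(FALSE, c(4, 4, 1)); tgt[2, 3, 1] <- TRUE
  out <- local_sphere_average(img, tis, radius = 2, target_mask = tgt)
  expect_equal(out[, 1], img$values[2, 3, 1, ])

  # uniform tissue field: regressor equals the field's series everywhere
  s <- rnorm(10)
  uni <- bold_image(array(rep(s, each = 16), c(4, 4, 1, 10)))
  outu <- local_sphere_average(uni, tis, radius = 7)
  expect_equal(outu, matrix(s, 10, 16), ignore_attr = TRUE, tolerance = 1e-12)

  # 3-voxel toy mask equals an exhaustive distance-filtered mean
  tis3 <- array(FALSE, c(4, 4, 1))
  tis3[c(1, 6, 16)] <- TRUE   # voxels (1,1,1), (2,2,1), (4,4,1)
  tgt1 <- array(FALSE, c(4, 4, 1)); tgt1[1, 1, 1] <- TRUE
  out3 <- local_sphere_average(img, tis3, radius = 5, target_mask = tgt1)
  # at 3 mm spacing, (1,1) reaches (2,2) (dist 4.24) but not (4,4)
  flat <- t(matrix(img$values, 16, 10))
  expect_equal(out3[, 1], rowMeans(flat[, c(1, 6)]), tolerance = 1e-12)

  # out-of-range targets fall back to the whole-mask average and are recorded
  tgt4 <- array(FALSE, c(4, 4, 1)); tgt4[4, 1, 1] <- TRUE
  tis1 <- array(FALSE, c(4, 4, 1)); tis1[1, 4, 1] <- TRUE
  out4 <- local_sphere_average(img, tis1, radius = 3, target_mask = tgt4)
  expect_equal(out4[, 1], flat[, 13])
  expect_identical(attr(out4, "fallback_voxels"), 4L)
  expect_error(local_sphere_average(img, array(FALSE, c(4, 4, 1))), "empty")
})

test_that("compcor components recover the toy eigenstructure", {
  # mask of identical copies of one series: first component is that series
  s <- as.numeric(scale(cumsum(rnorm(30))))
  img <- toy_image(matrix(rep(s, each = 3), 3))
  expect_warning(
    cc <- compcor_components(img, full_mask(c(3, 1, 1)), n_components = 3,
                             poly_order = 0), "rank")
  expect_identical(ncol(cc), 1L)
  expect_gt(abs(cor(cc[, 1], s)), 1 - 1e-10)

  # two orthogonal series: components span them; eigenvalues match oracle
  set.seed(4)
  a <- rnorm(40); a <- a - mean(a)
  b <- residuals(lm(rnorm(40) ~ a)); b <- b / sd(b) * sd(a) * 2
  m <- rbind(a, a, b, b)   # centered columns
  img2 <- toy_image(m)
  cc2 <- compcor_components(img2, full_mask(c(4, 1, 1)), n_components = 2,
                            poly_order = 0)
  ev <- attr(cc2, "explained_variance")
  oracle_ev <- sort(eigen(crossprod(t(m)) / (40 - 1))$values,
                    decreasing = TRUE)[1:2]
  expect_equal(ev, oracle_ev, tolerance = 1e-8)
  fit <- lm(cc2 ~ a + b)
  expect_lt(max(abs(resid(fit))), 1e-8)

  # n_components = 0 gives an empty matrix
  cc0 <- compcor_components(img2, full_mask(c(4, 1, 1)), n_components = 0)
  expect_identical(dim(cc0), c(40L, 0L))
})

test_that("build_design assembles the stated column set", {
  nt <- 40
  motion <- matrix(rnorm(nt * 6), nt, 6)
  vent <- rnorm(nt)
  lwm <- matrix(rnorm(nt * 5), nt, 5)
  cc <- matrix(rnorm(nt * 3), nt, 3)
  d <- build_design(motion = motion, ventricle = vent, local_wm = lwm,
                    compcor = cc, poly_order = 4)
  expect_identical(design_ncol(d), 16L)  # 6 + 1 + 1 + 3 + 5
  expect_identical(sum(d$sources == "polynomial"), 5L)

  d0 <- build_design(poly_order = 0, n_frames = nt)
  expect_identical(design_ncol(d0), 1L)

  dg <- build_design(motion = motion, poly_order = 4,
                     global_mean = rnorm(nt))
  expect_true("global_mean" %in% dg$sources)
  expect_identical(design_ncol(dg), 12L)

  expect_error(build_design(motion = motion, ventricle = rnorm(nt + 1)),
               "frame count")
  expect_error(build_design(motion = matrix(rnorm(nt * 5), nt, 5)),
               "6 columns")
})

test_that("residualize projects out the design exactly and is idempotent", {
  nt <- 50
  img <- random_image(c(3, 3, 1), nt, seed = 5)
  # design containing a voxel's own series zeroes that voxel
  own <- img$values[1, 1, 1, ]
  d <- build_design(ventricle = own, poly_order = 1)
  res <- residualize(img, d)
  expect_lt(max(abs(res$values[1, 1, 1, ])), 1e-10)

  # pure cubic trend is annihilated by a 4th-order polynomial baseline
  tt <- seq(-1, 1, length.out = nt)
  cub <- bold_image(array(rep(5 + 2 * tt - 3 * tt^3, each = 9),
                          c(3, 3, 1, nt)))
  d4 <- build_design(poly_order = 4, n_frames = nt)
  res4 <- residualize(cub, d4)
  expect_lt(max(abs(res4$values)), 1e-8 * max(abs(cub$values)))

  # residuals orthogonal to every static column and the local regressor
  lwm <- local_sphere_average(img, full_mask(c(3, 3, 1)), radius = 4)
  dn <- build_design(ventricle = rnorm(nt), local_wm = lwm, poly_order = 2)
  resn <- residualize(img, dn)
  R <- t(matrix(resn$values, 9, nt))
  expect_lt(max(abs(crossprod(dn$columns, R))) / max(abs(img$values)), 1e-8)
  proj <- colSums(lwm * R[, attr(lwm, "target_index")])
  expect_lt(max(abs(proj)) / max(abs(img$values)), 1e-8)

  # idempotence
  res2 <- residualize(resn, dn)
  expect_equal(res2$values, resn$values, tolerance = 1e-10)
})

test_that("rank-deficient designs are reported and fit on a pseudo-inverse basis", {
  nt <- 30
  v <- rnorm(nt)
  d <- suppressWarnings(build_design(ventricle = v, physio = cbind(v, rnorm(nt)),
                                     poly_order = 1))
  img <- random_image(c(2, 1, 1), nt, seed = 6)
  expect_warning(res <- residualize(img, d), "rank-deficient")
  R <- t(matrix(res$values, 2, nt))
  expect_lt(max(abs(crossprod(d$columns, R))), 1e-8 * max(abs(img$values)))
})
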