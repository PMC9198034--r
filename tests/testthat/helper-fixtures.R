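# Shared fixture builders and brute-force oracles. Oracles deliberately use
# the naive O(N^2) formulations so they stay independent of the package's
# fast aggregate identities.

# Wrap a voxels x frames matrix as a bold_image on an nx x 1 x 1 grid.
toy_image <- function(series_by_voxel, voxel_size = c(3, 3, 3), tr = 2.5) {
  m <- as.matrix(series_by_voxel)
  bold_image(array(m, dim = c(nrow(m), 1, 1, ncol(m))),
             voxel_size = voxel_size, tr = tr)
}

# Random bold_image on an arbitrary grid.
random_image <- function(grid, n_frames, seed = 1) {
  set.seed(seed)
  bold_image(array(rnorm(prod(grid) * n_frames), dim = c(grid, n_frames)))
}

full_mask <- function(grid) array(TRUE, dim = grid)

# O(N^2) oracle: per-voxel mean correlation with every other voxel.
brute_connectedness <- function(image, mask) {
  X <- t(matrix(image$values, prod(dim(image)[1:3]),
                dim(image)[4])[which(mask), , drop = FALSE])
  R <- cor(X)
  diag(R) <- NA
  colMeans(R, na.rm = TRUE)
}

# Exhaustive pairwise oracle for within/between/selectivity (raw r, pooled).
brute_selectivity <- function(image, parc) {
  labs_vol <- parc$labels
  idx <- which(labs_vol > 0L)
  labs <- labs_vol[idx]
  X <- t(matrix(image$values, prod(dim(image)[1:3]),
                dim(image)[4])[idx, , drop = FALSE])
  R <- cor(X)
  wr <- br <- c()
  n <- length(idx)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labs[i] == labs[j]) wr <- c(wr, R[i, j]) else br <- c(br, R[i, j])
  }
  c(within = mean(wr), between = mean(br),
    selectivity = mean(wr) - mean(br))
}

# Hand-coded BH step-up: q_(i) = min_{j >= i} m p_(j) / j, back to input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# Explicit two-regression partial-correlation oracle.
brute_partial_cor <- function(x, y, cov) {
  rx <- resid(lm(x ~ cov))
  ry <- resid(lm(y ~ cov))
  cor(rx, ry)
}

# Closed-form ridge solve by explicit matrix inversion on standardized X.
brute_ridge <- function(X, y, K) {
  Z <- scale(X)
  as.vector(solve(t(Z) %*% Z + K * diag(ncol(Z))) %*% t(Z) %*% (y - mean(y)))
}

# A small two-group cohort spec for fast pipeline-level tests.
micro_spec <- function(seed, n_a = 6, n_b = 6, n_networks = 4,
                       voxels_per_network = 6, n_frames = 60,
                       grid_shape = c(5, 5, 4), ...) {
  cohort_spec(n_group_a = n_a, n_group_b = n_b, grid_shape = grid_shape,
              n_networks = n_networks,
              voxels_per_network = voxels_per_network,
              n_frames = n_frames, n_wm_voxels = 10, n_vent_voxels = 6,
              seed = seed, ...)
}
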