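#' Specification of a synthetic two-group BOLD cohort
#'
#' Encodes the study design the generator emulates: a smaller high-motion,
#' high-coupling group A (n = 19 by default) and a larger group B (n = 33),
#' 123 retained frames at TR 2.5 s, and a 17-network parcellation. Each voxel
#' in network k carries the series
#' `x_i = sqrt(a) s_k + sqrt(g) h + sqrt(1 - a - g) eps_i`
#' with latent unit-variance network series `s_k` (`Corr(s_k, s_l) = c` for
#' `k != l`), a shared global series `h`, and i.i.d. unit-variance noise, so
#' the population voxel-pair correlation is `a + g` within a network and
#' `a c + g` across networks.
#'
#' @param n_group_a,n_group_b subjects per group (defaults 19 and 33).
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param n_frames frames per subject (default 123).
#' @param tr repetition time, seconds (default 2.5).
#' @param n_networks number of latent networks L (default 17).
#' @param voxels_per_network gray-matter voxels per network (default 6).
#' @param network_loading_a,network_loading_b shared-variance fraction `a`
#'   per group, in `[0, 1)`.
#' @param cross_network_corr_a,cross_network_corr_b off-diagonal latent
#'   correlation `c` per group, in `(-1, 1)` and above `-1/(L-1)`.
#' @param global_loading global shared-variance fraction `g`; length 1
#'   (both groups) or 2 `(g_a, g_b)`.
#' @param fd_mean_a,fd_mean_b group mean frame-wise displacement, mm/TR.
#' @param behavior_effect scalar `beta` linking behavior to the fixed linear
#'   combination `w' f` of network-pair Fisher-z features.
#' @param behavior_noise_sd residual SD `sigma` of the behavior score.
#' @param n_wm_voxels,n_vent_voxels sizes of the synthetic white-matter and
#'   ventricle slabs (disjoint from gray matter).
#' @param latent_corr optional full L x L latent correlation matrix override
#'   (one per group as a list of length 2, or a single matrix for both);
#'   replaces the exchangeable structure.
#' @param layout `"packed"` (default) fills consecutive voxels, giving one
#'   spatially connected gray-matter slab; `"separated"` places each network
#'   in its own z-plane with an empty plane between neighbors (requires
#'   `grid_shape[3] >= 2 * n_networks + 3`), so suprathreshold clusters of a
#'   spatially homogeneous effect stay network-wise disjoint.
#' @param seed integer RNG seed for the whole cohort.
#' @return A validated `cohort_spec` object (a list).
#' @export
cohort_spec <- function(n_group_a = 19, n_group_b = 33,
                        grid_shape = c(8, 8, 4),
                        n_frames = 123, tr = 2.5,
                        n_networks = 17, voxels_per_network = 6,
                        network_loading_a = 0.30, network_loading_b = 0.30,
                        cross_network_corr_a = 0.50,
                        cross_network_corr_b = 0.15,
                        global_loading = c(0.10, 0.02),
                        fd_mean_a = 0.14, fd_mean_b = 0.06,
                        behavior_effect = 1, behavior_noise_sd = 0.04,
                        n_wm_voxels = 12, n_vent_voxels = 6,
                        latent_corr = NULL, layout = c("packed", "separated"),
                        seed = 1L) {
  layout <- match.arg(layout)
  g <- rep(global_loading, length.out = 2L)
  spec <- list(n_group_a = as.integer(n_group_a),
               n_group_b = as.integer(n_group_b),
               grid_shape = as.integer(grid_shape),
               n_frames = as.integer(n_frames), tr = tr,
               n_networks = as.integer(n_networks),
               voxels_per_network = as.integer(voxels_per_network),
               network_loading_a = network_loading_a,
               network_loading_b = network_loading_b,
               cross_network_corr_a = cross_network_corr_a,
               cross_network_corr_b = cross_network_corr_b,
               global_loading = g,
               fd_mean_a = fd_mean_a, fd_mean_b = fd_mean_b,
               behavior_effect = behavior_effect,
               behavior_noise_sd = behavior_noise_sd,
               n_wm_voxels = as.integer(n_wm_voxels),
               n_vent_voxels = as.integer(n_vent_voxels),
               latent_corr = latent_corr, layout = layout,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  L <- s$n_networks
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (s$n_frames < 2L) stop("n_frames must be >= 2")
  for (grp in 1:2) {
    a <- if (grp == 1) s$network_loading_a else s$network_loading_b
    g <- s$global_loading[grp]
    if (a < 0 || a >= 1 || g < 0 || g >= 1)
      stop("loadings must lie in [0, 1)")
    if (a + g >= 1)
      stop(sprintf("network + global loading (a + g = %.3f) must be < 1 so residual noise variance stays positive", a + g))
    cc <- if (grp == 1) s$cross_network_corr_a else s$cross_network_corr_b
    if (abs(cc) >= 1) stop("cross-network correlation must lie in (-1, 1)")
    if (L > 1L && cc <= -1 / (L - 1))
      stop(sprintf("cross-network correlation %.3f makes the %dx%d exchangeable latent correlation matrix non-positive-definite (needs c > %.4f)",
                   cc, L, L, -1 / (L - 1)))
  }
  ngm <- s$voxels_per_network * L
  if (ngm > prod(s$grid_shape))
    stop("voxels_per_network x n_networks exceeds the grid")
  if (ngm + s$n_wm_voxels + s$n_vent_voxels > prod(s$grid_shape))
    stop("grid too small for gray matter plus white-matter/ventricle slabs")
  if (identical(s$layout, "separated")) {
    nxy <- s$grid_shape[1] * s$grid_shape[2]
    if (max(s$voxels_per_network, s$n_wm_voxels, s$n_vent_voxels) > nxy)
      stop("separated layout needs each tissue block to fit one z-plane")
    if (s$grid_shape[3] < 2 * L + 3)
      stop("separated layout needs grid_shape[3] >= 2 * n_networks + 3")
  }
  if (!is.null(s$latent_corr)) {
    mats <- if (is.list(s$latent_corr)) s$latent_corr else
      list(s$latent_corr, s$latent_corr)
    for (M in mats) {
      if (!isTRUE(all.equal(dim(M), c(L, L))))
        stop("latent_corr override must be L x L")
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-12)
        stop("latent_corr override is not positive definite")
    }
  }
  invisible(s)
}

# Cholesky factor of the group's latent L x L correlation matrix.
latent_chol <- function(spec, group) {
  L <- spec$n_networks
  if (!is.null(spec$latent_corr)) {
    M <- if (is.list(spec$latent_corr))
      spec$latent_corr[[if (group == "A") 1L else 2L]] else spec$latent_corr
  } else {
    cc <- if (group == "A") spec$cross_network_corr_a else
      spec$cross_network_corr_b
    M <- matrix(cc, L, L)
    diag(M) <- 1
  }
  chol(M)
}

#' Simulate a synthetic multi-subject BOLD cohort
#'
#' Generates one [bold_image] per subject under the generative model stated
#' in [cohort_spec()], a [parcellation], gray-matter / white-matter /
#' ventricle masks, per-subject random-walk motion tables realizing
#' group-specific frame-wise displacement, and a behavioral score linearly
#' linked to the subject's network-pair Fisher-z connectivity features
#' through a fixed unit-norm weight vector `w` drawn once from the cohort
#' seed. Identical spec (including seed) reproduces the cohort exactly;
#' subject streams are derived sub-streams keyed by subject index.
#'
#' White-matter and ventricle voxels carry independent noise plus a fraction
#' of the global series, giving ANATICOR-style regressors real signal to
#' remove.
#'
#' @param spec a [cohort_spec()].
#' @return A `synthetic_cohort` object: list with `subjects` (list; each has
#'   `subject_id`, `group`, `bold`, `motion`, `fd_true`, `behavior`,
#'   `roi_truth`), `parcellation`, `masks` (`gm`, `wm`, `ventricle`),
#'   `phenotype` (data.frame), `behavior_weights` (`w`), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  L <- spec$n_networks
  vpn <- spec$voxels_per_network
  g3 <- spec$grid_shape
  nvox <- prod(g3)
  ngm <- L * vpn

  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)

  # spatial layout: contiguous blocks of linear indices (slab geometry), or
  # one z-plane per network with empty separator planes
  if (identical(spec$layout %||% "packed", "separated")) {
    nxy <- g3[1] * g3[2]
    plane <- function(z, n) (z - 1L) * nxy + seq_len(n)
    gm_idx <- unlist(lapply(seq_len(L), function(k)
      plane(2L * k - 1L, vpn)))
    wm_idx <- plane(2L * L + 1L, spec$n_wm_voxels)
    vent_idx <- plane(2L * L + 3L, spec$n_vent_voxels)
  } else {
    gm_idx <- seq_len(ngm)
    wm_idx <- ngm + seq_len(spec$n_wm_voxels)
    vent_idx <- ngm + spec$n_wm_voxels + seq_len(spec$n_vent_voxels)
  }
  labels <- array(0L, dim = g3)
  labels[gm_idx] <- rep(seq_len(L), each = vpn)
  parc <- parcellation(labels, n_networks = L)
  mk_mask <- function(idx) {
    m <- array(FALSE, dim = g3); m[idx] <- TRUE; m
  }
  masks <- list(gm = mk_mask(gm_idx), wm = mk_mask(wm_idx),
                ventricle = mk_mask(vent_idx))

  # cohort-level draws: behavior weights and per-subject sub-seeds
  n_total <- spec$n_group_a + spec$n_group_b
  n_feat <- L * (L - 1) / 2
  w <- stats::rnorm(n_feat)
  w <- w / sqrt(sum(w^2))
  sub_seeds <- draw_subseed(n_total)

  groups <- c(rep("A", spec$n_group_a), rep("B", spec$n_group_b))
  ids <- sprintf("sub-%s%02d", tolower(groups),
                 c(seq_len(spec$n_group_a), seq_len(spec$n_group_b)))
  net_of_gm <- rep(seq_len(L), each = vpn)
  gw <- 0.2  # global-series share in noise-tissue voxels

  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(sub_seeds[i])
    grp <- groups[i]
    a <- if (grp == "A") spec$network_loading_a else spec$network_loading_b
    g <- spec$global_loading[if (grp == "A") 1L else 2L]
    nt <- spec$n_frames
    Sraw <- matrix(stats::rnorm(nt * L), nt, L) %*% latent_chol(spec, grp)
    h <- stats::rnorm(nt)
    vals <- matrix(0, nrow = nvox, ncol = nt)
    eps <- matrix(stats::rnorm(nt * ngm), nt, ngm)
    gmset <- sqrt(a) * Sraw[, net_of_gm] + sqrt(g) * h +
      sqrt(1 - a - g) * eps
    vals[gm_idx, ] <- t(gmset)
    n_noise <- spec$n_wm_voxels + spec$n_vent_voxels
    noise_idx <- c(wm_idx, vent_idx)
    vals[noise_idx, ] <- t(sqrt(gw) * h +
      sqrt(1 - gw) * matrix(stats::rnorm(nt * n_noise), nt, n_noise))
    bold <- bold_image(array(vals, dim = c(g3, nt)), tr = spec$tr)

    fd_mean <- if (grp == "A") spec$fd_mean_a else spec$fd_mean_b
    fd_true <- max(0.01, stats::rnorm(1, fd_mean, 0.5 * fd_mean))
    motion <- simulate_motion(nt, fd_true)

    # behavior from network-level ROI-pair Fisher-z features
    f <- roi_pairs_vector(roi_matrix(bold, parc$labels))
    behavior <- spec$behavior_effect * sum(w * f) +
      spec$behavior_noise_sd * stats::rnorm(1)

    subjects[[i]] <- list(
      subject_id = ids[i], group = grp, bold = bold, motion = motion,
      fd_true = fd_true, behavior = behavior,
      roi_truth = c(within = a + g,
                    between = a * (if (grp == "A") spec$cross_network_corr_a
                                   else spec$cross_network_corr_b) + g))
  }
  phenotype <- data.frame(
    subject_id = ids, group = groups,
    behavior = vapply(subjects, `[[`, 0, "behavior"),
    fd_true = vapply(subjects, `[[`, 0, "fd_true"),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, parcellation = parc, masks = masks,
                 phenotype = phenotype, behavior_weights = w, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d + %d subjects, %d networks x %d voxels, %d frames\n",
              x$spec$n_group_a, x$spec$n_group_b, x$spec$n_networks,
              x$spec$voxels_per_network, x$spec$n_frames))
  invisible(x)
}

#' Simulate a rigid-body motion table with a target frame-wise displacement
#'
#' Six independent Gaussian random-walk parameter columns (3 translations,
#' 3 rotations in degrees) whose increments are rescaled so the realized
#' mean frame-wise displacement of the table equals `fd_target` exactly
#' (FD is homogeneous of degree 1 in the parameter increments).
#' `fd_target = 0` yields constant columns.
#'
#' @param n_frames number of frames (>= 2).
#' @param fd_target desired mean FD in mm/TR (>= 0).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return frames x 6 numeric matrix (columns `trans_x..rot_z`).
#' @export
simulate_motion <- function(n_frames, fd_target, seed = NULL) {
  if (n_frames < 2L) stop("simulate_motion needs n_frames >= 2")
  if (fd_target < 0) stop("fd_target must be >= 0")
  if (!is.null(seed)) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
  }
  inc <- matrix(stats::rnorm((n_frames - 1L) * 6L), n_frames - 1L, 6L)
  inc[, 4:6] <- inc[, 4:6] / (pi / 180 * 50)  # rotations drawn on the arc scale
  tab <- rbind(0, apply(inc, 2L, cumsum))
  if (fd_target == 0) {
    tab[] <- 0
  } else {
    fd0 <- compute_fd(tab)
    tab <- tab * (fd_target / fd0)
  }
  colnames(tab) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  tab
}

# Seed the RNG and return a restorer for the previous state.
.Random.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
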