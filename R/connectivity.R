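#' Fisher z transform of correlation coefficients
#'
#' Variance-stabilizing transform `z = atanh(r)`. Correlations are clipped to
#' `+/-(1 - 1e-7)` before the transform so that degenerate inputs (perfectly
#' collinear series, `|r| = 1`) map to large finite values rather than
#' `+/-Inf`; the number of clipped values is attached as attribute
#' `"n_clipped"`.
#'
#' @param r numeric vector of correlations, `|r| <= 1` (values up to
#'   `1 + 1e-12` are tolerated as floating-point slop).
#' @return Fisher-z values, same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("fisher_z: |r| > 1; inputs must be correlations")
  n_clip <- sum(abs(r) > R_CLIP, na.rm = TRUE)
  z <- atanh(clip_r(r))
  attributes(z) <- attributes(r)
  attr(z, "n_clipped") <- n_clip
  z
}

#' Voxelwise whole-brain connectedness map
#'
#' For every gray-matter voxel, the mean Pearson correlation of its time
#' series with every *other* gray-matter voxel's series (self-correlation
#' excluded), Fisher-z transformed. Computed through the exact aggregate
#' identity: with each in-mask series standardized to zero mean and unit
#' norm (`u_i`), `mean_{j != i} r(i, j) = (u_i . S - 1) / (N - 1)` where
#' `S = sum_j u_j` — identical to the O(N^2) pairwise loop but linear in N.
#'
#' Constant (zero-variance) series inside the mask are flagged with a
#' warning, receive `NA`, and are excluded from `N` for the remaining voxels.
#'
#' @param image a [bold_image].
#' @param gm_mask 3D logical gray-matter mask on the image grid.
#' @param subject_id optional identifier carried into the result.
#' @return An object of class `connectedness_map`: list with `z` (3D array,
#'   `NA` off-mask), `mask`, `n_voxels` (voxels contributing), `n_clipped`,
#'   and `subject_id`.
#' @export
connectedness_map <- function(image, gm_mask, subject_id = NULL) {
  gm_mask <- as_mask(gm_mask, grid_dim(image))
  idx <- which(gm_mask)
  if (length(idx) < 2L) stop("connectedness needs >= 2 gray-matter voxels")
  X <- mask_series(image, gm_mask)
  U <- unit_norm_columns(X)
  const <- attr(U, "constant")
  if (any(const)) {
    warning(sprintf("%d constant in-mask series excluded from connectedness",
                    sum(const)))
    U <- U[, !const, drop = FALSE]
    idx <- idx[!const]
  }
  N <- ncol(U)
  if (N < 2L) stop("fewer than 2 non-constant gray-matter voxels")
  S <- rowSums(U)
  mean_r <- (as.vector(crossprod(U, S)) - 1) / (N - 1)
  z <- fisher_z(mean_r)
  vol <- array(NA_real_, dim = grid_dim(image))
  vol[idx] <- as.vector(z)
  structure(list(z = vol, mask = gm_mask, n_voxels = N,
                 n_clipped = attr(z, "n_clipped"),
                 subject_id = subject_id),
            class = "connectedness_map")
}

#' @export
print.connectedness_map <- function(x, ...) {
  cat(sprintf("<connectedness_map> %s, %d voxels, mean z = %.4f\n",
              x$subject_id %||% "(unnamed)", x$n_voxels,
              mean(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Average time series within an ROI mask
#'
#' @param image a [bold_image].
#' @param roi_mask 3D logical mask of the region.
#' @return numeric vector, one value per frame (unweighted voxel mean).
#' @export
roi_timeseries <- function(image, roi_mask) {
  roi_mask <- as_mask(roi_mask, grid_dim(image))
  if (!any(roi_mask)) stop("empty ROI mask")
  rowMeans(mask_series(image, roi_mask))
}

#' ROI-to-ROI Fisher-z connectivity matrix
#'
#' Pairwise Pearson correlations between ROI mean time series, Fisher-z
#' transformed. The diagonal is undefined and stored as 0. ROIs may be given
#' as a 3D integer label volume (labels `1..n`) or as a list of logical
#' masks.
#'
#' @param image a [bold_image].
#' @param rois 3D integer label array, or named list of 3D logical masks.
#' @return An `roi_connectivity` object: list with `z` (symmetric matrix,
#'   diagonal 0), `roi_ids`, and `undefined` (logical per ROI, `TRUE` where
#'   the ROI mean series was constant; its row/column is `NA`).
#' @export
roi_matrix <- function(image, rois) {
  series <- roi_series_matrix(image, rois)
  if (ncol(series) < 2L) stop("roi_matrix needs >= 2 ROIs")
  sds <- apply(series, 2L, stats::sd)
  undefined <- sds <= 0 | !is.finite(sds)
  if (any(undefined))
    warning(sprintf("constant mean series for ROI(s) %s; entries set NA",
                    paste(colnames(series)[undefined], collapse = ", ")))
  R <- suppressWarnings(stats::cor(series))
  Z <- fisher_z(ifelse(is.finite(R), R, NA_real_))
  attr(Z, "n_clipped") <- NULL
  Z <- (Z + t(Z)) / 2  # enforce exact symmetry
  diag(Z) <- 0
  Z[undefined, ] <- NA_real_
  Z[, undefined] <- NA_real_
  structure(list(z = Z, roi_ids = colnames(series), undefined = undefined),
            class = "roi_connectivity")
}

# frames x n_roi matrix of ROI mean series from a label volume or mask list.
roi_series_matrix <- function(image, rois) {
  if (is.list(rois)) {
    out <- vapply(rois, function(m) roi_timeseries(image, m),
                  numeric(n_frames(image)))
    if (is.null(colnames(out)))
      colnames(out) <- paste0("roi", seq_along(rois))
  } else {
    labs <- rois
    if (inherits(labs, "parcellation")) labs <- labs$labels
    ids <- sort(unique(as.integer(labs[labs > 0L])))
    if (length(ids) == 0L) stop("label volume contains no ROI voxels")
    out <- vapply(ids, function(k) roi_timeseries(image, labs == k),
                  numeric(n_frames(image)))
    colnames(out) <- paste0("roi", ids)
  }
  out
}

#' Vectorize the upper triangle of an ROI connectivity matrix
#'
#' @param mat an `roi_connectivity` object or a square symmetric matrix.
#' @return named numeric vector of the `n(n-1)/2` unique off-diagonal values,
#'   names `<roi_a>|<roi_b>` in column-major upper-triangle order.
#' @export
roi_pairs_vector <- function(mat) {
  Z <- if (inherits(mat, "roi_connectivity")) mat$z else mat
  ids <- if (inherits(mat, "roi_connectivity")) mat$roi_ids else
    (colnames(Z) %||% paste0("roi", seq_len(ncol(Z))))
  ut <- upper.tri(Z)
  v <- Z[ut]
  names(v) <- outer(ids, ids, paste, sep = "|")[ut]
  v
}

#' Within-network, between-network connectivity and network selectivity
#'
#' Averages the pairwise voxel correlations over all unordered pairs sharing
#' a network label (within) and over all pairs with different labels
#' (between); `selectivity = within - between`. The default pools every
#' qualifying voxel pair with equal weight and averages raw Pearson r. On
#' the r scale the pooled averages use exact aggregate identities on
#' unit-norm series (`sum` of within-network pair correlations for network k
#' is `(||S_k||^2 - N_k)/2` with `S_k = sum_{i in k} u_i`; the cross-network
#' (k, l) pair sum is `S_k . S_l`), avoiding the O(N^2) pairwise loop.
#'
#' @param image a [bold_image].
#' @param parc a [parcellation] on the image grid (label 0 = excluded).
#' @param scale `"r"` (default) averages raw correlations; `"z"` averages
#'   Fisher-z transformed correlations (requires the explicit pair matrix).
#' @param weighting `"pooled"` (default) weights every voxel pair equally;
#'   `"network"` first averages within each network (and each network pair),
#'   then averages those means without size weighting.
#' @param fd optional motion summary carried into the record.
#' @param subject_id optional identifier.
#' @return A one-row `data.frame` (class `selectivity_record`):
#'   `subject_id`, `within`, `between`, `selectivity`, `fd`.
#' @export
network_connectivity <- function(image, parc,
                                 scale = c("r", "z"),
                                 weighting = c("pooled", "network"),
                                 fd = NA_real_, subject_id = NA_character_) {
  scale <- match.arg(scale)
  weighting <- match.arg(weighting)
  stopifnot(inherits(parc, "parcellation"))
  if (!all(dim(parc$labels) == grid_dim(image)))
    stop("parcellation grid does not match image grid")
  labs_vol <- parc$labels
  idx <- which(labs_vol > 0L)
  labs <- as.integer(labs_vol[idx])
  X <- t(matrix(image$values, nrow = prod(grid_dim(image)))[idx, , drop = FALSE])
  U <- unit_norm_columns(X)
  const <- attr(U, "constant")
  if (any(const)) {
    warning(sprintf("%d constant voxels excluded from selectivity", sum(const)))
    U <- U[, !const, drop = FALSE]
    labs <- labs[!const]
  }
  counts <- table(factor(labs, levels = seq_len(parc$n_networks)))
  keep_nets <- as.integer(names(counts))[counts >= 2L]
  if (length(keep_nets) < 2L)
    stop("selectivity needs >= 2 networks with >= 2 voxels each")
  if (any(counts == 1L))
    warning("networks with a single voxel contribute no within-network pairs")

  nets <- sort(unique(labs))
  L <- length(nets)
  Nk <- as.numeric(table(factor(labs, levels = nets)))
  if (scale == "r") {
    # aggregate identities
    Sk <- vapply(nets, function(k) rowSums(U[, labs == k, drop = FALSE]),
                 numeric(nrow(U)))
    G <- crossprod(Sk)                     # L x L: Sk . Sl
    within_sum_k <- (diag(G) - Nk) / 2
    within_pairs_k <- Nk * (Nk - 1) / 2
    cross_sum <- G[upper.tri(G)]
    cross_pairs <- (outer(Nk, Nk))[upper.tri(G)]
    if (weighting == "pooled") {
      within <- sum(within_sum_k) / sum(within_pairs_k)
      between <- sum(cross_sum) / sum(cross_pairs)
    } else {
      wk <- within_sum_k / within_pairs_k
      within <- mean(wk[within_pairs_k > 0])
      between <- mean(cross_sum / cross_pairs)
    }
  } else {
    C <- crossprod(U)
    ZC <- atanh(clip_r(C))
    same <- outer(labs, labs, "==")
    ut <- upper.tri(C)
    if (weighting == "pooled") {
      within <- mean(ZC[ut & same])
      between <- mean(ZC[ut & !same])
    } else {
      wk <- vapply(nets, function(k) {
        sub <- ZC[labs == k, labs == k, drop = FALSE]
        if (nrow(sub) < 2L) NA_real_ else mean(sub[upper.tri(sub)])
      }, numeric(1))
      within <- mean(wk, na.rm = TRUE)
      bkl <- utils::combn(seq_len(L), 2L, function(ij)
        mean(ZC[labs == nets[ij[1]], labs == nets[ij[2]], drop = FALSE]))
      between <- mean(bkl)
    }
  }
  out <- data.frame(subject_id = subject_id, within = within,
                    between = between, selectivity = within - between,
                    fd = fd, stringsAsFactors = FALSE)
  class(out) <- c("selectivity_record", "data.frame")
  out
}
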