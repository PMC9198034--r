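#' Mean frame-wise displacement from rigid-body motion parameters
#'
#' Summarizes a frames x 6 motion-parameter table (3 translations in mm,
#' 3 rotations) as a single mm/TR value: rotations are converted to arc
#' length on a 50 mm sphere (degrees -> radians -> x 50 mm), the six
#' parameters are first-differenced across frame transitions, and FD is the
#' mean over transitions of the Euclidean norm of the six increments. A
#' sum-of-absolute-values variant (the other common convention) is available
#' via `method = "sum_abs"`.
#'
#' @param params numeric matrix, frames x 6: columns 1-3 translations (mm),
#'   columns 4-6 rotations.
#' @param rotation_unit `"degrees"` (default) or `"radians"`.
#' @param radius head-sphere radius in mm used to convert rotations to arc
#'   length (default 50).
#' @param method `"euclidean"` (default) or `"sum_abs"`.
#' @return FD in mm/TR (non-negative scalar; 0 iff all columns constant).
#' @export
compute_fd <- function(params, rotation_unit = c("degrees", "radians"),
                       radius = 50, method = c("euclidean", "sum_abs")) {
  rotation_unit <- match.arg(rotation_unit)
  method <- match.arg(method)
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion table must have 6 columns")
  if (nrow(params) < 2L) stop("FD needs at least 2 frames")
  conv <- params
  rot_scale <- if (rotation_unit == "degrees") pi / 180 * radius else radius
  conv[, 4:6] <- conv[, 4:6] * rot_scale
  d <- diff(conv)
  if (method == "euclidean") mean(sqrt(rowSums(d^2))) else mean(rowSums(abs(d)))
}

#' Partition subjects by the motion-exclusion rule
#'
#' Subjects are retained iff their mean frame-wise displacement is strictly
#' below the threshold (the inclusion rule is `fd < threshold`, so a subject
#' exactly at the threshold is excluded). Subjects with a missing FD are
#' reported as unevaluable rather than silently dropped.
#'
#' @param subjects data.frame with columns `subject_id` and `fd`, or a named
#'   numeric vector of FD values.
#' @param threshold exclusion threshold in mm/TR (default 0.30).
#' @return list with data.frames `retained`, `excluded`, `unevaluable`
#'   (columns `subject_id`, `fd`).
#' @export
exclude_by_motion <- function(subjects, threshold = 0.30) {
  if (is.numeric(subjects) && is.null(dim(subjects))) {
    subjects <- data.frame(
      subject_id = names(subjects) %||% sprintf("sub%d", seq_along(subjects)),
      fd = as.numeric(subjects), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("subject_id", "fd") %in% names(subjects)))
  df <- subjects[, c("subject_id", "fd")]
  una <- is.na(df$fd)
  list(retained = df[!una & df$fd < threshold, , drop = FALSE],
       excluded = df[!una & df$fd >= threshold, , drop = FALSE],
       unevaluable = df[una, , drop = FALSE])
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each frame with a separable isotropic Gaussian of the requested
#' full width at half maximum (`sigma = fwhm / (2 sqrt(2 log 2))` mm,
#' converted to voxel units per axis). Boundaries are handled by zero padding
#' followed by renormalization with the kernel mass falling inside the
#' volume, so uniform images stay uniform and the interior spatial mean is
#' preserved. `fwhm = 0` is the identity.
#'
#' @param image a [bold_image].
#' @param fwhm full width at half maximum, mm (default 6).
#' @return a smoothed [bold_image].
#' @export
smooth_gaussian <- function(image, fwhm = 6) {
  stopifnot(inherits(image, "bold_image"))
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(image)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  g <- grid_dim(image)
  kerns <- lapply(1:3, function(ax) {
    s <- sigma_mm / image$voxel_size[ax]
    hw <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-hw, hw))^2 / (2 * s^2))
    k / sum(k)
  })
  # renormalization field: separable smoothing of an all-ones volume
  norm1d <- lapply(1:3, function(ax) conv_mat(g[ax], kerns[[ax]]) %*% rep(1, g[ax]))
  norm3d <- array(outer(outer(as.vector(norm1d[[1]]), as.vector(norm1d[[2]])),
                        as.vector(norm1d[[3]])), dim = g)
  out <- image$values
  nt <- n_frames(image)
  for (f in seq_len(nt)) {
    vol <- out[, , , f]
    for (ax in 1:3) vol <- apply_along_axis(vol, ax, conv_mat(g[ax], kerns[[ax]]))
    out[, , , f] <- vol / norm3d
  }
  bold_image(out, voxel_size = image$voxel_size, tr = image$tr)
}

# Dense 1D zero-padded convolution operator (n x n) for kernel k.
conv_mat <- function(n, k) {
  hw <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - hw):(i + hw)
    ok <- j >= 1L & j <= n
    M[i, j[ok]] <- k[ok]
  }
  M
}

# Apply matrix M along the given axis of a 3D array.
apply_along_axis <- function(vol, axis, M) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  v <- matrix(v, nrow = d[axis])
  v <- M %*% v
  v <- array(v, dim = d[perm])
  aperm(v, order(perm))
}

#' Localized tissue average within a sphere (ANATICOR-style regressor)
#'
#' For each target voxel, the average time series over tissue-mask voxels
#' whose center-to-center distance is at most `radius` mm. Target voxels
#' with no tissue voxel in range receive the whole-mask average; their
#' linear indices are recorded in the `"fallback_voxels"` attribute.
#'
#' @param image a [bold_image].
#' @param tissue_mask 3D logical mask (e.g. white matter); must be non-empty.
#' @param radius sphere radius in mm (default 15).
#' @param target_mask 3D logical mask of voxels needing a regressor
#'   (default: every voxel in the grid).
#' @return frames x n_target matrix; columns follow linear index order of
#'   `target_mask`, with that index vector in attribute `"target_index"`.
#' @export
local_sphere_average <- function(image, tissue_mask, radius = 15,
                                 target_mask = NULL) {
  g <- grid_dim(image)
  tissue_mask <- as_mask(tissue_mask, g)
  if (!any(tissue_mask)) stop("empty tissue mask")
  if (is.null(target_mask)) target_mask <- array(TRUE, dim = g)
  target_mask <- as_mask(target_mask, g)
  tis_idx <- which(tissue_mask)
  tgt_idx <- which(target_mask)
  coord <- function(idx) {
    a <- arrayInd(idx, g)
    sweep(a, 2L, image$voxel_size, "*")
  }
  tis_xyz <- coord(tis_idx)
  tgt_xyz <- coord(tgt_idx)
  Xt <- mask_series(image, tissue_mask)          # frames x n_tissue
  global_mean <- rowMeans(Xt)
  out <- matrix(NA_real_, nrow = n_frames(image), ncol = length(tgt_idx))
  fallback <- integer(0)
  r2 <- radius^2
  for (j in seq_along(tgt_idx)) {
    d2 <- colSums((t(tis_xyz) - tgt_xyz[j, ])^2)
    sel <- d2 <= r2
    if (any(sel)) {
      out[, j] <- rowMeans(Xt[, sel, drop = FALSE])
    } else {
      out[, j] <- global_mean
      fallback <- c(fallback, tgt_idx[j])
    }
  }
  attr(out, "target_index") <- tgt_idx
  attr(out, "fallback_voxels") <- fallback
  out
}

#' aCompCor principal-component time series from a noise-tissue mask
#'
#' Voxel series inside the mask are detrended with a Legendre polynomial
#' baseline of order `poly_order` (which includes mean removal), then the top
#' principal-component time series of the detrended voxel ensemble are
#' returned, scaled to unit variance and ordered by explained variance.
#'
#' @param image a [bold_image].
#' @param mask 3D logical mask (e.g. combined ventricle + white matter).
#' @param n_components number of components (default 3; 0 gives an empty
#'   matrix).
#' @param poly_order detrending polynomial order applied before extraction
#'   (default 4).
#' @return frames x k matrix with attribute `"explained_variance"` (the
#'   eigenvalues); `k < n_components` with a warning when the detrended
#'   ensemble has lower rank.
#' @export
compcor_components <- function(image, mask, n_components = 3, poly_order = 4) {
  mask <- as_mask(mask, grid_dim(image))
  X <- mask_series(image, mask)
  nt <- nrow(X)
  if (ncol(X) < n_components)
    stop("mask voxel count must be >= n_components")
  if (n_components == 0)
    return(structure(matrix(numeric(0), nrow = nt, ncol = 0),
                     explained_variance = numeric(0)))
  P <- legendre_basis(nt, min(poly_order, nt - 1L))
  X <- stats::lm.fit(P, X)$residuals
  sv <- svd(X)
  ev <- sv$d^2 / (nt - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, rank)
  if (k < n_components)
    warning(sprintf("mask rank %d < requested %d components; returning %d",
                    rank, n_components, k))
  comp <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  comp <- sweep(comp, 2L, apply(comp, 2L, stats::sd), "/")
  colnames(comp) <- paste0("compcor", seq_len(k))
  structure(comp, explained_variance = ev[seq_len(k)])
}

#' Assemble the nuisance regression design
#'
#' Builds the full nuisance model: 6 motion parameters, the mean ventricle
#' series, the localized white-matter regressor (one conceptual column that
#' varies per voxel), precomputed physiological columns (e.g. 5 RVT + 8
#' Retroicor), aCompCor component series, a Legendre polynomial baseline of
#' order `poly_order`, and optionally a global gray-matter mean column.
#'
#' @param motion frames x 6 motion-parameter matrix, or `NULL`.
#' @param ventricle frames vector (mean ventricle series), or `NULL`.
#' @param local_wm frames x n_voxel matrix from [local_sphere_average()]
#'   (counted as one column in the design; substituted per voxel at fit
#'   time), or `NULL`.
#' @param compcor frames x k component matrix, or `NULL`.
#' @param physio frames x p matrix of precomputed physiological regressors,
#'   or `NULL`.
#' @param poly_order polynomial baseline order (default 4; order 0 is a
#'   single constant column).
#' @param global_mean frames vector (global gray-matter mean), or `NULL`.
#' @param n_frames frame count, required only if every input is `NULL`.
#' @return A `nuisance_design` object: list with `columns` (frames x R static
#'   matrix), `sources` (provenance tag per static column), `local_wm`
#'   (per-voxel matrix or `NULL`), `poly_order`.
#' @export
build_design <- function(motion = NULL, ventricle = NULL, local_wm = NULL,
                         compcor = NULL, physio = NULL, poly_order = 4,
                         global_mean = NULL, n_frames = NULL) {
  pieces <- list()
  sources <- character(0)
  add <- function(x, nm, src) {
    x <- as.matrix(x)
    colnames(x) <- if (ncol(x) == length(nm)) nm else
      paste0(nm, seq_len(ncol(x)))
    if (length(pieces) && nrow(x) != nrow(pieces[[1]]))
      stop("all design columns must share the same frame count")
    pieces[[length(pieces) + 1L]] <<- x
    sources <<- c(sources, rep(src, ncol(x)))
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L) stop("motion must have 6 columns")
    add(motion, c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z"),
        "motion")
  }
  if (!is.null(ventricle)) add(ventricle, "ventricle_mean", "ventricle_mean")
  if (!is.null(compcor) && NCOL(compcor) > 0)
    add(compcor, "compcor", "compcor")
  if (!is.null(physio)) add(physio, "physio", "physio")
  if (!is.null(global_mean)) add(global_mean, "global_mean", "global_mean")
  nt <- if (length(pieces)) nrow(pieces[[1]]) else
    if (!is.null(local_wm)) nrow(local_wm) else n_frames
  if (is.null(nt)) stop("cannot infer frame count; supply n_frames")
  if (poly_order < 0) stop("poly_order must be >= 0")
  add(legendre_basis(nt, poly_order), paste0("poly", 0:poly_order),
      "polynomial")
  columns <- do.call(cbind, pieces)
  if (nrow(columns) != nt)
    stop("all design columns must share the same frame count")
  if (!is.null(local_wm) && nrow(local_wm) != nt)
    stop("local_wm frame count does not match other columns")
  if (anyDuplicated(colnames(columns)))
    stop("duplicate column names in nuisance design")
  zero <- apply(columns, 2L, function(v) all(v == 0))
  if (any(zero))
    stop(sprintf("all-zero design column(s): %s",
                 paste(colnames(columns)[zero], collapse = ", ")))
  structure(list(columns = columns, sources = sources,
                 local_wm = local_wm, poly_order = poly_order),
            class = "nuisance_design")
}

#' Number of regressors in a nuisance design
#'
#' The per-voxel localized white-matter regressor counts as one column.
#' @param design a `nuisance_design`.
#' @return integer column count.
#' @export
design_ncol <- function(design) {
  ncol(design$columns) + as.integer(!is.null(design$local_wm))
}

#' @export
print.nuisance_design <- function(x, ...) {
  cat(sprintf("<nuisance_design> %d columns (%s)%s\n", design_ncol(x),
              paste(sprintf("%s:%d", names(table(x$sources)),
                            as.integer(table(x$sources))), collapse = ", "),
              if (!is.null(x$local_wm)) " + per-voxel local_wm" else ""))
  invisible(x)
}

#' Remove nuisance signal by voxelwise least squares
#'
#' Fits the nuisance design to every voxel's series by ordinary least squares
#' and subtracts the fitted series. When the design carries a per-voxel
#' localized white-matter regressor, the fit is exact block elimination: the
#' static columns are projected out of both the data and the local regressor,
#' then the residual local regressor is projected out voxel by voxel.
#' Rank-deficient static designs are handled through an SVD pseudo-inverse
#' with relative tolerance `1e-10`, and the dependent columns are reported.
#'
#' @param image a [bold_image].
#' @param design a `nuisance_design` from [build_design()]. If the design has
#'   a `local_wm` matrix its `"target_index"` attribute must cover every
#'   voxel to be cleaned (defaults from [local_sphere_average()] cover the
#'   whole grid).
#' @return a residualized [bold_image]; residuals are orthogonal to every
#'   design column (including the voxel's own local regressor).
#' @export
residualize <- function(image, design) {
  stopifnot(inherits(image, "bold_image"), inherits(design, "nuisance_design"))
  D <- design$columns
  nt <- n_frames(image)
  if (nrow(D) != nt) stop("design frame count does not match image")
  if (design_ncol(design) >= nt)
    stop("design has as many columns as frames; nothing identifiable remains")
  sv <- svd(D)
  keep <- sv$d > max(sv$d) * 1e-10
  if (!all(keep)) {
    qrD <- qr(D)
    dep <- colnames(D)[setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])]
    warning(sprintf(
      "rank-deficient design (rank %d of %d); dependent column(s): %s; fitting on pseudo-inverse basis",
      sum(keep), ncol(D), paste(dep, collapse = ", ")))
  }
  U <- sv$u[, keep, drop = FALSE]
  proj_resid <- function(Y) Y - U %*% crossprod(U, Y)

  g <- grid_dim(image)
  flat <- matrix(image$values, nrow = prod(g), ncol = nt)
  Y <- t(flat)                       # frames x all voxels
  R <- proj_resid(Y)
  if (!is.null(design$local_wm)) {
    tgt <- attr(design$local_wm, "target_index") %||% seq_len(prod(g))
    Lr <- proj_resid(design$local_wm)
    nrm2 <- colSums(Lr^2)
    ok <- nrm2 > max(nrm2, 0) * 1e-20 & nrm2 > 0
    beta <- ifelse(ok, colSums(Lr * R[, tgt, drop = FALSE]) / nrm2, 0)
    R[, tgt] <- R[, tgt, drop = FALSE] - sweep(Lr, 2L, beta, "*")
  }
  out <- array(t(R), dim = c(g, nt))
  bold_image(out, voxel_size = image$voxel_size, tr = image$tr)
}
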