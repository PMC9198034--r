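#' Construct a BOLD image
#'
#' A `bold_image` is the package's in-memory container for one subject's 4D
#' resting-state acquisition: an x-y-z-frame lattice of signal values plus the
#' grid geometry (voxel size in mm) and the repetition time.
#'
#' @param values 4D numeric array, dimensions `(x, y, z, frame)`.
#' @param voxel_size numeric length-3, mm per axis.
#' @param tr repetition time in seconds.
#' @return An object of class `bold_image`.
#' @export
bold_image <- function(values, voxel_size = c(3, 3, 3), tr = 2.5) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("`values` must be a 4D array (x, y, z, frame)")
  if (dim(values)[4] < 2L)
    stop("a bold_image needs at least 2 frames")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive mm values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 tr = as.numeric(tr)),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bold_image> %d x %d x %d voxels, %d frames, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size), collapse = " x "), x$tr))
  invisible(x)
}

#' @export
dim.bold_image <- function(x) dim(x$values)

n_frames <- function(image) dim(image$values)[4]

grid_dim <- function(image) dim(image$values)[1:3]

#' Construct a network parcellation
#'
#' Integer network label per voxel on the analysis grid; 0 marks background
#' (voxels outside every network).
#'
#' @param labels 3D integer array of labels in `0:L`.
#' @param n_networks number of networks `L`; defaults to `max(labels)`.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, n_networks = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  lab <- as.integer(labels)
  if (any(is.na(lab)) || any(lab < 0L))
    stop("labels must be non-negative integers (0 = background)")
  storage.mode(labels) <- "integer"
  L <- if (is.null(n_networks)) max(lab) else as.integer(n_networks)
  if (max(lab) > L) stop("labels exceed declared number of networks")
  structure(list(labels = labels, n_networks = L), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s grid, %d networks, %d labeled voxels\n",
              paste(dim(x$labels), collapse = " x "), x$n_networks,
              sum(x$labels > 0L)))
  invisible(x)
}

# Extract the frames x voxels matrix of series inside a logical mask.
# Voxel order follows R's linear (column-major) array order.
mask_series <- function(image, mask) {
  stopifnot(inherits(image, "bold_image"))
  mask <- as_mask(mask, grid_dim(image))
  nt <- n_frames(image)
  flat <- matrix(image$values, nrow = prod(grid_dim(image)), ncol = nt)
  t(flat[which(mask), , drop = FALSE])
}

# Coerce a mask (logical/0-1 array) to logical and check its grid.
as_mask <- function(mask, grid) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (!all(dim(mask) == grid))
    stop(sprintf("mask grid %s does not match image grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(grid, collapse = "x")))
  array(as.logical(mask), dim = dim(mask))
}
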