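# File formats: NIfTI-1 for volumes/labels (via RNifti), whitespace-delimited
# text for motion tables, TSV for all other tables, JSON for results and
# sidecars.

#' Write a BOLD image as 4D NIfTI-1
#'
#' @param image a [bold_image].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(image, path) {
  stopifnot(inherits(image, "bold_image"))
  img <- RNifti::asNifti(image$values)
  RNifti::pixdim(img) <- c(image$voxel_size, image$tr)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI-1 file as a BOLD image
#'
#' @param path NIfTI file.
#' @param tr repetition time override; default taken from the header.
#' @return a [bold_image].
#' @export
read_bold_nifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti_attrs(as.array(img))
  if (length(dim(arr)) != 4L)
    stop(sprintf("%s is not a 4D image", path))
  pd <- RNifti::pixdim(img)
  bold_image(arr, voxel_size = pd[1:3],
             tr = tr %||% (if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1))
}

#' Write a 3D volume (mask, labels, or statistic map) as NIfTI-1
#'
#' @param vol 3D array (logical masks are written as 0/1 integers).
#' @param path output file.
#' @param voxel_size mm per axis (default `c(3, 3, 3)`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(3, 3, 3)) {
  if (inherits(vol, "parcellation")) vol <- vol$labels
  if (is.logical(vol)) {
    vol <- array(as.integer(vol), dim = dim(vol))
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path NIfTI file.
#' @param as `"array"` (default), `"mask"` (logical, non-zero = TRUE) or
#'   `"parcellation"`.
#' @return 3D array, logical array, or [parcellation].
#' @export
read_volume_nifti <- function(path, as = c("array", "mask", "parcellation")) {
  as <- match.arg(as)
  arr <- strip_nifti_attrs(as.array(RNifti::readNifti(path)))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L) stop(sprintf("%s is not a 3D volume", path))
  switch(as,
         array = arr,
         mask = array(arr != 0, dim = dim(arr)),
         parcellation = parcellation(array(as.integer(round(arr)),
                                           dim = dim(arr))))
}

#' Write a motion-parameter table (whitespace-delimited, 6 columns per frame)
#'
#' @param params frames x 6 matrix.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_motion_table <- function(params, path) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion table must have 6 columns")
  utils::write.table(format(params, digits = 10, trim = TRUE, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a motion-parameter table
#'
#' @param path whitespace-delimited text, 6 columns per frame, no header.
#' @return frames x 6 numeric matrix (columns `trans_x..rot_z`).
#' @export
read_motion_table <- function(path) {
  tab <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(tab) != 6L)
    stop(sprintf("%s: expected 6 motion columns, found %d", path, ncol(tab)))
  colnames(tab) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  tab
}

#' Read and validate a phenotype table
#'
#' Tab-separated with a header; requires `subject_id` and `group` columns.
#' Duplicate subject ids and unknown group labels are rejected; extra columns
#' are preserved with a warning. Numeric columns use `"NA"` as the missing
#' token.
#'
#' @param path phenotype TSV.
#' @param group_levels optional character(2) of allowed group labels; default
#'   the two labels found (there must be exactly two).
#' @return validated data.frame with `group` as a 2-level factor.
#' @export
read_phenotype <- function(path, group_levels = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  req <- c("subject_id", "group")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("phenotype table %s lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids in phenotype table")
  if (is.null(group_levels)) {
    group_levels <- sort(unique(df$group))
    if (length(group_levels) != 2L)
      stop(sprintf("expected exactly 2 group labels, found: %s",
                   paste(group_levels, collapse = ", ")))
  } else if (!all(df$group %in% group_levels)) {
    stop(sprintf("unknown group label(s): %s",
                 paste(setdiff(df$group, group_levels), collapse = ", ")))
  }
  df$group <- factor(df$group, levels = group_levels)
  extra <- setdiff(names(df), c(req, "behavior", "fd_true", "sex", "age"))
  if (length(extra))
    warning(sprintf("unrecognized phenotype column(s) preserved: %s",
                    paste(extra, collapse = ", ")))
  df
}

#' Write a synthetic cohort to disk in the pipeline's input layout
#'
#' Creates `bold/<id>.nii.gz`, `motion/<id>.txt`, mask and parcellation
#' NIfTIs, `phenotype.tsv`, and `cohort.json` (the full spec plus the
#' behavior weight vector `w`) under `dir`.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (d in file.path(dir, c("bold", "motion")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  vx <- cohort$subjects[[1]]$bold$voxel_size
  for (s in cohort$subjects) {
    write_bold_nifti(s$bold, file.path(dir, "bold",
                                       paste0(s$subject_id, ".nii.gz")))
    write_motion_table(s$motion, file.path(dir, "motion",
                                           paste0(s$subject_id, ".txt")))
  }
  write_volume_nifti(cohort$masks$gm, file.path(dir, "gm_mask.nii.gz"), vx)
  write_volume_nifti(cohort$masks$wm, file.path(dir, "wm_mask.nii.gz"), vx)
  write_volume_nifti(cohort$masks$ventricle,
                     file.path(dir, "vent_mask.nii.gz"), vx)
  write_volume_nifti(cohort$parcellation,
                     file.path(dir, "parcellation.nii.gz"), vx)
  write_tsv(cohort$phenotype, file.path(dir, "phenotype.tsv"))
  spec <- cohort$spec
  spec$latent_corr <- NULL
  jsonlite::write_json(c(unclass(spec), list(w = cohort$behavior_weights)),
                       file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Drop RNifti's header attributes, keeping a plain R array.
strip_nifti_attrs <- function(arr) {
  array(as.vector(arr), dim = dim(arr))
}

# Tab-delimited writer used for every tabular artifact ('.' decimal, UTF-8,
# no quoting) so reruns are byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
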