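#' Pipeline configuration
#'
#' Collects the paths, thresholds, nuisance options and prediction settings
#' for [run_pipeline()]. Defaults mirror the analysis conventions of the rest
#' of the package: FD exclusion at 0.30 mm/TR, dual voxel threshold
#' `p < 1e-4` and `q < 0.05`, 10-voxel minimum cluster extent, ridge K = 5
#' with 10,000 permutations.
#'
#' @param input_dir directory holding `bold/<id>.nii.gz`, `motion/<id>.txt`,
#'   `gm_mask.nii.gz`, `wm_mask.nii.gz`, `vent_mask.nii.gz`,
#'   `parcellation.nii.gz`, `phenotype.tsv` (the layout of [write_cohort()]).
#' @param output_dir where stage outputs and sidecars are written.
#' @param fd_exclude motion-exclusion threshold, mm/TR.
#' @param p_thresh,q_thresh,min_cluster ROI-definition thresholds.
#' @param adjacency cluster connectivity (6, 18 or 26).
#' @param poly_order nuisance polynomial order.
#' @param include_global_mean add a global gray-matter mean regressor.
#' @param smooth_fwhm spatial smoothing FWHM in mm (0 disables).
#' @param local_wm_radius radius of the localized white-matter sphere, mm.
#' @param n_compcor number of aCompCor components.
#' @param K,B,predict_group ridge penalty, permutation count, and the group
#'   whose subjects enter the behavior prediction (`NULL` = all retained).
#' @param seed integer seed for stochastic stages.
#' @return a validated `pipeline_config` (list).
#' @export
pipeline_config <- function(input_dir, output_dir,
                            fd_exclude = 0.30,
                            p_thresh = 1e-4, q_thresh = 0.05,
                            min_cluster = 10, adjacency = 6,
                            poly_order = 4, include_global_mean = FALSE,
                            smooth_fwhm = 0, local_wm_radius = 15,
                            n_compcor = 3,
                            K = 5, B = 10000, predict_group = NULL,
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              fd_exclude = fd_exclude, p_thresh = p_thresh,
              q_thresh = q_thresh, min_cluster = min_cluster,
              adjacency = adjacency, poly_order = poly_order,
              include_global_mean = include_global_mean,
              smooth_fwhm = smooth_fwhm,
              local_wm_radius = local_wm_radius, n_compcor = n_compcor,
              K = K, B = B, predict_group = predict_group,
              seed = as.integer(seed))
  if (!(p_thresh > 0 && p_thresh <= 1) || !(q_thresh > 0 && q_thresh <= 1))
    stop("p_thresh and q_thresh must lie in (0, 1]")
  if (fd_exclude <= 0) stop("fd_exclude must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Hash of the semantically meaningful configuration fields
#'
#' @param config a `pipeline_config`.
#' @return 8-hex-digit string; changes iff any field value changes.
#' @export
config_hash <- function(config) {
  flat <- unclass(config)
  flat <- flat[order(names(flat))]
  fnv1a_hash(paste(names(flat),
                   vapply(flat, function(v)
                     paste(format(v, digits = 15), collapse = ","),
                     character(1)),
                   sep = "=", collapse = ";"))
}

PIPELINE_STAGES <- c("qc", "nuisance", "connectedness", "groupmap", "rois",
                     "roimatrix", "selectivity", "predict")

#' Run the connectivity analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`qc -> nuisance -> connectedness -> groupmap -> rois -> roimatrix ->
#' selectivity -> predict`) against the input layout described in
#' [pipeline_config()]. Every stage writes its tabular/volume outputs plus a
#' JSON sidecar carrying the config hash, the seed, and stage counts.
#' Rerunning with the same config and inputs reproduces the outputs exactly.
#'
#' Stages consume in-memory results of earlier stages run in the same call;
#' a stage whose upstream was neither run nor found on disk stops with a
#' message naming the absent stage.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of the stage names (default: all).
#' @return list (run manifest): per-stage output paths and key counts.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$manifest <- list(config_hash = config_hash(config))
  load_inputs(st, config)
  for (stage in stages) {
    switch(stage,
           qc = stage_qc(st, config),
           nuisance = stage_nuisance(st, config),
           connectedness = stage_connectedness(st, config),
           groupmap = stage_groupmap(st, config),
           rois = stage_rois(st, config),
           roimatrix = stage_roimatrix(st, config),
           selectivity = stage_selectivity(st, config),
           predict = stage_predict(st, config))
  }
  st$manifest
}

load_inputs <- function(st, config) {
  ind <- config$input_dir
  needed <- c("gm_mask.nii.gz", "wm_mask.nii.gz", "vent_mask.nii.gz",
              "parcellation.nii.gz", "phenotype.tsv")
  missing <- needed[!file.exists(file.path(ind, needed))]
  if (length(missing))
    stop(sprintf("input directory %s lacks: %s", ind,
                 paste(missing, collapse = ", ")))
  st$phenotype <- read_phenotype(file.path(ind, "phenotype.tsv"))
  st$gm <- read_volume_nifti(file.path(ind, "gm_mask.nii.gz"), as = "mask")
  st$wm <- read_volume_nifti(file.path(ind, "wm_mask.nii.gz"), as = "mask")
  st$vent <- read_volume_nifti(file.path(ind, "vent_mask.nii.gz"),
                               as = "mask")
  st$parc <- read_volume_nifti(file.path(ind, "parcellation.nii.gz"),
                               as = "parcellation")
  grids <- list(gm = dim(st$gm), wm = dim(st$wm), vent = dim(st$vent),
                parc = dim(st$parc$labels))
  if (length(unique(vapply(grids, paste, "", collapse = "x"))) != 1L)
    stop("mask/parcellation grids do not match")
  st$ids <- st$phenotype$subject_id
  bolds <- file.path(ind, "bold", paste0(st$ids, ".nii.gz"))
  motions <- file.path(ind, "motion", paste0(st$ids, ".txt"))
  absent <- st$ids[!file.exists(bolds) | !file.exists(motions)]
  if (length(absent))
    stop(sprintf("missing bold/motion inputs for: %s",
                 paste(absent, collapse = ", ")))
  st$bold_paths <- stats::setNames(bolds, st$ids)
  st$motion_paths <- stats::setNames(motions, st$ids)
}

sidecar <- function(st, config, stage, extra = list()) {
  path <- file.path(config$output_dir, paste0(stage, "_sidecar.json"))
  jsonlite::write_json(c(list(stage = stage,
                              config_hash = config_hash(config),
                              seed = config$seed), extra),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

require_stage <- function(st, what, stage) {
  if (is.null(st[[what]]))
    stop(sprintf("stage '%s' requires output of stage '%s'; run it first (or include it in `stages`)",
                 stage, what_stage(what)))
  st[[what]]
}

what_stage <- function(what) {
  c(qc = "qc", images = "nuisance", conn_maps = "connectedness",
    statmap = "groupmap", rois = "rois", roi_mats = "roimatrix",
    selectivity = "selectivity")[[what]]
}

stage_qc <- function(st, config) {
  fd <- vapply(st$motion_paths, function(p) compute_fd(read_motion_table(p)),
               numeric(1))
  qc <- data.frame(subject_id = st$ids, fd = as.numeric(fd),
                   stringsAsFactors = FALSE)
  part <- exclude_by_motion(qc, threshold = config$fd_exclude)
  qc$excluded_flag <- as.integer(qc$subject_id %in% part$excluded$subject_id)
  write_tsv(qc, file.path(config$output_dir, "qc.tsv"))
  st$qc <- qc
  st$retained <- part$retained$subject_id
  sidecar(st, config, "qc",
          list(n_subjects = nrow(qc), n_excluded = nrow(part$excluded),
               fd_threshold = config$fd_exclude))
  st$manifest$qc <- list(path = file.path(config$output_dir, "qc.tsv"),
                         n_retained = length(st$retained),
                         n_excluded = nrow(part$excluded))
  invisible(st)
}

# load (possibly smoothed + residualized) images for the retained subjects
stage_nuisance <- function(st, config) {
  qc <- require_stage(st, "qc", "nuisance")
  outdir <- file.path(config$output_dir, "residual")
  dir.create(outdir, showWarnings = FALSE)
  noise_mask <- st$wm | st$vent
  st$images <- list()
  for (id in st$retained) {
    img <- read_bold_nifti(st$bold_paths[[id]])
    if (!all(dim(img$values)[1:3] == dim(st$gm)))
      stop(sprintf("grid mismatch between %s and the masks", id))
    # ventricle mean extracted pre-smoothing
    vent_series <- roi_timeseries(img, st$vent)
    if (config$smooth_fwhm > 0)
      img <- smooth_gaussian(img, fwhm = config$smooth_fwhm)
    lwm <- local_sphere_average(img, st$wm, radius = config$local_wm_radius,
                                target_mask = array(TRUE, dim = dim(st$gm)))
    cc <- compcor_components(img, noise_mask, n_components = config$n_compcor,
                             poly_order = config$poly_order)
    gmean <- if (config$include_global_mean)
      roi_timeseries(img, st$gm) else NULL
    design <- build_design(motion = read_motion_table(st$motion_paths[[id]]),
                           ventricle = vent_series, local_wm = lwm,
                           compcor = cc, poly_order = config$poly_order,
                           global_mean = gmean)
    res <- residualize(img, design)
    write_bold_nifti(res, file.path(outdir, paste0(id, ".nii.gz")))
    st$images[[id]] <- res
  }
  sidecar(st, config, "nuisance",
          list(n_subjects = length(st$retained),
               n_design_columns = design_ncol(design),
               poly_order = config$poly_order,
               smooth_fwhm = config$smooth_fwhm))
  st$manifest$nuisance <- list(path = outdir,
                               n_design_columns = design_ncol(design))
  invisible(st)
}

stage_connectedness <- function(st, config) {
  images <- require_stage(st, "images", "connectedness")
  outdir <- file.path(config$output_dir, "connectedness")
  dir.create(outdir, showWarnings = FALSE)
  st$conn_maps <- lapply(st$retained, function(id) {
    cm <- connectedness_map(images[[id]], st$gm, subject_id = id)
    vol <- cm$z
    vol[is.na(vol)] <- 0
    write_volume_nifti(vol, file.path(outdir, paste0(id, ".nii.gz")),
                       images[[id]]$voxel_size)
    cm
  })
  names(st$conn_maps) <- st$retained
  sidecar(st, config, "connectedness",
          list(n_subjects = length(st$conn_maps),
               n_gm_voxels = st$conn_maps[[1]]$n_voxels,
               n_clipped = sum(vapply(st$conn_maps, `[[`, 0, "n_clipped"))))
  st$manifest$connectedness <- list(path = outdir)
  invisible(st)
}

stage_groupmap <- function(st, config) {
  maps <- require_stage(st, "conn_maps", "groupmap")
  qc <- require_stage(st, "qc", "groupmap")
  keep <- match(st$retained, st$phenotype$subject_id)
  group <- st$phenotype$group[keep]
  fd <- qc$fd[match(st$retained, qc$subject_id)]
  st$statmap <- voxelwise_group_glm(unname(maps), group, covariate = fd)
  vx <- if (!is.null(st$images)) st$images[[1]]$voxel_size else c(3, 3, 3)
  for (nm in c("t", "p", "q")) {
    vol <- st$statmap[[paste0(nm, "_vol")]]
    vol[is.na(vol)] <- if (nm == "t") 0 else 1
    write_volume_nifti(vol, file.path(config$output_dir,
                                      paste0("groupmap_", nm, ".nii.gz")), vx)
  }
  sidecar(st, config, "groupmap",
          list(df = st$statmap$df, model = st$statmap$model,
               n_subjects = length(st$retained)))
  st$manifest$groupmap <- list(df = st$statmap$df, model = st$statmap$model)
  invisible(st)
}

stage_rois <- function(st, config) {
  statmap <- require_stage(st, "statmap", "rois")
  st$rois <- define_rois(statmap, p_thresh = config$p_thresh,
                         q_thresh = config$q_thresh,
                         min_size = config$min_cluster,
                         adjacency = config$adjacency, parc = st$parc)
  write_tsv(st$rois$table, file.path(config$output_dir, "rois.tsv"))
  write_volume_nifti(st$rois$labels,
                     file.path(config$output_dir, "roi_labels.nii.gz"))
  sidecar(st, config, "rois",
          list(n_rois = nrow(st$rois$table),
               n_suprathreshold = st$rois$n_suprathreshold,
               p_thresh = config$p_thresh, q_thresh = config$q_thresh,
               min_cluster = config$min_cluster))
  st$manifest$rois <- list(n_rois = nrow(st$rois$table),
                           path = file.path(config$output_dir, "rois.tsv"))
  invisible(st)
}

stage_roimatrix <- function(st, config) {
  images <- require_stage(st, "images", "roimatrix")
  rois <- require_stage(st, "rois", "roimatrix")
  if (nrow(rois$table) < 2L)
    stop("roimatrix requires >= 2 ROIs from the 'rois' stage")
  st$roi_mats <- lapply(st$retained, function(id)
    roi_matrix(images[[id]], rois$labels))
  names(st$roi_mats) <- st$retained
  long <- do.call(rbind, lapply(st$retained, function(id) {
    v <- roi_pairs_vector(st$roi_mats[[id]])
    ab <- do.call(rbind, strsplit(names(v), "|", fixed = TRUE))
    data.frame(subject_id = id, roi_a = ab[, 1], roi_b = ab[, 2], z = v,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  write_tsv(long, file.path(config$output_dir, "roi_pairs.tsv"))
  sidecar(st, config, "roimatrix",
          list(n_rois = nrow(rois$table),
               n_pairs = nrow(rois$table) * (nrow(rois$table) - 1) / 2))
  st$manifest$roimatrix <- list(path = file.path(config$output_dir,
                                                 "roi_pairs.tsv"))
  invisible(st)
}

stage_selectivity <- function(st, config) {
  images <- require_stage(st, "images", "selectivity")
  qc <- require_stage(st, "qc", "selectivity")
  recs <- do.call(rbind, lapply(st$retained, function(id)
    network_connectivity(images[[id]], st$parc,
                         fd = qc$fd[qc$subject_id == id], subject_id = id)))
  write_tsv(recs, file.path(config$output_dir, "selectivity.tsv"))
  st$selectivity <- recs
  keep <- match(st$retained, st$phenotype$subject_id)
  anc <- ancova(recs$selectivity, st$phenotype$group[keep], recs$fd)
  jsonlite::write_json(
    list(F = as.list(anc$F), p = as.list(anc$p), df = anc$df,
         adjusted_means = as.list(anc$adjusted_means)),
    file.path(config$output_dir, "selectivity_ancova.json"),
    auto_unbox = TRUE, digits = NA)
  sidecar(st, config, "selectivity",
          list(n_subjects = nrow(recs),
               mean_selectivity = mean(recs$selectivity)))
  st$manifest$selectivity <- list(
    path = file.path(config$output_dir, "selectivity.tsv"),
    ancova_F_group = unname(anc$F["group"]))
  invisible(st)
}

stage_predict <- function(st, config) {
  mats <- require_stage(st, "roi_mats", "predict")
  keep <- st$retained
  if (!is.null(config$predict_group)) {
    grp <- st$phenotype$group[match(keep, st$phenotype$subject_id)]
    keep <- keep[grp == config$predict_group]
  }
  beh <- st$phenotype$behavior[match(keep, st$phenotype$subject_id)]
  if (is.null(beh) || all(is.na(beh)))
    stop("phenotype table has no usable 'behavior' column")
  ok <- !is.na(beh)
  features <- do.call(rbind, lapply(mats[keep[ok]], roi_pairs_vector))
  scores <- pca_reduce(features)
  out <- permutation_test(scores, beh[ok], K = config$K, B = config$B,
                          seed = config$seed)
  jsonlite::write_json(
    list(r_obs = out$r_obs, p_perm = out$p_perm, K = out$K, B = out$B,
         seed = config$seed, n_components = out$n_components,
         n_subjects = sum(ok)),
    file.path(config$output_dir, "prediction.json"),
    auto_unbox = TRUE, digits = NA)
  write_tsv(data.frame(subject_id = keep[ok], observed = out$observed,
                       predicted = out$predicted),
            file.path(config$output_dir, "prediction_pairs.tsv"))
  st$prediction <- out
  sidecar(st, config, "predict",
          list(r_obs = out$r_obs, p_perm = out$p_perm, B = out$B, K = out$K))
  st$manifest$predict <- list(r_obs = out$r_obs, p_perm = out$p_perm)
  invisible(st)
}
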