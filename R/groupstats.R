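#' Two-sample t test from summary statistics or raw vectors
#'
#' Pooled-variance Student t with `df = n_a + n_b - 2` (default), or the
#' Welch unequal-variance variant with Satterthwaite df. Accepts either the
#' printed summaries (means, SDs, ns) or raw vectors `x` and `y` (summaries
#' are computed first).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`sd >= 0`,
#'   `n >= 2`, SDs not both zero).
#' @param x,y alternatively, raw value vectors for the two groups.
#' @param var_equal `TRUE` (default) for the pooled test, `FALSE` for Welch.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(mean_a = NULL, sd_a = NULL, n_a = NULL,
                         mean_b = NULL, sd_b = NULL, n_b = NULL,
                         x = NULL, y = NULL, var_equal = TRUE) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    mean_a <- mean(x); sd_a <- stats::sd(x); n_a <- length(x)
    mean_b <- mean(y); sd_b <- stats::sd(y); n_b <- length(y)
  }
  if (n_a < 2 || n_b < 2) stop("both groups need n >= 2")
  if (sd_a < 0 || sd_b < 0) stop("SDs must be non-negative")
  if (sd_a == 0 && sd_b == 0) stop("zero variance in both groups")
  va <- sd_a^2; vb <- sd_b^2
  if (var_equal) {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / df
    if (sp2 <= 0) stop("zero pooled variance")
    tt <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    se2 <- va / n_a + vb / n_b
    tt <- (mean_a - mean_b) / sqrt(se2)
    df <- se2^2 / ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values `q_(i) = min_{j >= i} (m p_(j) / j)`, capped at
#' 1, mapped back to the input order. Delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return adjusted q values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Voxelwise group comparison with a motion covariate
#'
#' Per voxel, least-squares fit of
#' `value ~ intercept + group_indicator + covariate`; the reported statistic
#' is the group coefficient's t on `n - 3` df (or `n - 2` when no covariate
#' is supplied), with two-sided p and BH-FDR q across voxels.
#'
#' @param maps subjects x voxels numeric matrix (e.g. stacked connectedness
#'   z values), or a list of `connectedness_map` objects sharing one mask.
#' @param group factor/character with exactly 2 levels, or logical; the
#'   reported contrast is level 2 minus level 1 (alphabetical for character).
#' @param covariate optional numeric per-subject covariate (e.g. mean FD);
#'   must vary across subjects.
#' @return A `group_stat_map` object: list with per-voxel `t`, `p`, `q`
#'   vectors, `df`, `model` description, and (for map input) `mask` plus 3D
#'   `t_vol`/`p_vol`/`q_vol` arrays.
#' @export
voxelwise_group_glm <- function(maps, group, covariate = NULL) {
  mask <- NULL
  if (is.list(maps) && inherits(maps[[1]], "connectedness_map")) {
    mask <- maps[[1]]$mask
    Y <- t(vapply(maps, function(m) m$z[which(mask)], numeric(sum(mask))))
  } else {
    Y <- as.matrix(maps)
  }
  fit <- group_glm_fit(Y, group, covariate)
  vols <- NULL
  if (!is.null(mask)) {
    as_vol <- function(v) {
      a <- array(NA_real_, dim = dim(mask)); a[which(mask)] <- v; a
    }
    vols <- list(t_vol = as_vol(fit$t), p_vol = as_vol(fit$p),
                 q_vol = as_vol(fit$q))
  }
  structure(c(fit, list(mask = mask), vols), class = "group_stat_map")
}

# Shared GLM core: group coefficient t/p/q per column of Y.
group_glm_fit <- function(Y, group, covariate = NULL) {
  n <- nrow(Y)
  gind <- group_indicator(group)
  if (sum(gind) < 3 || sum(!gind) < 3)
    warning("fewer than 3 subjects in a group; inference is fragile")
  X <- cbind(intercept = 1, group = as.numeric(gind))
  model <- "value ~ 1 + group"
  if (!is.null(covariate)) {
    if (stats::sd(covariate) == 0)
      stop("covariate is constant; drop it instead")
    X <- cbind(X, covariate = covariate)
    model <- "value ~ 1 + group + covariate"
    if (kappa(crossprod(X)) > 1e8)
      stop("covariate is (near-)collinear with the group indicator; condition number exceeds 1e8")
  }
  df <- n - ncol(X)
  if (df < 1) stop("not enough subjects for the model")
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi["group", "group"])
  tt <- as.vector(B["group", ]) / se
  # an (essentially) perfect fit has no group effect to test: t = 0
  degenerate <- sigma2 <= 1e-20 * pmax(colMeans(Y^2), .Machine$double.xmin)
  tt[degenerate | se == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, p = p, q = bh_fdr(p), df = df, model = model)
}

group_indicator <- function(group) {
  if (is.logical(group)) return(group)
  f <- factor(group)
  if (nlevels(f) != 2L) stop("group must have exactly 2 levels")
  f == levels(f)[2L]
}

#' Define ROIs from a thresholded statistical map
#'
#' Voxels passing the dual threshold (`p < p_thresh` and `q < q_thresh`) are
#' grouped into connected components under the chosen adjacency; components
#' with at least `min_size` voxels (inclusive) become ROIs, ordered by
#' descending `|peak t|`. Each ROI records its size (voxels and mm^3), peak
#' voxel (max `|t|`), the sign of the group difference at the peak, and a
#' majority-vote network tag when a parcellation is supplied.
#'
#' @param statmap a `group_stat_map` with volumes (from map input), or a list
#'   with 3D arrays `t_vol`, `p_vol`, `q_vol`.
#' @param p_thresh,q_thresh dual significance thresholds (defaults `1e-4`,
#'   `0.05`).
#' @param min_size minimum cluster extent in voxels, inclusive (default 10).
#' @param adjacency 6 (faces, default), 18 (faces + edges) or 26 (full cube).
#' @param parc optional [parcellation] for the network tag.
#' @param voxel_size mm per axis, for the mm^3 size (default `c(3, 3, 3)`).
#' @return An `roi_set`: list with `table` (one row per ROI: `roi`, `size`,
#'   `size_mm3`, `peak_x/y/z` 0-based voxel coordinates, `peak_t`, `sign`,
#'   `network`) and `labels` (3D integer array, 0 outside ROIs). No
#'   suprathreshold voxels yields an empty (0-row) ROI set.
#' @export
define_rois <- function(statmap, p_thresh = 1e-4, q_thresh = 0.05,
                        min_size = 10, adjacency = 6, parc = NULL,
                        voxel_size = c(3, 3, 3)) {
  tv <- statmap$t_vol; pv <- statmap$p_vol; qv <- statmap$q_vol
  if (is.null(tv)) stop("statmap must carry t/p/q volumes")
  supra <- !is.na(pv) & !is.na(qv) & pv < p_thresh & qv < q_thresh
  comp <- label_components(supra, adjacency)
  labels <- array(0L, dim = dim(supra))
  rows <- list()
  kept <- 0L
  sizes <- tabulate(comp$labels[comp$labels > 0L])
  order_ids <- which(sizes >= min_size)
  if (length(order_ids)) {
    peak_t <- vapply(order_ids, function(k)
      max(abs(tv[comp$labels == k])), numeric(1))
    order_ids <- order_ids[order(peak_t, decreasing = TRUE)]
    for (k in order_ids) {
      kept <- kept + 1L
      vox <- which(comp$labels == k)
      labels[vox] <- kept
      pk <- vox[which.max(abs(tv[vox]))]
      pk_ijk <- arrayInd(pk, dim(supra))
      net <- NA_integer_
      if (!is.null(parc)) {
        labs <- parc$labels[vox]
        labs <- labs[labs > 0L]
        net <- if (length(labs))
          as.integer(names(which.max(table(labs)))) else NA_integer_
      }
      rows[[kept]] <- data.frame(
        roi = kept, size = length(vox),
        size_mm3 = length(vox) * prod(voxel_size),
        peak_x = pk_ijk[1] - 1L, peak_y = pk_ijk[2] - 1L,
        peak_z = pk_ijk[3] - 1L,
        peak_t = tv[pk], sign = sign(tv[pk]), network = net)
    }
  }
  table <- if (kept) do.call(rbind, rows) else
    data.frame(roi = integer(0), size = integer(0), size_mm3 = numeric(0),
               peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
               peak_t = numeric(0), sign = numeric(0), network = integer(0))
  structure(list(table = table, labels = labels,
                 n_suprathreshold = sum(supra)), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs (%d suprathreshold voxels)\n",
              nrow(x$table), x$n_suprathreshold))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

# Connected-component labeling of a 3D logical array by breadth-first
# search over 6/18/26-neighbor offsets.
label_components <- function(mask, adjacency = 6) {
  stopifnot(adjacency %in% c(6, 18, 26))
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nn <- rowSums(abs(offs))
  offs <- switch(as.character(adjacency),
                 "6" = offs[nn == 1, , drop = FALSE],
                 "18" = offs[nn >= 1 & nn <= 2, , drop = FALSE],
                 "26" = offs[nn >= 1, , drop = FALSE])
  labels <- array(0L, dim = d)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      nb <- sweep(offs, 2L, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- cur
      queue <- c(queue, lin)
    }
  }
  list(labels = labels, n = cur)
}

#' Group tests on every ROI pair
#'
#' For each unordered ROI pair, the same GLM as [voxelwise_group_glm()] on
#' the subjects' Fisher-z values for that pair, with one BH-FDR family across
#' all `n(n-1)/2` pairs. Subjects missing a pair's value are dropped for that
#' pair with a warning.
#'
#' @param matrices list of `roi_connectivity` objects (one per subject, same
#'   ROI set) or a 3D array `n_roi x n_roi x n_subjects`.
#' @param group 2-level group labels per subject.
#' @param covariate optional per-subject covariate (e.g. mean FD).
#' @return list with `pairs` (long data.frame: `roi_a`, `roi_b`, `t`, `p`,
#'   `q`, `n`), and square `t_matrix`, `q_matrix`, `sig_matrix`
#'   (`q < 0.05`).
#' @export
roi_pair_group_tests <- function(matrices, group, covariate = NULL) {
  if (is.list(matrices)) {
    ids <- matrices[[1]]$roi_ids
    arr <- vapply(matrices, function(m) {
      stopifnot(identical(m$roi_ids, ids))
      m$z
    }, matrix(0, length(ids), length(ids)))
  } else {
    arr <- matrices
    ids <- dimnames(arr)[[1]] %||% paste0("roi", seq_len(dim(arr)[1]))
  }
  nr <- dim(arr)[1]
  pair_idx <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
  res <- vector("list", nrow(pair_idx))
  for (k in seq_len(nrow(pair_idx))) {
    a <- pair_idx[k, 1]; b <- pair_idx[k, 2]
    y <- arr[a, b, ]
    ok <- !is.na(y)
    if (!all(ok))
      warning(sprintf("pair %s-%s: %d subject(s) missing, dropped",
                      ids[a], ids[b], sum(!ok)))
    fit <- group_glm_fit(matrix(y[ok], ncol = 1), group[ok],
                         if (is.null(covariate)) NULL else covariate[ok])
    res[[k]] <- data.frame(roi_a = ids[a], roi_b = ids[b],
                           t = fit$t, p = fit$p, n = sum(ok))
  }
  pairs <- do.call(rbind, res)
  pairs$q <- bh_fdr(pairs$p)
  tm <- qm <- matrix(NA_real_, nr, nr, dimnames = list(ids, ids))
  for (k in seq_len(nrow(pair_idx))) {
    a <- pair_idx[k, 1]; b <- pair_idx[k, 2]
    tm[a, b] <- tm[b, a] <- pairs$t[k]
    qm[a, b] <- qm[b, a] <- pairs$q[k]
  }
  list(pairs = pairs[, c("roi_a", "roi_b", "t", "p", "q", "n")],
       t_matrix = tm, q_matrix = qm, sig_matrix = qm < 0.05)
}

#' ANCOVA: group effect on an outcome adjusting for a covariate
#'
#' Linear model with effect-coded (sum-to-zero) group, centered covariate,
#' and their interaction; Type-III F tests (via `car::Anova`) on 1 and
#' `n - 4` df for group, covariate, and interaction, so main effects remain
#' interpretable with the interaction in the model.
#'
#' @param outcome numeric per-subject outcome (e.g. network selectivity).
#' @param group 2-level group labels.
#' @param covariate numeric per-subject covariate (e.g. mean FD); if
#'   constant, the covariate and interaction tests are reported as `NA`.
#' @return An `ancova_result`: list with `F`, `p` (named: group, covariate,
#'   interaction), `df` (c(1, residual)), and `adjusted_means` (per group, at
#'   the covariate mean).
#' @export
ancova <- function(outcome, group, covariate) {
  f <- factor(group)
  if (nlevels(f) != 2L) stop("ancova needs exactly 2 group levels")
  if (min(table(f)) < 3L) stop("ancova needs >= 3 subjects per group")
  if (stats::sd(covariate) == 0) {
    ts <- two_sample_t(x = outcome[f == levels(f)[1]],
                       y = outcome[f == levels(f)[2]])
    return(structure(list(
      F = c(group = ts$t^2, covariate = NA_real_, interaction = NA_real_),
      p = c(group = ts$p, covariate = NA_real_, interaction = NA_real_),
      df = c(1, ts$df),
      adjusted_means = tapply(outcome, f, mean)), class = "ancova_result"))
  }
  cc <- covariate - mean(covariate)
  dat <- data.frame(y = outcome, g = f, c = cc)
  fit <- stats::lm(y ~ g * c, data = dat,
                   contrasts = list(g = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  pick <- function(term, col) a3[rownames(a3) == term, col]
  Fv <- c(group = pick("g", "F value"), covariate = pick("c", "F value"),
          interaction = pick("g:c", "F value"))
  pv <- c(group = pick("g", "Pr(>F)"), covariate = pick("c", "Pr(>F)"),
          interaction = pick("g:c", "Pr(>F)"))
  cf <- stats::coef(fit)
  adj <- c(cf[1] + cf[2], cf[1] - cf[2])  # effect coding: +1 then -1 level
  names(adj) <- levels(f)
  structure(list(F = Fv, p = pv, df = c(1, stats::df.residual(fit)),
                 adjusted_means = adj), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  for (term in names(x$F))
    cat(sprintf("  %-11s F(%d, %d) = %.4g, p = %.4g\n", term,
                x$df[1], x$df[2], x$F[term], x$p[term]))
  invisible(x)
}

#' Partial correlation adjusting for one covariate
#'
#' Pearson correlation between the OLS residuals of `x` and `y` after each is
#' regressed on an intercept and the covariate; `df = n - 3` with a two-sided
#' p from the t distribution.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector, not constant.
#' @return list with `r`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (n < 4) stop("partial correlation needs n >= 4")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  rx <- stats::lm.fit(cbind(1, covariate), x)$residuals
  ry <- stats::lm.fit(cbind(1, covariate), y)$residuals
  if (stats::sd(rx) <= 1e-12 * stats::sd(x) ||
      stats::sd(ry) <= 1e-12 * stats::sd(y))
    stop("x or y is collinear with the covariate; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 3
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tt), df))
}
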