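## Receptor-enriched analysis of functional connectivity by targets (REACT):
## a two-step multiple-regression estimator. Step 1 regresses each fMRI
## volume spatially on the molecular templates, giving one time series per
## molecular system; step 2 regresses each voxel's BOLD time series on those
## system time series, giving one molecular-enriched FC map per system.
## Parcellation then averages the maps within atlas ROIs.

#' Min-max rescale template maps to [0, 1] within the mask
#'
#' Conditions each molecular density map to the unit interval over in-mask
#' voxels before it enters the spatial regression; out-of-mask voxels are
#' zero by construction. Rescaling is affine per map, so pairwise template
#' correlations are unchanged.
#'
#' @param templates a [template_set()]
#' @return a [template_set()] with each map on `[0, 1]`
#' @export
rescale_templates <- function(templates) {
  stopifnot(inherits(templates, "template_set"))
  maps <- templates$maps
  for (k in seq_len(ncol(maps))) {
    rng <- range(maps[, k])
    if (rng[2L] - rng[1L] <= 0) {
      abort("template '", templates$system_names[k],
            "' is constant inside the mask; cannot rescale")
    }
    maps[, k] <- (maps[, k] - rng[1L]) / (rng[2L] - rng[1L])
  }
  template_set(maps, templates$mask, templates$system_names, templates$affine)
}

#' Variance inflation factors of the template design
#'
#' For each map, `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from
#' regressing map k on the other K-1 maps (plus intercept) over in-mask
#' voxels. Values at or above the rule-of-thumb threshold of 5 indicate
#' collinearity likely to destabilise the spatial regression and trigger a
#' warning (not an error). Perfect collinearity is reported as `Inf`.
#'
#' @param templates a [template_set()] (rescaled or not; VIF is scale-free)
#' @return named numeric vector of VIFs, one per system
#' @export
compute_vif <- function(templates) {
  stopifnot(inherits(templates, "template_set"))
  K <- ncol(templates$maps)
  if (K < 2L) abort("VIF is undefined for a single template")
  vif <- setNames(numeric(K), templates$system_names)
  for (k in seq_len(K)) {
    y <- templates$maps[, k]
    X <- cbind(1, templates$maps[, -k, drop = FALSE])
    res <- qr.resid(qr(X), y)
    sst <- sum((y - mean(y))^2)
    r2 <- 1 - sum(res^2) / sst
    vif[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(vif))) {
    warning("perfectly collinear templates: ",
            paste(names(vif)[!is.finite(vif)], collapse = ", "))
  } else if (any(vif >= 5)) {
    warning("VIF >= 5 for: ", paste(names(vif)[vif >= 5], collapse = ", "),
            " (collinearity may destabilise the spatial regression)")
  }
  vif
}

#' REACT stage 1: spatial regression of each volume on the templates
#'
#' Each timepoint's in-mask volume (demeaned across voxels) is regressed on
#' the K rescaled template maps plus an intercept; the K fitted coefficients
#' form that timepoint's row of the system time series.
#'
#' @param bold a [bold_run()] on the same grid as the templates
#' @param templates a rescaled [template_set()]
#' @return a T x K matrix of system time series (class `system_timeseries`),
#'   columns named by system
#' @export
stage1_spatial_regression <- function(bold, templates) {
  stopifnot(inherits(bold, "bold_run"), inherits(templates, "template_set"))
  if (!identical(dim(bold$mask), dim(templates$mask))) {
    abort("BOLD and template grids differ: ",
          paste(dim(bold$mask), collapse = "x"), " vs ",
          paste(dim(templates$mask), collapse = "x"))
  }
  K <- ncol(templates$maps)
  Tn <- ncol(bold$data)
  if (Tn <= K + 1L) abort("need more timepoints than templates + 1")
  X <- cbind(intercept = 1, templates$maps)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(colnames(X), colnames(X)[piv])
    abort("rank-deficient spatial design; collinear system(s): ",
          paste(bad, collapse = ", "))
  }
  Y <- sweep(bold$data, 2L, colMeans(bold$data))  # demean each volume
  coefs <- qr.coef(qrX, Y)                         # (K+1) x T
  series <- t(coefs[-1L, , drop = FALSE])
  colnames(series) <- templates$system_names
  class(series) <- c("system_timeseries", class(series))
  series
}

#' REACT stage 2: temporal regression of each voxel on the system series
#'
#' Each system time series is z-scored (unit variance regressors make the
#' betas comparable across systems), then every in-mask voxel's time series
#' is regressed on the K normalised series plus an intercept. The K
#' coefficients form that voxel's row of the molecular-enriched FC maps:
#' positive values mean coupling to the system's dominant fluctuation,
#' negative values anti-correlation.
#'
#' @param bold the same [bold_run()] used in stage 1
#' @param series the stage-1 T x K system time series
#' @return a list of class `enriched_maps` with `betas` (in-mask voxels x K),
#'   `mask`, `system_names`, `affine` and `subject_id`
#' @export
stage2_temporal_regression <- function(bold, series) {
  stopifnot(inherits(bold, "bold_run"))
  series <- unclass(series)
  if (nrow(series) != ncol(bold$data)) {
    abort("system time series length does not match BOLD run")
  }
  sds <- apply(series, 2L, sd)
  if (any(sds == 0)) {
    abort("zero-variance system time series: ",
          paste(colnames(series)[sds == 0], collapse = ", "))
  }
  Z <- scale(series)                                # T x K, z-scored
  X <- cbind(intercept = 1, Z)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, t(bold$data))               # (K+1) x V
  betas <- t(coefs[-1L, , drop = FALSE])
  colnames(betas) <- colnames(series)
  structure(list(betas = betas, mask = bold$mask,
                 system_names = colnames(series),
                 affine = bold$affine, subject_id = bold$subject_id),
            class = "enriched_maps")
}

#' Average molecular-enriched FC values within atlas ROIs
#'
#' @param maps an `enriched_maps` object from [stage2_temporal_regression()]
#' @param atlas a [parcellation_atlas()] on the same grid
#' @return an R x K matrix of ROI values (one subject's slice of a
#'   [roi_matrix()]); ROIs with no in-mask voxels get `NA` with a warning
#' @export
parcellate <- function(maps, atlas) {
  stopifnot(inherits(maps, "enriched_maps"), inherits(atlas, "parcellation_atlas"))
  if (!identical(dim(maps$mask), dim(atlas$labels))) {
    abort("atlas grid does not match enriched-map grid")
  }
  lab <- atlas$labels[maps$mask]
  R <- n_rois(atlas)
  out <- matrix(NA_real_, R, ncol(maps$betas),
                dimnames = list(atlas$roi_names, maps$system_names))
  inside <- lab > 0L
  counts <- tabulate(lab[inside], nbins = R)
  sums <- rowsum(maps$betas[inside, , drop = FALSE], lab[inside])
  got <- as.integer(rownames(sums))
  out[got, ] <- sums / counts[got]
  if (any(counts == 0L)) {
    warning("ROI(s) with no in-mask voxels set to NA: ",
            paste(atlas$roi_names[counts == 0L], collapse = ", "))
  }
  out
}

#' Run the full REACT estimator for one subject
#'
#' Rescales the templates, runs both regression stages and parcellates.
#'
#' @param bold a [bold_run()]
#' @param templates a [template_set()] (raw; rescaled internally)
#' @param atlas a [parcellation_atlas()]
#' @return list with `series` (T x K), `maps` (`enriched_maps`) and
#'   `roi_values` (R x K matrix)
#' @export
react_subject <- function(bold, templates, atlas) {
  tpl <- rescale_templates(templates)
  series <- stage1_spatial_regression(bold, tpl)
  maps <- stage2_temporal_regression(bold, series)
  list(series = series, maps = maps, roi_values = parcellate(maps, atlas))
}

#' Run REACT over a simulated cohort
#'
#' Generates each subject's BOLD run from the forward model and estimates the
#' parcellated molecular-enriched FC values, one subject at a time (volumes
#' are not kept in memory).
#'
#' @param cohort a [make_cohort()] data.frame
#' @param templates a [template_set()]
#' @param atlas a [parcellation_atlas()]
#' @param truth a [make_ground_truth()] object carrying spatial loadings
#' @param config the [synth_config()]
#' @return a [roi_matrix()] (subject x ROI x system)
#' @export
react_cohort <- function(cohort, templates, atlas, truth, config) {
  R <- n_rois(atlas)
  K <- config$n_systems
  vals <- array(NA_real_, dim = c(nrow(cohort), R, K))
  tpl <- rescale_templates(templates)
  for (i in seq_len(nrow(cohort))) {
    sim <- make_bold(cohort[i, ], templates, truth, config)
    series <- stage1_spatial_regression(sim$bold, tpl)
    maps <- stage2_temporal_regression(sim$bold, series)
    vals[i, , ] <- parcellate(maps, atlas)
  }
  roi_matrix(vals, subject_ids = cohort$id, roi_names = atlas$roi_names,
             system_names = templates$system_names)
}
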