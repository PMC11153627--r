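## Synthetic study generator.
##
## Produces every input the analysis pipeline consumes -- molecular templates,
## a parcellation, a multi-site cohort, BOLD runs, parcellated FC values with
## planted patient deviations, and a psychometric battery with planted factor
## structure -- with a fully known ground truth, so each downstream stage can
## be validated against what was generated.
##
## Two generative levels are provided, both driven by the same ground truth:
##   * voxel level (`make_bold`): BOLD volumes built as the generative inverse
##     of the dual-regression estimator, for validating the REACT stages and
##     for end-to-end runs;
##   * ROI level (`make_roi_values`): molecular-enriched FC values drawn
##     directly from the normative linear model (age/sex fixed effects, site
##     offsets, site-specific noise), for normative-model and inference
##     simulations at larger n.

#' Configuration for a synthetic molecular-connectivity study
#'
#' Defines the study conditions of a simulated two-site cohort: a cubic
#' acquisition grid, K molecular systems, latent network dynamics, healthy
#' cohorts per site, three clinical groups recruited at the clinical site, a
#' target correlation between molecular templates, planted regional deviations
#' for patients, and a psychometric battery with latent factor structure.
#'
#' @param n_voxels_per_axis side of the cubic grid (voxels)
#' @param n_systems number K of molecular systems
#' @param n_timepoints BOLD timepoints T (must exceed `n_systems + 2`)
#' @param n_subjects_per_site named integer vector: healthy subjects per site;
#'   the last-named site is the clinical site where patient groups are added
#' @param n_patients_per_group named integer vector of clinical group sizes
#' @param age_range inclusive age bounds in years
#' @param template_pairwise_r target pairwise Pearson correlation between
#'   templates, in `[0, 1)`
#' @param snr ratio of signal sd to noise sd in the BOLD generator
#' @param deviation_effect planted patient shift, in units of the healthy
#'   residual sd at the affected (ROI, system) cell (negative = FC below the
#'   normative range)
#' @param n_dev_rois number of ROIs per clinical group carrying the planted
#'   shift
#' @param n_rois number of parcellation ROIs
#' @param n_symptom_measures number of psychometric measures
#' @param n_latent_factors number of latent symptom factors
#' @param symptom_coupling vector of length `n_latent_factors`: correlation
#'   between each factor score and the subject's planted deviation magnitude
#' @param symptom_noise_sd measure-level noise sd in the symptom generator
#' @param seed master seed; fully determines all generated outputs
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_voxels_per_axis = 14,
                         n_systems = 3,
                         n_timepoints = 120,
                         n_subjects_per_site = c(bank = 60, clinic = 40),
                         n_patients_per_group = c(G1 = 20, G2 = 20, G3 = 20),
                         age_range = c(18, 88),
                         template_pairwise_r = 0.3,
                         snr = 5,
                         deviation_effect = -1,
                         n_dev_rois = 10,
                         n_rois = 40,
                         n_symptom_measures = 28,
                         n_latent_factors = 4,
                         symptom_coupling = c(0, 0.6, 0, 0)[seq_len(n_latent_factors)],
                         symptom_noise_sd = 0.5,
                         seed = 1) {
  if (n_systems < 1L) abort("`n_systems` must be >= 1")
  if (n_timepoints <= n_systems + 2L) abort("`n_timepoints` must exceed n_systems + 2")
  if (length(n_subjects_per_site) < 1L || is.null(names(n_subjects_per_site))) {
    abort("`n_subjects_per_site` must be a nonempty named vector")
  }
  if (template_pairwise_r < 0 || template_pairwise_r >= 1) {
    abort("`template_pairwise_r` must lie in [0, 1)")
  }
  if (snr <= 0) abort("`snr` must be positive")
  if (n_latent_factors > n_symptom_measures) {
    abort("`n_latent_factors` cannot exceed `n_symptom_measures`")
  }
  if (diff(age_range) <= 0) abort("`age_range` must be increasing")
  structure(list(
    n_voxels_per_axis = as.integer(n_voxels_per_axis),
    n_systems = as.integer(n_systems),
    n_timepoints = as.integer(n_timepoints),
    n_subjects_per_site = n_subjects_per_site,
    n_patients_per_group = n_patients_per_group,
    age_range = age_range,
    template_pairwise_r = template_pairwise_r,
    snr = snr,
    deviation_effect = deviation_effect,
    n_dev_rois = as.integer(n_dev_rois),
    n_rois = as.integer(n_rois),
    n_symptom_measures = as.integer(n_symptom_measures),
    n_latent_factors = as.integer(n_latent_factors),
    symptom_coupling = symptom_coupling,
    symptom_noise_sd = symptom_noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

## Separable Gaussian smoothing of a 3D array (reflected edges).
gauss_smooth_3d <- function(arr, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth_vec <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[(n - half + 1L):n]))
    as.numeric(stats::filter(vp, kern, sides = 2))[(half + 1L):(half + n)]
  }
  for (ax in 1:3) {
    arr <- aperm(apply(arr, setdiff(1:3, ax), smooth_vec), order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

## Spherical grey-matter-like mask inside a cubic grid.
make_mask <- function(n) {
  ctr <- (n + 1) / 2
  r <- 0.45 * n
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2, dim = c(n, n, n))
}

#' Generate smooth, correlated, nonnegative molecular template maps
#'
#' Templates are built as smoothed Gaussian random fields (emulating smooth
#' PET/SPECT density maps), orthonormalised over the mask and then mixed with
#' a shared component so that every pair of maps attains exactly the target
#' Pearson correlation, and finally shifted to be nonnegative (which leaves
#' correlations unchanged).
#'
#' @param config a [synth_config()]
#' @return a [template_set()]
#' @export
make_templates <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_voxels_per_axis
  K <- config$n_systems
  r <- config$template_pairwise_r
  mask <- make_mask(n)
  V <- sum(mask)
  fields <- with_seed(substream_seed(config$seed, "templates"), {
    f <- matrix(NA_real_, V, K + 1L)
    for (j in seq_len(K + 1L)) {
      raw <- array(rnorm(n^3), dim = c(n, n, n))
      sm <- gauss_smooth_3d(raw, sigma = n / 8)
      f[, j] <- sm[mask]
    }
    f
  })
  ## demean (so inner products are correlations), then orthonormalise
  fields <- sweep(fields, 2L, colMeans(fields))
  Q <- qr.Q(qr(fields))
  maps <- matrix(NA_real_, V, K)
  for (k in seq_len(K)) {
    m <- sqrt(r) * Q[, 1L] + sqrt(1 - r) * Q[, k + 1L]
    maps[, k] <- m - min(m)  # nonnegative; correlation-preserving shift
  }
  template_set(maps, mask, system_names = default_system_names(K))
}

#' Generate a synthetic parcellation atlas over the mask
#'
#' In-mask voxels are partitioned into spatially compact parcels by k-means
#' on voxel coordinates (every parcel nonempty by construction).
#'
#' @param config a [synth_config()]
#' @param n_rois number of parcels; defaults to `config$n_rois`
#' @return a [parcellation_atlas()]
#' @export
make_atlas <- function(config, n_rois = config$n_rois) {
  mask <- make_mask(config$n_voxels_per_axis)
  coords <- which(mask, arr.ind = TRUE)
  if (n_rois > nrow(coords)) abort("more ROIs requested than mask voxels")
  km <- with_seed(substream_seed(config$seed, "atlas"),
                  kmeans(coords, centers = n_rois, nstart = 3, iter.max = 100))
  labels <- array(0L, dim = dim(mask))
  labels[mask] <- as.integer(km$cluster)
  parcellation_atlas(labels, roi_names = sprintf("roi%03d", seq_len(n_rois)))
}

#' Generate a multi-site cohort with demographics and diagnoses
#'
#' Healthy controls are generated at every site; the three clinical groups
#' are recruited at the clinical site (the last-named site), mirroring a
#' design in which one large healthy-ageing cohort is pooled with a clinical
#' phenomics cohort. Ages are uniform on `age_range`; sex is balanced
#' Bernoulli(0.5) coded 0/1.
#'
#' @param config a [synth_config()]
#' @return a data.frame with columns `id`, `site`, `age`, `sex`, `diagnosis`
#'   and `dev_scale` (subject-level multiplier on the planted deviation,
#'   mean 1; exactly 1 for healthy controls)
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sites <- names(config$n_subjects_per_site)
  if (length(sites) == 0L) abort("empty site map")
  clin_site <- sites[length(sites)]
  groups <- names(config$n_patients_per_group)
  site_col <- c(rep(sites, times = config$n_subjects_per_site),
                rep(clin_site, sum(config$n_patients_per_group)))
  diag_col <- c(rep("HC", sum(config$n_subjects_per_site)),
                rep(groups, times = config$n_patients_per_group))
  n <- length(site_col)
  with_seed(substream_seed(config$seed, "cohort"), {
    cohort <- data.frame(
      id = sprintf("sub%04d", seq_len(n)),
      site = site_col,
      age = runif(n, config$age_range[1L], config$age_range[2L]),
      sex = rbinom(n, 1L, 0.5),
      diagnosis = diag_col,
      stringsAsFactors = FALSE
    )
    cohort$dev_scale <- ifelse(cohort$diagnosis == "HC", 1,
                               runif(n, 0.6, 1.4))
    cohort
  })
}

#' Draw the ground truth of a synthetic study
#'
#' Holds everything downstream recovery tests compare against: the spatial
#' loadings used by the BOLD generator, per-system network-amplitude effects
#' of age/sex/site, the ROI-level normative coefficients (intercept, age
#' slope, sex effect), site offsets and site noise sds, the planted
#' per-group deviation map (zero for healthy controls), and the symptom
#' factor loadings.
#'
#' @param config a [synth_config()]
#' @param templates optional [template_set()]; generated from `config` when
#'   omitted (needed only for the voxel-level generator)
#' @param roi_names ROI labels; defaults to the `config$n_rois` synthetic atlas
#'   naming
#' @return an object of class `ground_truth`
#' @export
make_ground_truth <- function(config, templates = NULL, roi_names = NULL) {
  stopifnot(inherits(config, "synth_config"))
  K <- config$n_systems
  sites <- names(config$n_subjects_per_site)
  groups <- names(config$n_patients_per_group)
  systems <- default_system_names(K)
  if (is.null(roi_names)) roi_names <- sprintf("roi%03d", seq_len(config$n_rois))
  R <- length(roi_names)
  truth <- with_seed(substream_seed(config$seed, "truth"), {
    ## per-system network amplitude modulation (voxel-level generator):
    ## every system carries a genuine ageing effect of random sign (the
    ## dominant predictable source of network-strength variation), with
    ## smaller sex and site effects
    amp_age <- sample(c(-1, 1), K, replace = TRUE) * runif(K, 0.15, 0.35)
    amp_sex <- rnorm(K, 0, 0.10)
    amp_site <- matrix(rnorm(length(sites) * K, 0, 0.15), length(sites), K,
                       dimnames = list(sites, systems))
    ## ROI-level normative model coefficients
    beta0 <- matrix(rnorm(R * K, 0, 1), R, K, dimnames = list(roi_names, systems))
    age_slope <- matrix(rnorm(R * K, 0, 0.02), R, K, dimnames = list(roi_names, systems))
    sex_offset <- matrix(rnorm(R * K, 0, 0.3), R, K, dimnames = list(roi_names, systems))
    site_offsets <- setNames(rnorm(length(sites), 0, 0.5), sites)
    site_sds <- setNames(runif(length(sites), 0.8, 1.25), sites)
    ## planted deviations: each clinical group gets n_dev_rois ROIs in one
    ## system (groups cycle over systems)
    planted <- array(0, dim = c(length(groups), R, K),
                     dimnames = list(groups, roi_names, systems))
    n_dev <- min(config$n_dev_rois, R)
    for (gi in seq_along(groups)) {
      k <- ((gi - 1L) %% K) + 1L
      rois <- sample.int(R, n_dev)
      planted[gi, rois, k] <- config$deviation_effect
    }
    ## symptom factor loadings: block structure with small cross-loadings
    nm <- config$n_symptom_measures
    nf <- config$n_latent_factors
    main_f <- ((seq_len(nm) - 1L) %% nf) + 1L
    loadings <- matrix(rnorm(nm * nf, 0, 0.10), nm, nf)
    loadings[cbind(seq_len(nm), main_f)] <- runif(nm, 0.6, 0.9)
    list(amp_age = amp_age, amp_sex = amp_sex, amp_site = amp_site,
         beta0 = beta0, age_slope = age_slope, sex_offset = sex_offset,
         site_offsets = site_offsets, site_sds = site_sds,
         planted_deviation_map = planted, symptom_loadings = loadings,
         roi_names = roi_names, system_names = systems)
  })
  if (!is.null(templates)) {
    truth$spatial_loadings <- rescale_templates(templates)$maps
  }
  truth$age_center <- mean(config$age_range)
  truth$age_sd <- diff(config$age_range) / sqrt(12)  # sd of the uniform draw
  class(truth) <- "ground_truth"
  truth
}

#' Generate one subject's BOLD run from the forward model
#'
#' The BOLD signal is the generative inverse of the dual-regression
#' estimator: `BOLD(v, t) = sum_k s_k(t) m_k(v) + b_site + noise`, where the
#' `m_k` are the (rescaled) template maps and the latent system time courses
#' `s_k` are AR(1) series scaled by a per-subject network amplitude that
#' carries the age, sex and site effects into the estimated FC values.
#' Gaussian noise sd is set from the signal sd via `config$snr`.
#'
#' @param subject one row of the [make_cohort()] data.frame
#' @param templates a [template_set()]
#' @param truth a [make_ground_truth()] object holding `spatial_loadings`
#' @param config a [synth_config()]
#' @return a list with elements `bold` (a [bold_run()]) and `latent`
#'   (T x K matrix of the planted system time courses, amplitude included)
#' @export
make_bold <- function(subject, templates, truth, config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(truth$spatial_loadings)) {
    abort("`truth` lacks spatial loadings; build it with `templates=`")
  }
  if (!identical(dim(templates$mask), dim(make_mask(config$n_voxels_per_axis)))) {
    abort("template grid does not match config grid")
  }
  if (nrow(truth$spatial_loadings) != nrow(templates$maps)) {
    abort("ground-truth loadings and templates disagree on voxel count")
  }
  K <- config$n_systems
  Tn <- config$n_timepoints
  z_age <- (subject$age - truth$age_center) / truth$age_sd
  amp <- 1 + truth$amp_age * z_age + truth$amp_sex * subject$sex +
    truth$amp_site[subject$site, ]
  amp <- pmax(amp, 0.2)
  sid_hash <- sum(utf8ToInt(as.character(subject$id)))
  with_seed(substream_seed(config$seed, paste0("bold", sid_hash)), {
    ## AR(1) latent dynamics, unit marginal sd
    phi <- 0.4
    lat <- matrix(rnorm(Tn * K, 0, sqrt(1 - phi^2)), Tn, K)
    for (t in 2:Tn) lat[t, ] <- phi * lat[t - 1L, ] + lat[t, ]
    lat <- sweep(lat, 2L, amp, `*`)
    signal <- truth$spatial_loadings %*% t(lat)     # V x T
    noise_sd <- sd(as.numeric(signal)) / config$snr
    b_site <- truth$site_offsets[subject$site]
    data <- signal + b_site + matrix(rnorm(length(signal), 0, noise_sd),
                                     nrow(signal), ncol(signal))
    list(bold = bold_run(data, templates$mask, subject_id = subject$id,
                         affine = templates$affine),
         latent = lat)
  })
}

#' Draw molecular-enriched FC values directly from the ROI-level model
#'
#' Generates the subject x ROI x system value array from the normative linear
#' model itself: `y = beta0 + beta_age * age + beta_sex * sex + u_site + eps`,
#' with site-specific noise sd. This is the healthy (null) surface; patient
#' shifts are applied separately by [inject_deviations()].
#'
#' @param cohort a [make_cohort()] data.frame
#' @param truth a [make_ground_truth()] object
#' @param config a [synth_config()]
#' @return a [roi_matrix()]
#' @export
make_roi_values <- function(cohort, truth, config) {
  R <- length(truth$roi_names)
  K <- length(truth$system_names)
  n <- nrow(cohort)
  with_seed(substream_seed(config$seed, "roivalues"), {
    vals <- array(NA_real_, dim = c(n, R, K))
    noise_sd <- truth$site_sds[cohort$site]
    for (k in seq_len(K)) {
      mu <- outer(rep(1, n), truth$beta0[, k]) +
        outer(cohort$age, truth$age_slope[, k]) +
        outer(cohort$sex, truth$sex_offset[, k]) +
        truth$site_offsets[cohort$site]
      vals[, , k] <- mu + matrix(rnorm(n * R), n, R) * noise_sd
    }
    roi_matrix(vals, subject_ids = cohort$id, roi_names = truth$roi_names,
               system_names = truth$system_names)
  })
}

#' Apply planted patient deviations to an FC value array
#'
#' Shifts patient entries at the (group, ROI, system) cells named in the
#' ground truth by the planted amount expressed in units of the healthy
#' residual sd at that cell (the sd of healthy-control values after removing
#' age, sex and site by ordinary least squares), times the subject's
#' `dev_scale` multiplier. Healthy controls are untouched; zero planted maps
#' return the input unchanged.
#'
#' @param rm a [roi_matrix()]
#' @param cohort the matching cohort data.frame
#' @param truth a [make_ground_truth()] object with `planted_deviation_map`
#' @return a [roi_matrix()] of the same shape
#' @export
inject_deviations <- function(rm, cohort, truth) {
  planted <- truth$planted_deviation_map
  groups <- dimnames(planted)[[1L]]
  unknown <- setdiff(groups, unique(cohort$diagnosis))
  if (length(unknown)) {
    abort("planted deviation map names unknown group(s): ",
          paste(unknown, collapse = ", "))
  }
  if (all(planted == 0)) return(rm)
  hc <- cohort$diagnosis == "HC"
  Xh <- cbind(1, cohort$age[hc], cohort$sex[hc],
              outer(cohort$site[hc], unique(cohort$site)[-1L], `==`) * 1)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    rows <- which(cohort$diagnosis == g)
    pl_g <- matrix(planted[gi, , ], nrow = dim(planted)[2L])
    cells <- which(pl_g != 0, arr.ind = TRUE)
    if (length(rows) == 0L || nrow(cells) == 0L) next
    for (ci in seq_len(nrow(cells))) {
      r <- cells[ci, 1L]; k <- cells[ci, 2L]
      yh <- rm[hc, r, k]
      resid_sd <- sd(lm.fit(Xh, yh)$residuals)
      shift <- pl_g[r, k] * resid_sd
      rm[rows, r, k] <- rm[rows, r, k] + shift * cohort$dev_scale[rows]
    }
  }
  rm
}

#' Generate the psychometric battery with planted factor structure
#'
#' Measures are linear combinations of `n_latent_factors` latent factor
#' scores plus Gaussian noise. Healthy controls' factor scores are centred at
#' zero; for patients, factors with nonzero `symptom_coupling` are correlated
#' with the subject's planted deviation magnitude (standardised across
#' patients), so the deviation-symptom mapping has a recoverable signal.
#'
#' @param cohort a [make_cohort()] data.frame
#' @param truth a [make_ground_truth()] object
#' @param config a [synth_config()]
#' @param noise_sd measure noise sd; defaults to `config$symptom_noise_sd`
#' @return a data.frame with `id`, `diagnosis` and one column per measure;
#'   the generating factor scores and loadings are attached as attributes
#'   `factor_scores` and `loadings`
#' @export
make_symptoms <- function(cohort, truth, config,
                          noise_sd = config$symptom_noise_sd) {
  nm <- config$n_symptom_measures
  nf <- config$n_latent_factors
  n <- nrow(cohort)
  ## subject deviation magnitude: |mean planted shift| for the group, scaled
  planted <- truth$planted_deviation_map
  gmag <- apply(abs(planted), 1L, mean)
  dev_mag <- rep(0, n)
  pat <- cohort$diagnosis != "HC"
  dev_mag[pat] <- gmag[cohort$diagnosis[pat]] * cohort$dev_scale[pat]
  with_seed(substream_seed(config$seed, "symptoms"), {
    fs <- matrix(rnorm(n * nf), n, nf)
    if (any(pat) && sd(dev_mag[pat]) > 0) {
      d_std <- (dev_mag[pat] - mean(dev_mag[pat])) / sd(dev_mag[pat])
      for (j in seq_len(nf)) {
        rho <- config$symptom_coupling[j]
        if (rho != 0) {
          fs[pat, j] <- rho * d_std + sqrt(1 - rho^2) * fs[pat, j]
        }
      }
    }
    meas <- fs %*% t(truth$symptom_loadings) +
      matrix(rnorm(n * nm, 0, noise_sd), n, nm)
    colnames(meas) <- sprintf("measure%02d", seq_len(nm))
    out <- data.frame(id = cohort$id, diagnosis = cohort$diagnosis,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(meas))
    attr(out, "factor_scores") <- fs
    attr(out, "loadings") <- truth$symptom_loadings
    out
  })
}

#' Simulate a full ROI-level study
#'
#' Convenience wrapper chaining cohort, ground truth, ROI-level FC values,
#' planted patient deviations and the symptom table. Used by the normative,
#' similarity and mapping simulations, which do not need voxel data.
#'
#' @param config a [synth_config()]
#' @return a list with `config`, `cohort`, `truth`, `roi` (a [roi_matrix()],
#'   deviations injected) and `symptoms`
#' @export
simulate_roi_study <- function(config) {
  cohort <- make_cohort(config)
  truth <- make_ground_truth(config)
  rm0 <- make_roi_values(cohort, truth, config)
  rm1 <- inject_deviations(rm0, cohort, truth)
  sym <- make_symptoms(cohort, truth, config)
  list(config = config, cohort = cohort, truth = truth, roi = rm1,
       symptoms = sym)
}
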