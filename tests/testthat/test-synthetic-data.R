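test_that("config validation rejects impossible study conditions", {
  expect_error(tiny_config(template_pairwise_r = 1), "0, 1")
  expect_error(tiny_config(template_pairwise_r = -0.2), "0, 1")
  expect_error(tiny_config(snr = 0), "positive")
  expect_error(tiny_config(n_timepoints = 3, n_systems = 2), "exceed")
  expect_error(tiny_config(n_latent_factors = 40), "exceed")
  expect_error(synth_config(n_subjects_per_site = integer(0)), "named")
})

test_that("templates are nonnegative, hit the target correlation, and keep VIF < 5", {
  for (r in c(0, 0.3, 0.5)) {
    cfg <- tiny_config(n_systems = 3, template_pairwise_r = r)
    tpl <- make_templates(cfg)
    expect_true(all(tpl$maps >= 0))
    cc <- cor(tpl$maps)
    off <- cc[upper.tri(cc)]
    expect_true(all(abs(off - r) <= 0.1))
    vif <- compute_vif(tpl)
    expect_true(all(vif < 5))
  }
})

test_that("degenerate template cases behave: K = 1 and orthogonal K = 2", {
  tpl1 <- make_templates(tiny_config(n_systems = 1))
  expect_equal(ncol(tpl1$maps), 1L)
  tpl2 <- make_templates(tiny_config(n_systems = 2, template_pairwise_r = 0))
  expect_lte(abs(cor(tpl2$maps)[1, 2]), 0.1)
  expect_equal(unname(compute_vif(tpl2)), c(1, 1), tolerance = 1e-6)
})

test_that("the master seed makes every generator bit-reproducible", {
  cfg <- tiny_config(n_systems = 3, template_pairwise_r = 0.5, seed = 7)
  expect_identical(make_templates(cfg)$maps, make_templates(cfg)$maps)
  expect_identical(make_cohort(cfg), make_cohort(cfg))
  tpl <- make_templates(cfg)
  coh <- make_cohort(cfg)
  tr <- make_ground_truth(cfg, templates = tpl)
  b1 <- make_bold(coh[1, ], tpl, tr, cfg)
  b2 <- make_bold(coh[1, ], tpl, tr, cfg)
  expect_identical(b1$bold$data, b2$bold$data)
  ## different subjects draw from different noise substreams
  b3 <- make_bold(coh[2, ], tpl, tr, cfg)
  expect_false(identical(b1$bold$data, b3$bold$data))
})

test_that("cohort structure follows the site map and demographics bounds", {
  cfg <- tiny_config(n_subjects_per_site = c(A = 10),
                     n_patients_per_group = c(G1 = 0, G2 = 0, G3 = 0),
                     age_range = c(18, 88))
  coh <- make_cohort(cfg)
  expect_equal(nrow(coh), 10L)
  expect_true(all(coh$diagnosis == "HC"))
  expect_true(all(coh$site == "A"))
  expect_true(all(coh$age >= 18 & coh$age <= 88))
  expect_true(all(coh$sex %in% 0:1))
  cfg2 <- tiny_config()
  coh2 <- make_cohort(cfg2)
  ## patients recruited at the clinical (last-named) site only
  expect_true(all(coh2$site[coh2$diagnosis != "HC"] == "b"))
  expect_equal(sum(coh2$diagnosis == "HC"), 22L)
})

test_that("noiseless K = 1 BOLD volumes are exact affine images of the template", {
  cfg <- tiny_config(n_systems = 1, snr = Inf)
  tpl <- make_templates(cfg)
  coh <- make_cohort(cfg)
  tr <- make_ground_truth(cfg, templates = tpl)
  sim <- make_bold(coh[1, ], tpl, tr, cfg)
  m <- tr$spatial_loadings[, 1]
  for (t in c(1, 17, 60)) {
    fit <- lm(sim$bold$data[, t] ~ m)
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
})

test_that("noiseless stage-1 recovery of planted time courses is exact", {
  cfg <- tiny_config(n_systems = 2, snr = Inf, template_pairwise_r = 0.3)
  tpl <- make_templates(cfg)
  coh <- make_cohort(cfg)
  tr <- make_ground_truth(cfg, templates = tpl)
  sim <- make_bold(coh[1, ], tpl, tr, cfg)
  series <- stage1_spatial_regression(sim$bold, rescale_templates(tpl))
  expect_equal(unname(diag(cor(series, sim$latent))), c(1, 1), tolerance = 1e-8)
})

test_that("planted deviations shift patient cells by the healthy residual sd", {
  cfg <- tiny_config(n_subjects_per_site = c(a = 120, b = 120),
                     n_patients_per_group = c(G1 = 60, G2 = 10, G3 = 10),
                     n_rois = 8, deviation_effect = -1, seed = 5)
  coh <- make_cohort(cfg)
  tr <- make_ground_truth(cfg)
  rm0 <- make_roi_values(coh, tr, cfg)
  ## zero planted map is the identity
  tr0 <- tr
  tr0$planted_deviation_map[] <- 0
  expect_identical(inject_deviations(rm0, coh, tr0), rm0)
  rm1 <- inject_deviations(rm0, coh, tr)
  hc <- coh$diagnosis == "HC"
  g1 <- coh$diagnosis == "G1"
  pl <- matrix(tr$planted_deviation_map["G1", , ], nrow = cfg$n_rois)
  cell <- which(pl != 0, arr.ind = TRUE)[1, ]
  ## HC untouched
  expect_identical(rm1[hc, , ], rm0[hc, , ])
  ## G1 mean lower than before injection by about one residual sd
  shift_seen <- mean(rm1[g1, cell[1], cell[2]]) - mean(rm0[g1, cell[1], cell[2]])
  resid_sd <- sd(residuals(lm(rm0[hc, cell[1], cell[2]] ~
                                coh$age[hc] + coh$sex[hc] + factor(coh$site[hc]))))
  expect_lt(abs(shift_seen + resid_sd), 0.2 * resid_sd)
  ## unknown group label errors
  tr_bad <- tr
  dimnames(tr_bad$planted_deviation_map)[[1]][1] <- "nosuch"
  expect_error(inject_deviations(rm0, coh, tr_bad), "unknown group")
})

test_that("noiseless symptom tables have exactly the planted low rank", {
  cfg <- tiny_config(n_symptom_measures = 28, n_latent_factors = 4)
  coh <- make_cohort(cfg)
  tr <- make_ground_truth(cfg)
  sym <- make_symptoms(coh, tr, cfg, noise_sd = 0)
  m <- as.matrix(sym[, grep("^measure", names(sym))])
  expect_equal(qr(m)$rank, 4L)
  ## healthy factor scores centred at zero
  fs <- attr(sym, "factor_scores")
  expect_lt(max(abs(colMeans(fs[coh$diagnosis == "HC", ]))), 0.5)
})

test_that("symptom-deviation coupling is recovered at the planted strength", {
  ## planted coupling 0.6 between factor 2 and the deviation magnitude;
  ## Monte-Carlo over seeds at ~100 patients
  rs <- vapply(1:4, function(s) {
    cfg <- tiny_config(n_subjects_per_site = c(a = 10, b = 10),
                       n_patients_per_group = c(G1 = 34, G2 = 33, G3 = 33),
                       symptom_coupling = c(0, 0.6, 0, 0), seed = s)
    coh <- make_cohort(cfg)
    tr <- make_ground_truth(cfg)
    sym <- make_symptoms(coh, tr, cfg)
    pat <- coh$diagnosis != "HC"
    gmag <- apply(abs(tr$planted_deviation_map), 1, mean)
    dmag <- gmag[coh$diagnosis[pat]] * coh$dev_scale[pat]
    cor(attr(sym, "factor_scores")[pat, 2], dmag)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.15)
})

test_that("held-out healthy deviations from the ROI-level generator are calibrated", {
  cfg <- tiny_config(n_subjects_per_site = c(a = 200, b = 200),
                     n_patients_per_group = c(G1 = 2, G2 = 2, G3 = 2),
                     n_rois = 6, n_systems = 2, seed = 21)
  std <- simulate_roi_study(cfg)
  healthy <- std$cohort[std$cohort$diagnosis == "HC", ]
  sp <- stratified_split(healthy, 0.30, seed = 8)
  fit <- fit_normative(std$roi, std$cohort, sp$train_ids, mode = "eb")
  z <- deviation_scores(fit, std$roi, std$cohort, sp$test_ids)
  zz <- as.numeric(z)
  expect_gt(mean(zz), -0.1)
  expect_lt(mean(zz), 0.1)
  expect_gt(var(zz), 0.8)
  expect_lt(var(zz), 1.2)
})
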