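make_flat_cohort <- function(n, sites = "one", seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("s%04d", seq_len(n)),
             site = rep_len(sites, n),
             age = runif(n, 18, 88),
             sex = rbinom(n, 1, 0.5),
             diagnosis = "HC",
             dev_scale = 1,
             stringsAsFactors = FALSE)
}

test_that("stratified split reproduces the largest-remainder bookkeeping", {
  coh <- make_flat_cohort(496 + 111, sites = c(rep("camcan", 496), rep("ucla", 111)))
  sp <- stratified_split(coh, 0.30, seed = 1)
  expect_equal(sp$counts$n_test[sp$counts$site == "camcan"], 150L)
  expect_equal(sp$counts$n_test[sp$counts$site == "ucla"], 33L)
  expect_equal(sp$counts$n_train[sp$counts$site == "camcan"], 346L)
  expect_equal(sp$counts$n_train[sp$counts$site == "ucla"], 78L)
  ## single site of 10 at 0.30: ceiling(3.0) = 3 test, 7 train
  sp10 <- stratified_split(make_flat_cohort(10), 0.30, seed = 2)
  expect_equal(length(sp10$test_ids), 3L)
  expect_equal(length(sp10$train_ids), 7L)
  ## determinism and partition invariants
  sp2 <- stratified_split(coh, 0.30, seed = 1)
  expect_identical(sp$test_ids, sp2$test_ids)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), coh$id)
  expect_error(stratified_split(coh, 1.2), "between 0 and 1")
})

test_that("noiseless single-site data recover the generating line exactly", {
  coh <- make_flat_cohort(200, seed = 3)
  y <- array(1 + 2 * coh$age, dim = c(200, 1, 1))
  rmx <- roi_matrix(y, subject_ids = coh$id)
  fit <- fit_normative(rmx, coh, coh$id[1:150], mode = "eb")
  expect_equal(fit$beta[1, 1, 2], 2, tolerance = 0.05)
  expect_equal(fit$beta[1, 1, 1], 1, tolerance = 0.5)
})

test_that("two-site fits recover fixed effects and site offsets", {
  set.seed(4)
  n <- 400
  coh <- make_flat_cohort(n, sites = c(rep("p", 200), rep("q", 200)), seed = 4)
  u_true <- c(p = 0.5, q = -0.5)
  y <- 0.8 + 0.02 * coh$age + 0.4 * coh$sex + u_true[coh$site] +
    rnorm(n, 0, 1)
  rmx <- roi_matrix(array(y, c(n, 1, 1)), subject_ids = coh$id)
  for (mode in c("eb", "gibbs")) {
    fit <- fit_normative(rmx, coh, coh$id, mode = mode,
                         n_warmup = 500, n_draws = 500, seed = 11)
    expect_lt(abs(fit$beta[1, 1, 2] - 0.02), 0.01)
    expect_lt(abs(fit$beta[1, 1, 3] - 0.4), 0.25)
    ## offsets identified relative to their mean
    expect_lt(max(abs((fit$u[, 1, 1] - mean(fit$u[, 1, 1])) -
                        (u_true - mean(u_true)))), 0.15)
  }
})

test_that("both engines agree with the lme4 mixed-model oracle", {
  set.seed(5)
  n <- 300
  coh <- make_flat_cohort(n, sites = rep(c("p", "q", "r"), each = 100), seed = 5)
  y <- 0.3 - 0.015 * coh$age + 0.5 * coh$sex +
    c(p = 0.6, q = -0.2, r = -0.4)[coh$site] + rnorm(n, 0, 0.8)
  rmx <- roi_matrix(array(y, c(n, 1, 1)), subject_ids = coh$id)
  ref <- lme4::lmer(y ~ age + sex + (1 | site), data = cbind(coh, y = y))
  fe <- lme4::fixef(ref)
  for (mode in c("eb", "gibbs")) {
    fit <- fit_normative(rmx, coh, coh$id, mode = mode,
                         n_warmup = 500, n_draws = 500, seed = 12)
    expect_lt(abs(fit$beta[1, 1, 2] - fe["age"]), 0.005)
    expect_lt(abs(fit$beta[1, 1, 3] - fe["sex"]), 0.05)
    ## shrunken site offsets agree with the BLUPs
    blup <- lme4::ranef(ref)$site[["(Intercept)"]]
    expect_lt(max(abs(fit$u[, 1, 1] - blup)), 0.1)
  }
})

test_that("pure-noise slopes are covered by their credible intervals", {
  covered <- 0L
  reps <- 20L
  for (s in seq_len(reps)) {
    coh <- make_flat_cohort(120, sites = rep(c("p", "q"), each = 60), seed = 100 + s)
    set.seed(200 + s)
    y <- rnorm(120)
    rmx <- roi_matrix(array(y, c(120, 1, 1)), subject_ids = coh$id)
    fit <- fit_normative(rmx, coh, coh$id, mode = "eb")
    se <- sqrt(fit$Vbeta[1, 1, 2, 2])
    ci <- fit$beta[1, 1, 2] + c(-1.96, 1.96) * se
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1L
  }
  expect_gte(covered / reps, 0.9)
})

test_that("explained variance follows its defining arithmetic", {
  coh <- make_flat_cohort(60, sites = rep(c("p", "q"), each = 30), seed = 6)
  set.seed(6)
  y <- 0.05 * coh$age + rnorm(60, 0, 0.5)
  rmx <- roi_matrix(array(y, c(60, 1, 1)), subject_ids = coh$id)
  fit <- fit_normative(rmx, coh, coh$id[1:40], mode = "eb")
  test_ids <- coh$id[41:60]
  ev <- explained_variance(fit, rmx, coh, test_ids)
  ## hand-computed from the same posterior-mean predictions
  pred <- predict_normative(fit, coh, test_ids)
  obs <- y[41:60]
  sse <- sum((obs - pred$mu[, 1, 1])^2)
  sst <- sum((obs - mean(obs))^2)
  expect_equal(ev[1, 1], 1 - sse / sst, tolerance = 1e-12)
  ## perfect predictions give EV = 1; mean-prediction gives EV = 0
  rmx2 <- rmx; rmx2[41:60, 1, 1] <- pred$mu[, 1, 1]
  expect_equal(explained_variance(fit, rmx2, coh, test_ids)[1, 1], 1)
  rmx3 <- rmx; rmx3[41:60, 1, 1] <- mean(pred$mu[, 1, 1]) # constant: SST = 0 flag
  expect_true(is.na(explained_variance(fit, rmx3, coh, test_ids)[1, 1]))
  ## overlap with training is rejected
  expect_error(explained_variance(fit, rmx, coh, coh$id[1:5]), "overlap")
})

test_that("ROI retention uses strict EV > 0 with convergence precedence", {
  ev <- matrix(c(0.2, -0.1, 0), 3, 1)
  expect_equal(as.logical(retain_rois(ev)), c(TRUE, FALSE, FALSE))
  conv <- matrix(c(FALSE, TRUE, TRUE), 3, 1)
  ev2 <- matrix(c(0.3, 0.3, 0.3), 3, 1)
  expect_equal(as.logical(retain_rois(ev2, conv)), c(FALSE, TRUE, TRUE))
  expect_true(all(retain_rois(matrix(0.1, 2, 2))))
})

test_that("deviation scores are zero at the prediction, signed, and site-safe", {
  coh <- make_flat_cohort(80, sites = rep(c("p", "q"), each = 40), seed = 7)
  set.seed(7)
  y <- rnorm(80)
  rmx <- roi_matrix(array(y, c(80, 1, 1)), subject_ids = coh$id)
  fit <- fit_normative(rmx, coh, coh$id[1:60], mode = "eb")
  pred <- predict_normative(fit, coh, coh$id[61:80])
  rmx2 <- rmx; rmx2[61:80, 1, 1] <- pred$mu[, 1, 1]
  z0 <- deviation_scores(fit, rmx2, coh, coh$id[61:80])
  expect_lt(max(abs(z0)), 1e-12)
  ## observed above prediction gives positive z
  rmx3 <- rmx2; rmx3[61, 1, 1] <- rmx3[61, 1, 1] + 1
  z1 <- deviation_scores(fit, rmx3, coh, coh$id[61:80])
  expect_gt(z1[1, 1, 1], 0)
  ## unseen site errors rather than extrapolating
  coh2 <- coh; coh2$site[61] <- "mars"
  expect_error(deviation_scores(fit, rmx, coh2, coh$id[61:80]), "not seen")
})

test_that("shift invariance: adding c to all values leaves z unchanged", {
  coh <- make_flat_cohort(100, sites = rep(c("p", "q"), each = 50), seed = 8)
  set.seed(8)
  y <- 0.02 * coh$age + rnorm(100)
  rmx <- roi_matrix(array(y, c(100, 1, 1)), subject_ids = coh$id)
  fit1 <- fit_normative(rmx, coh, coh$id[1:70], mode = "eb")
  z1 <- deviation_scores(fit1, rmx, coh, coh$id[71:100])
  rmc <- roi_matrix(array(y + 5, c(100, 1, 1)), subject_ids = coh$id)
  fit2 <- fit_normative(rmc, coh, coh$id[1:70], mode = "eb")
  z2 <- deviation_scores(fit2, rmc, coh, coh$id[71:100])
  p1 <- predict_normative(fit1, coh, coh$id[71:100])
  p2 <- predict_normative(fit2, coh, coh$id[71:100])
  expect_equal(p2$mu, p1$mu + 5, tolerance = 1e-6)
  expect_equal(unclass(z2), unclass(z1), tolerance = 1e-6)
})

test_that("held-out healthy z-scores are close to standard normal", {
  cfg <- tiny_config(n_subjects_per_site = c(a = 350, b = 350),
                     n_patients_per_group = c(G1 = 2, G2 = 2, G3 = 2),
                     n_rois = 3, n_systems = 1, seed = 31)
  std <- simulate_roi_study(cfg)
  healthy <- std$cohort[std$cohort$diagnosis == "HC", ]
  sp <- stratified_split(healthy, 0.30, seed = 9)
  fit <- fit_normative(std$roi, std$cohort, sp$train_ids, mode = "eb")
  z <- as.numeric(deviation_scores(fit, std$roi, std$cohort, sp$test_ids))
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("summary deviation is the arithmetic mean over retained ROIs", {
  z <- array(NA_real_, c(3, 3, 1))
  z[1, , 1] <- c(1, -1, NA)
  z[2, , 1] <- c(2, 2, NA)
  z[3, , 1] <- c(0.3, 0.5, NA)
  ret <- matrix(c(TRUE, TRUE, FALSE), 3, 1)
  tens <- roi_matrix(z, subject_ids = c("a", "b", "c"))
  attr(tens, "retained") <- ret
  class(tens) <- c("deviation_tensor", class(tens))
  s <- summary_deviation(tens)
  expect_equal(unname(s[, 1]), c(0, 2, 0.4))
  ## empty mask warns and yields NA
  attr(tens, "retained") <- matrix(FALSE, 3, 1)
  expect_warning(s2 <- summary_deviation(tens), "zero ROIs")
  expect_true(all(is.na(s2)))
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(9)
  good <- rnorm(2000)
  expect_lt(split_rhat(good, 2), 1.02)
  bad <- c(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(split_rhat(bad, 2), 1.5)
})
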