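make_null_tensor <- function(n_per = 10, n_roi = 6, seed = 1) {
  set.seed(seed)
  groups <- rep(c("HC", "G1", "G2", "G3"), each = n_per)
  z <- array(rnorm(length(groups) * n_roi), c(length(groups), n_roi, 1))
  tens <- roi_matrix(z, subject_ids = sprintf("s%02d", seq_along(groups)))
  list(tensor = tens, groups = groups)
}

test_that("the observed F equals the closed-form one-way ANOVA oracle", {
  set.seed(2)
  y <- rnorm(24)
  g <- rep(c("a", "b", "c", "d"), each = 6)
  Fref <- unname(anova(aov(y ~ factor(g)))[1, "F value"])
  tens <- roi_matrix(array(y, c(24, 1, 1)), subject_ids = sprintf("s%02d", 1:24))
  res <- roi_group_anova(tens, g, n_perm = 100, seed = 1)
  expect_equal(res$stats$F[1], Fref, tolerance = 1e-10)
})

test_that("permutation p-values are reproducible, smoothed, and valid", {
  fx <- make_null_tensor(seed = 3)
  r1 <- roi_group_anova(fx$tensor, fx$groups, n_perm = 199, seed = 7)
  r2 <- roi_group_anova(fx$tensor, fx$groups, n_perm = 199, seed = 7)
  expect_identical(r1$stats, r2$stats)
  expect_true(all(r1$stats$p >= 1 / 200 & r1$stats$p <= 1))
  expect_true(all(r1$stats$p_fdr >= r1$stats$p))
  expect_warning(roi_group_anova(fx$tensor, fx$groups, n_perm = 50, seed = 1),
                 "coarse")
  expect_error(roi_group_anova(fx$tensor, rep("g", 40), n_perm = 100, seed = 1))
})

test_that("permutation p-values are approximately uniform under the null", {
  ## pool p-values across null replicates; discrete-uniform check
  ps <- c()
  for (s in 1:30) {
    fx <- make_null_tensor(n_per = 8, n_roi = 4, seed = 100 + s)
    r <- suppressWarnings(
      roi_group_anova(fx$tensor, fx$groups, n_perm = 99, seed = s))
    ps <- c(ps, r$stats$p)
  }
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_lt(abs(mean(ps <= 0.25) - 0.25), 0.08)
})

test_that("planted group shifts are discovered under FDR with few false positives", {
  cfg <- tiny_config(n_subjects_per_site = c(a = 10, b = 40),
                     n_patients_per_group = c(G1 = 40, G2 = 40, G3 = 40),
                     n_rois = 30, n_systems = 1, n_dev_rois = 10,
                     deviation_effect = -1, seed = 17)
  std <- simulate_roi_study(cfg)
  healthy <- std$cohort[std$cohort$diagnosis == "HC", ]
  sp <- stratified_split(healthy, 0.30, seed = 4)
  fit <- fit_normative(std$roi, std$cohort, sp$train_ids, mode = "eb")
  ids <- c(sp$test_ids, std$cohort$id[std$cohort$diagnosis != "HC"])
  z <- deviation_scores(fit, std$roi, std$cohort, ids)
  g <- std$cohort$diagnosis[match(ids, std$cohort$id)]
  res <- roi_group_anova(z, g, n_perm = 499, seed = 5)
  planted_g1 <- which(matrix(std$truth$planted_deviation_map["G1", , ],
                             ncol = 1)[, 1] != 0)
  planted_any <- which(apply(std$truth$planted_deviation_map != 0,
                             2, any))
  sig <- res$stats$roi[res$stats$p_fdr < 0.05]
  hits <- sum(dimnames(z)[[2]][planted_g1] %in% sig)
  expect_gte(hits, 8)
  false_pos <- setdiff(sig, dimnames(z)[[2]][planted_any])
  expect_lte(length(false_pos), 2)
  ## lower-level contrasts exist for significant ROIs and name the groups
  expect_true(nrow(res$contrasts) > 0)
  expect_true(any(grepl("G1", res$contrasts$contrast)))
})

test_that("summary ANOVA equals the hand-computed F with Tukey tables attached", {
  y <- c(1, 2, 3, 6, 7, 8, 2, 3, 4)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- summary_anova(cbind(sys1 = y), g)
  gm <- tapply(y, g, mean); mu <- mean(y)
  ssb <- sum(3 * (gm - mu)^2); ssw <- sum((y - rep(gm, each = 3))^2)
  Fh <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F[1], Fh, tolerance = 1e-10)
  expect_s3_class(res, "data.frame")
  tk <- attr(res, "tukey")$sys1
  expect_equal(nrow(tk), 3)
  ## equal means: F near 0, Tukey p near 1
  set.seed(5)
  y0 <- rnorm(300)
  res0 <- summary_anova(cbind(s = y0), rep(letters[1:4], each = 75))
  expect_lt(res0$F[1], 3)
  expect_gt(res0$p[1], 0.01)
})

test_that("AUC follows the rank formulation and its dual trapezoid form", {
  ## perfect separation
  x <- c(1:10, 21:30)
  cls <- rep(c(FALSE, TRUE), each = 10)
  res <- logistic_auc(x, cls)
  expect_equal(res$auc, 1)
  expect_false(res$converged)
  ## rank formula equals trapezoidal ROC integration
  set.seed(6)
  x2 <- rnorm(60); cls2 <- runif(60) < plogis(1.5 * x2)
  r2 <- logistic_auc(x2, cls2)
  trap <- sum(diff(r2$roc$fpr) * (head(r2$roc$tpr, -1) + r2$roc$tpr[-1]) / 2)
  expect_equal(r2$auc, trap, tolerance = 1e-10)
  expect_true(r2$converged)
  ## AUC invariant to monotone rescaling of the predictor
  expect_equal(logistic_auc(exp(x2), cls2)$auc, r2$auc, tolerance = 1e-12)
  ## pROC oracle on the model score
  sc <- fitted(suppressWarnings(glm(cls2 ~ x2, family = binomial())))
  ref <- pROC::auc(pROC::roc(cls2, sc, quiet = TRUE, direction = "<"))
  expect_equal(r2$auc, as.numeric(ref), tolerance = 1e-10)
  expect_error(logistic_auc(x2, rep(TRUE, 60)), "nonempty")
})

test_that("identical class distributions give chance-level AUC", {
  set.seed(7)
  aucs <- vapply(1:10, function(i) {
    logistic_auc(rnorm(200), rep(c(TRUE, FALSE), 100))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("deviation-symptom statistics equal the closed-form Pearson t", {
  set.seed(8)
  n <- 30
  z <- array(rnorm(n * 3), c(n, 3, 1))
  tens <- roi_matrix(z, subject_ids = sprintf("p%02d", 1:n))
  scores <- cbind(PC1 = rnorm(n))
  res <- deviation_symptom_regression(tens, scores, n_perm = 199, seed = 9)
  for (j in 1:3) {
    r <- cor(z[, j, 1], scores[, 1])
    expect_equal(res$r[j], r, tolerance = 1e-10)
    expect_equal(res$t[j], r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
  }
  ## determinism and FDR ordering
  res2 <- deviation_symptom_regression(tens, scores, n_perm = 199, seed = 9)
  expect_identical(res, res2)
  expect_true(all(res$p_fdr >= res$p))
  ## constant component flagged undefined
  resc <- deviation_symptom_regression(tens, cbind(PC1 = rep(1, n)),
                                       n_perm = 99, seed = 1)
  expect_true(all(is.na(resc$r)))
})

test_that("planted deviation-symptom links pass FDR; null links flagged at ~q", {
  set.seed(10)
  n <- 100; n_roi <- 20
  s <- rnorm(n)
  z <- array(rnorm(n * n_roi), c(n, n_roi, 1))
  linked <- 1:5
  for (r in linked) z[, r, 1] <- 0.5 * s + sqrt(1 - 0.25) * rnorm(n)
  tens <- roi_matrix(z, subject_ids = sprintf("p%03d", 1:n))
  res <- deviation_symptom_regression(tens, cbind(PC2 = s), n_perm = 499, seed = 11)
  sig <- which(res$p_fdr < 0.05)
  expect_gte(sum(sig %in% linked), 4)
  expect_lte(sum(!(sig %in% linked)), 2)
})

test_that("raw-FC values run through the identical ANOVA code path", {
  cfg <- tiny_config(n_rois = 6, n_systems = 1, seed = 13)
  std <- simulate_roi_study(cfg)
  res <- suppressWarnings(
    roi_group_anova(std$roi, std$cohort$diagnosis, n_perm = 99, seed = 2))
  expect_equal(nrow(res$stats), 6L)
  expect_true(all(is.finite(res$stats$F)))
})
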