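## Group-level inference on deviation z-scores (or raw FC values): ROI-wise
## permutation one-way ANOVA with Benjamini-Hochberg FDR per system and
## pairwise t contrasts for significant ROIs; parametric ANOVA with Tukey
## HSD on the per-subject summary deviations; logistic-regression AUC
## screening; and mass-univariate transdiagnostic deviation-symptom
## regression with permutation p-values and FDR.

## Vectorised one-way ANOVA F over the columns of Y (subjects x ROIs).
## g: integer group index 1..k. Returns the F statistic per column.
anova_f_columns <- function(Y, g, k = max(g)) {
  n <- nrow(Y)
  n_g <- tabulate(g, nbins = k)
  gm <- rowsum(Y, g) / n_g                 # k x R group means
  mu <- colMeans(Y)
  ssb <- colSums(n_g * sweep(gm, 2L, mu)^2)
  sst <- colSums(sweep(Y, 2L, mu)^2)
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' ROI-wise permutation ANOVA across diagnostic groups
#'
#' For each retained (ROI, system) cell, a one-way F statistic across the
#' diagnostic groups (e.g. held-out HC and three clinical groups) is
#' compared to its null distribution under free permutation of the group
#' labels; `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`. Benjamini-Hochberg
#' FDR is applied across retained ROIs within each system. ROIs passing the
#' FDR threshold get pairwise two-sided pooled-variance t contrasts to show
#' which groups drive the effect.
#'
#' @param tensor a `deviation_tensor` (or any [roi_matrix()]; the raw-FC
#'   comparison mode runs this identical code path on molecular-enriched FC
#'   values)
#' @param groups group label per subject (rows of the tensor)
#' @param n_perm number of label permutations (default 2000)
#' @param seed permutation seed (mandatory for reproducibility)
#' @param q FDR threshold used to select ROIs for the t contrasts
#' @param retained optional R x K logical retention matrix; defaults to the
#'   tensor's `retained` attribute, else all cells
#' @return list of class `roi_stat_map`: `stats` data.frame (roi, system,
#'   F, p, p_fdr) and `contrasts` data.frame of pairwise t values for
#'   FDR-significant ROIs
#' @export
roi_group_anova <- function(tensor, groups, n_perm = 2000, seed = 1, q = 0.05,
                            retained = NULL) {
  if (n_perm < 100) warning("n_perm < 100 gives very coarse permutation p-values")
  groups <- as.character(groups)
  lev <- unique(groups)
  k <- length(lev)
  if (k < 2L) abort("need at least 2 groups for a between-group ANOVA")
  if (any(table(groups) < 2L)) abort("every group needs at least 2 subjects")
  g <- match(groups, lev)
  retained <- retained %||% attr(tensor, "retained") %||%
    matrix(TRUE, dim(tensor)[2L], dim(tensor)[3L])
  systems <- dimnames(tensor)[[3L]]
  rois <- dimnames(tensor)[[2L]]
  stats_out <- NULL
  contrasts_out <- NULL
  n <- dim(tensor)[1L]
  for (ki in seq_along(systems)) {
    keep <- which(retained[, ki])
    if (!length(keep)) next
    Y <- tensor[, keep, ki, drop = TRUE]
    Y <- matrix(Y, nrow = n)
    Fobs <- anova_f_columns(Y, g, k)
    exceed <- integer(length(keep))
    with_seed(substream_seed(seed, paste0("anova", ki)), {
      for (b in seq_len(n_perm)) {
        Fb <- anova_f_columns(Y, g[sample.int(n)], k)
        exceed <- exceed + (Fb >= Fobs)
      }
    })
    p <- (1 + exceed) / (1 + n_perm)
    pf <- fdr_adjust(p)
    stats_out <- rbind(stats_out, data.frame(
      roi = rois[keep], system = systems[ki], F = Fobs, p = p, p_fdr = pf,
      stringsAsFactors = FALSE))
    sig <- which(pf < q)
    if (length(sig)) {
      pairs <- utils::combn(k, 2L)
      for (ri in sig) {
        y <- Y[, ri]
        for (pj in seq_len(ncol(pairs))) {
          a <- pairs[1L, pj]; bI <- pairs[2L, pj]
          ya <- y[g == a]; yb <- y[g == bI]
          na <- length(ya); nb <- length(yb)
          sp2 <- ((na - 1) * var(ya) + (nb - 1) * var(yb)) / (na + nb - 2)
          tval <- (mean(ya) - mean(yb)) / sqrt(sp2 * (1 / na + 1 / nb))
          contrasts_out <- rbind(contrasts_out, data.frame(
            roi = rois[keep][ri], system = systems[ki],
            contrast = paste(lev[a], "vs", lev[bI]), t = tval,
            df = na + nb - 2,
            p = 2 * pt(abs(tval), na + nb - 2, lower.tail = FALSE),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(stats_out)) {
    stats_out <- data.frame(roi = character(0), system = character(0),
                            F = numeric(0), p = numeric(0),
                            p_fdr = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(stats = stats_out, contrasts = contrasts_out,
                 n_perm = n_perm, seed = seed, q = q),
            class = "roi_stat_map")
}

#' Parametric ANOVA with Tukey HSD on summary deviations
#'
#' One-way ANOVA of the per-subject mean deviation of each molecular system
#' across diagnostic groups, with Tukey honestly-significant-difference
#' correction for the pairwise comparisons.
#'
#' @param summary subject x system matrix from [summary_deviation()]
#' @param groups group label per subject
#' @return data.frame per system: `F`, `df1`, `df2`, `p`, plus a `tukey`
#'   attribute (list of per-system TukeyHSD tables)
#' @export
summary_anova <- function(summary, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) abort("every group needs at least 2 subjects")
  systems <- colnames(summary)
  out <- data.frame(system = systems, F = NA_real_, df1 = NA_real_,
                    df2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  tuk <- list()
  for (j in seq_along(systems)) {
    y <- summary[, j]
    fit <- aov(y ~ groups)
    an <- anova(fit)
    out$F[j] <- an[1L, "F value"]
    out$df1[j] <- an[1L, "Df"]
    out$df2[j] <- an[2L, "Df"]
    out$p[j] <- an[1L, "Pr(>F)"]
    tuk[[systems[j]]] <- TukeyHSD(fit)$groups
  }
  attr(out, "tukey") <- tuk
  out
}

#' Logistic-regression screening of a summary deviation metric
#'
#' Fits an unregularised single-predictor logistic regression separating one
#' clinical group from healthy controls on the summary deviation metric, and
#' quantifies discrimination by the area under the ROC curve of the fitted
#' probabilities, computed with the rank (Mann-Whitney) formulation. The AUC
#' is invariant to monotone rescaling of the predictor; the model's
#' coefficient sign sets the direction, so protective (negative) effects
#' still report discrimination above 0.5. Perfect separation yields a valid
#' AUC (1.0) but flags the coefficient as non-converged.
#'
#' @param x summary deviation values (predictor)
#' @param is_case logical: TRUE for the clinical group, FALSE for HC
#' @return list of class `classifier_screen`: `coef` (intercept, slope),
#'   `auc`, `roc` (data.frame fpr/tpr), `converged`
#' @export
logistic_auc <- function(x, is_case) {
  is_case <- as.logical(is_case)
  if (!any(is_case) || all(is_case)) abort("both classes must be nonempty")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(is_case ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  converged <- fit$converged && !separation && !any(abs(coef(fit)) > 1e3)
  ## rank (Mann-Whitney) AUC of the fitted probabilities (monotone in the
  ## predictor; the model's coefficient sign sets the direction), ties half
  score <- fit$fitted.values
  r <- rank(score)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ## ROC curve at every observed threshold of the model score
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(is_case[ord]); fp <- cumsum(!is_case[ord])
  roc <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  structure(list(coef = coef(fit), auc = auc, roc = roc,
                 converged = converged),
            class = "classifier_screen")
}

#' Mass-univariate transdiagnostic deviation-symptom regression
#'
#' For each retained (ROI, system) cell and each retained symptom component,
#' the Pearson correlation of patients' deviation z with the component score
#' (equivalently the single-regressor GLM t, to which it is monotonically
#' related) is tested against its permutation null obtained by shuffling
#' component scores across patients; Benjamini-Hochberg FDR is applied
#' within each (system, component) family.
#'
#' @param tensor a `deviation_tensor` restricted to pooled patients
#' @param pc_scores patients x components score matrix (retained components)
#' @param n_perm number of permutations (default 2000)
#' @param seed permutation seed
#' @param retained optional retention matrix override
#' @return data.frame of class `deviation_symptom_map`: roi, system,
#'   component, r, t, p, p_fdr
#' @export
deviation_symptom_regression <- function(tensor, pc_scores, n_perm = 2000,
                                         seed = 1, retained = NULL) {
  pc_scores <- as.matrix(pc_scores)
  n <- dim(tensor)[1L]
  if (nrow(pc_scores) != n) abort("component scores not aligned with tensor subjects")
  retained <- retained %||% attr(tensor, "retained") %||%
    matrix(TRUE, dim(tensor)[2L], dim(tensor)[3L])
  systems <- dimnames(tensor)[[3L]]
  rois <- dimnames(tensor)[[2L]]
  comp_names <- colnames(pc_scores) %||% paste0("PC", seq_len(ncol(pc_scores)))
  out <- NULL
  for (ki in seq_along(systems)) {
    keep <- which(retained[, ki])
    if (!length(keep)) next
    Y <- matrix(tensor[, keep, ki, drop = TRUE], nrow = n)
    Yc <- sweep(Y, 2L, colMeans(Y))
    ynorm <- sqrt(colSums(Yc^2))
    for (cj in seq_len(ncol(pc_scores))) {
      s <- pc_scores[, cj]
      if (sd(s) == 0) {
        out <- rbind(out, data.frame(
          roi = rois[keep], system = systems[ki], component = comp_names[cj],
          r = NA_real_, t = NA_real_, p = NA_real_, p_fdr = NA_real_,
          stringsAsFactors = FALSE))
        next
      }
      sc <- s - mean(s)
      snorm <- sqrt(sum(sc^2))
      robs <- as.numeric(crossprod(Yc, sc)) / (ynorm * snorm)
      exceed <- integer(length(keep))
      with_seed(substream_seed(seed, paste0("devsym", ki, "_", cj)), {
        for (b in seq_len(n_perm)) {
          sp <- sc[sample.int(n)]
          rb <- as.numeric(crossprod(Yc, sp)) / (ynorm * snorm)
          exceed <- exceed + (abs(rb) >= abs(robs))
        }
      })
      p <- (1 + exceed) / (1 + n_perm)
      tval <- robs * sqrt((n - 2) / pmax(1 - robs^2, 1e-15))
      out <- rbind(out, data.frame(
        roi = rois[keep], system = systems[ki], component = comp_names[cj],
        r = robs, t = tval, p = p, p_fdr = fdr_adjust(p),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(roi = character(0), system = character(0),
                      component = character(0), r = numeric(0), t = numeric(0),
                      p = numeric(0), p_fdr = numeric(0),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("deviation_symptom_map", class(out))
  out
}
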