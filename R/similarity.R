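## Between-subject similarity of feature profiles (symptom scores or ROI
## deviation scores): the subject x subject correlation matrix, within- and
## between-group summaries, Friedman/Conover nonparametric comparisons,
## Kolmogorov-Smirnov distribution tests, and the transdiagnostic similarity
## metric with its deviation/symptom correlates.

#' Between-subject similarity matrix
#'
#' Correlates every pair of subjects' feature vectors (all symptom measures,
#' or one system's deviation z over its retained ROIs). The diagonal is set
#' to `NA` and excluded from every downstream summary.
#'
#' @param features subjects x variables numeric matrix (>= 3 variables)
#' @param labels group label per subject
#' @param method correlation method, `"pearson"` (default) or `"spearman"`
#' @return a list of class `similarity_matrix`: `sim` (subject x subject),
#'   `labels`
#' @export
subject_similarity_matrix <- function(features, labels,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (ncol(features) < 3L) abort("need at least 3 feature variables per subject")
  if (nrow(features) != length(labels)) abort("one label per subject required")
  degenerate <- apply(features, 1L, sd) == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " subject(s) with zero-variance feature vectors; ",
            "their similarities are NA")
  }
  sim <- suppressWarnings(cor(t(features), method = method))
  diag(sim) <- NA_real_
  structure(list(sim = sim, labels = as.character(labels), method = method),
            class = "similarity_matrix")
}

#' Per-subject within- and between-group mean similarity
#'
#' For each subject: the mean similarity to the other members of their own
#' group (within-group) and to the members of every other group
#' (between-group); a subject is never included in their own averages.
#'
#' @param sm a [subject_similarity_matrix()]
#' @return data.frame with `id` (rownames of the matrix), `group`, `within`,
#'   and one `between_<g>` column per other group; singleton groups get `NA`
#'   within-group values (flagged with a warning)
#' @export
group_similarity_summary <- function(sm) {
  stopifnot(inherits(sm, "similarity_matrix"))
  sim <- sm$sim
  labels <- sm$labels
  groups <- unique(labels)
  n <- nrow(sim)
  ids <- rownames(sim) %||% paste0("sub", seq_len(n))
  out <- data.frame(id = ids, group = labels, stringsAsFactors = FALSE)
  out$within <- vapply(seq_len(n), function(i) {
    peers <- which(labels == labels[i]); peers <- setdiff(peers, i)
    if (!length(peers)) NA_real_ else mean(sim[i, peers])
  }, numeric(1L))
  if (anyNA(out$within)) warning("singleton group(s): within-group similarity undefined")
  for (g in groups) {
    out[[paste0("between_", g)]] <- vapply(seq_len(n), function(i) {
      if (labels[i] == g) return(NA_real_)
      mean(sim[i, labels == g])
    }, numeric(1L))
  }
  out
}

#' Friedman test with Conover post-hoc comparisons
#'
#' Nonparametric repeated-measures comparison of k related similarity
#' conditions (e.g. each patient's within-group and two between-group mean
#' similarities). The Friedman chi-square uses within-subject average ranks
#' with the tie-corrected (Conover-Iman) form; post-hoc pairwise Conover t
#' statistics are computed from the rank sums with the pooled-variance form
#' on `(n-1)(k-1)` degrees of freedom, Bonferroni-adjusted over the pairs.
#' For fewer than 5 subjects an exact permutation p-value for the Friedman
#' statistic is substituted (with a warning).
#'
#' @param values n subjects x k conditions numeric matrix
#' @return list of class `friedman_conover`: `statistic` (chi-square), `df`,
#'   `p.value`, and `posthoc` data.frame (pair, t, df, p, p_bonf)
#' @export
friedman_conover <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 2L) abort("need at least 2 related conditions")
  cond <- colnames(values) %||% paste0("cond", seq_len(k))
  Rk <- t(apply(values, 1L, rank))          # average ranks for ties
  A <- sum(Rk^2)
  Rj <- colSums(Rk)
  B <- sum(Rj^2) / n
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  chisq <- if (denom <= 0) 0 else n * (k - 1) * (B - C) / denom
  df <- k - 1
  if (n < 5L) {
    warning("fewer than 5 subjects; using exact permutation p for the Friedman statistic")
    p <- friedman_exact_p(values, chisq)
  } else {
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  ## Conover post-hoc from rank sums; A - B is the within-subject (error)
  ## sum of squares of the ranks
  pairs <- utils::combn(k, 2L)
  df_t <- (n - 1) * (k - 1)
  se <- sqrt(max(2 * n * (A - B) / df_t, 0))
  posthoc <- data.frame(
    pair = apply(pairs, 2L, function(ix) paste(cond[ix], collapse = " vs ")),
    t = NA_real_, df = df_t, p = NA_real_, p_bonf = NA_real_,
    stringsAsFactors = FALSE
  )
  m <- ncol(pairs)
  for (j in seq_len(m)) {
    dR <- Rj[pairs[1L, j]] - Rj[pairs[2L, j]]
    tval <- if (se == 0) ifelse(dR == 0, 0, sign(dR) * Inf) else dR / se
    praw <- 2 * pt(abs(tval), df_t, lower.tail = FALSE)
    posthoc$t[j] <- tval
    posthoc$p[j] <- praw
    posthoc$p_bonf[j] <- min(1, praw * m)
  }
  structure(list(statistic = chisq, df = df, p.value = p, posthoc = posthoc,
                 n = n, k = k),
            class = "friedman_conover")
}

## Exact permutation null of the Friedman statistic for tiny n: enumerate
## independent within-row rank permutations (k! per row) by sampling the full
## product space when small, otherwise Monte Carlo.
friedman_exact_p <- function(values, observed, max_enum = 46656) {
  n <- nrow(values); k <- ncol(values)
  perms <- permutations_of(k)
  total <- nrow(perms)^n
  stat_for <- function(Rk) {
    A <- sum(Rk^2); Rj <- colSums(Rk); B <- sum(Rj^2) / n
    C <- n * k * (k + 1)^2 / 4
    if (A - C <= 0) 0 else n * (k - 1) * (B - C) / (A - C)
  }
  base <- t(apply(values, 1L, rank))
  if (total <= max_enum) {
    idx <- rep(1L, n)
    count <- 0L; ge <- 0L
    repeat {
      Rk <- base
      for (i in seq_len(n)) Rk[i, ] <- base[i, perms[idx[i], ]]
      count <- count + 1L
      if (stat_for(Rk) >= observed - 1e-12) ge <- ge + 1L
      j <- 1L
      while (j <= n) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(perms)) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > n) break
    }
    ge / count
  } else {
    B <- 2000L
    ge <- 0L
    for (b in seq_len(B)) {
      Rk <- base
      for (i in seq_len(n)) Rk[i, ] <- base[i, sample.int(k)]
      if (stat_for(Rk) >= observed - 1e-12) ge <- ge + 1L
    }
    (1 + ge) / (1 + B)
  }
}

## All permutations of 1..k (k! rows), built by inserting k at every position.
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}

#' Two-sample KS test of within-group similarity distributions
#'
#' Compares the within-group similarity coefficients of a clinical group with
#' those of a reference group (e.g. healthy controls) by a two-sample
#' Kolmogorov-Smirnov test. The Bonferroni family is the full set of
#' (molecular system x clinical group) comparisons; for six systems and
#' three clinical groups the denominator is 18.
#'
#' @param sm a [subject_similarity_matrix()] for one molecular system
#' @param clinical_group,reference_group group labels to compare
#' @param n_systems,n_clinical_groups family dimensions for the Bonferroni
#'   correction
#' @param alpha family-wise significance level
#' @return list: `D`, `p.value`, `family_size`, `alpha_corrected`,
#'   `significant`
#' @export
ks_within_group <- function(sm, clinical_group, reference_group,
                            n_systems = 6, n_clinical_groups = 3,
                            alpha = 0.05) {
  summ <- group_similarity_summary(sm)
  x <- summ$within[summ$group == clinical_group]
  y <- summ$within[summ$group == reference_group]
  if (!length(x) || !length(y)) abort("empty group sample in KS comparison")
  kt <- suppressWarnings(ks.test(x, y))
  family <- n_systems * n_clinical_groups
  list(D = unname(kt$statistic), p.value = kt$p.value,
       family_size = family, alpha_corrected = alpha / family,
       significant = kt$p.value < alpha / family)
}

#' Transdiagnostic similarity: each patient's mean similarity to all others
#'
#' Averages each patient's similarity over all other patients pooled across
#' clinical groups (healthy controls excluded), ignoring diagnosis.
#'
#' @param sm a [subject_similarity_matrix()]
#' @param hc_label label identifying healthy controls to exclude
#' @return named numeric vector, one mean similarity per patient
#' @export
transdiagnostic_similarity <- function(sm, hc_label = "HC") {
  stopifnot(inherits(sm, "similarity_matrix"))
  pat <- which(sm$labels != hc_label)
  if (length(pat) < 2L) abort("need at least 2 patients")
  sub <- sm$sim[pat, pat, drop = FALSE]
  out <- rowMeans(sub, na.rm = TRUE)
  names(out) <- rownames(sm$sim)[pat] %||% paste0("sub", pat)
  out
}

#' Correlate transdiagnostic similarity with deviation and symptom summaries
#'
#' Pearson correlation (two-sided t test) of the per-patient transdiagnostic
#' similarity against each target column (the mean-deviation summary and/or
#' retained symptom components), Bonferroni-corrected over the full family
#' of (molecular system x target) tests; for six systems and (1 summary +
#' 4 components) targets the denominator is 30.
#'
#' @param trans named vector from [transdiagnostic_similarity()]
#' @param targets numeric matrix or data.frame of aligned per-patient target
#'   columns
#' @param family_size Bonferroni denominator; defaults to
#'   `n_systems * ncol(targets)`
#' @param n_systems number of molecular systems in the family
#' @param alpha family-wise level
#' @return data.frame: target, r, p, p_bonf, significant; constant targets
#'   get `NA` r with a warning
#' @export
correlate_transdiag <- function(trans, targets, n_systems = 6,
                                family_size = NULL, alpha = 0.05) {
  targets <- as.matrix(targets)
  if (nrow(targets) != length(trans)) abort("targets not aligned with patients")
  if (is.null(family_size)) family_size <- n_systems * ncol(targets)
  tn <- colnames(targets) %||% paste0("target", seq_len(ncol(targets)))
  out <- data.frame(target = tn, r = NA_real_, p = NA_real_,
                    p_bonf = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  n <- length(trans)
  for (j in seq_len(ncol(targets))) {
    y <- targets[, j]
    if (sd(y) == 0) {
      warning("constant target '", tn[j], "': correlation undefined")
      next
    }
    r <- fast_cor(trans, y)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tval), n - 2, lower.tail = FALSE)
    out$r[j] <- r
    out$p[j] <- p
    out$p_bonf[j] <- min(1, p * family_size)
    out$significant[j] <- p < alpha / family_size
  }
  attr(out, "family_size") <- family_size
  out
}
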