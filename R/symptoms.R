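## Transdiagnostic reduction of the psychometric battery: z-scoring across
## pooled patients, the cross-correlation structure, and unrotated
## correlation-matrix PCA with the eigenvalue-one retention criterion.

#' Extract the numeric measure matrix from a symptom table
#'
#' @param symptoms data.frame with `id` and measure columns (non-measure
#'   metadata columns `id`/`diagnosis` are dropped), or a numeric matrix
#' @return numeric matrix, subjects x measures, rownames = subject ids
#' @keywords internal
symptom_matrix <- function(symptoms) {
  if (is.matrix(symptoms)) return(symptoms)
  meta <- intersect(c("id", "diagnosis"), names(symptoms))
  m <- as.matrix(symptoms[, setdiff(names(symptoms), meta), drop = FALSE])
  if ("id" %in% names(symptoms)) rownames(m) <- symptoms$id
  if (anyNA(m)) abort("symptom table contains missing entries; exclude incomplete subjects first")
  m
}

#' Z-score each psychometric measure across pooled patients
#'
#' Standardises every measure to mean 0 and population (1/n) sd 1 across all
#' subjects in the table pooled transdiagnostically, putting heterogeneous
#' clinical scales on a common footing before correlation and PCA.
#'
#' @param symptoms symptom table (data.frame with `id`, optional `diagnosis`,
#'   and measure columns) or numeric matrix
#' @return numeric matrix of standardised measures (subjects x measures)
#' @export
normalize_symptoms <- function(symptoms) {
  m <- symptom_matrix(symptoms)
  sds <- apply(m, 2L, sd_pop)
  if (any(sds == 0)) {
    abort("zero-variance measure(s): ",
          paste(colnames(m)[sds == 0], collapse = ", "))
  }
  sweep(sweep(m, 2L, colMeans(m)), 2L, sds, `/`)
}

#' Cross-correlation matrix of the psychometric measures
#'
#' @param symptoms symptom table or (normalised) measure matrix
#' @return measures x measures Pearson correlation matrix (symmetric, unit
#'   diagonal)
#' @export
symptom_cross_correlation <- function(symptoms) {
  m <- symptom_matrix(symptoms)
  if (nrow(m) < 3L) abort("need at least 3 subjects for cross-correlation")
  cor(m)
}

#' Unrotated PCA of the symptom correlation matrix
#'
#' Eigendecomposition of the Pearson correlation matrix of the pooled-patient
#' measures (equivalent to covariance PCA of the z-scored data). Components
#' are ordered by decreasing eigenvalue; the retained set is all components
#' with eigenvalue strictly greater than 1 (the eigenvalue-one criterion);
#' no rotation is applied. Signs are fixed deterministically: within each
#' component the largest-magnitude loading is made positive.
#'
#' @param symptoms symptom table or measure matrix (raw scales; standardised
#'   internally with the pooled-patient population sd)
#' @return a list of class `pca_result`: `loadings` (measures x components,
#'   orthonormal columns), `scores` (subjects x components, standardised data
#'   projected on the loadings), `eigenvalues`, `explained` (fractions of
#'   total variance), `n_retained`
#' @export
pca_reduce <- function(symptoms) {
  z <- normalize_symptoms(symptoms)
  n <- nrow(z); m <- ncol(z)
  if (m > n) warning("more measures (", m, ") than subjects (", n,
                     "); correlation matrix is rank deficient")
  cmat <- crossprod(z) / n           # correlation matrix of z-scored data
  eig <- eigen(cmat, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  loadings <- eig$vectors
  ## deterministic sign: largest-|loading| positive per component
  for (j in seq_len(m)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(z)
  colnames(loadings) <- paste0("PC", seq_len(m))
  scores <- z %*% loadings
  structure(list(loadings = loadings, scores = scores, eigenvalues = ev,
                 explained = ev / sum(ev), n_retained = sum(ev > 1)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", length(x$eigenvalues), "components;",
      x$n_retained, "retained (eigenvalue > 1), explaining",
      sprintf("%.1f%%", 100 * sum(x$explained[seq_len(x$n_retained)])),
      "of variance\n")
  invisible(x)
}

#' Scores of the retained components only
#'
#' @param pca a [pca_reduce()] result
#' @return subjects x retained-components score matrix
#' @export
retained_scores <- function(pca) {
  pca$scores[, seq_len(pca$n_retained), drop = FALSE]
}
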