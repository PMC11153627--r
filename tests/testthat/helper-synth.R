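## Shared fixtures: all synthetic, built in code at test time.

## Small default study used across tests; any field can be overridden.
tiny_config <- function(...) {
  defaults <- list(
    n_voxels_per_axis = 10, n_systems = 2, n_timepoints = 60,
    n_subjects_per_site = c(a = 12, b = 10),
    n_patients_per_group = c(G1 = 5, G2 = 5, G3 = 5),
    n_rois = 12, seed = 42
  )
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

## Wrap an arbitrary voxel x K value matrix as a template_set (trivial mask).
toy_templates <- function(values, names = NULL) {
  values <- as.matrix(values)
  mask <- array(TRUE, dim = c(nrow(values), 1L, 1L))
  template_set(values, mask, system_names = names)
}

toy_bold <- function(values, subject_id = "toy") {
  values <- as.matrix(values)
  mask <- array(TRUE, dim = c(nrow(values), 1L, 1L))
  bold_run(values, mask, subject_id = subject_id)
}

## Three-group similarity fixture: group members share a latent profile at
## strength rho, so within-group similarity concentrates near rho.
block_similarity_fixture <- function(n_per = 20, rho = 0.5, n_feat = 60, seed = 1) {
  set.seed(seed)
  labels <- rep(c("G1", "G2", "G3"), each = n_per)
  shared <- matrix(rnorm(3 * n_feat), 3, n_feat)
  feats <- t(vapply(seq_along(labels), function(i) {
    g <- match(labels[i], c("G1", "G2", "G3"))
    sqrt(rho) * shared[g, ] + sqrt(1 - rho) * rnorm(n_feat)
  }, numeric(n_feat)))
  rownames(feats) <- sprintf("p%02d", seq_along(labels))
  subject_similarity_matrix(feats, labels)
}

## Independent least-squares oracle: coefficients by explicit pseudo-inverse.
lsq_oracle <- function(X, y) {
  as.matrix(solve(t(X) %*% X, t(X) %*% y))
}

## Construct two unit-variance, zero-mean vectors with exact correlation r.
correlated_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  a <- rnorm(n); b <- rnorm(n)
  a <- (a - mean(a)); a <- a / sqrt(sum(a^2))
  b <- b - sum(a * b) * a
  b <- b - mean(b)  # stays orthogonal to a only approximately after demean
  ## re-orthogonalise exactly within the zero-mean subspace
  b <- b - sum(a * b) / sum(a^2) * a
  b <- b / sqrt(sum(b^2))
  cbind(a, r * a + sqrt(1 - r^2) * b)
}
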