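## Hierarchical Bayesian normative modelling of molecular-enriched FC.
##
## For every (ROI, system) cell, molecular-enriched FC of healthy training
## subjects is modelled as
##
##   y_i = b0 + b_age * age_i + b_sex * sex_i + u_site(i) + eps_i,
##   u_s ~ N(0, tau^2),   eps_i ~ N(0, sigma_s(i)^2),
##
## with the site offsets u_s and site noise variances sigma_s^2 tied through
## shared priors across sites. Two inference engines fit the same model:
##
##   * "eb"    -- fast closed-form empirical-Bayes / EM fit (default):
##                iterates WLS for the fixed effects, conjugate shrinkage of
##                the site offsets, and EM updates of tau^2 and the
##                site noise variances (partially pooled towards their
##                common mean). Deterministic and fast enough for thousands
##                of (ROI, system) cells.
##   * "gibbs" -- full-Bayes conjugate Gibbs sampler (weakly informative
##                Normal / Inverse-Gamma priors, Gamma hyperprior tying the
##                site noise variances), 2 chains, split-Rhat convergence
##                diagnostics.
##
## Deviation z-scores divide the residual (observed - posterior-mean
## prediction) by the full posterior-predictive sd, i.e. parameter
## uncertainty + site-offset uncertainty + site noise.

#' Stratified 70/30-style split of the healthy cohort
#'
#' The total held-out count is `ceiling(test_fraction * N)`; it is allocated
#' across sites proportionally by the largest-remainder rule so every site is
#' represented in both partitions, and membership within site is randomised
#' by `seed`. (For healthy cohorts of 496 and 111 at `test_fraction = 0.30`
#' this yields held-out counts of 150 and 33.)
#'
#' @param healthy data.frame of healthy subjects with columns `id` and `site`
#' @param test_fraction held-out proportion, in (0, 1); default 0.30
#' @param seed integer seed for the randomised membership
#' @return a list of class `split_spec`: `train_ids`, `test_ids`, and a
#'   `counts` data.frame (site, n, n_train, n_test)
#' @export
stratified_split <- function(healthy, test_fraction = 0.30, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1")
  }
  sites <- unique(healthy$site)
  n_s <- table(factor(healthy$site, levels = sites))
  if (any(n_s < 2L)) abort("need at least 2 healthy subjects per site")
  N <- nrow(healthy)
  total_test <- as.integer(ceiling(test_fraction * N))
  quota <- as.numeric(n_s) * total_test / N
  base <- floor(quota)
  rem <- total_test - sum(base)
  if (rem > 0L) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  ## keep both partitions nonempty at every site
  for (i in seq_along(base)) {
    if (base[i] == 0L) {
      donor <- which.max(base)
      base[donor] <- base[donor] - 1L
      base[i] <- 1L
    } else if (base[i] == n_s[i]) {
      base[i] <- base[i] - 1L
      taker <- which.max(n_s - base)
      base[taker] <- base[taker] + 1L
    }
  }
  test_ids <- with_seed(seed, {
    unlist(lapply(seq_along(sites), function(i) {
      ids <- healthy$id[healthy$site == sites[i]]
      sample(ids, base[i])
    }), use.names = FALSE)
  })
  train_ids <- setdiff(healthy$id, test_ids)
  counts <- data.frame(site = sites, n = as.integer(n_s),
                       n_train = as.integer(n_s) - base, n_test = base,
                       stringsAsFactors = FALSE)
  structure(list(train_ids = train_ids, test_ids = test_ids, counts = counts,
                 test_fraction = test_fraction, seed = seed),
            class = "split_spec")
}

## ---- per-cell engines ------------------------------------------------------

## Empirical-Bayes / EM fit of one (ROI, system) cell.
## y: response; X: n x p design (intercept, age, sex); site: integer 1..S.
fit_cell_eb <- function(y, X, site, S, a_pool = 4, max_iter = 200, tol = 1e-10) {
  n <- length(y)
  n_s <- tabulate(site, nbins = S)
  p <- ncol(X)
  var_y <- var(y)
  floor_s2 <- max(1e-10 * var_y, 1e-30)
  beta <- qr.coef(qr(X), y)
  r <- y - X %*% beta
  u <- as.numeric(rowsum(as.numeric(r), site) / n_s)
  sigma2 <- pmax(as.numeric(rowsum(as.numeric(r - u[site])^2, site)) /
                   pmax(n_s - 1L, 1L), floor_s2)
  tau2 <- if (S > 1L) max(var(u), floor_s2) else 0
  vu <- rep(0, S)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old <- c(beta, u, sigma2, tau2)
    w <- 1 / sigma2[site]
    Xw <- X * w
    XtWX <- crossprod(Xw, X)
    Vb <- solve(XtWX)
    beta <- as.numeric(Vb %*% crossprod(Xw, y - u[site]))
    r <- as.numeric(y - X %*% beta)
    if (S > 1L) {
      m_s <- as.numeric(rowsum(r, site)) / n_s
      shrink <- tau2 / (tau2 + sigma2 / n_s)
      u <- shrink * m_s
      vu <- shrink * sigma2 / n_s
      tau2 <- max(mean(u^2 + vu), floor_s2)
    }
    e <- r - u[site]
    sse_s <- as.numeric(rowsum(e^2, site)) + n_s * vu
    s2_pool <- sum(sse_s) / n
    sigma2 <- pmax((sse_s + a_pool * s2_pool) / (n_s + a_pool), floor_s2)
    if (max(abs(c(beta, u, sigma2, tau2) - old)) < tol * (1 + max(abs(old)))) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, Vbeta = Vb, u = u, vu = vu,
       cov_bu = matrix(0, p, S), sigma2 = sigma2, tau2 = tau2,
       converged = converged && all(is.finite(c(beta, u, sigma2))),
       rhat = NA_real_)
}

## Conjugate Gibbs sampler for one cell; same return contract as fit_cell_eb.
fit_cell_gibbs <- function(y, X, site, S, n_chains = 2L, n_warmup = 1000L,
                           n_draws = 1000L, rhat_threshold = 1.05,
                           seed = 1L) {
  n <- length(y)
  p <- ncol(X)
  n_s <- tabulate(site, nbins = S)
  var_y <- var(y)
  sd_x <- pmax(apply(X, 2L, sd), 1e-12); sd_x[1L] <- 1
  prior_prec_b <- diag(1 / (10 * sqrt(var_y) / sd_x)^2, p)
  a_t <- 2; b_t <- 0.5 * var_y          # tau^2 ~ IG(a_t, b_t)
  a_s <- 2                               # sigma_s^2 ~ IG(a_s, b_noise)
  g_shape <- 2; g_rate <- 2 / var_y      # b_noise ~ Gamma(g_shape, g_rate)
  total <- n_chains * n_draws
  Bdraw <- matrix(NA_real_, total, p)
  Udraw <- matrix(NA_real_, total, S)
  S2draw <- matrix(NA_real_, total, S)
  T2draw <- numeric(total)
  ## joint (beta, u) Gaussian block: design D = [X | site indicators];
  ## sampling the block jointly avoids the intercept/offset ridge
  use_u <- S > 1L
  Z <- if (use_u) outer(site, seq_len(S), `==`) * 1 else NULL
  D <- cbind(X, Z)
  q <- ncol(D)
  DtD_site <- lapply(seq_len(S), function(s) {
    rows <- site == s
    list(DtD = crossprod(D[rows, , drop = FALSE]),
         Dty = crossprod(D[rows, , drop = FALSE], y[rows]))
  })
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch * 7177L)
    sigma2 <- rep(var_y * runif(1L, 0.5, 2), S)
    tau2 <- var_y * runif(1L, 0.2, 1)
    b_noise <- var_y
    theta <- numeric(q)
    u <- rep(0, S)
    for (it in seq_len(n_warmup + n_draws)) {
      ## (beta, u) | rest: joint Gaussian draw
      A <- matrix(0, q, q)
      bvec <- numeric(q)
      for (s in seq_len(S)) {
        A <- A + DtD_site[[s]]$DtD / sigma2[s]
        bvec <- bvec + DtD_site[[s]]$Dty / sigma2[s]
      }
      A[seq_len(p), seq_len(p)] <- A[seq_len(p), seq_len(p)] + prior_prec_b
      if (use_u) {
        iu <- p + seq_len(S)
        A[cbind(iu, iu)] <- A[cbind(iu, iu)] + 1 / tau2
      }
      cA <- chol(A)
      theta <- backsolve(cA, backsolve(cA, bvec, transpose = TRUE)) +
        backsolve(cA, rnorm(q))
      beta <- theta[seq_len(p)]
      if (use_u) u <- theta[p + seq_len(S)]
      r <- as.numeric(y - D %*% theta)
      if (use_u) tau2 <- 1 / rgamma(1L, a_t + S / 2, b_t + sum(u^2) / 2)
      ## sigma_s^2 | rest, site noises tied by the shared Gamma hyperprior
      for (s in seq_len(S)) {
        e2 <- sum(r[site == s]^2)
        sigma2[s] <- 1 / rgamma(1L, a_s + n_s[s] / 2, b_noise + e2 / 2)
      }
      b_noise <- rgamma(1L, g_shape + S * a_s, g_rate + sum(1 / sigma2))
      if (it > n_warmup) {
        row <- (ch - 1L) * n_draws + (it - n_warmup)
        Bdraw[row, ] <- beta
        Udraw[row, ] <- u
        S2draw[row, ] <- sigma2
        T2draw[row] <- tau2
      }
    }
  }
  draws <- cbind(Bdraw, if (S > 1L) Udraw, S2draw)
  rhat <- max(apply(draws, 2L, split_rhat, n_chains = n_chains))
  BU <- cbind(Bdraw, Udraw)
  covBU <- stats::cov(BU)
  list(beta = colMeans(Bdraw),
       Vbeta = covBU[seq_len(p), seq_len(p), drop = FALSE],
       u = colMeans(Udraw),
       vu = apply(Udraw, 2L, var),
       cov_bu = covBU[seq_len(p), p + seq_len(S), drop = FALSE],
       sigma2 = colMeans(S2draw),
       tau2 = if (S > 1L) mean(T2draw) else 0,
       converged = is.finite(rhat) && rhat < rhat_threshold,
       rhat = rhat)
}

#' Split-Rhat convergence diagnostic for a single parameter
#'
#' Potential-scale-reduction factor computed after splitting each chain in
#' half; values near 1 indicate the chains mix over the same distribution.
#'
#' @param x vector of stacked posterior draws (chains concatenated)
#' @param n_chains number of chains concatenated in `x`
#' @return the split-Rhat statistic
#' @export
split_rhat <- function(x, n_chains = 2L) {
  n <- length(x) %/% n_chains
  half <- n %/% 2L
  chains <- lapply(seq_len(n_chains), function(ch) x[(ch - 1L) * n + seq_len(n)])
  splits <- unlist(lapply(chains, function(v) {
    list(v[seq_len(half)], v[(half + 1L):(2L * half)])
  }), recursive = FALSE)
  m <- length(splits)
  means <- vapply(splits, mean, numeric(1L))
  vars <- vapply(splits, var, numeric(1L))
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

## ---- whole-array fitting ---------------------------------------------------

#' Fit hierarchical Bayesian normative models for every (ROI, system) cell
#'
#' Trains, on healthy-control training subjects only, one normative model per
#' (ROI, system) cell of the value array: age and sex as fixed effects, site
#' as a random intercept with site-specific noise, tied through shared
#' priors.
#'
#' @param rm a [roi_matrix()] of molecular-enriched FC values
#' @param cohort the matching cohort data.frame (`id`, `site`, `age`, `sex`,
#'   `diagnosis`)
#' @param train_ids subject ids of the healthy training partition (all must
#'   be labelled `HC`)
#' @param mode `"eb"` (fast closed-form empirical Bayes, default) or
#'   `"gibbs"` (full-Bayes conjugate Gibbs sampler)
#' @param n_chains,n_warmup,n_draws Gibbs sampler settings
#' @param rhat_threshold convergence threshold on the largest split-Rhat of a
#'   cell; non-converged cells are flagged and excluded downstream
#' @param seed seed for the sampler (ignored by `"eb"`, which is
#'   deterministic)
#' @return an object of class `normative_fit`
#' @export
fit_normative <- function(rm, cohort, train_ids,
                          mode = c("eb", "gibbs"),
                          n_chains = 2L, n_warmup = 1000L, n_draws = 1000L,
                          rhat_threshold = 1.05, seed = 1L) {
  mode <- match.arg(mode)
  dn <- dimnames(rm)
  idx <- match(train_ids, dn[[1L]])
  if (anyNA(idx)) abort("some `train_ids` are missing from the value array")
  crows <- match(train_ids, cohort$id)
  if (anyNA(crows)) abort("some `train_ids` are missing from the cohort")
  if (any(cohort$diagnosis[crows] != "HC")) {
    abort("normative training data must be healthy controls only")
  }
  sub <- cohort[crows, ]
  sites <- sort(unique(sub$site))
  S <- length(sites)
  site_i <- match(sub$site, sites)
  X <- cbind(intercept = 1, age = sub$age, sex = sub$sex)
  R <- dim(rm)[2L]; K <- dim(rm)[3L]; p <- ncol(X)
  fit <- list(
    beta = array(NA_real_, c(R, K, p)),
    Vbeta = array(NA_real_, c(R, K, p, p)),
    u = array(NA_real_, c(S, R, K)),
    vu = array(NA_real_, c(S, R, K)),
    cov_bu = array(NA_real_, c(R, K, p, S)),
    sigma2 = array(NA_real_, c(S, R, K)),
    tau2 = matrix(NA_real_, R, K),
    converged = matrix(FALSE, R, K),
    rhat = matrix(NA_real_, R, K),
    sites = sites, roi_names = dn[[2L]], system_names = dn[[3L]],
    mode = mode, train_ids = train_ids
  )
  for (k in seq_len(K)) {
    for (r in seq_len(R)) {
      y <- rm[idx, r, k]
      cell <- if (mode == "eb") {
        fit_cell_eb(y, X, site_i, S)
      } else {
        fit_cell_gibbs(y, X, site_i, S, n_chains = n_chains,
                       n_warmup = n_warmup, n_draws = n_draws,
                       rhat_threshold = rhat_threshold,
                       seed = seed + 131L * r + 17L * k)
      }
      fit$beta[r, k, ] <- cell$beta
      fit$Vbeta[r, k, , ] <- cell$Vbeta
      fit$u[, r, k] <- cell$u
      fit$vu[, r, k] <- cell$vu
      fit$cov_bu[r, k, , ] <- cell$cov_bu
      fit$sigma2[, r, k] <- cell$sigma2
      fit$tau2[r, k] <- cell$tau2
      fit$converged[r, k] <- cell$converged
      fit$rhat[r, k] <- cell$rhat
    }
  }
  class(fit) <- "normative_fit"
  fit
}

#' @export
print.normative_fit <- function(x, ...) {
  cat("<normative_fit>", length(x$roi_names), "ROIs x",
      length(x$system_names), "systems;", x$mode, "mode;",
      sum(x$converged), "/", length(x$converged), "cells converged\n")
  invisible(x)
}

#' Posterior-mean predictions and predictive sds for a set of subjects
#'
#' @param fit a [fit_normative()] object
#' @param cohort cohort data.frame covering the requested subjects
#' @param subject_ids subjects to predict; their sites must have been seen in
#'   training (no silent extrapolation)
#' @return list with `mu` and `sd`, both subject x ROI x system arrays; the
#'   sd is the full posterior-predictive sd (fixed-effect + site-offset
#'   uncertainty + site noise)
#' @export
predict_normative <- function(fit, cohort, subject_ids) {
  crows <- match(subject_ids, cohort$id)
  if (anyNA(crows)) abort("unknown subject id(s)")
  sub <- cohort[crows, ]
  unseen <- setdiff(unique(sub$site), fit$sites)
  if (length(unseen)) {
    abort("site(s) not seen in training: ", paste(unseen, collapse = ", "))
  }
  site_i <- match(sub$site, fit$sites)
  X <- cbind(1, sub$age, sub$sex)
  n <- nrow(X); R <- length(fit$roi_names); K <- length(fit$system_names)
  p <- ncol(X)
  mu <- array(NA_real_, c(n, R, K))
  sdv <- array(NA_real_, c(n, R, K))
  for (k in seq_len(K)) {
    for (r in seq_len(R)) {
      b <- fit$beta[r, k, ]
      Vb <- fit$Vbeta[r, k, , ]
      cb <- fit$cov_bu[r, k, , , drop = TRUE]
      cb <- matrix(cb, nrow = p)
      m <- as.numeric(X %*% b) + fit$u[site_i, r, k]
      qf <- rowSums((X %*% Vb) * X)
      cross <- 2 * rowSums(X * t(cb[, site_i, drop = FALSE]))
      v <- qf + fit$vu[site_i, r, k] + cross + fit$sigma2[site_i, r, k]
      mu[, r, k] <- m
      sdv[, r, k] <- sqrt(pmax(v, 0))
    }
  }
  dn <- list(subject_ids, fit$roi_names, fit$system_names)
  dimnames(mu) <- dn; dimnames(sdv) <- dn
  list(mu = mu, sd = sdv)
}

#' Held-out explained variance per (ROI, system) cell
#'
#' `EV = 1 - SSE / SST` on the held-out healthy subjects, with SSE from the
#' posterior-mean predictions and SST about the held-out mean. Cells with
#' zero held-out variance are flagged `NA`.
#'
#' @param fit a [fit_normative()] object
#' @param rm the [roi_matrix()] of observed values
#' @param cohort the cohort data.frame
#' @param test_ids held-out healthy subject ids (disjoint from training)
#' @return an R x K matrix of EV values
#' @export
explained_variance <- function(fit, rm, cohort, test_ids) {
  if (length(intersect(test_ids, fit$train_ids))) {
    abort("test subjects overlap the training partition")
  }
  pred <- predict_normative(fit, cohort, test_ids)
  idx <- match(test_ids, dimnames(rm)[[1L]])
  obs <- rm[idx, , , drop = FALSE]
  R <- dim(rm)[2L]; K <- dim(rm)[3L]
  ev <- matrix(NA_real_, R, K,
               dimnames = list(fit$roi_names, fit$system_names))
  for (k in seq_len(K)) {
    ok <- matrix(obs[, , k], ncol = R)
    pk <- matrix(pred$mu[, , k], ncol = R)
    sse <- colSums((ok - pk)^2)
    sst <- colSums(sweep(ok, 2L, colMeans(ok))^2)
    ev[, k] <- ifelse(sst > 0, 1 - sse / sst, NA_real_)
  }
  ev
}

#' Per-system ROI retention masks from explained variance
#'
#' Retains, for each molecular system, the ROIs whose held-out explained
#' variance is strictly positive and whose model converged; all groups use
#' identical masks (patients never influence retention).
#'
#' @param ev the R x K EV matrix from [explained_variance()]
#' @param converged optional R x K logical convergence matrix (taken from
#'   the fit); cells flagged non-converged are dropped regardless of EV
#' @return an R x K logical retention matrix
#' @export
retain_rois <- function(ev, converged = NULL) {
  keep <- !is.na(ev) & ev > 0
  if (!is.null(converged)) keep <- keep & converged
  keep
}

#' Uncertainty-normalised deviation z-scores
#'
#' `z = (observed - predicted) / predictive sd` for every subject in
#' `subject_ids` at every retained (ROI, system) cell; observed above the
#' normative prediction gives positive z. Non-retained cells are `NA`.
#'
#' @param fit a [fit_normative()] object
#' @param rm the [roi_matrix()] of observed values
#' @param cohort the cohort data.frame
#' @param subject_ids subjects to score (typically held-out HC and all
#'   patients)
#' @param retained R x K logical retention matrix from [retain_rois()];
#'   defaults to all-retained
#' @return a `deviation_tensor`: a [roi_matrix()] of z-scores with the
#'   retention matrix in attribute `retained`
#' @export
deviation_scores <- function(fit, rm, cohort, subject_ids, retained = NULL) {
  pred <- predict_normative(fit, cohort, subject_ids)
  idx <- match(subject_ids, dimnames(rm)[[1L]])
  if (anyNA(idx)) abort("subject id(s) missing from the value array")
  obs <- rm[idx, , , drop = FALSE]
  z <- (obs - pred$mu) / pred$sd
  if (is.null(retained)) {
    retained <- matrix(TRUE, dim(rm)[2L], dim(rm)[3L],
                       dimnames = list(fit$roi_names, fit$system_names))
  }
  for (k in seq_len(dim(z)[3L])) z[, !retained[, k], k] <- NA_real_
  out <- roi_matrix(z, subject_ids = subject_ids,
                    roi_names = fit$roi_names,
                    system_names = fit$system_names)
  attr(out, "retained") <- retained
  class(out) <- c("deviation_tensor", class(out))
  out
}

#' Per-subject summary deviation: mean z over retained ROIs
#'
#' Collapses the deviation tensor to one mean z per subject and molecular
#' system, averaging over that system's retained ROIs only.
#'
#' @param tensor a `deviation_tensor` from [deviation_scores()]
#' @return a subject x system numeric matrix; a system retaining zero ROIs
#'   yields `NA` with a warning
#' @export
summary_deviation <- function(tensor) {
  retained <- attr(tensor, "retained")
  K <- dim(tensor)[3L]
  out <- matrix(NA_real_, dim(tensor)[1L], K,
                dimnames = list(dimnames(tensor)[[1L]], dimnames(tensor)[[3L]]))
  for (k in seq_len(K)) {
    keep <- retained[, k]
    if (!any(keep)) {
      warning("system '", dimnames(tensor)[[3L]][k],
              "' retains zero ROIs; summary deviation is NA")
      next
    }
    out[, k] <- rowMeans(tensor[, keep, k, drop = FALSE], na.rm = FALSE)
  }
  out
}
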