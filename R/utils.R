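## Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed
#'
#' A single master seed drives every stochastic component of a simulated
#' study. Each component (templates, cohort, noise, ...) draws from its own
#' substream so that, e.g., changing the number of timepoints does not
#' perturb the cohort. The derivation is a small deterministic hash kept
#' within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed
#' @param purpose character tag naming the substream
#' @return an integer seed
#' @keywords internal
substream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629) + 1L
}

## Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## stop() with a consistent prefix and no call in the message
abort <- function(...) stop(..., call. = FALSE)

## Population (1/n) standard deviation of a vector.
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

## Pearson correlation of two vectors without the dispatch overhead of cor()
## checks; used in tight loops.
fast_cor <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

## Benjamini-Hochberg adjusted p-values (thin alias, kept for readability).
fdr_adjust <- function(p) p.adjust(p, method = "BH")
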