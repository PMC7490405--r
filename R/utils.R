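#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG state and restore the caller's state after.
# All package randomness goes through here so results are reproducible and
# independent of the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Derive named per-stage random seeds from one master seed
#'
#' Every stochastic stage of the pipeline (cohort generation, k-means
#' initialisation, bootstrap resampling, data partitioning, cross-validation
#' fold assignment) draws its own seed from a single master seed, so stages
#' can be re-run in isolation while the end-to-end run stays reproducible.
#'
#' @param seed Integer master seed.
#' @return Named integer vector with elements `generator`, `kmeans`,
#'   `bootstrap`, `split`, `cv`.
#' @export
stage_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  stages <- c("generator", "kmeans", "bootstrap", "split", "cv")
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(stages)))
  stats::setNames(as.integer(s), stages)
}

# Shared input check helpers ------------------------------------------------

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
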