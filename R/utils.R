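# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# All user-facing randomness funnels through this so a seed argument makes
# the result reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  expr
}

# Quantile of a normal truncated below at `lower` (mean may be a vector).
# sd == 0 collapses to the (floored) mean, which gives exactly-degenerate
# draws for zero-variance configurations.
qtnorm <- function(p, mean, sd, lower) {
  if (sd < 0) stop("standard deviation must be >= 0")
  if (sd == 0) {
    return(rep_len(pmax(mean, lower), length(p)))
  }
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + p * (1 - plo), mean, sd)
}

rtnorm <- function(n, mean, sd, lower) {
  qtnorm(stats::runif(n), mean, sd, lower)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
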