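# Internal helpers shared across modules.

#' Clamp values to an interval
#' @param x numeric vector
#' @param lo,hi interval bounds
#' @return clamped vector
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Sample from a normal(mean, sd) truncated to [lo, hi] by inverse-CDF.
# sd = 0 degenerates to the (clamped) mean.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop_field("sd", "must be >= 0")
  if (sd == 0) return(rep(clamp(mean, lo, hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  clamp(qnorm(u, mean, sd), lo, hi)
}
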