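#' @importFrom stats var sd cor optim rbeta rbinom rlnorm rnorm runif
#' @importFrom stats qlogis plogis pchisq ks.test cor.test logLik vcov
#' @importFrom stats model.matrix simulate fitted setNames quantile median
#' @importFrom stats as.dist binom.test ave
#' @importFrom utils head read.csv write.csv combn
NULL

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (divide-by-n) standard deviation and coefficient of variation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

pop_cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  pop_sd(x) / m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

utc_year <- function(t) as.integer(format(t, "%Y", tz = "UTC"))
utc_date <- function(t) as.Date(format(t, "%Y-%m-%d", tz = "UTC"))
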