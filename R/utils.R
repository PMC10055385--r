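#' @import data.table
#' @importFrom stats glm binomial coef qnorm pnorm rnorm runif rpois rbinom
#'   quantile sd predict setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream: seeds with `seed`, pins the generator
# kind so results do not depend on session options, and restores the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == trunc(x) && x >= 0

# Truncated-normal draws by inverse CDF so the RNG stream length is fixed
# (one uniform per draw) regardless of the bounds.
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}
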