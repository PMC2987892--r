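#' @importFrom stats rnorm runif qnorm pnorm dnorm dpois rpois mad median
#'   sd var anova lm rgamma coef setNames complete.cases
NULL

## Condition helpers -------------------------------------------------------

pc_error <- function(msg, class) {
  stop(structure(
    class = c(class, "picocyte_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

param_error     <- function(msg) pc_error(msg, "picocyte_parameter_error")
detection_error <- function(msg) pc_error(msg, "picocyte_detection_error")
render_error    <- function(msg) pc_error(msg, "picocyte_render_error")
quality_error   <- function(msg) pc_error(msg, "picocyte_quality_error")
config_error    <- function(msg) pc_error(msg, "picocyte_config_error")

## Seeded evaluation -------------------------------------------------------

# All generator randomness funnels through here: a NULL seed uses the current
# RNG stream, an integer seed gives bit-identical results without disturbing
# the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

## Truncated distributions -------------------------------------------------

#' Truncated normal draws
#'
#' Inverse-CDF sampler for a normal distribution truncated below at `lower`
#' (default 0).  Vectorised over `mean` and `sd`; `sd = 0` returns
#' `pmax(mean, lower)` deterministically.
#'
#' @param n number of draws
#' @param mean,sd normal parameters (recycled)
#' @param lower lower truncation bound
#' @return numeric vector of length `n`
#' @keywords internal
rtnorm <- function(n, mean, sd, lower = 0) {
  mean <- rep_len(mean, n)
  sd   <- rep_len(sd, n)
  out  <- pmax(mean, lower)
  pos  <- sd > 0
  if (any(pos)) {
    plo <- pnorm(lower, mean[pos], sd[pos])
    u   <- plo + runif(sum(pos)) * (1 - plo)
    out[pos] <- qnorm(pmin(u, 1 - 1e-16), mean[pos], sd[pos])
  }
  pmax(out, lower)
}

# Poisson truncated to 0..cap via inverse CDF on the renormalised pmf.
rtpois <- function(n, lambda, cap) {
  pmf <- dpois(0:cap, lambda)
  s <- sum(pmf)
  if (s <= 0) param_error("truncated-Poisson support is empty")
  cdf <- cumsum(pmf) / s
  findInterval(runif(n), cdf) # 0-based counts
}

# Mean of the 0..cap truncated Poisson by direct enumeration of the pmf.
tpois_mean <- function(lambda, cap) {
  pmf <- dpois(0:cap, lambda)
  sum((0:cap) * pmf) / sum(pmf)
}

## Misc --------------------------------------------------------------------

pop_sd <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip14 <- function(x) pmin(pmax(x, 0), 16383)

# Bilinear interpolation of matrix img (dim nx x ny) at fractional (x, y).
bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(x, 1), nx - 1e-9)
  y <- pmin(pmax(y, 1), ny - 1e-9)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}
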