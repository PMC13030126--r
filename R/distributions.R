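#' Triangular distribution
#'
#' Density, distribution function, quantile function and random
#' generation for the triangular distribution with minimum `a`, mode
#' `c` and maximum `b` (`a <= c <= b`).  Used for the soil ingestion
#' rate, whose survey-derived uncertainty is conventionally encoded as
#' triangular(min, most-likely, max).  Random draws use the inverse-CDF
#' transform of `runif`, so they are reproducible under `set.seed`.
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param a,b,c Minimum, maximum and mode.
#' @return `dtri` the density, `ptri` the CDF, `qtri` the quantile
#'   function, `rtri` random draws.
#' @name triangular
NULL

#' @rdname triangular
#' @export
dtri <- function(x, a, c, b) {
  check_tri(a, c, b)
  if (a == b) return(ifelse(x == a, Inf, 0))
  out <- numeric(length(x))
  left <- x >= a & x < c
  right <- x >= c & x <= b
  if (c > a) out[left] <- 2 * (x[left] - a) / ((b - a) * (c - a))
  if (b > c) out[right] <- 2 * (b - x[right]) / ((b - a) * (b - c))
  if (b == c) out[x == c] <- 2 / (b - a)
  out
}

#' @rdname triangular
#' @export
ptri <- function(q, a, c, b) {
  check_tri(a, c, b)
  if (a == b) return(as.numeric(q >= a))
  out <- numeric(length(q))
  left <- q > a & q <= c
  right <- q > c & q < b
  if (c > a) out[left] <- (q[left] - a)^2 / ((b - a) * (c - a))
  if (c == a) out[q == a] <- 0
  out[right] <- 1 - (b - q[right])^2 / ((b - a) * (b - c))
  out[q >= b] <- 1
  out
}

#' @rdname triangular
#' @export
qtri <- function(p, a, c, b) {
  check_tri(a, c, b)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must be in [0, 1]", call. = FALSE)
  }
  if (a == b) return(rep(a, length(p)))
  fc <- (c - a) / (b - a)
  ifelse(p <= fc,
         a + sqrt(p * (b - a) * (c - a)),
         b - sqrt((1 - p) * (b - a) * (b - c)))
}

#' @rdname triangular
#' @export
rtri <- function(n, a, c, b) {
  qtri(stats::runif(n), a, c, b)
}

check_tri <- function(a, c, b) {
  if (!(a <= c && c <= b)) {
    stop("triangular parameters must satisfy min <= mode <= max",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Seeded triangular sampling
#'
#' Convenience wrapper over [rtri()] that optionally pins the RNG seed
#' locally (the global RNG state is untouched).
#'
#' @param min,mode,max Triangular parameters, `min <= mode <= max`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return `n` draws, all within `[min, max]`.
#' @examples
#' sample_triangular(66, 103, 161, n = 5, seed = 1)
#' @export
sample_triangular <- function(min, mode, max, n, seed = NULL) {
  check_tri(min, mode, max)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(seed)) rtri(n, min, mode, max)
  else withr::with_seed(seed, rtri(n, min, mode, max))
}

#' Distribution specification for a Monte Carlo input
#'
#' A small tagged container naming a parametric family and its
#' parameters.  `"fixed"` (a degenerate point mass at `value`) is
#' accepted everywhere a stochastic family is, which lets a simulation
#' collapse to the deterministic point estimate.
#'
#' @param family One of `"normal"`, `"lognormal"`, `"triangular"`,
#'   `"uniform"`, `"gamma"`, `"weibull"`, `"fixed"`.
#' @param ... Family parameters: `mean`/`sd` (normal), `meanlog`/`sdlog`
#'   (lognormal), `min`/`mode`/`max` (triangular), `min`/`max`
#'   (uniform), `shape`/`rate` (gamma), `shape`/`scale` (weibull),
#'   `value` (fixed).
#' @param source `"fitted"` or `"fixed"` provenance tag.
#' @return A `dist_spec` object.
#' @examples
#' dist_spec("triangular", min = 66, mode = 103, max = 161)
#' dist_spec("lognormal", meanlog = 1, sdlog = 0.5)
#' @export
dist_spec <- function(family = c("normal", "lognormal", "triangular",
                                 "uniform", "gamma", "weibull", "fixed"),
                      ..., source = c("fixed", "fitted")) {
  family <- match.arg(family)
  source <- match.arg(source)
  params <- list(...)
  need <- switch(family,
    normal = c("mean", "sd"), lognormal = c("meanlog", "sdlog"),
    triangular = c("min", "mode", "max"), uniform = c("min", "max"),
    gamma = c("shape", "rate"), weibull = c("shape", "scale"),
    fixed = "value")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop(family, " spec missing parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  ok <- switch(family,
    normal = params$sd >= 0,
    lognormal = params$sdlog >= 0,
    triangular = params$min <= params$mode && params$mode <= params$max,
    uniform = params$min <= params$max,
    gamma = params$shape > 0 && params$rate > 0,
    weibull = params$shape > 0 && params$scale > 0,
    fixed = is.finite(params$value))
  if (!isTRUE(ok)) stop("invalid ", family, " parameters", call. = FALSE)
  structure(list(family = family, params = params, source = source),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("dist_spec:", x$family, "(",
      paste(names(x$params), signif(unlist(x$params), 5), sep = " = ",
            collapse = ", "), ") [", x$source, "]\n")
  invisible(x)
}

#' Mean, CDF and sampler of a dist_spec
#'
#' `spec_mean` returns the analytic mean; `spec_cdf` evaluates the CDF
#' (used by the Anderson-Darling statistic); `sample_spec` draws `n`
#' values, optionally rejecting-and-resampling draws outside
#' `[lower, upper]` so that physical constraints (nonnegative
#' concentrations, bioaccessibility at most 1) hold.
#'
#' @param spec A [dist_spec()].
#' @param q Quantiles for `spec_cdf`.
#' @param n Number of draws.
#' @param lower,upper Acceptance bounds for rejection sampling.
#' @return Numeric mean, CDF values, or draws respectively.
#' @export
spec_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    normal = p$mean,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    triangular = (p$min + p$mode + p$max) / 3,
    uniform = (p$min + p$max) / 2,
    gamma = p$shape / p$rate,
    weibull = p$scale * gamma(1 + 1 / p$shape),
    fixed = p$value)
}

#' @rdname spec_mean
#' @export
spec_cdf <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    normal = stats::pnorm(q, p$mean, p$sd),
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
    triangular = ptri(q, p$min, p$mode, p$max),
    uniform = stats::punif(q, p$min, p$max),
    gamma = stats::pgamma(q, shape = p$shape, rate = p$rate),
    weibull = stats::pweibull(q, shape = p$shape, scale = p$scale),
    fixed = as.numeric(q >= p$value))
}

#' @rdname spec_mean
#' @export
sample_spec <- function(spec, n, lower = -Inf, upper = Inf) {
  p <- spec$params
  draw <- function(m) switch(spec$family,
    normal = stats::rnorm(m, p$mean, p$sd),
    lognormal = stats::rlnorm(m, p$meanlog, p$sdlog),
    triangular = rtri(m, p$min, p$mode, p$max),
    uniform = stats::runif(m, p$min, p$max),
    gamma = stats::rgamma(m, shape = p$shape, rate = p$rate),
    weibull = stats::rweibull(m, shape = p$shape, scale = p$scale),
    fixed = rep(p$value, m))
  if (spec$family == "fixed") {
    v <- p$value
    if (v < lower || v > upper) {
      stop("fixed value outside [lower, upper]", call. = FALSE)
    }
    return(rep(v, n))
  }
  out <- draw(n)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad)) {
    out[bad] <- draw(length(bad))
    bad <- bad[out[bad] < lower | out[bad] > upper]
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("rejection sampling failed: spec mass almost entirely outside ",
           "bounds", call. = FALSE)
    }
  }
  out
}
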