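#' Anderson-Darling goodness of fit against a candidate distribution
#'
#' Computes the A-squared statistic from the sorted probability-integral
#' transform,
#' \deqn{A^2 = -n - \frac{1}{n}\sum (2i-1)\left[\ln u_{(i)} +
#'   \ln(1 - u_{(n+1-i)})\right],}
#' and compares a small-sample-adjusted version against the 5-percent
#' critical value appropriate for the family (parameters-estimated
#' tables of Stephens for the normal/lognormal and Weibull cases, used
#' for gamma as well; the all-parameters-known value 2.492 for uniform
#' and triangular, whose moment-style fits do not match a tabulated
#' estimated-parameter case and are therefore judged conservatively).
#'
#' @param data Numeric sample, at least 5 distinct values.
#' @param spec A [dist_spec()] (typically the fitted candidate).
#' @return A `fit_result`: list with `spec`, `ad_statistic` (raw A2),
#'   `ad_modified`, `critical`, `n`, `accepted`.
#' @examples
#' x <- withr::with_seed(1, rnorm(100))
#' anderson_darling(x, dist_spec("normal", mean = mean(x), sd = sd(x)))
#' @export
anderson_darling <- function(data, spec) {
  data <- as.numeric(data)
  n <- length(data)
  if (n < 5 || length(unique(data)) < 5) {
    stop("need at least 5 distinct values", call. = FALSE)
  }
  u <- spec_cdf(spec, sort(data))
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  adj <- switch(spec$family,
    normal = ,
    lognormal = a2 * (1 + 0.75 / n + 2.25 / n^2),
    gamma = ,
    weibull = a2 * (1 + 0.2 / sqrt(n)),
    a2)
  crit <- switch(spec$family,
    normal = , lognormal = 0.752,
    gamma = , weibull = 0.757,
    2.492)
  structure(
    list(spec = spec, ad_statistic = a2, ad_modified = adj,
         critical = crit, n = n, accepted = adj < crit),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$spec$family, "A2 =", signif(x$ad_statistic, 4),
      "(n =", x$n, ")", if (x$accepted) "accepted" else "rejected",
      "at alpha = 0.05\n")
  invisible(x)
}

#' Fit one parametric family to data
#'
#' Normal and lognormal use closed-form maximum likelihood; gamma and
#' Weibull use [MASS::fitdistr()]; uniform uses the sample range;
#' triangular uses the sample range with a moment estimate of the mode
#' (`3*mean - min - max`, clipped into the range).  Families whose
#' support excludes the data (nonpositive values for the log families)
#' return `NULL`, as do numerical failures.
#'
#' @param data Numeric sample.
#' @param family Family name as in [dist_spec()].
#' @return A fitted [dist_spec()] (source `"fitted"`) or `NULL`.
#' @export
fit_family <- function(data, family) {
  x <- as.numeric(data)
  n <- length(x)
  tryCatch(switch(family,
    normal = dist_spec("normal", mean = mean(x),
                       sd = stats::sd(x) * sqrt((n - 1) / n),
                       source = "fitted"),
    lognormal = {
      if (any(x <= 0)) return(NULL)
      lx <- log(x)
      dist_spec("lognormal", meanlog = mean(lx),
                sdlog = stats::sd(lx) * sqrt((n - 1) / n),
                source = "fitted")
    },
    uniform = dist_spec("uniform", min = min(x), max = max(x),
                        source = "fitted"),
    triangular = {
      mode <- 3 * mean(x) - min(x) - max(x)
      dist_spec("triangular", min = min(x),
                mode = min(max(mode, min(x)), max(x)), max = max(x),
                source = "fitted")
    },
    gamma = {
      if (any(x <= 0)) return(NULL)
      start <- list(shape = mean(x)^2 / stats::var(x),
                    rate = mean(x) / stats::var(x))
      f <- suppressWarnings(MASS::fitdistr(x, "gamma", start = start,
                                           lower = c(1e-10, 1e-10)))
      dist_spec("gamma", shape = f$estimate[["shape"]],
                rate = f$estimate[["rate"]], source = "fitted")
    },
    weibull = {
      if (any(x <= 0)) return(NULL)
      f <- suppressWarnings(MASS::fitdistr(x, "weibull",
                                           lower = c(1e-10, 1e-10)))
      dist_spec("weibull", shape = f$estimate[["shape"]],
                scale = f$estimate[["scale"]], source = "fitted")
    },
    stop("unknown family: ", family, call. = FALSE)
  ), error = function(e) NULL)
}

#' Select the best-fitting candidate family by Anderson-Darling
#'
#' Fits every candidate family and returns the fit with the smallest
#' A-squared statistic; ties break deterministically by the order of
#' `families`.  Constant data short-circuit to a degenerate fixed-value
#' spec (flagged via `degenerate = TRUE`).
#'
#' @param data Numeric sample, n >= 5.
#' @param families Candidate family names, tried in order.
#' @return A `fit_result` (with `degenerate = TRUE` for constant data).
#' @examples
#' x <- withr::with_seed(7, rlnorm(200, 1, 0.5))
#' fit_best(x)$spec$family
#' @export
fit_best <- function(data,
                     families = c("normal", "lognormal", "triangular",
                                  "uniform", "gamma", "weibull")) {
  x <- as.numeric(data)
  if (length(x) < 5) stop("need n >= 5", call. = FALSE)
  if (length(unique(x)) == 1) {
    res <- list(spec = dist_spec("fixed", value = x[1]),
                ad_statistic = 0, ad_modified = 0, critical = NA_real_,
                n = length(x), accepted = TRUE, degenerate = TRUE)
    return(structure(res, class = "fit_result"))
  }
  fits <- list()
  for (fam in families) {
    spec <- fit_family(x, fam)
    if (is.null(spec)) next
    r <- tryCatch(anderson_darling(x, spec), error = function(e) NULL)
    if (!is.null(r) && is.finite(r$ad_statistic)) fits[[fam]] <- r
  }
  if (!length(fits)) stop("no candidate family could be fitted",
                          call. = FALSE)
  stat <- vapply(fits, `[[`, numeric(1), "ad_statistic")
  best <- fits[[which.min(stat)]]   # which.min keeps first on ties
  best$degenerate <- FALSE
  best
}

#' Monte Carlo simulation configuration
#'
#' @param n_iter Iterations (default 10000).
#' @param seed Integer seed; every random draw in the run is derived
#'   from it, so identical seeds give identical output.
#' @param params An [exposure_params()]; `EF`, `ED`, `BW`, `AT` and
#'   `CF` are treated as deterministic, and `IR_S` is superseded by the
#'   ingestion-rate spec of [run_simulation()].
#' @param weights A [fraction_weights()] held fixed across iterations
#'   (cohort mass-fraction variability is low relative to
#'   concentration/BA variability).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_iter = 10000, seed = 1, params,
                              weights = soil_weights()) {
  stopifnot(inherits(params, "exposure_params"))
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 params = params, weights = weights),
            class = "simulation_config")
}

# Deterministic 31-bit sub-seed per (seed, key) so each input variable
# owns its own reproducible stream regardless of evaluation order.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

#' Probabilistic hazard-quotient simulation
#'
#' Per iteration draws each (metal, fraction) concentration and
#' bioaccessibility independently from their specs, draws the ingestion
#' rate, applies the dose model with fixed exposure parameters and
#' fixed fraction weights, and divides by the RfD.  Concentrations are
#' constrained to be nonnegative and bioaccessibility to `[0, 1]` by
#' rejection resampling.  Each input variable has its own RNG substream
#' keyed by `(seed, metal, fraction, variable)`, so results do not
#' depend on metal ordering; one shared ingestion-rate stream is used
#' across metals (every metal is ingested with the same soil).
#'
#' @param conc_specs,ba_specs Nested named lists
#'   `specs[[metal]][[fraction]]` of [dist_spec()]s covering every
#'   metal in `rfd` and every fraction of the weight scheme.
#' @param ir_spec [dist_spec()] for the ingestion rate, mg/d (default
#'   the survey triangular 66/103/161).
#' @param config A [simulation_config()].
#' @param rfd Named RfD vector defining the metals simulated.
#' @return A `risk_summary`: per-metal list with `samples`,
#'   `percentiles` (p5/p50/p95/mean) and `exceedance` = P(HQ > 1),
#'   plus a `summary` tibble.
#' @export
run_simulation <- function(conc_specs, ba_specs,
                           ir_spec = dist_spec("triangular", min = 66,
                                               mode = 103, max = 161),
                           config, rfd = default_rfd()) {
  stopifnot(inherits(config, "simulation_config"))
  metals <- names(rfd)
  labels <- config$weights$scheme$labels
  w <- config$weights$w
  p <- config$params
  n <- config$n_iter
  for (m in metals) for (f in labels) {
    if (is.null(conc_specs[[m]][[f]])) {
      stop("missing concentration spec for (", m, ", ", f, ")",
           call. = FALSE)
    }
    if (is.null(ba_specs[[m]][[f]])) {
      stop("missing bioaccessibility spec for (", m, ", ", f, ")",
           call. = FALSE)
    }
  }
  ir <- withr::with_seed(derive_seed(config$seed, "IR"),
                         sample_spec(ir_spec, n, lower = 0))
  dists <- lapply(metals, function(m) {
    # same operation order as add_fraction()/hq_table() so that all-fixed
    # specs collapse bitwise onto the deterministic point estimate
    hq_cols <- matrix(0, nrow = n, ncol = length(labels))
    for (j in seq_along(labels)) {
      f <- labels[j]
      ci <- withr::with_seed(
        derive_seed(config$seed, paste("conc", m, f)),
        sample_spec(conc_specs[[m]][[f]], n, lower = 0))
      bi <- withr::with_seed(
        derive_seed(config$seed, paste("ba", m, f)),
        sample_spec(ba_specs[[m]][[f]], n, lower = 0, upper = 1))
      add_j <- ci * ir * p$CF * bi * p$EF * p$ED / (p$BW * p$AT)
      hq_cols[, j] <- add_j / rfd[[m]]
    }
    samples <- rowSums(sweep(hq_cols, 2, w, `*`))
    list(metal = m, samples = samples,
         percentiles = c(p5 = unname(stats::quantile(samples, 0.05,
                                                     names = FALSE)),
                         p50 = stats::median(samples),
                         p95 = unname(stats::quantile(samples, 0.95,
                                                      names = FALSE)),
                         mean = mean(samples)),
         exceedance = mean(samples > 1))
  })
  names(dists) <- metals
  summary <- tibble::tibble(
    metal = metals,
    p5 = vapply(dists, function(d) d$percentiles[["p5"]], numeric(1)),
    p50 = vapply(dists, function(d) d$percentiles[["p50"]], numeric(1)),
    p95 = vapply(dists, function(d) d$percentiles[["p95"]], numeric(1)),
    mean = vapply(dists, function(d) d$percentiles[["mean"]], numeric(1)),
    p_hq_gt_1 = vapply(dists, function(d) d$exceedance, numeric(1))
  )
  structure(list(distributions = dists, summary = summary,
                 seed = config$seed, n_iter = n),
            class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat("Monte Carlo risk summary (", x$n_iter, " iterations, seed ",
      x$seed, "):\n", sep = "")
  print(dplyr::mutate(x$summary,
                      dplyr::across(dplyr::where(is.numeric),
                                    ~ signif(.x, 3))))
  invisible(x)
}

#' Percentile table of simulated samples
#'
#' Percentiles are computed by linear interpolation between the two
#' closest order statistics (`stats::quantile` type 7).
#'
#' @param samples Nonempty numeric vector.
#' @param probs Percentiles in (0, 100).
#' @return Tibble with `prob_percent` and `value`, monotone in
#'   `probs`.
#' @examples
#' summarize_cdf(c(10, 20, 30, 40), 50)  # 25
#' @export
summarize_cdf <- function(samples, probs = c(5, 25, 50, 75, 95)) {
  if (!length(samples)) stop("empty sample", call. = FALSE)
  if (any(probs <= 0 | probs >= 100)) {
    stop("probs must lie in (0, 100)", call. = FALSE)
  }
  ord <- order(probs)
  tibble::tibble(
    prob_percent = probs[ord],
    value = stats::quantile(samples, probs[ord] / 100, names = FALSE,
                            type = 7)
  )
}
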