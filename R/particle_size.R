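#' One measured particle-size distribution
#'
#' Holds one subject's (or one site's) binned mass distribution as it
#' comes off a laser-diffraction sizer: strictly increasing bin edges in
#' micrometres and a nonnegative mass (or mass fraction) per bin.
#' Masses need not be normalized; operations that need proportions
#' normalize internally.
#'
#' @param subject_id Identifier (coerced to character).
#' @param bin_edges Strictly increasing diameters, um; length
#'   `length(mass_per_bin) + 1`.
#' @param mass_per_bin Nonnegative masses, one per bin; total must be
#'   positive.
#' @return A `psd_record` object.
#' @examples
#' psd_record("child01", c(0, 63, 150, 250, 352),
#'            c(0.643, 0.309, 0.0431, 0.0049))
#' @export
psd_record <- function(subject_id, bin_edges, mass_per_bin) {
  bin_edges <- as.numeric(bin_edges)
  mass_per_bin <- as.numeric(mass_per_bin)
  if (length(mass_per_bin) != length(bin_edges) - 1L) {
    stop("need length(mass_per_bin) == length(bin_edges) - 1", call. = FALSE)
  }
  if (anyNA(bin_edges) || any(diff(bin_edges) <= 0) || any(bin_edges < 0)) {
    stop("bin_edges must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  if (anyNA(mass_per_bin) || any(mass_per_bin < 0)) {
    stop("mass_per_bin must be nonnegative", call. = FALSE)
  }
  if (sum(mass_per_bin) <= 0) {
    stop("total mass must be positive", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id)[1],
         bin_edges = bin_edges, mass_per_bin = mass_per_bin),
    class = "psd_record"
  )
}

#' @export
print.psd_record <- function(x, ...) {
  cat("psd_record", x$subject_id, "-", length(x$mass_per_bin),
      "bins over", format_um(min(x$bin_edges)), "to",
      format_um(max(x$bin_edges)), "um\n")
  invisible(x)
}

#' Rebin a particle-size distribution onto a fraction scheme
#'
#' Mass in a measurement bin that straddles a scheme edge is split in
#' proportion to linear diameter width within the bin.  The output sums
#' to the mass of `psd` lying inside the scheme's range, so binning
#' conserves mass.
#'
#' @param psd A [psd_record()].
#' @param scheme A [size_scheme()].
#' @return Named numeric vector, one mass per scheme fraction.
#' @examples
#' bin_psd(psd_record("u", c(0, 352), 1), size_scheme())
#' @export
bin_psd <- function(psd, scheme = size_scheme()) {
  stopifnot(inherits(psd, "psd_record"), is_size_scheme(scheme))
  lo <- psd$bin_edges[-length(psd$bin_edges)]
  hi <- psd$bin_edges[-1]
  slo <- scheme$edges[-length(scheme$edges)]
  shi <- scheme$edges[-1]
  # overlap[i, j]: share of psd bin j falling in scheme fraction i
  out <- vapply(seq_along(slo), function(i) {
    ov <- pmax(0, pmin(hi, shi[i]) - pmax(lo, slo[i])) / (hi - lo)
    sum(psd$mass_per_bin * ov)
  }, numeric(1))
  if (sum(out) <= 0) stop("no mass in scheme range", call. = FALSE)
  names(out) <- scheme$labels
  out
}

#' Diameter at a cumulative mass percentile (D10/D50/D90)
#'
#' Interpolates the cumulative mass curve linearly against
#' log10(diameter) within the containing bin, the convention used when
#' reading Dxx values off laser-diffraction output.  A lower edge of 0
#' is floored at 0.01 um for the interpolation only.
#'
#' @param psd A [psd_record()].
#' @param p Percentile in (0, 100).
#' @return Diameter in um.
#' @examples
#' percentile_diameter(psd_record("u", c(10, 1000), 1), 50)  # 100 um
#' @export
percentile_diameter <- function(psd, p) {
  stopifnot(inherits(psd, "psd_record"))
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 100) {
    stop("p must be a single value in (0, 100)", call. = FALSE)
  }
  total <- sum(psd$mass_per_bin)
  target <- p / 100 * total
  cum <- cumsum(psd$mass_per_bin)
  i <- which(cum >= target - 1e-12 * total)[1]
  below <- if (i > 1) cum[i - 1] else 0
  lo <- max(psd$bin_edges[i], 0.01)
  hi <- psd$bin_edges[i + 1]
  m <- psd$mass_per_bin[i]
  if (m <= 0 || target <= below) return(psd$bin_edges[i])
  frac <- min((target - below) / m, 1)
  10^(log10(lo) + frac * (log10(hi) - log10(lo)))
}

#' Pool a cohort of PSDs into exposure weights
#'
#' Bins each record onto `scheme`, converts to per-subject proportions,
#' averages arithmetically across subjects and renormalizes to sum to
#' one — the convention used to turn a cohort of hand-rinse dust
#' distributions into a single exposure weight vector.
#'
#' @param psds List of [psd_record()]s (a single record is accepted).
#' @param scheme A [size_scheme()].
#' @return A [fraction_weights()] with provenance `"hand_dust"`.
#' @export
pooled_weights <- function(psds, scheme = size_scheme()) {
  if (inherits(psds, "psd_record")) psds <- list(psds)
  if (!length(psds)) stop("need at least one PSD record", call. = FALSE)
  per <- vapply(psds, function(p) {
    b <- bin_psd(p, scheme)
    b / sum(b)
  }, numeric(n_fractions(scheme)))
  w <- rowMeans(matrix(per, nrow = n_fractions(scheme)))
  fraction_weights(w, scheme, provenance = "hand_dust", normalize = TRUE)
}

#' Soil weights from three fine-fraction percentages under a sieve cap
#'
#' Sieved-soil reports often print only the finer fraction percentages;
#' the coarsest fraction (250 um up to the sieve cap) is the remainder
#' to 100 percent.
#'
#' @param fractions_percent Percent mass in the `<63`, `63-150` and
#'   `150-250` um fractions; nonnegative, summing to at most 100.
#' @param cap Sieve cap in um (upper edge of the coarsest fraction).
#' @return A [fraction_weights()] with provenance `"soil"` on the
#'   scheme `c(0, 63, 150, 250, cap)`.
#' @examples
#' soil_weights_under_cap(c(44.6, 30.9, 14.9))
#' @export
soil_weights_under_cap <- function(fractions_percent, cap = 352) {
  fractions_percent <- as.numeric(fractions_percent)
  if (length(fractions_percent) != 3 || anyNA(fractions_percent) ||
      any(fractions_percent < 0)) {
    stop("need three nonnegative percentages", call. = FALSE)
  }
  s <- sum(fractions_percent)
  if (s > 100 + 1e-9) stop("fraction percentages exceed 100", call. = FALSE)
  scheme <- size_scheme(c(0, 63, 150, 250, cap))
  fraction_weights(c(fractions_percent, 100 - s) / 100, scheme,
                   provenance = "soil")
}

#' Selective-adherence enrichment of hand dust over soil
#'
#' The elementwise ratio of hand-dust to soil weights per fraction: a
#' ratio above 1 marks fractions enriched on skin relative to ambient
#' soil (selective adherence of fine particles).  A fraction absent
#' from soil but present on hands is reported as `Inf`.
#'
#' @param hand,soil [fraction_weights()] on the same scheme.
#' @return Named numeric vector of ratios.
#' @examples
#' enrichment_ratio(hand_dust_weights(), soil_weights())
#' @export
enrichment_ratio <- function(hand, soil) {
  stopifnot(inherits(hand, "fraction_weights"),
            inherits(soil, "fraction_weights"))
  if (!same_scheme(hand$scheme, soil$scheme)) {
    stop("hand and soil weights use different schemes", call. = FALSE)
  }
  r <- hand$w / soil$w
  r[soil$w == 0 & hand$w == 0] <- NaN
  r
}

#' Read particle-size distributions from long-format CSV
#'
#' Expects columns `subject_id`, `bin_lower_um`, `bin_upper_um`,
#' `mass_fraction`; rows for one subject must form contiguous,
#' increasing bins.
#'
#' @param path CSV file path.
#' @return Named list of [psd_record()]s.
#' @export
read_psd_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "bin_lower_um", "bin_upper_um", "mass_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("psd csv missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  recs <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$bin_lower_um), ]
    if (any(abs(d$bin_upper_um[-nrow(d)] - d$bin_lower_um[-1]) > 1e-9)) {
      stop("bins for subject ", d$subject_id[1], " are not contiguous",
           call. = FALSE)
    }
    psd_record(d$subject_id[1],
               c(d$bin_lower_um, d$bin_upper_um[nrow(d)]),
               d$mass_fraction)
  })
  recs[unique(as.character(df$subject_id))]
}

#' @rdname read_psd_csv
#' @param psds Named list of [psd_record()]s.
#' @param path Output path.
#' @export
write_psd_csv <- function(psds, path) {
  rows <- lapply(psds, function(p) {
    tibble::tibble(
      subject_id = p$subject_id,
      bin_lower_um = p$bin_edges[-length(p$bin_edges)],
      bin_upper_um = p$bin_edges[-1],
      mass_fraction = p$mass_per_bin
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}
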