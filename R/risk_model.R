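#' Exposure parameters for incidental soil ingestion
#'
#' The scalar factors of the average-daily-dose model
#' \deqn{ADD_i = \frac{C_i \cdot IR_S \cdot CF \cdot BA_i \cdot EF
#'   \cdot ED}{BW \cdot AT}}
#' `IR_S` is the soil ingestion rate (mg/d), `CF` the mg-to-kg
#' conversion (1e-6), `EF` the exposure frequency (d/y), `ED` the
#' exposure duration (y), `BW` body weight (kg) and `AT` the averaging
#' time (d; `ED * 365` for non-carcinogenic endpoints).  `EF`, `ED`,
#' `BW` and `AT` are population-specific and must be supplied by the
#' user; only the ingestion rate (103 mg/d, the mode of the triangular
#' distribution used in the probabilistic layer) and `CF` have
#' defaults.
#'
#' @param IR_S Soil ingestion rate, mg/d.
#' @param CF Mass conversion factor, kg/mg.
#' @param EF Exposure frequency, d/y.
#' @param ED Exposure duration, y.
#' @param BW Body weight, kg.
#' @param AT Averaging time, d.
#' @return An `exposure_params` list.
#' @examples
#' exposure_params(EF = 350, ED = 6, BW = 20, AT = 6 * 365)
#' @export
exposure_params <- function(IR_S = 103, CF = 1e-6, EF, ED, BW, AT) {
  p <- list(IR_S = IR_S, CF = CF, EF = EF, ED = ED, BW = BW, AT = AT)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("exposure parameters must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "exposure_params")
}

#' @export
print.exposure_params <- function(x, ...) {
  cat("exposure_params: IR_S =", x$IR_S, "mg/d, EF =", x$EF, "d/y, ED =",
      x$ED, "y, BW =", x$BW, "kg, AT =", x$AT, "d\n")
  invisible(x)
}

#' Per-fraction average daily dose
#'
#' @param C Metal concentration in the fraction, mg/kg.
#' @param BA Bioaccessible fraction, unitless in `[0, 1]` (values up to
#'   1.5 tolerated as flagged mass-balance noise; anything larger is
#'   almost certainly a percentage passed where a fraction was meant
#'   and raises an error).
#' @param params An [exposure_params()].
#' @return ADD in mg/(kg d).
#' @examples
#' p <- exposure_params(EF = 350, ED = 6, BW = 20, AT = 2190)
#' add_fraction(100, 0.5, p)  # 2.4692e-4
#' @export
add_fraction <- function(C, BA, params) {
  stopifnot(inherits(params, "exposure_params"))
  if (any(C < 0, na.rm = TRUE)) stop("C must be nonnegative", call. = FALSE)
  if (any(BA < 0 | BA > 1.5, na.rm = TRUE)) {
    stop("BA outside [0, 1.5]: looks like percent where a fraction ",
         "was expected", call. = FALSE)
  }
  C * params$IR_S * params$CF * BA * params$EF * params$ED /
    (params$BW * params$AT)
}

#' Mass-fraction-weighted total across size fractions
#'
#' Combines per-fraction values (ADD or HQ; HQ is linear in ADD so the
#' operation commutes with division by the RfD) into a single total
#' using a normalized weight vector.
#'
#' @param values One value per fraction.
#' @param weights A [fraction_weights()] or bare numeric weight vector
#'   of the same length.
#' @return Weighted sum.
#' @examples
#' weighted_total(c(0.229, 0.170, 0.129, 0.0790), soil_weights())
#' @export
weighted_total <- function(values, weights) {
  w <- as_weight_vector(weights)
  if (length(values) != length(w)) {
    stop("values and weights differ in length", call. = FALSE)
  }
  sum(w * values)
}

#' Hazard quotient
#'
#' @param ADD Average daily dose, mg/(kg d).
#' @param rfd Oral reference dose, mg/(kg d), positive.
#' @return `ADD / rfd`, unitless.
#' @export
hq <- function(ADD, rfd) {
  if (any(rfd <= 0)) stop("rfd must be positive", call. = FALSE)
  ADD / rfd
}

#' Hazard index across metals
#'
#' @param total_hq_per_metal Named vector of per-metal total HQs.
#' @return Their sum (HI); HI < 1 is conventionally acceptable.
#' @export
hazard_index <- function(total_hq_per_metal) {
  if (!length(total_hq_per_metal)) stop("no metals supplied", call. = FALSE)
  sum(total_hq_per_metal)
}

#' Per-fraction contribution shares to each metal's total risk
#'
#' For each metal, the share of size fraction i is
#' `w_i * HQ_i / sum_j w_j * HQ_j`; shares sum to one per metal and are
#' invariant under rescaling of the HQ row.
#'
#' @param hq_matrix Metals-by-fractions matrix of hazard quotients.
#' @param weights A [fraction_weights()] (or numeric vector) matching
#'   the columns.
#' @return Matrix of shares, same shape as `hq_matrix`; an all-zero row
#'   yields `NaN`s with a warning.
#' @examples
#' contribution_by_fraction(smelter_hq_reference()$hq, soil_weights())
#' @export
contribution_by_fraction <- function(hq_matrix, weights) {
  hq_matrix <- as.matrix(hq_matrix)
  w <- as_weight_vector(weights, ncol(hq_matrix))
  weighted <- sweep(hq_matrix, 2, w, `*`)
  tot <- rowSums(weighted)
  if (any(tot == 0)) {
    warning("all-zero HQ row(s): contribution shares undefined",
            call. = FALSE)
  }
  sweep(weighted, 1, tot, `/`)
}

#' Each metal's share of the hazard index
#'
#' @param total_hq_per_metal Named vector of per-metal total HQs with
#'   positive sum.
#' @return Percent shares summing to 100.
#' @examples
#' metal_share_of_hi(smelter_hq_reference()$total)
#' @export
metal_share_of_hi <- function(total_hq_per_metal) {
  hi <- hazard_index(total_hq_per_metal)
  if (hi == 0) stop("hazard index is zero; shares undefined", call. = FALSE)
  100 * total_hq_per_metal / hi
}

#' Fine-to-coarse hazard-quotient ratio per metal
#'
#' Ratio of each metal's HQ in the finest fraction (first column) to
#' its HQ in the coarsest (last column); summarizes how much more risk
#' the fine particles carry per unit ingested mass.
#'
#' @param hq_matrix Metals-by-fractions HQ matrix.
#' @return List with per-metal `ratio` and the `min`/`max` across
#'   metals; a zero coarsest HQ gives `Inf` with a warning.
#' @export
fine_coarse_ratio <- function(hq_matrix) {
  hq_matrix <- as.matrix(hq_matrix)
  coarse <- hq_matrix[, ncol(hq_matrix)]
  if (any(coarse == 0)) {
    warning("zero HQ in coarsest fraction: ratio infinite", call. = FALSE)
  }
  r <- hq_matrix[, 1] / coarse
  list(ratio = r, min = min(r), max = max(r))
}

#' Build the full hazard-quotient table from concentrations and BA
#'
#' Applies the dose model per (metal, fraction), divides by the RfD,
#' weights across fractions, and assembles totals, the hazard index and
#' the contribution decomposition in one object.  Internal math is full
#' precision; rounding to 3 significant figures happens only in
#' `print()` and CSV display columns.
#'
#' @param conc Metals-by-fractions concentration matrix, mg/kg.
#' @param ba Metals-by-fractions bioaccessible-fraction matrix
#'   (unitless; conventionally the intestinal phase).
#' @param params An [exposure_params()].
#' @param rfd Named RfD vector covering the metals (default
#'   [default_rfd()]).
#' @param weights A [fraction_weights()]; default [soil_weights()],
#'   the vector that reproduces the bundled reference table.
#' @return An `hq_table`: list with `hq` (matrix), `add` (matrix),
#'   `totals`, `hi`, `contributions`, `weights`, plus Cr/Pb caveat
#'   notes.
#' @export
hq_table <- function(conc, ba, params, rfd = default_rfd(),
                     weights = soil_weights()) {
  conc <- as.matrix(conc)
  ba <- as.matrix(ba)
  if (!all(dim(conc) == dim(ba))) {
    stop("conc and ba must have identical dimensions", call. = FALSE)
  }
  metals <- rownames(conc)
  if (is.null(metals)) stop("conc needs metal rownames", call. = FALSE)
  if (!all(metals %in% names(rfd))) {
    stop("rfd missing for: ",
         paste(setdiff(metals, names(rfd)), collapse = ", "), call. = FALSE)
  }
  add <- add_fraction(conc, ba, params)
  hqm <- sweep(add, 1, rfd[metals], `/`)
  totals <- apply(hqm, 1, weighted_total, weights = weights)
  structure(
    list(
      hq = hqm, add = add, totals = totals, hi = hazard_index(totals),
      contributions = contribution_by_fraction(hqm, weights),
      weights = weights,
      notes = c(
        if ("Cr" %in% metals)
          "Cr: total Cr assessed against the Cr(VI) RfD (conservative).",
        if ("Pb" %in% metals)
          "Pb: HQ framework is a screening-level surrogate for blood-Pb modelling."
      )
    ),
    class = "hq_table"
  )
}

#' Wrap an existing hazard-quotient matrix as an hq_table
#'
#' For working with already-computed per-fraction HQs (e.g. a published
#' point-estimate table) without re-deriving doses.
#'
#' @param hq_matrix Metals-by-fractions HQ matrix.
#' @param weights A [fraction_weights()] matching the columns.
#' @return An `hq_table` (no `add` component).
#' @export
hq_table_from_matrix <- function(hq_matrix, weights = soil_weights()) {
  hq_matrix <- as.matrix(hq_matrix)
  totals <- apply(hq_matrix, 1, weighted_total, weights = weights)
  structure(
    list(hq = hq_matrix, add = NULL, totals = totals,
         hi = hazard_index(totals),
         contributions = contribution_by_fraction(hq_matrix, weights),
         weights = weights, notes = character()),
    class = "hq_table"
  )
}

#' @export
print.hq_table <- function(x, digits = 3, ...) {
  cat("Hazard quotients (", x$weights$provenance, " weights):\n", sep = "")
  print(signif(cbind(x$hq, Total = x$totals), digits))
  cat("Hazard index:", signif(x$hi, digits),
      if (x$hi < 1) "(below 1: acceptable)" else "(EXCEEDS 1)", "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
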