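#' Bundled reference values from a smelter-area child-exposure survey
#'
#' The package ships the summary statistics of a field survey of 17
#' courtyard soils and 30 children's hand-rinse dust samples collected
#' around a large nonferrous smelter.  They serve three purposes: as the
#' defaults of the synthetic-data generator, as worked-example inputs,
#' and as the reference point for the internal-consistency checks in the
#' test suite.  All concentrations are mg per kg dry soil; mass
#' fractions and bioaccessibilities are percentages as originally
#' reported.
#'
#' @name smelter_reference
#' @keywords datasets
NULL

METALS <- c("Cd", "Cr", "Cu", "Ni", "Pb")

#' @describeIn smelter_reference Oral reference doses, mg/(kg d)
#'   (Cr entered as the Cr(VI) value: using it against total Cr is
#'   conservative).
#' @export
default_rfd <- function() {
  c(Cd = 1e-3, Cr = 3e-3, Cu = 4e-3, Ni = 2e-3, Pb = 1.4e-3)
}

#' @describeIn smelter_reference Instrumental limits of detection,
#'   mg/kg.
#' @export
default_lods <- function() {
  c(Cd = 0.03, Cr = 2.00, Cu = 0.70, Ni = 2.00, Pb = 1.00)
}

#' @describeIn smelter_reference Mean hand-loaded-dust mass fractions
#'   (percent of total mass) for the four default size fractions.
#' @export
smelter_hand_fractions <- function() {
  c(`<63` = 64.3, `63-150` = 30.9, `150-250` = 4.31, `250-352` = 0.490)
}

#' @describeIn smelter_reference Courtyard-soil mass fractions (percent)
#'   under the 352-um sieve cap; the coarsest value is the remainder to
#'   100 of the three finer cuts.
#' @export
smelter_soil_fractions <- function() {
  c(`<63` = 44.6, `63-150` = 30.9, `150-250` = 14.9, `250-352` = 9.6)
}

#' @describeIn smelter_reference Mean total metal concentrations in
#'   soil, mg/kg.
#' @export
smelter_metal_means <- function() {
  c(Cd = 18.5, Cr = 67.9, Cu = 565, Ni = 26.2, Pb = 432)
}

#' @describeIn smelter_reference Mean PBET bioaccessibility (percent)
#'   by digestion phase.
#' @param phase `"gastric"` or `"intestinal"`.
#' @export
smelter_ba_means <- function(phase = c("gastric", "intestinal")) {
  phase <- match.arg(phase)
  switch(phase,
    gastric    = c(Cd = 49.1, Cr = 9.93, Cu = 32.1, Ni = 14.9, Pb = 24.1),
    intestinal = c(Cd = 26.3, Cr = 8.61, Cu = 28.0, Ni = 12.6, Pb = 20.1)
  )
}

#' @describeIn smelter_reference Point-estimate hazard quotients by
#'   metal and size fraction (metals as rows), together with the
#'   published weighted Total row and the soil-derived weight vector
#'   that reproduces it.
#' @export
smelter_hq_reference <- function() {
  scheme <- size_scheme()
  hq <- matrix(
    c(0.0210,  0.0125,  0.00851, 0.00667,   # Cd
      0.00666, 0.00441, 0.00387, 0.00265,   # Cr
      0.132,   0.0908,  0.0640,  0.0483,    # Cu
      0.00478, 0.00415, 0.00387, 0.00319,   # Ni
      0.229,   0.170,   0.129,   0.0790),   # Pb
    nrow = 5, byrow = TRUE,
    dimnames = list(METALS, scheme$labels)
  )
  list(
    hq = hq,
    total = c(Cd = 0.0149, Cr = 0.00523, Cu = 0.100, Ni = 0.00430,
              Pb = 0.183),
    weights = soil_weights()
  )
}

#' Preset exposure-weight vectors
#'
#' `hand_dust_weights()` is the pooled hand-loaded-dust distribution of
#' the 30-child reference cohort; `soil_weights()` is the sieved
#' courtyard-soil distribution.  The hand-dust vector represents the
#' particles actually ingested via hand-to-mouth contact; the soil
#' vector reproduces the reference point-estimate HQ table (see
#' [smelter_hq_reference()]), and is therefore the default of the
#' deterministic pipeline.  Which of the two is appropriate depends on
#' whether the per-fraction concentrations are to be weighted by what
#' adheres to hands or by what the ambient soil contains.
#'
#' @param scheme A [size_scheme()]; must have four fractions.
#' @return A [fraction_weights()] object.
#' @examples
#' hand_dust_weights()
#' soil_weights()
#' @export
hand_dust_weights <- function(scheme = size_scheme()) {
  fraction_weights(smelter_hand_fractions(), scheme,
                   provenance = "hand_dust", normalize = TRUE)
}

#' @rdname hand_dust_weights
#' @export
soil_weights <- function(scheme = size_scheme()) {
  fraction_weights(smelter_soil_fractions(), scheme,
                   provenance = "soil", normalize = TRUE)
}

check_metals <- function(x, what = "metal") {
  x <- as.character(x)
  bad <- setdiff(unique(x), METALS)
  if (length(bad)) {
    stop("unknown ", what, ": ", paste(bad, collapse = ", "),
         " (expected ", paste(METALS, collapse = "/"), ")", call. = FALSE)
  }
  x
}
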