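# Shared fixtures and independent oracles.

default_params <- function() {
  exposure_params(EF = 350, ED = 6, BW = 20, AT = 2190)
}

# A random PSD with integer-micron bin edges, so the 1-um brute-force
# rebinning oracle is an exact decomposition.
random_int_psd <- function(n_bins = 50, max_edge = 400) {
  edges <- sort(sample(0:max_edge, n_bins + 1))
  while (any(diff(edges) == 0)) edges <- sort(sample(0:max_edge, n_bins + 1))
  psd_record("rnd", edges, runif(n_bins))
}

# Brute-force oracle: expand each bin into 1-um slices of equal density,
# then sum slices into scheme fractions.
brute_force_bin <- function(psd, scheme) {
  lo <- psd$bin_edges[-length(psd$bin_edges)]
  hi <- psd$bin_edges[-1]
  dens <- psd$mass_per_bin / (hi - lo)
  slice_lo <- unlist(mapply(function(l, h) l:(h - 1), lo, hi,
                            SIMPLIFY = FALSE))
  slice_mass <- rep(dens, hi - lo)
  out <- vapply(seq_len(length(scheme$edges) - 1), function(i) {
    sum(slice_mass[slice_lo >= scheme$edges[i] &
                   slice_lo < scheme$edges[i + 1]])
  }, numeric(1))
  names(out) <- scheme$labels
  out
}

fixed_spec_list <- function(mat) {
  labels <- colnames(mat)
  out <- lapply(rownames(mat), function(m) {
    stats::setNames(lapply(mat[m, ], function(v)
      dist_spec("fixed", value = v)), labels)
  })
  stats::setNames(out, rownames(mat))
}
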