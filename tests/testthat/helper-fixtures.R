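# Shared fixtures: small genomes and profiles built in code.

# A toy genome of a few equal chromosomes for fast unit tests.
toy_grid <- function(n_chrom = 4, chrom_len = 10e6, bin_width = 5e5,
                     gc = NULL, mappability = NULL) {
  lens <- stats::setNames(rep(chrom_len, n_chrom), paste0("chr", seq_len(n_chrom)))
  build_bin_grid(lens, bin_width, gc = gc, mappability = mappability)
}

# 22 equal-length autosome-like chromosomes (for wGII arithmetic).
equal22_grid <- function(chrom_len = 10e6, bin_width = 5e5) {
  lens <- stats::setNames(rep(chrom_len, 22), paste0("chr", 1:22))
  build_bin_grid(lens, bin_width)
}

# Minimal segment profile constructed directly from a per-bin CN vector.
profile_from_cn <- function(cn, grid, f = 0.3, phi = 2, sample_id = "S1",
                            log2_from_cn = TRUE) {
  ratios <- list(
    sample_id = sample_id,
    log2_ratio = if (log2_from_cn) emission_mean(cn, f, phi) else rep(0, length(cn)),
    valid = !is.na(cn),
    reference_median = 1)
  class(ratios) <- "normalized_ratios"
  segs <- scnatrack:::segments_from_path(cn, ratios, grid)
  scnatrack:::new_segment_profile(sample_id, f = f, phi = phi, segments = segs,
                                  bin_cn = cn, loglik = 0, zero_ctdna = FALSE)
}

# Gaussian ratios around the emission means of a CN vector.
ratios_from_cn <- function(cn, grid, f, phi, sd = 0, seed = 1,
                           sample_id = "S1") {
  set.seed(seed)
  r <- emission_mean(cn, f, phi) + stats::rnorm(length(cn), 0, sd)
  structure(list(sample_id = sample_id, log2_ratio = r,
                 valid = rep(TRUE, length(cn)), reference_median = 1),
            class = "normalized_ratios")
}
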