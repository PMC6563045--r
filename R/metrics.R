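#' Weighted genomic instability index
#'
#' For each autosome, the fraction of its valid-bin length whose copy
#' number differs from the sample's rounded ploidy; wGII is the unweighted
#' mean of these per-chromosome fractions (so small chromosomes count as
#' much as large ones). Autosomes with no valid bins are excluded from the
#' mean.
#'
#' @param profile A `segment_profile` with a per-bin CN vector.
#' @param grid Its `bin_grid`.
#' @return wGII in \[0, 1\].
#' @export
wgii <- function(profile, grid) {
  cn <- profile$bin_cn
  if (is.null(cn) || all(is.na(cn)))
    stop("insufficient data: profile has no per-bin copy number", call. = FALSE)
  ref <- round(profile$phi)
  len <- bin_lengths(grid)
  fracs <- vapply(unique(grid$chrom), function(ch) {
    idx <- which(grid$chrom == ch & !is.na(cn))
    if (length(idx) == 0) return(NA_real_)
    sum(len[idx][cn[idx] != ref]) / sum(len[idx])
  }, numeric(1))
  mean(fracs, na.rm = TRUE)
}

#' Number of non-ploidy segments
#'
#' Count of merged segments (adjacent equal-CN segments are one segment)
#' whose copy number differs from the sample's rounded ploidy.
#'
#' @param profile A `segment_profile`.
#' @return Non-negative integer.
#' @export
nonploidy_segment_count <- function(profile) {
  s <- profile$segments
  if (nrow(s) == 0) return(0L)
  # merge adjacent same-CN segments defensively before counting
  run_id <- cumsum(c(1, diff(s$cn) != 0 | s$chrom[-1] != s$chrom[-nrow(s)]))
  cn_runs <- vapply(split(s$cn, run_id), `[`, numeric(1), 1)
  sum(cn_runs != round(profile$phi))
}

#' Absolute ctDNA concentration
#'
#' The plasma concentration of tumour-derived DNA: total cfDNA
#' concentration times the tumour fraction (ng/mL plasma).
#'
#' @param cfdna_conc Total cfDNA concentration, ng/mL plasma.
#' @param f Tumour fraction in \[0, 1\].
#' @return ctDNA concentration, ng/mL plasma.
#' @export
ctdna_concentration <- function(cfdna_conc, f) {
  if (any(cfdna_conc < 0) || any(f < 0) || any(f > 1))
    stop("invalid input: cfdna_conc must be >= 0 and f in [0, 1]", call. = FALSE)
  cfdna_conc * f
}

#' Rank-based tertile labels
#'
#' Splits samples into low/medium/high thirds by rank (ties broken by
#' stable input order). When the sample count is not divisible by 3 the
#' extra samples go to the lower tertiles first, so group sizes differ by
#' at most one and groupings are reproducible.
#'
#' @param values Numeric metric values, one per sample.
#' @return Character vector of labels `low`/`medium`/`high`.
#' @export
tertile_assign <- function(values) {
  n <- length(values)
  if (n < 3) stop("invalid input: need >= 3 samples for tertiles", call. = FALSE)
  if (diff(range(values)) == 0) {
    warning("all values equal; assigning every sample to 'medium'")
    return(rep("medium", n))
  }
  sizes <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra >= 1) sizes[1] <- sizes[1] + 1
  if (extra == 2) sizes[2] <- sizes[2] + 1
  rk <- rank(values, ties.method = "first")
  labels <- rep(c("low", "medium", "high"), times = sizes)
  labels[rk]
}

#' Per-sample metric table
#'
#' Combines instability metrics from the segment profiles with the three
#' circulating-DNA metrics (cfDNA concentration, ctDNA fraction, ctDNA
#' concentration) and their tertile labels.
#'
#' @param profiles Named list of `segment_profile` objects.
#' @param meta Sample metadata with `sample_id` and `cfdna_conc` columns.
#' @param grid The `bin_grid`.
#' @return data.frame with one row per sample.
#' @export
sample_metrics <- function(profiles, meta, grid) {
  rows <- lapply(profiles, function(p) {
    m <- meta[meta$sample_id == p$sample_id, , drop = FALSE]
    cf <- if (nrow(m) == 1) m$cfdna_conc else NA_real_
    data.frame(sample_id = p$sample_id,
               wgii = if (p$zero_ctdna) NA_real_ else wgii(p, grid),
               nonploidy_segments = if (p$zero_ctdna) NA_integer_ else
                 nonploidy_segment_count(p),
               ploidy = p$phi,
               ctdna_fraction = p$f,
               zero_ctdna = p$zero_ctdna,
               cfdna_conc = cf,
               ctdna_conc = ctdna_concentration(cf, p$f),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$tertile_cfdna <- tertile_assign(out$cfdna_conc)
  out$tertile_ctdna_fraction <- tertile_assign(out$ctdna_fraction)
  out$tertile_ctdna_conc <- tertile_assign(out$ctdna_conc)
  out
}
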