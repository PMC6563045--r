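#' Paired pretreatment-versus-progression copy number change
#'
#' Computes the per-bin difference in continuous absolute tumour copy
#' number between a patient's progression and pretreatment samples. A pair
#' is eligible only when tumour content is above 10% at both timepoints
#' and similar between them (fraction ratio at most `similarity_ratio`),
#' to avoid artefacts from differing tumour content. Each sample's
#' absolute CN is derived from its own segment-mean log2 ratios via
#' [absolute_copy_number()] with its own (f, phi). A bin counts as changed
#' iff |delta| strictly exceeds `delta_threshold` (enriching for
#' aneuploidies acquired by the bulk of the tumour rather than small
#' subclones); percent genome changed is over the jointly valid length.
#'
#' @param profile_pre,profile_prog `segment_profile`s of the same patient
#'   on the same grid.
#' @param grid The `bin_grid`.
#' @param f_min Minimum tumour fraction at both timepoints (default 0.10).
#' @param similarity_ratio Maximum ratio of the larger to the smaller
#'   tumour fraction (default 2.5).
#' @param phi_tolerance Maximum difference between the two timepoints'
#'   fitted ploidies (default 0.5): when the solutions disagree on the
#'   absolute scale (typically a mirror misassignment in one of them),
#'   subtracting absolute copy numbers would report a near-genome-wide
#'   artefactual change, so the pair is declared ineligible instead.
#' @param delta_threshold Absolute CN change that must be exceeded
#'   (default 0.8, strict).
#' @return A `paired_change`: patient_id, eligibility (+ reason), per-bin
#'   `delta`, `changed` mask and `percent_genome_changed`.
#' @export
paired_change <- function(profile_pre, profile_prog, grid, f_min = 0.10,
                          similarity_ratio = 2.5, phi_tolerance = 0.5,
                          delta_threshold = 0.8) {
  pid <- sub("_prog$", "", profile_prog$sample_id)
  ineligible <- function(reason)
    structure(list(patient_id = pid, eligible = FALSE, reason = reason,
                   delta = NULL, changed = NULL,
                   percent_genome_changed = NA_real_),
              class = "paired_change")
  f1 <- profile_pre$f; f2 <- profile_prog$f
  if (f1 <= f_min || f2 <= f_min)
    return(ineligible(sprintf("fraction <= %.2f", f_min)))
  if (max(f1, f2) / min(f1, f2) > similarity_ratio)
    return(ineligible(sprintf("fraction ratio > %.2f", similarity_ratio)))
  if (abs(profile_pre$phi - profile_prog$phi) > phi_tolerance)
    return(ineligible(sprintf("ploidy solutions discordant (%.2f vs %.2f)",
                              profile_pre$phi, profile_prog$phi)))

  cn_pre <- per_bin_absolute_cn(profile_pre, grid)
  cn_prog <- per_bin_absolute_cn(profile_prog, grid)
  if (length(cn_pre) != length(cn_prog))
    stop("coordinate mismatch: profiles are on different grids", call. = FALSE)
  both <- !is.na(cn_pre) & !is.na(cn_prog)
  delta <- rep(NA_real_, length(cn_pre))
  delta[both] <- cn_prog[both] - cn_pre[both]
  changed <- !is.na(delta) & abs(delta) > delta_threshold
  len <- bin_lengths(grid)
  pct <- 100 * sum(len[changed]) / sum(len[both])
  structure(list(patient_id = pid, eligible = TRUE, reason = NA_character_,
                 delta = delta, changed = changed,
                 percent_genome_changed = pct),
            class = "paired_change")
}

# Continuous absolute tumour CN per bin, from the segment-mean log2 ratio
# of the segment covering each bin (segment means average out bin-level
# noise, as in segmented absolute copy number output).
per_bin_absolute_cn <- function(profile, grid) {
  out <- rep(NA_real_, nrow(grid))
  if (profile$f <= 0) return(out)
  s <- profile$segments
  mid <- (grid$start + grid$end) / 2
  for (j in seq_len(nrow(s))) {
    hit <- grid$chrom == s$chrom[j] & mid >= s$start[j] & mid < s$end[j]
    out[hit] <- absolute_copy_number(s$mean_log2[j], profile$f, profile$phi)
  }
  if (!is.null(profile$bin_cn)) out[is.na(profile$bin_cn)] <- NA_real_
  out
}

#' Recurrence of copy number changes at progression
#'
#' Per-bin count of eligible pairs gaining (delta above the threshold) or
#' losing (below the negative threshold) copies at progression relative to
#' pretreatment.
#'
#' @param changes List of `paired_change` objects.
#' @param grid The shared `bin_grid`.
#' @param delta_threshold Change threshold (strict; default 0.8).
#' @return `list(gain=, loss=, n_pairs=)`: per-bin counts over eligible
#'   pairs.
#' @export
change_recurrence <- function(changes, grid, delta_threshold = 0.8) {
  eligible <- Filter(function(ch) isTRUE(ch$eligible), changes)
  if (length(eligible) == 0) {
    warning("no eligible pairs; empty recurrence track")
    return(list(gain = integer(nrow(grid)), loss = integer(nrow(grid)),
                n_pairs = 0L))
  }
  gain <- integer(nrow(grid)); loss <- integer(nrow(grid))
  for (ch in eligible) {
    gain <- gain + as.integer(!is.na(ch$delta) & ch$delta > delta_threshold)
    loss <- loss + as.integer(!is.na(ch$delta) & ch$delta < -delta_threshold)
  }
  list(gain = gain, loss = loss, n_pairs = length(eligible))
}
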