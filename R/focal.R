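#' Call narrow high-level amplifications on 50 kb bins
#'
#' Converts each 50 kb bin's log2 ratio to continuous tumour copy number
#' with the sample's (f, phi) from the 500 kb profile, then calls maximal
#' runs of at least `min_bins` consecutive valid bins with CN at or above
#' `phi + min_excess`, of total width at most `max_width`; runs separated
#' by a single sub-threshold bin are merged. Arm-level single-copy gains
#' stay below the excess threshold and are not called.
#'
#' @param ratios50 `normalized_ratios` on the 50 kb grid.
#' @param profile The sample's `segment_profile` from the 500 kb analysis
#'   (supplies f and phi).
#' @param grid50 The 50 kb `bin_grid`.
#' @param min_excess Minimum CN above ploidy (default +3, "high-level").
#' @param min_bins Minimum consecutive bins (default 2).
#' @param max_width Maximum call width in bp (default 10 Mb, "narrow").
#' @return data.frame of calls: sample_id, chrom, start, end, width,
#'   mean_log2, cn (mean over the run); empty with attribute
#'   `zero_ctdna = TRUE` when the sample has no detectable ctDNA.
#' @export
call_focal_amplifications <- function(ratios50, profile, grid50,
                                      min_excess = 3, min_bins = 2,
                                      max_width = 10e6) {
  if (abs(grid_bin_width(grid50) - 5e4) > 0.5)
    stop("invalid input: focal calling requires a 50 kb grid", call. = FALSE)
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), width = numeric(),
                      mean_log2 = numeric(), cn = numeric(),
                      stringsAsFactors = FALSE)
  if (profile$zero_ctdna || profile$f <= 0) {
    attr(empty, "zero_ctdna") <- TRUE
    return(empty)
  }
  f <- profile$f; phi <- profile$phi
  cn <- rep(NA_real_, nrow(grid50))
  cn[ratios50$valid] <- absolute_copy_number(
    ratios50$log2_ratio[ratios50$valid], f, phi)
  # the copy number threshold expressed as a log2-ratio threshold; at low
  # tumour fraction this can fall inside bin-level noise, so a noise floor
  # (3 robust sd of the ratios) is imposed — below it, high-level events
  # are not detectable and are not called
  r_thresh <- log2((f * (phi + min_excess) + (1 - f) * 2) /
                     (f * phi + (1 - f) * 2))
  sigma_hat <- stats::mad(ratios50$log2_ratio[ratios50$valid])
  eff_thresh <- max(r_thresh, 3 * sigma_hat)
  above <- ratios50$valid & !is.na(ratios50$log2_ratio) &
    ratios50$log2_ratio >= eff_thresh

  # merge runs separated by a single sub-threshold (or masked) bin
  hit <- above
  idx <- which(!hit)
  bridge <- idx[idx > 1 & idx < length(hit)]
  bridge <- bridge[hit[bridge - 1] & hit[bridge + 1] &
                     grid50$chrom[bridge - 1] == grid50$chrom[bridge + 1]]
  hit[bridge] <- TRUE

  run_id <- cumsum(c(1, diff(hit) != 0 |
                       grid50$chrom[-1] != grid50$chrom[-nrow(grid50)]))
  calls <- list()
  for (ids in split(seq_len(nrow(grid50)), run_id)) {
    if (!hit[ids[1]]) next
    n_above <- sum(above[ids])
    if (n_above < min_bins) next
    width <- grid50$end[ids[length(ids)]] - grid50$start[ids[1]]
    if (width > max_width) next
    keep <- ids[!is.na(cn[ids])]
    # a focal amplification must also stand out over its local background:
    # this separates genuine narrow events from noise fragments riding on
    # broad high-level gains, whose flanks are equally elevated
    flank <- setdiff(c(max(1, ids[1] - 20):(ids[1] - 1),
                       (ids[length(ids)] + 1):min(nrow(grid50),
                                                  ids[length(ids)] + 20)),
                     ids)
    flank <- flank[grid50$chrom[flank] == grid50$chrom[ids[1]] &
                     !is.na(cn[flank])]
    flank_cn <- if (length(flank) >= 5) stats::median(cn[flank]) else 2
    if (mean(cn[keep]) < flank_cn + min_excess) next
    calls[[length(calls) + 1]] <- data.frame(
      sample_id = profile$sample_id,
      chrom = grid50$chrom[ids[1]], start = grid50$start[ids[1]],
      end = grid50$end[ids[length(ids)]], width = width,
      mean_log2 = mean(ratios50$log2_ratio[keep]),
      cn = mean(cn[keep]), stringsAsFactors = FALSE)
  }
  if (length(calls) == 0) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Annotate focal amplification calls with driver genes
#'
#' A gene symbol is attached iff its interval overlaps the call interval
#' (half-open overlap).
#'
#' @param calls Output of [call_focal_amplifications()].
#' @param genes Gene catalog, default [driver_genes()].
#' @return `calls` with an added `genes` column (comma-separated symbols,
#'   empty string when none overlap).
#' @export
annotate_amplifications <- function(calls, genes = driver_genes()) {
  if (nrow(calls) == 0) {
    calls$genes <- character(0)
    return(calls)
  }
  calls$genes <- vapply(seq_len(nrow(calls)), function(i) {
    hit <- genes$chrom == calls$chrom[i] &
      genes$start < calls$end[i] & genes$end > calls$start[i]
    paste(genes$gene[hit], collapse = ",")
  }, character(1))
  calls
}
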