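#!/usr/bin/env Rscript
# Stage 5: cohort frequency tracks and responder-unique regions.
#
# Puts all detectable pretreatment profiles on a common segment grid,
# tallies ploidy-relative gains/losses per response group, extracts
# regions aberrant only in one group, and reduces each to its minimal
# consistent region (the core shared by all contributing cases).

library(scnatrack)

SEED <- 42
outdir <- "results/analysis"
meta <- read_sample_meta(file.path(outdir, "sample_meta.tsv"))
profiles <- read_seg(file.path(outdir, "profiles.seg"))
names(profiles) <- vapply(profiles, `[[`, character(1), "sample_id")
pre_ids <- meta$sample_id[meta$timepoint == "pretreatment"]
pre <- profiles[pre_ids]

mat <- aberration_matrix(pre)
grp <- meta$response_group[match(mat$sample_ids, meta$sample_id)]
tr_resp <- group_frequency(mat, grp == "responder")
tr_non <- group_frequency(mat, grp == "nonresponder")

tracks <- data.frame(mat$segments,
                     gain_responder = tr_resp$gain, loss_responder = tr_resp$loss,
                     gain_nonresponder = tr_non$gain, loss_nonresponder = tr_non$loss)
write.table(tracks, file.path(outdir, "frequency_tracks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

uq <- unique_regions(tr_resp, tr_non)
write.table(uq, file.path(outdir, "responder_unique_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d regions uniquely aberrant in responders (%d frequent, >1/3 of cases)",
                nrow(uq), sum(uq$frequent)))

mcrs <- NULL
for (i in seq_len(nrow(uq))) {
  mcr <- minimal_consistent_region(
    mat, list(chrom = uq$chrom[i], start = uq$start[i], end = uq$end[i]),
    uq$direction[i])
  if (!is.null(mcr))
    mcrs <- rbind(mcrs, data.frame(chrom = mcr$chrom, start = mcr$start,
                                   end = mcr$end, direction = uq$direction[i],
                                   carriers = mcr$carriers,
                                   width_mb = (mcr$end - mcr$start) / 1e6))
}
if (!is.null(mcrs)) {
  write.table(mcrs, file.path(outdir, "minimal_consistent_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("largest minimal consistent region: ",
          sprintf("%.1f Mb on %s (%d carriers)",
                  max(mcrs$width_mb), mcrs$chrom[which.max(mcrs$width_mb)],
                  mcrs$carriers[which.max(mcrs$width_mb)]))
}
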