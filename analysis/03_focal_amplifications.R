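#!/usr/bin/env Rscript
# Stage 3: focal amplification calling at 50 kb resolution.
#
# Re-simulates each detectable sample's reads on the 50 kb grid (the
# analysis consumes bin counts, so the two resolutions are two binnings
# of the same underlying truth), normalises them, converts bin ratios to
# continuous copy number with the sample's 500 kb (f, ploidy) fit, and
# calls narrow high-level amplifications annotated with driver genes.

library(scnatrack)

SEED <- 42
outdir <- "results/analysis"
grid <- annotate_grid_synthetic(build_bin_grid(hg19_autosomes(), 5e5),
                                seed = SEED)
g50 <- annotate_grid_synthetic(build_bin_grid(hg19_autosomes(), 5e4),
                               seed = SEED)
sim <- simulate_cohort(cohort_config(grid = grid, n_patients = 30,
                                     n_reads = 12e6), seed = SEED)
profiles <- read_seg(file.path(outdir, "profiles.seg"))
names(profiles) <- vapply(profiles, `[[`, character(1), "sample_id")

all_calls <- list()
for (id in names(sim$truths)) {
  p <- profiles[[id]]
  if (is.null(p) || p$zero_ctdna) next
  cnt50 <- simulate_bin_counts(sim$truths[[id]], g50, n_reads = 12e6,
                               seed = SEED + match(id, names(sim$truths)))
  r50 <- normalize_counts(cnt50, g50)
  calls <- call_focal_amplifications(r50, p, g50)
  if (nrow(calls) > 0) all_calls[[id]] <- annotate_amplifications(calls)
}
calls <- if (length(all_calls)) do.call(rbind, all_calls) else
  data.frame()
write.table(calls, file.path(outdir, "focal_amplifications.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth_amps <- do.call(rbind, lapply(sim$truths, function(tr)
  if (nrow(tr$focal_amps) && tr$f > 0)
    data.frame(sample_id = tr$sample_id, gene = tr$focal_amps$gene)))
hit <- 0
if (!is.null(truth_amps)) for (i in seq_len(nrow(truth_amps))) {
  cc <- calls[calls$sample_id == truth_amps$sample_id[i], ]
  if (nrow(cc) && any(grepl(truth_amps$gene[i], cc$genes))) hit <- hit + 1
}
message(sprintf("%d focal amplification calls across %d samples",
                nrow(calls), length(all_calls)))
if (!is.null(truth_amps))
  message(sprintf("recalled %d/%d simulated driver amplifications in samples with ctDNA",
                  hit, nrow(truth_amps)))
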