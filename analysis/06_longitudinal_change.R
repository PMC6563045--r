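#!/usr/bin/env Rscript
# Stage 6: paired pretreatment-versus-progression change analysis.
#
# For every patient with a progression sample: eligibility (tumour
# content above 10% and similar at both timepoints), per-bin difference
# of continuous absolute copy number, the strict |delta| > 0.8 changed
# mask, percent genome changed, and the cross-patient recurrence track of
# changes acquired at progression.

library(scnatrack)

SEED <- 42
outdir <- "results/analysis"
grid <- annotate_grid_synthetic(build_bin_grid(hg19_autosomes(), 5e5),
                                seed = SEED)
meta <- read_sample_meta(file.path(outdir, "sample_meta.tsv"))

fit <- function(id) {
  cnt <- read_bin_counts(file.path(outdir, paste0(id, ".counts.tsv")), grid,
                         sample_id = id)
  estimate_profile(normalize_counts(cnt, grid), grid, counts = cnt)
}

prog_ids <- meta$sample_id[meta$timepoint == "progression"]
pairs <- list()
for (id in prog_ids) {
  pid <- sub("_prog$", "", id)
  pairs[[pid]] <- paired_change(fit(pid), fit(id), grid)
  with(pairs[[pid]], message(sprintf(
    "%s: %s%s", pid,
    if (eligible) sprintf("percent genome changed = %.2f%%",
                          percent_genome_changed)
    else "ineligible", if (eligible) "" else paste0(" (", reason, ")"))))
}

tab <- do.call(rbind, lapply(pairs, function(ch)
  data.frame(patient_id = ch$patient_id, eligible = ch$eligible,
             reason = ch$reason,
             percent_genome_changed = round(ch$percent_genome_changed, 3))))
write.table(tab, file.path(outdir, "paired_changes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

eligible <- tab$eligible
message(sprintf("%d/%d pairs eligible for quantitative comparison (study: 7/20)",
                sum(eligible), length(eligible)))
resp <- meta$response_group[match(tab$patient_id, meta$patient_id)]
for (g in c("responder", "nonresponder")) {
  v <- tab$percent_genome_changed[eligible & resp == g]
  if (length(v))
    message(sprintf("median percent genome changed, %ss: %.2f%% (n=%d)",
                    g, median(v), length(v)))
}

if (sum(eligible) > 0) {
  rec <- change_recurrence(pairs, grid)
  write.table(data.frame(chrom = grid$chrom, start = grid$start,
                         end = grid$end, gain = rec$gain, loss = rec$loss),
              file.path(outdir, "change_recurrence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("maximum recurrence of any change at progression: %d of %d pairs",
                  max(rec$gain, rec$loss), rec$n_pairs))
}
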