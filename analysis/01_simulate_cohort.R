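#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic patient cohort.
#
# Emulates the study cohort: 30 patients with advanced oesophagogastric
# adenocarcinoma sampled before first-line chemotherapy (7 with no
# detectable ctDNA), 20 of them resampled at radiological progression,
# sequenced to ~12 million 100 bp reads and summarised as 500 kb bin
# counts over the hg19 autosomes with GC/mappability bias.
#
# Writes per-sample bin counts, the clinical metadata table and the
# simulation ground truth under results/analysis/.

library(scnatrack)

SEED <- 42
outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

grid <- annotate_grid_synthetic(build_bin_grid(hg19_autosomes(), 5e5),
                                seed = SEED)
config <- cohort_config(grid = grid, n_patients = 30, n_reads = 12e6)
sim <- simulate_cohort(config, seed = SEED)

for (id in names(sim$counts))
  write_bin_counts(sim$counts[[id]], grid,
                   file.path(outdir, paste0(id, ".counts.tsv")))
write_sample_meta(sim$meta, file.path(outdir, "sample_meta.tsv"))

truth <- do.call(rbind, lapply(sim$truths, function(tr)
  data.frame(sample_id = tr$sample_id, true_f = tr$f,
             true_ploidy = round(tr$phi, 4))))
write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pre <- sim$meta[sim$meta$timepoint == "pretreatment", ]
message(sprintf("simulated %d pretreatment + %d progression samples", nrow(pre),
                sum(sim$meta$timepoint == "progression")))
message(sprintf("%d/%d patients carry no ctDNA (target 7/30)",
                sum(pre$true_f == 0), nrow(pre)))
message(sprintf("median cfDNA concentration %.2f ng/mL (study: 8.88)",
                median(pre$cfdna_conc)))
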