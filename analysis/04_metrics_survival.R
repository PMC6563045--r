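#!/usr/bin/env Rscript
# Stage 4: chromosomal-instability and circulating-DNA metrics; survival.
#
# Per pretreatment sample: wGII, non-ploidy segment count, ploidy, and
# the three circulating DNA metrics (cfDNA concentration, ctDNA fraction,
# ctDNA concentration = product of the two) with rank tertiles. Compares
# metrics between responders and nonresponders (Mann-Whitney) and runs
# Kaplan-Meier / log-rank survival analyses by tertile.

library(scnatrack)

SEED <- 42
outdir <- "results/analysis"
grid <- annotate_grid_synthetic(build_bin_grid(hg19_autosomes(), 5e5),
                                seed = SEED)
meta <- read_sample_meta(file.path(outdir, "sample_meta.tsv"))
pre_meta <- meta[meta$timepoint == "pretreatment", ]

# per-bin CN vectors are rebuilt from the called profiles
sim <- simulate_cohort(cohort_config(grid = grid, n_patients = 30,
                                     n_reads = 12e6), seed = SEED)
profiles <- list()
for (id in pre_meta$sample_id) {
  cnt <- read_bin_counts(file.path(outdir, paste0(id, ".counts.tsv")), grid,
                         sample_id = id)
  ratios <- normalize_counts(cnt, grid)
  profiles[[id]] <- estimate_profile(ratios, grid, counts = cnt)
}
metrics <- sample_metrics(profiles, pre_meta, grid)
write.table(metrics, file.path(outdir, "metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

resp <- pre_meta$response_group[match(metrics$sample_id, pre_meta$sample_id)]
det <- !metrics$zero_ctdna
for (m in c("wgii", "nonploidy_segments", "ploidy")) {
  mw <- mann_whitney(metrics[[m]][det & resp == "responder"],
                     metrics[[m]][det & resp == "nonresponder"])
  message(sprintf("%s responders vs nonresponders: Mann-Whitney p = %.3f",
                  m, mw$p))
}

surv <- NULL
tert_col <- c(cfdna_conc = "tertile_cfdna",
              ctdna_fraction = "tertile_ctdna_fraction",
              ctdna_conc = "tertile_ctdna_conc")
for (m in names(tert_col)) {
  tert <- metrics[[tert_col[[m]]]]
  kr <- km_logrank(pre_meta$os_months, pre_meta$os_event, tert,
                   ordered_levels = c("low", "medium", "high"))
  surv <- rbind(surv, data.frame(metric = m, chisq = round(kr$chisq, 3),
                                 p = round(kr$p, 4),
                                 trend_chisq = round(kr$trend_chisq, 3),
                                 trend_p = round(kr$trend_p, 4)))
  message(sprintf("OS by %s tertile: log-rank chisq=%.2f p=%.3f (trend p=%.3f)",
                  m, kr$chisq, kr$p, kr$trend_p))
}
write.table(surv, file.path(outdir, "survival_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
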