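#' Scaled-down genome for demonstrations and tests
#'
#' hg19 autosome lengths divided by `factor`. Used with the unchanged
#' 500 kb bin width and a read budget divided by the same factor, per-bin
#' depth and noise match the full-genome setting, so small runs are
#' statistically faithful.
#'
#' @param factor Scale divisor (default 10).
#' @return Named length vector for [build_bin_grid()].
#' @export
scaled_autosomes <- function(factor = 10) {
  round(hg19_autosomes() / factor)
}

#' Pipeline run configuration
#'
#' A single configuration object covering every stage; round-trips to YAML
#' via [yaml::write_yaml()] for provenance. The default is the 8-patient
#' demonstration cohort on a 1/10-scale genome with a proportionally
#' scaled read budget (per-bin depth equal to the full 12M-read setting).
#'
#' @param outdir Output directory.
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param n_patients Cohort size.
#' @param genome_scale Genome scale divisor.
#' @param n_reads Reads per sample.
#' @param mappability_min Mask threshold for normalisation.
#' @param stages Character vector of stages to run, in dependency order.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(outdir = "results/pipeline", seed = 1L,
                            n_patients = 8, genome_scale = 10,
                            n_reads = 12e6 / 10, mappability_min = 0.9,
                            stages = c("simulate", "normalize", "call",
                                       "metrics", "cohort", "longitudinal",
                                       "survival")) {
  list(outdir = outdir, seed = seed, n_patients = n_patients,
       genome_scale = genome_scale, n_reads = n_reads,
       mappability_min = mappability_min, stages = stages,
       n_paired = max(2, round(n_patients * 20 / 30)),
       zero_ctdna_fraction = 7 / 30)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order — cohort simulation,
#' GC/mappability normalisation, HMM profile estimation, per-sample
#' metrics, cohort frequency/unique-region analysis, paired-change
#' analysis and tertile survival analysis — writing every output file
#' under `config$outdir` and recording each with an md5 checksum in the
#' returned manifest. Re-running with the same config reproduces
#' byte-identical outputs.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return Manifest list: parameter echo, per-stage outputs with
#'   checksums.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "grid")],
                   outputs = list())
  record <- function(stage, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]],
                                    stats::setNames(unname(tools::md5sum(path)), path))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(stage, file.path(config$outdir, "FAILED"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  grid <- annotate_grid_synthetic(
    build_bin_grid(scaled_autosomes(config$genome_scale), 5e5),
    seed = config$seed)
  cc <- cohort_config(grid = grid, n_patients = config$n_patients,
                      n_reads = config$n_reads)
  cc$n_paired <- config$n_paired
  cc$zero_ctdna_fraction <- config$zero_ctdna_fraction
  cc$prog_zero_n <- min(1, cc$n_paired)

  sim <- NULL; ratios <- NULL; profiles <- NULL; metrics_tab <- NULL
  pairs <- NULL

  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    sim <<- simulate_cohort(cc, seed = config$seed)
    for (id in names(sim$counts)) {
      p <- file.path(config$outdir, paste0(id, ".counts.tsv"))
      write_bin_counts(sim$counts[[id]], grid, p)
      record("simulate", p)
    }
    p <- file.path(config$outdir, "sample_meta.tsv")
    write_sample_meta(sim$meta, p)
    record("simulate", p)
    tp <- file.path(config$outdir, "truth.tsv")
    truth_tab <- do.call(rbind, lapply(sim$truths, function(tr)
      data.frame(sample_id = tr$sample_id, f = tr$f, phi = tr$phi)))
    utils::write.table(truth_tab, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("simulate", tp)
  })

  if ("normalize" %in% config$stages) run_stage("normalize", function() {
    ratios <<- lapply(sim$counts, function(cnt)
      normalize_counts(cnt, grid, mappability_min = config$mappability_min))
    p <- file.path(config$outdir, "log2_ratios.tsv")
    tab <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end)
    for (id in names(ratios))
      tab[[id]] <- round(ratios[[id]]$log2_ratio, 6)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    record("normalize", p)
  })

  if ("call" %in% config$stages) run_stage("call", function() {
    profiles <<- lapply(ratios, function(r) estimate_profile(r, grid))
    p <- file.path(config$outdir, "profiles.seg")
    write_seg(unname(profiles), p)
    record("call", p)
    sm <- file.path(config$outdir, "fit_summary.tsv")
    tab <- do.call(rbind, lapply(profiles, function(pr)
      data.frame(sample_id = pr$sample_id, f = round(pr$f, 4),
                 phi = round(pr$phi, 4), zero_ctdna = pr$zero_ctdna,
                 loglik = round(pr$loglik, 2))))
    utils::write.table(tab, sm, sep = "\t", quote = FALSE, row.names = FALSE)
    record("call", sm)
  })

  if ("metrics" %in% config$stages) run_stage("metrics", function() {
    pre <- profiles[sim$meta$sample_id[sim$meta$timepoint == "pretreatment"]]
    metrics_tab <<- sample_metrics(pre, sim$meta, grid)
    p <- file.path(config$outdir, "metrics.tsv")
    num <- vapply(metrics_tab, is.numeric, logical(1))
    metrics_tab[num] <- lapply(metrics_tab[num], round, 6)
    utils::write.table(metrics_tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("metrics", p)
  })

  if ("cohort" %in% config$stages) run_stage("cohort", function() {
    pre_ids <- sim$meta$sample_id[sim$meta$timepoint == "pretreatment"]
    pre <- profiles[pre_ids]
    det <- !vapply(pre, `[[`, logical(1), "zero_ctdna")
    mat <- suppressWarnings(aberration_matrix(pre))
    grp <- sim$meta$response_group[match(mat$sample_ids, sim$meta$sample_id)]
    fq <- mat$segments
    for (gname in unique(grp)) {
      tr <- group_frequency(mat, grp == gname)
      fq[[paste0("gain_", gname)]] <- tr$gain
      fq[[paste0("loss_", gname)]] <- tr$loss
    }
    pf <- file.path(config$outdir, "frequency_tracks.tsv")
    utils::write.table(fq, pf, sep = "\t", quote = FALSE, row.names = FALSE)
    record("cohort", pf)
    if (all(c("responder", "nonresponder") %in% grp)) {
      tr_r <- group_frequency(mat, grp == "responder")
      tr_n <- group_frequency(mat, grp == "nonresponder")
      uq <- unique_regions(tr_r, tr_n)
      p <- file.path(config$outdir, "responder_unique_regions.tsv")
      utils::write.table(uq, p, sep = "\t", quote = FALSE, row.names = FALSE)
      record("cohort", p)
    }
  })

  if ("longitudinal" %in% config$stages) run_stage("longitudinal", function() {
    prog_ids <- sim$meta$sample_id[sim$meta$timepoint == "progression"]
    pairs <<- lapply(prog_ids, function(id) {
      pid <- sub("_prog$", "", id)
      paired_change(profiles[[pid]], profiles[[id]], grid)
    })
    tab <- do.call(rbind, lapply(pairs, function(ch)
      data.frame(patient_id = ch$patient_id, eligible = ch$eligible,
                 reason = ch$reason,
                 percent_genome_changed = round(ch$percent_genome_changed, 4))))
    p <- file.path(config$outdir, "paired_changes.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    record("longitudinal", p)
    n_eligible <- sum(vapply(pairs, function(ch) isTRUE(ch$eligible), logical(1)))
    rec <- if (n_eligible > 0) change_recurrence(pairs, grid) else
      list(n_pairs = 0L)
    if (rec$n_pairs > 0) {
      rp <- file.path(config$outdir, "change_recurrence.tsv")
      utils::write.table(data.frame(chrom = grid$chrom, start = grid$start,
                                    end = grid$end, gain = rec$gain,
                                    loss = rec$loss),
                         rp, sep = "\t", quote = FALSE, row.names = FALSE)
      record("longitudinal", rp)
    }
  })

  if ("survival" %in% config$stages) run_stage("survival", function() {
    pre_meta <- sim$meta[sim$meta$timepoint == "pretreatment", ]
    m <- metrics_tab[match(pre_meta$sample_id, metrics_tab$sample_id), ]
    rows <- lapply(c(cfdna_conc = "tertile_cfdna",
                     ctdna_fraction = "tertile_ctdna_fraction",
                     ctdna_conc = "tertile_ctdna_conc"), function(col) {
      kr <- km_logrank(pre_meta$os_months, pre_meta$os_event, m[[col]],
                       ordered_levels = c("low", "medium", "high"))
      data.frame(chisq = round(kr$chisq, 4), df = kr$df, p = round(kr$p, 6),
                 trend_chisq = round(kr$trend_chisq, 4),
                 trend_p = round(kr$trend_p, 6))
    })
    tab <- cbind(metric = names(rows), do.call(rbind, rows))
    p <- file.path(config$outdir, "survival_tests.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    record("survival", p)
  })

  cfg_path <- file.path(config$outdir, "run_config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "grid")], cfg_path)
  record("config", cfg_path)
  manifest
}
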