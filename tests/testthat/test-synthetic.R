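test_that("event-free truth is uniformly diploid", {
  g <- toy_grid()
  tr <- simulate_truth_profile(
    g, truth_params(n_arm_events = 0, focal_genes = character(),
                    homdel_genes = character(), high_gain_arms = 0), seed = 1)
  expect_true(all(truth_bin_cn(tr, g) == 2))
  expect_equal(tr$phi, 2)
})

test_that("one whole-chromosome gain on 22 equal autosomes gives phi 2 + 1/22", {
  g <- equal22_grid()
  # construct via a manual single-clone event covering chr1 entirely
  tr <- simulate_truth_profile(
    g, truth_params(n_arm_events = 0, focal_genes = character(),
                    homdel_genes = character(), high_gain_arms = 0), seed = 1)
  tr$clones[[1]]$events <- data.frame(chrom = "chr1", start = 0, end = 10e6,
                                      cn = 3)
  expect_equal(scnatrack:::truth_ploidy(tr, g), 2 + 1 / 22, tolerance = 1e-12)
})

test_that("truth simulation is reproducible and validates params", {
  g <- toy_grid(n_chrom = 6)
  t1 <- simulate_truth_profile(g, truth_params(n_arm_events = 4), seed = 9)
  t2 <- simulate_truth_profile(g, truth_params(n_arm_events = 4), seed = 9)
  expect_identical(truth_bin_cn(t1, g), truth_bin_cn(t2, g))
  expect_identical(t1$phi, t2$phi)
  expect_error(
    simulate_truth_profile(g, truth_params(n_arm_events = 100), seed = 1),
    "invalid params")
})

test_that("mixture consistency: mixed CN equals the weighted clone sum", {
  g <- toy_grid(n_chrom = 6)
  tr <- simulate_truth_profile(
    g, truth_params(n_arm_events = 4,
                    subclone = list(weight = 0.3, n_private_events = 2)),
    seed = 17)
  w <- vapply(tr$clones, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1)
  manual <- rowSums(vapply(tr$clones, function(cl)
    cl$weight * scnatrack:::clone_bin_cn(cl$events, tr$baseline_cn, g),
    numeric(nrow(g))))
  expect_equal(truth_bin_cn(tr, g), manual, tolerance = 1e-12)
  # stored phi equals recomputed length-weighted mean
  expect_equal(tr$phi, scnatrack:::truth_ploidy(tr, g), tolerance = 1e-9)
})

test_that("count model: expected counts proportional to the cfDNA mixture", {
  lens <- stats::setNames(rep(50e6, 4), paste0("chr", 1:4))
  g <- build_bin_grid(lens, 5e4)  # 4,000 bins
  tr <- simulate_truth_profile(
    g, truth_params(f = 1, n_arm_events = 2, focal_genes = character(),
                    homdel_genes = character(), high_gain_arms = 0),
    seed = 23)
  cnt <- simulate_bin_counts(tr, g, n_reads = 4e6,
                             bias = list(gc_coef = c(0, 0), dispersion = 1e8),
                             seed = 23)
  cn <- truth_bin_cn(tr, g)
  # f=1: mean count ratio between CN4 and CN2 regions ~ 2
  if (any(cn == 4) && any(cn == 2)) {
    ratio <- mean(cnt$counts[cn == 4]) / mean(cnt$counts[cn == 2])
    expect_equal(ratio, 2, tolerance = 0.05)
  }
  # regression through the origin: counts vs mixture CN slope recovers scale
  fit <- lm(cnt$counts ~ 0 + cn)
  expect_equal(unname(coef(fit)[1]) * sum(cn), 4e6, tolerance = 0.02 * 4e6)
})

test_that("f = 0 gives flat expected coverage", {
  g <- toy_grid(n_chrom = 4, chrom_len = 30e6)
  tr <- simulate_truth_profile(g, truth_params(f = 0, n_arm_events = 5),
                               seed = 29)
  cnt <- simulate_bin_counts(tr, g, n_reads = 2.4e6,
                             bias = list(gc_coef = c(0, 0), dispersion = 100),
                             seed = 29)
  cn <- truth_bin_cn(tr, g)
  m_ab <- mean(cnt$counts[cn != 2]); m_n <- mean(cnt$counts[cn == 2])
  se <- sd(cnt$counts) * sqrt(1 / sum(cn != 2) + 1 / sum(cn == 2))
  expect_lt(abs(m_ab - m_n), 3 * se)
})

test_that("dispersion to infinity approaches Poisson", {
  lens <- c(chrA = 5e8)
  g <- build_bin_grid(lens, 5e4)  # 10,000 bins
  tr <- simulate_truth_profile(
    g, truth_params(f = 0, n_arm_events = 0, focal_genes = character(),
                    homdel_genes = character(), high_gain_arms = 0), seed = 1)
  cnt <- simulate_bin_counts(tr, g, n_reads = 1e7,
                             bias = list(gc_coef = c(0, 0), dispersion = 1e8),
                             seed = 31)
  expect_equal(var(cnt$counts) / mean(cnt$counts), 1, tolerance = 0.1)
})

test_that("degenerate zero-mass input errors", {
  g <- toy_grid(mappability = rep(0, 80))
  tr <- simulate_truth_profile(g, truth_params(f = 0, n_arm_events = 0),
                               seed = 1)
  expect_error(simulate_bin_counts(tr, g, n_reads = 1e6, seed = 1),
               "degenerate")
})

test_that("progression pairs preserve the trunk and shift only private bins", {
  g <- toy_grid(n_chrom = 6, chrom_len = 20e6)
  pre <- simulate_truth_profile(
    g, truth_params(n_arm_events = 3,
                    subclone = list(weight = 0.2, n_private_events = 2)),
    seed = 37)
  # zero shift: identical mixed profile
  same <- simulate_progression_pair(pre, list(weights = c(0.8, 0.2)), seed = 1)
  expect_equal(truth_bin_cn(same, g), truth_bin_cn(pre, g), tolerance = 1e-12)

  # weight flip changes exactly the subclone-private bins
  flip <- simulate_progression_pair(pre, list(weights = c(0.2, 0.8)), seed = 1)
  pre_cn <- truth_bin_cn(pre, g); flip_cn <- truth_bin_cn(flip, g)
  private <- scnatrack:::clone_bin_cn(pre$clones[[2]]$events, pre$baseline_cn, g) !=
    scnatrack:::clone_bin_cn(pre$clones[[1]]$events, pre$baseline_cn, g)
  expect_true(all((flip_cn != pre_cn) == private))

  # invalid weights rejected
  expect_error(simulate_progression_pair(pre, list(weights = c(0.6, 0.6))),
               "sum to 1")
  single <- simulate_truth_profile(g, truth_params(n_arm_events = 2), seed = 5)
  expect_error(simulate_progression_pair(single, list(weights = 1)),
               ">= 2 clones")
})

test_that("two-clone mixture arithmetic on a single differing chromosome", {
  g <- toy_grid(n_chrom = 4, chrom_len = 20e6)
  pre <- simulate_truth_profile(
    g, truth_params(n_arm_events = 0, focal_genes = character(),
                    homdel_genes = character(), high_gain_arms = 0,
                    subclone = list(weight = 0.2, n_private_events = 0)),
    seed = 41)
  # give clone 2 a private whole-chr4 gain by hand
  pre$clones[[2]]$events <- rbind(pre$clones[[2]]$events,
                                  data.frame(chrom = "chr4", start = 0,
                                             end = 20e6, cn = 4))
  pre$phi <- scnatrack:::truth_ploidy(pre, g)
  prog <- simulate_progression_pair(pre, list(weights = c(0.2, 0.8)), seed = 1)
  pre_cn <- truth_bin_cn(pre, g); prog_cn <- truth_bin_cn(prog, g)
  on4 <- g$chrom == "chr4"
  expect_equal(pre_cn[on4], rep(2 + 0.2 * 2, sum(on4)), tolerance = 1e-12)
  expect_equal(prog_cn[on4], rep(2 + 0.8 * 2, sum(on4)), tolerance = 1e-12)
  expect_equal(pre_cn[!on4], prog_cn[!on4])
})

test_that("cohort simulation honours composition and is deterministic", {
  g <- annotate_grid_synthetic(
    build_bin_grid(scaled_autosomes(40), 5e5), seed = 1)
  cc <- cohort_config(grid = g, n_patients = 30, n_reads = 3e5)
  sim <- simulate_cohort(cc, seed = 11)
  pre <- sim$meta[sim$meta$timepoint == "pretreatment", ]
  expect_equal(nrow(pre), 30)
  # exactly 7/30 zero-ctDNA samples, per the configured fraction
  expect_equal(sum(pre$true_f == 0), 7)
  # paired samples share patient ids with distinct timepoints
  prog <- sim$meta[sim$meta$timepoint == "progression", ]
  expect_equal(nrow(prog), 20)
  expect_true(all(prog$patient_id %in% pre$patient_id))
  # metadata complete
  expect_false(any(is.na(pre$os_months)))
  expect_true(all(pre$os_months >= 0 & pre$pfs_months >= 0))
  # determinism
  sim2 <- simulate_cohort(cc, seed = 11)
  expect_identical(sim$meta, sim2$meta)
  expect_identical(sim$counts[["P3"]]$counts, sim2$counts[["P3"]]$counts)
  # invalid config rejected
  bad <- cc; bad$zero_ctdna_fraction <- 1.5
  expect_error(simulate_cohort(bad, seed = 1), "invalid params")
})

test_that("liver-metastasis stratification raises the tumour fraction", {
  g <- annotate_grid_synthetic(
    build_bin_grid(scaled_autosomes(100), 5e5), seed = 1)
  cc <- cohort_config(grid = g, n_patients = 200, n_reads = 1e5)
  cc$n_paired <- 0
  sim <- simulate_cohort(cc, seed = 19)
  pre <- sim$meta[sim$meta$timepoint == "pretreatment" & sim$meta$true_f > 0, ]
  med_liver <- median(pre$true_f[pre$liver_mets == "yes"])
  med_other <- median(pre$true_f[pre$liver_mets == "no"])
  expect_gt(med_liver, med_other)
})

test_that("null survival configuration gives a near-null log-rank statistic", {
  g <- annotate_grid_synthetic(
    build_bin_grid(scaled_autosomes(100), 5e5), seed = 1)
  cc <- cohort_config(grid = g, n_patients = 60, n_reads = 1e5)
  cc$os_median_by_tertile <- c(12, 12, 12)   # hazard ratio 1
  cc$n_paired <- 0
  stats <- replicate(10, NA_real_)
  for (i in 1:10) {
    sim <- simulate_cohort(cc, seed = 100 + i)
    pre <- sim$meta[sim$meta$timepoint == "pretreatment", ]
    tert <- tertile_assign(pre$cfdna_conc * pre$true_f)
    stats[i] <- km_logrank(pre$os_months, pre$os_event, tert,
                           ordered_levels = c("low", "medium", "high"))$chisq
  }
  # chi-square with 2 df has mean 2
  expect_lt(mean(stats), 4)
})
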