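#' Default parameters for a single simulated truth profile
#'
#' @param f Tumour fraction of cfDNA in \[0, 1\].
#' @param baseline_cn Baseline (modal) tumour copy number; 2 for near-diploid
#'   truths, 3 for near-triploid ones.
#' @param n_arm_events Number of whole-arm gains/losses.
#' @param arm_cn_states Allowed CN values for arm events (drawn uniformly,
#'   excluding the baseline).
#' @param focal_genes Driver gene symbols receiving a narrow high-level
#'   amplification (default ERBB2, the archetypal OGA driver). High-copy
#'   focal content is characteristic of CIN-type genomes and, together
#'   with the homozygous deletions, anchors the absolute copy number
#'   scale, which relative read depth alone leaves ambiguous.
#' @param focal_cn Copy number of focal amplifications (high-level, >= 8).
#' @param focal_width Width of focal events in bp.
#' @param max_focal_width Upper bound on focal event width.
#' @param homdel_genes Gene symbols at which a truncal homozygous deletion
#'   (CN 0) of `homdel_width` bp is placed. Defaults to the CDKN2A locus
#'   and the FHIT/WWOX fragile sites, recurrently deleted in
#'   oesophagogastric adenocarcinoma; these floor-state regions pin the
#'   absolute ploidy.
#' @param homdel_width Width of homozygous deletions in bp.
#' @param high_gain_arms Number of arms carried at CN 5 (broad high-level
#'   gain, e.g. chr8q in OGA); near-ceiling broad content complements the
#'   deletions in pinning the absolute scale.
#' @param subclone NULL, or `list(weight=, n_private_events=)` to add a
#'   subclone carrying private arm events (used for progression pairs).
#' @return Parameter list for [simulate_truth_profile()].
#' @export
truth_params <- function(f = 0.3, baseline_cn = 2, n_arm_events = 8,
                         arm_cn_states = NULL, focal_genes = "ERBB2",
                         focal_cn = 12, focal_width = 1e6,
                         max_focal_width = 3e6,
                         homdel_genes = c("CDKN2A", "FHIT", "WWOX"),
                         homdel_width = 3e6, high_gain_arms = 1,
                         subclone = NULL) {
  if (is.null(arm_cn_states))
    arm_cn_states <- c(baseline_cn - 1, baseline_cn + 1)
  list(f = f, baseline_cn = baseline_cn, n_arm_events = n_arm_events,
       arm_cn_states = arm_cn_states, focal_genes = focal_genes,
       focal_cn = focal_cn, focal_width = focal_width,
       max_focal_width = max_focal_width, homdel_genes = homdel_genes,
       homdel_width = homdel_width, high_gain_arms = high_gain_arms,
       subclone = subclone)
}

chrom_arms <- function(grid) {
  lens <- attr(grid, "chrom_lengths")
  cen <- hg19_centromeres()
  out <- lapply(names(lens), function(ch) {
    len <- lens[[ch]]
    mid <- if (ch %in% names(cen)) min(cen[[ch]], len * 0.9) else len / 2
    data.frame(chrom = ch, start = c(0, mid), end = c(mid, len),
               arm = c("p", "q"), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Materialize one clone's per-bin CN on a grid: events applied in order,
# later events override earlier ones; a bin belongs to an event iff its
# midpoint falls inside the event interval.
clone_bin_cn <- function(events, baseline_cn, grid) {
  cn <- rep(baseline_cn, nrow(grid))
  if (is.null(events) || nrow(events) == 0) return(cn)
  mid <- (grid$start + grid$end) / 2
  for (i in seq_len(nrow(events))) {
    hit <- grid$chrom == events$chrom[i] &
      mid >= events$start[i] & mid < events$end[i]
    cn[hit] <- events$cn[i]
  }
  cn
}

#' Mixed tumour copy number of a truth profile on a grid
#'
#' Length-weighted clone mixture: per bin, sum of clone weight times clone CN.
#'
#' @param truth A `truth_profile`.
#' @param grid Target `bin_grid` (defaults to the grid the truth was built on).
#' @return Numeric per-bin mixed tumour copy number.
#' @export
truth_bin_cn <- function(truth, grid = truth$grid) {
  mats <- vapply(truth$clones, function(cl)
    cl$weight * clone_bin_cn(cl$events, truth$baseline_cn, grid),
    numeric(nrow(grid)))
  if (is.null(dim(mats))) mats <- matrix(mats, nrow = nrow(grid))
  rowSums(mats)
}

truth_ploidy <- function(truth, grid = truth$grid) {
  len <- bin_lengths(grid)
  sum(truth_bin_cn(truth, grid) * len) / sum(len)
}

#' Simulate a ground-truth tumour copy number profile
#'
#' Draws whole-arm gains/losses on distinct chromosome arms and optional
#' narrow high-level focal amplifications at driver gene loci, for one or
#' two clones. The stored tumour ploidy is the length-weighted mean copy
#' number of the mixed tumour genome.
#'
#' @param grid A `bin_grid` (the 500 kb analysis grid).
#' @param params See [truth_params()].
#' @param seed Integer seed; profiles are reproducible given the seed.
#' @param sample_id Sample identifier.
#' @return A `truth_profile`: sample_id, f, phi, baseline_cn, clones
#'   (weight + event table), focal_amps, grid.
#' @export
simulate_truth_profile <- function(grid, params = truth_params(), seed = 1L,
                                   sample_id = "S1") {
  arms <- chrom_arms(grid)
  n_ev <- params$n_arm_events
  n_hg <- if (is.null(params$high_gain_arms)) 0L else params$high_gain_arms
  n_sub <- if (is.null(params$subclone)) 0L else params$subclone$n_private_events
  if (n_ev + n_hg + n_sub > nrow(arms))
    stop("invalid params: requested ", n_ev + n_hg + n_sub,
         " arm events but only ", nrow(arms), " arms available", call. = FALSE)
  if (params$focal_width > params$max_focal_width)
    stop("invalid params: focal_width exceeds max_focal_width", call. = FALSE)

  rng <- local_rng(seed, paste0("truth-", sample_id))
  on.exit(restore_rng(rng))

  pick <- if (n_ev + n_hg + n_sub > 0)
    sample.int(nrow(arms), n_ev + n_hg + n_sub) else integer()
  states <- setdiff(params$arm_cn_states, params$baseline_cn)
  mk_events <- function(idx) {
    if (length(idx) == 0)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), cn = numeric()))
    data.frame(chrom = arms$chrom[idx], start = arms$start[idx],
               end = arms$end[idx],
               cn = sample(states, length(idx), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  trunk <- mk_events(pick[seq_len(n_ev)])
  if (n_hg > 0) {
    hg <- pick[n_ev + seq_len(n_hg)]
    trunk <- rbind(trunk, data.frame(chrom = arms$chrom[hg],
                                     start = arms$start[hg],
                                     end = arms$end[hg], cn = 5,
                                     stringsAsFactors = FALSE))
  }

  # focal events are truncal: appended last so they override arm CN
  genes <- driver_genes()
  focal <- genes[genes$gene %in% params$focal_genes, , drop = FALSE]
  if (nrow(focal) > 0) {
    mid <- (focal$start + focal$end) / 2
    trunk <- rbind(trunk, data.frame(
      chrom = focal$chrom, start = pmax(0, mid - params$focal_width / 2),
      end = mid + params$focal_width / 2,
      cn = params$focal_cn, stringsAsFactors = FALSE))
  }
  hd <- genes[genes$gene %in% params$homdel_genes, , drop = FALSE]
  if (nrow(hd) > 0) {
    mid <- (hd$start + hd$end) / 2
    trunk <- rbind(trunk, data.frame(
      chrom = hd$chrom, start = pmax(0, mid - params$homdel_width / 2),
      end = mid + params$homdel_width / 2, cn = 0, stringsAsFactors = FALSE))
  }

  clones <- list(list(weight = 1, events = trunk))
  if (!is.null(params$subclone)) {
    private <- mk_events(pick[n_ev + n_hg + seq_len(n_sub)])
    clones <- list(
      list(weight = 1 - params$subclone$weight, events = trunk),
      list(weight = params$subclone$weight, events = rbind(trunk, private)))
  }

  truth <- structure(list(sample_id = sample_id, f = params$f, phi = NA_real_,
                          baseline_cn = params$baseline_cn, clones = clones,
                          focal_amps = if (nrow(focal) > 0)
                            data.frame(gene = focal$gene, cn = params$focal_cn)
                          else data.frame(gene = character(), cn = numeric()),
                          grid = grid),
                     class = "truth_profile")
  truth$phi <- truth_ploidy(truth)
  truth
}

#' GC bias curve used by the read-count simulator
#'
#' Multiplicative log-quadratic curve `exp(c1*(gc-0.45) + c2*(gc-0.45)^2)`,
#' strictly positive.
#'
#' @param gc GC fractions.
#' @param coef Length-2 coefficient vector; `c(0, 0)` is a flat (bias-free)
#'   curve.
#' @return Relative rate per bin.
#' @export
gc_bias_curve <- function(gc, coef = c(-1, -8)) {
  exp(coef[1] * (gc - 0.45) + coef[2] * (gc - 0.45)^2)
}

#' Simulate binned read counts for a truth profile
#'
#' Counts are drawn per bin from a negative binomial whose mean is
#' proportional to bin length times the cfDNA copy number mixture
#' `f * CN_tumour + (1 - f) * 2`, times the GC bias curve and mappability,
#' scaled so the expected total equals `n_reads`. Read-level simulation is
#' deliberately skipped: the analysis consumes only bin counts.
#'
#' @param truth A `truth_profile`.
#' @param grid Target `bin_grid`.
#' @param n_reads Expected total read count (default 12 million, the study's
#'   per-sample sequencing target).
#' @param bias `list(gc_coef=, dispersion=)`; `dispersion` is the negative
#'   binomial size parameter (larger = closer to Poisson).
#' @param seed Integer seed.
#' @return A `bin_counts` object.
#' @export
simulate_bin_counts <- function(truth, grid = truth$grid, n_reads = 12e6,
                                bias = list(gc_coef = c(-1, -8), dispersion = 100),
                                seed = 1L) {
  stopifnot(n_reads > 0, bias$dispersion > 0)
  mix <- truth$f * truth_bin_cn(truth, grid) + (1 - truth$f) * 2
  mu <- bin_lengths(grid) * mix * gc_bias_curve(grid$gc, bias$gc_coef) *
    grid$mappability
  if (all(mu == 0))
    stop("degenerate input: expected read mass is zero everywhere", call. = FALSE)
  mu <- mu * (n_reads / sum(mu))
  rng <- local_rng(seed, paste0("counts-", truth$sample_id))
  on.exit(restore_rng(rng))
  counts <- stats::rnbinom(length(mu), mu = mu, size = bias$dispersion)
  bin_counts(truth$sample_id, counts, grid)
}

#' Simulate a matched progression sample by shifting clone weights
#'
#' The trunk events are preserved; the mixed copy number changes only in
#' bins private to reweighted clones, emulating a shift in clonal
#' composition during chemotherapy. Optionally adds progression-private
#' arm events as a new clone.
#'
#' @param truth_pre Pretreatment `truth_profile`.
#' @param shift `list(weights=, f_prog=, n_new_events=)`: new clone weights
#'   (must sum to 1; length = number of clones, +1 if `n_new_events > 0`),
#'   the progression tumour fraction, and the number of arm events private
#'   to a newly arising clone.
#' @param seed Integer seed.
#' @return A `truth_profile` for the progression timepoint.
#' @export
simulate_progression_pair <- function(truth_pre, shift, seed = 1L) {
  n_new <- if (is.null(shift$n_new_events)) 0L else shift$n_new_events
  if (length(truth_pre$clones) < 2 && n_new == 0)
    stop("invalid params: need >= 2 clones or new private events", call. = FALSE)
  clones <- truth_pre$clones
  if (n_new > 0) {
    rng <- local_rng(seed, paste0("prog-", truth_pre$sample_id))
    arms <- chrom_arms(truth_pre$grid)
    used <- unique(unlist(lapply(clones, function(cl)
      paste(cl$events$chrom, cl$events$start))))
    free <- which(!paste(arms$chrom, arms$start) %in% used)
    if (length(free) < n_new)
      stop("invalid params: not enough unused arms for new events", call. = FALSE)
    idx <- free[sample.int(length(free), n_new)]
    states <- setdiff(c(truth_pre$baseline_cn - 1, truth_pre$baseline_cn + 1),
                      truth_pre$baseline_cn)
    private <- data.frame(chrom = arms$chrom[idx], start = arms$start[idx],
                          end = arms$end[idx],
                          cn = sample(states, n_new, replace = TRUE),
                          stringsAsFactors = FALSE)
    restore_rng(rng)
    parent <- clones[[length(clones)]]
    clones <- c(clones, list(list(weight = 0,
                                  events = rbind(parent$events, private))))
  }
  if (length(shift$weights) != length(clones))
    stop("invalid params: weights length must match clone count", call. = FALSE)
  if (abs(sum(shift$weights) - 1) > 1e-9)
    stop("invalid params: clone weights must sum to 1", call. = FALSE)
  for (i in seq_along(clones)) clones[[i]]$weight <- shift$weights[i]
  prog <- truth_pre
  prog$sample_id <- paste0(truth_pre$sample_id, "_prog")
  prog$clones <- clones
  prog$f <- if (is.null(shift$f_prog)) truth_pre$f else shift$f_prog
  prog$phi <- truth_ploidy(prog)
  prog
}

#' Default synthetic cohort configuration
#'
#' The defaults emulate the study cohort: 30 patients, 7 of them with zero
#' ctDNA; tumour fractions drawn lognormally, stratified so that patients
#' with liver metastases have a higher median fraction (0.18 vs 0.07) and
#' patients with the primary in situ skew higher; cfDNA concentration
#' lognormal with median 8.9 ng/mL; overall survival exponential with
#' median depending on the ctDNA-concentration tertile (19.5 / 11.3 / 12.8
#' months, low to high); 20 patients paired with a progression sample whose
#' tumour fraction drops in responders (median ratio 0.45) but not in
#' nonresponders.
#'
#' @param grid A `bin_grid`; defaults to the hg19 autosomes at 500 kb.
#' @param n_patients Number of patients.
#' @param n_reads Reads per sample.
#' @param dispersion Negative binomial size for count simulation.
#' @return Config list for [simulate_cohort()].
#' @export
cohort_config <- function(grid = NULL, n_patients = 30, n_reads = 12e6,
                          dispersion = 100) {
  if (is.null(grid))
    grid <- annotate_grid_synthetic(build_bin_grid(hg19_autosomes(), 5e5))
  list(
    grid = grid, n_patients = n_patients, n_reads = n_reads,
    dispersion = dispersion, gc_coef = c(-1, -8),
    zero_ctdna_fraction = 7 / 30,
    liver_mets_prob = 16 / 30, primary_in_situ_prob = 23 / 30,
    gastric_prob = 6 / 30, responder_prob = 13 / 23,
    f_median_liver = 0.18, f_median_no_liver = 0.07, f_sdlog = 0.7,
    f_range = c(0.04, 0.55),
    cfdna_median = 8.9, cfdna_sdlog = 0.8,
    os_median_by_tertile = c(19.5, 11.3, 12.8),
    pfs_median_by_tertile = c(9, 6.5, 6.5),
    followup_months = 36,
    n_paired = 20, prog_zero_n = 3,
    prog_f_ratio_responder = 0.45, prog_f_ratio_nonresponder = 1.0,
    subclone_weight = 0.2, subclone_events = 2,
    n_arm_events = 8, ploidy3_prob = 0.3,
    focal_gene_pool = c("ERBB2", "EGFR", "MET", "KRAS", "MYC", "CCND1",
                        "GATA4", "VEGFA"),
    focal_prob = 0.7, focal_cn = 12,
    homdel_gene = c("CDKN2A", "FHIT", "WWOX")
  )
}

#' Simulate a full synthetic patient cohort
#'
#' Generates ground-truth copy number profiles, binned read counts with GC
#' and mappability bias, clinical metadata (response group, survival,
#' cfDNA concentration) and paired progression samples for a subset of
#' patients. Deterministic given `seed`.
#'
#' @param config See [cohort_config()].
#' @param seed Integer seed.
#' @return `list(counts=, meta=, truths=)`: bin counts and truth profiles
#'   keyed by sample id (pretreatment ids `P<k>`, progression `P<k>_prog`),
#'   and one metadata row per sample.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (config$zero_ctdna_fraction > 1 || config$zero_ctdna_fraction < 0)
    stop("invalid params: zero_ctdna_fraction must be in [0, 1]", call. = FALSE)
  grid <- config$grid
  n <- config$n_patients
  rng <- local_rng(seed, "cohort")
  on.exit(restore_rng(rng))

  liver <- stats::runif(n) < config$liver_mets_prob
  in_situ <- stats::runif(n) < config$primary_in_situ_prob
  gastric <- stats::runif(n) < config$gastric_prob
  responder <- stats::runif(n) < config$responder_prob

  # zero-ctDNA patients: exactly round(fraction * n), biased away from liver
  # metastases (the study's zero cases had locally advanced or low-burden
  # disease)
  n_zero <- round(config$zero_ctdna_fraction * n)
  w <- ifelse(liver, 0.2, 1)
  zero_idx <- sample.int(n, n_zero, prob = w)

  f_med <- ifelse(liver, config$f_median_liver, config$f_median_no_liver) *
    ifelse(in_situ, 1.2, 0.6)
  f <- stats::rlnorm(n, log(f_med), config$f_sdlog)
  f <- pmin(config$f_range[2], pmax(config$f_range[1], f))
  f[zero_idx] <- 0

  cfdna <- stats::rlnorm(n, log(config$cfdna_median) * ifelse(in_situ, 1.05, 0.85),
                         config$cfdna_sdlog)
  ctdna_conc <- cfdna * f

  # survival: exponential with median set by ctDNA-concentration tertile
  tert <- tertile_assign(ctdna_conc)
  tert_i <- match(tert, c("low", "medium", "high"))
  os_rate <- log(2) / config$os_median_by_tertile[tert_i]
  pfs_rate <- log(2) / config$pfs_median_by_tertile[tert_i]
  os_t <- stats::rexp(n, os_rate)
  pfs_t <- stats::rexp(n, pfs_rate)
  os_event <- as.integer(os_t <= config$followup_months)
  pfs_event <- as.integer(pfs_t <= config$followup_months)
  os_t <- pmin(os_t, config$followup_months)
  pfs_t <- pmin(pfs_t, config$followup_months)

  detectable <- which(f > 0)
  paired <- detectable[seq_len(min(config$n_paired, length(detectable)))]

  truth_seeds <- sample.int(2^30, n)
  prog_seeds <- sample.int(2^30, n)
  focal_draw <- stats::runif(n)
  focal_gene <- sample(config$focal_gene_pool, n, replace = TRUE)
  ploidy3 <- stats::runif(n) < config$ploidy3_prob
  prog_zero <- if (length(paired) > 0)
    paired[sample.int(length(paired), min(config$prog_zero_n, length(paired)))]
  else integer()
  prog_ratio_draw <- stats::rlnorm(n, 0, 0.25)

  truths <- list(); counts <- list(); meta_rows <- list()
  for (i in seq_len(n)) {
    pid <- paste0("P", i)
    base_cn <- if (ploidy3[i]) 3 else 2
    params <- truth_params(
      f = f[i], baseline_cn = base_cn, n_arm_events = config$n_arm_events,
      focal_genes = if (f[i] > 0 && focal_draw[i] < config$focal_prob)
        focal_gene[i] else character(),
      focal_cn = config$focal_cn,
      homdel_genes = config$homdel_gene,
      subclone = if (i %in% paired)
        list(weight = config$subclone_weight,
             n_private_events = config$subclone_events) else NULL)
    tr <- simulate_truth_profile(grid, params, seed = truth_seeds[i],
                                 sample_id = pid)
    truths[[pid]] <- tr
    counts[[pid]] <- simulate_bin_counts(
      tr, grid, n_reads = config$n_reads,
      bias = list(gc_coef = config$gc_coef, dispersion = config$dispersion),
      seed = truth_seeds[i])
    meta_rows[[pid]] <- data.frame(
      sample_id = pid, patient_id = pid, timepoint = "pretreatment",
      response_group = if (responder[i]) "responder" else "nonresponder",
      cfdna_conc = cfdna[i], true_f = f[i],
      os_months = os_t[i], os_event = os_event[i],
      pfs_months = pfs_t[i], pfs_event = pfs_event[i],
      liver_mets = ifelse(liver[i], "yes", "no"),
      primary_in_situ = ifelse(in_situ[i], "yes", "no"),
      site = ifelse(gastric[i], "gastric", "nongastric"),
      stringsAsFactors = FALSE)

    if (i %in% paired) {
      ratio <- if (responder[i]) config$prog_f_ratio_responder else
        config$prog_f_ratio_nonresponder
      f_prog <- if (i %in% prog_zero) 0 else
        min(config$f_range[2], f[i] * ratio * prog_ratio_draw[i])
      w_pre <- config$subclone_weight
      pr <- simulate_progression_pair(
        tr, shift = list(weights = c(w_pre, 1 - w_pre), f_prog = f_prog),
        seed = prog_seeds[i])
      pid_prog <- pr$sample_id
      truths[[pid_prog]] <- pr
      counts[[pid_prog]] <- simulate_bin_counts(
        pr, grid, n_reads = config$n_reads,
        bias = list(gc_coef = config$gc_coef, dispersion = config$dispersion),
        seed = prog_seeds[i])
      m <- meta_rows[[pid]]
      m$sample_id <- pid_prog
      m$timepoint <- "progression"
      m$true_f <- f_prog
      meta_rows[[pid_prog]] <- m
    }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  list(counts = counts, meta = meta, truths = truths)
}
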