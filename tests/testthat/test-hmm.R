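test_that("emission means match the cfDNA mixture model", {
  expect_equal(emission_mean(0:5, 0, 2), rep(0, 6))
  expect_equal(emission_mean(4, 1, 2), 1)
  expect_equal(emission_mean(3, 0.5, 2), log2(2.5 / 2))
  expect_equal(emission_mean(3, 0.5, 2), 0.3219281, tolerance = 1e-7)
  # degenerate numerator returns the configured floor
  expect_equal(emission_mean(0, 1, 2), -8)
  expect_equal(emission_mean(0, 1, 2, floor = -12), -12)
  expect_error(emission_mean(2, -0.1, 2), "f must")
  expect_error(emission_mean(2, 0.5, 0), "phi")
})

test_that("absolute copy number inverts the emission mean", {
  expect_equal(absolute_copy_number(0, 0.37, 2), 2)
  expect_equal(absolute_copy_number(0.3219281, 0.5, 2), 3, tolerance = 1e-6)
  expect_error(absolute_copy_number(0.1, 0, 2), "undefined")
  for (phi in c(2, 3)) for (f in seq(0.1, 1, by = 0.1)) for (c in 0:5) {
    m <- emission_mean(c, f, phi, floor = -Inf)
    expect_equal(absolute_copy_number(m, f, phi), c, tolerance = 1e-9)
  }
})

test_that("Viterbi matches exhaustive enumeration with the neutral tie-break", {
  states <- 0:5
  n <- 6
  paths <- enumerate_paths(n, 6)
  g <- one_chrom_grid(n)
  set.seed(101)
  for (i in 1:25) {
    f <- runif(1, 0.1, 0.8)
    phi <- runif(1, 1.8, 3.2)
    sd <- runif(1, 0.05, 0.3)
    self <- runif(1, 0.5, 0.999)
    mu <- emission_mean(states, f, phi)
    r <- rnorm(n, sample(mu, n, replace = TRUE), sd)
    p <- hmm_params(f, phi, sd, states, self)
    got <- viterbi_states(ratio_obj(r), p, g)
    trans <- scnatrack:::transition_matrix(6, self)
    oracle <- brute_viterbi(r, mu, sd, trans, states, paths)
    expect_equal(got, states[oracle$path])
  }
})

test_that("noiseless ratios at state means are recovered exactly", {
  states <- 0:5
  g <- one_chrom_grid(12)
  mu <- emission_mean(states, 0.4, 2)
  truth <- c(rep(3, 4), rep(1, 4), rep(5, 4))
  r <- mu[match(truth, states)]
  p <- hmm_params(0.4, 2, 0.05, states, 0.99)
  expect_equal(viterbi_states(ratio_obj(r), p, g), truth)
  # all-zero ratios with f > 0 give the all-neutral path
  p2 <- hmm_params(0.3, 2, 0.1, states, 0.99)
  expect_true(all(viterbi_states(ratio_obj(rep(0, 12)), p2, g) == 2))
})

test_that("forward-backward posteriors match enumeration and sum to one", {
  states <- 0:5
  n <- 6
  paths <- enumerate_paths(n, 6)
  g <- one_chrom_grid(n)
  set.seed(103)
  for (i in 1:10) {
    f <- runif(1, 0.2, 0.7); phi <- runif(1, 1.9, 3); sd <- runif(1, 0.08, 0.25)
    self <- runif(1, 0.6, 0.99)
    mu <- emission_mean(states, f, phi)
    r <- rnorm(n, sample(mu, n, replace = TRUE), sd)
    p <- hmm_params(f, phi, sd, states, self)
    fb <- scnatrack:::forward_backward(ratio_obj(r), p, g)
    expect_equal(rowSums(fb$gamma), rep(1, n), tolerance = 1e-9)
    trans <- scnatrack:::transition_matrix(6, self)
    oracle <- brute_viterbi(r, mu, sd, trans, states, paths)
    expect_equal(fb$gamma, brute_posteriors(oracle$scores, paths, n, 6),
                 tolerance = 1e-6)
    # total log-likelihood equals the log-sum over all paths
    expect_equal(fb$loglik,
                 max(oracle$scores) + log(sum(exp(oracle$scores - max(oracle$scores)))),
                 tolerance = 1e-6)
  }
})

test_that("non-finite ratios in valid bins are rejected", {
  g <- one_chrom_grid(4)
  r <- ratio_obj(c(0, NA, 0, 0))
  p <- hmm_params(0.3, 2, 0.1)
  expect_error(viterbi_states(r, p, g), "non-finite")
})

test_that("EM increases the likelihood and converges fast on clean data", {
  g <- one_chrom_grid(300)
  cn <- rep(2L, 300); cn[50:120] <- 3L; cn[200:240] <- 1L
  r <- ratios_from_cn(cn, g, f = 0.3, phi = 2, sd = 0.02, seed = 5)
  fit <- em_fit(r, g, init_f = 0.3, init_phi = 2)
  expect_lte(fit$n_iter, 5)
  expect_equal(fit$f, 0.3, tolerance = 0.02)

  # monotone likelihood on noisier random data (em_fit errors on decrease)
  set.seed(6)
  for (i in 1:3) {
    rr <- ratios_from_cn(cn, g, f = 0.25, phi = 2, sd = 0.15, seed = 10 + i)
    expect_no_error(em_fit(rr, g, init_f = runif(1, 0.1, 0.5), init_phi = 2))
  }
})

test_that("profile estimation recovers parameters on a small genome", {
  g <- annotate_grid_synthetic(build_bin_grid(scaled_autosomes(4), 5e5),
                               seed = 3)
  tr <- simulate_truth_profile(g, truth_params(f = 0.35, n_arm_events = 8),
                               seed = 7)
  cnt <- simulate_bin_counts(tr, g, n_reads = 3e6, seed = 8)
  r <- normalize_counts(cnt, g)
  pr <- estimate_profile(r, g, counts = cnt)
  expect_false(pr$zero_ctdna)
  expect_equal(pr$f, 0.35, tolerance = 0.07)
  expect_equal(pr$phi, tr$phi, tolerance = 0.3)
  # segments partition valid bins; adjacent segments differ in CN
  s <- pr$segments
  for (ch in unique(s$chrom)) {
    sc <- s[s$chrom == ch, ]
    if (nrow(sc) > 1) expect_true(all(diff(sc$cn) != 0))
  }
  expect_equal(sum(s$n_bins), sum(r$valid))
})

test_that("a flat sample is flagged zero-ctDNA", {
  g <- annotate_grid_synthetic(build_bin_grid(scaled_autosomes(4), 5e5),
                               seed = 3)
  tr <- simulate_truth_profile(
    g, truth_params(f = 0, n_arm_events = 0, focal_genes = character(),
                    homdel_genes = character(), high_gain_arms = 0), seed = 9)
  cnt <- simulate_bin_counts(tr, g, n_reads = 3e6, seed = 10)
  r <- normalize_counts(cnt, g)
  pr <- estimate_profile(r, g, counts = cnt)
  expect_true(pr$zero_ctdna)
  expect_equal(pr$f, 0)
  expect_true(all(pr$bin_cn[r$valid] == 2))
})

test_that("ambiguous mirror data resolve to the smaller aberration load", {
  # ~40% of the genome elevated: explainable as 40% gained (load 0.4) or
  # 60% lost at a different fraction (load 0.6); selection must choose the
  # parsimonious gain interpretation
  g <- annotate_grid_synthetic(build_bin_grid(scaled_autosomes(4), 5e5),
                               seed = 3)
  tr <- simulate_truth_profile(
    g, truth_params(f = 0.4, n_arm_events = 0, focal_genes = character(),
                    homdel_genes = character(), high_gain_arms = 0), seed = 11)
  arms <- scnatrack:::chrom_arms(g)
  set.seed(12)
  pick <- sample(nrow(arms), 18)
  tr$clones[[1]]$events <- data.frame(chrom = arms$chrom[pick],
                                      start = arms$start[pick],
                                      end = arms$end[pick], cn = 3)
  tr$phi <- scnatrack:::truth_ploidy(tr)
  cnt <- simulate_bin_counts(tr, g, n_reads = 3e6, seed = 13)
  r <- normalize_counts(cnt, g)
  pr <- estimate_profile(r, g, counts = cnt)
  frac_gain <- mean(pr$bin_cn[r$valid] > 2)
  frac_loss <- mean(pr$bin_cn[r$valid] < 2)
  expect_gt(frac_gain, 0.25)
  expect_lt(frac_loss, 0.1)
})

test_that("uniform resegmentation is an identity for one profile", {
  g <- toy_grid(n_chrom = 2, chrom_len = 20e6)
  cn <- rep(2L, nrow(g)); cn[5:12] <- 3L; cn[50:60] <- 1L
  p <- profile_from_cn(cn, g)
  rs <- uniform_resegment(list(p))
  expect_equal(rs$segments$start, p$segments$start)
  expect_equal(rs$segments$end, p$segments$end)
  expect_equal(unname(rs$cn[1, ]), p$segments$cn)
})

test_that("uniform resegmentation unions breakpoints and preserves means", {
  g <- toy_grid(n_chrom = 2, chrom_len = 20e6)
  set.seed(55)
  for (rep in 1:10) {
    profs <- lapply(1:3, function(i) {
      cn <- rep(2L, nrow(g))
      for (k in 1:2) {
        ch <- sample(unique(g$chrom), 1)
        idx <- which(g$chrom == ch)
        a <- sort(sample(idx, 2))
        cn[a[1]:a[2]] <- sample(c(1L, 3L, 4L), 1)
      }
      profile_from_cn(cn, g, sample_id = paste0("S", i))
    })
    rs <- uniform_resegment(profs)
    # breakpoint union oracle
    for (ch in unique(g$chrom)) {
      bp <- sort(unique(unlist(lapply(profs, function(p) {
        s <- p$segments[p$segments$chrom == ch, ]
        c(s$start, s$end)
      }))))
      expect_equal(nrow(rs$segments[rs$segments$chrom == ch, ]),
                   length(bp) - 1)
    }
    # conservation of length-weighted mean CN
    seg_len <- rs$segments$end - rs$segments$start
    for (i in 1:3) {
      orig <- profs[[i]]$segments
      orig_mean <- sum((orig$end - orig$start) * orig$cn) /
        sum(orig$end - orig$start)
      new_mean <- sum(seg_len * rs$cn[i, ]) / sum(seg_len)
      expect_equal(new_mean, orig_mean, tolerance = 1e-12)
    }
  }
})

test_that("model-free segmentation finds short interior segments", {
  g <- one_chrom_grid(200)
  set.seed(77)
  r <- rnorm(200, 0, 0.1)
  r[80:86] <- r[80:86] - 0.6   # 7-bin deep dip
  r[120:160] <- r[120:160] + 0.3
  segs <- pcf_segments(ratio_obj(r), g)
  dip <- segs[segs$mean_log2 < -0.3, ]
  expect_equal(nrow(dip), 1)
  expect_equal(dip$n_bins, 7)
  expect_equal(dip$start, g$start[80])
})
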