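test_that("aberration matrix uses ploidy-relative semantics", {
  g <- toy_grid(n_chrom = 2, chrom_len = 20e6)
  n <- nrow(g)
  cn_a <- rep(2L, n); cn_a[1:10] <- 3L          # gain on chr1
  cn_b <- rep(3L, n)                            # uniformly CN3, phi 3
  profs <- list(profile_from_cn(cn_a, g, phi = 2, sample_id = "A"),
                profile_from_cn(cn_b, g, phi = 3, sample_id = "B"))
  m <- aberration_matrix(profs)
  # sample B: CN 3 at phi 3 is neutral everywhere
  expect_true(all(m$calls[2, ] == "neutral"))
  # sample A: gain where CN 3
  gain_cols <- m$segments$chrom == "chr1" & m$segments$end <= 5e6
  expect_true(all(m$calls[1, gain_cols] == "gain"))
})

test_that("aberration matrix matches brute-force comparison on random toys", {
  g <- toy_grid(n_chrom = 3, chrom_len = 10e6)
  set.seed(31)
  for (rep in 1:10) {
    cns <- lapply(1:4, function(i) {
      cn <- rep(2L, nrow(g))
      for (k in 1:3) {
        ch <- sample(unique(g$chrom), 1)
        idx <- which(g$chrom == ch)
        a <- sort(sample(idx, 2))
        cn[a[1]:a[2]] <- sample(c(0:1, 3:5), 1)
      }
      cn
    })
    profs <- make_cohort_profiles(cns, g)
    m <- aberration_matrix(profs)
    mid <- (m$segments$start + m$segments$end) / 2
    for (i in 1:4) for (j in seq_len(nrow(m$segments))) {
      bin <- which(g$chrom == m$segments$chrom[j] &
                     g$start <= mid[j] & g$end > mid[j])
      d <- cns[[i]][bin] - 2
      expected <- if (d >= 1) "gain" else if (d <= -1) "loss" else "neutral"
      expect_equal(m$calls[i, j], expected)
    }
  }
})

test_that("zero-ctDNA samples are excluded from the aberration matrix", {
  g <- toy_grid(n_chrom = 2, chrom_len = 10e6)
  p1 <- profile_from_cn(rep(2L, nrow(g)), g, sample_id = "A")
  p0 <- profile_from_cn(rep(2L, nrow(g)), g, sample_id = "Z")
  p0$zero_ctdna <- TRUE
  expect_warning(m <- aberration_matrix(list(p1, p0)), "zero-ctDNA")
  expect_equal(m$sample_ids, "A")
  expect_error(suppressWarnings(aberration_matrix(list(p0))), "no detectable")
  expect_error(aberration_matrix(list()), "empty")
})

test_that("group frequencies are bounded tallies matching brute force", {
  g <- toy_grid(n_chrom = 2, chrom_len = 20e6)
  set.seed(41)
  cns <- lapply(1:6, function(i) {
    cn <- rep(2L, nrow(g))
    idx <- sample(nrow(g), 15)
    cn[idx] <- sample(c(1L, 3L), 15, replace = TRUE)
    cn
  })
  profs <- make_cohort_profiles(cns, g)
  m <- aberration_matrix(profs)
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  tr <- group_frequency(m, grp)
  expect_true(all(tr$gain <= tr$group_size))
  expect_true(all(tr$loss <= tr$group_size))
  expect_equal(tr$gain, colSums(m$calls[grp, , drop = FALSE] == "gain"))
  expect_equal(tr$loss, colSums(m$calls[grp, , drop = FALSE] == "loss"))
  # single-sample group equals its own indicators
  tr1 <- group_frequency(m, c(TRUE, rep(FALSE, 5)))
  expect_equal(tr1$gain, as.integer(m$calls[1, ] == "gain"))
  expect_error(group_frequency(m, rep(FALSE, 6)), "empty group")
})

test_that("unique regions reproduce the responder-specific gain structure", {
  # 13 'responders' of whom 5 carry a gain over one region; 10 comparison
  # samples with none: one unique region with carrier count 5
  g <- toy_grid(n_chrom = 2, chrom_len = 20e6)
  n <- nrow(g)
  region_bins <- which(g$chrom == "chr2")[5:20]
  cns_a <- lapply(1:13, function(i) {
    cn <- rep(2L, n)
    if (i <= 5) cn[region_bins] <- 3L
    cn
  })
  cns_b <- lapply(1:10, function(i) rep(2L, n))
  profs <- make_cohort_profiles(c(cns_a, cns_b), g)
  m <- aberration_matrix(profs)
  tr_a <- group_frequency(m, 1:13)
  tr_b <- group_frequency(m, 14:23)
  uq <- unique_regions(tr_a, tr_b)
  expect_equal(nrow(uq), 1)
  expect_equal(uq$direction, "gain")
  expect_equal(uq$carriers, 5)
  expect_true(uq$frequent)  # 5/13 > 1/3
  expect_equal(uq$chrom, "chr2")

  # identical tracks give no unique regions
  expect_equal(nrow(unique_regions(tr_a, tr_a)), 0)
})

test_that("unique regions match a brute-force scan and are disjoint", {
  g <- toy_grid(n_chrom = 2, chrom_len = 10e6)
  set.seed(51)
  for (rep in 1:10) {
    cns <- lapply(1:6, function(i) {
      cn <- rep(2L, nrow(g))
      idx <- sample(nrow(g), 8)
      cn[idx] <- sample(c(1L, 3L), 8, replace = TRUE)
      cn
    })
    profs <- make_cohort_profiles(cns, g)
    m <- aberration_matrix(profs)
    a_idx <- 1:3
    tr_a <- group_frequency(m, a_idx)
    tr_b <- group_frequency(m, 4:6)
    uq <- unique_regions(tr_a, tr_b, min_length = 0)
    # brute force per segment and direction
    for (dir in c("gain", "loss")) {
      expect_uniq <- tr_a[[dir]] > 0 & tr_b[[dir]] == 0
      covered <- rep(FALSE, nrow(m$segments))
      rows <- uq[uq$direction == dir, ]
      if (nrow(rows)) for (q in seq_len(nrow(rows))) {
        covered <- covered | (m$segments$chrom == rows$chrom[q] &
                                m$segments$start >= rows$start[q] &
                                m$segments$end <= rows$end[q])
      }
      expect_equal(covered, expect_uniq)
    }
    # symmetry: unique(A,B) and unique(B,A) never overlap in same direction
    uq_ba <- unique_regions(tr_b, tr_a, min_length = 0)
    for (dir in c("gain", "loss")) {
      ra <- uq[uq$direction == dir, ]
      rb <- uq_ba[uq_ba$direction == dir, ]
      if (nrow(ra) && nrow(rb)) for (x in seq_len(nrow(ra)))
        expect_false(any(rb$chrom == ra$chrom[x] & rb$start < ra$end[x] &
                           rb$end > ra$start[x]))
    }
  }
})

test_that("minimal consistent region is the deepest shared core", {
  # carriers aberrant on [2,10), [4,12), [6,14) Mb -> core [6,10)
  g <- toy_grid(n_chrom = 1, chrom_len = 20e6, bin_width = 1e6)
  mk <- function(from, to) {
    cn <- rep(2L, nrow(g))
    cn[(g$start >= from * 1e6) & (g$end <= to * 1e6)] <- 3L
    cn
  }
  profs <- make_cohort_profiles(list(mk(2, 10), mk(4, 12), mk(6, 14)), g)
  m <- aberration_matrix(profs)
  mcr <- minimal_consistent_region(m, list(chrom = "chr1", start = 0, end = 20e6),
                                   "gain")
  expect_equal(mcr$start, 6e6)
  expect_equal(mcr$end, 10e6)
  expect_equal(mcr$carriers, 3)

  # single carrier: MCR equals its own aberrant interval
  m1 <- aberration_matrix(make_cohort_profiles(list(mk(3, 8), mk(0, 0)), g))
  mcr1 <- minimal_consistent_region(m1, list(chrom = "chr1", start = 0, end = 20e6),
                                    "gain")
  expect_equal(c(mcr1$start, mcr1$end), c(3e6, 8e6))

  # nested intervals: the innermost wins
  m2 <- aberration_matrix(make_cohort_profiles(list(mk(2, 18), mk(6, 10)), g))
  mcr2 <- minimal_consistent_region(m2, list(chrom = "chr1", start = 0, end = 20e6),
                                    "gain")
  expect_equal(c(mcr2$start, mcr2$end), c(6e6, 10e6))

  # no carriers
  m3 <- aberration_matrix(make_cohort_profiles(list(mk(0, 0), mk(0, 0)), g))
  expect_null(minimal_consistent_region(
    m3, list(chrom = "chr1", start = 0, end = 20e6), "gain"))
})

test_that("exact Mann-Whitney p values match enumeration", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  # identical samples (fully tied) -> p = 1 under the tie-corrected method
  expect_equal(mann_whitney(c(1, 3, 5), c(1, 3, 5))$p, 1, tolerance = 0.01)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact enumeration oracle agrees for small samples", {
  # brute-force: all label assignments of the combined sample
  exact_p <- function(x, y) {
    all_v <- c(x, y)
    n <- length(all_v)
    u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    combs <- combn(n, length(x))
    us <- apply(combs, 2, function(idx) {
      xs <- all_v[idx]; ys <- all_v[-idx]
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    })
    mu <- length(x) * length(y) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(61)
  for (i in 1:10) {
    x <- round(rnorm(4), 4); y <- round(rnorm(5) + 0.5, 4)
    expect_equal(mann_whitney(x, y)$p, exact_p(x, y), tolerance = 1e-9)
  }
})

test_that("normal approximation tracks the exact Mann-Whitney p", {
  set.seed(71)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 1)
    approx_p <- mann_whitney(x, y)$p  # n = 20 -> approximation
    exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("log-rank statistic is zero for identical groups", {
  times <- c(2, 4, 6, 8, 10, 12)
  events <- rep(1, 6)
  res <- km_logrank(rep(times, 2), rep(events, 2),
                    rep(c("a", "b"), each = 6))
  expect_equal(res$chisq, 0, tolerance = 1e-9)
  expect_equal(res$p, 1, tolerance = 1e-9)
})

test_that("KM estimator and log-rank match hand computation on a 6-subject toy", {
  # group A: events at 1, 3, 5; group B: events at 2, 4, censored 6
  times <- c(1, 3, 5, 2, 4, 6)
  events <- c(1, 1, 1, 1, 1, 0)
  groups <- c("A", "A", "A", "B", "B", "B")
  res <- km_logrank(times, events, groups)
  # hand-computed observed and expected for group A:
  # t=1: at risk A3 B3, d=1, eA = 1*3/6
  # t=2: at risk A2 B3, d=1, eA = 2/5
  # t=3: at risk A2 B2, d=1, eA = 2/4
  # t=4: at risk A1 B2, d=1, eA = 1/3
  # t=5: at risk A1 B1, d=1, eA = 1/2
  eA <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2
  oA <- 3
  # variance terms: d*(n-d)*n1*n2/(n^2*(n-1)) with d=1 -> n1*n2/n^2
  vA <- (3 * 3) / 36 + (2 * 3) / 25 + (2 * 2) / 16 + (1 * 2) / 9 + (1 * 1) / 4
  expect_equal(res$chisq, (oA - eA)^2 / vA, tolerance = 1e-9)

  # KM: survival drops to 0 beyond the last event when all events observed
  kmA <- summary(res$km)
  sA <- kmA$surv[kmA$strata == "g=A"]
  expect_equal(sA, c(2 / 3, 1 / 3, 0))
})

test_that("trend log-rank is reported for ordered tertiles", {
  set.seed(81)
  n <- 60
  g <- rep(c("low", "medium", "high"), each = n / 3)
  rate <- c(low = 0.03, medium = 0.08, high = 0.12)[g]
  t <- rexp(n, rate)
  ev <- as.integer(t < 30); t <- pmin(t, 30)
  res <- km_logrank(t, ev, g, ordered_levels = c("low", "medium", "high"))
  expect_equal(res$df, 2)
  expect_false(is.na(res$trend_chisq))
  expect_lt(res$trend_p, 0.05)
  expect_error(km_logrank(t, rep(0, n), g), "undefined")
})
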