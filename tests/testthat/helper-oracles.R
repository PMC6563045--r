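# Brute-force oracles -------------------------------------------------------

# enumerate all K^n paths once; score with the same tie-break rule
# (ties toward the state closest to CN 2)
enumerate_paths <- function(n, K) {
  as.matrix(expand.grid(rep(list(seq_len(K)), n)))[, n:1, drop = FALSE]
}

brute_viterbi <- function(r, mu, sd, trans, states, paths) {
  n <- length(r)
  logemis <- vapply(mu, function(m) dnorm(r, m, sd, log = TRUE), numeric(n))
  logtrans <- log(trans)
  scores <- rep(-log(length(states)), nrow(paths))
  for (t in seq_len(n)) scores <- scores + logemis[cbind(t, paths[, t])]
  for (t in seq_len(n - 1))
    scores <- scores + logtrans[cbind(paths[, t], paths[, t + 1])]
  best <- max(scores)
  cand <- which(scores >= best - 1e-9)
  ndist <- rowSums(matrix(abs(states[paths[cand, , drop = FALSE]] - 2),
                          nrow = length(cand)))
  list(path = paths[cand[which.min(ndist)], ], score = best, scores = scores)
}

brute_posteriors <- function(scores, paths, n, K) {
  w <- exp(scores - max(scores))
  gamma <- matrix(0, n, K)
  for (t in seq_len(n))
    for (k in seq_len(K))
      gamma[t, k] <- sum(w[paths[, t] == k])
  gamma / rowSums(gamma)
}

ratio_obj <- function(r, chrom = "chr1") {
  structure(list(sample_id = "t", log2_ratio = r,
                 valid = rep(TRUE, length(r)), reference_median = 1),
            class = "normalized_ratios")
}

one_chrom_grid <- function(n, width = 5e5) {
  build_bin_grid(c(chr1 = n * width), width)
}

make_cohort_profiles <- function(cn_list, g, phi = 2) {
  lapply(seq_along(cn_list), function(i)
    profile_from_cn(cn_list[[i]], g, phi = phi,
                    sample_id = paste0("S", i)))
}

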