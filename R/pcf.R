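#' Model-free multiscale segmentation of log2 ratios
#'
#' Recursive circular-binary-segmentation-style search per chromosome: at
#' each step the interval whose mean differs most from the rest of the
#' current segment (z statistic, noise sd estimated robustly from first
#' differences) is split out, as long as the statistic exceeds `thresh`.
#' Unlike prefix-based binary splitting this finds short interior
#' segments (e.g. focal homozygous deletions) inside long flat stretches.
#' Being independent of any copy number model, the resulting segment
#' means serve as neutral evidence when ranking candidate (tumour
#' fraction, ploidy) solutions. Quadratic in bins per chromosome; meant
#' for the 500 kb analysis grid.
#'
#' @param ratios A `normalized_ratios` object.
#' @param grid The `bin_grid`.
#' @param thresh z threshold for accepting a split (default 4; interval
#'   search over all (i, j) pairs multiplies the number of comparisons,
#'   so the threshold is stricter than for a single test).
#' @param min_bins Minimum bins per split-out interval (default 2).
#' @return data.frame: chrom, start, end, n_bins, mean_log2, length.
#' @export
pcf_segments <- function(ratios, grid, thresh = 4, min_bins = 2) {
  out <- list()
  for (ch in unique(grid$chrom)) {
    i <- which(grid$chrom == ch & ratios$valid)
    if (length(i) < 1) next
    x <- ratios$log2_ratio[i]
    bp <- cbs_breaks(x, thresh, min_bins)
    bounds <- c(0, bp, length(i))
    for (s in seq_len(length(bounds) - 1)) {
      idx <- i[(bounds[s] + 1):bounds[s + 1]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = grid$start[idx[1]], end = grid$end[idx[length(idx)]],
        n_bins = length(idx), mean_log2 = mean(ratios$log2_ratio[idx]),
        length = sum(grid$end[idx] - grid$start[idx]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# breakpoints (index of last element of each left part) by recursive
# most-deviant-interval splitting
cbs_breaks <- function(x, thresh, min_n) {
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma == 0) return(integer())
  breaks <- integer(0)
  rec <- function(a, b) {
    n <- b - a + 1
    if (n < min_n + 1) return()
    xs <- x[a:b]
    cs <- c(0, cumsum(xs))
    tot <- cs[n + 1]
    # z statistic for every interval (i, j], vectorised over j per i
    best <- c(z = 0, i = 0, j = 0)
    for (i in 0:(n - min_n)) {
      j <- (i + min_n):n
      m <- j - i
      rest <- n - m
      keep <- rest > 0 | m == n
      j <- j[rest > 0]
      if (length(j) == 0) next
      m <- j - i
      rest <- n - m
      mean_in <- (cs[j + 1] - cs[i + 1]) / m
      mean_out <- (tot - (cs[j + 1] - cs[i + 1])) / rest
      z <- abs(mean_in - mean_out) / (sigma * sqrt(1 / m + 1 / rest))
      k <- which.max(z)
      if (z[k] > best["z"]) best <- c(z = z[k], i = i, j = j[k])
    }
    if (best["z"] > thresh) {
      i <- best[["i"]]; j <- best[["j"]]
      if (i > 0) breaks <<- c(breaks, a + i - 1)
      if (j < n) breaks <<- c(breaks, a + j - 1)
      if (i > 0) rec(a, a + i - 1)
      rec(a + i, a + j - 1)
      if (j < n) rec(a + j, b)
    }
  }
  rec(1, length(x))
  sort(unique(breaks))
}
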