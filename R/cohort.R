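#' Ploidy-relative gain/loss matrix on a common segment grid
#'
#' Re-expresses the profiles on a common segment grid
#' ([uniform_resegment()]) and calls each segment, per sample, as a gain
#' (CN at least one copy above the sample's rounded ploidy), a loss (at
#' least one below) or neutral. Zero-ctDNA samples are excluded with a
#' warning.
#'
#' @param profiles List of `segment_profile` objects on one bin grid.
#' @return `list(segments=, calls=, sample_ids=)`; `calls` is a character
#'   matrix (samples x segments) in \{"loss","neutral","gain"\} (NA where
#'   uncovered).
#' @export
aberration_matrix <- function(profiles) {
  if (length(profiles) == 0)
    stop("invalid input: empty profile set", call. = FALSE)
  zero <- vapply(profiles, `[[`, logical(1), "zero_ctdna")
  if (any(zero)) {
    warning(sum(zero), " zero-ctDNA sample(s) excluded from aberration matrix")
    profiles <- profiles[!zero]
  }
  if (length(profiles) == 0)
    stop("invalid input: no detectable samples", call. = FALSE)
  rs <- uniform_resegment(profiles)
  ref <- round(rs$phi)
  calls <- matrix(NA_character_, nrow(rs$cn), ncol(rs$cn))
  for (i in seq_len(nrow(rs$cn))) {
    d <- rs$cn[i, ] - ref[i]
    calls[i, ] <- ifelse(is.na(d), NA_character_,
                         ifelse(d >= 1, "gain", ifelse(d <= -1, "loss", "neutral")))
  }
  list(segments = rs$segments, calls = calls, sample_ids = rs$sample_ids)
}

#' Per-segment gain/loss frequency for a sample group
#'
#' @param matrix An aberration matrix from [aberration_matrix()].
#' @param members Logical or index vector selecting the group's samples.
#' @return `list(segments=, gain=, loss=, group_size=)` with per-segment
#'   carrier counts.
#' @export
group_frequency <- function(matrix, members) {
  calls <- matrix$calls[members, , drop = FALSE]
  if (nrow(calls) == 0)
    stop("invalid input: empty group", call. = FALSE)
  list(segments = matrix$segments,
       gain = colSums(calls == "gain", na.rm = TRUE),
       loss = colSums(calls == "loss", na.rm = TRUE),
       group_size = nrow(calls))
}

#' Aberrations unique to one group
#'
#' Maximal runs of consecutive segments where group A carries an
#' aberration of a given direction (frequency > 0) and group B carries
#' none, filtered by a minimum genomic length. Runs whose maximum carrier
#' fraction exceeds 1/3 of group A are flagged `frequent`.
#'
#' @param track_a,track_b Frequency tracks from [group_frequency()] on the
#'   same segment grid.
#' @param min_length Minimum region length in bp (default 1 Mb, to
#'   suppress single-bin artefacts).
#' @return data.frame: chrom, start, end, direction, carriers (max count
#'   within the run), frequent flag.
#' @export
unique_regions <- function(track_a, track_b, min_length = 1e6) {
  if (!identical(track_a$segments, track_b$segments))
    stop("coordinate mismatch: tracks are on different segment grids",
         call. = FALSE)
  seg <- track_a$segments
  out <- list()
  for (dir in c("gain", "loss")) {
    a <- track_a[[dir]]
    b <- track_b[[dir]]
    uniq <- a > 0 & b == 0
    run_id <- cumsum(c(1, diff(uniq) != 0 | seg$chrom[-1] != seg$chrom[-nrow(seg)]))
    for (ids in split(seq_len(nrow(seg)), run_id)) {
      if (!uniq[ids[1]]) next
      len <- seg$end[ids[length(ids)]] - seg$start[ids[1]]
      if (len < min_length) next
      carriers <- max(a[ids])
      out[[length(out) + 1]] <- data.frame(
        chrom = seg$chrom[ids[1]], start = seg$start[ids[1]],
        end = seg$end[ids[length(ids)]], direction = dir,
        carriers = carriers,
        frequent = carriers / track_a$group_size > 1 / 3,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), carriers = integer(),
                      frequent = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minimal consistent region of an aberration
#'
#' Within a region of interest, the maximal contiguous run of segments
#' where the carrier count (samples with the given aberration direction)
#' equals the maximum carrier count observed in the region — the genomic
#' core shared by all contributing cases. The leftmost such run wins ties.
#'
#' @param matrix An aberration matrix from [aberration_matrix()].
#' @param region `list(chrom=, start=, end=)` bounding the search.
#' @param direction `"gain"` or `"loss"`.
#' @return `list(chrom=, start=, end=, carriers=)`, or NULL when no sample
#'   carries the aberration in the region.
#' @export
minimal_consistent_region <- function(matrix, region, direction) {
  seg <- matrix$segments
  inside <- which(seg$chrom == region$chrom & seg$start < region$end &
                    seg$end > region$start)
  if (length(inside) == 0) return(NULL)
  count <- colSums(matrix$calls[, inside, drop = FALSE] == direction,
                   na.rm = TRUE)
  if (max(count) == 0) return(NULL)
  peak <- count == max(count)
  run_id <- cumsum(c(1, diff(peak) != 0))
  for (ids in split(seq_along(inside), run_id)) {
    if (peak[ids[1]]) {
      sel <- inside[ids]
      return(list(chrom = region$chrom, start = seg$start[sel[1]],
                  end = seg$end[sel[length(sel)]], carriers = max(count)))
    }
  }
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p by enumeration when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie and continuity correction. Thin wrapper around [stats::wilcox.test()]
#' pinned to that contract.
#'
#' @param x,y Numeric samples.
#' @return `list(U=, p=)` where U is the statistic for `x`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("invalid input: both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Kaplan-Meier curves and log-rank tests across groups
#'
#' Product-limit estimates per group, the k-group log-rank chi-square
#' (k - 1 df), and — for ordered groups such as tertiles — the score-
#' weighted trend version computed from the log-rank
#' observed/expected/variance components with scores 1..k.
#'
#' @param times Survival times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels; `ordered_levels` fixes the trend ordering.
#' @param ordered_levels Optional character vector of group levels in
#'   increasing order (e.g. `c("low","medium","high")`).
#' @return `list(km=, chisq=, df=, p=, trend_chisq=, trend_p=)`; `km` is a
#'   `survival::survfit` object.
#' @export
km_logrank <- function(times, events, groups, ordered_levels = NULL) {
  g <- if (is.null(ordered_levels)) factor(groups) else
    factor(groups, levels = ordered_levels)
  if (nlevels(droplevels(g)) < 2)
    stop("invalid input: need >= 2 non-empty groups", call. = FALSE)
  if (sum(events) == 0)
    stop("statistic undefined: no events in any group", call. = FALSE)
  km <- survival::survfit(survival::Surv(times, events) ~ g)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  k <- length(sd$n)
  p <- stats::pchisq(sd$chisq, df = k - 1, lower.tail = FALSE)
  trend_chisq <- NA_real_; trend_p <- NA_real_
  if (k > 2 || !is.null(ordered_levels)) {
    s <- seq_len(k)
    oe <- sd$obs - sd$exp
    V <- sd$var
    denom <- as.numeric(t(s) %*% V %*% s)
    if (denom > 0) {
      trend_chisq <- as.numeric(sum(s * oe))^2 / denom
      trend_p <- stats::pchisq(trend_chisq, df = 1, lower.tail = FALSE)
    }
  }
  list(km = km, chisq = unname(sd$chisq), df = k - 1, p = p,
       trend_chisq = trend_chisq, trend_p = trend_p)
}
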