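#' Fit a GC bias curve to binned counts
#'
#' Local polynomial (loess) smoothing of count-per-unit-length against GC
#' fraction over usable bins (positive count, mappability above the filter),
#' normalised to mean 1 over those bins. The returned object predicts a
#' relative rate for any GC value, clamping outside the observed range.
#'
#' @param counts A `bin_counts` object.
#' @param grid Its `bin_grid`.
#' @param span Loess span (smoothing bandwidth). The default was chosen so
#'   that a bias-free simulation recovers a flat curve within a few percent.
#' @param mappability_min Bins below this mappability are ignored when
#'   fitting.
#' @return A `bias_curve`: function-like list with `predict(gc)`.
#' @export
fit_gc_bias <- function(counts, grid, span = 0.3, mappability_min = 0.9) {
  use <- counts$counts > 0 & grid$mappability >= mappability_min &
    bin_lengths(grid) > 0
  if (sum(use) < 50)
    stop("insufficient data: need >= 50 usable bins to fit GC bias", call. = FALSE)
  gc <- grid$gc[use]
  rate <- counts$counts[use] / (bin_lengths(grid)[use] * grid$mappability[use])
  # the curve has one predictor and little fine structure, so on dense
  # 50 kb genomes it is fitted on an even GC-ordered subsample to keep the
  # loess cost bounded
  if (length(gc) > 5000) {
    ord <- order(gc)
    keep_i <- ord[round(seq(1, length(ord), length.out = 5000))]
    gc <- gc[keep_i]
    rate <- rate[keep_i]
  }
  if (diff(range(gc)) < 1e-6) {
    warning("degenerate GC annotation (all equal); returning constant curve 1")
    curve <- list(predict = function(x) rep(1, length(x)),
                  gc_range = range(gc))
    class(curve) <- "bias_curve"
    return(curve)
  }
  # two-pass trimmed fit: a first curve is fitted on all usable bins, then
  # refitted on bins whose residual lies close to the modal residual. This
  # keeps copy-number-aberrant bins (whole arms, which share coherent GC)
  # from dragging the curve and compressing the signal.
  fit <- stats::loess(rate ~ gc, span = span, degree = 2)
  resid <- log2(rate / pmax(stats::predict(fit), 1e-9))
  band <- stats::mad(resid)
  keep <- is.finite(resid) & abs(resid - stats::median(resid)) < band
  if (sum(keep) >= 50 && diff(range(gc[keep])) > 1e-6) {
    df <- data.frame(gc = gc[keep], rate = rate[keep])
    fit <- stats::loess(rate ~ gc, data = df, span = span, degree = 2)
  }
  lo <- stats::quantile(gc, 0.005)
  hi <- stats::quantile(gc, 0.995)
  raw <- function(x) {
    x <- pmin(hi, pmax(lo, x))
    stats::predict(fit, data.frame(gc = x))
  }
  # normalise to mean 1 over the bins used for fitting, floor at a small
  # positive rate so corrected counts stay finite
  scale <- mean(raw(gc))
  curve <- list(predict = function(x) pmax(raw(x) / scale, 1e-3),
                gc_range = c(lo, hi))
  class(curve) <- "bias_curve"
  curve
}

#' Correct binned counts for GC and mappability bias
#'
#' Divides each bin's count by bin length, the fitted GC bias curve and the
#' bin's mappability, masks unusable bins (low mappability, zero length or
#' zero count), and median-centres: the log2 ratio of a bin is
#' `log2(corrected / median(corrected over valid bins))`.
#'
#' @param counts A `bin_counts` object.
#' @param curve A `bias_curve` from [fit_gc_bias()] (or NULL for no GC
#'   correction).
#' @param grid The `bin_grid`.
#' @param mappability_min Bins below this mappability are masked
#'   (default 0.9, standard HMMcopy practice).
#' @return A `normalized_ratios` object: sample_id, per-bin `log2_ratio`
#'   (NA where masked), `valid` mask, and the `reference_median` corrected
#'   count scale.
#' @export
correct_counts <- function(counts, curve, grid, mappability_min = 0.9) {
  if (mappability_min < 0 || mappability_min > 1)
    stop("mappability_min must be in [0, 1]", call. = FALSE)
  len <- bin_lengths(grid)
  gc_rate <- if (is.null(curve)) rep(1, nrow(grid)) else curve$predict(grid$gc)
  valid <- grid$mappability >= mappability_min & len > 0 & counts$counts > 0
  corrected <- rep(NA_real_, nrow(grid))
  corrected[valid] <- counts$counts[valid] /
    (len[valid] * gc_rate[valid] * grid$mappability[valid])
  if (sum(valid) < 50)
    stop("insufficient data: fewer than 50 valid bins after masking", call. = FALSE)
  # centring in log space makes the median of valid log2 ratios exactly 0
  # (for an even bin count the reference is the geometric mean of the two
  # middle corrected values)
  med_log <- stats::median(log2(corrected[valid]))
  ref <- 2^med_log
  log2_ratio <- rep(NA_real_, nrow(grid))
  log2_ratio[valid] <- log2(corrected[valid]) - med_log
  structure(list(sample_id = counts$sample_id, log2_ratio = log2_ratio,
                 valid = valid, reference_median = ref),
            bin_width = grid_bin_width(grid),
            class = "normalized_ratios")
}

#' One-step normalisation: fit GC bias, then correct
#'
#' @inheritParams fit_gc_bias
#' @inheritParams correct_counts
#' @return A `normalized_ratios` object.
#' @export
normalize_counts <- function(counts, grid, span = 0.3, mappability_min = 0.9) {
  curve <- fit_gc_bias(counts, grid, span = span,
                       mappability_min = mappability_min)
  correct_counts(counts, curve, grid, mappability_min = mappability_min)
}
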