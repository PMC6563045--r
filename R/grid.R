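#' hg19 autosome lengths
#'
#' Chromosome lengths (bp) for the 22 human autosomes (hg19/GRCh37).
#' Sex chromosomes are excluded throughout: the instability metrics are
#' defined over the 22 autosomes only.
#'
#' @return Named integer-valued numeric vector, `chr1`..`chr22`.
#' @export
hg19_autosomes <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
}

#' Approximate hg19 centromere positions
#'
#' Used only to delimit chromosome arms for the arm-level event simulator;
#' positions are approximate (band-level resolution).
#'
#' @return Named numeric vector of centromere midpoints (bp) per autosome.
#' @export
hg19_centromeres <- function() {
  c(chr1 = 125.0e6, chr2 = 93.3e6, chr3 = 91.0e6, chr4 = 50.4e6,
    chr5 = 48.4e6, chr6 = 61.0e6, chr7 = 59.9e6, chr8 = 45.6e6,
    chr9 = 49.0e6, chr10 = 40.2e6, chr11 = 53.7e6, chr12 = 35.8e6,
    chr13 = 17.9e6, chr14 = 17.6e6, chr15 = 19.0e6, chr16 = 36.6e6,
    chr17 = 24.0e6, chr18 = 17.2e6, chr19 = 26.5e6, chr20 = 27.5e6,
    chr21 = 13.2e6, chr22 = 14.7e6)
}

#' Partition a genome into fixed-width bins
#'
#' Tiles each chromosome with nonoverlapping bins of `bin_width` bp in
#' 0-based half-open coordinates; the last bin of a chromosome may be
#' shorter. This grid is the shared coordinate frame for read counts,
#' normalised ratios and copy number profiles.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp,
#'   in the desired genome order (e.g. [hg19_autosomes()]).
#' @param bin_width Bin width in bp (500000 for the genome-wide analysis,
#'   50000 for focal-amplification calling).
#' @param gc Optional per-bin GC fraction in \[0, 1\]; defaults to a flat 0.45.
#' @param mappability Optional per-bin mappability in \[0, 1\]; defaults to 1.
#'
#' @return A `bin_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mappability`, plus attributes `bin_width` and `chrom_lengths`.
#' @export
build_bin_grid <- function(chrom_lengths, bin_width, gc = NULL, mappability = NULL) {
  if (length(chrom_lengths) < 1L)
    stop("at least one chromosome is required", call. = FALSE)
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number", call. = FALSE)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive", call. = FALSE)

  pieces <- lapply(seq_along(chrom_lengths), function(i) {
    len <- chrom_lengths[[i]]
    starts <- seq(0, len - 1, by = bin_width)
    data.frame(chrom = names(chrom_lengths)[i],
               start = starts,
               end = pmin(starts + bin_width, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  n <- nrow(grid)
  grid$gc <- if (is.null(gc)) rep(0.45, n) else gc
  grid$mappability <- if (is.null(mappability)) rep(1, n) else mappability
  if (length(grid$gc) != n || length(grid$mappability) != n)
    stop("gc and mappability must have one value per bin", call. = FALSE)
  if (any(!is.finite(grid$gc)) || any(grid$gc < 0 | grid$gc > 1))
    stop("gc must be finite and in [0, 1]", call. = FALSE)
  if (any(!is.finite(grid$mappability)) || any(grid$mappability < 0 | grid$mappability > 1))
    stop("mappability must be finite and in [0, 1]", call. = FALSE)

  structure(grid,
            bin_width = bin_width,
            chrom_lengths = chrom_lengths,
            class = c("bin_grid", "data.frame"))
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %s bp over %d chromosomes\n",
              nrow(x), format(attr(x, "bin_width"), big.mark = ","),
              length(attr(x, "chrom_lengths"))))
  invisible(x)
}

bin_lengths <- function(grid) grid$end - grid$start

#' Bin width of a grid
#' @param grid A `bin_grid`.
#' @return The nominal bin width in bp.
#' @export
grid_bin_width <- function(grid) attr(grid, "bin_width")

stopifnot_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !isTRUE(all.equal(a$start, b$start)) ||
      !isTRUE(all.equal(a$end, b$end)))
    stop("coordinate mismatch: objects are not on the same bin grid", call. = FALSE)
  invisible(TRUE)
}

#' Attach synthetic GC and mappability tracks to a grid
#'
#' Generates a smooth per-bin GC fraction (autocorrelated around a genome
#' mean of ~0.41, range roughly 0.3--0.6, as in binned hg19 data) and a
#' mappability track equal to 1 except for a configurable fraction of
#' low-mappability bins. These emulate the bin annotations that HMMcopy-style
#' pipelines read from wig tracks.
#'
#' @param grid A `bin_grid`.
#' @param seed Integer seed; the tracks are deterministic given the seed.
#' @param low_map_fraction Fraction of bins assigned mappability below 0.9
#'   (drawn uniformly on \[0.3, 0.9\)); these exercise the mappability filter.
#' @return The grid with `gc` and `mappability` columns replaced.
#' @export
annotate_grid_synthetic <- function(grid, seed = 1L, low_map_fraction = 0.05) {
  n <- nrow(grid)
  rng <- local_rng(seed, "grid-annotation")
  # AR(1) walk per chromosome gives spatially coherent GC
  gc <- numeric(n)
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    m <- length(idx)
    e <- stats::rnorm(m, 0, 0.02)
    z <- numeric(m)
    z[1] <- stats::rnorm(1, 0, 0.05)
    if (m > 1) for (i in 2:m) z[i] <- 0.95 * z[i - 1] + e[i]
    gc[idx] <- 0.41 + z
  }
  gc <- pmin(0.65, pmax(0.30, gc))
  map <- rep(1, n)
  n_low <- round(low_map_fraction * n)
  if (n_low > 0) {
    low <- sample.int(n, n_low)
    map[low] <- stats::runif(n_low, 0.3, 0.9)
  }
  restore_rng(rng)
  grid$gc <- gc
  grid$mappability <- map
  grid
}

# Scoped RNG: derive a substream from (seed, label) without clobbering the
# caller's RNG state. Returns the previous state for restore_rng().
local_rng <- function(seed, label) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  sub <- (as.numeric(seed) * 69069 + sum(utf8ToInt(label))) %% 2147483647
  set.seed(as.integer(sub))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
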