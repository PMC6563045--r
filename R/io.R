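#' Construct a per-bin read count object
#'
#' @param sample_id Sample identifier.
#' @param counts Non-negative integer vector, one value per grid bin.
#' @param grid The `bin_grid` the counts are aligned to.
#' @return A `bin_counts` object (sample_id, counts, total_reads).
#' @export
bin_counts <- function(sample_id, counts, grid) {
  if (length(counts) != nrow(grid))
    stop("counts length (", length(counts), ") does not match grid (",
         nrow(grid), " bins)", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  structure(list(sample_id = sample_id,
                 counts = as.numeric(counts),
                 total_reads = sum(counts)),
            bin_width = grid_bin_width(grid),
            class = "bin_counts")
}

#' Write per-bin counts as a 4-column bedGraph-like file
#'
#' Tab-separated `chrom  start  end  count`, 0-based half-open, in grid order.
#'
#' @param counts A `bin_counts` object.
#' @param grid Its `bin_grid`.
#' @param path Output path.
#' @export
write_bin_counts <- function(counts, grid, path) {
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   count = counts$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-bin counts and align them to a grid
#'
#' Rows may appear in any order; they are matched to grid bins by exact
#' (chrom, start, end) coordinates. A row whose coordinates do not tile the
#' declared grid is an error.
#'
#' @param path 4-column tab-separated file (chrom, start, end, count).
#' @param grid The `bin_grid` the file must match.
#' @param sample_id Sample identifier to attach (default: file base name).
#' @return A `bin_counts` object in grid order.
#' @export
read_bin_counts <- function(path, grid, sample_id = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "count"),
                          stringsAsFactors = FALSE)
  if (nrow(df) != nrow(grid))
    stop("coordinate mismatch: file has ", nrow(df), " bins, grid has ",
         nrow(grid), call. = FALSE)
  key_grid <- paste(grid$chrom, grid$start, grid$end)
  key_file <- paste(df$chrom, df$start, df$end)
  pos <- match(key_grid, key_file)
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("coordinate mismatch: grid bin ", key_grid[bad],
         " not found in file", call. = FALSE)
  }
  bin_counts(sample_id = if (is.null(sample_id))
    sub("\\.[^.]*$", "", basename(path)) else sample_id,
    counts = df$count[pos], grid = grid)
}

seg_columns <- c("Sample", "Chromosome", "Start", "End",
                 "Num_Probes", "Segment_Mean", "Copy_Number")

#' Write segment profiles as an IGV SEG file
#'
#' Columns are `Sample, Chromosome, Start, End, Num_Probes, Segment_Mean`
#' plus an extension column `Copy_Number`. Coordinates are converted from
#' the internal 0-based half-open convention to IGV's 1-based inclusive on
#' write. Per-sample tumour fraction, ploidy and the zero-ctDNA flag are
#' preserved in `#meta` header comments so that profiles round-trip.
#'
#' @param profiles List of `segment_profile` objects.
#' @param path Output path.
#' @export
write_seg <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles)
    writeLines(sprintf("#meta\t%s\t%.10g\t%.10g\t%d\t%.6f",
                       p$sample_id, p$f, p$phi,
                       as.integer(p$zero_ctdna), p$loglik), con)
  writeLines(paste(seg_columns, collapse = "\t"), con)
  for (p in profiles) {
    s <- p$segments
    if (nrow(s) == 0) next
    writeLines(sprintf("%s\t%s\t%d\t%d\t%d\t%.6f\t%d",
                       p$sample_id, s$chrom, s$start + 1L, s$end,
                       s$n_bins, s$mean_log2, s$cn), con)
  }
  invisible(path)
}

#' Read an IGV SEG file written by [write_seg()]
#'
#' @param path SEG file path.
#' @return List of `segment_profile` objects (segments, f, phi, zero_ctdna,
#'   loglik; the per-bin CN vector is not stored in SEG and is left NULL).
#' @export
read_seg <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#meta\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0 || !identical(strsplit(body[1], "\t")[[1]], seg_columns))
    stop("parse error at line 1: missing or malformed SEG header", call. = FALSE)
  meta <- list()
  for (m in meta_lines) {
    f <- strsplit(m, "\t")[[1]]
    meta[[f[2]]] <- list(f = as.numeric(f[3]), phi = as.numeric(f[4]),
                         zero_ctdna = as.integer(f[5]) == 1L,
                         loglik = as.numeric(f[6]))
  }
  rows <- lapply(seq_along(body[-1]), function(i) {
    f <- strsplit(body[i + 1], "\t")[[1]]
    if (length(f) != 7 || anyNA(suppressWarnings(as.numeric(f[3:7]))))
      stop("parse error at line ", which(lines == body[i + 1]),
           ": malformed SEG row", call. = FALSE)
    data.frame(Sample = f[1], chrom = f[2],
               start = as.numeric(f[3]) - 1, end = as.numeric(f[4]),
               n_bins = as.integer(f[5]), mean_log2 = as.numeric(f[6]),
               cn = as.integer(f[7]), stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Sample = character(), chrom = character(), start = numeric(),
               end = numeric(), n_bins = integer(), mean_log2 = numeric(),
               cn = integer(), stringsAsFactors = FALSE)
  ids <- if (length(meta)) names(meta) else unique(df$Sample)
  lapply(ids, function(id) {
    s <- df[df$Sample == id, c("chrom", "start", "end", "cn", "mean_log2", "n_bins")]
    rownames(s) <- NULL
    m <- meta[[id]]
    new_segment_profile(sample_id = id, f = if (is.null(m)) NA_real_ else m$f,
                        phi = if (is.null(m)) NA_real_ else m$phi,
                        segments = s, bin_cn = NULL,
                        loglik = if (is.null(m)) NA_real_ else m$loglik,
                        zero_ctdna = if (is.null(m)) FALSE else m$zero_ctdna)
  })
}

new_segment_profile <- function(sample_id, f, phi, segments, bin_cn,
                                loglik, zero_ctdna) {
  structure(list(sample_id = sample_id, f = f, phi = phi,
                 segments = segments, bin_cn = bin_cn,
                 loglik = loglik, zero_ctdna = zero_ctdna),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile %s: f=%.3f phi=%.2f %s, %d segments\n",
              x$sample_id, x$f, x$phi,
              if (x$zero_ctdna) "(zero ctDNA)" else "", nrow(x$segments)))
  invisible(x)
}

#' Write / read a sample metadata table
#'
#' Plain tab-separated round-trip of the clinical/assay covariate table
#' produced by [simulate_cohort()].
#'
#' @param meta data.frame of sample metadata.
#' @param path File path.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
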