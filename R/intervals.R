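#' Construct a genomic interval
#'
#' Intervals are 0-based, half-open (`[start, end)`), the BED convention,
#' everywhere inside the package; 1-based coordinates appear only in
#' human-readable output tables.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp).
#' @param end Exclusive end (bp); must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A `genome_interval` object (a named list).
#' @export
genome_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

#' Width of a genomic interval in bp
#' @param x A `genome_interval`.
#' @return Integer width.
#' @export
interval_width <- function(x) x$end - x$start

# Convert a data.frame with chrom/start/end columns (0-based half-open) to
# GRanges for overlap machinery. GRanges is 1-based closed, so start+1.
.df_to_granges <- function(df, chrom = "chrom", start = "start", end = "end",
                           strand = NULL) {
  str <- if (!is.null(strand) && strand %in% names(df)) df[[strand]] else "*"
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]]),
    strand = str
  )
}

# Point positions (e.g. enhancer centers) to GRanges.
.points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}
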