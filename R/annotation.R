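#' Read gene models from BED12 or refGene-style annotation
#'
#' Gene models carry their 5' and 3' boundaries as `tss` and `tts`, expressed
#' as 0-based boundary coordinates: a plus-strand gene occupies
#' `[tss, tts)` and a minus-strand gene `[tts, tss)`, so `tss < tts` on `+`
#' and `tss > tts` on `-`.
#'
#' @param path Annotation file. BED12 (12+ columns, no header) or a
#'   refGene-style TSV (bin, name, chrom, strand, txStart, txEnd, ...,
#'   name2).
#' @param format `"auto"` (default), `"bed12"` or `"refgene"`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tts`, `length`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed12", "refgene")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) stop("empty annotation file: ", path)
  if (format == "auto") {
    format <- if (all(dt[[4]] %in% c("+", "-"))) "refgene" else "bed12"
  }
  if (format == "bed12") {
    if (ncol(dt) < 6L)
      stop("annotation '", path, "': BED12 needs >= 6 columns ",
           "(chrom, chromStart, chromEnd, name, score, strand)")
    ann <- data.frame(gene_id = as.character(dt[[4]]),
                      chrom = as.character(dt[[1]]),
                      strand = as.character(dt[[6]]),
                      start = as.integer(dt[[2]]),
                      end = as.integer(dt[[3]]),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(dt) < 6L)
      stop("annotation '", path, "': refGene dialect needs >= 6 columns ",
           "(bin, name, chrom, strand, txStart, txEnd)")
    ann <- data.frame(gene_id = as.character(dt[[2]]),
                      chrom = as.character(dt[[3]]),
                      strand = as.character(dt[[4]]),
                      start = as.integer(dt[[5]]),
                      end = as.integer(dt[[6]]),
                      stringsAsFactors = FALSE)
    if (ncol(dt) >= 13L) ann$symbol <- as.character(dt[[13]])
  }
  if (!all(ann$strand %in% c("+", "-")))
    stop("annotation '", path, "': gene strand must be '+' or '-'")
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann$tts <- ifelse(ann$strand == "+", ann$end, ann$start)
  ann$length <- ann$end - ann$start
  ann
}

#' Read known-enhancer regions from BED
#'
#' @param path BED file with at least chrom, start, end; a 4th column is used
#'   as the enhancer id, otherwise `chrom:start-end` ids are generated.
#' @return `data.frame` with `chrom`, `start`, `end`, `id`.
#' @export
read_known_enhancers <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("known-enhancer BED '", path, "' needs >= 3 columns")
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  out$id <- if (ncol(dt) >= 4L) as.character(dt[[4]]) else
    sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Read an enhancer-TSS association table
#'
#' Four tab-separated columns: enhancer chrom, start, end, associated gene
#' id. A header row naming these columns is accepted.
#'
#' @param path TSV path.
#' @return `data.frame` with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_enhancer_tss_associations <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  need <- c("chrom", "start", "end", "gene_id")
  if (all(need %in% names(dt))) {
    dt <- dt[, need, with = FALSE]
  } else if (ncol(dt) >= 4L) {
    dt <- dt[, 1:4]
    data.table::setnames(dt, need)
  } else {
    stop("association table '", path, "' missing required columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  data.frame(chrom = as.character(dt$chrom), start = as.integer(dt$start),
             end = as.integer(dt$end), gene_id = as.character(dt$gene_id),
             stringsAsFactors = FALSE)
}

#' Read a chromatin-interaction table
#'
#' Tab-separated columns: chromA, startA, endA, chromB, startB, endB, tissue,
#' method (last two optional). A header row with these names is accepted.
#'
#' @param path TSV path.
#' @return `data.frame` with the eight columns above.
#' @export
read_interactions <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  if (!all(need %in% names(dt))) {
    if (ncol(dt) < 6L)
      stop("interaction table '", path, "' missing required columns: ",
           paste(setdiff(need, names(dt)), collapse = ", "))
    nm <- c(need, "tissue", "method")[seq_len(min(ncol(dt), 8L))]
    dt <- dt[, seq_along(nm), with = FALSE]
    data.table::setnames(dt, nm)
  }
  out <- data.frame(chromA = as.character(dt$chromA),
                    startA = as.integer(dt$startA),
                    endA = as.integer(dt$endA),
                    chromB = as.character(dt$chromB),
                    startB = as.integer(dt$startB),
                    endB = as.integer(dt$endB),
                    stringsAsFactors = FALSE)
  out$tissue <- if ("tissue" %in% names(dt)) as.character(dt$tissue) else NA_character_
  out$method <- if ("method" %in% names(dt)) as.character(dt$method) else NA_character_
  out
}

#' Read ChIP-seq peaks from BED or narrowPeak
#'
#' The peak anchor is the summit (narrowPeak column 10, as an offset from
#' `start`) when present and non-negative, otherwise the peak midpoint.
#'
#' @param path BED (>= 3 columns) or narrowPeak (10 columns) file.
#' @return `data.frame` with `chrom`, `start`, `end`, `anchor`, `score`.
#' @export
read_peaks <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("peak file '", path, "' needs >= 3 columns")
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  out$score <- if (ncol(dt) >= 5L) suppressWarnings(as.numeric(dt[[5]])) else NA_real_
  mid <- out$start + (out$end - out$start) %/% 2L
  if (ncol(dt) >= 10L) {
    summit <- suppressWarnings(as.integer(dt[[10]]))
    out$anchor <- ifelse(!is.na(summit) & summit >= 0L, out$start + summit, mid)
  } else {
    out$anchor <- mid
  }
  bad <- which(out$anchor < out$start | out$anchor >= out$end)
  if (length(bad)) out$anchor[bad] <- mid[bad]
  out
}
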