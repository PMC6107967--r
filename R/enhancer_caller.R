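#' Transcript-caller parameters
#'
#' Knobs for the sliding-window de novo transcript caller. Initiation of a
#' transcript requires a window density above `tss_fold` times the local
#' background; extension requires `body_fold` times the background. The
#' background at each window is the median window density over a flanking
#' span, floored by `bg_density` so signal-free regions still carry a
#' nonzero baseline.
#'
#' @param tss_fold Initiation fold over background (default 4).
#' @param body_fold Extension fold over background (default 3).
#' @param window Window size in bp (default 200).
#' @param step Window step in bp (default 50).
#' @param max_gap Same-strand runs closer than this are joined (default
#'   1000 bp).
#' @param min_length Minimum transcript length in bp (default 250).
#' @param bg_density Background pseudo-density floor in reads/bp
#'   (default 0.05).
#' @param bg_span Flanking span for the local background median in bp
#'   (default 100000).
#' @return Named list of validated parameters.
#' @export
transcript_caller_params <- function(tss_fold = 4, body_fold = 3,
                                     window = 200L, step = 50L,
                                     max_gap = 1000L, min_length = 250L,
                                     bg_density = 0.05, bg_span = 100000L) {
  stopifnot(tss_fold > 1, body_fold > 1, window > 0, step > 0,
            max_gap > 0, min_length > 0, bg_density > 0, bg_span >= window)
  list(tss_fold = tss_fold, body_fold = body_fold, window = as.integer(window),
       step = as.integer(step), max_gap = as.integer(max_gap),
       min_length = as.integer(min_length), bg_density = bg_density,
       bg_span = as.integer(bg_span))
}

#' Call de novo transcripts from pooled coverage
#'
#' Scans each (chromosome, strand) track with sliding windows. Windows whose
#' read density exceeds `body_fold` times the local background are candidate
#' transcript territory; candidate windows separated by less than `max_gap`
#' are joined into runs; a run is emitted as a transcript if it contains at
#' least one window exceeding `tss_fold` times background and its span is at
#' least `min_length`. Boundaries are accurate to about one window.
#'
#' @param cov A pooled [stranded_coverage] (see [pool_coverage]).
#' @param params From [transcript_caller_params].
#' @param strands Strands to scan (default both).
#' @return `data.frame` of transcripts: `chrom`, `start`, `end`, `strand`,
#'   `five_prime`, `read_count`, `length`, sorted by position; zero rows if
#'   no coverage.
#' @export
call_transcripts <- function(cov, params = transcript_caller_params(),
                             strands = c("+", "-")) {
  out <- list()
  for (key in names(cov$pos)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    chrom <- parts[1]; strand <- parts[2]
    if (!(strand %in% strands)) next
    tr <- .call_transcripts_track(cov, chrom, strand, params)
    if (!is.null(tr)) out[[key]] <- tr
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), five_prime = integer(),
                      read_count = numeric(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

.call_transcripts_track <- function(cov, chrom, strand, p) {
  pos <- cov$pos[[.cov_key(chrom, strand)]]
  if (length(pos) == 0L) return(NULL)
  # pad the scan beyond the data by the background span so that the running
  # median at the track edges sees the genuine (typically empty) flank
  lo <- max(0L, min(pos) - p$bg_span)
  hi <- max(pos) + p$bg_span
  starts <- seq.int(lo, hi, by = p$step)
  dens <- .window_counts(cov, chrom, strand, starts, p$window) / p$window
  # local background: running median over bg_span, floored by bg_density.
  # Edge windows inherit the background of the nearest interior window with
  # a full span, so signal at a track edge cannot inflate its own baseline.
  n <- length(dens)
  k <- max(3L, 2L * (p$bg_span %/% (2L * p$step)) + 1L)
  if (n > k) {
    bg <- stats::runmed(dens, k, endrule = "keep")
    h <- (k - 1L) %/% 2L
    bg[seq_len(h)] <- bg[h + 1L]
    bg[(n - h + 1L):n] <- bg[n - h]
  } else {
    bg <- rep(stats::median(dens), n)
  }
  bg <- pmax(bg, p$bg_density)
  body_ok <- dens > p$body_fold * bg
  tss_ok <- dens > p$tss_fold * bg
  if (!any(body_ok)) return(NULL)
  # group passing windows into runs, joining gaps < max_gap
  idx <- which(body_ok)
  ws <- starts[idx]; we <- starts[idx] + p$window
  gap_before <- c(Inf, ws[-1] - we[-length(ws)])
  run_id <- cumsum(gap_before >= p$max_gap)
  rows <- lapply(split(seq_along(idx), run_id), function(ii) {
    s <- ws[ii[1]]; e <- we[ii[length(ii)]]
    if (e - s < p$min_length) return(NULL)
    if (!any(tss_ok[idx[ii]])) return(NULL)
    data.frame(chrom = chrom, start = s, end = e, strand = strand,
               five_prime = if (strand == "+") s else e - 1L,
               read_count = .track_count(cov, chrom, strand, s, e),
               length = e - s, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Restrict transcripts to intergenic space
#'
#' Removes any transcript overlapping an annotated gene extended `dtss` bp
#' upstream of its TSS and `dtts` bp downstream of its TTS (strand-aware
#' extension, strand-blind overlap): promoter-proximal transcription and
#' post-TTS read-through are not candidate enhancers.
#'
#' @param transcripts `data.frame` from [call_transcripts].
#' @param genes Annotation `data.frame` from [read_gene_annotation].
#' @param dtss Upstream extension in bp (default 2000).
#' @param dtts Downstream extension in bp (default 20000).
#' @return The surviving transcripts.
#' @export
filter_intergenic <- function(transcripts, genes, dtss = 2000L, dtts = 20000L) {
  if (nrow(transcripts) == 0L || nrow(genes) == 0L) return(transcripts)
  ext_start <- ifelse(genes$strand == "+", genes$start - dtss,
                      genes$start - dtts)
  ext_end <- ifelse(genes$strand == "+", genes$end + dtts,
                    genes$end + dtss)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(ext_start, 0L) + 1L, ext_end))
  gr_tx <- .df_to_granges(transcripts)
  hits <- GenomicRanges::findOverlaps(gr_tx, gr_genes, ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) transcripts[-drop, , drop = FALSE] else transcripts
}

#' Pair divergent transcripts into enhancers
#'
#' A plus-strand and a minus-strand transcript form a bidirectional pair
#' when either (a) the distance between their 5' ends is at most `pair_gap`
#' bp (overlap included), giving an enhancer center at the midpoint of the
#' two 5' ends (odd spans round down), or (b) one transcript lies entirely
#' within the other, giving a center at the 5' end of the contained
#' transcript. Transcripts connected through shared pairs collapse into one
#' enhancer whose region is the strandless hull of its members and whose
#' centers are the sorted unique centers of its pairs.
#'
#' @param transcripts `data.frame` from [call_transcripts] (after
#'   [filter_intergenic]); both strands together.
#' @param pair_gap Maximum 5'-to-5' distance in bp, inclusive (default 400).
#' @return `data.frame` of pre-merge enhancers: `chrom`, `start`, `end`,
#'   `centers` (comma-joined, strictly increasing), `n_centers`,
#'   `tx_members` (comma-joined row keys `chrom:start-end/strand`). The
#'   `"paired_tx"` attribute lists member keys, letting callers exclude
#'   paired transcripts from long-eRNA extraction.
#' @export
pair_bidirectional <- function(transcripts, pair_gap = 400L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      centers = character(), n_centers = integer(),
                      tx_members = character(), stringsAsFactors = FALSE)
  if (nrow(transcripts) == 0L) {
    attr(empty, "paired_tx") <- character()
    return(empty)
  }
  tx <- transcripts[order(transcripts$chrom, transcripts$start,
                          transcripts$strand), , drop = FALSE]
  tx$key <- sprintf("%s:%d-%d/%s", tx$chrom, tx$start, tx$end, tx$strand)
  plus <- which(tx$strand == "+"); minus <- which(tx$strand == "-")
  pair_i <- integer(); pair_j <- integer(); pair_center <- integer()
  for (i in plus) {
    for (j in minus) {
      if (tx$chrom[i] != tx$chrom[j]) next
      p5 <- tx$five_prime[i]; m5 <- tx$five_prime[j]
      if (abs(p5 - m5) <= pair_gap) {
        pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
        pair_center <- c(pair_center, (p5 + m5) %/% 2L)
      }
      contained_minus <- tx$start[j] >= tx$start[i] && tx$end[j] <= tx$end[i]
      contained_plus <- tx$start[i] >= tx$start[j] && tx$end[i] <= tx$end[j]
      if (contained_minus || contained_plus) {
        short5 <- if (contained_minus) m5 else p5
        pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
        pair_center <- c(pair_center, short5)
      }
    }
  }
  if (!length(pair_i)) {
    attr(empty, "paired_tx") <- character()
    return(empty)
  }
  # connected components over transcripts sharing pairs
  comp <- seq_len(nrow(tx))
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (k in seq_along(pair_i)) {
    a <- find(pair_i[k]); b <- find(pair_j[k])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(nrow(tx)), find, integer(1))
  pair_root <- roots[pair_i]
  rows <- lapply(unique(pair_root), function(r) {
    ks <- which(pair_root == r)
    members <- sort(unique(c(pair_i[ks], pair_j[ks])))
    centers <- sort(unique(pair_center[ks]))
    data.frame(chrom = tx$chrom[members[1]],
               start = min(tx$start[members]),
               end = max(tx$end[members]),
               centers = paste(centers, collapse = ","),
               n_centers = length(centers),
               tx_members = paste(tx$key[members], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "paired_tx") <-
    unique(tx$key[sort(unique(c(pair_i, pair_j)))])
  out
}

.parse_centers <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

#' Merge nearby enhancers
#'
#' Enhancers whose regions are separated by less than `merge_gap` bp are
#' merged (transitively); the merged region is the hull and the centers are
#' the sorted union. Idempotent. Gaps of exactly `merge_gap` are not merged.
#'
#' @param enhancers `data.frame` from [pair_bidirectional].
#' @param merge_gap Strict merge threshold in bp (default 500).
#' @return Merged enhancers with enhancer ids `enh_1`, `enh_2`, ... assigned
#'   in genomic order.
#' @export
merge_enhancers <- function(enhancers, merge_gap = 500L) {
  if (nrow(enhancers) == 0L) {
    enhancers$id <- character()
    return(enhancers)
  }
  e <- enhancers[order(enhancers$chrom, enhancers$start), , drop = FALSE]
  gap <- c(Inf, e$start[-1] - cummax_by_chrom(e))
  same <- c(FALSE, e$chrom[-1] == e$chrom[-nrow(e)])
  grp <- cumsum(!(same & gap < merge_gap))
  rows <- lapply(split(seq_len(nrow(e)), grp), function(ii) {
    centers <- sort(unique(unlist(lapply(e$centers[ii], .parse_centers))))
    members <- unique(unlist(strsplit(e$tx_members[ii], ",", fixed = TRUE)))
    data.frame(chrom = e$chrom[ii[1]], start = min(e$start[ii]),
               end = max(e$end[ii]),
               centers = paste(centers, collapse = ","),
               n_centers = length(centers),
               tx_members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$id <- sprintf("enh_%d", seq_len(nrow(out)))
  attr(out, "paired_tx") <- attr(enhancers, "paired_tx")
  out
}

# running max of `end` within chromosome, lagged by one row, for gap
# computation against the closest preceding region hull
cummax_by_chrom <- function(e) {
  res <- numeric(nrow(e) - 1L)
  cm <- -Inf; prev_chrom <- ""
  for (i in seq_len(nrow(e))) {
    if (e$chrom[i] != prev_chrom) { cm <- -Inf; prev_chrom <- e$chrom[i] }
    if (i > 1L) res[i - 1L] <- cm
    cm <- max(cm, e$end[i])
  }
  res
}

#' Annotate enhancers against a known-enhancer catalog
#'
#' An enhancer is known when any of its centers falls inside a catalog
#' interval (`[start, end)` containment); region overlap without center
#' containment does not count.
#'
#' @param enhancers Merged enhancers (with an `id` column).
#' @param known `data.frame` from [read_known_enhancers]; `NULL` or empty
#'   marks everything novel (with a warning).
#' @return Enhancers with `is_known` and `known_ids` columns.
#' @export
annotate_enhancers <- function(enhancers, known = NULL) {
  enhancers$is_known <- FALSE
  enhancers$known_ids <- ""
  if (is.null(known) || nrow(known) == 0L) {
    if (nrow(enhancers)) warning("no known-enhancer regions supplied; ",
                                 "all enhancers marked novel")
    return(enhancers)
  }
  gr_known <- .df_to_granges(known)
  for (i in seq_len(nrow(enhancers))) {
    centers <- .parse_centers(enhancers$centers[i])
    gr_c <- .points_to_granges(rep(enhancers$chrom[i], length(centers)), centers)
    hits <- GenomicRanges::findOverlaps(gr_c, gr_known, ignore.strand = TRUE)
    ids <- unique(known$id[S4Vectors::subjectHits(hits)])
    if (length(ids)) {
      enhancers$is_known[i] <- TRUE
      enhancers$known_ids[i] <- paste(ids, collapse = ",")
    }
  }
  enhancers
}

#' Count reads over enhancers in each sample
#'
#' Both eRNAs of a bidirectional pair report on the same enhancer, so the
#' count is the strand-blind sum over the enhancer region.
#'
#' @param enhancers Merged enhancers with `id`.
#' @param covs Named list of [stranded_coverage], one per sample.
#' @return Integer-valued matrix, enhancers x samples. The
#'   `"total_mapped"` attribute carries per-sample library sizes.
#' @export
quantify_enhancers <- function(enhancers, covs) {
  m <- matrix(0, nrow = nrow(enhancers), ncol = length(covs),
              dimnames = list(enhancers$id, names(covs)))
  for (j in seq_along(covs)) {
    for (i in seq_len(nrow(enhancers))) {
      m[i, j] <- .track_count(covs[[j]], enhancers$chrom[i], "+",
                              enhancers$start[i], enhancers$end[i]) +
        .track_count(covs[[j]], enhancers$chrom[i], "-",
                     enhancers$start[i], enhancers$end[i])
    }
  }
  attr(m, "total_mapped") <- vapply(covs, function(x) x$total_mapped, 0)
  m
}

#' Extract long eRNAs from unpaired intergenic transcripts
#'
#' Unidirectional intergenic transcripts strictly longer than
#' `long_erna_min` bp that were not consumed by a bidirectional pair are
#' treated as long eRNAs; each is then quantified like a gene (TSS = 5'
#' end, TTS = 3' end).
#'
#' @param transcripts Intergenic transcripts (post [filter_intergenic]).
#' @param paired_tx Character vector of transcript keys consumed by
#'   [pair_bidirectional] (its `"paired_tx"` attribute).
#' @param long_erna_min Strict length threshold in bp (default 10000).
#' @return `data.frame` of long eRNAs shaped like a gene annotation
#'   (`gene_id`, `chrom`, `strand`, `tss`, `tts`, `length`, `start`, `end`),
#'   ready for [quantify_genes].
#' @export
extract_long_ernas <- function(transcripts, paired_tx = character(),
                               long_erna_min = 10000L) {
  if (nrow(transcripts) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(), tts = integer(),
                      length = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- sprintf("%s:%d-%d/%s", transcripts$chrom, transcripts$start,
                 transcripts$end, transcripts$strand)
  keep <- !(key %in% paired_tx) & transcripts$length > long_erna_min
  tx <- transcripts[keep, , drop = FALSE]
  data.frame(
    gene_id = sprintf("longeRNA_%s:%d-%d", tx$chrom, tx$start, tx$end),
    chrom = tx$chrom, strand = tx$strand,
    tss = ifelse(tx$strand == "+", tx$start, tx$end),
    tts = ifelse(tx$strand == "+", tx$end, tx$start),
    length = tx$length, start = tx$start, end = tx$end,
    stringsAsFactors = FALSE)
}
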