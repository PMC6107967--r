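#' Locate the promoter-proximal region of a gene
#'
#' Scans every `window`-bp window with a `step`-bp sliding step along the
#' coding strand within +/- `span` bp of the TSS and returns the window with
#' the largest sense-strand read count. Ties are broken by proximity of the
#' window center to the TSS, then by the more upstream window (strand-aware),
#' so the result is deterministic.
#'
#' @param cov A [stranded_coverage].
#' @param gene One row of a gene-annotation `data.frame`
#'   (see [read_gene_annotation]): needs `chrom`, `strand`, `tss`.
#' @param window Window size in bp (default 50).
#' @param step Sliding step in bp (default 5).
#' @param span Scan half-width around the TSS in bp (default 500).
#' @return List with `region` ([genome_interval]), `count`, and `density`
#'   (reads/bp, `count / window`).
#' @export
find_pp_region <- function(cov, gene, window = 50L, step = 5L, span = 500L) {
  tss <- gene$tss
  starts <- seq.int(tss - span, tss + span - window, by = step)
  starts <- starts[starts >= 0L]
  counts <- .window_counts(cov, gene$chrom, gene$strand, starts, window)
  centers <- starts + window / 2
  # upstream = smaller coordinate on +, larger on -
  upstream_key <- if (gene$strand == "+") starts else -starts
  o <- order(-counts, abs(centers - tss), upstream_key)
  best <- o[1]
  list(region = genome_interval(gene$chrom, starts[best],
                                starts[best] + window, gene$strand),
       count = counts[best],
       density = counts[best] / window)
}

#' Gene-body region of a gene
#'
#' The gene body runs from `offset` bp downstream of the TSS to the TTS
#' (strand-aware). Genes not longer than `offset` have no body and return
#' `NULL`; callers skip (and log) them.
#'
#' @param gene One annotation row with `chrom`, `strand`, `tss`, `tts`.
#' @param offset Downstream offset from the TSS in bp (default 1000).
#' @return A [genome_interval], or `NULL` for genes shorter than `offset`.
#' @export
gene_body_region <- function(gene, offset = 1000L) {
  len <- abs(gene$tts - gene$tss)
  if (len <= offset) return(NULL)
  if (gene$strand == "+") {
    genome_interval(gene$chrom, gene$tss + offset, gene$tts, "+")
  } else {
    genome_interval(gene$chrom, gene$tts, gene$tss - offset, "-")
  }
}

#' Pausing index
#'
#' Ratio of promoter-proximal read density to gene-body read density;
#' `NA` when the gene body has no signal.
#'
#' @param pp_density Promoter-proximal density (reads/bp).
#' @param gb_density Gene-body density (reads/bp).
#' @return Numeric ratio, or `NA` when `gb_density` is zero.
#' @export
pausing_index <- function(pp_density, gb_density) {
  ifelse(gb_density > 0, pp_density / gb_density, NA_real_)
}

#' Significance of promoter-proximal pausing
#'
#' One-sided Fisher's exact test of the observed (pp, gb) read split against
#' the split expected from region lengths alone: the 2x2 table is
#' `rbind(c(pp_count, gb_count), c(E_pp, E_gb))` with
#' `E_pp = round(N * pp_len / (pp_len + gb_len))`, `E_gb = N - E_pp`, and the
#' alternative is enrichment of the observed promoter-proximal count.
#'
#' @param pp_count,gb_count Observed read counts.
#' @param pp_len,gb_len Region lengths in bp.
#' @return One-sided p-value (`1` when no reads were observed).
#' @export
pausing_significance <- function(pp_count, gb_count, pp_len, gb_len) {
  stopifnot(pp_len > 0, gb_len > 0, pp_count >= 0, gb_count >= 0)
  n <- pp_count + gb_count
  if (n == 0) return(1)
  e_pp <- round(n * pp_len / (pp_len + gb_len))
  e_gb <- n - e_pp
  tab <- rbind(c(pp_count, gb_count), c(e_pp, e_gb))
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Classify a gene as transcriptionally active
#'
#' Active means promoter-proximal density strictly greater than zero and
#' gene-body density strictly greater than `threshold` reads/kb after the
#' library is scaled to `scale` mapped reads.
#'
#' @param pp_density Promoter-proximal density (reads/bp).
#' @param gb_count Gene-body read count.
#' @param gb_len Gene-body length (bp).
#' @param total_mapped Library size (mapped reads).
#' @param scale Library-size normalization target (default `1e7`).
#' @param threshold Normalized gene-body density cutoff in reads/kb
#'   (default 4).
#' @return Logical.
#' @export
active_gene_filter <- function(pp_density, gb_count, gb_len, total_mapped,
                               scale = 1e7, threshold = 4) {
  stopifnot(total_mapped > 0, gb_len > 0)
  norm_gb_per_kb <- (gb_count * scale / total_mapped) / (gb_len / 1000)
  (pp_density > 0) & (norm_gb_per_kb > threshold)
}

#' Quantify all genes in one sample
#'
#' Runs the promoter-proximal window search, gene-body definition, pausing
#' index, pausing significance and active-gene classification for every gene.
#' Genes shorter than `gb_offset` are skipped and reported in the
#' `"skipped"` attribute.
#'
#' @param cov A [stranded_coverage].
#' @param genes Annotation `data.frame` from [read_gene_annotation].
#' @param window,step,span Promoter-proximal search parameters
#'   (see [find_pp_region]).
#' @param gb_offset Gene-body offset from the TSS (default 1000 bp).
#' @param scale,active_threshold Active-gene normalization target and
#'   reads/kb cutoff (see [active_gene_filter]).
#' @param norm_factor Optional user normalization factor overriding plain
#'   library-size scaling: effective library size = `total_mapped *
#'   norm_factor`.
#' @return `data.frame` with one row per quantified gene: pp/gb coordinates,
#'   counts, densities, pausing index and p, and the `active` flag.
#' @export
quantify_genes <- function(cov, genes, window = 50L, step = 5L, span = 500L,
                           gb_offset = 1000L, scale = 1e7,
                           active_threshold = 4, norm_factor = 1) {
  n <- nrow(genes)
  keep <- logical(n)
  rows <- vector("list", n)
  eff_total <- cov$total_mapped * norm_factor
  for (i in seq_len(n)) {
    g <- genes[i, ]
    gb <- gene_body_region(g, gb_offset)
    if (is.null(gb)) next
    keep[i] <- TRUE
    pp <- find_pp_region(cov, g, window, step, span)
    gb_count <- count_region(cov, gb)
    gb_len <- interval_width(gb)
    gb_density <- gb_count / gb_len
    rows[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      tss = g$tss, tts = g$tts,
      pp_start = pp$region$start, pp_end = pp$region$end,
      pp_count = pp$count, pp_density = pp$density,
      gb_start = gb$start, gb_end = gb$end,
      gb_count = gb_count, gb_len = gb_len,
      gb_density = gb_density, gb_density_kb = gb_density * 1000,
      pausing_index = pausing_index(pp$density, gb_density),
      pausing_p = pausing_significance(pp$count, gb_count, window, gb_len),
      active = active_gene_filter(pp$density, gb_count, gb_len,
                                  max(eff_total, 1), scale, active_threshold),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) out <- data.frame()
  attr(out, "skipped") <- genes$gene_id[!keep]
  out
}

#' Binned signal profile around genomic anchor points
#'
#' For each anchor (TSS or enhancer center), counts reads in consecutive
#' bins spanning +/- `span` bp and scales them to `scale` mapped reads.
#'
#' @param cov A [stranded_coverage].
#' @param centers `data.frame` with `id`, `chrom`, `pos` and optionally
#'   `strand` columns. With a strand column, bins are counted on the sense
#'   strand and reported 5'->3'; otherwise both strands are summed.
#' @param span Half-width in bp (default 5000).
#' @param bin Bin size in bp (default 200); must divide `span`.
#' @param scale Library-size normalization target (default `1e7`).
#' @return Numeric matrix, rows = `centers$id`, columns = bin start offsets.
#' @export
signal_profile <- function(cov, centers, span = 5000L, bin = 200L,
                           scale = 1e7) {
  stopifnot(span %% bin == 0L)
  offsets <- seq.int(-span, span - bin, by = bin)
  stranded <- "strand" %in% names(centers)
  sf <- if (cov$total_mapped > 0) scale / cov$total_mapped else 0
  mat <- matrix(0, nrow = nrow(centers), ncol = length(offsets),
                dimnames = list(centers$id, offsets))
  for (i in seq_len(nrow(centers))) {
    starts <- centers$pos[i] + offsets
    ok <- starts >= 0L
    if (stranded) {
      v <- .window_counts(cov, centers$chrom[i], centers$strand[i],
                          starts[ok], bin)
      row <- numeric(length(offsets)); row[ok] <- v
      if (centers$strand[i] == "-") row <- rev(row)
    } else {
      v <- .window_counts(cov, centers$chrom[i], "+", starts[ok], bin) +
        .window_counts(cov, centers$chrom[i], "-", starts[ok], bin)
      row <- numeric(length(offsets)); row[ok] <- v
    }
    mat[i, ] <- row * sf
  }
  mat
}

#' Per-bin log2 fold-change matrix around TSSs
#'
#' Builds [signal_profile] matrices for two conditions (averaging the
#' normalized per-sample profiles within each condition) and returns
#' `log2((b + pseudocount) / (a + pseudocount))` per bin.
#'
#' @param covs_a,covs_b Lists of [stranded_coverage], one per sample, for
#'   the reference and the comparison condition.
#' @param centers Anchor table as in [signal_profile].
#' @param span,bin,scale Binning and normalization (see [signal_profile]).
#' @param pseudocount Added to both normalized signals before the ratio
#'   (default 1).
#' @return Numeric matrix of per-bin log2 fold changes (condition B over A).
#' @export
tss_profile_matrix <- function(covs_a, covs_b, centers, span = 5000L,
                               bin = 200L, scale = 1e7, pseudocount = 1) {
  avg <- function(covs) {
    mats <- lapply(covs, signal_profile, centers = centers, span = span,
                   bin = bin, scale = scale)
    Reduce(`+`, mats) / length(mats)
  }
  a <- avg(covs_a); b <- avg(covs_b)
  log2((b + pseudocount) / (a + pseudocount))
}
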