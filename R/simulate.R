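#' Default desk-scale simulation configuration
#'
#' One 5 Mb chromosome, 40 genes (10 kb, alternating strands, spaced 120 kb
#' apart) and 20 intergenic enhancers, each centered 40 kb downstream of its
#' gene's TSS: outside every gene's -2 kb/+20 kb exclusion zone (so planted
#' enhancers are callable), uniquely closest to its gene, and within the
#' default 50 kb linking window. Two replicates per condition. Rates give roughly 2e5 reads
#' per sample: a 50 bp paused block at 2 reads/bp, gene bodies at 0.4
#' reads/bp, and two divergent 800 bp eRNA transcripts at 0.5 reads/bp per
#' enhancer.
#'
#' Condition effects: genes 1-10 gain promoter-proximal signal (log2FC 1.2)
#' with a milder gene-body gain (0.4); genes 11-15 lose both (-1); the rest
#' are null. Enhancers 1-6 are upregulated (log2FC 1.5; enhancer 1 at 2.5
#' with a ChIP peak at its center and the strongest concordant gene change),
#' enhancers 7-8 are downregulated (-1.5), the rest null. Enhancers 2 and 3
#' carry displaced peaks (8 kb from center) so binding evidence
#' differentiates ranks.
#'
#' @param seed Integer seed stored in the config (default 1).
#' @param replicates Replicates per condition (default 2).
#' @param n_genes,n_enhancers Feature counts (defaults 40 and 20).
#' @param nb_dispersion NB dispersion of per-base counts (default 0.05).
#' @param bg_rate Uniform background rate in reads/bp on both strands
#'   (default 0: clean intergenic space).
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(seed = 1L, replicates = 2L, n_genes = 40L,
                               n_enhancers = 20L, nb_dispersion = 0.05,
                               bg_rate = 0) {
  chrom <- "chr1"; chrom_len <- 5e6
  gene_len <- 10000L; spacing <- 120000L; first <- 60000L
  gs <- first + (seq_len(n_genes) - 1L) * spacing
  strand <- rep(c("+", "-"), length.out = n_genes)
  pp_lfc <- numeric(n_genes); gb_lfc <- numeric(n_genes)
  up <- seq_len(min(10L, n_genes))
  dn <- intersect(11:15, seq_len(n_genes))
  pp_lfc[up] <- 1.2; gb_lfc[up] <- 0.4
  pp_lfc[dn] <- -1; gb_lfc[dn] <- -1
  genes <- data.frame(
    gene_id = sprintf("gene_%02d", seq_len(n_genes)),
    chrom = chrom, strand = strand,
    start = gs, end = gs + gene_len,
    pp_rate = 2, gb_rate = 0.4, pp_lfc = pp_lfc, gb_lfc = gb_lfc,
    stringsAsFactors = FALSE)
  genes$pp_lfc[1] <- 2    # strongest concordant gene change, near enhancer 1
  ne <- min(n_enhancers, n_genes)
  tss <- ifelse(strand == "+", gs, gs + gene_len)
  centers <- tss[seq_len(ne)] + 40000L
  lfc <- numeric(ne)
  lfc[seq_len(min(6L, ne))] <- 1.5
  lfc[1] <- 2.5
  if (ne >= 8L) lfc[7:8] <- -1.5
  enhancers <- data.frame(
    id = sprintf("true_enh_%02d", seq_len(ne)),
    chrom = chrom, center = centers, erna_rate = 0.5, span = 800L,
    lfc = lfc,
    has_peak = c(TRUE, rep(FALSE, ne - 1L)),
    peak_offset = 0L,
    linked_gene = genes$gene_id[seq_len(ne)],
    stringsAsFactors = FALSE)
  if (ne >= 3L) {
    enhancers$has_peak[2:3] <- TRUE
    enhancers$peak_offset[2:3] <- 8000L
  }
  structure(list(genome = data.frame(chrom = chrom, length = chrom_len),
                 genes = genes, enhancers = enhancers,
                 nb_dispersion = nb_dispersion, replicates = replicates,
                 depth = 1, bg_rate = bg_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.check_sim_config <- function(cfg, dtss = 2000L, dtts = 20000L) {
  g <- cfg$genes
  ext_start <- ifelse(g$strand == "+", g$start - dtss, g$start - dtts)
  ext_end <- ifelse(g$strand == "+", g$end + dtts, g$end + dtss)
  for (i in seq_len(nrow(cfg$enhancers))) {
    e <- cfg$enhancers[i, ]
    lo <- e$center - e$span; hi <- e$center + e$span
    clash <- any(g$chrom == e$chrom & lo < ext_end & hi > ext_start)
    if (clash)
      stop("planted enhancer ", e$id, " violates the -", dtss, "/+", dtts,
           " intergenic exclusion zone around a gene")
  }
  invisible(TRUE)
}

# NB draw of per-base counts over [start, end) at the given mean rate;
# returns integer vector of length end-start
.nb_base_counts <- function(n, mu, dispersion) {
  if (mu <= 0 || n <= 0) return(integer(max(n, 0)))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a complete desk-scale dataset
#'
#' Draws per-base read counts from a negative binomial
#' (`mu = rate * depth * 2^(lfc * condition)`, the condition indicator being
#' 0/1) independently per sample, and writes per-sample BED6 read files plus
#' matching annotation (BED12), known-enhancer BED, enhancer-TSS association
#' TSV, chromatin-interaction TSV, ChIP-seq narrowPeak, and a truth table
#' listing every planted feature with its true effect. Reads are 1 bp since
#' downstream counting is single-base. Deterministic given `cfg$seed`.
#'
#' Gene signal is sense-strand only: a 50 bp paused block at the TSS at
#' `pp_rate` plus a uniform body at `gb_rate`. Enhancer signal is two
#' divergent `span`-bp transcripts flanking the center at `erna_rate`.
#'
#' @param cfg A `sim_config` (see [default_sim_config]).
#' @param dir Output directory (created if needed).
#' @return List with `samples` (data.frame: sample, condition, path),
#'   `annotation`, `known_enhancers`, `associations`, `interactions`,
#'   `peaks`, `truth` file paths, and `truth_table` as a data.frame.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  .check_sim_config(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  n_rep <- cfg$replicates
  samples <- data.frame(
    sample = c(sprintf("cond1_rep%d", seq_len(n_rep)),
               sprintf("cond2_rep%d", seq_len(n_rep))),
    condition = rep(c("cond1", "cond2"), each = n_rep),
    stringsAsFactors = FALSE)
  depth <- rep(cfg$depth, length.out = nrow(samples))

  paths <- character(nrow(samples))
  for (s in seq_len(nrow(samples))) {
    cond_ind <- as.integer(samples$condition[s] == "cond2")
    rows <- list()
    emit <- function(chrom, from, n, strand, rate, lfc) {
      mu <- rate * depth[s] * 2^(lfc * cond_ind)
      cnts <- .nb_base_counts(n, mu, cfg$nb_dispersion)
      hit <- which(cnts > 0L)
      if (!length(hit)) return(NULL)
      pos <- rep(from + hit - 1L, cnts[hit])
      data.table::data.table(chrom = chrom, start = pos, end = pos + 1L,
                             name = ".", score = 0L, strand = strand)
    }
    for (i in seq_len(nrow(cfg$genes))) {
      g <- cfg$genes[i, ]
      if (g$strand == "+") {
        rows[[length(rows) + 1L]] <- emit(g$chrom, g$start, 50L, "+",
                                          g$pp_rate, g$pp_lfc)
        rows[[length(rows) + 1L]] <- emit(g$chrom, g$start + 50L,
                                          g$end - g$start - 50L, "+",
                                          g$gb_rate, g$gb_lfc)
      } else {
        rows[[length(rows) + 1L]] <- emit(g$chrom, g$end - 50L, 50L, "-",
                                          g$pp_rate, g$pp_lfc)
        rows[[length(rows) + 1L]] <- emit(g$chrom, g$start,
                                          g$end - g$start - 50L, "-",
                                          g$gb_rate, g$gb_lfc)
      }
    }
    for (i in seq_len(nrow(cfg$enhancers))) {
      e <- cfg$enhancers[i, ]
      rows[[length(rows) + 1L]] <- emit(e$chrom, e$center, e$span, "+",
                                        e$erna_rate, e$lfc)
      rows[[length(rows) + 1L]] <- emit(e$chrom, e$center - e$span, e$span,
                                        "-", e$erna_rate, e$lfc)
    }
    if (cfg$bg_rate > 0) {
      for (ch in seq_len(nrow(cfg$genome))) {
        len <- cfg$genome$length[ch]
        for (str in c("+", "-"))
          rows[[length(rows) + 1L]] <- emit(cfg$genome$chrom[ch], 0L,
                                            as.integer(len), str,
                                            cfg$bg_rate, 0)
      }
    }
    dt <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
    data.table::setorderv(dt, c("chrom", "start", "strand"))
    paths[s] <- file.path(dir, paste0(samples$sample[s], ".bed"))
    data.table::fwrite(dt, paths[s], sep = "\t", col.names = FALSE)
  }
  samples$path <- paths

  g <- cfg$genes
  ann <- data.table::data.table(
    chrom = g$chrom, start = g$start, end = g$end, name = g$gene_id,
    score = 0L, strand = g$strand, thickStart = g$start, thickEnd = g$end,
    rgb = "0", blockCount = 1L, blockSizes = paste0(g$end - g$start, ","),
    blockStarts = "0,")
  ann_path <- file.path(dir, "annotation.bed12")
  data.table::fwrite(ann, ann_path, sep = "\t", col.names = FALSE)

  e <- cfg$enhancers
  known_idx <- which(seq_len(nrow(e)) %% 2L == 1L)   # odd ones are "known"
  known <- data.table::data.table(chrom = e$chrom[known_idx],
                                  start = e$center[known_idx] - 1000L,
                                  end = e$center[known_idx] + 1000L,
                                  id = sprintf("known_%02d", known_idx))
  known_path <- file.path(dir, "known_enhancers.bed")
  data.table::fwrite(known, known_path, sep = "\t", col.names = FALSE)

  assoc_idx <- seq_len(min(5L, nrow(e)))
  assoc <- data.table::data.table(chrom = e$chrom[assoc_idx],
                                  start = e$center[assoc_idx] - 1000L,
                                  end = e$center[assoc_idx] + 1000L,
                                  gene_id = e$linked_gene[assoc_idx])
  assoc_path <- file.path(dir, "associations.tsv")
  data.table::fwrite(assoc, assoc_path, sep = "\t", col.names = TRUE)

  gi <- match(e$linked_gene, g$gene_id)
  tss <- ifelse(g$strand[gi] == "+", g$start[gi], g$end[gi])
  inter <- data.table::data.table(
    chromA = e$chrom, startA = e$center - 2000L, endA = e$center + 2000L,
    chromB = g$chrom[gi], startB = pmax(tss - 1000L, 0L), endB = tss + 1000L,
    tissue = rep(c("liver", "brain"), length.out = nrow(e)),
    method = "HiC")
  inter_path <- file.path(dir, "interactions.tsv")
  data.table::fwrite(inter, inter_path, sep = "\t", col.names = TRUE)

  pk_idx <- which(e$has_peak)
  peaks <- data.table::data.table(
    chrom = e$chrom[pk_idx],
    start = e$center[pk_idx] + e$peak_offset[pk_idx] - 250L,
    end = e$center[pk_idx] + e$peak_offset[pk_idx] + 250L,
    name = sprintf("peak_%02d", seq_along(pk_idx)), score = 100L,
    strand = ".", signal = 10, p = 5, q = 3, summit = 250L)
  peaks_path <- file.path(dir, "peaks.narrowPeak")
  data.table::fwrite(peaks, peaks_path, sep = "\t", col.names = FALSE)

  truth <- data.frame(feature_id = g$gene_id, type = "gene", chrom = g$chrom,
                      start = g$start, end = g$end, strand = g$strand,
                      center = ifelse(g$strand == "+", g$start, g$end),
                      pp_lfc = g$pp_lfc, lfc = g$gb_lfc,
                      has_peak = FALSE, linked_gene = NA_character_,
                      stringsAsFactors = FALSE)
  if (nrow(e)) {
    truth <- rbind(truth, data.frame(
      feature_id = e$id, type = "enhancer", chrom = e$chrom,
      start = e$center - e$span, end = e$center + e$span,
      strand = ".", center = e$center, pp_lfc = NA_real_,
      lfc = e$lfc, has_peak = e$has_peak,
      linked_gene = e$linked_gene, stringsAsFactors = FALSE))
  }
  truth_path <- file.path(dir, "truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t", col.names = TRUE)

  list(samples = samples, annotation = ann_path,
       known_enhancers = known_path, associations = assoc_path,
       interactions = inter_path, peaks = peaks_path, truth = truth_path,
       truth_table = truth)
}

#' Hand-built bidirectional-pairing scenarios
#'
#' Seven small transcript configurations covering every enhancer-center
#' rule: (a) 5'-overlapping divergent pair, (b) divergent pair with a gap
#' below the pairing cutoff (midpoint centers); (c)/(d) full containment of
#' one transcript in the opposite-strand one (center at the 5' end of the
#' short transcript); (e) both rules firing on one pair (two centers);
#' (f) one transcript pairing with two opposite-strand transcripts
#' (two centers); (g) two pairs whose hulls fall within the merge distance
#' (one merged enhancer, two centers).
#'
#' @return Named list of scenarios; each has `transcripts` (a data.frame
#'   accepted by [pair_bidirectional]), `expected_centers`, and
#'   `expected_enhancers` after [merge_enhancers].
#' @export
scenario_fixtures <- function() {
  tx <- function(start, end, strand)
    data.frame(chrom = "chrX", start = start, end = end, strand = strand,
               five_prime = ifelse(strand == "+", start, end - 1L),
               read_count = 0, length = end - start,
               stringsAsFactors = FALSE)
  list(
    overlap_5p = list(
      transcripts = rbind(tx(1000L, 3000L, "+"), tx(200L, 1200L, "-")),
      expected_centers = 1099L, expected_enhancers = 1L),
    gap_5p = list(
      transcripts = rbind(tx(2000L, 4000L, "+"), tx(500L, 1700L, "-")),
      expected_centers = 1849L, expected_enhancers = 1L),
    contained_minus = list(
      transcripts = rbind(tx(1000L, 3000L, "+"), tx(1500L, 1800L, "-")),
      expected_centers = 1799L, expected_enhancers = 1L),
    contained_plus = list(
      transcripts = rbind(tx(1000L, 3000L, "-"), tx(1600L, 1900L, "+")),
      expected_centers = 1600L, expected_enhancers = 1L),
    both_rules = list(
      transcripts = rbind(tx(1000L, 3000L, "+"), tx(1000L, 1300L, "-")),
      expected_centers = c(1149L, 1299L), expected_enhancers = 1L),
    multi_partner = list(
      transcripts = rbind(tx(1000L, 5000L, "+"), tx(600L, 1200L, "-"),
                          tx(2000L, 2600L, "-")),
      expected_centers = c(1099L, 2599L), expected_enhancers = 1L),
    merge_adjacent = list(
      transcripts = rbind(tx(1000L, 2000L, "+"), tx(400L, 1100L, "-"),
                          tx(2400L, 3400L, "+"), tx(2350L, 2500L, "-")),
      expected_centers = c(1049L, 2449L), expected_enhancers = 1L)
  )
}
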