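#' Build and validate a run configuration
#'
#' Collects the sample sheet, annotation paths and all analysis parameters
#' (with their standard defaults) for [run_genes] and [run_enhancers].
#'
#' @param samples `data.frame` with columns `sample`, `path`, `condition`
#'   (exactly two condition labels for differential runs; a single condition
#'   is allowed for quantification-only runs).
#' @param annotation Path to the gene annotation (see
#'   [read_gene_annotation]).
#' @param out_dir Output directory.
#' @param known_enhancers,associations,interactions,peaks Optional paths to
#'   the known-enhancer BED, enhancer-TSS association TSV,
#'   chromatin-interaction TSV and ChIP-seq peak file.
#' @param norm_factors Optional named numeric vector of per-sample
#'   normalization factors overriding RLE.
#' @param params Named list overriding defaults: `window` (50), `step` (5),
#'   `span` (500), `gb_offset` (1000), `active_threshold` (4 reads/kb),
#'   `scale` (1e7), `tss_fold` (4), `body_fold` (3), `dtss` (2000),
#'   `dtts` (20000), `pair_gap` (400), `merge_gap` (500),
#'   `long_erna_min` (10000), `link_distance` (50000), `w` (0.5),
#'   `d0` (5000), `aggregate` ("mean"), `tissue` (NULL),
#'   `profile_span` (5000), `profile_bin` (200), plus the caller knobs of
#'   [transcript_caller_params].
#' @param mapq_min,count_mode,flip_strand Alignment-loading options
#'   (see [load_alignments]).
#' @return A validated `run_config` list.
#' @export
run_config <- function(samples, annotation, out_dir,
                       known_enhancers = NULL, associations = NULL,
                       interactions = NULL, peaks = NULL,
                       norm_factors = NULL, params = list(),
                       mapq_min = 10L, count_mode = "five-prime",
                       flip_strand = FALSE) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "path", "condition") %in% names(samples)))
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in sample sheet")
  n_cond <- length(unique(samples$condition))
  if (n_cond > 2L)
    stop("differential runs support exactly two condition labels, got ",
         n_cond)
  for (p in c(samples$path, annotation, known_enhancers, associations,
              interactions, peaks)) {
    if (!is.null(p) && !file.exists(p)) stop("referenced path missing: ", p)
  }
  defaults <- list(window = 50L, step = 5L, span = 500L, gb_offset = 1000L,
                   active_threshold = 4, scale = 1e7,
                   tss_fold = 4, body_fold = 3,
                   caller_window = 200L, caller_step = 50L,
                   max_gap = 1000L, min_length = 250L, bg_density = 0.05,
                   dtss = 2000L, dtts = 20000L, pair_gap = 400L,
                   merge_gap = 500L, long_erna_min = 10000L,
                   link_distance = 50000L, w = 0.5, d0 = 5000,
                   aggregate = "mean", tissue = NULL,
                   profile_span = 5000L, profile_bin = 200L)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameters: ",
                            paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(samples = samples, annotation = annotation,
                 out_dir = out_dir, known_enhancers = known_enhancers,
                 associations = associations, interactions = interactions,
                 peaks = peaks, norm_factors = norm_factors,
                 params = defaults, mapq_min = mapq_min,
                 count_mode = count_mode, flip_strand = flip_strand),
            class = "run_config")
}

.load_all_samples <- function(cfg) {
  covs <- lapply(seq_len(nrow(cfg$samples)), function(i)
    load_alignments(cfg$samples$path[i], cfg$mapq_min, cfg$count_mode,
                    cfg$flip_strand, sample_id = cfg$samples$sample[i]))
  names(covs) <- cfg$samples$sample
  covs
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  data.table::fwrite(df, path, sep = "\t", col.names = TRUE, na = "NA")
  path
}

.write_matrix_tsv <- function(mat, dir, name, id_col = "feature") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, dir, name)
}

# size factors honoring user overrides
.size_factors <- function(cfg, counts) {
  if (!is.null(cfg$norm_factors)) {
    sf <- cfg$norm_factors[colnames(counts)]
    if (any(is.na(sf))) stop("norm_factors missing for some samples")
    return(sf)
  }
  tryCatch(rle_size_factors(counts), error = function(e) {
    warning("RLE size factors unavailable (", conditionMessage(e),
            "); falling back to library-size factors")
    tm <- attr(counts, "total_mapped")
    sf <- tm / exp(mean(log(pmax(tm, 1))))
    stats::setNames(sf, colnames(counts))
  })
}

# pp/gb/pausing tables across samples; shared by genes and long eRNAs.
# file_prefix "" for genes, "longeRNA-" for long eRNAs.
.gene_table_set <- function(covs, genes, cfg, conditions, out, file_prefix,
                            log) {
  p <- cfg$params
  quants <- lapply(covs, quantify_genes, genes = genes, window = p$window,
                   step = p$step, span = p$span, gb_offset = p$gb_offset,
                   scale = p$scale, active_threshold = p$active_threshold)
  base <- quants[[1]][, c("gene_id", "chrom", "strand", "tss", "tts")]
  pindex <- base
  norm_tab <- base
  pp_counts <- sapply(quants, function(q) q$pp_count)
  gb_counts <- sapply(quants, function(q) q$gb_count)
  if (nrow(base) == 1L) {
    pp_counts <- matrix(pp_counts, nrow = 1)
    gb_counts <- matrix(gb_counts, nrow = 1)
  }
  rownames(pp_counts) <- rownames(gb_counts) <- base$gene_id
  colnames(pp_counts) <- colnames(gb_counts) <- names(covs)
  totals <- vapply(covs, function(x) x$total_mapped, 0)
  for (s in names(covs)) {
    q <- quants[[s]]
    sf <- p$scale / max(totals[[s]], 1)
    pindex[[paste0(s, ".pausing_index")]] <- q$pausing_index
    pindex[[paste0(s, ".pausing_p")]] <- q$pausing_p
    pindex[[paste0(s, ".active")]] <- q$active
    norm_tab[[paste0(s, ".pp_norm")]] <- q$pp_count * sf
    norm_tab[[paste0(s, ".gb_norm")]] <- q$gb_count * sf
    norm_tab[[paste0(s, ".gb_density_kb_norm")]] <- q$gb_density_kb * sf
  }
  .write_tsv(pindex, out, paste0(file_prefix, "pindex.txt"))
  .write_tsv(norm_tab, out, paste0(file_prefix, "normalized_pp_gb.txt"))

  # a feature is analysed when active in at least one sample (genes) or
  # carrying any signal (long eRNAs)
  if (file_prefix == "") {
    use <- Reduce(`|`, lapply(quants, function(q) q$active))
  } else {
    use <- rowSums(pp_counts + gb_counts) > 0
  }
  log$quantified <- nrow(base); log$analysed <- sum(use)
  res <- list(quants = quants, active = base$gene_id[use], log = log)
  if (length(unique(conditions)) != 2L || sum(use) == 0L) return(res)

  cm_pp <- pp_counts[use, , drop = FALSE]
  cm_gb <- gb_counts[use, , drop = FALSE]
  attr(cm_gb, "total_mapped") <- totals
  sf <- .size_factors(cfg, cm_gb)
  pp_diff <- nb_differential(round(cm_pp), conditions, sf)
  gb_diff <- nb_differential(round(cm_gb), conditions, sf)
  .write_tsv(pp_diff, out, paste0(file_prefix, "pp_change.txt"))
  .write_tsv(gb_diff, out, paste0(file_prefix, "gb_change.txt"))

  # pausing-index change: Fisher without replicates, CMH with
  i1 <- which(conditions == unique(conditions)[1])
  i2 <- which(conditions == unique(conditions)[2])
  n_strata <- min(length(i1), length(i2))
  ids <- base$gene_id[use]
  pc <- lapply(seq_along(ids), function(k) {
    i <- which(base$gene_id == ids[k])
    if (n_strata < 2L) {
      f <- pindex_change_fisher(pp_counts[i, i1[1]], gb_counts[i, i1[1]],
                                pp_counts[i, i2[1]], gb_counts[i, i2[1]])
      c(or = f$odds_ratio, p = f$p)
    } else {
      strata <- lapply(seq_len(n_strata), function(r)
        rbind(c(pp_counts[i, i1[r]], gb_counts[i, i1[r]]),
              c(pp_counts[i, i2[r]], gb_counts[i, i2[r]])))
      m <- pindex_change_cmh(strata)
      c(or = m$common_or, p = m$p)
    }
  })
  pc <- do.call(rbind, pc)
  pch <- data.frame(gene_id = ids, odds_ratio = pc[, "or"], p = pc[, "p"],
                    fdr = stats::p.adjust(pc[, "p"], method = "BH"),
                    method = if (n_strata < 2L) "fisher" else "cmh",
                    stringsAsFactors = FALSE)
  .write_tsv(pch, out, paste0(file_prefix, "pindex_change.txt"))
  res$pp_diff <- pp_diff; res$gb_diff <- gb_diff; res$pindex_change <- pch
  res
}

#' Run the known-gene analysis
#'
#' Quantifies promoter-proximal and gene-body signal for every annotated
#' gene in every sample, writes the pausing table (`pindex.txt`) and
#' normalized counts (`normalized_pp_gb.txt`), and -- when two conditions
#' are present -- the differential tables `pp_change.txt`, `gb_change.txt`
#' and `pindex_change.txt` (Fisher without replicates, CMH with), the
#' TSS-centered log2 fold-change profile matrix, and the per-condition
#' replicate-variation histograms.
#'
#' @param cfg A [run_config].
#' @return Invisibly, a list with the quantifications, differential tables,
#'   active-gene ids and a `log` of filter counts.
#' @export
run_genes <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  covs <- .load_all_samples(cfg)
  genes <- read_gene_annotation(cfg$annotation)
  log <- list(n_genes = nrow(genes),
              skipped_short = sum(genes$length <= p$gb_offset))
  conditions <- cfg$samples$condition
  res <- .gene_table_set(covs, genes, cfg, conditions, out, "", log)

  two_cond <- length(unique(conditions)) == 2L
  if (two_cond && length(res$active)) {
    act <- genes[genes$gene_id %in% res$active, , drop = FALSE]
    centers <- data.frame(id = act$gene_id, chrom = act$chrom,
                          pos = act$tss, strand = act$strand,
                          stringsAsFactors = FALSE)
    cond <- unique(conditions)
    prof <- tss_profile_matrix(covs[conditions == cond[1]],
                               covs[conditions == cond[2]],
                               centers, span = p$profile_span,
                               bin = p$profile_bin, scale = p$scale)
    if (!is.null(res$pp_diff)) {
      o <- order(-res$pp_diff$log2fc[match(rownames(prof),
                                           res$pp_diff$feature)])
      prof <- prof[o, , drop = FALSE]
    }
    .write_matrix_tsv(prof, out, "heatmap_tss_log2fc.txt", "gene_id")
    # replicate histograms per condition
    gbc <- round(sapply(res$quants, function(q) q$gb_count))
    if (is.null(dim(gbc))) gbc <- matrix(gbc, nrow = 1)
    rownames(gbc) <- res$quants[[1]]$gene_id
    gbc <- gbc[rownames(gbc) %in% res$active, , drop = FALSE]
    sf <- .size_factors(cfg, structure(gbc, total_mapped =
      vapply(covs, function(x) x$total_mapped, 0)))
    hists <- replicate_change_histogram(gbc, conditions, sf)
    for (i in seq_along(hists)) {
      .write_tsv(hists[[i]], out,
                 sprintf("Reps_condition%d.txt",
                         match(names(hists)[i], unique(conditions))))
    }
  }
  # per-sample density tables backing the box plots
  box <- do.call(rbind, lapply(names(covs), function(s) {
    q <- res$quants[[s]]
    sf <- p$scale / max(covs[[s]]$total_mapped, 1)
    data.frame(sample = s, gene_id = q$gene_id,
               pp_density_norm = q$pp_density * sf,
               gb_density_kb_norm = q$gb_density_kb * sf,
               pausing_index = q$pausing_index, stringsAsFactors = FALSE)
  }))
  .write_tsv(box, out, "density_by_sample.txt")
  invisible(res)
}

#' Run the enhancer analysis
#'
#' Calls de novo transcripts on reads pooled from all samples, restricts
#' them to intergenic space, pairs divergent transcripts into enhancers,
#' merges and annotates them, quantifies per-sample enhancer counts, tests
#' condition-dependent changes, extracts and quantifies long eRNAs, links
#' enhancers to active genes by up to four strategies, and -- when a peak
#' file is configured -- ranks enhancers by the combined binding/functional
#' score. Writes `Enhancer.txt`, `Enhancer_center.txt`,
#' `normalized_count_enhancer.txt`, `Enhancer_change.txt`, `long_eRNA.txt`,
#' the `longeRNA-*` table set and the enhancer-center signal matrix.
#'
#' @param cfg A [run_config].
#' @param gene_quant Optional result of [run_genes] (reused for the
#'   active-gene set and gene changes); computed if missing.
#' @return Invisibly, a list with enhancers, counts, differential results,
#'   links, scores and a `log` of filter counts.
#' @export
run_enhancers <- function(cfg, gene_quant = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  covs <- .load_all_samples(cfg)
  genes <- read_gene_annotation(cfg$annotation)
  conditions <- cfg$samples$condition
  two_cond <- length(unique(conditions)) == 2L

  pooled <- pool_coverage(covs)
  caller <- transcript_caller_params(
    tss_fold = p$tss_fold, body_fold = p$body_fold, window = p$caller_window,
    step = p$caller_step, max_gap = p$max_gap, min_length = p$min_length,
    bg_density = p$bg_density)
  tx <- call_transcripts(pooled, caller)
  tx_ig <- filter_intergenic(tx, genes, p$dtss, p$dtts)
  pre <- pair_bidirectional(tx_ig, p$pair_gap)
  enh <- merge_enhancers(pre, p$merge_gap)
  known <- if (!is.null(cfg$known_enhancers))
    read_known_enhancers(cfg$known_enhancers) else NULL
  enh <- suppressWarnings(annotate_enhancers(enh, known))
  log <- list(n_transcripts = nrow(tx), n_intergenic = nrow(tx_ig),
              n_pre_merge = nrow(pre), n_enhancers = nrow(enh))

  counts <- quantify_enhancers(enh, covs)
  totals <- attr(counts, "total_mapped")
  norm_counts <- sweep(counts, 2, p$scale / pmax(totals, 1), "*")
  .write_matrix_tsv(norm_counts, out, "normalized_count_enhancer.txt",
                    "enhancer_id")
  centers_tab <- do.call(rbind, lapply(seq_len(nrow(enh)), function(i)
    data.frame(enhancer_id = enh$id[i], chrom = enh$chrom[i],
               center = .parse_centers(enh$centers[i]),
               stringsAsFactors = FALSE)))
  if (is.null(centers_tab))
    centers_tab <- data.frame(enhancer_id = character(), chrom = character(),
                              center = integer())
  .write_tsv(centers_tab, out, "Enhancer_center.txt")

  enh_diff <- NULL
  if (two_cond && nrow(enh)) {
    tested <- rowSums(counts) > 0
    sf <- .size_factors(cfg, counts[tested, , drop = FALSE])
    enh_diff <- nb_differential(round(counts[tested, , drop = FALSE]),
                                conditions, sf)
    .write_tsv(enh_diff, out, "Enhancer_change.txt")
  }

  # long eRNAs: unpaired unidirectional intergenic transcripts > threshold
  lerna <- extract_long_ernas(tx_ig, attr(pre, "paired_tx"),
                              p$long_erna_min)
  log$n_long_erna <- nrow(lerna)
  .write_tsv(lerna, out, "long_eRNA.txt")
  if (nrow(lerna)) {
    .gene_table_set(covs, lerna, cfg, conditions, out, "longeRNA-",
                    list())
  }

  # linking and prioritization against active genes
  gq <- gene_quant
  if (is.null(gq)) {
    gcfg <- cfg; gcfg$out_dir <- file.path(out, "genes")
    gq <- run_genes(gcfg)
  }
  active <- genes[genes$gene_id %in% gq$active, , drop = FALSE]
  assoc <- if (!is.null(cfg$associations))
    read_enhancer_tss_associations(cfg$associations) else NULL
  inter <- if (!is.null(cfg$interactions))
    read_interactions(cfg$interactions) else NULL
  links <- suppressMessages(
    link_enhancers(enh, active, assoc, inter, p$link_distance, p$tissue))
  log$n_links <- nrow(links)

  scores <- NULL
  enh_tab <- enh
  if (two_cond && !is.null(enh_diff)) {
    enh_changes <- stats::setNames(enh_diff$log2fc, enh_diff$feature)
    gene_changes <- if (!is.null(gq$pp_diff))
      stats::setNames(gq$pp_diff$log2fc, gq$pp_diff$feature) else numeric()
    peaks <- if (!is.null(cfg$peaks)) read_peaks(cfg$peaks) else NULL
    scores <- prioritize_enhancers(enh, links, enh_changes, gene_changes,
                                   peaks, w = p$w, d0 = p$d0,
                                   aggregate = p$aggregate)
    keep_cols <- if (is.null(peaks)) c("enhancer_id", "C_en", "F_s") else
      c("enhancer_id", "d", "B_s", "C_en", "F_s", "E_s", "rank")
    enh_tab <- merge(enh_tab, scores[, keep_cols], by.x = "id",
                     by.y = "enhancer_id", all.x = TRUE, sort = FALSE)
  }
  targets <- vapply(enh_tab$id, function(i) {
    l <- links[links$enhancer_id == i, , drop = FALSE]
    if (!nrow(l)) return("")
    paste(sprintf("%s(%s)", l$gene_id, l$strategy), collapse = ",")
  }, "")
  enh_tab$target_genes <- targets
  .write_tsv(enh_tab, out, "Enhancer.txt")

  # pooled signal around enhancer centers
  if (nrow(centers_tab)) {
    ecent <- data.frame(id = sprintf("%s@%d", centers_tab$enhancer_id,
                                     centers_tab$center),
                        chrom = centers_tab$chrom, pos = centers_tab$center,
                        stringsAsFactors = FALSE)
    sig <- signal_profile(pooled, ecent, span = 2000L, bin = 20L,
                          scale = p$scale)
    .write_matrix_tsv(sig, out, "signal_around_enhancer-center.txt",
                      "center_id")
  }
  invisible(list(enhancers = enh_tab, counts = counts, diff = enh_diff,
                 long_ernas = lerna, links = links, scores = scores,
                 log = log))
}
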