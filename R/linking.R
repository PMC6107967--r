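#' Enhancer-gene links
#'
#' The four linking strategies produce rows of a common link table:
#' `enhancer_id`, `gene_id`, `strategy` (one of `closest`, `distance`,
#' `fantom5`, `4dgenome`) and `distance` (nearest enhancer center to the
#' gene TSS, bp; `NA` where a catalog, not geometry, made the link).
#' Enhancers are only ever assigned to active genes.
#'
#' @name enhancer_gene_links
NULL

.enh_centers <- function(enhancers) {
  lapply(seq_len(nrow(enhancers)), function(i)
    .parse_centers(enhancers$centers[i]))
}

.center_tss_dist <- function(centers, tss) min(abs(centers - tss))

.link_frame <- function(enhancer_id = character(), gene_id = character(),
                        strategy = character(), distance = numeric()) {
  data.frame(enhancer_id = enhancer_id, gene_id = gene_id,
             strategy = strategy, distance = distance,
             stringsAsFactors = FALSE)
}

#' Link each enhancer to the closest active gene
#'
#' The active gene whose TSS is nearest to any center of the enhancer (ties
#' link all tied genes). Enhancers on chromosomes without an active gene get
#' no link.
#'
#' @param enhancers Merged enhancers (`id`, `chrom`, `centers`).
#' @param active_genes Annotation rows of active genes (`gene_id`, `chrom`,
#'   `tss`).
#' @return Link `data.frame` (see [enhancer_gene_links]).
#' @export
link_closest <- function(enhancers, active_genes) {
  out <- list()
  cl <- .enh_centers(enhancers)
  for (i in seq_len(nrow(enhancers))) {
    g <- active_genes[active_genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- vapply(g$tss, function(t) .center_tss_dist(cl[[i]], t), 0)
    best <- which(d == min(d))
    out[[i]] <- .link_frame(rep(enhancers$id[i], length(best)),
                            g$gene_id[best], "closest", d[best])
  }
  do.call(rbind, c(out, list(.link_frame())))
}

#' Link enhancers to all active genes within a distance
#'
#' Every active gene whose TSS lies within `max_dist` bp (inclusive) of any
#' enhancer center.
#'
#' @param enhancers Merged enhancers.
#' @param active_genes Active gene annotation rows.
#' @param max_dist Inclusive center-to-TSS cutoff in bp (default 50000).
#' @return Link `data.frame`.
#' @export
link_within_distance <- function(enhancers, active_genes, max_dist = 50000L) {
  out <- list()
  cl <- .enh_centers(enhancers)
  for (i in seq_len(nrow(enhancers))) {
    g <- active_genes[active_genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- vapply(g$tss, function(t) .center_tss_dist(cl[[i]], t), 0)
    sel <- which(d <= max_dist)
    if (length(sel))
      out[[i]] <- .link_frame(rep(enhancers$id[i], length(sel)),
                              g$gene_id[sel], "distance", d[sel])
  }
  do.call(rbind, c(out, list(.link_frame())))
}

#' Link enhancers through a curated enhancer-TSS association catalog
#'
#' An enhancer is linked to a catalog gene when one of its centers falls
#' inside the catalog's associated enhancer interval. Only active genes are
#' kept. Such catalogs (FANTOM5-style) exist only for some species; passing
#' `NULL` skips the strategy with a message.
#'
#' @param enhancers Merged enhancers.
#' @param associations `data.frame` from [read_enhancer_tss_associations],
#'   or `NULL`.
#' @param active_genes Active gene annotation rows.
#' @return Link `data.frame` (strategy `"fantom5"`).
#' @export
link_fantom5 <- function(enhancers, associations, active_genes) {
  if (is.null(associations) || nrow(associations) == 0L) {
    message("no enhancer-TSS association catalog supplied; ",
            "catalog linking strategy skipped")
    return(.link_frame())
  }
  active_ids <- active_genes$gene_id
  tss_by_gene <- stats::setNames(active_genes$tss, active_genes$gene_id)
  out <- list()
  cl <- .enh_centers(enhancers)
  gr_assoc <- .df_to_granges(associations)
  for (i in seq_len(nrow(enhancers))) {
    gr_c <- .points_to_granges(rep(enhancers$chrom[i], length(cl[[i]])),
                               cl[[i]])
    hits <- GenomicRanges::findOverlaps(gr_c, gr_assoc, ignore.strand = TRUE)
    gid <- unique(associations$gene_id[S4Vectors::subjectHits(hits)])
    gid <- gid[gid %in% active_ids]
    if (length(gid)) {
      d <- vapply(gid, function(g)
        .center_tss_dist(cl[[i]], tss_by_gene[[g]]), 0)
      out[[i]] <- .link_frame(rep(enhancers$id[i], length(gid)), gid,
                              "fantom5", d)
    }
  }
  do.call(rbind, c(out, list(.link_frame())))
}

#' Link enhancers through experimentally detected chromatin interactions
#'
#' An enhancer is linked to an active gene when one interaction anchor
#' contains an enhancer center and the other contains the gene's TSS within
#' `tss_tol` bp (interaction anchors are coarse). An optional tissue filter
#' restricts the interaction rows first.
#'
#' @param enhancers Merged enhancers.
#' @param interactions `data.frame` from [read_interactions].
#' @param active_genes Active gene annotation rows.
#' @param tissue_filter Optional tissue name; rows with a different tissue
#'   are dropped before matching.
#' @param tss_tol TSS tolerance in bp (default 2000).
#' @return Link `data.frame` (strategy `"4dgenome"`).
#' @export
link_4dgenome <- function(enhancers, interactions, active_genes,
                          tissue_filter = NULL, tss_tol = 2000L) {
  if (is.null(interactions) || nrow(interactions) == 0L) return(.link_frame())
  if (!is.null(tissue_filter))
    interactions <- interactions[!is.na(interactions$tissue) &
                                   interactions$tissue == tissue_filter, ,
                                 drop = FALSE]
  if (nrow(interactions) == 0L) return(.link_frame())
  cl <- .enh_centers(enhancers)
  out <- list()
  in_anchor <- function(chrom, pos, achrom, astart, aend, tol = 0L)
    chrom == achrom & pos >= astart - tol & pos < aend + tol
  for (i in seq_len(nrow(enhancers))) {
    for (g in seq_len(nrow(active_genes))) {
      gene <- active_genes[g, ]
      hit <- FALSE
      for (k in seq_len(nrow(interactions))) {
        r <- interactions[k, ]
        ce_in_a <- any(in_anchor(enhancers$chrom[i], cl[[i]], r$chromA,
                                 r$startA, r$endA))
        ce_in_b <- any(in_anchor(enhancers$chrom[i], cl[[i]], r$chromB,
                                 r$startB, r$endB))
        g_in_a <- in_anchor(gene$chrom, gene$tss, r$chromA, r$startA,
                            r$endA, tss_tol)
        g_in_b <- in_anchor(gene$chrom, gene$tss, r$chromB, r$startB,
                            r$endB, tss_tol)
        if ((ce_in_a && g_in_b) || (ce_in_b && g_in_a)) { hit <- TRUE; break }
      }
      if (hit)
        out[[length(out) + 1L]] <- .link_frame(
          enhancers$id[i], gene$gene_id, "4dgenome",
          .center_tss_dist(cl[[i]], gene$tss))
    }
  }
  do.call(rbind, c(out, list(.link_frame())))
}

#' Run all four linking strategies
#'
#' @param enhancers Merged enhancers.
#' @param active_genes Active gene annotation rows.
#' @param associations Optional association catalog (see [link_fantom5]).
#' @param interactions Optional interaction table (see [link_4dgenome]).
#' @param max_dist,tissue_filter,tss_tol Passed through.
#' @return Combined link `data.frame`.
#' @export
link_enhancers <- function(enhancers, active_genes, associations = NULL,
                           interactions = NULL, max_dist = 50000L,
                           tissue_filter = NULL, tss_tol = 2000L) {
  rbind(
    link_closest(enhancers, active_genes),
    link_within_distance(enhancers, active_genes, max_dist),
    link_fantom5(enhancers, associations, active_genes),
    link_4dgenome(enhancers, interactions, active_genes, tissue_filter,
                  tss_tol)
  )
}

#' Binding-affinity score of an enhancer
#'
#' Exponential decay of the distance between the nearest ChIP-seq peak
#' anchor and the nearest enhancer center: `B_s = exp(-d / d0)`. With no
#' peak on the enhancer's chromosome, `B_s = 0` (the d -> Inf limit).
#'
#' @param enhancer One enhancer row (`chrom`, `centers`).
#' @param peaks `data.frame` from [read_peaks].
#' @param d0 Decay constant in bp (default 5000).
#' @return List with `B_s` in `[0, 1]` and the distance `d` (bp, `NA` when
#'   no peak).
#' @export
binding_affinity_score <- function(enhancer, peaks, d0 = 5000) {
  stopifnot(d0 > 0)
  centers <- .parse_centers(enhancer$centers)
  pk <- peaks[peaks$chrom == enhancer$chrom, , drop = FALSE]
  if (nrow(pk) == 0L) return(list(B_s = 0, d = NA_real_))
  d <- min(vapply(pk$anchor, function(a) min(abs(a - centers)), 0))
  list(B_s = exp(-d / d0), d = d)
}

#' Functional-activity score of an enhancer
#'
#' `F_s = (I_closest + I_distance + I_fantom5 + I_4dgenome terms) / 4`,
#' where each strategy's term is its indicator times `C_en` times the
#' aggregated `C_g` of the genes it linked. `C_en` and `C_g` are
#' transcriptional changes on a common normalized scale (see
#' [normalize_changes]).
#'
#' @param enhancer_id Enhancer id.
#' @param links Link table from [link_enhancers].
#' @param C_en Normalized transcriptional change of this enhancer.
#' @param gene_changes Named vector of normalized gene changes (`C_g`).
#' @param aggregate `"mean"` (default) or `"max"` over multiple linked
#'   genes within a strategy.
#' @return Numeric `F_s` (0 when the enhancer has no links).
#' @export
functional_activity_score <- function(enhancer_id, links, C_en, gene_changes,
                                      aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else max
  strategies <- c("closest", "distance", "fantom5", "4dgenome")
  terms <- vapply(strategies, function(s) {
    g <- links$gene_id[links$enhancer_id == enhancer_id & links$strategy == s]
    g <- g[g %in% names(gene_changes)]
    if (!length(g)) return(0)
    C_en * agg(gene_changes[g])
  }, 0)
  sum(terms) / 4
}

#' Normalize transcriptional changes to a common [0, 1] scale
#'
#' Either `"scale"` (default): log2 fold changes floored at zero and divided
#' by the maximum over the set, so only concordant increases score and the
#' strongest change maps to 1; or `"rank"`: floored values replaced by their
#' fractional rank among positive changes.
#'
#' @param log2fc Numeric vector (NAs become 0).
#' @param method `"scale"` or `"rank"`.
#' @return Numeric vector in `[0, 1]`, same names as input.
#' @export
normalize_changes <- function(log2fc, method = c("scale", "rank")) {
  method <- match.arg(method)
  x <- log2fc
  x[is.na(x)] <- 0
  x <- pmax(x, 0)
  if (method == "scale") {
    mx <- max(x)
    if (mx > 0) x <- x / mx
  } else {
    pos <- x > 0
    if (any(pos)) x[pos] <- rank(x[pos], ties.method = "average") / sum(pos)
  }
  x
}

#' Combined enhancer priority score and ranking
#'
#' `E_s = w * B_s + (1 - w) * F_s`, ranked in decreasing order. Equal `E_s`
#' values share a (dense) rank; within a tie, rows are ordered by `B_s`
#' then id.
#'
#' @param scores `data.frame` with `enhancer_id`, `B_s`, `F_s`.
#' @param w Weight of binding evidence in `[0, 1]` (default 0.5).
#' @return The input with `E_s` and `rank` columns, sorted best-first.
#' @export
combined_score_and_rank <- function(scores, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  scores$E_s <- w * scores$B_s + (1 - w) * scores$F_s
  o <- order(-scores$E_s, -scores$B_s, scores$enhancer_id)
  scores <- scores[o, , drop = FALSE]
  scores$rank <- cumsum(!duplicated(scores$E_s))
  rownames(scores) <- NULL
  scores
}

#' Score and rank all enhancers
#'
#' Convenience wrapper combining [binding_affinity_score],
#' [functional_activity_score] and [combined_score_and_rank].
#'
#' @param enhancers Merged enhancers.
#' @param links Link table from [link_enhancers].
#' @param enh_changes Named vector of enhancer log2 fold changes.
#' @param gene_changes Named vector of gene log2 fold changes.
#' @param peaks Peak table from [read_peaks], or `NULL` to skip binding
#'   evidence (all `B_s = 0` and ranking by `F_s` alone).
#' @param w,d0,aggregate,normalize See the component functions.
#' @return Ranked score `data.frame` with `enhancer_id`, `d`, `B_s`, `C_en`,
#'   `F_s`, `E_s`, `rank`.
#' @export
prioritize_enhancers <- function(enhancers, links, enh_changes, gene_changes,
                                 peaks = NULL, w = 0.5, d0 = 5000,
                                 aggregate = "mean", normalize = "scale") {
  C_en_all <- normalize_changes(enh_changes, normalize)
  C_g_all <- normalize_changes(gene_changes, normalize)
  rows <- lapply(seq_len(nrow(enhancers)), function(i) {
    id <- enhancers$id[i]
    b <- if (is.null(peaks)) list(B_s = 0, d = NA_real_) else
      binding_affinity_score(enhancers[i, ], peaks, d0)
    C_en <- if (id %in% names(C_en_all)) C_en_all[[id]] else 0
    f <- functional_activity_score(id, links, C_en, C_g_all, aggregate)
    data.frame(enhancer_id = id, d = b$d, B_s = b$B_s, C_en = C_en,
               F_s = f, stringsAsFactors = FALSE)
  })
  combined_score_and_rank(do.call(rbind, rows), w)
}
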