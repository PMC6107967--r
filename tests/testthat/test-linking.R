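.lk <- function(e, g, s) data.frame(enhancer_id = e, gene_id = g,
                                    strategy = s, distance = NA_real_,
                                    stringsAsFactors = FALSE)

# A small fixed universe: three enhancers and four genes on chr1, one gene
# on another chromosome.
mk_enh <- function() {
  data.frame(id = c("e1", "e2", "e3"), chrom = "chr1",
             start = c(4000, 200000, 500000), end = c(6000, 202000, 502000),
             centers = c("5000", "201000", "501000"),
             n_centers = 1L, tx_members = "", stringsAsFactors = FALSE)
}
mk_genes <- function() {
  rbind(gene_row("gA", strand = "+", start = 4000L, end = 24000L),
        gene_row("gB", strand = "+", start = 7000L, end = 27000L),
        gene_row("gC", strand = "-", start = 130000L, end = 190000L),
        gene_row("gD", strand = "+", start = 260000L, end = 280000L),
        gene_row("gE", chrom = "chr7", strand = "+",
                 start = 1000L, end = 30000L))
}

test_that("closest linking picks the minimum-distance active TSS", {
  l <- link_closest(mk_enh(), mk_genes())
  expect_equal(l$gene_id[l$enhancer_id == "e1"], "gA")
  expect_equal(l$distance[l$enhancer_id == "e1"], 1000)
  # e2 at 201000: gC TSS = 190000 (d 11000), gD TSS = 260000 (d 59000)
  expect_equal(l$gene_id[l$enhancer_id == "e2"], "gC")
  # with the nearest gene excluded (inactive), the next active gene wins
  l2 <- link_closest(mk_enh(), mk_genes()[-3, ])
  expect_equal(l2$gene_id[l2$enhancer_id == "e2"], "gD")
  # no active gene on the chromosome: no link
  l3 <- link_closest(mk_enh()[1, ], mk_genes()[5, , drop = FALSE])
  expect_equal(nrow(l3), 0)
})

test_that("an exact distance tie links both genes", {
  enh <- mk_enh()[1, , drop = FALSE]
  genes <- rbind(gene_row("gL", strand = "+", start = 4200L, end = 30000L),
                 gene_row("gR", strand = "-", start = 100L, end = 5800L))
  # both TSSs 800 bp from center 5000
  l <- link_closest(enh, genes)
  expect_setequal(l$gene_id, c("gL", "gR"))
})

test_that("distance linking is inclusive at the cutoff", {
  enh <- mk_enh()[1, , drop = FALSE]   # center 5000
  genes <- rbind(gene_row("g10k", strand = "+", start = 15000L, end = 40000L),
                 gene_row("g49k", strand = "+", start = 54000L, end = 90000L),
                 gene_row("g50k", strand = "+", start = 55000L, end = 90000L),
                 gene_row("g51k", strand = "+", start = 56000L, end = 90000L))
  l <- link_within_distance(enh, genes, max_dist = 50000L)
  expect_setequal(l$gene_id, c("g10k", "g49k", "g50k"))
  # every closest link reappears when max_dist covers its distance
  lc <- link_closest(enh, genes)
  expect_true(all(lc$gene_id %in% l$gene_id))
})

test_that("catalog linking requires center containment and active genes", {
  enh <- mk_enh()
  assoc <- data.frame(chrom = "chr1",
                      start = c(4900, 200500, 400000),
                      end = c(5100, 201500, 400100),
                      gene_id = c("gB", "gZ", "gA"),
                      stringsAsFactors = FALSE)
  l <- link_fantom5(enh, assoc, mk_genes())
  # e1 center 5000 in [4900,5100) -> gB; gZ is not an active gene; the
  # third row contains no center
  expect_equal(nrow(l), 1)
  expect_equal(l$gene_id, "gB")
  expect_equal(l$enhancer_id, "e1")
  expect_message(l0 <- link_fantom5(enh, NULL, mk_genes()), "skipped")
  expect_equal(nrow(l0), 0)
})

test_that("interaction linking joins center and TSS anchors with tissue filter", {
  enh <- mk_enh()
  inter <- data.frame(chromA = "chr1", startA = 200900, endA = 201100,
                      chromB = "chr1", startB = 189000, endB = 191000,
                      tissue = c("liver"), method = "HiC",
                      stringsAsFactors = FALSE)
  l <- link_4dgenome(enh, inter, mk_genes())
  expect_equal(l$enhancer_id, "e2")
  expect_equal(l$gene_id, "gC")
  # inactive genes are never linked
  l2 <- link_4dgenome(enh, inter, mk_genes()[-3, ])
  expect_equal(nrow(l2), 0)
  # tissue filter drops non-matching rows
  l3 <- link_4dgenome(enh, inter, mk_genes(), tissue_filter = "brain")
  expect_equal(nrow(l3), 0)
  l4 <- link_4dgenome(enh, inter, mk_genes(), tissue_filter = "liver")
  expect_equal(nrow(l4), 1)
  # TSS tolerance: anchor B ending 1 bp short of the TSS still matches
  inter5 <- transform(inter, startB = 186000, endB = 188500)
  l5 <- link_4dgenome(enh, inter5, mk_genes(), tss_tol = 2000L)
  expect_equal(nrow(l5), 1)
  l6 <- link_4dgenome(enh, inter5, mk_genes(), tss_tol = 1000L)
  expect_equal(nrow(l6), 0)
})

test_that("binding affinity decays exponentially and handles absent peaks", {
  enh <- mk_enh()[1, , drop = FALSE]
  pk <- function(anchor) data.frame(chrom = "chr1", start = anchor - 100,
                                    end = anchor + 100, anchor = anchor,
                                    score = 1, stringsAsFactors = FALSE)
  expect_equal(binding_affinity_score(enh, pk(5000))$B_s, 1)
  b <- binding_affinity_score(enh, pk(10000), d0 = 5000)
  expect_equal(b$B_s, exp(-1), tolerance = 1e-12)
  expect_equal(b$d, 5000)
  none <- data.frame(chrom = "chr9", start = 1, end = 3, anchor = 2,
                     score = 1, stringsAsFactors = FALSE)
  expect_equal(binding_affinity_score(enh, none)$B_s, 0)
  # monotone non-increasing in distance
  ds <- seq(0, 30000, by = 3000)
  bs <- vapply(ds, function(d) binding_affinity_score(enh, pk(5000 + d))$B_s, 0)
  expect_true(all(diff(bs) <= 0))
  expect_true(all(bs >= 0 & bs <= 1))
})

test_that("the functional score averages indicator-weighted change products", {
  links <- rbind(
    .lk("e1", "g1", "closest"), .lk("e1", "g1", "distance"),
    .lk("e1", "g1", "fantom5"), .lk("e1", "g1", "4dgenome"))
  gc <- c(g1 = 1, g2 = 0.8)
  expect_equal(functional_activity_score("e1", links, 1, gc), 1)
  only_closest <- .lk("e2", "g2", "closest")
  expect_equal(functional_activity_score("e2", only_closest, 0.5, gc),
               0.5 * 0.8 / 4)
  expect_equal(functional_activity_score("e9", links, 1, gc), 0)
  # aggregate over multiple genes within one strategy
  two <- rbind(.lk("e3", "g1", "distance"), .lk("e3", "g2", "distance"))
  expect_equal(functional_activity_score("e3", two, 1, gc), mean(c(1, 0.8)) / 4)
  expect_equal(functional_activity_score("e3", two, 1, gc, aggregate = "max"),
               1 / 4)
})

test_that("change normalization floors at zero and scales the maximum to one", {
  x <- c(a = 2, b = 1, c = -3, d = NA)
  n <- normalize_changes(x)
  expect_equal(unname(n), c(1, 0.5, 0, 0))
  r <- normalize_changes(x, method = "rank")
  expect_equal(unname(r[c("a", "b")]), c(1, 0.5))
  expect_equal(unname(r[c("c", "d")]), c(0, 0))
  expect_equal(unname(normalize_changes(c(x1 = -1, x2 = -2))), c(0, 0))
})

test_that("combined scoring ranks by the convex combination with tie rules", {
  sc <- data.frame(enhancer_id = c("eA", "eB", "eC"),
                   B_s = c(1, 0.2, 0.6), F_s = c(0, 1, 0.6),
                   stringsAsFactors = FALSE)
  r1 <- combined_score_and_rank(sc, w = 1)
  expect_equal(r1$enhancer_id[1], "eA")           # pure binding order
  r0 <- combined_score_and_rank(sc, w = 0)
  expect_equal(r0$enhancer_id[1], "eB")
  rh <- combined_score_and_rank(sc, w = 0.5)
  expect_equal(rh$E_s, c(0.6, 0.6, 0.5), tolerance = 1e-12)
  expect_equal(rh$rank, c(1, 1, 2))               # tie shares the rank
  expect_equal(rh$enhancer_id[1:2], c("eC", "eB"))  # tie broken by B_s
  # E_s strictly increases in F_s at fixed B_s for w < 1
  f <- seq(0, 1, by = 0.1)
  es <- 0.5 * 0.3 + 0.5 * f
  expect_true(all(diff(es) > 0))
})
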