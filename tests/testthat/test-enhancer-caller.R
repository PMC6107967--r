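make_block_cov <- function(blocks) {
  # blocks: data.frame(start, end, strand, rate)
  pos <- integer(); strand <- character()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    p <- seq.int(b$start, b$end - 1L)
    reps <- rep(p, round(b$rate))
    pos <- c(pos, reps)
    strand <- c(strand, rep(b$strand, length(reps)))
  }
  cov_from_reads("chr1", pos, strand)
}

test_that("a uniform signal block is called as one transcript within a window", {
  cov <- make_block_cov(data.frame(start = 1000L, end = 3000L,
                                   strand = "+", rate = 10))
  p <- transcript_caller_params()
  tx <- call_transcripts(cov, p)
  expect_equal(nrow(tx), 1)
  expect_equal(tx$strand, "+")
  expect_lte(abs(tx$start - 1000), p$window)
  expect_lte(abs(tx$end - 3000), p$window)
  expect_equal(tx$five_prime, tx$start)
  expect_equal(tx$read_count,
               count_region(cov, genome_interval("chr1", tx$start, tx$end, "+")))
})

test_that("empty coverage yields no transcripts", {
  cov <- cov_from_reads("chr1", integer(), "+")
  expect_equal(nrow(call_transcripts(cov)), 0)
})

test_that("blocks separated by far more than max_gap stay distinct", {
  p <- transcript_caller_params()
  cov <- make_block_cov(data.frame(
    start = c(1000L, 1000L + 2000L + 10L * p$max_gap),
    end = c(3000L, 3000L + 2000L + 10L * p$max_gap),
    strand = "+", rate = 10))
  tx <- call_transcripts(cov, p)
  expect_equal(nrow(tx), 2)
})

test_that("sub-threshold signal is not called", {
  # density equal to the pseudo-background floor: below every fold threshold
  cov <- make_block_cov(data.frame(start = 1000L, end = 21000L,
                                   strand = "+", rate = 1))
  p <- transcript_caller_params(bg_density = 1)
  expect_equal(nrow(call_transcripts(cov, p)), 0)
})

test_that("intergenic filtering removes the -2kb/+20kb neighborhood of genes", {
  genes <- gene_row("g1", strand = "+", start = 10000L, end = 20000L)
  tx <- rbind(tx_row(25000, 26000, "+"),    # within +20 kb of the TTS
              tx_row(41000, 42000, "+"),    # beyond the window
              tx_row(12000, 13000, "-"),    # overlapping the body, antisense
              tx_row(7500, 8200, "+"))      # within -2 kb of the TSS
  kept <- filter_intergenic(tx, genes)
  expect_equal(kept$start, 41000)
  # minus-strand gene mirrors the extension
  genes_m <- gene_row("g2", strand = "-", start = 50000L, end = 60000L)
  tx2 <- rbind(tx_row(61000, 61500, "+"),   # within +2 kb upstream of TSS
               tx_row(63000, 63500, "+"),   # beyond
               tx_row(31000, 31500, "+"),   # within 20 kb downstream of TTS
               tx_row(29000, 29500, "+"))   # beyond
  kept2 <- filter_intergenic(tx2, genes_m)
  expect_equal(sort(kept2$start), c(29000, 63000))
})

test_that("divergent 5'-end pairing applies the inclusive distance rule", {
  # distance 199, overlapping 5' ends
  e <- pair_bidirectional(rbind(tx_row(1000, 3000, "+"),
                                tx_row(200, 1200, "-")))
  expect_equal(nrow(e), 1)
  expect_equal(e$centers, "1099")
  expect_equal(c(e$start, e$end), c(200, 3000))

  # distance exactly 400 pairs (inclusive): minus 5' at 1600, plus 5' at 2000
  e400 <- pair_bidirectional(rbind(tx_row(2000, 4000, "+"),
                                   tx_row(500, 1601, "-")))
  expect_equal(nrow(e400), 1)
  expect_equal(e400$centers, as.character((2000 + 1600) %/% 2))

  # distance 401 does not pair
  e401 <- pair_bidirectional(rbind(tx_row(2000, 4000, "+"),
                                   tx_row(500, 1600, "-")))
  expect_equal(nrow(e401), 0)
})

test_that("full containment sets the center at the short transcript's 5' end", {
  e <- pair_bidirectional(rbind(tx_row(1000, 3000, "+"),
                                tx_row(1500, 1800, "-")))
  expect_equal(e$centers, "1799")
  # convergent non-contained geometry never pairs
  conv <- pair_bidirectional(rbind(tx_row(1000, 2000, "+"),
                                   tx_row(1900, 3500, "-")))
  expect_equal(nrow(conv), 0)
})

test_that("pairing output is invariant to transcript input order", {
  tx <- rbind(tx_row(1000, 5000, "+"), tx_row(600, 1200, "-"),
              tx_row(2000, 2600, "-"), tx_row(9000, 9900, "+"),
              tx_row(8800, 9300, "-"))
  e1 <- pair_bidirectional(tx)
  set.seed(2)
  for (i in 1:5) {
    e2 <- pair_bidirectional(tx[sample(nrow(tx)), ])
    expect_equal(e2, e1, ignore_attr = TRUE)
  }
})

test_that("merging applies the strict gap rule transitively and idempotently", {
  pre <- pair_bidirectional(rbind(
    tx_row(1000, 2000, "+"), tx_row(400, 1100, "-"),
    tx_row(2400, 2600, "+"), tx_row(2100, 2500, "-")))
  expect_equal(nrow(pre), 2)
  m <- merge_enhancers(pre)   # gap 2100 - 2000 = 100 < 500
  expect_equal(nrow(m), 1)
  expect_equal(m$n_centers, 2)
  expect_equal(c(m$start, m$end), c(400, 2600))
  m2 <- merge_enhancers(m)
  expect_equal(m2$centers, m$centers)
  expect_equal(nrow(m2), 1)

  # gap construction at the strict boundary
  mk <- function(gap) {
    # first hull ends at 2000; second hull starts at 2000 + gap
    a <- pair_bidirectional(rbind(tx_row(1000, 2000, "+"),
                                  tx_row(400, 1100, "-")))
    b <- pair_bidirectional(rbind(tx_row(2600 + gap, 3600 + gap, "+"),
                                  tx_row(2000 + gap, 2700 + gap, "-")))
    merge_enhancers(rbind(a, b))
  }
  expect_equal(nrow(mk(499L)), 1)
  expect_equal(nrow(mk(500L)), 2)
})

test_that("merged enhancer gaps are all at least merge_gap", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 12
    anchors <- sort(sample(seq(1000, 200000, by = 100), n))
    tx <- do.call(rbind, lapply(anchors, function(a)
      rbind(tx_row(a, a + 700, "+"), tx_row(a - 700, a + 50, "-"))))
    m <- merge_enhancers(pair_bidirectional(tx))
    if (nrow(m) > 1) {
      gaps <- m$start[-1] - m$end[-nrow(m)]
      expect_true(all(gaps >= 500))
    }
  }
})

test_that("every pairing scenario fixture yields its expected centers", {
  for (name in names(scenario_fixtures())) {
    sc <- scenario_fixtures()[[name]]
    enh <- merge_enhancers(pair_bidirectional(sc$transcripts))
    expect_equal(nrow(enh), sc$expected_enhancers, label = name)
    expect_equal(enh_centers_of(enh), sort(sc$expected_centers),
                 label = name)
  }
})

test_that("known/novel annotation is decided by center containment", {
  enh <- merge_enhancers(pair_bidirectional(rbind(
    tx_row(1000, 3000, "+"), tx_row(200, 1200, "-"))))   # center 1099
  known_in <- data.frame(chrom = "chr1", start = 1050, end = 1300,
                         id = "K1", stringsAsFactors = FALSE)
  a <- annotate_enhancers(enh, known_in)
  expect_true(a$is_known)
  expect_equal(a$known_ids, "K1")
  # region overlap without center containment stays novel
  known_out <- data.frame(chrom = "chr1", start = 2000, end = 2500,
                          id = "K2", stringsAsFactors = FALSE)
  b <- annotate_enhancers(enh, known_out)
  expect_false(b$is_known)
  expect_warning(annotate_enhancers(enh, NULL), "novel")
})

test_that("enhancer quantification sums both strands and scales linearly", {
  enh <- merge_enhancers(pair_bidirectional(rbind(
    tx_row(1000, 3000, "+"), tx_row(200, 1200, "-"))))
  cov <- cov_from_reads("chr1",
                        c(rep(1500L, 7), rep(800L, 5)),
                        c(rep("+", 7), rep("-", 5)))
  m <- quantify_enhancers(enh, list(s1 = cov))
  expect_equal(unname(m[1, 1]), 12)
  m2 <- quantify_enhancers(enh, list(s1 = cov, s2 = pool_coverage(
    list(cov, cov))))
  expect_equal(unname(m2[1, 2]), 24)
})

test_that("long-eRNA extraction applies the strict length rule and precedence", {
  long_tx <- tx_row(100000, 115000, "+")
  at_thresh <- tx_row(200000, 210000, "+")      # exactly 10 kb: excluded
  over_thresh <- tx_row(300000, 310001, "+")    # 10,001 bp: included
  tx <- rbind(long_tx, at_thresh, over_thresh)
  le <- extract_long_ernas(tx)
  expect_equal(sort(le$start), c(100000, 300000))
  expect_equal(le$tss[le$start == 100000], 100000)

  # a paired 15 kb transcript becomes an enhancer, not a long eRNA
  paired <- rbind(tx_row(100000, 115000, "+"), tx_row(99800, 100300, "-"))
  pre <- pair_bidirectional(paired)
  expect_equal(nrow(pre), 1)
  le2 <- extract_long_ernas(paired, attr(pre, "paired_tx"))
  expect_equal(nrow(le2), 0)

  # minus-strand 5' end maps to the transcript end
  lem <- extract_long_ernas(tx_row(50000, 70000, "-"))
  expect_equal(lem$tss, 70000)
  expect_equal(lem$tts, 50000)
})
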