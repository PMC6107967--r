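test_that("RLE size factors reproduce hand median-of-ratios", {
  m <- rbind(c(2, 4), c(4, 8), c(6, 12))
  sf <- rle_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(sf), unname(hand_rle(m)), tolerance = 1e-12)

  ident <- matrix(rpois(30, 50), ncol = 3)
  ident <- cbind(ident[, 1], ident[, 1], ident[, 1])
  expect_equal(unname(rle_size_factors(ident)), rep(1, 3))

  single <- matrix(1:5, ncol = 1)
  expect_equal(unname(rle_size_factors(single)), 1)

  allz <- rbind(c(0, 5), c(3, 0))
  expect_error(rle_size_factors(allz), "user normalization factors")
})

test_that("RLE matches the hand oracle on random matrices and is scale-equivariant", {
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(rnbinom(40 * 4, mu = 100, size = 5) + 1, ncol = 4)
    expect_equal(unname(rle_size_factors(m)), unname(hand_rle(m)),
                 tolerance = 1e-12)
    k <- runif(1, 0.5, 3)
    m2 <- m; m2[, 2] <- round(m2[, 2] * k)
    sf <- rle_size_factors(m)
    sf2 <- rle_size_factors(m2)
    # scaling one sample by k scales its factor by k relative to the others
    # (absolute factors renormalize through the geometric-mean reference)
    expect_equal(unname((sf2[2] / sf2[1]) / (sf[2] / sf[1])), k,
                 tolerance = 0.05)
  }
})

test_that("nb_differential returns null results for identical counts", {
  m <- matrix(rep(c(100, 250, 7, 0), each = 4), ncol = 4, byrow = TRUE)
  rownames(m) <- paste0("f", 1:4)
  res <- nb_differential(m, c("a", "a", "b", "b"))
  expect_equal(res$log2fc[1:3], rep(0, 3))
  expect_true(all(res$p[1:3] > 0.9))
  # all-zero feature excluded from testing
  expect_true(is.na(res$p[4]))
  expect_true(is.na(res$fdr[4]))
})

test_that("nb_differential type-I error is near nominal and effects are unbiased", {
  set.seed(42)
  n <- 2500
  mu <- exp(runif(n, log(20), log(2000)))
  m <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 1 / 0.05))
  rownames(m) <- paste0("f", 1:n)
  res <- nb_differential(m, c("a", "a", "b", "b"))
  t1 <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gte(t1, 0.03)
  expect_lte(t1, 0.07)

  n2 <- 500
  m2 <- cbind(sapply(1:2, function(j) rnbinom(n2, mu = 200, size = 1 / 0.01)),
              sapply(1:2, function(j) rnbinom(n2, mu = 800, size = 1 / 0.01)))
  rownames(m2) <- paste0("g", 1:n2)
  r2 <- nb_differential(m2, c("a", "a", "b", "b"), size_factors = rep(1, 4))
  expect_lt(abs(mean(r2$log2fc) - 2), 0.3)
  expect_gt(mean(r2$fdr < 0.05), 0.95)
})

test_that("nb_differential log2FC direction and BH monotonicity", {
  set.seed(8)
  n <- 300
  m <- cbind(rnbinom(n, mu = 100, size = 20), rnbinom(n, mu = 100, size = 20),
             rnbinom(n, mu = 400, size = 20), rnbinom(n, mu = 400, size = 20))
  rownames(m) <- paste0("f", 1:n)
  res <- nb_differential(m, c("wt", "wt", "ko", "ko"),
                         size_factors = rep(1, 4))
  expect_gt(median(res$log2fc), 1.5)
  o <- order(res$p)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
  expect_true(all(res$fdr >= res$p - 1e-12))
})

test_that("fold changes and calls agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  n <- 400
  mu <- exp(runif(n, log(30), log(1000)))
  lfc_true <- sample(c(0, 0, 0, 1.5, -1.5), n, replace = TRUE)
  m <- cbind(sapply(1:2, function(j) rnbinom(n, mu = mu, size = 1 / 0.05)),
             sapply(1:2, function(j) rnbinom(n, mu = mu * 2^lfc_true,
                                             size = 1 / 0.05)))
  rownames(m) <- paste0("f", 1:n)
  colnames(m) <- paste0("s", 1:4)
  mine <- nb_differential(m, c("a", "a", "b", "b"))

  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(condition = factor(c("a", "a", "b", "b"))), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)

  ok <- !is.na(mine$log2fc) & !is.na(ref$log2FoldChange)
  expect_gt(cor(mine$log2fc[ok], ref$log2FoldChange[ok]), 0.95)
  # significance calls mostly coincide at FDR 0.05
  both <- table(mine = mine$fdr[ok] < 0.05, ref = ref$padj[ok] < 0.05)
  agree <- sum(diag(both)) / sum(both)
  expect_gt(agree, 0.85)
})

test_that("one sample per condition falls back to trend dispersion", {
  m <- matrix(c(100, 200, 50, 50, 10, 40), ncol = 2, byrow = TRUE)
  rownames(m) <- paste0("f", 1:3)
  res <- nb_differential(m, c("a", "b"), size_factors = c(1, 1))
  expect_true(attr(res, "single_replicate"))
  expect_true(all(is.finite(res$p)))
})

test_that("two-sided Fisher pausing-change test matches brute-force summation", {
  null <- pindex_change_fisher(10, 100, 10, 100)
  expect_equal(null$p, 1)
  expect_equal(null$odds_ratio, 1, tolerance = 1e-6)

  up <- pindex_change_fisher(40, 100, 10, 100)
  expect_gt(up$odds_ratio, 1)
  expect_equal(up$p, brute_fisher_two_sided(40, 100, 10, 100),
               tolerance = 1e-9)
  # swapping rows inverts the odds ratio but keeps p
  sw <- pindex_change_fisher(10, 100, 40, 100)
  expect_equal(sw$p, up$p, tolerance = 1e-12)
  expect_equal(sw$odds_ratio, 1 / up$odds_ratio, tolerance = 1e-6)
  # zero margin
  z <- pindex_change_fisher(0, 0, 5, 10)
  expect_equal(z$p, 1)
  expect_true(is.na(z$odds_ratio))
})

test_that("CMH test matches the textbook Mantel-Haenszel formulas", {
  t_null <- rbind(c(10, 100), c(10, 100))
  null <- pindex_change_cmh(list(t_null, t_null))
  expect_equal(null$common_or, 1, tolerance = 1e-9)
  expect_gt(null$p, 0.9)

  t_up <- rbind(c(40, 100), c(10, 100))
  res <- pindex_change_cmh(list(t_up, t_up))
  oracle <- mh_formulas(list(t_up, t_up))
  expect_equal(res$common_or, oracle$common_or, tolerance = 1e-9)
  expect_equal(res$p, oracle$p, tolerance = 1e-9)

  # one enriched and one inverted stratum of equal weight cancel
  t_dn <- rbind(c(10, 100), c(40, 100))
  canc <- pindex_change_cmh(list(t_up, t_dn))
  expect_equal(canc$common_or, 1, tolerance = 1e-9)

  # degenerate strata
  degen <- list(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(is.na(pindex_change_cmh(degen)$common_or))
})

test_that("CMH agrees in direction with Fisher on a shared table", {
  t_up <- rbind(c(40, 100), c(10, 100))
  f <- pindex_change_fisher(40, 100, 10, 100)
  c2 <- pindex_change_cmh(list(t_up, t_up))
  expect_true((f$odds_ratio > 1) == (c2$common_or > 1))
})

test_that("replicate histograms center at zero after RLE and expose shifts", {
  set.seed(13)
  base <- rnbinom(400, mu = 300, size = 50) + 1
  # proportional replicates: RLE removes the scale entirely
  m <- cbind(base, base * 3)
  colnames(m) <- c("r1", "r2")
  h <- replicate_change_histogram(m, c("c1", "c1"))
  hc <- h[["c1"]]
  expect_equal(sum(hc$count[abs(hc$mid) < 0.06]), 400)

  # 2x global shift with unit factors: mode at log2FC = 1
  m2 <- cbind(base * 2, base)
  colnames(m2) <- c("r1", "r2")
  h2 <- replicate_change_histogram(m2, c("c1", "c1"),
                                   size_factors = c(1, 1))
  hc2 <- h2[["c1"]]
  expect_equal(hc2$mid[which.max(hc2$count)], 1, tolerance = 0.06)

  # single replicate skipped with a notice
  expect_message(
    h3 <- replicate_change_histogram(matrix(base, ncol = 1,
                                            dimnames = list(NULL, "r1")),
                                     "c1", size_factors = 1),
    "single replicate")
  expect_length(h3, 0)
})
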