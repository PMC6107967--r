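# Independent oracles and fixture builders shared across test files.
# These deliberately use naive direct computations (explicit loops,
# hypergeometric summation, textbook formulas) so they stay independent of
# the package's own code paths.

# Coverage from explicit read positions (1 bp reads), via the public BED
# loader so fixtures exercise the real input path.
cov_from_reads <- function(chrom, pos, strand, dir = tempdir()) {
  path <- tempfile("reads", tmpdir = dir, fileext = ".bed")
  if (length(pos)) {
    writeLines(sprintf("%s\t%d\t%d\t.\t0\t%s", chrom, pos, pos + 1L, strand),
               path)
  } else {
    file.create(path)
  }
  load_alignments(path)
}

# One-row gene annotation in the package's internal shape.
gene_row <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     start = 10000L, end = 30000L) {
  tss <- if (strand == "+") start else end
  tts <- if (strand == "+") end else start
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = start, end = end, tss = tss, tts = tts,
             length = end - start, stringsAsFactors = FALSE)
}

# Brute-force promoter-proximal window scan: literal loop over every window,
# counting reads by subsetting the raw position vector.
brute_pp_scan <- function(read_pos, read_cnt, tss, strand,
                          window = 50L, step = 5L, span = 500L) {
  starts <- seq.int(tss - span, tss + span - window, by = step)
  starts <- starts[starts >= 0L]
  counts <- vapply(starts, function(s)
    sum(read_cnt[read_pos >= s & read_pos < s + window]), 0)
  centers <- starts + window / 2
  upstream <- if (strand == "+") starts else -starts
  o <- order(-counts, abs(centers - tss), upstream)
  list(start = starts[o[1]], count = counts[o[1]])
}

# Brute-force one-sided (enrichment) Fisher p by hypergeometric summation.
brute_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  sum(stats::dhyper(a:hi, r1, r2, c1))
}

# Brute-force two-sided Fisher p: sum of all conditional table probabilities
# not exceeding the observed one (with fisher.test's relative tolerance).
brute_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook Mantel-Haenszel common odds ratio and continuity-corrected CMH
# chi-square p over a list of 2x2 tables.
mh_formulas <- function(strata) {
  num <- 0; den <- 0; a_sum <- 0; e_sum <- 0; v_sum <- 0
  for (t in strata) {
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
    n <- a + b + c + d
    num <- num + a * d / n
    den <- den + b * c / n
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    a_sum <- a_sum + a
    e_sum <- e_sum + r1 * c1 / n
    v_sum <- v_sum + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  stat <- (abs(a_sum - e_sum) - 0.5)^2 / v_sum
  list(common_or = num / den,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Hand median-of-ratios size factors.
hand_rle <- function(m) {
  pos <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[pos, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  apply(m[pos, , drop = FALSE], 2, function(col) median(col / geo))
}

# Transcript rows in the caller's output shape, for pairing/merging tests.
tx_row <- function(start, end, strand, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand,
             five_prime = ifelse(strand == "+", as.integer(start),
                                 as.integer(end) - 1L),
             read_count = 0, length = as.integer(end - start),
             stringsAsFactors = FALSE)
}

enh_centers_of <- function(enh)
  sort(unlist(lapply(enh$centers, function(s)
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))))
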