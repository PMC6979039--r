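test_that("IUPAC symbols map to uniform base sets", {
  m <- iupac_to_pwm("NRA", pseudocount = 0)
  expect_equal(unname(m$probs[, 1]), rep(0.25, 4))
  expect_equal(unname(m$probs[, 2]), c(0.5, 0, 0.5, 0))   # R = A/G
  expect_equal(unname(m$probs[, 3]), c(1, 0, 0, 0))
  expect_error(iupac_to_pwm("ACXG"), "non-IUPAC")
})

test_that("log-odds follow the pseudocount arithmetic", {
  # uniform column, uniform background: all zeros
  u <- motif_model(matrix(1, 4, 2), pseudocount = 0)
  expect_equal(unname(u$log_odds), matrix(0, 4, 2))
  # certain base, no pseudocount: ln(1 / 0.25)
  c1 <- motif_model(matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(c1$log_odds[1, 1]), log(4))
  # counts (8,0,0,0), pseudocount 1: ln((9/12) / 0.25) = ln(3)
  c2 <- motif_model(matrix(c(8, 0, 0, 0), 4, 1), pseudocount = 1)
  expect_equal(unname(c2$log_odds[1, 1]), log(3))
  expect_error(motif_model(matrix(1, 4, 1),
                           background = c(0.5, 0.5, 0, 0)),
               "background")
})

test_that("normalized score is exactly 1 at the consensus and 0 at the anti-word", {
  set.seed(5)
  counts <- matrix(rexp(4 * 7), 4, 7)
  m <- motif_model(counts, pseudocount = 0.1)
  best <- sum(apply(m$log_odds, 2, max))
  worst <- sum(apply(m$log_odds, 2, min))
  expect_equal(normalized_score(m, best), 1)
  expect_equal(normalized_score(m, worst), 0)
  word <- consensus_word(m)
  expect_equal(nchar(word), 7L)
})

test_that("lattice p-values are exact against full enumeration (L <= 8)", {
  for (L in c(3L, 5L, 8L)) {
    set.seed(L)
    counts <- matrix(rexp(4 * L) * 10, 4, L)
    m <- motif_model(counts, pseudocount = 0.5)
    g <- 1e-3
    thresholds <- quantile(c(m$min_score, m$max_score), c(0.2, 0.5, 0.9))
    for (t in c(thresholds, m$max_score)) {
      p_dp <- pwm_pvalue(m, t, granularity = g)
      exact <- oracle_pwm_tail(m$log_odds, m$background, t)
      relaxed <- oracle_pwm_tail(m$log_odds, m$background, t - (L + 1) * g)
      expect_gte(p_dp + 1e-12, exact)      # guaranteed upper bound
      expect_lte(p_dp, relaxed + 1e-12)    # within one lattice step
      expect_gte(exact + 1e-12, attr(p_dp, "lower"))
    }
  }
})

test_that("a unique-consensus trinucleotide has consensus p-value 1/64", {
  m <- iupac_to_pwm("ACG", pseudocount = 1e-6)
  expect_equal(as.numeric(pwm_pvalue(m, m$max_score)), 1 / 64)
  expect_equal(as.numeric(pwm_pvalue(m, m$min_score)), 1)
})

test_that("p-values are monotone nonincreasing in the raw score", {
  set.seed(9)
  m <- motif_model(matrix(rexp(4 * 6), 4, 6), pseudocount = 0.2)
  ts <- seq(m$min_score, m$max_score, length.out = 25)
  ps <- vapply(ts, function(t) as.numeric(pwm_pvalue(m, t)), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("scanning finds planted words with exact coordinates and strands", {
  m <- iupac_to_pwm("GGTCAC", pseudocount = 1e-6)
  set.seed(11)
  bg <- paste(sample(c("A", "C"), 300, replace = TRUE), collapse = "")
  seq_plus <- paste0(substr(bg, 1, 100), "GGTCAC", substr(bg, 107, 300))
  h <- scan_sequence(m, seq_plus, min_normalized_score = 1)
  expect_equal(h$start, 100L)
  expect_equal(h$end, 106L)
  expect_equal(h$strand, "+")
  expect_equal(h$normalized_score, 1)

  # reverse-complement planted: minus-strand hit on the same interval
  seq_minus <- paste0(substr(bg, 1, 100), "GTGACC", substr(bg, 107, 300))
  hm <- scan_sequence(m, seq_minus, min_normalized_score = 1)
  expect_equal(hm$start, 100L)
  expect_equal(hm$strand, "-")

  # threshold 1 on a consensus-free sequence is empty (A/C-only background
  # cannot contain GGTCAC or its reverse complement)
  expect_equal(nrow(scan_sequence(m, bg, min_normalized_score = 1)), 0L)
})

test_that("minus-strand scanning equals scanning the reverse complement", {
  m <- motif_model(matrix(rexp(4 * 5), 4, 5), pseudocount = 0.3)
  set.seed(12)
  sq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  fwd_on_rc <- scan_sequence(m, rc, 0.6, both_strands = FALSE)
  minus_on_sq <- scan_sequence(m, sq, 0.6)
  minus_on_sq <- minus_on_sq[minus_on_sq$strand == "-", ]
  # map [s, e) on the reverse complement to forward coordinates
  mapped <- sort(400 - fwd_on_rc$end)
  expect_equal(sort(minus_on_sq$start), mapped)
  expect_equal(sort(minus_on_sq$raw_score), sort(fwd_on_rc$raw_score),
               tolerance = 1e-12)
})

test_that("ambiguous bases skip windows with a message", {
  m <- iupac_to_pwm("ACGT", pseudocount = 1e-6)
  expect_message(h <- scan_sequence(m, "ACGTNACGT", 0.5), "skipped")
  expect_true(all(h$start %in% c(0L, 5L)))
})

test_that("fimo_scan scores every window and its q-values follow BH", {
  m <- iupac_to_pwm("ACGTAC", pseudocount = 0.01)
  set.seed(13)
  sq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  all_hits <- fimo_scan(m, sq, q_threshold = 1.01)
  expect_equal(attr(all_hits, "n_scored"), 2L * (200L - 6L + 1L))
  o <- order(all_hits$p_value)
  expect_true(all(diff(all_hits$q_value[o]) >= -1e-12))
})

test_that("promoter extraction follows the upstream-window arithmetic", {
  set.seed(14)
  src <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  seqs <- c(chrA = src)
  p <- extract_promoter(seqs, "geneP", "chrA", tss = 3000, length = 2400,
                        strand = "+")
  expect_equal(c(p$start, p$end), c(600, 3000))
  expect_identical(p$sequence, substr(src, 601, 3000))

  pm <- extract_promoter(seqs, "geneM", "chrA", tss = 600, length = 288,
                         strand = "-")
  expect_equal(c(pm$start, pm$end), c(600, 888))
  expect_identical(
    pm$sequence,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(src, 601, 888)))))

  # nested windows: the 288 bp region is the TSS-adjacent suffix of the
  # 480 bp region
  p480 <- extract_promoter(seqs, "geneP", "chrA", 3000, 480, "+")
  p288 <- extract_promoter(seqs, "geneP", "chrA", 3000, 288, "+")
  expect_identical(substr(p480$sequence, 480 - 288 + 1, 480), p288$sequence)

  expect_error(extract_promoter(seqs, "g", "chrA", 3500, 100, "+"), "TSS")
  expect_error(extract_promoter(seqs, "g", "chrA", 100, 2400, "+"),
               "outside")
  tr <- extract_promoter(seqs, "g", "chrA", 100, 2400, "+",
                         allow_truncation = TRUE)
  expect_true(tr$truncated)
  expect_equal(tr$length, 100)
})

test_that("region restriction applies the inclusive/exclusive window bounds", {
  hits <- data.frame(sequence_id = "p", start = c(2000, 2112, 1915),
                     end = c(2006, 2118, 1921), strand = "+",
                     motif_id = "m",
                     raw_score = 1, normalized_score = 1,
                     p_value = NA_real_, q_value = NA_real_)
  # TSS-relative: [-400,-394) kept; [-288,-282) dropped; [-485,-479) kept
  out <- restrict_to_region(hits, promoter_length = 2400,
                            window = c(-480, -288))
  expect_setequal(out$start, c(2000, 1915))
})

test_that("MEME and JASPAR parsers round-trip motif content", {
  mots <- list(iupac_to_pwm("RGKTCA", motif_id = "half"),
               iupac_to_pwm("ACGT", motif_id = "tiny"))
  names(mots) <- c("half", "tiny")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(mots, path)
  back <- read_meme(path, pseudocount = 0.01)
  expect_setequal(names(back), c("half", "tiny"))
  expect_equal(back$half$probs, mots$half$probs, tolerance = 1e-5)
  expect_identical(consensus_word(back$half), consensus_word(mots$half))

  jas <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TestTF",
               "A  [ 4  19  0  0  0 ]",
               "C  [16   0 20  0  0 ]",
               "G  [ 0   1  0 20  0 ]",
               "T  [ 0   0  0  0 20 ]"), jas)
  jm <- read_jaspar(jas)
  expect_identical(names(jm), "TestTF")
  expect_equal(motif_length <- ncol(jm$TestTF$probs), 5L)
  expect_identical(consensus_word(jm$TestTF), "CACGT")
})
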