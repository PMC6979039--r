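toy_network <- function() {
  edges <- data.frame(
    tf = c("A", "A", "B", "A"),
    target = c("g1", "g2", "g1", "B"),
    mi = 1, p_value = 0.001, q_value = 0.001)
  structure(list(edges = edges, tf_list = c("A", "B"),
                 gene_list = c("A", "B", "g1", "g2"), config = NULL),
            class = "regulatory_network")
}

test_that("regulon extraction applies the size threshold and TF-TF symmetry", {
  net <- toy_network()
  regs <- extract_regulons(net, min_regulon_size = 2L)
  expect_setequal(regs$A$targets, c("g1", "g2", "B"))
  expect_equal(regs$B$targets, c("A", "g1"))          # A via the TF-TF edge
  regs1 <- extract_regulons(net, min_regulon_size = 3L)
  expect_false("B" %in% names(regs1))                 # below threshold
  expect_true("A" %in% names(regs1))
})

test_that("enrichment score reproduces the hand-worked extremes", {
  sig <- ranked_signature(paste0("g", 1:5), c(5, 4, 3, 2, 1))
  expect_equal(enrichment_score(sig, "g1")$es, 1.0)    # top gene: hit 5/5 first
  expect_equal(enrichment_score(sig, "g5")$es, -1.0)   # four misses of 1/4 each
  expect_equal(enrichment_score(sig, paste0("g", 1:5))$es, 1.0)  # no misses
  expect_error(enrichment_score(sig, "absent"), "no overlap")
})

test_that("enrichment score equals the brute-force running sum on random cases", {
  for (s in 1:50) {
    case <- random_signature_case(s)
    got <- enrichment_score(case$sig, case$members)
    want <- oracle_enrichment_score(case$sig$gene, case$sig$score,
                                    case$members)
    expect_equal(got$es, want, tolerance = 1e-12, label = paste("seed", s))
    expect_lte(abs(got$es), 1)
    expect_equal(got$running_sum[length(got$running_sum)], 0,
                 tolerance = 1e-12)
  }
})

test_that("the fast hit-position path agrees with the full running sum", {
  for (s in 101:140) {
    case <- random_signature_case(s)
    full <- enrichment_score(case$sig, case$members)$es
    w <- abs(case$sig$score)
    pos <- sort(which(case$sig$gene %in% case$members))
    fast <- mrascan:::es_from_hits(pos, w, nrow(case$sig))
    expect_equal(fast, full, tolerance = 1e-12, label = paste("seed", s))
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  for (s in 1:25) {
    case <- random_signature_case(s + 500)
    stats <- setNames(case$sig$score, case$sig$gene)
    fg <- fgsea::calcGseaStat(
      stats, selectedStats = which(case$sig$gene %in% case$members),
      gseaParam = 1)
    expect_equal(enrichment_score(case$sig, case$members)$es, fg,
                 tolerance = 1e-9, label = paste("seed", s))
  }
})

test_that("gsea_test is seeded, signed consistently, and detects separation", {
  set.seed(1)
  genes <- paste0("g", 1:200)
  scores <- c(rnorm(20, 8), rnorm(180))
  sig <- ranked_signature(genes, scores)
  reg <- structure(list(tf = "TF1", targets = paste0("g", 1:20)),
                   class = "regulon")
  r1 <- gsea_test(sig, reg, n_permutations = 1000L, seed = 7L)
  r2 <- gsea_test(sig, reg, n_permutations = 1000L, seed = 7L)
  expect_identical(r1, r2)
  expect_lte(r1$p_value, 0.01)
  expect_equal(sign(r1$nes), sign(r1$es))
  # depleted set gives a negative score with matching NES sign
  regneg <- structure(list(tf = "TF2", targets = paste0("g", 181:200)),
                      class = "regulon")
  rn <- gsea_test(sig, regneg, n_permutations = 1000L, seed = 7L)
  expect_lt(rn$es, 0)
  expect_equal(sign(rn$nes), sign(rn$es))
})

test_that("run_mra flags the planted regulator and controls the null", {
  set.seed(2)
  genes <- paste0("g", 1:300)
  regulons <- lapply(1:12, function(i) {
    structure(list(tf = paste0("TF", i),
                   targets = sample(genes, 15)), class = "regulon")
  })
  names(regulons) <- paste0("TF", 1:12)
  scores <- rnorm(300)
  scores[genes %in% regulons$TF5$targets] <-
    rnorm(15, mean = 8)                     # TF5 is the planted regulator
  sig <- ranked_signature(genes, scores)
  res <- run_mra(regulons, sig, n_permutations = 2000L, seed = 9L)
  expect_identical(res$tf[res$is_master_regulator], "TF5")
  expect_equal(res$tf[1], "TF5")            # smallest p-value
  # null signature: essentially no candidates at FDR 0.01
  null_sig <- ranked_signature(genes, rnorm(300))
  res0 <- run_mra(regulons, null_sig, n_permutations = 500L, seed = 10L)
  expect_equal(sum(res0$is_candidate), 0L)
  # q-values are a monotone transform of p-values
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  # tightening the FDR never grows the candidate set
  res_tight <- run_mra(regulons, sig, n_permutations = 2000L,
                       candidate_fdr = 0.001, seed = 9L)
  expect_true(all(res_tight$tf[res_tight$is_candidate] %in%
                    res$tf[res$is_candidate]))
})

test_that("a single tested TF cannot exceed its own |NES| percentile", {
  set.seed(3)
  genes <- paste0("g", 1:100)
  scores <- c(rnorm(15, 10), rnorm(85))
  sig <- ranked_signature(genes, scores)
  regulons <- list(TF1 = structure(list(tf = "TF1",
                                        targets = paste0("g", 1:15)),
                                   class = "regulon"))
  res <- run_mra(regulons, sig, n_permutations = 2000L, seed = 4L)
  expect_lte(res$p_value, 0.001)
  expect_true(res$is_candidate)
  expect_false(res$is_master_regulator)     # strict > against itself fails
})

test_that("untested TFs are reported, not dropped", {
  genes <- paste0("g", 1:50)
  sig <- ranked_signature(genes, rnorm(50))
  regulons <- list(
    TF1 = structure(list(tf = "TF1", targets = genes[1:12]),
                    class = "regulon"),
    TF2 = structure(list(tf = "TF2", targets = paste0("x", 1:12)),
                    class = "regulon"))
  res <- run_mra(regulons, sig, n_permutations = 200L, seed = 1L)
  expect_equal(nrow(res), 2L)
  expect_true(is.na(res$p_value[res$tf == "TF2"]))
  expect_false(res$is_master_regulator[res$tf == "TF2"])
  # nothing testable at all is an error
  expect_error(run_mra(regulons["TF2"], sig, n_permutations = 100L),
               "testable")
})

test_that("rank files round-trip and keep the descending order", {
  sig <- ranked_signature(c("b", "a", "c"), c(1, 3, 2))
  expect_identical(sig$gene, c("a", "c", "b"))
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(sig, path)
  expect_identical(read_rnk(path), sig)
  expect_error(ranked_signature(c("a", "a"), c(1, 2)), "unique")
})
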