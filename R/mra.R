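#' Extract regulons from a regulatory network
#'
#' A TF's regulon is every gene connected to it in the network. TF-TF edges
#' (stored once, unordered) contribute each TF to the other's regulon. TFs
#' with fewer than `min_regulon_size` connected genes are dropped:
#' enrichment statistics degenerate for tiny sets.
#'
#' @param network a `regulatory_network` (or list with `edges`, `tf_list`).
#' @param min_regulon_size smallest regulon retained.
#' @return named list of regulons; each is `list(tf =, targets =)` of class
#'   `regulon`.
#' @export
extract_regulons <- function(network, min_regulon_size = 10L) {
  e <- network$edges
  tfs <- network$tf_list
  out <- list()
  for (tf in sort(tfs)) {
    targets <- sort(unique(c(e$target[e$tf == tf], e$tf[e$target == tf])))
    targets <- setdiff(targets, tf)
    if (length(targets) >= min_regulon_size)
      out[[tf]] <- structure(list(tf = tf, targets = targets),
                             class = "regulon")
  }
  out
}

#' Ranked differential-expression signature
#'
#' Validates and sorts a two-column (gene, score) table descending by
#' score; ties are broken by gene id so the ordering is deterministic.
#'
#' @param genes character vector of unique gene ids, or a two-column data
#'   frame.
#' @param scores numeric ranking statistic (e.g. a differential-expression
#'   t-statistic), one per gene.
#' @return data frame of class `ranked_signature` with columns `gene`,
#'   `score`, sorted descending.
#' @export
ranked_signature <- function(genes, scores = NULL) {
  if (is.data.frame(genes)) {
    scores <- genes[[2L]]
    genes <- as.character(genes[[1L]])
  }
  if (anyDuplicated(genes)) stop("gene ids in a signature must be unique")
  if (length(genes) != length(scores)) stop("genes and scores differ in length")
  o <- order(-scores, genes)
  structure(data.frame(gene = genes[o], score = as.numeric(scores[o]),
                       stringsAsFactors = FALSE),
            class = c("ranked_signature", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running-sum statistic: walking down the ranked signature,
#' regulon members ("hits") increment the running sum by
#' `|score|^weight_exponent / sum_hits |score|^weight_exponent` and
#' non-members decrement it by `1 / (N - N_hits)`. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (first
#' such position on ties), so `es` lies in `[-1, 1]`.
#'
#' @param signature a [ranked_signature()] (or coercible data frame).
#' @param regulon a `regulon` or character vector of member gene ids.
#' @param weight_exponent weight on the ranking scores (1 = classic
#'   weighted GSEA; 0 = unweighted Kolmogorov-Smirnov).
#' @return list with `es` and the full `running_sum` vector (length N).
#' @export
enrichment_score <- function(signature, regulon, weight_exponent = 1) {
  sig <- as_signature(signature)
  members <- regulon_targets(regulon)
  hit <- sig$gene %in% members
  if (!any(hit))
    stop("no overlap between regulon and signature (TF untested)")
  N <- nrow(sig)
  n_hits <- sum(hit)
  if (n_hits == N) {
    w <- abs(sig$score)^weight_exponent
    running <- cumsum(w / sum(w))
    return(list(es = running[which.max(abs(running))], running_sum = running))
  }
  w <- abs(sig$score)^weight_exponent
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - n_hits))
  running <- cumsum(inc)
  list(es = running[which.max(abs(running))], running_sum = running)
}

as_signature <- function(signature) {
  if (inherits(signature, "ranked_signature")) return(signature)
  ranked_signature(signature)
}

regulon_targets <- function(regulon) {
  if (inherits(regulon, "regulon")) regulon$targets else as.character(regulon)
}

# O(n_hits) enrichment score from sorted hit positions; used in the
# permutation loop. `w` are |score|^exponent for the whole signature.
es_from_hits <- function(hit_pos, w, N) {
  k <- length(hit_pos)
  wh <- w[hit_pos]
  cw <- cumsum(wh) / sum(wh)
  d <- 1 / (N - k)
  after <- cw - (hit_pos - seq_len(k)) * d
  before <- after - wh / sum(wh)
  cand <- c(rbind(before, after))
  cand[which.max(abs(cand))]
}

#' GSEA permutation test for one regulon
#'
#' Null enrichment scores are generated by gene-label permutation: regulon
#' membership is reassigned to random gene sets of the same size drawn from
#' the signature. Positive and negative sides are treated separately:
#' `p = (1 + #{same-sign null with |es_null| >= |es|}) / (n_same_sign + 1)`
#' and `nes = es / mean(|es_null| of the same sign)`. This is the only
#' implementable null when the input is a precomputed ranked signature
#' rather than sample-level data.
#'
#' @inheritParams enrichment_score
#' @param n_permutations number of null permutations.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @return one-row data frame: `tf`, `n_hits`, `es`, `nes`, `p_value`,
#'   `q_value` (`NA`, filled by [run_mra()]).
#' @export
gsea_test <- function(signature, regulon, n_permutations = 10000L,
                      weight_exponent = 1, seed = NULL) {
  sig <- as_signature(signature)
  tf <- if (inherits(regulon, "regulon")) regulon$tf else NA_character_
  obs <- enrichment_score(sig, regulon, weight_exponent)
  N <- nrow(sig)
  k <- sum(sig$gene %in% regulon_targets(regulon))
  w <- abs(sig$score)^weight_exponent
  if (!is.null(seed)) set.seed(seed)
  null_es <- vapply(seq_len(n_permutations), function(i)
    es_from_hits(sort(sample.int(N, k)), w, N), numeric(1))
  es <- obs$es
  if (es == 0) {
    return(mr_row(tf, k, es = 0, nes = 0, p = 1))
  }
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same) < 10L)
    warning("fewer than 10 same-sign null enrichment scores; ",
            "p-value and NES are degenerate")
  p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  mr_row(tf, k, es, nes, p)
}

mr_row <- function(tf, n_hits, es, nes, p) {
  data.frame(tf = tf, n_hits = n_hits, es = es, nes = nes, p_value = p,
             q_value = NA_real_, stringsAsFactors = FALSE)
}

#' Master regulator analysis
#'
#' Scores every testable regulon against the signature with [gsea_test()],
#' applies Benjamini-Hochberg adjustment across all tested TFs, and flags:
#'
#' * **candidates**: `q_value <= candidate_fdr`;
#' * **master regulators**: candidates with `p_value <= mr_p` and `|nes|`
#'   strictly greater than the `nes_percentile`-th percentile
#'   (nearest-rank) of `|nes|` over the reference population
#'   (`nes_percentile_over`, all tested TFs by default).
#'
#' TFs whose regulon has no overlap with the signature are reported
#' untested (`NA` statistics), never silently dropped.
#'
#' @param network a `regulatory_network`, or a named list of regulons.
#' @param signature a [ranked_signature()].
#' @param n_permutations,weight_exponent passed to [gsea_test()].
#' @param candidate_fdr BH q-value cutoff for the candidate set.
#' @param mr_p p-value cutoff of the master-regulator filter.
#' @param nes_percentile percentile (0-100) of `|nes|` that a master
#'   regulator must strictly exceed.
#' @param nes_percentile_over `"tested"` (default) or `"candidates"`:
#'   population over which the percentile is taken.
#' @param min_regulon_size passed to [extract_regulons()].
#' @param seed integer seed for the permutation streams.
#' @return data frame of class `mra_result`, one row per TF (tested or
#'   not), ordered by p-value, with logical columns `is_candidate` and
#'   `is_master_regulator`; the percentile threshold is stored in
#'   `attr(, "nes_threshold")`.
#' @export
run_mra <- function(network, signature, n_permutations = 10000L,
                    candidate_fdr = 0.01, mr_p = 0.001, nes_percentile = 70,
                    nes_percentile_over = c("tested", "candidates"),
                    weight_exponent = 1, min_regulon_size = 10L,
                    seed = NULL) {
  nes_percentile_over <- match.arg(nes_percentile_over)
  regulons <- if (inherits(network, "regulatory_network"))
    extract_regulons(network, min_regulon_size) else network
  sig <- as_signature(signature)
  if (length(regulons) == 0L)
    stop("no regulon of size >= min_regulon_size; nothing to test")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(regulons[order(names(regulons))], function(reg) {
    if (!any(sig$gene %in% reg$targets))
      return(mr_row(reg$tf, 0L, NA_real_, NA_real_, NA_real_))
    gsea_test(sig, reg, n_permutations, weight_exponent, seed = NULL)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  tested <- !is.na(res$p_value)
  if (!any(tested)) stop("no testable TF: no regulon overlaps the signature")
  res$q_value[tested] <- p.adjust(res$p_value[tested], method = "BH")
  res$is_candidate <- !is.na(res$q_value) & res$q_value <= candidate_fdr
  pop <- switch(nes_percentile_over,
                tested = abs(res$nes[tested]),
                candidates = abs(res$nes[res$is_candidate]))
  thr <- nearest_rank_percentile(pop, nes_percentile)
  res$is_master_regulator <- res$is_candidate &
    !is.na(res$p_value) & res$p_value <= mr_p &
    !is.na(res$nes) & !is.na(thr) & abs(res$nes) > thr
  res <- res[order(res$p_value, res$tf), , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("mra_result", "data.frame"),
            nes_threshold = thr,
            params = list(n_permutations = n_permutations,
                          candidate_fdr = candidate_fdr, mr_p = mr_p,
                          nes_percentile = nes_percentile,
                          nes_percentile_over = nes_percentile_over,
                          weight_exponent = weight_exponent,
                          min_regulon_size = min_regulon_size, seed = seed))
}

# Nearest-rank percentile: value at rank ceil(p/100 * n) of the sorted
# multiset (strictly-greater comparisons against it are the caller's job).
nearest_rank_percentile <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sort(x)[max(1L, ceiling(p / 100 * length(x)))]
}

#' @export
print.mra_result <- function(x, ...) {
  cat("Master regulator analysis:", nrow(x), "TFs,",
      sum(!is.na(x$p_value)), "tested,",
      sum(x$is_candidate), "candidates,",
      sum(x$is_master_regulator), "master regulator(s)\n")
  thr <- attr(x, "nes_threshold")
  if (!is.na(thr)) cat("|NES| percentile threshold:", signif(thr, 4), "\n")
  print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
plot.mra_result <- function(x, ...) {
  tested <- !is.na(x$p_value)
  plot(x$nes[tested], -log10(x$p_value[tested]),
       xlab = "NES", ylab = "-log10 p",
       pch = ifelse(x$is_master_regulator[tested], 19, 1),
       col = ifelse(x$is_master_regulator[tested], "firebrick", "grey30"),
       ...)
  if (any(x$is_master_regulator))
    text(x$nes[x$is_master_regulator],
         -log10(x$p_value[x$is_master_regulator]),
         labels = x$tf[x$is_master_regulator], pos = 2, cex = 0.8)
  invisible(x)
}

#' Read / write rank files and MRA result tables
#'
#' Rank (`.rnk`) files are two tab-separated columns, gene id and ranking
#' score, no header, descending.
#'
#' @param path file path.
#' @return `read_rnk()` returns a [ranked_signature()].
#' @export
read_rnk <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  ranked_signature(as.character(df[[1L]]), as.numeric(df[[2L]]))
}

#' @rdname read_rnk
#' @param signature a [ranked_signature()].
#' @export
write_rnk <- function(signature, path) {
  write.table(as_signature(signature), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_rnk
#' @param result an `mra_result`.
#' @export
write_mra_tsv <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
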