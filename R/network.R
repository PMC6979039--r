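#' Score every TF-gene pair by mutual information
#'
#' Builds the candidate edge list: one edge per (TF, gene) pair with
#' `tf != target`; TF-TF pairs are included once as unordered pairs (the
#' member earlier in lexicographic order is stored in the `tf` column).
#' Rows are ordered by (tf, target).
#'
#' @param matrix gene-level expression matrix (genes x conditions).
#' @param tf_list character vector of TF identifiers, all present among the
#'   matrix rows.
#' @param config an [inference_config()].
#' @return data frame with columns `tf`, `target`, `mi`, `p_value`,
#'   `q_value` (the last two `NA` until [permutation_fdr()]).
#' @export
build_mi_edges <- function(matrix, tf_list, config = inference_config()) {
  genes <- rownames(matrix)
  if (!all(tf_list %in% genes))
    stop("unknown TF id(s): ",
         paste(setdiff(tf_list, genes), collapse = ", "))
  tf_list <- unique(tf_list)
  empty <- data.frame(tf = character(), target = character(), mi = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  if (length(tf_list) == 0L) return(empty)
  non_tf <- setdiff(genes, tf_list)
  tf <- c(rep(tf_list, each = length(non_tf)),
          if (length(tf_list) > 1L)
            unlist(lapply(seq_len(length(tf_list) - 1L), function(i) {
              s <- sort(tf_list)
              rep(s[i], length(tf_list) - i)
            })))
  target <- c(rep(non_tf, times = length(tf_list)),
              if (length(tf_list) > 1L)
                unlist(lapply(seq_len(length(tf_list) - 1L), function(i) {
                  s <- sort(tf_list)
                  s[(i + 1L):length(s)]
                })))
  if (length(tf) == 0L) return(empty)
  edges <- data.frame(tf = tf, target = target, stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  B <- n_bins_for(ncol(matrix), config$n_bins)
  bins <- t(apply(matrix, 1L, rank_bins, n_bins = B))
  idx <- setNames(seq_along(genes), genes)
  edges$mi <- .mi_edges_c(bins, idx[edges$tf], idx[edges$target], B)
  edges$p_value <- NA_real_
  edges$q_value <- NA_real_
  edges
}

#' Prune indirect edges with the data processing inequality
#'
#' For every triplet of nodes whose three pairwise edges are all present,
#' the edge with the strictly smallest MI is removed when its MI falls
#' below `min(other two) * (1 - tolerance)`; with the default strict
#' tolerance 0 this removes exactly the strict minimum of each triangle.
#' All removal decisions are evaluated against the original edge set in one
#' pass, so the result does not depend on triangle enumeration order. Ties
#' (no strict minimum) remove nothing. Edges outside any complete triangle
#' are never touched.
#'
#' @param edges edge data frame (see [build_mi_edges()]).
#' @param tolerance DPI tolerance in `[0, 1)`.
#' @return the surviving subset of `edges`.
#' @export
apply_dpi <- function(edges, tolerance = 0) {
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  if (nrow(edges) == 0L) return(edges)
  nodes <- sort(unique(c(edges$tf, edges$target)))
  id <- setNames(seq_along(nodes), nodes)
  a <- pmin(id[edges$tf], id[edges$target])
  b <- pmax(id[edges$tf], id[edges$target])
  key <- paste(a, b)
  mi <- setNames(edges$mi, key)
  adj <- vector("list", length(nodes))
  for (k in seq_along(a)) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  drop <- character(0)
  for (u in seq_along(nodes)) {
    nb <- adj[[u]]
    nb <- nb[nb > u]
    if (length(nb) < 2L) next
    for (ii in seq_len(length(nb) - 1L)) {
      v <- nb[ii]
      common <- intersect(nb[(ii + 1L):length(nb)], adj[[v]])
      for (w in common) {
        k_uv <- paste(u, v); k_uw <- paste(u, w); k_vw <- paste(v, w)
        m <- c(mi[[k_uv]], mi[[k_uw]], mi[[k_vw]])
        lo <- which(m == min(m))
        if (length(lo) > 1L) next  # no strict minimum
        others <- m[-lo]
        if (m[lo] < min(others) * (1 - tolerance))
          drop <- c(drop, c(k_uv, k_uw, k_vw)[lo])
      }
    }
  }
  edges[!(key %in% drop), , drop = FALSE]
}

#' Permutation test and FDR filter for network edges
#'
#' For each link the null distribution is obtained by recomputing the MI
#' `n_permutations` times against a randomly permuted copy of the target
#' profile; the add-one estimator `p = (1 + #{null >= observed}) /
#' (n_permutations + 1)` never returns exactly zero, so Benjamini-Hochberg
#' adjustment over all tested links is valid. Links with
#' `q <= fdr_threshold` are retained.
#'
#' In `null_mode = "pooled"` each link contributes
#' `ceiling(n_permutations / n_edges)` permutations to a single pooled null
#' shared by all links -- a documented approximation for large edge sets.
#'
#' @inheritParams build_mi_edges
#' @param edges candidate edges (typically the [apply_dpi()] survivors).
#' @return the retained edges with `mi`, `p_value` and `q_value` filled.
#' @export
permutation_fdr <- function(edges, matrix, config = inference_config()) {
  if (nrow(edges) == 0L) return(edges)
  genes <- rownames(matrix)
  if (!all(c(edges$tf, edges$target) %in% genes))
    stop("edges reference rows absent from the matrix")
  B <- n_bins_for(ncol(matrix), config$n_bins)
  bins <- t(apply(matrix, 1L, rank_bins, n_bins = B))
  idx <- setNames(seq_along(genes), genes)
  set.seed(config$seed)
  if (config$null_mode == "per_edge") {
    res <- .mi_perm_c(bins, idx[edges$tf], idx[edges$target], B,
                      config$n_permutations)
    edges$mi <- res$mi
    edges$p_value <- res$p_value
  } else {
    per <- max(1L, as.integer(ceiling(config$n_permutations / nrow(edges))))
    obs <- .mi_edges_c(bins, idx[edges$tf], idx[edges$target], B)
    pool <- unlist(lapply(seq_len(nrow(edges)), function(e) {
      y <- bins[idx[edges$target[e]], ]
      vapply(seq_len(per), function(i)
        .mi_bins_c(bins[idx[edges$tf[e]], ], sample(y), B), numeric(1))
    }))
    edges$mi <- obs
    edges$p_value <- vapply(obs, function(o)
      (1 + sum(pool >= o)) / (length(pool) + 1), numeric(1))
  }
  edges$q_value <- p.adjust(edges$p_value, method = "BH")
  edges[edges$q_value <= config$fdr_threshold, , drop = FALSE]
}

#' Infer a TF-gene regulatory network
#'
#' Three-stage procedure in the ARACNE family: (i) mutual information for
#' every TF-gene pair ([build_mi_edges()]); (ii) data-processing-inequality
#' pruning of indirect edges ([apply_dpi()]); (iii) per-link permutation
#' test with Benjamini-Hochberg FDR control over the DPI survivors
#' ([permutation_fdr()]).
#'
#' @inheritParams build_mi_edges
#' @return object of class `regulatory_network`: list with `edges`,
#'   `tf_list`, `gene_list`, `config` and per-stage edge counts.
#' @export
infer_network <- function(matrix, tf_list, config = inference_config()) {
  e1 <- build_mi_edges(matrix, tf_list, config)
  e2 <- apply_dpi(e1, config$dpi_tolerance)
  e3 <- permutation_fdr(e2, matrix, config)
  rownames(e3) <- NULL
  structure(list(edges = e3, tf_list = unique(tf_list),
                 gene_list = rownames(matrix), config = config,
                 stage_counts = c(mi = nrow(e1), dpi = nrow(e2),
                                  fdr = nrow(e3))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", nrow(x$edges), "edges |",
      length(x$tf_list), "TFs |", length(x$gene_list), "genes\n")
  cat("stage edge counts: MI", x$stage_counts["mi"],
      "-> DPI", x$stage_counts["dpi"],
      "-> FDR", x$stage_counts["fdr"],
      sprintf("(q <= %g, %d permutations)\n",
              x$config$fdr_threshold, x$config$n_permutations))
  invisible(x)
}

#' @export
summary.regulatory_network <- function(object, ...) {
  e <- object$edges
  deg <- table(factor(e$tf, levels = object$tf_list))
  cat("Regulatory network summary\n")
  print(object)
  if (nrow(e)) {
    cat("MI range: [", signif(min(e$mi), 4), ",", signif(max(e$mi), 4), "]\n")
    cat("regulon size (edges per TF): median", stats::median(deg),
        "max", max(deg), "\n")
  }
  invisible(object)
}

#' Read / write the network TSV format
#'
#' Columns `tf`, `target`, `mi`, `p_value`, `q_value`; rows ordered by
#' (tf, target).
#'
#' @param network a `regulatory_network` or an edge data frame.
#' @param path file path.
#' @export
write_network_tsv <- function(network, path) {
  e <- if (inherits(network, "regulatory_network")) network$edges else network
  e <- e[order(e$tf, e$target), , drop = FALSE]
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "mi")
  if (!all(need %in% names(e))) stop("not a network TSV: ", path)
  tf_list <- sort(unique(e$tf))
  structure(list(edges = e, tf_list = tf_list,
                 gene_list = sort(unique(c(e$tf, e$target))),
                 config = NULL,
                 stage_counts = c(mi = NA, dpi = NA, fdr = nrow(e))),
            class = "regulatory_network")
}
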