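#' Configuration of the synthetic expression compendium
#'
#' Describes a planted linear-Gaussian regulatory model and the
#' perturbation compendium design used to exercise the pipeline: each TF
#' receives `perturb_reps` dedicated over-expression and `perturb_reps`
#' knock-down conditions (its value shifted by +/- `perturbation_magnitude`
#' there) on top of shared baseline conditions.
#'
#' @param n_tf number of transcription factors.
#' @param n_genes total genes (TFs included among them); `n_tf <= n_genes`.
#' @param n_conditions total conditions; must cover the perturbation block
#'   (`>= 2 * perturb_reps * n_tf`).
#' @param regulon_size_range integer `(min, max)` regulon sizes, each >= 1.
#' @param edge_weight_range regulatory weight range; a weight's sign is
#'   positive (activating) in this generator.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   each regulated gene.
#' @param chain_fraction fraction of each regulon's targets that are
#'   second-order: reachable from the TF only through an intermediate,
#'   with no direct edge.
#' @param perturbation_magnitude shift applied to a TF in its dedicated
#'   perturbation conditions.
#' @param perturb_reps dedicated "up" (and "down") conditions per TF.
#' @param seed integer RNG seed; identical seed + parameters give
#'   byte-identical outputs.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_tf = 20L, n_genes = 200L,
                              n_conditions = 120L,
                              regulon_size_range = c(12L, 18L),
                              edge_weight_range = c(0.6, 1.0),
                              noise_sd = 0.5, chain_fraction = 0,
                              perturbation_magnitude = 3,
                              perturb_reps = 2L, seed = 1L) {
  stopifnot(n_tf >= 1L, n_genes >= n_tf, noise_sd >= 0,
            length(regulon_size_range) == 2L,
            regulon_size_range[1L] >= 1L,
            regulon_size_range[1L] <= regulon_size_range[2L],
            length(edge_weight_range) == 2L,
            edge_weight_range[1L] <= edge_weight_range[2L],
            chain_fraction >= 0, chain_fraction <= 1, perturb_reps >= 0L)
  if (n_conditions < 2L * perturb_reps * n_tf)
    stop("n_conditions must cover the perturbation block (>= ",
         2L * perturb_reps * n_tf, ")")
  if (regulon_size_range[2L] > n_genes - n_tf)
    stop("regulon_size_range exceeds the available non-TF gene pool")
  structure(list(n_tf = as.integer(n_tf), n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 regulon_size_range = as.integer(regulon_size_range),
                 edge_weight_range = as.numeric(edge_weight_range),
                 noise_sd = noise_sd, chain_fraction = chain_fraction,
                 perturbation_magnitude = perturbation_magnitude,
                 perturb_reps = as.integer(perturb_reps),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

gene_ids <- function(config) {
  sprintf("G%03d", seq_len(config$n_genes))
}

tf_ids <- function(config) {
  gene_ids(config)[seq_len(config$n_tf)]
}

#' Plant a regulatory network with known ground truth
#'
#' Every TF receives a regulon of direct targets sampled from the non-TF
#' gene pool; a `chain_fraction` of each regulon is rewired as second-order
#' targets: the TF regulates an intermediate which regulates the target,
#' with no direct TF-to-target edge (the structure the data processing
#' inequality is meant to prune). Intermediates are drawn from the TF's
#' direct targets; when `chain_fraction = 1` leaves none, a dedicated
#' intermediate gene is added (with its direct edge). The planted master
#' regulator is the TF with the largest regulon (ties to the first id).
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_truth`: `direct_edges`
#'   (tf, target, weight), `chain_edges` (tf, target, intermediate),
#'   `parents` (child, parent, weight; the full causal model),
#'   `tf_ids`, `gene_ids`, `planted_mr`, `config`, `seed`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- gene_ids(config)
  tfs <- tf_ids(config)
  pool <- setdiff(genes, tfs)
  direct <- list(); chain <- list(); parents <- list()
  used_aux <- character(0)
  for (tf in tfs) {
    s <- if (config$regulon_size_range[1L] == config$regulon_size_range[2L])
      config$regulon_size_range[1L] else
        sample(config$regulon_size_range[1L]:config$regulon_size_range[2L], 1L)
    targets <- sample(pool, s)
    n_chain <- round(config$chain_fraction * s)
    chain_t <- if (n_chain > 0L) targets[seq_len(n_chain)] else character(0)
    direct_t <- setdiff(targets, chain_t)
    rweight <- function(k) runif(k, config$edge_weight_range[1L],
                                 config$edge_weight_range[2L])
    if (length(direct_t)) {
      w <- rweight(length(direct_t))
      direct[[tf]] <- data.frame(tf = tf, target = direct_t, weight = w,
                                 stringsAsFactors = FALSE)
      parents[[length(parents) + 1L]] <-
        data.frame(child = direct_t, parent = tf, weight = w,
                   stringsAsFactors = FALSE)
    }
    if (length(chain_t)) {
      inter_pool <- direct_t
      if (!length(inter_pool)) {
        # no direct target to route through: add a dedicated intermediate
        aux_pool <- setdiff(pool, c(targets, used_aux))
        if (!length(aux_pool)) stop("gene pool exhausted for intermediates")
        aux <- sample(aux_pool, 1L)
        used_aux <- c(used_aux, aux)
        w <- rweight(1L)
        direct[[tf]] <- rbind(direct[[tf]],
                              data.frame(tf = tf, target = aux, weight = w,
                                         stringsAsFactors = FALSE))
        parents[[length(parents) + 1L]] <-
          data.frame(child = aux, parent = tf, weight = w,
                     stringsAsFactors = FALSE)
        inter_pool <- aux
      }
      inter <- sample(inter_pool, length(chain_t), replace = TRUE)
      w <- rweight(length(chain_t))
      chain[[tf]] <- data.frame(tf = tf, target = chain_t,
                                intermediate = inter,
                                stringsAsFactors = FALSE)
      parents[[length(parents) + 1L]] <-
        data.frame(child = chain_t, parent = inter, weight = w,
                   stringsAsFactors = FALSE)
    }
  }
  direct <- do.call(rbind, c(direct, list(make.row.names = FALSE)))
  chain <- if (length(chain))
    do.call(rbind, c(chain, list(make.row.names = FALSE))) else
      data.frame(tf = character(), target = character(),
                 intermediate = character(), stringsAsFactors = FALSE)
  parents <- do.call(rbind, c(parents, list(make.row.names = FALSE)))
  regsize <- vapply(tfs, function(tf)
    sum(direct$tf == tf) + sum(chain$tf == tf), integer(1))
  structure(list(direct_edges = direct, chain_edges = chain,
                 parents = parents, tf_ids = tfs, gene_ids = genes,
                 planted_mr = tfs[which.max(regsize)], config = config,
                 seed = config$seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", length(x$tf_ids), "TFs,", length(x$gene_ids),
      "genes;", nrow(x$direct_edges), "direct +", nrow(x$chain_edges),
      "chain edges; planted MR:", x$planted_mr, "\n")
  invisible(x)
}

condition_design <- function(config) {
  tfs <- tf_ids(config)
  k <- config$perturb_reps
  pert <- if (k > 0L)
    data.frame(
      condition = paste0(rep(tfs, each = 2L * k), "_",
                         rep(rep(c("up", "dn"), each = k), length(tfs)),
                         rep(seq_len(k), 2L * length(tfs))),
      tf = rep(tfs, each = 2L * k),
      shift = rep(rep(c(1, -1), each = k), length(tfs)) *
        config$perturbation_magnitude,
      stringsAsFactors = FALSE)
  else data.frame(condition = character(), tf = character(),
                  shift = numeric(), stringsAsFactors = FALSE)
  n_base <- config$n_conditions - nrow(pert)
  base <- data.frame(condition = sprintf("base%03d", seq_len(n_base)),
                     tf = NA_character_, shift = 0,
                     stringsAsFactors = FALSE)
  rbind(pert, base)
}

#' Simulate an expression compendium from a planted network
#'
#' TFs (and unregulated genes) are independent standard normals per
#' condition; a TF is additionally shifted by its perturbation design in
#' its dedicated conditions. Every regulated gene is the weighted sum of
#' its parents plus `Gaussian(0, noise_sd)` noise, evaluated in causal
#' order, so `noise_sd = 0` yields exact linear relations.
#'
#' @param truth a `synthetic_truth` from [simulate_network()].
#' @param config the [simulation_config()] used to build `truth`.
#' @return genes x conditions matrix (see [expression_matrix()]).
#' @export
simulate_expression <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "simulation_config"))
  if (!identical(truth$gene_ids, gene_ids(config)))
    stop("truth and config disagree on the gene set")
  set.seed(config$seed + 1L)
  design <- condition_design(config)
  n <- nrow(design)
  genes <- truth$gene_ids
  regulated <- unique(truth$parents$child)
  m <- matrix(NA_real_, nrow = length(genes), ncol = n,
              dimnames = list(genes, design$condition))
  for (g in genes) {
    if (g %in% regulated) next
    m[g, ] <- rnorm(n)
    if (g %in% truth$tf_ids) {
      pc <- which(design$tf == g)
      m[g, pc] <- m[g, pc] + design$shift[pc]
    }
  }
  remaining <- regulated
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(g) {
      pa <- truth$parents$parent[truth$parents$child == g]
      !any(pa %in% remaining)
    }, logical(1))]
    if (!length(ready)) stop("cycle in the planted parent structure")
    for (g in ready) {
      rows <- truth$parents[truth$parents$child == g, , drop = FALSE]
      val <- rnorm(n, sd = config$noise_sd)
      for (r in seq_len(nrow(rows)))
        val <- val + rows$weight[r] * m[rows$parent[r], ]
      m[g, ] <- val
    }
    remaining <- setdiff(remaining, ready)
  }
  expression_matrix(m, level = "gene")
}

#' Regulon of the planted master regulator
#'
#' Direct plus chain targets of `truth$planted_mr` (chain targets respond
#' to the regulator through their intermediate, so they belong to its
#' functional regulon).
#'
#' @param truth a `synthetic_truth`.
#' @export
planted_regulon <- function(truth) {
  mr <- truth$planted_mr
  sort(unique(c(truth$direct_edges$target[truth$direct_edges$tf == mr],
                truth$chain_edges$target[truth$chain_edges$tf == mr])))
}

#' Simulate a ranked differential signature enriched for the planted MR
#'
#' Members of the planted master regulator's regulon receive ranking
#' scores drawn `Normal(effect_size, 1)`; `n_other` other genes (all
#' remaining genes if `n_other` is `NULL` or exceeds the pool) receive
#' `Normal(0, 1)`. The output is sorted descending.
#'
#' @param truth a `synthetic_truth`.
#' @param effect_size mean ranking score of the planted regulon.
#' @param n_other number of background genes (`NULL` = all remaining).
#' @param seed integer seed.
#' @return a [ranked_signature()].
#' @export
simulate_signature <- function(truth, effect_size, n_other = NULL,
                               seed = truth$seed) {
  reg <- planted_regulon(truth)
  if (!length(reg)) stop("planted master regulator has an empty regulon")
  set.seed(seed + 2L)
  rest <- setdiff(truth$gene_ids, c(reg, truth$planted_mr))
  if (is.null(n_other) || n_other >= length(rest)) {
    other <- rest
  } else {
    other <- sort(sample(rest, n_other))
  }
  genes <- c(reg, other)
  scores <- c(rnorm(length(reg), mean = effect_size), rnorm(length(other)))
  ranked_signature(genes, scores)
}

#' Simulate promoter sequences with planted motif instances
#'
#' Generates `n_seqs` i.i.d. background sequences and writes motif words
#' at recorded non-overlapping positions with uniformly chosen strands;
#' minus-strand placements insert the reverse complement. By default the
#' planted word is the motif's consensus (so recovery at normalized score
#' 1 is exact); `sample_from_pwm` draws each planted word from the motif's
#' probability columns instead.
#'
#' @param motifs list of `motif_model`s (recycled over placements).
#' @param n_seqs number of sequences.
#' @param length sequence length (>= every motif length).
#' @param placements_per_seq planted instances per sequence.
#' @param background base frequencies (A, C, G, T) summing to 1.
#' @param seed integer seed.
#' @param sample_from_pwm sample planted words from the PWM instead of
#'   writing the consensus.
#' @return list with `sequences` (named character vector) and
#'   `placements` (data frame: sequence_id, start, end, strand, motif_id;
#'   0-based half-open forward-strand coordinates).
#' @export
simulate_promoters <- function(motifs, n_seqs = 1L, length = 2400L,
                               placements_per_seq = 1L,
                               background = rep(0.25, 4), seed = 1L,
                               sample_from_pwm = FALSE) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L, n_seqs >= 1L, placements_per_seq >= 0L)
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  maxL <- max(vapply(motifs, motif_length, integer(1)))
  if (length < maxL) stop("sequence length shorter than the longest motif")
  if (placements_per_seq * maxL > length)
    stop("impossible packing: placements do not fit in the sequence")
  set.seed(seed)
  seqs <- character(n_seqs)
  names(seqs) <- sprintf("seq%03d", seq_len(n_seqs))
  placements <- list()
  for (s in seq_len(n_seqs)) {
    chars <- sample(DNA, length, replace = TRUE, prob = background)
    occupied <- integer(0)
    for (pl in seq_len(placements_per_seq)) {
      mot <- motifs[[(pl - 1L) %% length(motifs) + 1L]]
      L <- motif_length(mot)
      word <- if (sample_from_pwm)
        paste(apply(mot$probs, 2L, function(p) sample(DNA, 1L, prob = p)),
              collapse = "") else consensus_word(mot)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        start <- sample.int(length - L + 1L, 1L) - 1L  # 0-based
        span <- (start + 1L):(start + L)
        if (!any(span %in% occupied)) { placed <- TRUE; break }
      }
      if (!placed) stop("impossible packing: could not place motif ",
                        mot$motif_id, " in ", names(seqs)[s])
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "-") revcomp(word) else word
      chars[span] <- strsplit(ins, "")[[1L]]
      occupied <- c(occupied, span)
      placements[[base::length(placements) + 1L]] <-
        data.frame(sequence_id = names(seqs)[s], start = start,
                   end = start + L, strand = strand,
                   motif_id = mot$motif_id, stringsAsFactors = FALSE)
    }
    seqs[s] <- paste(chars, collapse = "")
  }
  placements <- if (base::length(placements))
    do.call(rbind, placements) else
      data.frame(sequence_id = character(), start = integer(),
                 end = integer(), strand = character(),
                 motif_id = character(), stringsAsFactors = FALSE)
  list(sequences = seqs, placements = placements)
}

#' Write planted ground truth as tab-separated tables
#'
#' `edges.tsv` holds direct and chain edges with a `type` column;
#' `placements.tsv` the planted motif instances.
#'
#' @param truth a `synthetic_truth`.
#' @param placements placements data frame from [simulate_promoters()].
#' @param dir output directory.
#' @export
write_truth_tables <- function(truth, placements = NULL, dir = ".") {
  d <- truth$direct_edges
  d$type <- "direct"; d$intermediate <- NA_character_
  ch <- truth$chain_edges
  if (nrow(ch)) { ch$weight <- NA_real_; ch$type <- "chain" }
  else ch <- data.frame(tf = character(), target = character(),
                        intermediate = character(), weight = numeric(),
                        type = character(), stringsAsFactors = FALSE)
  cols <- c("tf", "target", "type", "weight", "intermediate")
  edges <- rbind(d[, cols], ch[, cols])
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(placements))
    write.table(placements, file.path(dir, "placements.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
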