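#' Build the shipped synthetic end-to-end fixture
#'
#' Writes a complete, self-consistent input set for [run_pipeline()] with
#' planted ground truth into `dir`:
#'
#' * a 200-gene x 120-condition perturbation compendium over 20 TFs
#'   (regulons of 12-18 genes, weights 0.6-1.0, noise sd 0.5, 20% chain
#'   targets, perturbation magnitude 3 with 2 up/2 down conditions per
#'   TF);
#' * a ranked signature enriched (effect size 10) for the planted master
#'   regulator's regulon;
#' * one motif per TF (random length-12 consensus, one-hot counts) in
#'   MEME minimal format with the TF-to-motif map;
#' * a 2,400 bp target promoter with the planted master regulator's
#'   consensus inserted at TSS-relative position -400 (inside the
#'   retinoic-acid-responsive window);
#' * ground-truth tables and a ready-to-run `pipeline.yaml`.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed; everything written is a pure function of it.
#' @return invisible list: `dir`, the `truth` object, the planted
#'   regulator id, the planted placement, and the `config_path`.
#' @export
demo_fixture <- function(dir = tempfile("mrascan_demo_"), seed = 101L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- simulation_config(n_tf = 20L, n_genes = 200L, n_conditions = 120L,
                           regulon_size_range = c(12L, 18L),
                           edge_weight_range = c(0.6, 1.0),
                           noise_sd = 0.5, chain_fraction = 0.2,
                           perturbation_magnitude = 3, perturb_reps = 2L,
                           seed = seed)
  truth <- simulate_network(cfg)
  expr <- simulate_expression(truth, cfg)
  write_expression_tsv(expr, file.path(dir, "expression.tsv"))
  writeLines(truth$tf_ids, file.path(dir, "tfs.txt"))

  sig <- simulate_signature(truth, effect_size = 10, seed = seed)
  write_rnk(sig, file.path(dir, "signature.rnk"))

  set.seed(seed + 3L)
  motifs <- lapply(truth$tf_ids, function(tf) {
    word <- sample(DNA, 12L, replace = TRUE)
    counts <- matrix(0, nrow = 4L, ncol = 12L, dimnames = list(DNA, NULL))
    counts[cbind(match(word, DNA), seq_len(12L))] <- 10
    motif_model(counts, motif_id = paste0("M_", tf), pseudocount = 0.25)
  })
  names(motifs) <- vapply(motifs, `[[`, "", "motif_id")
  write_meme(motifs, file.path(dir, "motifs.meme"))
  write.table(data.frame(tf = truth$tf_ids,
                         motif_id = paste0("M_", truth$tf_ids)),
              file.path(dir, "tf2motif.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # 2,400 bp background promoter; plant the planted MR's consensus on the
  # forward strand at TSS-relative -400 (promoter position 2000).
  bg <- simulate_promoters(motifs[[1L]], n_seqs = 1L, length = 2400L,
                           placements_per_seq = 0L, seed = seed + 4L)
  prom <- bg$sequences[[1L]]
  mr_motif <- motifs[[paste0("M_", truth$planted_mr)]]
  word <- consensus_word(mr_motif)
  start <- 2000L
  substr(prom, start + 1L, start + nchar(word)) <- word
  proms <- setNames(prom, "target_promoter")
  write_fasta(proms, file.path(dir, "promoters.fa"))
  placement <- data.frame(sequence_id = "target_promoter", start = start,
                          end = start + nchar(word), strand = "+",
                          motif_id = mr_motif$motif_id,
                          stringsAsFactors = FALSE)
  write_truth_tables(truth, placement, dir)

  yaml::write_yaml(list(
    expression = "expression.tsv", tf_list = "tfs.txt",
    signature = "signature.rnk", promoters = "promoters.fa",
    motifs = "motifs.meme", tf2motif = "tf2motif.tsv",
    target_promoter = "target_promoter",
    seed = as.integer(seed)), file.path(dir, "pipeline.yaml"))

  invisible(list(dir = dir, truth = truth, planted_mr = truth$planted_mr,
                 placement = placement,
                 config_path = file.path(dir, "pipeline.yaml")))
}
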