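#' Pipeline configuration
#'
#' Collects file paths and stage thresholds for [run_pipeline()]. Defaults
#' are the conventional operating point of the method: network FDR 0.01
#' with 1,000 permutations per link; MRA candidate FDR 0.01, master
#' regulator filter p <= 0.001 with |NES| above the 70th percentile at
#' 10,000 permutations; promoter binding at normalized score >= 0.7 and
#' p <= 1e-4; RARE scan at q < 0.1; promoter windows of 2,400, 480 and
#' 288 bp upstream of the TSS.
#'
#' @param expression path to the expression TSV (gene level).
#' @param tf_list path to the TF list (one id per line).
#' @param signature path to the ranked signature (`.rnk`).
#' @param promoters path to the promoter FASTA; each sequence is the
#'   upstream region of one gene, ending at the TSS (its last base is
#'   TSS-relative position -1).
#' @param motifs path to a MEME minimal motif file.
#' @param tf2motif path to the TF-to-motif mapping TSV (`tf`, `motif_id`).
#' @param target_promoter name of the promoter sequence to scan.
#' @param inference list of [inference_config()] overrides.
#' @param mra list of [run_mra()] overrides.
#' @param min_normalized_score,p_threshold binder thresholds.
#' @param rare_q q-value cutoff of the RARE scan.
#' @param promoter_lengths promoter window lengths (bp upstream of TSS).
#' @param binder_region window length used for the binder decision.
#' @param restrict_to_rar_window additionally require binder hits to
#'   overlap the TSS-relative `rar_window`.
#' @param rar_window TSS-relative window, inclusive upstream bound,
#'   exclusive downstream bound.
#' @param quantile_normalize quantile-normalize the expression matrix
#'   before inference.
#' @param seed global pipeline seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, tf_list, signature, promoters,
                            motifs, tf2motif, target_promoter,
                            inference = list(), mra = list(),
                            min_normalized_score = 0.7,
                            p_threshold = 1e-4, rare_q = 0.1,
                            promoter_lengths = c(2400L, 480L, 288L),
                            binder_region = 2400L,
                            restrict_to_rar_window = FALSE,
                            rar_window = c(-480, -288),
                            quantile_normalize = TRUE, seed = 1L) {
  stopifnot(min_normalized_score >= 0, min_normalized_score <= 1,
            p_threshold > 0, p_threshold < 1, rare_q > 0, rare_q < 1,
            binder_region %in% promoter_lengths)
  structure(list(expression = expression, tf_list = tf_list,
                 signature = signature, promoters = promoters,
                 motifs = motifs, tf2motif = tf2motif,
                 target_promoter = target_promoter,
                 inference = inference, mra = mra,
                 min_normalized_score = min_normalized_score,
                 p_threshold = p_threshold, rare_q = rare_q,
                 promoter_lengths = as.integer(promoter_lengths),
                 binder_region = as.integer(binder_region),
                 restrict_to_rar_window = restrict_to_rar_window,
                 rar_window = rar_window,
                 quantile_normalize = quantile_normalize,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Relative file paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("expression", "tf_list", "signature", "promoters", "motifs",
              "tf2motif"))
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  do.call(pipeline_config, y)
}

#' Intersect master regulators with promoter binders
#'
#' A TF is a promoter binder when it has at least one motif hit with
#' `normalized_score >= min_normalized_score` and
#' `p_value <= p_threshold`. Direct regulators are the flagged master
#' regulators that are also binders. Master regulators without a motif
#' mapping are reported `unscannable`, never silently dropped.
#'
#' @param mra_result an `mra_result` from [run_mra()].
#' @param hits_by_tf named list (TF id -> hit data frame with filled
#'   `p_value`); TFs absent from the list are unscannable.
#' @param min_normalized_score,p_threshold binder thresholds.
#' @return object of class `direct_regulator_report`.
#' @export
identify_direct_regulators <- function(mra_result, hits_by_tf,
                                       min_normalized_score = 0.7,
                                       p_threshold = 1e-4) {
  mrs <- mra_result$tf[mra_result$is_master_regulator]
  binder_of <- function(h) {
    nrow(h) > 0L && any(h$normalized_score >= min_normalized_score &
                          !is.na(h$p_value) & h$p_value <= p_threshold)
  }
  binders <- names(hits_by_tf)[vapply(hits_by_tf, binder_of, logical(1))]
  unscannable <- setdiff(mrs, names(hits_by_tf))
  best_hits <- lapply(hits_by_tf[binders], function(h) {
    ok <- h$normalized_score >= min_normalized_score &
      !is.na(h$p_value) & h$p_value <= p_threshold
    h <- h[ok, , drop = FALSE]
    h[which.max(h$normalized_score), , drop = FALSE]
  })
  structure(list(master_regulators = sort(mrs),
                 promoter_binders = sort(binders),
                 direct_regulators = sort(intersect(mrs, binders)),
                 unscannable = sort(unscannable),
                 best_hits = best_hits,
                 thresholds = list(
                   min_normalized_score = min_normalized_score,
                   p_threshold = p_threshold)),
            class = "direct_regulator_report")
}

#' @export
print.direct_regulator_report <- function(x, ...) {
  cat("Direct-regulator report\n")
  cat("  master regulators :",
      if (length(x$master_regulators))
        paste(x$master_regulators, collapse = ", ") else "(none)", "\n")
  cat("  promoter binders  :",
      if (length(x$promoter_binders))
        paste(x$promoter_binders, collapse = ", ") else "(none)", "\n")
  cat("  direct regulators :",
      if (length(x$direct_regulators))
        paste(x$direct_regulators, collapse = ", ") else "(none)", "\n")
  if (length(x$unscannable))
    cat("  unscannable MRs   :", paste(x$unscannable, collapse = ", "),
        "\n")
  invisible(x)
}

#' Run the full pipeline
#'
#' Preprocess -> network inference -> master regulator analysis ->
#' promoter scan -> direct-regulator intersection. Every intermediate
#' artifact is written under `output_dir` (normalized expression, network
#' TSV, MRA table, per-window hit BEDs, RARE hits, `report.json`);
#' identical config + seed give a byte-identical report. Stage failures
#' abort with the failing stage named.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param output_dir directory for intermediate artifacts (created if
#'   missing).
#' @return a `pipeline_report`: the [identify_direct_regulators()] report
#'   plus per-region binder lists, RARE scan summary, stage summaries and
#'   the config snapshot.
#' @export
run_pipeline <- function(config, output_dir = tempfile("mrascan_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  expr <- stage("expression", {
    m <- read_expression_tsv(config$expression, level = "gene")
    if (config$quantile_normalize) m <- quantile_normalize(m)
    m
  })
  tfs <- stage("expression", read_tf_list(config$tf_list))
  write_expression_tsv(expr, file.path(output_dir, "expression_normalized.tsv"))

  icfg <- stage("network", do.call(inference_config,
                                   c(config$inference,
                                     list(seed = config$seed))))
  network <- stage("network", infer_network(expr, tfs, icfg))
  write_network_tsv(network, file.path(output_dir, "network.tsv"))

  sig <- stage("mra", read_rnk(config$signature))
  mra <- stage("mra", do.call(run_mra,
                              c(list(network = network, signature = sig,
                                     seed = config$seed + 1L),
                                config$mra)))
  write_mra_tsv(mra, file.path(output_dir, "mra.tsv"))

  proms <- stage("scan", read_fasta(config$promoters))
  if (!config$target_promoter %in% names(proms))
    stop("pipeline stage 'scan' failed: target promoter '",
         config$target_promoter, "' not in ", config$promoters,
         call. = FALSE)
  motifs <- stage("scan", read_meme(config$motifs))
  t2m <- stage("scan", read_tf2motif(config$tf2motif))
  full <- proms[[config$target_promoter]]

  regions <- lapply(config$promoter_lengths, function(len) {
    substr(full, max(0L, nchar(full) - len) + 1L, nchar(full))
  })
  names(regions) <- paste0("upstream_", config$promoter_lengths)

  scan_region <- function(seqchr, len) {
    hits_by_tf <- list()
    for (i in seq_len(nrow(t2m))) {
      tf <- t2m$tf[i]; mid <- t2m$motif_id[i]
      if (!mid %in% names(motifs)) next
      mot <- motifs[[mid]]
      if (nchar(seqchr) < motif_length(mot)) {
        hits_by_tf[[tf]] <- empty_hits()
        next
      }
      h <- scan_sequence(mot, seqchr,
                         min_normalized_score = config$min_normalized_score,
                         sequence_id = config$target_promoter)
      if (nrow(h)) {
        lat <- pwm_lattice(mot, 1e-3)
        h$p_value <- vapply(h$raw_score, function(s)
          unname(lattice_pvalue(lat, s)["upper"]), numeric(1))
      }
      if (config$restrict_to_rar_window)
        h <- restrict_to_region(h, nchar(seqchr), config$rar_window)
      hits_by_tf[[tf]] <- h
    }
    hits_by_tf
  }
  hits_by_region <- stage("scan", {
    res <- lapply(seq_along(regions), function(i)
      scan_region(regions[[i]], config$promoter_lengths[i]))
    names(res) <- names(regions)
    res
  })
  for (rn in names(hits_by_region)) {
    all_hits <- do.call(rbind, hits_by_region[[rn]])
    if (is.null(all_hits)) all_hits <- empty_hits()
    write_hits_bed(all_hits, file.path(output_dir,
                                       paste0("hits_", rn, ".bed")))
  }

  rare <- stage("rare", {
    mots <- rare_motifs()
    do.call(rbind, lapply(mots, function(m)
      fimo_scan(m, full, q_threshold = config$rare_q,
                sequence_id = config$target_promoter)))
  })
  rownames(rare) <- NULL
  write_hits_bed(rare, file.path(output_dir, "rare_hits.bed"))

  binder_name <- paste0("upstream_", config$binder_region)
  report <- identify_direct_regulators(
    mra, hits_by_region[[binder_name]],
    min_normalized_score = config$min_normalized_score,
    p_threshold = config$p_threshold)

  binders_per_region <- lapply(hits_by_region, function(hbt) {
    sort(names(hbt)[vapply(hbt, function(h)
      nrow(h) > 0L && any(h$normalized_score >= config$min_normalized_score &
                            !is.na(h$p_value) &
                            h$p_value <= config$p_threshold),
      logical(1))])
  })

  out <- structure(list(
    direct_regulators = report$direct_regulators,
    master_regulators = report$master_regulators,
    promoter_binders = binders_per_region,
    binder_region = binder_name,
    unscannable = report$unscannable,
    n_rare_hits = nrow(rare),
    stage_summaries = list(
      expression = list(n_genes = nrow(expr), n_conditions = ncol(expr)),
      network = as.list(network$stage_counts),
      mra = list(n_tested = sum(!is.na(mra$p_value)),
                 n_candidates = sum(mra$is_candidate),
                 n_master_regulators = sum(mra$is_master_regulator))),
    config = unclass(config),
    seed = config$seed),
    class = "pipeline_report")
  jsonlite::write_json(unclass(out), file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  out$output_dir <- output_dir
  out$mra <- mra
  out$network <- network
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ")\n")
  s <- x$stage_summaries
  cat("  expression:", s$expression$n_genes, "genes x",
      s$expression$n_conditions, "conditions\n")
  cat("  network   :", s$network$mi, "-> DPI", s$network$dpi, "-> FDR",
      s$network$fdr, "edges\n")
  cat("  MRA       :", s$mra$n_tested, "tested,", s$mra$n_candidates,
      "candidates,", s$mra$n_master_regulators, "master regulator(s)\n")
  cat("  RARE scan :", x$n_rare_hits, "hit(s)\n")
  cat("  binders (", x$binder_region, "):",
      paste(x$promoter_binders[[x$binder_region]], collapse = ", "), "\n")
  cat("  direct regulators:",
      if (length(x$direct_regulators))
        paste(x$direct_regulators, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
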