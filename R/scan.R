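revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Raw log-odds score of every window of `seq` (character) for one strand of
# the motif. Windows containing a base outside A/C/G/T score NA.
window_scores <- function(motif, seq) {
  L <- motif_length(motif)
  code <- match(strsplit(toupper(seq), "")[[1L]], DNA)
  n <- length(code)
  W <- n - L + 1L
  if (W < 1L) stop("sequence shorter than the motif")
  sc <- numeric(W)
  na <- logical(W)
  for (i in seq_len(L)) {
    ci <- code[i:(i + W - 1L)]
    bad <- is.na(ci)
    na <- na | bad
    ci[bad] <- 1L
    sc <- sc + motif$log_odds[cbind(ci, i)]
  }
  sc[na] <- NA_real_
  sc
}

empty_hits <- function() {
  data.frame(sequence_id = character(), start = integer(), end = integer(),
             strand = character(), motif_id = character(),
             raw_score = numeric(), normalized_score = numeric(),
             p_value = numeric(), q_value = numeric(),
             stringsAsFactors = FALSE)
}

# Score all windows on the requested strands with forward-strand 0-based
# half-open coordinates. Internal; scan_sequence/fimo_scan filter it.
scan_all_windows <- function(motif, seq, both_strands = TRUE,
                             sequence_id = "seq") {
  L <- motif_length(motif)
  n <- nchar(seq)
  fwd <- window_scores(motif, seq)
  res <- data.frame(sequence_id = sequence_id,
                    start = seq_along(fwd) - 1L,
                    end = seq_along(fwd) - 1L + L,
                    strand = "+", motif_id = motif$motif_id,
                    raw_score = fwd, stringsAsFactors = FALSE)
  if (both_strands) {
    rev <- window_scores(motif, revcomp(seq))
    # window j (0-based) of the reverse complement covers forward
    # interval [n - j - L, n - j)
    res_m <- data.frame(sequence_id = sequence_id,
                        start = n - seq_along(rev) + 1L - L,
                        end = n - seq_along(rev) + 1L,
                        strand = "-", motif_id = motif$motif_id,
                        raw_score = rev, stringsAsFactors = FALSE)
    res <- rbind(res, res_m)
  }
  n_skipped <- sum(is.na(res$raw_score))
  if (n_skipped > 0L)
    message(n_skipped, " window(s) skipped (ambiguous base) in ",
            sequence_id)
  res <- res[!is.na(res$raw_score), , drop = FALSE]
  res$normalized_score <- normalized_score(motif, res$raw_score)
  res$p_value <- NA_real_
  res$q_value <- NA_real_
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Scan a sequence for motif matches above a normalized-score threshold
#'
#' Every window of the sequence (both strands by default) is scored with
#' the motif's log-odds matrix; windows whose normalized binding score
#' `(raw - min) / (max - min)` reaches `min_normalized_score` are returned.
#' Coordinates are 0-based, half-open, always on the forward strand; a
#' minus-strand hit means the reverse complement of the forward interval
#' matches the motif. Windows containing ambiguous bases (e.g. N) are
#' skipped with a message.
#'
#' @param motif a `motif_model`.
#' @param seq nucleotide string (or length-1 `DNAStringSet` element).
#' @param min_normalized_score hit threshold in `[0, 1]`.
#' @param both_strands also scan the reverse strand?
#' @param sequence_id id carried into the hit table.
#' @return hit data frame: `sequence_id`, `start`, `end`, `strand`,
#'   `motif_id`, `raw_score`, `normalized_score`, `p_value`/`q_value`
#'   (`NA` here; see [fimo_scan()]).
#' @export
scan_sequence <- function(motif, seq, min_normalized_score = 0.7,
                          both_strands = TRUE, sequence_id = "seq") {
  seq <- as.character(seq)
  res <- scan_all_windows(motif, seq, both_strands, sequence_id)
  res <- res[res$normalized_score >= min_normalized_score, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' FIMO-style scan: per-position p-values and q-values
#'
#' Scores every window on both strands, converts raw scores to exact
#' lattice p-values ([pwm_pvalue()]; one dynamic program per call),
#' applies Benjamini-Hochberg adjustment over all positions scanned in
#' this call, and returns hits with `q < q_threshold`.
#'
#' @inheritParams scan_sequence
#' @param q_threshold strict q-value cutoff.
#' @param granularity lattice step for the p-value dynamic program.
#' @return hit data frame as in [scan_sequence()] with `p_value` and
#'   `q_value` filled; the number of scored positions is in
#'   `attr(, "n_scored")`.
#' @export
fimo_scan <- function(motif, seq, q_threshold = 0.1, granularity = 1e-3,
                      both_strands = TRUE, sequence_id = "seq") {
  seq <- as.character(seq)
  res <- scan_all_windows(motif, seq, both_strands, sequence_id)
  lat <- pwm_lattice(motif, granularity)
  res$p_value <- vapply(res$raw_score, function(s)
    unname(lattice_pvalue(lat, s)["upper"]), numeric(1))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  out <- res[res$q_value < q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scored") <- nrow(res)
  out
}

#' Extract a fixed-length promoter window upstream of a TSS
#'
#' For a plus-strand gene with TSS at position `tss` (0-based) of the
#' supplied sequence, returns the bases of forward interval
#' `[tss - length, tss)`. For a minus-strand gene the forward interval is
#' `[tss, tss + length)`, reverse-complemented so the returned sequence
#' always reads away from the gene, ending adjacent to the TSS. Requests
#' extending past the sequence boundary are an error unless
#' `allow_truncation` is set, in which case the truncation is recorded.
#'
#' @param sequences named character vector or `DNAStringSet` of source
#'   sequences.
#' @param gene gene id (used to label the region).
#' @param seqname name of the source sequence.
#' @param tss 0-based TSS coordinate on the source sequence.
#' @param length promoter length in bp (conventional choices: 2400, 480,
#'   288).
#' @param strand `"+"` or `"-"`.
#' @param allow_truncation clip at the sequence boundary instead of
#'   erroring.
#' @return object of class `promoter_region`: gene, strand, requested and
#'   actual length, forward-strand `start`/`end` on the source, and the
#'   promoter-oriented `sequence`.
#' @export
extract_promoter <- function(sequences, gene, seqname, tss, length,
                             strand = c("+", "-"),
                             allow_truncation = FALSE) {
  strand <- match.arg(strand)
  seqs <- if (is.character(sequences)) sequences else
    setNames(as.character(sequences), names(sequences))
  if (!seqname %in% names(seqs)) stop("sequence not found: ", seqname)
  src <- seqs[[seqname]]
  n <- nchar(src)
  if (tss < 0 || tss > n) stop("TSS outside the supplied sequence")
  if (strand == "+") {
    start <- tss - length; end <- tss
  } else {
    start <- tss; end <- tss + length
  }
  truncated <- FALSE
  if (start < 0 || end > n) {
    if (!allow_truncation)
      stop("promoter window [", start, ", ", end, ") outside sequence ",
           seqname, " (length ", n, ")")
    start <- max(0L, start); end <- min(n, end); truncated <- TRUE
  }
  sub <- substr(src, start + 1L, end)
  if (strand == "-") sub <- revcomp(sub)
  structure(list(gene = gene, seqname = seqname, tss = tss,
                 strand = strand, requested_length = length,
                 length = end - start, start = start, end = end,
                 truncated = truncated, sequence = sub),
            class = "promoter_region")
}

#' @export
print.promoter_region <- function(x, ...) {
  cat("Promoter of", x$gene, "(", x$strand, "strand ):", x$length,
      "bp upstream of TSS at", x$tss, "on", x$seqname,
      sprintf("[%d, %d)%s\n", x$start, x$end,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Restrict hits to a TSS-relative window
#'
#' Hit coordinates are promoter-relative (0 = promoter start, promoter of
#' length `promoter_length` ends at the TSS), so promoter position `i`
#' maps to TSS-relative coordinate `i - promoter_length`. A hit is kept
#' when its interval overlaps the window by at least one base; the window
#' is inclusive at its upstream bound and exclusive at its downstream
#' bound (default `[-480, -288)`, the retinoic-acid-responsive region).
#'
#' @param hits hit data frame from [scan_sequence()] / [fimo_scan()] run
#'   on a promoter sequence.
#' @param promoter_length length of the scanned promoter.
#' @param window numeric length-2, TSS-relative `(upstream, downstream)`.
#' @export
restrict_to_region <- function(hits, promoter_length,
                               window = c(-480, -288)) {
  rel_start <- hits$start - promoter_length
  rel_end <- hits$end - promoter_length
  keep <- rel_start < window[2L] & rel_end > window[1L]
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default retinoic-acid response element motif set
#'
#' Direct repeats of the RGKTCA half-site with spacers of 1, 2 and 5 bp
#' (DR1, DR2, DR5), as editable IUPAC strings converted via
#' [iupac_to_pwm()]; `half_site` alone gives the bare half-site model.
#'
#' @param which subset of `c("DR1", "DR2", "DR5", "half_site")`.
#' @param pseudocount,background passed to [iupac_to_pwm()].
#' @return named list of `motif_model`s.
#' @export
rare_motifs <- function(which = c("DR1", "DR2", "DR5"), pseudocount = 0.01,
                        background = rep(0.25, 4)) {
  half <- "RGKTCA"
  defs <- list(DR1 = paste0(half, "N", half),
               DR2 = paste0(half, "NN", half),
               DR5 = paste0(half, "NNNNN", half),
               half_site = half)
  which <- match.arg(which, names(defs), several.ok = TRUE)
  lapply(setNames(which, which), function(nm)
    iupac_to_pwm(defs[[nm]], motif_id = paste0("RARE_", nm),
                 pseudocount = pseudocount, background = background))
}

#' Write motif hits as BED6+
#'
#' Columns: sequence id, start, end, motif id, normalized score, strand,
#' then p-value and q-value.
#'
#' @param hits hit data frame.
#' @param path file path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$sequence_id, hits$start, hits$end, hits$motif_id,
                    signif(hits$normalized_score, 6), hits$strand,
                    hits$p_value, hits$q_value)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
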