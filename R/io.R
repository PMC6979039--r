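#' Read / write FASTA sequence files
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] returning plain
#' named character vectors (the internal sequence representation).
#'
#' @param path file path.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the `MOTIF` / `letter-probability matrix` blocks of a MEME
#' minimal-format file (the `iupac2meme` output dialect); the file's
#' `Background letter frequencies` line, when present, provides the
#' default background.
#'
#' @param path file path.
#' @param pseudocount per-cell pseudocount for the resulting models.
#' @param background override the file background (A, C, G, T
#'   frequencies).
#' @return named list of `motif_model`s.
#' @export
read_meme <- function(path, pseudocount = 0.01, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  bg <- c(0.25, 0.25, 0.25, 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    lets <- toupper(toks[is.na(vals)])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 4L) bg[match(lets, DNA)] <- vals
  }
  if (!is.null(background)) bg <- background
  motif_i <- grep("^MOTIF\\b", lines)
  if (!length(motif_i)) stop("no MOTIF block in ", path)
  out <- list()
  for (mi in motif_i) {
    id <- strsplit(trimws(lines[mi]), "\\s+")[[1L]][2L]
    hdr <- mi + grep("^letter-probability matrix",
                     lines[(mi + 1L):length(lines)])[1L]
    if (is.na(hdr)) stop("motif ", id, " has no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- unname(t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]][1:4]), numeric(4))))
    out[[id]] <- motif_model(t(mat), motif_id = id,
                             pseudocount = pseudocount, background = bg)
  }
  out
}

#' @rdname read_meme
#' @param motifs named list of `motif_model`s.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies", paste(
                 "A", format(motifs[[1L]]$background[1L]),
                 "C", format(motifs[[1L]]$background[2L]),
                 "G", format(motifs[[1L]]$background[3L]),
                 "T", format(motifs[[1L]]$background[4L])), ""), con)
  for (m in motifs) {
    L <- motif_length(m)
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", L),
      con)
    probs <- sweep(m$counts, 2L, colSums(m$counts), "/")
    for (i in seq_len(L))
      writeLines(paste(sprintf("%.6f", probs[, i]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a JASPAR PFM file
#'
#' Accepts the JASPAR position-frequency-matrix text format: a `>`
#' header line followed by four rows, either bracketed
#' (`A [ 3 10 ... ]`) or bare numbers in A, C, G, T order. Multiple
#' records per file are supported.
#'
#' @inheritParams read_meme
#' @return named list of `motif_model`s.
#' @export
read_jaspar <- function(path, pseudocount = 0.1,
                        background = rep(0.25, 4)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' header in ", path)
  out <- list()
  for (h in hdr) {
    id <- sub("^>\\s*", "", lines[h])
    id <- strsplit(id, "\\s+")[[1L]]
    id <- if (length(id) > 1L) id[2L] else id[1L]
    rows <- lines[(h + 1L):(h + 4L)]
    mat <- unname(t(vapply(rows, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }, numeric(nchar_row(lines[h + 1L])))))
    out[[id]] <- motif_model(mat, motif_id = id, pseudocount = pseudocount,
                             background = background)
  }
  out
}

nchar_row <- function(line) {
  l <- gsub("^[ACGTacgt]\\s*", "", trimws(line))
  l <- gsub("[][]", " ", l)
  length(strsplit(trimws(l), "\\s+")[[1L]])
}

#' Read a TF list / TF-to-motif mapping table
#'
#' `read_tf_list()` reads one identifier per line. `read_tf2motif()` reads
#' a two-column tab-separated table (`tf`, `motif_id`) with header.
#'
#' @param path file path.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_tf_list
#' @export
read_tf2motif <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "motif_id") %in% names(df)))
    stop("tf2motif table needs columns tf and motif_id")
  df
}
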