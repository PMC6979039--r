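DNA <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Build a motif model from counts or probabilities
#'
#' A motif model holds the 4 x L base frequency matrix (rows A, C, G, T), a
#' per-cell pseudocount, the background base distribution, and the derived
#' natural-log odds matrix `log(prob / background)` with its cached minimum
#' and maximum attainable scores.
#'
#' Pseudocount convention: probabilities are
#' `(counts + pseudocount) / (column total + 4 * pseudocount)`, i.e. a flat
#' per-cell pseudocount (so counts `(8,0,0,0)` with pseudocount 1 give
#' `9/12` for the observed base).
#'
#' @param x nonnegative 4 x L numeric matrix of counts or probabilities;
#'   rows in A, C, G, T order (rownames, if present, are checked).
#' @param motif_id identifier carried into hit tables.
#' @param pseudocount nonnegative per-cell pseudocount.
#' @param background base frequencies (A, C, G, T), summing to 1, all > 0.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(x, motif_id = "motif", pseudocount = 0.1,
                        background = rep(0.25, 4)) {
  if (!is.matrix(x) || nrow(x) != 4L) stop("x must be a 4 x L matrix")
  if (any(x < 0)) stop("negative entries in motif matrix")
  if (!is.null(rownames(x)) && !identical(toupper(rownames(x)), DNA))
    stop("rows must be in A, C, G, T order")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 frequencies summing to 1")
  dimnames(x) <- list(DNA, NULL)
  m <- structure(list(motif_id = motif_id, counts = x,
                      pseudocount = pseudocount,
                      background = setNames(as.numeric(background), DNA)),
                 class = "motif_model")
  build_log_odds(m)
}

#' Derive the log-odds matrix of a motif model
#'
#' Applies the pseudocount, renormalizes each column, and fills
#' `log_odds[b, i] = ln(prob[b, i] / background[b])` together with the
#' cached minimum and maximum attainable window scores.
#'
#' @param motif a `motif_model`.
#' @return the model with `probs`, `log_odds`, `min_score`, `max_score`
#'   set.
#' @export
build_log_odds <- function(motif) {
  if (!inherits(motif, "motif_model")) stop("not a motif_model")
  if (any(motif$background <= 0))
    stop("zero background frequency: log-odds undefined")
  cs <- colSums(motif$counts)
  if (any(cs <= 0)) stop("empty motif column")
  probs <- sweep(motif$counts + motif$pseudocount, 2L,
                 cs + 4 * motif$pseudocount, "/")
  lo <- log(probs / motif$background)
  motif$probs <- probs
  motif$log_odds <- lo
  motif$min_score <- sum(apply(lo, 2L, min))
  motif$max_score <- sum(apply(lo, 2L, max))
  motif
}

#' Convert an IUPAC consensus string to a motif model
#'
#' Each IUPAC symbol becomes a column that is uniform over the symbol's
#' base set before the pseudocount is applied (e.g. `R` gives A = G = 1/2,
#' `N` gives 1/4 each).
#'
#' @param consensus string over the IUPAC nucleotide alphabet.
#' @param motif_id identifier (defaults to the consensus string).
#' @param pseudocount per-cell pseudocount applied to the unit-total
#'   probability columns (keep it small relative to 1).
#' @inheritParams motif_model
#' @export
iupac_to_pwm <- function(consensus, motif_id = consensus, pseudocount = 0.01,
                         background = rep(0.25, 4)) {
  chars <- strsplit(toupper(consensus), "")[[1L]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) stop("non-IUPAC character(s): ", paste(bad, collapse = ""))
  cols <- vapply(chars, function(ch) {
    v <- numeric(4)
    names(v) <- DNA
    v[IUPAC_SETS[[ch]]] <- 1 / length(IUPAC_SETS[[ch]])
    v
  }, numeric(4))
  motif_model(cols, motif_id = motif_id, pseudocount = pseudocount,
              background = background)
}

#' Highest-probability word of a motif
#'
#' Column-wise argmax (ties broken toward the earlier base in A, C, G, T
#' order, deterministically).
#'
#' @param motif a `motif_model`.
#' @return character string of the motif's length.
#' @export
consensus_word <- function(motif) {
  paste(DNA[apply(motif$probs, 2L, which.max)], collapse = "")
}

motif_length <- function(motif) ncol(motif$log_odds)

#' Normalized binding score of a raw PWM score
#'
#' `(raw - min attainable) / (max attainable - min attainable)`, in
#' `[0, 1]`: 1 is attained exactly by the column-wise argmax word(s), 0 by
#' the argmin word(s).
#'
#' @param motif a `motif_model`.
#' @param raw_score raw log-odds score(s).
#' @export
normalized_score <- function(motif, raw_score) {
  rng <- motif$max_score - motif$min_score
  if (rng <= 0) stop("uniform motif: score range is zero")
  (raw_score - motif$min_score) / rng
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif", x$motif_id, "| length", motif_length(x),
      "| consensus", consensus_word(x), "\n")
  cat(sprintf("score range [%.3f, %.3f] nats, pseudocount %g\n",
              x$min_score, x$max_score, x$pseudocount))
  invisible(x)
}

# Integer score lattice of a motif at granularity `g`: entries floored to
# lattice units. Returns the exact tail distribution of the lattice score
# of a random background word, as a function tail(s) = P(D >= s).
pwm_lattice <- function(motif, granularity) {
  if (granularity <= 0) stop("granularity must be positive")
  d <- matrix(as.integer(floor(motif$log_odds / granularity)), nrow = 4L)
  L <- ncol(d)
  lo <- sum(apply(d, 2L, min))
  hi <- sum(apply(d, 2L, max))
  dist <- 1
  offset <- 0L
  bg <- motif$background
  for (i in seq_len(L)) {
    di <- d[, i]
    mi <- min(di)
    newlen <- length(dist) + (max(di) - mi)
    nd <- numeric(newlen)
    for (b in 1:4) {
      sh <- di[b] - mi
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + bg[b] * dist
    }
    dist <- nd
    offset <- offset + mi
  }
  tail <- rev(cumsum(rev(dist)))
  list(d = d, L = L, lo = lo, hi = hi, offset = offset, tail = tail,
       granularity = granularity)
}

# Bounds on P(raw background score >= t) from the lattice:
# upper uses threshold floor(t/g) - L (superset of the exact event),
# lower uses ceiling(t/g) (subset). Exact p lies within [lower, upper].
lattice_pvalue <- function(lat, t) {
  g <- lat$granularity
  p_at <- function(s) {
    i <- s - lat$offset + 1L
    if (i <= 0L) return(1)
    if (i > length(lat$tail)) return(0)
    lat$tail[i]
  }
  up <- p_at(as.integer(floor(t / g)) - lat$L)
  low <- p_at(as.integer(ceiling(t / g)))
  c(lower = low, upper = up)
}

#' Exact p-value of a PWM score by dynamic programming
#'
#' Computes `P(score of a random background word >= raw_score)` over the
#' lattice of log-odds scores floored to multiples of `granularity`. The
#' returned value is a guaranteed upper bound on the infinite-precision
#' p-value; the matching lower bound brackets it within the lattice
#' resolution (`(L + 1) * granularity` on the score axis). When
#' `threshold` is supplied and the bracket straddles it, the granularity is
#' refined (up to `max_refine` times, 4x each) until the decision is
#' unambiguous or the refinement budget is exhausted.
#'
#' @param motif a `motif_model`.
#' @param raw_score raw log-odds score.
#' @param granularity lattice step on the log-odds scale.
#' @param threshold optional decision threshold triggering refinement.
#' @param max_refine maximum number of 4-fold granularity refinements.
#' @return p-value (upper bound), with the lower bound in
#'   `attr(, "lower")`.
#' @export
pwm_pvalue <- function(motif, raw_score, granularity = 1e-3,
                       threshold = NULL, max_refine = 3L) {
  g <- granularity
  repeat {
    lat <- pwm_lattice(motif, g)
    b <- lattice_pvalue(lat, raw_score)
    if (is.null(threshold) || max_refine <= 0L ||
        !(b["lower"] < threshold && b["upper"] >= threshold))
      break
    g <- g / 4
    max_refine <- max_refine - 1L
  }
  structure(unname(b["upper"]), lower = unname(b["lower"]))
}
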