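# Independent brute-force oracles, deliberately written in the most naive
# style so they share no code path with the package implementation.

# Step-by-step GSEA running sum: literal loop over the ranked list.
oracle_enrichment_score <- function(genes, scores, members, exponent = 1) {
  N <- length(genes)
  hit <- genes %in% members
  w <- abs(scores)^exponent
  sumw <- sum(w[hit])
  nmiss <- N - sum(hit)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + w[i] / sumw else cur - 1 / nmiss
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# One-pass DPI by exhaustive triplet enumeration over node labels.
oracle_dpi <- function(edges, tolerance = 0) {
  nodes <- sort(unique(c(edges$tf, edges$target)))
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  mi <- setNames(edges$mi, mapply(ekey, edges$tf, edges$target))
  has <- function(a, b) !is.na(mi[ekey(a, b)])
  doomed <- character(0)
  n <- length(nodes)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (!(i < j && j < k)) next
    a <- nodes[i]; b <- nodes[j]; c <- nodes[k]
    if (!(has(a, b) && has(a, c) && has(b, c))) next
    keys <- c(ekey(a, b), ekey(a, c), ekey(b, c))
    vals <- mi[keys]
    lo <- which(vals == min(vals))
    if (length(lo) != 1L) next
    if (vals[lo] < min(vals[-lo]) * (1 - tolerance))
      doomed <- c(doomed, keys[lo])
  }
  keep <- !(mapply(ekey, edges$tf, edges$target) %in% doomed)
  edges[keep, , drop = FALSE]
}

# Exact PWM score tail by enumerating all 4^L words.
oracle_pwm_tail <- function(log_odds, background, threshold) {
  L <- ncol(log_odds)
  words <- expand.grid(rep(list(1:4), L))
  total <- 0
  for (r in seq_len(nrow(words))) {
    idx <- as.integer(words[r, ])
    sc <- sum(log_odds[cbind(idx, seq_len(L))])
    if (sc >= threshold) total <- total + prod(background[idx])
  }
  total
}

# A random ranked signature plus a random regulon drawn from its genes.
random_signature_case <- function(seed, n = 60, k_max = 12) {
  set.seed(seed)
  genes <- paste0("g", sample(1000, n))
  scores <- round(rnorm(n, sd = 3), 3)
  k <- sample(2:k_max, 1)
  members <- sample(genes, k)
  list(sig = ranked_signature(genes, scores), members = members)
}

# Markov-chain triplet X -> Y -> Z as an expression matrix.
chain_matrix <- function(n, w1 = 0.8, w2 = 0.8, noise = 0.6, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- w1 * x + rnorm(n, sd = noise)
  z <- w2 * y + rnorm(n, sd = noise)
  m <- rbind(X = x, Y = y, Z = z)
  colnames(m) <- paste0("c", seq_len(n))
  m
}
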