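# Independent oracles and fixture builders used across the suite. These are
# deliberately written as brute-force enumerations, independent of the code
# paths they check.

# Exhaustive search over every (gene subset, layer subset) pair satisfying
# the miner's feasibility constraints (min size, per-layer mean internal
# weight >= threshold, per-gene mean attachment weight >= threshold over the
# selected layers); returns the maximum heaviness, 0 if no pair is feasible.
oracle_best_heaviness <- function(tensor, threshold = 0.41, min_size = 3L) {
  n <- length(tensor$genes)
  m <- length(tensor$layers)
  best <- 0
  for (b in seq_len(2^n - 1L)) {
    idx <- which(as.logical(bitwAnd(b, 2^(seq_len(n) - 1L))))
    s <- length(idx)
    if (s < min_size) next
    for (lb in seq_len(2^m - 1L)) {
      ls <- which(as.logical(bitwAnd(lb, 2^(seq_len(m) - 1L))))
      hk <- vapply(ls, function(k) sum(tensor$a[idx, idx, k]) / 2, numeric(1L))
      if (any(hk / choose(s, 2) < threshold - 1e-12)) next
      att <- vapply(idx, function(g) sum(tensor$a[g, idx, ls]), numeric(1L)) /
        ((s - 1) * length(ls))
      if (min(att) < threshold - 1e-12) next
      h <- sum(hk)
      if (h > best) best <- h
    }
  }
  best
}

# Hypergeometric upper tail P(X >= k) by direct mass summation (no phyper).
brute_hyper_tail <- function(k, K, n, N) {
  j <- seq.int(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Dense symmetric tensor with i.i.d. U(0,1) off-diagonal weights.
random_dense_tensor <- function(n, m, seed) {
  set.seed(seed)
  a <- array(0, dim = c(n, n, m))
  for (k in seq_len(m)) {
    u <- matrix(0, n, n)
    u[upper.tri(u)] <- stats::runif(n * (n - 1) / 2)
    a[, , k] <- u + t(u)
  }
  genes <- sprintf("g%02d", seq_len(n))
  layers <- sprintf("L%d", seq_len(m))
  dimnames(a) <- list(genes, genes, layers)
  structure(list(genes = genes, layers = layers, a = a),
            class = "multilayer_tensor")
}

# Tensor wrapper for a hand-built array (names added if absent).
as_tensor <- function(a) {
  n <- dim(a)[1L]
  m <- dim(a)[3L]
  genes <- sprintf("g%02d", seq_len(n))
  layers <- sprintf("L%d", seq_len(m))
  dimnames(a) <- list(genes, genes, layers)
  structure(list(genes = genes, layers = layers, a = a),
            class = "multilayer_tensor")
}

# Write a small edge list to a temp file and return the path.
edge_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
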