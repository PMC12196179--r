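# Independent oracles used to cross-check the package's own algorithms.
# These deliberately use different machinery than the implementation:
# matrix-power path counting instead of Brandes, exhaustive subset
# enumeration instead of distribution functions, and the textbook Welch
# formulas instead of t.test().

# All-pairs shortest-path centralities via adjacency-matrix powers:
# the first power k with (A^k)[s,t] > 0 gives the distance, and its entry
# counts the shortest s-t paths.
oracle_centralities <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$from[i], net$edges$to[i]] <- 1
    A[net$edges$to[i], net$edges$from[i]] <- 1
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- diag(1, n)
  Ak <- diag(1, n)
  for (k in seq_len(n - 1)) {
    Ak <- Ak %*% A
    newly <- is.infinite(D) & Ak > 0
    D[newly] <- k
    S[newly] <- Ak[newly]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && is.finite(D[s, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
          acc <- acc + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
    bc[v] <- acc
  }
  cc <- vapply(seq_len(n), function(s) {
    d <- D[s, -s]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (n - 1))
  }, numeric(1))
  tibble::tibble(node = net$nodes, dc = as.integer(rowSums(A)), bc = bc, cc = cc)
}

# Exhaustive hypergeometric tail: enumerate every size-n draw from a
# background of N genes of which the first K are annotated.
oracle_hypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Textbook Welch statistic with Satterthwaite degrees of freedom.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Erdos-Renyi test graph as a ppi_network (non-isolated nodes only, by
# construction of the container).
random_test_network <- function(n, p, seed) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample(ncol(pairs), 1)] <- TRUE
  labels <- sprintf("N%02d", seq_len(n))
  ppi_network(tibble::tibble(
    from = labels[pairs[1, keep]],
    to = labels[pairs[2, keep]],
    confidence = 1
  ))
}
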