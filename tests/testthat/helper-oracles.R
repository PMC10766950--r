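# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Brute-force BH by definition: adjusted p_i = min over sorted positions
# j >= rank(i) of m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(ord == i)
    cand <- vapply(ri:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj[i] <- min(1, cand)
  }
  adj
}

# Exhaustive hypergeometric upper tail: enumerate every draw of size |B|
# from the background and count overlaps >= k.
hyper_brute <- function(background, setA, sizeB, k) {
  draws <- utils::combn(background, sizeB)
  hits <- apply(draws, 2, function(d) length(intersect(d, setA)) >= k)
  mean(hits)
}

# Floyd-Warshall all-pairs shortest paths on an unweighted adjacency matrix.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dimnames(d) <- dimnames(adj)
  d
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two vectors with an exact sample Pearson correlation rho.
vectors_with_cor <- function(rho, n = 20) {
  x <- seq_len(n)
  z <- stats::residuals(stats::lm(rnorm(n) ~ x))
  xs <- as.numeric(scale(x)); zs <- as.numeric(scale(z))
  list(x = xs, y = rho * xs + sqrt(1 - rho^2) * zs)
}

# Small single-tissue count container built by hand.
toy_counts <- function(counts, genotype, tissue = "DRG", fl = character()) {
  colnames(counts) <- colnames(counts) %||% paste0("s", seq_len(ncol(counts)))
  meta <- data.frame(sample_id = colnames(counts), tissue = tissue,
                     genotype = genotype, sex = "F")
  fd_counts(counts, meta, fl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
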