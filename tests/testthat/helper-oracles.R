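# Independent brute-force oracles and small fixtures used across the suite.
# All oracles are deliberately naive (double/triple loops, subset
# enumeration) and share no code with the implementation paths they check.

options(hlca.quiet = TRUE)

path_ppi <- function() ppi_network(rbind(c("a", "b"), c("b", "c")))

triangle_ppi <- function() {
  ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
}

clique_edges <- function(ids) t(utils::combn(ids, 2L))

two_cliques_bridge <- function(k = 4L) {
  ppi_network(rbind(clique_edges(paste0("x", 1:k)),
                    clique_edges(paste0("y", 1:k)),
                    c("x1", "y1")))
}

# Erdos-Renyi network fixture with guaranteed non-emptiness.
random_ppi <- function(n, p, seed) {
  prs <- t(utils::combn(sprintf("n%02d", 1:n), 2L))
  keep <- withr::with_seed(seed, stats::runif(nrow(prs)) < p)
  if (!any(keep)) keep[1L] <- TRUE
  ppi_network(prs[keep, , drop = FALSE])
}

# Set-based edge-list cleaner: the dedup/self-loop oracle for ppi_io.
brute_clean_pairs <- function(u, v) {
  keep <- u != v
  key <- paste(pmin(u[keep], v[keep]), pmax(u[keep], v[keep]))
  length(unique(key))
}

# O(n^2) double-loop modularity under the package's stated convention:
# self-pairs excluded from the adjacency term, retained in the null term,
# m = half the off-diagonal sum of the normalized adjacency.
brute_modularity <- function(hg, membership) {
  A <- as.matrix(normalized_adjacency(hg))
  n <- nrow(A)
  P <- outer(hg$Dv, hg$Dv) / sum(hg$Dv)
  m <- (sum(A) - sum(diag(A))) / 2
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      if (i != j) q <- q + A[i, j]
      q <- q - P[i, j]
    }
  }
  q / (2 * m)
}

# Exponential-time maximal-clique enumeration over all node subsets.
brute_max_cliques <- function(ppi, min_size = 3L) {
  A <- as.matrix(ppi$adjacency)
  n <- nrow(A)
  is_clique <- function(s) all(A[s, s][upper.tri(diag(length(s)))] == 1)
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(s) < min_size || !is_clique(s)) next
    maximal <- !any(vapply(setdiff(seq_len(n), s), function(v) {
      all(A[v, s] == 1)
    }, NA))
    if (maximal) cliques[[length(cliques) + 1L]] <- s
  }
  cliques
}

set_signature <- function(sets) sort(vapply(sets, function(s) paste(sort(s), collapse = ","), ""))

# Triple-loop common-neighbour counts.
brute_common_neighbours <- function(ppi) {
  A <- as.matrix(ppi$adjacency)
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    S[i, j] <- S[i, j] + A[i, k] * A[k, j]
  }
  S
}

# Dense evaluation of the two-layer hypergraph convolution.
dense_convolve <- function(hg, X, theta) {
  H <- as.matrix(hg$incidence)
  M <- diag(1 / sqrt(hg$Dv)) %*% H %*% diag(hg$omega / sqrt(hg$De), nrow = length(hg$De)) %*%
    t(H) %*% diag(1 / sqrt(hg$Dv))
  r <- function(x) pmax(x, 0)
  Z1 <- r(M %*% (X %*% theta[[1L]]))
  r(M %*% (Z1 %*% theta[[2L]]))
}

# All set partitions of 1..n (Bell-number enumeration, tiny n only).
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (lab in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, lab)
  }
  out
}
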