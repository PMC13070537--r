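#' Clique-expansion adjacency of a hypergraph
#'
#' Replaces every hyperedge by a clique over its members, weighted by the
#' hyperedge weight: \eqn{A_{clique} = H W H^T}. The diagonal of the raw
#' product is retained; callers that need the loop-free weighted degree
#' remove it (\code{deg(v) = \sum_e H(v,e)\,\omega(e)\,(D_e(e)-1)}).
#'
#' @param hg a \code{hypergraph}.
#' @return a sparse symmetric matrix.
#' @export
clique_adjacency <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  H <- hg$incidence
  H %*% Matrix::Diagonal(x = hg$omega) %*% Matrix::t(H)
}

#' Degree-preserving normalized adjacency of a hypergraph
#'
#' The clique expansion \eqn{H W H^T} inflates the degree of nodes sitting in
#' large hyperedges. Normalising each hyperedge's contribution by
#' \eqn{(D_e - I)^{-1}} restores the hypergraph degrees exactly:
#' \eqn{A_{hyp} = H\,W\,(D_e - I)^{-1} H^T} satisfies
#' \eqn{\sum_{j \ne i} A_{hyp}(i,j) = D_v(i)} for every node \eqn{i}. This is
#' the weighted graph on which modularity is optimised.
#'
#' @param hg a \code{hypergraph}; every hyperedge must have size >= 2.
#' @return a sparse symmetric matrix (diagonal entries present; modularity
#'   sums exclude them).
#' @export
normalized_adjacency <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  if (any(hg$De < 2)) stop("hyperedge of size 1 violates the hypergraph invariant", call. = FALSE)
  H <- hg$incidence
  H %*% Matrix::Diagonal(x = hg$omega / (hg$De - 1)) %*% Matrix::t(H)
}

#' Degree-preserving null model
#'
#' Expected interaction weight between nodes under random rewiring that
#' preserves the weighted hypergraph degrees:
#' \eqn{P_{hyp}(i,j) = D_v(i) D_v(j) / \sum_v D_v(v)}. The grand sum of the
#' matrix equals the total node degree.
#'
#' @param hg a \code{hypergraph}.
#' @return a dense symmetric rank-1 matrix.
#' @export
null_expectation <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  tot <- total_node_degree(hg)
  if (tot <= 0) stop("total node degree must be positive", call. = FALSE)
  outer(hg$Dv, hg$Dv) / tot
}

#' Hypergraph modularity of a partition
#'
#' Newman-style modularity on the degree-preserving weighted graph:
#' \deqn{Q = \frac{1}{2m} \sum_{ij} [A_{hyp}(i,j) - P_{hyp}(i,j)]\,
#'   \delta(c_i, c_j)}
#' where self-pairs are excluded from the \eqn{A_{hyp}} term (the weighted
#' graph is loop-free) but retained in the null term, and
#' \eqn{m} is half the off-diagonal sum of \eqn{A_{hyp}} (equal to
#' \eqn{\sum_v D_v / 2} by degree preservation). \eqn{Q} is invariant under
#' relabelling of communities.
#'
#' @param hg a \code{hypergraph}.
#' @param membership integer vector of community labels, one per node.
#' @return a scalar in \eqn{[-1, 1]}.
#' @export
hg_modularity <- function(hg, membership) {
  stopifnot(inherits(hg, "hypergraph"))
  n <- length(hg$node_ids)
  if (length(membership) != n) stop("membership must cover all nodes", call. = FALSE)
  A <- methods::as(normalized_adjacency(hg), "TsparseMatrix")
  off <- A@i != A@j
  two_m <- sum(A@x[off])
  if (two_m <= 0) stop("degenerate weighted graph (m = 0)", call. = FALSE)
  within <- off & (membership[A@i + 1L] == membership[A@j + 1L])
  a_in <- sum(A@x[within])
  dtot <- tapply(hg$Dv, membership, sum)
  p_in <- sum(dtot^2) / total_node_degree(hg)
  (a_in - p_in) / two_m
}

#' Optimise a partition by seeded local moves
#'
#' Louvain-style first phase on the degree-preserving weighted graph: every
#' node starts in its own community; nodes are visited in an order shuffled
#' once per sweep from the run seed, and a node moves to the neighbouring
#' community with the largest strictly positive modularity gain (ties broken
#' toward the lowest community label). Sweeps repeat until a full sweep makes
#' no move. The result is deterministic given the seed and its modularity is
#' never below that of the singleton partition.
#'
#' @param hg a \code{hypergraph}.
#' @param seed integer seed controlling the node visit order.
#' @param gain_tol minimum modularity gain for a move (guards float noise).
#' @return integer vector of dense community labels (1-based, labelled by
#'   first appearance in node order).
#' @export
optimize_partition <- function(hg, seed = 1L, gain_tol = 1e-10) {
  stopifnot(inherits(hg, "hypergraph"))
  n <- length(hg$node_ids)
  A <- methods::as(normalized_adjacency(hg), "TsparseMatrix")
  off <- A@i != A@j
  ei <- A@i[off] + 1L; ej <- A@j[off] + 1L; ex <- A@x[off]
  # symmetric storage: both (i,j) and (j,i) present, so per-node rows of the
  # weighted graph are the entries with ei == node
  nbr <- split(seq_along(ei), ei)
  k <- numeric(n)
  ks <- tapply(ex, ei, sum)
  k[as.integer(names(ks))] <- ks
  two_m <- sum(ex)
  if (two_m <= 0) stop("degenerate weighted graph (m = 0)", call. = FALSE)
  m <- two_m / 2
  comm <- seq_len(n)
  dtot <- k
  with_seed(seed, {
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        rows <- nbr[[as.character(i)]]
        if (is.null(rows)) next
        js <- ej[rows]; ws <- ex[rows]
        ci <- comm[i]
        dtot[ci] <- dtot[ci] - k[i]
        link <- tapply(ws, comm[js], sum)
        cand <- as.integer(names(link))
        if (!(ci %in% cand)) { cand <- c(cand, ci); link <- c(link, 0) }
        gain <- as.numeric(link) / m - k[i] * dtot[cand] / (2 * m * m)
        best <- order(-gain, cand)[1L]
        base <- gain[match(ci, cand)]
        if (cand[best] != ci && gain[best] > base + gain_tol) {
          comm[i] <- cand[best]
          dtot[cand[best]] <- dtot[cand[best]] + k[i]
          moved <- TRUE
        } else {
          dtot[ci] <- dtot[ci] + k[i]
        }
      }
      if (!moved) break
    }
  })
  match(comm, unique(comm))
}

#' Aggregate a partitioned hypergraph into supernodes
#'
#' Collapses each community into a supernode. Every hyperedge maps to the set
#' of supernodes it touches; hyperedges that fall entirely inside one
#' supernode vanish (size-1 images are dropped), identical images are merged,
#' and weights are recomputed as \eqn{\omega(e) = 1/|e|} on the new sets.
#'
#' @param hg a \code{hypergraph}.
#' @param membership integer community labels, one per node.
#' @return a list with \code{hypergraph} (the aggregated level) and
#'   \code{groups} (list mapping each supernode to the node indices of the
#'   input level it absorbs, in deterministic order).
#' @export
aggregate_hypergraph <- function(hg, membership) {
  stopifnot(inherits(hg, "hypergraph"))
  n <- length(hg$node_ids)
  if (length(membership) != n) stop("membership must cover all nodes", call. = FALSE)
  # supernodes ordered by their smallest constituent node index
  first <- tapply(seq_len(n), membership, min)
  labs <- as.integer(names(sort(first)))
  snode <- match(membership, labs)
  groups <- split(seq_len(n), snode)
  images <- lapply(hg$hyperedges, function(e) sort(unique(snode[e])))
  images <- images[lengths(images) >= 2L]
  if (length(images)) {
    images <- images[!duplicated(vapply(images, set_key, ""))]
    images <- images[order(vapply(images, min, 1L), lengths(images))]
  }
  list(hypergraph = new_hypergraph(paste0("sn", seq_along(groups)), images),
       groups = groups)
}

#' Hierarchical compression of a hypergraph
#'
#' Alternates modularity optimisation and supernode aggregation, producing a
#' stack of progressively smaller hypergraphs. Level 1 is the input
#' hypergraph; each further level collapses the optimised communities of the
#' previous one. Compression stops when a sweep finds no improving move, when
#' aggregation no longer shrinks the hypergraph, when the aggregated
#' hyperedge set becomes empty, or at \code{max_levels}.
#'
#' @param hg a \code{hypergraph}.
#' @param max_levels maximum number of levels to retain (including level 1).
#' @param seed integer seed; level \eqn{\ell} uses \code{seed +} \eqn{\ell}
#'   for its visit order, so the whole stack is reproducible.
#' @param gain_tol minimum modularity gain for a local move.
#' @return an object of class \code{level_stack}: \code{levels} (list of
#'   hypergraphs), \code{lineage} (per level, a list mapping each node of
#'   that level to the original node indices it represents), \code{q} (the
#'   optimised modularity measured at each level where optimisation ran),
#'   and \code{he} (the level count).
#' @export
compress <- function(hg, max_levels = 5L, seed = 1L, gain_tol = 1e-10) {
  stopifnot(inherits(hg, "hypergraph"), max_levels >= 1L)
  n <- length(hg$node_ids)
  levels <- list(hg)
  lineage <- list(as.list(seq_len(n)))
  q <- numeric(0)
  while (length(levels) < max_levels) {
    cur <- levels[[length(levels)]]
    part <- optimize_partition(cur, seed = seed + length(levels), gain_tol = gain_tol)
    q <- c(q, hg_modularity(cur, part))
    if (max(part) == length(cur$node_ids)) break   # all singletons: converged
    agg <- aggregate_hypergraph(cur, part)
    if (length(agg$hypergraph$hyperedges) == 0L) break
    if (length(agg$hypergraph$node_ids) == length(cur$node_ids)) break
    prev <- lineage[[length(lineage)]]
    lineage[[length(lineage) + 1L]] <-
      unname(lapply(agg$groups, function(g) sort(unlist(prev[g], use.names = FALSE))))
    levels[[length(levels) + 1L]] <- agg$hypergraph
  }
  structure(list(levels = levels, lineage = lineage, q = q,
                 he = length(levels)), class = "level_stack")
}

#' @export
print.level_stack <- function(x, ...) {
  cat(sprintf("<level_stack> %d level(s): %s nodes\n", x$he,
              paste(vapply(x$levels, function(h) length(h$node_ids), 1L),
                    collapse = " -> ")))
  invisible(x)
}
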