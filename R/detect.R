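#' Cosine-weighted PPI network
#'
#' Re-weights every PPI edge by the cosine similarity of the two proteins'
#' final embedding rows (clamped to \eqn{[-1, 1]}). The topology is that of
#' the source network; only edges carry weights. A zero-norm embedding row
#' yields weight 0 with a logged warning.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @param fd final embedding matrix, one row per node (as from
#'   \code{\link{embed_levels}}).
#' @return an object of class \code{weighted_ppi}: the network plus
#'   \code{weights} (per edge, aligned with \code{ppi$edges}) and \code{wmat}
#'   (sparse symmetric weight matrix).
#' @export
build_weighted_network <- function(ppi, fd) {
  stopifnot(inherits(ppi, "ppi_network"))
  fd <- as.matrix(fd)
  if (nrow(fd) != n_nodes(ppi)) stop("fd must have one row per node", call. = FALSE)
  nrm <- sqrt(rowSums(fd^2))
  if (any(nrm == 0)) {
    hlca_message(sprintf("%d zero-norm embedding row(s); their edge weights set to 0",
                         sum(nrm == 0)))
  }
  ei <- ppi$edges[, 1L]; ej <- ppi$edges[, 2L]
  dot <- rowSums(fd[ei, , drop = FALSE] * fd[ej, , drop = FALSE])
  den <- nrm[ei] * nrm[ej]
  w <- ifelse(den > 0, dot / den, 0)
  w <- pmin(1, pmax(-1, w))
  wmat <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = c(w, w),
                               dims = rep(n_nodes(ppi), 2L),
                               dimnames = list(ppi$node_ids, ppi$node_ids))
  structure(c(ppi, list(weights = w, wmat = wmat)),
            class = c("weighted_ppi", "ppi_network"))
}

# Sum of pairwise cosine weights over the PPI edges inside a node-index set
# (the candidate-core ranking score; not size-normalised).
cosine_density <- function(idx, wmat) {
  if (length(idx) < 2L) return(0)
  sum(wmat[idx, idx]) / 2
}

# Unweighted cluster density 2E / (N (N - 1)); 0 below two nodes.
edge_density_idx <- function(idx, adj) {
  nn <- length(idx)
  if (nn < 2L) return(0)
  e <- sum(adj[idx, idx]) / 2
  2 * e / (nn * (nn - 1))
}

new_core_cluster <- function(members, density, stage) {
  structure(list(members = members, density = density, stage = stage),
            class = "core_cluster")
}

#' Enumerate candidate cores (maximal cliques)
#'
#' All maximal cliques of the network topology with at least
#' \code{min_size} nodes, each scored by the sum of its pairwise cosine
#' weights and returned in deterministic order (score descending, then
#' lexicographic members).
#'
#' @param gw a \code{weighted_ppi}.
#' @param min_size minimum clique size (default 3; smaller complexes are
#'   considered biologically unreliable).
#' @return list of \code{core_cluster} objects at stage \code{"candidate"},
#'   members stored as node indices.
#' @export
enumerate_cliques <- function(gw, min_size = 3L) {
  stopifnot(inherits(gw, "weighted_ppi"))
  g <- igraph::graph_from_edgelist(gw$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes(gw) - igraph::vcount(g)))
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  dens <- vapply(cl, cosine_density, 0, wmat = gw$wmat)
  keys <- vapply(cl, function(x) set_key(gw$node_ids[x]), "")
  ord <- order(-dens, keys)
  mapply(function(m, d) new_core_cluster(m, d, "candidate"),
         cl[ord], dens[ord], SIMPLIFY = FALSE)
}

#' Select pairwise-disjoint seed cores
#'
#' Greedy selection: move the densest candidate into the seed set, strip its
#' members from every remaining candidate, drop candidates that fall below
#' three members, recompute densities on the stripped sets, re-sort, and
#' repeat until no candidates remain. Seeds are pairwise disjoint by
#' construction.
#'
#' @param candidates list of \code{core_cluster} from
#'   \code{\link{enumerate_cliques}}.
#' @param gw the \code{weighted_ppi} (for density recomputation).
#' @return list of \code{core_cluster} at stage \code{"seed"}.
#' @export
select_seed_cores <- function(candidates, gw) {
  stopifnot(inherits(gw, "weighted_ppi"))
  sets <- lapply(candidates, `[[`, "members")
  seeds <- list()
  while (length(sets) > 0L) {
    dens <- vapply(sets, cosine_density, 0, wmat = gw$wmat)
    keys <- vapply(sets, function(x) set_key(gw$node_ids[x]), "")
    top <- order(-dens, keys)[1L]
    chosen <- sets[[top]]
    seeds[[length(seeds) + 1L]] <- new_core_cluster(chosen, dens[top], "seed")
    sets <- lapply(sets[-top], setdiff, chosen)
    sets <- sets[lengths(sets) >= 3L]
  }
  seeds
}

#' Grow a seed core by density-increasing neighbours
#'
#' Evaluates the cluster's first-order PPI neighbours, ranked by (edges into
#' the cluster, descending; node identifier ascending) - the number of edges
#' a candidate has into the cluster counts exactly the triangles it closes
#' with cluster edges. A neighbour is admitted only when the unweighted
#' cluster density \eqn{2E/(N(N-1))} strictly increases; the scan repeats
#' until no neighbour is admissible. A consequence of strictness: a clique
#' never grows, since no addition can raise density 1.
#'
#' @param seed a \code{core_cluster} of size >= 3.
#' @param ppi the \code{\link{ppi_network}}.
#' @return the grown \code{core_cluster} at stage \code{"core"}.
#' @export
grow_core <- function(seed, ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  adj <- ppi$adjacency
  members <- seed$members
  repeat {
    cur <- edge_density_idx(members, adj)
    nbr <- setdiff(which(Matrix::rowSums(adj[, members, drop = FALSE]) > 0), members)
    if (length(nbr) == 0L) break
    into <- Matrix::rowSums(adj[nbr, members, drop = FALSE])
    nbr <- nbr[order(-into, ppi$node_ids[nbr])]
    admitted <- FALSE
    for (v in nbr) {
      if (edge_density_idx(c(members, v), adj) > cur) {
        members <- sort(c(members, v))
        admitted <- TRUE
        break
      }
    }
    if (!admitted) break
  }
  new_core_cluster(members, edge_density_idx(members, adj), "core")
}

#' Filter grown cores by the density threshold
#'
#' Keeps cores whose unweighted cluster density reaches \code{dens}; the
#' survivors are the valid core clusters passed to attachment.
#'
#' @param grown list of \code{core_cluster}.
#' @param dens density threshold in \eqn{[0, 1]} (default 0.8).
#' @param ppi the \code{\link{ppi_network}}.
#' @return the filtered list.
#' @export
filter_cores <- function(grown, dens = 0.8, ppi) {
  stopifnot(dens >= 0, dens <= 1)
  keep <- vapply(grown, function(cc) {
    edge_density_idx(cc$members, ppi$adjacency) >= dens
  }, NA)
  grown[keep]
}

#' Edge density of a node set (hyperedge density)
#'
#' Treating the cluster (plus a candidate node) as a hyperedge, its internal
#' connectivity is the fraction of member pairs joined by a PPI edge:
#' \eqn{2 \sum_{pairs} \gamma(e) / (k(k-1))}. Identical to the unweighted
#' cluster density on the same node set.
#'
#' @param node_set character vector of protein identifiers (size >= 2).
#' @param ppi the \code{\link{ppi_network}}.
#' @return a value in \eqn{[0, 1]}.
#' @export
hyperedge_density <- function(node_set, ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  idx <- match(unique(node_set), ppi$node_ids)
  idx <- idx[!is.na(idx)]
  if (length(unique(node_set)) < 2L) stop("node set must have at least 2 members", call. = FALSE)
  nn <- length(unique(node_set))
  e <- if (length(idx) >= 2L) sum(ppi$adjacency[idx, idx]) / 2 else 0
  2 * e / (nn * (nn - 1))
}

#' Maximum overlap of a node set with other cores
#'
#' The largest Jaccard index between the (enlarged) core and any other core;
#' 0 when there are no other cores. Caps node sharing between complexes
#' during attachment.
#'
#' @param node_set character vector of protein identifiers.
#' @param others list of character vectors (the other cores).
#' @return a value in \eqn{[0, 1]}.
#' @export
hyperedge_overlap <- function(node_set, others) {
  if (length(others) == 0L) return(0)
  s <- unique(node_set)
  max(vapply(others, function(o) {
    o <- unique(o)
    length(intersect(s, o)) / length(union(s, o))
  }, 0))
}

#' Attach peripheral proteins to core clusters
#'
#' Candidate proteins (those not in any core) are gradually absorbed:
#' for each core, the adjacent candidate whose admission keeps the enlarged
#' cluster's edge density highest is tested first, and it joins when that
#' density reaches \code{epsilon} and the enlarged cluster's maximum Jaccard
#' overlap with the other cores stays at or below \code{theta}. Each
#' admission updates the cluster before the next candidate is evaluated, so
#' density degrades monotonically toward \code{epsilon} and absorption
#' terminates; a protein may still join several cores under the overlap
#' cap. Ties break on node identifier; duplicate final complexes are
#' emitted once.
#'
#' @param cores list of \code{core_cluster} (the valid core clusters).
#' @param ppi the \code{\link{ppi_network}}.
#' @param epsilon hyperedge-density threshold in \eqn{[0, 1]} (default 0.7).
#' @param theta hyperedge-overlap cap in \eqn{[0, 1]} (default 0.5).
#' @return a \code{\link{complex_set}} of predicted complexes (size >= 3).
#' @export
attach_peripherals <- function(cores, ppi, epsilon = 0.7, theta = 0.5) {
  stopifnot(epsilon >= 0, epsilon <= 1, theta >= 0, theta <= 1)
  if (length(cores) == 0L) return(structure(list(complexes = list(), labels = NULL),
                                            class = "complex_set"))
  adj <- ppi$adjacency
  core_sets <- lapply(cores, `[[`, "members")
  in_core <- sort(unique(unlist(core_sets)))
  cand <- setdiff(seq_len(n_nodes(ppi)), in_core)
  other_ids <- lapply(seq_along(core_sets), function(k) {
    lapply(core_sets[-k], function(i) ppi$node_ids[i])
  })
  final <- vector("list", length(core_sets))
  for (k in seq_along(core_sets)) {
    cluster <- core_sets[[k]]
    avail <- cand
    repeat {
      if (length(avail) == 0L) break
      touching <- avail[Matrix::rowSums(adj[avail, cluster, drop = FALSE]) > 0]
      if (length(touching) == 0L) break
      hd <- vapply(touching, function(v) edge_density_idx(c(cluster, v), adj), 0)
      ord <- order(-hd, ppi$node_ids[touching])
      admitted <- FALSE
      for (ix in ord) {
        if (hd[ix] < epsilon) break   # densities only fall further down the order
        v <- touching[ix]
        ho <- hyperedge_overlap(ppi$node_ids[c(cluster, v)], other_ids[[k]])
        if (ho <= theta) {
          cluster <- sort(c(cluster, v))
          avail <- setdiff(avail, v)
          admitted <- TRUE
          break
        }
      }
      if (!admitted) break
    }
    final[[k]] <- cluster
  }
  final <- final[lengths(final) >= 3L]
  final <- final[!duplicated(vapply(final, set_key, ""))]
  complex_set(lapply(final, function(i) ppi$node_ids[i]))
}

#' Run the full complex-detection pipeline
#'
#' Executes hypergraph construction, hierarchical compression, multi-level
#' hypergraph-convolution embedding, cosine re-weighting, and
#' core-attachment clustering, deterministically for a given seed.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @param dens core density threshold (default 0.8).
#' @param epsilon attachment density threshold (default 0.7).
#' @param theta attachment overlap cap (default 0.5).
#' @param dim embedding dimension per level (default 64).
#' @param mu attribute-similarity weight (default 0.5).
#' @param seed integer run seed.
#' @param max_levels maximum compression levels (default 5).
#' @param train_mode embedding parameter mode, see
#'   \code{\link{embed_levels}}.
#' @param epochs,lr training budget when \code{train_mode} is
#'   \code{"reconstruction"}.
#' @return an object of class \code{hlca_result}: \code{complexes} (a
#'   \code{\link{complex_set}}) and \code{report} (level count, modularity
#'   per level, cluster counts per stage, and the effective parameters).
#' @export
run_hlca <- function(ppi, dens = 0.8, epsilon = 0.7, theta = 0.5,
                     dim = 64L, mu = 0.5, seed = 1L, max_levels = 5L,
                     train_mode = c("off", "reconstruction"),
                     epochs = 50L, lr = 0.1) {
  train_mode <- match.arg(train_mode)
  stopifnot(inherits(ppi, "ppi_network"),
            dens >= 0, dens <= 1, epsilon >= 0, epsilon <= 1,
            theta >= 0, theta <= 1, dim >= 1, max_levels >= 1)
  hg <- build_hypergraph(ppi)
  stack <- compress(hg, max_levels = max_levels, seed = seed)
  emb <- embed_levels(ppi, stack, hg, dim = dim, mu = mu, seed = seed,
                      train_mode = train_mode, epochs = epochs, lr = lr)
  gw <- build_weighted_network(ppi, emb$final)
  cand <- enumerate_cliques(gw)
  if (length(cand) == 0L) {
    hlca_message("no maximal clique of size >= 3: empty prediction")
    complexes <- structure(list(complexes = list(), labels = NULL),
                           class = "complex_set")
    seeds <- cores <- list()
  } else {
    seeds <- select_seed_cores(cand, gw)
    grown <- lapply(seeds, grow_core, ppi = ppi)
    cores <- filter_cores(grown, dens = dens, ppi = ppi)
    complexes <- attach_peripherals(cores, ppi, epsilon = epsilon, theta = theta)
  }
  report <- list(n_nodes = n_nodes(ppi), n_edges = n_edges(ppi),
                 level_count = stack$he, q_per_level = stack$q,
                 n_candidates = length(cand), n_seeds = length(seeds),
                 n_cores = length(cores),
                 n_complexes = length(complexes$complexes),
                 params = list(dens = dens, epsilon = epsilon, theta = theta,
                               dim = dim, mu = mu, seed = seed,
                               max_levels = max_levels, train_mode = train_mode))
  structure(list(complexes = complexes, report = report), class = "hlca_result")
}

#' @export
print.hlca_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<hlca_result> %d complexes from %d proteins / %d interactions\n",
              r$n_complexes, r$n_nodes, r$n_edges))
  cat(sprintf("  levels: %d (Q: %s); candidates %d -> seeds %d -> cores %d\n",
              r$level_count, paste(sprintf("%.4f", r$q_per_level), collapse = ", "),
              r$n_candidates, r$n_seeds, r$n_cores))
  invisible(x)
}
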