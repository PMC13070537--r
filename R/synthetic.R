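#' Specification of a synthetic planted-complex PPI network
#'
#' Describes a sparse background network (Erdős–Rényi) with planted dense
#' complexes: each complex is a near-clique whose internal pairs are kept
#' with probability \code{p_within}, over background pairs drawn with the
#' much smaller probability \code{p_background}. A fraction of complexes may
#' share one node with the previously planted complex. The defaults are the
#' standing test-bench conditions used throughout the package: 120 nodes, 10
#' complexes of size 4–8, \code{p_within = 0.9}, \code{p_background = 0.05},
#' seed 17.
#'
#' @param n_nodes total number of proteins.
#' @param n_complexes number of planted complexes.
#' @param size_range integer vector \code{c(min, max)}; minimum >= 3.
#' @param p_within within-complex edge retention probability.
#' @param p_background background edge probability (strictly below
#'   \code{p_within}).
#' @param overlap_fraction fraction of complexes sharing one node with the
#'   previous complex.
#' @param seed integer generator seed.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_nodes = 120L, n_complexes = 10L,
                           size_range = c(4L, 8L), p_within = 0.9,
                           p_background = 0.05, overlap_fraction = 0,
                           seed = 17L) {
  stopifnot(size_range[1L] >= 3L, size_range[2L] >= size_range[1L],
            p_background >= 0, p_background < p_within, p_within <= 1,
            overlap_fraction >= 0, overlap_fraction <= 1, n_complexes >= 1L)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 p_within = p_within, p_background = p_background,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic PPI network with planted complexes
#'
#' Plants \code{n_complexes} near-cliques on (mostly) disjoint node sets,
#' resampling a complex's internal edges until its induced density is at
#' least \eqn{p_{within} - 3\sigma} (binomial \eqn{\sigma} over its pair
#' count), then adds background edges between pairs not internal to any one
#' complex. Deterministic for a given spec seed. Nodes left without any edge
#' cannot be represented in an edge-list network and are absent from the
#' result.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list with \code{network} (a \code{\link{ppi_network}}) and
#'   \code{truth} (the planted \code{\link{complex_set}}).
#' @export
generate_synthetic_ppi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    ids <- sprintf("p%03d", seq_len(spec$n_nodes))
    sizes <- sample(seq(spec$size_range[1L], spec$size_range[2L]),
                    spec$n_complexes, replace = TRUE)
    n_ov <- round(spec$overlap_fraction * spec$n_complexes)
    overlapped <- if (n_ov > 0) seq_len(spec$n_complexes) %in%
      sample(2:spec$n_complexes, min(n_ov, spec$n_complexes - 1L)) else
        rep(FALSE, spec$n_complexes)
    pool <- seq_len(spec$n_nodes)
    members <- vector("list", spec$n_complexes)
    for (k in seq_len(spec$n_complexes)) {
      fresh_needed <- sizes[k] - if (overlapped[k]) 1L else 0L
      if (fresh_needed > length(pool)) {
        stop("infeasible spec: planted complexes exceed the node budget", call. = FALSE)
      }
      fresh <- pool[seq_len(fresh_needed)]
      pool <- pool[-seq_len(fresh_needed)]
      members[[k]] <- sort(c(fresh, if (overlapped[k]) sample(members[[k - 1L]], 1L)))
    }
    edge_rows <- list()
    for (k in seq_len(spec$n_complexes)) {
      m <- members[[k]]
      prs <- t(utils::combn(m, 2L))
      npair <- nrow(prs)
      sigma <- sqrt(spec$p_within * (1 - spec$p_within) / npair)
      for (try in 1:100) {
        keep <- stats::runif(npair) < spec$p_within
        if (sum(keep) / npair >= spec$p_within - 3 * sigma) break
      }
      edge_rows[[k]] <- prs[keep, , drop = FALSE]
    }
    # background: pairs not internal to any single complex
    all_pairs <- t(utils::combn(seq_len(spec$n_nodes), 2L))
    internal <- rep(FALSE, nrow(all_pairs))
    key <- all_pairs[, 1L] * (spec$n_nodes + 1L) + all_pairs[, 2L]
    for (m in members) {
      prs <- t(utils::combn(m, 2L))
      internal <- internal | key %in% (prs[, 1L] * (spec$n_nodes + 1L) + prs[, 2L])
    }
    bg <- all_pairs[!internal & stats::runif(nrow(all_pairs)) < spec$p_background,
                    , drop = FALSE]
    edges <- rbind(do.call(rbind, edge_rows), bg)
    if (nrow(edges) == 0L) stop("spec produced no edges", call. = FALSE)
    net <- ppi_network(cbind(ids[edges[, 1L]], ids[edges[, 2L]]))
    list(network = net,
         truth = complex_set(lapply(members, function(m) ids[m])))
  })
}
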