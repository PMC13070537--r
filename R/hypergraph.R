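#' Build the closed-neighbourhood hypergraph of a PPI network
#'
#' Lifts an undirected PPI network to a hypergraph: every protein \eqn{v}
#' contributes its closed neighbourhood \eqn{\{v\} \cup N(v)} as a candidate
#' hyperedge, and candidates that coincide as sets are merged into a single
#' hyperedge. Each hyperedge \eqn{e} carries weight \eqn{\omega(e) = 1/|e|},
#' which damps the influence of large neighbourhoods; the hyperedge degree
#' \eqn{D_e(e) = |e|} and the weighted node degree
#' \eqn{D_v(v) = \sum_e \omega(e) H(v,e)} follow from the incidence matrix
#' \eqn{H}. A useful exact identity: \eqn{\sum_v D_v(v)} equals the number of
#' hyperedges, because each hyperedge contributes \eqn{\omega(e) D_e(e) = 1}.
#'
#' Hyperedges are ordered by (smallest member index, size) so the incidence
#' matrix is reproducible across runs.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @return an object of class \code{hypergraph} with components
#'   \code{node_ids}, \code{hyperedges} (list of sorted integer index
#'   vectors), \code{incidence} (sparse 0/1 \code{Matrix}, nodes x
#'   hyperedges), \code{omega}, \code{De}, \code{Dv}.
#' @export
build_hypergraph <- function(ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  n <- n_nodes(ppi)
  nbr <- vector("list", n)
  for (r in seq_len(n_edges(ppi))) {
    u <- ppi$edges[r, 1L]; v <- ppi$edges[r, 2L]
    nbr[[u]] <- c(nbr[[u]], v)
    nbr[[v]] <- c(nbr[[v]], u)
  }
  cand <- lapply(seq_len(n), function(i) sort(c(i, nbr[[i]])))
  keys <- vapply(cand, set_key, "")
  cand <- cand[!duplicated(keys)]
  ord <- order(vapply(cand, min, 1L), lengths(cand))
  he <- cand[ord]
  new_hypergraph(ppi$node_ids, he)
}

# Assemble incidence, weights and degrees from a list of sorted index sets.
new_hypergraph <- function(node_ids, hyperedges) {
  n <- length(node_ids)
  ne <- length(hyperedges)
  De <- lengths(hyperedges)
  H <- Matrix::sparseMatrix(i = unlist(hyperedges),
                            j = rep.int(seq_len(ne), De),
                            x = 1, dims = c(n, ne))
  rownames(H) <- node_ids
  omega <- 1 / De
  Dv <- as.numeric(H %*% omega)
  structure(list(node_ids = node_ids, hyperedges = hyperedges,
                 incidence = H, omega = omega, De = De, Dv = Dv),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d nodes, %d hyperedges (sizes %d-%d)\n",
              length(x$node_ids), length(x$hyperedges),
              if (length(x$De)) min(x$De) else 0L,
              if (length(x$De)) max(x$De) else 0L))
  invisible(x)
}

#' Total weighted node degree of a hypergraph
#'
#' Returns \eqn{\sum_v D_v(v)}, the normalising constant of the
#' degree-preserving null model. Equals the number of hyperedges exactly.
#'
#' @param hg a \code{hypergraph}.
#' @return a positive scalar.
#' @export
total_node_degree <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  sum(hg$Dv)
}
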