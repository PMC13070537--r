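#' Thresholded attribute-similarity matrix
#'
#' Uses each node's adjacency row as its attribute vector, so
#' \eqn{S(i,j) = x_i^T x_j} counts the neighbours shared by \eqn{i} and
#' \eqn{j}. Raw common-neighbour counts create many weak false-positive
#' links, so an entry is kept only when it reaches the smallest similarity
#' node \eqn{i} has with its own PPI neighbours,
#' \eqn{S(i,j) \ge \min\{S(i,k) : k \in N(i)\}}; surviving in either
#' endpoint's row keeps the (symmetric) entry. The diagonal is zeroed:
#' the matrix plays the role of an adjacency and must stay loop-free.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @return a sparse symmetric matrix of retained common-neighbour counts.
#' @export
attribute_similarity <- function(ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  A <- ppi$adjacency
  S <- methods::as(A %*% A, "TsparseMatrix")
  # per-node threshold: min similarity to own PPI neighbours
  ei <- ppi$edges[, 1L]; ej <- ppi$edges[, 2L]
  sv <- as.numeric(S[cbind(c(ei, ej), c(ej, ei))])
  thr <- rep(Inf, n_nodes(ppi))
  tmin <- tapply(sv, c(ei, ej), min)
  thr[as.integer(names(tmin))] <- as.numeric(tmin)
  keep <- S@i != S@j &
    S@x >= pmin(thr[S@i + 1L], thr[S@j + 1L])
  Matrix::sparseMatrix(i = S@i[keep] + 1L, j = S@j[keep] + 1L, x = S@x[keep],
                       dims = dim(S), dimnames = dimnames(A))
}

#' Similarity-enhanced adjacency
#'
#' Blends the PPI adjacency with the thresholded attribute similarity:
#' \eqn{\tilde A = A + \mu \hat S}. \code{mu = 0} recovers \eqn{A} exactly.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @param s_hat thresholded similarity matrix from
#'   \code{\link{attribute_similarity}}.
#' @param mu nonnegative balancing weight.
#' @return a sparse symmetric nonnegative matrix.
#' @export
enhanced_adjacency <- function(ppi, s_hat, mu = 0.5) {
  stopifnot(inherits(ppi, "ppi_network"))
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0) {
    stop("`mu` must be a single nonnegative number", call. = FALSE)
  }
  ppi$adjacency + mu * s_hat
}

#' First-layer node features by graph convolution
#'
#' One symmetric-normalised graph convolution over the enhanced adjacency:
#' \eqn{\varphi^{(1)} = D^{-1/2} \tilde A D^{-1/2} \varphi^{(0)} W^{(0)}},
#' with \eqn{\varphi^{(0)}} the rows of the PPI adjacency and \eqn{W^{(0)}}
#' an \eqn{n \times d} projection drawn once from the seed (symmetric
#' uniform, scaled by \eqn{1/\sqrt{n}}). These features feed the first
#' hypergraph convolution layer.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @param a_tilde enhanced adjacency from \code{\link{enhanced_adjacency}}.
#' @param d embedding dimension (columns of the result).
#' @param seed integer seed for the projection.
#' @return a dense \eqn{n \times d} matrix.
#' @export
initial_features <- function(ppi, a_tilde, d = 64L, seed = 1L) {
  stopifnot(inherits(ppi, "ppi_network"), d >= 1L)
  n <- n_nodes(ppi)
  deg <- Matrix::rowSums(a_tilde)
  if (any(deg <= 0)) stop("zero-degree row in the enhanced adjacency", call. = FALSE)
  W <- with_seed(seed, matrix(stats::runif(n * d, -1, 1), n, d) / sqrt(n))
  Dn <- Matrix::Diagonal(x = 1 / sqrt(deg))
  as.matrix(Dn %*% a_tilde %*% Dn %*% (ppi$adjacency %*% W))
}

# Symmetric-normalised hypergraph propagation operator
# Dv^{-1/2} H W De^{-1/2} H^T Dv^{-1/2} (sparse). Aggregated levels can
# contain supernodes touched by no surviving hyperedge; their degree is
# normalised by pseudo-inverse, leaving them a zero row (zero embedding).
propagation_operator <- function(hg) {
  H <- hg$incidence
  dvn <- ifelse(hg$Dv > 0, 1 / sqrt(hg$Dv), 0)
  Dvn <- Matrix::Diagonal(x = dvn)
  Dvn %*% H %*% Matrix::Diagonal(x = hg$omega / sqrt(hg$De)) %*% Matrix::t(H) %*% Dvn
}

# Fan-in-scaled symmetric-uniform parameter draw.
draw_theta <- function(d_in, d_out, seed) {
  with_seed(seed, matrix(stats::runif(d_in * d_out, -1, 1), d_in, d_out) / sqrt(d_in))
}

#' Two-layer hypergraph convolution
#'
#' Propagates features with the symmetric-normalised hypergraph operator
#' \eqn{M = D_v^{-1/2} H W D_e^{-1/2} H^T D_v^{-1/2}} through two ReLU
#' layers: \eqn{Z^{(1)} = \mathrm{ReLU}(M X \theta_1)},
#' \eqn{Z^{(2)} = \mathrm{ReLU}(M Z^{(1)} \theta_2)}. By default the
#' parameter matrices are drawn once from \code{params_seed} (untrained
#' graph-filter mode); precomputed matrices can be supplied via
#' \code{theta} to reuse trained parameters.
#'
#' @param hg a \code{hypergraph}; nodes with zero hypergraph degree (possible
#'   at aggregated levels) receive zero embeddings.
#' @param features matrix with one row per node of \code{hg}.
#' @param params_seed integer seed for the parameter draw.
#' @param d output dimension (defaults to \code{ncol(features)}).
#' @param theta optional list of two matrices \eqn{\theta_1, \theta_2}.
#' @return the nonnegative embedding matrix \eqn{Z^{(2)}}.
#' @export
hypergraph_convolve <- function(hg, features, params_seed = 1L,
                                d = ncol(features), theta = NULL) {
  stopifnot(inherits(hg, "hypergraph"))
  features <- as.matrix(features)
  if (nrow(features) != length(hg$node_ids)) {
    stop("feature row count must equal the level's node count", call. = FALSE)
  }
  if (any(hg$De <= 0)) {
    stop("all hyperedge degrees must be strictly positive", call. = FALSE)
  }
  if (is.null(theta)) {
    theta <- list(draw_theta(ncol(features), d, params_seed),
                  draw_theta(d, d, params_seed + 1L))
  }
  M <- propagation_operator(hg)
  Z1 <- relu(as.matrix(M %*% (features %*% theta[[1L]])))
  relu(as.matrix(M %*% (Z1 %*% theta[[2L]])))
}

# Unsupervised adjacency-reconstruction training of the two theta matrices:
# full-batch gradient descent on the logistic reconstruction loss of the
# binarised level adjacency from Z2 %*% t(Z2).
train_theta <- function(hg, features, d, seed, epochs = 50L, lr = 0.1) {
  n <- length(hg$node_ids)
  M <- as.matrix(propagation_operator(hg))
  B <- as.matrix(clique_adjacency(hg)) > 0
  diag(B) <- FALSE
  B <- B * 1
  th1 <- draw_theta(ncol(features), d, seed)
  th2 <- draw_theta(d, d, seed + 1L)
  X <- as.matrix(features)
  MX <- M %*% X
  for (ep in seq_len(epochs)) {
    P1 <- MX %*% th1
    Z1 <- relu(P1)
    MZ1 <- M %*% Z1
    P2 <- MZ1 %*% th2
    Z2 <- relu(P2)
    Sg <- 1 / (1 + exp(-(Z2 %*% t(Z2))))
    G <- (Sg - B) / (n * n)
    dZ2 <- 2 * (G %*% Z2)
    dP2 <- dZ2 * (P2 > 0)
    dth2 <- t(MZ1) %*% dP2
    dZ1 <- (M %*% dP2) %*% t(th2)
    dP1 <- dZ1 * (P1 > 0)
    dth1 <- t(MX) %*% dP1
    th1 <- th1 - lr * dth1
    th2 <- th2 - lr * dth2
  }
  list(th1, th2)
}

#' Redistribute supernode embeddings to original nodes
#'
#' A supernode's embedding is handed back to each constituent original node
#' scaled by that node's share of the supernode's hypergraph degree,
#' \eqn{\omega(v) = D_v(v) / \sum_{u \in SN(n)} D_v(u)}; the shares within
#' each supernode sum to 1. At the uncompressed level every supernode is a
#' singleton and the embedding passes through unchanged.
#'
#' @param stack a \code{level_stack}.
#' @param per_level list of embedding matrices, one per level (rows = that
#'   level's nodes).
#' @param dv_original weighted node degrees of the original hypergraph.
#' @return list of \eqn{n \times d} matrices, one per level, rows indexed by
#'   original node.
#' @export
redistribute_embeddings <- function(stack, per_level, dv_original) {
  stopifnot(inherits(stack, "level_stack"),
            length(per_level) == stack$he)
  n <- length(stack$lineage[[1L]])
  lapply(seq_len(stack$he), function(l) {
    gz <- as.matrix(per_level[[l]])
    out <- matrix(0, n, ncol(gz))
    lin <- stack$lineage[[l]]
    covered <- sort(unlist(lin, use.names = FALSE))
    if (!identical(covered, seq_len(n))) {
      stop("lineage at level ", l, " does not partition the original nodes",
           call. = FALSE)
    }
    for (s in seq_along(lin)) {
      members <- lin[[s]]
      w <- dv_original[members] / sum(dv_original[members])
      out[members, ] <- tcrossprod(w, gz[s, ])
    }
    out
  })
}

#' Concatenate per-level embeddings into the final representation
#'
#' Row \eqn{v} of the result is the concatenation of node \eqn{v}'s
#' redistributed embedding at every level, giving \eqn{d \times he} columns.
#'
#' @param redistributed list of per-level \eqn{n \times d} matrices (from
#'   \code{\link{redistribute_embeddings}}).
#' @return the final embedding matrix \code{FD}.
#' @export
concat_embeddings <- function(redistributed) {
  nr <- vapply(redistributed, nrow, 1L)
  if (length(unique(nr)) != 1L) stop("ragged levels: unequal row counts", call. = FALSE)
  do.call(cbind, redistributed)
}

#' Multi-level hypergraph embedding of a PPI network
#'
#' Runs the full embedding stage: attribute-similarity enhancement of the
#' adjacency, one graph convolution for initial features, a two-layer
#' hypergraph convolution at every compression level (supernode input
#' features are the degree-weighted average of their constituent nodes'
#' first-layer features), redistribution back to original nodes, and
#' concatenation across levels.
#'
#' By default the convolution parameters are drawn once per level from the
#' seed (untrained propagation). With
#' \code{train_mode = "reconstruction"} they are instead fitted per level by
#' gradient descent on a logistic reconstruction loss of the level's
#' binarised adjacency from \eqn{Z^{(2)} Z^{(2)T}}.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @param stack a \code{level_stack} from \code{\link{compress}}.
#' @param hg the original-level \code{hypergraph} (for degree weights).
#' @param dim embedding dimension per level.
#' @param mu attribute-similarity balancing weight.
#' @param seed integer seed controlling all parameter draws.
#' @param train_mode \code{"off"} (untrained propagation, default) or
#'   \code{"reconstruction"}.
#' @param epochs,lr training budget for the reconstruction mode.
#' @return an object of class \code{embedding_set}: \code{per_level},
#'   \code{redistributed}, and \code{final} (the \eqn{n \times (d \cdot he)}
#'   matrix \code{FD}, rows named by protein).
#' @export
embed_levels <- function(ppi, stack, hg, dim = 64L, mu = 0.5, seed = 1L,
                         train_mode = c("off", "reconstruction"),
                         epochs = 50L, lr = 0.1) {
  train_mode <- match.arg(train_mode)
  stopifnot(inherits(ppi, "ppi_network"), inherits(stack, "level_stack"))
  s_hat <- attribute_similarity(ppi)
  a_tilde <- enhanced_adjacency(ppi, s_hat, mu)
  phi1 <- initial_features(ppi, a_tilde, d = dim, seed = seed)
  per_level <- vector("list", stack$he)
  for (l in seq_len(stack$he)) {
    lev <- stack$levels[[l]]
    lin <- stack$lineage[[l]]
    feats <- if (l == 1L) phi1 else {
      do.call(rbind, lapply(lin, function(members) {
        w <- hg$Dv[members] / sum(hg$Dv[members])
        as.numeric(crossprod(phi1[members, , drop = FALSE], w))
      }))
    }
    pseed <- seed + 1000L * l
    theta <- if (train_mode == "reconstruction") {
      train_theta(lev, feats, d = dim, seed = pseed, epochs = epochs, lr = lr)
    } else NULL
    per_level[[l]] <- hypergraph_convolve(lev, feats, params_seed = pseed,
                                          d = dim, theta = theta)
  }
  redist <- redistribute_embeddings(stack, per_level, hg$Dv)
  fd <- concat_embeddings(redist)
  rownames(fd) <- ppi$node_ids
  if (any(!is.finite(fd))) stop("non-finite entries in the final embedding", call. = FALSE)
  structure(list(per_level = per_level, redistributed = redist, final = fd),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d nodes x %d dims (%d level(s))\n",
              nrow(x$final), ncol(x$final), length(x$per_level)))
  invisible(x)
}
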