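#' Construct a cleaned PPI network from an edge table
#'
#' Builds an undirected protein-protein interaction network from a two-column
#' table of interacting protein identifiers. Self-interactions and duplicate
#' pairs (in either orientation) are dropped; identifiers are treated as
#' case-sensitive strings and whitespace-trimmed. Node order is the order of
#' first appearance, which fixes the row/column indexing of every matrix
#' derived downstream.
#'
#' @param edges a two-column character matrix or data frame; each row one
#'   interaction.
#' @return an object of class \code{ppi_network} with components
#'   \code{node_ids} (character), \code{edges} (integer matrix, one row per
#'   undirected edge, column 1 < column 2), and \code{adjacency} (sparse
#'   symmetric 0/1 \code{Matrix} with zero diagonal).
#' @export
ppi_network <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("`edges` needs at least two columns", call. = FALSE)
  u <- trimws(as.character(edges[, 1L]))
  v <- trimws(as.character(edges[, 2L]))
  n_in <- length(u)
  keep <- u != v
  n_self <- sum(!keep)
  u <- u[keep]; v <- v[keep]
  # node order: first appearance scanning u1, v1, u2, v2, ...
  ids <- unique(as.vector(rbind(u, v)))
  ui <- match(u, ids); vi <- match(v, ids)
  lo <- pmin(ui, vi); hi <- pmax(ui, vi)
  dup <- duplicated(cbind(lo, hi))
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  if (length(lo) == 0L) stop("empty network after cleaning", call. = FALSE)
  if (n_self > 0L || n_dup > 0L) {
    hlca_message(sprintf("dropped %d self-interaction(s) and %d duplicate interaction(s) of %d input rows",
                         n_self, n_dup, n_in))
  }
  adj <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1,
                              dims = c(length(ids), length(ids)),
                              dimnames = list(ids, ids))
  structure(list(node_ids = ids,
                 edges = cbind(lo, hi, deparse.level = 0),
                 adjacency = adj),
            class = "ppi_network")
}

#' Read a PPI network from an edge-list file
#'
#' Parses a whitespace- or delimiter-separated edge list (two or more columns;
#' the first two are used) and returns a cleaned \code{\link{ppi_network}}.
#' Lines starting with \code{#} and blank lines are skipped. With
#' \code{sif = TRUE} the SIF dialect (\code{a interacts b}) is accepted and
#' columns 1 and 3 are used.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; \code{NULL} (default) splits on any run
#'   of whitespace.
#' @param sif logical; interpret lines as SIF triples (use columns 1 and 3).
#' @return a \code{\link{ppi_network}}.
#' @export
read_ppi_edge_list <- function(path, delimiter = NULL, sif = FALSE) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  idx <- which(body)
  if (length(idx) == 0L) stop("empty network: no edges in ", path, call. = FALSE)
  split_re <- if (is.null(delimiter)) "[ \t]+" else delimiter
  toks <- strsplit(trimws(lines[idx]), split_re, fixed = FALSE)
  need <- if (sif) 3L else 2L
  nt <- lengths(toks)
  if (any(nt < need)) {
    bad <- idx[which(nt < need)[1L]]
    stop(sprintf("parse error at line %d: expected >= %d fields, got %d",
                 bad, need, nt[which(nt < need)[1L]]), call. = FALSE)
  }
  cols <- if (sif) c(1L, 3L) else c(1L, 2L)
  ppi_network(cbind(vapply(toks, `[[`, "", cols[1L]),
                    vapply(toks, `[[`, "", cols[2L])))
}

#' Write a PPI network as a tab-separated edge list
#'
#' One undirected edge per line, two identifier columns. The edge order and
#' within-edge orientation follow the network's deterministic internal order,
#' so identical networks produce byte-identical files.
#'
#' @param ppi a \code{\link{ppi_network}}.
#' @param path output file path.
#' @export
write_edge_list <- function(ppi, path) {
  stopifnot(inherits(ppi, "ppi_network"))
  writeLines(paste(ppi$node_ids[ppi$edges[, 1L]],
                   ppi$node_ids[ppi$edges[, 2L]], sep = "\t"), path)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n",
              length(x$node_ids), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(ppi) length(ppi$node_ids)
n_edges <- function(ppi) nrow(ppi$edges)

#' Construct a set of protein complexes
#'
#' A complex set is a list of protein-identifier sets, used both for
#' predicted complexes and for reference catalogues (e.g. CYC2008/MIPS-style
#' files). Duplicate members within a complex are collapsed.
#'
#' @param complexes a list of character vectors.
#' @param labels optional character vector of complex labels.
#' @return an object of class \code{complex_set}.
#' @export
complex_set <- function(complexes, labels = NULL) {
  complexes <- lapply(complexes, function(m) unique(as.character(m)))
  if (any(lengths(complexes) == 0L)) stop("empty complex not allowed", call. = FALSE)
  structure(list(complexes = complexes, labels = labels), class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  sz <- lengths(x$complexes)
  cat(sprintf("<complex_set> %d complexes, sizes %d-%d (median %g)\n",
              length(sz), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' Read a complex catalogue
#'
#' One complex per line, whitespace-separated protein identifiers (the
#' common CYC2008/MIPS catalogue layout). Duplicate members within a line are
#' collapsed; comment lines starting with \code{#} are skipped.
#'
#' @param path path to the catalogue file.
#' @return a \code{\link{complex_set}}.
#' @export
read_complexes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty catalogue: ", path, call. = FALSE)
  complex_set(strsplit(trimws(lines), "[ \t]+"))
}

#' Write a complex set to a catalogue file
#'
#' One complex per line, members sorted lexicographically so files diff
#' reproducibly; \code{read_complexes(write_complexes(x))} recovers an equal
#' set.
#'
#' @param cs a \code{\link{complex_set}}.
#' @param path output file path.
#' @export
write_complexes <- function(cs, path) {
  stopifnot(inherits(cs, "complex_set"))
  if (length(cs$complexes) == 0L) stop("refusing to write an empty complex set", call. = FALSE)
  writeLines(vapply(cs$complexes,
                    function(m) paste(sort(m), collapse = " "), ""), path)
}
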