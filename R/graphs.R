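#' Graph containers for maximum-entropy network models
#'
#' `binary_graph()`, `weighted_graph()` and `bipartite_graph()` build the thin,
#' validated containers the rest of the package operates on. Internally a graph
#' is a dense adjacency (or biadjacency) matrix plus a handful of flags; node
#' labels are kept separate from the 0-based contiguous indexing used by the
#' numerics, so that I/O labels never leak into the solvers.
#'
#' Self-loops are invalid in every model supported here (all constraint sums
#' exclude the diagonal), so a non-zero diagonal is rejected at construction.
#'
#' @param adj square binary adjacency matrix (entries 0/1, zero diagonal);
#'   symmetric unless `directed = TRUE`.
#' @param directed logical; interpret the matrix as directed.
#' @param labels optional character vector of node labels (defaults to
#'   `"v1"..."vN"`).
#' @return an object of class `maxent_graph`.
#' @examples
#' g <- binary_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3), directed = FALSE)
#' degrees(g)
#' @export
binary_graph <- function(adj, directed = FALSE, labels = NULL) {
  adj <- as.matrix(adj)
  check_square(adj)
  if (!all(adj %in% c(0, 1))) {
    stop("binary adjacency entries must be 0 or 1", call. = FALSE)
  }
  new_graph(adj, directed = directed, weighted = FALSE,
            bipartite = FALSE, domain = "integer", labels = labels)
}

#' @rdname binary_graph
#' @param w square non-negative weight matrix, zero diagonal.
#' @param domain `"integer"` or `"real"`; with `"integer"` all weights must be
#'   whole numbers (the Bernoulli-geometric models require integer weights,
#'   the conditional exponential model works on the non-negative reals).
#' @export
weighted_graph <- function(w, directed = FALSE,
                           domain = c("integer", "real"), labels = NULL) {
  w <- as.matrix(w)
  domain <- match.arg(domain)
  check_square(w)
  if (any(w < 0)) stop("negative weights are not allowed", call. = FALSE)
  if (domain == "integer" && any(w != round(w))) {
    stop("weight domain is 'integer' but non-integer weights found; ",
         "use round_weights() or domain = 'real'", call. = FALSE)
  }
  new_graph(w, directed = directed, weighted = TRUE,
            bipartite = FALSE, domain = domain, labels = labels)
}

#' @rdname binary_graph
#' @param biadj rectangular binary biadjacency matrix, rows = bottom layer,
#'   columns = top layer.
#' @param bottom_labels,top_labels optional per-layer label vectors.
#' @export
bipartite_graph <- function(biadj, bottom_labels = NULL, top_labels = NULL) {
  biadj <- as.matrix(biadj)
  if (!all(biadj %in% c(0, 1))) {
    stop("biadjacency entries must be 0 or 1", call. = FALSE)
  }
  if (is.null(bottom_labels)) bottom_labels <- paste0("b", seq_len(nrow(biadj)))
  if (is.null(top_labels)) top_labels <- paste0("t", seq_len(ncol(biadj)))
  stopifnot(length(bottom_labels) == nrow(biadj),
            length(top_labels) == ncol(biadj))
  structure(list(mat = unname(biadj), directed = FALSE, weighted = FALSE,
                 bipartite = TRUE, domain = "integer",
                 labels = list(bottom = as.character(bottom_labels),
                               top = as.character(top_labels))),
            class = "maxent_graph")
}

check_square <- function(m) {
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (any(diag(m) != 0)) {
    stop("self-loops are not allowed (non-zero diagonal)", call. = FALSE)
  }
  invisible(m)
}

new_graph <- function(mat, directed, weighted, bipartite, domain, labels) {
  if (!directed && !isTRUE(all.equal(mat, t(mat), tolerance = 0))) {
    stop("undirected graph requires a symmetric matrix", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("v", seq_len(nrow(mat)))
  stopifnot(length(labels) == nrow(mat))
  structure(list(mat = unname(mat), directed = directed, weighted = weighted,
                 bipartite = bipartite, domain = domain,
                 labels = as.character(labels)),
            class = "maxent_graph")
}

#' @export
print.maxent_graph <- function(x, ...) {
  if (x$bipartite) {
    cat(sprintf("<maxent_graph> bipartite binary, %d x %d nodes, %d links\n",
                nrow(x$mat), ncol(x$mat), sum(x$mat)))
  } else {
    kind <- paste0(if (x$directed) "directed" else "undirected",
                   if (x$weighted) paste0(" weighted (", x$domain, ")")
                   else " binary")
    nl <- if (x$directed) sum(x$mat != 0) else sum(x$mat != 0) / 2
    cat(sprintf("<maxent_graph> %s, %d nodes, %d links\n",
                kind, nrow(x$mat), as.integer(nl)))
  }
  invisible(x)
}

#' Number of nodes of a graph
#' @param g a `maxent_graph`.
#' @return integer; for bipartite graphs a length-2 vector (bottom, top).
#' @export
n_nodes <- function(g) {
  stopifnot(inherits(g, "maxent_graph"))
  if (g$bipartite) c(bottom = nrow(g$mat), top = ncol(g$mat)) else nrow(g$mat)
}

#' Degree and strength sequences
#'
#' The local constraints of the configuration models: `degrees()` counts the
#' neighbours of each node of an undirected binary graph, `directed_degrees()`
#' returns the out- and in-degree sequences, `bipartite_degrees()` the per-layer
#' degree sequences, and `strengths()` the (out-/in-) strength sequences of a
#' weighted graph, i.e. the row/column sums of the weight matrix.
#'
#' @param g a `maxent_graph` of the appropriate kind.
#' @return a numeric vector, or a named list of two vectors for the directed
#'   and bipartite variants.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "maxent_graph"), !g$directed, !g$bipartite)
  m <- if (g$weighted) (g$mat > 0) + 0 else g$mat
  as.vector(rowSums(m))
}

#' @rdname degrees
#' @export
directed_degrees <- function(g) {
  stopifnot(inherits(g, "maxent_graph"), g$directed)
  m <- if (g$weighted) (g$mat > 0) + 0 else g$mat
  list(out = as.vector(rowSums(m)), `in` = as.vector(colSums(m)))
}

#' @rdname degrees
#' @export
bipartite_degrees <- function(g) {
  stopifnot(inherits(g, "maxent_graph"), g$bipartite)
  list(bottom = as.vector(rowSums(g$mat)), top = as.vector(colSums(g$mat)))
}

#' @rdname degrees
#' @export
strengths <- function(g) {
  stopifnot(inherits(g, "maxent_graph"), g$weighted)
  if (g$directed) {
    list(out = as.vector(rowSums(g$mat)), `in` = as.vector(colSums(g$mat)))
  } else {
    as.vector(rowSums(g$mat))
  }
}

#' Binarize a weighted graph
#'
#' Returns the binary support of a weighted graph: an edge exists wherever the
#' weight is strictly positive (Heaviside step of the weight matrix).
#'
#' @param g a weighted `maxent_graph`.
#' @return a binary `maxent_graph` with the same directedness and labels.
#' @export
binarize <- function(g) {
  stopifnot(inherits(g, "maxent_graph"))
  if (!g$weighted) return(g)
  if (any(g$mat < 0)) stop("negative weights are not allowed", call. = FALSE)
  binary_graph((g$mat > 0) + 0, directed = g$directed, labels = g$labels)
}

#' Round real weights to integers
#'
#' Replaces each weight by its nearest integer. Ties (x.5) round away from
#' zero by default -- `round()`'s banker's rounding is available via
#' `ties = "even"`. Weights rounding to zero drop out of the edge set.
#'
#' @param g a weighted `maxent_graph`.
#' @param ties `"away"` (default, half away from zero) or `"even"`.
#' @return an integer-weighted `maxent_graph`.
#' @export
round_weights <- function(g, ties = c("away", "even")) {
  stopifnot(inherits(g, "maxent_graph"), g$weighted)
  ties <- match.arg(ties)
  w <- g$mat
  r <- if (ties == "away") trunc(w + 0.5 * sign(w)) else round(w)
  weighted_graph(r, directed = g$directed, domain = "integer",
                 labels = g$labels)
}

#' Read and write plain-text edge lists
#'
#' One edge per line, `u v [w]`; fields separated by runs of whitespace or a
#' single comma; lines starting with `#` are comments. Labels are mapped to
#' contiguous internal indices in order of first appearance. Duplicate edges
#' are merged: weights are summed, binary entries are OR-ed; for undirected
#' graphs `u v` and `v u` name the same edge. Self-loops are rejected.
#'
#' @param path file path.
#' @param directed,weighted,bipartite flags describing the file contents.
#' @return `read_edge_list()` returns a `maxent_graph`; `write_edge_list()`
#'   (invisibly) the path written. A write-then-read round trip preserves the
#'   graph up to label order.
#' @export
read_edge_list <- function(path, directed = FALSE, weighted = FALSE,
                           bipartite = FALSE) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no edges in file: ", path, call. = FALSE)
  toks <- strsplit(trimws(gsub(",", " ", lines, fixed = TRUE)), "\\s+")
  nf <- lengths(toks)
  want <- if (weighted) 3L else 2L
  bad <- which(nf != want)
  if (length(bad)) {
    stop(sprintf("malformed line %d in '%s': expected %d fields, got %d",
                 lineno[bad[1]], path, want, nf[bad[1]]), call. = FALSE)
  }
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  w <- if (weighted) {
    wn <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
    if (anyNA(wn)) {
      stop(sprintf("malformed line %d in '%s': non-numeric weight",
                   lineno[which(is.na(wn))[1]], path), call. = FALSE)
    }
    wn
  } else rep(1, length(u))
  if (!bipartite && any(u == v)) {
    stop(sprintf("self-loop at line %d in '%s'",
                 lineno[which(u == v)[1]], path), call. = FALSE)
  }
  if (bipartite) {
    bl <- unique(u); tl <- unique(v)
    m <- matrix(0, length(bl), length(tl))
    i <- match(u, bl); j <- match(v, tl)
    for (e in seq_along(i)) m[i[e], j[e]] <- m[i[e], j[e]] + w[e]
    m <- (m > 0) + 0
    return(bipartite_graph(m, bottom_labels = bl, top_labels = tl))
  }
  labs <- unique(c(rbind(u, v)))
  n <- length(labs)
  m <- matrix(0, n, n)
  i <- match(u, labs); j <- match(v, labs)
  for (e in seq_along(i)) {
    m[i[e], j[e]] <- m[i[e], j[e]] + w[e]
    if (!directed) m[j[e], i[e]] <- m[j[e], i[e]] + w[e]
  }
  if (weighted) {
    domain <- if (all(m == round(m))) "integer" else "real"
    weighted_graph(m, directed = directed, domain = domain, labels = labs)
  } else {
    binary_graph((m > 0) + 0, directed = directed, labels = labs)
  }
}

#' @rdname read_edge_list
#' @param g graph to write.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "maxent_graph"))
  m <- g$mat
  if (g$bipartite) {
    idx <- which(m != 0, arr.ind = TRUE)
    lines <- sprintf("%s %s", g$labels$bottom[idx[, 1]], g$labels$top[idx[, 2]])
  } else {
    if (!g$directed) m[lower.tri(m, diag = TRUE)] <- 0
    idx <- which(m != 0, arr.ind = TRUE)
    lines <- if (g$weighted) {
      sprintf("%s %s %s", g$labels[idx[, 1]], g$labels[idx[, 2]],
              format(m[idx], digits = 17, trim = TRUE, scientific = FALSE))
    } else {
      sprintf("%s %s", g$labels[idx[, 1]], g$labels[idx[, 2]])
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write dense matrices as plain text
#'
#' Rows of whitespace-separated numbers; a companion to the edge-list format
#' for small dense inputs such as marginal-probability matrices.
#'
#' @param path file path.
#' @return `read_dense_matrix()` returns a numeric matrix.
#' @export
read_dense_matrix <- function(path) {
  rows <- readLines(path, warn = FALSE)
  rows <- rows[!grepl("^\\s*(#|$)", rows)]
  vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
  nc <- unique(lengths(vals))
  if (length(nc) != 1L) stop("ragged rows in dense matrix file", call. = FALSE)
  do.call(rbind, vals)
}

#' @rdname read_dense_matrix
#' @param m numeric matrix to write.
#' @export
write_dense_matrix <- function(m, path) {
  writeLines(apply(m, 1L, function(r) {
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")
  }), path)
  invisible(path)
}
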