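#' Distance representation of a vertex with respect to landmarks
#'
#' The representation vector r(v | S) lists the shortest-path distances from
#' \code{v} to each landmark in order. A vertex set S resolves the graph when
#' all n representation vectors are pairwise distinct.
#'
#' @param dm distance matrix from \code{\link{all_pairs_distances}}.
#' @param landmarks ordered vector of distinct vertex indices (1-based).
#' @param v a vertex index.
#' @return Integer vector of length \code{length(landmarks)}.
#' @export
representation_vector <- function(dm, landmarks, v) {
  check_vertex_indices(dm, c(landmarks, v))
  if (length(landmarks) == 0L) {
    stop("argument error: landmarks must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(landmarks)) {
    stop("argument error: landmarks must be distinct", call. = FALSE)
  }
  as.integer(dm[v, landmarks])
}

#' Test whether a vertex subset is a resolving set
#'
#' @param dm distance matrix from \code{\link{all_pairs_distances}}.
#' @param subset vector of distinct vertex indices (1-based).
#' @return \code{TRUE} iff the representation vectors of all vertices with
#'   respect to \code{subset} are pairwise distinct.
#' @export
is_resolving <- function(dm, subset) {
  check_vertex_indices(dm, subset)
  if (length(subset) == 0L) {
    stop("argument error: subset must be non-empty", call. = FALSE)
  }
  n <- nrow(dm)
  pw <- (n + 1)^(seq_along(subset) - 1)
  codes <- dm[, subset, drop = FALSE] %*% pw
  anyDuplicated(codes) == 0L
}

check_vertex_indices <- function(dm, idx) {
  n <- nrow(dm)
  if (any(idx < 1L | idx > n)) {
    stop(sprintf("argument error: vertex index out of range 1..%d", n),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Twin vertex pairs of a graph
#'
#' Two vertices are twins when they are equidistant from every other vertex;
#' no subset omitting both members of a twin pair can resolve the graph, so
#' every metric basis hits each pair.
#'
#' @param dm distance matrix.
#' @return Integer matrix with two columns, one row per twin pair (possibly
#'   zero rows).
#' @export
twin_pairs <- function(dm) {
  n <- nrow(dm)
  out <- matrix(integer(0), ncol = 2L)
  if (n < 3L) return(out)
  for (u in seq_len(n - 1L)) {
    for (v in (u + 1L):n) {
      rest <- setdiff(seq_len(n), c(u, v))
      if (all(dm[u, rest] == dm[v, rest])) out <- rbind(out, c(u, v))
    }
  }
  out
}

#' Metric dimension and all metric bases by exhaustive search
#'
#' Searches vertex subsets in increasing size k = 1, 2, ... (lexicographic
#' within each size) until some k-subset resolves the graph; that k is the
#' metric dimension beta(G). All resolving subsets of size beta are then
#' collected — the full collection is needed to assign per-vertex resolving
#' degrees. Representation vectors are compared through exact integer
#' encodings; the search is fully deterministic.
#'
#' @param g a \code{\link{molecular_graph}} with at least 2 vertices.
#' @param prune_twins skip subsets that miss both members of some twin pair.
#'   This is a pure accelerator: no resolving set can miss a twin pair, so
#'   the result is identical with and without pruning.
#' @return A list of class \code{resolving_search}: \code{beta} (integer),
#'   \code{bases} (list of integer vertex vectors, lexicographic order),
#'   \code{basis_labels} (the same bases as sorted character labels),
#'   \code{labels} and \code{n_checked} (number of subsets tested).
#' @export
minimum_resolving_sets <- function(g, prune_twins = TRUE) {
  stopifnot(inherits(g, "molgraph"))
  if (g$n < 2L) {
    stop("argument error: metric dimension requires at least 2 vertices",
         call. = FALSE)
  }
  dm <- all_pairs_distances(g)
  n <- g$n
  twins <- if (prune_twins) twin_pairs(dm) else matrix(integer(0), ncol = 2L)
  n_checked <- 0L
  for (k in seq_len(n - 1L)) {
    comb <- utils::combn(n, k)
    if (nrow(twins) > 0L) {
      keep <- rep(TRUE, ncol(comb))
      for (i in seq_len(nrow(twins))) {
        keep <- keep &
          colSums(comb == twins[i, 1L] | comb == twins[i, 2L]) > 0L
      }
      comb <- comb[, keep, drop = FALSE]
    }
    pw <- (n + 1)^(seq_len(k) - 1)
    bases <- list()
    for (j in seq_len(ncol(comb))) {
      s <- comb[, j]
      n_checked <- n_checked + 1L
      codes <- dm[, s, drop = FALSE] %*% pw
      if (anyDuplicated(codes) == 0L) bases[[length(bases) + 1L]] <- s
    }
    if (length(bases) > 0L) {
      basis_labels <- lapply(bases, function(s) sort(g$labels[s]))
      return(structure(
        list(beta = k, bases = bases, basis_labels = basis_labels,
             labels = g$labels, n_checked = n_checked),
        class = "resolving_search"
      ))
    }
  }
  stop("internal error: full vertex set failed to resolve", call. = FALSE)
}

#' @export
print.resolving_search <- function(x, ...) {
  cat(sprintf("<resolving_search: beta = %d, %d metric bases, %d subsets checked>\n",
              x$beta, length(x$bases), x$n_checked))
  invisible(x)
}

#' Per-vertex resolving degrees
#'
#' The resolving degree of a vertex v is the minimum size of a resolving set
#' containing v. It equals beta(G) exactly when v lies in some metric basis,
#' and beta(G) + 1 otherwise (a basis plus v still resolves, so the degree
#' never exceeds beta + 1). The two-valued range is asserted on every result.
#'
#' @param g a \code{\link{molecular_graph}}.
#' @param search optional precomputed \code{\link{minimum_resolving_sets}}
#'   result for \code{g}.
#' @return A list of class \code{resolving_degrees}: \code{beta}, and
#'   \code{degrees} — an integer vector named by vertex labels.
#' @export
resolving_degrees <- function(g, search = NULL) {
  stopifnot(inherits(g, "molgraph"))
  if (is.null(search)) search <- minimum_resolving_sets(g)
  beta <- search$beta
  in_basis <- rep(FALSE, g$n)
  in_basis[unique(unlist(search$bases))] <- TRUE
  degrees <- as.integer(ifelse(in_basis, beta, beta + 1L))
  stopifnot(all(degrees >= beta & degrees <= beta + 1L),
            sum(degrees == beta) >= beta)
  names(degrees) <- g$labels
  structure(list(beta = beta, degrees = degrees,
                 labels = g$labels),
            class = "resolving_degrees")
}

#' Resolving-degree graph invariants
#'
#' Counts the quantities that drive the closed-form resolving indices:
#' eta — vertices whose resolving degree equals beta; xi1 — edges with one
#' endpoint at beta and one at beta + 1; xi2 — edges with both endpoints at
#' beta + 1.
#'
#' @param g a \code{\link{molecular_graph}}.
#' @param deg optional precomputed \code{\link{resolving_degrees}}.
#' @return A \code{\link{graph_invariants_record}}.
#' @export
graph_invariants <- function(g, deg = NULL) {
  stopifnot(inherits(g, "molgraph"))
  if (is.null(deg)) deg <- resolving_degrees(g)
  d <- deg$degrees
  beta <- deg$beta
  du <- d[g$edges[, 1L]]
  dv <- d[g$edges[, 2L]]
  graph_invariants_record(
    beta = beta,
    eta = sum(d == beta),
    xi1 = sum(du != dv),
    xi2 = sum(du == beta + 1L & dv == beta + 1L),
    n_vertices = g$n, n_edges = g$m
  )
}

#' Assemble a graph-invariants record
#'
#' Container for the tuple (beta, eta, xi1, xi2, |V|, |E|) that feeds the
#' closed-form resolving indices, whether it comes from the exhaustive solver
#' or from a published invariant table.
#'
#' @param beta,eta,xi1,xi2,n_vertices,n_edges non-negative integers.
#' @return A list of class \code{graph_invariants}.
#' @export
graph_invariants_record <- function(beta, eta, xi1, xi2, n_vertices, n_edges) {
  x <- list(beta = as.integer(beta), eta = as.integer(eta),
            xi1 = as.integer(xi1), xi2 = as.integer(xi2),
            n_vertices = as.integer(n_vertices), n_edges = as.integer(n_edges))
  if (!(x$beta <= x$eta && x$eta <= x$n_vertices)) {
    stop("invariant violation: need beta <= eta <= |V|", call. = FALSE)
  }
  if (x$xi1 < 0L || x$xi2 < 0L || x$xi1 + x$xi2 > x$n_edges) {
    stop("invariant violation: need 0 <= xi1 + xi2 <= |E|", call. = FALSE)
  }
  structure(x, class = "graph_invariants")
}

#' @export
print.graph_invariants <- function(x, ...) {
  cat(sprintf("<graph_invariants: |V|=%d |E|=%d beta=%d eta=%d xi1=%d xi2=%d>\n",
              x$n_vertices, x$n_edges, x$beta, x$eta, x$xi1, x$xi2))
  invisible(x)
}
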