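#' Construct a hydrogen-suppressed molecular graph
#'
#' A molecular graph is a simple, connected, undirected graph whose vertices
#' are heavy atoms and whose edges are chemical bonds with multiplicity
#' collapsed (a double or aromatic bond is a single edge). Vertices carry
#' textual labels (e.g. \code{"C7"}) and are numbered 1..n internally in
#' first-appearance order.
#'
#' @param edges two-column character matrix or data frame of vertex label
#'   pairs, one row per bond.
#' @param name text label for the graph.
#' @return An object of class \code{molgraph}: a list with elements
#'   \code{name}, \code{labels} (character vector, length n), \code{edges}
#'   (m x 2 integer matrix, each row sorted), \code{n}, \code{m}.
#' @examples
#' g <- molecular_graph(cbind(c("a", "b"), c("b", "c")), name = "path3")
#' g$n # 3
#' @export
molecular_graph <- function(edges, name = "graph") {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L || nrow(edges) == 0L) {
    stop("format error: edge input must have two columns and at least one row",
         call. = FALSE)
  }
  mode(edges) <- "character"
  labels <- unique(as.vector(t(edges)))  # first-appearance order
  u <- match(edges[, 1L], labels)
  v <- match(edges[, 2L], labels)
  if (any(u == v)) {
    bad <- edges[which(u == v)[1L], 1L]
    stop(sprintf("format error: self-loop at vertex '%s'", bad), call. = FALSE)
  }
  em <- cbind(pmin(u, v), pmax(u, v))
  key <- paste(em[, 1L], em[, 2L])
  if (anyDuplicated(key)) {
    d <- em[which(duplicated(key))[1L], ]
    stop(sprintf("format error: duplicate edge {%s, %s}",
                 labels[d[1L]], labels[d[2L]]), call. = FALSE)
  }
  g <- structure(
    list(name = name, labels = labels, edges = em,
         n = length(labels), m = nrow(em)),
    class = "molgraph"
  )
  comp <- igraph::components(as_igraph(g))
  if (comp$no > 1L) {
    parts <- split(labels, comp$membership)
    stop(sprintf(
      "connectivity error: graph '%s' has %d components: %s", name, comp$no,
      paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","), "}"),
                   character(1)), collapse = " ")),
      call. = FALSE)
  }
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph '%s': %d vertices, %d edges>\n", x$name, x$n, x$m))
  invisible(x)
}

# igraph view of a molgraph (internal; all algorithms go through here so the
# public surface stays a plain edge list)
as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE)
}

#' Read a molecular graph from an edge-list file
#'
#' File dialect: UTF-8 text, one edge per line as two whitespace-separated
#' vertex labels; lines starting with \code{#} and blank lines are ignored.
#' Vertices are numbered by first appearance.
#'
#' @param path path to the edge-list file.
#' @param name graph label; defaults to the file name without extension.
#' @return A \code{\link{molecular_graph}}.
#' @export
load_edge_list <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("format error: no such file '%s'", path), call. = FALSE)
  }
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop(sprintf("format error: '%s' contains no edges", path), call. = FALSE)
  }
  toks <- strsplit(lines, "[[:space:]]+")
  nt <- lengths(toks)
  if (any(nt != 2L)) {
    stop(sprintf("format error: line '%s' in '%s' does not have exactly two tokens",
                 lines[which(nt != 2L)[1L]], path), call. = FALSE)
  }
  molecular_graph(do.call(rbind, toks), name = name)
}

#' All-pairs shortest-path distances of a molecular graph
#'
#' Hop-count (breadth-first-search) distances between every pair of atoms,
#' i.e. the minimum number of bonds traversed.
#'
#' @param g a \code{\link{molecular_graph}}.
#' @return An n x n symmetric integer matrix with zero diagonal; dimnames are
#'   the vertex labels.
#' @export
all_pairs_distances <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  d <- igraph::distances(as_igraph(g))
  storage.mode(d) <- "integer"
  dimnames(d) <- list(g$labels, g$labels)
  d
}
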