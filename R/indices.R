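#' Resolving topological indices by direct summation
#'
#' Computes the five resolving-degree based indices from the per-vertex
#' resolving degrees d(v):
#' \itemize{
#'   \item FRZI1 = sum over vertices of d(v)^2 (first resolving Zagreb),
#'   \item FRZI2 = sum over edges of d(u) + d(v),
#'   \item SRZI  = sum over edges of d(u) * d(v) (second resolving Zagreb),
#'   \item RHM   = sum over edges of (d(u) + d(v))^2 (resolving hyper-Zagreb),
#'   \item RF    = sum over edges of d(u)^2 + d(v)^2 (resolving forgotten).
#' }
#' All arithmetic is exact integer arithmetic. The algebraic identity
#' RHM = RF + 2 SRZI is asserted on every result.
#'
#' @param g a \code{\link{molecular_graph}}.
#' @param deg a \code{\link{resolving_degrees}} result for \code{g}.
#' @return A list of class \code{resolving_indices} with integer fields
#'   \code{frzi1}, \code{frzi2}, \code{srzi}, \code{rhm}, \code{rf}.
#' @export
indices_direct <- function(g, deg) {
  stopifnot(inherits(g, "molgraph"), inherits(deg, "resolving_degrees"))
  if (length(deg$degrees) != g$n || !identical(deg$labels, g$labels)) {
    stop("argument error: degree map does not cover the graph's vertices",
         call. = FALSE)
  }
  d <- as.numeric(deg$degrees)
  du <- d[g$edges[, 1L]]
  dv <- d[g$edges[, 2L]]
  resolving_indices_record(
    frzi1 = sum(d^2),
    frzi2 = sum(du + dv),
    srzi = sum(du * dv),
    rhm = sum((du + dv)^2),
    rf = sum(du^2 + dv^2)
  )
}

#' Resolving topological indices in closed form
#'
#' Because every resolving degree is beta or beta + 1, the five indices are
#' determined by the invariant tuple (beta, eta, xi1, xi2, |V|, |E|) alone:
#' \itemize{
#'   \item FRZI1 = eta beta^2 + (|V| - eta)(beta + 1)^2
#'   \item FRZI2 = 2 |E| beta + (xi1 + 2 xi2)
#'   \item SRZI  = |E| beta^2 + (xi1 + 2 xi2) beta + xi2
#'   \item RHM   = 4 beta^2 |E| + 4 beta (xi1 + 2 xi2) + (xi1 + 4 xi2)
#'   \item RF    = 2 beta^2 |E| + 2 beta (xi1 + 2 xi2) + (xi1 + 2 xi2)
#' }
#'
#' @param inv a \code{\link{graph_invariants_record}}.
#' @return A \code{resolving_indices} record, as in \code{\link{indices_direct}}.
#' @export
indices_closed <- function(inv) {
  stopifnot(inherits(inv, "graph_invariants"))
  b <- as.numeric(inv$beta); e <- as.numeric(inv$n_edges)
  eta <- as.numeric(inv$eta); x1 <- as.numeric(inv$xi1); x2 <- as.numeric(inv$xi2)
  s <- x1 + 2 * x2
  resolving_indices_record(
    frzi1 = eta * b^2 + (inv$n_vertices - eta) * (b + 1)^2,
    frzi2 = 2 * e * b + s,
    srzi = e * b^2 + s * b + x2,
    rhm = 4 * b^2 * e + 4 * b * s + (x1 + 4 * x2),
    rf = 2 * b^2 * e + 2 * b * s + s
  )
}

resolving_indices_record <- function(frzi1, frzi2, srzi, rhm, rf) {
  x <- list(frzi1 = as.integer(frzi1), frzi2 = as.integer(frzi2),
            srzi = as.integer(srzi), rhm = as.integer(rhm),
            rf = as.integer(rf))
  if (any(unlist(x) <= 0L)) {
    stop("invariant violation: resolving indices must be positive integers",
         call. = FALSE)
  }
  if (x$rhm != x$rf + 2L * x$srzi) {
    stop("invariant violation: RHM != RF + 2*SRZI", call. = FALSE)
  }
  structure(x, class = "resolving_indices")
}

#' @export
print.resolving_indices <- function(x, ...) {
  cat(sprintf("<resolving_indices: FRZI1=%d FRZI2=%d SRZI=%d RHM=%d RF=%d>\n",
              x$frzi1, x$frzi2, x$srzi, x$rhm, x$rf))
  invisible(x)
}

#' Index table for a collection of molecular graphs
#'
#' Runs the full chain (exhaustive resolving-set search, resolving degrees,
#' invariants, indices) on each graph. Every row is computed twice — by
#' direct summation and by closed form — and the two are required to agree
#' before the row is emitted.
#'
#' @param graphs list of \code{\link{molecular_graph}} objects.
#' @return A data frame with columns \code{drug}, \code{n_vertices},
#'   \code{n_edges}, \code{beta}, \code{eta}, \code{xi1}, \code{xi2},
#'   \code{FRZI1}, \code{FRZI2}, \code{SRZI}, \code{RHM}, \code{RF}.
#' @export
index_table <- function(graphs) {
  cols <- c("drug", "n_vertices", "n_edges", "beta", "eta", "xi1", "xi2",
            "FRZI1", "FRZI2", "SRZI", "RHM", "RF")
  rows <- lapply(graphs, function(g) {
    deg <- resolving_degrees(g)
    inv <- graph_invariants(g, deg)
    direct <- indices_direct(g, deg)
    closed <- indices_closed(inv)
    if (!identical(unclass(direct), unclass(closed))) {
      stop(sprintf(
        "internal-consistency error: direct and closed-form indices disagree for '%s'",
        g$name), call. = FALSE)
    }
    data.frame(drug = g$name, n_vertices = inv$n_vertices,
               n_edges = inv$n_edges, beta = inv$beta, eta = inv$eta,
               xi1 = inv$xi1, xi2 = inv$xi2, FRZI1 = closed$frzi1,
               FRZI2 = closed$frzi2, SRZI = closed$srzi, RHM = closed$rhm,
               RF = closed$rf)
  })
  if (length(rows) == 0L) {
    out <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  do.call(rbind, rows)
}
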