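# Run expr with a private RNG stream: the caller's .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

decode_pruefer <- function(code, n) {
  # classical decoding: leaves are attached in increasing order
  degree <- tabulate(code, nbins = n) + 1L
  edges <- matrix(integer(0), ncol = 2L)
  avail <- rep(TRUE, n)
  for (c_i in code) {
    leaf <- which(avail & degree == 1L)[1L]
    edges <- rbind(edges, c(leaf, c_i))
    degree[leaf] <- 0L
    avail[leaf] <- FALSE
    degree[c_i] <- degree[c_i] - 1L
  }
  last <- which(avail & degree >= 1L)
  rbind(edges, last)
}

#' Random connected molecular-like graph
#'
#' Generates a simple connected graph with exactly the requested vertex and
#' edge counts and a bounded maximum degree (default 4, mimicking organic
#' skeletons). Construction: a uniformly random labelled spanning tree
#' (Pruefer sequence, rejection-sampled to respect the degree cap), then
#' uniformly random admissible non-edges until the edge count is reached.
#' Fully deterministic given \code{seed}; the global RNG state is left
#' untouched.
#'
#' @param n_vertices number of vertices (>= 2).
#' @param n_edges number of edges, between \code{n_vertices - 1} (a tree) and
#'   \code{floor(n_vertices * max_degree / 2)}.
#' @param max_degree maximum vertex degree (default 4).
#' @param seed integer seed controlling all randomness.
#' @param name graph label.
#' @return A \code{\link{molecular_graph}} with vertex labels
#'   \code{"v1"..."vn"}.
#' @export
random_connected_graph <- function(n_vertices, n_edges, max_degree = 4L,
                                   seed = 1L, name = "synthetic") {
  n <- as.integer(n_vertices)
  m <- as.integer(n_edges)
  if (n < 2L) stop("argument error: need at least 2 vertices", call. = FALSE)
  if (max_degree < 1L) stop("argument error: max_degree must be >= 1",
                            call. = FALSE)
  m_max <- min(choose(n, 2L), floor(n * max_degree / 2))
  if (m < n - 1L || m > m_max) {
    stop(sprintf(
      "argument error: n_edges must lie in [%d, %d] for n = %d, max_degree = %d",
      n - 1L, m_max, n, max_degree), call. = FALSE)
  }
  with_local_seed(seed, {
    for (attempt in seq_len(100L)) {
      # spanning tree with degree cap
      repeat {
        if (n == 2L) {
          edges <- matrix(c(1L, 2L), ncol = 2L)
          break
        }
        code <- sample.int(n, n - 2L, replace = TRUE)
        if (max(tabulate(code, nbins = n)) + 1L <= max_degree) {
          edges <- decode_pruefer(code, n)
          break
        }
      }
      degree <- tabulate(c(edges), nbins = n)
      present <- matrix(FALSE, n, n)
      present[edges] <- TRUE
      present[edges[, 2:1, drop = FALSE]] <- TRUE
      ok <- TRUE
      while (nrow(edges) < m) {
        free <- which(degree < max_degree)
        cand <- which(
          upper.tri(present) & !present &
            outer(degree < max_degree, degree < max_degree, `&`),
          arr.ind = TRUE)
        if (nrow(cand) == 0L) { ok <- FALSE; break }
        pick <- cand[sample.int(nrow(cand), 1L), ]
        edges <- rbind(edges, pick)
        present[pick[1L], pick[2L]] <- TRUE
        present[pick[2L], pick[1L]] <- TRUE
        degree[pick] <- degree[pick] + 1L
      }
      if (ok) {
        labels <- paste0("v", seq_len(n))
        return(molecular_graph(
          cbind(labels[edges[, 1L]], labels[edges[, 2L]]), name = name))
      }
    }
    stop("argument error: could not realise the requested (n_edges, max_degree) combination",
         call. = FALSE)
  })
}

#' Synthetic property vector from a polynomial in an index
#'
#' Emulates the statistical structure assumed by the QSPR regression layer:
#' property = polynomial(index) + Gaussian noise. With \code{noise_sd = 0}
#' the generating coefficients are exactly recoverable by OLS.
#'
#' @param index_values numeric vector of topological index values.
#' @param coefficients numeric vector (intercept first) of length 2, 3 or 4
#'   (linear, quadratic, cubic generator).
#' @param noise_sd standard deviation of the additive Gaussian noise (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of property values, same length as
#'   \code{index_values}.
#' @export
synthesize_property <- function(index_values, coefficients, noise_sd = 0,
                                seed = 1L) {
  if (!length(coefficients) %in% 2:4) {
    stop("argument error: coefficients must have length 2, 3 or 4 (intercept first)",
         call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("argument error: noise_sd must be non-negative", call. = FALSE)
  }
  mu <- drop(stats::poly(index_values, length(coefficients) - 1L,
                         raw = TRUE) %*% coefficients[-1L]) + coefficients[1L]
  with_local_seed(seed, mu + stats::rnorm(length(index_values), 0, noise_sd))
}

#' Write a molecular graph as an edge-list file
#'
#' Emits the package's edge-list dialect (one \code{label label} pair per
#' line, \code{#} comments) so generated graphs round-trip through
#' \code{\link{load_edge_list}}.
#'
#' @param g a \code{\link{molecular_graph}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "molgraph"))
  lines <- c(sprintf("# %s: %d vertices, %d edges", g$name, g$n, g$m),
             paste(g$labels[g$edges[, 1L]], g$labels[g$edges[, 2L]]))
  writeLines(lines, path)
  invisible(path)
}
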