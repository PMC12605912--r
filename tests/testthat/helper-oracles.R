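# Independent oracles and small builders shared across test files.

# Floyd-Warshall all-pairs distances, independent of the igraph-backed path.
floyd_warshall_oracle <- function(g) {
  n <- g$n
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(g$m)) {
    u <- g$edges[i, 1L]; v <- g$edges[i, 2L]
    d[u, v] <- 1; d[v, u] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  storage.mode(d) <- "integer"
  dimnames(d) <- list(g$labels, g$labels)
  d
}

# Naive resolving-set check: compare all representation-vector pairs directly.
brute_is_resolving <- function(dm, subset) {
  n <- nrow(dm)
  for (u in seq_len(n - 1L)) {
    for (v in (u + 1L):n) {
      if (all(dm[u, subset] == dm[v, subset])) return(FALSE)
    }
  }
  TRUE
}

label_pairs <- function(a, b) cbind(a, b)

path_graph <- function(n) {
  lab <- paste0("p", seq_len(n))
  molecular_graph(label_pairs(lab[-n], lab[-1L]), name = sprintf("path%d", n))
}

cycle_graph <- function(n) {
  lab <- paste0("c", seq_len(n))
  molecular_graph(label_pairs(lab, lab[c(2:n, 1L)]),
                  name = sprintf("cycle%d", n))
}

complete_graph <- function(n) {
  lab <- paste0("k", seq_len(n))
  e <- t(utils::combn(n, 2L))
  molecular_graph(label_pairs(lab[e[, 1L]], lab[e[, 2L]]),
                  name = sprintf("K%d", n))
}

complete_bipartite <- function(m, n) {
  a <- paste0("a", seq_len(m)); b <- paste0("b", seq_len(n))
  e <- expand.grid(a, b, stringsAsFactors = FALSE)
  molecular_graph(label_pairs(e[[1L]], e[[2L]]), name = sprintf("K%d_%d", m, n))
}

write_tmp_edges <- function(lines) {
  f <- withr::local_tempfile(fileext = ".edges",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# The full drug solve is reused by several files; cache it per session.
.cache <- new.env(parent = emptyenv())
solved_drug_table <- function() {
  if (is.null(.cache$tab)) {
    .cache$tab <- index_table(lapply(load_all_drugs(), `[[`, "graph"))
  }
  .cache$tab
}

# Pool of small random connected graphs with fixed seeds.
random_graph_pool <- function(n_graphs = 40L, n_max = 12L, seed0 = 100L) {
  lapply(seq_len(n_graphs), function(i) {
    set.seed(seed0 + i)  # sizes drawn here; graph generator reseeds itself
    n <- sample(4:n_max, 1L)
    m_max <- min(choose(n, 2L), floor(n * 4 / 2))
    m <- sample((n - 1L):m_max, 1L)
    random_connected_graph(n, m, max_degree = 4L, seed = seed0 + i,
                           name = sprintf("rnd%d", i))
  })
}
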