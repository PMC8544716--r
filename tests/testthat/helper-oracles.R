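# Independent oracles used across the suite. Deliberately naive: explicit
# all-pairs matrices and literal definitions, no shared code with the
# implementations they check.

# DBSCAN oracle: explicit neighbour matrix, core rule "count incl. self
# >= npt", clusters = graph components of cores, border points join the
# cluster of their lowest-indexed core neighbour.
dbscan_oracle <- function(coords, eps = 25, npt = 2) {
  n <- nrow(coords)
  if (n == 0) return(list(label = integer(0)))
  adj <- as.matrix(stats::dist(coords)) <= eps
  core <- rowSums(adj) >= npt          # diagonal TRUE counts the point
  label <- rep(0L, n)
  if (any(core)) {
    g <- igraph::graph_from_adjacency_matrix(
      adj[core, core, drop = FALSE], mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    label[core] <- as.integer(comp)
    for (i in which(!core)) {
      cn <- which(adj[i, ] & core)
      if (length(cn) > 0) label[i] <- label[min(cn)]
    }
  }
  list(label = label, core = core)
}

# flat cluster labels (0 = noise) from a density_cluster() result
labels_from_result <- function(res, n) {
  lab <- rep(0L, n)
  for (i in seq_len(nrow(res$clusters))) {
    lab[res$clusters$members[[i]]] <- res$clusters$cluster_id[i]
  }
  lab
}

# TRUE when two labelings agree up to renaming of cluster ids
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- a != 0L
  length(unique(paste(a[ok], b[ok]))) ==
    length(unique(a[ok])) &&
    length(unique(paste(a[ok], b[ok]))) == length(unique(b[ok]))
}

# literal step-up BH definition: q_i = min_{j >= rank(i)} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q
}

# quick localization tibble
loc_tbl <- function(x, y, z, channel = "sRNA", cell_id = 1L) {
  tibble::tibble(x = x, y = y, z = z, frame = seq_along(x) - 1L,
                 channel = channel, cell_id = as.integer(cell_id))
}
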