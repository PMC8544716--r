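#' Density-based clustering parameters
#'
#' The Eps/Npt rule used to turn blink localizations into RNA clusters: a
#' localization is a core point iff at least `npt` localizations (itself
#' included) lie within 3D Euclidean distance `eps`; clusters grow by
#' eps-connectivity of core points and capture border points within `eps` of
#' a core. Defaults are the empirically determined imaging values
#' (`eps` = 25 nm, `npt` = 2).
#'
#' @param eps Neighbourhood radius in nm (> 0).
#' @param npt Minimum number of localizations within `eps`, counting the
#'   point itself (>= 1).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(eps = 25, npt = 2) {
  if (!is.numeric(eps) || length(eps) != 1 || !is.finite(eps) || eps <= 0) {
    abort("eps must be a single positive number (nm)",
          class = "smcoloc_param_error")
  }
  if (!is.numeric(npt) || length(npt) != 1 || npt < 1 || npt != round(npt)) {
    abort("npt must be a single integer >= 1", class = "smcoloc_param_error")
  }
  structure(list(eps = eps, npt = as.integer(npt)), class = "cluster_params")
}

# neighbour index lists under the eps relation (self included), exact.
# dense all-pairs for small n, grid-bucketed search above that; both are
# exactly equivalent to the all-pairs definition.
eps_neighbours <- function(coords, eps) {
  n <- nrow(coords)
  if (n == 0) return(list())
  if (n <= 3000) {
    sq <- rowSums(coords^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
    hits <- which(d2 <= eps^2 + 1e-9, arr.ind = TRUE)  # self included
    return(unname(split(hits[, 2], factor(hits[, 1], levels = seq_len(n)))))
  }
  bin <- floor(sweep(coords, 2, rep(0, 3)) / eps)
  key <- paste(bin[, 1], bin[, 2], bin[, 3])
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    cand <- integer(0)
    for (o in seq_len(27)) {
      k <- paste(bin[i, 1] + offs[o, 1], bin[i, 2] + offs[o, 2],
                 bin[i, 3] + offs[o, 3])
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (coords[cand, 1] - coords[i, 1])^2 +
      (coords[cand, 2] - coords[i, 2])^2 +
      (coords[cand, 3] - coords[i, 3])^2
    sort(cand[d2 <= eps2])
  })
}

#' Density-cluster a set of localizations
#'
#' DBSCAN-style labelling under the Eps/Npt rule (see [cluster_params()]).
#' Border points reachable from cores of two clusters are assigned to the
#' cluster of their lowest-indexed core neighbour, making the labelling
#' deterministic. All localizations are assumed to come from one cell and
#' one channel; use [cluster_localizations()] to iterate over cells and
#' channels.
#'
#' @param locs Tibble/data frame with columns `x`, `y`, `z` (nm), or a
#'   numeric matrix with 3 columns.
#' @param params A [cluster_params()] object.
#' @return A list with `clusters` (tibble: `cluster_id`, `n_spots`, `cx`,
#'   `cy`, `cz`, `members` list-column of input row indices) and `noise`
#'   (integer vector of unclustered row indices).
#' @export
density_cluster <- function(locs, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  coords <- if (is.matrix(locs)) locs else as.matrix(locs[, c("x", "y", "z")])
  n <- nrow(coords)
  empty <- tibble(cluster_id = integer(0), n_spots = integer(0),
                  cx = numeric(0), cy = numeric(0), cz = numeric(0),
                  members = list())
  if (n == 0) return(list(clusters = empty, noise = integer(0)))
  nb <- eps_neighbours(coords, params$eps)
  core <- vapply(nb, length, integer(1)) >= params$npt
  label <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || label[i] != 0L) next
    cid <- cid + 1L
    # flood fill over eps-connected core points
    stack <- i
    label[i] <- cid
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nxt <- nb[[p]]
      nxt <- nxt[core[nxt] & label[nxt] == 0L]
      label[nxt] <- cid
      stack <- c(stack, nxt)
    }
  }
  # border points: lowest-indexed core neighbour decides the cluster
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn) > 0) label[i] <- label[min(cn)]
  }
  noise <- which(label == 0L)
  ids <- seq_len(cid)
  members <- split(which(label > 0L), label[label > 0L])
  members <- members[as.character(ids)]
  cent <- t(vapply(members, function(m) {
    colMeans(coords[m, , drop = FALSE])
  }, numeric(3)))
  clusters <- tibble(
    cluster_id = ids,
    n_spots = vapply(members, length, integer(1)),
    cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
    members = unname(members))
  list(clusters = clusters, noise = noise)
}

#' Centroid of a cluster's member coordinates
#'
#' Coordinate-wise arithmetic mean.
#'
#' @param members Numeric matrix (rows = members, columns = x, y, z) or data
#'   frame with `x`, `y`, `z`.
#' @return Numeric vector `c(x, y, z)`.
#' @export
cluster_centroid <- function(members) {
  m <- if (is.matrix(members)) members else
    as.matrix(members[, c("x", "y", "z")])
  if (nrow(m) == 0) abort("cannot take centroid of zero members",
                          class = "smcoloc_param_error")
  colMeans(m)
}

#' Cluster a localization table per cell and channel
#'
#' Runs [density_cluster()] independently for every (cell, channel)
#' combination of an assigned localization table and binds the results into
#' one cluster table with globally unique cluster ids. Unassigned
#' localizations (`cell_id` `NA`) are skipped.
#'
#' @param locs Localization tibble with `x`, `y`, `z`, `channel`, `cell_id`.
#' @param params A [cluster_params()] object.
#' @return Tibble with one row per cluster: `cell_id`, `channel`,
#'   `cluster_id`, `n_spots`, `cx`, `cy`, `cz`, `members` (row indices into
#'   `locs`).
#' @export
cluster_localizations <- function(locs, params = cluster_params()) {
  keep <- which(!is.na(locs$cell_id))
  if (length(keep) == 0) {
    return(tibble(cell_id = integer(0), channel = character(0),
                  cluster_id = integer(0), n_spots = integer(0),
                  cx = numeric(0), cy = numeric(0), cz = numeric(0),
                  members = list()))
  }
  sub <- locs[keep, ]
  groups <- split(seq_len(nrow(sub)),
                  list(cell = sub$cell_id, channel = sub$channel),
                  drop = TRUE)
  out <- purrr::imap(groups, function(idx, key) {
    res <- density_cluster(sub[idx, ], params)
    cl <- res$clusters
    if (nrow(cl) == 0) return(NULL)
    cl$cell_id <- sub$cell_id[idx[1]]
    cl$channel <- sub$channel[idx[1]]
    cl$members <- lapply(cl$members, function(m) keep[idx[m]])
    cl
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(cell_id = integer(0), channel = character(0),
                  cluster_id = integer(0), n_spots = integer(0),
                  cx = numeric(0), cy = numeric(0), cz = numeric(0),
                  members = list()))
  }
  out$cluster_id <- seq_len(nrow(out))
  dplyr::select(out, "cell_id", "channel", "cluster_id", "n_spots",
                "cx", "cy", "cz", "members")
}
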