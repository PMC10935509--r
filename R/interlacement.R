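# Dual-outlier-free spatial neighbor graph, pairwise degree of interlacement
# (DOI), and the cluster interlacement graph (CI-graph).

DIST_FLOOR <- 1e-6 # micrometers; keeps 1/Dist finite for coincident cells

#' Build the dual-outlier-free spatial neighbor graph
#'
#' For every cell the `k` nearest neighbors by Euclidean distance are found
#' with a k-d tree (ties broken by cell index). Two outlier rules then refine
#' the graph:
#'
#' * *sparse-type*: a cell with fewer than `k` other cells within `radius` sits
#'   in a sparsely populated region; only its neighbors at distance <= `radius`
#'   are retained, so it cannot link to distant cells.
#' * *orphan-type*: a cell with fewer than `orphan_min_n` same-cluster cells
#'   among its retained neighbors is masked out entirely (as source and as
#'   target) so that stray cells do not inflate cluster coverage.
#'
#' @param cells A [spatial_cells()] table with >= 2 cells.
#' @param k Number of nearest neighbors (default 30).
#' @param radius Sparse-outlier radius in micrometers (default 50).
#' @param orphan_min_n Minimum same-cluster neighbors to escape orphan masking
#'   (default 1).
#' @return A `neighbor_graph`: per-cell integer neighbor lists, matching
#'   distances, an orphan mask, and the parameters used.
#' @export
neighbor_graph <- function(cells, k = 30, radius = 50, orphan_min_n = 1) {
  cells <- check_cells(cells)
  n <- nrow(cells)
  if (n < 2) cw_abort("need at least 2 cells", "insufficient_data")
  if (k < 1) cw_abort("k must be >= 1", "parameter_error")
  if (radius <= 0) cw_abort("radius must be > 0", "parameter_error")
  xy <- coord_matrix(cells)
  kk <- min(k, n - 1)

  nn <- RANN::nn2(xy, xy, k = kk + 1)
  idx <- nn$nn.idx
  dst <- nn$nn.dists

  # count of other cells within `radius`: only the threshold "< k" matters,
  # so querying k+1 candidates is enough to decide it
  rk <- min(n, k + 1)
  nr <- RANN::nn2(xy, xy, k = rk, searchtype = "radius", radius = radius)
  within_r <- rowSums(nr$nn.idx != 0) - 1L # exclude self

  neighbors <- vector("list", n)
  distances <- vector("list", n)
  for (i in seq_len(n)) {
    js <- idx[i, ]
    ds <- dst[i, ]
    drop_self <- match(i, js)
    if (is.na(drop_self)) drop_self <- length(js) # duplicate-coord corner case
    js <- js[-drop_self]; ds <- ds[-drop_self]
    ord <- order(ds, js) # deterministic tie-break by cell index
    js <- js[ord]; ds <- ds[ord]
    if (within_r[i] < k) { # sparse-type: truncate to the radius
      keep <- ds <= radius
      js <- js[keep]; ds <- ds[keep]
    }
    neighbors[[i]] <- js
    distances[[i]] <- ds
  }

  lab <- as.integer(cells$cluster)
  orphan <- vapply(seq_len(n), function(i) {
    sum(lab[neighbors[[i]]] == lab[i]) < orphan_min_n
  }, logical(1))

  structure(
    list(
      neighbors = neighbors, distances = distances, orphan_mask = orphan,
      k = k, radius = radius, orphan_min_n = orphan_min_n,
      n_cells = n
    ),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph: ", x$n_cells, " cells, k = ", x$k, ", radius = ",
      x$radius, ", ", sum(x$orphan_mask), " orphan-masked>\n", sep = "")
  invisible(x)
}

#' @export
tidy.neighbor_graph <- function(x, ...) {
  tibble(
    cell = rep.int(seq_len(x$n_cells), lengths(x$neighbors)),
    neighbor = unlist(x$neighbors, use.names = FALSE),
    distance = unlist(x$distances, use.names = FALSE)
  )
}

# flatten (source cell, neighbor, contribution) for all unmasked source and
# target cells; contribution = (1 / max(dist, floor)) / |N_i|
doi_contributions <- function(graph, cells) {
  n <- graph$n_cells
  sizes <- lengths(graph$neighbors)
  src <- rep.int(seq_len(n), sizes)
  tgt <- unlist(graph$neighbors, use.names = FALSE)
  dd <- unlist(graph$distances, use.names = FALSE)
  w <- (1 / pmax(dd, DIST_FLOOR)) / rep.int(sizes, sizes)
  keep <- !graph$orphan_mask[src] & !graph$orphan_mask[tgt]
  tibble(src = src[keep], tgt = tgt[keep], w = w[keep])
}

#' Pairwise degree of interlacement between two clusters
#'
#' The interlacement score from cluster `x` toward cluster `y` is
#' \deqn{I_{xy} = \sum_{i \in C_x} \frac{1}{|N_i|}
#'   \sum_{j \in N_i,\, j \in C_y} \frac{1}{\mathrm{Dist}(i,j)},}
#' i.e. the per-cell mean inverse distance to neighboring cells of the other
#' cluster, summed over the cluster. Orphan-masked cells are excluded both as
#' sources and as targets; `|N_i|` counts the neighbors retained after
#' sparse-type truncation; coincident cells have their distance floored at
#' 1e-6 micrometers.
#'
#' @param graph A [neighbor_graph()].
#' @param cells The [spatial_cells()] the graph was built from.
#' @param x,y Distinct cluster labels.
#' @return A single nonnegative number.
#' @export
interlacement_score <- function(graph, cells, x, y) {
  cells <- check_cells(cells)
  labs <- cluster_levels(cells)
  if (!x %in% labs || !y %in% labs) {
    cw_abort("unknown cluster label", "lookup_error")
  }
  if (identical(x, y)) cw_abort("x and y must differ", "invalid_pair")
  lab <- as.integer(cells$cluster)
  con <- doi_contributions(graph, cells)
  xi <- match(x, labs); yi <- match(y, labs)
  sum(con$w[lab[con$src] == xi & lab[con$tgt] == yi])
}

#' Build the cluster interlacement graph (CI-graph)
#'
#' Computes all pairwise interlacement scores on the dual-outlier-free
#' neighbor graph and symmetrizes them: the edge weight between clusters `x`
#' and `y` is `max(I_xy, I_yx)`; the diagonal is zero.
#'
#' @inheritParams neighbor_graph
#' @return A `ci_graph`: list with `clusters` (ordered labels), `adjacency`
#'   (symmetric nonnegative matrix), and the parameters used.
#' @examples
#' cells <- spatial_cells(
#'   data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1),
#'              cluster = c("L", "L", "R", "R")))
#' ci <- ci_graph(cells, k = 3, radius = 50)
#' ci$adjacency
#' @export
ci_graph <- function(cells, k = 30, radius = 50, orphan_min_n = 1) {
  cells <- check_cells(cells)
  labs <- cluster_levels(cells)
  m <- length(labs)
  if (m < 2) cw_abort("need at least 2 clusters", "insufficient_clusters")
  graph <- neighbor_graph(cells, k = k, radius = radius,
                          orphan_min_n = orphan_min_n)
  lab <- as.integer(cells$cluster)
  con <- doi_contributions(graph, cells)
  imat <- matrix(0, m, m)
  if (nrow(con) > 0) {
    acc <- rowsum(con$w, group = (lab[con$src] - 1L) * m + lab[con$tgt])
    cell <- as.integer(rownames(acc))
    imat[cbind((cell - 1L) %/% m + 1L, (cell - 1L) %% m + 1L)] <- acc[, 1]
  }
  adj <- pmax(imat, t(imat))
  diag(adj) <- 0
  dimnames(adj) <- list(labs, labs)
  structure(
    list(clusters = labs, adjacency = adj,
         params = list(k = k, radius = radius, orphan_min_n = orphan_min_n)),
    class = "ci_graph"
  )
}

#' @export
print.ci_graph <- function(x, ...) {
  cat("<ci_graph: ", length(x$clusters), " clusters, mean DOI = ",
      signif(mean(x$adjacency[upper.tri(x$adjacency)]), 4), ">\n", sep = "")
  invisible(x)
}

#' @export
tidy.ci_graph <- function(x, ...) {
  graph_edges(x$adjacency, c("cluster1", "cluster2"), "doi")
}

#' @export
glance.ci_graph <- function(x, ...) {
  w <- x$adjacency[upper.tri(x$adjacency)]
  tibble(
    n_clusters = length(x$clusters),
    mean_doi = mean(w), max_doi = max(w), min_doi = min(w),
    cv_doi = sd(w) / mean(w)
  )
}

# coefficient of variation of the CI-graph edge weights (off-diagonal)
ci_edge_cv <- function(ci) {
  w <- ci$adjacency[upper.tri(ci$adjacency)]
  sd(w) / mean(w)
}

#' Export / import a CI-graph
#'
#' `write_ci_graph()` writes either an edge-list TSV (`cluster1`, `cluster2`,
#' `doi`; upper triangle) or a square matrix CSV with labels as header
#' row/column. `read_ci_graph_matrix()` reads the matrix form back.
#'
#' @param ci A `ci_graph`.
#' @param path Output path.
#' @param format `"edges"` (TSV) or `"matrix"` (CSV).
#' @return `path`, invisibly; `read_ci_graph_matrix()` returns a `ci_graph`.
#' @export
write_ci_graph <- function(ci, path, format = c("edges", "matrix")) {
  format <- arg_match(format)
  if (format == "edges") {
    readr::write_tsv(tidy(ci), path, progress = FALSE)
  } else {
    df <- as.data.frame(ci$adjacency)
    df <- cbind(cluster = rownames(ci$adjacency), df)
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_ci_graph
#' @export
read_ci_graph_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labs <- as.character(df[[1]])
  adj <- as.matrix(df[, -1])
  dimnames(adj) <- list(labs, labs)
  structure(list(clusters = labs, adjacency = adj, params = list()),
            class = "ci_graph")
}
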