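# Integrative colorization across sections / label sets: cluster
# correspondence (expression Pearson or label IoU), greedy injective matching,
# CI-graph merging, and the shared-color multi-section pipeline.

new_correspondence <- function(S, kind, threshold) {
  structure(
    list(S = S, kind = kind, threshold = threshold),
    class = "cw_correspondence"
  )
}

#' @export
print.cw_correspondence <- function(x, ...) {
  cat("<correspondence: ", nrow(x$S), " x ", ncol(x$S), ", kind = ", x$kind,
      ", threshold = ", x$threshold, ">\n", sep = "")
  invisible(x)
}

#' @export
tidy.cw_correspondence <- function(x, ...) {
  as_tibble(as.data.frame.table(x$S, responseName = "similarity",
                                stringsAsFactors = FALSE)) |>
    rename(cluster1 = "Var1", cluster2 = "Var2")
}

#' Cluster correspondence from mean expression profiles
#'
#' Computes the Pearson correlation between every pair of cluster-mean
#' expression profiles across the top `n_hvg` highly variable genes. Profiles
#' are log1p-normalized; variability is ranked by the variance of the
#' log-normalized expression across all clusters of both sections jointly.
#'
#' @param means1,means2 Cluster-by-gene matrices of mean expression, with
#'   cluster labels as row names and gene identifiers as column names.
#' @param n_hvg Number of highly variable genes (default 5000; all genes if
#'   fewer are shared).
#' @return A correspondence object holding the similarity matrix
#'   (`expression_pearson`, values in \[-1, 1\], default match threshold 0.5).
#' @export
expression_similarity <- function(means1, means2, n_hvg = 5000) {
  means1 <- as.matrix(means1); means2 <- as.matrix(means2)
  shared <- intersect(colnames(means1), colnames(means2))
  if (length(shared) < 2) {
    cw_abort("fewer than 2 shared genes between the sections",
             "incompatibility_error")
  }
  l1 <- log1p(means1[, shared, drop = FALSE])
  l2 <- log1p(means2[, shared, drop = FALSE])
  v <- apply(rbind(l1, l2), 2, stats::var)
  hvg <- shared[order(-v, seq_along(v))][seq_len(min(n_hvg, length(shared)))]
  S <- cor(t(l1[, hvg, drop = FALSE]), t(l2[, hvg, drop = FALSE]))
  dimnames(S) <- list(rownames(means1), rownames(means2))
  new_correspondence(S, "expression_pearson", threshold = 0.5)
}

#' Cluster correspondence from label overlap (IoU)
#'
#' For two labelings of the same cell set, the similarity of cluster `x` in
#' labeling 1 and cluster `y` in labeling 2 is the intersection over union of
#' their member cell sets.
#'
#' @param labels1,labels2 Per-cell label vectors over the same cells (aligned
#'   by position, or by names when both are named).
#' @return A correspondence object (`label_iou`, values in \[0, 1\], default
#'   match threshold 0).
#' @export
iou_similarity <- function(labels1, labels2) {
  if (!is.null(names(labels1)) && !is.null(names(labels2))) {
    if (!setequal(names(labels1), names(labels2))) {
      cw_abort("labelings cover different cell sets", "incompatibility_error")
    }
    labels2 <- labels2[names(labels1)]
  } else if (length(labels1) != length(labels2)) {
    cw_abort("labelings cover different cell sets", "incompatibility_error")
  }
  f1 <- factor(as.character(labels1), levels = unique(as.character(labels1)))
  f2 <- factor(as.character(labels2), levels = unique(as.character(labels2)))
  inter <- table(f1, f2)
  n1 <- rowSums(inter); n2 <- colSums(inter)
  uni <- outer(n1, n2, `+`) - inter
  S <- as.matrix(inter / uni)
  dimnames(S) <- list(levels(f1), levels(f2))
  new_correspondence(S, "label_iou", threshold = 0)
}

#' Greedily match clusters across two labelings
#'
#' Repeatedly takes the global maximum of the similarity matrix, records the
#' pair, and zeroes its row and column so the mapping stays injective in both
#' directions. Stops when all rows or columns are matched or when the maximum
#' drops to the threshold or below; remaining labels are reported unmatched.
#' Ties at the maximum are broken by (row, column) lexicographic order.
#'
#' @param S A correspondence object or a numeric similarity matrix with
#'   dimnames.
#' @param threshold Stop threshold; defaults to the correspondence's own
#'   (0 for IoU, 0.5 for expression similarity).
#' @return A `cluster_match`: tibble of matched pairs (`cluster1`, `cluster2`,
#'   `similarity`) with attributes `unmatched1` / `unmatched2`.
#' @examples
#' S <- matrix(c(0.9, 0.3, 0.2, 0.8), 2,
#'             dimnames = list(c("r1", "r2"), c("c1", "c2")))
#' greedy_match(S, threshold = 0.5)
#' @export
greedy_match <- function(S, threshold = NULL) {
  if (inherits(S, "cw_correspondence")) {
    if (is.null(threshold)) threshold <- S$threshold
    S <- S$S
  }
  if (is.null(threshold)) threshold <- 0
  if (any(!is.finite(S))) cw_abort("similarities must be finite", "parameter_error")
  W <- S
  rows <- rownames(W) %||% as.character(seq_len(nrow(W)))
  cols <- colnames(W) %||% as.character(seq_len(ncol(W)))
  pairs <- list()
  active <- W
  repeat {
    if (length(active) == 0) break
    mx <- max(active)
    if (mx <= threshold) break
    hit <- which(active == mx, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    pairs[[length(pairs) + 1]] <- tibble(
      cluster1 = rows[hit[1]], cluster2 = cols[hit[2]], similarity = mx
    )
    active[hit[1], ] <- -Inf
    active[, hit[2]] <- -Inf
    if (length(pairs) >= min(nrow(W), ncol(W))) break
  }
  out <- if (length(pairs)) bind_rows(pairs) else
    tibble(cluster1 = character(), cluster2 = character(),
           similarity = numeric())
  attr(out, "unmatched1") <- setdiff(rows, out$cluster1)
  attr(out, "unmatched2") <- setdiff(cols, out$cluster2)
  class(out) <- c("cluster_match", class(out))
  out
}

# unified label lookup for graph g (1 or 2) given a cluster_match: matched
# clusters of section 2 take the section-1 label; unmatched labels keep their
# own name, disambiguated with a section suffix if both sections use it
unify_labels <- function(match, labs1, labs2) {
  map2 <- setNames(match$cluster1, match$cluster2)
  un1 <- setdiff(labs1, match$cluster1)
  un2 <- setdiff(labs2, match$cluster2)
  clash <- intersect(un1, un2)
  u1 <- setNames(labs1, labs1)
  u2 <- vapply(labs2, function(l) {
    if (l %in% names(map2)) unname(map2[[l]])
    else if (l %in% clash) paste0(l, ".2")
    else l
  }, character(1))
  list(u1, setNames(u2, labs2))
}

#' Merge CI-graphs under a cluster correspondence
#'
#' Relabels each graph's vertices to unified labels (matched clusters share
#' the first section's label) and merges the adjacency matrices over the label
#' union. Edges present in several graphs are combined by element-wise
#' maximum, consistent with the max-symmetrization of the CI-graph itself.
#'
#' @param graphs A list of two [ci_graph()] objects.
#' @param correspondence A `cluster_match` from [greedy_match()].
#' @return A merged `ci_graph`.
#' @export
merge_ci_graphs <- function(graphs, correspondence) {
  stopifnot(length(graphs) == 2)
  g1 <- graphs[[1]]; g2 <- graphs[[2]]
  bad <- c(setdiff(correspondence$cluster1, g1$clusters),
           setdiff(correspondence$cluster2, g2$clusters))
  if (length(bad) > 0) {
    cw_abort(paste0("correspondence references unknown label(s): ",
                    paste(bad, collapse = ", ")), "lookup_error")
  }
  u <- unify_labels(correspondence, g1$clusters, g2$clusters)
  labs <- unique(c(unname(u[[1]]), unname(u[[2]])))
  m <- length(labs)
  adj <- matrix(0, m, m, dimnames = list(labs, labs))
  place <- function(g, map) {
    ul <- unname(map[g$clusters])
    ii <- match(ul, labs)
    adj[ii, ii] <<- pmax(adj[ii, ii], g$adjacency)
  }
  place(g1, u[[1]])
  place(g2, u[[2]])
  diag(adj) <- 0
  structure(
    list(clusters = labs, adjacency = adj, params = g1$params),
    class = "ci_graph"
  )
}

#' Colorize multiple sections with shared colors
#'
#' End-to-end integrative colorization: builds a CI-graph per section, matches
#' cluster labels across sections (by mean-expression Pearson correlation when
#' profiles are given, by label IoU when both sections cover the same cells),
#' merges the CI-graphs over unified labels, obtains one palette for the
#' merged graph, and optimizes a single assignment on it. Matched clusters
#' therefore receive identical hex colors in every section.
#'
#' @param cells_list List of two [spatial_cells()] tables.
#' @param means_list Optional list of two cluster-by-gene mean-expression
#'   matrices (enables expression matching).
#' @param palette Optional palette; generated from the merged CI-graph when
#'   `NULL`.
#' @param cvd_mode See [color_difference()].
#' @param n_hvg Highly variable genes for expression matching.
#' @inheritParams assign_colors
#' @return A list with `mappings` (per-section tibbles `cluster`, `hex`),
#'   `match` (the cluster correspondence), `merged_ci`, and `coloring` (the
#'   shared `cluster_coloring` on unified labels).
#' @export
colorize_sections <- function(cells_list, means_list = NULL, palette = NULL,
                              cvd_mode = "none", n_hvg = 5000,
                              k = 30, radius = 50, orphan_min_n = 1,
                              n_initial = 2000, max_swaps = 5000,
                              patience = 100, seed = 42,
                              embed_method = "umap", L_range = c(20, 85)) {
  stopifnot(length(cells_list) == 2)
  cells_list <- lapply(cells_list, check_cells)
  cis <- lapply(cells_list, ci_graph, k = k, radius = radius,
                orphan_min_n = orphan_min_n)
  corr <- if (!is.null(means_list)) {
    expression_similarity(means_list[[1]], means_list[[2]], n_hvg = n_hvg)
  } else {
    iou_similarity(
      setNames(as.character(cells_list[[1]]$cluster), cells_list[[1]]$cell_id),
      setNames(as.character(cells_list[[2]]$cluster), cells_list[[2]]$cell_id)
    )
  }
  match_tbl <- greedy_match(corr)
  merged <- merge_ci_graphs(cis, match_tbl)
  if (is.null(palette)) {
    palette <- embed_palette(merged, method = embed_method, L_range = L_range,
                             seed = seed)
  } else {
    palette <- as_palette(palette)
    if (nrow(palette) > length(merged$clusters)) {
      palette <- trim_palette(palette, length(merged$clusters))
    }
  }
  cd <- cd_graph(palette, cvd_mode = cvd_mode)
  coloring <- optimize_assignment(merged, cd, n_initial = n_initial,
                                  max_swaps = max_swaps, patience = patience,
                                  seed = seed)
  u <- unify_labels(match_tbl, cis[[1]]$clusters, cis[[2]]$clusters)
  lut <- setNames(coloring$mapping$hex, coloring$mapping$cluster)
  mappings <- list(
    tibble(cluster = cis[[1]]$clusters, hex = unname(lut[u[[1]][cis[[1]]$clusters]])),
    tibble(cluster = cis[[2]]$clusters, hex = unname(lut[u[[2]][cis[[2]]$clusters]]))
  )
  list(mappings = mappings, match = match_tbl, merged_ci = merged,
       coloring = coloring)
}
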