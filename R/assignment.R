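# Cluster-color assignment: match the CI-graph to the CD-graph with a
# coarse-to-fine stochastic search over permutations.

# internal loss on a permutation *vector* p (cluster i gets color p[i]):
# || P A_ci P^T - A_cd ||_F == || A_ci - A_cd[p, p] ||_F
perm_loss <- function(p, a_ci, a_cd) {
  sqrt(sum((a_ci - a_cd[p, p])^2))
}

perm_vec_to_matrix <- function(p) {
  n <- length(p)
  m <- matrix(0L, n, n)
  m[cbind(p, seq_len(n))] <- 1L
  m
}

perm_matrix_to_vec <- function(P) {
  n <- nrow(P)
  ok <- all(P %in% c(0, 1)) && all(rowSums(P) == 1) && all(colSums(P) == 1)
  if (!ok) cw_abort("P is not a permutation matrix", "parameter_error")
  apply(P, 2, which.max)
}

#' Graph-matching loss of a cluster-to-color permutation
#'
#' The Frobenius norm \eqn{L(P) = \lVert P A_{CI} P^\top - A_{CD} \rVert_F}
#' measuring how well the permuted cluster interlacement adjacency lines up
#' with the color difference adjacency. Minimizing it over permutations pairs
#' heavily interlaced clusters with strongly contrasting colors.
#'
#' @param P A permutation: either an n-by-n 0/1 matrix with unit row and
#'   column sums, or an integer vector `p` with `p[i]` the color index of
#'   cluster `i`.
#' @param a_ci,a_cd Square adjacency matrices of equal order.
#' @return A single nonnegative number.
#' @export
matching_loss <- function(P, a_ci, a_cd) {
  if (!is.matrix(a_ci) || !is.matrix(a_cd) ||
      nrow(a_ci) != ncol(a_ci) || !all(dim(a_ci) == dim(a_cd))) {
    cw_abort("adjacency matrices must be square and of equal order",
             "parameter_error")
  }
  p <- if (is.matrix(P)) {
    if (!all(dim(P) == dim(a_ci))) {
      cw_abort("P has the wrong order", "parameter_error")
    }
    perm_matrix_to_vec(P)
  } else {
    p <- as.integer(P)
    if (length(p) != nrow(a_ci) || !setequal(p, seq_along(p))) {
      cw_abort("P is not a permutation of 1..n", "parameter_error")
    }
    p
  }
  perm_loss(p, a_ci, a_cd)
}

# sample a permutation of all positions that respects fixed assignments
sample_perm <- function(n, fixed_pos = integer(0), fixed_val = integer(0)) {
  p <- integer(n)
  p[fixed_pos] <- fixed_val
  free_pos <- setdiff(seq_len(n), fixed_pos)
  free_val <- setdiff(seq_len(n), fixed_val)
  p[free_pos] <- free_val[sample.int(length(free_val))]
  p
}

#' Optimize the cluster-to-color assignment
#'
#' Coarse stage: draw `n_initial` uniformly random permutations (respecting
#' any fixed assignments) and keep the one with minimal [matching_loss()].
#' Fine stage: repeatedly pick a uniformly random pair of non-fixed clusters
#' and swap their colors, keeping the swap only if the loss strictly
#' decreases; stop after `max_swaps` total attempts or `patience` consecutive
#' non-improving attempts. A single seeded generator drives both stages
#' (coarse draws first, then fine-stage pair draws), so results are
#' reproducible per seed.
#'
#' @param ci A [ci_graph()].
#' @param cd A [cd_graph()] with exactly as many colors as `ci` has clusters.
#' @param n_initial Coarse-stage sample size (default 2000).
#' @param max_swaps Fine-stage attempt cap (default 5000).
#' @param patience Consecutive non-improving attempts before stopping
#'   (default 100).
#' @param seed Integer seed (default 1).
#' @param fixed Optional named character vector `c(cluster = "#RRGGBB", ...)`
#'   of user-fixed colors; fixed clusters are excluded from both stages.
#' @return A `cluster_coloring`: mapping tibble (`cluster`, `hex`), the
#'   permutation vector, the final loss, and the seed.
#' @export
optimize_assignment <- function(ci, cd, n_initial = 2000, max_swaps = 5000,
                                patience = 100, seed = 1, fixed = NULL) {
  a_ci <- ci$adjacency
  a_cd <- cd$adjacency
  n <- nrow(a_ci)
  if (nrow(a_cd) != n) {
    cw_abort("CI-graph and CD-graph must have the same number of vertices",
             "size_error")
  }
  if (n_initial < 1 || max_swaps < 0 || patience < 1) {
    cw_abort("n_initial >= 1, max_swaps >= 0, patience >= 1 required",
             "parameter_error")
  }
  fixed_pos <- integer(0); fixed_val <- integer(0)
  if (!is.null(fixed) && length(fixed) > 0) {
    fixed_pos <- match(names(fixed), ci$clusters)
    fixed_val <- match(toupper(unname(fixed)), toupper(cd$colors$hex))
    if (anyNA(fixed_pos)) cw_abort("fixed cluster not in CI-graph", "lookup_error")
    if (anyNA(fixed_val)) cw_abort("fixed color not in palette", "lookup_error")
    if (anyDuplicated(fixed_pos) || anyDuplicated(fixed_val)) {
      cw_abort("fixed assignments must be one-to-one", "parameter_error")
    }
  }
  free_pos <- setdiff(seq_len(n), fixed_pos)

  res <- withr::with_seed(seed, {
    best_p <- sample_perm(n, fixed_pos, fixed_val)
    best_loss <- perm_loss(best_p, a_ci, a_cd)
    if (n_initial > 1) {
      for (t in seq_len(n_initial - 1)) {
        p <- sample_perm(n, fixed_pos, fixed_val)
        l <- perm_loss(p, a_ci, a_cd)
        if (l < best_loss) {
          best_loss <- l
          best_p <- p
        }
      }
    }
    coarse_loss <- best_loss
    stalled <- 0L
    attempts <- 0L
    while (attempts < max_swaps && stalled < patience && length(free_pos) >= 2) {
      attempts <- attempts + 1L
      ij <- free_pos[sample.int(length(free_pos), 2)]
      p <- best_p
      p[ij] <- p[rev(ij)]
      l <- perm_loss(p, a_ci, a_cd)
      if (l < best_loss) { # strict decrease only
        best_loss <- l
        best_p <- p
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
      }
    }
    list(p = best_p, loss = best_loss, coarse_loss = coarse_loss,
         swap_attempts = attempts)
  })

  new_cluster_coloring(ci$clusters, cd$colors, res$p, res$loss, seed,
                       coarse_loss = res$coarse_loss,
                       cvd_mode = cd$cvd_mode, fixed = names(fixed))
}

new_cluster_coloring <- function(clusters, palette, perm, loss, seed,
                                 coarse_loss = NA_real_, cvd_mode = "none",
                                 fixed = NULL) {
  structure(
    list(
      mapping = tibble(cluster = clusters, hex = palette$hex[perm]),
      palette = palette,
      permutation = perm,
      loss = loss,
      coarse_loss = coarse_loss,
      cvd_mode = cvd_mode,
      seed = seed,
      fixed = fixed
    ),
    class = "cluster_coloring"
  )
}

#' @export
print.cluster_coloring <- function(x, ...) {
  cat("<cluster_coloring: ", nrow(x$mapping), " clusters, loss = ",
      signif(x$loss, 6), ", seed = ", x$seed, ">\n", sep = "")
  print(x$mapping)
  invisible(x)
}

#' @export
tidy.cluster_coloring <- function(x, ...) x$mapping

#' @export
glance.cluster_coloring <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$mapping),
    loss = x$loss,
    coarse_loss = x$coarse_loss,
    cvd_mode = x$cvd_mode,
    seed = x$seed
  )
}

#' Write a cluster-color mapping as JSON
#'
#' @param coloring A `cluster_coloring`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coloring <- function(coloring, path) {
  m <- setNames(as.list(coloring$mapping$hex), coloring$mapping$cluster)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# farthest-point-sampling trim of a palette to n colors under the redmean
# metric; `keep` rows are always retained
trim_palette <- function(palette, n, keep = integer(0)) {
  if (nrow(palette) < n) {
    cw_abort("palette has fewer colors than clusters", "insufficient_palette")
  }
  if (nrow(palette) == n) return(palette)
  rgb <- palette_rgb(palette)
  d <- redmean_cross(rgb, rgb)
  sel <- as.integer(keep)
  if (length(sel) == 0) {
    far <- which(d == max(d), arr.ind = TRUE)[1, ]
    sel <- sort(as.integer(far))[seq_len(min(2, n))]
  }
  while (length(sel) < n) {
    cand <- setdiff(seq_len(nrow(palette)), sel)
    mind <- apply(d[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[which.max(mind)]) # ties: lowest palette index
  }
  out <- palette[sort(sel), ]
  class(out) <- class(palette)
  attr(out, "source") <- attr(palette, "source")
  out
}

#' Spatially aware color assignment, end to end
#'
#' Builds the CI-graph from the cells, obtains a palette (generated by CI-graph
#' embedding when none is given; trimmed to the cluster count by farthest point
#' sampling when larger), builds the CD-graph under the requested CVD mode, and
#' optimizes the cluster-to-color permutation.
#'
#' @inheritParams neighbor_graph
#' @inheritParams optimize_assignment
#' @param palette A `cw_palette`, character vector of hex strings, or `NULL`
#'   to generate one by [embed_palette()]. Must have at least as many colors
#'   as there are clusters.
#' @param cvd_mode See [color_difference()].
#' @param embed_method,L_range Passed to [embed_palette()] when generating.
#' @param seed Single seed driving palette generation and optimization.
#' @return A `cluster_coloring`.
#' @examples
#' cells <- simulate_cluster_pair("adjacent", seed = 7)
#' assign_colors(cells, palette = c("#D62728", "#1F77B4"), k = 10)
#' @export
assign_colors <- function(cells, palette = NULL, cvd_mode = "none",
                          k = 30, radius = 50, orphan_min_n = 1,
                          n_initial = 2000, max_swaps = 5000, patience = 100,
                          seed = 42, fixed = NULL,
                          embed_method = "umap", L_range = c(20, 85)) {
  cells <- check_cells(cells)
  check_cvd_mode(cvd_mode)
  ci <- ci_graph(cells, k = k, radius = radius, orphan_min_n = orphan_min_n)
  n <- length(ci$clusters)
  if (is.null(palette)) {
    palette <- embed_palette(ci, method = embed_method, L_range = L_range,
                             seed = seed)
  } else {
    palette <- as_palette(palette)
    if (nrow(palette) < n) {
      cw_abort("palette has fewer colors than clusters", "insufficient_palette")
    }
    if (nrow(palette) > n) {
      keep <- if (!is.null(fixed)) {
        match(toupper(unname(fixed)), toupper(palette$hex))
      } else integer(0)
      if (anyNA(keep)) cw_abort("fixed color not in palette", "lookup_error")
      palette <- trim_palette(palette, n, keep = keep)
    }
  }
  cd <- cd_graph(palette, cvd_mode = cvd_mode)
  optimize_assignment(ci, cd, n_initial = n_initial, max_swaps = max_swaps,
                      patience = patience, seed = seed, fixed = fixed)
}
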