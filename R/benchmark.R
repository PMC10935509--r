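# Synthetic spatial data emulating the five canonical cluster-pair topologies,
# plus perceptual discernibility scoring for palettes and fields of view.

SCENARIOS <- c(mixed = 10, overlapped = 50, adjacent = 70,
               isolated = 120, distant = 300)
DENSITY_N <- c(dense = 100L, sparse = 25L)

#' Simulate a pair of Gaussian cell clusters
#'
#' Two isotropic Gaussian point sets (standard deviation 25 micrometers) whose
#' centers sit `center distance` apart along the x axis. The scenario fixes
#' the center distance: mixed 10, overlapped 50, adjacent 70, isolated 120,
#' distant 300. A dense set has 100 cells, a sparse set 25.
#'
#' @param scenario One of `"mixed"`, `"overlapped"`, `"adjacent"`,
#'   `"isolated"`, `"distant"`.
#' @param density1,density2 `"dense"` or `"sparse"` for the two clusters.
#' @param sd Isotropic standard deviation in micrometers (default 25).
#' @param seed Optional integer seed; the draw is reproducible per seed.
#' @return A [spatial_cells()] table with clusters `"A"` and `"B"`.
#' @examples
#' simulate_cluster_pair("mixed", seed = 1)
#' @export
simulate_cluster_pair <- function(scenario = names(SCENARIOS),
                                  density1 = c("dense", "sparse"),
                                  density2 = c("dense", "sparse"),
                                  sd = 25, seed = NULL) {
  scenario <- arg_match(scenario)
  density1 <- arg_match(density1)
  density2 <- arg_match(density2)
  d <- SCENARIOS[[scenario]]
  n1 <- DENSITY_N[[density1]]
  n2 <- DENSITY_N[[density2]]
  draw <- function() {
    tibble(
      x = c(rnorm(n1, 0, sd), rnorm(n2, d, sd)),
      y = c(rnorm(n1, 0, sd), rnorm(n2, 0, sd)),
      cluster = rep(c("A", "B"), c(n1, n2))
    )
  }
  df <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  spatial_cells(df, "x", "y", "cluster")
}

#' Degree-of-interlacement benchmark over the five scenarios
#'
#' For each scenario and replicate, simulates a cluster pair and computes the
#' DOI (the single CI-graph edge weight) at the given neighbor-graph
#' parameters. Replicate seeds are derived deterministically from `base_seed`.
#'
#' @inheritParams simulate_cluster_pair
#' @inheritParams neighbor_graph
#' @param n_reps Replicates per scenario (default 20).
#' @param base_seed Seed from which all replicate seeds are drawn.
#' @return A tibble (`scenario`, `replicate`, `doi`); summarize with
#'   [doi_summary()].
#' @export
doi_benchmark <- function(density1 = "dense", density2 = "dense",
                          n_reps = 20, base_seed = 1,
                          k = 30, radius = 50, orphan_min_n = 1) {
  if (n_reps < 1) cw_abort("n_reps must be >= 1", "parameter_error")
  seeds <- withr::with_seed(base_seed,
                            matrix(sample.int(.Machine$integer.max - 1,
                                              5 * n_reps),
                                   nrow = 5))
  purrr::map_dfr(seq_along(SCENARIOS), function(si) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      cells <- simulate_cluster_pair(names(SCENARIOS)[si], density1, density2,
                                     seed = seeds[si, r])
      ci <- ci_graph(cells, k = k, radius = radius,
                     orphan_min_n = orphan_min_n)
      tibble(scenario = names(SCENARIOS)[si], replicate = r,
             doi = ci$adjacency["A", "B"])
    })
  })
}

#' Summarize a DOI benchmark: scenario means and min-max normalized scores
#'
#' @param scores A tibble from [doi_benchmark()].
#' @return A tibble (`scenario`, `mean_doi`, `normalized`) where `normalized`
#'   min-max rescales the scenario means to \[0, 1\] (highest-mean scenario 1,
#'   lowest 0).
#' @export
doi_summary <- function(scores) {
  out <- scores |>
    group_by(.data$scenario) |>
    summarise(mean_doi = mean(.data$doi), .groups = "drop")
  out <- out[match(names(SCENARIOS)[names(SCENARIOS) %in% out$scenario],
                   out$scenario), ]
  rng <- range(out$mean_doi)
  out$normalized <- if (diff(rng) == 0) rep(0, nrow(out)) else
    (out$mean_doi - rng[1]) / diff(rng)
  out
}

#' Per-field-of-view color discernibility
#'
#' Grids the bounding box into `fov_size`-square tiles (anchored at the
#' minimum corner, half-open intervals) and scores each tile as the mean
#' perceptual color difference over all unordered pairs of distinct cells in
#' it. Same-cluster pairs share a color and contribute zero; tiles with fewer
#' than two cells score zero.
#'
#' @param cells A [spatial_cells()] table.
#' @param coloring A `cluster_coloring` covering every cluster present.
#' @param fov_size Tile side length in micrometers (default 500).
#' @param cvd_mode See [color_difference()].
#' @return A tibble (`fov_x`, `fov_y`, `n_cells`, `score`).
#' @export
fov_discernibility <- function(cells, coloring, fov_size = 500,
                               cvd_mode = "none") {
  cells <- check_cells(cells)
  lut <- setNames(coloring$mapping$hex, coloring$mapping$cluster)
  labs <- as.character(cells$cluster)
  if (!all(labs %in% names(lut))) {
    cw_abort("coloring does not cover every cluster present", "lookup_error")
  }
  pal_hex <- unname(lut[cluster_levels(cells)])
  # pairwise differences between cluster colors under the mode, computed once
  dm <- matrix(0, length(pal_hex), length(pal_hex))
  if (length(pal_hex) > 1) {
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    v <- color_difference(pal_hex[idx[, 1]], pal_hex[idx[, 2]], cvd_mode)
    dm[idx] <- v
    dm <- dm + t(dm)
  }
  fx <- floor((cells$x - min(cells$x)) / fov_size)
  fy <- floor((cells$y - min(cells$y)) / fov_size)
  cl <- as.integer(cells$cluster)
  tibble(fov_x = fx, fov_y = fy, cl = cl) |>
    group_by(.data$fov_x, .data$fov_y) |>
    summarise(
      n_cells = n(),
      score = fov_pair_mean(.data$cl, dm),
      .groups = "drop"
    )
}

# mean pairwise difference from per-cluster counts: sum_{c<c'} n_c n_c' D_cc'
# over choose(n, 2); same-cluster pairs contribute 0
fov_pair_mean <- function(cl, dm) {
  n <- length(cl)
  if (n < 2) return(0)
  cnt <- tabulate(cl, nbins = nrow(dm))
  tot <- as.numeric(cnt %*% dm %*% cnt) / 2 # D has zero diagonal
  tot / choose(n, 2)
}

#' Palette discernibility
#'
#' All pairwise perceptual color differences within a palette, and their mean.
#'
#' @param palette A `cw_palette` or hex vector with >= 2 colors.
#' @param cvd_mode See [color_difference()].
#' @return A list with `mean` and `differences` (tibble `color1`, `color2`,
#'   `difference` over all C(n, 2) pairs).
#' @export
palette_discernibility <- function(palette, cvd_mode = "none") {
  palette <- as_palette(palette)
  if (nrow(palette) < 2) {
    cw_abort("palette discernibility needs at least 2 colors",
             "insufficient_palette")
  }
  g <- cd_graph(palette, cvd_mode = cvd_mode)
  diffs <- tidy(g)
  list(mean = mean(diffs$difference), differences = diffs)
}

#' Simulate a multi-cluster spatial layout
#'
#' Gaussian blobs (standard deviation `sd`) centered on a jittered square
#' grid. At the default spacing of 70 micrometers — the adjacent-scenario
#' center distance — grid neighbors interlace to varying degrees while
#' opposite corners are isolated, so one dataset exhibits the full range of
#' pairwise relationships. Used for end-to-end demonstrations and for
#' checking that assigned color differences track DOI.
#'
#' @param n_clusters Number of clusters (default 8).
#' @param n_per_cluster Cells per cluster (default 100).
#' @param sd Blob standard deviation in micrometers (default 25).
#' @param spacing Grid spacing in micrometers (default 70); centers are
#'   jittered uniformly by up to 10 micrometers per axis.
#' @param seed Optional integer seed.
#' @return A [spatial_cells()] table.
#' @export
simulate_cluster_field <- function(n_clusters = 8, n_per_cluster = 100,
                                   sd = 25, spacing = 70, seed = NULL) {
  draw <- function() {
    side <- ceiling(sqrt(n_clusters))
    cx <- ((seq_len(n_clusters) - 1) %% side) * spacing +
      runif(n_clusters, -10, 10)
    cy <- ((seq_len(n_clusters) - 1) %/% side) * spacing +
      runif(n_clusters, -10, 10)
    tibble(
      x = as.vector(vapply(seq_len(n_clusters),
                           function(i) rnorm(n_per_cluster, cx[i], sd),
                           numeric(n_per_cluster))),
      y = as.vector(vapply(seq_len(n_clusters),
                           function(i) rnorm(n_per_cluster, cy[i], sd),
                           numeric(n_per_cluster))),
      cluster = rep(paste0("C", seq_len(n_clusters)), each = n_per_cluster)
    )
  }
  df <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  spatial_cells(df, "x", "y", "cluster")
}
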