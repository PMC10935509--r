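test_that("matching loss is the Frobenius norm of the permuted difference", {
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(matching_loss(1:2, A, A), 0)
  expect_equal(matching_loss(diag(2), A, A), 0)

  # 3x3: the strong DOI edge must land on the strong color edge
  a_ci <- matrix(c(0, 1, 0,
                   1, 0, 0,
                   0, 0, 0), 3, byrow = TRUE)
  a_cd <- matrix(c(0, 0.1, 0.2,
                   0.1, 0, 5,
                   0.2, 5, 0), 3, byrow = TRUE)
  losses <- vapply(all_perms(3), function(p) {
    matching_loss(as.integer(p), a_ci, a_cd)
  }, numeric(1))
  best <- all_perms(3)[[which.min(losses)]]
  # clusters 1,2 (the DOI edge) must map to colors 2,3 (the big edge)
  expect_setequal(best[1:2], c(2L, 3L))
  # permutation-vector and permutation-matrix forms agree
  for (p in all_perms(3)) {
    expect_equal(matching_loss(as.integer(p), a_ci, a_cd),
                 matching_loss(colorweave:::perm_vec_to_matrix(as.integer(p)),
                               a_ci, a_cd))
  }
  # relabeling both graphs consistently leaves the optimum unchanged
  sw <- c(2L, 1L, 3L)
  losses_sw <- vapply(all_perms(3), function(p) {
    matching_loss(as.integer(p), a_ci[sw, sw], a_cd)
  }, numeric(1))
  expect_equal(min(losses_sw), min(losses))

  expect_error(matching_loss(c(1L, 1L, 3L), a_ci, a_cd),
               class = "colorweave_parameter_error")
  expect_error(matching_loss(1:2, a_ci, a_cd),
               class = "colorweave_parameter_error")
  expect_error(matching_loss(1:3, a_ci, a_cd[1:2, 1:2]),
               class = "colorweave_parameter_error")
})

random_graph_pair <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(runif(n * n), n); A <- A + t(A); diag(A) <- 0
    B <- matrix(runif(n * n) * 700, n); B <- B + t(B); diag(B) <- 0
  })
  ci <- structure(list(clusters = paste0("k", seq_len(n)), adjacency = A),
                  class = "ci_graph")
  pal <- as_palette(default_palette_20()$hex[seq_len(n)])
  cd <- structure(list(colors = pal, adjacency = B, cvd_mode = "none"),
                  class = "cd_graph")
  list(ci = ci, cd = cd)
}

test_that("two-cluster optimization always returns the better permutation", {
  for (s in 1:10) {
    g <- random_graph_pair(2, seed = 500 + s)
    res <- optimize_assignment(g$ci, g$cd, seed = s)
    expect_equal(res$loss, brute_best_loss(g$ci$adjacency, g$cd$adjacency),
                 tolerance = 1e-12)
  }
})

test_that("the fine stage never worsens the coarse-stage loss", {
  for (s in 1:5) {
    g <- random_graph_pair(7, seed = 600 + s)
    res <- optimize_assignment(g$ci, g$cd, seed = s)
    expect_lte(res$loss, res$coarse_loss)
    expect_equal(res$loss,
                 matching_loss(res$permutation, g$ci$adjacency,
                               g$cd$adjacency))
  }
})

test_that("optimization is reproducible per seed", {
  g <- random_graph_pair(6, seed = 9)
  a <- optimize_assignment(g$ci, g$cd, seed = 123)
  b <- optimize_assignment(g$ci, g$cd, seed = 123)
  expect_identical(a$permutation, b$permutation)
  expect_identical(a$mapping, b$mapping)
  c <- optimize_assignment(g$ci, g$cd, seed = 124)
  expect_s3_class(tidy(c), "tbl_df")
})

test_that("user-fixed colors are never reassigned", {
  for (s in 1:5) {
    g <- random_graph_pair(6, seed = 700 + s)
    fix_hex <- g$cd$colors$hex[4]
    res <- optimize_assignment(g$ci, g$cd, seed = s,
                               fixed = c(k2 = fix_hex))
    expect_equal(res$mapping$hex[res$mapping$cluster == "k2"], fix_hex)
  }
  g <- random_graph_pair(3, seed = 1)
  expect_error(optimize_assignment(g$ci, g$cd, fixed = c(zz = "#000000")),
               class = "colorweave_lookup_error")
})

test_that("palette trimming keeps a maximally separated subset", {
  pal <- default_palette_20()
  tr <- colorweave:::trim_palette(pal, 5)
  expect_equal(nrow(tr), 5)
  expect_true(all(tr$hex %in% pal$hex))
  # trimmed subset is no worse separated than a contiguous head subset
  d_tr <- cd_graph(tr)$adjacency
  d_hd <- cd_graph(pal[1:5, ])$adjacency
  expect_gte(min(d_tr[upper.tri(d_tr)]), min(d_hd[upper.tri(d_hd)]))
  keep <- match("#2CA02C", pal$hex)
  tr2 <- colorweave:::trim_palette(pal, 4, keep = keep)
  expect_true("#2CA02C" %in% tr2$hex)
})

test_that("end-to-end assignment gives interlaced pairs the strong contrast", {
  # A,B mixed; C,D distant from everyone and each other
  df <- withr::with_seed(42, rbind(
    data.frame(x = rnorm(100, 0, 25), y = rnorm(100, 0, 25), cluster = "A"),
    data.frame(x = rnorm(100, 10, 25), y = rnorm(100, 0, 25), cluster = "B"),
    data.frame(x = rnorm(100, 1000, 25), y = rnorm(100, 0, 25), cluster = "C"),
    data.frame(x = rnorm(100, 0, 25), y = rnorm(100, 1000, 25), cluster = "D")
  ))
  cells <- spatial_cells(df)
  # palette with one dominant contrast pair (black/white) and two mid grays
  pal <- c("#000000", "#FFFFFF", "#777788", "#887777")
  res <- assign_colors(cells, palette = pal, seed = 3)
  lut <- setNames(res$mapping$hex, res$mapping$cluster)
  d_ab <- redmean_difference(lut[["A"]], lut[["B"]])
  d_cd <- redmean_difference(lut[["C"]], lut[["D"]])
  expect_gt(d_ab, d_cd)
  expect_setequal(c(lut[["A"]], lut[["B"]]), c("#000000", "#FFFFFF"))

  # same inputs + same seed give the identical mapping
  res2 <- assign_colors(cells, palette = pal, seed = 3)
  expect_identical(res$mapping, res2$mapping)

  expect_error(assign_colors(cells, palette = pal[1:3]),
               class = "colorweave_insufficient_palette")
})
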