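test_that("expression similarity is Pearson on log cluster means", {
  genes <- paste0("g", 1:4)
  m1 <- rbind(c1 = c(1, 1, 0, 0), c2 = c(0, 0, 1, 1))
  colnames(m1) <- genes
  m2 <- rbind(d1 = c(1, 1, 0, 0), d2 = c(0, 0, 1, 1))
  colnames(m2) <- genes
  s <- expression_similarity(m1, m2)
  expect_equal(s$S["c1", "d1"], 1)
  expect_equal(s$S["c1", "d2"], -1)
  expect_true(all(s$S >= -1 - 1e-12 & s$S <= 1 + 1e-12))
  expect_equal(s$threshold, 0.5)

  # HVG cap: with n_hvg = 2 only the two most variable genes are used
  m3 <- rbind(a = c(10, 0, 5, 5), b = c(0, 10, 5, 5))
  colnames(m3) <- genes
  s2 <- expression_similarity(m3, m3, n_hvg = 2)
  expect_equal(unname(diag(s2$S)), c(1, 1))

  bad <- m1; colnames(bad) <- paste0("h", 1:4)
  expect_error(expression_similarity(m1, bad),
               class = "colorweave_incompatibility_error")
})

test_that("IoU similarity is exact set arithmetic", {
  l1 <- c(a = "x", b = "x", c = "x", d = "q")
  l2 <- c(b = "y", c = "y", d = "y", a = "q")
  s <- iou_similarity(l1, l2)
  # x = {a,b,c}, y = {b,c,d}: intersection 2, union 4
  expect_equal(s$S["x", "y"], 0.5)
  expect_equal(s$threshold, 0)

  same <- c("u", "u", "v", "v", "w")
  s2 <- iou_similarity(same, same)
  expect_equal(unname(diag(s2$S)), rep(1, 3))
  expect_true(all(s2$S[upper.tri(s2$S)] == 0))

  expect_error(iou_similarity(c("a", "b"), c("a", "b", "c")),
               class = "colorweave_incompatibility_error")
})

test_that("greedy matching traces the worked 2x2 example and stays injective", {
  S <- matrix(c(0.9, 0.3, 0.2, 0.8), 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  m <- greedy_match(S, threshold = 0.5)
  expect_equal(m$cluster1, c("r1", "r2"))
  expect_equal(m$cluster2, c("c1", "c2"))
  expect_equal(m$similarity, c(0.9, 0.8))

  low <- greedy_match(S * 0.1, threshold = 0.5)
  expect_equal(nrow(low), 0)
  expect_setequal(attr(low, "unmatched1"), c("r1", "r2"))

  for (s in 1:20) {
    W <- withr::with_seed(800 + s, matrix(runif(16), 4,
      dimnames = list(paste0("r", 1:4), paste0("c", 1:4))))
    mm <- greedy_match(W, threshold = 0)
    expect_equal(anyDuplicated(mm$cluster1), 0)
    expect_equal(anyDuplicated(mm$cluster2), 0)
    expect_identical(mm, greedy_match(W, threshold = 0)) # deterministic
  }
})

test_that("identical partitions match perfectly at IoU 1", {
  labs <- withr::with_seed(12, sample(letters[1:5], 200, replace = TRUE))
  m <- greedy_match(iou_similarity(labs, labs))
  expect_equal(nrow(m), 5)
  expect_equal(m$cluster1, m$cluster2)
  expect_true(all(m$similarity == 1))
})

test_that("CI-graph merging is idempotent and takes element-wise maxima", {
  f <- simulate_cluster_field(4, seed = 21)
  ci <- ci_graph(f)
  ident <- greedy_match(iou_similarity(
    setNames(as.character(f$cluster), f$cell_id),
    setNames(as.character(f$cluster), f$cell_id)))
  merged <- merge_ci_graphs(list(ci, ci), ident)
  expect_equal(merged$adjacency, ci$adjacency)

  # two 2-cluster graphs sharing one matched pair
  g1 <- structure(list(clusters = c("A", "B"),
                       adjacency = matrix(c(0, 0.2, 0.2, 0), 2,
                                          dimnames = list(c("A", "B"),
                                                          c("A", "B"))),
                       params = list()), class = "ci_graph")
  g2 <- structure(list(clusters = c("P", "Q"),
                       adjacency = matrix(c(0, 0.7, 0.7, 0), 2,
                                          dimnames = list(c("P", "Q"),
                                                          c("P", "Q"))),
                       params = list()), class = "ci_graph")
  corr <- tibble::tibble(cluster1 = c("A", "B"), cluster2 = c("P", "Q"),
                         similarity = c(1, 1))
  merged2 <- merge_ci_graphs(list(g1, g2), corr)
  expect_equal(merged2$adjacency["A", "B"], 0.7)

  # disjoint unmatched clusters give zero cross-blocks
  none <- tibble::tibble(cluster1 = character(), cluster2 = character(),
                         similarity = numeric())
  merged3 <- merge_ci_graphs(list(g1, g2), none)
  expect_equal(dim(merged3$adjacency), c(4, 4))
  expect_equal(merged3$adjacency["A", "P"], 0)
  expect_identical(merged3$adjacency, t(merged3$adjacency))

  bad <- tibble::tibble(cluster1 = "A", cluster2 = "ZZ", similarity = 1)
  expect_error(merge_ci_graphs(list(g1, g2), bad),
               class = "colorweave_lookup_error")
})

test_that("matched clusters share identical colors across sections", {
  f1 <- simulate_cluster_field(5, seed = 61)
  # section 2: the same tissue with one cluster renamed and one missing
  df2 <- as.data.frame(f1)
  df2$cluster <- as.character(df2$cluster)
  df2$cluster[df2$cluster == "C2"] <- "C2b"
  f2 <- spatial_cells(df2)

  means <- withr::with_seed(5, matrix(rexp(5 * 30), 5, 30,
    dimnames = list(paste0("C", 1:5), paste0("g", 1:30))))
  means2 <- means
  rownames(means2)[2] <- "C2b"

  res <- colorize_sections(list(f1, f2), means_list = list(means, means2),
                           seed = 17, n_initial = 300, max_swaps = 800)
  m1 <- setNames(res$mappings[[1]]$hex, res$mappings[[1]]$cluster)
  m2 <- setNames(res$mappings[[2]]$hex, res$mappings[[2]]$cluster)
  expect_equal(unname(m1["C2"]), unname(m2["C2b"]))
  for (cl in c("C1", "C3", "C4", "C5")) {
    expect_equal(unname(m1[cl]), unname(m2[cl]))
  }
  expect_equal(nrow(res$match), 5)
})
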