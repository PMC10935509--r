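test_that("embedded palettes honor the lightness contract and the seed", {
  f <- simulate_cluster_field(6, seed = 31)
  ci <- ci_graph(f)
  pal <- embed_palette(ci, seed = 7)
  expect_equal(nrow(pal), 6)
  expect_true(all(pal$L >= 20 - 1e-9 & pal$L <= 85 + 1e-9))
  expect_lt(abs(min(pal$L) - 20), 0.5)
  expect_lt(abs(max(pal$L) - 85), 0.5)
  expect_equal(length(unique(pal$hex)), 6)

  again <- embed_palette(ci, seed = 7)
  expect_identical(pal$hex, again$hex)

  narrow <- embed_palette(ci, L_range = c(40, 60), seed = 7)
  expect_true(all(narrow$L >= 40 - 1e-9 & narrow$L <= 60 + 1e-9))

  expect_error(embed_palette(ci, n_colors = 4),
               class = "colorweave_parameter_error")
  expect_error(embed_palette(ci, L_range = c(50, 40)),
               class = "colorweave_parameter_error")
})

test_that("interlaced pairs embed farther apart than isolated ones (MDS)", {
  # A-B heavily interlaced; C and D mutually isolated with near-identical
  # (near-zero) DOI profiles. The embedded colors of A and B must be farther
  # apart than those of C and D. (Per-axis min-max rescaling preserves
  # near-coincidence, so this ordering is robust; raw triangle-distance
  # orderings at n = 3 are not, because a low-variance axis is stretched to
  # the full +/-128 channel.)
  A <- matrix(c(0, 10, 0.10, 0.10,
                10, 0, 0.03, 0.03,
                0.10, 0.03, 0, 0,
                0.10, 0.03, 0, 0), 4, 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  ci <- structure(list(clusters = LETTERS[1:4], adjacency = A),
                  class = "ci_graph")
  pal <- embed_palette(ci, method = "mds")
  lab <- colorweave:::palette_lab(pal)
  d_ab <- sqrt(sum((lab[1, ] - lab[2, ])^2))
  d_cd <- sqrt(sum((lab[3, ] - lab[4, ])^2))
  expect_gt(d_ab, d_cd)
})

test_that("strongly bimodal DOI weights produce a bimodal palette", {
  # six isolated clusters (a hub of near-identical colors) plus one heavily
  # interlaced pair: the pairwise-difference distribution splits in two
  A <- matrix(0, 8, 8)
  A[7, 8] <- A[8, 7] <- 5
  dimnames(A) <- list(paste0("g", 1:8), paste0("g", 1:8))
  ci <- structure(list(clusters = paste0("g", 1:8), adjacency = A),
                  class = "ci_graph")
  d <- sort(colorweave:::pairwise_de(
    colorweave:::palette_lab(embed_palette(ci, method = "mds"))))
  n_hub_pairs <- choose(6, 2)
  gap_at <- which.max(diff(d))
  expect_equal(gap_at, n_hub_pairs)
  expect_gt(max(diff(d)), 10 * max(d[seq_len(n_hub_pairs)] -
                                     d[1], na.rm = TRUE) + 1)
})

test_that("image histograms bin, filter and count as declared", {
  img1 <- array(rep(c(0.5, 0.2, 0.3), each = 1), c(1, 1, 3))
  h1 <- image_histogram(img1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$frequency, 1)

  two <- block_image(c("#C03020", "#2060C0"), block_px = 10)
  h2 <- image_histogram(two)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$frequency, c(100, 100))

  # very dark and very bright pixels fall outside the default L range
  dark_bright <- block_image(c("#050505", "#FDFDFD", "#C03020"), block_px = 4)
  h3 <- image_histogram(dark_bright)
  expect_equal(nrow(h3), 1)

  noise <- withr::with_seed(8, array(runif(120 * 120 * 3), c(120, 120, 3)))
  hn <- image_histogram(noise, L_range = c(0, 100), percentile_cut = 0)
  expect_lte(nrow(hn), 20^3)
  expect_gt(nrow(hn), 100)
  expect_error(image_histogram(array(0, c(0, 4, 3))),
               class = "colorweave_empty_input")
})

test_that("frequency decay zeroes the pulled bin and spares distant bins", {
  lab <- rbind(c(50, 0, 0), c(50, 2, 0), c(55, 95, -90))
  h <- manual_hist(lab, c(100, 99, 98))
  pal <- select_theme_palette(h, 2, sigma = 80)
  # the near-duplicate of the first pull loses; the far bin wins
  expect_equal(colorweave:::palette_lab(pal)[1, ], c(50, 0, 0),
               ignore_attr = TRUE)
  expect_equal(colorweave:::palette_lab(pal)[2, ], c(55, 95, -90),
               ignore_attr = TRUE)

  # after pulling b, a bin with E(a,b) = 0 has frequency exactly 0:
  # selecting 2 colors from two identical bins plus a distinct one must
  # take the distinct one second
  h2 <- manual_hist(rbind(c(50, 0, 0), c(50, 0, 0), c(70, 30, 30)),
                    c(100, 90, 1))
  pal2 <- select_theme_palette(h2, 2)
  expect_equal(colorweave:::palette_lab(pal2)[2, ], c(70, 30, 30),
               ignore_attr = TRUE)

  # decay is selective: a near-duplicate bin is annihilated while a distant
  # bin keeps a substantial share of its frequency
  e_near <- ciede2000(c(50, 0, 0), c(50, 2, 0))
  e_far <- ciede2000(c(50, 0, 0), c(55, 95, -90))
  expect_lt(1 - exp(-(e_near / 80)^2), 0.01)
  expect_gt(1 - exp(-(e_far / 80)^2), 0.10)
  expect_error(select_theme_palette(manual_hist(lab, c(1, 1, 1)), 5),
               class = "colorweave_insufficient_colors")
})

test_that("theme selection never reuses a histogram bin", {
  img <- withr::with_seed(2, array(runif(40 * 40 * 3), c(40, 40, 3)))
  h <- image_histogram(img)
  pal <- select_theme_palette(h, 8)
  expect_equal(length(unique(attr(pal, "bins"))), 8)
})

test_that("FPS refinement never reduces the minimum pairwise separation", {
  img <- withr::with_seed(14, array(runif(60 * 60 * 3), c(60, 60, 3)))
  h <- image_histogram(img)
  pal <- select_theme_palette(h, 6)
  before <- colorweave:::min_pairwise_de(colorweave:::palette_lab(pal))
  ref <- refine_palette(pal, h)
  after <- colorweave:::min_pairwise_de(colorweave:::palette_lab(ref))
  expect_gte(after, before)

  # two-bin histogram: the 2-color palette is already every available color
  h2 <- image_histogram(block_image(c("#C03020", "#2060C0"), block_px = 6))
  p2 <- select_theme_palette(h2, 2)
  r2 <- refine_palette(p2, h2)
  expect_equal(r2$hex, p2$hex)
})

test_that("CI-graph CV stopping rule caps refinement early", {
  # near-uniform CI edge weights have tiny CV, so refinement on a palette
  # whose distances vary at all must stop on the CV rule immediately
  A <- matrix(1, 5, 5) + withr::with_seed(3, matrix(runif(25, 0, 1e-4), 5))
  A <- (A + t(A)) / 2; diag(A) <- 0
  dimnames(A) <- list(paste0("c", 1:5), paste0("c", 1:5))
  ci <- structure(list(clusters = paste0("c", 1:5), adjacency = A),
                  class = "ci_graph")
  img <- withr::with_seed(15, array(runif(60 * 60 * 3), c(60, 60, 3)))
  h <- image_histogram(img)
  pal <- select_theme_palette(h, 6)
  ref <- refine_palette(pal, h, ci = ci)
  expect_equal(ref$hex, pal$hex)
})
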