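# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own code paths (plain loops, no k-d tree, no vectorized
# shortcuts) so that agreement is evidence, not tautology.

# all permutations of 1..n, lexicographic-ish order
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(all_perms(n - 1), function(p) {
    lapply(seq_len(n), function(k) append(p, n, after = k - 1))
  }))
}

# brute-force interlacement score: plain double loop over cells and neighbors
brute_doi <- function(df, x, y, k = 30, r = 50, nmin = 1) {
  n <- nrow(df)
  xy <- as.matrix(df[, c("x", "y")])
  D <- as.matrix(stats::dist(xy))
  nb_idx <- vector("list", n)
  nb_d <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    d <- D[i, idx]
    o <- order(d, idx)
    idx <- idx[o]; d <- d[o]
    kk <- min(k, n - 1)
    idx <- idx[seq_len(kk)]; d <- d[seq_len(kk)]
    if (sum(D[i, -i] <= r) < k) {
      keep <- d <= r
      idx <- idx[keep]; d <- d[keep]
    }
    nb_idx[[i]] <- idx
    nb_d[[i]] <- d
  }
  lab <- as.character(df$cluster)
  orphan <- vapply(seq_len(n), function(i) {
    sum(lab[nb_idx[[i]]] == lab[i]) < nmin
  }, logical(1))
  total <- 0
  for (i in seq_len(n)) {
    if (orphan[i] || lab[i] != x) next
    ni <- length(nb_idx[[i]])
    if (ni == 0) next
    for (t in seq_len(ni)) {
      j <- nb_idx[[i]][t]
      if (!orphan[j] && lab[j] == y) {
        total <- total + (1 / max(nb_d[[i]][t], 1e-6)) / ni
      }
    }
  }
  total
}

# brute-force minimum graph-matching loss over all n! permutations
brute_best_loss <- function(a_ci, a_cd) {
  min(vapply(all_perms(nrow(a_ci)), function(p) {
    sqrt(sum((a_ci - a_cd[p, p])^2))
  }, numeric(1)))
}

# independent redmean arithmetic, scalar, written from the formula directly
redmean_scalar <- function(rgb1, rgb2) {
  rbar <- (rgb1[1] + rgb2[1]) / 2
  dr <- rgb1[1] - rgb2[1]; dg <- rgb1[2] - rgb2[2]; db <- rgb1[3] - rgb2[3]
  sqrt((2 + rbar / 256) * dr^2 + 4 * dg^2 + (2 + (255 - rbar) / 256) * db^2)
}

# image of horizontal solid blocks, one per hex color, block_px^2 pixels each
block_image <- function(hexes, block_px = 16) {
  n <- length(hexes)
  rgb <- t(vapply(hexes, function(h) {
    as.numeric(grDevices::col2rgb(h)) / 255
  }, numeric(3)))
  img <- array(0, c(block_px, block_px * n, 3))
  for (i in seq_len(n)) {
    cols <- ((i - 1) * block_px + 1):(i * block_px)
    for (ch in 1:3) img[, cols, ch] <- rgb[i, ch]
  }
  img
}

# greedy maximin selection of n mutually distant sRGB colors (CIEDE2000),
# constrained to centroid lightness safely inside [20, 85]
maximin_hexes <- function(n) {
  g <- seq(0, 255, length.out = 7)
  rgb <- as.matrix(expand.grid(r = g, g = g, b = g))
  lab <- farver::convert_colour(rgb, from = "rgb", to = "lab")
  keep <- lab[, 1] >= 25 & lab[, 1] <= 80
  rgb <- rgb[keep, , drop = FALSE]
  lab <- lab[keep, , drop = FALSE]
  sel <- which.max(lab[, 1])
  while (length(sel) < n) {
    dmin <- apply(farver::compare_colour(lab, lab[sel, , drop = FALSE],
                                         from_space = "lab",
                                         method = "cie2000"), 1, min)
    sel <- c(sel, which.max(dmin))
  }
  list(
    hex = as.character(farver::encode_colour(rgb[sel, , drop = FALSE])),
    min_pairwise = {
      d <- farver::compare_colour(lab[sel, , drop = FALSE],
                                  lab[sel, , drop = FALSE],
                                  from_space = "lab", method = "cie2000")
      min(d[upper.tri(d)])
    }
  )
}

# hand-built image histogram for unit tests of the selection/refinement rules
manual_hist <- function(lab, frequency, n_pixels = sum(frequency)) {
  lab <- rbind(lab)
  out <- tibble::tibble(
    L = lab[, 1], a = lab[, 2], b = lab[, 3],
    hex = farver::encode_colour(
      pmin(pmax(round(farver::convert_colour(lab, "lab", "rgb")), 0), 255)),
    frequency = frequency,
    bin = seq_len(nrow(lab))
  )
  class(out) <- c("image_histogram", class(out))
  attr(out, "n_pixels") <- n_pixels
  attr(out, "bins_per_channel") <- 20
  attr(out, "L_range") <- c(20, 85)
  out
}

# 4-cell unit square: left column cluster L, right column cluster R
square_cells <- function() {
  spatial_cells(data.frame(
    x = c(0, 0, 1, 1), y = c(0, 1, 0, 1),
    cluster = c("L", "L", "R", "R")
  ))
}

random_two_cluster_cells <- function(n, seed, spread = 60) {
  withr::with_seed(seed, {
    data.frame(
      x = runif(n, 0, spread), y = runif(n, 0, spread),
      cluster = sample(c("A", "B"), n, replace = TRUE)
    )
  })
}

# published CIEDE2000 worked-example pairs shipped with the package
ciede2000_reference <- function() {
  read.csv(system.file("extdata", "ciede2000-reference-pairs.csv",
                       package = "colorweave"))
}
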