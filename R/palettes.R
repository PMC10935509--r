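# Adaptive palette generation: CI-graph embedding into CIELab, and image-guided
# theme extraction (Lab histogram -> frequency-decay selection -> FPS
# refinement).

LAB_A_RANGE <- c(-128, 127)
LAB_B_RANGE <- c(-128, 127)

rescale_to <- function(v, lo, hi, tol = 0) {
  r <- range(v)
  # a numerically degenerate axis (eigen-noise) must not be amplified to the
  # full target range; treat it as constant and map to the midpoint
  if (diff(r) <= tol) return(rep((lo + hi) / 2, length(v)))
  (v - r[1]) / diff(r) * (hi - lo) + lo
}

#' Generate a palette by embedding the CI-graph into CIELab
#'
#' Vertices of the cluster interlacement graph are embedded in 3D by the
#' distances between their DOI profiles (each vertex's adjacency row read as a
#' feature vector). Clusters that interlace nobody have near-zero profiles and
#' aggregate into a hub of mutually similar colors, while a strongly
#' interlaced pair — each carrying a large DOI entry at the other's position —
#' is pushed far apart, so pairs with low DOI end up at small color distances
#' and pairs with high DOI at large ones. The three embedding axes are min-max
#' rescaled onto `[L_range]` x `[-128, 127]` x `[-128, 127]` and read as
#' CIELab colors.
#'
#' With `method = "umap"` the embedding is uwot's UMAP (seeded, single-thread,
#' classical-MDS initialization, hence reproducible per seed); graphs with
#' three or fewer vertices fall back to classical MDS, which is also available
#' directly via `method = "mds"`.
#'
#' @param ci A [ci_graph()].
#' @param n_colors Number of colors; must equal the number of clusters
#'   (default).
#' @param L_range Lightness range of the generated colors (default `c(20, 85)`
#'   to avoid too-dark and too-bright extremes).
#' @param method `"umap"` or `"mds"`.
#' @param seed Integer seed for the stochastic embedding (default 42).
#' @return A `cw_palette` with `source = "embedded"`; stored Lab values are
#'   the canonical coordinates (RGB is the clipped in-gamut rendering).
#' @export
embed_palette <- function(ci, n_colors = NULL, L_range = c(20, 85),
                          method = c("umap", "mds"), seed = 42) {
  method <- arg_match(method)
  n <- length(ci$clusters)
  if (is.null(n_colors)) n_colors <- n
  if (n_colors != n) {
    cw_abort("n_colors must equal the number of CI-graph vertices",
             "parameter_error")
  }
  if (any(L_range < 0) || any(L_range > 100) || L_range[1] >= L_range[2]) {
    cw_abort("L_range must be an increasing pair within [0, 100]",
             "parameter_error")
  }
  dis <- as.matrix(stats::dist(ci$adjacency)) # distance between DOI profiles
  emb <- embed_points(dis, method, seed)
  tol <- 1e-6 * max(apply(emb, 2, function(v) diff(range(v))))
  lab <- cbind(
    rescale_to(emb[, 1], L_range[1], L_range[2], tol),
    rescale_to(emb[, 2], LAB_A_RANGE[1], LAB_A_RANGE[2], tol),
    rescale_to(emb[, 3], LAB_B_RANGE[1], LAB_B_RANGE[2], tol)
  )
  pal <- as_palette(lab, source = "embedded", seed = seed)
  attr(pal, "clusters") <- ci$clusters
  pal
}

embed_points <- function(dis, method, seed) {
  n <- nrow(dis)
  d <- stats::as.dist(dis)
  mds3 <- function() {
    e <- cmdscale(d, k = min(3, n - 1))
    if (ncol(e) < 3) e <- cbind(e, matrix(0, n, 3 - ncol(e)))
    e
  }
  if (method == "mds" || n <= 3) return(mds3())
  init <- mds3()
  withr::with_seed(seed, {
    uwot::umap(d, n_components = 3, n_neighbors = min(15, n - 1),
               init = init, n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  })
}

# ---- image-guided theme extraction ----------------------------------------

read_image_array <- function(image) {
  if (is.character(image)) {
    if (!file.exists(image)) {
      cw_abort(paste0("no such file: ", image), "input_error")
    }
    if (grepl("\\.png$", image, ignore.case = TRUE)) {
      image <- png::readPNG(image)
    } else if (grepl("\\.jpe?g$", image, ignore.case = TRUE)) {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        cw_abort("package jpeg is required to read JPEG images", "input_error")
      }
      image <- jpeg::readJPEG(image)
    } else {
      cw_abort("unsupported image format (use PNG or JPEG)", "input_error")
    }
  }
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] < 3) {
    cw_abort("image must be an HxWx3 array or a PNG/JPEG path", "input_error")
  }
  if (prod(dim(image)[1:2]) == 0) cw_abort("empty image", "empty_input")
  image[, , 1:3, drop = FALSE]
}

#' Bin an image's pixels into a CIELab color histogram
#'
#' Every pixel is converted to CIELab and assigned to a cell of a
#' `bins_per_channel`^3 grid over the Lab ranges (L in \[0, 100\], a and b in
#' \[-128, 127\]) — at the default of 20 bins per channel, at most 8,000
#' distinct binned colors. Each occupied bin is represented by the centroid
#' (mean Lab) of its member pixels. Bins whose centroid lightness falls
#' outside `L_range` (too dark / too bright) and bins whose frequency is below
#' the `percentile_cut`-th percentile (non-theme colors) are removed.
#'
#' @param image A PNG/JPEG file path or an HxWx3 numeric array in \[0, 1\].
#' @param bins_per_channel Bins per Lab channel (default 20).
#' @param L_range Retained centroid lightness range (default `c(20, 85)`).
#' @param percentile_cut Frequency percentile below which bins are dropped
#'   (default 3).
#' @return An `image_histogram` tibble (`L`, `a`, `b`, `hex`, `frequency`)
#'   with attributes `n_pixels` and `bins_per_channel`.
#' @export
image_histogram <- function(image, bins_per_channel = 20, L_range = c(20, 85),
                            percentile_cut = 3) {
  img <- read_image_array(image)
  npx <- prod(dim(img)[1:2])
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3])) * 255
  lab <- rgb_to_lab(rgb)
  b <- bins_per_channel
  cut_idx <- function(v, lo, hi) {
    pmin(pmax(floor((v - lo) / (hi - lo) * b), 0), b - 1)
  }
  bin <- cut_idx(lab[, 1], 0, 100) * b * b +
    cut_idx(lab[, 2], LAB_A_RANGE[1], LAB_A_RANGE[2] + 1) * b +
    cut_idx(lab[, 3], LAB_B_RANGE[1], LAB_B_RANGE[2] + 1)
  agg <- rowsum(cbind(lab, 1), group = bin)
  freq <- agg[, 4]
  cent <- agg[, 1:3, drop = FALSE] / freq
  keep <- cent[, 1] >= L_range[1] & cent[, 1] <= L_range[2]
  cent <- cent[keep, , drop = FALSE]
  freq <- freq[keep]
  bin_id <- as.integer(rownames(agg))[keep]
  if (length(freq) > 0) {
    # strict "below the percentile" rule: drop only frequencies < threshold
    thr <- quantile(freq, percentile_cut / 100)
    keep2 <- freq >= thr
    cent <- cent[keep2, , drop = FALSE]
    freq <- freq[keep2]
    bin_id <- bin_id[keep2]
  }
  out <- tibble(
    L = cent[, 1], a = cent[, 2], b = cent[, 3],
    hex = rgb_to_hex(lab_to_rgb(cent)),
    frequency = as.numeric(freq),
    bin = bin_id
  )
  class(out) <- c("image_histogram", class(out))
  attr(out, "n_pixels") <- npx
  attr(out, "bins_per_channel") <- bins_per_channel
  attr(out, "L_range") <- L_range
  out
}

#' Select an initial theme palette by frequency decay
#'
#' Colors are pulled from the histogram in descending order of frequency; after
#' each pull of color `b_t`, every remaining frequency is damped by
#' \deqn{f_a \leftarrow f_a \, (1 - e^{-(E(a, b_t)/\sigma)^2})}
#' with `E` the CIEDE2000 difference and decay scale `sigma` (default 80), so
#' that colors similar to an already-pulled one are strongly suppressed. The
#' pulled bin's own frequency is driven to zero (E = 0), so no bin can be
#' selected twice.
#'
#' @param hist An [image_histogram()].
#' @param n_colors Number of colors to extract.
#' @param sigma Decay scale of the frequency update (CIEDE2000 units,
#'   default 80).
#' @return A `cw_palette` with `source = "image"` and an attribute
#'   `frequencies` (the original frequency of each selected bin).
#' @export
select_theme_palette <- function(hist, n_colors, sigma = 80) {
  if (n_colors < 1) cw_abort("n_colors must be >= 1", "parameter_error")
  if (nrow(hist) < n_colors) {
    cw_abort("histogram has fewer occupied bins than requested colors",
             "insufficient_colors")
  }
  lab <- as.matrix(hist[, c("L", "a", "b")])
  f <- hist$frequency
  picked <- integer(0)
  for (t in seq_len(n_colors)) {
    best <- which.max(f) # ties: first (lowest bin index) wins
    picked <- c(picked, best)
    e <- as.numeric(ciede2000_cross(lab, lab[best, , drop = FALSE]))
    f <- f * (1 - exp(-(e / sigma)^2))
    f[picked] <- -Inf
  }
  pal <- as_palette(lab[picked, , drop = FALSE], source = "image")
  attr(pal, "frequencies") <- hist$frequency[picked]
  attr(pal, "bins") <- hist$bin[picked]
  pal
}

min_pairwise_de <- function(lab) {
  if (nrow(lab) < 2) return(Inf)
  d <- ciede2000_cross(lab, lab)
  min(d[upper.tri(d)])
}

pairwise_de <- function(lab) {
  d <- ciede2000_cross(lab, lab)
  d[upper.tri(d)]
}

#' Refine a theme palette by farthest point sampling
#'
#' Iteratively improves the minimum pairwise separation of an image-derived
#' palette. Each iteration: (1) the `k_candidates` unselected histogram colors
#' farthest from the current palette (by minimum CIEDE2000 distance, the FPS
#' distance `d_a`) are shortlisted; (2) each candidate is scored
#' `S_a = w_s * s_a + w_f * f_a + d_a`, where `f_a` is its histogram frequency
#' and `s_a` its linear-separation score (minimum redmean distance to the
#' palette; `s_a` and `d_a` are min-max normalized over the shortlist);
#' (3) in the palette's closest pair, the member whose removal most increases
#' the minimum pairwise distance is replaced by the top-scoring candidate, and
#' the replacement is kept only if it strictly improves the minimum pairwise
#' separation. Iteration stops when the coefficient of variation of the
#' pairwise palette distances exceeds the CV of the CI-graph edge weights
#' (when a CI-graph is supplied), when a replacement is rejected (the state is
#' then a fixed point), or at `max_iter` (default 20 x palette size).
#'
#' @param palette A `cw_palette` from [select_theme_palette()].
#' @param hist The [image_histogram()] the palette was drawn from.
#' @param ci Optional [ci_graph()] supplying the CV stopping rule.
#' @param w_s Weight of the linear-separation score (default 0.15).
#' @param w_f Weight of the frequency score; default `1 / (0.0003 * n_pixels)`
#'   (the inverse of 0.03 percent of the image's pixel count).
#' @param k_candidates Shortlist size (default 3).
#' @param max_iter Iteration cap (default `20 * nrow(palette)`).
#' @return A refined `cw_palette`; its minimum pairwise CIEDE2000 distance is
#'   never below the input palette's.
#' @export
refine_palette <- function(palette, hist, ci = NULL, w_s = 0.15, w_f = NULL,
                           k_candidates = 3, max_iter = NULL) {
  palette <- as_palette(palette)
  if (is.null(w_f)) {
    npx <- attr(hist, "n_pixels") %||% sum(hist$frequency)
    w_f <- 1 / (0.0003 * npx)
  }
  if (is.null(max_iter)) max_iter <- 20L * nrow(palette)
  cv_limit <- if (!is.null(ci)) ci_edge_cv(ci) else Inf
  lab_pal <- palette_lab(palette)
  rgb_pal <- palette_rgb(palette)
  lab_all <- as.matrix(hist[, c("L", "a", "b")])
  freq_all <- hist$frequency
  in_pal <- hist$bin %in% (attr(palette, "bins") %||% integer(0))

  for (it in seq_len(max_iter)) {
    cur_d <- ciede2000_cross(lab_pal, lab_pal)
    cur_pd <- cur_d[upper.tri(cur_d)]
    if (length(cur_pd) >= 2) {
      cv <- sd(cur_pd) / mean(cur_pd)
      if (is.finite(cv) && cv > cv_limit) break
    }
    pool <- which(!in_pal)
    if (length(pool) == 0) break
    d_a <- apply(ciede2000_cross(lab_all[pool, , drop = FALSE], lab_pal), 1, min)
    k <- min(k_candidates, length(pool))
    short <- pool[order(-d_a, pool)[seq_len(k)]]
    d_short <- d_a[match(short, pool)]
    s_a <- apply(redmean_cross(lab_to_rgb(lab_all[short, , drop = FALSE]),
                               rgb_pal), 1, min)
    norm01 <- function(v) {
      if (diff(range(v)) == 0) rep(0, length(v)) else
        (v - min(v)) / diff(range(v))
    }
    score <- w_s * norm01(s_a) + w_f * freq_all[short] + norm01(d_short)
    cand <- short[which.max(score)]

    # member of the closest pair whose removal most increases min separation
    old_min <- min(cur_pd)
    pair <- which(cur_d == old_min & upper.tri(cur_d), arr.ind = TRUE)[1, ]
    gain <- vapply(pair, function(m) {
      min_pairwise_de(lab_pal[-m, , drop = FALSE])
    }, numeric(1))
    victim <- pair[which.max(gain)] # ties: first index (row of the pair)

    new_lab <- lab_pal
    new_lab[victim, ] <- lab_all[cand, ]
    if (min_pairwise_de(new_lab) > old_min) {
      lab_pal <- new_lab
      rgb_pal[victim, ] <- lab_to_rgb(lab_all[cand, , drop = FALSE])
      swap_bin <- hist$bin[cand]
      old_bins <- attr(palette, "bins")
      if (!is.null(old_bins)) {
        old_bins[victim] <- swap_bin
        attr(palette, "bins") <- old_bins
      }
      in_pal <- hist$bin %in% (old_bins %||% integer(0))
    } else {
      break # deterministic state: nothing will change next iteration
    }
  }
  out <- as_palette(lab_pal, source = "image")
  attr(out, "bins") <- attr(palette, "bins")
  out
}
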