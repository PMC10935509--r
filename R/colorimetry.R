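# Perceptual color differences, CVD simulation and the color-difference graph.

#' Redmean color difference
#'
#' Weighted Euclidean distance in 8-bit sRGB whose channel weights depend on
#' the mean red value of the two colors:
#' \deqn{\bar r = (R_1 + R_2)/2,\quad
#'  \Delta C = \sqrt{(2 + \bar r/256)\Delta R^2 + 4\Delta G^2 +
#'  (2 + (255-\bar r)/256)\Delta B^2}.}
#' This is the edge-weight metric of the color-difference graph; it operates on
#' the non-linear 8-bit sRGB channels directly.
#'
#' @param c1,c2 Hex strings (vectorized, recycled to a common length).
#' @return Nonnegative numeric vector of differences.
#' @examples
#' redmean_difference("#000000", "#FFFFFF") # ~ 764.83
#' @export
redmean_difference <- function(c1, c2) {
  r1 <- hex_to_rgb(c1)
  r2 <- hex_to_rgb(c2)
  if (nrow(r1) != nrow(r2)) {
    n <- max(nrow(r1), nrow(r2))
    r1 <- r1[rep_len(seq_len(nrow(r1)), n), , drop = FALSE]
    r2 <- r2[rep_len(seq_len(nrow(r2)), n), , drop = FALSE]
  }
  redmean_rgb(r1, r2)
}

redmean_rgb <- function(r1, r2) {
  rbar <- (r1[, 1] + r2[, 1]) / 2
  d <- r1 - r2
  sqrt((2 + rbar / 256) * d[, 1]^2 + 4 * d[, 2]^2 +
         (2 + (255 - rbar) / 256) * d[, 3]^2)
}

# full cross matrix of redmean differences between two RGB matrices
redmean_cross <- function(r1, r2) {
  n1 <- nrow(r1); n2 <- nrow(r2)
  rbar <- outer(r1[, 1], r2[, 1], function(a, b) (a + b) / 2)
  dr <- outer(r1[, 1], r2[, 1], `-`)
  dg <- outer(r1[, 2], r2[, 2], `-`)
  db <- outer(r1[, 3], r2[, 3], `-`)
  sqrt((2 + rbar / 256) * dr^2 + 4 * dg^2 + (2 + (255 - rbar) / 256) * db^2)
}

#' CIEDE2000 color difference
#'
#' The CIE's refined perceptual difference \eqn{\Delta E_{00}} with
#' \eqn{k_L = k_C = k_H = 1}, used for image-palette frequency decay and
#' farthest-point-sampling refinement.
#'
#' @param lab1,lab2 Lab triples: length-3 vectors or n-by-3 matrices. If one
#'   argument has a single row it is broadcast against the other.
#' @return Nonnegative numeric vector of pairwise differences.
#' @export
ciede2000 <- function(lab1, lab2) {
  lab1 <- rbind(lab1); lab2 <- rbind(lab2)
  if (nrow(lab1) == 1 && nrow(lab2) > 1) {
    return(as.numeric(ciede2000_cross(lab2, lab1)))
  }
  if (nrow(lab2) == 1 && nrow(lab1) > 1) {
    return(as.numeric(ciede2000_cross(lab1, lab2)))
  }
  if (nrow(lab1) != nrow(lab2)) cw_abort("Lab inputs differ in length", "parameter_error")
  vapply(seq_len(nrow(lab1)), function(i) {
    as.numeric(ciede2000_cross(lab1[i, , drop = FALSE], lab2[i, , drop = FALSE]))
  }, numeric(1))
}

ciede2000_cross <- function(lab1, lab2) {
  unname(farver::compare_colour(rbind(lab1), rbind(lab2),
                                from_space = "lab", method = "cie2000"))
}

# ---- dichromat simulation -------------------------------------------------

# sRGB (linear) -> XYZ (D65) -> Hunt-Pointer-Estevez LMS. The per-type
# deficiency is a single-plane projection in LMS: the missing cone response is
# replaced by a linear combination of the other two, with coefficients solved
# so that the white point and one anchor primary map to themselves. Grays lie
# on the white axis, so they are preserved exactly; the map is a projection,
# hence idempotent (up to 8-bit quantization and gamut clipping).
cvd_projections <- function() {
  m_rgb2xyz <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), 3, 3, byrow = TRUE)
  m_hpe <- matrix(c(
    0.4002, 0.7076, -0.0808,
    -0.2263, 1.1653, 0.0457,
    0.0000, 0.0000, 0.9182
  ), 3, 3, byrow = TRUE)
  t_lms <- m_hpe %*% m_rgb2xyz
  white <- as.numeric(t_lms %*% c(1, 1, 1))
  blue <- as.numeric(t_lms %*% c(0, 0, 1))
  red <- as.numeric(t_lms %*% c(1, 0, 0))
  plane <- function(missing, keep, anchor) {
    ab <- solve(rbind(white[keep], anchor[keep]), c(white[missing], anchor[missing]))
    p <- diag(3)
    p[missing, ] <- 0
    p[missing, keep] <- ab
    p
  }
  list(
    t_lms = t_lms,
    t_inv = solve(t_lms),
    protanopia = plane(1L, c(2L, 3L), blue),
    deuteranopia = plane(2L, c(1L, 3L), blue),
    tritanopia = plane(3L, c(1L, 2L), red)
  )
}

the_cvd <- new.env(parent = emptyenv())

get_cvd_projection <- function(type) {
  if (is.null(the_cvd$mats)) the_cvd$mats <- cvd_projections()
  if (!type %in% c("protanopia", "deuteranopia", "tritanopia")) {
    cw_abort(paste0("unknown CVD type: ", type), "parameter_error")
  }
  the_cvd$mats[[type]]
}

srgb_to_linear <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

linear_to_srgb <- function(v) {
  ifelse(v <= 0.0031308, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Simulate dichromatic color vision deficiency
#'
#' Projects a color onto the surface seen by a dichromat: sRGB is linearized,
#' mapped to Hunt-Pointer-Estevez LMS cone space, the missing cone response is
#' reconstructed from the remaining two by a fixed single-plane projection
#' (anchored at the white point and one spectral primary), and the result is
#' mapped back and clipped to the 8-bit gamut. Neutral grays are preserved and
#' the simulation is idempotent up to quantization.
#'
#' @param color Hex string(s).
#' @param cvd_type One of `"protanopia"`, `"deuteranopia"`, `"tritanopia"`.
#' @return Hex string(s) of the simulated color(s).
#' @examples
#' simulate_cvd("#808080", "protanopia") # grays are unchanged
#' @export
simulate_cvd <- function(color, cvd_type) {
  rgb <- hex_to_rgb(color)
  rgb_to_hex(simulate_cvd_rgb(rgb, cvd_type))
}

simulate_cvd_rgb <- function(rgb, cvd_type) {
  p <- get_cvd_projection(cvd_type)
  t_lms <- the_cvd$mats$t_lms
  t_inv <- the_cvd$mats$t_inv
  lin <- srgb_to_linear(rgb / 255)
  lms <- lin %*% t(t_lms)
  sim <- lms %*% t(p)
  out <- linear_to_srgb(pmin(pmax(sim %*% t(t_inv), 0), 1))
  pmin(pmax(round(out * 255), 0), 255)
}

cvd_modes <- c("none", "protanopia", "deuteranopia", "tritanopia", "general")

check_cvd_mode <- function(cvd_mode) {
  if (length(cvd_mode) != 1 || !cvd_mode %in% cvd_modes) {
    cw_abort(paste0("cvd_mode must be one of: ", paste(cvd_modes, collapse = ", ")),
             "parameter_error")
  }
  cvd_mode
}

#' Perceptual color difference with optional CVD support
#'
#' Under `cvd_mode = "none"` this is the redmean difference of the colors as
#' given. Under a single deficiency type, the redmean difference of the two
#' CVD-simulated colors. Under `"general"`, the mean of four redmean values:
#' the full-color-vision difference plus the difference under each of the
#' three simulated deficiencies.
#'
#' @param c1,c2 Hex strings (vectorized).
#' @param cvd_mode One of `"none"`, `"protanopia"`, `"deuteranopia"`,
#'   `"tritanopia"`, `"general"`.
#' @return Nonnegative numeric vector.
#' @export
color_difference <- function(c1, c2, cvd_mode = "none") {
  check_cvd_mode(cvd_mode)
  if (cvd_mode == "none") return(redmean_difference(c1, c2))
  if (cvd_mode == "general") {
    types <- c("protanopia", "deuteranopia", "tritanopia")
    parts <- c(
      list(redmean_difference(c1, c2)),
      lapply(types, function(tp) {
        redmean_difference(simulate_cvd(c1, tp), simulate_cvd(c2, tp))
      })
    )
    return(Reduce(`+`, parts) / 4)
  }
  redmean_difference(simulate_cvd(c1, cvd_mode), simulate_cvd(c2, cvd_mode))
}

#' Build a color-difference graph (CD-graph)
#'
#' Palette colors become vertices; every pair is connected by an edge weighted
#' with its perceptual difference under the requested CVD mode. The adjacency
#' matrix is symmetric with a zero diagonal and is the second operand of the
#' graph-matching color assignment.
#'
#' @param palette A `cw_palette` or character vector of hex strings (>= 2).
#' @param cvd_mode See [color_difference()].
#' @return A `cd_graph`: list with `colors` (the palette) and `adjacency`.
#' @export
cd_graph <- function(palette, cvd_mode = "none") {
  palette <- as_palette(palette)
  check_cvd_mode(cvd_mode)
  if (nrow(palette) < 2) {
    cw_abort("a CD-graph needs at least 2 colors", "insufficient_palette")
  }
  rgb <- palette_rgb(palette)
  if (cvd_mode == "none") {
    adj <- redmean_cross(rgb, rgb)
  } else if (cvd_mode == "general") {
    types <- c("protanopia", "deuteranopia", "tritanopia")
    mats <- c(
      list(redmean_cross(rgb, rgb)),
      lapply(types, function(tp) {
        s <- simulate_cvd_rgb(rgb, tp)
        redmean_cross(s, s)
      })
    )
    adj <- Reduce(`+`, mats) / 4
  } else {
    s <- simulate_cvd_rgb(rgb, cvd_mode)
    adj <- redmean_cross(s, s)
  }
  diag(adj) <- 0
  adj <- (adj + t(adj)) / 2 # exact symmetry against fp noise
  dimnames(adj) <- list(palette$hex, palette$hex)
  structure(
    list(colors = palette, adjacency = adj, cvd_mode = cvd_mode),
    class = "cd_graph"
  )
}

#' @export
print.cd_graph <- function(x, ...) {
  cat("<cd_graph: ", nrow(x$adjacency), " colors, cvd_mode = ", x$cvd_mode,
      ">\n", sep = "")
  invisible(x)
}

#' @export
tidy.cd_graph <- function(x, ...) {
  graph_edges(x$adjacency, c("color1", "color2"), "difference")
}

graph_edges <- function(adj, names2, value) {
  labs <- rownames(adj)
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  out <- tibble(
    a = labs[idx[, 1]],
    b = labs[idx[, 2]],
    v = adj[idx]
  )
  names(out) <- c(names2, value)
  out
}
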