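# Color representation. All user-facing color values are "#RRGGBB" hex strings;
# internally colors move between 8-bit sRGB and CIELab (D65) via farver.

hex_to_rgb <- function(hex) {
  if (!is.character(hex) || anyNA(hex) ||
      !all(grepl("^#[0-9A-Fa-f]{6}$", hex))) {
    cw_abort("colors must be '#RRGGBB' hex strings", "parse_error")
  }
  m <- farver::decode_colour(hex)
  storage.mode(m) <- "double"
  unname(m)
}

rgb_to_hex <- function(rgb) {
  rgb <- rbind(rgb)
  rgb <- pmin(pmax(round(rgb), 0), 255)
  farver::encode_colour(rgb)
}

rgb_to_lab <- function(rgb) {
  unname(farver::convert_colour(rbind(rgb), from = "rgb", to = "lab"))
}

lab_to_rgb <- function(lab) {
  rgb <- farver::convert_colour(rbind(lab), from = "lab", to = "rgb")
  pmin(pmax(round(rgb), 0), 255)
}

#' Construct a palette
#'
#' A palette is an ordered tibble of colors with 8-bit sRGB and CIELab (D65)
#' representations side by side. Palettes come from three places: generated by
#' embedding a cluster interlacement graph ([embed_palette()]), extracted from a
#' theme image ([select_theme_palette()]), or supplied by the user as hex
#' strings.
#'
#' When constructed from hex strings, CIELab values are derived from the sRGB
#' coordinates. When constructed from Lab triples (the generative path), the Lab
#' values are canonical and the sRGB representation is the in-gamut projection
#' (channel-wise clip after conversion), so stored `L` is exact even for colors
#' near the gamut boundary.
#'
#' @param x Character vector of `"#RRGGBB"` strings, or a numeric matrix with 3
#'   columns of Lab triples.
#' @param source Provenance tag: `"user"`, `"embedded"`, or `"image"`.
#' @param seed Integer seed recorded for generated palettes, or `NULL`.
#' @return A `cw_palette` tibble with columns `hex`, `R`, `G`, `B`, `L`, `a`, `b`.
#' @examples
#' as_palette(c("#1F77B4", "#FF7F0E", "#2CA02C"))
#' @export
as_palette <- function(x, source = "user", seed = NULL) {
  if (inherits(x, "cw_palette")) return(x)
  if (is.character(x)) {
    rgb <- hex_to_rgb(x)
    lab <- rgb_to_lab(rgb)
    hex <- toupper(x)
  } else if (is.numeric(x)) {
    lab <- rbind(x)
    if (ncol(lab) != 3) cw_abort("Lab input must have 3 columns", "parse_error")
    rgb <- lab_to_rgb(lab)
    hex <- rgb_to_hex(rgb)
  } else {
    cw_abort("cannot interpret `x` as colors", "parse_error")
  }
  out <- tibble(
    hex = unname(hex),
    R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
    L = lab[, 1], a = lab[, 2], b = lab[, 3]
  )
  class(out) <- c("cw_palette", class(out))
  attr(out, "source") <- source
  attr(out, "seed") <- seed
  out
}

#' @export
print.cw_palette <- function(x, ...) {
  cat("<palette: ", nrow(x), " colors, source = ", attr(x, "source") %||% "user",
      ">\n", sep = "")
  NextMethod()
}

palette_rgb <- function(palette) as.matrix(palette[, c("R", "G", "B")])
palette_lab <- function(palette) as.matrix(palette[, c("L", "a", "b")])

#' Read or write a palette as a JSON list of hex strings
#'
#' @param path File path.
#' @param palette A `cw_palette` or character vector of hex strings.
#' @return `read_palette()` returns a `cw_palette`; `write_palette()` returns
#'   `path` invisibly.
#' @export
read_palette <- function(path) {
  if (!file.exists(path)) cw_abort(paste0("no such file: ", path), "input_error")
  as_palette(as.character(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' @rdname read_palette
#' @export
write_palette <- function(palette, path) {
  palette <- as_palette(palette)
  jsonlite::write_json(palette$hex, path)
  invisible(path)
}

#' A fixed 20-color categorical default palette
#'
#' The widely used "category 20" hue cycle found in mainstream plotting
#' libraries, bundled as the spatially unaware baseline against which generated
#' palettes are compared.
#'
#' @return A `cw_palette` of 20 colors.
#' @export
default_palette_20 <- function() {
  as_palette(c(
    "#1F77B4", "#AEC7E8", "#FF7F0E", "#FFBB78", "#2CA02C",
    "#98DF8A", "#D62728", "#FF9896", "#9467BD", "#C5B0D5",
    "#8C564B", "#C49C94", "#E377C2", "#F7B6D2", "#7F7F7F",
    "#C7C7C7", "#BCBD22", "#DBDB8D", "#17BECF", "#9EDAE5"
  ))
}
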