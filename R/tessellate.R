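#' Tessellate an annotated slide into non-overlapping tumor tiles
#'
#' Lays a tile grid of edge \code{tile_edge} anchored at the slide origin
#' (0, 0) over the slide and retains every tile whose overlap with the tumor
#' annotation covers at least \code{min_tumor_fraction} of the tile area
#' (inclusive).  Anchoring at the origin, not at the annotation bounding
#' box, keeps tile identity stable under re-annotation.
#'
#' @param slide Either a numeric \code{c(width, height)} in pixels or a
#'   \code{height x width x 3} image array.
#' @param annotation A \code{"tumor_annotation"} (see
#'   \code{\link{read_qupath_annotation}}).
#' @param tile_edge Tile edge length in pixels (default 512).
#' @param min_tumor_fraction Minimum tumor area fraction for retention
#'   (default 0.5).
#' @return Data frame of tile specs sorted by \code{(grid_row, grid_col)}:
#'   \code{slide_id, grid_row, grid_col, x, y, tile_edge, tumor_fraction}.
#'   \code{(x, y)} is the top-left corner of the half-open tile box.
#' @export
tessellate <- function(slide, annotation, tile_edge = 512,
                       min_tumor_fraction = 0.5) {
  dims <- slide_dims(slide)
  bb <- annotation_bbox(annotation)
  if (bb["xmin"] < 0 || bb["ymin"] < 0 ||
      bb["xmax"] > dims["width"] || bb["ymax"] > dims["height"])
    stop("annotation extends outside slide bounds")
  tile_area <- tile_edge^2
  rows <- seq(floor(bb["ymin"] / tile_edge), ceiling(bb["ymax"] / tile_edge) - 1)
  cols <- seq(floor(bb["xmin"] / tile_edge), ceiling(bb["xmax"] / tile_edge) - 1)
  out <- vector("list", length(rows) * length(cols))
  n <- 0L
  for (r in rows) for (cc in cols) {
    x0 <- cc * tile_edge; y0 <- r * tile_edge
    frac <- annotation_rect_area(annotation, x0, x0 + tile_edge,
                                 y0, y0 + tile_edge) / tile_area
    if (frac >= min_tumor_fraction - 1e-9) {
      n <- n + 1L
      out[[n]] <- data.frame(slide_id = annotation$slide_id,
                             grid_row = as.integer(r), grid_col = as.integer(cc),
                             x = x0, y = y0, tile_edge = tile_edge,
                             tumor_fraction = min(1, frac),
                             stringsAsFactors = FALSE)
    }
  }
  if (n == 0L)
    return(data.frame(slide_id = character(), grid_row = integer(),
                      grid_col = integer(), x = numeric(), y = numeric(),
                      tile_edge = numeric(), tumor_fraction = numeric()))
  res <- do.call(rbind, out[seq_len(n)])
  res[order(res$grid_row, res$grid_col), , drop = FALSE]
}

slide_dims <- function(slide) {
  if (is.numeric(slide) && length(slide) == 2)
    return(c(width = slide[1], height = slide[2]))
  d <- dim(slide)
  if (length(d) == 3) return(c(width = d[2], height = d[1]))
  stop("slide must be c(width, height) or a height x width x 3 array")
}

#' Extract a tile's pixels from a slide image array
#'
#' @param slide \code{height x width x 3} array with values in \[0, 1\] or
#'   \[0, 255\].
#' @param spec One row of a \code{\link{tessellate}} result (or any list with
#'   \code{x}, \code{y}, \code{tile_edge}).
#' @return \code{tile_edge x tile_edge x 3} array (same value scale as input).
#' @export
extract_tile <- function(slide, spec) {
  e <- spec$tile_edge
  rows <- (spec$y + 1):(spec$y + e)
  cols <- (spec$x + 1):(spec$x + e)
  d <- dim(slide)
  if (max(rows) > d[1] || max(cols) > d[2])
    stop("tile box extends outside the slide image")
  slide[rows, cols, , drop = FALSE]
}

#' Read and write tiles as PNG
#'
#' Tiles are stored as 8-bit RGB PNG named \code{{slide}_{row}_{col}.png}.
#' In memory a tile is a \code{T x T x 3} array scaled to \[0, 1\].
#'
#' @param tile \code{T x T x 3} array in \[0, 1\].
#' @param dir Output directory (created if absent).
#' @param slide_id,grid_row,grid_col Tile identity.
#' @return The file path written.
#' @export
write_tile_png <- function(tile, dir, slide_id, grid_row, grid_col) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%d_%d.png", slide_id, grid_row, grid_col))
  png::writePNG(tile, path)
  path
}

#' @rdname write_tile_png
#' @param path PNG path to read.
#' @export
read_tile_png <- function(path) {
  if (!file.exists(path)) stop("cannot read tile: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  px[, , 1:3, drop = FALSE]
}
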