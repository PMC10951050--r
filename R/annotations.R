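#' @section Coordinate conventions:
#' All annotation coordinates are level-0 pixels, 0-based, x growing right
#' and y growing downward.  Tiles are half-open boxes
#' \code{[x, x + edge) x [y, y + edge)} anchored at the slide origin.
#' @name histotype-coordinates
#' @keywords internal
NULL

# Strip a repeated closing vertex; rings are stored open.
as_ring <- function(coords) {
  m <- if (is.matrix(coords)) coords else do.call(rbind, lapply(coords, unlist))
  m <- m[, 1:2, drop = FALSE]
  n <- nrow(m)
  if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3) stop("ring with fewer than 3 distinct vertices")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

new_tumor_annotation <- function(slide_id, polygons) {
  structure(list(slide_id = slide_id, polygons = polygons),
            class = "tumor_annotation")
}

#' Construct a tumor annotation from polygon rings
#'
#' @param slide_id Slide identifier.
#' @param polygons List of polygons; each polygon is a list with an
#'   \code{exterior} ring (n x 2 matrix of x, y pixel coordinates) and an
#'   optional list of \code{holes}.
#' @return A \code{"tumor_annotation"} object.
#' @export
tumor_annotation <- function(slide_id, polygons) {
  polys <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(exterior = p, holes = list())
    list(exterior = as_ring(p$exterior),
         holes = lapply(if (is.null(p$holes)) list() else p$holes, as_ring))
  })
  ann <- new_tumor_annotation(slide_id, polys)
  if (annotation_area(ann) <= 0) stop("annotation has zero total area")
  ann
}

#' Read a QuPath-style GeoJSON tumor annotation
#'
#' Accepts a GeoJSON \code{FeatureCollection} (or bare geometry) of
#' \code{Polygon} / \code{MultiPolygon} features, as exported by QuPath.
#' All features are merged into a single annotation; coordinates are taken
#' verbatim as level-0 pixel coordinates.
#'
#' @param path Path to the GeoJSON file.
#' @param slide_id Slide identifier; defaults to the file name without
#'   extension.
#' @return A \code{"tumor_annotation"} object.
#' @export
read_qupath_annotation <- function(path,
                                   slide_id = sub("\\.[^.]*$", "",
                                                  basename(path))) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(g$type %||% "",
    FeatureCollection = lapply(g$features, function(f) f$geometry),
    Feature = list(g$geometry),
    Polygon = , MultiPolygon = list(g),
    stop("unsupported GeoJSON type: ", g$type %||% "<missing>"))
  if (!length(feats)) stop("empty annotation collection")
  polys <- list()
  for (geom in feats) {
    if (is.null(geom$type) || !geom$type %in% c("Polygon", "MultiPolygon"))
      stop("non-polygon geometry in annotation: ", geom$type %||% "<missing>")
    multis <- if (geom$type == "Polygon") list(geom$coordinates)
              else geom$coordinates
    for (poly in multis) {
      rings <- lapply(poly, as_ring)
      polys[[length(polys) + 1L]] <-
        list(exterior = rings[[1]], holes = rings[-1])
    }
  }
  ann <- new_tumor_annotation(slide_id, polys)
  if (annotation_area(ann) <= 0) stop("annotation has zero total area")
  ann
}

#' Write an annotation as a GeoJSON FeatureCollection
#'
#' @param annotation A \code{"tumor_annotation"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_qupath_annotation <- function(annotation, path) {
  close_ring <- function(m) {
    m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feats <- lapply(annotation$polygons, function(p) {
    list(type = "Feature", properties = list(classification = "Tumor"),
         geometry = list(type = "Polygon",
                         coordinates = c(list(close_ring(p$exterior)),
                                         lapply(p$holes, close_ring))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shoelace area of an open ring (absolute value).
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:nrow(ring), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Total annotated area in square pixels
#'
#' Hole areas are subtracted from their enclosing exterior ring.
#'
#' @param annotation A \code{"tumor_annotation"}.
#' @return Area in square pixels.
#' @export
annotation_area <- function(annotation) {
  sum(vapply(annotation$polygons, function(p) {
    ring_area(p$exterior) - sum(vapply(p$holes, ring_area, 0))
  }, 0))
}

#' Bounding box of an annotation
#'
#' @param annotation A \code{"tumor_annotation"}.
#' @return Named vector \code{(xmin, ymin, xmax, ymax)} in pixels.
#' @export
annotation_bbox <- function(annotation) {
  pts <- do.call(rbind, lapply(annotation$polygons, `[[`, "exterior"))
  c(xmin = min(pts[, 1]), ymin = min(pts[, 2]),
    xmax = max(pts[, 1]), ymax = max(pts[, 2]))
}

#' @export
print.tumor_annotation <- function(x, ...) {
  bb <- annotation_bbox(x)
  cat("Tumor annotation for slide '", x$slide_id, "': ",
      length(x$polygons), " polygon(s), area ",
      format(annotation_area(x), big.mark = ","), " px^2, bbox [",
      bb["xmin"], ", ", bb["ymin"], "] - [", bb["xmax"], ", ", bb["ymax"],
      "]\n", sep = "")
  invisible(x)
}

# Sutherland-Hodgman clip of a ring against one axis-aligned half-plane.
# keep(p) TRUE when the point is inside; cross(p, q) returns the boundary
# intersection of segment p-q.
clip_halfplane <- function(ring, keep, cross) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  out <- matrix(0, 2 * n, 2)
  m <- 0L
  inside <- keep(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- ring[i, ]; q <- ring[j, ]
    if (inside[i]) {
      m <- m + 1L; out[m, ] <- p
      if (!inside[j]) { m <- m + 1L; out[m, ] <- cross(p, q) }
    } else if (inside[j]) {
      m <- m + 1L; out[m, ] <- cross(p, q)
    }
  }
  out[seq_len(m), , drop = FALSE]
}

# Area of the intersection of a simple ring with an axis-aligned rectangle.
ring_rect_area <- function(ring, x0, x1, y0, y1) {
  r <- ring
  r <- clip_halfplane(r, function(p) if (is.matrix(p)) p[, 1] >= x0 else p[1] >= x0,
                      function(p, q) { t <- (x0 - p[1]) / (q[1] - p[1])
                        c(x0, p[2] + t * (q[2] - p[2])) })
  r <- clip_halfplane(r, function(p) if (is.matrix(p)) p[, 1] <= x1 else p[1] <= x1,
                      function(p, q) { t <- (x1 - p[1]) / (q[1] - p[1])
                        c(x1, p[2] + t * (q[2] - p[2])) })
  r <- clip_halfplane(r, function(p) if (is.matrix(p)) p[, 2] >= y0 else p[2] >= y0,
                      function(p, q) { t <- (y0 - p[2]) / (q[2] - p[2])
                        c(p[1] + t * (q[1] - p[1]), y0) })
  r <- clip_halfplane(r, function(p) if (is.matrix(p)) p[, 2] <= y1 else p[2] <= y1,
                      function(p, q) { t <- (y1 - p[2]) / (q[2] - p[2])
                        c(p[1] + t * (q[1] - p[1]), y1) })
  if (nrow(r) < 3) 0 else ring_area(r)
}

# Annotated area falling inside an axis-aligned rectangle.
annotation_rect_area <- function(annotation, x0, x1, y0, y1) {
  sum(vapply(annotation$polygons, function(p) {
    ring_rect_area(p$exterior, x0, x1, y0, y1) -
      sum(vapply(p$holes, ring_rect_area, 0, x0, x1, y0, y1))
  }, 0))
}

#' Rasterize an annotation to a pixel mask
#'
#' Even-odd scanline rasterization at pixel centers: pixel \code{(row, col)}
#' (1-based matrix indices) covers the unit square
#' \code{[col-1, col) x [row-1, row)} and is inside when its center is inside
#' an odd number of rings.
#'
#' @param annotation A \code{"tumor_annotation"}.
#' @param width,height Slide dimensions in pixels.
#' @return Logical \code{height x width} matrix.
#' @export
rasterize_annotation <- function(annotation, width, height) {
  mask <- matrix(FALSE, height, width)
  rings <- unlist(lapply(annotation$polygons,
                         function(p) c(list(p$exterior), p$holes)),
                  recursive = FALSE)
  for (r in seq_len(height)) {
    yc <- r - 0.5
    xs <- numeric(0)
    for (ring in rings) {
      x1 <- ring[, 1]; y1 <- ring[, 2]
      j <- c(2:nrow(ring), 1L)
      x2 <- x1[j]; y2 <- y1[j]
      hit <- (y1 <= yc & yc < y2) | (y2 <= yc & yc < y1)
      if (any(hit))
        xs <- c(xs, x1[hit] + (yc - y1[hit]) *
                  (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    }
    if (length(xs) < 2) next
    xs <- sort(xs)
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c1 <- max(1L, floor(xs[i] + 0.5) + 1L)
      c2 <- min(width, ceiling(xs[i + 1] + 0.5) - 1L)
      if (c1 <= c2) mask[r, c1:c2] <- TRUE
    }
  }
  mask
}
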