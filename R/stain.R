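#' Stain profiles and Macenko estimation
#'
#' H&E color appearance is modeled in optical density (OD) space,
#' \code{OD = -log10((I + 1) / 256)} per channel with \code{I} the 8-bit
#' intensity, where Beer-Lambert absorption is linear: each pixel's OD is a
#' non-negative mixture of two unit-norm stain direction vectors
#' (hematoxylin and eosin).  A \code{stain_profile} holds the 2 x 3 stain
#' matrix (rows H, E) and the per-stain reference maximum concentrations
#' (a high percentile of the observed concentration distribution).
#'
#' @param stain_matrix 2 x 3 matrix of OD directions, rows hematoxylin and
#'   eosin; rows are unit-normalized on construction.
#' @param max_concentrations Positive length-2 vector of reference maximum
#'   concentrations.
#' @return A \code{"stain_profile"} object.
#' @export
stain_profile <- function(stain_matrix, max_concentrations = c(1, 1)) {
  m <- as.matrix(stain_matrix)
  if (!all(dim(m) == c(2, 3))) stop("stain_matrix must be 2 x 3")
  if (any(m < -1e-8)) stop("stain OD directions must be non-negative")
  m <- pmax(m, 0)
  m <- m / sqrt(rowSums(m^2))
  if (any(max_concentrations <= 0)) stop("max_concentrations must be > 0")
  structure(list(stain_matrix = m,
                 max_concentrations = as.numeric(max_concentrations)),
            class = "stain_profile")
}

#' @rdname stain_profile
#' @details \code{default_stain_profile()} is the fixed normalization target:
#'   the canonical H&E OD vectors H = (0.65, 0.70, 0.29) and
#'   E = (0.07, 0.99, 0.11), unit-normalized, with unit reference
#'   concentrations.  Normalizing every slide to this one reference removes
#'   scanner- and batch-level color variation.
#' @export
default_stain_profile <- function() {
  stain_profile(rbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11)),
                c(1, 1))
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("Stain profile (rows: OD directions)\n")
  print(round(x$stain_matrix, 4))
  cat("max concentrations:",
      paste(round(x$max_concentrations, 4), collapse = ", "), "\n")
  invisible(x)
}

# RGB [0,1] array -> n x 3 OD matrix (and back).
rgb_to_od <- function(px) {
  v <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  -log10((v * 255 + 1) / 256)
}

od_to_rgb <- function(od, nr, nc) {
  v <- (256 * 10^(-od) - 1) / 255
  v <- pmin(1, pmax(0, v))
  array(v, c(nr, nc, 3))
}

# Non-negative stain concentrations by least-squares projection onto the
# stain plane, clipped at zero.
stain_concentrations <- function(od, stain_matrix) {
  pinv <- solve(stain_matrix %*% t(stain_matrix)) %*% stain_matrix
  pmax(od %*% t(pinv), 0)
}

#' Estimate a slide's stain profile from a tile (Macenko method)
#'
#' Converts the tile to optical density, discards near-transparent pixels
#' (OD Euclidean norm at or below \code{od_threshold}), projects the
#' remaining OD cloud onto the plane of its top two singular vectors, and
#' takes the directions at the extreme \code{angle_percentile} /
#' \code{100 - angle_percentile} percentiles of the in-plane angle as the
#' two stain vectors.  The vector with the larger blue-channel OD is called
#' hematoxylin.  Reference maximum concentrations are the
#' \code{conc_percentile} percentile of the non-negative projected
#' concentrations.
#'
#' @param tile \code{T x T x 3} RGB array in \[0, 1\] or \[0, 255\].
#' @param od_threshold OD norm below which a pixel is treated as background
#'   (default 0.15).
#' @param angle_percentile Percentile (in percent) of the angle distribution
#'   used for the extreme stain directions (default 1).
#' @param conc_percentile Percentile (in percent) defining the reference
#'   maximum concentration (default 99).
#' @return A \code{"stain_profile"}.
#' @export
estimate_stains <- function(tile, od_threshold = 0.15, angle_percentile = 1,
                            conc_percentile = 99) {
  px <- tile_unit_scale(tile)
  od <- rgb_to_od(px)
  tissue <- od[sqrt(rowSums(od^2)) > od_threshold, , drop = FALSE]
  if (nrow(tissue) < 100)
    stop("insufficient tissue: fewer than 100 pixels above the OD threshold")
  v <- svd(tissue, nu = 0, nv = 2)$v
  proj <- tissue %*% v
  if (mean(proj[, 1]) < 0) { v[, 1] <- -v[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100,
                        names = FALSE)
  dir1 <- as.vector(v %*% c(cos(qs[1]), sin(qs[1])))
  dir2 <- as.vector(v %*% c(cos(qs[2]), sin(qs[2])))
  fix <- function(d) {
    if (sum(d) < 0) d <- -d
    d <- pmax(d, 0)
    d / sqrt(sum(d^2))
  }
  dir1 <- fix(dir1); dir2 <- fix(dir2)
  # hematoxylin absorbs more in the blue channel
  m <- if (dir1[3] >= dir2[3]) rbind(H = dir1, E = dir2)
       else rbind(H = dir2, E = dir1)
  conc <- stain_concentrations(tissue, m)
  maxc <- apply(conc, 2, stats::quantile, probs = conc_percentile / 100,
                names = FALSE)
  maxc <- pmax(maxc, 1e-6)
  stain_profile(m, maxc)
}

#' Normalize a tile's stain appearance to a target profile
#'
#' Decomposes the tile into stain concentrations under the \code{source}
#' profile, rescales each stain's concentrations by the ratio of target to
#' source reference maxima, and re-renders with the target stain matrix.
#' Output values are clipped to the valid intensity range.  White
#' (OD about 0) pixels have near-zero concentration and stay white.
#'
#' @param tile \code{T x T x 3} RGB array in \[0, 1\] or \[0, 255\].
#' @param source Stain profile of the tile's slide/scanner (see
#'   \code{\link{estimate_stains}}).
#' @param target Reference profile (default \code{default_stain_profile()}).
#' @return Normalized tile, same shape, values in \[0, 1\].
#' @export
normalize_stain <- function(tile, source, target = default_stain_profile()) {
  stopifnot(inherits(source, "stain_profile"), inherits(target, "stain_profile"))
  px <- tile_unit_scale(tile)
  d <- dim(px)
  od <- rgb_to_od(px)
  conc <- stain_concentrations(od, source$stain_matrix)
  conc <- sweep(conc, 2,
                target$max_concentrations / source$max_concentrations, `*`)
  od_to_rgb(conc %*% target$stain_matrix, d[1], d[2])
}

#' Angular distance between stain direction vectors
#'
#' @param a,b Unit (or arbitrary) 3-vectors.
#' @return Angle in degrees.
#' @export
stain_angle_deg <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}
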