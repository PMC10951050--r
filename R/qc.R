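#' Tile quality control
#'
#' Pure function of the tile pixels with two rejection rules, applied in
#' order: a tile is rejected as \code{"background"} when the fraction of
#' background pixels (HSV saturation below \code{bg_sat} and value above
#' \code{bg_val}, i.e. bright and colorless) exceeds \code{max_bg_fraction};
#' otherwise it is rejected as \code{"blur"} when the variance of its
#' grayscale Laplacian falls below \code{min_laplacian_var} (defocused tissue
#' has little high-frequency content); otherwise it is accepted.
#'
#' @param tile \code{T x T x 3} RGB array, values in \[0, 1\] or \[0, 255\].
#' @param bg_sat Background saturation ceiling in \[0, 1\] (default 0.08).
#' @param bg_val Background value floor on the 0-255 scale (default 220).
#' @param max_bg_fraction Maximum tolerated background fraction (default 0.5,
#'   exclusive).
#' @param min_laplacian_var Minimum Laplacian variance on the 0-255 grayscale
#'   (default 15).
#' @return List with \code{accept} (logical), \code{reason} (\code{NA},
#'   \code{"background"} or \code{"blur"}), \code{background_fraction} and
#'   \code{laplacian_var}.
#' @export
qc_tile <- function(tile, bg_sat = 0.08, bg_val = 220,
                    max_bg_fraction = 0.5, min_laplacian_var = 15) {
  px <- tile_unit_scale(tile)
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  bg <- hsv[2, ] < bg_sat & hsv[3, ] * 255 > bg_val
  bg_fraction <- mean(bg)
  lap_var <- laplacian_variance(px)
  if (bg_fraction > max_bg_fraction) {
    res <- list(accept = FALSE, reason = "background")
  } else if (lap_var < min_laplacian_var) {
    res <- list(accept = FALSE, reason = "blur")
  } else {
    res <- list(accept = TRUE, reason = NA_character_)
  }
  c(res, list(background_fraction = bg_fraction, laplacian_var = lap_var))
}

# Variance of the 4-neighbor Laplacian of the 0-255 luma image.
laplacian_variance <- function(px) {
  g <- 255 * (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  n <- nrow(g); m <- ncol(g)
  if (n < 3 || m < 3) return(0)
  ctr <- g[2:(n - 1), 2:(m - 1)]
  lap <- g[1:(n - 2), 2:(m - 1)] + g[3:n, 2:(m - 1)] +
         g[2:(n - 1), 1:(m - 2)] + g[2:(n - 1), 3:m] - 4 * ctr
  stats::var(as.vector(lap))
}

# Accept [0,1] or [0,255] tiles; return [0,1].
tile_unit_scale <- function(tile) {
  if (length(dim(tile)) != 3 || dim(tile)[3] < 3)
    stop("tile must be a T x T x 3 RGB array")
  if (max(tile) > 1.5) tile / 255 else tile
}
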