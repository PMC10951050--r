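#' Aggregate tile predictions into a slide-level call
#'
#' The slide-level probability of each class, \eqn{p^{WSI}}, is the
#' arithmetic mean of the tile-level probabilities; the slide label is the
#' class with the larger mean.  Calls are banded by the winning probability:
#' \emph{high} confidence when \eqn{\max p^{WSI} \ge 0.7}, \emph{low} when
#' \eqn{\max p^{WSI} \le 0.6} (i.e. the winning score lies in \[0.4, 0.6\]),
#' \emph{intermediate} in the open gap (0.6, 0.7).  An exact 0.5/0.5 tie is
#' labeled luminal, banded low and flagged.
#'
#' @param tile_predictions Data frame with columns \code{p_luminal},
#'   \code{p_basal} (rows of one slide), optionally \code{slide_id}.
#' @return A one-row data frame of class \code{"slide_prediction"}:
#'   \code{slide_id, p_wsi_luminal, p_wsi_basal, label, confidence_band,
#'   n_tiles, tie}.
#' @export
aggregate_slide <- function(tile_predictions) {
  tp <- validate_tile_predictions(tile_predictions)
  sid <- unique(as.character(tp$slide_id %||% "slide"))
  if (length(sid) > 1)
    stop("tile predictions span several slides: ",
         paste(sid, collapse = ", "))
  p_lum <- mean(tp$p_luminal)
  p_bas <- mean(tp$p_basal)
  tie <- isTRUE(all.equal(p_lum, p_bas, tolerance = 1e-12))
  label <- if (tie || p_lum > p_bas) "luminal" else "basal"
  res <- data.frame(slide_id = sid, p_wsi_luminal = p_lum,
                    p_wsi_basal = p_bas, label = label,
                    confidence_band = confidence_band(max(p_lum, p_bas)),
                    n_tiles = nrow(tp), tie = tie,
                    stringsAsFactors = FALSE)
  class(res) <- c("slide_prediction", "data.frame")
  res
}

#' @rdname aggregate_slide
#' @details \code{aggregate_slides()} applies the rule per \code{slide_id}
#'   over a cohort-level tile-prediction table.
#' @export
aggregate_slides <- function(tile_predictions) {
  stopifnot(!is.null(tile_predictions$slide_id))
  parts <- split(tile_predictions, tile_predictions$slide_id)
  out <- do.call(rbind, lapply(parts, aggregate_slide))
  rownames(out) <- NULL
  out[order(out$slide_id), , drop = FALSE]
}

#' Confidence band of a winning slide-level probability
#'
#' The three bands partition \[0.5, 1\]: high \eqn{[0.7, 1]}, intermediate
#' \eqn{(0.6, 0.7)}, low \eqn{[0.5, 0.6]}.
#'
#' @param p_max Winning class probability in \[0.5, 1\].
#' @return \code{"high"}, \code{"intermediate"} or \code{"low"}.
#' @export
confidence_band <- function(p_max) {
  # tolerance so means landing exactly on a threshold are banded stably
  ifelse(p_max >= 0.7 - 1e-9, "high",
         ifelse(p_max <= 0.6 + 1e-9, "low", "intermediate"))
}

validate_tile_predictions <- function(tp) {
  if (is.null(tp) || nrow(tp) == 0) stop("no tile predictions supplied")
  if (is.null(tp$p_luminal) || is.null(tp$p_basal))
    stop("tile predictions need p_luminal and p_basal columns")
  if (any(tp$p_luminal < -1e-9 | tp$p_basal < -1e-9) ||
      any(abs(tp$p_luminal + tp$p_basal - 1) > 1e-6))
    stop("tile probabilities must be non-negative and sum to 1")
  tp
}

#' Ensemble slide prediction from multiple trained models
#'
#' Each model's slide-level mean prediction is computed as in
#' \code{\link{aggregate_slide}}; the ensemble call is the class with the
#' highest average of those slide-level values across models, banded on the
#' averaged values.  Intended for external cohorts, using the three
#' fold-models of the best-performing repetition.
#'
#' @param models List of fitted \code{\link{tile_classifier}} models
#'   (exactly 3 unless \code{allow_any_k}).
#' @param tiles Tiles of one slide (arrays, paths, or a feature matrix with
#'   \code{features = TRUE}).
#' @param slide_id Slide identifier for the output.
#' @param allow_any_k Permit a model count other than 3.
#' @param features Treat \code{tiles} as precomputed features.
#' @return A \code{"slide_prediction"} row.
#' @export
ensemble_predict <- function(models, tiles, slide_id = "slide",
                             allow_any_k = FALSE, features = FALSE) {
  if (length(models) != 3 && !allow_any_k)
    stop("ensemble expects exactly 3 models (set allow_any_k to override)")
  per_model <- vapply(models, function(m) {
    p <- predict_tiles(m, tiles, features = features)
    c(mean(p$p_luminal), mean(p$p_basal))
  }, numeric(2))
  avg <- rowMeans(per_model)
  res <- aggregate_slide(data.frame(slide_id = slide_id,
                                    p_luminal = avg[1], p_basal = avg[2]))
  n <- if (is.matrix(tiles) || is.data.frame(tiles)) nrow(tiles)
       else if (is.list(tiles) && !is.array(tiles)) length(tiles)
       else if (is.character(tiles)) length(tiles) else 1L
  res$n_tiles <- n
  res
}

#' Build a tile-grid prediction map
#'
#' One entry per retained tile carrying the winning class and its
#' probability (in \[0.5, 1\]).
#'
#' @param tile_predictions Data frame with \code{grid_row}, \code{grid_col},
#'   \code{p_luminal}, \code{p_basal} (one slide).
#' @return A \code{"prediction_map"}: data frame \code{grid_row, grid_col,
#'   label, prob} with the slide id as attribute.
#' @export
build_prediction_map <- function(tile_predictions) {
  tp <- validate_tile_predictions(tile_predictions)
  if (is.null(tp$grid_row) || is.null(tp$grid_col))
    stop("tile predictions need grid_row and grid_col")
  if (anyDuplicated(paste(tp$grid_row, tp$grid_col)))
    stop("duplicate grid coordinates in prediction map")
  win_lum <- tp$p_luminal >= tp$p_basal
  out <- data.frame(grid_row = as.integer(tp$grid_row),
                    grid_col = as.integer(tp$grid_col),
                    label = ifelse(win_lum, "luminal", "basal"),
                    prob = pmax(tp$p_luminal, tp$p_basal),
                    stringsAsFactors = FALSE)
  out <- out[order(out$grid_row, out$grid_col), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "slide_id") <- unique(as.character(tp$slide_id %||% "slide"))
  class(out) <- c("prediction_map", "data.frame")
  out
}

#' Render a prediction map as an RGB overlay
#'
#' Luminal tiles are drawn red, basal tiles blue, blended over white with
#' opacity \eqn{\alpha = 2 (p - 0.5)}: a coin-flip tile is invisible, a
#' certain tile fully saturated.
#'
#' @param map A \code{\link{build_prediction_map}} result.
#' @param path Optional PNG output path.
#' @return \code{rows x cols x 3} RGB array in \[0, 1\] (invisibly when
#'   written).
#' @export
render_prediction_map <- function(map, path = NULL) {
  r0 <- min(map$grid_row); c0 <- min(map$grid_col)
  nr <- max(map$grid_row) - r0 + 1L
  nc <- max(map$grid_col) - c0 + 1L
  img <- array(1, c(nr, nc, 3))
  cols <- list(luminal = c(1, 0, 0), basal = c(0, 0, 1))
  for (i in seq_len(nrow(map))) {
    a <- 2 * (map$prob[i] - 0.5)
    base <- cols[[map$label[i]]]
    img[map$grid_row[i] - r0 + 1L, map$grid_col[i] - c0 + 1L, ] <-
      a * base + (1 - a) * 1
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}

#' @export
plot.prediction_map <- function(x, ...) {
  img <- render_prediction_map(x)
  op <- graphics::par(mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(c(0, ncol(img)), c(0, nrow(img)), type = "n", asp = 1,
                 xlab = "", ylab = "",
                 main = paste("Prediction map:", attr(x, "slide_id")), ...)
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, ncol(img), nrow(img))
  invisible(x)
}

#' Detect candidate heterogeneous slides from a prediction map
#'
#' Operationalizes "distinguishable clusters of luminal and basal tiles":
#' tiles whose winning probability reaches \code{prob_floor} are assigned to
#' their class; 4-connected components are computed per class on the tile
#' grid; the slide is a heterogeneity candidate when \emph{both} classes own
#' at least one component covering at least \code{min_component_fraction} of
#' all retained tiles.
#'
#' @param map A \code{\link{build_prediction_map}} result.
#' @param min_component_fraction Minimum component size as a fraction of all
#'   retained tiles (default 0.2).
#' @param prob_floor Minimum winning probability for class assignment
#'   (default 0.6).
#' @return A \code{"heterogeneity_report"}: list with \code{components}
#'   (per-class integer vectors of component sizes), \code{n_tiles},
#'   \code{is_candidate} and the two parameters.
#' @export
detect_heterogeneity <- function(map, min_component_fraction = 0.2,
                                 prob_floor = 0.6) {
  if (nrow(map) == 0) stop("empty prediction map")
  n_tiles <- nrow(map)
  comps <- lapply(c(luminal = "luminal", basal = "basal"), function(cl) {
    sub <- map[map$label == cl & map$prob >= prob_floor, , drop = FALSE]
    grid_components(sub$grid_row, sub$grid_col)
  })
  thresh <- min_component_fraction * n_tiles
  is_candidate <- all(vapply(comps, function(s) any(s >= thresh), logical(1)))
  structure(list(components = comps, n_tiles = n_tiles,
                 min_component_fraction = min_component_fraction,
                 prob_floor = prob_floor, is_candidate = is_candidate),
            class = "heterogeneity_report")
}

# Sizes of 4-connected components of a set of grid cells (BFS).
grid_components <- function(rows, cols) {
  n <- length(rows)
  if (n == 0) return(integer())
  key <- paste(rows, cols)
  idx <- stats::setNames(seq_len(n), key)
  seen <- logical(n)
  sizes <- integer()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      nb <- c(paste(rows[cur] - 1, cols[cur]), paste(rows[cur] + 1, cols[cur]),
              paste(rows[cur], cols[cur] - 1), paste(rows[cur], cols[cur] + 1))
      hit <- idx[nb]
      hit <- hit[!is.na(hit)]
      new <- hit[!seen[hit]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat("Heterogeneity report: ", x$n_tiles, " tiles; candidate: ",
      x$is_candidate, "\n", sep = "")
  for (cl in names(x$components)) {
    s <- x$components[[cl]]
    cat("  ", cl, ": ", length(s), " component(s)",
        if (length(s)) paste0(" of size ", paste(s, collapse = ", ")),
        "\n", sep = "")
  }
  invisible(x)
}
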