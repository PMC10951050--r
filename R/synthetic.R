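#' Simulation parameters for synthetic H-score cohorts
#'
#' Emulates the three-latent-subtype block structure of the marker panel:
#' luminal patients express the luminal markers strongly (mean 220, SD 40)
#' and the basal markers weakly (mean 20, SD 15), basal patients are
#' mirrored, and indifferent patients express everything weakly (mean 15,
#' SD 10).  Each patient contributes \code{cores_per_patient} tissue cores
#' whose H-scores scatter around the patient's latent marker vector with
#' SD \code{core_noise_sd}; all values are truncated to \[0, 300\].
#'
#' @param n_per_subtype Patients per subtype (scalar or named vector over
#'   luminal/basal/indifferent; default 30).
#' @param high_mean,high_sd Latent mean/SD of a subtype's own marker panel.
#' @param low_mean,low_sd Latent mean/SD of the opposite panel.
#' @param indiff_mean,indiff_sd Latent mean/SD of all markers for the
#'   indifferent subtype.
#' @param cores_per_patient Cores per patient (default 4).
#' @param core_noise_sd Core-level measurement noise SD (default 15).
#' @param seed Integer seed.
#' @return An \code{"hscore_sim_params"} list.
#' @export
hscore_sim_params <- function(n_per_subtype = 30, high_mean = 220,
                              high_sd = 40, low_mean = 20, low_sd = 15,
                              indiff_mean = 15, indiff_sd = 10,
                              cores_per_patient = 4, core_noise_sd = 15,
                              seed = 1) {
  n <- if (length(n_per_subtype) == 1)
    stats::setNames(rep(n_per_subtype, 3),
                    c("luminal", "basal", "indifferent"))
  else n_per_subtype[c("luminal", "basal", "indifferent")]
  stopifnot(all(n >= 0), high_sd > 0, low_sd > 0, indiff_sd > 0,
            cores_per_patient >= 1, core_noise_sd >= 0)
  structure(list(n_per_subtype = n, high_mean = high_mean, high_sd = high_sd,
                 low_mean = low_mean, low_sd = low_sd,
                 indiff_mean = indiff_mean, indiff_sd = indiff_sd,
                 cores_per_patient = as.integer(cores_per_patient),
                 core_noise_sd = core_noise_sd, seed = seed),
            class = "hscore_sim_params")
}

#' Generate a synthetic H-score cohort with planted subtypes
#'
#' Pure function of its parameter object (including the seed): per patient a
#' latent marker mean vector is drawn from the subtype's distribution, then
#' each core's H-score adds independent noise; everything is truncated to
#' \[0, 300\].
#'
#' @param params An \code{\link{hscore_sim_params}} object.
#' @return List with \code{measurements} (long-format data frame
#'   \code{patient_id, core_id, marker, h_score}) and \code{truth}
#'   (\code{patient_id, label}).
#' @export
gen_hscore_cohort <- function(params = hscore_sim_params()) {
  stopifnot(inherits(params, "hscore_sim_params"))
  markers <- hscore_markers()
  with_seed(params$seed, {
    rows <- list(); truth <- list(); pid <- 0L
    for (subtype in c("luminal", "basal", "indifferent")) {
      for (i in seq_len(params$n_per_subtype[[subtype]])) {
        pid <- pid + 1L
        id <- sprintf("P%03d", pid)
        mu <- vapply(markers, function(mk) {
          high <- (subtype == "luminal" && mk %in% luminal_markers()) ||
                  (subtype == "basal" && mk %in% basal_markers())
          if (subtype == "indifferent")
            stats::rnorm(1, params$indiff_mean, params$indiff_sd)
          else if (high) stats::rnorm(1, params$high_mean, params$high_sd)
          else stats::rnorm(1, params$low_mean, params$low_sd)
        }, numeric(1))
        mu <- pmin(300, pmax(0, mu))
        for (core in seq_len(params$cores_per_patient)) {
          h <- pmin(300, pmax(0, mu + stats::rnorm(length(markers), 0,
                                                   params$core_noise_sd)))
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = id, core_id = core, marker = markers,
            h_score = unname(h), stringsAsFactors = FALSE)
        }
        truth[[pid]] <- data.frame(patient_id = id, label = subtype,
                                   stringsAsFactors = FALSE)
      }
    }
    list(measurements = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Parameters for a textured pseudo-slide
#'
#' Pseudo-slides are crude but controllable proxies of H&E appearance: the
#' luminal texture is a dense field of dark blue-purple nuclear ellipses on
#' a pink background (dense nuclei with small stroma bridges), the basal
#' texture oriented pink stromal fibers with sparse bright keratin blobs
#' (dense stroma and keratinization).  Outside the tumor polygon the slide
#' is near-white; optional artifacts (a white margin, a Gaussian-blurred
#' patch) exercise quality control.
#'
#' @param width,height Slide dimensions in pixels (default 3072 x 2048).
#' @param layout \code{"luminal"}, \code{"basal"} or
#'   \code{"heterogeneous"} (vertical split, luminal left).
#' @param split_fraction Luminal fraction of a heterogeneous slide's width
#'   (default 0.5).
#' @param annotation Optional \code{"tumor_annotation"}; default a
#'   full-coverage rectangle.
#' @param nucleus_density Nuclei per pixel^2 of luminal tissue
#'   (default 4e-3).
#' @param nucleus_radius Range of nuclear semi-axis lengths in pixels.
#' @param fiber_density Fibers per pixel^2 of basal tissue (default 1.2e-3).
#' @param fiber_length Mean fiber length in pixels (default 60).
#' @param keratin_rate Keratin blobs per pixel^2 (default 2e-5).
#' @param noise_sd SD of additive Gaussian stain-concentration noise.
#' @param white_margin Leave the leftmost \code{margin_px} of the tumor
#'   area white (background-rejection fixture).
#' @param margin_px Width of the white margin (default 640).
#' @param blur_patch Blur the top-right tile-sized patch
#'   (blur-rejection fixture).
#' @param tile_edge Tile edge used for the ground-truth label grid.
#' @param slide_id Slide identifier.
#' @param seed Integer seed.
#' @return A \code{"pseudo_slide_params"} list.
#' @export
pseudo_slide_params <- function(width = 3072, height = 2048,
                                layout = c("luminal", "basal",
                                           "heterogeneous"),
                                split_fraction = 0.5, annotation = NULL,
                                nucleus_density = 4e-3,
                                nucleus_radius = c(4, 8),
                                fiber_density = 1.2e-3, fiber_length = 60,
                                keratin_rate = 2e-5, noise_sd = 0.015,
                                white_margin = FALSE, margin_px = 640,
                                blur_patch = FALSE, tile_edge = 512,
                                slide_id = "slide", seed = 1) {
  layout <- match.arg(layout)
  stopifnot(width >= 2 * tile_edge, height >= 2 * tile_edge,
            split_fraction > 0, split_fraction < 1)
  structure(as.list(environment()), class = "pseudo_slide_params")
}

#' Generate a textured pseudo-slide with annotation and tile ground truth
#'
#' @param params A \code{\link{pseudo_slide_params}} object.
#' @return List with \code{image} (\code{height x width x 3} array in
#'   \[0, 1\]), \code{annotation} (a \code{"tumor_annotation"}),
#'   \code{truth} (data frame \code{grid_row, grid_col, label} for tiles
#'   with tumor fraction at least 0.5 and at least half their area in one
#'   texture region) and \code{params}.
#' @export
gen_pseudo_slide <- function(params = pseudo_slide_params()) {
  stopifnot(inherits(params, "pseudo_slide_params"))
  w <- params$width; h <- params$height
  ann <- params$annotation
  if (is.null(ann))
    ann <- tumor_annotation(params$slide_id, list(rbind(
      c(0, 0), c(w, 0), c(w, h), c(0, h))))
  ann$slide_id <- params$slide_id
  split_x <- switch(params$layout, luminal = w, basal = 0,
                    heterogeneous = round(params$split_fraction * w))
  pal <- stain_conc_palette()
  with_seed(params$seed, {
    mask <- rasterize_annotation(ann, w, h)
    cols <- col(mask)
    conc_h <- matrix(0, h, w)
    conc_e <- matrix(0, h, w)
    lum_px <- mask & cols <= split_x
    bas_px <- mask & cols > split_x
    conc_h[lum_px] <- pal$lum_bg[1]; conc_e[lum_px] <- pal$lum_bg[2]
    conc_h[bas_px] <- pal$bas_bg[1]; conc_e[bas_px] <- pal$bas_bg[2]
    rm(lum_px, bas_px, cols)
    if (split_x > 0) {                     # luminal texture: dense nuclei
      px <- scatter_ellipses(mask, c(1, split_x), params$nucleus_density,
                             params$nucleus_radius)
      if (px$n) {
        conc_h[px$lin] <- pmax(0, pal$nucleus[1] +
                                    stats::rnorm(px$n, 0, 0.15))[px$e]
        conc_e[px$lin] <- pmax(0, pal$nucleus[2] +
                                    stats::rnorm(px$n, 0, 0.05))[px$e]
      }
    }
    if (split_x < w) {                     # basal texture: fibers + keratin
      px <- scatter_fibers(mask, c(split_x + 1, w), params$fiber_density,
                           params$fiber_length)
      if (px$n) {
        conc_h[px$lin] <- pmax(0, pal$fiber[1] +
                                    stats::rnorm(px$n, 0, 0.03))[px$e]
        conc_e[px$lin] <- pmax(0, pal$fiber[2] +
                                    stats::rnorm(px$n, 0, 0.08))[px$e]
      }
      px <- scatter_ellipses(mask, c(split_x + 1, w), params$keratin_rate,
                             c(6, 12))
      if (px$n) {
        conc_h[px$lin] <- pmax(0, pal$keratin[1] +
                                    stats::rnorm(px$n, 0, 0.02))[px$e]
        conc_e[px$lin] <- pmax(0, pal$keratin[2] +
                                    stats::rnorm(px$n, 0, 0.10))[px$e]
      }
    }
    if (params$white_margin) {
      m <- min(params$margin_px, w)
      conc_h[, seq_len(m)] <- 0
      conc_e[, seq_len(m)] <- 0
    }
    if (params$noise_sd > 0) {
      conc_h <- pmax(0, conc_h + matrix(stats::rnorm(h * w, 0,
                                                     params$noise_sd), h, w))
      conc_e <- pmax(0, conc_e + matrix(stats::rnorm(h * w, 0,
                                                     params$noise_sd), h, w))
    }
    od <- cbind(as.vector(conc_h), as.vector(conc_e)) %*%
      default_stain_profile()$stain_matrix
    rm(conc_h, conc_e)
    img <- od_to_rgb(od, h, w)
    rm(od)
    if (params$blur_patch) {               # top-right tile-aligned patch
      e <- min(params$tile_edge, w, h)
      x0 <- (floor(w / e) - 1) * e
      img[1:e, (x0 + 1):(x0 + e), ] <-
        blur_stack(img[1:e, (x0 + 1):(x0 + e), , drop = FALSE],
                   radius = 6, passes = 3)
    }
    truth <- tile_truth(ann, c(w, h), params$tile_edge, split_x)
    list(image = img, annotation = ann, truth = truth, params = params)
  })
}

# Reference stain concentrations (hematoxylin, eosin) of the texture
# elements, chosen so both textures are well inside the H&E stain plane and
# the luminal texture absorbs markedly more in the blue channel.
stain_conc_palette <- function() {
  list(lum_bg = c(0.10, 0.30), bas_bg = c(0.05, 0.12),
       nucleus = c(1.30, 0.30), fiber = c(0.12, 0.40),
       keratin = c(0.05, 0.80))
}

# Ground-truth labels for retained tiles; a tile is labeled when >= 50% of
# its area lies in one texture region.
tile_truth <- function(ann, dims, tile_edge, split_x) {
  specs <- tessellate(dims, ann, tile_edge, 0.5)
  if (nrow(specs) == 0)
    return(data.frame(grid_row = integer(), grid_col = integer(),
                      label = character()))
  area <- tile_edge^2
  lab <- vapply(seq_len(nrow(specs)), function(i) {
    x0 <- specs$x[i]; y0 <- specs$y[i]
    lum <- if (split_x > x0)
      annotation_rect_area(ann, x0, min(x0 + tile_edge, split_x),
                           y0, y0 + tile_edge) / area else 0
    bas <- if (split_x < x0 + tile_edge)
      annotation_rect_area(ann, max(x0, split_x), x0 + tile_edge,
                           y0, y0 + tile_edge) / area else 0
    if (lum >= 0.5) "luminal" else if (bas >= 0.5) "basal"
    else NA_character_
  }, character(1))
  data.frame(grid_row = specs$grid_row, grid_col = specs$grid_col,
             label = lab, stringsAsFactors = FALSE)
}

# Pixel indices of filled rotated ellipses scattered over the masked region
# (chunked for memory); returns linear indices and their element ids.
scatter_ellipses <- function(mask, xlim, density, radius) {
  h <- nrow(mask)
  area <- (xlim[2] - xlim[1] + 1) * h
  n <- stats::rpois(1, density * area)
  if (n == 0) return(list(lin = integer(), e = integer(), n = 0L))
  cx <- stats::runif(n, xlim[1], xlim[2])
  cy <- stats::runif(n, 1, h)
  r1 <- stats::runif(n, radius[1], radius[2])
  r2 <- r1 * stats::runif(n, 0.6, 1)
  th <- stats::runif(n, 0, pi)
  rmax <- ceiling(max(r1))
  off <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  K <- nrow(off)
  chunk <- max(1, floor(2e6 / K))
  lin_all <- vector("list", ceiling(n / chunk))
  e_all <- vector("list", ceiling(n / chunk))
  bi <- 0L
  for (s in seq(1, n, by = chunk)) {
    ii <- s:min(s + chunk - 1, n)
    dx <- rep(off$dx, times = length(ii))
    dy <- rep(off$dy, times = length(ii))
    e <- rep(ii, each = K)
    u <- dx * cos(th[e]) + dy * sin(th[e])
    v <- -dx * sin(th[e]) + dy * cos(th[e])
    inside <- (u / r1[e])^2 + (v / r2[e])^2 <= 1
    x <- round(cx[e[inside]]) + dx[inside]
    y <- round(cy[e[inside]]) + dy[inside]
    e <- e[inside]
    keep <- x >= xlim[1] & x <= xlim[2] & y >= 1 & y <= h
    x <- x[keep]; y <- y[keep]; e <- e[keep]
    keep <- mask[cbind(y, x)]
    bi <- bi + 1L
    lin_all[[bi]] <- y[keep] + (x[keep] - 1) * h
    e_all[[bi]] <- e[keep]
  }
  list(lin = unlist(lin_all), e = unlist(e_all), n = n)
}

# Pixel indices of oriented fibers (~3 px thick line segments).
scatter_fibers <- function(mask, xlim, density, length_mean) {
  h <- nrow(mask)
  area <- (xlim[2] - xlim[1] + 1) * h
  n <- stats::rpois(1, density * area)
  if (n == 0) return(list(lin = integer(), e = integer(), n = 0L))
  cx <- stats::runif(n, xlim[1], xlim[2])
  cy <- stats::runif(n, 1, h)
  th <- stats::runif(n, 0, pi)
  len <- pmax(10, round(stats::rnorm(n, length_mean, length_mean / 4)))
  lin_all <- list(); e_all <- list()
  chunk <- 2000L
  for (s in seq(1, n, by = chunk)) {
    ii <- s:min(s + chunk - 1, n)
    ts <- unlist(lapply(len[ii], function(L) seq(-L / 2, L / 2)))
    e <- rep(ii, times = len[ii] + 1)
    ex <- cx[e] + ts * cos(th[e])
    ey <- cy[e] + ts * sin(th[e])
    x <- round(c(ex + sin(th[e]), ex, ex - sin(th[e])))
    y <- round(c(ey - cos(th[e]), ey, ey + cos(th[e])))
    e3 <- rep.int(e, 3)
    keep <- x >= xlim[1] & x <= xlim[2] & y >= 1 & y <= h
    x <- x[keep]; y <- y[keep]; e3 <- e3[keep]
    keep <- mask[cbind(y, x)]
    lin_all[[length(lin_all) + 1L]] <- y[keep] + (x[keep] - 1) * h
    e_all[[length(e_all) + 1L]] <- e3[keep]
  }
  list(lin = unlist(lin_all), e = unlist(e_all), n = n)
}

# Separable box blur, repeated `passes` times (approximates a Gaussian).
blur_stack <- function(patch, radius = 5, passes = 3) {
  box1d <- function(m, r) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(n, seq_len(n) + r); lo <- pmax(0, seq_len(n) - r - 1)
    (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) / (hi - lo)
  }
  for (ch in 1:3) {
    m <- patch[, , ch]
    for (p in seq_len(passes)) m <- t(box1d(t(box1d(m, radius)), radius))
    patch[, , ch] <- m
  }
  patch
}

#' Generate a synthetic slide cohort with manifest and metadata
#'
#' Builds per-slide generation parameters (one patient per slide) with
#' per-slide seeds derived from the master seed and the slide index, so a
#' cohort is stable under count changes for existing indices.  Metadata
#' columns (tumor type, PD-L1 status, FGFR3 status) are planted with a
#' configurable association strength to the subtype: at strength 1 the
#' association is deterministic (luminal slides papillary / FGFR3-mutated,
#' basal slides non-papillary / PD-L1 positive), at strength 0 the columns
#' are independent coin flips.
#'
#' @param n_luminal,n_basal,n_heterogeneous Slide counts per layout.
#' @param seed Master seed.
#' @param width,height Slide dimensions passed to every slide.
#' @param assoc_strength Association strength in \[0, 1\] (default 1).
#' @param ... Further arguments forwarded to
#'   \code{\link{pseudo_slide_params}} for every slide.
#' @return A \code{"slide_cohort"}: list with \code{slides} (data frame
#'   \code{slide_id, patient_id, label, seed}), \code{metadata}, and the
#'   generation arguments.  Realize slide \code{i} with
#'   \code{\link{realize_slide}}.
#' @export
gen_cohort <- function(n_luminal, n_basal, n_heterogeneous = 0, seed = 1,
                       width = 3072, height = 2048, assoc_strength = 1,
                       ...) {
  stopifnot(n_luminal >= 0, n_basal >= 0, n_heterogeneous >= 0,
            assoc_strength >= 0, assoc_strength <= 1)
  labels <- rep(c("luminal", "basal", "heterogeneous"),
                c(n_luminal, n_basal, n_heterogeneous))
  n <- length(labels)
  slides <- data.frame(
    slide_id = sprintf("S%03d", seq_len(n)),
    patient_id = sprintf("PT%03d", seq_len(n)),
    label = labels,
    seed = vapply(seq_len(n), function(i) slide_seed(seed, i), numeric(1)),
    stringsAsFactors = FALSE)
  meta <- with_seed(slide_seed(seed, 0), {
    p_assoc <- 0.5 + assoc_strength / 2
    draw <- function(lab, yes, no, p_yes_for, p) {
      ifelse(stats::runif(n) < ifelse(lab == p_yes_for, p, 1 - p), yes, no)
    }
    data.frame(
      slide_id = slides$slide_id, patient_id = slides$patient_id,
      true_label = labels,
      tumor_type = draw(labels, "papillary", "non-papillary",
                        "luminal", p_assoc),
      pdl1_cps_status = draw(labels, "positive", "negative",
                             "basal", p_assoc),
      fgfr3_status = draw(labels, "mutated", "wild-type",
                          "luminal", p_assoc),
      stringsAsFactors = FALSE)
  })
  meta$tumor_type[labels == "heterogeneous"] <- NA
  structure(list(slides = slides, metadata = meta, seed = seed,
                 width = width, height = height,
                 assoc_strength = assoc_strength, extra = list(...)),
            class = "slide_cohort")
}

# Per-slide seed from (master seed, slide index), kept below 2^31.
slide_seed <- function(seed, index) {
  (as.numeric(seed) * 1000003 + index * 7919) %% 2147483647
}

#' @rdname gen_cohort
#' @param cohort A \code{"slide_cohort"}.
#' @param i Slide index.
#' @export
realize_slide <- function(cohort, i) {
  stopifnot(inherits(cohort, "slide_cohort"))
  row <- cohort$slides[i, ]
  args <- c(list(width = cohort$width, height = cohort$height,
                 layout = row$label, slide_id = row$slide_id,
                 seed = row$seed),
            cohort$extra)
  gen_pseudo_slide(do.call(pseudo_slide_params, args))
}

#' @export
print.slide_cohort <- function(x, ...) {
  cat("Synthetic slide cohort: ", nrow(x$slides), " slides (",
      paste(names(table(x$slides$label)), table(x$slides$label),
            sep = ": ", collapse = ", "),
      "), ", x$width, "x", x$height, " px, master seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}
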