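# Independent oracles used across tests.  Each deliberately takes a
# different computational route than the package implementation.

# AUROC by explicit double loop over all (positive, negative) pairs.
oracle_auroc <- function(scores, labels, positive = "basal") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Fisher 2x2 probabilities from the log-factorial hypergeometric formula.
oracle_fisher_two_sided <- function(m) {
  lf <- lgamma(seq_len(sum(m) + 1))          # lf[k+1] = log(k!)
  lfac <- function(k) lf[k + 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); c2 <- sum(m[, 2]); n <- sum(m)
  tab_prob <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    exp(lfac(r1) + lfac(r2) + lfac(c1) + lfac(c2) - lfac(n) -
          lfac(a) - lfac(b) - lfac(cc) - lfac(d))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, tab_prob, numeric(1))
  p_obs <- probs[match(m[1, 1], support)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

# 4-connected component sizes by iterative mask dilation on a grid matrix.
oracle_components <- function(rows, cols) {
  if (length(rows) == 0) return(integer())
  r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
  nr <- max(rows) - r0 + 1L; nc <- max(cols) - c0 + 1L
  occ <- matrix(FALSE, nr + 2, nc + 2)       # 1-cell border simplifies shifts
  occ[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  sizes <- integer()
  while (any(occ)) {
    seedcell <- which(occ, arr.ind = TRUE)[1, , drop = FALSE]
    comp <- matrix(FALSE, nrow(occ), ncol(occ))
    comp[seedcell] <- TRUE
    repeat {
      grown <- comp
      idx <- which(comp, arr.ind = TRUE)
      grown[idx + cbind(rep(1L, nrow(idx)), 0L)] <- TRUE
      grown[idx - cbind(rep(1L, nrow(idx)), 0L)] <- TRUE
      grown[idx + cbind(0L, rep(1L, nrow(idx)))] <- TRUE
      grown[idx - cbind(0L, rep(1L, nrow(idx)))] <- TRUE
      grown <- grown & occ
      if (identical(grown, comp)) break
      comp <- grown
    }
    sizes <- c(sizes, sum(comp))
    occ <- occ & !comp
  }
  sort(sizes, decreasing = TRUE)
}

# Tile retention count by brute-force per-pixel rasterized overlap.
# `scale` supersamples the raster so discretization error (~1/(scale*T))
# stays well below the distance of any fixture tile to the threshold.
oracle_tile_retention <- function(ann, width, height, tile_edge,
                                  min_fraction, scale = 4L) {
  sann <- ann
  sann$polygons <- lapply(ann$polygons, function(p)
    list(exterior = p$exterior * scale,
         holes = lapply(p$holes, function(hh) hh * scale)))
  mask <- rasterize_annotation(sann, width * scale, height * scale)
  e <- tile_edge * scale
  kept <- 0L
  for (r in seq_len(height %/% tile_edge) - 1L) {
    for (cc in seq_len(width %/% tile_edge) - 1L) {
      frac <- mean(mask[(r * e + 1):((r + 1) * e),
                        (cc * e + 1):((cc + 1) * e)])
      if (frac >= min_fraction - 1e-9) kept <- kept + 1L
    }
  }
  kept
}

# Random simple polygon: jittered radial star around a center.
random_polygon <- function(width, height, n_vertices = 9) {
  cx <- runif(1, 0.3 * width, 0.7 * width)
  cy <- runif(1, 0.3 * height, 0.7 * height)
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.15, 0.45) * min(width, height)
  ring <- cbind(pmin(width, pmax(0, cx + rad * cos(ang))),
                pmin(height, pmax(0, cy + rad * sin(ang))))
  tumor_annotation("rand", list(ring))
}
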