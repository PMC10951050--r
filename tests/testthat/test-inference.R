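tp <- function(pl, slide = "s", row = NULL, col = NULL) {
  d <- data.frame(slide_id = slide, p_luminal = pl, p_basal = 1 - pl)
  if (!is.null(row)) { d$grid_row <- row; d$grid_col <- col }
  d
}

# A stub classifier whose softmax head outputs a fixed probability pair.
constant_model <- function(p_luminal) {
  b <- backbone_spec()
  d <- 3 * b$pool_edge^2
  structure(list(w1 = matrix(0, d, b$hidden), b1 = numeric(b$hidden),
                 w2 = matrix(0, b$hidden, 2),
                 b2 = log(c(p_luminal, 1 - p_luminal)),
                 mu = numeric(d), sigma = rep(1, d), backbone = b,
                 classes = c("luminal", "basal")),
            class = "tile_classifier")
}

test_that("slide aggregation averages tiles and bands the winner", {
  s <- aggregate_slide(tp(c(0.9, 0.7)))
  expect_equal(s$p_wsi_luminal, 0.8)
  expect_identical(s$label, "luminal")
  expect_identical(s$confidence_band, "high")      # 0.7 threshold inclusive
  s <- aggregate_slide(tp(c(0.55, 0.65)))
  expect_equal(s$p_wsi_luminal, 0.6)
  expect_identical(s$confidence_band, "low")       # 0.6 still low
  s <- aggregate_slide(tp(0.61))
  expect_identical(s$confidence_band, "intermediate")
  expect_equal(s$n_tiles, 1)
})

test_that("exact ties are labeled luminal, banded low, and flagged", {
  s <- aggregate_slide(tp(c(0.3, 0.7)))
  expect_true(s$tie)
  expect_identical(s$label, "luminal")
  expect_identical(s$confidence_band, "low")
})

test_that("aggregation is order-invariant and duplication-invariant", {
  p <- tp(c(0.9, 0.6, 0.2))
  expect_equal(aggregate_slide(p)$p_wsi_luminal,
               aggregate_slide(p[3:1, ])$p_wsi_luminal)
  expect_equal(aggregate_slide(p)$p_wsi_luminal,
               aggregate_slide(rbind(p, p))$p_wsi_luminal)
})

test_that("degenerate aggregation inputs error", {
  empty <- data.frame(p_luminal = numeric(0), p_basal = numeric(0))
  expect_error(aggregate_slide(empty), "no tile predictions")
  two <- rbind(tp(0.8, "a"), tp(0.2, "b"))
  expect_error(aggregate_slide(two), "several slides")
  bad <- data.frame(slide_id = "s", p_luminal = 0.8, p_basal = 0.1)
  expect_error(aggregate_slide(bad), "sum to 1")
})

test_that("bands partition [0.5, 1] with no gaps", {
  p <- seq(0.5, 1, by = 0.001)
  bands <- confidence_band(p)
  expect_true(all(bands %in% c("low", "intermediate", "high")))
  expect_identical(unique(bands[p <= 0.6]), "low")
  expect_identical(unique(bands[p >= 0.7]), "high")
  expect_identical(unique(bands[p > 0.6 & p < 0.7]), "intermediate")
})

test_that("the three-model ensemble averages slide-level predictions", {
  models <- lapply(c(0.8, 0.4, 0.9), constant_model)
  feats <- matrix(runif(5 * 768), 5)
  s <- ensemble_predict(models, feats, features = TRUE)
  expect_equal(s$p_wsi_luminal, 0.7)
  expect_identical(s$label, "luminal")
  expect_identical(s$confidence_band, "high")
  # symmetric in model order
  s2 <- ensemble_predict(models[c(3, 1, 2)], feats, features = TRUE)
  expect_equal(s2$p_wsi_luminal, s$p_wsi_luminal)
  # identical models reproduce their shared prediction
  s3 <- ensemble_predict(lapply(rep(0.9, 3), constant_model), feats,
                         features = TRUE)
  expect_equal(s3$p_wsi_luminal, 0.9, tolerance = 1e-12)
  expect_error(ensemble_predict(models[1:2], feats, features = TRUE),
               "exactly 3")
  expect_equal(ensemble_predict(models[1:2], feats, allow_any_k = TRUE,
                                features = TRUE)$p_wsi_luminal, 0.6)
})

test_that("prediction maps carry one winning entry per tile", {
  p <- tp(rep(0.99, 6), row = rep(0:1, each = 3), col = rep(0:2, 2))
  map <- build_prediction_map(p)
  expect_equal(nrow(map), 6)
  expect_identical(unique(map$label), "luminal")
  img <- render_prediction_map(map)
  expect_equal(dim(img), c(2, 3, 3))
  expect_true(all(img[, , 1] > 0.97))       # red channel saturated
  expect_true(all(img[, , 2] < 0.05))
  # a coin-flip tile renders with zero opacity (white)
  img0 <- render_prediction_map(build_prediction_map(tp(0.5, row = 0,
                                                        col = 0)))
  expect_equal(as.vector(img0), c(1, 1, 1))
  dup <- rbind(p, p[1, ])
  expect_error(build_prediction_map(dup), "duplicate grid")
})

test_that("heterogeneity candidates need two large opposite components", {
  all_lum <- build_prediction_map(tp(rep(0.9, 9), row = rep(0:2, 3),
                                     col = rep(0:2, each = 3)))
  expect_false(detect_heterogeneity(all_lum)$is_candidate)
  # left half luminal, right half basal, all confident
  p <- tp(rep(c(0.9, 0.1), each = 8),
          row = rep(0:3, 4), col = rep(0:3, each = 4))
  rep_het <- detect_heterogeneity(build_prediction_map(p))
  expect_true(rep_het$is_candidate)
  expect_equal(rep_het$components$luminal, 8)
  expect_equal(rep_het$components$basal, 8)
  # salt-and-pepper: all components are singletons
  chk <- (rep(0:3, 4) + rep(0:3, each = 4)) %% 2
  sp <- tp(ifelse(chk == 0, 0.9, 0.1), row = rep(0:3, 4),
           col = rep(0:3, each = 4))
  rep_sp <- detect_heterogeneity(build_prediction_map(sp),
                                 min_component_fraction = 0.2)
  expect_false(rep_sp$is_candidate)
  expect_true(all(rep_sp$components$luminal == 1))
})

test_that("component sizes match the flood-fill oracle on random maps", {
  set.seed(77)
  for (i in 1:10) {
    n <- 20
    keep <- runif(n * n) < 0.45
    rows <- rep(seq_len(n), n)[keep]
    cols <- rep(seq_len(n), each = n)[keep]
    got <- histotype:::grid_components(rows, cols)
    expect_identical(got, oracle_components(rows, cols))
  }
})

test_that("a heterogeneous pseudo-slide maps into two contiguous regions", {
  sl <- gen_pseudo_slide(pseudo_slide_params(width = 2048, height = 1024,
                                             layout = "heterogeneous",
                                             seed = 31))
  # oracle probabilities from ground truth stand in for a trained model
  truth <- sl$truth
  p <- data.frame(slide_id = "s", grid_row = truth$grid_row,
                  grid_col = truth$grid_col,
                  p_luminal = ifelse(truth$label == "luminal", 0.95, 0.05))
  p$p_basal <- 1 - p$p_luminal
  rep_het <- detect_heterogeneity(build_prediction_map(p))
  expect_true(rep_het$is_candidate)
  expect_length(rep_het$components$luminal, 1)
  expect_length(rep_het$components$basal, 1)
})
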