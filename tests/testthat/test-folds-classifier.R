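toy_manifest <- function(n_patients, tiles_per_patient = 2,
                         labels = NULL) {
  pid <- sprintf("P%02d", seq_len(n_patients))
  if (is.null(labels))
    labels <- rep(c("luminal", "basal"), length.out = n_patients)
  data.frame(
    slide_id = rep(pid, each = tiles_per_patient),
    patient_id = rep(pid, each = tiles_per_patient),
    label = rep(labels, each = tiles_per_patient),
    stringsAsFactors = FALSE)
}

test_that("fold sizes are near-equal with the remainder up front", {
  p9 <- plan_folds(toy_manifest(9), 3, 1, seed = 1)
  expect_equal(unname(table(p9$assignment[, 1])), c(3, 3, 3),
               ignore_attr = TRUE)
  p10 <- plan_folds(toy_manifest(10), 3, 1, seed = 1)
  expect_equal(sort(unname(table(p10$assignment[, 1])), decreasing = TRUE),
               c(4, 3, 3), ignore_attr = TRUE)
  expect_error(plan_folds(toy_manifest(2), 3, 1, seed = 1), "fewer patients")
})

test_that("validation folds partition the patients in every repetition", {
  m <- toy_manifest(17)
  plan <- plan_folds(m, 3, 3, seed = 9)
  for (rep in 1:3) {
    folds <- lapply(1:3, function(f) validation_patients(plan, rep, f))
    expect_setequal(unlist(folds), unique(m$patient_id))
    expect_equal(sum(lengths(folds)), 17)   # pairwise disjoint
  }
})

test_that("plans are bit-identical for identical patients and seed", {
  m <- toy_manifest(12)
  p1 <- plan_folds(m, 3, 2, seed = 33)
  p2 <- plan_folds(m[sample(nrow(m)), ], 3, 2, seed = 33)  # row order moot
  expect_identical(p1$assignment, p2$assignment)
  p3 <- plan_folds(m, 3, 2, seed = 34)
  expect_false(identical(p1$assignment, p3$assignment))
})

test_that("fold plans survive a JSON round trip", {
  plan <- plan_folds(toy_manifest(8), 2, 2, seed = 5)
  path <- file.path(tempdir(), "plan.json")
  write_fold_plan(plan, path)
  back <- read_fold_plan(path)
  expect_equal(back$assignment, plan$assignment, ignore_attr = TRUE)
  expect_equal(back$patients, plan$patients)
})

test_that("manifest validation catches inconsistent slides", {
  m <- toy_manifest(4)
  m$label[1] <- "basal"                     # same slide, two labels
  expect_error(plan_folds(m, 2, 1, seed = 1), "more than one")
})

test_that("balancing equalizes class counts without inventing rows", {
  m <- toy_manifest(16, tiles_per_patient = 25,
                    labels = rep(c("luminal", "basal"), c(10, 6)))
  bal <- balance_training_tiles(m, seed = 3)
  expect_equal(unname(table(bal$label)), c(150, 150), ignore_attr = TRUE)
  keys <- paste(m$patient_id, ave(seq_len(nrow(m)), m$patient_id,
                                  FUN = seq_along))
  expect_true(all(rownames(bal) %in% rownames(m)))
  expect_identical(bal, balance_training_tiles(m, seed = 3))  # deterministic
  expect_false(identical(bal, balance_training_tiles(m, seed = 4)))
  already <- toy_manifest(4, tiles_per_patient = 5)
  expect_identical(balance_training_tiles(already, 1), already)
  single <- toy_manifest(4, labels = rep("luminal", 4))
  expect_error(balance_training_tiles(single, 1), "single class")
})

test_that("the tiny backbone learns separable textures and is seeded", {
  slides <- list(
    gen_pseudo_slide(pseudo_slide_params(1024, 1024, "luminal", seed = 21,
                                         tile_edge = 128)),
    gen_pseudo_slide(pseudo_slide_params(1024, 1024, "basal", seed = 22,
                                         tile_edge = 128)))
  tiles <- list(); labels <- character()
  for (sl in slides) {
    specs <- tessellate(sl$image, sl$annotation, 128, 0.5)
    tiles <- c(tiles, lapply(seq_len(nrow(specs)),
                             function(i) extract_tile(sl$image, specs[i, ])))
    labels <- c(labels, rep(sl$params$layout, nrow(specs)))
  }
  rows <- data.frame(label = labels, stringsAsFactors = FALSE)
  feats <- featurize_tiles(tiles, backbone_spec())
  cfg <- train_config(epochs = 3, seed = 17)
  model <- tile_classifier(rows, features = feats, config = cfg)
  expect_gte(tail(model$log$accuracy, 1), 0.9)
  expect_lt(tail(model$log$loss, 1), model$log$loss[1])
  # determinism: identical seed, identical predictions
  model2 <- tile_classifier(rows, features = feats, config = cfg)
  p1 <- predict_tiles(model, feats, features = TRUE)
  p2 <- predict_tiles(model2, feats, features = TRUE)
  expect_identical(p1, p2)
  # probabilities normalize and duplicated tiles predict identically
  expect_true(all(abs(p1$p_luminal + p1$p_basal - 1) < 1e-6))
  expect_identical(p1[1, ], predict_tiles(model, feats[c(1, 1), ,
                                                       drop = FALSE],
                                          features = TRUE)[2, ],
                   ignore_attr = TRUE)
  # trained model separates the classes on average
  lum <- labels == "luminal"
  expect_gt(mean(p1$p_luminal[lum]), mean(p1$p_basal[lum]))
  expect_gt(mean(p1$p_basal[!lum]), mean(p1$p_luminal[!lum]))
})

test_that("an untrained model predicts near one half everywhere", {
  rows <- data.frame(label = rep(c("luminal", "basal"), 8))
  feats <- matrix(runif(16 * 768), 16)
  model <- tile_classifier(rows, features = feats,
                           config = train_config(epochs = 0))
  p <- predict_tiles(model, feats, features = TRUE)
  expect_true(all(abs(p$p_luminal - 0.5) < 0.05))
})

test_that("dihedral augmentation expands features eightfold", {
  rows <- data.frame(label = rep(c("luminal", "basal"), 4))
  feats <- matrix(runif(8 * 768), 8)
  m <- tile_classifier(rows, features = feats,
                       config = train_config(epochs = 1, augment = TRUE))
  expect_equal(m$n_train, 64)
})

test_that("unknown backbones and label sets are rejected", {
  expect_error(backbone_spec("resnet50"), "unknown backbone")
  rows <- data.frame(label = c("luminal", "indifferent"))
  expect_error(tile_classifier(rows, features = matrix(0, 2, 768)),
               "indifferent")
})
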