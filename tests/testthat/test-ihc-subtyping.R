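make_measurements <- function(values) {
  # values: named list patient -> named marker vector or per-core matrix
  do.call(rbind, lapply(names(values), function(p) {
    v <- values[[p]]
    if (is.null(dim(v))) v <- matrix(v, 1, dimnames = list(NULL, names(v)))
    do.call(rbind, lapply(seq_len(nrow(v)), function(core)
      data.frame(patient_id = p, core_id = core,
                 marker = colnames(v), h_score = unname(v[core, ]),
                 stringsAsFactors = FALSE)))
  }))
}

full_panel <- function(per_core) {
  m <- matrix(per_core, nrow = length(per_core), ncol = 6)
  colnames(m) <- hscore_markers()
  m
}

test_that("core aggregation takes per-marker medians and keeps order", {
  meas <- make_measurements(list(
    Pb = full_panel(c(100, 200, 150, 300)),
    Pa = full_panel(50),
    Pz = full_panel(c(0, 0, 0, 0))))
  m <- aggregate_cores(meas)
  expect_identical(rownames(m), c("Pb", "Pa", "Pz"))  # first-appearance order
  expect_equal(unname(m["Pb", ]), rep(175, 6))
  expect_equal(unname(m["Pa", ]), rep(50, 6))
  expect_equal(unname(m["Pz", ]), rep(0, 6))
})

test_that("aggregation errors name the patient and marker with no cores", {
  meas <- make_measurements(list(Pa = full_panel(c(10, 20))))
  meas <- meas[meas$marker != "GATA3" | meas$patient_id != "Pa", ]
  expect_error(aggregate_cores(meas), "Pa.*GATA3")
})

test_that("measurement validation rejects malformed tables", {
  meas <- make_measurements(list(Pa = full_panel(c(10, 20))))
  bad <- meas; bad$h_score[1] <- 301
  expect_error(aggregate_cores(bad), "\\[0, 300\\]")
  bad <- meas; bad$marker[1] <- "KRT77"
  expect_error(aggregate_cores(bad), "unknown marker")
  expect_error(aggregate_cores(rbind(meas, meas[1, ])), "duplicated")
})

test_that("duplicating every core of a patient leaves the median unchanged", {
  meas <- make_measurements(list(Pa = full_panel(c(10, 80, 120))))
  m1 <- aggregate_cores(meas)
  dup <- meas; dup$core_id <- dup$core_id + 10
  m2 <- aggregate_cores(rbind(meas, dup))
  expect_equal(m1, m2)
})

test_that("standardization yields exact column z-scores", {
  m <- cbind(matrix(c(0, 300), 2, 1), matrix(c(10, 20), 2, 5))
  colnames(m) <- hscore_markers()
  z <- standardize(m)
  expect_equal(unname(z[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(standardize(z)[, 1]), unname(z[, 1]),
               tolerance = 1e-9)   # idempotent on z-scores
})

test_that("standardized synthetic cohort has zero-mean unit-SD columns", {
  coh <- gen_hscore_cohort(hscore_sim_params(
    n_per_subtype = c(luminal = 80, basal = 42, indifferent = 41),
    seed = 11))
  z <- standardize(aggregate_cores(coh$measurements))
  expect_equal(nrow(z), 163)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
})

test_that("zero-variance markers abort standardization", {
  m <- full_panel(c(10, 20, 30)); m[, "CD44"] <- 7
  expect_error(standardize(m), "zero-variance.*CD44")
})

test_that("clustering recovers planted subtypes and names them correctly", {
  coh <- gen_hscore_cohort(hscore_sim_params(n_per_subtype = 30, seed = 7))
  fit <- ihc_subtype(coh$measurements, k = 3)
  expect_s3_class(fit, "ihc_subtype")
  agreement <- mean(as.character(fit$label) == coh$truth$label)
  expect_gte(agreement, 0.95)
  expect_identical(fit$linkage, "ward.D2")
  expect_identical(fit$distance, "euclidean")
  expect_setequal(fit$cluster_labels, c("luminal", "basal", "indifferent"))
})

test_that("the centroid rule is forced on a two-patient mirrored pair", {
  m <- rbind(A = c(-1, -1, -1, 2, 2, 2), B = c(2, 2, 2, -1, -1, -1))
  colnames(m) <- hscore_markers()     # basal markers first, then luminal
  fit <- ihc_subtype(m, k = 2)
  expect_identical(as.character(fit$label[["A"]]), "luminal")
  expect_identical(as.character(fit$label[["B"]]), "basal")
})

test_that("subtype labels are invariant to patient order", {
  coh <- gen_hscore_cohort(hscore_sim_params(n_per_subtype = 12, seed = 5))
  fit1 <- ihc_subtype(coh$measurements)
  perm <- with(coh, measurements[order(rev(measurements$patient_id)), ])
  fit2 <- ihc_subtype(perm)
  a1 <- subtype_assignments(fit1); a2 <- subtype_assignments(fit2)
  expect_identical(a1$label, a2$label[match(a1$patient_id, a2$patient_id)])
})

test_that("assignments round-trip through the CSV writer with metadata", {
  coh <- gen_hscore_cohort(hscore_sim_params(n_per_subtype = 8, seed = 2))
  fit <- ihc_subtype(coh$measurements)
  path <- file.path(tempdir(), "subtypes.csv")
  write_subtypes(fit, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$label, subtype_assignments(fit)$label)
  meta <- jsonlite::fromJSON(sub("csv$", "json", path))
  expect_identical(meta$linkage, "ward.D2")
  expect_identical(meta$k, 3L)
})
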