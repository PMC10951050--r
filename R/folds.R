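#' Patient-level repeated cross-validation plans
#'
#' Splits patients (never tiles) into \code{n_folds} near-equal validation
#' sets, independently for each of \code{n_repetitions} repetitions, so that
#' no patient contributes tiles to both the training and validation side of
#' any split.  Plans are a pure function of the patient set and the seed:
#' identical inputs give bit-identical plans regardless of manifest row
#' order.
#'
#' @param manifest Data frame with columns \code{slide_id},
#'   \code{patient_id}, \code{label} (one row per tile; a
#'   \code{tile_path}/feature reference column is allowed and ignored here).
#' @param n_folds Number of folds (default 3).
#' @param n_repetitions Number of repetitions (default 3).
#' @param seed Integer seed.
#' @param stratify Stratify the split by slide label (default \code{FALSE},
#'   plain patient-level randomization).  With few patients per class,
#'   stratification guards against training folds that lack a class, which
#'   would invalidate the plan.
#' @return A \code{"fold_plan"}: list with \code{patients},
#'   \code{assignment} (patients x repetitions integer matrix of fold
#'   indices), \code{n_folds}, \code{n_repetitions}, \code{seed},
#'   \code{stratify}.
#' @export
plan_folds <- function(manifest, n_folds = 3, n_repetitions = 3, seed,
                       stratify = FALSE) {
  validate_manifest(manifest)
  patients <- sort(unique(manifest$patient_id), method = "radix")
  if (length(patients) < n_folds)
    stop("fewer patients (", length(patients), ") than folds (", n_folds, ")")
  pat_label <- manifest$label[match(patients, manifest$patient_id)]
  assignment <- matrix(NA_integer_, length(patients), n_repetitions,
                       dimnames = list(patients, NULL))
  for (rep in seq_len(n_repetitions)) {
    rep_seed <- derive_seed(seed, rep)
    groups <- if (stratify) split(seq_along(patients), pat_label)
              else list(seq_along(patients))
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      ord <- with_seed((rep_seed + 104729 * gi) %% 2147483647,
                       idx[sample.int(length(idx))])
      sizes <- fold_sizes(length(ord), n_folds)
      assignment[ord, rep] <- rep.int(seq_len(n_folds), sizes)
    }
  }
  structure(list(patients = patients, assignment = assignment,
                 n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 seed = seed, stratify = stratify),
            class = "fold_plan")
}

# Near-equal fold sizes; the remainder goes to the earliest folds.
fold_sizes <- function(n, k) {
  base <- n %/% k
  base + as.integer(seq_len(k) <= n %% k)
}

# Deterministic sub-seed for (seed, repetition), kept below 2^31.
derive_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) * 7919 + rep * 15485863) %% 2147483647)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

validate_manifest <- function(manifest) {
  need <- c("slide_id", "patient_id", "label")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  per_slide <- unique(manifest[, c("slide_id", "patient_id", "label")])
  if (anyDuplicated(per_slide$slide_id))
    stop("a slide_id maps to more than one patient or label")
  tp <- manifest$tile_path[!is.na(manifest$tile_path)]
  if (length(tp) && anyDuplicated(tp))
    stop("duplicated tile_path in manifest")
  invisible(manifest)
}

#' Patients or tile rows of one validation fold
#'
#' @param plan A \code{"fold_plan"}.
#' @param repetition,fold 1-based repetition and fold indices.
#' @return \code{validation_patients()}: character vector.
#'   \code{fold_rows()}: list with \code{train} and \code{validation} row
#'   indices into \code{manifest}.
#' @export
validation_patients <- function(plan, repetition, fold) {
  stopifnot(inherits(plan, "fold_plan"))
  plan$patients[plan$assignment[, repetition] == fold]
}

#' @rdname validation_patients
#' @param manifest Tile manifest the plan was built from.
#' @export
fold_rows <- function(plan, manifest, repetition, fold) {
  val <- validation_patients(plan, repetition, fold)
  is_val <- manifest$patient_id %in% val
  list(train = which(!is_val), validation = which(is_val))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Patient-level CV plan: ", length(x$patients), " patients, ",
      x$n_folds, " folds x ", x$n_repetitions, " repetition(s), seed ",
      x$seed, if (x$stratify) ", stratified" else "", "\n", sep = "")
  invisible(x)
}

#' Serialize / read a fold plan as JSON
#'
#' @param plan A \code{"fold_plan"}.
#' @param path JSON path.
#' @return \code{path} (write) or a \code{"fold_plan"} (read).
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(
    list(patients = plan$patients,
         assignment = unname(split(plan$assignment,
                                   col(plan$assignment))),
         n_folds = plan$n_folds, n_repetitions = plan$n_repetitions,
         seed = plan$seed, stratify = plan$stratify),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::fromJSON(path)
  a <- x$assignment                     # simplified to a matrix or vector
  assignment <- if (is.list(a)) do.call(cbind, a)
                else if (is.matrix(a)) t(a) else cbind(a)
  dimnames(assignment) <- list(x$patients, NULL)
  structure(list(patients = x$patients, assignment = assignment,
                 n_folds = x$n_folds, n_repetitions = x$n_repetitions,
                 seed = x$seed, stratify = x$stratify),
            class = "fold_plan")
}

#' Equalize per-class tile counts in a training set
#'
#' Downsamples every class, without replacement, to the minority-class tile
#' count, so the classifier does not learn the cohort's class imbalance.
#' Validation rows are never balanced.  Deterministic under \code{seed}; the
#' result is always a subset of the input rows, in their original order.
#'
#' @param train_rows Manifest rows of the training split (must contain a
#'   \code{label} column with at least two classes present).
#' @param seed Integer seed.
#' @return Subset of \code{train_rows} with equal class counts.
#' @export
balance_training_tiles <- function(train_rows, seed) {
  counts <- table(as.character(train_rows$label))
  if (length(counts) < 2)
    stop("training fold contains a single class; plan invalid ",
         "(re-seed or stratify the split)")
  m <- min(counts)
  keep <- with_seed(derive_seed(seed, 424243L), {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(train_rows$label == cl)
      if (length(idx) > m) sort(idx[sample.int(length(idx), m)]) else idx
    }))
  })
  train_rows[sort(keep), , drop = FALSE]
}
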