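#' Marker panels for protein-based urothelial subtyping
#'
#' Six immunohistochemical differentiation markers of the urothelium define
#' the subtyping panel: three luminal (CK20, FOXA1, GATA3) and three basal
#' (CD44, CK5, CK14).  H-scores are semiquantitative in \[0, 300\],
#' proportional to staining intensity and the fraction of positive cells.
#'
#' @return Character vector of marker names.
#' @export
luminal_markers <- function() c("CK20", "FOXA1", "GATA3")

#' @rdname luminal_markers
#' @export
basal_markers <- function() c("CD44", "CK5", "CK14")

#' @rdname luminal_markers
#' @export
hscore_markers <- function() c(basal_markers(), luminal_markers())

# Validate a long-format H-score table (patient_id, core_id, marker, h_score).
validate_hscores <- function(x) {
  need <- c("patient_id", "core_id", "marker", "h_score")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("H-score table lacks column(s): ", paste(miss, collapse = ", "))
  x$patient_id <- as.character(x$patient_id)
  x$marker <- as.character(x$marker)
  x$h_score <- as.numeric(x$h_score)
  bad <- !x$marker %in% hscore_markers()
  if (any(bad))
    stop("unknown marker(s): ", paste(unique(x$marker[bad]), collapse = ", "))
  if (any(!is.finite(x$h_score)) || any(x$h_score < 0 | x$h_score > 300))
    stop("h_score values must be finite and within [0, 300]")
  key <- paste(x$patient_id, x$core_id, x$marker, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (patient, core, marker) measurement(s)")
  x
}

#' Read a long-format H-score CSV
#'
#' Expects columns \code{patient_id}, \code{core_id}, \code{marker},
#' \code{h_score}; one row per tissue-microarray core measurement.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame of measurements.
#' @export
read_hscores <- function(path) {
  validate_hscores(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Aggregate per-core H-scores to a patient-by-marker matrix
#'
#' Each patient's expression of a marker is the median H-score across that
#' patient's available tissue-microarray cores (typically four).  Patients
#' keep their order of first appearance in the input.
#'
#' @param measurements Data frame with columns \code{patient_id},
#'   \code{core_id}, \code{marker}, \code{h_score}.
#' @return Numeric matrix, patients x 6 markers, of core-median H-scores.
#' @export
aggregate_cores <- function(measurements) {
  m <- validate_hscores(measurements)
  patients <- unique(m$patient_id)
  markers <- hscore_markers()
  out <- matrix(NA_real_, length(patients), length(markers),
                dimnames = list(patients, markers))
  med <- stats::aggregate(h_score ~ patient_id + marker, data = m,
                          FUN = stats::median)
  out[cbind(match(med$patient_id, patients), match(med$marker, markers))] <-
    med$h_score
  if (anyNA(out)) {
    idx <- which(is.na(out), arr.ind = TRUE)[1, ]
    stop("patient '", patients[idx[1]], "' has no core measurement for marker '",
         markers[idx[2]], "'")
  }
  out
}

#' Standardize a marker matrix to per-marker z-scores
#'
#' Centers and scales each marker column to mean 0 and sample standard
#' deviation 1, so clustering weighs markers equally regardless of their raw
#' dynamic range.
#'
#' @param matrix Patients x markers numeric matrix (see
#'   \code{\link{aggregate_cores}}).
#' @return Matrix of the same shape holding z-scores.
#' @export
standardize <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 2)
    stop("standardization needs a matrix with at least 2 patients")
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance marker column(s): ",
         paste(colnames(matrix)[sds == 0], collapse = ", "),
         " (subtyping undefined)")
  scale(matrix, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Protein-based subtyping by hierarchical clustering of H-scores
#'
#' Fits the protein-based subtype model: per-core H-scores are aggregated to
#' patient-level core medians, standardized per marker, and clustered by
#' agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distance).  The tree is cut into \code{k} clusters, which are then named
#' by a centroid rule: with \eqn{L(c)} the mean z-score of the luminal
#' markers (CK20, FOXA1, GATA3) and \eqn{B(c)} of the basal markers (CD44,
#' CK5, CK14) in cluster \eqn{c}, the cluster maximizing \eqn{L - B} is
#' \emph{luminal}, the cluster maximizing \eqn{B - L} is \emph{basal}, and
#' (for \code{k = 3}) the remaining cluster, typically with low expression of
#' both panels, is \emph{indifferent}.
#'
#' @param x Either a long-format measurement data frame (columns
#'   \code{patient_id}, \code{core_id}, \code{marker}, \code{h_score}) or an
#'   already aggregated patients x markers matrix.
#' @param k Number of clusters, 2 or 3 (default 3).
#' @return An object of class \code{"ihc_subtype"} with components
#'   \code{matrix} (core medians), \code{z} (standardized matrix),
#'   \code{hclust}, \code{cluster} (integer cluster index per patient),
#'   \code{label} (factor with levels luminal/basal/indifferent),
#'   \code{centroids}, \code{cluster_labels}, and metadata (\code{linkage},
#'   \code{distance}, \code{k}, \code{marker_sets}).
#' @examples
#' coh <- gen_hscore_cohort(hscore_sim_params(n_per_subtype = 10, seed = 1))
#' fit <- ihc_subtype(coh$measurements, k = 3)
#' table(subtype_assignments(fit)$label, coh$truth$label)
#' @export
ihc_subtype <- function(x, k = 3) {
  if (!k %in% 2:3) stop("k must be 2 or 3")
  mat <- if (is.matrix(x)) x else aggregate_cores(x)
  if (nrow(mat) < k) stop("need at least k patients")
  z <- standardize(mat)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  centroids <- t(vapply(seq_len(k),
                        function(c) colMeans(z[cl == c, , drop = FALSE]),
                        numeric(ncol(z))))
  colnames(centroids) <- colnames(z)
  L <- rowMeans(centroids[, luminal_markers(), drop = FALSE])
  B <- rowMeans(centroids[, basal_markers(), drop = FALSE])
  i_lum <- which.max(L - B)   # which.max breaks ties at the lower index
  i_bas <- which.max(B - L)
  if (i_lum == i_bas)
    stop("centroid rule is degenerate: one cluster maximizes both ",
         "luminal-basal contrasts; manual review required")
  cluster_labels <- rep("indifferent", k)
  cluster_labels[i_lum] <- "luminal"
  cluster_labels[i_bas] <- "basal"
  label <- factor(cluster_labels[cl],
                  levels = c("luminal", "basal", "indifferent"))
  structure(list(
    matrix = mat, z = z, hclust = hc,
    cluster = stats::setNames(as.integer(cl), rownames(mat)),
    label = stats::setNames(label, rownames(mat)),
    centroids = centroids, cluster_labels = cluster_labels,
    k = k, linkage = "ward.D2", distance = "euclidean",
    marker_sets = list(luminal = luminal_markers(), basal = basal_markers()),
    call = match.call()
  ), class = "ihc_subtype")
}

#' Per-patient subtype assignments from a fitted subtype model
#'
#' @param fit An \code{\link{ihc_subtype}} fit.
#' @return Data frame with columns \code{patient_id}, \code{cluster_index},
#'   \code{label}.
#' @export
subtype_assignments <- function(fit) {
  stopifnot(inherits(fit, "ihc_subtype"))
  data.frame(patient_id = names(fit$cluster),
             cluster_index = unname(fit$cluster),
             label = as.character(unname(fit$label)),
             stringsAsFactors = FALSE)
}

#' @export
print.ihc_subtype <- function(x, ...) {
  cat("Protein-based subtype model (hierarchical clustering)\n")
  cat("  patients:", nrow(x$matrix), " markers:", ncol(x$matrix), "\n")
  cat("  linkage:", x$linkage, " distance:", x$distance, " k:", x$k, "\n")
  tab <- table(x$label)
  cat("  subtypes:",
      paste(sprintf("%s %d (%.1f%%)", names(tab), tab,
                    100 * tab / length(x$label)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ihc_subtype <- function(object, ...) {
  out <- list(counts = table(object$label),
              shares = 100 * table(object$label) / length(object$label),
              centroids = object$centroids,
              cluster_labels = object$cluster_labels,
              k = object$k, linkage = object$linkage,
              distance = object$distance)
  class(out) <- "summary.ihc_subtype"
  out
}

#' @export
print.summary.ihc_subtype <- function(x, ...) {
  cat("Subtype counts:\n")
  print(x$counts)
  cat("\nCluster centroids (marker z-scores):\n")
  rownames(x$centroids) <- paste0(seq_len(x$k), " (", x$cluster_labels, ")")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Heatmap of standardized marker expression ordered by the clustering
#'
#' @param x An \code{\link{ihc_subtype}} fit.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.ihc_subtype <- function(x, ...) {
  ord <- x$hclust$order
  z <- x$z[ord, , drop = FALSE]
  lab <- x$label[ord]
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  lim <- max(abs(z))
  op <- graphics::par(mar = c(5, 6, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, zlim = c(-lim, lim),
                  col = pal, xlab = "patients (tree order)", ylab = "",
                  yaxt = "n", main = "Standardized H-scores", ...)
  graphics::axis(2, at = seq_len(ncol(z)), labels = colnames(z), las = 1)
  band <- c(luminal = "#B2182B", basal = "#2166AC", indifferent = "#4DAF4A")
  graphics::rect(seq_len(nrow(z)) - 0.5, ncol(z) + 0.35,
                 seq_len(nrow(z)) + 0.5, ncol(z) + 0.5,
                 col = band[as.character(lab)], border = NA, xpd = NA)
  invisible(x)
}

#' Write subtype assignments and a metadata sidecar
#'
#' Writes \code{patient_id, cluster_index, label} as CSV and the clustering
#' metadata (linkage, distance, k, marker sets) as a JSON sidecar next to it.
#'
#' @param fit An \code{\link{ihc_subtype}} fit.
#' @param path Output CSV path; the sidecar replaces the extension with
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_subtypes <- function(fit, path) {
  utils::write.csv(subtype_assignments(fit), path, row.names = FALSE)
  meta <- list(linkage = fit$linkage, distance = fit$distance, k = fit$k,
               luminal_markers = fit$marker_sets$luminal,
               basal_markers = fit$marker_sets$basal)
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
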