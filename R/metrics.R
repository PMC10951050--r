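#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the pair statistic
#' \deqn{AUROC = (\#\{pos > neg\} + 0.5\,\#\{pos = neg\}) / (n_{pos} n_{neg})}
#' via midranks.  By convention the basal subtype is the positive class.
#'
#' @param scores Numeric prediction scores for the positive class.
#' @param labels Vector of class labels aligned with \code{scores}.
#' @param positive Label value treated as positive (default \code{"basal"}).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels, positive = "basal") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC needs both a positive and a negative example")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics for slide-level predictions
#'
#' Accuracy, precision, recall and F1 with the basal subtype as positive
#' class (matching the AUROC convention), plus AUROC when scores are given.
#' \code{average = "macro"} instead averages per-class precision/recall/F1
#' over the two classes.
#'
#' @param truth,predicted Label vectors (\code{"luminal"}/\code{"basal"}).
#' @param scores Optional positive-class scores for AUROC.
#' @param positive Positive class (default \code{"basal"}).
#' @param average \code{"binary"} or \code{"macro"}.
#' @return Named list of metrics in \[0, 1\].
#' @export
classification_metrics <- function(truth, predicted, scores = NULL,
                                   positive = "basal",
                                   average = c("binary", "macro")) {
  average <- match.arg(average)
  stopifnot(length(truth) == length(predicted))
  prf <- function(pos) {
    tp <- sum(truth == pos & predicted == pos)
    fp <- sum(truth != pos & predicted == pos)
    fn <- sum(truth == pos & predicted != pos)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0))
      2 * precision * recall / (precision + recall) else NA_real_
    c(precision = precision, recall = recall, f1 = f1)
  }
  m <- if (average == "binary") prf(positive)
       else rowMeans(cbind(prf(positive),
                           prf(setdiff(c("luminal", "basal"), positive))),
                     na.rm = TRUE)
  out <- list(accuracy = mean(truth == predicted),
              precision = unname(m["precision"]),
              recall = unname(m["recall"]), f1 = unname(m["f1"]))
  if (!is.null(scores))
    out <- c(list(auroc = auroc(scores, truth, positive)), out)
  out
}

#' Summarize per-fold metrics with Student-t confidence intervals
#'
#' For each metric column, reports the mean across the K validation folds of
#' one repetition and the 95 percent confidence interval
#' \eqn{\bar{x} \pm t_{0.975, K-1}\, s / \sqrt{K}} based on Student's
#' t-distribution (for K = 3 the multiplier is about 4.30265).
#'
#' @param folds Data frame with one row per fold; every numeric column
#'   except \code{repetition}/\code{fold} is summarized.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame \code{metric, mean, ci_low, ci_high, k}.
#' @export
summarize_fold_metrics <- function(folds, conf_level = 0.95) {
  k <- nrow(folds)
  if (k < 2) stop("need at least 2 folds to form a confidence interval")
  cols <- setdiff(names(folds)[vapply(folds, is.numeric, logical(1))],
                  c("repetition", "fold"))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = k - 1)
  do.call(rbind, lapply(cols, function(cl) {
    x <- folds[[cl]]
    hw <- tq * stats::sd(x) / sqrt(k)
    data.frame(metric = cl, mean = mean(x), ci_low = mean(x) - hw,
               ci_high = mean(x) + hw, k = k, stringsAsFactors = FALSE)
  }))
}

#' Confusion matrix concatenated over validation folds
#'
#' Assembles the repetition-level confusion matrix by pooling every
#' validation fold's slide predictions; each slide must be predicted exactly
#' once (a slide appearing twice indicates split leakage).  Also reports the
#' per-class true-positive rate (diagonal over row sum), \code{NA} for an
#' empty class row.
#'
#' @param fold_predictions Data frame with columns \code{slide_id},
#'   \code{truth}, \code{predicted} (pooled rows of all folds).
#' @param classes Class levels (default luminal, basal).
#' @return A \code{"confusion_matrix"}: list with \code{table} (true x
#'   predicted counts) and \code{tpr}.
#' @export
confusion_concat <- function(fold_predictions,
                             classes = c("luminal", "basal")) {
  fp <- fold_predictions
  stopifnot(all(c("slide_id", "truth", "predicted") %in% names(fp)))
  if (anyDuplicated(fp$slide_id))
    stop("slide predicted in more than one fold (split leakage): ",
         fp$slide_id[duplicated(fp$slide_id)][1])
  tab <- table(factor(fp$truth, classes), factor(fp$predicted, classes),
               dnn = c("true", "predicted"))
  rs <- rowSums(tab)
  tpr <- ifelse(rs > 0, diag(tab) / rs, NA_real_)
  structure(list(table = tab, tpr = tpr), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$table)
  cat("\nPer-class true-positive rate:\n")
  print(round(100 * x$tpr, 1))
  invisible(x)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact hypergeometric enumeration over all tables with the observed
#' margins.  The two-sided p-value sums the probabilities of every table no
#' more probable than the observed one (with 1e-12 slack for floating-point
#' ties); \code{"greater"}/\code{"less"} sum the upper/lower tail of the
#' top-left cell.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @param alternative \code{"two_sided"}, \code{"greater"} or \code{"less"}.
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- as.matrix(table)
  if (!all(dim(m) == 2) || any(m < 0) || any(m != round(m)))
    stop("need a 2 x 2 table of non-negative integer counts")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n)
    stop("zero margin: Fisher's exact test undefined")
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  a <- m[1, 1]
  p_obs <- probs[match(a, support)]
  p <- switch(alternative,
    two_sided = sum(probs[probs <= p_obs + 1e-12]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]))
  min(1, p)
}

#' Nonparametric rank tests for group comparisons
#'
#' Dispatches to the Wilcoxon rank-sum test (two independent groups), the
#' Kruskal-Wallis test (more than two groups) or the one-tailed Wilcoxon
#' signed-rank test (paired samples), using midranks for ties.  The
#' two-sample and paired tests use exact enumeration for sample sizes up to
#' 25 (when no ties are present) and the normal approximation otherwise;
#' zero paired differences are dropped.
#'
#' @param values Numeric vector; for \code{signed_rank_one_tailed} either a
#'   vector of paired differences or the first members of the pairs (then
#'   give \code{paired_with}).
#' @param groups Group labels for \code{rank_sum}/\code{kruskal_wallis}.
#' @param paired_with Second members of the pairs for the signed-rank test.
#' @param kind \code{"rank_sum"}, \code{"kruskal_wallis"} or
#'   \code{"signed_rank_one_tailed"}.
#' @param alternative Test direction for the two-sample test (default
#'   \code{"two.sided"}); the signed-rank test is one-tailed
#'   (\code{"greater"} on the differences) by construction.
#' @return List with \code{statistic}, \code{p_value}, \code{method}.
#' @export
rank_tests <- function(values, groups = NULL, paired_with = NULL,
                       kind = c("rank_sum", "kruskal_wallis",
                                "signed_rank_one_tailed"),
                       alternative = "two.sided") {
  kind <- match.arg(kind)
  if (kind == "signed_rank_one_tailed") {
    d <- if (is.null(paired_with)) values else values - paired_with
    d <- d[d != 0]
    if (!length(d)) stop("all paired differences are zero")
    ht <- suppressWarnings(stats::wilcox.test(
      d, alternative = "greater", exact = length(d) <= 25, correct = TRUE))
  } else {
    if (is.null(groups) || length(groups) != length(values))
      stop("groups must be given and aligned with values")
    split_vals <- split(values, groups)
    if (any(lengths(split_vals) == 0)) stop("empty group")
    if (kind == "kruskal_wallis") {
      ht <- stats::kruskal.test(values, factor(groups))
    } else {
      if (length(split_vals) != 2)
        stop("rank_sum needs exactly two groups")
      n <- length(values)
      ht <- suppressWarnings(stats::wilcox.test(
        split_vals[[1]], split_vals[[2]], alternative = alternative,
        exact = n <= 25, correct = TRUE))
    }
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}
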