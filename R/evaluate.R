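#' Format a rate as a percentage with one decimal place
#'
#' Truncates (rather than rounds) at the third significant decimal, the
#' convention used for the reported rates: 45/48 prints as 93.7, not
#' 93.8.
#'
#' @param frac A rate in \[0, 1\].
#' @return Character scalar, e.g. `"93.7"`.
#' @examples
#' format_percent(45 / 48)
#' @export
format_percent <- function(frac) {
  sprintf("%.1f", floor(1000 * frac + 1e-9) / 10)
}

#' Build a 3x3 confusion matrix
#'
#' Rows are the network's predicted label, columns the reference
#' ("visual assignment") label, both in the canonical order first_order,
#' erlang, split_peak.
#'
#' @param predicted,reference Label vectors (character or factor) of
#'   equal length, values among the three shape labels.
#' @return Integer 3x3 matrix of class `confusion_matrix`.
#' @examples
#' build_confusion(c("erlang", "erlang"), c("erlang", "first_order"))
#' @export
build_confusion <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must have equal length")
  }
  lv <- shape_levels()
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  bad <- setdiff(unique(c(predicted, reference)), lv)
  if (length(bad)) {
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  cm <- table(factor(predicted, levels = lv), factor(reference, levels = lv))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(predicted = lv, reference = lv))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Classification accuracy of a confusion matrix
#'
#' Number of correct predictions (the trace) over the total number of
#' evaluated profiles.
#'
#' @param cm A `confusion_matrix`.
#' @return Accuracy as a fraction.
#' @examples
#' accuracy_of(build_confusion(rep("erlang", 4), rep("erlang", 4)))
#' @export
accuracy_of <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' No-information (uninformative) rate
#'
#' The accuracy achievable by always predicting the most common reference
#' class: the largest column total divided by the grand total.
#'
#' @param cm A `confusion_matrix`.
#' @return No-information rate as a fraction.
#' @export
no_information_rate <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  max(colSums(cm)) / total
}

#' Exact binomial test of accuracy against chance
#'
#' One-sided upper-tail exact binomial probability of observing at least
#' `correct` successes in `total` trials when the success probability is
#' `p0` (typically the no-information rate) — the standard
#' accuracy-vs-chance comparison.
#'
#' @param correct Number of correct classifications.
#' @param total Number of classified profiles.
#' @param p0 Chance success probability, in (0, 1).
#' @return The p-value.
#' @examples
#' binomial_test_vs_chance(45, 48, 22 / 48)
#' @export
binomial_test_vs_chance <- function(correct, total, p0) {
  if (correct < 0 || total < 1 || correct > total) {
    stop("need 0 <= correct <= total with total >= 1")
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  stats::binom.test(correct, total, p = p0,
                    alternative = "greater")$p.value
}

#' Confidence summary of classifications
#'
#' For each probability threshold, counts correct and incorrect
#' assignments whose maximum class probability exceeds it, and returns
#' the full list of maximum probabilities for the incorrect assignments.
#'
#' @param predictions data.frame from [classify()] (three `p_*` columns
#'   plus `assigned`).
#' @param reference Reference label vector of the same length.
#' @param thresholds Probability thresholds (default `c(0.75, 0.9)`).
#' @return List with `counts` (data.frame: threshold, correct_above,
#'   incorrect_above), `max_prob`, `correct` (logical), and
#'   `incorrect_probs`.
#' @export
confidence_summary <- function(predictions, reference,
                               thresholds = c(0.75, 0.9)) {
  if (nrow(predictions) != length(reference)) {
    stop("predictions and reference must have equal length")
  }
  pm <- as.matrix(predictions[paste0("p_", shape_levels())])
  max_prob <- if (nrow(pm)) apply(pm, 1, max) else numeric(0)
  correct <- as.character(predictions$assigned) == as.character(reference)
  counts <- data.frame(
    threshold = thresholds,
    correct_above = vapply(thresholds, function(th)
      sum(correct & max_prob > th), integer(1)),
    incorrect_above = vapply(thresholds, function(th)
      sum(!correct & max_prob > th), integer(1)))
  list(counts = counts, max_prob = max_prob, correct = correct,
       incorrect_probs = max_prob[!correct])
}

#' Evaluate a trained network on a labeled dataset
#'
#' Computes the full performance report: confusion matrix, accuracy,
#' cross-entropy loss, no-information rate, the exact binomial test of
#' accuracy against the no-information rate, and the confidence summary
#' of maximum class probabilities.
#'
#' @param net A trained `mlp`.
#' @param ds A labeled `pk_dataset`.
#' @param thresholds Probability thresholds for [confidence_summary()].
#' @return An object of class `evaluation_report`.
#' @export
evaluate_model <- function(net, ds, thresholds = c(0.75, 0.9)) {
  feats <- assemble_features(ds)
  preds <- classify(net, feats$x)
  cm <- build_confusion(preds$assigned, feats$labels)
  acc <- accuracy_of(cm)
  nir <- no_information_rate(cm)
  structure(
    list(confusion = cm,
         n = sum(cm),
         accuracy = acc,
         loss = cross_entropy(as.matrix(preds[paste0("p_", shape_levels())]),
                              feats$y),
         no_information_rate = nir,
         binomial_p = binomial_test_vs_chance(sum(diag(cm)), sum(cm), nir),
         confidence = confidence_summary(preds, feats$labels, thresholds),
         predictions = preds),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation of %d profiles\n", x$n))
  cat(sprintf("  accuracy            %s%%\n", format_percent(x$accuracy)))
  cat(sprintf("  cross-entropy loss  %.4g\n", x$loss))
  cat(sprintf("  no-information rate %s%%\n",
              format_percent(x$no_information_rate)))
  cat(sprintf("  binomial p-value    %.3g\n", x$binomial_p))
  cat("Confusion matrix (rows = predicted, cols = reference):\n")
  print(unclass(x$confusion))
  invisible(x)
}
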