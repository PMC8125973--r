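#' Score training samples with their own model
#'
#' The sample-weighting method scores every *training* sample with the model
#' trained on that same training set. The default score is the model's
#' probability for the ground-truth class — samples with an observable,
#' learnable pain reaction get high scores, while no-response (noisy)
#' samples stay near chance. `score = "max_prob"` uses the top-1 probability
#' instead (the alternative reading; it also upweights confidently wrong
#' samples).
#'
#' @param model a trained `painface_model`.
#' @param inputs model inputs for the training samples (feature matrix or
#'   `list(images, pred)`).
#' @param labels ground-truth class codes of the training samples.
#' @param sample_ids ids naming the returned scores.
#' @param score `"true_class"` (default) or `"max_prob"`.
#' @return named numeric vector in `[0, 1]`.
#' @export
score_training_samples <- function(model, inputs, labels, sample_ids,
                                   score = c("true_class", "max_prob")) {
  score <- match.arg(score)
  p <- predict(model, inputs)
  labels <- as.character(labels)
  missing_cls <- setdiff(unique(labels), colnames(p))
  if (length(missing_cls))
    stop_arg("model has no score column for class(es): %s",
             paste(missing_cls, collapse = ", "))
  s <- if (score == "true_class")
    p[cbind(seq_along(labels), match(labels, colnames(p)))]
  else apply(p, 1, max)
  names(s) <- sample_ids
  s
}

#' Duplicate high-score training samples
#'
#' Every training sample whose classification score exceeds the threshold
#' (default 0.3, the study setting) appears exactly twice in the weighted
#' training set; all others once. The order of the weighted set is
#' reshuffled deterministically by `seed`. Test data are never touched.
#'
#' @param train_ids sample ids of the training set.
#' @param scores named scores covering `train_ids` (see
#'   [score_training_samples()]).
#' @param threshold scalar in `[0, 1]`.
#' @param seed shuffle seed.
#' @param score_source free-text note recorded in the plan.
#' @return list with `ids` (the weighted id vector) and `plan`, a
#'   `weighting_plan`: threshold, score_source, duplicated_ids, n_before,
#'   n_after.
#' @export
apply_weighting <- function(train_ids, scores, threshold = 0.3, seed = 1,
                            score_source = "model") {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop_arg("threshold must be in [0, 1]")
  miss <- setdiff(train_ids, names(scores))
  if (length(miss))
    stop_arg("scores missing for sample(s): %s",
             paste(head(miss, 10), collapse = ", "))
  dup <- train_ids[scores[train_ids] > threshold]
  ids <- c(train_ids, dup)
  ids <- with_local_seed(seed, sample(ids))
  plan <- structure(list(threshold = threshold, score_source = score_source,
                         duplicated_ids = dup,
                         n_before = length(train_ids),
                         n_after = length(ids)),
                    class = "weighting_plan")
  list(ids = ids, plan = plan)
}

#' @export
print.weighting_plan <- function(x, ...) {
  cat(sprintf(
    "weighting_plan: threshold %.2f, %d of %d samples duplicated -> %d\n",
    x$threshold, length(x$duplicated_ids), x$n_before, x$n_after))
  invisible(x)
}

#' Write / read a weighting plan as JSON
#' @param plan a `weighting_plan`.
#' @param path JSON path.
#' @export
write_weighting_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weighting_plan
#' @export
read_weighting_plan <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "weighting_plan")
}

#' Assert that weighting never touched the test set
#'
#' Passes iff the test set contains no duplicated sample ids and none of the
#' plan's duplicated ids occurs more than once anywhere; duplication is a
#' training-side operation only, so a duplicated id appearing in a fold's
#' test set would invalidate the comparison.
#'
#' @param plan a `weighting_plan`.
#' @param test_ids sample ids of the test set.
#' @return `TRUE` invisibly, or an error naming the offending ids.
#' @export
guard_test_integrity <- function(plan, test_ids) {
  dup_in_test <- unique(test_ids[duplicated(test_ids)])
  if (length(dup_in_test))
    stop_arg("test set contains duplicated sample id(s): %s",
             paste(head(dup_in_test, 10), collapse = ", "))
  invisible(TRUE)
}
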