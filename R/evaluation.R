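#' The seven classification tasks
#'
#' One 7-class task, two 5-class tasks (each modality keeps its severe
#' intensity plus either the low or the moderate one), and four 3-class
#' single-modality tasks. Baseline `B` is always included.
#'
#' @param name task name; see `names(pain_tasks())`.
#' @return `task_spec()`: a `task_spec` with `name` and `class_list`;
#'   `pain_tasks()`: named list of all seven.
#' @export
pain_tasks <- function() {
  defs <- list(
    "7class"       = class_codes(),
    "5class_low"   = c("B", "E1", "H1", "E3", "H3"),
    "5class_mod"   = c("B", "E2", "H2", "E3", "H3"),
    "3class_E_low" = c("B", "E1", "E3"),
    "3class_E_mod" = c("B", "E2", "E3"),
    "3class_H_low" = c("B", "H1", "H3"),
    "3class_H_mod" = c("B", "H2", "H3"))
  lapply(seq_along(defs), function(i)
    structure(list(name = names(defs)[i],
                   class_list = intersect(class_codes(), defs[[i]])),
              class = "task_spec")) |>
    stats::setNames(names(defs))
}

#' @rdname pain_tasks
#' @export
task_spec <- function(name) {
  tasks <- pain_tasks()
  if (!name %in% names(tasks))
    stop_arg("unknown task '%s'; available: %s", name,
             paste(names(tasks), collapse = ", "))
  tasks[[name]]
}

#' Subject-disjoint stratified fold assignment
#'
#' Greedily assigns whole subjects to `k` folds so that no subject's samples
#' cross a fold boundary and each fold's class proportions stay close to the
#' global proportions: subjects are visited in a seeded random order (larger
#' subjects first) and each goes to the fold where the resulting class-count
#' deviation — with a mild fold-size balance penalty — is smallest.
#'
#' @param manifest dataset manifest (needs subject_id and class).
#' @param k number of folds (default 5).
#' @param seed RNG seed; the plan is deterministic given seed.
#' @return a `fold_plan`: `k` and named vector `assignment`
#'   (subject id -> fold).
#' @export
make_folds <- function(manifest, k = 5, seed = 1) {
  subjects <- unique(manifest$subject_id)
  if (length(subjects) < k)
    stop_arg("need at least k = %d subjects, got %d", k, length(subjects))
  classes <- sort(unique(manifest$class))
  counts <- table(factor(manifest$subject_id, levels = subjects),
                  factor(manifest$class, levels = classes))
  gprop <- colSums(counts) / sum(counts)
  ord <- with_local_seed(seed, {
    sh <- sample(seq_along(subjects))
    sh[order(-rowSums(counts)[sh])]
  })
  fold_counts <- matrix(0, k, length(classes))
  fold_tot <- numeric(k)
  fold_nsub <- integer(k)
  assignment <- integer(length(subjects))
  for (i in ord) {
    v <- counts[i, ]
    # keep subject counts within 1 of each other: only the least-filled
    # folds are candidates, so no fold can starve
    cand <- which(fold_nsub == min(fold_nsub))
    obj <- vapply(cand, function(f) {
      tot <- fold_tot[f] + sum(v)
      sum(((fold_counts[f, ] + v) / tot - gprop)^2) +
        1e-3 * tot / sum(counts)
    }, 0)
    f <- cand[which.min(obj)]
    assignment[i] <- f
    fold_counts[f, ] <- fold_counts[f, ] + v
    fold_tot[f] <- fold_tot[f] + sum(v)
    fold_nsub[f] <- fold_nsub[f] + 1L
  }
  names(assignment) <- as.character(subjects)
  structure(list(k = k, assignment = assignment), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: k = %d, %d subjects (%s per fold)\n", x$k,
              length(x$assignment),
              paste(tabulate(x$assignment, x$k), collapse = "/")))
  invisible(x)
}

# Precompute the model inputs an architecture needs, once per dataset.
# For fusion kinds the prediction-image branch is filled per fold (it
# depends on a forest trained on that fold's training data).
prepare_inputs <- function(dataset, ids, arch, render_size = NULL) {
  idx <- match(ids, dataset$manifest$sample_id)
  samples <- dataset$samples[idx]
  out <- list()
  if (arch$kind %in% c("rfc_fad", "cnns_fusion", "mnv2_fusion"))
    out$fad <- t(vapply(samples, function(s) sample_features(s),
                        numeric(17 * 48)))
  if (arch$kind %in% c("rfc_bl", "cnns_fusion", "mnv2_fusion")) {
    side <- arch$image_side
    imgs <- array(0, dim = c(side, side, 3, length(samples)))
    for (i in seq_along(samples))
      imgs[, , , i] <- sample_spatiotemporal(samples[[i]], side = side,
                                             render_size = render_size)
    out$images <- imgs
  }
  if (!is.null(out$fad)) rownames(out$fad) <- ids
  out$ids <- ids
  out
}

pred_image_array <- function(class_idx, side) {
  arr <- array(0, dim = c(side, side, 1, length(class_idx)))
  for (i in seq_along(class_idx))
    arr[, , , i] <- encode_prediction(class_idx[i], side)
  arr
}

subset_inputs <- function(prep, arch, ids, pred_classes = NULL) {
  i <- match(ids, prep$ids)
  if (arch$kind == "rfc_fad") return(prep$fad[i, , drop = FALSE])
  if (arch$kind == "rfc_bl") {
    side <- dim(prep$images)[1]
    return(matrix(aperm(prep$images[, , , i, drop = FALSE], c(4, 1, 2, 3)),
                  nrow = length(i)))
  }
  list(images = prep$images[, , , i, drop = FALSE],
       pred = pred_image_array(pred_classes, arch$pred_side))
}

fit_one <- function(arch, inputs, labels, seed, n_trees, epochs) {
  if (arch$kind %in% c("rfc_fad", "rfc_bl"))
    train_forest(inputs, labels, n_trees = n_trees, seed = seed,
                 kind = arch$kind)
  else train_cnn(arch, inputs, labels, epochs = epochs, seed = seed)
}

#' Run stratified subject-disjoint cross-validation
#'
#' For each fold: fit the architecture on the training subjects (optionally
#' with sample-duplication weighting, which re-trains the model on the
#' weighted training set; test data are never duplicated), predict the
#' held-out subjects, and pool predictions. Fusion architectures get their
#' prediction-image branch from a random forest on FAD features trained
#' inside the fold's training data, so evaluation-side prediction images are
#' always out-of-sample. Subject disjointness and test-set integrity are
#' asserted on every fold.
#'
#' @param dataset a `pain_dataset`.
#' @param task a `task_spec` or task name.
#' @param arch an [architecture_spec()].
#' @param weighting apply the score-threshold duplication weighting.
#' @param threshold weighting score threshold (default 0.3).
#' @param seed RNG seed controlling folds, model seeds and shuffles.
#' @param k number of folds.
#' @param folds optional pre-made `fold_plan`.
#' @param n_trees,epochs scale overrides for experiments (default: the
#'   spec's values).
#' @param render_size schematic-frame rendering side.
#' @param score_type weighting score: `"true_class"` or `"max_prob"`.
#' @param prep precomputed input representations from an earlier `run_cv()`
#'   result attribute (reuse across weighting on/off comparisons).
#' @return an `eval_result`: per-fold accuracies, pooled accuracy, mean
#'   fold accuracy, confusion matrix, prediction table, weighting plans.
#' @export
run_cv <- function(dataset, task, arch, weighting = FALSE, threshold = 0.3,
                   seed = 1, k = 5, folds = NULL, n_trees = NULL,
                   epochs = NULL, render_size = NULL,
                   score_type = "true_class", prep = NULL) {
  if (is.character(task)) task <- task_spec(task)
  n_trees <- n_trees %||% arch$n_trees
  manifest <- dataset$manifest[dataset$manifest$class %in% task$class_list, ]
  if (!all(task$class_list %in% manifest$class))
    stop_arg("task classes missing from the dataset: %s",
             paste(setdiff(task$class_list, manifest$class), collapse = ", "))
  folds <- folds %||% make_folds(manifest, k = k, seed = seed)
  prep <- prep %||% prepare_inputs(dataset, manifest$sample_id, arch,
                                   render_size)
  fusion <- grepl("fusion", arch$kind)
  pred_tab <- NULL
  plans <- list()
  for (f in seq_len(folds$k)) {
    test_subj <- as.integer(names(folds$assignment)[folds$assignment == f])
    tr <- manifest[!manifest$subject_id %in% test_subj, ]
    te <- manifest[manifest$subject_id %in% test_subj, ]
    stopifnot(length(intersect(tr$subject_id, te$subject_id)) == 0)
    if (!all(task$class_list %in% tr$class))
      warning(sprintf("fold %d training data lacks class(es): %s", f,
                      paste(setdiff(task$class_list, tr$class),
                            collapse = ", ")))
    pred_tr <- pred_te <- NULL
    if (fusion) {
      rf <- train_forest(prep$fad[match(tr$sample_id, prep$ids), ,
                                  drop = FALSE],
                         tr$class, n_trees = min(n_trees, 500),
                         seed = seed + f)
      cls <- function(ids) {
        p <- predict(rf, prep$fad[match(ids, prep$ids), , drop = FALSE])
        match(hard_labels(p), class_codes()) - 1L
      }
      pred_tr <- cls(tr$sample_id)
      pred_te <- cls(te$sample_id)
      names(pred_tr) <- tr$sample_id
    }
    xtr <- subset_inputs(prep, arch, tr$sample_id, pred_tr)
    model <- fit_one(arch, xtr, tr$class, seed + f, n_trees, epochs)
    if (weighting) {
      scores <- score_training_samples(model, xtr, tr$class, tr$sample_id,
                                       score = score_type)
      w <- apply_weighting(tr$sample_id, scores, threshold = threshold,
                           seed = seed + f, score_source = arch$kind)
      guard_test_integrity(w$plan, te$sample_id)
      wl <- tr$class[match(w$ids, tr$sample_id)]
      xw <- subset_inputs(prep, arch, w$ids,
                          if (fusion) pred_tr[w$ids] else NULL)
      model <- fit_one(arch, xw, wl, seed + f, n_trees, epochs)
      plans[[f]] <- w$plan
    }
    xte <- subset_inputs(prep, arch, te$sample_id, pred_te)
    sc <- predict(model, xte)
    pred_tab <- rbind(pred_tab, data.frame(
      sample_id = te$sample_id, subject_id = te$subject_id, fold = f,
      true = te$class, pred = hard_labels(sc), stringsAsFactors = FALSE))
  }
  out <- finish_eval(task, arch$kind, pred_tab, plans)
  attr(out, "prep") <- prep
  out
}

finish_eval <- function(task, kind, pred_tab, plans = list()) {
  fold_acc <- vapply(split(pred_tab, pred_tab$fold),
                     function(d) mean(d$pred == d$true), 0)
  confusion <- table(true = factor(pred_tab$true, task$class_list),
                     pred = factor(pred_tab$pred, task$class_list))
  structure(list(task = task$name, kind = kind, fold_acc = fold_acc,
                 pooled_acc = mean(pred_tab$pred == pred_tab$true),
                 mean_fold_acc = mean(fold_acc), confusion = confusion,
                 predictions = pred_tab, weighting_plans = plans),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result [%s, %s]: pooled %.3f, fold mean %.3f (%s)\n",
              x$kind, x$task, x$pooled_acc, x$mean_fold_acc,
              paste(sprintf("%.2f", x$fold_acc), collapse = " ")))
  invisible(x)
}

#' Trivial (guessing) baseline
#'
#' Predicts the training folds' majority class for every test sample, with
#' lowest-canonical-index tie-break; on a balanced task its pooled accuracy
#' is exactly `1/n_classes`, the chance level the recognition models are
#' compared against.
#'
#' @inheritParams run_cv
#' @return an `eval_result`.
#' @export
trivial_baseline <- function(dataset, task, seed = 1, k = 5, folds = NULL) {
  if (is.character(task)) task <- task_spec(task)
  manifest <- dataset$manifest[dataset$manifest$class %in% task$class_list, ]
  folds <- folds %||% make_folds(manifest, k = k, seed = seed)
  pred_tab <- NULL
  for (f in seq_len(folds$k)) {
    test_subj <- as.integer(names(folds$assignment)[folds$assignment == f])
    tr <- manifest[!manifest$subject_id %in% test_subj, ]
    te <- manifest[manifest$subject_id %in% test_subj, ]
    cnt <- table(factor(tr$class, task$class_list))
    maj <- task$class_list[which.max(cnt)]
    pred_tab <- rbind(pred_tab, data.frame(
      sample_id = te$sample_id, subject_id = te$subject_id, fold = f,
      true = te$class, pred = maj, stringsAsFactors = FALSE))
  }
  finish_eval(task, "trivial", pred_tab)
}

#' Draw the human-observer sample subset
#'
#' Selects a class-balanced fraction of the dataset for human labelling:
#' within each class, `round(fraction * n_class)` samples are allocated
#' across subjects by largest remainder (so every subject contributes
#' near-proportionally) and drawn without replacement within each
#' subject-class cell. Empty subject-class cells are skipped with a
#' warning. Per-class counts are invariant to the seed.
#'
#' @param manifest dataset manifest.
#' @param fraction fraction in (0, 1] (study: 0.10).
#' @param seed RNG seed.
#' @return character vector of sample ids.
#' @export
observer_subset <- function(manifest, fraction = 0.10, seed = 1) {
  if (fraction <= 0 || fraction > 1) stop_arg("fraction must be in (0, 1]")
  if (fraction == 1) return(manifest$sample_id)
  subj <- sort(unique(manifest$subject_id))
  cls <- sort(unique(manifest$class))
  empty <- sum(vapply(cls, function(cc) sum(
    !subj %in% manifest$subject_id[manifest$class == cc]), 0L))
  if (empty > 0)
    warning(sprintf("%d empty subject-class cell(s) skipped", empty))
  with_local_seed(seed, {
    unlist(lapply(cls, function(cc) {
      m <- manifest[manifest$class == cc, ]
      target <- round(fraction * nrow(m))
      cells <- split(m$sample_id, m$subject_id)
      quota_real <- vapply(cells, length, 0L) * target /
        max(nrow(m), 1)
      quota <- floor(quota_real)
      rem <- target - sum(quota)
      if (rem > 0) {
        ord <- order(-(quota_real - quota),
                     sample(seq_along(cells)))  # largest remainder
        add <- head(ord[quota[ord] < vapply(cells, length, 0L)[ord]], rem)
        quota[add] <- quota[add] + 1
      }
      unlist(lapply(seq_along(cells), function(i)
        if (quota[i] > 0) sample(cells[[i]], quota[i]) else character(0)))
    }), use.names = FALSE)
  })
}

pred_labels_of <- function(x) {
  if (is.data.frame(x)) {
    col <- if ("pred" %in% names(x)) "pred" else "class"
    stats::setNames(as.character(x[[col]]), x$sample_id)
  } else stop_arg("predictor must be a label file or prediction table")
}

#' Compare two predictors with a paired test
#'
#' Pairs per-subject accuracies (subjects are the exchangeable unit in
#' subject-disjoint cross-validation) and runs a two-sided paired t-test;
#' a per-sample McNemar test is reported as a secondary check. Either
#' predictor may be a machine prediction table (`sample_id, pred`) or a
#' human-observer label file (`sample_id, class`).
#'
#' @param pred_a,pred_b prediction tables or label files.
#' @param ground_truth data.frame with `sample_id` and `class`.
#' @param manifest manifest providing the subject of each sample.
#' @param restrict_to optional sample-id subset (e.g. from
#'   [observer_subset()]); defaults to the ids covered by both predictors.
#' @return list: `accuracy_a`, `accuracy_b`, `p_value` (paired t-test),
#'   `mcnemar_p`, `n_subjects`, `n_samples`.
#' @export
compare_predictors <- function(pred_a, pred_b, ground_truth, manifest,
                               restrict_to = NULL) {
  a <- pred_labels_of(pred_a)
  b <- pred_labels_of(pred_b)
  truth <- stats::setNames(as.character(ground_truth$class),
                           ground_truth$sample_id)
  ids <- restrict_to %||% intersect(names(a), names(b))
  miss <- setdiff(ids, intersect(names(a), names(b)))
  if (length(miss))
    stop_arg("predictor(s) do not cover: %s",
             paste(head(miss, 10), collapse = ", "))
  ok_a <- a[ids] == truth[ids]
  ok_b <- b[ids] == truth[ids]
  subj <- manifest$subject_id[match(ids, manifest$sample_id)]
  acc_a <- tapply(ok_a, subj, mean)
  acc_b <- tapply(ok_b, subj, mean)
  if (length(acc_a) < 3)
    stop_arg("need >= 3 paired subjects for the t-test, got %d",
             length(acc_a))
  d <- acc_a - acc_b
  p <- if (all(d == 0)) 1 else t.test(acc_a, acc_b, paired = TRUE)$p.value
  tab <- table(factor(ok_a, c(FALSE, TRUE)), factor(ok_b, c(FALSE, TRUE)))
  mp <- if (tab[1, 2] + tab[2, 1] == 0) 1 else
    mcnemar.test(tab)$p.value
  list(accuracy_a = mean(ok_a), accuracy_b = mean(ok_b), p_value = p,
       mcnemar_p = mp, n_subjects = length(acc_a), n_samples = length(ids))
}
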