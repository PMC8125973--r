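test_that("the seven tasks carry the published class subsets", {
  tasks <- pain_tasks()
  expect_length(tasks, 7)
  expect_setequal(tasks[["7class"]]$class_list, class_codes())
  expect_setequal(tasks[["5class_low"]]$class_list,
                  c("B", "E1", "H1", "E3", "H3"))
  expect_setequal(tasks[["5class_mod"]]$class_list,
                  c("B", "E2", "H2", "E3", "H3"))
  expect_setequal(tasks[["3class_H_mod"]]$class_list, c("B", "H2", "H3"))
  for (t in tasks) expect_true("B" %in% t$class_list)
  expect_error(task_spec("8class"), "unknown task")
})

test_that("folds are subject-disjoint and class-balanced", {
  ds <- tiny_dataset()
  # 6 subjects, k = 3 -> 2 subjects each; balanced classes -> exact props
  plan <- make_folds(ds$manifest, k = 3, seed = 1)
  expect_equal(unname(tabulate(plan$assignment)), c(2, 2, 2))
  for (f in 1:3) {
    subj <- names(plan$assignment)[plan$assignment == f]
    m <- ds$manifest[ds$manifest$subject_id %in% as.integer(subj), ]
    expect_true(all(table(m$class) == nrow(m) / 7))
  }
  # disjointness across seeds and k
  for (seed in 1:5) {
    p <- make_folds(ds$manifest, k = 3, seed = seed)
    expect_equal(anyDuplicated(names(p$assignment)), 0)
    expect_length(p$assignment, 6)
  }
  expect_identical(make_folds(ds$manifest, k = 3, seed = 9),
                   make_folds(ds$manifest, k = 3, seed = 9))
  expect_error(make_folds(ds$manifest[ds$manifest$subject_id < 5, ], k = 5),
               "at least k")
})

test_that("trivial baseline hits exact chance on balanced tasks", {
  ds <- tiny_dataset()
  expect_equal(trivial_baseline(ds, "7class", seed = 1, k = 3)$pooled_acc,
               1 / 7, tolerance = 1e-12)
  expect_equal(trivial_baseline(ds, "3class_E_low", seed = 1,
                                k = 3)$pooled_acc, 1 / 3, tolerance = 1e-12)
  # 60/40 binary: majority-class rate
  manifest <- data.frame(
    sample_id = sprintf("x%03d", 1:100),
    subject_id = rep(1:10, each = 10),
    class = rep(c(rep("B", 6), rep("E3", 4)), 10),
    stringsAsFactors = FALSE)
  fake <- structure(list(manifest = manifest), class = "pain_dataset")
  task <- structure(list(name = "binary", class_list = c("B", "E3")),
                    class = "task_spec")
  expect_equal(trivial_baseline(fake, task, seed = 1, k = 5)$pooled_acc, 0.6)
})

test_that("observer subset is class-balanced at the requested fraction", {
  ds <- generate_dataset(n_subjects = 10, reps_per_class = 4, seed = 6)
  ids <- observer_subset(ds$manifest, fraction = 0.10, seed = 1)
  expect_length(ids, 28)
  cls <- ds$manifest$class[match(ids, ds$manifest$sample_id)]
  expect_true(all(table(cls) == 4))
  expect_setequal(observer_subset(ds$manifest, fraction = 1),
                  ds$manifest$sample_id)
  # per-class counts invariant to the seed, subsets differ
  ids2 <- observer_subset(ds$manifest, fraction = 0.10, seed = 2)
  cls2 <- ds$manifest$class[match(ids2, ds$manifest$sample_id)]
  expect_equal(as.vector(table(cls2)), as.vector(table(cls)))
  expect_false(setequal(ids, ids2))
  expect_error(observer_subset(ds$manifest, fraction = 0), "fraction")
})

test_that("cross-validation recovers signal and respects subject splits", {
  ds <- strong_dataset()
  arch <- architecture_spec("rfc_fad", n_trees = 150)
  res <- run_cv(ds, "3class_E_low", arch, seed = 2, k = 5)
  expect_gt(res$pooled_acc, 2 / 3)  # strong-signal regime
  expect_true(all(res$fold_acc >= 0 & res$fold_acc <= 1))
  expect_equal(sum(res$confusion),
               sum(ds$manifest$class %in% c("B", "E1", "E3")))
  # no subject in both train and test: every subject appears in one fold
  by_subj <- tapply(res$predictions$fold, res$predictions$subject_id,
                    function(f) length(unique(f)))
  expect_true(all(by_subj == 1))
})

test_that("paired predictor comparison behaves analytically", {
  ds <- generate_dataset(n_subjects = 8, reps_per_class = 2, seed = 9)
  manifest <- ds$manifest
  truth <- data.frame(sample_id = manifest$sample_id,
                      class = manifest$class)
  perfect <- data.frame(sample_id = manifest$sample_id,
                        pred = manifest$class)
  cmp <- compare_predictors(perfect, perfect, truth, manifest)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$accuracy_a, cmp$accuracy_b)
  # flipping every sample of one subject shifts accuracy by its weight
  flipped <- perfect
  flip <- manifest$subject_id == 3
  flipped$pred[flip] <- ifelse(manifest$class[flip] == "B", "E1", "B")
  cmp2 <- compare_predictors(perfect, flipped, truth, manifest)
  expect_equal(cmp2$accuracy_a - cmp2$accuracy_b,
               sum(flip) / nrow(manifest))
  # perfect vs chance over 30 subjects is significant
  ds30 <- generate_dataset(n_subjects = 30, reps_per_class = 1, seed = 10)
  m30 <- ds30$manifest
  truth30 <- data.frame(sample_id = m30$sample_id, class = m30$class)
  perfect30 <- data.frame(sample_id = m30$sample_id, pred = m30$class)
  chance30 <- data.frame(sample_id = m30$sample_id,
                         pred = painface:::with_local_seed(
                           1, sample(m30$class)))
  cmp3 <- compare_predictors(perfect30, chance30, truth30, m30)
  expect_lt(cmp3$p_value, 0.01)
  expect_error(compare_predictors(
    perfect[1:7, ], perfect[1:7, ], truth, manifest,
    restrict_to = manifest$sample_id[1:7]), "3 paired")
})

test_that("restricting to an observer subset reports both accuracies", {
  ds <- generate_dataset(n_subjects = 10, reps_per_class = 2, seed = 12)
  manifest <- ds$manifest
  truth <- data.frame(sample_id = manifest$sample_id, class = manifest$class)
  sub <- observer_subset(manifest, 0.5, seed = 3)
  machine <- data.frame(sample_id = manifest$sample_id,
                        pred = manifest$class)
  observer <- data.frame(
    sample_id = manifest$sample_id,
    class = painface:::with_local_seed(2, ifelse(runif(nrow(manifest)) < 0.5,
                                                 manifest$class,
                                                 sample(class_codes(),
                                                        nrow(manifest),
                                                        TRUE))))
  cmp <- compare_predictors(machine, observer, truth, manifest,
                            restrict_to = sub)
  expect_equal(cmp$n_samples, length(sub))
  expect_equal(cmp$accuracy_a, 1)
  expect_lt(cmp$accuracy_b, 1)
})
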