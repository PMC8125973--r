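test_that("architecture specs validate their fields", {
  a <- architecture_spec("rfc_fad")
  expect_equal(a$n_trees, 5000)     # study forest size
  c <- architecture_spec("cnns_fusion")
  expect_equal(c$epochs, 150)       # study training schedule
  expect_equal(c$learning_rate, 1e-4)
  expect_error(architecture_spec("rfc_fad", mtl_variant = "softmax_mse"),
               "CNN kinds")
  expect_error(architecture_spec("rfc_fad", n_trees = 0), "n_trees")
})

test_that("forests fit separable data perfectly and expose probabilities", {
  set.seed(31)
  n <- 60
  f <- cbind(x1 = c(rnorm(n, -3), rnorm(n, 3)), x2 = rnorm(2 * n))
  labels <- rep(c("B", "E3"), each = n)
  m <- train_forest(f, labels, n_trees = 100, seed = 1)
  p <- predict(m, f)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_equal(mean(hard_labels(p) == labels), 1)
  expect_identical(colnames(p), c("B", "E3"))
  # identical seed, identical predictions
  m2 <- train_forest(f, labels, n_trees = 100, seed = 1)
  expect_equal(predict(m2, f), p)
  expect_error(train_forest(f, rep("B", 2 * n)), "single class")
})

test_that("more trees do not hurt on noisy data", {
  set.seed(32)
  accs <- vapply(1:5, function(sd) {
    set.seed(sd)
    n <- 80
    f <- cbind(rnorm(2 * n, rep(c(0, 0.8), each = n)),
               matrix(rnorm(2 * n * 5), ncol = 5))
    y <- rep(c("B", "E3"), each = n)
    te <- sample(2 * n, 60)
    m1 <- train_forest(f[-te, ], y[-te], n_trees = 1, seed = sd)
    m2 <- train_forest(f[-te, ], y[-te], n_trees = 500, seed = sd)
    mean(hard_labels(predict(m2, f[te, ])) == y[te]) -
      mean(hard_labels(predict(m1, f[te, ])) == y[te])
  }, 0)
  expect_gte(mean(accs), 0)
})

test_that("hard labels break ties towards the first class", {
  sc <- matrix(1 / 7, 2, 7, dimnames = list(NULL, class_codes()))
  expect_identical(hard_labels(sc), c("B", "B"))
})

test_that("multi-task outputs map onto the 7-class alphabet", {
  expect_identical(mtl_to_class("E", 2L), "E2")
  expect_identical(mtl_to_class("H", 3L), "H3")
  expect_identical(mtl_to_class("E", 0L), "B")
  pm <- rbind(c(0.1, 0.7, 0.2),   # E
              c(0.6, 0.1, 0.3),   # B top but intensity 1 -> H wins of E/H
              c(0.2, 0.3, 0.5))   # H
  expect_identical(mtl_to_class(pm, c(1L, 1L, 0L)), c("E1", "H1", "B"))
  expect_error(mtl_to_class("B", 2L), "incompatible")
})

test_that("an untrained CNN predicts near-chance, a trained one learns", {
  ds <- strong_dataset()
  keep <- ds$manifest$class %in% c("B", "E3")
  ids <- ds$manifest$sample_id[keep]
  labels <- ds$manifest$class[keep]
  arch <- architecture_spec("cnns_fusion", epochs = 6, image_side = 16,
                            pred_side = 12, batch_size = 16,
                            learning_rate = 1e-3)
  prep <- painface:::prepare_inputs(ds, ids, arch, render_size = 32)
  inputs <- list(images = prep$images,
                 pred = painface:::pred_image_array(
                   ifelse(labels == "B", 0L, 6L), arch$pred_side))
  m0 <- train_cnn(arch, inputs, labels, epochs = 0, seed = 1)
  p0 <- predict(m0, inputs)
  expect_true(all(abs(rowSums(p0) - 1) < 1e-6))
  acc0 <- mean(hard_labels(p0) == labels)
  expect_lt(acc0, 0.75)  # near the 0.5 chance level at initialisation
  m <- train_cnn(arch, inputs, labels, seed = 1)
  expect_length(m$loss_history, 6)
  expect_lt(mean(tail(m$loss_history, 2)), mean(head(m$loss_history, 2)))
  acc <- mean(hard_labels(predict(m, inputs)) == labels)
  expect_gt(acc, 0.7)  # clearly above 2-class chance on training data
  # deterministic retrain
  m2 <- train_cnn(arch, inputs, labels, seed = 1)
  expect_equal(predict(m2, inputs), predict(m, inputs), tolerance = 1e-12)
})

test_that("multi-task training lifts both heads above chance", {
  ds <- strong_dataset()
  ids <- ds$manifest$sample_id
  labels <- ds$manifest$class
  arch <- architecture_spec("cnns_fusion", mtl_variant = "softmax_softmax",
                            epochs = 6, image_side = 16, pred_side = 12,
                            batch_size = 16, learning_rate = 1e-3)
  prep <- painface:::prepare_inputs(ds, ids, arch, render_size = 32)
  inputs <- list(images = prep$images,
                 pred = painface:::pred_image_array(
                   match(labels, class_codes()) - 1L, arch$pred_side))
  m <- train_cnn(arch, inputs, labels, seed = 2)
  fw <- painface:::net_forward(m$net, inputs$images, inputs$pred)
  tg <- painface:::mtl_targets(labels)
  acc_mod <- mean(max.col(fw$heads$head_mod) == tg$modality)
  acc_int <- mean(max.col(fw$heads$head_int) == tg$intensity + 1)
  expect_gt(acc_mod, 1 / 3 + 0.1)
  expect_gt(acc_int, 1 / 4 + 0.1)
  # joint 7-class scores are a probability table
  p <- predict(m, inputs)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_identical(colnames(p), class_codes())
})
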