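# Engine-level checks: forward ops against naive oracles and analytic
# gradients against central finite differences.

test_that("convolution forward matches a naive loop implementation", {
  set.seed(21)
  x <- array(runif(9 * 8 * 3 * 2), c(9, 8, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4, 0, 0.3), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (cfg in list(c(1, 1), c(2, 1), c(1, 0))) {
    y <- painface:::cpp_conv_fw(x, w, b, cfg[1], cfg[2])
    for (n in 1:2)
      expect_equal(y[, , , n], naive_conv2d(x[, , , n], w, b, cfg[1],
                                            cfg[2]),
                   tolerance = 1e-12)
  }
})

test_that("max pooling matches a naive implementation", {
  set.seed(22)
  x <- array(rnorm(10 * 10 * 2 * 2), c(10, 10, 2, 2))
  mp <- painface:::cpp_maxpool_fw(x, 3L, 2L)
  for (n in 1:2)
    for (c in 1:2)
      for (oh in 1:4)
        for (ow in 1:4)
          expect_equal(mp$y[oh, ow, c, n],
                       max(x[(oh - 1) * 2 + 1:3, (ow - 1) * 2 + 1:3, c, n]))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(23)
  ximg <- array(runif(14 * 14 * 3 * 3), c(14, 14, 3, 3))
  xpred <- array(runif(10 * 10 * 1 * 3), c(10, 10, 1, 3))
  labels <- c("B", "E1", "H3")
  cl <- c("B", "E1", "H3")
  net <- painface:::with_local_seed(5, {
    b1 <- painface:::chain_build(
      list(painface:::layer_conv(4), painface:::layer_relu(),
           painface:::layer_maxpool(3, 2), painface:::layer_gap(),
           painface:::layer_dense(6), painface:::layer_relu()),
      c(14, 14, 3))
    b2 <- painface:::chain_build(
      list(painface:::layer_dwconv(3), painface:::layer_relu(6),
           painface:::layer_conv(4, kernel = 1, pad = 0),
           painface:::layer_gap(), painface:::layer_dense(6),
           painface:::layer_relu()),
      c(10, 10, 1))
    build_fusion(b1, b2, 3, "none")
  })
  # move biases off the ReLU hinge so finite differences are valid
  params <- painface:::net_params(net$chains)
  set.seed(24)
  for (nm in grep("[.]b$", names(params), value = TRUE))
    params[[nm]] <- rnorm(length(params[[nm]]), 0, 0.05)
  net$chains <- painface:::net_set_params(net$chains, params)
  lossfn <- function(net) {
    fw <- painface:::net_forward(net, ximg, xpred, keep_cache = TRUE)
    painface:::net_loss_grads(net, fw$heads, labels, cl)$loss
  }
  fw <- painface:::net_forward(net, ximg, xpred, keep_cache = TRUE)
  lg <- painface:::net_loss_grads(net, fw$heads, labels, cl)
  an <- painface:::net_backward(net, fw$cache, lg$grads)
  eps <- 1e-5
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][j] <- p2[[nm]][j] + eps
      n2 <- net; n2$chains <- painface:::net_set_params(net$chains, p2)
      lp <- lossfn(n2)
      p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
      n2$chains <- painface:::net_set_params(net$chains, p2)
      lm <- lossfn(n2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(an[[nm]][j], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, j))
    }
  }
})

test_that("simple CNN has the stated layer plan and size limits", {
  ch <- painface:::with_local_seed(1, build_simple_cnn(c(96, 96, 3)))
  types <- vapply(ch, `[[`, "", "type")
  convs <- which(types == "conv")
  expect_length(convs, 6)
  expect_equal(vapply(ch[convs], `[[`, 0, "filters"),
               c(16, 16, 32, 32, 64, 64))
  expect_equal(sum(types == "maxpool"), 2)
  expect_equal(attr(ch, "output_shape"), 1024)
  expect_equal(attr(ch, "gap_channels"), 64)
  # 28x28 single channel is valid; GAP sees 64 channels
  ch28 <- painface:::with_local_seed(1, build_simple_cnn(c(28, 28, 1)))
  expect_equal(attr(ch28, "output_shape"), 1024)
  expect_error(build_simple_cnn(c(8, 8, 1)), "too small")
  expect_error(build_simple_cnn(c(96, 96, 2)), "channels")
})

test_that("reduced MobileNetV2 keeps 5 blocks and the branch contract", {
  ch <- painface:::with_local_seed(2, build_reduced_mnv2(c(64, 64, 3)))
  expect_equal(attr(ch, "n_blocks"), 5)
  expect_equal(attr(ch, "output_shape"), 1024)
  # deterministic init under a fixed seed
  p1 <- painface:::net_params(list(c = painface:::with_local_seed(
    9, build_reduced_mnv2(c(64, 64, 3)))))
  p2 <- painface:::net_params(list(c = painface:::with_local_seed(
    9, build_reduced_mnv2(c(64, 64, 3)))))
  expect_identical(p1, p2)
  expect_error(build_reduced_mnv2(c(64, 64, 3), pretrained = TRUE),
               "weights")
  # interchangeability: either branch kind plugs into the same fusion
  set.seed(30)
  for (branch in list(painface:::with_local_seed(
    3, build_simple_cnn(c(32, 32, 3))), painface:::with_local_seed(
    3, build_reduced_mnv2(c(32, 32, 3))))) {
    pred_branch <- painface:::with_local_seed(
      4, build_simple_cnn(c(14, 14, 1)))
    net <- painface:::with_local_seed(5,
      build_fusion(branch, pred_branch, 7, "none"))
    out <- painface:::net_forward(
      net, array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)),
      array(runif(14 * 14 * 1 * 2), c(14, 14, 1, 2)))
    expect_identical(dim(out$heads$head_main), c(2L, 7L))
  }
})

test_that("fusion heads have the widths of each multi-task variant", {
  b <- function() painface:::with_local_seed(6,
    build_simple_cnn(c(16, 16, 3)))
  p <- function() painface:::with_local_seed(7,
    build_simple_cnn(c(14, 14, 1)))
  net <- build_fusion(b(), p(), 7, "none")
  expect_equal(attr(net$chains$head_main, "output_shape"), 7)
  net <- build_fusion(b(), p(), 7, "softmax_softmax")
  expect_equal(attr(net$chains$head_mod, "output_shape"), 3)
  expect_equal(attr(net$chains$head_int, "output_shape"), 4)
  net <- build_fusion(b(), p(), 7, "softmax_mse")
  expect_equal(attr(net$chains$head_int, "output_shape"), 1)
  net <- build_fusion(b(), p(), 7, "softmax_sigmoid")
  expect_equal(attr(net$chains$head_int, "output_shape"), 1)
  expect_error(build_fusion(b(), p(), 7, "bogus"), "mtl_variant")
  # trunk is the documented 1024/512/128 stack
  trunk_units <- vapply(Filter(function(l) l$type == "dense",
                               net$chains$trunk), `[[`, 0, "units")
  expect_equal(trunk_units, c(1024, 512, 128))
})
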