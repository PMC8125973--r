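test_that("subject profiles respect their invariants and configuration", {
  subs <- make_subjects(127, seed = 1)
  expect_length(subs, 127)
  for (s in subs[1:20]) {
    expect_true(all(s$response_prob >= 0 & s$response_prob <= 1))
    expect_true(!is.unsorted(s$response_prob))
    expect_gte(s$expressiveness, 0)
  }
  expect_identical(make_subjects(10, seed = 4), make_subjects(10, seed = 4))
  one <- make_subjects(1, seed = 7, nonresponder_frac = 1.0)
  expect_equal(one[[1]]$expressiveness, 0)
  expect_error(make_subjects(0), "positive")
})

test_that("population response probability matches its configured mean", {
  subs <- make_subjects(50, seed = 3)
  p3 <- vapply(subs, function(s) s$response_prob[3], 0)
  expect_equal(mean(p3), synth_config()$response_prob_mean[3],
               tolerance = 0.1)
})

test_that("samples are 17 x 7s matrices with stimulus-derived labels", {
  subs <- make_subjects(2, seed = 2, nonresponder_frac = 0)
  s <- generate_sample(subs[[1]], stimulus_spec("heat", 2), seed = 5)
  expect_identical(dim(s$series), c(17L, 175L))
  expect_true(all(s$series >= 0))
  expect_identical(s$label, "H2")
  b <- generate_sample(subs[[1]], stimulus_spec("none", 0), seed = 5)
  expect_identical(b$label, "B")
  expect_equal(b$bump_amp, 0)
  expect_error(generate_sample(subs[[1]], stimulus_spec("heat", 2),
                               fps = -1), "fps")
  expect_error(stimulus_spec("none", 2), "intensity")
  expect_error(stimulus_spec("heat", 0), "intensity")
})

test_that("zero expressiveness yields pure baseline noise", {
  non <- make_subjects(1, seed = 7, nonresponder_frac = 1.0)[[1]]
  cfg <- synth_config(response_prob_mean = c(1, 1, 1))
  s <- generate_sample(non, stimulus_spec("electrical", 3), seed = 9,
                       config = cfg)
  expect_equal(s$bump_amp, 0)
  b <- generate_sample(non, stimulus_spec("none", 0), seed = 9, config = cfg)
  expect_equal(max(abs(s$series - b$series)), 0)
})

test_that("electrical responses peak earlier than heat responses", {
  subs <- make_subjects(1, seed = 1, nonresponder_frac = 0)
  cfg <- synth_config(response_prob_mean = c(1, 1, 1))
  pain_rows <- match(pain_au_defaults <- c("AU04", "AU06", "AU07"),
                     au_names())
  earlier <- vapply(1:100, function(i) {
    e <- generate_sample(subs[[1]], stimulus_spec("electrical", 3),
                         seed = i, config = cfg)
    h <- generate_sample(subs[[1]], stimulus_spec("heat", 3), seed = i,
                         config = cfg)
    which.max(colMeans(e$series[pain_rows, ])) <
      which.max(colMeans(h$series[pain_rows, ]))
  }, NA)
  expect_gt(mean(earlier), 0.5)
})

test_that("no-response fraction converges to 1 - response_prob", {
  subs <- make_subjects(1, seed = 13, nonresponder_frac = 0)[[1]]
  subs$response_prob <- c(0.6, 0.6, 0.6)
  cfg <- synth_config()
  n <- 500
  zero <- vapply(seq_len(n), function(i)
    generate_sample(subs, stimulus_spec("heat", 2), seed = i,
                    config = cfg)$bump_amp == 0, NA)
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(mean(zero) - 0.4), 2 * se + 1e-9)
})

test_that("schematic rendering is deterministic and AU-sensitive", {
  ds <- tiny_dataset()
  s <- ds$samples[[1]]
  f1 <- render_frame(s, 10, size = 48)
  f2 <- render_frame(s, 10, size = 48)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(48L, 48L))
  expect_true(all(f1 >= 0 & f1 <= 1))
  # neutral template: all-zero AUs, identical across calls
  s0 <- s
  s0$series[] <- 0
  expect_identical(render_frame(s0, 1, size = 48),
                   render_frame(s0, 2, size = 48))
  # maximal brow lowerer moves brow-region pixels
  s4 <- s0
  s4$series["AU04", ] <- 5
  d <- abs(render_frame(s4, 1, size = 48) - render_frame(s0, 1, size = 48))
  brow_rows <- 10:22  # upper-face band
  expect_gt(sum(d[brow_rows, ]), 0)
  expect_error(render_frame(s, 1, size = 16), ">= 32")
  frames <- render_frames(s, size = 32)
})

test_that("render_frames covers every frame of a 7 s sample", {
  subs <- make_subjects(1, seed = 2)
  s <- generate_sample(subs[[1]], stimulus_spec("none", 0), seed = 1,
                       fps = 25)
  expect_length(render_frames(s, size = 32), 175)
})

test_that("datasets are balanced, counted and reproducible", {
  ds <- generate_dataset(n_subjects = 10, reps_per_class = 4, seed = 2)
  expect_equal(nrow(ds$manifest), 10 * 7 * 4)
  counts <- table(ds$manifest$subject_id, ds$manifest$class)
  expect_true(all(counts == 4))
  # full-study arithmetic: 127 subjects x 7 classes x 30 reps
  expect_equal(127 * 7 * 30, 26670)
  ds2 <- generate_dataset(n_subjects = 10, reps_per_class = 4, seed = 2)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$samples[[5]]$series, ds2$samples[[5]]$series)
  expect_error(generate_dataset(reps_per_class = 0), "reps_per_class")
})
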