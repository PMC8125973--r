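# Independent brute-force reference implementations used as oracles.
# Deliberately written with loops / different algorithms than the package.

naive_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

naive_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  mx <- x[1]; mn <- x[1]; imax <- 1; imin <- 1
  for (i in seq_len(n)) {
    if (x[i] > mx) { mx <- x[i]; imax <- i }
    if (x[i] < mn) { mn <- x[i]; imin <- i }
  }
  sdev <- if (n == 1) 0 else sqrt(sum((x - m)^2) / (n - 1))
  area <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) area <- area + (x[i] + x[i + 1]) / 2
    area <- area / (n - 1)
  } else area <- x
  slope <- if (n == 1) 0 else unname(stats::lm(x ~ seq_len(n))$coefficients[2])
  nloc <- 0
  if (n >= 3)
    for (i in 2:(n - 1)) if (x[i] > x[i - 1] && x[i] > x[i + 1])
      nloc <- nloc + 1
  c(mean = m, median = naive_quantile(x, 0.5), sd = sdev, min = mn,
    max = mx, range = mx - mn,
    iqr = naive_quantile(x, 0.75) - naive_quantile(x, 0.25),
    p10 = naive_quantile(x, 0.10), p90 = naive_quantile(x, 0.90),
    reltmax = if (n == 1) 0 else (imax - 1) / (n - 1),
    reltmin = if (n == 1) 0 else (imin - 1) / (n - 1),
    rms = sqrt(sum(x^2) / n), mad = sum(abs(x - m)) / n, area = area,
    slope = slope, nlocmax = nloc)
}

# naive valid/padded convolution of one channel plane, one filter slice
naive_conv2d <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; OC <- dim(w)[4]
  OH <- (H + 2 * pad - kh) %/% stride + 1
  OW <- (W + 2 * pad - kw) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  out <- array(0, c(OH, OW, OC))
  for (oc in seq_len(OC))
    for (oh in seq_len(OH))
      for (ow in seq_len(OW)) {
        acc <- b[oc]
        for (c in seq_len(C))
          acc <- acc + sum(xp[(oh - 1) * stride + seq_len(kh),
                              (ow - 1) * stride + seq_len(kw), c] *
                             w[, , c, oc])
        out[oh, ow, oc] <- acc
      }
  out
}

# small, shared synthetic dataset (built once per test run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(n_subjects = 6, reps_per_class = 2,
                                 seed = 11)
    cache
  }
})

strong_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(n_subjects = 10, reps_per_class = 2,
                                 seed = 5, response_prob_mean = c(1, 1, 1),
                                 nonresponder_frac = 0,
                                 expressiveness_mean = 1.5)
    cache
  }
})
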