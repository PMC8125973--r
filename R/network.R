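# Minimal conv-net engine backing the deep-learning classifiers.
#
# A network is a named list of *chains*; a chain is a list of layers applied
# in sequence. Spatial activations are H x W x C x N arrays, dense
# activations N x F matrices; global average pooling bridges the two.
# Residual connections are expressed with paired skip_start/skip_end
# markers. Convolution/pooling kernels live in src/conv_ops.cpp; everything
# else is plain matrix algebra.

layer_conv <- function(filters, kernel = 3, stride = 1,
                       pad = (kernel - 1) %/% 2)
  list(type = "conv", filters = filters, kernel = kernel, stride = stride,
       pad = pad)
layer_dwconv <- function(kernel = 3, stride = 1, pad = (kernel - 1) %/% 2)
  list(type = "dwconv", kernel = kernel, stride = stride, pad = pad)
layer_relu <- function(cap = Inf) list(type = "relu", cap = cap)
layer_maxpool <- function(kernel = 3, stride = 2)
  list(type = "maxpool", kernel = kernel, stride = stride)
layer_gap <- function() list(type = "gap")
layer_dense <- function(units) list(type = "dense", units = units)
layer_skip_start <- function(id) list(type = "skip_start", id = id)
layer_skip_end <- function(id) list(type = "skip_end", id = id)

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# Allocate parameters and compute shapes. `input_shape` is c(H, W, C) for
# spatial chains or a single integer for dense chains. Uses the current RNG
# stream (callers seed it).
chain_build <- function(layers, input_shape) {
  shape <- input_shape
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    switch(l$type,
      conv = {
        if (length(shape) != 3) stop_arg("conv needs spatial input")
        os <- (shape[1:2] + 2 * l$pad - l$kernel) %/% l$stride + 1
        if (any(os < 1)) stop_arg("input too small for convolution stack")
        layers[[i]]$w <- he_init(c(l$kernel, l$kernel, shape[3], l$filters),
                                 l$kernel^2 * shape[3])
        layers[[i]]$b <- numeric(l$filters)
        shape <- c(os, l$filters)
      },
      dwconv = {
        os <- (shape[1:2] + 2 * l$pad - l$kernel) %/% l$stride + 1
        if (any(os < 1)) stop_arg("input too small for convolution stack")
        layers[[i]]$w <- he_init(c(l$kernel, l$kernel, shape[3]), l$kernel^2)
        layers[[i]]$b <- numeric(shape[3])
        shape <- c(os, shape[3])
      },
      maxpool = {
        os <- (shape[1:2] - l$kernel) %/% l$stride + 1
        if (any(os < 2))
          stop_arg("input too small: a %dx%d pool over %dx%d leaves < 2 px",
                   l$kernel, l$kernel, shape[1], shape[2])
        shape <- c(os, shape[3])
      },
      gap = shape <- shape[3],
      dense = {
        if (length(shape) != 1) stop_arg("dense needs flat input")
        layers[[i]]$w <- he_init(c(shape, l$units), shape)
        layers[[i]]$b <- numeric(l$units)
        shape <- l$units
      },
      relu = NULL, skip_start = NULL, skip_end = NULL,
      stop_arg("unknown layer type %s", l$type))
  }
  attr(layers, "output_shape") <- shape
  attr(layers, "input_shape") <- input_shape
  layers
}

chain_forward <- function(layers, x, keep_cache = TRUE) {
  caches <- vector("list", length(layers))
  saved <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (keep_cache && l$type %in% c("conv", "dwconv", "dense", "relu"))
      caches[[i]] <- x
    x <- switch(l$type,
      conv = cpp_conv_fw(x, l$w, l$b, l$stride, l$pad),
      dwconv = cpp_dwconv_fw(x, l$w, l$b, l$stride, l$pad),
      relu = pmin(pmax(x, 0), l$cap),
      maxpool = {
        mp <- cpp_maxpool_fw(x, l$kernel, l$stride)
        if (keep_cache) caches[[i]] <- list(dim = dim(x), idx = mp$idx)
        mp$y
      },
      gap = {
        d <- dim(x)
        if (keep_cache) caches[[i]] <- d
        matrix(colMeans(matrix(x, d[1] * d[2])), d[4], d[3], byrow = TRUE)
      },
      dense = sweep(x %*% l$w, 2, l$b, `+`),
      skip_start = { saved[[as.character(l$id)]] <- x; x },
      skip_end = x + saved[[as.character(l$id)]])
  }
  list(out = x, caches = caches)
}

chain_backward <- function(layers, caches, gout) {
  grads <- vector("list", length(layers))
  pending <- list()
  g <- gout
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    g <- switch(l$type,
      conv = {
        bw <- cpp_conv_bw(caches[[i]], l$w, g, l$stride, l$pad)
        grads[[i]] <- list(w = bw$dw, b = bw$db)
        bw$dx
      },
      dwconv = {
        bw <- cpp_dwconv_bw(caches[[i]], l$w, g, l$stride, l$pad)
        grads[[i]] <- list(w = bw$dw, b = bw$db)
        bw$dx
      },
      relu = g * (caches[[i]] > 0 & caches[[i]] < l$cap),
      maxpool = cpp_maxpool_bw(caches[[i]]$dim, caches[[i]]$idx, g),
      gap = {
        d <- caches[[i]]
        array(rep(as.vector(t(g)) / (d[1] * d[2]), each = d[1] * d[2]),
              dim = d)
      },
      dense = {
        grads[[i]] <- list(w = crossprod(caches[[i]], g), b = colSums(g))
        g %*% t(l$w)
      },
      skip_start = {
        extra <- pending[[as.character(l$id)]]
        if (!is.null(extra)) g + extra else g
      },
      skip_end = { pending[[as.character(l$id)]] <- g; g })
  }
  list(gin = g, grads = grads)
}

# --- parameter plumbing -----------------------------------------------------

net_params <- function(chains) {
  out <- list()
  for (cn in names(chains))
    for (i in seq_along(chains[[cn]]))
      if (!is.null(chains[[cn]][[i]]$w)) {
        out[[paste0(cn, ".", i, ".w")]] <- chains[[cn]][[i]]$w
        out[[paste0(cn, ".", i, ".b")]] <- chains[[cn]][[i]]$b
      }
  out
}

net_set_params <- function(chains, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    chains[[parts[1]]][[as.integer(parts[2])]][[parts[3]]] <- params[[nm]]
  }
  chains
}

grads_to_params <- function(chains, grad_lists) {
  out <- list()
  for (cn in names(grad_lists))
    for (i in seq_along(grad_lists[[cn]]))
      if (!is.null(grad_lists[[cn]][[i]])) {
        out[[paste0(cn, ".", i, ".w")]] <- grad_lists[[cn]][[i]]$w
        out[[paste0(cn, ".", i, ".b")]] <- grad_lists[[cn]][[i]]$b
      }
  out
}

adam_init <- function(params)
  list(m = lapply(params, function(p) as.numeric(p) * 0),
       v = lapply(params, function(p) as.numeric(p) * 0), t = 0)

# Updates `params` (and the moment buffers) in place through the C++
# kernel; the training loop owns all three structures.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    cpp_adam_update(params[[nm]], g, state$m[[nm]],
                    state$v[[nm]], lr, state$t, beta1, beta2, eps)
  }
  list(params = params, state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
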