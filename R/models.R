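#' Specify a classifier architecture
#'
#' Four model families share one train/predict contract: `rfc_bl` (random
#' forest on flattened spatio-temporal pixels, the automatic baseline),
#' `rfc_fad` (random forest on the 816-dim facial activity descriptor),
#' `cnns_fusion` (two simple CNN branches — face image + prediction image —
#' fused by three dense layers) and `mnv2_fusion` (reduced MobileNetV2
#' image branch + simple CNN prediction branch, same fusion). CNN kinds may
#' carry a multi-task variant with two output heads: stimulus modality
#' (B/E/H) and pain intensity (0-3).
#'
#' @param kind one of `"rfc_bl"`, `"rfc_fad"`, `"mnv2_fusion"`,
#'   `"cnns_fusion"`.
#' @param mtl_variant `"none"`, `"softmax_softmax"`, `"softmax_mse"` or
#'   `"softmax_sigmoid"`; only valid for the CNN kinds.
#' @param n_trees forest size (default 5000, the study setting).
#' @param epochs,learning_rate,batch_size CNN training settings (defaults
#'   150 epochs at 1e-4, batch 64).
#' @param pretrained_backbone if `TRUE`, `mnv2_fusion` expects backbone
#'   weights via `backbone_weights`; the tested default is random
#'   initialisation.
#' @param image_side,pred_side input image sides (96 and 28).
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(kind = c("rfc_fad", "rfc_bl", "cnns_fusion",
                                       "mnv2_fusion"),
                              mtl_variant = c("none", "softmax_softmax",
                                              "softmax_mse",
                                              "softmax_sigmoid"),
                              n_trees = 5000, epochs = 150,
                              learning_rate = 1e-4, batch_size = 64,
                              pretrained_backbone = FALSE,
                              image_side = 96, pred_side = 28) {
  kind <- match.arg(kind)
  mtl_variant <- match.arg(mtl_variant)
  if (n_trees < 1) stop_arg("n_trees must be >= 1")
  if (mtl_variant != "none" && !grepl("fusion", kind))
    stop_arg("multi-task variants apply only to the CNN kinds")
  structure(list(kind = kind, mtl_variant = mtl_variant, n_trees = n_trees,
                 epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size,
                 pretrained_backbone = pretrained_backbone,
                 image_side = image_side, pred_side = pred_side),
            class = "architecture_spec")
}

#' Build the simple CNN branch
#'
#' Six 3x3 convolutions, each followed by ReLU: two with 16 channels, a 3x3
#' max-pool of stride 2, two with 32 channels, another pool, two with 64
#' channels, then global average pooling and a 1024-unit ReLU dense layer.
#' Errors when the input is too small for the two stride-2 pools (every
#' pooled spatial dimension must stay at least 2 pixels).
#'
#' @param input_shape `c(H, W, C)`; C is 1 or 3.
#' @return a built layer chain; `attr(,"output_shape")` is 1024 and
#'   `attr(,"gap_channels")` 64.
#' @export
build_simple_cnn <- function(input_shape) {
  if (length(input_shape) != 3 || !input_shape[3] %in% c(1, 3))
    stop_arg("input_shape must be c(H, W, C) with 1 or 3 channels")
  layers <- list(
    layer_conv(16), layer_relu(), layer_conv(16), layer_relu(),
    layer_maxpool(3, 2),
    layer_conv(32), layer_relu(), layer_conv(32), layer_relu(),
    layer_maxpool(3, 2),
    layer_conv(64), layer_relu(), layer_conv(64), layer_relu(),
    layer_gap(), layer_dense(1024), layer_relu())
  ch <- chain_build(layers, input_shape)
  attr(ch, "gap_channels") <- 64
  ch
}

# one inverted residual block: 1x1 expand (ReLU6), 3x3 depthwise (ReLU6),
# 1x1 linear projection, with identity skip when stride 1 and channels match
inverted_residual <- function(in_ch, out_ch, stride, expand, id) {
  layers <- list()
  if (expand != 1)
    layers <- c(layers, list(layer_conv(in_ch * expand, kernel = 1, pad = 0),
                             layer_relu(6)))
  layers <- c(layers, list(layer_dwconv(3, stride = stride, pad = 1),
                           layer_relu(6),
                           layer_conv(out_ch, kernel = 1, pad = 0)))
  if (stride == 1 && in_ch == out_ch)
    layers <- c(list(layer_skip_start(id)), layers,
                list(layer_skip_end(id)))
  layers
}

#' Build the reduced MobileNetV2 image branch
#'
#' MobileNetV2-design stem (3x3 stride-2 convolution, 32 channels, ReLU6)
#' followed by the first 5 inverted residual blocks only, then global
#' average pooling and a 1024-unit ReLU dense layer so the branch plugs into
#' the fusion trunk interchangeably with the simple CNN. With
#' `pretrained = FALSE` (the default) weights are randomly initialised;
#' ImageNet-pretrained weights can be injected via `weights`, a parameter
#' list as produced by the engine.
#'
#' @param input_shape `c(H, W, 3)`.
#' @param pretrained logical; requires `weights` when `TRUE`.
#' @param weights optional named parameter list to load.
#' @return a built layer chain with `attr(,"n_blocks")` = 5.
#' @export
build_reduced_mnv2 <- function(input_shape = c(96, 96, 3),
                               pretrained = FALSE, weights = NULL) {
  if (length(input_shape) != 3 || input_shape[3] != 3)
    stop_arg("input_shape must be c(H, W, 3)")
  layers <- c(
    list(layer_conv(32, kernel = 3, stride = 2, pad = 1), layer_relu(6)),
    inverted_residual(32, 16, 1, 1, "b1"),
    inverted_residual(16, 24, 2, 6, "b2"),
    inverted_residual(24, 24, 1, 6, "b3"),
    inverted_residual(24, 32, 2, 6, "b4"),
    inverted_residual(32, 32, 1, 6, "b5"),
    list(layer_gap(), layer_dense(1024), layer_relu()))
  ch <- chain_build(layers, input_shape)
  if (pretrained) {
    if (is.null(weights))
      stop_arg("pretrained = TRUE requires a `weights` parameter list")
    ch <- net_set_params(list(img = ch), weights)$img
  }
  attr(ch, "n_blocks") <- 5
  ch
}

#' Fuse two branches into a classifier network
#'
#' Concatenates the two branch outputs and adds three ReLU dense layers of
#' 1024, 512 and 128 units, then the output head(s): a single softmax over
#' `n_classes`, or, for the multi-task variants, a 3-class modality softmax
#' (B/E/H) plus an intensity head — 4-class softmax (`softmax_softmax`),
#' linear scalar trained with squared error (`softmax_mse`), or sigmoid
#' scalar trained with cross-entropy (`softmax_sigmoid`).
#'
#' @param image_branch,prediction_branch built chains (see
#'   [build_simple_cnn()], [build_reduced_mnv2()]).
#' @param n_classes number of classes of the single-task head.
#' @param mtl_variant see [architecture_spec()].
#' @return a `painface_cnn` network object (untrained).
#' @export
build_fusion <- function(image_branch, prediction_branch, n_classes,
                         mtl_variant = "none") {
  if (!mtl_variant %in% c("none", "softmax_softmax", "softmax_mse",
                          "softmax_sigmoid"))
    stop_arg("invalid mtl_variant %s", mtl_variant)
  fdim <- attr(image_branch, "output_shape") +
    attr(prediction_branch, "output_shape")
  trunk <- chain_build(list(layer_dense(1024), layer_relu(),
                            layer_dense(512), layer_relu(),
                            layer_dense(128), layer_relu()), fdim)
  chains <- list(img = image_branch, pred = prediction_branch, trunk = trunk)
  if (mtl_variant == "none") {
    chains$head_main <- chain_build(list(layer_dense(n_classes)), 128)
  } else {
    chains$head_mod <- chain_build(list(layer_dense(3)), 128)
    int_units <- if (mtl_variant == "softmax_softmax") 4 else 1
    chains$head_int <- chain_build(list(layer_dense(int_units)), 128)
  }
  structure(list(chains = chains, mtl_variant = mtl_variant,
                 n_classes = n_classes),
            class = "painface_cnn")
}

net_forward <- function(net, ximg, xpred, keep_cache = FALSE) {
  f1 <- chain_forward(net$chains$img, ximg, keep_cache)
  f2 <- chain_forward(net$chains$pred, xpred, keep_cache)
  z <- cbind(f1$out, f2$out)
  tr <- chain_forward(net$chains$trunk, z, keep_cache)
  heads <- list()
  hc <- list()
  for (hn in grep("^head_", names(net$chains), value = TRUE)) {
    h <- chain_forward(net$chains[[hn]], tr$out, keep_cache)
    heads[[hn]] <- h$out
    hc[[hn]] <- h$caches
  }
  list(heads = heads,
       cache = if (keep_cache) list(img = f1$caches, pred = f2$caches,
                                    trunk = tr$caches, heads = hc,
                                    nimg = ncol(f1$out)) else NULL)
}

net_backward <- function(net, cache, head_grads) {
  grad_lists <- list()
  gh <- 0
  for (hn in names(head_grads)) {
    bw <- chain_backward(net$chains[[hn]], cache$heads[[hn]],
                         head_grads[[hn]])
    grad_lists[[hn]] <- bw$grads
    gh <- gh + bw$gin
  }
  bt <- chain_backward(net$chains$trunk, cache$trunk, gh)
  grad_lists$trunk <- bt$grads
  n1 <- cache$nimg
  b1 <- chain_backward(net$chains$img, cache$img,
                       bt$gin[, seq_len(n1), drop = FALSE])
  b2 <- chain_backward(net$chains$pred, cache$pred,
                       bt$gin[, -seq_len(n1), drop = FALSE])
  grad_lists$img <- b1$grads
  grad_lists$pred <- b2$grads
  grads_to_params(net$chains, grad_lists)
}

mtl_targets <- function(labels) {
  list(modality = match(substr(labels, 1, 1), c("B", "E", "H")),
       intensity = ifelse(labels == "B", 0L,
                          as.integer(substr(labels, 2, 2))))
}

# loss value and per-head output gradients for one batch
net_loss_grads <- function(net, heads, labels, class_list) {
  n <- length(labels)
  if (net$mtl_variant == "none") {
    z <- heads$head_main
    p <- softmax_rows(z)
    yi <- match(labels, class_list)
    loss <- -mean(log(pmax(p[cbind(seq_len(n), yi)], 1e-12)))
    gy <- p
    gy[cbind(seq_len(n), yi)] <- gy[cbind(seq_len(n), yi)] - 1
    return(list(loss = loss, grads = list(head_main = gy / n)))
  }
  tg <- mtl_targets(labels)
  pm <- softmax_rows(heads$head_mod)
  loss_m <- -mean(log(pmax(pm[cbind(seq_len(n), tg$modality)], 1e-12)))
  gm <- pm
  gm[cbind(seq_len(n), tg$modality)] <- gm[cbind(seq_len(n),
                                                 tg$modality)] - 1
  out <- list(head_mod = gm / n)
  if (net$mtl_variant == "softmax_softmax") {
    pi <- softmax_rows(heads$head_int)
    ii <- tg$intensity + 1L
    loss_i <- -mean(log(pmax(pi[cbind(seq_len(n), ii)], 1e-12)))
    gi <- pi
    gi[cbind(seq_len(n), ii)] <- gi[cbind(seq_len(n), ii)] - 1
    out$head_int <- gi / n
  } else if (net$mtl_variant == "softmax_mse") {
    z <- heads$head_int[, 1]
    loss_i <- mean((z - tg$intensity)^2)
    out$head_int <- matrix(2 * (z - tg$intensity) / n, ncol = 1)
  } else {
    s <- stats::plogis(heads$head_int[, 1])
    t <- tg$intensity / 3
    loss_i <- -mean(t * log(pmax(s, 1e-12)) +
                      (1 - t) * log(pmax(1 - s, 1e-12)))
    out$head_int <- matrix((s - t) / n, ncol = 1)
  }
  list(loss = loss_m + loss_i, grads = out)
}

#' Train a random forest classifier
#'
#' Probability forest (via ranger) over either flattened spatio-temporal
#' pixel vectors (`rfc_bl`) or facial activity descriptors (`rfc_fad`).
#' The study setting is 5000 trees; scale down for experiments.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels class codes, same length as `nrow(features)`.
#' @param n_trees number of trees.
#' @param seed RNG seed; fixes the tree seeds, so accuracy is reproducible.
#' @param kind `"rfc_fad"` or `"rfc_bl"` (metadata only).
#' @return a `painface_model` whose [predict()] returns per-class
#'   probability rows summing to 1.
#' @export
train_forest <- function(features, labels, n_trees = 5000, seed = 1,
                         kind = "rfc_fad") {
  labels <- as.character(labels)
  class_list <- intersect(class_codes(), unique(labels))
  if (length(class_list) < 2)
    stop_arg("training set contains a single class (%s)", labels[1])
  if (nrow(features) < length(class_list))
    stop_arg("fewer samples than classes")
  df <- data.frame(features, check.names = FALSE)
  fit <- ranger::ranger(x = df,
                        y = factor(labels, levels = class_list),
                        num.trees = n_trees, probability = TRUE,
                        seed = seed, num.threads = 1)
  structure(list(kind = kind, fit = fit, class_list = class_list,
                 n_trees = n_trees),
            class = c("painface_forest", "painface_model"))
}

#' Train a fusion CNN
#'
#' Builds the network described by `spec` (two-CNN or reduced-MNV2 fusion,
#' optional multi-task heads) and trains it with Adam at the configured
#' learning rate on paired (spatio-temporal image, prediction image)
#' inputs. Deterministic given the seed and a fixed thread count.
#' `epochs = 0` returns the model at initialisation.
#'
#' @param spec an [architecture_spec()] with a CNN kind.
#' @param inputs list with `images` (H x W x 3 x N array) and `pred`
#'   (p x p x 1 x N array of prediction images).
#' @param labels class codes of length N.
#' @param epochs,lr,batch_size override the spec's settings.
#' @param seed RNG seed for initialisation and batch shuffling.
#' @param verbose print per-epoch loss.
#' @return a `painface_model` with `loss_history`.
#' @export
train_cnn <- function(spec, inputs, labels, epochs = NULL, lr = NULL,
                      batch_size = NULL, seed = 1, verbose = FALSE) {
  if (!grepl("fusion", spec$kind))
    stop_arg("train_cnn() needs a CNN architecture kind")
  labels <- as.character(labels)
  class_list <- intersect(class_codes(), unique(labels))
  epochs <- epochs %||% spec$epochs
  lr <- lr %||% spec$learning_rate
  batch_size <- batch_size %||% spec$batch_size
  ximg <- inputs$images
  xpred <- inputs$pred
  n <- dim(ximg)[4]
  if (dim(xpred)[4] != n || length(labels) != n)
    stop_arg("images, prediction images and labels disagree in length")
  net <- with_local_seed(seed, {
    img_branch <- if (spec$kind == "mnv2_fusion")
      build_reduced_mnv2(dim(ximg)[1:3],
                         pretrained = spec$pretrained_backbone)
    else build_simple_cnn(dim(ximg)[1:3])
    build_fusion(img_branch, build_simple_cnn(dim(xpred)[1:3]),
                 n_classes = length(class_list),
                 mtl_variant = spec$mtl_variant)
  })
  params <- net_params(net$chains)
  opt <- adam_init(params)
  losses <- numeric(0)
  if (epochs > 0) with_local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        fw <- net_forward(net, ximg[, , , idx, drop = FALSE],
                          xpred[, , , idx, drop = FALSE], keep_cache = TRUE)
        lg <- net_loss_grads(net, fw$heads, labels[idx], class_list)
        if (!is.finite(lg$loss))
          stop_arg("training diverged: non-finite loss at epoch %d", ep)
        grads <- net_backward(net, fw$cache, lg$grads)
        st <- adam_step(params, grads, opt, lr)
        params <- st$params
        opt <- st$state
        net$chains <- net_set_params(net$chains, params)
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      losses[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, losses[ep]))
    }
  })
  structure(list(kind = spec$kind, spec = spec, net = net,
                 class_list = class_list, loss_history = losses),
            class = c("painface_cnn_model", "painface_model"))
}

#' @export
print.painface_model <- function(x, ...) {
  cat(sprintf("painface_model (%s), classes: %s\n", x$kind,
              paste(x$class_list, collapse = " ")))
  invisible(x)
}

#' Predict per-class scores
#'
#' Rows are probability vectors over `class_list` summing to 1. For
#' multi-task models the two heads are combined into joint 7-class scores:
#' `p(B) = p_mod(B) p_int(0)`, `p(Mk) = p_mod(M) p_int(k)`, renormalised;
#' scalar intensity heads contribute a one-hot vector at the rounded
#' intensity (clamped to 0..3).
#'
#' @param object a `painface_model`.
#' @param newdata feature matrix (forests) or `list(images, pred)` (CNNs).
#' @param ... unused.
#' @return numeric matrix N x K with `colnames = class_list`.
#' @export
predict.painface_forest <- function(object, newdata, ...) {
  p <- predict(object$fit, data.frame(newdata, check.names = FALSE),
               num.threads = 1)$predictions
  p <- p[, object$class_list, drop = FALSE]
  p / rowSums(p)
}

intensity_probs <- function(net, heads) {
  if (net$mtl_variant == "softmax_softmax")
    return(softmax_rows(heads$head_int))
  z <- heads$head_int[, 1]
  val <- if (net$mtl_variant == "softmax_mse") z else 3 * stats::plogis(z)
  k <- pmin(pmax(round(val), 0), 3)
  out <- matrix(0, length(k), 4)
  out[cbind(seq_along(k), k + 1L)] <- 1
  out
}

#' @rdname predict.painface_forest
#' @export
predict.painface_cnn_model <- function(object, newdata, ...) {
  fw <- net_forward(object$net, newdata$images, newdata$pred)
  if (object$net$mtl_variant == "none") {
    p <- softmax_rows(fw$heads$head_main)
    colnames(p) <- object$class_list
    return(p)
  }
  pm <- softmax_rows(fw$heads$head_mod)  # columns B, E, H
  pi <- intensity_probs(object$net, fw$heads)
  joint <- cbind(pm[, 1] * pi[, 1],
                 pm[, 3] * pi[, 2], pm[, 3] * pi[, 3], pm[, 3] * pi[, 4],
                 pm[, 2] * pi[, 2], pm[, 2] * pi[, 3], pm[, 2] * pi[, 4])
  colnames(joint) <- class_codes()
  joint <- joint[, intersect(class_codes(), object$class_list),
                 drop = FALSE]
  joint / pmax(rowSums(joint), 1e-12)
}

#' Hard class labels from a score matrix
#'
#' Argmax per row with lowest-index tie-break (so uniform scores map to the
#' first class in canonical order).
#'
#' @param scores matrix with class codes as column names.
#' @return character vector of class codes.
#' @export
hard_labels <- function(scores) {
  colnames(scores)[apply(scores, 1, which.max)]
}

#' Map multi-task head outputs to a 7-class code
#'
#' `B` if and only if the predicted intensity is 0; otherwise the modality
#' head decides between `E` and `H` (by their head probabilities) and the
#' intensity attaches.
#'
#' @param modality character vector in `c("B","E","H")` or a 3-column
#'   probability matrix (columns B, E, H).
#' @param intensity integer vector in 0..3.
#' @return character class codes.
#' @export
mtl_to_class <- function(modality, intensity) {
  if (is.matrix(modality)) {
    # letter used when intensity > 0: the better of E/H even when B tops
    pick <- ifelse(modality[, 2] >= modality[, 3], "E", "H")
    top <- c("B", "E", "H")[max.col(modality, ties.method = "first")]
    modality <- ifelse(top == "B", pick, top)
  }
  if (any(modality == "B" & intensity > 0))
    stop_arg("modality 'B' is incompatible with a positive intensity")
  ifelse(intensity == 0, "B", paste0(modality, intensity))
}
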