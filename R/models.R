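#' Training configuration for the neural classifiers
#'
#' Collects architecture and optimisation settings shared by the uni-modal
#' and multi-modal trainers. Defaults follow the referral-cascade setup
#' (two dropout layers at rate 0.40 in the tabular branch, Adam with a
#' decaying initial learning rate of 1e-3, cross-entropy loss for
#' Monte-Carlo-dropout models and the evidential sum-of-squares loss for
#' evidential models); widths, depths and the decay factor are package
#' defaults chosen for CPU-scale cohorts.
#'
#' @param loss `"edl_sos"` (evidential head: ReLU evidence, sum-of-squares
#'   Dirichlet loss) or `"cross_entropy"` (softmax head).
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param lr Initial Adam learning rate (> 0).
#' @param lr_decay Exponential decay factor applied per epoch.
#' @param hidden Integer vector of hidden widths of the tabular branch; each
#'   hidden layer is followed by ReLU and dropout.
#' @param embed_dim Width of the penultimate (embedding) layer of the
#'   tabular branch.
#' @param dropout Dropout rate of the tabular-branch dropout layers.
#' @param img_channels Channel widths of the image branch: stem convolution
#'   then one residual block per remaining entry (strided), plus a final
#'   stride-1 block.
#' @param img_embed_dim Width of the image-branch embedding after global
#'   average pooling.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   weight matrices (effective per-step shrinkage is `lr * weight_decay`).
#'   The default keeps weight norms, and hence logits on out-of-support
#'   inputs, temperate -- without it the dropout-based uncertainty saturates
#'   under heavy input corruption.
#' @param kl_weight Optional KL-regulariser weight for the evidential loss
#'   (default 0: plain sum-of-squares).
#' @param transform Tabular feature transform applied before scaling:
#'   `"log1p"` (default; region volumes are positive and right-skewed with
#'   multiplicative class effects, so the log scale linearises them) or
#'   `"none"`.
#' @param scaling Per-feature scaling fitted on the training data:
#'   `"zscore"` or `"minmax"`. `"auto"` resolves by loss: evidential models
#'   z-score (their vacuity point is the feature baseline), cross-entropy /
#'   Monte-Carlo models min-max scale (out-of-support values stay bounded).
#' @param missing Handling of exact-zero raw volumes, which are physically
#'   implausible and mark absent measurements: `"impute_mean"` maps them to
#'   the scaled training mean (no deviation from baseline; required by the
#'   evidential head so that absent evidence yields vacuity), `"as_is"`
#'   passes the scaled zero through (missingness stays visible to the model
#'   as an out-of-support input, which is what Monte-Carlo dropout
#'   instability responds to). `"auto"` resolves by loss.
#' @param seed Integer seed; training is bit-reproducible on one machine.
#' @return A `train_config` list.
#' @export
train_config <- function(loss = c("edl_sos", "cross_entropy"),
                         epochs = 60,
                         batch_size = 32,
                         lr = 1e-3,
                         lr_decay = 0.96,
                         hidden = c(256, 128),
                         embed_dim = 64,
                         dropout = 0.4,
                         img_channels = c(8, 16, 32),
                         img_embed_dim = 64,
                         weight_decay = 0.2,
                         kl_weight = 0,
                         transform = c("log1p", "none"),
                         scaling = c("auto", "zscore", "minmax"),
                         missing = c("auto", "impute_mean", "as_is"),
                         seed = 1) {
  loss <- match.arg(loss)
  transform <- match.arg(transform)
  scaling <- match.arg(scaling)
  missing <- match.arg(missing)
  if (scaling == "auto") scaling <- if (loss == "edl_sos") "zscore" else "minmax"
  if (missing == "auto") missing <- if (loss == "edl_sos") "impute_mean" else "as_is"
  if (lr <= 0) stop("`lr` must be > 0", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  structure(list(loss = loss, epochs = epochs, batch_size = batch_size,
                 lr = lr, lr_decay = lr_decay, hidden = hidden,
                 embed_dim = embed_dim, dropout = dropout,
                 img_channels = img_channels, img_embed_dim = img_embed_dim,
                 weight_decay = weight_decay, kl_weight = kl_weight,
                 transform = transform, scaling = scaling, missing = missing,
                 seed = seed),
            class = "train_config")
}

feature_columns <- function(records) {
  reg <- grep("^region_\\d+$", names(records), value = TRUE)
  if (length(reg) == 0) stop("no `region_*` feature columns found", call. = FALSE)
  reg
}

records_matrix <- function(records, cols = feature_columns(records)) {
  X <- as.matrix(records[cols])
  storage.mode(X) <- "double"
  X
}

records_classes <- function(records) {
  lab <- records$label
  if (is.null(lab)) stop("records must have a `label` column", call. = FALSE)
  if (is.factor(lab)) levels(lab) else sort(unique(as.character(lab)))
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

# image list-columns -> N x H x W x 6 tensor (left channels 1:3, right 4:6)
image_tensor <- function(records) {
  if (is.null(records$image_left) || is.null(records$image_right)) {
    stop("records must have `image_left` and `image_right` list-columns", call. = FALSE)
  }
  d <- dim(records$image_left[[1]])
  n <- nrow(records)
  X <- array(0, c(n, d[1], d[2], 6))
  for (i in seq_len(n)) {
    li <- records$image_left[[i]]
    ri <- records$image_right[[i]]
    if (!identical(dim(li), d) || !identical(dim(ri), d)) {
      stop("inconsistent image dimensions in records", call. = FALSE)
    }
    X[i, , , 1:3] <- li
    X[i, , , 4:6] <- ri
  }
  X - 0.5
}

build_tab_trunk <- function(d_in, config) {
  layers <- list()
  for (w in config$hidden) {
    layers <- c(layers, list(nn_dense(d_in, w), nn_relu(), nn_dropout(config$dropout)))
    d_in <- w
  }
  c(layers, list(nn_dense(d_in, config$embed_dim), nn_relu()))
}

build_img_trunk <- function(config) {
  ch <- config$img_channels
  layers <- list(nn_conv(3, 6, ch[1], stride = 2), nn_relu())
  c_in <- ch[1]
  for (c_out in ch[-1]) {
    layers <- c(layers, list(nn_resblock(c_in, c_out, stride = 2)))
    c_in <- c_out
  }
  layers <- c(layers, list(nn_resblock(c_in, c_in, stride = 1), nn_gap(),
                           nn_dense(c_in, config$img_embed_dim), nn_relu()))
  layers
}

head_eval <- function(config, z, Y) {
  if (config$loss == "cross_entropy") head_softmax_ce(z, Y) else head_edl(z, Y)
}

transform_features <- function(X, transform) {
  if (transform == "log1p") {
    if (any(X < 0)) stop("log1p transform requires non-negative features", call. = FALSE)
    log1p(X)
  } else X
}

check_two_classes <- function(labels, classes) {
  tab <- table(factor(as.character(labels), levels = classes))
  if (length(classes) < 2 || any(tab < 2)) {
    stop("training records must contain at least 2 instances of each class",
         call. = FALSE)
  }
}

#' Train the uni-modal tabular classifier
#'
#' Fits a multilayer perceptron over the per-region volume columns of
#' `records` (log-transformed and scaled on the training data; see `scaling`/`missing` in [train_config()]), with two dropout layers in the
#' default architecture and either a softmax or an evidential head. The
#' penultimate layer is the embedding `g(x)` used by the distance-based gate.
#'
#' @param records A tibble of training subjects with `region_*` columns and a
#'   `label` column (factor `cn`/`ad`).
#' @param config A [train_config()].
#' @return A `unimodal_model` object with elements `net` (trunk + head),
#'   `scaler`, `classes`, `history` (tibble of per-epoch mean loss), `config`.
#' @export
train_unimodal <- function(records, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  cols <- feature_columns(records)
  classes <- records_classes(records)
  check_two_classes(records$label, classes)
  X_raw <- records_matrix(records, cols)
  scaler <- fit_scaler(transform_features(X_raw, config$transform), config)
  Xs <- apply_scaler(X_raw, config, scaler)
  Y <- one_hot(records$label, classes)
  K <- length(classes)

  withr::with_seed(config$seed, {
    trunk <- build_tab_trunk(ncol(Xs), config)
    head <- nn_dense(config$embed_dim, K)
    st <- adam_state_new()
    history <- numeric(config$epochs)
    n <- nrow(Xs)
    for (ep in seq_len(config$epochs)) {
      lr <- config$lr * config$lr_decay^(ep - 1)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        ft <- stack_forward(trunk, Xs[idx, , drop = FALSE], stochastic = TRUE)
        fh <- layer_forward(head, ft$y)
        hv <- head_eval(config, fh$y, Y[idx, , drop = FALSE])
        losses <- c(losses, hv$loss)
        bh <- layer_backward(head, fh$cache, hv$dz)
        bt <- stack_backward(trunk, ft$caches, bh$dx)
        layers <- adam_step(c(trunk, list(head)), c(bt$grads, list(bh$grads)),
                            st, lr, weight_decay = config$weight_decay)
        trunk <- layers[seq_along(trunk)]
        head <- layers[[length(layers)]]
      }
      history[ep] <- mean(losses)
    }
    structure(list(net = list(trunk = trunk, head = head),
                   scaler = scaler,
                   feature_cols = cols,
                   classes = classes,
                   config = config,
                   history = tibble::tibble(epoch = seq_len(config$epochs),
                                            loss = history)),
              class = c("unimodal_model", "mg_model"))
  })
}

#' Train the late-fusion multi-modal classifier
#'
#' Fits a model whose tabular branch has the same architecture as the
#' uni-modal model's and whose image branch is a small residual convolutional
#' network over the stacked left/right images (6 input channels). The two
#' branch embeddings are concatenated at the latent space and a linear head
#' produces the class outputs; the fused embedding is the model's penultimate
#' representation.
#'
#' @inheritParams train_unimodal
#' @return A `multimodal_model` object.
#' @export
train_multimodal <- function(records, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  cols <- feature_columns(records)
  classes <- records_classes(records)
  check_two_classes(records$label, classes)
  X_raw <- records_matrix(records, cols)
  scaler <- fit_scaler(transform_features(X_raw, config$transform), config)
  Xs <- apply_scaler(X_raw, config, scaler)
  IMG <- image_tensor(records)
  Y <- one_hot(records$label, classes)
  K <- length(classes)

  withr::with_seed(config$seed, {
    tab <- build_tab_trunk(ncol(Xs), config)
    img <- build_img_trunk(config)
    head <- nn_dense(config$embed_dim + config$img_embed_dim, K)
    n_tab <- length(tab); n_img <- length(img)
    st <- adam_state_new()
    history <- numeric(config$epochs)
    n <- nrow(Xs)
    for (ep in seq_len(config$epochs)) {
      lr <- config$lr * config$lr_decay^(ep - 1)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        ft <- stack_forward(tab, Xs[idx, , drop = FALSE], stochastic = TRUE)
        fi <- stack_forward(img, IMG[idx, , , , drop = FALSE], stochastic = TRUE)
        z <- cbind(ft$y, fi$y)
        fh <- layer_forward(head, z)
        hv <- head_eval(config, fh$y, Y[idx, , drop = FALSE])
        losses <- c(losses, hv$loss)
        bh <- layer_backward(head, fh$cache, hv$dz)
        e_t <- ncol(ft$y)
        bt <- stack_backward(tab, ft$caches, bh$dx[, seq_len(e_t), drop = FALSE])
        bi <- stack_backward(img, fi$caches, bh$dx[, -seq_len(e_t), drop = FALSE])
        layers <- adam_step(c(tab, img, list(head)),
                            c(bt$grads, bi$grads, list(bh$grads)), st, lr,
                            weight_decay = config$weight_decay)
        tab <- layers[seq_len(n_tab)]
        img <- layers[n_tab + seq_len(n_img)]
        head <- layers[[n_tab + n_img + 1]]
      }
      history[ep] <- mean(losses)
    }
    structure(list(net = list(tab = tab, img = img, head = head),
                   scaler = scaler,
                   feature_cols = cols,
                   classes = classes,
                   config = config,
                   history = tibble::tibble(epoch = seq_len(config$epochs),
                                            loss = history)),
              class = c("multimodal_model", "mg_model"))
  })
}

fit_scaler <- function(Xt, config) {
  if (config$scaling == "zscore") {
    ctr <- colMeans(Xt)
    scl <- pmax(apply(Xt, 2, stats::sd), 1e-8)
  } else {
    ctr <- apply(Xt, 2, min)
    scl <- pmax(apply(Xt, 2, max) - ctr, 1e-8)
  }
  Z <- scale(Xt, ctr, scl)
  list(center = ctr, scale = scl, scaled_mean = colMeans(Z))
}

# Exact-zero raw volumes are physically implausible: they mark an absent
# measurement, not a tiny structure. Under "impute_mean" they are mapped to
# the scaled training mean, so a record loses information (rather than
# gaining spurious signal) as more regions are blanked.
apply_scaler <- function(X_raw, config, scaler) {
  Z <- scale(transform_features(X_raw, config$transform),
             scaler$center, scaler$scale)
  if (config$missing == "impute_mean") {
    miss <- X_raw == 0
    if (any(miss)) Z[miss] <- matrix(scaler$scaled_mean, nrow(Z), ncol(Z),
                                     byrow = TRUE)[miss]
  }
  Z
}

scale_features <- function(model, records) {
  apply_scaler(records_matrix(records, model$feature_cols), model$config,
               model$scaler)
}

# deterministic (dropout-off) forward to the head logits
forward_logits <- function(model, records, stochastic = FALSE) {
  if (inherits(model, "unimodal_model")) {
    ft <- stack_forward(model$net$trunk, scale_features(model, records), stochastic)
    layer_forward(model$net$head, ft$y)$y
  } else {
    ft <- stack_forward(model$net$tab, scale_features(model, records), stochastic)
    fi <- stack_forward(model$net$img, image_tensor(records), stochastic)
    layer_forward(model$net$head, cbind(ft$y, fi$y))$y
  }
}

logits_to_probs <- function(model, z) {
  if (model$config$loss == "cross_entropy") {
    list(prob = softmax_rows(z), uncertainty = NULL)
  } else {
    s <- opinion_summary(pmax(z, 0))
    list(prob = s$prob, uncertainty = s$uncertainty)
  }
}

#' Predict from a fitted uni-modal or multi-modal model
#'
#' @param object A fitted `unimodal_model` or `multimodal_model`.
#' @param newdata A tibble of subjects (with image list-columns for the
#'   multi-modal model).
#' @param type `"prob"` for per-class expected probabilities, `"class"` for
#'   the argmax label, `"opinion"` (evidential models only) for
#'   probabilities plus the Dirichlet uncertainty mass and strength.
#' @param ... Unused.
#' @return A tibble with `.pred_<class>` columns (`prob`), a `.pred_class`
#'   column (`class`), or both plus `.uncertainty` and `.strength`
#'   (`opinion`).
#' @export
predict.unimodal_model <- function(object, newdata,
                                   type = c("prob", "class", "opinion"), ...) {
  predict_mg(object, newdata, match.arg(type))
}

#' @rdname predict.unimodal_model
#' @export
predict.multimodal_model <- function(object, newdata,
                                     type = c("prob", "class", "opinion"), ...) {
  predict_mg(object, newdata, match.arg(type))
}

predict_mg <- function(model, newdata, type) {
  z <- forward_logits(model, newdata)
  res <- logits_to_probs(model, z)
  p <- res$prob
  cls <- model$classes
  out <- tibble::as_tibble(stats::setNames(as.data.frame(p), paste0(".pred_", cls)))
  out$.pred_class <- factor(cls[max.col(p, ties.method = "first")], levels = cls)
  if (type == "prob") return(out[paste0(".pred_", cls)])
  if (type == "class") return(out[".pred_class"])
  if (model$config$loss != "edl_sos") {
    stop("`type = \"opinion\"` requires an evidential model (loss = \"edl_sos\")",
         call. = FALSE)
  }
  out$.uncertainty <- res$uncertainty
  out$.strength <- rowSums(pmax(z, 0) + 1)
  out
}

#' Penultimate-layer embeddings
#'
#' Deterministic (dropout-off) activations at the penultimate layer: the
#' tabular embedding `g(x)` for the uni-modal model, the fused
#' tabular+image embedding for the multi-modal model. Used by the
#' distance-based gate.
#'
#' @param model A fitted model.
#' @param records A tibble of subjects.
#' @param ... Passed to methods.
#' @return A numeric matrix, one row per subject.
#' @export
embed <- function(model, records, ...) UseMethod("embed")

#' @rdname embed
#' @export
embed.unimodal_model <- function(model, records, ...) {
  stack_forward(model$net$trunk, scale_features(model, records), FALSE)$y
}

#' @rdname embed
#' @export
embed.multimodal_model <- function(model, records, ...) {
  ft <- stack_forward(model$net$tab, scale_features(model, records), FALSE)
  fi <- stack_forward(model$net$img, image_tensor(records), FALSE)
  cbind(ft$y, fi$y)
}

#' @export
print.mg_model <- function(x, ...) {
  cat(sprintf("<%s> loss=%s classes=%s epochs=%d final loss=%.4g\n",
              class(x)[1], x$config$loss, paste(x$classes, collapse = "/"),
              nrow(x$history), utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @describeIn train_unimodal per-epoch training history as a tibble.
#' @param x A fitted model.
#' @param ... Unused.
#' @export
tidy.mg_model <- function(x, ...) x$history

count_params <- function(layers) {
  n <- 0
  walk <- function(l) {
    for (nm in names(l)) {
      if (nm %in% c("W", "b")) n <<- n + length(l[[nm]])
      else if (is.list(l[[nm]])) walk(l[[nm]])
    }
  }
  for (l in layers) walk(l)
  n
}

#' @describeIn train_unimodal one-row model summary (loss type, epochs,
#'   final training loss, parameter count, seed).
#' @export
glance.mg_model <- function(x, ...) {
  layers <- if (inherits(x, "unimodal_model")) {
    c(x$net$trunk, list(x$net$head))
  } else {
    c(x$net$tab, x$net$img, list(x$net$head))
  }
  tibble::tibble(loss_type = x$config$loss,
                 epochs = nrow(x$history),
                 final_loss = utils::tail(x$history$loss, 1),
                 n_parameters = count_params(layers),
                 seed = x$config$seed)
}
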