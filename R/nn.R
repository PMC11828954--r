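# Minimal neural-network engine: dense / conv2d / dropout / residual blocks,
# manual backprop, Adam with exponential learning-rate decay. All state is
# plain R lists of numeric arrays; all randomness comes from R's RNG so that
# seeded training is bit-reproducible on one machine.
#
# Conventions: batches of tabular data are N x D matrices; batches of images
# are N x H x W x C arrays. A "layer stack" is an unnamed list of layers; each
# layer is a named list with a `kind` field and its parameter arrays.

nn_he_init <- function(fan_in, n) {
  stats::rnorm(n, mean = 0, sd = sqrt(2 / fan_in))
}

nn_dense <- function(d_in, d_out) {
  list(kind = "dense",
       W = matrix(nn_he_init(d_in, d_in * d_out), d_in, d_out),
       b = numeric(d_out))
}

nn_relu <- function() list(kind = "relu")

nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", rate = rate)
}

nn_conv <- function(k, c_in, c_out, stride = 1, pad = (k - 1) %/% 2) {
  fan_in <- k * k * c_in
  list(kind = "conv",
       W = array(nn_he_init(fan_in, fan_in * c_out), c(k, k, c_in, c_out)),
       b = numeric(c_out),
       k = k, stride = stride, pad = pad)
}

nn_gap <- function() list(kind = "gap")

# Pre-activation-free basic residual block: y = relu(conv2(relu(conv1(x))) + skip)
# with a 1x1 strided projection on the skip path when shape changes.
nn_resblock <- function(c_in, c_out, stride = 1) {
  proj <- if (stride != 1 || c_in != c_out) nn_conv(1, c_in, c_out, stride, pad = 0) else NULL
  list(kind = "resblock",
       conv1 = nn_conv(3, c_in, c_out, stride),
       conv2 = nn_conv(3, c_out, c_out, 1),
       proj = proj)
}

# im2col index matrix: idx[p, j] is the column of the padded N x (Hp*Wp*C)
# matrix holding kernel cell j of patch p (patches ordered row index fastest).
conv_indices <- function(Hp, Wp, C, k, stride) {
  H2 <- (Hp - k) %/% stride + 1
  W2 <- (Wp - k) %/% stride + 1
  h0 <- (seq_len(H2) - 1L) * stride
  w0 <- (seq_len(W2) - 1L) * stride
  A <- 1L + rep(h0, times = W2) + Hp * rep(w0, each = H2)
  oh <- rep(0:(k - 1L), times = k * C)
  ow <- rep(rep(0:(k - 1L), each = k), times = C)
  oc <- rep(0:(C - 1L), each = k * k)
  B <- oh + Hp * ow + Hp * Wp * oc
  list(idx = outer(A, B, "+"), H2 = H2, W2 = W2)
}

conv_pad <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

conv_forward <- function(layer, x) {
  d <- dim(x); N <- d[1]; C <- d[4]
  xp <- conv_pad(x, layer$pad)
  dp <- dim(xp); Hp <- dp[2]; Wp <- dp[3]
  ci <- conv_indices(Hp, Wp, C, layer$k, layer$stride)
  P <- ci$H2 * ci$W2
  KC <- layer$k * layer$k * C
  xmat <- x_as_mat(xp)
  Pm <- xmat[, as.vector(ci$idx), drop = FALSE]
  dim(Pm) <- c(N * P, KC)
  Wmat <- layer$W
  dim(Wmat) <- c(KC, length(layer$b))
  out <- Pm %*% Wmat
  out <- out + rep(layer$b, each = N * P)
  y <- out
  dim(y) <- c(N, ci$H2, ci$W2, length(layer$b))
  list(y = y,
       cache = list(Pm = Pm, idx = ci$idx, N = N, P = P, KC = KC,
                    Hp = Hp, Wp = Wp, C = C, H = d[2], W = d[3]))
}

x_as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

conv_backward <- function(layer, cache, dy) {
  N <- cache$N; P <- cache$P; KC <- cache$KC
  c_out <- length(layer$b)
  dim(dy) <- c(N * P, c_out)
  dW <- crossprod(cache$Pm, dy)
  dim(dW) <- dim(layer$W)
  db <- colSums(dy)
  Wmat <- layer$W
  dim(Wmat) <- c(KC, c_out)
  dPm <- dy %*% t(Wmat)
  dim(dPm) <- c(N, P * KC)
  dxp <- matrix(0, N, cache$Hp * cache$Wp * cache$C)
  idx <- cache$idx
  for (j in seq_len(KC)) {
    cols <- idx[, j]
    dxp[, cols] <- dxp[, cols] + dPm[, (j - 1L) * P + seq_len(P), drop = FALSE]
  }
  dim(dxp) <- c(N, cache$Hp, cache$Wp, cache$C)
  pad <- layer$pad
  dx <- if (pad > 0) {
    dxp[, pad + seq_len(cache$H), pad + seq_len(cache$W), , drop = FALSE]
  } else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

# mode: list(stochastic = TRUE/FALSE) -- dropout draws masks only when stochastic.
layer_forward <- function(layer, x, stochastic = FALSE) {
  switch(layer$kind,
    dense = {
      y <- x %*% layer$W
      y <- y + rep(layer$b, each = nrow(y))
      list(y = y, cache = x)
    },
    relu = {
      y <- pmax(x, 0)
      list(y = y, cache = y)
    },
    dropout = {
      if (stochastic && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        y <- x * mask
        if (!is.null(dim(x))) dim(y) <- dim(x)
        list(y = y, cache = mask)
      } else {
        list(y = x, cache = NULL)
      }
    },
    conv = conv_forward(layer, x),
    gap = {
      d <- dim(x)
      xa <- aperm(x, c(2, 3, 1, 4))
      dim(xa) <- c(d[2] * d[3], d[1] * d[4])
      y <- colSums(xa) / (d[2] * d[3])
      dim(y) <- c(d[1], d[4])
      list(y = y, cache = d)
    },
    resblock = {
      r1 <- conv_forward(layer$conv1, x)
      a1 <- pmax(r1$y, 0)
      r2 <- conv_forward(layer$conv2, a1)
      if (!is.null(layer$proj)) {
        rp <- conv_forward(layer$proj, x)
        skip <- rp$y
      } else {
        rp <- NULL
        skip <- x
      }
      y <- pmax(r2$y + skip, 0)
      list(y = y, cache = list(c1 = r1$cache, a1 = a1, c2 = r2$cache,
                               cp = if (is.null(rp)) NULL else rp$cache, y = y))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$kind,
    dense = {
      list(dx = dy %*% t(layer$W),
           grads = list(W = crossprod(cache, dy), b = colSums(dy)))
    },
    relu = {
      dx <- dy * (cache > 0)
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) return(list(dx = dy, grads = NULL))
      dx <- dy * cache
      if (!is.null(dim(dy))) dim(dx) <- dim(dy)
      list(dx = dx, grads = NULL)
    },
    conv = conv_backward(layer, cache, dy),
    gap = {
      d <- cache
      M <- d[2] * d[3]
      tmp <- array(as.vector(dy) / M, c(d[1], d[4], M))
      dx <- aperm(tmp, c(1, 3, 2))
      dim(dx) <- c(d[1], d[2], d[3], d[4])
      list(dx = dx, grads = NULL)
    },
    resblock = {
      dpre <- dy * (cache$y > 0)
      b2 <- conv_backward(layer$conv2, cache$c2, dpre)
      da1 <- b2$dx * (cache$a1 > 0)
      b1 <- conv_backward(layer$conv1, cache$c1, da1)
      if (!is.null(layer$proj)) {
        bp <- conv_backward(layer$proj, cache$cp, dpre)
        dx <- b1$dx + bp$dx
        grads <- list(conv1 = b1$grads, conv2 = b2$grads, proj = bp$grads)
      } else {
        dx <- b1$dx + dpre
        grads <- list(conv1 = b1$grads, conv2 = b2$grads)
      }
      list(dx = dx, grads = grads)
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

stack_forward <- function(layers, x, stochastic = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, stochastic)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

stack_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)
  }
  list(dx = dy, grads = grads)
}

stack_has_dropout <- function(layers) {
  any(vapply(layers, function(l) l$kind == "dropout", logical(1)))
}

# ---- Adam ----------------------------------------------------------------

adam_state_new <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}

# Update every numeric parameter reachable through `grads` (which mirrors the
# structure of `layers`): named elements W/b are parameters, other named list
# elements are sub-layers.
adam_step <- function(layers, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(layer, grad, path) {
    for (nm in names(grad)) {
      g <- grad[[nm]]
      if (is.null(g)) next
      key <- paste0(path, ".", nm)
      if (is.list(g)) {
        layer[[nm]] <- upd(layer[[nm]], g, key)
      } else {
        m <- state$m[[key]]
        v <- state$v[[key]]
        if (is.null(m)) { m <- g * 0; v <- g * 0 }
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        state$m[[key]] <- m
        state$v[[key]] <- v
        mhat <- m / (1 - beta1^t)
        vhat <- v / (1 - beta2^t)
        # decoupled (AdamW-style) decay on weight matrices, not biases
        decay <- if (weight_decay > 0 && nm == "W") lr * weight_decay * layer[[nm]] else 0
        layer[[nm]] <- layer[[nm]] - lr * mhat / (sqrt(vhat) + eps) - decay
      }
    }
    layer
  }
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    layers[[i]] <- upd(layers[[i]], grads[[i]], paste0("L", i))
  }
  layers
}

# ---- classification heads ------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy head: returns mean loss and gradient w.r.t. logits.
head_softmax_ce <- function(z, Y) {
  p <- softmax_rows(z)
  eps <- 1e-12
  loss <- -mean(rowSums(Y * log(p + eps)))
  list(loss = loss, dz = (p - Y) / nrow(z), p = p)
}

# Evidential head: evidence = activation(z), alpha = evidence + 1, and the
# sum-of-squares Dirichlet loss with its analytic gradient.
head_edl <- function(z, Y, activation = "relu") {
  if (activation != "relu") stop("unsupported evidence activation: ", activation)
  e <- pmax(z, 0)
  alpha <- e + 1
  S <- rowSums(alpha)
  p <- alpha / S
  err <- Y - p
  var_term <- p * (1 - p) / (S + 1)
  loss <- mean(rowSums(err^2 + var_term))
  cc <- -2 * err + (1 - 2 * p) / (S + 1)
  q <- rowSums(p * (1 - p)) / (S + 1)^2
  dalpha <- (cc - rowSums(cc * p)) / S - q
  dz <- dalpha * (z > 0) / nrow(z)
  list(loss = loss, dz = dz, p = p, alpha = alpha)
}
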