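# A small convolutional scorer in plain matrix algebra.
#
# Architecture: one convolution (F filters, k x k, stride s) -> ReLU ->
# average pooling onto a fixed ph x pw grid -> optional ReLU hidden layer
# -> linear logit -> sigmoid. Trained by minibatch SGD with momentum on a
# class-weighted binary cross-entropy. The convolution is implemented as
# im2col (patch matrix) times the filter bank, which keeps the whole
# forward/backward pass in BLAS-friendly matrix products.

conv_geometry <- function(h, w, k, stride, ph, pw) {
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  if (oh < 1 || ow < 1) stop_config("input_size too small for kernel/stride")
  if (ph > oh || pw > ow) stop_config("pool_grid finer than the conv output")
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  ri <- (oi - 1L) * stride        # top-left row offset (0-based)
  rj <- (oj - 1L) * stride
  ## linear indices of each k x k patch, column-major within the patch
  qr <- rep(seq_len(k), times = k)
  qc <- rep(seq_len(k), each = k)
  idx <- outer(ri, qr, `+`) + outer(rj, qc - 1L, `+`) * h +
    matrix(0L, oh * ow, k * k)
  cell <- ceiling(oi * ph / oh) + (ceiling(oj * pw / ow) - 1L) * ph
  list(oh = oh, ow = ow, P = oh * ow, idx = idx,
       cell = cell, counts = tabulate(cell, ph * pw), G = ph * pw)
}

im2col <- function(x, geom) matrix(x[geom$idx], nrow = geom$P)

net_init <- function(n_feat, config, conv = TRUE) {
  k2 <- config$kernel_size^2
  hw <- config$head_width %||% 0L
  p <- list()
  if (conv) {
    p$W1 <- matrix(rnorm(k2 * config$n_filters, sd = sqrt(2 / k2)),
                   k2, config$n_filters)
    p$b1 <- rep(0, config$n_filters)
  }
  if (hw > 0) {
    p$Wh <- matrix(rnorm(n_feat * hw, sd = sqrt(2 / n_feat)), n_feat, hw)
    p$bh <- rep(0, hw)
    p$Wo <- rnorm(hw, sd = sqrt(1 / hw))
  } else {
    p$Wo <- rnorm(n_feat, sd = sqrt(1 / n_feat))
  }
  p$bo <- 0
  p
}

# forward through conv + pooling; returns pooled feature vector (+cache)
conv_features <- function(C, params, geom, cache = FALSE) {
  Z <- C %*% params$W1
  Z <- Z + matrix(params$b1, nrow(Z), ncol(Z), byrow = TRUE)
  A <- Z * (Z > 0)
  pooled <- rowsum(A, geom$cell) / geom$counts
  feat <- as.vector(pooled)
  if (cache) list(feat = feat, A_pos = Z > 0) else feat
}

head_forward <- function(feat, params, cache = FALSE) {
  if (!is.null(params$Wh)) {
    hz <- drop(crossprod(params$Wh, feat)) + params$bh
    ha <- hz * (hz > 0)
    logit <- sum(params$Wo * ha) + params$bo
    if (cache) list(logit = logit, ha = ha, h_pos = hz > 0) else logit
  } else {
    logit <- sum(params$Wo * feat) + params$bo
    if (cache) list(logit = logit) else logit
  }
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# one sample's gradient contributions, accumulated into `acc`
net_backward <- function(acc, dlogit, feat, hcache, params,
                         C = NULL, ccache = NULL, geom = NULL) {
  if (!is.null(params$Wh)) {
    dha <- dlogit * params$Wo
    dhz <- dha * hcache$h_pos
    acc$Wo <- acc$Wo + dlogit * hcache$ha
    acc$bo <- acc$bo + dlogit
    acc$Wh <- acc$Wh + tcrossprod(feat, dhz)
    acc$bh <- acc$bh + dhz
    dfeat <- drop(params$Wh %*% dhz)
  } else {
    acc$Wo <- acc$Wo + dlogit * feat
    acc$bo <- acc$bo + dlogit
    dfeat <- dlogit * params$Wo
  }
  if (!is.null(C)) {
    F_ <- ncol(params$W1)
    dpool <- matrix(dfeat, geom$G, F_)
    dA <- dpool[geom$cell, , drop = FALSE] / geom$counts[geom$cell]
    dZ <- dA * ccache$A_pos
    acc$W1 <- acc$W1 + crossprod(C, dZ)
    acc$b1 <- acc$b1 + colSums(dZ)
  }
  acc
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# SGD with momentum over precomputed per-sample inputs.
# inputs: list of im2col matrices (conv path) or feature vectors (head-only)
net_train <- function(inputs, y, weights, params, config, geom = NULL,
                      val = NULL) {
  n <- length(inputs)
  lr <- config$learning_rate
  mom <- config$momentum
  bs <- min(config$batch_size, n)
  vel <- zero_like(params)
  conv <- !is.null(geom)
  history <- vector("list", config$epochs)

  fwd <- function(inp, p) {
    if (conv) {
      cc <- conv_features(inp, p, geom, cache = TRUE)
      hc <- head_forward(cc$feat, p, cache = TRUE)
      list(feat = cc$feat, ccache = cc, hcache = hc, logit = hc$logit)
    } else {
      hc <- head_forward(inp, p, cache = TRUE)
      list(feat = inp, ccache = NULL, hcache = hc, logit = hc$logit)
    }
  }

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_w <- 0; ep_correct <- 0
    for (start in seq(1, n, by = bs)) {
      batch <- ord[start:min(start + bs - 1, n)]
      acc <- zero_like(params)
      for (i in batch) {
        fw <- fwd(inputs[[i]], params)
        pr <- sigmoid(fw$logit)
        pr_c <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - weights[i] *
          (y[i] * log(pr_c) + (1 - y[i]) * log(1 - pr_c))
        ep_w <- ep_w + weights[i]
        ep_correct <- ep_correct + ((pr > 0.5) == (y[i] == 1))
        dlogit <- weights[i] * (pr - y[i]) / length(batch)
        acc <- net_backward(acc, dlogit, fw$feat, fw$hcache, params,
                            C = if (conv) inputs[[i]] else NULL,
                            ccache = fw$ccache, geom = geom)
      }
      for (nm in names(params)) {
        vel[[nm]] <- mom * vel[[nm]] - lr * acc[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    hrow <- tibble::tibble(epoch = ep, train_loss = ep_loss / ep_w,
                           train_accuracy = ep_correct / n)
    if (!is.null(val)) {
      vp <- vapply(val$inputs, function(inp) sigmoid(fwd(inp, params)$logit),
                   numeric(1))
      vp_c <- pmin(pmax(vp, 1e-12), 1 - 1e-12)
      hrow$val_loss <- -mean(val$y * log(vp_c) + (1 - val$y) * log(1 - vp_c))
      hrow$val_accuracy <- mean((vp > 0.5) == (val$y == 1))
    }
    history[[ep]] <- hrow
  }
  list(params = params, history = dplyr::bind_rows(history))
}
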