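## A small 1-D convolutional network engine in base R.
##
## Batches are stored segment-major: a batch of B segments of length L with
## C channels is a (L*B) x C matrix whose first L rows are segment 1. 'Same'
## convolutions are computed as k shifted GEMMs (one per kernel tap), which
## keeps everything inside BLAS. Max pooling uses non-overlapping windows
## (pool size must divide the length at every block), batch normalization is
## per channel over batch x position, and all randomness (init, shuffling,
## dropout) comes from R's global generator so training is exactly
## reproducible under a seed.

## Thin wrappers over the compiled kernels (src/engine.cpp).

conv1d_forward <- function(X, Wlist, bias, L, B) {
  Wbig <- do.call(rbind, Wlist)
  Y <- cpp_conv1d_fw(X, Wbig, bias, L, B)
  list(Y = Y, X = X, Wbig = Wbig, c_in = ncol(X), L = L, B = B)
}

conv1d_backward <- function(dY, cache, Wlist) {
  C <- cache$c_in
  k <- length(Wlist)
  out <- cpp_conv1d_bw(cache$X, dY, cache$Wbig, cache$L, cache$B)
  dW <- lapply(seq_len(k), function(o)
    out$dWbig[(o - 1L) * C + seq_len(C), , drop = FALSE])
  list(dW = dW, db = as.numeric(out$db), dX = out$dX)
}

maxpool_forward <- function(X, p, L, B) {
  if (p == 1L) return(list(Y = X, lin = NULL))
  out <- cpp_maxpool_fw(X, p)
  list(Y = out$Y, lin = out$arg)
}

maxpool_backward <- function(dY, lin, n_in) {
  if (is.null(lin)) return(dY)
  cpp_maxpool_bw(dY, lin, n_in)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_forward <- function(X, gamma, beta, run, training) {
  if (training) {
    out <- cpp_bn_fw(X, gamma, beta, BN_EPS)
    run$mean <- BN_MOMENTUM * run$mean +
      (1 - BN_MOMENTUM) * as.numeric(out$mu)
    run$var <- BN_MOMENTUM * run$var + (1 - BN_MOMENTUM) * as.numeric(out$var)
    list(Y = out$Y, inv = as.numeric(out$inv), xhat = out$xhat, run = run)
  } else {
    ## inference: frozen statistics, so backprop (saliency) treats them as
    ## constants
    N <- nrow(X)
    inv <- 1 / sqrt(run$var + BN_EPS)
    xhat <- (X - rep(run$mean, each = N)) * rep(inv, each = N)
    list(Y = xhat * rep(gamma, each = N) + rep(beta, each = N),
         inv = inv, xhat = xhat, run = run, frozen = TRUE)
  }
}

bn_backward <- function(dY, cache, gamma) {
  if (isTRUE(cache$frozen)) {
    N <- nrow(dY)
    scale <- gamma * cache$inv
    return(list(dX = dY * rep(scale, each = N),
                dgamma = colSums(dY * cache$xhat),
                dbeta = colSums(dY)))
  }
  out <- cpp_bn_bw(dY, cache$xhat, cache$inv, gamma)
  list(dX = out$dX, dgamma = as.numeric(out$dgamma),
       dbeta = as.numeric(out$dbeta))
}

flatten_forward <- function(X, L, B) {
  C <- ncol(X)
  matrix(aperm(array(X, dim = c(L, B, C)), c(2L, 1L, 3L)), nrow = B)
}

flatten_backward <- function(dF, L, B, C) {
  matrix(aperm(array(dF, dim = c(B, L, C)), c(2L, 1L, 3L)), nrow = L * B)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## ---------------------------------------------------------------- params --

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

## Initialize all weights for a model spec; returns list(params, bn_state).
## Draws from the current RNG state.
init_params <- function(spec) {
  params <- list()
  bn_state <- list()
  flat_len <- 0L
  for (b in seq_along(spec$branches)) {
    br <- spec$branches[[b]]
    L <- spec$input_len
    c_in <- 1L
    for (j in seq_len(br$blocks)) {
      key <- sprintf("br%d_blk%d", b, j)
      fan_in <- br$kernel * c_in
      params[[paste0(key, "_W")]] <- lapply(seq_len(br$kernel), function(o)
        he_init(c_in, br$n_filters, fan_in))
      params[[paste0(key, "_b")]] <- numeric(br$n_filters)
      if (br$use_batch_norm) {
        params[[paste0(key, "_gamma")]] <- rep(1, br$n_filters)
        params[[paste0(key, "_beta")]] <- numeric(br$n_filters)
        bn_state[[key]] <- list(mean = numeric(br$n_filters),
                                var = rep(1, br$n_filters))
      }
      L <- L %/% br$pool
      c_in <- br$n_filters
    }
    flat_len <- flat_len + L * c_in
  }
  params$dense_W <- he_init(flat_len, spec$dense_units, flat_len)
  params$dense_b <- numeric(spec$dense_units)
  params$out_W <- he_init(spec$dense_units, 1L, spec$dense_units)
  params$out_b <- 0
  list(params = params, bn_state = bn_state, flat_len = flat_len)
}

## ---------------------------------------------------------------- forward --

## X: B x input_len matrix. Returns scores and (optionally) the caches
## needed for backprop.
forward_batch <- function(spec, params, bn_state, X, training = FALSE,
                          dropout_rate = spec$dropout_rate,
                          keep_cache = training) {
  B <- nrow(X)
  L0 <- spec$input_len
  x0 <- matrix(as.vector(t(X)), ncol = 1L)   # segment-major column
  flats <- list()
  caches <- list()
  for (b in seq_along(spec$branches)) {
    br <- spec$branches[[b]]
    h <- x0
    L <- L0
    blocks <- list()
    for (j in seq_len(br$blocks)) {
      key <- sprintf("br%d_blk%d", b, j)
      cv <- conv1d_forward(h, params[[paste0(key, "_W")]],
                           params[[paste0(key, "_b")]], L, B)
      relu_mask <- cv$Y > 0
      a <- cv$Y * relu_mask
      mp <- maxpool_forward(a, br$pool, L, B)
      L <- L %/% br$pool
      if (br$use_batch_norm) {
        bn <- bn_forward(mp$Y, params[[paste0(key, "_gamma")]],
                         params[[paste0(key, "_beta")]],
                         bn_state[[key]], training)
        if (training) bn_state[[key]] <- bn$run
        h <- bn$Y
      } else bn <- NULL
      if (!br$use_batch_norm) h <- mp$Y
      blocks[[j]] <- if (keep_cache)
        list(cv = cv, relu_mask = relu_mask, mp = mp, bn = bn,
             n_in = nrow(a), L_out = L) else NULL
    }
    flats[[b]] <- flatten_forward(h, L, B)
    caches[[b]] <- list(blocks = blocks, L_final = L,
                        C_final = br$n_filters)
  }
  feat <- do.call(cbind, flats)
  z1 <- feat %*% params$dense_W + rep(params$dense_b, each = B)
  mask1 <- z1 > 0
  h1 <- z1 * mask1
  if (training && dropout_rate > 0) {
    dmask <- matrix((stats::runif(length(h1)) >= dropout_rate) /
                      (1 - dropout_rate), nrow(h1), ncol(h1))
    h1d <- h1 * dmask
  } else {
    dmask <- NULL
    h1d <- h1
  }
  z <- h1d %*% params$out_W + params$out_b
  p <- sigmoid(as.numeric(z))
  list(scores = p,
       cache = if (keep_cache)
         list(branches = caches, feat = feat, mask1 = mask1, h1d = h1d,
              dmask = dmask, B = B) else NULL,
       bn_state = bn_state)
}

## ---------------------------------------------------------------- backward --

## dz: gradient of the objective w.r.t. the pre-sigmoid output, length B.
## Returns flat gradient list matching params, plus (optionally) the input
## gradient and the gradient at each branch's last block output.
backward_batch <- function(spec, params, fw, dz, want_input_grad = FALSE) {
  cache <- fw$cache
  B <- cache$B
  grads <- list()
  dzm <- matrix(dz, ncol = 1L)
  grads$out_W <- crossprod(cache$h1d, dzm)
  grads$out_b <- sum(dz)
  dh1d <- dzm %*% t(params$out_W)            # B x dense_units
  if (!is.null(cache$dmask)) dh1d <- dh1d * cache$dmask
  dz1 <- dh1d * cache$mask1
  grads$dense_W <- crossprod(cache$feat, dz1)
  grads$dense_b <- colSums(dz1)
  dfeat <- dz1 %*% t(params$dense_W)           # B x flat_len
  dX_total <- if (want_input_grad) matrix(0, B, spec$input_len) else NULL
  dblock_last <- list()
  col0 <- 0L
  for (b in seq_along(spec$branches)) {
    br <- spec$branches[[b]]
    bc <- cache$branches[[b]]
    ncols <- bc$L_final * bc$C_final
    dflat <- dfeat[, col0 + seq_len(ncols), drop = FALSE]
    col0 <- col0 + ncols
    dh <- flatten_backward(dflat, bc$L_final, B, bc$C_final)
    for (j in rev(seq_len(br$blocks))) {
      key <- sprintf("br%d_blk%d", b, j)
      blk <- bc$blocks[[j]]
      if (j == br$blocks) dblock_last[[b]] <- dh
      if (br$use_batch_norm) {
        bnb <- bn_backward(dh, blk$bn, params[[paste0(key, "_gamma")]])
        grads[[paste0(key, "_gamma")]] <- bnb$dgamma
        grads[[paste0(key, "_beta")]] <- bnb$dbeta
        dh <- bnb$dX
      }
      dh <- maxpool_backward(dh, blk$mp$lin, blk$n_in)
      dh <- dh * blk$relu_mask
      cvb <- conv1d_backward(dh, blk$cv, params[[paste0(key, "_W")]])
      grads[[paste0(key, "_W")]] <- cvb$dW
      grads[[paste0(key, "_b")]] <- cvb$db
      dh <- cvb$dX
    }
    if (want_input_grad)
      dX_total <- dX_total + matrix(dh, nrow = B, byrow = TRUE)
  }
  list(grads = grads, dX = dX_total, dblock_last = dblock_last)
}

## ------------------------------------------------------------------- Adam --

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in names(grads)) {
    o <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- o$p
    state$m[[nm]] <- o$m
    state$v[[nm]] <- o$v
  }
  list(params = params, state = state)
}

## Weighted binary cross-entropy on clamped probabilities; returns the mean
## loss and the gradient w.r.t. the pre-sigmoid output.
bce_loss_grad <- function(p, y, w) {
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loss <- mean(w * (-y * log(pc) - (1 - y) * log(1 - pc)))
  dz <- w * (pc - y) / length(y)
  list(loss = loss, dz = dz)
}
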