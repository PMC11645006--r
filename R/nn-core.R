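# Minimal seeded neural-network engine.
#
# Layers: conv2d (valid or zero-padded, stride 1), batch norm (per channel for
# 4-d activations, per feature for matrices), ReLU, 2x2 max pool, flatten,
# dense. Training uses Adam with a fused sigmoid output (binary cross-entropy
# or squared error). Everything is plain R; the heavy lifting is BLAS matmul
# over im2col buffers, which is fast enough at the patch scale (32x32) this
# package operates on.
#
# Convolutional activations are stored H x W x C x N (column-major friendly);
# dense activations are N x F matrices.

nn_conv <- function(in_ch, out_ch, kernel = 3L, pad = 0L) {
  list(kind = "conv", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       k = as.integer(kernel), pad = as.integer(pad))
}
nn_bnorm <- function(n) list(kind = "bnorm", n = as.integer(n))
nn_relu <- function() list(kind = "relu")
nn_pool <- function(size = 2L) list(kind = "pool", size = as.integer(size))
nn_flatten <- function() list(kind = "flatten")
nn_dense <- function(d_in, d_out) {
  list(kind = "dense", d_in = as.integer(d_in), d_out = as.integer(d_out))
}

# He-scaled gaussian init; seeded by the caller (nn_fit wraps in with_seed).
nn_init_params <- function(layers) {
  lapply(layers, function(ly) {
    switch(ly$kind,
      conv = {
        fan_in <- ly$k * ly$k * ly$in_ch
        list(W = matrix(stats::rnorm(fan_in * ly$out_ch, sd = sqrt(2 / fan_in)),
                        fan_in, ly$out_ch),
             b = numeric(ly$out_ch))
      },
      dense = list(
        W = matrix(stats::rnorm(ly$d_in * ly$d_out, sd = sqrt(2 / ly$d_in)),
                   ly$d_in, ly$d_out),
        b = numeric(ly$d_out)),
      bnorm = list(gamma = rep(1, ly$n), beta = numeric(ly$n)),
      NULL)
  })
}

nn_init_state <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$kind == "bnorm") {
      # `fresh` marks stats never updated: the first training batch seeds the
      # running estimates outright (an exponential average warming up from
      # (0, 1) needs dozens of batches before inference-mode output is sane)
      list(mean = numeric(ly$n), var = rep(1, ly$n), fresh = TRUE)
    } else NULL
  })
}

# Convolutional activations use the layout H x W x N x C (batch before
# channel): spatial slices then reshape directly into matmul-ready matrices
# with no aperm copies. Public patch arrays are H x W x C x N; nn_fit and
# nn_predict convert at the boundary.

pad_hw <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  out
}

# Weight rows are ordered ((dx-1)*k + (dy-1)) * C + c, matching the offset
# loop below.
conv_forward <- function(ly, par, X) {
  Xp <- pad_hw(X, ly$pad)
  d <- dim(Xp)
  k <- ly$k
  oh <- d[1] - k + 1L
  ow <- d[2] - k + 1L
  N <- d[3]
  C <- ly$in_ch
  Y <- matrix(rep(par$b, each = oh * ow * N), oh * ow * N, ly$out_ch)
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      sub <- Xp[dy:(dy + oh - 1L), dx:(dx + ow - 1L), , , drop = FALSE]
      rows <- ((dx - 1L) * k + (dy - 1L)) * C + seq_len(C)
      Y <- Y + matrix(sub, oh * ow * N, C) %*%
        par$W[rows, , drop = FALSE]
    }
  }
  list(out = array(Y, c(oh, ow, N, ly$out_ch)),
       cache = list(Xp = Xp, oh = oh, ow = ow, N = N))
}

conv_backward <- function(ly, par, cache, dout) {
  k <- ly$k
  oh <- cache$oh; ow <- cache$ow; N <- cache$N; C <- ly$in_ch
  dm <- matrix(dout, oh * ow * N, ly$out_ch)
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  dXp <- array(0, dim(cache$Xp))
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      sub <- cache$Xp[dy:(dy + oh - 1L), dx:(dx + ow - 1L), , , drop = FALSE]
      rows <- ((dx - 1L) * k + (dy - 1L)) * C + seq_len(C)
      dW[rows, ] <- crossprod(matrix(sub, oh * ow * N, C), dm)
      dsub <- dm %*% t(par$W[rows, , drop = FALSE])
      dXp[dy:(dy + oh - 1L), dx:(dx + ow - 1L), , ] <-
        dXp[dy:(dy + oh - 1L), dx:(dx + ow - 1L), , , drop = FALSE] +
        array(dsub, c(oh, ow, N, C))
    }
  }
  p <- ly$pad
  dX <- if (p > 0L) {
    d <- dim(cache$Xp)
    dXp[p + seq_len(d[1] - 2 * p), p + seq_len(d[2] - 2 * p), , , drop = FALSE]
  } else dXp
  list(grads = list(W = dW, b = colSums(dm)), dX = dX)
}

pool_forward <- function(ly, X) {
  s <- ly$size
  d <- dim(X)
  oh <- d[1] %/% s
  ow <- d[2] %/% s
  rows <- seq_len(oh * s)
  cols <- seq_len(ow * s)
  cur <- NULL
  amax <- NULL
  i <- 0L
  for (dx in seq_len(s)) {
    for (dy in seq_len(s)) {
      i <- i + 1L
      slice <- X[rows[seq(dy, oh * s, by = s)],
                 cols[seq(dx, ow * s, by = s)], , , drop = FALSE]
      if (is.null(cur)) {
        cur <- slice
        amax <- array(1L, dim(slice))
      } else {
        upd <- slice > cur
        amax[upd] <- i
        cur[upd] <- slice[upd]
      }
    }
  }
  list(out = cur, cache = list(amax = amax, din = d, oh = oh, ow = ow))
}

pool_backward <- function(ly, cache, dout) {
  s <- ly$size
  dX <- array(0, cache$din)
  oh <- cache$oh; ow <- cache$ow
  i <- 0L
  for (dx in seq_len(s)) {
    for (dy in seq_len(s)) {
      i <- i + 1L
      sel <- cache$amax == i
      contrib <- array(0, dim(dout))
      contrib[sel] <- dout[sel]
      dX[seq(dy, oh * s, by = s), seq(dx, ow * s, by = s), , ] <- contrib
    }
  }
  dX
}

bn_forward <- function(ly, par, state, X, train, momentum = 0.1, eps = 1e-5) {
  conv_mode <- length(dim(X)) == 4L
  nC <- ly$n
  if (train && isTRUE(state$fresh)) {
    momentum <- 1
    state$fresh <- FALSE
  }
  if (!train) {
    # inference: a single fused scale/shift per channel (or feature)
    iv <- 1 / sqrt(state$var + eps)
    scale <- par$gamma * iv
    shift <- par$beta - state$mean * scale
    if (conv_mode) {
      d <- dim(X)
      per <- d[1] * d[2] * d[3]
      out <- X * rep(scale, each = per) + rep(shift, each = per)
    } else {
      out <- sweep(sweep(X, 2L, scale, "*"), 2L, shift, "+")
    }
    return(list(out = out, state = state, cache = NULL))
  }
  if (conv_mode) {
    xhat <- X
    ivar <- numeric(nC)
    mu <- numeric(nC)
    for (c in seq_len(nC)) {
      xs <- X[, , , c, drop = FALSE]
      if (train) {
        m <- mean(xs)
        v <- mean((xs - m)^2)
        state$mean[c] <- (1 - momentum) * state$mean[c] + momentum * m
        state$var[c] <- (1 - momentum) * state$var[c] + momentum * v
      } else {
        m <- state$mean[c]
        v <- state$var[c]
      }
      iv <- 1 / sqrt(v + eps)
      xhat[, , , c] <- (xs - m) * iv
      ivar[c] <- iv
      mu[c] <- m
    }
    out <- xhat
    for (c in seq_len(nC)) {
      out[, , , c] <- xhat[, , , c, drop = FALSE] * par$gamma[c] + par$beta[c]
    }
    list(out = out, state = state,
         cache = list(xhat = xhat, ivar = ivar, conv = TRUE))
  } else {
    if (train) {
      m <- colMeans(X)
      v <- colMeans(sweep(X, 2L, m)^2)
      state$mean <- (1 - momentum) * state$mean + momentum * m
      state$var <- (1 - momentum) * state$var + momentum * v
    } else {
      m <- state$mean
      v <- state$var
    }
    iv <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(X, 2L, m), 2L, iv, "*")
    out <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
    list(out = out, state = state,
         cache = list(xhat = xhat, ivar = iv, conv = FALSE))
  }
}

bn_backward <- function(ly, par, cache, dout) {
  if (cache$conv) {
    nC <- ly$n
    dX <- dout
    dgamma <- numeric(nC)
    dbeta <- numeric(nC)
    for (c in seq_len(nC)) {
      dy <- dout[, , , c, drop = FALSE]
      xh <- cache$xhat[, , , c, drop = FALSE]
      dgamma[c] <- sum(dy * xh)
      dbeta[c] <- sum(dy)
      dxhat <- dy * par$gamma[c]
      dX[, , , c] <- cache$ivar[c] *
        (dxhat - mean(dxhat) - xh * mean(dxhat * xh))
    }
    list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
  } else {
    xh <- cache$xhat
    dgamma <- colSums(dout * xh)
    dbeta <- colSums(dout)
    dxhat <- sweep(dout, 2L, par$gamma, "*")
    n <- nrow(dout)
    dX <- sweep(dxhat, 2L, colMeans(dxhat)) -
      xh * matrix(colMeans(dxhat * xh), n, ncol(dout), byrow = TRUE)
    dX <- sweep(dX, 2L, cache$ivar, "*")
    list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
  }
}

nn_forward <- function(layers, params, state, X, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      fw <- conv_forward(ly, params[[i]], X)
      X <- fw$out
      caches[[i]] <- fw$cache
    } else if (ly$kind == "bnorm") {
      fw <- bn_forward(ly, params[[i]], state[[i]], X, train)
      X <- fw$out
      state[[i]] <- fw$state
      caches[[i]] <- fw$cache
    } else if (ly$kind == "relu") {
      caches[[i]] <- X > 0
      X[!caches[[i]]] <- 0
    } else if (ly$kind == "pool") {
      fw <- pool_forward(ly, X)
      X <- fw$out
      caches[[i]] <- fw$cache
    } else if (ly$kind == "flatten") {
      d <- dim(X) # H W N C
      caches[[i]] <- d
      X <- t(matrix(aperm(X, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3]))
    } else if (ly$kind == "dense") {
      caches[[i]] <- X
      X <- sweep(X %*% params[[i]]$W, 2L, params[[i]]$b, "+")
    } else {
      stop("unknown layer kind: ", ly$kind)
    }
  }
  list(out = X, caches = caches, state = state)
}

nn_backward <- function(layers, params, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      bw <- conv_backward(ly, params[[i]], caches[[i]], dout)
      grads[[i]] <- bw$grads
      dout <- bw$dX
    } else if (ly$kind == "bnorm") {
      bw <- bn_backward(ly, params[[i]], caches[[i]], dout)
      grads[[i]] <- bw$grads
      dout <- bw$dX
    } else if (ly$kind == "relu") {
      dout[!caches[[i]]] <- 0
    } else if (ly$kind == "pool") {
      dout <- pool_backward(ly, caches[[i]], dout)
    } else if (ly$kind == "flatten") {
      d <- caches[[i]] # H W N C
      dout <- aperm(array(t(dout), c(d[1], d[2], d[4], d[3])),
                    c(1L, 2L, 4L, 3L))
    } else if (ly$kind == "dense") {
      X <- caches[[i]]
      grads[[i]] <- list(W = crossprod(X, dout), b = colSums(dout))
      dout <- dout %*% t(params[[i]]$W)
    }
  }
  grads
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Fused loss on logits z with sigmoid output activation.
nn_loss_grad <- function(z, y, loss) {
  s <- sigmoid(z)
  n <- nrow(z)
  if (loss == "bce") {
    eps <- 1e-12
    value <- -mean(rowSums(y * log(s + eps) + (1 - y) * log(1 - s + eps)))
    dz <- (s - y) / n
  } else if (loss == "mse") {
    value <- mean(rowSums((s - y)^2))
    dz <- 2 * (s - y) * s * (1 - s) / n
  } else stop("unknown loss: ", loss)
  list(value = value, dz = dz)
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(w) list(m = w * 0, v = w * 0))
  })
}

adam_step <- function(params, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(params = params, opt = opt)
}

# Slice a batch from conv (4-d, H W N C layout) or dense (matrix) inputs.
nn_take <- function(X, idx) {
  if (length(dim(X)) == 4L) X[, , idx, , drop = FALSE] else X[idx, , drop = FALSE]
}
nn_nobs <- function(X) {
  if (length(dim(X)) == 4L) dim(X)[3] else nrow(X)
}

# Public patch arrays are H x W x C x N; internal conv layout is H x W x N x C.
nn_to_internal <- function(X) {
  if (length(dim(X)) == 4L) aperm(X, c(1L, 2L, 4L, 3L)) else X
}

#' @keywords internal
nn_fit <- function(layers, X, Y, loss = c("bce", "mse"), epochs = 10L,
                   batch = 32L, lr = 1e-3, seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  Y <- as_plain_matrix(Y)
  X <- nn_to_internal(X)
  n <- nn_nobs(X)
  assert_that(n == nrow(Y), "X and Y disagree on the number of observations")
  with_seed(seed, {
    params <- nn_init_params(layers)
    state <- nn_init_state(layers)
    opt <- adam_init(params)
    t <- 0L
    history <- data.frame(epoch = integer(), loss = numeric(),
                          accuracy = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        xb <- nn_take(X, idx)
        yb <- Y[idx, , drop = FALSE]
        fw <- nn_forward(layers, params, state, xb, train = TRUE)
        state <- fw$state
        lg <- nn_loss_grad(fw$out, yb, loss)
        grads <- nn_backward(layers, params, fw$caches, lg$dz)
        t <- t + 1L
        upd <- adam_step(params, grads, opt, lr, t)
        params <- upd$params
        opt <- upd$opt
        ep_loss <- ep_loss + lg$value * length(idx)
        if (ncol(Y) > 1L) {
          ep_correct <- ep_correct +
            sum(max.col(fw$out, ties.method = "first") ==
                  max.col(yb, ties.method = "first"))
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = ep_loss / n,
        accuracy = if (ncol(Y) > 1L) ep_correct / n else NA_real_))
      if (verbose) {
        message(sprintf("epoch %d/%d loss %.5f", ep, epochs, ep_loss / n))
      }
    }
    list(params = params, state = state, history = history)
  })
}

# Chunked inference; returns sigmoid activations (n x out_dim).
nn_predict <- function(layers, params, state, X, chunk = 512L) {
  X <- nn_to_internal(X)
  n <- nn_nobs(X)
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- nn_forward(layers, params, state, nn_take(X, idx), train = FALSE)
    piece <- sigmoid(fw$out)
    out <- if (is.null(out)) piece else rbind(out, piece)
  }
  out
}

#' Save or load a trained model checkpoint
#'
#' Checkpoints are single-file archives holding the architecture descriptor,
#' weights, batch-norm running statistics and training metadata.
#'
#' @param model A trained model (`seg_model`, `depth_model` or `stress_model`).
#' @param path File path for the checkpoint.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "canopy3d_model"), "not a canopy3d model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  assert_that(inherits(model, "canopy3d_model"), "file is not a canopy3d checkpoint")
  model
}

#' @export
print.canopy3d_model <- function(x, ...) {
  cat(sprintf("<%s> layers: %s\n", class(x)[1],
              paste(vapply(x$layers, `[[`, "", "kind"), collapse = " -> ")))
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, final loss %.5f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  }
  invisible(x)
}
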