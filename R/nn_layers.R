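## Minimal neural-network layer set with hand-written backpropagation.
## Feature-map tensors are arrays (H, W, C, N); vector activations are
## matrices (N, F). Convolution is im2col + BLAS gemm, built by looping
## over the k*k kernel offsets so every copy is a vectorized slice.

nn_rnorm <- function(n, sd) stats::rnorm(n, sd = sd)

## ---- convolution -----------------------------------------------------

make_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L) {
  fan_in <- kernel * kernel * in_ch
  W <- matrix(nn_rnorm(fan_in * out_ch, sqrt(2 / fan_in)), fan_in, out_ch)
  list(type = "conv", W = W, kernel = kernel, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch)
}

conv_forward <- function(layer, x) {
  d <- dim(x); k <- layer$kernel; s <- layer$stride; p <- layer$pad
  Ho <- (d[1L] + 2L * p - k) %/% s + 1L
  Wo <- (d[2L] + 2L * p - k) %/% s + 1L
  P <- cpp_im2col(x, d[1L], d[2L], d[3L], d[4L], k, s, p, Ho, Wo)
  M <- P %*% layer$W
  y <- cpp_col2feat(M, Ho, Wo, d[4L])
  dim(y) <- c(Ho, Wo, layer$out_ch, d[4L])
  list(y = y, cache = list(P = P, in_dim = d, Ho = Ho, Wo = Wo))
}

conv_backward <- function(layer, cache, dy) {
  d <- cache$in_dim; k <- layer$kernel; s <- layer$stride; p <- layer$pad
  m <- cpp_feat2col(dy, cache$Ho, cache$Wo, layer$out_ch, d[4L])
  dW <- crossprod(cache$P, m)
  dP <- m %*% t(layer$W)
  dx <- cpp_col2im(dP, d[1L], d[2L], d[3L], d[4L], k, s, p,
                   cache$Ho, cache$Wo)
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW))
}

## ---- batch normalization --------------------------------------------

make_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, ch), beta = rep(0, ch),
       run_mean = rep(0, ch), run_var = rep(1, ch),
       eps = eps, momentum = momentum, ch = ch)
}

## x as matrix (rows = samples-or-pixels, cols = channels)
bn_core_forward <- function(layer, xm, training) {
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc^2)
  } else {
    mu <- layer$run_mean; va <- layer$run_var
    xc <- sweep(xm, 2L, mu)
  }
  inv <- 1 / sqrt(va + layer$eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, mu = mu, va = va,
                           n = nrow(xm)))
}

bn_core_backward <- function(layer, cache, dym) {
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  n <- nrow(dym)
  t1 <- sweep(dym, 2L, dbeta / n)
  t2 <- sweep(xhat, 2L, dgamma / n, `*`)
  dx <- sweep(t1 - t2, 2L, layer$gamma * cache$inv, `*`)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

bn2d_reshape <- function(x) {
  d <- dim(x)
  cpp_feat2col(x, d[1L], d[2L], d[3L], d[4L])
}

bn2d_unshape <- function(m, d) {
  y <- cpp_col2feat(m, d[1L], d[2L], d[4L])
  dim(y) <- d
  y
}

bn_update_running <- function(layer, mu, va) {
  mom <- layer$momentum
  layer$run_mean <- (1 - mom) * layer$run_mean + mom * mu
  layer$run_var  <- (1 - mom) * layer$run_var  + mom * va
  layer
}

bn_accumulate <- function(layer, mu, va, n) {
  if (is.null(layer$acc_n)) {
    layer$acc_n <- 0; layer$acc_mean <- 0 * mu; layer$acc_m2 <- 0 * va
  }
  layer$acc_n <- layer$acc_n + n
  layer$acc_mean <- layer$acc_mean + n * mu
  layer$acc_m2 <- layer$acc_m2 + n * (va + mu^2)
  layer
}

bn_finalize_accumulation <- function(layer) {
  if (is.null(layer$acc_n) || layer$acc_n == 0) return(layer)
  mu <- layer$acc_mean / layer$acc_n
  layer$run_mean <- mu
  layer$run_var <- pmax(layer$acc_m2 / layer$acc_n - mu^2, 0)
  layer$acc_n <- NULL; layer$acc_mean <- NULL; layer$acc_m2 <- NULL
  layer
}

## ---- activations, dropout, pooling ----------------------------------

make_relu <- function() list(type = "relu")
relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dy) dy * cache

make_elu <- function(alpha = 1) list(type = "elu", alpha = alpha)
elu_forward <- function(layer, x) {
  neg <- x <= 0
  y <- x
  y[neg] <- layer$alpha * (exp(x[neg]) - 1)
  list(y = y, cache = list(neg = neg, y = y))
}
elu_backward <- function(layer, cache, dy) {
  g <- array(1, dim = if (is.null(dim(dy))) length(dy) else dim(dy))
  g[cache$neg] <- cache$y[cache$neg] + layer$alpha
  dy * g
}

make_dropout <- function(p = 0.1) list(type = "dropout", p = p)
dropout_forward <- function(layer, x, training) {
  if (!training || layer$p <= 0) return(list(y = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= layer$p,
                dim = if (is.null(dim(x))) length(x) else dim(x))
  list(y = x * keep / (1 - layer$p), cache = keep)
}
dropout_backward <- function(layer, cache, dy) {
  if (is.null(cache)) dy else dy * cache / (1 - layer$p)
}

make_maxpool <- function(kernel = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", kernel = kernel, stride = stride, pad = pad)
}

maxpool_forward <- function(layer, x) {
  d <- dim(x); k <- layer$kernel; s <- layer$stride; p <- layer$pad
  Hp <- d[1L] + 2L * p; Wp <- d[2L] + 2L * p
  xp <- array(-Inf, c(Hp, Wp, d[3L], d[4L]))
  xp[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  y <- array(-Inf, c(Ho, Wo, d[3L], d[4L]))
  arg <- array(0L, c(Ho, Wo, d[3L], d[4L]))
  idx <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    idx <- idx + 1L
    ri <- seq.int(ki, by = s, length.out = Ho)
    cj <- seq.int(kj, by = s, length.out = Wo)
    slice <- xp[ri, cj, , , drop = FALSE]
    upd <- slice > y
    y[upd] <- slice[upd]
    arg[upd] <- idx
  }
  list(y = y, cache = list(arg = arg, in_dim = d, Ho = Ho, Wo = Wo))
}

maxpool_backward <- function(layer, cache, dy) {
  d <- cache$in_dim; k <- layer$kernel; s <- layer$stride; p <- layer$pad
  Ho <- cache$Ho; Wo <- cache$Wo
  dxp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  idx <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    idx <- idx + 1L
    ri <- seq.int(ki, by = s, length.out = Ho)
    cj <- seq.int(kj, by = s, length.out = Wo)
    dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] +
      dy * (cache$arg == idx)
  }
  dxp[p + seq_len(d[1L]), p + seq_len(d[2L]), , , drop = FALSE]
}

make_avgpool2 <- function() list(type = "avgpool2")

avgpool2_forward <- function(x) {
  d <- dim(x)
  i1 <- seq.int(1L, d[1L], by = 2L); i2 <- pmin(i1 + 1L, d[1L])
  j1 <- seq.int(1L, d[2L], by = 2L); j2 <- pmin(j1 + 1L, d[2L])
  ## duplicated border indices replicate values, so /4 is always the mean
  y <- (x[i1, j1, , , drop = FALSE] + x[i2, j1, , , drop = FALSE] +
        x[i1, j2, , , drop = FALSE] + x[i2, j2, , , drop = FALSE]) / 4
  list(y = y, cache = list(in_dim = d, i1 = i1, i2 = i2, j1 = j1, j2 = j2))
}

avgpool2_backward <- function(cache, dy) {
  d <- cache$in_dim
  dx <- array(0, d)
  q <- dy / 4
  for (ii in list(cache$i1, cache$i2)) for (jj in list(cache$j1, cache$j2))
    dx[ii, jj, , ] <- dx[ii, jj, , , drop = FALSE] + q
  dx
}

make_gap <- function() list(type = "gap")
gap_forward <- function(x) {
  d <- dim(x)
  ## output matrix (N, C)
  m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L], d[4L] * d[3L])
  y <- matrix(colMeans(m), d[4L], d[3L])
  list(y = y, cache = d)
}
gap_backward <- function(cache, dy) {
  d <- cache
  hw <- d[1L] * d[2L]
  ## dy is (N, C); broadcast back over H, W
  m <- matrix(rep(as.vector(dy), each = hw) / hw, hw, d[4L] * d[3L])
  aperm(array(m, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

## ---- linear ----------------------------------------------------------

make_linear <- function(n_in, n_out) {
  list(type = "linear",
       W = matrix(nn_rnorm(n_in * n_out, sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}
linear_forward <- function(layer, x) {
  list(y = sweep(x %*% layer$W, 2L, layer$b, `+`), cache = x)
}
linear_backward <- function(layer, cache, dy) {
  list(dx = dy %*% t(layer$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

## ---- loss ------------------------------------------------------------

#' Softmax cross-entropy loss and logit gradient
#' @param logits Matrix (N, 2).
#' @param labels Integer vector in {0, 1} (1 = positive class).
#' @return List with `loss` (mean cross-entropy), `dlogits`, `probs`
#'   (positive-class probability).
#' @keywords internal
softmax_xent <- function(logits, labels) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(logits)
  labels <- unname(labels)
  onehot <- matrix(c(1 - labels, labels), n, 2L)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), labels + 1L)], 1e-12)))
  list(loss = loss, dlogits = (p - onehot) / n, probs = p[, 2L])
}
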