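# Internal differentiable primitives. Feature maps are arrays (C, H, W, N)
# (channel fastest); convolution is im2col (C++) + one BLAS matrix product.
# Every *_fwd returns list(out, cache); *_bwd takes the cache and the
# upstream gradient and returns gradients for inputs and parameters.

conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  k <- as.integer(sqrt(ncol(W) / C))
  stopifnot(ncol(W) == C * k * k)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (Wd + 2L * pad - k) %/% stride + 1L
  cols <- im2col_chw(as.numeric(x), C, H, Wd, N, k, stride, pad)
  y <- W %*% cols + b
  dim(y) <- c(nrow(W), Ho, Wo, N)
  list(out = y, cache = list(cols = cols, dims = c(C, H, Wd, N),
                             k = k, stride = stride, pad = pad, W = W))
}

conv_bwd <- function(cache, dy) {
  d <- dim(dy)
  Cout <- d[1]
  dy_mat <- matrix(dy, Cout, prod(d[-1]))
  dW <- tcrossprod(dy_mat, cache$cols)
  db <- rowSums(dy_mat)
  dcols <- crossprod(cache$W, dy_mat)
  dm <- cache$dims
  dx <- col2im_chw(dcols, dm[1], dm[2], dm[3], dm[4],
                   cache$k, cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(mask, dy) dy * mask

# global average pool: (C,H,W,N) -> (C,N)
gap_fwd <- function(x) {
  d <- dim(x)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  dim(x) <- c(C, HW, N)
  out <- colMeans(aperm(x, c(2, 1, 3)))  # (C, N)
  dim(out) <- c(C, N)
  list(out = out, cache = d)
}

gap_bwd <- function(d, dy) {
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  HW <- H * W
  dx <- array(0, c(C, HW, N))
  for (n in seq_len(N)) dx[, , n] <- dy[, n] / HW
  dim(dx) <- c(C, H, W, N)
  dx
}

# linear layer on column-features: x (Din, N) -> (Dout, N)
linear_fwd <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x, W = W))
}

linear_bwd <- function(cache, dy) {
  list(dx = crossprod(cache$W, dy),
       dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

# columnwise softmax, numerically stabilized
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# mean cross-entropy over columns; targets are integer codes 1..K
softmax_xent <- function(logits, targets) {
  p <- softmax_cols(logits)
  N <- ncol(logits)
  idx <- cbind(targets, seq_len(N))
  loss <- -mean(log(pmax(p[cbind(targets, seq_len(N))], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N, probs = p)
}

# He-normal conv weight (Cout x C*k*k) and fan-in-scaled linear weight
init_conv <- function(Cout, Cin, k) {
  matrix(rnorm(Cout * Cin * k * k, sd = sqrt(2 / (Cin * k * k))), Cout, Cin * k * k)
}

init_linear <- function(Dout, Din) {
  matrix(rnorm(Dout * Din, sd = sqrt(2 / Din)), Dout, Din)
}

# torch-style uniform init for recurrent weights
init_recurrent <- function(Dout, Din, hidden) {
  s <- 1 / sqrt(hidden)
  matrix(runif(Dout * Din, -s, s), Dout, Din)
}

# Adam with bias correction over a named flat list of arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
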