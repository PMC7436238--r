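# Residual feature extractor: stem conv (3 -> widths[1]) then four basic
# blocks (two 3x3 convs + identity/projection shortcut); blocks 2-4 halve the
# spatial size with stride 2; global average pooling yields one D-vector per
# frame (D = widths[4]).

init_extractor_params <- function(spec) {
  w <- spec$widths
  p <- list()
  p[["stem.W"]] <- init_conv(w[1], 3L, 3L)
  p[["stem.b"]] <- numeric(w[1])
  win <- w[1]
  for (b in 1:4) {
    wout <- w[b]
    stride <- if (b == 1) 1L else 2L
    pre <- sprintf("block%d.", b)
    p[[paste0(pre, "conv1.W")]] <- init_conv(wout, win, 3L)
    p[[paste0(pre, "conv1.b")]] <- numeric(wout)
    p[[paste0(pre, "conv2.W")]] <- init_conv(wout, wout, 3L)
    p[[paste0(pre, "conv2.b")]] <- numeric(wout)
    if (stride != 1L || win != wout) {
      p[[paste0(pre, "proj.W")]] <- init_conv(wout, win, 1L)
      p[[paste0(pre, "proj.b")]] <- numeric(wout)
    }
    win <- wout
  }
  p
}

block_fwd <- function(params, pre, x, stride) {
  c1 <- conv_fwd(x, params[[paste0(pre, "conv1.W")]],
                 params[[paste0(pre, "conv1.b")]], stride = stride, pad = 1L)
  r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(r1$out, params[[paste0(pre, "conv2.W")]],
                 params[[paste0(pre, "conv2.b")]], stride = 1L, pad = 1L)
  has_proj <- !is.null(params[[paste0(pre, "proj.W")]])
  if (has_proj) {
    pj <- conv_fwd(x, params[[paste0(pre, "proj.W")]],
                   params[[paste0(pre, "proj.b")]], stride = stride, pad = 0L)
    shortcut <- pj$out
  } else {
    pj <- NULL
    shortcut <- x
  }
  r2 <- relu_fwd(c2$out + shortcut)
  list(out = r2$out,
       cache = list(c1 = c1$cache, m1 = r1$cache, c2 = c2$cache,
                    pj = if (has_proj) pj$cache, m2 = r2$cache))
}

block_bwd <- function(cache, pre, dy) {
  grads <- list()
  dsum <- relu_bwd(cache$m2, dy)
  b2 <- conv_bwd(cache$c2, dsum)
  grads[[paste0(pre, "conv2.W")]] <- b2$dW
  grads[[paste0(pre, "conv2.b")]] <- b2$db
  dr1 <- relu_bwd(cache$m1, b2$dx)
  b1 <- conv_bwd(cache$c1, dr1)
  grads[[paste0(pre, "conv1.W")]] <- b1$dW
  grads[[paste0(pre, "conv1.b")]] <- b1$db
  dx <- b1$dx
  if (!is.null(cache$pj)) {
    bp <- conv_bwd(cache$pj, dsum)
    grads[[paste0(pre, "proj.W")]] <- bp$dW
    grads[[paste0(pre, "proj.b")]] <- bp$db
    dx <- dx + bp$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = grads)
}

# x: (3, H, W, N) -> features (D, N); cache kept only when training
extractor_fwd <- function(params, x, keep_cache = FALSE) {
  stem <- conv_fwd(x, params[["stem.W"]], params[["stem.b"]], 1L, 1L)
  rs <- relu_fwd(stem$out)
  h <- rs$out
  caches <- vector("list", 4)
  for (b in 1:4) {
    bl <- block_fwd(params, sprintf("block%d.", b), h,
                    stride = if (b == 1) 1L else 2L)
    h <- bl$out
    caches[[b]] <- bl$cache
  }
  gp <- gap_fwd(h)
  cache <- if (keep_cache)
    list(stem = stem$cache, stem_mask = rs$cache, blocks = caches, gap = gp$cache)
  list(features = gp$out, cache = cache)
}

extractor_bwd <- function(cache, dfeat) {
  grads <- list()
  dh <- gap_bwd(cache$gap, dfeat)
  for (b in 4:1) {
    bb <- block_bwd(cache$blocks[[b]], sprintf("block%d.", b), dh)
    grads <- c(grads, bb$grads)
    dh <- bb$dx
  }
  dstem <- relu_bwd(cache$stem_mask, dh)
  bs <- conv_bwd(cache$stem, dstem)
  grads[["stem.W"]] <- bs$dW
  grads[["stem.b"]] <- bs$db
  grads
}

#' Extract per-frame feature vectors
#'
#' Runs the convolutional feature extractor over a batch of frames. Each
#' frame is processed independently (the extractor is stateless), so the
#' feature vector of a frame does not depend on which other frames share its
#' batch.
#'
#' @param model A `pullback_model` from [build_model()] or [train_model()].
#' @param images Array of frames, either `(H, W, 3)` for a single frame or
#'   `(H, W, 3, N)`, intensities in `[0, 1]`.
#' @return Numeric matrix with one row per frame and `D` columns.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "pullback_model"))
  x <- frames_to_input(images, model$spec)
  t(extractor_fwd(model$params, x)$features)
}

# (H,W,3[,N]) image array -> channel-first (3,H,W,N), with size validation
frames_to_input <- function(images, spec) {
  d <- dim(images)
  if (length(d) == 3L) {
    dim(images) <- c(d, 1L)
    d <- dim(images)
  }
  if (length(d) != 4L || d[3] != 3L)
    stop("`images` must be (H, W, 3) or (H, W, 3, N)")
  if (d[1] != spec$image_size || d[2] != spec$image_size)
    stop(sprintf("frame size %dx%d does not match model input %dx%d",
                 d[1], d[2], spec$image_size, spec$image_size))
  aperm(images, c(3, 1, 2, 4))
}
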