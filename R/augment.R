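# Per-sequence-constant random affine augmentation: one transform (rotation,
# shear, translation/crop) is sampled per sequence and applied identically to
# every frame, so the augmentation never injects fake motion into a sequence.

#' Sample one random affine transform
#'
#' @param augment List with `max_rotation_deg`, `translate_crop_frac`,
#'   `max_shear_deg` (see [train_config()]).
#' @return List of transform parameters (`rotation_deg`, `shear_deg`,
#'   `translate_frac` length-2).
#' @export
sample_affine <- function(augment) {
  list(rotation_deg = runif(1, -augment$max_rotation_deg,
                            augment$max_rotation_deg),
       shear_deg = runif(1, -augment$max_shear_deg, augment$max_shear_deg),
       translate_frac = runif(2, -augment$translate_crop_frac,
                              augment$translate_crop_frac))
}

#' Affine coordinate map of a transform
#'
#' Returns the source coordinates (in pixel units, centered at the image
#' center) that each output pixel samples from, as used by
#' [augment_sequence()]. Exposed so the per-sequence rigidity of the
#' augmentation can be verified on a coordinate grid.
#'
#' @param size Image side length in pixels.
#' @param params Output of [sample_affine()].
#' @return List of matrices `sx`, `sy` (`size x size` source coordinates,
#'   1-based).
#' @export
affine_grid <- function(size, params) {
  th <- params$rotation_deg * pi / 180
  sh <- tan(params$shear_deg * pi / 180)
  # inverse map: output pixel -> source pixel; shear then rotate
  M <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) %*%
    rbind(c(1, sh), c(0, 1))
  ctr <- (size + 1) / 2
  gx <- matrix(seq_len(size), size, size)          # row coordinate
  gy <- t(gx)                                      # column coordinate
  dx <- gx - ctr
  dy <- gy - ctr
  sx <- M[1, 1] * dx + M[1, 2] * dy + ctr + params$translate_frac[1] * size
  sy <- M[2, 1] * dx + M[2, 2] * dy + ctr + params$translate_frac[2] * size
  list(sx = sx, sy = sy)
}

# bilinear sampling of (H,W,3[,N]) at the grid; edge pixels clamp (the
# translated-out border is cropped to the nearest edge value)
warp_images <- function(images, grid) {
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  S <- dim(images)[1]
  x0 <- floor(grid$sx); y0 <- floor(grid$sy)
  fx <- grid$sx - x0; fy <- grid$sy - y0
  cl <- function(v) pmin(pmax(v, 1), S)
  i00 <- cbind(as.vector(cl(x0)), as.vector(cl(y0)))
  i10 <- cbind(as.vector(cl(x0 + 1)), as.vector(cl(y0)))
  i01 <- cbind(as.vector(cl(x0)), as.vector(cl(y0 + 1)))
  i11 <- cbind(as.vector(cl(x0 + 1)), as.vector(cl(y0 + 1)))
  w00 <- as.vector((1 - fx) * (1 - fy)); w10 <- as.vector(fx * (1 - fy))
  w01 <- as.vector((1 - fx) * fy);       w11 <- as.vector(fx * fy)
  out <- images
  for (n in seq_len(dim(images)[4])) {
    for (ch in 1:3) {
      m <- images[, , ch, n]
      out[, , ch, n] <- matrix(m[i00] * w00 + m[i10] * w10 +
                                 m[i01] * w01 + m[i11] * w11, S, S)
    }
  }
  if (length(d) == 3L) dim(out) <- d
  out
}

#' Augment a training sequence with one constant affine transform
#'
#' @param images Array `(H, W, 3, L)` — the frames of one sequence.
#' @param augment Augmentation bounds (see [train_config()]).
#' @param params Optional pre-sampled transform (defaults to a fresh draw);
#'   the same `params` are applied to every frame.
#' @return Array of the same shape; the sampled transform is attached as
#'   attribute `"affine"`.
#' @export
augment_sequence <- function(images, augment, params = sample_affine(augment)) {
  d <- dim(images)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("`images` must be an (H, W, 3[, L]) array")
  if (augment$max_rotation_deg == 0 && augment$max_shear_deg == 0 &&
      augment$translate_crop_frac == 0) {
    attr(images, "affine") <- params
    return(images)
  }
  grid <- affine_grid(d[1], params)
  out <- warp_images(images, grid)
  attr(out, "affine") <- params
  out
}
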