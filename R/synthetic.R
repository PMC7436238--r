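#' Configuration for the synthetic pullback generator
#'
#' The generator emulates the statistical structure of an esophageal pullback
#' recording: the five tissue classes traversed in fixed anatomical order
#' St -> Tz -> B -> Ts -> Sq, one contiguous run per class with run lengths
#' proportional to the cohort class mix (Barrett dominant), gradual
#' appearance transitions around run boundaries (pixels blend, labels stay
#' crisp), per-frame pixel noise, and sporadic non-informative frames
#' (blur, bubbles, contrast extremes, motion smear).
#'
#' @param image_size Side length in pixels of the square frames (3 channels,
#'   intensities in `[0, 1]`). Must be a multiple of 8.
#' @param frames_per_video Frames per generated video (>= 5, one per class).
#' @param class_proportions Five fractions summing to 1, the expected share
#'   of each class in anatomical order. The default mirrors the clinical
#'   class mix (Barrett dominant at ~47%, squamous rare).
#' @param transition_width Frames over which appearance blends between
#'   adjacent classes on each side of a run boundary (0 = hard cuts).
#' @param noninformative_rate Fraction of frames degraded and flagged
#'   non-informative (never the last frame of a video).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param run_length_jitter Relative jitter applied to the apportioned run
#'   lengths (anatomy varies between patients); 0 disables it.
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return A `synthetic_config` object (list).
#' @export
#' @examples
#' cfg <- synthetic_config(frames_per_video = 50)
#' video <- generate_pullback(cfg, "P001", seed = 7)
#' table(video$frames$label)
synthetic_config <- function(image_size = 32L,
                             frames_per_video = 100L,
                             class_proportions = c(St = 0.13, Tz = 0.15,
                                                   B = 0.47, Ts = 0.21,
                                                   Sq = 0.04),
                             transition_width = 8L,
                             noninformative_rate = 0.05,
                             noise_sd = 0.05,
                             run_length_jitter = 0.10,
                             seed = 1L) {
  p <- as.numeric(class_proportions)
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("`class_proportions` must be 5 non-negative fractions summing to 1")
  if (transition_width < 0) stop("`transition_width` must be >= 0")
  if (noninformative_rate < 0 || noninformative_rate >= 1)
    stop("`noninformative_rate` must be in [0, 1)")
  if (frames_per_video < 5L)
    stop("`frames_per_video` must be >= 5 (one frame per tissue class)")
  if (image_size < 8L || image_size %% 8L != 0L)
    stop("`image_size` must be a multiple of 8 and >= 8")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 frames_per_video = as.integer(frames_per_video),
                 class_proportions = setNames(p, tissue_classes()),
                 transition_width = as.numeric(transition_width),
                 noninformative_rate = noninformative_rate,
                 noise_sd = noise_sd,
                 run_length_jitter = run_length_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Largest-remainder apportionment of frames to class runs
#'
#' Splits `n` frames into five run lengths proportional to `proportions`
#' using the largest-remainder rule, then guarantees every class at least one
#' frame (borrowing from the largest run), so a generated video always visits
#' all five classes.
#'
#' @param n Total frame count (>= 5).
#' @param proportions Five non-negative fractions summing to 1.
#' @return Integer vector of 5 run lengths summing to `n`.
#' @export
#' @examples
#' apportion_run_lengths(100, c(.13, .15, .47, .21, .04))
apportion_run_lengths <- function(n, proportions) {
  n <- as.integer(n)
  if (n < 5L) stop("need at least 5 frames")
  q <- n * proportions / sum(proportions)
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  while (any(base == 0)) {
    base[which.max(base)] <- max(base) - 1
    base[which(base == 0)[1]] <- 1
  }
  as.integer(base)
}

# class appearance model: base hue + oriented sinusoidal grating whose
# spatial frequency and orientation are class-specific; slow phase drift
# with time stands in for camera motion
class_base_rgb <- function() {
  rbind(St = c(0.80, 0.30, 0.20),
        Tz = c(0.90, 0.60, 0.30),
        B  = c(0.85, 0.40, 0.55),
        Ts = c(0.95, 0.75, 0.60),
        Sq = c(0.88, 0.86, 0.80))
}

class_texture <- function(class_idx, size, t) {
  freq <- c(2, 3, 5, 7, 9)[class_idx]
  theta <- (class_idx - 1) * pi / 5
  amp <- c(0.10, 0.06, 0.06)
  base <- class_base_rgb()[class_idx, ]
  gx <- matrix(seq_len(size) / size, size, size)
  gy <- t(gx)
  wave <- sin(2 * pi * freq * (gx * cos(theta) + gy * sin(theta)) + 0.3 * t)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] + amp[ch] * wave
  img
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate one synthetic pullback video
#'
#' @param cfg A [synthetic_config()].
#' @param patient_id Patient identifier string.
#' @param seed Integer seed for this video's randomness.
#' @param video_id Video identifier (defaults to `<patient_id>_v1`).
#' @return A `pullback_video`: list with `images` (array `H x W x 3 x T`),
#'   `frames` (tibble `patient_id`, `video_id`, `frame_index`, `label`,
#'   `informative`), `patient_id`, `video_id`.
#' @export
generate_pullback <- function(cfg, patient_id, seed = cfg$seed,
                              video_id = paste0(patient_id, "_v1")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  n <- cfg$frames_per_video
  props <- cfg$class_proportions
  if (cfg$run_length_jitter > 0) {
    j <- runif(5, 1 - cfg$run_length_jitter, 1 + cfg$run_length_jitter)
    props <- props * j / sum(props * j)
  }
  runs <- apportion_run_lengths(n, props)
  labels <- rep.int(seq_len(5L), runs)
  bounds <- cumsum(runs)[1:4] - 0.5  # boundary between frame i and i+1 (0-based)

  S <- cfg$image_size
  images <- array(0, c(S, S, 3, n))
  w <- cfg$transition_width
  for (t in seq_len(n)) {
    pos <- t - 1
    k <- labels[t]
    weights <- numeric(5)
    weights[k] <- 1
    if (w > 0) {
      # ramp toward each adjacent run: 50/50 at the boundary itself
      if (k > 1L) {
        d <- pos - bounds[k - 1L]
        a <- max(0, (1 - d / w) / 2)
        weights[k - 1L] <- a
        weights[k] <- weights[k] - a
      }
      if (k < 5L) {
        d <- bounds[k] - pos
        a <- max(0, (1 - d / w) / 2)
        weights[k + 1L] <- weights[k + 1L] + a
        weights[k] <- weights[k] - a
      }
    }
    img <- array(0, c(S, S, 3))
    for (cl in which(weights > 0))
      img <- img + weights[cl] * class_texture(cl, S, t)
    if (cfg$noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = cfg$noise_sd), dim(img))
    images[, , , t] <- clamp01(img)
  }

  informative <- rep(TRUE, n)
  n_bad <- floor(cfg$noninformative_rate * n)
  if (n_bad > 0) {
    bad <- sample(seq_len(n - 1L), n_bad)  # never the last frame
    kinds <- sample(c("blur", "bubbles", "contrast", "motion"),
                    n_bad, replace = TRUE)
    for (i in seq_along(bad)) {
      images[, , , bad[i]] <- degrade_image(images[, , , bad[i]], kinds[i])
      informative[bad[i]] <- FALSE
    }
  }

  frames <- tibble::tibble(
    patient_id = patient_id,
    video_id = video_id,
    frame_index = 0:(n - 1L),
    label = factor(tissue_classes()[labels], levels = tissue_classes()),
    informative = informative)
  structure(list(images = images, frames = frames,
                 patient_id = patient_id, video_id = video_id),
            class = "pullback_video")
}

#' @export
print.pullback_video <- function(x, ...) {
  cat("<pullback_video>", x$video_id, "patient", x$patient_id, "-",
      nrow(x$frames), "frames of",
      paste(dim(x$images)[1:2], collapse = "x"), "px;",
      sum(!x$frames$informative), "non-informative\n")
  invisible(x)
}

#' Generate a cohort of synthetic pullback videos
#'
#' One video per patient; each patient gets a derived seed so cohorts are
#' reproducible and videos differ.
#'
#' @param cfg A [synthetic_config()].
#' @param n_patients Number of patients (>= 1).
#' @param seed Cohort seed (defaults to `cfg$seed`).
#' @return A `pullback_cohort`: list of `pullback_video`, with unique
#'   patient ids `P001, P002, ...`.
#' @export
generate_cohort <- function(cfg, n_patients, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), n_patients >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  videos <- lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    generate_pullback(cfg, pid, seed = seeds[i])
  })
  structure(videos, class = "pullback_cohort")
}

#' @export
print.pullback_cohort <- function(x, ...) {
  nf <- sum(vapply(x, function(v) nrow(v$frames), integer(1)))
  cat("<pullback_cohort>", length(x), "videos,", nf, "frames\n")
  invisible(x)
}

#' Per-frame metadata of a cohort as one tibble
#'
#' @param cohort A `pullback_cohort` (or list of `pullback_video`).
#' @return Tibble binding every video's `frames` table.
#' @export
cohort_frames <- function(cohort) {
  dplyr::bind_rows(lapply(cohort, function(v) v$frames))
}

# image-level degradations; `strength` scales the effect (0 = identity for
# the smoothing kinds)
degrade_image <- function(img, kind, strength = 1) {
  switch(kind,
    blur = gaussian_blur(img, sigma = 1.5 * strength),
    motion = motion_smear(img, len = round(5 * strength)),
    bubbles = add_bubbles(img, n = max(1, round(4 * strength))),
    contrast = {
      gain <- 1 + 2 * strength
      clamp01(0.5 + gain * (img - 0.5))
    },
    stop("unknown degradation kind: ", kind))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(-r:r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  for (ch in 1:3) {
    m <- img[, , ch]
    m <- apply(m, 2, conv_reflect, kern = kern)
    m <- t(apply(m, 1, conv_reflect, kern = kern))
    img[, , ch] <- m
  }
  img
}

# 1-D convolution with reflected edges
conv_reflect <- function(x, kern) {
  r <- (length(kern) - 1L) %/% 2L
  n <- length(x)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  xx <- x[pmin(pmax(idx, 1L), n)]
  as.numeric(stats::filter(xx, kern, sides = 2))[r + seq_len(n)]
}

motion_smear <- function(img, len) {
  if (len <= 0) return(img)
  S <- dim(img)[1]
  theta <- runif(1, 0, pi)
  out <- img * 0
  shifts <- seq(0, len)
  for (s in shifts) {
    dx <- round(s * cos(theta)); dy <- round(s * sin(theta))
    ri <- pmin(pmax(seq_len(S) + dy, 1L), S)
    ci <- pmin(pmax(seq_len(S) + dx, 1L), dim(img)[2])
    out <- out + img[ri, ci, , drop = FALSE]
  }
  out / length(shifts)
}

add_bubbles <- function(img, n) {
  S <- dim(img)[1]
  gx <- matrix(seq_len(S), S, dim(img)[2])
  gy <- t(matrix(seq_len(dim(img)[2]), dim(img)[2], S))
  for (i in seq_len(n)) {
    cx <- runif(1, 1, dim(img)[2]); cy <- runif(1, 1, S)
    rad <- runif(1, S / 12, S / 5)
    d2 <- (gy - cx)^2 + (gx - cy)^2
    mask <- exp(-d2 / (2 * (rad / 2)^2))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.8 * mask
  }
  clamp01(img)
}

#' Degrade one frame into a non-informative copy
#'
#' Produces the kinds of uninformative frames seen in real recordings:
#' `blur` (out-of-focus Gaussian smoothing), `bubbles` (bright circular
#' blobs), `contrast` (intensity stretch toward saturation) and `motion`
#' (directional smear). The tissue label is untouched; only the
#' `informative` flag drops to `FALSE`.
#'
#' @param frame A frame as returned by [get_frame()]: list with `image`
#'   (H x W x 3) and metadata fields.
#' @param kind One of `"blur"`, `"bubbles"`, `"contrast"`, `"motion"`.
#' @param strength Effect size multiplier; 0 leaves the image unchanged for
#'   the smoothing kinds.
#' @param seed Optional seed for the degradation's randomness.
#' @return The frame with a degraded `image` and `informative = FALSE`.
#' @export
degrade_frame <- function(frame, kind, strength = 1, seed = NULL) {
  if (!is.list(frame) || is.null(frame$image))
    stop("`frame` must be a frame list with an `image` field")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  frame$image <- degrade_image(frame$image, kind, strength)
  frame$informative <- FALSE
  frame
}

#' Extract one frame from a video
#'
#' @param video A `pullback_video`.
#' @param i Frame position (1-based).
#' @return List with `image` and the metadata of that frame.
#' @export
get_frame <- function(video, i) {
  stopifnot(inherits(video, "pullback_video"), i >= 1, i <= nrow(video$frames))
  meta <- video$frames[i, ]
  list(image = video$images[, , , i],
       label = meta$label,
       informative = meta$informative,
       patient_id = meta$patient_id,
       video_id = meta$video_id,
       frame_index = meta$frame_index)
}

# validate the pullback_video invariants (used by load_dataset and tests)
validate_video <- function(video) {
  fr <- video$frames
  if (is.unsorted(fr$frame_index, strictly = TRUE))
    stop("frame_index must be strictly increasing")
  if (length(unique(fr$patient_id)) != 1L || length(unique(fr$video_id)) != 1L)
    stop("all frames must share patient_id and video_id")
  runs <- rle(as.character(fr$label))$values
  if (!identical(runs, tissue_classes()[tissue_classes() %in% runs]) ||
      anyDuplicated(runs) > 0)
    stop("labels must form one contiguous run per class in anatomical order")
  rng <- range(video$images)
  if (!all(is.finite(video$images)) || rng[1] < 0 || rng[2] > 1)
    stop("image intensities must be finite and in [0, 1]")
  invisible(video)
}
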