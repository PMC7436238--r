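test_that("largest-remainder apportionment matches the closed form", {
  # independent oracle: quotas, floors, then +1 to the largest remainders
  oracle <- function(n, p) {
    q <- n * p / sum(p)
    base <- floor(q)
    left <- n - sum(base)
    ord <- order(q - base, decreasing = TRUE)
    if (left > 0) base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    as.integer(base)
  }
  expect_identical(apportion_run_lengths(100, c(.13, .15, .47, .21, .04)),
                   c(13L, 15L, 47L, 21L, 4L))
  for (n in c(37, 60, 96, 251)) {
    p <- c(.13, .15, .47, .21, .04)
    expect_identical(apportion_run_lengths(n, p), oracle(n, p))
    expect_equal(sum(apportion_run_lengths(n, p)), n)
  }
  # every class gets at least one frame even when its quota rounds to zero
  tiny <- apportion_run_lengths(12, c(.01, .01, .94, .02, .02))
  expect_true(all(tiny >= 1L))
  expect_equal(sum(tiny), 12L)
})

test_that("generated videos traverse the five classes in anatomical order", {
  cfg <- synthetic_config(image_size = 8L, frames_per_video = 60L, seed = 3)
  co <- generate_cohort(cfg, 10)
  for (v in co) {
    runs <- rle(as.character(v$frames$label))$values
    expect_identical(runs, tissue_classes())
    expect_identical(v$frames$frame_index, 0:(nrow(v$frames) - 1L))
    expect_true(all(is.finite(v$images)))
    expect_true(min(v$images) >= 0 && max(v$images) <= 1)
    # non-informative frames never close a video
    expect_true(v$frames$informative[nrow(v$frames)])
  }
})

test_that("cohort class frequencies recover the configured proportions", {
  cfg <- synthetic_config(image_size = 8L, frames_per_video = 100L, seed = 5)
  co <- generate_cohort(cfg, 50)
  freq <- table(cohort_frames(co)$label) / (50 * 100)
  expect_true(all(abs(as.numeric(freq) - cfg$class_proportions) <= 0.03))
})

test_that("with no transition, no noise, classes are linearly separable", {
  co <- separable_cohort(6, frames = 60)
  X <- do.call(cbind, lapply(co, function(v)
    matrix(v$images, ncol = dim(v$images)[4])))
  y <- as.integer(cohort_frames(co)$label)
  centroids <- sapply(1:5, function(k) rowMeans(X[, y == k, drop = FALSE]))
  pred <- apply(X, 2, function(col) which.min(colSums((centroids - col)^2)))
  expect_equal(mean(pred == y), 1)
})

test_that("transition_width = 0 yields pure single-class textures", {
  cfg0 <- synthetic_config(image_size = 8L, frames_per_video = 40L,
                           transition_width = 0, noise_sd = 0,
                           noninformative_rate = 0, run_length_jitter = 0,
                           seed = 2)
  v <- generate_pullback(cfg0, "P001", seed = 2)
  # frames adjacent to a boundary must equal the pure class texture
  runs <- rle(as.character(v$frames$label))$lengths
  boundary_frame <- cumsum(runs)[1]          # last frame of first run
  pure <- pullbacknet:::clamp01(
    pullbacknet:::class_texture(1L, 8L, boundary_frame))
  expect_equal(v$images[, , , boundary_frame], pure, tolerance = 1e-12)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(image_size = 8L, frames_per_video = 40L, seed = 9)
  expect_identical(generate_pullback(cfg, "P001", seed = 4),
                   generate_pullback(cfg, "P001", seed = 4))
  expect_identical(generate_cohort(cfg, 4, seed = 8),
                   generate_cohort(cfg, 4, seed = 8))
  expect_false(identical(generate_pullback(cfg, "P001", seed = 4),
                         generate_pullback(cfg, "P001", seed = 5)))
})

test_that("cohort patients are unique and sized as requested", {
  cfg <- synthetic_config(image_size = 8L, frames_per_video = 20L, seed = 1)
  co <- generate_cohort(cfg, 5)
  expect_length(co, 5)
  expect_length(unique(vapply(co, function(v) v$patient_id, character(1))), 5)
  expect_equal(nrow(cohort_frames(co)), 100)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(class_proportions = c(.2, .2, .2, .2, .1)),
               "summing to 1")
  expect_error(synthetic_config(transition_width = -1), "transition_width")
  expect_error(synthetic_config(noninformative_rate = 1), "noninformative")
  expect_error(synthetic_config(frames_per_video = 4), ">= 5")
})

test_that("degradations flag frames non-informative and keep the label", {
  cfg <- synthetic_config(image_size = 16L, frames_per_video = 20L,
                          noninformative_rate = 0, seed = 6)
  v <- generate_pullback(cfg, "P001", seed = 6)
  f <- get_frame(v, 5)
  for (kind in c("blur", "bubbles", "contrast", "motion")) {
    g <- degrade_frame(f, kind, seed = 1)
    expect_false(g$informative)
    expect_identical(g$label, f$label)
    expect_equal(dim(g$image), dim(f$image))
    expect_true(all(is.finite(g$image)))
  }
  expect_error(degrade_frame(f, "fog"), "unknown degradation")
})

test_that("zero-strength smoothing degradations are the identity", {
  cfg <- synthetic_config(image_size = 16L, frames_per_video = 20L,
                          noninformative_rate = 0, seed = 6)
  f <- get_frame(generate_pullback(cfg, "P001", seed = 6), 8)
  expect_equal(degrade_frame(f, "blur", strength = 0)$image, f$image)
  expect_equal(degrade_frame(f, "motion", strength = 0)$image, f$image)
})

test_that("blur reduces pixel variance of a textured frame", {
  cfg <- synthetic_config(image_size = 16L, frames_per_video = 20L,
                          noise_sd = 0.1, noninformative_rate = 0, seed = 7)
  f <- get_frame(generate_pullback(cfg, "P001", seed = 7), 10)
  g <- degrade_frame(f, "blur", seed = 2)
  expect_lt(var(as.vector(g$image)), var(as.vector(f$image)))
})
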