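#' Training configuration
#'
#' Mirrors the training protocol: per iteration, a class- and case-balanced
#' draw of `batch_sequences` sequences of 1 (FC heads) or 10 (recurrent
#' heads) consecutive frames ending on an informative frame; one random
#' affine transform per sequence (rotation up to 5 degrees, translation/crop
#' up to 2.5% of the image length, shear up to 5 degrees) held constant
#' across the sequence's frames; cross-entropy loss on the final frame's
#' prediction; Adam at an initial learning rate of 1e-4 under a cyclic
#' cosine schedule that restarts every `scheduler_period` iterations.
#'
#' @param sequence_length Frames per sequence; `NULL` picks the head's
#'   convention (1 for `fc`/`fc_avg`, 10 for `lstm`/`gru`).
#' @param batch_sequences Sequences per iteration.
#' @param base_lr Initial (peak) learning rate of each cosine cycle.
#' @param scheduler_period Iterations per cosine cycle.
#' @param total_iterations Optimizer steps to run.
#' @param augment List of augmentation bounds: `max_rotation_deg`,
#'   `translate_crop_frac`, `max_shear_deg`.
#' @param supervise `"all"` (default) spreads the cross-entropy loss over
#'   every frame of a sequence, which supervises the "classify now from
#'   history" contract at every state depth and makes whole-video streaming
#'   inference well-behaved; `"last"` trains on the final frame only.
#' @param seed RNG seed for sampling, augmentation and initialization order.
#' @return A `train_config` object (list).
#' @export
train_config <- function(sequence_length = NULL,
                         batch_sequences = 512L,
                         base_lr = 1e-4,
                         scheduler_period = 500L,
                         total_iterations = 2000L,
                         augment = list(max_rotation_deg = 5,
                                        translate_crop_frac = 0.025,
                                        max_shear_deg = 5),
                         supervise = c("all", "last"),
                         seed = 1L) {
  supervise <- match.arg(supervise)
  if (!is.null(sequence_length) && sequence_length < 1L)
    stop("`sequence_length` must be >= 1")
  if (batch_sequences < 1L) stop("`batch_sequences` must be >= 1")
  if (base_lr <= 0) stop("`base_lr` must be > 0")
  if (scheduler_period < 1L) stop("`scheduler_period` must be >= 1")
  if (total_iterations < 0L) stop("`total_iterations` must be >= 0")
  aug <- modifyList(list(max_rotation_deg = 5, translate_crop_frac = 0.025,
                         max_shear_deg = 5), augment)
  structure(list(sequence_length = if (!is.null(sequence_length))
                   as.integer(sequence_length),
                 batch_sequences = as.integer(batch_sequences),
                 base_lr = base_lr,
                 scheduler_period = as.integer(scheduler_period),
                 total_iterations = as.integer(total_iterations),
                 augment = aug,
                 supervise = supervise,
                 seed = as.integer(seed)),
            class = "train_config")
}

default_sequence_length <- function(spec, cfg) {
  cfg$sequence_length %||%
    if (spec$head_kind %in% c("lstm", "gru")) 10L else 1L
}

#' Cyclic cosine learning rate
#'
#' `lr(i) = base_lr * (1 + cos(pi * (i mod period) / period)) / 2`: each
#' cycle decays from `base_lr` toward 0 along a half cosine and restarts.
#'
#' @param iteration 0-based iteration counter (vectorized).
#' @param base_lr Peak learning rate.
#' @param period Iterations per cycle (>= 1).
#' @return Learning rate(s).
#' @export
cyclic_cosine_lr <- function(iteration, base_lr, period) {
  if (period < 1) stop("`period` must be >= 1")
  base_lr * (1 + cos(pi * (iteration %% period) / period)) / 2
}

#' Train a classifier on a cohort
#'
#' Runs the full protocol: balanced sequence sampling, per-sequence-constant
#' affine augmentation, forward pass (recurrent heads consume each sequence
#' from a zero state), cross-entropy loss, backpropagation (through time for
#' the recurrent heads) and an Adam step at the scheduled learning rate.
#' Fully seeded: the same model, cohort and config reproduce the same loss
#' history bit for bit.
#'
#' @param model A freshly built or previously trained `pullback_model`.
#' @param cohort A `pullback_cohort` (or list of `pullback_video`) whose
#'   frame size matches the model spec.
#' @param cfg A [train_config()].
#' @return The trained `pullback_model`, with the per-iteration history
#'   (tibble `iteration`, `lr`, `loss`) attached as `model$history`.
#' @export
train_model <- function(model, cohort, cfg = train_config()) {
  stopifnot(inherits(model, "pullback_model"), inherits(cfg, "train_config"))
  spec <- model$spec
  L <- default_sequence_length(spec, cfg)
  history <- tibble::tibble(iteration = integer(), lr = numeric(),
                            loss = numeric())
  if (cfg$total_iterations == 0L) {
    model$history <- history
    return(model)
  }
  weights <- compute_sampling_weights(cohort, sequence_length = L)
  if (length(unique(weights$label[weights$eligible])) < spec$n_classes)
    warning("not every class has an eligible sequence end")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  params <- model$params
  opt <- adam_init(params)
  B <- cfg$batch_sequences
  recurrent <- spec$head_kind %in% c("lstm", "gru")
  hist_lr <- numeric(cfg$total_iterations)
  hist_loss <- numeric(cfg$total_iterations)

  for (it in seq_len(cfg$total_iterations)) {
    lr <- cyclic_cosine_lr(it - 1L, cfg$base_lr, cfg$scheduler_period)
    batch <- draw_batch(cohort, weights, L, B)
    imgs <- batch$images
    for (b in seq_len(B)) {
      span <- ((b - 1L) * L + 1L):(b * L)
      imgs[, , , span] <- augment_sequence(imgs[, , , span, drop = FALSE],
                                           cfg$augment)
    }
    x <- aperm(imgs, c(3, 1, 2, 4))
    ext <- extractor_fwd(params, x, keep_cache = TRUE)

    if (!recurrent) {
      # FC heads: every column is one frame; supervise each sampled end
      if (L > 1L) {
        keep <- seq_len(B) * L
        feats <- ext$features[, keep, drop = FALSE]
      } else feats <- ext$features
      hf <- fc_head_fwd(params, feats)
      ce <- softmax_xent(hf$logits, batch$targets)
      hb <- fc_head_bwd(hf$cache, ce$dlogits)
      dfeat <- matrix(0, spec$feature_dim, ncol(ext$features))
      if (L > 1L) dfeat[, seq_len(B) * L] <- hb$dX else dfeat <- hb$dX
      grads <- hb$grads
    } else {
      X <- array(ext$features, c(spec$feature_dim, L, B))
      rf <- rnn_fwd(params, spec, X, zero_state(spec, B))
      if (cfg$supervise == "last") {
        last_logits <- matrix(rf$logits[, L, ], spec$n_classes, B)
        ce <- softmax_xent(last_logits, batch$targets)
        dlogits <- array(0, dim(rf$logits))
        dlogits[, L, ] <- ce$dlogits
      } else {
        flat <- matrix(rf$logits, spec$n_classes, L * B)
        ce <- softmax_xent(flat, batch$labels)
        dlogits <- array(ce$dlogits, dim(rf$logits))
      }
      rb <- rnn_bwd(params, spec, rf$cache, dlogits)
      dfeat <- matrix(rb$dX, spec$feature_dim, L * B)
      grads <- rb$grads
    }
    if (!is.finite(ce$loss))
      stop("non-finite loss at iteration ", it,
           " (lr = ", signif(lr, 3), "); try a lower base_lr")
    grads <- c(grads, extractor_bwd(ext$cache, dfeat))
    step <- adam_step(params, grads, opt, lr)
    params <- step$params
    opt <- step$state
    hist_lr[it] <- lr
    hist_loss[it] <- ce$loss
  }
  model$params <- params
  model$history <- tibble::tibble(iteration = seq_len(cfg$total_iterations),
                                  lr = hist_lr, loss = hist_loss)
  model
}
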