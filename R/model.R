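#' Model specification
#'
#' Describes one classifier: a compact residual convolutional feature
#' extractor (four residual blocks in the style of ResNet18's basic blocks,
#' global average pooling, no classification stem) followed by one of four
#' interchangeable heads:
#'
#' * `"fc"` — two fully connected layers with a ReLU in between, applied to
#'   each frame independently;
#' * `"fc_avg"` — the same FC head, with a causal moving-average filter of
#'   `avg_window` frames applied to the output probabilities at inference;
#' * `"lstm"` — a two-layer LSTM followed by a fully connected layer;
#' * `"gru"` — a two-layer GRU followed by a fully connected layer.
#'
#' @param head_kind One of `"fc"`, `"fc_avg"`, `"lstm"`, `"gru"`.
#' @param image_size Input side length in pixels (square frames, 3 channels).
#'   Must be a multiple of 8 and at least 8: the extractor downsamples three
#'   times.
#' @param widths Integer vector of 4 channel widths, one per residual block.
#'   The last width is the feature dimension `D`.
#' @param hidden_size Hidden units of the FC bottleneck / recurrent layers.
#' @param recurrent_layers Number of stacked recurrent layers.
#' @param avg_window Causal averaging window (frames) for the `fc_avg` head.
#' @param n_classes Number of tissue classes (fixed at 5 here).
#' @return A `model_spec` object (list).
#' @export
#' @examples
#' model_spec("lstm")
model_spec <- function(head_kind = c("fc", "fc_avg", "lstm", "gru"),
                       image_size = 32L,
                       widths = c(16L, 32L, 64L, 128L),
                       hidden_size = 128L,
                       recurrent_layers = 2L,
                       avg_window = 5L,
                       n_classes = 5L) {
  head_kind <- match.arg(head_kind)
  image_size <- as.integer(image_size)
  widths <- as.integer(widths)
  if (length(widths) != 4L || any(widths < 1L))
    stop("`widths` must be 4 positive block widths")
  if (image_size < 8L || image_size %% 8L != 0L)
    stop("`image_size` must be a multiple of 8 and >= 8")
  if (hidden_size < 1L) stop("`hidden_size` must be >= 1")
  if (recurrent_layers < 1L) stop("`recurrent_layers` must be >= 1")
  if (avg_window < 1L) stop("`avg_window` must be >= 1")
  structure(list(head_kind = head_kind,
                 image_size = image_size,
                 widths = widths,
                 feature_dim = widths[4],
                 hidden_size = as.integer(hidden_size),
                 recurrent_layers = as.integer(recurrent_layers),
                 avg_window = as.integer(avg_window),
                 n_classes = as.integer(n_classes)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> head:", x$head_kind,
      "| input:", paste0(x$image_size, "x", x$image_size, "x3"),
      "| widths:", paste(x$widths, collapse = "/"),
      "| D:", x$feature_dim,
      if (x$head_kind %in% c("lstm", "gru"))
        paste("| hidden:", x$hidden_size, "x", x$recurrent_layers, "layers")
      else paste("| hidden:", x$hidden_size),
      "\n")
  invisible(x)
}

#' Build (initialize) a classifier from a spec
#'
#' Draws fresh weights: He-normal for convolutional and fully connected
#' layers, uniform \eqn{\pm 1/\sqrt{H}} for recurrent layers, LSTM forget-gate
#' bias at 1.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the weight draw.
#' @return A `pullback_model` (list with `spec` and named parameter list).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  params <- c(init_extractor_params(spec), init_head_params(spec))
  structure(list(spec = spec, params = params), class = "pullback_model")
}

#' @export
print.pullback_model <- function(x, ...) {
  print(x$spec)
  cat("  parameters:", n_parameters(x), "\n")
  invisible(x)
}

#' Total number of trainable parameters
#'
#' @param model A `pullback_model`.
#' @return Integer count over all weight and bias arrays.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the spec and all weights.
#'
#' @param model A `pullback_model`.
#' @param path File path (conventionally `.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `pullback_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pullback_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pullback_model"))
    stop("not a pullback_model checkpoint: ", path)
  model
}

# preserve caller RNG around internally seeded draws
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
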