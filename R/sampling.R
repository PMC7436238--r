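#' Class- and case-balanced sampling weights
#'
#' Random under-sampling for training-set stratification: every frame gets a
#' sampling probability such that each (patient case, tissue class) cell
#' carries the same total mass, and frames within a cell are equally likely.
#' A frame is *eligible* as a sequence end only if it is labeled informative
#' and has at least `sequence_length - 1` predecessors in its video;
#' ineligible frames get zero weight before normalization.
#'
#' @param cohort A `pullback_cohort` (or list of `pullback_video`).
#' @param sequence_length Length `L` of the training sequences the weights
#'   will terminate.
#' @return Tibble with one row per frame: `video` (index into the cohort),
#'   `patient_id`, `video_id`, `pos` (1-based position), `frame_index`,
#'   `label`, `informative`, `eligible`, `weight`. Weights sum to 1.
#' @export
compute_sampling_weights <- function(cohort, sequence_length = 1L) {
  if (length(cohort) == 0L) stop("empty dataset")
  L <- as.integer(sequence_length)
  tbl <- dplyr::bind_rows(lapply(seq_along(cohort), function(i) {
    fr <- cohort[[i]]$frames
    tibble::tibble(video = i,
                   patient_id = fr$patient_id,
                   video_id = fr$video_id,
                   pos = seq_len(nrow(fr)),
                   frame_index = fr$frame_index,
                   label = fr$label,
                   informative = fr$informative)
  }))
  tbl$eligible <- tbl$informative & tbl$pos >= L
  if (!any(tbl$eligible))
    stop("no frame is eligible as a sequence end (sequence_length = ", L, ")")
  cell <- paste(tbl$patient_id, tbl$label, sep = "\r")
  cell[!tbl$eligible] <- NA
  sizes <- table(cell)
  n_cells <- length(sizes)
  tbl$weight <- ifelse(tbl$eligible,
                       1 / (n_cells * as.numeric(sizes[cell])), 0)
  tbl$weight[is.na(tbl$weight)] <- 0
  tbl
}

#' Draw a batch of training sequences
#'
#' Samples `B` sequence end-frames according to `weights` (with replacement)
#' and assembles, for each, the `L` consecutive frames of its video that end
#' there. The supervision target is the label of the last frame, which is
#' always informative by construction of the weights; earlier frames of a
#' sequence may be non-informative.
#'
#' @param cohort The cohort the weights were computed on.
#' @param weights Output of [compute_sampling_weights()].
#' @param L Sequence length in frames.
#' @param B Number of sequences.
#' @return List with `images` (array `H x W x 3 x (B*L)`, frames of a
#'   sequence contiguous), `targets` (integer class codes 1..5, length `B`),
#'   `labels` (integer codes for every frame, length `B*L`) and `ends`
#'   (tibble of the sampled end rows).
#' @export
draw_batch <- function(cohort, weights, L, B) {
  L <- as.integer(L); B <- as.integer(B)
  pick <- sample.int(nrow(weights), B, replace = TRUE, prob = weights$weight)
  ends <- weights[pick, ]
  S <- dim(cohort[[ends$video[1]]]$images)[1:2]
  images <- array(0, c(S[1], S[2], 3, B * L))
  labels <- integer(B * L)
  for (b in seq_len(B)) {
    v <- cohort[[ends$video[b]]]
    span <- (ends$pos[b] - L + 1L):ends$pos[b]
    images[, , , ((b - 1L) * L + 1L):(b * L)] <- v$images[, , , span]
    labels[((b - 1L) * L + 1L):(b * L)] <- as.integer(v$frames$label[span])
  }
  list(images = images,
       targets = as.integer(ends$label),
       labels = labels,
       ends = ends)
}
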