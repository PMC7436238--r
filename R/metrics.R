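#' Correspondence map between predicted and acceptable true labels
#'
#' Transition zones have no hard visual boundary, so a prediction adjacent to
#' the annotated class is still clinically correct. The default map declares,
#' for each predicted label, the set of ground-truth labels that count as a
#' true positive:
#'
#' | predicted | acceptable truth |
#' |-----------|------------------|
#' | St        | St               |
#' | Tz        | Tz, B            |
#' | B         | Tz, B, Ts        |
#' | Ts        | B, Ts            |
#' | Sq        | Sq               |
#'
#' The identity map (each label acceptable only for itself) reduces the
#' mapped accuracy to plain frame accuracy.
#'
#' @param mapping Named list: predicted label -> character vector of
#'   acceptable true labels. Every set must contain the predicted label
#'   itself.
#' @return A `correspondence_map` object.
#' @export
#' @examples
#' m <- correspondence_map()
#' is_true_positive("B", "Tz", m)
correspondence_map <- function(mapping = list(St = "St",
                                              Tz = c("Tz", "B"),
                                              B = c("Tz", "B", "Ts"),
                                              Ts = c("B", "Ts"),
                                              Sq = "Sq")) {
  cls <- tissue_classes()
  if (!setequal(names(mapping), cls))
    stop("mapping must have exactly one entry per tissue class")
  mapping <- mapping[cls]
  for (k in cls) {
    if (!(k %in% mapping[[k]]))
      stop("acceptable set for ", k, " must contain ", k, " itself")
    if (!all(mapping[[k]] %in% cls))
      stop("unknown label in acceptable set for ", k)
  }
  structure(mapping, class = "correspondence_map")
}

#' Identity correspondence map (plain accuracy)
#' @return A `correspondence_map` mapping every label to itself only.
#' @export
identity_map <- function() {
  correspondence_map(setNames(as.list(tissue_classes()), tissue_classes()))
}

#' Is a prediction a true positive under a correspondence map?
#'
#' @param predicted,truth Label vectors (character or factor); recycled to a
#'   common length.
#' @param map A [correspondence_map()].
#' @return Logical vector: `truth` is in the acceptable set of `predicted`.
#' @export
is_true_positive <- function(predicted, truth, map = correspondence_map()) {
  stopifnot(inherits(map, "correspondence_map"))
  p <- as.character(tissue_factor(predicted))
  tr <- as.character(tissue_factor(truth))
  n <- max(length(p), length(tr))
  p <- rep_len(p, n); tr <- rep_len(tr, n)
  vapply(seq_len(n), function(i) tr[i] %in% map[[p[i]]], logical(1))
}

#' Correspondence-mapped label accuracy of one track
#'
#' The fraction of frames whose prediction is a true positive under the map:
#' the per-video accuracy \eqn{\mathrm{LabelAcc} = \frac{1}{N_v}\sum_j TP_j}.
#'
#' @param pred,truth Label vectors of equal length (aligned frames).
#' @param map A [correspondence_map()].
#' @return Fraction in `[0, 1]`.
#' @export
label_accuracy <- function(pred, truth, map = correspondence_map()) {
  pred <- label_track_vector(pred)
  truth <- label_track_vector(truth)
  if (length(pred) != length(truth))
    stop("pred and truth tracks differ in length (",
         length(pred), " vs ", length(truth), ")")
  if (length(pred) == 0L) stop("empty label track")
  mean(is_true_positive(pred, truth, map))
}

# accept either a bare label vector or a label-track tibble
label_track_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!"label" %in% names(x)) stop("label track tibble needs a `label` column")
    x <- x[order(x$frame_index %||% seq_len(nrow(x))), , drop = FALSE]$label
  }
  as.character(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean label accuracy over patients
#'
#' The unweighted mean of per-patient accuracies
#' \eqn{\frac{1}{N_p}\sum_i \mathrm{Acc}(L_i)}: every patient counts equally
#' regardless of video length.
#'
#' @param per_patient Numeric vector of per-patient accuracies.
#' @return Scalar in `[0, 1]`.
#' @export
mean_label_accuracy <- function(per_patient) {
  if (length(per_patient) == 0L) stop("no patient accuracies supplied")
  mean(per_patient)
}

#' Count label switches in a prediction track
#'
#' The stability unit: one switch whenever the predicted label at frame
#' `t+1` differs from frame `t`. Equals (number of maximal constant runs)
#' minus 1; a track that visits each of the five classes once in anatomical
#' order scores exactly 4.
#'
#' @param track Label vector or label-track tibble.
#' @return Non-negative integer switch count.
#' @export
count_label_switches <- function(track) {
  x <- label_track_vector(track)
  if (length(x) == 0L) stop("empty label track")
  sum(x[-1] != x[-length(x)])
}

#' Per-patient-normalized confusion matrix
#'
#' For each patient the raw confusion counts (rows = true label, columns =
#' predicted label, no correspondence mapping) are row-normalized; each row
#' of the result is the average over the patients that have at least one
#' frame of that true class, times 100.
#'
#' @param tracks Tibble with columns `patient_id`, `truth`, `pred` (one row
#'   per frame), or a list of per-patient `(pred, truth)` pairs.
#' @return 5x5 matrix of percentages; rows with no data are `NA`.
#' @export
patient_confusion_matrix <- function(tracks) {
  if (!is.data.frame(tracks)) {
    tracks <- dplyr::bind_rows(lapply(seq_along(tracks), function(i) {
      tibble::tibble(patient_id = sprintf("patient%03d", i),
                     pred = as.character(tracks[[i]]$pred),
                     truth = as.character(tracks[[i]]$truth))
    }))
  }
  cls <- tissue_classes()
  acc <- array(0, c(5, 5), dimnames = list(truth = cls, pred = cls))
  cnt <- matrix(0, 5, 5, dimnames = dimnames(acc))
  for (pid in unique(tracks$patient_id)) {
    sub <- tracks[tracks$patient_id == pid, ]
    tab <- table(factor(sub$truth, cls), factor(sub$pred, cls))
    rs <- rowSums(tab)
    for (r in which(rs > 0)) {
      acc[r, ] <- acc[r, ] + tab[r, ] / rs[r]
      cnt[r, ] <- cnt[r, ] + 1
    }
  }
  out <- 100 * acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Evaluate prediction tracks against ground truth
#'
#' Joins predictions and truth on `(patient_id, video_id, frame_index)` and
#' computes every evaluation quantity: per-video mapped label accuracy over
#' informative frames, per-patient accuracy (frames of a patient's videos
#' pooled), the patient-averaged mean label accuracy, per-video switch
#' counts over *all* frames (a live system keeps emitting on degraded
#' frames), and the per-patient-normalized confusion matrix.
#'
#' @param pred Tibble with `patient_id`, `video_id`, `frame_index`, `label`.
#' @param truth Tibble with the same keys plus `label` and (optionally)
#'   `informative`; missing `informative` means all frames count.
#' @param map A [correspondence_map()].
#' @return A `pullback_evaluation` object; see [tidy.pullback_evaluation()].
#' @export
evaluate_predictions <- function(pred, truth, map = correspondence_map()) {
  keys <- c("patient_id", "video_id", "frame_index")
  stopifnot(all(keys %in% names(pred)), all(keys %in% names(truth)))
  if (!"informative" %in% names(truth)) truth$informative <- TRUE
  joined <- dplyr::inner_join(
    dplyr::select(pred, dplyr::all_of(keys), pred = "label"),
    dplyr::select(truth, dplyr::all_of(keys), truth = "label",
                  "informative"),
    by = keys)
  if (nrow(joined) == 0L) stop("no overlapping frames between pred and truth")
  joined <- dplyr::arrange(joined, .data$patient_id, .data$video_id,
                           .data$frame_index)
  joined$tp <- is_true_positive(joined$pred, joined$truth, map)

  per_video <- joined |>
    dplyr::group_by(.data$patient_id, .data$video_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      n_informative = sum(.data$informative),
      switches = count_label_switches(.data$pred),
      accuracy = mean(.data$tp[.data$informative]),
      .groups = "drop")

  inf <- joined[joined$informative, ]
  per_patient <- inf |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_frames = dplyr::n(),
                     accuracy = mean(.data$tp), .groups = "drop")

  per_class <- inf |>
    dplyr::group_by(.data$patient_id, truth = .data$truth) |>
    dplyr::summarise(acc = mean(.data$tp), .groups = "drop") |>
    dplyr::group_by(.data$truth) |>
    dplyr::summarise(accuracy = mean(.data$acc),
                     n_patients = dplyr::n(), .groups = "drop")

  structure(list(per_video = per_video,
                 per_patient = per_patient,
                 per_class = per_class,
                 mean_label_accuracy = mean_label_accuracy(per_patient$accuracy),
                 mean_switches = mean(per_video$switches),
                 confusion = patient_confusion_matrix(
                   dplyr::select(inf, "patient_id", "pred", "truth")),
                 map = map),
            class = "pullback_evaluation")
}

#' @export
print.pullback_evaluation <- function(x, ...) {
  cat("<pullback_evaluation>", nrow(x$per_patient), "patients,",
      nrow(x$per_video), "videos\n")
  cat(sprintf("  mean label accuracy: %.1f%%   mean switches/video: %.2f\n",
              100 * x$mean_label_accuracy, x$mean_switches))
  invisible(x)
}

#' Tidy an evaluation: one row per video
#'
#' @param x A `pullback_evaluation`.
#' @param ... Unused.
#' @return Tibble with per-video frame counts, switch counts and accuracies.
#' @export
tidy.pullback_evaluation <- function(x, ...) x$per_video

#' One-row summary of an evaluation
#'
#' @param x A `pullback_evaluation`.
#' @param ... Unused.
#' @return Tibble with `n_patients`, `n_videos`, `mean_label_accuracy`,
#'   `mean_switches`, `sd_switches`.
#' @export
glance.pullback_evaluation <- function(x, ...) {
  tibble::tibble(n_patients = nrow(x$per_patient),
                 n_videos = nrow(x$per_video),
                 mean_label_accuracy = x$mean_label_accuracy,
                 mean_switches = x$mean_switches,
                 sd_switches = sd(x$per_video$switches))
}
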