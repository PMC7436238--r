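# On-disk dataset dialect: one directory per video containing zero-padded
# PNG frames (frame_000000.png, ...) and a shared labels.csv at the root
# with columns patient_id,video_id,frame_index,label,informative.

labels_csv_cols <- readr::cols(
  patient_id = readr::col_character(),
  video_id = readr::col_character(),
  frame_index = readr::col_integer(),
  label = readr::col_character(),
  informative = readr::col_integer())

#' Write a cohort to a frame-directory dataset
#'
#' @param cohort A `pullback_cohort` (or list of `pullback_video`).
#' @param root Output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(cohort, root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  labels <- cohort_frames(cohort)
  labels$label <- as.character(labels$label)
  labels$informative <- as.integer(labels$informative)
  readr::write_csv(labels, file.path(root, "labels.csv"))
  for (v in cohort) {
    vdir <- file.path(root, v$video_id)
    dir.create(vdir, showWarnings = FALSE)
    for (i in seq_len(nrow(v$frames))) {
      png::writePNG(v$images[, , , i],
                    file.path(vdir, sprintf("frame_%06d.png",
                                            v$frames$frame_index[i])))
    }
  }
  invisible(root)
}

#' Load a frame-directory dataset
#'
#' Reads `labels.csv`, validates every label against the five-class
#' alphabet (reporting the offending row on failure), loads each referenced
#' PNG frame (reporting the missing file on failure) and assembles the
#' videos with frames sorted by `frame_index`.
#'
#' @param root Dataset directory containing `labels.csv`.
#' @return A `pullback_cohort`.
#' @export
load_dataset <- function(root) {
  csv <- file.path(root, "labels.csv")
  if (!file.exists(csv))
    stop("no labels.csv found in ", root)
  labels <- readr::read_csv(csv, col_types = labels_csv_cols)
  if (nrow(labels) == 0L) stop("labels.csv is empty: ", csv)
  bad <- which(!labels$label %in% tissue_classes())
  if (length(bad) > 0L)
    stop("unknown label \"", labels$label[bad[1]], "\" in labels.csv row ",
         bad[1] + 1L, " (counting the header)")
  if (anyDuplicated(labels[c("video_id", "frame_index")]) > 0L)
    stop("duplicate (video_id, frame_index) rows in labels.csv")

  videos <- lapply(split(labels, labels$video_id), function(fr) {
    fr <- dplyr::arrange(fr, .data$frame_index)
    paths <- file.path(root, fr$video_id[1],
                       sprintf("frame_%06d.png", fr$frame_index))
    missing <- !file.exists(paths)
    if (any(missing))
      stop("missing frame file: ", paths[which(missing)[1]])
    imgs <- lapply(paths, png::readPNG)
    d <- dim(imgs[[1]])
    images <- array(0, c(d[1], d[2], 3, length(imgs)))
    for (i in seq_along(imgs)) {
      im <- imgs[[i]]
      if (length(dim(im)) == 2L) im <- array(rep(im, 3), c(dim(im), 3))
      images[, , , i] <- im[, , 1:3]
    }
    structure(list(images = images,
                   frames = tibble::tibble(
                     patient_id = fr$patient_id,
                     video_id = fr$video_id,
                     frame_index = fr$frame_index,
                     label = tissue_factor(fr$label),
                     informative = fr$informative == 1L),
                   patient_id = fr$patient_id[1],
                   video_id = fr$video_id[1]),
              class = "pullback_video")
  })
  videos <- videos[order(vapply(videos, function(v) v$video_id, character(1)))]
  structure(unname(videos), class = "pullback_cohort")
}

#' Manifest of an on-disk dataset
#'
#' @param root Dataset directory.
#' @return A list with `root`, a per-video tibble (`patient_id`,
#'   `video_id`, `n_frames`, one count column per class), and the MD5
#'   checksum of `labels.csv`.
#' @export
dataset_manifest <- function(root) {
  csv <- file.path(root, "labels.csv")
  if (!file.exists(csv)) stop("no labels.csv found in ", root)
  labels <- readr::read_csv(csv, col_types = labels_csv_cols)
  per_video <- labels |>
    dplyr::count(.data$patient_id, .data$video_id,
                 label = factor(.data$label, tissue_classes())) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(n_frames = rowSums(dplyr::pick(dplyr::any_of(tissue_classes()))))
  for (v in seq_len(nrow(per_video))) {
    vid <- per_video$video_id[v]
    fr <- labels$frame_index[labels$video_id == vid]
    paths <- file.path(root, vid, sprintf("frame_%06d.png", fr))
    missing <- !file.exists(paths)
    if (any(missing)) stop("missing frame file: ", paths[which(missing)[1]])
  }
  list(root = root, videos = per_video,
       labels_md5 = unname(tools::md5sum(csv)))
}
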