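#' Patient-level fold assignment
#'
#' Seeded random partition of patients into `k` folds whose sizes differ by
#' at most one. Fold membership is by patient, so every video (and frame) of
#' a patient travels together and no patient can appear on both sides of a
#' train/test split.
#'
#' @param patient_ids Character vector (duplicates collapse to one patient).
#' @param k Number of folds (>= 2, <= number of patients).
#' @param seed RNG seed.
#' @return Tibble `patient_id`, `fold` (0-based fold index).
#' @export
make_folds <- function(patient_ids, k, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  if (k > length(ids)) stop("more folds than patients")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  shuffled <- sample(ids)
  tibble::tibble(patient_id = shuffled,
                 fold = rep_len(0:(k - 1L), length(ids))) |>
    dplyr::arrange(.data$patient_id)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on matched per-patient accuracy differences. Zero
#' differences are dropped; tied absolute differences are mid-ranked. The
#' reported statistic is the signed rank sum
#' `W = sum(sign(d) * rank(|d|))`, so swapping the two conditions flips its
#' sign and leaves the p-value unchanged. The p-value uses the exact
#' distribution for up to 25 non-zero differences without ties, and the
#' normal approximation with continuity correction otherwise.
#'
#' @param acc_a,acc_b Paired numeric vectors (same patients, same order).
#' @return Tibble: `statistic` (signed W), `p_value`, `n_effective`
#'   (non-zero differences), `method`, `degenerate` (`TRUE` when all
#'   differences are zero, in which case `p_value` is `NA`).
#' @export
wilcoxon_signed_rank <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b))
  d <- acc_a - acc_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble::tibble(statistic = 0, p_value = NA_real_,
                          n_effective = 0L, method = "degenerate",
                          degenerate = TRUE))
  }
  if (n < 6L)
    warning("fewer than 6 non-zero differences; the test has little power")
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  tibble::tibble(statistic = W, p_value = p, n_effective = n,
                 method = if (exact) "exact" else "normal approximation",
                 degenerate = FALSE)
}

derive_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Patient-level k-fold cross-validated head comparison
#'
#' For each fold, trains every requested head on the out-of-fold patients
#' and stream-predicts each in-fold video (recurrent state carried across
#' the whole video). The `fc_avg` head is the trained `fc` network with the
#' causal averaging filter applied to its output, so when both are requested
#' they share one training run per fold. After all folds, every patient has
#' been predicted exactly once and the evaluation metrics are aggregated per
#' patient; heads are compared pairwise with the Wilcoxon signed-rank test
#' on per-patient accuracies.
#'
#' @param cohort A `pullback_cohort` spanning at least `k` patients.
#' @param heads Character vector from `c("fc", "fc_avg", "lstm", "gru")`.
#' @param k Number of folds.
#' @param seed Master seed (folds, weight init, sampling).
#' @param widths,hidden_size,avg_window Model hyperparameters passed to
#'   [model_spec()]; the image size is taken from the cohort.
#' @param train_cfg A [train_config()]; its `seed` is re-derived per fold
#'   and head so replicate runs differ only through `seed`.
#' @param map Correspondence map for the accuracy metrics.
#' @return A `pullback_cv` object: per-head evaluations, summary table,
#'   pairwise Wilcoxon results, predictions, and the fold assignment. See
#'   [tidy.pullback_cv()].
#' @export
run_cross_validation <- function(cohort,
                                 heads = c("fc", "fc_avg", "lstm", "gru"),
                                 k = 5L, seed = 1L,
                                 widths = c(16L, 32L, 64L, 128L),
                                 hidden_size = 128L,
                                 avg_window = 5L,
                                 train_cfg = train_config(),
                                 map = correspondence_map()) {
  heads <- match.arg(heads, several.ok = TRUE)
  truth <- cohort_frames(cohort)
  pids <- unique(truth$patient_id)
  if (length(pids) < k) stop("dataset spans fewer than k patients")
  image_size <- dim(cohort[[1]]$images)[1]
  folds <- make_folds(pids, k, seed = seed)

  base_heads <- unique(ifelse(heads == "fc_avg", "fc", heads))
  seeds <- matrix(derive_seeds(seed, k * length(base_heads)),
                  nrow = k, dimnames = list(NULL, base_heads))

  preds <- setNames(vector("list", length(heads)), heads)
  for (f in 0:(k - 1L)) {
    test_ids <- folds$patient_id[folds$fold == f]
    in_test <- vapply(cohort, function(v) v$patient_id %in% test_ids,
                      logical(1))
    train_set <- cohort[!in_test]
    test_set <- cohort[in_test]
    for (h in base_heads) {
      spec <- model_spec(h, image_size = image_size, widths = widths,
                         hidden_size = hidden_size, avg_window = avg_window)
      run_seed <- seeds[f + 1L, h]
      model <- build_model(spec, seed = run_seed)
      cfg <- train_cfg
      cfg$seed <- run_seed
      model <- tryCatch(
        train_model(model, train_set, cfg),
        error = function(e) stop("fold ", f, ", head ", h, ": ",
                                 conditionMessage(e), call. = FALSE))
      serve <- intersect(heads, if (h == "fc") c("fc", "fc_avg") else h)
      for (hh in serve) {
        m <- model
        m$spec$head_kind <- hh
        fold_preds <- dplyr::bind_rows(lapply(test_set, function(v)
          predict_video(m, v)))
        fold_preds$fold <- f
        preds[[hh]] <- dplyr::bind_rows(preds[[hh]], fold_preds)
      }
    }
  }

  evals <- lapply(preds, function(p)
    evaluate_predictions(dplyr::select(p, "patient_id", "video_id",
                                       "frame_index", "label"),
                         truth, map = map))
  summary <- dplyr::bind_rows(lapply(heads, function(h) {
    ev <- evals[[h]]
    tibble::tibble(head = h,
                   mean_label_accuracy = ev$mean_label_accuracy,
                   mean_switches = ev$mean_switches,
                   sd_switches = sd(ev$per_video$switches))
  }))
  pairs <- if (length(heads) > 1L) utils::combn(heads, 2, simplify = FALSE)
  wilcoxon <- dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- evals[[pr[1]]]$per_patient
    b <- evals[[pr[2]]]$per_patient
    ab <- dplyr::inner_join(a, b, by = "patient_id",
                            suffix = c("_a", "_b"))
    res <- wilcoxon_signed_rank(ab$accuracy_a, ab$accuracy_b)
    dplyr::bind_cols(tibble::tibble(head_a = pr[1], head_b = pr[2]), res)
  }))

  structure(list(evaluations = evals, summary = summary,
                 wilcoxon = wilcoxon, predictions = preds,
                 folds = folds, k = k, seed = seed,
                 heads = heads),
            class = "pullback_cv")
}

#' @export
print.pullback_cv <- function(x, ...) {
  cat("<pullback_cv>", x$k, "folds,", nrow(x$folds), "patients, heads:",
      paste(x$heads, collapse = ", "), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s accuracy %.1f%%  switches %.2f (sd %.2f)\n",
                s$head[i], 100 * s$mean_label_accuracy[i],
                s$mean_switches[i], s$sd_switches[i]))
  invisible(x)
}

#' Tidy a cross-validation report: one row per head
#'
#' @param x A `pullback_cv`.
#' @param ... Unused.
#' @return The per-head summary tibble (`head`, `mean_label_accuracy`,
#'   `mean_switches`, `sd_switches`).
#' @export
tidy.pullback_cv <- function(x, ...) x$summary

#' One-row summary of a cross-validation run
#'
#' @param x A `pullback_cv`.
#' @param ... Unused.
#' @return Tibble with fold/patient counts and the best head by accuracy.
#' @export
glance.pullback_cv <- function(x, ...) {
  tibble::tibble(k = x$k,
                 n_patients = nrow(x$folds),
                 n_heads = length(x$heads),
                 best_head = x$summary$head[which.max(
                   x$summary$mean_label_accuracy)],
                 seed = x$seed)
}

#' Per-class accuracy table of a cross-validation run
#'
#' One row per tissue class (plus `Overall`), one column per head, values in
#' percent: the patient-averaged mapped accuracy restricted to frames of
#' that true class.
#'
#' @param cv A `pullback_cv`.
#' @return Tibble in wide layout.
#' @export
cv_class_table <- function(cv) {
  stopifnot(inherits(cv, "pullback_cv"))
  rows <- lapply(cv$heads, function(h) {
    ev <- cv$evaluations[[h]]
    pc <- setNames(ev$per_class$accuracy, as.character(ev$per_class$truth))
    tibble::tibble(head = h,
                   label = c(tissue_classes(), "Overall"),
                   accuracy = 100 * c(pc[tissue_classes()],
                                      ev$mean_label_accuracy))
  })
  dplyr::bind_rows(rows) |>
    tidyr::pivot_wider(names_from = "head", values_from = "accuracy")
}
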