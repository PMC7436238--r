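#' Desk-scale configuration of the head-comparison experiment
#'
#' The packaged study conditions for comparing the four heads on synthetic
#' pullbacks: a cohort of 12 patients with 96-frame videos at 16x16 px,
#' heavy label-region ambiguity (transition blending over 12 frames on each
#' side of a boundary, pixel noise sd 0.15, 12% non-informative frames), a
#' reduced extractor (widths 8/16/16/32) with the full 2x128 recurrent
#' stack, and 120 Adam iterations of 8 sequences at a cyclic cosine schedule
#' (period 60, peak 1e-3). These sizes keep a full 5-fold, 4-head,
#' 3-replicate comparison within minutes on one CPU while preserving the
#' structure of the clinical task; the methods vignette discusses the
#' choices.
#'
#' @return List with `synth` (a [synthetic_config()]), `n_patients`,
#'   `widths`, `hidden_size`, `train` (a [train_config()]) and `k`.
#' @export
desk_scale_config <- function() {
  list(synth = synthetic_config(image_size = 16L,
                                frames_per_video = 96L,
                                transition_width = 12,
                                noise_sd = 0.15,
                                noninformative_rate = 0.12),
       n_patients = 12L,
       widths = c(8L, 16L, 16L, 32L),
       hidden_size = 128L,
       train = train_config(batch_sequences = 8L,
                            base_lr = 1e-3,
                            scheduler_period = 60L,
                            total_iterations = 120L),
       k = 5L)
}

#' Replicated cross-validated comparison of the four heads
#'
#' Runs [run_cross_validation()] on `n_replicates` independently generated
#' synthetic cohorts (fresh cohort, folds, initialization and sampling per
#' replicate, all derived from `seed`) and aggregates: per-head mean label
#' accuracy and mean/sd of per-video switch counts across replicates, and
#' pairwise Wilcoxon signed-rank tests on the pooled per-patient accuracies.
#'
#' @param seed Master seed.
#' @param n_replicates Number of replicate cohorts.
#' @param heads Heads to compare.
#' @param config Study conditions, see [desk_scale_config()].
#' @param progress Print a line per replicate.
#' @return A `head_comparison` object: `aggregate` (per-head tibble),
#'   `per_replicate` (per seed x head), `per_video` (pooled switch counts),
#'   `wilcoxon` (pooled pairwise tests), `replicates` (the `pullback_cv`
#'   objects).
#' @export
run_head_comparison <- function(seed = 1L, n_replicates = 3L,
                                heads = c("fc", "fc_avg", "lstm", "gru"),
                                config = desk_scale_config(),
                                progress = FALSE) {
  rep_seeds <- derive_seeds(seed, n_replicates)
  cvs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cohort <- generate_cohort(config$synth, config$n_patients,
                              seed = rep_seeds[r])
    cvs[[r]] <- run_cross_validation(cohort, heads = heads, k = config$k,
                                     seed = rep_seeds[r],
                                     widths = config$widths,
                                     hidden_size = config$hidden_size,
                                     train_cfg = config$train)
    if (progress)
      message(sprintf("replicate %d/%d done", r, n_replicates))
  }
  per_replicate <- dplyr::bind_rows(lapply(seq_len(n_replicates), function(r)
    dplyr::mutate(cvs[[r]]$summary, replicate = r, .before = 1)))
  per_video <- dplyr::bind_rows(lapply(seq_len(n_replicates), function(r)
    dplyr::bind_rows(lapply(heads, function(h)
      dplyr::mutate(cvs[[r]]$evaluations[[h]]$per_video,
                    head = h, replicate = r)))))
  aggregate <- per_video |>
    dplyr::group_by(head = factor(.data$head, heads)) |>
    dplyr::summarise(mean_switches = mean(.data$switches),
                     sd_switches = sd(.data$switches), .groups = "drop") |>
    dplyr::left_join(
      per_replicate |>
        dplyr::group_by(head = factor(.data$head, heads)) |>
        dplyr::summarise(mean_label_accuracy =
                           mean(.data$mean_label_accuracy),
                         .groups = "drop"),
      by = "head") |>
    dplyr::mutate(head = as.character(.data$head))
  # pooled per-patient accuracies (replicates are distinct cohorts)
  pooled <- lapply(heads, function(h)
    unlist(lapply(seq_len(n_replicates), function(r)
      cvs[[r]]$evaluations[[h]]$per_patient$accuracy)))
  names(pooled) <- heads
  pairs <- if (length(heads) > 1L) utils::combn(heads, 2, simplify = FALSE)
  wilcoxon <- dplyr::bind_rows(lapply(pairs, function(pr)
    dplyr::bind_cols(tibble::tibble(head_a = pr[1], head_b = pr[2]),
                     wilcoxon_signed_rank(pooled[[pr[1]]], pooled[[pr[2]]]))))
  structure(list(aggregate = aggregate, per_replicate = per_replicate,
                 per_video = per_video, wilcoxon = wilcoxon,
                 replicates = cvs, heads = heads, seed = seed),
            class = "head_comparison")
}

#' @export
print.head_comparison <- function(x, ...) {
  cat("<head_comparison>", length(x$replicates), "replicates, heads:",
      paste(x$heads, collapse = ", "), "\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-6s accuracy %.1f%%  switches %.2f (sd %.2f)\n",
                a$head[i], 100 * a$mean_label_accuracy[i],
                a$mean_switches[i], a$sd_switches[i]))
  invisible(x)
}

#' Tidy a head comparison: one row per head
#' @param x A `head_comparison`.
#' @param ... Unused.
#' @return The aggregate per-head tibble.
#' @export
tidy.head_comparison <- function(x, ...) x$aggregate
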