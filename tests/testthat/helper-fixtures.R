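# Shared fixtures, built in code.

# a hand-built video with exact label runs and informative flags, images
# filled with a constant (sampler/metric tests do not look at pixels)
make_video <- function(patient_id, runs, informative = NULL,
                       video_id = paste0(patient_id, "_v1"), size = 8L) {
  labels <- rep(tissue_classes()[seq_along(runs)], runs)
  n <- length(labels)
  if (is.null(informative)) informative <- rep(TRUE, n)
  structure(list(
    images = array(0.5, c(size, size, 3, n)),
    frames = tibble::tibble(patient_id = patient_id, video_id = video_id,
                            frame_index = 0:(n - 1L),
                            label = tissue_factor(labels),
                            informative = informative),
    patient_id = patient_id, video_id = video_id),
    class = "pullback_video")
}

# tiny separable cohort for fast end-to-end training tests
separable_cohort <- function(n_patients = 5, frames = 60, seed = 11) {
  cfg <- synthetic_config(image_size = 16L, frames_per_video = frames,
                          transition_width = 0, noise_sd = 0,
                          noninformative_rate = 0, seed = seed)
  generate_cohort(cfg, n_patients)
}

tiny_spec <- function(kind, hidden = 32L) {
  model_spec(kind, image_size = 16L, widths = c(4L, 8L, 8L, 16L),
             hidden_size = hidden)
}

# one-hot probability track from a label string vector
onehot_track <- function(labels) {
  P <- matrix(0, length(labels), 5,
              dimnames = list(NULL, tissue_classes()))
  P[cbind(seq_along(labels), match(labels, tissue_classes()))] <- 1
  dplyr::bind_cols(tibble::tibble(frame_index = seq_along(labels) - 1L),
                   tibble::as_tibble(P))
}
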