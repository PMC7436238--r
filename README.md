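# pullbacknet

Frame-by-frame tissue classification for esophageal **pullback videos**,
with an emphasis on *temporal stability*. During a pullback the endoscope
is withdrawn from the stomach to the healthy squamous esophagus, so five
tissue classes appear in a fixed anatomical order — stomach (`St`),
transition Z-line (`Tz`), Barrett (`B`), transition squamous (`Ts`),
squamous (`Sq`). A reliable tissue gate lets a Barrett-neoplasia detector
fire only inside the Barrett segment. Classifying frames independently
makes that gate flicker: blurred, bubbly or over-exposed frames and the
gradual transitions between adjacent tissues destabilize single-frame
decisions.

The package implements one convolutional feature extractor (four residual
blocks, global average pooling) with four interchangeable classifier heads,
and asks which use of time is most stable and most accurate:

| head     | temporal mechanism                                   |
|----------|------------------------------------------------------|
| `fc`     | none — two FC layers, frame-independent              |
| `fc_avg` | causal moving average over the last 5 output rows    |
| `lstm`   | two LSTM layers (hidden 128), state streamed         |
| `gru`    | two GRU layers (hidden 128), state streamed          |

Two bespoke metrics score the heads. **Label accuracy** uses a
correspondence map that absorbs transition-zone ambiguity — a prediction is
a true positive when the annotated label lies in its acceptable set
(`St→{St}`, `Tz→{Tz,B}`, `B→{Tz,B,Ts}`, `Ts→{B,Ts}`, `Sq→{Sq}`); per-video
accuracy is `LabelAcc = (1/Nv) Σ TPj`, and the headline number averages
per-patient accuracies, `(1/Np) Σ Acc(Li)`, to normalize for video length.
**Stability** counts label switches per video — one switch per adjacent
frame pair with differing predictions; an ideal pullback prediction scores
exactly 4.

Since clinical pullback recordings are private, the package ships a
synthetic generator that reproduces the statistical structure of the task
(fixed class order, Barrett-dominant class mix, pixel-level blending at
transitions with crisp labels, noise, sporadic non-informative frames) so
the whole pipeline — balanced sequence sampling, per-sequence-constant
affine augmentation, Adam with a cyclic cosine schedule, patient-level
5-fold cross-validation, paired Wilcoxon comparison — runs end to end on a
desk.

## Worked example

```r
library(pullbacknet)

cfg    <- synthetic_config(image_size = 16, frames_per_video = 96,
                           transition_width = 12, noise_sd = 0.15,
                           noninformative_rate = 0.12)
cohort <- generate_cohort(cfg, n_patients = 12, seed = 1)

cv <- run_cross_validation(
  cohort, heads = c("fc", "fc_avg", "lstm", "gru"), k = 5, seed = 1,
  widths = c(8, 16, 16, 32),
  train_cfg = train_config(batch_sequences = 8, base_lr = 1e-3,
                           scheduler_period = 60, total_iterations = 120))
cv
```

```
<pullback_cv> 5 folds, 12 patients, heads: fc, fc_avg, lstm, gru
  fc     accuracy 87.9%  switches 16.67 (sd 4.33)
  fc_avg accuracy 90.1%  switches 4.50 (sd 1.51)
  lstm   accuracy 90.3%  switches 2.83 (sd 0.39)
  gru    accuracy 89.4%  switches 4.42 (sd 1.56)
```

Reading the output: `accuracy` is the patient-averaged, correspondence-
mapped label accuracy (1.0 would mean every informative frame acceptable);
`switches` is the mean number of predicted-label changes per 96-frame video
(the anatomical ideal is 4, one switch per tissue boundary). The
frame-independent `fc` head flickers four times above the ideal; every
temporal mechanism — causal averaging or recurrence — collapses that
instability to near the ideal while matching or beating `fc`'s accuracy,
with the LSTM the most stable head here. `autoplot(cv)` draws the summary;
`plot_label_tracks()` draws per-video label strips;
`autoplot(cv$evaluations$lstm)` draws the per-patient-normalized confusion
matrix.

A command-line interface covers the same pipeline
(`inst/cli/pullbacknet simulate | train | evaluate | experiment`).

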