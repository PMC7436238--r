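test_that("feature extraction is shape-correct, stateless and finite", {
  spec <- tiny_spec("fc")
  m <- build_model(spec, seed = 1)
  set.seed(2)
  imgs <- array(runif(16 * 16 * 3 * 10), c(16, 16, 3, 10))
  F1 <- extract_features(m, imgs)
  expect_equal(dim(F1), c(10, spec$feature_dim))
  expect_true(all(is.finite(F1)))
  # same frame in two different batches -> identical features
  F2 <- extract_features(m, imgs[, , , c(3, 1, 7)])
  expect_equal(F2[2, ], F1[1, ])
  # all-zero image stays finite
  expect_true(all(is.finite(extract_features(m, array(0, c(16, 16, 3))))))
  expect_error(extract_features(m, array(0, c(8, 8, 3))), "does not match")
})

test_that("backpropagated gradients match finite differences", {
  # numeric oracle: central differences through the full loss
  for (kind in c("fc", "lstm", "gru")) {
    spec <- model_spec(kind, image_size = 8L, widths = c(2L, 3L, 3L, 4L),
                       hidden_size = 5L)
    m <- build_model(spec, seed = 4)
    set.seed(9)
    L <- if (kind == "fc") 1L else 4L
    B <- 2L
    x <- array(runif(3 * 8 * 8 * L * B), c(3, 8, 8, L * B))
    targets <- c(2L, 5L)
    lossfun <- function(params) {
      ext <- pullbacknet:::extractor_fwd(params, x, keep_cache = TRUE)
      if (kind == "fc") {
        hf <- pullbacknet:::fc_head_fwd(params, ext$features)
        pullbacknet:::softmax_xent(hf$logits, targets)$loss
      } else {
        X <- array(ext$features, c(spec$feature_dim, L, B))
        rf <- pullbacknet:::rnn_fwd(params, spec, X,
                                    pullbacknet:::zero_state(spec, B))
        last <- matrix(rf$logits[, L, ], spec$n_classes, B)
        pullbacknet:::softmax_xent(last, targets)$loss
      }
    }
    ext <- pullbacknet:::extractor_fwd(m$params, x, keep_cache = TRUE)
    if (kind == "fc") {
      hf <- pullbacknet:::fc_head_fwd(m$params, ext$features)
      ce <- pullbacknet:::softmax_xent(hf$logits, targets)
      hb <- pullbacknet:::fc_head_bwd(hf$cache, ce$dlogits)
      grads <- c(hb$grads, pullbacknet:::extractor_bwd(ext$cache, hb$dX))
    } else {
      X <- array(ext$features, c(spec$feature_dim, L, B))
      rf <- pullbacknet:::rnn_fwd(m$params, spec, X,
                                  pullbacknet:::zero_state(spec, B))
      last <- matrix(rf$logits[, L, ], spec$n_classes, B)
      ce <- pullbacknet:::softmax_xent(last, targets)
      dlog <- array(0, dim(rf$logits))
      dlog[, L, ] <- ce$dlogits
      rb <- pullbacknet:::rnn_bwd(m$params, spec, rf$cache, dlog)
      dfeat <- matrix(rb$dX, spec$feature_dim, L * B)
      grads <- c(rb$grads, pullbacknet:::extractor_bwd(ext$cache, dfeat))
    }
    eps <- 1e-6
    rel <- c()
    set.seed(13)
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (j in sample(length(p), min(3, length(p)))) {
        pp <- m$params; pp[[nm]][j] <- pp[[nm]][j] + eps
        pm <- m$params; pm[[nm]][j] <- pm[[nm]][j] - eps
        num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
        rel <- c(rel, abs(num - grads[[nm]][j]) /
                   max(1e-8, abs(num) + abs(grads[[nm]][j])))
      }
    }
    # ReLU kinks can spoil individual finite differences; the bulk must agree
    expect_lt(median(rel), 1e-6)
    expect_lt(mean(rel > 1e-4), 0.1)
  }
})

test_that("every head emits probability rows that sum to one", {
  set.seed(5)
  for (kind in c("fc", "fc_avg", "lstm", "gru")) {
    m <- build_model(tiny_spec(kind), seed = 2)
    feats <- matrix(rnorm(12 * m$spec$feature_dim), 12)
    res <- head_forward(m, feats)
    P <- pullbacknet:::track_matrix(res$track)
    expect_equal(rowSums(P), rep(1, 12), tolerance = 1e-6)
    expect_true(all(P >= 0))
  }
})

test_that("the FC head is frame-independent: permuting rows permutes output", {
  m <- build_model(tiny_spec("fc"), seed = 3)
  set.seed(6)
  feats <- matrix(rnorm(8 * m$spec$feature_dim), 8)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  P <- pullbacknet:::track_matrix(head_forward(m, feats)$track)
  Pp <- pullbacknet:::track_matrix(head_forward(m, feats[perm, ])$track)
  expect_equal(Pp, P[perm, ], tolerance = 1e-12)
})

test_that("recurrent heads stream: chunked forward equals whole forward", {
  set.seed(7)
  for (kind in c("lstm", "gru")) {
    m <- build_model(tiny_spec(kind), seed = 5)
    feats <- matrix(rnorm(10 * m$spec$feature_dim), 10)
    whole <- head_forward(m, feats)
    first <- head_forward(m, feats[1:5, ])
    second <- head_forward(m, feats[6:10, ], state = first$state)
    P_whole <- pullbacknet:::track_matrix(whole$track)
    P_chunk <- rbind(pullbacknet:::track_matrix(first$track),
                     pullbacknet:::track_matrix(second$track))
    expect_equal(P_chunk, P_whole, tolerance = 1e-5)
    # mismatched state shape is rejected
    bad <- pullbacknet:::zero_state(m$spec, 2L)
    expect_error(head_forward(m, feats, state = bad), "state")
  }
})

test_that("causal averaging is causal, simplex-preserving, identity at n=1", {
  tr <- onehot_track(c("St", "Tz", "B", "Ts", "Sq", "B", "B"))
  expect_equal(causal_average(tr, 1), tr)
  sm <- causal_average(tr, 3)
  P <- pullbacknet:::track_matrix(sm)
  expect_equal(rowSums(P), rep(1, 7), tolerance = 1e-12)
  # hand-computed causal window: row 3 = mean of rows 1..3
  expect_equal(unname(P[3, ]), c(1, 1, 1, 0, 0) / 3)
  # constant track is unchanged
  const <- onehot_track(rep("B", 6))
  expect_equal(causal_average(const, 4), const)
  expect_error(causal_average(onehot_track(character(0)), 3), "empty")
})

test_that("a single flipped frame is absorbed by n=5 averaging", {
  tr <- onehot_track(c(rep("St", 5), "Tz", rep("St", 4)))
  dec <- decode_labels(causal_average(tr, 5))
  expect_true(all(dec$label == "St"))  # max Tz mass in any window is 1/5
  expect_equal(count_label_switches(dec), 0)
})

test_that("label decoding breaks ties toward the earlier anatomical class", {
  tr <- onehot_track(c("B"))
  expect_equal(as.character(decode_labels(tr)$label), "B")
  tie <- tr
  tie[1, tissue_classes()] <- as.list(rep(0.2, 5))
  expect_equal(as.character(decode_labels(tie)$label), "St")
  two <- dplyr::bind_rows(tr, tie)
  two$frame_index <- 0:1
  expect_equal(as.character(decode_labels(two)$label), c("B", "St"))
})

test_that("fc_avg with window 1 decodes exactly like fc (same weights)", {
  m <- build_model(tiny_spec("fc"), seed = 8)
  set.seed(10)
  feats <- matrix(rnorm(15 * m$spec$feature_dim), 15)
  fc_track <- decode_labels(head_forward(m, feats)$track)
  m$spec$head_kind <- "fc_avg"
  m$spec$avg_window <- 1L
  avg_track <- decode_labels(head_forward(m, feats)$track)
  expect_identical(avg_track, fc_track)
})

test_that("parameter counts match the architecture's closed form", {
  conv_n <- function(cout, cin, k) cout * cin * k * k + cout
  widths <- c(16L, 32L, 64L, 128L)
  ext <- conv_n(16, 3, 3) +
    2 * conv_n(16, 16, 3) +                                  # block 1
    conv_n(32, 16, 3) + conv_n(32, 32, 3) + conv_n(32, 16, 1) +
    conv_n(64, 32, 3) + conv_n(64, 64, 3) + conv_n(64, 32, 1) +
    conv_n(128, 64, 3) + conv_n(128, 128, 3) + conv_n(128, 64, 1)
  D <- 128; H <- 128; K <- 5
  fc <- (H * D + H) + (K * H + K)
  lstm <- (4 * H * (D + H) + 4 * H) + (4 * H * (H + H) + 4 * H) + (K * H + K)
  gru <- (3 * H * (D + H) + 6 * H) + (3 * H * (H + H) + 6 * H) + (K * H + K)
  expect_equal(n_parameters(build_model(model_spec("fc"), 1)), ext + fc)
  expect_equal(n_parameters(build_model(model_spec("lstm"), 1)), ext + lstm)
  expect_equal(n_parameters(build_model(model_spec("gru"), 1)), ext + gru)
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_spec("gru"), seed = 12)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$spec, m$spec)
  saveRDS(list(1), path)
  expect_error(load_checkpoint(path), "not a pullback_model")
  unlink(path)
})
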