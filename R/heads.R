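# Classifier heads on top of the extractor features. All heads emit one
# softmax probability row per frame. The recurrent heads (two stacked LSTM or
# GRU layers, then a fully connected layer) carry hidden state so a whole
# pullback can be processed as a stream; the FC heads are frame-independent.

init_head_params <- function(spec) {
  D <- spec$feature_dim
  H <- spec$hidden_size
  K <- spec$n_classes
  p <- list()
  if (spec$head_kind %in% c("fc", "fc_avg")) {
    p[["fc1.W"]] <- init_linear(H, D)
    p[["fc1.b"]] <- numeric(H)
    p[["fc2.W"]] <- init_linear(K, H)
    p[["fc2.b"]] <- numeric(K)
    return(p)
  }
  din <- D
  for (l in seq_len(spec$recurrent_layers)) {
    pre <- sprintf("rnn%d.", l)
    if (spec$head_kind == "lstm") {
      p[[paste0(pre, "Wi")]] <- init_recurrent(4L * H, din, H)
      p[[paste0(pre, "Wh")]] <- init_recurrent(4L * H, H, H)
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      p[[paste0(pre, "b")]] <- b
    } else {
      p[[paste0(pre, "Wi")]] <- init_recurrent(3L * H, din, H)
      p[[paste0(pre, "Wh")]] <- init_recurrent(3L * H, H, H)
      p[[paste0(pre, "bi")]] <- numeric(3L * H)
      p[[paste0(pre, "bh")]] <- numeric(3L * H)
    }
    din <- H
  }
  p[["out.W"]] <- init_linear(K, H)
  p[["out.b"]] <- numeric(K)
  p
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# fresh all-zero recurrent state for a stream of B parallel sequences
zero_state <- function(spec, batch = 1L) {
  if (!spec$head_kind %in% c("lstm", "gru")) return(NULL)
  H <- spec$hidden_size
  lapply(seq_len(spec$recurrent_layers), function(l) {
    s <- list(h = matrix(0, H, batch))
    if (spec$head_kind == "lstm") s$c <- matrix(0, H, batch)
    s
  })
}

check_state <- function(spec, state, batch) {
  if (is.null(state)) return(zero_state(spec, batch))
  ok <- is.list(state) && length(state) == spec$recurrent_layers &&
    all(vapply(state, function(s) {
      is.matrix(s$h) && all(dim(s$h) == c(spec$hidden_size, batch)) &&
        (spec$head_kind != "lstm" ||
           (is.matrix(s$c) && all(dim(s$c) == c(spec$hidden_size, batch))))
    }, logical(1)))
  if (!ok) stop("recurrent state does not match the model spec/batch size")
  state
}

# ---- LSTM layer ----------------------------------------------------------
# X: (Din, L, B); returns outputs (H, L, B), final state, cache for BPTT

lstm_layer_fwd <- function(Wi, Wh, b, X, h0, c0) {
  d <- dim(X); L <- d[2]; B <- d[3]
  H <- nrow(Wh) / 4L
  out <- array(0, c(H, L, B))
  h <- h0; cc <- c0
  steps <- vector("list", L)
  ih <- 1:H; fh <- (H + 1L):(2L * H); gh <- (2L * H + 1L):(3L * H)
  oh <- (3L * H + 1L):(4L * H)
  for (t in seq_len(L)) {
    x <- matrix(X[, t, ], d[1], B)
    z <- Wi %*% x + Wh %*% h + b
    i <- sigmoid(z[ih, , drop = FALSE]); f <- sigmoid(z[fh, , drop = FALSE])
    g <- tanh(z[gh, , drop = FALSE]);    o <- sigmoid(z[oh, , drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    steps[[t]] <- list(x = x, h_prev = h, c_prev = cc,
                       i = i, f = f, g = g, o = o, tc = tc)
    h <- h_new; cc <- c_new
    out[, t, ] <- h
  }
  list(out = out, h = h, c = cc, cache = steps)
}

lstm_layer_bwd <- function(Wi, Wh, cache, dout) {
  L <- length(cache); B <- ncol(cache[[1]]$x)
  H <- nrow(Wh) / 4L
  dWi <- Wi * 0; dWh <- Wh * 0; db <- numeric(4L * H)
  dX <- array(0, c(ncol(Wi), L, B))
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  for (t in rev(seq_len(L))) {
    s <- cache[[t]]
    dh <- matrix(dout[, t, ], H, B) + dh_next
    do <- dh * s$tc
    dc <- dc_next + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g; dg <- dc * s$i; df <- dc * s$c_prev
    dc_next <- dc * s$f
    dz <- rbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dWi <- dWi + tcrossprod(dz, s$x)
    dWh <- dWh + tcrossprod(dz, s$h_prev)
    db <- db + rowSums(dz)
    dX[, t, ] <- crossprod(Wi, dz)
    dh_next <- crossprod(Wh, dz)
  }
  list(dX = dX, dWi = dWi, dWh = dWh, db = db)
}

# ---- GRU layer -----------------------------------------------------------

gru_layer_fwd <- function(Wi, Wh, bi, bh, X, h0) {
  d <- dim(X); L <- d[2]; B <- d[3]
  H <- nrow(Wh) / 3L
  out <- array(0, c(H, L, B))
  h <- h0
  steps <- vector("list", L)
  rh <- 1:H; zh <- (H + 1L):(2L * H); nh <- (2L * H + 1L):(3L * H)
  for (t in seq_len(L)) {
    x <- matrix(X[, t, ], d[1], B)
    ai <- Wi %*% x + bi
    ah <- Wh %*% h + bh
    r <- sigmoid(ai[rh, , drop = FALSE] + ah[rh, , drop = FALSE])
    z <- sigmoid(ai[zh, , drop = FALSE] + ah[zh, , drop = FALSE])
    hn <- ah[nh, , drop = FALSE]
    n <- tanh(ai[nh, , drop = FALSE] + r * hn)
    h_new <- (1 - z) * n + z * h
    steps[[t]] <- list(x = x, h_prev = h, r = r, z = z, n = n, hn = hn)
    h <- h_new
    out[, t, ] <- h
  }
  list(out = out, h = h, cache = steps)
}

gru_layer_bwd <- function(Wi, Wh, cache, dout) {
  L <- length(cache); B <- ncol(cache[[1]]$x)
  H <- nrow(Wh) / 3L
  dWi <- Wi * 0; dWh <- Wh * 0
  dbi <- numeric(3L * H); dbh <- numeric(3L * H)
  dX <- array(0, c(ncol(Wi), L, B))
  dh_next <- matrix(0, H, B)
  for (t in rev(seq_len(L))) {
    s <- cache[[t]]
    dh <- matrix(dout[, t, ], H, B) + dh_next
    dn <- dh * (1 - s$z)
    dz <- dh * (s$h_prev - s$n)
    dh_prev <- dh * s$z
    dan_i <- dn * (1 - s$n^2)
    dr <- dan_i * s$hn
    dan_h <- dan_i * s$r
    dar <- dr * s$r * (1 - s$r)
    daz <- dz * s$z * (1 - s$z)
    dai <- rbind(dar, daz, dan_i)
    dah <- rbind(dar, daz, dan_h)
    dWi <- dWi + tcrossprod(dai, s$x)
    dWh <- dWh + tcrossprod(dah, s$h_prev)
    dbi <- dbi + rowSums(dai)
    dbh <- dbh + rowSums(dah)
    dX[, t, ] <- crossprod(Wi, dai)
    dh_next <- dh_prev + crossprod(Wh, dah)
  }
  list(dX = dX, dWi = dWi, dWh = dWh, dbi = dbi, dbh = dbh)
}

# ---- stacked recurrent forward/backward ---------------------------------
# X: (D, L, B); state: list per layer; returns logits for every t

rnn_fwd <- function(params, spec, X, state) {
  caches <- vector("list", spec$recurrent_layers)
  inp <- X
  new_state <- state
  for (l in seq_len(spec$recurrent_layers)) {
    pre <- sprintf("rnn%d.", l)
    if (spec$head_kind == "lstm") {
      res <- lstm_layer_fwd(params[[paste0(pre, "Wi")]],
                            params[[paste0(pre, "Wh")]],
                            params[[paste0(pre, "b")]],
                            inp, state[[l]]$h, state[[l]]$c)
      new_state[[l]] <- list(h = res$h, c = res$c)
    } else {
      res <- gru_layer_fwd(params[[paste0(pre, "Wi")]],
                           params[[paste0(pre, "Wh")]],
                           params[[paste0(pre, "bi")]],
                           params[[paste0(pre, "bh")]],
                           inp, state[[l]]$h)
      new_state[[l]] <- list(h = res$h)
    }
    caches[[l]] <- res$cache
    inp <- res$out
  }
  d <- dim(inp)  # (H, L, B)
  hmat <- matrix(inp, d[1], d[2] * d[3])
  lin <- linear_fwd(hmat, params[["out.W"]], params[["out.b"]])
  logits <- array(lin$out, c(spec$n_classes, d[2], d[3]))
  list(logits = logits, state = new_state,
       cache = list(layers = caches, lin = lin$cache, hdim = d))
}

# dlogits: (K, L, B) -> grads for all rnn + out params and dX (D, L, B)
rnn_bwd <- function(params, spec, cache, dlogits) {
  d <- cache$hdim
  dl <- matrix(dlogits, spec$n_classes, d[2] * d[3])
  lb <- linear_bwd(cache$lin, dl)
  grads <- list("out.W" = lb$dW, "out.b" = lb$db)
  dout <- array(lb$dx, d)
  for (l in rev(seq_len(spec$recurrent_layers))) {
    pre <- sprintf("rnn%d.", l)
    if (spec$head_kind == "lstm") {
      bk <- lstm_layer_bwd(params[[paste0(pre, "Wi")]],
                           params[[paste0(pre, "Wh")]],
                           cache$layers[[l]], dout)
      grads[[paste0(pre, "Wi")]] <- bk$dWi
      grads[[paste0(pre, "Wh")]] <- bk$dWh
      grads[[paste0(pre, "b")]] <- bk$db
    } else {
      bk <- gru_layer_bwd(params[[paste0(pre, "Wi")]],
                          params[[paste0(pre, "Wh")]],
                          cache$layers[[l]], dout)
      grads[[paste0(pre, "Wi")]] <- bk$dWi
      grads[[paste0(pre, "Wh")]] <- bk$dWh
      grads[[paste0(pre, "bi")]] <- bk$dbi
      grads[[paste0(pre, "bh")]] <- bk$dbh
    }
    dout <- bk$dX
  }
  list(grads = grads, dX = dout)
}

# FC head on features (D, N) -> logits (K, N)
fc_head_fwd <- function(params, feats) {
  l1 <- linear_fwd(feats, params[["fc1.W"]], params[["fc1.b"]])
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, params[["fc2.W"]], params[["fc2.b"]])
  list(logits = l2$out, cache = list(l1 = l1$cache, m = r1$cache, l2 = l2$cache))
}

fc_head_bwd <- function(cache, dlogits) {
  b2 <- linear_bwd(cache$l2, dlogits)
  dr <- relu_bwd(cache$m, b2$dx)
  b1 <- linear_bwd(cache$l1, dr)
  list(grads = list("fc2.W" = b2$dW, "fc2.b" = b2$db,
                    "fc1.W" = b1$dW, "fc1.b" = b1$db),
       dX = b1$dx)
}

# ---- public surface ------------------------------------------------------

#' Run a classifier head over an ordered block of feature rows
#'
#' Applies the model's head to pre-extracted features. FC heads treat every
#' row independently (and ignore `state`); recurrent heads consume the rows
#' in order, starting from `state` (`NULL` means a fresh all-zero state) and
#' return the updated state, so a long video can be processed in chunks:
#' feeding 10 rows at once or 5 rows twice with the carried state gives the
#' same probabilities. The `fc_avg` head additionally smooths the emitted
#' probabilities with [causal_average()] over the spec's `avg_window`.
#'
#' @param model A `pullback_model`.
#' @param features Matrix of ordered feature rows (frames x D), as returned
#'   by [extract_features()].
#' @param state Recurrent state from a previous call, or `NULL`.
#' @param frame_index Optional integer vector labelling the rows; defaults to
#'   `0:(n-1)`.
#' @return List with `track` (a probability track tibble: `frame_index` plus
#'   one column per tissue class, each row summing to 1) and `state` (updated
#'   recurrent state, or `NULL` for FC heads).
#' @export
head_forward <- function(model, features, state = NULL, frame_index = NULL) {
  stopifnot(inherits(model, "pullback_model"))
  spec <- model$spec
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != spec$feature_dim)
    stop("features must have D = ", spec$feature_dim, " columns")
  n <- nrow(features)
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  feats <- t(features)  # (D, n)
  if (spec$head_kind %in% c("fc", "fc_avg")) {
    probs <- softmax_cols(fc_head_fwd(model$params, feats)$logits)
    out_state <- NULL
  } else {
    state <- check_state(spec, state, batch = 1L)
    X <- array(feats, c(spec$feature_dim, n, 1L))
    res <- rnn_fwd(model$params, spec, X, state)
    probs <- softmax_cols(matrix(res$logits, spec$n_classes, n))
    out_state <- res$state
  }
  track <- prob_track(t(probs), frame_index)
  if (spec$head_kind == "fc_avg")
    track <- causal_average(track, spec$avg_window)
  list(track = track, state = out_state)
}

# probs: (n x K) matrix -> tidy probability track
prob_track <- function(probs, frame_index) {
  colnames(probs) <- tissue_classes()
  dplyr::bind_cols(tibble::tibble(frame_index = as.integer(frame_index)),
                   tibble::as_tibble(probs))
}

track_matrix <- function(track) {
  as.matrix(track[, tissue_classes()])
}

#' Causal moving average of a class-probability track
#'
#' Row `t` becomes the unweighted mean of rows `max(1, t - n + 1) .. t`: a
#' causal window that only looks at past frames (shorter at the start of the
#' track), so the filter is usable on live video. Averaging rows of a
#' probability simplex stays on the simplex, so each output row still sums
#' to 1.
#'
#' @param track Probability track tibble (`frame_index` + one column per
#'   class).
#' @param n Window length in frames; `n = 1` is the identity.
#' @return Smoothed probability track of the same shape.
#' @export
causal_average <- function(track, n) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  P <- track_matrix(track)
  if (nrow(P) == 0L) stop("empty probability track")
  if (n > 1L) {
    cs <- apply(P, 2, cumsum)
    if (nrow(P) == 1L) cs <- matrix(cs, 1L)
    out <- P
    for (t in seq_len(nrow(P))) {
      lo <- max(0L, t - n)
      out[t, ] <- (cs[t, ] - if (lo > 0L) cs[lo, ] else 0) / (t - lo)
    }
    P <- out
  }
  prob_track(P, track$frame_index)
}

#' Decode hard labels from a probability track
#'
#' Per-row argmax over the five classes; ties are broken toward the earlier
#' class in the anatomical order `St < Tz < B < Ts < Sq`.
#'
#' @param track Probability track tibble.
#' @return Label track tibble (`frame_index`, `label` factor).
#' @export
decode_labels <- function(track) {
  P <- track_matrix(track)
  idx <- max.col(P, ties.method = "first")
  tibble::tibble(frame_index = track$frame_index,
                 label = factor(tissue_classes()[idx], levels = tissue_classes()))
}

#' Stream-predict a whole pullback video
#'
#' Extracts features frame by frame, runs the head over the full video as a
#' single stream (recurrent state carried across all frames, starting from
#' zero), applies the head's output filter (`fc_avg`), and decodes hard
#' labels.
#'
#' @param model A `pullback_model`.
#' @param video A `pullback_video`.
#' @return Tibble with `patient_id`, `video_id`, `frame_index`, one
#'   probability column per class, and the decoded `label`.
#' @export
predict_video <- function(model, video) {
  stopifnot(inherits(video, "pullback_video"))
  feats <- extract_features(model, video$images)
  res <- head_forward(model, feats, state = NULL,
                      frame_index = video$frames$frame_index)
  lab <- decode_labels(res$track)
  dplyr::bind_cols(
    tibble::tibble(patient_id = video$frames$patient_id,
                   video_id = video$frames$video_id),
    res$track,
    tibble::tibble(label = lab$label))
}
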