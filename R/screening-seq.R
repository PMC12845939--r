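#' Sequence-classifier configuration
#'
#' Configuration of the random-convolution sequence classifier: a bank of
#' random 1-D convolutional kernels (random weights, dilations and biases)
#' is applied to 2-channel stimulus windows (pupil percent-change, gaze
#' speed); each kernel contributes max-pooled and proportion-of-positive
#' pooled features; a ridge-penalised logistic readout is trained on the
#' training split with the penalty chosen on the validation split. The split
#' is at participant level (70/15/15 by default) to prevent stimulus-level
#' leakage.
#'
#' @param n_kernels number of random kernels.
#' @param kernel_length kernel taps.
#' @param window_s window length, seconds.
#' @param split train/validation/test fractions (participant level).
#' @param seed seed for kernel generation and the split.
#' @return list of class `seq_config`.
#' @export
seq_config <- function(n_kernels = 200L, kernel_length = 9L, window_s = 13,
                       split = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(n_kernels = as.integer(n_kernels),
                 kernel_length = as.integer(kernel_length),
                 window_s = window_s, split = split, seed = as.integer(seed)),
            class = "seq_config")
}

#' Simulate per-stimulus signal windows for a cohort
#'
#' For every screening-session stimulus of the cohort, simulates a
#' single-block trace driven by that stimulus's tabulated features and cuts
#' a 13 s window (last 3 s of baseline + 8 s stimulus + 2 s rest) with two
#' channels: pupil percent change from the baseline mean, and gaze speed
#' (deg/s, scaled by 1/100 to a comparable range).
#'
#' @param cohort a [generate_cohort()] result (traces not required).
#' @param seed integer seed.
#' @return list with `x` (matrix, one row per window, channels
#'   concatenated), `len` (samples per channel), `channels`,
#'   `participant_id`, `label` (1 = depressed).
#' @export
simulate_feature_windows <- function(cohort, seed = 1L) {
  cfg <- cohort$cfg
  fs <- cfg$sampling_rate
  feats <- cohort$features[cohort$features$session_type == "screening", ]
  grp <- cohort$participants$group[match(feats$participant_id,
                                         cohort$participants$participant_id)]
  sch <- block_schedule("none", 5000, 8000, 5000)
  onset <- sch$onset_ms[1]
  win <- c(onset - 3000, onset + 10000)
  L <- as.integer(13 * fs)
  n <- nrow(feats)
  x <- matrix(0, n, 2L * L)
  seed0 <- substream_seed(seed, "windows")
  for (i in seq_len(n)) {
    pp <- pupil_params(amplitude = feats$PDA[i], latency_ms = feats$CL[i],
                       noise_sd = 0.02, blink_rate = 0, sampling_rate = fs)
    gp <- gaze_params(fixation_mean = max(60, feats$FD[i]), fixation_sd = 30,
                      saccade_amp_mean = max(0.5, feats$SA[i]),
                      saccade_amp_sd = 1.5, sampling_rate = fs)
    s_i <- (seed0 + i) %% 2147483647
    pup <- simulate_pupil_trace(pp, sch, seed = s_i, both_eyes = FALSE)
    gaz <- simulate_gaze_trace(gp, sch, seed = s_i + 1)
    sel <- pup$t_ms >= win[1] & pup$t_ms < win[2]
    B <- mean(pup$pupil_mm[pup$t_ms >= onset - 3000 & pup$t_ms < onset])
    pct <- 100 * (pup$pupil_mm[sel] - B) / B
    vx <- c(0, diff(gaz$gaze_x_deg)) * fs
    vy <- c(0, diff(gaz$gaze_y_deg)) * fs
    speed <- sqrt(vx^2 + vy^2)[sel] / 100
    x[i, ] <- c(pct[seq_len(L)], speed[seq_len(L)])
  }
  list(x = x, len = L, channels = 2L, participant_id = feats$participant_id,
       label = as.integer(grp == "depressed"))
}

# Draw the random kernel bank: each kernel picks a channel, mean-centred
# Gaussian weights, a bias, and a dyadic dilation fitting the window.
make_kernels <- function(cfg, len) {
  kl <- cfg$kernel_length
  max_dil <- max(0L, floor(log2((len - 1) / (kl - 1))))
  lapply(seq_len(cfg$n_kernels), function(i) {
    w <- stats::rnorm(kl); w <- w - mean(w)
    list(channel = sample(1:2, 1L), weights = w,
         bias = stats::runif(1, -1, 1),
         dilation = 2L^sample(0:min(max_dil, 6L), 1L))
  })
}

# Convolve all windows with the kernel bank; per kernel emit max pooling and
# the proportion of positive responses.
apply_kernels <- function(x, len, kernels) {
  n <- nrow(x)
  feats <- matrix(0, n, 2L * length(kernels))
  for (k in seq_along(kernels)) {
    kr <- kernels[[k]]
    span <- (length(kr$weights) - 1L) * kr$dilation
    npos <- len - span
    off <- (kr$channel - 1L) * len
    acc <- matrix(kr$bias, n, npos)
    for (j in seq_along(kr$weights)) {
      cols <- off + (j - 1L) * kr$dilation + seq_len(npos)
      acc <- acc + kr$weights[j] * x[, cols, drop = FALSE]
    }
    feats[, 2L * k - 1L] <- apply(acc, 1, max)
    feats[, 2L * k] <- rowMeans(acc > 0)
  }
  feats
}

#' Train the sequence classifier
#'
#' Random-convolution transform plus ridge-logistic readout (`glmnet`,
#' `alpha = 0`): the penalty is selected by validation-split log-loss (the
#' early-stopping analogue), the split is by participant, and everything is
#' deterministic under the configuration seed.
#'
#' @param windows a [simulate_feature_windows()] result (or compatible
#'   list).
#' @param cfg a [seq_config()].
#' @return object of class `seq_classifier` with the kernel bank, scaler,
#'   readout, chosen penalty, split, and per-participant test predictions.
#' @export
train_seq_classifier <- function(windows, cfg = seq_config()) {
  pid <- windows$participant_id
  y <- windows$label
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  ids <- unique(pid)
  plab <- y[match(ids, pid)]
  split <- participant_split(ids, plab, cfg$split, seed = cfg$seed)

  kernels <- with_local_seed(substream_seed(cfg$seed, "kernels"),
                             make_kernels(cfg, windows$len))
  feats <- apply_kernels(windows$x, windows$len, kernels)
  tr <- pid %in% split$train
  va <- pid %in% split$validation
  te <- pid %in% split$test
  mu <- colMeans(feats[tr, , drop = FALSE])
  sg <- pmax(apply(feats[tr, , drop = FALSE], 2, stats::sd), 1e-8)
  fz <- sweep(sweep(feats, 2, mu), 2, sg, `/`)

  fit <- glmnet::glmnet(fz[tr, , drop = FALSE], y[tr], family = "binomial",
                        alpha = 0, nlambda = 40, standardize = FALSE)
  pv <- stats::predict(fit, fz[va, , drop = FALSE], type = "response")
  eps <- 1e-12
  val_loss <- apply(pv, 2, function(p)
    -mean(y[va] * log(p + eps) + (1 - y[va]) * log(1 - p + eps)))
  lam <- fit$lambda[which.min(val_loss)]

  model <- structure(list(kernels = kernels, mu = mu, sigma = sg, fit = fit,
                          lambda = lam, len = windows$len, split = split,
                          cfg = cfg),
                     class = "seq_classifier")
  model$test <- predict(model, windows, subset = te)
  model
}

#' Predict with the sequence classifier
#'
#' Per-window probabilities, aggregated per participant by the mean.
#'
#' @param object a [train_seq_classifier()] model.
#' @param windows windows list (same layout as training).
#' @param subset optional logical row subset.
#' @param ... unused.
#' @return list with `window_prob`, and per-participant `participant_id`,
#'   `prob`, `label`.
#' @export
predict.seq_classifier <- function(object, windows, subset = NULL, ...) {
  keep <- subset %||% rep(TRUE, nrow(windows$x))
  feats <- apply_kernels(windows$x[keep, , drop = FALSE], windows$len,
                         object$kernels)
  fz <- sweep(sweep(feats, 2, object$mu), 2, object$sigma, `/`)
  p <- as.numeric(stats::predict(object$fit, fz, type = "response",
                                 s = object$lambda))
  pid <- windows$participant_id[keep]
  lab <- windows$label[keep]
  agg <- tapply(p, pid, mean)
  ids <- names(agg)
  list(window_prob = p, participant_id = ids, prob = as.numeric(agg),
       label = lab[match(ids, pid)])
}

#' @export
print.seq_classifier <- function(x, ...) {
  cat(sprintf("seq_classifier: %d random kernels, ridge-logistic readout (lambda = %.4g)\n",
              length(x$kernels), x$lambda))
  cat(sprintf("  split: %d train / %d validation / %d test participants\n",
              length(x$split$train), length(x$split$validation),
              length(x$split$test)))
  invisible(x)
}
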