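# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by a different route than the implementation.

# Fractional Hamming distance with shift search, computed by explicitly
# rebuilding the shifted bit vector position by position.
oracle_hamming <- function(bits_a, bits_b, n_angular, max_shift) {
  n_radial <- length(bits_a) / (2 * n_angular)
  best <- Inf
  for (s in -max_shift:max_shift) {
    shifted <- integer(length(bits_b))
    for (r in seq_len(n_radial)) {
      for (j in seq_len(n_angular)) {
        src <- ((j - 1 - s) %% n_angular) + 1      # position that moves into j
        for (k in 1:2) {
          dst <- ((r - 1) * n_angular + (j - 1)) * 2 + k
          from <- ((r - 1) * n_angular + (src - 1)) * 2 + k
          shifted[dst] <- bits_b[from]
        }
      }
    }
    best <- min(best, sum(bits_a != shifted) / length(bits_a))
  }
  best
}

# ICC(2,1) via R's own two-way ANOVA decomposition (aov), not the closed-form
# mean-square sums used by the implementation.
oracle_icc <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(y = as.vector(mat),
                     item = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ item + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- if (length(ms) >= 3) ms[3] else 0
  if (is.na(mse)) mse <- 0
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# A minimal synthetic session trace: constant pupil with an optional
# piecewise-linear plateau bump, constant gaze.
constant_trace <- function(duration_ms = 18000, fs = 100, pupil = 4.0,
                           gaze = c(0, 0)) {
  t <- seq(0, duration_ms - 1000 / fs, by = 1000 / fs)
  data.frame(t_ms = t, pupil_mm = rep(pupil, length(t)),
             gaze_x_deg = gaze[1], gaze_y_deg = gaze[2],
             valid = TRUE)
}

# Insert a trapezoidal excursion to `peak` between onset+rise and the window
# end; the flat plateau makes the peak immune to moving-average smoothing.
add_plateau <- function(trace, onset_ms, peak, rise_ms = 500,
                        plateau_ms = 2000) {
  t <- trace$t_ms
  base <- trace$pupil_mm[1]
  up <- t >= onset_ms & t < onset_ms + rise_ms
  flat <- t >= onset_ms + rise_ms & t < onset_ms + rise_ms + plateau_ms
  down <- t >= onset_ms + rise_ms + plateau_ms &
    t < onset_ms + 2 * rise_ms + plateau_ms
  trace$pupil_mm[up] <- base + (peak - base) * (t[up] - onset_ms) / rise_ms
  trace$pupil_mm[flat] <- peak
  trace$pupil_mm[down] <- peak - (peak - base) *
    (t[down] - (onset_ms + rise_ms + plateau_ms)) / rise_ms
  trace
}

core_cols <- c("PDA_neg", "PDA_pos", "FD", "SV")

# The participant-level logistic screening pipeline used by several tests:
# train on 70% of participants, report AUC on a held-out set.
logit_pipeline_auc <- function(seed, holdout = c("test", "both")) {
  holdout <- match.arg(holdout)
  coh <- generate_cohort(cohort_config(seed = seed), traces = FALSE)
  Xp <- participant_core_features(coh)
  y <- as.integer(Xp$group == "depressed")
  sp <- participant_split(Xp$participant_id, y, seed = seed)
  tr <- Xp$participant_id %in% sp$train
  ho <- if (holdout == "test") Xp$participant_id %in% sp$test else !tr
  fit <- fit_logistic(Xp[tr, core_cols], y[tr])
  roc_auc(predict(fit, Xp[ho, core_cols]), y[ho])$auc
}

# Seeded permutation helper (restores nothing; used for label-shuffling).
with_seed_sample <- function(x, seed) { set.seed(seed); sample(x) }
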