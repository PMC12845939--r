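#' Cohort configuration for the synthetic study population
#'
#' Defines the study conditions emulated by [generate_cohort()]: a cohort of
#' `n_total` participants of whom `n_depressed` carry the depressive response
#' pattern, with group-level distributions for the four feature contrasts the
#' study reports (pupil dilation amplitude to negative and to positive news,
#' fixation duration, saccade velocity). Defaults reproduce the reported
#' cohort: 242 participants, 81 depressed (33.5%), PDA to negative news
#' 18.4 (SD 6.7) vs 27.9 (SD 8.3) percent, PDA to positive news 6.2 (4.1) vs
#' -1.3 (5.0) percent, fixation duration 280 (40) vs 345 (52) ms, saccade
#' velocity 320 (45) vs 276 (51) deg/s.
#'
#' Deviations toward the depressive pattern are equicorrelated across features
#' with coefficient `inter_feature_rho` (a shared severity factor), and
#' per-stimulus values scatter around the participant-level latent mean with
#' standard deviation `within_frac` times the between-participant SD.
#'
#' @param n_total total number of participants.
#' @param n_depressed number carrying the depressive response pattern.
#' @param feature_effects data frame with columns `feature`, `control_mean`,
#'   `control_sd`, `depressed_mean`, `depressed_sd` for the four core features
#'   `PDA_neg`, `PDA_pos`, `FD`, `SV`.
#' @param inter_feature_rho equicorrelation of severity-aligned deviations,
#'   in `[0, 1)`.
#' @param stimuli_per_session named count vector `c(pos = 3, neg = 3)`.
#' @param sampling_rate trace sampling rate in Hz (valid 90-120).
#' @param block named block durations in seconds
#'   `c(baseline = 5, stimulus = 8, rest = 5)`.
#' @param within_frac per-stimulus (within-participant) SD as a fraction of
#'   the between-participant SD.
#' @param pdv_scale latent dilation-velocity per unit dilation amplitude
#'   (%/s per %).
#' @param seed root seed; every generator derives named substreams from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 242L,
                          n_depressed = 81L,
                          feature_effects = default_feature_effects(),
                          inter_feature_rho = 0.25,
                          stimuli_per_session = c(pos = 3L, neg = 3L),
                          sampling_rate = 100,
                          block = c(baseline = 5, stimulus = 8, rest = 5),
                          within_frac = 0.3,
                          pdv_scale = 1.7,
                          seed = 1L) {
  n_total <- as.integer(n_total); n_depressed <- as.integer(n_depressed)
  if (n_depressed > n_total) stop("n_depressed must not exceed n_total")
  if (n_total < 1L) stop("n_total must be positive")
  req <- c("feature", "control_mean", "control_sd", "depressed_mean", "depressed_sd")
  if (!all(req %in% names(feature_effects)))
    stop("feature_effects must have columns ", paste(req, collapse = ", "))
  if (any(feature_effects$control_sd <= 0) || any(feature_effects$depressed_sd <= 0))
    stop("all SDs must be positive")
  if (inter_feature_rho < 0 || inter_feature_rho >= 1)
    stop("inter_feature_rho must lie in [0, 1) (positive-definite equicorrelation)")
  if (sampling_rate < 90 || sampling_rate > 120)
    stop("sampling_rate must lie in [90, 120] Hz")
  if (any(block <= 0)) stop("block durations must be positive")
  structure(list(
    n_total = n_total, n_depressed = n_depressed,
    feature_effects = feature_effects,
    inter_feature_rho = inter_feature_rho,
    stimuli_per_session = stimuli_per_session,
    sampling_rate = sampling_rate, block = block,
    within_frac = within_frac, pdv_scale = pdv_scale,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Reported group-level feature distributions
#'
#' The four feature contrasts with printed group means/SDs: PDA to negative
#' news (% of baseline), PDA to positive news (%), fixation duration (ms),
#' saccade velocity (deg/s).
#'
#' @return data frame with one row per feature.
#' @export
default_feature_effects <- function() {
  data.frame(
    feature        = c("PDA_neg", "PDA_pos", "FD", "SV"),
    control_mean   = c(18.4, 6.2, 280, 320),
    control_sd     = c(6.7, 4.1, 40, 45),
    depressed_mean = c(27.9, -1.3, 345, 276),
    depressed_sd   = c(8.3, 5.0, 52, 51),
    stringsAsFactors = FALSE
  )
}

# Direction of the depressive shift for each core contrast (+1: depressed
# mean higher). Used to align the severity factor across features.
effect_direction <- function(fe) {
  sign(fe$depressed_mean - fe$control_mean)
}

#' Generate a synthetic study cohort
#'
#' Draws participants with group labels, a participant-level latent feature
#' vector per state (reference latents centred on the control-group
#' distribution, screening latents on the participant's own group), three
#' reference sessions (rested / tired / stressed) and one screening session of
#' 3 positive + 3 negative stimuli, each stimulus carrying the full feature
#' octet. Optionally simulates pupil and gaze traces per session.
#'
#' A shared severity factor with equicorrelation `inter_feature_rho` links the
#' four core features, aligned so that a more "depressive" deviation in one
#' feature co-occurs with more depressive deviations in the others. The same
#' participant trait deviation underlies reference and screening latents, so
#' screening deviates from the individual baseline only through the group
#' shift (depressed) and within-session noise (everyone).
#'
#' @param cfg a [cohort_config()].
#' @param traces logical; also simulate per-session pupil/gaze traces
#'   (slower). Feature-level analyses need only the feature table.
#' @return an object of class `cohort`: list with `participants`,
#'   `features` (one row per session x stimulus), `latent`, `schedules` and
#'   `traces` (the latter two `NULL` unless `traces = TRUE`), and `cfg`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_total = 12, n_depressed = 4), traces = FALSE)
#' table(coh$participants$group)
#' @export
generate_cohort <- function(cfg = cohort_config(), traces = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  fe <- cfg$feature_effects
  p <- nrow(fe)
  dirs <- effect_direction(fe)
  n <- cfg$n_total

  with_local_seed(substream_seed(cfg$seed, "cohort"), {
    group <- rep("control", n)
    if (cfg$n_depressed > 0L) group[seq_len(cfg$n_depressed)] <- "depressed"
    ids <- sprintf("P%04d", seq_len(n))
    participants <- data.frame(participant_id = ids, group = group,
                               stringsAsFactors = FALSE)

    # severity-aligned trait deviations, shared across states
    u <- rmvn_equicorr(n, p, cfg$inter_feature_rho)      # n x p, unit scale
    e <- sweep(u, 2, dirs, `*`)                          # aligned deviations

    dep <- group == "depressed"
    lat_screen <- matrix(NA_real_, n, p, dimnames = list(NULL, fe$feature))
    lat_ref <- lat_screen
    for (j in seq_len(p)) {
      mu <- ifelse(dep, fe$depressed_mean[j], fe$control_mean[j])
      sd <- ifelse(dep, fe$depressed_sd[j], fe$control_sd[j])
      lat_screen[, j] <- mu + sd * e[, j]
      # individual baseline: the participant's own neutral reactivity
      lat_ref[, j] <- fe$control_mean[j] + fe$control_sd[j] * e[, j]
    }

    # ancillary latents without printed group contrasts
    lat_cl <- rnorm(n, 400, 80)                 # response delay, ms
    lat_gde <- clamp(rnorm(n, 4.2, 0.5), 0.5, 5.8)
    lat_ema <- abs(rnorm(n, 0.05, 0.04))

    states <- c("rested", "tired", "stressed")
    n_pos <- cfg$stimuli_per_session[["pos"]]
    n_neg <- cfg$stimuli_per_session[["neg"]]
    valences <- c(rep("pos", n_pos), rep("neg", n_neg))
    n_stim <- length(valences)
    w <- cfg$within_frac
    n_sess <- 4L
    N <- n * n_sess * n_stim

    i_idx <- rep(seq_len(n), each = n_sess * n_stim)
    s_idx <- rep(rep(1:n_sess, each = n_stim), times = n)
    k_idx <- rep(seq_len(n_stim), times = n * n_sess)
    is_ref <- s_idx <= 3L
    sess_of <- (i_idx - 1L) * n_sess + s_idx

    # randomised stimulus order per session
    val <- character(N)
    val[order(sess_of, runif(N))] <- rep(valences, times = n * n_sess)

    # session-level state wobble (reference sessions only), per feature
    soff <- matrix(0, n * n_sess, p)
    ref_sess <- which(rep(1:n_sess, times = n) <= 3L)
    soff[ref_sess, ] <- matrix(rnorm(length(ref_sess) * p), ncol = p) %*%
      diag(w * fe$control_sd, p)

    lat_of <- function(col) ifelse(is_ref, lat_ref[cbind(i_idx, col)],
                                   lat_screen[cbind(i_idx, col)])
    base_sd_of <- function(j) ifelse(is_ref | !dep[i_idx],
                                     fe$control_sd[j], fe$depressed_sd[j])

    is_neg <- val == "neg"
    pda_lat <- ifelse(is_neg, lat_of(1L) + soff[cbind(sess_of, rep(1L, N))],
                      lat_of(2L) + soff[cbind(sess_of, rep(2L, N))])
    pda_sd <- ifelse(is_neg, base_sd_of(1L), base_sd_of(2L))
    pda <- pda_lat + rnorm(N, 0, w * pda_sd)
    pdv <- cfg$pdv_scale * pda_lat + rnorm(N, 0, w * cfg$pdv_scale * pda_sd)
    fd <- pmax(60, lat_of(3L) + soff[cbind(sess_of, rep(3L, N))] +
                 rnorm(N, 0, w * base_sd_of(3L)))
    sv <- pmax(30, lat_of(4L) + soff[cbind(sess_of, rep(4L, N))] +
                 rnorm(N, 0, w * base_sd_of(4L)))
    features <- data.frame(
      participant_id = ids[i_idx],
      session_id = sprintf("%s_S%d", ids[i_idx], s_idx),
      session_type = ifelse(is_ref, "reference", "screening"),
      state = ifelse(is_ref, states[pmin(s_idx, 3L)], "screening"),
      stimulus_idx = k_idx, valence = val,
      PDA = pda, CL = pmax(80, lat_cl[i_idx] + rnorm(N, 0, 60)),
      CL_censored = FALSE, PDV = pdv, FD = fd, SV = sv,
      SA = main_sequence_amplitude(sv),
      GDE = clamp(lat_gde[i_idx] + rnorm(N, 0, 0.3), 0, 6),
      EMA = pmax(0, lat_ema[i_idx] + rnorm(N, 0, 0.02)),
      stringsAsFactors = FALSE
    )
    latent <- data.frame(participant_id = ids, group = group, lat_screen,
                         stringsAsFactors = FALSE)

    bundle <- structure(list(
      participants = participants, features = features, latent = latent,
      schedules = NULL, traces = NULL, cfg = cfg
    ), class = "cohort")
  })

  if (traces) bundle <- add_cohort_traces(bundle)
  bundle
}

# Simulate pupil + gaze traces for every session in the cohort, driven by the
# tabulated per-stimulus features, under the "trace" substream.
add_cohort_traces <- function(bundle) {
  cfg <- bundle$cfg
  feats <- bundle$features
  sess <- unique(feats$session_id)
  schedules <- vector("list", length(sess)); names(schedules) <- sess
  tr <- vector("list", length(sess)); names(tr) <- sess
  seed0 <- substream_seed(cfg$seed, "trace")
  for (i in seq_along(sess)) {
    f <- feats[feats$session_id == sess[i], ]
    sch <- block_schedule(f$valence,
                          baseline_ms = cfg$block[["baseline"]] * 1000,
                          stimulus_ms = cfg$block[["stimulus"]] * 1000,
                          rest_ms = cfg$block[["rest"]] * 1000)
    pp <- pupil_params(amplitude = f$PDA, latency_ms = mean(f$CL),
                       sampling_rate = cfg$sampling_rate)
    gp <- gaze_params(fixation_mean = mean(f$FD), fixation_sd = 40,
                      saccade_amp_mean = mean(f$SA), saccade_amp_sd = 2,
                      sampling_rate = cfg$sampling_rate)
    s_i <- (seed0 + i) %% 2147483647
    pup <- simulate_pupil_trace(pp, sch, seed = s_i)
    gaz <- simulate_gaze_trace(gp, sch, seed = s_i + 1)
    tr[[i]] <- merge_session_trace(pup, gaz)
    schedules[[i]] <- sch
  }
  bundle$schedules <- schedules
  bundle$traces <- tr
  bundle
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic screening cohort\n")
  cat(sprintf("  participants: %d (%d depressed, %.1f%%)\n",
              x$cfg$n_total, x$cfg$n_depressed,
              100 * x$cfg$n_depressed / x$cfg$n_total))
  cat(sprintf("  sessions per participant: 4 (3 reference + 1 screening)\n"))
  cat(sprintf("  feature rows: %d; traces: %s\n", nrow(x$features),
              if (is.null(x$traces)) "not simulated" else "simulated"))
  invisible(x)
}
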