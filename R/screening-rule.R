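#' Configuration of the 2-SD baseline-deviation screening rule
#'
#' A stimulus is flagged when the participant's baseline-relative z-scores of
#' the core features (PDA, PDV, FD) deviate by at least `k_sd` standard
#' deviations *in the direction the depressive pattern predicts*: toward
#' hyper-response (PDA+, PDV+) and longer fixation (FD+) for negative news,
#' toward blunted/negative pupil response (PDA-, PDV-) but still longer
#' fixation (FD+) for positive news. A participant is labelled
#' depressive-pattern when at least `min_flagged_stimuli` of the six stimuli
#' are flagged.
#'
#' @param k_sd deviation threshold in baseline SD units (inclusive,
#'   "at least").
#' @param core core feature names.
#' @param mode per-stimulus aggregation over core features: `"any"` (1 of
#'   3), `"majority"` (2 of 3, default), `"all"` (3 of 3).
#' @param min_flagged_stimuli participant-level threshold on flagged stimuli.
#' @param direction direction table: named list `neg`/`pos`, each a named
#'   vector of +1/-1 per core feature.
#' @return list of class `rule_config`.
#' @export
rule_config <- function(k_sd = 2, core = c("PDA", "PDV", "FD"),
                        mode = c("majority", "any", "all"),
                        min_flagged_stimuli = 3L,
                        direction = list(neg = c(PDA = 1, PDV = 1, FD = 1),
                                        pos = c(PDA = -1, PDV = -1, FD = 1))) {
  mode <- match.arg(mode)
  if (k_sd <= 0) stop("k_sd must be positive")
  if (min_flagged_stimuli < 1L) stop("min_flagged_stimuli must be at least 1")
  if (!all(vapply(direction, function(d) all(core %in% names(d)), logical(1))))
    stop("direction table must cover every core feature")
  structure(list(k_sd = k_sd, core = core, mode = mode,
                 min_flagged_stimuli = as.integer(min_flagged_stimuli),
                 direction = direction), class = "rule_config")
}

#' Flag one stimulus from its z-scored features
#'
#' Per core feature, the deviation is sign-gated: feature `f` is deviant iff
#' `direction[valence][f] * z_f >= k_sd`. Missing z-scores count as
#' non-deviant. The stimulus is flagged according to the aggregation mode.
#'
#' @param z named numeric vector (or one-row data frame) of z-scores
#'   containing the core features.
#' @param valence `"pos"` or `"neg"`.
#' @param cfg a [rule_config()].
#' @return logical flag.
#' @export
flag_stimulus <- function(z, valence, cfg = rule_config()) {
  if (is.data.frame(z)) z <- unlist(z[intersect(names(z), cfg$core)])
  if (!valence %in% names(cfg$direction))
    stop("unknown valence: ", valence)
  dirs <- cfg$direction[[valence]][cfg$core]
  zz <- z[cfg$core]
  deviant <- !is.na(zz) & (dirs * zz >= cfg$k_sd)
  n <- sum(deviant)
  switch(cfg$mode,
         any = n >= 1L,
         majority = n >= ceiling(length(cfg$core) / 2 + 0.001),
         all = n == length(cfg$core))
}

#' Participant-level rule classification
#'
#' Depressive-pattern iff at least `min_flagged_stimuli` of the stimulus
#' flags are set. This is a screening label, explicitly not a clinical
#' diagnosis.
#'
#' @param flags logical vector of per-stimulus flags (normally 6: 3 positive
#'   + 3 negative stimuli).
#' @param cfg a [rule_config()].
#' @return `"depressive-pattern"` or `"non-depressive"`.
#' @export
classify_rule <- function(flags, cfg = rule_config()) {
  if (length(flags) < cfg$min_flagged_stimuli)
    stop(sprintf("need at least %d stimuli, got %d",
                 cfg$min_flagged_stimuli, length(flags)))
  if (sum(flags, na.rm = TRUE) >= cfg$min_flagged_stimuli)
    "depressive-pattern" else "non-depressive"
}

#' Screen every participant of a feature table against baseline profiles
#'
#' Z-scores the screening-session stimuli against each participant's
#' baseline profile, applies the per-stimulus rule and the participant-level
#' decision.
#'
#' @param features per-stimulus feature rows (screening sessions), with
#'   `participant_id`, `valence` and the core feature columns.
#' @param profile a [build_baseline()] result.
#' @param cfg a [rule_config()].
#' @return data frame: `participant_id`, `n_flagged`, `n_stimuli`,
#'   `rule_label`.
#' @export
screen_participants <- function(features, profile, cfg = rule_config()) {
  z <- zscore_features(features, profile)
  out <- lapply(unique(z$participant_id), function(pid) {
    zp <- z[z$participant_id == pid, ]
    flags <- vapply(seq_len(nrow(zp)), function(i)
      flag_stimulus(zp[i, cfg$core], zp$valence[i], cfg), logical(1))
    data.frame(participant_id = pid, n_flagged = sum(flags),
               n_stimuli = length(flags),
               rule_label = classify_rule(flags, cfg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
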