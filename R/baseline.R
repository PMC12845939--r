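# Minimum meaningful per-feature scatter, in feature units; prevents
# degenerate z-scores when reference sessions happen to be over-consistent.
feature_sd_eps <- c(PDA = 0.5, CL = 20, PDV = 0.5, FD = 5, SV = 5,
                    SA = 0.25, GDE = 0.1, EMA = 0.02)

baseline_feature_names <- function() names(feature_sd_eps)

#' Build per-participant baseline profiles from reference sessions
#'
#' All screening is relative to the individual: for every participant and
#' every feature, the mean and standard deviation across reference sessions
#' (session-level feature means) define the baseline profile. At least 3
#' reference sessions covering at least 2 distinct states (rested / tired /
#' stressed) are required. The SD is floored at
#' `max(floor_frac * |mean|, eps_feature)` so over-consistent references
#' cannot produce unbounded z-scores.
#'
#' Pupil responses differ by stimulus valence by design (dilation to negative
#' news, blunting to positive news), so the features in `by_valence` get a
#' separate baseline per valence (profile rows `PDA.neg`, `PDA.pos`, ...)
#' whenever the feature table carries a `valence` column; valence-neutral
#' features are profiled across all stimuli.
#'
#' @param features data frame with `participant_id`, `session_id`, `state`
#'   and feature columns (any of PDA, CL, PDV, FD, SV, SA, GDE, EMA); one row
#'   per stimulus (rows are first averaged per session).
#' @param floor_frac relative SD floor.
#' @param by_valence features profiled separately per valence.
#' @return data frame of class `baseline_profile`: one row per participant x
#'   (possibly valence-split) feature with `mean`, `sd`, `n_sessions`,
#'   `states`.
#' @export
build_baseline <- function(features, floor_frac = 0.05,
                           by_valence = c("PDA", "PDV")) {
  fcols <- intersect(baseline_feature_names(), names(features))
  if (!length(fcols)) stop("no feature columns found")
  has_val <- "valence" %in% names(features)
  out <- list()
  for (pid in unique(features$participant_id)) {
    fp <- features[features$participant_id == pid, ]
    sess <- unique(fp$session_id)
    states <- unique(fp$state)
    if (length(sess) < 3L)
      stop(sprintf("participant %s has %d reference session(s); at least 3 required",
                   pid, length(sess)))
    if (length(states) < 2L)
      stop(sprintf("participant %s covers %d state(s); at least 2 required",
                   pid, length(states)))
    # censored response delays do not inform the baseline
    if ("CL" %in% fcols && "CL_censored" %in% names(fp))
      fp$CL[fp$CL_censored %in% TRUE] <- NA_real_
    specs <- list()
    for (f in fcols) {
      if (has_val && f %in% by_valence) {
        for (v in unique(fp$valence))
          specs[[paste(f, v, sep = ".")]] <- list(col = f, valence = v)
      } else specs[[f]] <- list(col = f, valence = NULL)
    }
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      rows <- if (is.null(sp$valence)) fp else fp[fp$valence == sp$valence, ]
      v <- vapply(sess, function(s)
        mean(rows[[sp$col]][rows$session_id == s], na.rm = TRUE), numeric(1))
      v <- v[is.finite(v)]
      if (!length(v)) next
      m <- mean(v)
      s <- if (length(v) > 1) stats::sd(v) else 0
      s <- max(s, floor_frac * abs(m), feature_sd_eps[[sp$col]])
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, feature = nm, mean = m, sd = s,
        n_sessions = length(v), states = paste(sort(states), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("baseline_profile", "data.frame"))
}

#' Z-score stimulus features against a baseline profile
#'
#' `z = (x - mean) / sd` per feature, using the participant's baseline
#' profile; features with valence-specific baselines are matched on the
#' stimulus valence. Missing features and censored response delays
#' propagate as `NA`.
#'
#' @param features data frame of per-stimulus features with
#'   `participant_id` and feature columns.
#' @param profile a [build_baseline()] result.
#' @return data frame: identifying columns plus z-scored feature columns.
#' @export
zscore_features <- function(features, profile) {
  base_of <- sub("\\..*$", "", profile$feature)
  fcols <- intersect(unique(base_of), names(features))
  idcols <- intersect(c("participant_id", "session_id", "stimulus_idx",
                        "valence"), names(features))
  out <- features[idcols]
  for (f in fcols) out[[f]] <- NA_real_
  has_val <- "valence" %in% names(features)
  for (pid in unique(features$participant_id)) {
    rows <- which(features$participant_id == pid)
    pp <- profile[profile$participant_id == pid, ]
    for (f in fcols) {
      x <- features[[f]][rows]
      if (f == "CL" && "CL_censored" %in% names(features))
        x[features$CL_censored[rows] %in% TRUE] <- NA_real_
      plain <- pp[pp$feature == f, ]
      for (i in seq_along(rows)) {
        nm <- if (has_val) paste(f, features$valence[rows[i]], sep = ".") else f
        pf <- pp[pp$feature == nm, ]
        if (!nrow(pf)) pf <- plain
        if (!nrow(pf)) next
        out[[f]][rows[i]] <- (x[i] - pf$mean[1]) / pf$sd[1]
      }
    }
  }
  out
}
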