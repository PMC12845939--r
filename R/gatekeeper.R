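#' Fuse identity and screening outcomes into an access decision
#'
#' The four-situation decision logic: identity accepted and no depressive
#' pattern grants access; accepted but flagged yields a temporary denial
#' pending further investigation; rejected identity denies access regardless
#' of the screening outcome (screening alone never grants), and a rejected
#' identity combined with a depressive flag is denied with a
#' separate-handling marker. Screening is skipped - and recorded as not run -
#' when identification fails, since the screening module only runs after a
#' successful identification.
#'
#' @param match a [identify_probe()] result (or logical: identity
#'   accepted?).
#' @param screen screening outcome: a `"depressive-pattern"` /
#'   `"non-depressive"` label, a logical flag, or `NULL` when screening was
#'   not run.
#' @return object of class `access_decision`: `outcome` (one of `GRANT`,
#'   `DENY_TEMP_SCREEN`, `DENY_IDENTITY`, `DENY_BOTH`), `reasons`,
#'   `separate_handling`, `screening_run`, `timestamp`, plus probe/match
#'   references when available.
#' @export
decide_access <- function(match, screen = NULL) {
  if (missing(match) || is.null(match))
    stop("identity result is required; screening alone never grants access")
  accepted <- if (inherits(match, "match_result")) match$accepted
  else isTRUE(match)
  flagged <- if (is.null(screen)) NA
  else if (is.character(screen)) identical(screen, "depressive-pattern")
  else isTRUE(screen)

  if (accepted && !is.na(flagged) && !flagged) {
    outcome <- "GRANT"; reasons <- "identity accepted; no depressive pattern"
  } else if (accepted && !is.na(flagged) && flagged) {
    outcome <- "DENY_TEMP_SCREEN"
    reasons <- c("identity accepted", "depressive pattern flagged",
                 "temporary denial: further investigation required")
  } else if (accepted && is.na(flagged)) {
    stop("screening result is required once identity is accepted")
  } else if (!accepted && (is.na(flagged) || !flagged)) {
    outcome <- "DENY_IDENTITY"
    reasons <- c("identity rejected (biometric error or attempted fraud)",
                 if (is.na(flagged)) "screening not run" else
                   "no depressive pattern")
  } else {
    outcome <- "DENY_BOTH"
    reasons <- c("identity rejected", "depressive pattern flagged",
                 "handle data separately")
  }
  structure(list(
    outcome = outcome, reasons = reasons,
    separate_handling = identical(outcome, "DENY_BOTH"),
    screening_run = !is.na(flagged),
    identity_accepted = accepted,
    best_id = if (inherits(match, "match_result")) match$best_id else NA,
    distance = if (inherits(match, "match_result")) match$distance else NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "access_decision")
}

#' @export
print.access_decision <- function(x, ...) {
  cat(sprintf("access_decision: %s\n", x$outcome))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Append an access decision to a JSON-lines audit log
#'
#' @param decision an [decide_access()] result.
#' @param path audit file path (created if absent; records are appended).
#' @return the path, invisibly.
#' @export
write_audit <- function(decision, path) {
  rec <- unclass(decision)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(line, con)
  invisible(path)
}

#' Read an audit log
#'
#' @param path audit JSON-lines file.
#' @return list of decision records.
#' @export
read_audit <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"),
         function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Run the integrated screening pipeline end to end
#'
#' Orchestrates the full synthetic workflow under one root seed: generate a
#' cohort, build baseline profiles from the reference sessions, apply the
#' 2-SD rule and the logistic feature model to the screening sessions,
#' enrol code-level iris identities and identify every participant's probe,
#' then fuse the two module outcomes into per-participant access decisions.
#'
#' @param cfg a [cohort_config()].
#' @param seed root seed (overrides `cfg$seed` when given).
#' @param flip_prob intra-class code noise of the identity simulation.
#' @return list with `cohort`, `profiles`, `screen` (per-participant rule +
#'   logistic results), `identity` (per-participant match), `decisions`
#'   (data frame), and `metrics` (rule confusion metrics + logistic AUC).
#' @export
run_pipeline <- function(cfg = cohort_config(), seed = NULL,
                         flip_prob = 0.08) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cohort <- generate_cohort(cfg, traces = FALSE)
  feats <- cohort$features
  ref <- feats[feats$session_type == "reference", ]
  scr <- feats[feats$session_type == "screening", ]
  profiles <- build_baseline(ref)
  rule <- screen_participants(scr, profiles, rule_config())

  # participant-level logistic model on the four core contrasts
  Xp <- participant_core_features(cohort)
  y <- as.integer(Xp$group == "depressed")
  # small or strongly separated cohorts: freeze the published slopes and fit
  # only the intercept instead of an unstable maximum-likelihood fit
  fit <- tryCatch(fit_logistic(Xp[c("PDA_neg", "PDA_pos", "FD", "SV")], y),
                  error = function(e) {
                    if (!grepl("separation", conditionMessage(e))) stop(e)
                    fit_logistic(Xp[c("PDA_neg", "PDA_pos", "FD")], y,
                                 fixed_coef = published_logit_slopes())
                  })
  logit_p <- fit$fitted

  # code-level identity check: enrol one template per participant, probe with
  # a noisy re-acquisition
  n <- cfg$n_total
  gal <- simulate_code_gallery(n_identities = n, n_samples = 1L,
                               flip_prob = flip_prob,
                               seed = substream_seed(cfg$seed, "iris"))
  enrolled <- gal$templates
  probes <- gal$codes
  matches <- lapply(seq_len(n), function(i)
    identify_probe(probes[[i]], enrolled))

  decisions <- do.call(rbind, lapply(seq_len(n), function(i) {
    dec <- decide_access(matches[[i]],
                         if (matches[[i]]$accepted) rule$rule_label[i] else NULL)
    data.frame(participant_id = rule$participant_id[i],
               identity_accepted = matches[[i]]$accepted,
               rule_label = rule$rule_label[i],
               logistic_p = logit_p[i], outcome = dec$outcome,
               stringsAsFactors = FALSE)
  }))

  pred_pos <- rule$rule_label == "depressive-pattern"
  truth <- cohort$participants$group == "depressed"
  cm <- confusion_metrics(sum(!pred_pos & !truth), sum(pred_pos & !truth),
                          sum(!pred_pos & truth), sum(pred_pos & truth))
  list(cohort = cohort, profiles = profiles, screen = rule,
       identity = matches, decisions = decisions,
       metrics = list(rule = cm, logistic_auc = roc_auc(logit_p, y)$auc,
                      logistic = fit))
}

#' Participant-level core features of a cohort
#'
#' Mean screening-session feature per participant: PDA over negative
#' stimuli, PDA over positive stimuli, FD and SV over all stimuli.
#'
#' @param cohort a [generate_cohort()] result.
#' @return data frame `participant_id`, `group`, `PDA_neg`, `PDA_pos`,
#'   `FD`, `SV`.
#' @export
participant_core_features <- function(cohort) {
  scr <- cohort$features[cohort$features$session_type == "screening", ]
  out <- lapply(split(scr, scr$participant_id), function(d) {
    data.frame(participant_id = d$participant_id[1],
               PDA_neg = mean(d$PDA[d$valence == "neg"]),
               PDA_pos = mean(d$PDA[d$valence == "pos"]),
               FD = mean(d$FD), SV = mean(d$SV), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[match(cohort$participants$participant_id, out$participant_id), ]
  out$group <- cohort$participants$group
  rownames(out) <- NULL
  out[c("participant_id", "group", "PDA_neg", "PDA_pos", "FD", "SV")]
}
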