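#' Corpus labelling configuration
#'
#' Thresholds of the stimulus labelling procedure: items with a valence mean
#' of at most `neg_valence_max` are negative, at least `pos_valence_min`
#' positive; items with arousal means at the extremes (at most
#' `arousal_low_max` or at least `arousal_high_min`, inclusive) are excluded,
#' as are items where any rater pair differs by more than `max_rater_range`
#' scale points on either scale.
#'
#' @param neg_valence_max,pos_valence_min valence thresholds.
#' @param arousal_low_max,arousal_high_min arousal exclusion bounds.
#' @param max_rater_range largest allowed max-minus-min rater range.
#' @param session_pos,session_neg stimuli per class in a session.
#' @return list of class `corpus_config`.
#' @export
corpus_config <- function(neg_valence_max = 3.5, pos_valence_min = 6.5,
                          arousal_low_max = 2, arousal_high_min = 8,
                          max_rater_range = 2, session_pos = 3L,
                          session_neg = 3L) {
  if (neg_valence_max >= pos_valence_min)
    stop("neg_valence_max must be below pos_valence_min")
  structure(list(neg_valence_max = neg_valence_max,
                 pos_valence_min = pos_valence_min,
                 arousal_low_max = arousal_low_max,
                 arousal_high_min = arousal_high_min,
                 max_rater_range = max_rater_range,
                 session_pos = as.integer(session_pos),
                 session_neg = as.integer(session_neg)),
            class = "corpus_config")
}

#' Label one corpus item
#'
#' Exclusion checks run first: rater disagreement (range strictly greater
#' than `max_rater_range` on either scale), then extreme arousal (inclusive
#' bounds). Surviving items are labelled by valence mean; means in the open
#' neutral interval are excluded as neutral.
#'
#' @param valence,arousal complete integer rating vectors (one per rater).
#' @param cfg a [corpus_config()].
#' @return list `label` (`"negative"`, `"positive"` or `"excluded"`) and
#'   `reason` (`""`, `"disagreement"`, `"arousal"`, `"neutral"`).
#' @export
label_item <- function(valence, arousal, cfg = corpus_config()) {
  if (anyNA(valence) || anyNA(arousal) || !length(valence) || !length(arousal))
    stop("ratings must be complete")
  rng <- function(x) max(x) - min(x)
  if (rng(valence) > cfg$max_rater_range || rng(arousal) > cfg$max_rater_range)
    return(list(label = "excluded", reason = "disagreement"))
  am <- mean(arousal)
  if (am <= cfg$arousal_low_max || am >= cfg$arousal_high_min)
    return(list(label = "excluded", reason = "arousal"))
  vm <- mean(valence)
  if (vm <= cfg$neg_valence_max) return(list(label = "negative", reason = ""))
  if (vm >= cfg$pos_valence_min) return(list(label = "positive", reason = ""))
  list(label = "excluded", reason = "neutral")
}

#' Label a whole rating matrix
#'
#' @param ratings a [rating_matrix()].
#' @param cfg a [corpus_config()].
#' @return data frame `item_id`, `label`, `reason`.
#' @export
label_corpus <- function(ratings, cfg = corpus_config()) {
  stopifnot(inherits(ratings, "rating_matrix"))
  out <- lapply(seq_len(nrow(ratings$valence)), function(i)
    label_item(ratings$valence[i, ], ratings$arousal[i, ], cfg))
  data.frame(item_id = ratings$item_ids,
             label = vapply(out, `[[`, character(1), "label"),
             reason = vapply(out, `[[`, character(1), "reason"),
             stringsAsFactors = FALSE)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the two-way ANOVA mean squares:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with `MSR` the between-item, `MSC` the between-rater and `MSE` the
#' residual mean square, `n` items and `k` raters.
#'
#' @param mat numeric matrix, items x raters, no missing cells.
#' @return the ICC (`NA` when total variance is zero).
#' @export
icc_agreement <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 items and 2 raters")
  if (anyNA(mat)) stop("rating matrix must be complete")
  grand <- mean(mat)
  if (all(mat == grand)) return(NA_real_)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Select a stimulus session from a labelled corpus
#'
#' Draws, uniformly at random without replacement, `session_pos` positive
#' and `session_neg` negative items the participant has not seen before.
#' Deterministic under `seed`.
#'
#' @param labels a [label_corpus()] result.
#' @param history character vector of item ids already presented to the
#'   participant.
#' @param cfg a [corpus_config()].
#' @param seed integer seed.
#' @return character vector of `session_pos + session_neg` item ids
#'   (positives first).
#' @export
select_session <- function(labels, history = character(0),
                           cfg = corpus_config(), seed = 1L) {
  avail <- labels[!(labels$item_id %in% history), ]
  pos <- avail$item_id[avail$label == "positive"]
  neg <- avail$item_id[avail$label == "negative"]
  if (length(pos) < cfg$session_pos)
    stop(sprintf("insufficient unseen positive items (%d < %d)",
                 length(pos), cfg$session_pos))
  if (length(neg) < cfg$session_neg)
    stop(sprintf("insufficient unseen negative items (%d < %d)",
                 length(neg), cfg$session_neg))
  with_local_seed(substream_seed(seed, "session-select"), {
    c(sample(pos, cfg$session_pos), sample(neg, cfg$session_neg))
  })
}
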