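#' Generate a synthetic rater matrix for a stimulus corpus
#'
#' Emulates the corpus-annotation protocol: `n_items` news items rated by
#' `n_raters` independent evaluators on 1-9 Likert scales, separately for
#' valence and arousal. Each item has a latent true score; raters add
#' independent Gaussian noise; ratings are rounded and clipped to the scale.
#' The `profile` controls the item-truth spread and rater noise, so
#' inter-rater reliability (ICC) is tunable: with item SD `s_i` and rater
#' noise SD `s_e`, the population single-measure ICC is approximately
#' `s_i^2 / (s_i^2 + s_e^2)` (rounding to integers attenuates it slightly).
#'
#' @param n_items number of items (default 186).
#' @param n_raters number of raters (at least 2; default 3).
#' @param profile list with `valence_mean`, `valence_sd`, `arousal_mean`,
#'   `arousal_sd` (item-truth distributions) and `rater_sd` (rater noise).
#' @param seed integer seed.
#' @return object of class `rating_matrix`: list with integer matrices
#'   `valence` and `arousal` (items x raters, entries 1-9) and `item_ids`.
#' @export
generate_rating_matrix <- function(n_items = 186L, n_raters = 3L,
                                   profile = list(valence_mean = 5,
                                                  valence_sd = 2,
                                                  arousal_mean = 5,
                                                  arousal_sd = 1.5,
                                                  rater_sd = 0.8),
                                   seed = 1L) {
  if (n_raters < 2L) stop("at least 2 raters are required")
  with_local_seed(substream_seed(seed, "ratings"), {
    rate <- function(truth) {
      noise <- matrix(rnorm(n_items * n_raters, 0, profile$rater_sd),
                      n_items, n_raters)
      m <- round(truth + noise)
      matrix(as.integer(clamp(m, 1L, 9L)), n_items, n_raters)
    }
    val <- rate(rnorm(n_items, profile$valence_mean, profile$valence_sd))
    aro <- rate(rnorm(n_items, profile$arousal_mean, profile$arousal_sd))
    rating_matrix(val, aro, sprintf("item%04d", seq_len(n_items)))
  })
}

#' Construct a rating matrix object
#'
#' @param valence,arousal integer matrices (items x raters) with entries 1-9.
#' @param item_ids optional item identifiers.
#' @return object of class `rating_matrix`.
#' @export
rating_matrix <- function(valence, arousal, item_ids = NULL) {
  valence <- as.matrix(valence); arousal <- as.matrix(arousal)
  if (!all(dim(valence) == dim(arousal)))
    stop("valence and arousal planes must have identical dimensions")
  if (ncol(valence) < 2L) stop("at least 2 raters are required")
  for (m in list(valence, arousal))
    if (any(is.na(m)) || any(m < 1 | m > 9) || any(m != round(m)))
      stop("ratings must be integers in 1..9")
  if (is.null(item_ids)) item_ids <- sprintf("item%04d", seq_len(nrow(valence)))
  structure(list(valence = valence, arousal = arousal,
                 item_ids = as.character(item_ids)),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("rating_matrix: %d items x %d raters (valence + arousal, 1-9)\n",
              nrow(x$valence), ncol(x$valence)))
  invisible(x)
}
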