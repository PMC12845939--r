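#' Confusion-matrix metrics
#'
#' Accuracy `(tp+tn)/n`, sensitivity (recall) `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, precision `tp/(tp+fp)`, and F1 (harmonic mean of precision
#' and sensitivity). Metrics with a zero denominator are reported as `NA`
#' (undefined), never as an error.
#'
#' @param tn,fp,fn,tp non-negative integer cell counts (true/false
#'   negatives/positives).
#' @return list of class `confusion_metrics` with the counts and metrics.
#' @export
confusion_metrics <- function(tn, fp, fn, tp) {
  cells <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  n <- sum(cells)
  if (n == 0) stop("empty confusion matrix")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
  else 2 * prec * sens / (prec + sens)
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp, n = n,
                 accuracy = (tp + tn) / n, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("Confusion matrix (rows: actual, cols: predicted)\n")
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(c("actual neg", "actual pos"),
                              c("pred neg", "pred pos")))
  print(m)
  cat(sprintf("accuracy %.4f  sensitivity %.4f  specificity %.4f  precision %.4f  F1 %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Decision rule `p >= t` is positive. Points are swept over all distinct
#' scores; the curve starts at (0, 0) and ends at (1, 1); AUC is the
#' trapezoidal area, which equals the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg` (ties counted half).
#'
#' @param probabilities numeric scores.
#' @param labels binary labels (0/1 or logical), 1 = positive.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc` (`NA` when only one class is present).
#' @export
roc_auc <- function(probabilities, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    return(list(points = NULL, auc = NA_real_))
  np <- sum(y == 1); nn <- sum(y == 0)
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(probabilities >= t & y == 1) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(probabilities >= t & y == 0) / nn,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Sensitivity/specificity at fixed probability thresholds
#'
#' The trade-off table of the screening probability: `p >= t` is classified
#' positive (inclusive).
#'
#' @param probabilities numeric scores in `[0, 1]`.
#' @param labels binary labels.
#' @param thresholds probability thresholds (default 0.4, 0.5, 0.6).
#' @return data frame `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
threshold_sweep <- function(probabilities, labels,
                            thresholds = c(0.4, 0.5, 0.6)) {
  y <- as.integer(labels)
  do.call(rbind, lapply(thresholds, function(t) {
    pred <- as.integer(probabilities >= t)
    cm <- confusion_metrics(sum(pred == 0 & y == 0), sum(pred == 1 & y == 0),
                            sum(pred == 0 & y == 1), sum(pred == 1 & y == 1))
    data.frame(threshold = t, sensitivity = cm$sensitivity,
               specificity = cm$specificity, accuracy = cm$accuracy)
  }))
}

#' Two-group comparison statistics
#'
#' Pooled-variance two-sample t test (df = `nA + nB - 2`), Cohen's d with
#' pooled SD, Mann-Whitney U (normal approximation for the p value), and
#' per-group Shapiro-Wilk normality screens.
#'
#' @param a,b numeric vectors (each of length at least 2).
#' @return list of class `group_stats`.
#' @export
group_stats <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  d <- if (sp2 == 0) NA_real_ else (mean(a) - mean(b)) / sqrt(sp2)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  shapiro_p <- function(x) {
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  structure(list(t = unname(tt$statistic), df = na + nb - 2,
                 p = tt$p.value, cohen_d = d,
                 mann_whitney_u = unname(wt$statistic), mw_p = wt$p.value,
                 normal_a = shapiro_p(a), normal_b = shapiro_p(b),
                 mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.3g; Cohen d = %.3f; Mann-Whitney U = %.1f (p = %.3g)\n",
              x$df, x$t, x$p, x$cohen_d, x$mann_whitney_u, x$mw_p))
  cat(sprintf("means %.3f vs %.3f (n = %d, %d); Shapiro p: %.3g / %.3g\n",
              x$mean_a, x$mean_b, x$n_a, x$n_b, x$normal_a, x$normal_b))
  invisible(x)
}

#' Participant-level train/validation/test split
#'
#' Splits participants (not stimuli) into train/validation/test fractions to
#' prevent stimulus-level leakage; stratified by label.
#'
#' @param participant_id participant of each row (or the unique ids).
#' @param labels binary label per participant (aligned with
#'   `unique(participant_id)` order if per-row).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return named list of participant-id character vectors `train`,
#'   `validation`, `test`.
#' @export
participant_split <- function(participant_id, labels,
                              fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  ids <- unique(participant_id)
  lab <- labels[match(ids, unique(participant_id))]
  with_local_seed(substream_seed(seed, "split"), {
    out <- list(train = character(0), validation = character(0),
                test = character(0))
    for (cl in unique(lab)) {
      g <- sample(ids[lab == cl])
      n <- length(g)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      out$train <- c(out$train, g[seq_len(n_tr)])
      out$validation <- c(out$validation, g[n_tr + seq_len(min(n_va, n - n_tr))])
      out$test <- c(out$test, g[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
    out
  })
}
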