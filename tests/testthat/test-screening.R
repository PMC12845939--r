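test_that("stimulus flagging is sign-gated and boundary-inclusive", {
  cfg <- rule_config()
  expect_false(flag_stimulus(c(PDA = 0, PDV = 0, FD = 0), "neg", cfg))
  expect_true(flag_stimulus(c(PDA = 2.5, PDV = 2.2, FD = 0.5), "neg", cfg))
  # "at least 2 SD" is inclusive, also in all-features mode
  all_cfg <- rule_config(mode = "all")
  expect_true(flag_stimulus(c(PDA = 2, PDV = 2, FD = 2), "neg", all_cfg))
  # positive stimuli gate the pupil features in the blunted direction
  expect_true(flag_stimulus(c(PDA = -2.5, PDV = -2.1, FD = 0), "pos", cfg))
  expect_false(flag_stimulus(c(PDA = 2.5, PDV = 2.1, FD = 0), "pos", cfg))
  # missing z counts as non-deviant
  expect_false(flag_stimulus(c(PDA = NA, PDV = 2.5, FD = NA), "neg", cfg))
  expect_error(flag_stimulus(c(PDA = 1, PDV = 1, FD = 1), "meh", cfg),
               "valence")
})

test_that("raising a gated deviation never un-flags; raising k never flags more", {
  cfg <- rule_config()
  set.seed(6)
  for (i in 1:200) {
    z <- c(PDA = rnorm(1, 0, 2), PDV = rnorm(1, 0, 2), FD = rnorm(1, 0, 2))
    v <- sample(c("pos", "neg"), 1)
    f0 <- flag_stimulus(z, v, cfg)
    dirs <- cfg$direction[[v]]
    j <- sample(3, 1)
    z2 <- z; z2[j] <- z2[j] + dirs[[names(z)[j]]] * runif(1, 0, 3)
    if (f0) expect_true(flag_stimulus(z2, v, cfg))
    f_hi <- flag_stimulus(z, v, rule_config(k_sd = cfg$k_sd + runif(1, 0, 2)))
    expect_true(f0 || !f_hi)
  }
})

test_that("participant rule equals the >= 3 of 6 enumeration oracle", {
  cfg <- rule_config()
  expect_equal(classify_rule(rep(FALSE, 6), cfg), "non-depressive")
  expect_equal(classify_rule(c(rep(TRUE, 3), rep(FALSE, 3)), cfg),
               "depressive-pattern")
  expect_equal(classify_rule(c(rep(TRUE, 2), rep(FALSE, 4)), cfg),
               "non-depressive")
  # all 2^6 flag patterns against direct enumeration
  for (m in 0:63) {
    flags <- as.logical(bitwAnd(m, 2^(0:5)) > 0)
    expect_equal(classify_rule(flags, cfg),
                 if (sum(flags) >= 3) "depressive-pattern" else "non-depressive")
  }
  expect_error(classify_rule(c(TRUE, FALSE), cfg), "at least 3")
})

test_that("logistic scoring and odds ratios follow the model form", {
  b <- c(`(Intercept)` = 0, PDA_neg = 0, PDA_pos = 0, FD = 0)
  expect_equal(logistic_score(b, c(PDA_neg = 20, PDA_pos = 5, FD = 300)), 0.5)
  expect_equal(round(odds_ratio(0.085), 2), 1.09)
  expect_equal(round(odds_ratio(-0.11), 2), 0.90)
  expect_equal(odds_ratio(0.085), exp(0.085))
  expect_error(logistic_score(b, c(PDA_neg = Inf, PDA_pos = 1, FD = 2)),
               "finite")
  expect_error(logistic_score(b, c(PDA_neg = 1, PDA_pos = 2)), "finite")
})

test_that("maximum-likelihood fitting recovers known coefficients", {
  set.seed(15)
  n <- 5000
  X <- data.frame(PDA_neg = rnorm(n, 22, 8), PDA_pos = rnorm(n, 3, 5),
                  FD = rnorm(n, 300, 50))
  beta <- c(PDA_neg = 0.085, PDA_pos = -0.11, FD = 0.007)
  eta <- -3.2 + as.matrix(X) %*% beta
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fit_logistic(X, y)
  for (v in names(beta))
    expect_lt(abs(fit$coefficients[[v]] - beta[[v]]), 3 * fit$se[[v]])
  expect_gt(fit$nagelkerke, 0)
  expect_lt(fit$lr_p, 1e-6)

  # null data: slopes within 3 SE of zero
  y0 <- rbinom(n, 1, 0.4)
  fit0 <- fit_logistic(X, y0)
  for (v in names(beta))
    expect_lt(abs(fit0$coefficients[[v]]), 3 * fit0$se[[v]])

  # intercept-only fit has Nagelkerke R2 exactly zero
  expect_equal(fit_logistic(NULL, y)$nagelkerke, 0)

  # frozen published slopes: only the intercept is estimated
  ffix <- fit_logistic(X, y, fixed_coef = published_logit_slopes())
  expect_equal(unname(ffix$coefficients[names(beta)]),
               unname(published_logit_slopes()[names(beta)]))

  # perfect separation is an error, not a silent fit
  Xs <- data.frame(x = c(rnorm(50, -5), rnorm(50, 5)))
  ys <- rep(0:1, each = 50)
  expect_error(fit_logistic(Xs, ys), "separation")
})

test_that("confusion metrics reproduce the reported operating point", {
  cm <- confusion_metrics(tn = 145, fp = 16, fn = 11, tp = 70)
  expect_equal(cm$n, 242)
  expect_equal(round(cm$accuracy, 4), 0.8884)
  expect_equal(round(cm$specificity, 4), 0.9006)
  expect_equal(round(cm$sensitivity, 4), 0.8642)
  expect_equal(round(cm$precision, 4), 0.8140)
  expect_equal(round(cm$f1, 4), 0.8383)

  # accuracy identity: (sens*P + spec*N) / (P + N)
  set.seed(2)
  for (i in 1:25) {
    cells <- rpois(4, 20) + c(1, 0, 0, 1)
    m <- confusion_metrics(cells[1], cells[2], cells[3], cells[4])
    P <- m$tp + m$fn; N <- m$tn + m$fp
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
  }

  # zero denominators yield NA, not errors
  expect_true(is.na(confusion_metrics(0, 0, 2, 5)$specificity))
  expect_true(is.na(confusion_metrics(5, 2, 0, 0)$sensitivity))
  expect_error(confusion_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("ROC/AUC equals the normalised Mann-Whitney statistic", {
  # inclusive decision rule p >= t: the tied 0.8 negative counts positive
  pos <- c(0.9, 0.8); neg <- c(0.8, 0.1)
  sw <- threshold_sweep(c(pos, neg), c(1, 1, 0, 0), thresholds = 0.75)
  expect_equal(sw$sensitivity, 1.0)
  expect_equal(sw$specificity, 0.5)
  expect_equal(roc_auc(c(pos, neg), c(1, 1, 0, 0))$auc, 0.875)  # tie = 1/2

  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)

  set.seed(19)
  p <- runif(2000); y <- rbinom(2000, 1, 0.5)
  ra <- roc_auc(p, y)
  expect_lt(abs(ra$auc - 0.5), 0.05)
  # identity with U / (n1 * n0)
  U <- unname(stats::wilcox.test(p[y == 1], p[y == 0], exact = FALSE)$statistic)
  expect_equal(ra$auc, U / (sum(y == 1) * sum(y == 0)), tolerance = 1e-10)
  # invariant under strictly monotone transforms
  expect_equal(roc_auc(stats::qlogis(p), y)$auc, ra$auc)
  # curve anchors and monotonicity
  expect_equal(ra$points$fpr[1], 0); expect_equal(ra$points$tpr[1], 0)
  expect_equal(utils::tail(ra$points$fpr, 1), 1)
  expect_true(all(diff(ra$points$tpr) >= 0))
  # single-class labels leave AUC undefined
  expect_true(is.na(roc_auc(p, rep(1, 2000))$auc))

  # cross-check against an independent ROC implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    ext <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ra$auc, ext, tolerance = 1e-10)
  }
})

test_that("threshold sweep trades sensitivity against specificity", {
  set.seed(23)
  y <- rbinom(500, 1, 0.33)
  p <- plogis(rnorm(500, ifelse(y == 1, 1, -1)))
  sw <- threshold_sweep(p, y)
  expect_equal(sw$threshold, c(0.4, 0.5, 0.6))
  expect_true(all(diff(sw$sensitivity) <= 0))
  expect_true(all(diff(sw$specificity) >= 0))
})

test_that("group statistics match hand-computed oracles", {
  g0 <- group_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g0$t, 0); expect_equal(g0$cohen_d, 0)

  g <- group_stats(c(1, 2, 3), c(3, 4, 5))
  expect_equal(g$cohen_d, -2.0)                 # pooled SD = 1
  expect_equal(g$t, -2.449, tolerance = 1e-3)
  expect_equal(g$df, 4)
  # direction convention: d sign follows the mean difference
  expect_equal(group_stats(c(3, 4, 5), c(1, 2, 3))$cohen_d, 2.0)
  expect_equal(g$mann_whitney_u,
               unname(stats::wilcox.test(c(1, 2, 3), c(3, 4, 5),
                                         exact = FALSE)$statistic))

  # power at the reported group parameters
  set.seed(29)
  sig <- vapply(1:200, function(i) {
    group_stats(stats::rnorm(161, 18.4, 6.7), stats::rnorm(81, 27.9, 8.3))$p
  }, numeric(1))
  expect_gte(mean(sig < 0.001), 0.99)

  expect_error(group_stats(1, c(1, 2)), "at least 2")
})

test_that("screening pipeline separates the groups on the default cohort", {
  coh <- generate_cohort(cohort_config(seed = 17), traces = FALSE)
  feats <- coh$features
  prof <- build_baseline(feats[feats$session_type == "reference", ])
  res <- screen_participants(feats[feats$session_type == "screening", ],
                             prof, rule_config())
  truth <- coh$participants$group[match(res$participant_id,
                                        coh$participants$participant_id)]
  pred <- res$rule_label == "depressive-pattern"
  cm <- confusion_metrics(sum(!pred & truth == "control"),
                          sum(pred & truth == "control"),
                          sum(!pred & truth == "depressed"),
                          sum(pred & truth == "depressed"))
  expect_gt(cm$sensitivity, 0.5)
  expect_gt(cm$specificity, 0.5)
})

test_that("held-out AUC of the logistic pipeline is stable across seeds", {
  aucs <- vapply(1:25, logit_pipeline_auc, numeric(1), holdout = "both")
  expect_lt(stats::sd(aucs), 0.04)
  expect_gt(mean(aucs), 0.85)
})

test_that("sequence classifier is deterministic and learns a separable cohort", {
  # strongly separable cohort: tripled group contrasts
  fe <- default_feature_effects()
  fe$depressed_mean <- fe$control_mean + 3 * (fe$depressed_mean - fe$control_mean)
  coh <- generate_cohort(cohort_config(n_total = 48, n_depressed = 16,
                                       feature_effects = fe, seed = 33),
                         traces = FALSE)
  w <- simulate_feature_windows(coh, seed = 33)
  cfg <- seq_config(n_kernels = 100, seed = 33)
  m1 <- train_seq_classifier(w, cfg)
  m2 <- train_seq_classifier(w, cfg)
  expect_identical(m1$test$prob, m2$test$prob)   # deterministic under seed
  held <- w$participant_id %in% c(m1$split$validation, m1$split$test)
  pr <- predict(m1, w, subset = held)
  expect_gte(roc_auc(pr$prob, pr$label)$auc, 0.95)
})
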