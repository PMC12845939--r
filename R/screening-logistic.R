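#' Fit the logistic depressive-status model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `glm`) of depressive status on the feature battery, with fit
#' diagnostics: likelihood-ratio chi-square against the intercept-only model
#' and Nagelkerke pseudo R-squared,
#' `R2 = (1 - exp((2/n) (ll0 - ll1))) / (1 - exp((2/n) ll0))`.
#'
#' Slopes can be frozen at externally given values (e.g. published
#' coefficients) via `fixed_coef`; the intercept is then fit on the data
#' through an offset.
#'
#' @param X numeric matrix or data frame of predictors.
#' @param y binary response (0/1, logical, or factor with 2 levels).
#' @param fixed_coef optional named vector of slopes to freeze; only the
#'   intercept is estimated.
#' @return object of class `dep_logit` with `coefficients`, `se`,
#'   `intercept_only_ll`, `ll`, `lr_chisq`, `lr_df`, `lr_p`, `nagelkerke`,
#'   `n`, `fitted`.
#' @export
fit_logistic <- function(X, y, fixed_coef = NULL) {
  X <- if (is.null(X)) data.frame(row.names = seq_along(y)) else as.data.frame(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("response must contain both classes")
  if (ncol(X) && any(!is.finite(as.matrix(X)))) stop("predictors must be finite")
  n <- length(y)

  if (ncol(X) == 0L) {
    fit <- stats::glm(y ~ 1, family = stats::binomial())
    coefs <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  } else if (!is.null(fixed_coef)) {
    miss <- setdiff(names(fixed_coef), names(X))
    if (length(miss)) stop("fixed_coef names absent from X: ",
                           paste(miss, collapse = ", "))
    off <- as.matrix(X[names(fixed_coef)]) %*% fixed_coef
    fit <- stats::glm(y ~ 1, family = stats::binomial(), offset = off)
    coefs <- c(`(Intercept)` = unname(stats::coef(fit)[1]), fixed_coef)
    se <- c(sqrt(diag(stats::vcov(fit))), rep(NA_real_, length(fixed_coef)))
    names(se) <- names(coefs)
  } else {
    dat <- cbind(.y = y, X)
    warned_sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w)))
          warned_sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs <- stats::coef(fit)
    if (warned_sep && all(abs(stats::fitted(fit) - y) < 1e-3))
      stop("perfect (or quasi-perfect) separation; consider a penalised fit",
           call. = FALSE)
    se <- sqrt(diag(stats::vcov(fit)))
  }

  ll1 <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(y ~ 1, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(fit0))
  lr <- 2 * (ll1 - ll0)
  df <- length(coefs) - 1L
  r2 <- (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
  structure(list(coefficients = coefs, se = se, ll = ll1,
                 intercept_only_ll = ll0, lr_chisq = lr, lr_df = df,
                 lr_p = stats::pchisq(lr, max(df, 1), lower.tail = FALSE),
                 nagelkerke = r2, n = n,
                 fitted = as.numeric(stats::fitted(fit)),
                 terms = names(X)),
            class = "dep_logit")
}

#' @export
print.dep_logit <- function(x, ...) {
  cat("Logistic depressive-status model\n")
  cat(sprintf("  n = %d, LR chi2(%d) = %.2f (p = %.3g), Nagelkerke R2 = %.3f\n",
              x$n, x$lr_df, x$lr_chisq, x$lr_p, x$nagelkerke))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.dep_logit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    odds_ratio = exp(object$coefficients))
  print(object)
  cat("\n")
  print(round(tab, 4))
  invisible(tab)
}

#' @export
coef.dep_logit <- function(object, ...) object$coefficients

#' @export
predict.dep_logit <- function(object, newdata, type = "response", ...) {
  X <- as.data.frame(newdata)
  b <- object$coefficients
  eta <- b[["(Intercept)"]] +
    as.matrix(X[setdiff(names(b), "(Intercept)")]) %*%
    b[setdiff(names(b), "(Intercept)")]
  if (type == "link") as.numeric(eta) else 1 / (1 + exp(-as.numeric(eta)))
}

#' Probability from a coefficient set
#'
#' `p = 1 / (1 + exp(-(intercept + sum(beta * x))))`.
#'
#' @param model a `dep_logit`, or a named coefficient vector including
#'   `(Intercept)`.
#' @param features named numeric vector (or one-row data frame) of
#'   predictors; all model features must be present and finite.
#' @return probability in (0, 1).
#' @export
logistic_score <- function(model, features) {
  b <- if (inherits(model, "dep_logit")) model$coefficients else model
  if (is.data.frame(features)) features <- unlist(features)
  vars <- setdiff(names(b), "(Intercept)")
  x <- features[vars]
  if (any(is.na(x)) || any(!is.finite(x)))
    stop("all model features must be present and finite")
  eta <- (b[["(Intercept)"]] %||% 0) + sum(b[vars] * x)
  1 / (1 + exp(-eta))
}

#' Odds ratio of a logistic coefficient
#'
#' `OR = exp(beta)`: the multiplicative change in the odds of depressive
#' status per unit increase of the predictor.
#'
#' @param beta logistic slope(s).
#' @return odds ratio(s).
#' @export
odds_ratio <- function(beta) exp(beta)

#' Published slope defaults of the predictive model
#'
#' The three printed coefficients: PDA to negative news 0.085 per %,
#' pupil response to positive news -0.11 per %, fixation duration 0.007
#' per ms.
#'
#' @return named numeric vector.
#' @export
published_logit_slopes <- function() {
  c(PDA_neg = 0.085, PDA_pos = -0.11, FD = 0.007)
}
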