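## Logistic / linear model core
##
## All analysis variables are numeric columns (0/1 indicators or bounded
## scores entered linearly), so models are fitted directly on a numeric
## design matrix through stats::glm.fit.  Separation -- likely for the 2%
## gang-membership mediator in bootstrap resamples -- is detected and
## resolved by a small ridge penalty, never silently.

#' Fit a logistic or linear model on cohort columns
#'
#' Maximum-likelihood logistic regression (IRLS, deviance tolerance
#' \code{1e-10}) or least-squares linear regression of one outcome column
#' on a set of predictor columns, with listwise deletion of incomplete
#' rows.  Divergence diagnostic of separation (non-convergence in 100
#' iterations or any non-intercept coefficient beyond \eqn{\pm 15}) leads
#' to a refit with a small ridge penalty (\eqn{\lambda = 10^{-4}} on
#' non-intercept terms) and an annotation; the convergence flag is then
#' \code{FALSE}.
#'
#' @param data data frame holding the columns.
#' @param outcome outcome column name; must not be among the predictors.
#' @param predictors character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param family \code{"binomial"} (logit link) or \code{"gaussian"}.
#' @return an object of class \code{gc_glm}: coefficients, Wald covariance
#'   from the observed information, convergence/separation flags, number
#'   of rows used, and log-likelihood.
#' @export
fit_glm <- function(data, outcome, predictors = character(),
                    family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  if (outcome %in% predictors) stop("outcome must not be among the predictors")
  vars <- c(outcome, predictors)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[vars])
  n <- sum(cc)
  if (n == 0) stop("no listwise-complete rows for this model")
  if (n < length(predictors) + 1L)
    stop("fewer complete rows (", n, ") than coefficients (",
         length(predictors) + 1L, ")")
  y <- data[[outcome]][cc]
  X <- cbind("(Intercept)" = 1,
             as.matrix(data[cc, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  fit_glm_mat(X, y, family, outcome, predictors)
}

## matrix-level fitter shared with fit_model_system (which converts the
## complete-case data to a matrix once for all component models)
fit_glm_mat <- function(X, y, family, outcome, predictors) {
  n <- length(y)
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam,
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  separated <- family == "binomial" &&
    (!fit$converged || anyNA(beta) || any(abs(beta[-1]) > 15))
  note <- NULL
  if (separated) {
    rf <- ridge_logit(X, y, lambda = 1e-4)
    beta <- rf$beta
    vc <- rf$vcov
    ll <- rf$loglik
    note <- "separation detected; ridge-penalized (lambda = 1e-4) estimates"
  } else {
    w <- fit$weights
    info <- crossprod(X * sqrt(w))
    if (family == "gaussian") {
      sigma2 <- sum(fit$residuals^2) / (n - ncol(X))
      vc <- solve(info) * sigma2
      ll <- -0.5 * n * (log(2 * pi * sum(fit$residuals^2) / n) + 1)
    } else {
      vc <- solve(info)
      mu <- fit$fitted.values
      ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    }
  }
  dimnames(vc) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = vc,
                 converged = !separated, separation = separated, note = note,
                 n = n, loglik = ll, family = family, outcome = outcome,
                 predictors = predictors),
            class = "gc_glm")
}

## Ridge-penalized logistic IRLS; penalty excluded from the intercept.
ridge_logit <- function(X, y, lambda = 1e-4, maxit = 200, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X * sqrt(w)) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(grad)) < tol) break
  }
  names(beta) <- colnames(X)
  mu <- expit(drop(X %*% beta))
  list(beta = beta, vcov = solve(H),
       loglik = sum(y * log(mu) + (1 - y) * log1p(-mu)))
}

#' @export
print.gc_glm <- function(x, ...) {
  cat(sprintf("<gc_glm> %s model of '%s' on %d predictor(s), n = %d\n",
              x$family, x$outcome, length(x$predictors), x$n))
  if (x$separation) cat("  note:", x$note, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Odds ratio (or coefficient) with Wald confidence interval
#'
#' For logistic fits returns \eqn{OR = e^b} with the interval
#' \eqn{e^{b \pm 1.96\,SE}} and a two-sided Wald p-value; for linear fits
#' returns the coefficient and interval on the identity scale.
#'
#' @param model a \code{gc_glm} fit.
#' @param term coefficient name.
#' @param conf confidence level (default 0.95).
#' @return a one-row data frame: term, estimate, lower, upper, p, scale.
#' @export
odds_ratio_ci <- function(model, term, conf = 0.95) {
  if (!term %in% names(model$coefficients))
    stop("term '", term, "' not among fitted coefficients")
  b <- model$coefficients[[term]]
  se <- sqrt(model$vcov[term, term])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- 2 * stats::pnorm(-abs(b / se))
  if (model$family == "binomial") {
    data.frame(term = term, estimate = exp(b), lower = exp(b - z * se),
               upper = exp(b + z * se), p = p, scale = "odds_ratio",
               stringsAsFactors = FALSE)
  } else {
    data.frame(term = term, estimate = b, lower = b - z * se,
               upper = b + z * se, p = p, scale = "coefficient",
               stringsAsFactors = FALSE)
  }
}

#' Staged association table
#'
#' One fresh model fit per (predictor, outcome) pair and adjustment stage,
#' mirroring staged exposure-mediator and mediator-outcome analyses: each
#' stage is a named set of adjustment covariates added to the predictor of
#' interest.  Fitting errors are annotated per row; the table is still
#' returned.
#'
#' @param cohort data frame.
#' @param pairs data frame with character columns \code{predictor} and
#'   \code{outcome}, one row per association of interest.
#' @param stages named list of character vectors; each vector is the
#'   adjustment set of that stage (use \code{character()} for unadjusted).
#'   The outcome and predictor are removed from the set automatically.
#' @return a data frame with one row per pair and stage: estimate (OR for
#'   binary outcomes, coefficient for numeric), Wald 95\% CI, p-value,
#'   formatted p (floored at \code{"<0.001"}), n used, convergence flag,
#'   and an annotation column.
#' @export
association_table <- function(cohort, pairs, stages) {
  stopifnot(is.data.frame(pairs), all(c("predictor", "outcome") %in% names(pairs)))
  if (is.null(names(stages)) || any(names(stages) == ""))
    stop("stages must be a named list of adjustment sets")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pred <- pairs$predictor[i]; out <- pairs$outcome[i]
    fam <- if (is_binary_col(cohort[[out]])) "binomial" else "gaussian"
    for (s in names(stages)) {
      adj <- setdiff(stages[[s]], c(pred, out))
      row <- tryCatch({
        fit <- fit_glm(cohort, out, c(pred, adj), family = fam)
        est <- odds_ratio_ci(fit, pred)
        data.frame(predictor = pred, outcome = out, stage = s,
                   estimate = est$estimate, lower = est$lower,
                   upper = est$upper, p = est$p,
                   p_formatted = format_p(est$p), n = fit$n,
                   converged = fit$converged,
                   note = if (is.null(fit$note)) "" else fit$note,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(predictor = pred, outcome = out, stage = s,
                   estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                   p = NA_real_, p_formatted = "", n = NA_integer_,
                   converged = FALSE, note = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Format a p-value for reporting
#'
#' Three decimals with a \code{"<0.001"} floor.
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}
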