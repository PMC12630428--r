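## Multivariate imputation by chained equations and Rubin's-rules pooling.
##
## Cyclic conditional imputation: binary columns by logistic draws,
## numeric columns by linear draws with noise, each conditional model's
## parameters drawn from their approximate sampling distribution so that
## between-imputation variance is properly propagated.  Every other
## column of the table (including auxiliary columns outside the analysis
## roles) serves as a predictor in each conditional model.

#' Multiple imputation by chained equations
#'
#' Produces \code{m} completed copies of a cohort.  After initializing
#' missing cells by simple random draws from the observed values of their
#' column, the sampler sweeps \code{iterations} times over the incomplete
#' columns in increasing order of missingness; each sweep refits the
#' column's conditional model (logistic for binary columns, Gaussian
#' linear for numeric) on the currently completed data, draws coefficients
#' from their approximate posterior, and redraws the missing cells
#' stochastically (binary cells from the predicted probability, numeric
#' cells with residual noise).  Observed cells are never altered.
#'
#' @param cohort data frame with missing cells; every column must be
#'   numeric (binary 0/1 or numeric score).
#' @param m number of completed data sets.
#' @param iterations chained-equation sweeps per data set.
#' @param seed integer root seed; the same \code{(cohort, m, seed)} gives
#'   an identical imputation set.
#' @return an object of class \code{imputation_set}: list of \code{m}
#'   completed data frames plus metadata.
#' @export
impute_chained <- function(cohort, m = 40, iterations = 10, seed = 1L) {
  stopifnot(m >= 1, iterations >= 1)
  n <- nrow(cohort)
  miss_frac <- vapply(cohort, function(x) mean(is.na(x)), numeric(1))
  all_miss <- names(miss_frac)[miss_frac >= 1]
  if (length(all_miss))
    stop("cannot impute: column(s) 100% missing: ",
         paste(all_miss, collapse = ", "))
  if (!any(miss_frac > 0)) {
    completed <- replicate(m, cohort, simplify = FALSE)
  } else {
    targets <- names(sort(miss_frac[miss_frac > 0]))
    families <- vapply(cohort[targets], function(x)
      if (is_binary_col(x)) "binomial" else "gaussian", character(1))
    completed <- lapply(seq_len(m), function(im) {
      impute_one(cohort, targets, families, iterations,
                 derive_seed(seed, im))
    })
  }
  structure(list(completed = completed, m = m, iterations = iterations,
                 seed = seed,
                 families = if (any(miss_frac > 0)) families else character(),
                 missing_fraction = miss_frac),
            class = "imputation_set")
}

impute_one <- function(cohort, targets, families, iterations, seed) {
  set.seed(seed)
  data <- cohort
  na_idx <- lapply(cohort[targets], function(x) which(is.na(x)))
  ## random-fill initialization from observed values
  for (nm in targets) {
    obs <- cohort[[nm]][!is.na(cohort[[nm]])]
    data[[nm]][na_idx[[nm]]] <- sample(obs, length(na_idx[[nm]]),
                                       replace = TRUE)
  }
  preds_of <- lapply(stats::setNames(nm = targets),
                     function(nm) setdiff(names(cohort), nm))
  for (it in seq_len(iterations)) {
    for (nm in targets) {
      idx <- na_idx[[nm]]
      obs_rows <- setdiff(seq_len(nrow(data)), idx)
      X <- cbind(1, as.matrix(data[preds_of[[nm]]]))
      y <- data[[nm]][obs_rows]
      draw <- impute_draw(X[obs_rows, , drop = FALSE], y,
                          X[idx, , drop = FALSE], families[[nm]])
      data[[nm]][idx] <- draw
    }
  }
  data
}

## Fit the conditional model, perturb its parameters by a draw from the
## approximate posterior, and draw replacement values for missing cells.
impute_draw <- function(Xobs, y, Xmis, family) {
  fit <- tryCatch({
    fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
    suppressWarnings(stats::glm.fit(Xobs, y, family = fam,
                                    control = stats::glm.control(maxit = 50)))
  }, error = function(e) NULL)
  n_mis <- nrow(Xmis)
  if (is.null(fit)) {
    ## degenerate conditional model: fall back to marginal draws
    return(sample(y, n_mis, replace = TRUE))
  }
  beta <- fit$coefficients
  if (anyNA(beta)) {             # rank deficiency: drop aliased columns
    keep <- !is.na(beta)
    Xobs <- Xobs[, keep, drop = FALSE]
    Xmis <- Xmis[, keep, drop = FALSE]
    beta <- beta[keep]
  }
  w <- fit$weights
  info <- crossprod(Xobs * sqrt(w))
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (family == "gaussian") {
    rss <- sum(fit$residuals^2)
    df <- max(length(y) - ncol(Xobs), 1L)
    sigma2 <- rss / stats::rchisq(1L, df)
    if (!is.null(V)) V <- V * sigma2
  }
  if (!is.null(V)) {
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (!is.null(R))
      beta <- beta + drop(t(R) %*% stats::rnorm(length(beta)))
  }
  eta <- drop(Xmis %*% beta)
  if (family == "binomial") {
    p <- pmin(pmax(expit(eta), 1e-8), 1 - 1e-8)
    stats::rbinom(n_mis, 1L, p)
  } else {
    eta + stats::rnorm(n_mis, 0, sqrt(sigma2))
  }
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed data sets, %d sweep(s)\n",
              x$m, x$iterations))
  mf <- x$missing_fraction[x$missing_fraction > 0]
  if (length(mf))
    cat("  imputed columns:",
        paste(sprintf("%s (%.1f%%)", names(mf), 100 * mf), collapse = ", "),
        "\n")
  else cat("  no missing cells; copies of the input\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point = mean of the points; within-variance = mean squared SE;
#' between-variance = sample variance of the points; total variance =
#' within + (1 + 1/m) between.  The confidence interval uses the normal
#' reference by default; the small-sample Barnard-Rubin degrees-of-freedom
#' correction is available behind \code{df_correction}.
#'
#' @param points numeric vector of per-imputation estimates on a pooling
#'   scale (e.g. log odds ratios).
#' @param ses numeric vector of matching standard errors (finite).
#' @param conf confidence level.
#' @param df_correction use the Barnard-Rubin t reference instead of the
#'   normal.
#' @return a list: pooled point, within/between/total variance, SE, CI
#'   bounds, m, and the reference degrees of freedom.
#' @export
pool_rubin <- function(points, ses, conf = 0.95, df_correction = FALSE) {
  if (length(points) != length(ses)) stop("points and ses differ in length")
  if (length(points) < 1L) stop("need at least one estimate")
  if (any(!is.finite(points)) || any(!is.finite(ses)))
    stop("estimates and standard errors must be finite")
  m <- length(points)
  qbar <- mean(points)
  within <- mean(ses^2)
  between <- if (m > 1L) stats::var(points) else 0
  total <- within + (1 + 1 / m) * between
  se <- sqrt(total)
  alpha <- 1 - conf
  if (df_correction && m > 1L && between > 0) {
    df <- (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
    q <- stats::qt(1 - alpha / 2, df)
  } else {
    df <- Inf
    q <- stats::qnorm(1 - alpha / 2)
  }
  list(estimate = qbar, within = within, between = between, total = total,
       se = se, lower = qbar - q * se, upper = qbar + q * se, m = m, df = df)
}

#' Mediation analysis on multiply imputed data
#'
#' Runs \code{\link{bootstrap_effects}} within each completed data set and
#' pools each effect on its log-odds-ratio (or mean-difference) scale by
#' Rubin's rules, with the bootstrap variance as the within-imputation
#' variance.
#'
#' @inheritParams bootstrap_effects
#' @param m number of imputations.
#' @param iterations chained-equation sweeps.
#' @param imputations optional pre-computed \code{imputation_set}; when
#'   supplied, \code{m} and \code{iterations} are taken from it.
#' @return a \code{mediation_estimates} object whose \code{ci} table and
#'   effects are Rubin-pooled across imputations.
#' @export
pooled_mediation <- function(cohort, roles, outcome, m = 40, B = 50,
                             copies = 100, iterations = 10, seed = 1L,
                             baseline = roles$baseline,
                             intermediate = roles$intermediate,
                             strict = FALSE, imputations = NULL) {
  ## a complete cohort needs no pooling: the m copies would be identical,
  ## so the analysis collapses to a single run with zero between-variance
  if (!anyNA(cohort)) {
    out <- bootstrap_effects(cohort, roles, outcome, B = B, copies = copies,
                             seed = derive_seed(seed, 1L),
                             baseline = baseline,
                             intermediate = intermediate, strict = strict)
    out$ci$between <- 0
    out$meta$m <- m
    out$meta$pooling <- "rubin"
    return(out)
  }
  imp <- if (!is.null(imputations)) imputations
         else impute_chained(cohort, m = m, iterations = iterations,
                             seed = derive_seed(seed, 777L))
  m <- imp$m
  fits <- lapply(seq_len(m), function(im) {
    bootstrap_effects(imp$completed[[im]], roles, outcome, B = B,
                      copies = copies, seed = derive_seed(seed, im),
                      baseline = baseline, intermediate = intermediate,
                      strict = strict)
  })
  onlog <- fits[[1L]]$scale == "odds_ratio"
  eff_names <- fits[[1L]]$ci$effect
  pooled <- lapply(seq_along(eff_names), function(i) {
    pts <- vapply(fits, function(f)
      if (onlog) log(f$ci$estimate[i]) else f$ci$estimate[i], numeric(1))
    ses <- vapply(fits, function(f) f$ci$se[i], numeric(1))
    pool_rubin(pts, ses)
  })
  est <- vapply(pooled, `[[`, numeric(1), "estimate")
  lower <- vapply(pooled, `[[`, numeric(1), "lower")
  upper <- vapply(pooled, `[[`, numeric(1), "upper")
  if (onlog) { est <- exp(est); lower <- exp(lower); upper <- exp(upper) }
  effects <- stats::setNames(est, eff_names)
  out <- fits[[1L]]
  out$effects <- effects
  out$prevalences <- rowMeans(vapply(fits, `[[`, numeric(3), "prevalences"))
  out$pm <- proportion_mediated(effects[["TCE"]], effects[["NIE"]],
                                out$scale)
  out$ci <- data.frame(effect = eff_names, estimate = unname(est),
                       lower = unname(lower), upper = unname(upper),
                       se = vapply(pooled, `[[`, numeric(1), "se"),
                       between = vapply(pooled, `[[`, numeric(1), "between"),
                       row.names = NULL, stringsAsFactors = FALSE)
  out$meta$m <- m
  out$meta$pooling <- "rubin"
  out$meta$failed_resamples <- sum(vapply(fits, function(f)
    f$meta$failed_resamples, numeric(1)))
  out
}
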