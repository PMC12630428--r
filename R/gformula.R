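## Parametric g-computation for mediation with a mediator block and
## intermediate confounders.
##
## Estimand: with exposure-induced mediator-outcome confounders L, natural
## direct/indirect effects are not nonparametrically identified; the
## implementation targets their randomized interventional analogues.  In
## the scenario (x_direct, x_mediator): L* is drawn from its law under
## x_direct; the mediator block is drawn from its counterfactual law under
## x_mediator marginalized over an independent draw L~ of the intermediate
## confounders; the outcome is evaluated at (x_direct, L*, M).  The total
## effect contrasts (1,1) with (0,0), the direct effect (1,0) with (0,0),
## and the indirect effect (1,1) with (1,0), so on the odds-ratio scale
## TCE = NDE x NIE holds exactly by construction.

## ---- canonical enumeration form --------------------------------------

## A "gsystem" is the common enumeration form of either fitted models or
## the synthetic generator: an exposure name, a weighted support of the
## baseline-confounder rows, and coefficient vectors for every L, M and Y
## equation.

gsystem_from_params <- function(params, outcome) {
  roles <- params$roles
  sp_y <- params$vars[[outcome]]
  if (is.null(sp_y)) stop("unknown outcome: ", outcome)
  if (!identical(sp_y$type, "binary"))
    stop("unsupported configuration: exact enumeration requires a binary outcome")
  for (nm in c(roles$intermediate, roles$mediators))
    if (!identical(params$vars[[nm]]$type, "binary"))
      stop("unsupported configuration: non-binary variable '", nm, "'")
  supports <- lapply(roles$baseline, function(nm) {
    sp <- params$vars[[nm]]
    switch(sp$type,
           binary = 0:1,
           count = 0:sp$size,
           stop("unsupported configuration: numeric baseline variable '", nm, "'"))
  })
  n_c <- prod(lengths(supports))
  if (n_c > 5e5) stop("enumeration support too large (", n_c, " configurations)")
  grid <- expand.grid(stats::setNames(supports, roles$baseline),
                      KEEP.OUT.ATTRS = FALSE)
  w <- rep(1, n_c)
  for (nm in roles$baseline) {
    sp <- params$vars[[nm]]
    p <- expit(lin_pred(sp$coef, grid))
    w <- w * switch(sp$type,
                    binary = ifelse(grid[[nm]] == 1, p, 1 - p),
                    count = stats::dbinom(grid[[nm]], sp$size, p))
  }
  list(exposure = roles$exposure,
       c_vars = roles$baseline,
       c_support = as.matrix(grid), c_weights = w,
       l_models = lapply(stats::setNames(nm = roles$intermediate),
                         function(nm) params$vars[[nm]]$coef),
       m_models = lapply(stats::setNames(nm = roles$mediators),
                         function(nm) params$vars[[nm]]$coef),
       y_coef = sp_y$coef, y_family = "binomial")
}

gsystem_from_system <- function(system) {
  n <- nrow(system$c_pop)
  list(exposure = system$exposure,
       c_vars = system$c_vars,
       c_support = as.matrix(system$c_pop),
       c_weights = rep(1 / max(n, 1L), max(n, 1L)),
       l_models = lapply(system$l_models, function(m) m$coefficients),
       m_models = lapply(system$m_models, function(m) m$coefficients),
       y_coef = system$y_model$coefficients,
       y_family = system$y_model$family)
}

as_gsystem <- function(object, outcome = NULL) {
  if (inherits(object, "dgp_params")) {
    if (is.null(outcome)) stop("supply `outcome` when enumerating dgp_params")
    gsystem_from_params(object, outcome)
  } else if (inherits(object, "model_system")) {
    gsystem_from_system(object)
  } else if (is.list(object) && !is.null(object$y_coef)) {
    object
  } else stop("cannot interpret object as a g-formula system")
}

## linear-predictor pieces over the confounder support and over binary
## configuration grids; coefficient names select the relevant columns
cpart <- function(coef, CS, exposure, x) {
  nms <- intersect(setdiff(names(coef), "(Intercept)"), colnames(CS))
  val <- coef[["(Intercept)"]]
  if (exposure %in% names(coef)) val <- val + coef[[exposure]] * x
  if (length(nms))
    val <- val + drop(CS[, nms, drop = FALSE] %*% coef[nms])
  else val <- rep.int(val, nrow(CS))
  val
}

gpart <- function(coef, G) {
  nms <- intersect(names(coef), colnames(G))
  if (length(nms)) drop(G[, nms, drop = FALSE] %*% coef[nms])
  else rep.int(0, nrow(G))
}

binary_grid <- function(vars) {
  if (!length(vars)) return(matrix(numeric(0), nrow = 1L, ncol = 0L))
  g <- as.matrix(expand.grid(rep(list(0:1), length(vars)),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- vars
  g
}

## P(block = config | C, x) for a sequential block of logistic equations;
## G's columns include the block variables (and, for the mediator block,
## the L~ configuration the equations may condition on).
block_probs <- function(models, CS, G, exposure, x) {
  P <- matrix(1, nrow(CS), nrow(G))
  for (nm in names(models)) {
    p <- expit(outer(cpart(models[[nm]], CS, exposure, x),
                     gpart(models[[nm]], G), "+"))
    zero <- which(G[, nm] == 0)
    if (length(zero)) p[, zero] <- 1 - p[, zero, drop = FALSE]
    P <- P * p
  }
  P
}

#' Exact g-formula counterfactual prevalence by enumeration
#'
#' Computes a counterfactual outcome prevalence with no simulation error
#' by summing over every configuration of the intermediate confounders
#' (under both exposure assignments) and the mediator block, weighted by
#' the model probabilities, and over the baseline-confounder support
#' (exact support with binomial weights for synthetic parameters; the
#' empirical standardization rows for a fitted system).  All intermediate
#' confounders and mediators must be binary.
#'
#' @param object a \code{dgp_params} object, a fitted
#'   \code{\link{fit_model_system}} object, or an internal gsystem list.
#' @param x_direct exposure value (0/1) driving the intermediate
#'   confounders and the outcome model.
#' @param x_mediator exposure value (0/1) driving the mediator block.
#' @param outcome outcome name; required when \code{object} is a
#'   \code{dgp_params}.
#' @return the exact counterfactual prevalence (scalar).
#' @export
exact_gformula <- function(object, x_direct, x_mediator, outcome = NULL) {
  gs <- as_gsystem(object, outcome)
  stopifnot(x_direct %in% c(0, 1), x_mediator %in% c(0, 1))
  CS <- gs$c_support
  GL <- binary_grid(names(gs$l_models))
  GM <- binary_grid(names(gs$m_models))
  n_gl <- nrow(GL); n_gm <- nrow(GM)
  ## mediator-block law under x_mediator, marginalized over independent L~
  PL_xm <- block_probs(gs$l_models, CS, GL, gs$exposure, x_mediator)
  GLH <- cbind(GL[rep(seq_len(n_gl), times = n_gm), , drop = FALSE],
               GM[rep(seq_len(n_gm), each = n_gl), , drop = FALSE])
  PMgL <- block_probs(gs$m_models, CS, GLH, gs$exposure, x_mediator)
  PM <- vapply(seq_len(n_gm), function(h) {
    cols <- ((h - 1L) * n_gl + 1L):(h * n_gl)
    rowSums(PL_xm * PMgL[, cols, drop = FALSE])
  }, numeric(nrow(CS)))
  PM <- matrix(PM, nrow = nrow(CS))
  ## outcome under x_direct with its own L* draw and the M block above
  PL_xd <- if (x_direct == x_mediator) PL_xm
           else block_probs(gs$l_models, CS, GL, gs$exposure, x_direct)
  ylh <- gpart(gs$y_coef, GLH)
  yc <- cpart(gs$y_coef, CS, gs$exposure, x_direct)
  S <- outer(yc, ylh, "+")
  if (gs$y_family == "binomial") S <- expit(S)
  W <- PL_xd[, rep(seq_len(n_gl), times = n_gm), drop = FALSE] *
    PM[, rep(seq_len(n_gm), each = n_gl), drop = FALSE]
  sum(gs$c_weights * rowSums(S * W))
}

## ---- effect assembly --------------------------------------------------

effects_from_scenarios <- function(p00, p10, p11, scale, meta = list()) {
  prev <- c(p00 = p00, p10 = p10, p11 = p11)
  if (scale == "odds_ratio") {
    bad <- names(prev)[prev <= 0 | prev >= 1]
    if (length(bad))
      stop("undefined odds: counterfactual prevalence at boundary in scenario ",
           paste(bad, collapse = ", "))
    eff <- c(TCE = or_from_p(p11, p00), NDE = or_from_p(p10, p00),
             NIE = or_from_p(p11, p10))
  } else {
    eff <- c(TCE = p11 - p00, NDE = p10 - p00, NIE = p11 - p10)
  }
  structure(list(prevalences = prev, effects = eff,
                 pm = proportion_mediated(eff[["TCE"]], eff[["NIE"]], scale),
                 scale = scale, ci = NULL, meta = meta),
            class = "mediation_estimates")
}

#' Proportion mediated
#'
#' On the odds-ratio scale, \eqn{PM = \ln(NIE)/\ln(TCE)}; on the
#' mean-difference scale, \eqn{PM = NIE/TCE}.  Returns \code{NA} (not
#' calculated) under inconsistent mediation -- the direct and indirect
#' contributions pull in opposite directions -- or when the total effect
#' is very small (\eqn{|\ln TCE| < 0.01}, or \eqn{|TCE| < 0.01} on the
#' difference scale), where the ratio is unstable.
#'
#' @param tce total causal effect (odds ratio, or mean difference).
#' @param nie natural indirect effect on the same scale.
#' @param scale \code{"odds_ratio"} or \code{"mean_difference"}.
#' @return the mediated fraction, or \code{NA_real_} when not calculated.
#' @export
proportion_mediated <- function(tce, nie, scale = c("odds_ratio", "mean_difference")) {
  scale <- match.arg(scale)
  if (scale == "odds_ratio") {
    if (!is.finite(tce) || !is.finite(nie) || tce <= 0 || nie <= 0)
      stop("odds ratios must be positive and finite")
    lt <- log(tce); ln <- log(nie)
  } else {
    lt <- tce; ln <- nie
  }
  if (abs(lt) < 0.01) return(NA_real_)
  if (ln != 0 && sign(ln) != sign(lt)) return(NA_real_)
  ln / lt
}

#' @export
print.mediation_estimates <- function(x, ...) {
  lab <- if (x$scale == "odds_ratio") "odds ratios" else "mean differences"
  hdr <- if (isTRUE(x$meta$truth)) "ground truth" else "estimates"
  cat(sprintf("<mediation_estimates> %s (%s)\n", hdr, lab))
  cat(sprintf("  counterfactual outcomes: p(0,0)=%.4f p(1,0)=%.4f p(1,1)=%.4f\n",
              x$prevalences[["p00"]], x$prevalences[["p10"]],
              x$prevalences[["p11"]]))
  if (is.null(x$ci)) {
    for (e in names(x$effects))
      cat(sprintf("  %s = %.3f\n", e, x$effects[[e]]))
  } else {
    for (i in seq_len(nrow(x$ci)))
      cat(sprintf("  %s = %.3f (95%% CI %.3f, %.3f)\n", x$ci$effect[i],
                  x$ci$estimate[i], x$ci$lower[i], x$ci$upper[i]))
  }
  cat(sprintf("  proportion mediated: %s\n",
              if (is.na(x$pm)) "n/a" else sprintf("%.0f%%", 100 * x$pm)))
  invisible(x)
}

## ---- model system -----------------------------------------------------

#' Fit the parametric model system for g-computation
#'
#' Fits, on the listwise-complete rows, one logistic model per
#' intermediate confounder (on exposure, baseline confounders, and earlier
#' intermediate confounders), one per mediator (adding all intermediate
#' confounders and earlier mediators), and the outcome model (adding all
#' mediators), and stores the complete-case baseline-confounder rows as
#' the standardization population.  Component separation is resolved by a
#' penalized refit and annotated, never silently.
#'
#' @param cohort data frame.
#' @param roles a \code{\link{cohort_roles}} object.
#' @param outcome one outcome column name.
#' @param baseline,intermediate adjustment sets actually used (defaults:
#'   all declared); pass subsets to reproduce narrower adjustment tiers,
#'   or \code{character()} for an unadjusted system.
#' @return an object of class \code{model_system}.
#' @export
fit_model_system <- function(cohort, roles, outcome,
                             baseline = roles$baseline,
                             intermediate = roles$intermediate) {
  check_roles(cohort, roles, outcome)
  xname <- roles$exposure
  vars <- c(xname, baseline, intermediate, roles$mediators, outcome)
  cc <- stats::complete.cases(cohort[vars])
  data <- cohort[cc, vars, drop = FALSE]
  for (nm in c(xname, intermediate, roles$mediators))
    if (!is_binary_col(data[[nm]]))
      stop("column '", nm, "' must be binary (0/1) for g-computation")
  if (nrow(data) < length(vars) + 1L)
    stop("fewer complete rows (", nrow(data), ") than model coefficients")
  DM <- cbind("(Intercept)" = 1, as.matrix(data))
  storage.mode(DM) <- "double"
  comp <- function(out_nm, preds, fam)
    fit_glm_mat(DM[, c("(Intercept)", preds), drop = FALSE], DM[, out_nm],
                fam, out_nm, preds)
  l_models <- list()
  for (j in seq_along(intermediate)) {
    nm <- intermediate[j]
    l_models[[nm]] <- comp(nm, c(xname, baseline,
                                 intermediate[seq_len(j - 1L)]), "binomial")
  }
  m_models <- list()
  for (k in seq_along(roles$mediators)) {
    nm <- roles$mediators[k]
    m_models[[nm]] <- comp(nm, c(xname, baseline, intermediate,
                                 roles$mediators[seq_len(k - 1L)]), "binomial")
  }
  y_family <- if (is_binary_col(data[[outcome]])) "binomial" else "gaussian"
  y_model <- comp(outcome, c(xname, baseline, intermediate, roles$mediators),
                  y_family)
  seps <- vapply(c(l_models, m_models, list(outcome = y_model)),
                 function(m) m$separation, logical(1))
  structure(list(exposure = xname, c_vars = baseline,
                 c_pop = data[, baseline, drop = FALSE],
                 l_models = l_models, m_models = m_models, y_model = y_model,
                 outcome = outcome, n = nrow(data),
                 mediator_order = roles$mediators,
                 separation = names(seps)[seps]),
            class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat(sprintf("<model_system> outcome '%s' (%s), %d intermediate confounder(s), %d mediator(s), n = %d\n",
              x$outcome, x$y_model$family, length(x$l_models),
              length(x$m_models), x$n))
  if (length(x$separation))
    cat("  separation-annotated components:",
        paste(x$separation, collapse = ", "), "\n")
  invisible(x)
}

## ---- Monte Carlo counterfactual simulation ----------------------------

## Uniform draws reused across scenarios (common random numbers) so that
## effect contrasts carry far less Monte Carlo noise than the scenario
## means themselves.  Stored on the logit scale: U < expit(lp) iff
## qlogis(U) < lp, so each per-variable draw is a single comparison.
scenario_uniforms <- function(n_rows, nl, nm, seed) {
  set.seed(seed)
  list(L = matrix(stats::qlogis(stats::runif(n_rows * nl)), n_rows, nl),
       Lt = matrix(stats::qlogis(stats::runif(n_rows * nl)), n_rows, nl),
       M = matrix(stats::qlogis(stats::runif(n_rows * nm)), n_rows, nm))
}

## Per-model baseline-confounder parts of the linear predictors, computed
## once on the standardization rows and replicated, so that each scenario
## only adds the exposure and post-exposure terms.
confounder_parts <- function(system, copies) {
  CS <- as.matrix(system$c_pop)
  cvars <- colnames(CS)
  one <- function(coef) {
    nms <- intersect(setdiff(names(coef), "(Intercept)"), cvars)
    v <- if (length(nms)) coef[["(Intercept)"]] +
           drop(CS[, nms, drop = FALSE] %*% coef[nms])
         else rep.int(coef[["(Intercept)"]], nrow(CS))
    rep(v, times = copies)
  }
  list(L = lapply(system$l_models, function(m) one(m$coefficients)),
       M = lapply(system$m_models, function(m) one(m$coefficients)),
       Y = one(system$y_model$coefficients))
}

## linear predictor = replicated confounder part + exposure term +
## post-exposure (L/M) terms drawn so far
post_pred <- function(coef, cpartvec, data, x, exposure, post_vars) {
  lp <- cpartvec
  if (exposure %in% names(coef)) lp <- lp + coef[[exposure]] * x
  for (nm in intersect(names(coef), post_vars))
    lp <- lp + coef[[nm]] * data[[nm]]
  lp
}

draw_block_core <- function(models, parts, x, data, Zmat, xname, post) {
  for (j in seq_along(models)) {
    nm <- names(models)[j]
    lp <- post_pred(models[[nm]]$coefficients, parts[[nm]], data, x,
                    xname, post)
    data[[nm]] <- (Zmat[, j] < lp) + 0
  }
  data
}

sim_scenario_core <- function(system, x_direct, x_mediator, copies, U,
                              cparts = confounder_parts(system, copies)) {
  xname <- system$exposure
  post <- c(names(system$l_models), names(system$m_models))
  lstar <- draw_block_core(system$l_models, cparts$L, x_direct, list(),
                           U$L, xname, post)
  ltil <- draw_block_core(system$l_models, cparts$L, x_mediator, list(),
                          U$Lt, xname, post)
  mstar <- draw_block_core(system$m_models, cparts$M, x_mediator, ltil,
                           U$M, xname, post)
  ydata <- lstar
  for (nm in names(system$m_models)) ydata[[nm]] <- mstar[[nm]]
  lp <- post_pred(system$y_model$coefficients, cparts$Y, ydata, x_direct,
                  xname, post)
  if (system$y_model$family == "binomial") mean(expit(lp)) else mean(lp)
}

#' Simulate one counterfactual scenario
#'
#' Replicates the standardization population \code{copies} times; draws
#' the intermediate confounders under \code{x_direct}, an independent copy
#' under \code{x_mediator}, the mediator block under \code{x_mediator}
#' given that independent copy, and evaluates the outcome model under
#' \code{x_direct}; returns the average counterfactual outcome.
#'
#' @param system a \code{\link{fit_model_system}} object.
#' @param x_direct,x_mediator exposure assignments (0/1) for the
#'   direct-path and mediator-path variables.
#' @param copies Monte Carlo replications of the standardization rows.
#' @param seed integer seed.
#' @return counterfactual prevalence (binary outcome) or mean (numeric).
#' @export
simulate_scenario <- function(system, x_direct, x_mediator, copies = 100,
                              seed = 1L) {
  stopifnot(copies >= 1)
  U <- scenario_uniforms(nrow(system$c_pop) * copies,
                         length(system$l_models), length(system$m_models),
                         seed)
  sim_scenario_core(system, x_direct, x_mediator, copies, U)
}

estimate_from_system <- function(system, copies, seed) {
  U <- scenario_uniforms(nrow(system$c_pop) * copies,
                         length(system$l_models), length(system$m_models),
                         seed)
  cp <- confounder_parts(system, copies)
  xname <- system$exposure
  post <- c(names(system$l_models), names(system$m_models))
  ## under common random numbers the three scenarios share sub-draws:
  ## p10 reuses p11's L* draw (both at x_direct = 1) and p00's mediator
  ## draw (both at x_mediator = 0)
  L0 <- draw_block_core(system$l_models, cp$L, 0, list(), U$L, xname, post)
  L1 <- draw_block_core(system$l_models, cp$L, 1, list(), U$L, xname, post)
  Lt0 <- draw_block_core(system$l_models, cp$L, 0, list(), U$Lt, xname, post)
  Lt1 <- draw_block_core(system$l_models, cp$L, 1, list(), U$Lt, xname, post)
  M0 <- draw_block_core(system$m_models, cp$M, 0, Lt0, U$M, xname, post)
  M1 <- draw_block_core(system$m_models, cp$M, 1, Lt1, U$M, xname, post)
  yev <- function(x, Ldata, Mdata) {
    yd <- Ldata
    for (nm in names(system$m_models)) yd[[nm]] <- Mdata[[nm]]
    lp <- post_pred(system$y_model$coefficients, cp$Y, yd, x, xname, post)
    if (system$y_model$family == "binomial") mean(expit(lp)) else mean(lp)
  }
  p00 <- yev(0, L0, M0)
  p10 <- yev(1, L1, M0)
  p11 <- yev(1, L1, M1)
  scale <- if (system$y_model$family == "binomial") "odds_ratio"
           else "mean_difference"
  effects_from_scenarios(p00, p10, p11, scale,
                         meta = list(copies = copies, seed = seed,
                                     n = system$n,
                                     mediator_order = system$mediator_order,
                                     separation = system$separation))
}

#' Point estimates of mediation effects by parametric g-computation
#'
#' Fits the model system and contrasts the counterfactual scenarios
#' (1,1), (1,0), (0,0) simulated with common random numbers.  Binary
#' outcomes give odds ratios with \eqn{TCE = NDE \times NIE} holding
#' exactly; numeric outcomes give marginal mean differences with
#' \eqn{TCE = NDE + NIE}.
#'
#' @inheritParams fit_model_system
#' @param copies Monte Carlo replications of the standardization rows.
#' @param seed integer root seed.
#' @return a \code{mediation_estimates} object (no confidence intervals).
#' @export
estimate_effects <- function(cohort, roles, outcome, copies = 100, seed = 1L,
                             baseline = roles$baseline,
                             intermediate = roles$intermediate) {
  system <- fit_model_system(cohort, roles, outcome, baseline, intermediate)
  estimate_from_system(system, copies, seed)
}

#' Bootstrap confidence intervals for mediation effects
#'
#' Full-procedure nonparametric bootstrap: each of \code{B} resamples of
#' cohort rows refits every component model and recomputes the effects;
#' the standard error of each effect is the standard deviation of its
#' log-odds-ratio (or mean-difference) across resamples and the normal
#' 95\% interval is taken around the full-sample point estimate on that
#' scale.  Resamples failing with separation-related or undefined-odds
#' errors are dropped and counted.
#'
#' @inheritParams estimate_effects
#' @param B number of bootstrap resamples (>= 2).
#' @param strict if \code{TRUE}, more than 20\% failed resamples is an
#'   error rather than a warning.
#' @return a \code{mediation_estimates} object with a \code{ci} table and
#'   bootstrap metadata.
#' @export
bootstrap_effects <- function(cohort, roles, outcome, B = 50, copies = 100,
                              seed = 1L, baseline = roles$baseline,
                              intermediate = roles$intermediate,
                              strict = FALSE) {
  stopifnot(B >= 2)
  point <- estimate_effects(cohort, roles, outcome, copies,
                            derive_seed(seed, 0L), baseline, intermediate)
  onlog <- point$scale == "odds_ratio"
  n <- nrow(cohort)
  reps <- matrix(NA_real_, B, 3L, dimnames = list(NULL, names(point$effects)))
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, 2L * b))
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      estimate_effects(cohort[idx, , drop = FALSE], roles, outcome, copies,
                       derive_seed(seed, 2L * b + 1L), baseline, intermediate),
      error = function(e) NULL)
    if (!is.null(est))
      reps[b, ] <- if (onlog) log(est$effects) else est$effects
  }
  failed <- sum(is.na(reps[, 1L]))
  if (failed > 0.2 * B) {
    msg <- sprintf("%d of %d bootstrap resamples failed", failed, B)
    if (strict) stop(msg) else warning(msg)
  }
  se <- apply(reps, 2L, stats::sd, na.rm = TRUE)
  centre <- if (onlog) log(point$effects) else point$effects
  lower <- centre - 1.96 * se
  upper <- centre + 1.96 * se
  if (onlog) { lower <- exp(lower); upper <- exp(upper) }
  point$ci <- data.frame(effect = names(point$effects),
                         estimate = unname(point$effects),
                         lower = unname(lower), upper = unname(upper),
                         se = unname(se), row.names = NULL,
                         stringsAsFactors = FALSE)
  point$meta$B <- B
  point$meta$failed_resamples <- failed
  point$meta$seed <- seed
  point
}

#' Single-mediator sensitivity analysis
#'
#' Re-roles all mediators other than \code{primary_mediator} as
#' intermediate confounders (appended to the L-block in their declared
#' temporal order) and runs the g-formula with a one-mediator block,
#' giving the specific indirect effect via the primary mediator under the
#' assumption that the earlier mediators cause it.  The caller's role map
#' is not modified.
#'
#' @inheritParams bootstrap_effects
#' @param primary_mediator name of the mediator kept in the mediator
#'   block.
#' @return a \code{mediation_estimates} object (bootstrap CIs when
#'   \code{B >= 2}, point estimates when \code{B = 0}).
#' @export
single_mediator_effects <- function(cohort, roles, outcome, primary_mediator,
                                    copies = 100, B = 50, seed = 1L,
                                    baseline = roles$baseline,
                                    intermediate = roles$intermediate,
                                    strict = FALSE) {
  if (!primary_mediator %in% roles$mediators)
    stop("'", primary_mediator, "' is not a declared mediator")
  others <- setdiff(roles$mediators, primary_mediator)
  roles2 <- cohort_roles(exposure = roles$exposure, baseline = roles$baseline,
                         intermediate = c(roles$intermediate, others),
                         mediators = primary_mediator,
                         outcomes = roles$outcomes)
  intermediate2 <- c(intermediate, others)
  if (B >= 2)
    bootstrap_effects(cohort, roles2, outcome, B, copies, seed, baseline,
                      intermediate2, strict)
  else
    estimate_effects(cohort, roles2, outcome, copies, seed, baseline,
                     intermediate2)
}
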