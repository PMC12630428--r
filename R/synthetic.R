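## Synthetic birth-cohort generator
##
## Forward-simulates a directed acyclic graph with the structure the
## mediation analysis assumes: baseline confounders C -> binary exposure X
## -> intermediate confounders L -> mediators M1..M3 -> outcomes Y, every
## arrow carrying a nonzero coefficient so that confounding and mediation
## are present by construction, plus a missing-at-random masking mechanism
## driven by the exposure and baseline confounders.

#' Default synthetic-cohort parameters
#'
#' Fixed, documented structural parameters for a synthetic cohort that
#' emulates the variable structure and marginal prevalences of a Brazilian
#' birth cohort followed from birth to age 22: a binary high-conduct-
#' problems exposure (31\%), three adolescent "snare" mediators -- police
#' arrest (4\%), gang membership (2\%), school noncompletion (43\%) -- two
#' binary substance-use outcomes -- hazardous alcohol use (22\%), current
#' illicit drug use (14\%) -- two numeric alcohol-scale outcomes
#' (consumption 0--12, problems 0--28), six baseline confounders and five
#' intermediate confounders.  Intercepts were calibrated by large-sample
#' simulation so the six key marginal prevalences match the study's
#' descriptive table; slope coefficients are fixed plausible log-odds
#' encoding every arrow of the assumed causal graph.
#'
#' Baseline confounders compress the study's ten into six: three binary
#' (female sex, parental separation, parental smoking), two bounded count
#' scores (sociodemographic/health risk 0--5, maternal depression 0--20),
#' and the comorbidity confounder hyperactivity (0--10).  Intermediate
#' confounders are binary: peer deviance, adolescent smoking, adolescent
#' alcohol use, peer drug use, and the comorbidity confounder high
#' emotional problems.
#'
#' @return an object of class \code{dgp_params}: generation order, one
#'   structural equation per variable, the role map, and the missingness
#'   model.  Calling it twice returns identical values.
#' @seealso \code{\link{generate_cohort}}, \code{\link{true_mediation_effects}}
#' @export
default_pelotas_params <- function() {
  v <- list()
  ## ---- baseline confounders (no parents; mutually independent) ----
  v$female <- list(type = "binary", parents = character(),
                   coef = c("(Intercept)" = logit(0.51)))
  v$parental_separation <- list(type = "binary", parents = character(),
                                coef = c("(Intercept)" = logit(0.57)))
  v$parental_smoking <- list(type = "binary", parents = character(),
                             coef = c("(Intercept)" = logit(0.73)))
  ## bounded count scores, binomial with logit-constant cell probability
  v$ses_risk <- list(type = "count", size = 5L, parents = character(),
                     coef = c("(Intercept)" = logit(0.18)))
  v$maternal_depression <- list(type = "count", size = 20L, parents = character(),
                                coef = c("(Intercept)" = logit(0.2845)))
  v$hyperactivity <- list(type = "count", size = 10L, parents = character(),
                          coef = c("(Intercept)" = logit(0.43)))

  ## ---- exposure: high conduct problems at 11 (target 31%) ----
  v$conduct_problems <- list(
    type = "binary",
    parents = c("female", "parental_separation", "parental_smoking",
                "ses_risk", "maternal_depression", "hyperactivity"),
    coef = c("(Intercept)" = -2.20711,
             female = -0.50, parental_separation = 0.35, parental_smoking = 0.25,
             ses_risk = 0.20, maternal_depression = 0.05, hyperactivity = 0.18))

  ## ---- intermediate confounders (ages 11-15) ----
  v$peer_deviance <- list(
    type = "binary",
    parents = c("conduct_problems", "female", "parental_separation",
                "ses_risk", "hyperactivity"),
    coef = c("(Intercept)" = -0.71815,
             conduct_problems = 0.50, female = -0.30, parental_separation = 0.20,
             ses_risk = 0.15, hyperactivity = 0.08))
  v$smoking_15 <- list(
    type = "binary",
    parents = c("conduct_problems", "peer_deviance", "parental_smoking",
                "ses_risk", "hyperactivity"),
    coef = c("(Intercept)" = -4.14634,
             conduct_problems = 0.40, peer_deviance = 0.80, parental_smoking = 0.50,
             ses_risk = 0.15, hyperactivity = 0.06))
  v$alcohol_15 <- list(
    type = "binary",
    parents = c("conduct_problems", "peer_deviance", "smoking_15",
                "parental_separation", "female"),
    coef = c("(Intercept)" = -1.56022,
             conduct_problems = 0.30, peer_deviance = 0.60, smoking_15 = 0.90,
             parental_separation = 0.15, female = -0.20))
  v$peer_drug_use <- list(
    type = "binary",
    parents = c("conduct_problems", "peer_deviance", "smoking_15",
                "alcohol_15", "ses_risk"),
    coef = c("(Intercept)" = -2.82782,
             conduct_problems = 0.35, peer_deviance = 0.90, smoking_15 = 0.60,
             alcohol_15 = 0.50, ses_risk = 0.10))
  v$emotional_high <- list(
    type = "binary",
    parents = c("conduct_problems", "female", "maternal_depression",
                "hyperactivity"),
    coef = c("(Intercept)" = -2.02352,
             conduct_problems = 0.40, female = 0.50, maternal_depression = 0.06,
             hyperactivity = 0.10))

  ## ---- mediators, temporal order: arrest -> gang -> noncompletion ----
  v$police_arrest <- list(
    type = "binary",
    parents = c("conduct_problems", "female", "ses_risk", "peer_deviance",
                "smoking_15", "alcohol_15", "peer_drug_use", "hyperactivity",
                "emotional_high"),
    coef = c("(Intercept)" = -4.12303,
             conduct_problems = 0.55, female = -1.20, ses_risk = 0.20,
             peer_deviance = 0.50, smoking_15 = 0.40, alcohol_15 = 0.30,
             peer_drug_use = 0.60, hyperactivity = 0.08, emotional_high = 0.10))
  v$gang_member <- list(
    type = "binary",
    parents = c("conduct_problems", "female", "ses_risk", "peer_deviance",
                "peer_drug_use", "hyperactivity", "police_arrest"),
    coef = c("(Intercept)" = -4.85276,
             conduct_problems = 0.45, female = -1.00, ses_risk = 0.20,
             peer_deviance = 0.50, peer_drug_use = 0.70, hyperactivity = 0.10,
             police_arrest = 1.60))
  v$school_noncompletion <- list(
    type = "binary",
    parents = c("conduct_problems", "female", "ses_risk", "maternal_depression",
                "parental_separation", "parental_smoking", "peer_deviance",
                "smoking_15", "alcohol_15", "peer_drug_use", "hyperactivity",
                "emotional_high", "police_arrest", "gang_member"),
    coef = c("(Intercept)" = -2.12203,
             conduct_problems = 0.50, female = -0.20, ses_risk = 0.35,
             maternal_depression = 0.03, parental_separation = 0.30,
             parental_smoking = 0.30, peer_deviance = 0.40, smoking_15 = 0.70,
             alcohol_15 = 0.20, peer_drug_use = 0.30, hyperactivity = 0.12,
             emotional_high = 0.05, police_arrest = 0.80, gang_member = 0.60))

  ## ---- outcomes at 22 ----
  v$hazardous_alcohol <- list(
    type = "binary",
    parents = c("conduct_problems", "female", "parental_separation",
                "alcohol_15", "peer_deviance", "peer_drug_use", "hyperactivity",
                "emotional_high", "police_arrest", "gang_member",
                "school_noncompletion"),
    coef = c("(Intercept)" = -1.72737,
             conduct_problems = 0.15, female = -0.90, parental_separation = 0.10,
             alcohol_15 = 0.80, peer_deviance = 0.30, peer_drug_use = 0.40,
             hyperactivity = 0.04, emotional_high = 0.05, police_arrest = 0.50,
             gang_member = 0.60, school_noncompletion = 0.15))
  v$illicit_drug <- list(
    type = "binary",
    parents = c("conduct_problems", "female", "ses_risk", "peer_deviance",
                "smoking_15", "peer_drug_use", "hyperactivity", "emotional_high",
                "police_arrest", "gang_member", "school_noncompletion"),
    coef = c("(Intercept)" = -2.59422,
             conduct_problems = 0.05, female = -0.70, ses_risk = 0.10,
             peer_deviance = 0.50, smoking_15 = 0.60, peer_drug_use = 1.00,
             hyperactivity = 0.05, emotional_high = 0.10, police_arrest = 1.30,
             gang_member = 1.90, school_noncompletion = 0.15))
  ## numeric alcohol-scale outcomes: rounded, range-clipped linear responses
  v$audit_consumption <- list(
    type = "numeric", sd = 2.6, range = c(0, 12),
    parents = c("conduct_problems", "female", "alcohol_15", "peer_deviance",
                "police_arrest", "gang_member", "school_noncompletion"),
    coef = c("(Intercept)" = 3.40,
             conduct_problems = 0.30, female = -1.40, alcohol_15 = 1.60,
             peer_deviance = 0.40, police_arrest = 0.90, gang_member = 0.80,
             school_noncompletion = 0.15))
  v$audit_problems <- list(
    type = "numeric", sd = 2.8, range = c(0, 28),
    parents = c("conduct_problems", "female", "alcohol_15", "peer_deviance",
                "peer_drug_use", "police_arrest", "gang_member",
                "school_noncompletion"),
    coef = c("(Intercept)" = 0.90,
             conduct_problems = 0.30, female = -1.00, alcohol_15 = 1.30,
             peer_deviance = 0.40, peer_drug_use = 0.60, police_arrest = 0.70,
             gang_member = 0.80, school_noncompletion = 0.15))

  roles <- cohort_roles(
    exposure = "conduct_problems",
    baseline = c("female", "parental_separation", "parental_smoking",
                 "ses_risk", "maternal_depression", "hyperactivity"),
    intermediate = c("peer_deviance", "smoking_15", "alcohol_15",
                     "peer_drug_use", "emotional_high"),
    mediators = c("police_arrest", "gang_member", "school_noncompletion"),
    outcomes = c("hazardous_alcohol", "illicit_drug",
                 "audit_consumption", "audit_problems"))

  structure(list(
    order = names(v),
    vars = v,
    roles = roles,
    ## comorbidity confounders enter only the widest adjustment tier
    comorbidity = list(baseline = "hyperactivity", intermediate = "emotional_high"),
    missingness = list(
      ## attrition never touches perinatal/baseline data or the exposure
      columns = c(roles$intermediate, roles$mediators, roles$outcomes),
      rate = 0.06,
      coef = c(conduct_problems = 0.45, female = -0.35, ses_risk = 0.15,
               maternal_depression = 0.03, hyperactivity = 0.05))
  ), class = "dgp_params")
}

#' Role map of the default synthetic cohort
#' @param params a \code{dgp_params} object.
#' @return the \code{cohort_roles} object embedded in the parameters.
#' @export
pelotas_roles <- function(params = default_pelotas_params()) params$roles

check_params <- function(params) {
  stopifnot(inherits(params, "dgp_params"))
  seen <- character()
  for (nm in params$order) {
    sp <- params$vars[[nm]]
    if (!all(sp$parents %in% seen))
      stop("structural specification error: parents of '", nm,
           "' are not generated before it (order is not topological)")
    if (!is.finite(sp$coef[["(Intercept)"]]))
      stop("non-finite intercept for '", nm, "'")
    if (identical(sp$type, "numeric") && (!is.numeric(sp$sd) || sp$sd <= 0))
      stop("noise SD for '", nm, "' must be > 0")
    seen <- c(seen, nm)
  }
  invisible(TRUE)
}

lin_pred <- function(coef, data, x = NULL, exposure = NULL) {
  nr <- if (is.data.frame(data)) nrow(data)
        else if (!is.null(attr(data, "n_rows"))) attr(data, "n_rows")
        else length(data[[1L]])
  lp <- rep.int(coef[["(Intercept)"]], nr)
  for (nm in setdiff(names(coef), "(Intercept)")) {
    if (!is.null(exposure) && nm == exposure && !is.null(x)) {
      lp <- lp + coef[[nm]] * x
    } else {
      lp <- lp + coef[[nm]] * data[[nm]]
    }
  }
  lp
}

#' Generate a fully observed synthetic cohort
#'
#' Simulates the structural equations forward in topological order.  Each
#' variable draws from its own deterministic random substream of the root
#' seed, so the same \code{(params, n, seed)} always yields a bitwise
#' identical table.
#'
#' @param params a \code{dgp_params} object (see
#'   \code{\link{default_pelotas_params}}).
#' @param n number of rows (participants).
#' @param seed integer root seed.
#' @return a data frame with one column per generated variable and no
#'   missing cells.
#' @export
generate_cohort <- function(params, n, seed = 1L) {
  stopifnot(n >= 1)
  check_params(params)
  out <- data.frame(row.names = seq_len(n))
  for (i in seq_along(params$order)) {
    nm <- params$order[i]
    sp <- params$vars[[nm]]
    set.seed(derive_seed(seed, i))
    lp <- lin_pred(sp$coef, out)
    out[[nm]] <- switch(sp$type,
      binary = stats::rbinom(n, 1L, expit(lp)),
      count = stats::rbinom(n, sp$size, expit(lp)),
      numeric = pmin(pmax(round(lp + stats::rnorm(n, 0, sp$sd)), sp$range[1]),
                     sp$range[2]),
      stop("unknown variable type: ", sp$type))
  }
  out
}

#' Impose missing-at-random attrition on a fully observed cohort
#'
#' Masks cells of the post-exposure columns (intermediate confounders,
#' mediators, outcomes) with a per-cell probability that depends on the
#' exposure and baseline confounders -- never on the masked value itself.
#' The model intercept is solved so that the expected fraction of masked
#' cells equals \code{rate}.
#'
#' @param cohort a fully observed cohort data frame.
#' @param params a \code{dgp_params} object supplying the missingness model.
#' @param rate target overall fraction of maskable cells set missing, in
#'   \code{[0, 1)}.
#' @param seed integer root seed.
#' @return the cohort with \code{NA}s introduced.
#' @export
impose_missingness <- function(cohort, params, rate = params$missingness$rate,
                               seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("missingness rate must lie in [0, 1)")
  if (anyNA(cohort)) stop("cohort must be fully observed before masking")
  if (rate == 0) return(cohort)
  mm <- params$missingness
  lp0 <- lin_pred(c("(Intercept)" = 0, mm$coef), cohort)
  ## intercept such that mean masking probability equals the target rate
  a <- stats::uniroot(function(a) mean(expit(a + lp0)) - rate,
                      interval = c(-30, 30), tol = 1e-10)$root
  p <- expit(a + lp0)
  for (j in seq_along(mm$columns)) {
    set.seed(derive_seed(seed, 1000L + j))
    mask <- stats::runif(nrow(cohort)) < p
    cohort[[mm$columns[j]]][mask] <- NA
  }
  cohort
}

#' Ground-truth mediation effects implied by synthetic parameters
#'
#' Computes the counterfactual outcome prevalences (or means) and the
#' total, natural direct, and natural indirect effects directly from the
#' structural equations: by exact enumeration over the joint support of
#' the generated variables for binary outcomes, or by large Monte Carlo
#' for the range-clipped numeric outcomes.  No estimation error enters the
#' binary case; results are flagged as truth and carry no confidence
#' intervals.
#'
#' @param params a \code{dgp_params} object.
#' @param outcome name of an outcome column in \code{params}.
#' @param mc_n Monte Carlo draws for numeric outcomes (ignored for binary
#'   outcomes); must be supplied when the outcome is numeric.
#' @param seed seed for the Monte Carlo fallback.
#' @return a \code{mediation_estimates} object with \code{truth = TRUE}.
#' @export
true_mediation_effects <- function(params, outcome, mc_n = NULL, seed = 1L) {
  check_params(params)
  sp <- params$vars[[outcome]]
  if (is.null(sp)) stop("unknown outcome: ", outcome)
  if (identical(sp$type, "binary")) {
    gs <- gsystem_from_params(params, outcome)
    p00 <- exact_gformula(gs, x_direct = 0, x_mediator = 0)
    p10 <- exact_gformula(gs, x_direct = 1, x_mediator = 0)
    p11 <- exact_gformula(gs, x_direct = 1, x_mediator = 1)
    effects_from_scenarios(p00, p10, p11, scale = "odds_ratio",
                           meta = list(truth = TRUE, method = "enumeration"))
  } else {
    if (is.null(mc_n))
      stop("unsupported configuration: numeric outcome requires a Monte-Carlo ",
           "fallback size (mc_n)")
    m <- function(xd, xm, k) mc_truth_mean(params, outcome, xd, xm, mc_n,
                                           derive_seed(seed, k))
    effects_from_scenarios(m(0, 0, 1), m(1, 0, 2), m(1, 1, 3),
                           scale = "mean_difference",
                           meta = list(truth = TRUE, method = "monte_carlo",
                                       mc_n = mc_n))
  }
}

## Monte Carlo scenario mean straight from the structural equations:
## C as generated; L* under x_direct; an independent L~ under x_mediator;
## M under (x_mediator, L~); Y under (x_direct, L*, M).
mc_truth_mean <- function(params, outcome, x_direct, x_mediator, n, seed) {
  roles <- params$roles
  xname <- roles$exposure
  base <- generate_cohort(params, n, seed)[roles$baseline]
  draw_block <- function(vars, x, data, offset) {
    for (i in seq_along(vars)) {
      sp <- params$vars[[vars[i]]]
      set.seed(derive_seed(seed, offset + i))
      lp <- lin_pred(sp$coef, data, x = x, exposure = xname)
      data[[vars[i]]] <- stats::rbinom(n, 1L, expit(lp))
    }
    data
  }
  lstar <- draw_block(roles$intermediate, x_direct, base, 100L)
  ltil <- draw_block(roles$intermediate, x_mediator, base, 200L)
  mstar <- draw_block(roles$mediators, x_mediator, ltil, 300L)
  ydata <- cbind(lstar, mstar[roles$mediators])
  sp <- params$vars[[outcome]]
  lp <- lin_pred(sp$coef, ydata, x = x_direct, exposure = xname)
  if (identical(sp$type, "binary")) return(mean(expit(lp)))
  set.seed(derive_seed(seed, 999L))
  mean(pmin(pmax(round(lp + stats::rnorm(n, 0, sp$sd)), sp$range[1]), sp$range[2]))
}
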