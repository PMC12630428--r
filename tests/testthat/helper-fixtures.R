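## Fixtures built in code: small structural-parameter objects with known
## truth, coefficient surgery helpers, and an independent enumeration
## oracle for factual marginals.

## One binary baseline confounder, one mediator, no intermediate
## confounders: the 8-configuration system used for hand enumeration.
tiny_params <- function(pc = 0.4,
                        bx = c(i = -1.2, c1 = 0.9),
                        bm = c(i = -1.0, x = 0.8, c1 = 0.5),
                        by = c(i = -1.5, x = 0.7, c1 = 1.1, m1 = 0.6)) {
  v <- list(
    c1 = list(type = "binary", parents = character(),
              coef = c("(Intercept)" = stats::qlogis(pc))),
    x = list(type = "binary", parents = "c1",
             coef = c("(Intercept)" = bx[["i"]], c1 = bx[["c1"]])),
    m1 = list(type = "binary", parents = c("x", "c1"),
              coef = c("(Intercept)" = bm[["i"]], x = bm[["x"]],
                       c1 = bm[["c1"]])),
    y = list(type = "binary", parents = c("x", "c1", "m1"),
             coef = c("(Intercept)" = by[["i"]], x = by[["x"]],
                      c1 = by[["c1"]], m1 = by[["m1"]])))
  roles <- cohort_roles(exposure = "x", baseline = "c1",
                        intermediate = character(),
                        mediators = "m1", outcomes = "y")
  structure(list(order = names(v), vars = v, roles = roles,
                 comorbidity = list(baseline = character(),
                                    intermediate = character()),
                 missingness = list(columns = c("m1", "y"), rate = 0.1,
                                    coef = c(x = 0.5, c1 = 0.3))),
            class = "dgp_params")
}

## zero selected coefficient names inside one structural equation
zero_coefs <- function(params, var, terms) {
  keep <- intersect(terms, names(params$vars[[var]]$coef))
  params$vars[[var]]$coef[keep] <- 0
  params
}

## zero the exposure term of every (or the given) downstream equation
zero_exposure_in <- function(params, vars = NULL) {
  xname <- params$roles$exposure
  targets <- if (is.null(vars)) setdiff(params$order, xname) else vars
  for (nm in targets) params <- zero_coefs(params, nm, xname)
  params
}

## disconnect a variable: no incoming arrows beyond the intercept, and a
## zero coefficient wherever it appears downstream
neutralize_var <- function(params, var) {
  cf <- params$vars[[var]]$coef
  params$vars[[var]]$coef[setdiff(names(cf), "(Intercept)")] <- 0
  for (nm in params$order)
    params <- zero_coefs(params, nm, var)
  params
}

## Independent oracle: exact factual marginal prevalences, computed as a
## plain sum of joint-probability products over all configurations of the
## binary downstream variables and the full baseline support.  Written
## against the generator's parameter layout only; shares no code with the
## package's counterfactual enumeration.
enumerate_factual_marginals <- function(params) {
  roles <- params$roles
  sup <- lapply(roles$baseline, function(nm) {
    sp <- params$vars[[nm]]
    if (sp$type == "binary") 0:1 else 0:sp$size
  })
  names(sup) <- roles$baseline
  Cgrid <- expand.grid(sup, KEEP.OUT.ATTRS = FALSE)
  wC <- rep(1, nrow(Cgrid))
  for (nm in roles$baseline) {
    sp <- params$vars[[nm]]
    pr <- stats::plogis(sp$coef[["(Intercept)"]])
    wC <- wC * if (sp$type == "binary") ifelse(Cgrid[[nm]] == 1, pr, 1 - pr)
          else stats::dbinom(Cgrid[[nm]], sp$size, pr)
  }
  downstream <- c(roles$exposure, roles$intermediate, roles$mediators)
  G <- expand.grid(rep(list(0:1), length(downstream)),
                   KEEP.OUT.ATTRS = FALSE)
  names(G) <- downstream
  out_names <- Filter(function(nm) params$vars[[nm]]$type == "binary",
                      roles$outcomes)
  marg <- stats::setNames(numeric(length(downstream) + length(out_names)),
                          c(downstream, out_names))
  lp_of <- function(sp, g) {
    lp <- sp$coef[["(Intercept)"]]
    for (pa in setdiff(names(sp$coef), "(Intercept)"))
      lp <- lp + sp$coef[[pa]] *
        (if (pa %in% names(Cgrid)) Cgrid[[pa]] else g[[pa]])
    lp
  }
  for (gi in seq_len(nrow(G))) {
    g <- G[gi, , drop = FALSE]
    pg <- wC
    for (nm in downstream) {
      p1 <- stats::plogis(lp_of(params$vars[[nm]], g))
      pg <- pg * if (g[[nm]] == 1) p1 else 1 - p1
    }
    for (nm in downstream)
      if (g[[nm]] == 1) marg[nm] <- marg[nm] + sum(pg)
    for (nm in out_names)
      marg[nm] <- marg[nm] + sum(pg * stats::plogis(lp_of(params$vars[[nm]], g)))
  }
  marg
}

## re-role synthetic parameters for the single-mediator estimand: all
## mediators but `primary` join the intermediate-confounder block
single_mediator_params <- function(params, primary) {
  roles <- params$roles
  others <- setdiff(roles$mediators, primary)
  params$roles <- cohort_roles(
    exposure = roles$exposure, baseline = roles$baseline,
    intermediate = c(roles$intermediate, others),
    mediators = primary, outcomes = roles$outcomes)
  params
}

## rows of a 2x2 table expanded to unit records
expand_2x2 <- function(a, b, c, d) {
  ## a: exposed cases, b: exposed non-cases, c: unexposed cases,
  ## d: unexposed non-cases
  data.frame(x = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
             y = rep(c(1, 0, 1, 0), times = c(a, b, c, d)))
}
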