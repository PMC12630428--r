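## Hand enumeration oracle for the 8-configuration system (one baseline
## confounder, one mediator, no intermediate confounders): a plain double
## sum written independently of the package's enumeration code.
hand_prevalence <- function(p, x_direct, x_mediator) {
  pc <- stats::plogis(p$vars$c1$coef[["(Intercept)"]])
  bm <- p$vars$m1$coef
  by <- p$vars$y$coef
  total <- 0
  for (cv in 0:1) {
    wc <- if (cv == 1) pc else 1 - pc
    pm1 <- stats::plogis(bm[["(Intercept)"]] + bm[["x"]] * x_mediator +
                           bm[["c1"]] * cv)
    for (mv in 0:1) {
      wm <- if (mv == 1) pm1 else 1 - pm1
      py <- stats::plogis(by[["(Intercept)"]] + by[["x"]] * x_direct +
                            by[["c1"]] * cv + by[["m1"]] * mv)
      total <- total + wc * wm * py
    }
  }
  total
}

test_that("exact enumeration matches hand arithmetic on the 8-configuration system", {
  p <- tiny_params()
  for (s in list(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) {
    expect_equal(exact_gformula(p, s[1], s[2], outcome = "y"),
                 hand_prevalence(p, s[1], s[2]), tolerance = 1e-12)
  }
})

test_that("an all-zero coefficient system returns the outcome intercept prevalence", {
  p <- tiny_params()
  for (nm in p$order) {
    cf <- p$vars[[nm]]$coef
    p$vars[[nm]]$coef[setdiff(names(cf), "(Intercept)")] <- 0
  }
  expect_equal(exact_gformula(p, 1, 0, outcome = "y"),
               stats::plogis(p$vars$y$coef[["(Intercept)"]]),
               tolerance = 1e-14)
})

test_that("the effect decomposition is exact and the truth identity holds", {
  ## TCE = NDE x NIE whenever the three odds ratios come from the same
  ## three scenario prevalences
  for (seed in 1:5) {
    set.seed(seed)
    p <- tiny_params(pc = runif(1, 0.2, 0.8),
                     bx = c(i = rnorm(1), c1 = rnorm(1)),
                     bm = c(i = rnorm(1), x = rnorm(1), c1 = rnorm(1)),
                     by = c(i = rnorm(1), x = rnorm(1), c1 = rnorm(1),
                            m1 = rnorm(1)))
    tr <- true_mediation_effects(p, "y")
    expect_lt(abs(tr$effects[["TCE"]] -
                  tr$effects[["NDE"]] * tr$effects[["NIE"]]), 1e-12)
  }
})

test_that("enumeration of numeric variables is refused as unsupported", {
  p <- default_pelotas_params()
  expect_error(exact_gformula(p, 1, 1, outcome = "audit_consumption"),
               "unsupported configuration")
})

test_that("a system with no intermediate confounders is valid and recoverable", {
  p <- tiny_params()
  co <- generate_cohort(p, 3e4, seed = 2)
  sys <- fit_model_system(co, p$roles, "y")
  expect_length(sys$l_models, 0)
  ## fitted-system enumeration approaches the generating truth
  tr <- true_mediation_effects(p, "y")
  est <- sapply(list(c(0, 0), c(1, 0), c(1, 1)),
                function(s) exact_gformula(sys, s[1], s[2]))
  expect_equal(unname(est), unname(tr$prevalences), tolerance = 0.02)
})

test_that("component models recover the generating coefficients at large n", {
  p <- default_pelotas_params()
  roles <- p$roles
  co <- generate_cohort(p, 1e5, seed = 13)
  sys <- fit_model_system(co, roles, "hazardous_alcohol")
  models <- c(sys$l_models, sys$m_models, list(sys$y_model))
  names(models)[length(models)] <- "hazardous_alcohol"
  for (nm in names(models)) {
    fit <- models[[nm]]
    truth <- p$vars[[nm]]$coef
    for (term in intersect(names(truth), names(fit$coefficients))) {
      se <- sqrt(fit$vcov[term, term])
      expect_lt(abs(fit$coefficients[[term]] - truth[[term]]), 4 * se,
                label = sprintf("%s ~ %s recovery", nm, term))
    }
  }
})

test_that("Monte Carlo scenarios converge to the enumeration oracle", {
  p <- default_pelotas_params()
  co <- generate_cohort(p, 4599, seed = 3)
  sys <- fit_model_system(co, p$roles, "hazardous_alcohol")
  ex <- exact_gformula(sys, 1, 1)
  mc <- simulate_scenario(sys, 1, 1, copies = 200, seed = 9)
  expect_lt(abs(mc - ex), 0.005)
})

test_that("estimation is deterministic given the seed", {
  p <- tiny_params()
  co <- generate_cohort(p, 1500, seed = 4)
  b1 <- bootstrap_effects(co, p$roles, "y", B = 5, copies = 10, seed = 11)
  b2 <- bootstrap_effects(co, p$roles, "y", B = 5, copies = 10, seed = 11)
  expect_identical(b1, b2)
  b3 <- bootstrap_effects(co, p$roles, "y", B = 5, copies = 10, seed = 12)
  expect_false(identical(b1$ci, b3$ci))
  expect_equal(b1$meta$B, 5)
  expect_true(b1$meta$failed_resamples >= 0)
})

test_that("null mediation and null direct paths estimate as unit odds ratios", {
  p <- default_pelotas_params()
  ## exposure severed from intermediate confounders and mediators: no
  ## indirect channel remains
  pnm <- zero_exposure_in(p, c(p$roles$intermediate, p$roles$mediators))
  co <- generate_cohort(pnm, 2e4, seed = 6)
  est <- estimate_effects(co, pnm$roles, "illicit_drug", copies = 200, seed = 1)
  expect_lt(abs(log(est$effects[["NIE"]])), 0.06)
  ## exposure influences mediators only: no direct channel remains
  pnd <- zero_exposure_in(p, c(p$roles$intermediate, "illicit_drug"))
  co2 <- generate_cohort(pnd, 2e4, seed = 7)
  est2 <- estimate_effects(co2, pnd$roles, "illicit_drug", copies = 200,
                           seed = 2)
  expect_lt(abs(log(est2$effects[["NDE"]])), 0.08)
})

test_that("degenerate counterfactual prevalences raise the undefined-odds error", {
  expect_error(gcmediate:::effects_from_scenarios(1, 0.5, 0.4, "odds_ratio"),
               "undefined odds.*p00")
  expect_error(gcmediate:::effects_from_scenarios(0.2, 0.5, 0, "odds_ratio"),
               "undefined odds.*p11")
})

test_that("bootstrap intervals tighten with sample size", {
  p <- default_pelotas_params()
  widths <- sapply(c(2500, 20000), function(n) {
    w <- sapply(1:3, function(r) {
      co <- generate_cohort(p, n, seed = 700 + r)
      b <- bootstrap_effects(co, p$roles, "hazardous_alcohol", B = 20,
                             copies = 10, seed = r)
      log(b$ci$upper[b$ci$effect == "TCE"]) -
        log(b$ci$lower[b$ci$effect == "TCE"])
    })
    stats::median(w)
  })
  expect_lt(widths[2], widths[1])
})

test_that("proportion mediated follows the log-ratio rule with its n/a cases", {
  expect_equal(proportion_mediated(1.20, 1.16), log(1.16) / log(1.20),
               tolerance = 1e-12)
  expect_equal(round(100 * proportion_mediated(1.20, 1.16)), 81)
  expect_equal(proportion_mediated(1.5, 1.0), 0)
  expect_equal(proportion_mediated(2.0, 2.0), 1)
  expect_true(is.na(proportion_mediated(1.005, 1.2)))   # tiny total effect
  expect_true(is.na(proportion_mediated(1.3, 0.9)))     # inconsistent
  expect_error(proportion_mediated(-1, 1.1), "positive")
  expect_equal(proportion_mediated(0.5, 0.25, scale = "mean_difference"), 0.5)
})

test_that("the single-mediator re-roling matches its exact estimand and is pure", {
  p <- default_pelotas_params()
  ## with the first two snares disconnected, the block indirect effect is
  ## exactly the school-noncompletion-specific indirect effect
  pz <- neutralize_var(neutralize_var(p, "police_arrest"), "gang_member")
  tr3 <- true_mediation_effects(pz, "illicit_drug")
  tr1 <- true_mediation_effects(
    single_mediator_params(pz, "school_noncompletion"), "illicit_drug")
  expect_equal(tr1$effects[["NIE"]], tr3$effects[["NIE"]], tolerance = 1e-10)
  expect_equal(tr1$prevalences, tr3$prevalences, tolerance = 1e-10)
  ## estimation side: severed primary mediator gives a null specific NIE
  pn <- zero_coefs(zero_coefs(p, "school_noncompletion", "conduct_problems"),
                   "illicit_drug", "school_noncompletion")
  co <- generate_cohort(pn, 2e4, seed = 8)
  roles_before <- pn$roles
  est <- single_mediator_effects(co, pn$roles, "illicit_drug",
                                 "school_noncompletion", copies = 150,
                                 B = 0, seed = 3)
  expect_lt(abs(log(est$effects[["NIE"]])), 0.05)
  expect_identical(pn$roles, roles_before)
  expect_error(single_mediator_effects(co, pn$roles, "illicit_drug",
                                       "not_a_mediator", B = 0),
               "not a declared mediator")
})
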