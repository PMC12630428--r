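test_that("default parameters are a pure constant with a topological order", {
  p1 <- default_pelotas_params()
  p2 <- default_pelotas_params()
  expect_identical(p1, p2)
  expect_true(gcmediate:::check_params(p1))
  ## every exposure -> mediator and mediator -> outcome arrow is nonzero
  for (m in p1$roles$mediators)
    expect_gt(abs(p1$vars[[m]]$coef[[p1$roles$exposure]]), 0)
  for (y in c("hazardous_alcohol", "illicit_drug"))
    for (m in p1$roles$mediators)
      expect_gt(abs(p1$vars[[y]]$coef[[m]]), 0)
})

test_that("generation is deterministic, complete, and respects declared types", {
  p <- default_pelotas_params()
  co1 <- generate_cohort(p, 4599, seed = 1)
  co2 <- generate_cohort(p, 4599, seed = 1)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 4599)
  expect_equal(sum(is.na(co1)), 0)
  expect_false(identical(co1, generate_cohort(p, 4599, seed = 2)))
  for (nm in c(p$roles$exposure, p$roles$intermediate, p$roles$mediators))
    expect_true(all(co1[[nm]] %in% 0:1))
  expect_true(all(co1$audit_consumption >= 0 & co1$audit_consumption <= 12))
  expect_true(all(co1$audit_problems >= 0 & co1$audit_problems <= 28))
})

test_that("a non-topological parent order is a structural error", {
  p <- default_pelotas_params()
  p$order <- rev(p$order)
  expect_error(generate_cohort(p, 10, seed = 1), "topological")
})

test_that("sample marginals match exact enumeration of the generating DAG", {
  p <- default_pelotas_params()
  truth <- enumerate_factual_marginals(p)
  n <- 1e5
  co <- generate_cohort(p, n, seed = 7)
  for (nm in names(truth)) {
    se <- sqrt(truth[[nm]] * (1 - truth[[nm]]) / n)
    expect_lt(abs(mean(co[[nm]]) - truth[[nm]]), 3 * se,
              label = sprintf("|%s sample - enumeration| (%.4f vs %.4f)",
                              nm, mean(co[[nm]]), truth[[nm]]))
  }
})

test_that("a fully disconnected exposure shows no sample associations", {
  ## outgoing arrows severed and incoming confounding removed, so the
  ## marginal odds ratio of every downstream variable on the exposure is
  ## null by construction
  p0 <- zero_exposure_in(default_pelotas_params())
  p0 <- zero_coefs(p0, "conduct_problems",
                   setdiff(names(p0$vars$conduct_problems$coef),
                           "(Intercept)"))
  co <- generate_cohort(p0, 1e5, seed = 11)
  for (nm in c(p0$roles$mediators, "hazardous_alcohol", "illicit_drug")) {
    fit <- fit_glm(co, nm, p0$roles$exposure)
    b <- fit$coefficients[[p0$roles$exposure]]
    se <- sqrt(fit$vcov[2, 2])
    expect_lt(abs(b), 3 * se, label = paste("null log OR for", nm))
  }
})

test_that("ground-truth effects: null DAG, no-direct-path, and decomposition", {
  p <- default_pelotas_params()
  ## fully severed exposure: all three effects exactly null
  tr0 <- true_mediation_effects(zero_exposure_in(p), "illicit_drug")
  expect_equal(unname(tr0$effects), c(1, 1, 1), tolerance = 1e-12)
  expect_true(is.na(tr0$pm))
  ## exposure influences only the mediators: direct effect exactly null
  pnd <- zero_exposure_in(p, c(p$roles$intermediate, "hazardous_alcohol"))
  trnd <- true_mediation_effects(pnd, "hazardous_alcohol")
  expect_equal(trnd$effects[["NDE"]], 1, tolerance = 1e-12)
  ## defaults: mediation present by construction, identity exact
  tr <- true_mediation_effects(p, "illicit_drug")
  expect_gt(tr$effects[["NIE"]], 1)
  expect_lt(abs(tr$effects[["TCE"]] -
                tr$effects[["NDE"]] * tr$effects[["NIE"]]), 1e-10)
  expect_true(isTRUE(tr$meta$truth))
})

test_that("enumeration truth agrees with the structural Monte Carlo truth", {
  p <- default_pelotas_params()
  gs <- gcmediate:::gsystem_from_params(p, "hazardous_alcohol")
  for (s in list(c(0, 0), c(1, 0), c(1, 1))) {
    ex <- exact_gformula(gs, s[1], s[2])
    mc <- gcmediate:::mc_truth_mean(p, "hazardous_alcohol", s[1], s[2],
                                    n = 2e6, seed = 19)
    expect_lt(abs(ex - mc), 0.002,
              label = sprintf("scenario (%d,%d) enumeration vs MC", s[1], s[2]))
  }
})

test_that("numeric outcomes require a Monte Carlo fallback and then work", {
  p <- default_pelotas_params()
  expect_error(true_mediation_effects(p, "audit_consumption"),
               "Monte-Carlo fallback")
  tr <- true_mediation_effects(p, "audit_consumption", mc_n = 2e5, seed = 3)
  expect_identical(tr$scale, "mean_difference")
  expect_gt(tr$effects[["NIE"]], 0)
  expect_equal(tr$effects[["TCE"]],
               tr$effects[["NDE"]] + tr$effects[["NIE"]], tolerance = 1e-12)
})

test_that("missingness imposition hits the configured rate under a MAR law", {
  p <- default_pelotas_params()
  co <- generate_cohort(p, 1e5, seed = 5)
  expect_identical(impose_missingness(co, p, rate = 0, seed = 1), co)
  expect_error(impose_missingness(co, p, rate = 1.2, seed = 1), "\\[0, 1\\)")
  com <- impose_missingness(co, p, rate = 0.25, seed = 2)
  frac <- mean(is.na(com[p$missingness$columns]))
  expect_lt(abs(frac - 0.25), 0.02)
  ## baseline block and exposure stay fully observed
  expect_equal(sum(is.na(com[c(p$roles$baseline, p$roles$exposure)])), 0)
  ## exposed rows are more often incomplete, as in cohort attrition
  com2 <- impose_missingness(co, p, seed = 3)
  miss <- data.frame(any_missing = as.numeric(!stats::complete.cases(com2)),
                     x = co$conduct_problems)
  fit <- fit_glm(miss, "any_missing", "x")
  est <- odds_ratio_ci(fit, "x")
  expect_gt(est$estimate, 1)
  expect_lt(est$p, 0.05)
  ## masking is reproducible and refuses partially observed input
  expect_identical(com, impose_missingness(co, p, rate = 0.25, seed = 2))
  expect_error(impose_missingness(com, p, seed = 1), "fully observed")
})
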