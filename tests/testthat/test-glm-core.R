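test_that("logistic fit on a saturated 2x2 equals the closed-form odds ratio", {
  ## exposed 40 cases / 10 non-cases, unexposed 20 / 30: OR = ad/bc = 6
  d <- expand_2x2(40, 10, 20, 30)
  fit <- fit_glm(d, "y", "x")
  expect_true(fit$converged)
  expect_equal(fit$coefficients[["x"]], log(6), tolerance = 1e-8)
  ## Woolf variance 1/a + 1/b + 1/c + 1/d
  se_woolf <- sqrt(1 / 40 + 1 / 10 + 1 / 20 + 1 / 30)
  expect_equal(sqrt(fit$vcov["x", "x"]), se_woolf, tolerance = 1e-6)
  est <- odds_ratio_ci(fit, "x")
  expect_equal(est$lower, exp(log(6) - stats::qnorm(0.975) * se_woolf),
               tolerance = 1e-6)
  expect_equal(est$upper, exp(log(6) + stats::qnorm(0.975) * se_woolf),
               tolerance = 1e-6)
})

test_that("independent balanced exposure and outcome give a null estimate", {
  d <- expand_2x2(25, 25, 25, 25)
  fit <- fit_glm(d, "y", "x")
  expect_equal(fit$coefficients[["x"]], 0, tolerance = 1e-10)
  expect_equal(odds_ratio_ci(fit, "x")$estimate, 1, tolerance = 1e-10)
})

test_that("perfect separation is annotated and resolved by a penalized refit", {
  d <- expand_2x2(30, 0, 10, 40)   # every exposed row is a case
  fit <- fit_glm(d, "y", "x")
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_match(fit$note, "separation")
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(sqrt(diag(fit$vcov)))))
})

test_that("the Wald interval around a null coefficient is exp(+-1.96 SE)", {
  model <- structure(list(coefficients = c("(Intercept)" = 0.2, x = 0),
                          vcov = diag(c(0.04, 0.01)), family = "binomial",
                          converged = TRUE),
                     class = "gc_glm")
  dimnames(model$vcov) <- rep(list(c("(Intercept)", "x")), 2)
  est <- odds_ratio_ci(model, "x")
  expect_equal(est$estimate, 1)
  expect_equal(est$lower, 0.822, tolerance = 1e-3)
  expect_equal(est$upper, 1.217, tolerance = 1e-3)
  expect_equal(est$p, 1)
  expect_error(odds_ratio_ci(model, "nope"), "not among")
})

test_that("recoding the exposure inverts the odds ratio", {
  set.seed(42)
  d <- data.frame(x = rbinom(400, 1, 0.4))
  d$y <- rbinom(400, 1, gcmediate:::expit(-0.5 + 0.8 * d$x))
  d$xr <- 1 - d$x
  or1 <- odds_ratio_ci(fit_glm(d, "y", "x"), "x")$estimate
  or2 <- odds_ratio_ci(fit_glm(d, "y", "xr"), "xr")$estimate
  expect_equal(or1, 1 / or2, tolerance = 1e-8)
})

test_that("the linear family equals the normal-equations solution", {
  set.seed(7)
  d <- data.frame(a = rnorm(200), b = rbinom(200, 1, 0.5))
  d$y <- 1.5 + 0.8 * d$a - 0.4 * d$b + rnorm(200)
  fit <- fit_glm(d, "y", c("a", "b"), family = "gaussian")
  X <- cbind(1, d$a, d$b)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-10)
  ## Wald covariance matches the classical least-squares covariance
  lmfit <- stats::lm(y ~ a + b, data = d)
  expect_equal(unname(fit$vcov), unname(stats::vcov(lmfit)), tolerance = 1e-8)
})

test_that("listwise deletion and input checks behave as declared", {
  d <- data.frame(x = c(1, 0, 1, NA, 0, 1), y = c(1, 0, 0, 1, NA, 1))
  fit <- fit_glm(d, "y", "x")
  expect_equal(fit$n, 4)
  expect_error(fit_glm(d, "y", "y"), "not.*among the predictors")
  expect_error(fit_glm(d, "y", "zz"), "not found")
  expect_error(fit_glm(data.frame(x = NA_real_, y = NA_real_), "y", "x"),
               "complete")
})

test_that("an unadjusted table row equals a lone fit, and adjustment removes confounding", {
  p <- tiny_params(pc = 0.5, bx = c(i = -1.5, c1 = 2.0),
                   bm = c(i = -1.5, x = 0.9, c1 = 1.8),
                   by = c(i = -1.5, x = 0.7, c1 = 1.1, m1 = 0.6))
  co <- generate_cohort(p, 4e4, seed = 21)
  tab <- association_table(co, data.frame(predictor = "x", outcome = "m1"),
                           list(unadjusted = character(), adjusted = "c1"))
  lone <- odds_ratio_ci(fit_glm(co, "m1", "x"), "x")
  expect_equal(tab$estimate[tab$stage == "unadjusted"], lone$estimate,
               tolerance = 1e-12)
  ## the adjusted estimate recovers the structural conditional log odds
  ## ratio (0.9); the unadjusted one is confounded away from it
  b_adj <- log(tab$estimate[tab$stage == "adjusted"])
  b_un <- log(tab$estimate[tab$stage == "unadjusted"])
  expect_lt(abs(b_adj - 0.9), abs(b_un - 0.9))
  se_adj <- (log(tab$upper[tab$stage == "adjusted"]) - b_adj) / 1.96
  expect_lt(abs(b_adj - 0.9), 3 * se_adj)
})

test_that("a null exposure-mediator arrow keeps intervals covering one across stages", {
  ## exposure fully disconnected (no incoming confounding, no outgoing
  ## arrows to post-exposure variables): every adjustment stage then
  ## targets a genuinely null association
  p <- default_pelotas_params()
  p <- zero_exposure_in(p, c(p$roles$intermediate, p$roles$mediators))
  p <- zero_coefs(p, "conduct_problems",
                  setdiff(names(p$vars$conduct_problems$coef), "(Intercept)"))
  stages <- list(unadjusted = character(),
                 baseline = p$roles$baseline,
                 full = c(p$roles$baseline, p$roles$intermediate))
  n_rep <- 30
  cover <- matrix(NA, n_rep, length(stages))
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(p, 4599, seed = 500 + r)
    tab <- association_table(co,
                             data.frame(predictor = "conduct_problems",
                                        outcome = "gang_member"), stages)
    cover[r, ] <- tab$lower <= 1 & tab$upper >= 1
  }
  for (j in seq_along(stages))
    expect_gte(mean(cover[, j]), 0.9)
})

test_that("fitting errors are annotated per row and the table is still returned", {
  d <- data.frame(x = c(1, 0, 1, 0), m = c(1, 1, 0, 0), y = c(NA, NA, NA, NA))
  tab <- association_table(d, data.frame(predictor = "x",
                                         outcome = c("m", "y")),
                           list(unadjusted = character()))
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$estimate[tab$outcome == "y"]))
  expect_match(tab$note[tab$outcome == "y"], "complete")
})

test_that("p-values print to three decimals with the <0.001 floor", {
  expect_identical(format_p(c(0.0004, 0.049999, 0.5, NA)),
                   c("<0.001", "0.050", "0.500", NA))
})
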