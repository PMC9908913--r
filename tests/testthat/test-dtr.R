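make_panel_k1 <- function(d) {
  stage_panel(list(list(eta = rep(1, length(d$a)), treatment = d$a,
                        features = d$x)),
              response = d$y)
}

test_that("panel validation enforces the at-risk structure", {
  expect_error(stage_panel(list(list(eta = c(1, 0), treatment = c(0, 1),
                                     features = matrix(0, 2, 1)))),
               "at risk at stage 1")
  expect_error(stage_panel(list(
    list(eta = c(1, 1), treatment = c(0, 1), features = matrix(0, 2, 1)),
    list(eta = c(1, 1), treatment = c(0, 1), features = matrix(0, 2, 1)),
    list(eta = c(1, 0), treatment = c(0, 1), features = matrix(0, 2, 1)),
    list(eta = c(1, 1), treatment = c(0, 1), features = matrix(0, 2, 1)))),
    "nonincreasing")
})

test_that("terminal-stage contrast equals the single-stage AIPW contrast", {
  set.seed(51)
  d <- gen_single_stage(200)
  pan <- make_panel_k1(d)
  pr <- fit_propensity(d$a, kind = "empirical")
  om <- fit_outcome_model(d$y, d$a, d$x)
  cv_stage <- stage_dr_contrast(pan, 1, d$y, pr, outcome = om)
  cv_direct <- dr_contrast(d$y, d$a, pr, om, d$x)
  expect_equal(cv_stage$contrast, cv_direct$contrast, tolerance = 1e-12)
  # null Q-model: reduces to IPW applied to the propagated value
  om0 <- fit_outcome_model(rep(0, 200), d$a, d$x)
  cv0 <- stage_dr_contrast(pan, 1, d$y, pr, outcome = om0)
  cv_ipw <- ipw_contrast(d$y, d$a, pr, d$x)
  expect_equal(cv0$contrast, cv_ipw$contrast, tolerance = 1e-12)
})

test_that("the four-term stage contrast evaluates as printed", {
  # A=1, pi1=0.5, V=2, mu1=1, mu0=3 -> 2/0.5 - 1 - 3 = 0
  pan <- stage_panel(list(list(eta = rep(1, 2), treatment = c(1, 0),
                               features = matrix(0, 2, 1))),
                     response = c(2, 2))
  pr <- fit_propensity(c(1, 0), kind = "known",
                       known_fun = function(x) rep(0.5, nrow(x)))
  om <- structure(list(arms = c(0, 1), p = 1,
                       fits = list(`0` = list(kind = "linear", coef = c(3, 0)),
                                   `1` = list(kind = "linear", coef = c(1, 0)))),
                  class = "outcome_model")
  cv <- suppressWarnings(stage_dr_contrast(pan, 1, c(2, 2), pr, outcome = om))
  expect_equal(cv$contrast[1], 0, tolerance = 1e-12)
})

test_that("value propagation follows the regret identities", {
  cv <- contrast_vector(c(2, -1, 0.5))
  attr(cv, "index") <- 1:3
  a <- c(0, 1, 1); eta <- c(1, 1, 1); v <- c(5, 5, 5)
  dec <- c(1, 0, 1)
  up <- propagate_value(v, cv, dec, a, eta, "maximize")
  expect_equal(up, c(7, 6, 5))                       # +|C| on mismatch
  dn <- propagate_value(v, cv, dec, a, eta, "minimize")
  expect_equal(dn, c(3, 4, 5))
  # matched decisions leave the value untouched
  expect_equal(propagate_value(v, cv, a, a, eta, "maximize"), v)
  # eta = 0 rows pass through
  cv2 <- contrast_vector(2); attr(cv2, "index") <- 2L
  expect_equal(propagate_value(c(1, 1, 1), cv2, 1, c(0, 0, 0), c(0, 1, 0),
                               "maximize"), c(1, 3, 1))
  # regret identity elementwise
  expect_equal(up - v, abs(cv$contrast) * (dec != a), tolerance = 1e-12)
})

test_that("K = 1 backward fit equals the standalone single-stage pipeline", {
  set.seed(52)
  d <- gen_single_stage(250)
  pan <- make_panel_k1(d)
  fit <- fit_dtr(pan, "maximize", "pdwl", scad = scad_spec(lambda = 0.02))
  pr <- fit_propensity(d$a, kind = "empirical")
  om <- fit_outcome_model(d$y, d$a, d$x)
  cv <- dr_contrast(d$y, d$a, pr, om, d$x)
  rule <- fit_rule(d$x, cv, scad_spec(lambda = 0.02))
  expect_identical(fit$rules[[1]]$coefficients, rule$coefficients)
  expect_identical(fit$rules[[1]]$intercept, rule$intercept)
})

test_that("two-stage fits keep the value monotone and recover both rules", {
  th_err <- cdr1 <- numeric(3)
  for (i in 1:3) {
    spec <- scenario_spec("s1_survival", n = 1000, censoring = 0.15,
                          seed = 30 + i)
    sim <- sim_scenario(spec)
    y <- jackknife_pseudo(sim$data$time, sim$data$cause,
                          pseudo_target("survival", 3))
    fit <- with_seed(9 + i,
                     fit_dtr(sim$panel, "maximize", "pdwl", response = y,
                             scad = scad_spec(grid_length = 10),
                             folds = 3))
    expect_true(all(fit$values[, 1] >= fit$values[, 2] - 1e-12))
    expect_true(all(fit$values[, 2] >= fit$values[, 3] - 1e-12))
    # stage-2 rule loads on x2 (feature 12) with threshold near 0.5
    r2 <- fit$rules[[2]]
    expect_gt(abs(r2$coefficients[12]), 0)
    th_err[i] <- abs(-r2$intercept / r2$coefficients[12] - 0.5)
    ev <- evaluate_regime(fit, "s1_survival", n_test = 20000, seed = 99 + i)
    cdr1[i] <- ev$cdr1
  }
  expect_lt(mean(th_err), 0.2)
  expect_gt(mean(cdr1), 0.85)
})

test_that("competing-risks objective flips the classification sign", {
  spec <- scenario_spec("s1_competing", n = 800, censoring = 0.15, seed = 32)
  sim <- sim_scenario(spec)
  y <- jackknife_pseudo(sim$data$time, sim$data$cause,
                        pseudo_target("cif", 3, cause = 1))
  fit <- with_seed(10, fit_dtr(sim$panel, "minimize", "pdwl", response = y,
                               scad = scad_spec(grid_length = 10),
                               folds = 3))
  expect_true(all(fit$values[, 1] <= fit$values[, 3] + 1e-12))
  ev <- evaluate_regime(fit, "s1_competing", n_test = 20000, seed = 100)
  expect_gt(ev$cdr1, 0.7)
  expect_lt(ev$value, 0.33)  # clearly below the constant-rule incidence
})

test_that("predict_regime applies the strict indicator rule", {
  pan <- stage_panel(list(list(eta = c(1, 1), treatment = c(0, 1),
                               features = matrix(c(0, 0.7), 2, 1))),
                     response = c(0, 1))
  fit <- list(rules = list(linear_rule(-0.5, 1)), K = 1L)
  class(fit) <- "dtr_fit"
  expect_equal(predict_regime(fit, matrix(c(0.7, 0.3, 0.5), 3, 1), 1),
               c(1, 0, 0))
  expect_error(predict_regime(fit, matrix(0, 1, 2), 1), "dimension")
})
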