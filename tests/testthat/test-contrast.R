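test_that("empirical and known propensities pass through", {
  pr <- fit_propensity(c(1, 1, 0, 0), kind = "empirical")
  p <- predict(pr, matrix(0, 4, 1))
  expect_equal(unname(p[, "1"]), rep(0.5, 4))
  prk <- fit_propensity(c(0, 1), kind = "known",
                        known_fun = function(x) rep(0.3, nrow(x)))
  expect_equal(unname(predict(prk, matrix(0, 3, 1))[, "1"]), rep(0.3, 3))
  expect_error(fit_propensity(rep(1, 5)), "two observed arms")
})

test_that("logistic propensity recovers the assignment model", {
  set.seed(31)
  n <- 5000
  x <- matrix(runif(3 * n, -2, 2), n, 3)
  p1 <- 1 / (1 + exp(-(x[, 2] - 0.6 * x[, 3])))
  a <- rbinom(n, 1, p1)
  pr <- fit_propensity(a, x, kind = "logistic")
  phat <- predict(pr, x)[, "1"]
  expect_lt(mean(abs(phat - p1)), 0.02)
  # multinomial route agrees on two arms
  prm <- fit_propensity(a, x, kind = "multinomial")
  expect_lt(max(abs(predict(prm, x)[, "1"] - phat)), 0.02)
})

test_that("outcome model is exact for noiseless linear responses", {
  set.seed(32)
  x <- matrix(runif(60, -1, 1), 30, 2)
  a <- rep(c(0, 1), 15)
  y <- 2 * a + x[, 1]
  om <- fit_outcome_model(y, a, x)
  expect_equal(predict(om, 1, x) - predict(om, 0, x), rep(2, 30),
               tolerance = 1e-10)
  # constant response in both arms: zero contrast
  om0 <- fit_outcome_model(rep(3.3, 30), a, x)
  expect_equal(predict(om0, 1, x) - predict(om0, 0, x), rep(0, 30),
               tolerance = 1e-10)
  expect_error(fit_outcome_model(y[1:3], a[1:3], x[1:3, ]), "fewer")
})

test_that("IPW contrast evaluates the weighting identity", {
  pr <- fit_propensity(c(0, 1), kind = "known",
                       known_fun = function(x) rep(0.5, nrow(x)))
  cv <- ipw_contrast(c(2, 2, 0), c(1, 0, 1), pr, matrix(0, 3, 1))
  expect_equal(cv$contrast, c(4, -4, 0))
  expect_equal(cv$weight * cv$label, cv$contrast)  # w * Z reconstructs C
  expect_equal(cv$label[3], 1)                      # zero tie-break to +1
})

test_that("AIPW arm mean matches its algebra", {
  pr <- fit_propensity(c(0, 1), kind = "known",
                       known_fun = function(x) rep(0.5, nrow(x)))
  om <- fit_outcome_model(c(1.5, 1.5, 9, 9), c(1, 1, 0, 0),
                          matrix(0, 4, 1))
  # A=1, a=1: 2*2 + (1-2)*1.5 = 2.5
  expect_equal(dr_mu(2, 1, pr, om, 1, matrix(0, 1, 1)), 2.5)
  # A=0, a=1: augmentation only
  expect_equal(dr_mu(2, 0, pr, om, 1, matrix(0, 1, 1)), 1.5)
  # propensity exactly I(A=a): returns Y
  prd <- fit_propensity(c(0, 1), kind = "known",
                        known_fun = function(x) rep(1 - 1e-9, nrow(x)),
                        trunc = c(1e-12, 1))
  expect_equal(dr_mu(2, 1, prd, om, 1, matrix(0, 1, 1)), 2,
               tolerance = 1e-6)
})

test_that("doubly-robust contrast reduces to IPW with a null Q-model", {
  set.seed(33)
  d <- gen_single_stage(100)
  pr <- fit_propensity(d$a, d$x, kind = "logistic")
  om0 <- fit_outcome_model(rep(0, 100), d$a, d$x)  # mu == 0 exactly
  cv_dr <- dr_contrast(d$y, d$a, pr, om0, d$x)
  cv_ipw <- ipw_contrast(d$y, d$a, pr, d$x)
  expect_equal(cv_dr$contrast, cv_ipw$contrast, tolerance = 1e-12)
})

test_that("the contrast is consistent when either model is correct", {
  # double robustness: mean contrast near truth under single misspecification
  set.seed(34)
  truth <- -0.3  # E(x2) - 0.3
  for (mis in c("propensity", "outcome")) {
    est <- replicate(60, {
      d <- gen_single_stage(400)
      pr <- if (mis == "propensity")
        fit_propensity(d$a, kind = "empirical")     # wrong: ignores x1
      else fit_propensity(d$a, d$x, kind = "logistic")
      om <- if (mis == "outcome")
        fit_outcome_model(d$y, d$a, 0 * d$x)  # intercept-only: wrong Q-model
      else fit_outcome_model(d$y, d$a, d$x)
      mean(dr_contrast(d$y, d$a, pr, om, d$x)$contrast)
    })
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - truth), 3 * mc_se + 0.02)
  }
})

test_that("AIPW is no noisier than IPW when both models are correct", {
  set.seed(35)
  wins <- replicate(30, {
    d <- gen_single_stage(500)
    pr <- fit_propensity(d$a, d$x, kind = "logistic")
    om <- fit_outcome_model(d$y, d$a, d$x)
    var(dr_contrast(d$y, d$a, pr, om, d$x)$contrast) <=
      var(ipw_contrast(d$y, d$a, pr, d$x)$contrast)
  })
  expect_gt(mean(wins), 0.5)
})
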