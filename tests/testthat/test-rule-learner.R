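test_that("SCAD derivative follows its three branches", {
  expect_equal(scad_derivative(0.5, 1), 1)
  expect_equal(scad_derivative(10, 1), 0)
  expect_equal(scad_derivative(2, 1), (3.7 - 2) / 2.7)
  expect_equal(scad_derivative(c(0, 1, 5), 0), rep(0, 3))
  expect_error(scad_derivative(1, 1, gamma = 2), "gamma > 2")
})

test_that("l2-SVM initializer finds the separating direction", {
  r <- init_rule_l2(matrix(c(1, -1), 2, 1), c(1, -1), c(1, 1))
  expect_gt(r$coefficients[1], 0)
  rf <- init_rule_l2(matrix(c(1, -1), 2, 1), c(-1, 1), c(1, 1))
  expect_lt(rf$coefficients[1], 0)
  expect_warning(init_rule_l2(matrix(1:3, 3, 1), c(1, 1, 1), rep(1, 3)),
                 "single-class")
})

test_that("l2-SVM solution is optimal (duality gap and generic oracle)", {
  set.seed(41)
  for (r in 1:5) {
    n <- 30
    x <- matrix(rnorm(n * 2), n, 2)
    z <- sign(x[, 1] + 0.5 * rnorm(n)); z[z == 0] <- 1
    w <- rexp(n)
    rule <- init_rule_l2(x, z, w, cost = 1)
    obj <- attr(rule, "objective")
    oracle <- l2svm_oracle(x, z, w, cost = 1)
    expect_lte(obj, oracle + 1e-4)   # never worse than the generic solver
    expect_gte(obj, oracle - 0.05)   # and the oracle did not fail badly
  }
})

test_that("LP solution matches the separable and degenerate corners", {
  # separable pair, no penalty: zero slack, zero objective
  sol <- solve_weighted_l1_svm(matrix(c(1, -1), 2, 1), c(1, -1), c(1, 1), 0)
  expect_equal(sol$objective, 0, tolerance = 1e-9)
  expect_equal(sol$slacks, c(0, 0), tolerance = 1e-9)
  expect_equal(sol$status, "optimal")
  # all weights zero: the penalty alone drives beta to zero
  sol0 <- solve_weighted_l1_svm(matrix(rnorm(10), 5, 2), rep(1, 5),
                                rep(0, 5), c(1, 1))
  expect_equal(sol0$rule$coefficients, c(0, 0))
  expect_equal(sol0$objective, 0, tolerance = 1e-12)
})

test_that("LP objective matches a generic simplex oracle", {
  skip_if_not_installed("boot")
  set.seed(42)
  for (r in 1:25) {
    n <- sample(8:40, 1); p <- sample(1:6, 1)
    h <- matrix(rnorm(n * p), n)
    z <- sample(c(-1, 1), n, TRUE)
    w <- rexp(n) * rbinom(n, 1, 0.9)
    d <- rexp(p) * rbinom(p, 1, 0.85)
    sol <- solve_weighted_l1_svm(h, z, w, d)
    o <- lp_oracle(h, z, w, d)
    expect_equal(sol$objective, o$objective, tolerance = 1e-6)
    # feasibility of the recovered primal
    f <- sol$rule$intercept + drop(h %*% sol$rule$coefficients)
    expect_true(all(z * f >= 1 - sol$slacks - 1e-8))
  }
})

test_that("weight/penalty rescaling and beta rescaling leave decisions fixed", {
  set.seed(43)
  n <- 40
  h <- matrix(rnorm(n * 3), n)
  z <- sign(h[, 1] + 0.3 * rnorm(n)); z[z == 0] <- 1
  w <- rexp(n); d <- c(0.05, 0.05, 0.05)
  s1 <- solve_weighted_l1_svm(h, z, w, d)
  s2 <- solve_weighted_l1_svm(h, z, 7 * w, 7 * d)
  grid <- matrix(rnorm(600), 200, 3)
  expect_equal(predict(s1$rule, grid), predict(s2$rule, grid))
  expect_equal(s2$objective, 7 * s1$objective, tolerance = 1e-8)
  # positive rescaling of a rule never changes its decisions
  r2 <- linear_rule(3 * s1$rule$intercept, 3 * s1$rule$coefficients)
  expect_equal(predict(s1$rule, grid), predict(r2, grid))
})

test_that("label flip mirrors the fitted rule", {
  set.seed(44)
  h <- matrix(rnorm(60), 30, 2)
  z <- sign(h[, 1]); z[z == 0] <- 1
  w <- rexp(30)
  s <- solve_weighted_l1_svm(h, z, w, c(0.1, 0.1))
  sf <- solve_weighted_l1_svm(h, -z, w, c(0.1, 0.1))
  grid <- matrix(rnorm(400), 200, 2)
  f1 <- s$rule$intercept + drop(grid %*% s$rule$coefficients)
  f2 <- sf$rule$intercept + drop(grid %*% sf$rule$coefficients)
  expect_equal(f1, -f2, tolerance = 1e-6)
})

test_that("a dominating penalty yields an intercept-only rule", {
  set.seed(45)
  d <- gen_single_stage(150)
  cv <- contrast_vector(d$true_contrast + rnorm(150, 0, 0.2))
  r <- fit_rule(d$x, cv, scad_spec(lambda = 50))
  expect_equal(r$coefficients, c(0, 0))
})

test_that("the boundary decision is strict", {
  r <- linear_rule(0, 1)
  expect_equal(predict(r, matrix(0, 1, 1)), 0)  # f == 0 -> action 0
  expect_equal(predict(linear_rule(-1, 0), matrix(5, 1, 1)), 0)
  expect_equal(predict(linear_rule(-0.5, 1), matrix(0.7, 1, 1)), 1)
})

test_that("rule recovery: stage-2-type contrast with a single tailoring variable", {
  set.seed(46)
  n <- 1000
  x <- matrix(runif(n, -2, 2), n, 1)
  # doubly-robust-style weights around the true threshold 0.5
  cv <- contrast_vector(x[, 1] - 0.5 + rnorm(n, 0, 0.4))
  r <- fit_rule(x, cv, scad_spec(lambda = 0.01))
  expect_lt(abs(-r$intercept / r$coefficients[1] - 0.5), 0.15)
})

test_that("SCAD path zeroes most noise coefficients", {
  set.seed(47)
  hits <- replicate(15, {
    n <- 400; p <- 10
    x <- matrix(runif(n * p, -2, 2), n, p)
    cv <- contrast_vector(x[, 1] - 0.4 * x[, 2] + rnorm(n, 0, 0.4))
    r <- fit_rule(x, cv, scad_spec(grid_length = 10), folds = 3)
    sum(r$coefficients[3:10] == 0)
  })
  expect_gte(mean(hits >= 6), 0.8)
})

test_that("lambda selection degenerates sensibly", {
  set.seed(48)
  x <- matrix(runif(200, -1, 1), 100, 2)
  cv <- contrast_vector(rnorm(100))
  expect_equal(select_lambda(x, cv, scad_spec(lambda_grid = 0.3)), 0.3)
  # pure noise labels: prefer the sparsest model most of the time
  grid <- c(0.001, 0.01, 0.5)
  top <- replicate(30, {
    cvr <- contrast_vector(rnorm(100))
    select_lambda(x, cvr, scad_spec(lambda_grid = grid), folds = 3)
  })
  expect_gte(mean(top == 0.5), 0.7)
})

test_that("tuned rules beat the intercept-only rule under strong signal", {
  set.seed(49)
  wins <- replicate(12, {
    n <- 300
    x <- matrix(runif(2 * n, -2, 2), n, 2)
    cv <- contrast_vector(x[, 1] - 0.5 + rnorm(n, 0, 0.3))
    lam <- select_lambda(x, cv, scad_spec(grid_length = 10),
                         folds = 3)
    r <- fit_rule(x, cv, scad_spec(lambda = lam))
    r0 <- fit_rule(x, cv, scad_spec(lambda = 50))  # intercept-only
    ho <- gen_single_stage(2000)
    xh <- matrix(runif(4000, -2, 2), 2000, 2)
    zt <- ifelse(xh[, 1] > 0.5, 1, -1)
    mean(ifelse(predict(r, xh) == 1, 1, -1) == zt) >=
      mean(ifelse(predict(r0, xh) == 1, 1, -1) == zt)
  })
  expect_gte(mean(wins), 0.9)
})
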