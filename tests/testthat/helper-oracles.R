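# Independent reference implementations used to cross-check the package.

# Primal LP oracle for the weighted L1-SVM, built directly from the split
# variable formulation and solved with boot::simplex (generic dense simplex,
# unrelated to the package's dual solver).  boot::simplex mishandles systems
# with only ">=" constraints, so one loose "<=" row is added.
lp_oracle <- function(h, z, w, d) {
  n <- nrow(h); p <- ncol(h)
  nv <- 2L + 2L * p + n  # b0+, b0-, beta+, beta-, xi
  a2 <- cbind(z, -z, z * h, -(z * h), diag(n))
  s <- boot::simplex(a = c(0, 0, d, d, w),
                     A1 = matrix(1, 1, nv), b1 = 1e6,
                     A2 = a2, b2 = rep(1, n), maxi = FALSE,
                     n.iter = 200 * (n + 2 * p + 2), eps = 1e-10)
  list(objective = unname(s$value), solved = s$solved)
}

# exact weighted-hinge + ridge objective of the l2-SVM
l2svm_objective <- function(par, x, z, w, cost) {
  b0 <- par[1L]; beta <- par[-1L]
  0.5 * sum(beta^2) +
    cost * sum(w * pmax(0, 1 - z * (b0 + drop(x %*% beta))))
}

# multi-start Nelder-Mead minimizer of the convex l2-SVM objective
l2svm_oracle <- function(x, z, w, cost = 1, starts = 6L) {
  p <- ncol(x)
  best <- Inf
  set.seed(4242)
  for (s in seq_len(starts)) {
    par0 <- if (s == 1L) rep(0, p + 1L) else rnorm(p + 1L)
    for (pass in 1:3) {
      o <- optim(par0, l2svm_objective, x = x, z = z, w = w, cost = cost,
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
      par0 <- o$par
    }
    best <- min(best, o$value)
  }
  best
}

# small random censored survival sample
rand_surv <- function(n, n_causes = 1L, cens_prob = 0.3) {
  time <- round(rexp(n, 0.3), 2)  # rounding forces ties
  status <- ifelse(runif(n) < cens_prob, 0L, sample(n_causes, n, TRUE))
  list(time = time, status = status)
}

# simple single-stage generative model for contrast-module checks:
# A ~ Bern(expit(0.8 x1)), Y = 1 + x1 + A * (x2 - 0.3) + noise
gen_single_stage <- function(n, sd = 0.5) {
  x <- matrix(runif(2L * n, -1, 1), n, 2L,
              dimnames = list(NULL, c("x1", "x2")))
  pa <- 1 / (1 + exp(-0.8 * x[, 1L]))
  a <- rbinom(n, 1L, pa)
  y <- 1 + x[, 1L] + a * (x[, 2L] - 0.3) + rnorm(n, 0, sd)
  list(x = x, a = a, y = y, pa = pa, true_contrast = x[, 2L] - 0.3)
}

default_grid <- function(len = 6L) exp(seq(log(2e-4), log(0.2),
                                           length.out = len))
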