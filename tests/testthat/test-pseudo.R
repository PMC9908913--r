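test_that("product-limit survival matches hand calculations", {
  # no censoring: empirical proportion beyond t
  expect_equal(km_survival(c(1, 2, 4, 5), c(1, 1, 1, 1), 3), 0.5)
  # one censored at 2: risk sets {3,2,1}, jump only at t = 1 and 4
  expect_equal(km_survival(c(1, 2, 4), c(1, 0, 1), 3), 2 / 3)
  expect_equal(km_survival(c(1, 2, 4), c(1, 0, 1), 0), 1)
  # beyond the last event
  expect_equal(km_survival(c(1, 2, 4, 5), c(1, 1, 1, 1), 99), 0)
  expect_error(km_survival(numeric(0), numeric(0), 1), "no observations")
})

test_that("survival curve is nonincreasing and matches survfit", {
  set.seed(11)
  for (r in 1:20) {
    d <- rand_surv(30)
    ts <- sort(unique(c(0, d$time, max(d$time) + 1)))
    s <- km_survival(d$time, d$status, ts)
    expect_true(all(diff(s) <= 1e-12))
    fit <- survival::survfit(survival::Surv(d$time, d$status) ~ 1)
    expect_equal(km_survival(d$time, d$status, fit$time), fit$surv,
                 tolerance = 1e-12)
  }
})

test_that("cumulative incidence matches hand calculation and survfit", {
  # jump 1/3 at t=1 (cause 1); cause-2 jump at t=2 not counted
  expect_equal(cause_specific_cif(c(1, 2, 3), c(1, 2, 1), 2.5, 1), 1 / 3)
  expect_equal(cause_specific_cif(c(1, 2, 3), c(1, 2, 1), 0, 1), 0)
  expect_warning(cause_specific_cif(c(1, 2), c(1, 1), 1, cause = 2),
                 "no events")
  set.seed(12)
  for (r in 1:10) {
    d <- rand_surv(40, n_causes = 2L)
    st <- factor(ifelse(d$status == 0, "censor", paste0("cause", d$status)),
                 levels = c("censor", "cause1", "cause2"))
    fit <- survival::survfit(survival::Surv(d$time, st) ~ 1)
    for (cs in 1:2) {
      col <- match(paste0("cause", cs), fit$states)
      mine <- cause_specific_cif(d$time, d$status, fit$time, cs)
      expect_equal(mine, unname(fit$pstate[, col]), tolerance = 1e-12)
      expect_true(all(diff(mine) >= -1e-12))  # nondecreasing
    }
  }
})

test_that("with no censoring, CIFs and survival partition the mass", {
  set.seed(13)
  d <- rand_surv(60, n_causes = 3L, cens_prob = 0)
  tt <- c(0.5, 2, 5, 20)
  tot <- km_survival(d$time, d$status, tt) +
    Reduce(`+`, lapply(1:3, function(cs)
      cause_specific_cif(d$time, d$status, tt, cs)))
  expect_equal(tot, rep(1, length(tt)))
})

test_that("complete-data pseudo-values reproduce the event indicators", {
  set.seed(14)
  n <- 50
  tm <- rexp(n, 0.25)
  dd <- sample(1:2, n, TRUE)
  ps <- jackknife_pseudo(tm, dd, pseudo_target("survival", 3))
  expect_equal(as.numeric(ps), as.numeric(tm > 3), tolerance = 1e-12)
  pc <- jackknife_pseudo(tm, dd, pseudo_target("cif", 3, cause = 1))
  expect_equal(as.numeric(pc), as.numeric(tm <= 3 & dd == 1),
               tolerance = 1e-12)
})

test_that("pseudo-value mean identity and n = 1 guard hold", {
  set.seed(15)
  d <- rand_surv(25)
  tg <- pseudo_target("survival", 2)
  ps <- jackknife_pseudo(d$time, d$status, tg)
  # mean of pseudo-values equals n*theta - (n-1)*mean(loo)
  expect_equal(mean(ps), length(d$time) * km_survival(d$time, d$status, 2) -
                 (length(d$time) - 1) *
                 mean(vapply(seq_along(d$time), function(i)
                   km_survival(d$time[-i], d$status[-i], 2), numeric(1))))
  expect_error(jackknife_pseudo(1, 1, tg), "n >= 2")
})

test_that("grouped jackknife equals the naive survfit refit", {
  set.seed(16)
  targets <- list(pseudo_target("survival", 2),
                  pseudo_target("cif", 2, cause = 1),
                  pseudo_target("rmst", 2.5))
  for (r in 1:15) {
    d <- rand_surv(sample(5:40, 1), n_causes = sample(1:2, 1))
    for (tg in targets) {
      if (tg$functional == "cif" && !any(d$status == 1)) next
      a <- suppressWarnings(jackknife_pseudo(d$time, d$status, tg, "grouped"))
      b <- suppressWarnings(jackknife_pseudo(d$time, d$status, tg, "naive"))
      expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
    }
  }
})

test_that("censoring models behave at the edges", {
  set.seed(17)
  # no censored records: degenerate G == 1 with a warning
  expect_warning(G1 <- fit_censoring_model(1:5, rep(1, 5)), "no censored")
  expect_equal(G1$survivor(c(1, 4)), c(1, 1))
  # all censored: G equals the KM of the observed times
  d <- rand_surv(30, cens_prob = 1)
  G <- fit_censoring_model(d$time, d$status, kind = "marginal_km")
  flip <- survival::survfit(survival::Surv(d$time, 1 - (d$status > 0)) ~ 1)
  expect_equal(G$survivor(flip$time), flip$surv, tolerance = 1e-12)
})

test_that("Cox censoring fit ignores a null covariate", {
  set.seed(18)
  n <- 1500
  x <- cbind(z1 = runif(n, -1, 1))
  tm <- rexp(n, 0.3)
  cn <- rexp(n, 0.2)  # censoring free of x
  time <- pmin(tm, cn); status <- as.integer(tm <= cn)
  G <- fit_censoring_model(time, status, covariates = x,
                           kind = "cox_on_covariates")
  g_lo <- G$survivor(rep(1.5, 2), cbind(z1 = c(-0.9, 0.9)))
  expect_lt(abs(diff(g_lo)), 0.1)
})

test_that("IPCW pseudo-values reduce to the plain jackknife without censoring", {
  set.seed(19)
  n <- 40
  tm <- rexp(n, 0.3); st <- rep(1L, n)
  plain <- jackknife_pseudo(tm, st, pseudo_target("survival", 2))
  G <- suppressWarnings(fit_censoring_model(tm, st))
  for (v in c("weighted", "direct")) {
    ip <- ipcw_pseudo_survival(tm, st, 2, G, variant = v)
    expect_equal(as.numeric(ip), as.numeric(plain), tolerance = 1e-10)
  }
})

test_that("plain and IPCW estimators agree under independent censoring", {
  # Monte Carlo: all three pseudo-value means estimate the same survival
  set.seed(20)
  diffs <- replicate(30, {
    n <- 200
    tm <- rexp(n, 0.25); cn <- rexp(n, 0.1)
    time <- pmin(tm, cn); status <- as.integer(tm <= cn)
    G <- fit_censoring_model(time, status, kind = "marginal_km")
    s_plain <- mean(jackknife_pseudo(time, status,
                                     pseudo_target("survival", 3)))
    s_w <- mean(ipcw_pseudo_survival(time, status, 3, G, variant = "weighted"))
    s_d <- mean(ipcw_pseudo_survival(time, status, 3, G, variant = "direct"))
    c(abs(s_plain - s_w), abs(s_plain - s_d))
  })
  expect_lt(mean(diffs[1, ]), 0.03)
  expect_lt(mean(diffs[2, ]), 0.03)
})
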