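#' Specify the survival functional targeted by pseudo-observations
#'
#' A pseudo-observation target is a functional theta = E s(T) of the event
#' time: `"survival"` uses s(T) = I(T > t), `"cif"` uses
#' s(T) = I(T <= t, D = cause) under competing risks, and `"rmst"` uses
#' s(T) = min(T, tau), the restricted mean survival time.
#'
#' @param functional one of `"survival"`, `"cif"`, `"rmst"`.
#' @param horizon positive time horizon: `t` for survival/CIF, `tau` for RMST.
#' @param cause failure-cause code of interest (CIF only), an integer in
#'   `1..M`.
#' @return an object of class `"pseudo_target"`.
#' @examples
#' pseudo_target("survival", horizon = 3)
#' pseudo_target("cif", horizon = 3, cause = 1)
#' @export
pseudo_target <- function(functional = c("survival", "cif", "rmst"),
                          horizon, cause = 1L) {
  functional <- match.arg(functional)
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  cause <- as.integer(cause)
  if (functional == "cif" && cause < 1L)
    stop("'cause' must be a positive failure-cause code for the CIF target")
  structure(list(functional = functional, horizon = as.numeric(horizon),
                 cause = cause),
            class = "pseudo_target")
}

#' @export
print.pseudo_target <- function(x, ...) {
  lab <- switch(x$functional,
                survival = sprintf("P(T > %g)", x$horizon),
                cif = sprintf("P(T <= %g, D = %d)", x$horizon, x$cause),
                rmst = sprintf("E min(T, %g)", x$horizon))
  cat("pseudo-observation target:", lab, "\n")
  invisible(x)
}

# ---- nonparametric curve machinery ------------------------------------------
# Event ordering at tied times follows the usual product-limit convention:
# subjects censored at time u are still in the risk set for deaths at u.

# distinct-time summary: times (sorted), n at risk, events per cause, censorings
risk_table <- function(time, status) {
  stopifnot(length(time) == length(status), all(time >= 0), all(status >= 0))
  ut <- sort(unique(time))
  n <- length(time)
  # counts per distinct time
  d_all <- tabulate(match(time[status > 0], ut), nbins = length(ut))
  c_cnt <- tabulate(match(time[status == 0], ut), nbins = length(ut))
  atrisk <- n - c(0, cumsum(d_all + c_cnt))[seq_along(ut)]
  list(times = ut, atrisk = atrisk, d = d_all, cens = c_cnt, n = n)
}

# overall KM survivor curve S(t) evaluated at the distinct times (right limits)
km_steps <- function(rt) {
  haz <- ifelse(rt$atrisk > 0, rt$d / rt$atrisk, 0)
  cumprod(1 - haz)
}

step_eval <- function(times, values, t, init = 1) {
  idx <- findInterval(t, times)
  out <- ifelse(idx == 0, init, values[pmax(idx, 1L)])
  as.numeric(out)
}

#' Kaplan-Meier estimate of overall survival at a time point
#'
#' Product-limit estimate of P(T > t); any positive cause code counts as an
#' event, so under competing risks this is the all-cause survivor function.
#' If `t` exceeds the largest observed time while the risk set is still open
#' (largest time censored), the last value is carried forward.
#'
#' @param time nonnegative observed times, `min(T, C)`.
#' @param status integer cause codes: `0` censored, `1..M` event causes.
#' @param t evaluation time(s), `>= 0`.
#' @return estimated survival probabilities, one per element of `t`.
#' @examples
#' km_survival(c(1, 2, 4, 5), c(1, 1, 1, 1), 3)   # 0.5
#' @export
km_survival <- function(time, status, t) {
  if (length(time) == 0L) stop("no observations")
  stopifnot(all(t >= 0))
  rt <- risk_table(time, status)
  s <- km_steps(rt)
  last_open <- rt$cens[length(rt$cens)] > 0 && s[length(s)] > 0
  if (any(t > max(rt$times)) && last_open)
    pdtr_log("km_survival: t beyond last observed time with open risk set; carrying last value")
  step_eval(rt$times, s, t, init = 1)
}

#' Aalen-Johansen estimate of a cause-specific cumulative incidence function
#'
#' Estimates F_d(t) = P(T <= t, D = d) as the integral of the left-limit
#' all-cause survivor curve against the cause-d Nelson-Aalen increments:
#' sum over event times u <= t of S(u-) d_d(u) / n(u).
#'
#' @inheritParams km_survival
#' @param cause failure-cause code of interest.
#' @return estimated cumulative incidences, one per element of `t`.
#' @examples
#' cause_specific_cif(c(1, 2, 3), c(1, 2, 1), 2.5, cause = 1)  # 1/3
#' @export
cause_specific_cif <- function(time, status, t, cause = 1L) {
  if (length(time) == 0L) stop("no observations")
  stopifnot(cause >= 1L, all(t >= 0))
  if (!any(status == cause))
    warning("no events of cause ", cause, "; CIF is identically zero")
  rt <- risk_table(time, status)
  s <- km_steps(rt)
  s_minus <- c(1, s[-length(s)])
  d_cause <- tabulate(match(time[status == cause], rt$times),
                      nbins = length(rt$times))
  jump <- ifelse(rt$atrisk > 0, s_minus * d_cause / rt$atrisk, 0)
  step_eval(rt$times, cumsum(jump), t, init = 0)
}

#' Restricted mean survival time estimate
#'
#' Integral of the Kaplan-Meier survivor curve over `[0, tau]`.
#'
#' @inheritParams km_survival
#' @param tau positive truncation time.
#' @return estimated E min(T, tau).
#' @export
rmst <- function(time, status, tau) {
  stopifnot(tau > 0)
  rt <- risk_table(time, status)
  s <- km_steps(rt)
  knots <- c(0, pmin(rt$times, tau), tau)
  vals <- c(1, s, NA)  # survivor value on [knots_i, knots_{i+1})
  widths <- diff(knots)
  sum(widths * vals[seq_along(widths)])
}

# evaluate the target functional on a (time, status) sample
eval_functional <- function(time, status, target) {
  switch(target$functional,
         survival = km_survival(time, status, target$horizon),
         cif = cause_specific_cif(time, status, target$horizon, target$cause),
         rmst = rmst(time, status, target$horizon))
}

#' Jackknife pseudo-observations of a survival functional
#'
#' Computes per-subject pseudo-observations
#' `theta_i = n * theta_hat - (n - 1) * theta_hat^(-i)`
#' for t-year survival, t-year cause-specific cumulative incidence, or
#' restricted mean survival time, where `theta_hat` is the nonparametric
#' (Kaplan-Meier / Aalen-Johansen) estimate.  Pseudo-values are intentionally
#' not clipped to `[0, 1]`: they can fall outside the range of the functional
#' and that is what makes their mean unbiased.
#'
#' Two computational routes are provided.  `"grouped"` (default) recomputes
#' the leave-one-out estimate once per distinct `(time, status)` pair from
#' updated risk tables; `"naive"` refits [survival::survfit()] n times and is
#' kept as an independent reference implementation.  The two agree to
#' numerical precision and this equality is part of the test suite.
#'
#' @inheritParams km_survival
#' @param target a [pseudo_target()].
#' @param method `"grouped"` (fast) or `"naive"` (n survfit refits).
#' @return numeric vector of pseudo-observations with attribute `target`;
#'   class `"pseudo_vector"`.
#' @examples
#' tm <- c(1, 2, 4, 5); st <- c(1, 1, 0, 1)
#' jackknife_pseudo(tm, st, pseudo_target("survival", 3))
#' @export
jackknife_pseudo <- function(time, status, target,
                             method = c("grouped", "naive")) {
  method <- match.arg(method)
  n <- length(time)
  if (n < 2L) stop("jackknife pseudo-observations require n >= 2")
  stopifnot(inherits(target, "pseudo_target"), length(status) == n)
  full <- eval_functional(time, status, target)
  loo <- if (method == "grouped") {
    grp <- match(paste(time, status), unique(paste(time, status)))
    loo_by_group <- vapply(seq_len(max(grp)), function(g) {
      i <- which(grp == g)[1L]
      eval_functional(time[-i], status[-i], target)
    }, numeric(1))
    loo_by_group[grp]
  } else {
    vapply(seq_len(n), function(i) naive_functional(time[-i], status[-i], target),
           numeric(1))
  }
  out <- n * full - (n - 1) * loo
  structure(out, target = target, variant = "plain_jackknife",
            class = c("pseudo_vector", "numeric"))
}

# reference leave-one-out estimator built on survival::survfit
naive_functional <- function(time, status, target) {
  if (target$functional == "cif" || any(status > 1)) {
    st <- factor(ifelse(status == 0, "censor", paste0("cause", status)),
                 levels = c("censor", paste0("cause", sort(unique(status[status > 0])))))
    fit <- survival::survfit(survival::Surv(time, st) ~ 1)
    if (target$functional == "cif") {
      col <- match(paste0("cause", target$cause), fit$states)
      if (is.na(col)) return(0)
      p <- fit$pstate[, col]
      return(step_eval(fit$time, p, target$horizon, init = 0))
    }
    surv <- fit$pstate[, match("(s0)", fit$states)]
  } else {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1)
    surv <- fit$surv
  }
  if (target$functional == "survival")
    return(step_eval(fit$time, surv, target$horizon, init = 1))
  # rmst
  knots <- c(0, pmin(fit$time, target$horizon), target$horizon)
  vals <- c(1, surv)
  sum(diff(knots) * vals[seq_len(length(knots) - 1L)])
}

#' @export
print.pseudo_vector <- function(x, ...) {
  tg <- attr(x, "target")
  cat(sprintf("pseudo-observations (%s, horizon %g, %s), n = %d\n",
              tg$functional, tg$horizon, attr(x, "variant"), length(x)))
  print(summary(as.numeric(x)))
  invisible(x)
}
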