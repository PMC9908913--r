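#' Fit a model for the censoring survivor function G(u | x)
#'
#' Treats censoring (`status == 0`) as the event of interest and fits either
#' a marginal Kaplan-Meier curve or a Cox proportional hazards model on
#' covariates (Breslow baseline; `ties` passed through to
#' [survival::coxph()]).  The fitted object evaluates
#' `G(u | x) = P(C > u | x)`, used to build inverse-probability-of-censoring
#' weights under covariate-dependent censoring.
#'
#' @inheritParams km_survival
#' @param covariates numeric matrix or data.frame of covariates (required for
#'   `kind = "cox_on_covariates"`).
#' @param kind `"marginal_km"`, `"cox_on_covariates"`, or `"none"` (G == 1).
#' @param ties tie-handling for the Cox fit, `"breslow"` (default) or
#'   `"efron"`.
#' @return object of class `"censoring_model"` with elements `kind` and
#'   `survivor(u, covariates)`.
#' @export
fit_censoring_model <- function(time, status, covariates = NULL,
                                kind = c("marginal_km", "cox_on_covariates",
                                         "none"),
                                ties = c("breslow", "efron")) {
  kind <- match.arg(kind)
  ties <- match.arg(ties)
  n <- length(time)
  cens_ind <- as.numeric(status == 0)
  if (kind != "none" && sum(cens_ind) == 0L) {
    warning("no censored observations; returning degenerate G == 1")
    kind <- "none"
  }
  survivor <- switch(kind,
    none = function(u, covariates = NULL) rep(1, length(u)),
    marginal_km = {
      rt <- risk_table(time, cens_ind)
      s <- km_steps(rt)
      function(u, covariates = NULL) step_eval(rt$times, s, u, init = 1)
    },
    cox_on_covariates = {
      x <- as.matrix(covariates)
      if (is.null(covariates) || nrow(x) != n)
        stop("'covariates' with one row per subject required for the Cox censoring model")
      df <- data.frame(.time = time, .cens = cens_ind, x)
      fml <- as.formula(paste("survival::Surv(.time, .cens) ~",
                              paste(colnames(df)[-(1:2)], collapse = " + ")))
      fit <- survival::coxph(fml, data = df, ties = ties)
      bh <- survival::basehaz(fit, centered = FALSE)
      function(u, covariates = NULL) {
        xb <- as.matrix(covariates) %*% coef(fit)
        h0 <- step_eval(bh$time, bh$hazard, u, init = 0)
        # Breslow baseline survivor raised to exp(linear predictor)
        exp(-h0 * exp(drop(xb)))
      }
    })
  structure(list(kind = kind, survivor = survivor, n_censored = sum(cens_ind)),
            class = "censoring_model")
}

#' @export
print.censoring_model <- function(x, ...) {
  cat(sprintf("censoring model (%s), %d censored observations\n",
              x$kind, x$n_censored))
  invisible(x)
}

#' IPCW-adjusted pseudo-observations of t-year survival
#'
#' Builds jackknife pseudo-observations on an inverse-probability-of-censoring
#' weighted survival estimator, valid when censoring is independent of the
#' event time only conditionally on covariates.  With weights
#' `v_i = I(C_i >= T_i ^ t) / G(Tobs_i ^ t | x_i)`, the `"weighted"` variant
#' uses the ratio estimator `sum I(T_i > t) v_i / sum v_i` and the `"direct"`
#' variant the plain average `n^-1 sum I(T_i > t) v_i`.  `G` is held fixed
#' while leaving subjects out, so the direct-variant pseudo-values reduce to
#' the per-subject weighted indicators.  `G` is floored (default 0.05) before
#' inversion; the number of floored evaluations is tallied in
#' [pdtr_counters()].
#'
#' @inheritParams km_survival
#' @param t time horizon.
#' @param G a [fit_censoring_model()] object.
#' @param covariates covariates passed to `G` (Cox kind only).
#' @param variant `"weighted"` or `"direct"`.
#' @param g_floor lower truncation bound for G before inversion.
#' @return a `"pseudo_vector"` as in [jackknife_pseudo()].
#' @export
ipcw_pseudo_survival <- function(time, status, t, G, covariates = NULL,
                                 variant = c("weighted", "direct"),
                                 g_floor = 0.05) {
  variant <- match.arg(variant)
  stopifnot(inherits(G, "censoring_model"), t > 0)
  n <- length(time)
  if (n < 2L) stop("need n >= 2")
  ghat <- G$survivor(pmin(time, t), covariates)
  nclip <- sum(ghat < g_floor)
  if (nclip > 0L) {
    pdtr_count("ipcw_clipped", as.integer(nclip))
    pdtr_log("ipcw: %d censoring-survivor values floored at %g", nclip, g_floor)
  }
  ghat <- pmax(ghat, g_floor)
  uncens_by_t <- as.numeric(status > 0 | time > t)  # I(C >= T ^ t) observable
  v <- uncens_by_t / ghat
  ind <- as.numeric(time > t) * uncens_by_t        # I(T > t), known when v > 0
  out <- if (variant == "weighted") {
    num <- sum(ind * v); den <- sum(v)
    full <- num / den
    loo <- (num - ind * v) / (den - v)
    n * full - (n - 1) * loo
  } else {
    # n * mean(term) - (n-1) * mean(term[-i]) == term_i
    ind * v
  }
  structure(out, target = pseudo_target("survival", t),
            variant = paste0("ipcw_", variant),
            class = c("pseudo_vector", "numeric"))
}
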