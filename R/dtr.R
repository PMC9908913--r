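#' Assemble a multi-stage panel
#'
#' Bundles per-stage at-risk indicators, binary treatments, and history
#' feature matrices into the container consumed by [fit_dtr()].  Stage-k
#' history features `H_k` are whatever the caller assembles (typically all
#' prior covariates, treatments, and intermediate outcomes); rows with
#' `eta_k = 0` are ignored at stage k (their feature values may be `NA`).
#'
#' @param stages list of length K; each element a list with components
#'   `eta` (0/1 at-risk), `treatment` (0/1), and `features` (numeric matrix,
#'   one row per subject).
#' @param response terminal pseudo-response vector `Y` (may be attached
#'   later).
#' @return object of class `"stage_panel"`.
#' @export
stage_panel <- function(stages, response = NULL) {
  K <- length(stages)
  stopifnot(K >= 1L)
  n <- length(stages[[1L]]$eta)
  for (k in seq_len(K)) {
    st <- stages[[k]]
    stopifnot(length(st$eta) == n, length(st$treatment) == n,
              nrow(as.matrix(st$features)) == n)
    if (k == 1L && !all(st$eta == 1))
      stop("every subject must be at risk at stage 1 (eta_1 == 1)")
    if (k > 1L && any(st$eta > stages[[k - 1L]]$eta))
      stop("at-risk indicators must be nonincreasing across stages")
    stages[[k]]$features <- as.matrix(st$features)
  }
  if (!is.null(response)) stopifnot(length(response) == n)
  structure(list(stages = stages, response = response, K = K, n = n),
            class = "stage_panel")
}

#' @export
print.stage_panel <- function(x, ...) {
  cat(sprintf("stage panel: %d subjects, %d stage(s)\n", x$n, x$K))
  for (k in seq_len(x$K))
    cat(sprintf("  stage %d: %d at risk, %d features\n", k,
                sum(x$stages[[k]]$eta == 1), ncol(x$stages[[k]]$features)))
  invisible(x)
}

#' Stage-wise doubly-robust contrast for backward induction
#'
#' Evaluates, on the at-risk subjects of stage k, the AIPW contrast with the
#' propagated value `V_{k+1}` as response:
#' `C_k = A V/pi1 - ((A - pi1)/pi1) mu1 - [ (1-A) V/pi0 + ((A - pi1)/pi0) mu0 ]`,
#' where the stage Q-functions `mu_a` are fitted by regressing `V_{k+1}` on
#' the stage history within each arm.  With `mu1 = mu0 = 0` this reduces to
#' the IPW contrast applied to `V_{k+1}`; at the terminal stage
#' (`V_{K+1} = Y`) it equals [dr_contrast()].
#'
#' @param panel a [stage_panel()].
#' @param k stage index.
#' @param value_next numeric vector `V_{k+1}` (length n).
#' @param propensity a [fit_propensity()] object for stage k (fitted on the
#'   at-risk rows).
#' @param outcome optional [fit_outcome_model()]; fitted internally when
#'   `NULL`.
#' @param scheme `"dr"` or `"ipw"`.
#' @return a [contrast_vector()] of length `sum(eta_k)` with attribute
#'   `index` giving the at-risk row numbers.
#' @export
stage_dr_contrast <- function(panel, k, value_next, propensity,
                              outcome = NULL, scheme = c("dr", "ipw")) {
  scheme <- match.arg(scheme)
  st <- panel$stages[[k]]
  idx <- which(st$eta == 1)
  if (min(table(st$treatment[idx])) < 10L)
    warning("stage ", k, " has fewer than 10 at-risk subjects in an arm")
  h <- st$features[idx, , drop = FALSE]
  a <- st$treatment[idx]
  v <- value_next[idx]
  cv <- if (scheme == "ipw") {
    ipw_contrast(v, a, propensity, h)
  } else {
    if (is.null(outcome)) outcome <- fit_outcome_model(v, a, h)
    dr_contrast(v, a, propensity, outcome, h)
  }
  attr(cv, "index") <- idx
  cv
}

#' Propagate the value vector one stage backward
#'
#' Implements the sample value recursion in regret form: with the fitted
#' stage rule `g_k` and estimated contrast `C_k`, the stage regret is
#' `eta_k * |C_k| * I{g_k(H_k) != A_k}` -- the outcome foregone by not
#' taking the stage-optimal action.  For a maximized objective (t-year
#' survival) the regret is added, `V_k = V_{k+1} + regret`; for a minimized
#' one (t-year cumulative incidence) it is subtracted,
#' `V_k = V_{k+1} - regret`, so that `V_k` always estimates the response a
#' subject would attain under optimal decisions from stage k onward.
#' Subjects already following the stage-optimal action keep their value
#' unchanged, and subjects with `eta_k = 0` pass through untouched.  When
#' `g_k` is the sign rule of `C_k`, the added term equals
#' `C_k * (g_k - A_k)`, the product form of the recursion.
#'
#' @param value_next numeric `V_{k+1}` (length n).
#' @param contrast stage contrast (a [contrast_vector()] on the at-risk
#'   rows, with attribute `index`, as returned by [stage_dr_contrast()]).
#' @param decisions 0/1 decisions of the fitted stage rule on the at-risk
#'   rows.
#' @param treatment observed 0/1 stage treatments (length n).
#' @param eta 0/1 at-risk indicator (length n).
#' @param objective `"maximize"` or `"minimize"`.
#' @return numeric vector `V_k` of length n.
#' @export
propagate_value <- function(value_next, contrast, decisions, treatment, eta,
                            objective = c("maximize", "minimize")) {
  objective <- match.arg(objective)
  idx <- attr(contrast, "index")
  if (is.null(idx)) idx <- which(eta == 1)
  stopifnot(length(decisions) == length(idx))
  v <- value_next
  regret <- abs(contrast$contrast) * (decisions != treatment[idx])
  v[idx] <- v[idx] + if (objective == "maximize") regret else -regret
  v
}

#' Estimate an optimal dynamic treatment regime by backward induction
#'
#' Runs the backward recursion over stages `k = K, ..., 1`: set
#' `V_{K+1} = Y` (the pseudo-response); at each stage estimate the
#' treatment contrast on the at-risk subjects, fit a linear decision rule by
#' weighted-SVM classification of the contrast sign with weight `|C_k|`,
#' and propagate the value vector backward.  For competing-risks objectives
#' (`objective = "minimize"`) the contrast is negated before the
#' weight/label split, so the rule targets the treatment that lowers the
#' cumulative incidence.
#'
#' Four method configurations mirror the usual comparator set:
#' \describe{
#'   \item{`"pdwl"`}{doubly-robust contrast + SCAD-penalized L1-SVM (the
#'     proposed method);}
#'   \item{`"powl"`}{IPW contrast + SCAD-penalized L1-SVM;}
#'   \item{`"dwl"`}{doubly-robust contrast + unpenalized weighted l2-SVM;}
#'   \item{`"owl"`}{IPW contrast + unpenalized weighted l2-SVM.}
#' }
#'
#' @param panel a [stage_panel()] with `response` set (or `response`
#'   supplied here).
#' @param objective `"maximize"` (survival-type response) or `"minimize"`
#'   (cumulative incidence).
#' @param method one of `"pdwl"`, `"powl"`, `"dwl"`, `"owl"`.
#' @param response optional pseudo-response overriding `panel$response`.
#' @param propensity propensity kind per stage: `"empirical"` (randomized
#'   designs) or `"logistic"` (observational designs, main-effects model on
#'   the stage history).
#' @param scad a [scad_spec()]; per-stage `lambda` is selected by
#'   cross-validation when its `lambda` is `NULL`.
#' @param folds cross-validation folds for the per-stage lambda selection.
#' @param cost soft-margin cost of the l2-SVM initializer.
#' @param n_lla_steps local linear approximation steps for the SCAD path.
#' @return object of class `"dtr_fit"`: per-stage `rules` (each a
#'   [linear_rule()]), the `objective`, `method`, per-stage diagnostics, and
#'   the matrix of propagated values.
#' @export
fit_dtr <- function(panel,
                    objective = c("maximize", "minimize"),
                    method = c("pdwl", "powl", "dwl", "owl"),
                    response = NULL,
                    propensity = c("empirical", "logistic"),
                    scad = scad_spec(), folds = 3L, cost = 1,
                    n_lla_steps = 1L) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  propensity <- match.arg(propensity)
  stopifnot(inherits(panel, "stage_panel"))
  y <- if (!is.null(response)) response else panel$response
  if (is.null(y)) stop("panel has no terminal response")
  scheme <- if (method %in% c("pdwl", "dwl")) "dr" else "ipw"
  penalty <- if (method %in% c("pdwl", "powl")) "scad" else "none"

  K <- panel$K
  rules <- vector("list", K)
  diagnostics <- vector("list", K)
  values <- matrix(NA_real_, panel$n, K + 1L)
  values[, K + 1L] <- as.numeric(y)
  v_next <- as.numeric(y)

  for (k in rev(seq_len(K))) {
    st <- panel$stages[[k]]
    idx <- which(st$eta == 1)
    h <- st$features[idx, , drop = FALSE]
    a <- st$treatment[idx]
    prop <- fit_propensity(a,
                           covariates = if (propensity == "logistic") h,
                           kind = propensity)
    cv <- stage_dr_contrast(panel, k, v_next, prop, scheme = scheme)
    # competing-risks sign: classify toward the incidence-lowering arm
    cls <- if (objective == "minimize")
      contrast_vector(-cv$contrast, scheme = cv$scheme) else cv
    rule <- fit_rule(h, cls, scad = scad, n_lla_steps = n_lla_steps,
                     penalty = penalty, cost = cost, folds = folds)
    dec <- as.numeric(rule_f(rule, h) > 0)
    v_next <- propagate_value(v_next, cv, dec, st$treatment, st$eta,
                              objective)
    # invariant: optimal-play values move monotonically with the objective
    if (objective == "maximize") stopifnot(all(v_next >= values[, k + 1L] - 1e-12))
    else stopifnot(all(v_next <= values[, k + 1L] + 1e-12))
    values[, k] <- v_next
    rules[[k]] <- rule
    diagnostics[[k]] <- list(
      n_at_risk = length(idx),
      lambda = attr(rule, "lambda"),
      n_nonzero = sum(rule$coefficients != 0),
      mean_abs_contrast = mean(cv$weight),
      prop_positive = mean(cls$label > 0))
  }
  structure(list(rules = rules, objective = objective, method = method,
                 scheme = scheme, penalty = penalty,
                 diagnostics = diagnostics, values = values, K = K),
            class = "dtr_fit")
}

#' @export
print.dtr_fit <- function(x, ...) {
  cat(sprintf("dynamic treatment regime fit: %s, %d stage(s), objective %s\n",
              toupper(x$method), x$K, x$objective))
  for (k in seq_len(x$K)) {
    d <- x$diagnostics[[k]]
    cat(sprintf("  stage %d: %d at risk, %d/%d nonzero coefficients%s\n",
                k, d$n_at_risk, d$n_nonzero,
                length(x$rules[[k]]$coefficients),
                if (!is.null(d$lambda)) sprintf(", lambda = %.4g", d$lambda)
                else ""))
  }
  invisible(x)
}

#' Apply a fitted regime's stage rule
#'
#' @param fit a [fit_dtr()] object.
#' @param features history feature matrix laid out as at fitting time for
#'   stage `k`.
#' @param k stage index.
#' @return 0/1 treatment decisions.
#' @export
predict_regime <- function(fit, features, k = 1L) {
  stopifnot(inherits(fit, "dtr_fit"), k >= 1L, k <= fit$K)
  predict(fit$rules[[k]], features)
}
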