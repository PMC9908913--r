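#' Fit a propensity model for treatment assignment
#'
#' Estimates arm-assignment probabilities pi_a(H).  `"empirical"` uses the
#' observed arm proportions (the natural choice for randomized studies);
#' `"logistic"` and `"multinomial"` fit main-effects generalized linear
#' models on the covariates; `"known"` wraps a user-supplied function.
#' Predicted probabilities are truncated to `trunc` (default `[0.01, 0.99]`)
#' as a positivity guard; truncations are tallied in [pdtr_counters()].
#'
#' @param treatment vector of arm codes (any integers; two or more arms).
#' @param covariates covariate matrix/data.frame (ignored for `"empirical"`).
#' @param kind one of `"empirical"`, `"logistic"`, `"multinomial"`, `"known"`.
#' @param known_fun for `kind = "known"`: `function(covariates)` returning an
#'   n x L matrix of arm probabilities (columns in `sort(unique(treatment))`
#'   order) or, with two arms, a vector of P(A = higher arm code).
#' @param trunc length-2 truncation bounds for each probability.
#' @return object of class `"propensity_model"` with `predict(covariates)`
#'   returning an n x L probability matrix (columns named by arm code).
#' @export
fit_propensity <- function(treatment,
                           covariates = NULL,
                           kind = c("empirical", "logistic", "multinomial",
                                    "known"),
                           known_fun = NULL, trunc = c(0.01, 0.99)) {
  kind <- match.arg(kind)
  arms <- sort(unique(treatment))
  if (length(arms) < 2L && kind != "known")
    stop("need at least two observed arms; arm(s) present: ",
         paste(arms, collapse = ", "))
  tab <- table(factor(treatment, levels = arms))
  if (kind != "known" && any(tab == 0L))
    stop("arm with zero observations: ", names(tab)[tab == 0L][1L])

  predfun <- switch(kind,
    empirical = {
      prop <- as.numeric(tab) / length(treatment)
      function(covariates) {
        n <- if (is.null(covariates)) 1L else nrow(as.matrix(covariates))
        matrix(prop, n, length(arms), byrow = TRUE,
               dimnames = list(NULL, arms))
      }
    },
    logistic = {
      if (length(arms) != 2L) stop("'logistic' requires exactly two arms")
      x <- as.matrix(covariates)
      fit <- glm.fit(cbind(1, x), as.numeric(treatment == arms[2L]),
                     family = binomial())
      cf <- fit$coefficients
      function(covariates) {
        eta <- drop(cbind(1, as.matrix(covariates)) %*% cf)
        p1 <- 1 / (1 + exp(-eta))
        cbind(`0` = 1 - p1, `1` = p1) |>
          (\(m) {colnames(m) <- arms; m})()
      }
    },
    multinomial = {
      x <- as.matrix(covariates)
      df <- data.frame(.a = factor(treatment, levels = arms), x)
      fit <- nnet::multinom(.a ~ ., data = df, trace = FALSE)
      function(covariates) {
        nd <- data.frame(as.matrix(covariates))
        p <- predict(fit, newdata = nd, type = "probs")
        if (is.null(dim(p))) p <- cbind(1 - p, p)
        colnames(p) <- arms
        p
      }
    },
    known = {
      stopifnot(is.function(known_fun))
      function(covariates) {
        p <- known_fun(covariates)
        if (is.null(dim(p))) p <- cbind(1 - p, p)
        colnames(p) <- arms
        p
      }
    })

  structure(list(kind = kind, arms = arms, trunc = trunc,
                 .predict = predfun),
            class = "propensity_model")
}

#' @export
predict.propensity_model <- function(object, covariates = NULL, ...) {
  p <- object$.predict(covariates)
  ntr <- sum(p < object$trunc[1L] | p > object$trunc[2L])
  if (ntr > 0L) {
    pdtr_count("propensity_truncated", as.integer(ntr))
    pdtr_log("propensity: %d probabilities truncated to [%g, %g]",
             ntr, object$trunc[1L], object$trunc[2L])
  }
  p <- pmin(pmax(p, object$trunc[1L]), object$trunc[2L])
  p / rowSums(p)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("propensity model (%s), arms: %s\n", x$kind,
              paste(x$arms, collapse = ", ")))
  invisible(x)
}

#' Fit an outcome (Q) model for the pseudo-response
#'
#' Fits the conditional mean mu_a(H) = E(Y | A = a, H) separately within
#' each arm.  The default is ordinary least squares, which is the natural
#' choice for pseudo-observation responses (they may fall outside [0, 1]);
#' any regressor exposing `fit(x, y)` returning an object with a
#' `predict(object, x)` method can be plugged in.
#'
#' @param y numeric response (typically a `pseudo_vector`).
#' @param treatment arm codes.
#' @param covariates covariate matrix/data.frame.
#' @param kind `"linear"` or `"pluggable"`.
#' @param regressor for `kind = "pluggable"`: list with elements `fit` and
#'   `predict`.
#' @return object of class `"outcome_model"`; use
#'   `predict(object, arm, covariates)`.
#' @export
fit_outcome_model <- function(y, treatment, covariates,
                              kind = c("linear", "pluggable"),
                              regressor = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(covariates)
  stopifnot(length(y) == length(treatment), nrow(x) == length(y))
  arms <- sort(unique(treatment))
  fits <- lapply(arms, function(a) {
    idx <- treatment == a
    if (kind == "linear") {
      if (sum(idx) < ncol(x) + 1L)
        stop("arm ", a, " has fewer observations (", sum(idx),
             ") than coefficients (", ncol(x) + 1L, ")")
      xa <- cbind(1, x[idx, , drop = FALSE])
      list(kind = "linear", coef = qr.coef(qr(xa), as.numeric(y[idx])))
    } else {
      list(kind = "pluggable", fit = regressor$fit(x[idx, , drop = FALSE],
                                                   as.numeric(y[idx])),
           predict = regressor$predict)
    }
  })
  names(fits) <- as.character(arms)
  structure(list(arms = arms, fits = fits, p = ncol(x)),
            class = "outcome_model")
}

#' @export
#' @rdname fit_outcome_model
#' @param object fitted `outcome_model`.
#' @param arm arm code at which to predict.
#' @param ... unused.
predict.outcome_model <- function(object, arm, covariates, ...) {
  f <- object$fits[[as.character(arm)]]
  if (is.null(f)) stop("no outcome model fitted for arm ", arm)
  x <- as.matrix(covariates)
  if (f$kind == "linear") {
    cf <- ifelse(is.na(f$coef), 0, f$coef)
    drop(cbind(1, x) %*% cf)
  } else {
    f$predict(f$fit, x)
  }
}

# ---- contrast container -----------------------------------------------------

#' Construct a treatment-contrast vector
#'
#' Wraps per-subject contrast estimates C_i into the weight/label form used
#' by the weighted classification step: `weight = |C|` and
#' `label = sign(C)`, with the zero-contrast tie broken to `+1` (such
#' subjects carry zero weight and do not influence the classifier).
#'
#' @param contrast numeric vector of estimated contrasts.
#' @param scheme `"ipw"` or `"dr"`.
#' @return object of class `"contrast_vector"` with elements `contrast`,
#'   `weight`, `label`, `scheme`.
#' @export
contrast_vector <- function(contrast, scheme = c("dr", "ipw")) {
  scheme <- match.arg(scheme)
  contrast <- as.numeric(contrast)
  structure(list(contrast = contrast,
                 weight = abs(contrast),
                 label = ifelse(contrast >= 0, 1, -1),
                 scheme = scheme),
            class = "contrast_vector")
}

#' @export
print.contrast_vector <- function(x, ...) {
  cat(sprintf("contrast vector (%s), n = %d, mean %.4f, %.1f%% positive\n",
              x$scheme, length(x$contrast), mean(x$contrast),
              100 * mean(x$label > 0)))
  invisible(x)
}

#' Inverse-probability-weighted treatment contrast
#'
#' Per-subject IPW contrast
#' `C_i = (A_i / pi1_i - (1 - A_i) / (1 - pi1_i)) * Y_i`
#' for binary arms, an unbiased (but noisy) estimate of
#' `mu_1(H) - mu_0(H)` when the propensity model is correct.
#'
#' @param y pseudo-response vector.
#' @param treatment binary treatment, coded 0/1.
#' @param propensity a [fit_propensity()] object.
#' @param covariates covariates passed to the propensity model.
#' @return a [contrast_vector()] with `scheme = "ipw"`.
#' @export
ipw_contrast <- function(y, treatment, propensity, covariates = NULL) {
  stopifnot(all(treatment %in% c(0, 1)))
  p <- predict(propensity, covariates)
  pi1 <- p[, ncol(p)]
  if (length(pi1) == 1L) pi1 <- rep(pi1, length(y))
  cc <- (treatment / pi1 - (1 - treatment) / (1 - pi1)) * as.numeric(y)
  contrast_vector(cc, scheme = "ipw")
}

#' Augmented IPW (doubly-robust) arm mean
#'
#' Elementwise AIPW estimate of mu_a(H_i):
#' `I(A = a)/pi_a * Y + (1 - I(A = a)/pi_a) * muhat_a(H)`, a weighted
#' average of the observed pseudo-response and its outcome-model substitute.
#' Consistent when either the propensity model or the outcome model is
#' correct.
#'
#' @inheritParams ipw_contrast
#' @param outcome a [fit_outcome_model()] object.
#' @param arm arm code a.
#' @return numeric vector of per-subject AIPW arm means.
#' @export
dr_mu <- function(y, treatment, propensity, outcome, arm, covariates = NULL) {
  p <- predict(propensity, covariates)
  col <- match(as.character(arm), colnames(p))
  if (is.na(col)) stop("arm ", arm, " not in the propensity model")
  pia <- p[, col]
  if (length(pia) == 1L) pia <- rep(pia, length(y))
  ind <- as.numeric(treatment == arm)
  mua <- predict(outcome, arm, covariates)
  unname((ind / pia) * as.numeric(y) + (1 - ind / pia) * mua)
}

#' Doubly-robust treatment contrast
#'
#' `C^DR = mu1^DR(H) - mu0^DR(H)` built from [dr_mu()].  With an identically
#' zero outcome model this reduces algebraically to [ipw_contrast()].
#' For objectives that are minimized (cumulative incidence under competing
#' risks) the caller negates the contrast before the weight/label split; see
#' [fit_dtr()].
#'
#' @inheritParams dr_mu
#' @return a [contrast_vector()] with `scheme = "dr"`.
#' @export
dr_contrast <- function(y, treatment, propensity, outcome, covariates = NULL) {
  stopifnot(all(treatment %in% c(0, 1)))
  cc <- dr_mu(y, treatment, propensity, outcome, 1, covariates) -
        dr_mu(y, treatment, propensity, outcome, 0, covariates)
  contrast_vector(cc, scheme = "dr")
}
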