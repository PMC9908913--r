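#' Order estimated arm-specific Q-values per subject
#'
#' Sorts the per-subject mean-outcome estimates `mu_a(H_i)` across L arms,
#' keeping the rank-to-arm map.  Ties are broken by ranking the lower arm
#' code lower, so with an all-equal row the highest arm code is "best".
#'
#' @param q_values n x L numeric matrix of estimated arm means; column
#'   names, if present, are used as arm codes, otherwise `1..L`.
#' @return object of class `"treatment_ordering"`: `sorted` (n x L
#'   nondecreasing values), `order_index` (n x L arm codes by rank),
#'   `best_arm`, `runner_up_arm`, `worst_arm`, `arms`.
#' @export
order_arms <- function(q_values) {
  q <- as.matrix(q_values)
  L <- ncol(q)
  stopifnot(L >= 2L)
  arms <- colnames(q)
  if (is.null(arms)) arms <- as.character(seq_len(L))
  colnames(q) <- arms
  # canonical column order by arm code: tie-breaks are code-based, not
  # column-position-based
  ord_cols <- order(suppressWarnings(as.numeric(arms)), arms, na.last = TRUE)
  q <- q[, ord_cols, drop = FALSE]
  arms <- arms[ord_cols]
  ord <- t(apply(q, 1L, order))            # ties: lower column ranked lower
  sorted <- t(vapply(seq_len(nrow(q)),
                     function(i) q[i, ord[i, ]], numeric(L)))
  oi <- matrix(arms[ord], nrow(q), L)
  structure(list(sorted = sorted, order_index = oi,
                 best_arm = oi[, L], runner_up_arm = oi[, L - 1L],
                 worst_arm = oi[, 1L], arms = arms, q = q),
            class = "treatment_ordering")
}

#' Sub-optimality bound weights for multi-arm rule learning
#'
#' Classification weights from the ordered Q-values: the `"lower"` bound
#' uses the gap between the best and second-best arms,
#' `mu_(L) - mu_(L-1)`, and the `"upper"` bound the gap between the best
#' and worst arms, `mu_(L) - mu_(1)`.  Minimizing the weighted
#' misclassification of the best arm with these weights minimizes,
#' respectively, a lower and an upper bound on the expected outcome lost to
#' sub-optimal treatment; `0 <= lower <= upper` always holds.  At L = 2
#' both collapse to `|mu_1 - mu_0|`.
#'
#' @param ordering a [order_arms()] object.
#' @param bound `"lower"` or `"upper"`.
#' @param positive_arm arm code mapped to label `+1` (default: the highest
#'   arm code); the label is `+1` when the subject's best arm equals
#'   `positive_arm`.
#' @return a [contrast_vector()] with the gap as weight; attribute
#'   `best_arm` keeps the per-subject best arm.
#' @export
bound_weights <- function(ordering, bound = c("lower", "upper"),
                          positive_arm = NULL) {
  bound <- match.arg(bound)
  stopifnot(inherits(ordering, "treatment_ordering"))
  L <- ncol(ordering$sorted)
  gap <- ordering$sorted[, L] -
    (if (bound == "lower") ordering$sorted[, L - 1L] else ordering$sorted[, 1L])
  if (is.null(positive_arm)) positive_arm <- ordering$arms[length(ordering$arms)]
  sgn <- ifelse(ordering$best_arm == as.character(positive_arm), 1, -1)
  cv <- contrast_vector(sgn * gap, scheme = "dr")
  attr(cv, "best_arm") <- ordering$best_arm
  attr(cv, "bound") <- bound
  cv
}

#' Per-arm Q-value estimates (AIPW or IPW) for multi-arm problems
#'
#' Builds the n x L matrix of arm-mean estimates feeding [order_arms()].
#' `"dr"` uses the arm-wise AIPW estimate
#' `I(A = a)/pi_a * Y + (1 - I(A = a)/pi_a) * muhat_a(H)` with multinomial
#' (or supplied) propensities and per-arm linear outcome models; `"ipw"`
#' uses `I(A = a)/pi_a * Y` alone.
#'
#' @param y pseudo-response.
#' @param treatment arm codes (L >= 2 distinct values).
#' @param covariates covariate matrix.
#' @param scheme `"dr"` or `"ipw"`.
#' @param propensity optional [fit_propensity()] object; default multinomial
#'   for L > 2, empirical proportions if `covariates` is `NULL`.
#' @return n x L matrix with arm codes as column names.
#' @export
q_values <- function(y, treatment, covariates, scheme = c("dr", "ipw"),
                     propensity = NULL) {
  scheme <- match.arg(scheme)
  arms <- sort(unique(treatment))
  if (is.null(propensity))
    propensity <- fit_propensity(treatment, covariates,
                                 kind = if (length(arms) > 2L) "multinomial"
                                        else "logistic")
  out <- matrix(NA_real_, length(y), length(arms),
                dimnames = list(NULL, as.character(arms)))
  if (scheme == "dr") {
    om <- fit_outcome_model(y, treatment, covariates)
    for (a in arms)
      out[, as.character(a)] <- dr_mu(y, treatment, propensity, om, a,
                                      covariates)
  } else {
    p <- predict(propensity, covariates)
    for (a in arms) {
      pia <- p[, as.character(a)]
      out[, as.character(a)] <- as.numeric(treatment == a) / pia *
        as.numeric(y)
    }
  }
  out
}

#' Multi-arm treatment rule by weighted one-versus-one decomposition
#'
#' Learns a rule recommending one of L >= 2 arms from estimated Q-values.
#' `scheme = "ovo"` fits all `L(L-1)/2` pairwise sparse rules, each
#' weighted by the pairwise contrast `|mu_a - mu_b|` and labeled by its
#' sign, and predicts by majority vote.  `"bound_lower"` / `"bound_upper"`
#' keep the pairwise sign labels but replace each subject's weight by its
#' sub-optimality gap from [bound_weights()] (best minus second-best, or
#' best minus worst), so misclassifying subjects with more outcome at
#' stake costs more.  Vote ties go to the lowest arm code.  At L = 2 every
#' scheme reduces to the binary [fit_rule()] path.
#'
#' @param x feature matrix.
#' @param q n x L Q-value matrix (see [q_values()]).
#' @param scheme `"ovo"`, `"bound_lower"`, or `"bound_upper"`.
#' @param scad a [scad_spec()]; `penalty = "none"` skips the SCAD step.
#' @param penalty `"scad"` or `"none"`.
#' @param ... passed to [fit_rule()].
#' @return object of class `"multi_rule"` with the pairwise rules; use
#'   `predict(object, newdata)` for arm codes.
#' @export
fit_multiclass_rule <- function(x, q,
                                scheme = c("ovo", "bound_lower",
                                           "bound_upper"),
                                scad = scad_spec(), penalty = c("scad",
                                                                "none"),
                                ...) {
  scheme <- match.arg(scheme)
  penalty <- match.arg(penalty)
  x <- as.matrix(x)
  q <- as.matrix(q)
  if (ncol(q) < 2L) stop("need at least two arms")
  ordering <- order_arms(q)
  q <- ordering$q          # canonical arm-code column order
  arms <- ordering$arms
  pairs <- utils::combn(arms, 2L, simplify = FALSE)
  gap <- if (scheme == "ovo") NULL
         else bound_weights(ordering, bound = sub("bound_", "", scheme))$weight
  rules <- lapply(pairs, function(pr) {
    a <- pr[1L]; b <- pr[2L]           # a < b; positive action is b
    sgn <- ifelse(q[, b] - q[, a] >= 0, 1, -1)
    cc <- if (scheme == "ovo") q[, b] - q[, a] else sgn * gap
    rule <- fit_rule(x, contrast_vector(cc, scheme = "dr"),
                     scad = scad, penalty = penalty, ...)
    rule$positive_action <- b
    rule$negative_action <- a
    rule
  })
  structure(list(rules = rules, pairs = pairs, arms = arms, scheme = scheme),
            class = "multi_rule")
}

#' @export
#' @rdname fit_multiclass_rule
#' @param object fitted `multi_rule`.
#' @param newdata feature matrix.
predict.multi_rule <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  votes <- matrix(0L, n, length(object$arms),
                  dimnames = list(NULL, object$arms))
  for (r in object$rules) {
    dec <- predict(r, newdata)
    for (a in object$arms) votes[, a] <- votes[, a] + (dec == a)
  }
  # ties -> lowest arm code (max.col with ties.method "first" on ordered cols)
  object$arms[max.col(votes, ties.method = "first")]
}

#' @export
print.multi_rule <- function(x, ...) {
  cat(sprintf("multi-arm rule (%s), %d arms, %d pairwise rule(s)\n",
              x$scheme, length(x$arms), length(x$rules)))
  invisible(x)
}
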