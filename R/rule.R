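#' SCAD penalty derivative
#'
#' Evaluates the derivative of the smoothly clipped absolute deviation
#' penalty,
#' `P'_lambda(b) = lambda * ( I(b <= lambda) +
#'   (gamma*lambda - b)_+ / ((gamma - 1)*lambda) * I(b > lambda) )`,
#' which equals `lambda` near zero, decays linearly, and vanishes beyond
#' `gamma * lambda` (near-unbiasedness for large coefficients).  Used as the
#' local linear approximation weight on each `|beta_j|`.
#'
#' @param beta_abs nonnegative coefficient magnitudes.
#' @param lambda penalty level, `>= 0`.
#' @param gamma SCAD shape, `> 2`; default 3.7.
#' @return elementwise derivative values (0 when `lambda == 0`).
#' @examples
#' scad_derivative(c(0.5, 2, 10), lambda = 1)  # 1, (3.7-2)/2.7, 0
#' @export
scad_derivative <- function(beta_abs, lambda, gamma = 3.7) {
  stopifnot(all(beta_abs >= 0), lambda >= 0, gamma > 2)
  if (lambda == 0) return(rep(0, length(beta_abs)))
  lambda * (as.numeric(beta_abs <= lambda) +
            pmax(gamma * lambda - beta_abs, 0) / ((gamma - 1) * lambda) *
              as.numeric(beta_abs > lambda))
}

#' SCAD penalty specification
#'
#' @param lambda penalty level (per-sample scale; the `1/n` factor of the
#'   weighted-hinge risk is absorbed here, so values are comparable across
#'   sample sizes).  `NULL` means "select by cross-validation over
#'   `lambda_grid`".
#' @param gamma SCAD shape parameter, `> 2`.
#' @param lambda_grid candidate grid for [select_lambda()]; `NULL` for the
#'   default of `grid_length` log-spaced points spanning `[1e-4, 1]` times
#'   the largest absolute weighted margin gradient at beta = 0 (computed on
#'   the standardized features of the data at hand).
#' @param grid_length number of points of the default data-driven grid.
#' @return object of class `"scad_spec"`.
#' @export
scad_spec <- function(lambda = NULL, gamma = 3.7, lambda_grid = NULL,
                      grid_length = 20L) {
  stopifnot(gamma > 2, is.null(lambda) || lambda >= 0, grid_length >= 1L)
  structure(list(lambda = lambda, gamma = gamma, lambda_grid = lambda_grid,
                 grid_length = as.integer(grid_length)),
            class = "scad_spec")
}

default_lambda_grid <- function(x, weight, label, length_out = 20L) {
  g <- abs(crossprod(x, weight * label)) / nrow(x)
  lmax <- max(g, 1e-8)
  exp(seq(log(1e-4 * lmax), log(lmax), length.out = length_out))
}

#' Linear decision rule
#'
#' A rule `g(H) = I(intercept + H %*% coefficients > 0)`, strict at the
#' boundary (a zero decision function assigns the reference action 0).
#'
#' @param intercept scalar intercept.
#' @param coefficients numeric coefficient vector.
#' @param positive_action treatment code returned when the decision function
#'   is positive (default `1`).
#' @param negative_action code returned otherwise (default `0`).
#' @return object of class `"linear_rule"`.
#' @export
linear_rule <- function(intercept, coefficients, positive_action = 1L,
                        negative_action = 0L) {
  structure(list(intercept = as.numeric(intercept),
                 coefficients = as.numeric(coefficients),
                 positive_action = positive_action,
                 negative_action = negative_action),
            class = "linear_rule")
}

#' @export
print.linear_rule <- function(x, digits = 4, ...) {
  cat("linear decision rule: action", x$positive_action, "if f(H) > 0\n")
  cf <- c(`(Intercept)` = x$intercept, setNames(x$coefficients,
          paste0("h", seq_along(x$coefficients))))
  print(round(cf, digits))
  cat(sprintf("%d of %d coefficients nonzero\n",
              sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

# decision function values
rule_f <- function(rule, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(rule$coefficients))
    stop("feature dimension ", ncol(x), " does not match rule dimension ",
         length(rule$coefficients))
  drop(rule$intercept + x %*% rule$coefficients)
}

#' @export
#' @rdname linear_rule
#' @param object a `linear_rule`.
#' @param newdata feature matrix.
#' @param ... unused.
predict.linear_rule <- function(object, newdata, ...) {
  ifelse(rule_f(object, newdata) > 0, object$positive_action,
         object$negative_action)
}

#' Weighted soft-margin linear SVM (ridge-penalized hinge loss)
#'
#' Solves `min 0.5 ||beta||^2 + cost * sum_i w_i xi_i` subject to
#' `z_i (b0 + h_i' beta) >= 1 - xi_i`, `xi >= 0`, through the dual quadratic
#' program (box constraints `0 <= alpha_i <= cost * w_i`, one equality),
#' using [kernlab::ipop()] with a jittered Gram matrix.  The intercept is
#' recovered by exact one-dimensional minimization of the weighted hinge
#' loss given `beta` (robust when no margin support vectors exist).
#' Used as the initializer `beta^(0)` whose magnitudes set the local linear
#' approximation weights of the SCAD step, and as the unpenalized rule of
#' the OWL/DWL comparators.
#'
#' @param x feature matrix (no intercept column).
#' @param label vector in -1/+1.
#' @param weight nonnegative case weights.
#' @param cost soft-margin cost multiplier.
#' @return a [linear_rule()] with attribute `objective` (primal objective).
#' @export
init_rule_l2 <- function(x, label, weight, cost = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(label) == n, length(weight) == n, all(weight >= 0))
  keep <- weight > 0
  if (length(unique(label[keep])) < 2L) {
    maj <- if (sum(weight[label > 0]) >= sum(weight[label < 0])) 1 else -1
    warning("single-class input; returning constant rule")
    return(linear_rule(maj, rep(0, p)))
  }
  zx <- x * label
  K <- tcrossprod(zx)
  alpha <- NULL
  for (jit in c(1e-7, 1e-4, 1e-2)) {
    fit <- tryCatch(
      kernlab::ipop(c = matrix(-1, n), H = K + diag(jit, n),
                    A = matrix(as.numeric(label), 1), b = 0,
                    l = matrix(0, n), u = matrix(cost * weight, n),
                    r = 0, sigf = 7, maxiter = 100),
      error = function(e) NULL)
    if (!is.null(fit)) { alpha <- kernlab::primal(fit); break }
  }
  if (is.null(alpha)) {
    # degenerate QP (e.g. near-duplicate rows): fall back to the weighted
    # least-squares direction, which only seeds the penalty linearization
    pdtr_log("l2-SVM dual QP failed; using weighted least-squares direction")
    beta <- qr.coef(qr(sqrt(weight) * cbind(1, x)),
                    sqrt(weight) * label)[-1L]
    beta[is.na(beta)] <- 0
    b0 <- hinge_intercept(drop(x %*% beta), label, weight)
    obj <- 0.5 * sum(beta^2) +
      cost * sum(weight * pmax(0, 1 - label * (b0 + drop(x %*% beta))))
    return(structure(linear_rule(b0, beta), objective = obj))
  }
  beta <- drop(crossprod(zx, alpha))
  b0 <- hinge_intercept(drop(x %*% beta), label, weight)
  obj <- 0.5 * sum(beta^2) +
    cost * sum(weight * pmax(0, 1 - label * (b0 + drop(x %*% beta))))
  structure(linear_rule(b0, beta), objective = obj)
}

# exact minimizer over b0 of sum w * hinge(1 - z*(b0 + f)); piecewise linear
# convex, so the optimum is attained at a breakpoint b0 = (1 - z*f)/z.
hinge_intercept <- function(f, z, w) {
  br <- (1 - z * f) / z
  cand <- unique(c(br, 0))
  obj <- vapply(cand, function(b) sum(w * pmax(0, 1 - z * (b + f))),
                numeric(1))
  cand[which.min(obj)]
}

#' Weighted L1-penalized SVM as a linear program
#'
#' Minimizes `sum_i w_i xi_i + sum_j d_j (beta_j^+ + beta_j^-)` subject to
#' `z_i (b0 + h_i' beta) >= 1 - xi_i` with all split variables nonnegative,
#' where `d_j >= 0` are per-coefficient penalty weights (typically SCAD
#' derivatives at an initial estimate) and the intercept is unpenalized.
#' The LP is solved through its dual by a bounded-variable revised simplex
#' (compiled code); with slack variables the LP is always feasible and
#' bounded, so a non-optimal solver status signals a numerical problem and
#' raises an error.
#'
#' @param x feature matrix, no intercept column.
#' @param label vector in -1/+1.
#' @param weight nonnegative case weights.
#' @param penalty_weight nonnegative vector `d` of length `ncol(x)`.
#' @return list of class `"lp_solution"`: `rule` (a [linear_rule()]),
#'   `slacks`, `objective`, `status` (`"optimal"`), `iterations`.
#' @export
solve_weighted_l1_svm <- function(x, label, weight, penalty_weight) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(label) == n, length(weight) == n,
            length(penalty_weight) == p, all(weight >= 0),
            all(penalty_weight >= 0))
  sol <- .lp_weighted_l1_svm(x, as.numeric(label), as.numeric(weight),
                             as.numeric(penalty_weight))
  if (sol$status != 0)
    stop("weighted L1-SVM linear program did not reach optimality (status ",
         sol$status, " after ", sol$iterations,
         " iterations); this indicates a numerical problem")
  beta <- drop(sol$beta)
  beta[abs(beta) < 1e-9 * max(1, abs(beta))] <- 0  # exact sparsity
  structure(list(rule = linear_rule(sol$beta0, beta),
                 slacks = drop(sol$xi),
                 objective = sol$objective,
                 dual_objective = sol$dual_objective,
                 status = "optimal",
                 iterations = sol$iterations),
            class = "lp_solution")
}

# standardize features; returns list with scaled matrix and back-transform
standardize_features <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

destandardize_rule <- function(rule, std) {
  beta <- rule$coefficients / std$scale
  b0 <- rule$intercept - sum(rule$coefficients * std$center / std$scale)
  linear_rule(b0, beta, rule$positive_action, rule$negative_action)
}

#' Fit a sparse linear treatment rule by SCAD-penalized weighted SVM
#'
#' Minimizes the weighted hinge risk
#' `n^-1 sum_i w_i [1 - Z_i f(H_i)]_+ + sum_j P_lambda(|beta_j|)` with
#' `f(H) = b0 + H' beta` and the SCAD penalty, by one (default) local linear
#' approximation step: an l2-type weighted SVM provides `beta^(0)`, the
#' penalty is linearized with weights `P'_lambda(|beta_j^(0)|)`, and the
#' resulting weighted L1 problem is solved exactly as a linear program.
#' Features are standardized internally and coefficients back-transformed,
#' so `lambda` is comparable across covariates.
#'
#' @param x feature matrix (no intercept column).
#' @param contrast a [contrast_vector()] (or any list with `weight`,
#'   `label`).
#' @param scad a [scad_spec()]; if its `lambda` is `NULL` it is chosen by
#'   [select_lambda()].
#' @param n_lla_steps number of local linear approximation steps (default 1:
#'   a single linearization around the l2-SVM initializer).
#' @param penalty `"scad"` or `"none"`; `"none"` returns the weighted
#'   l2-SVM rule itself (the unpenalized comparator).
#' @param cost soft-margin cost of the initializer.
#' @param folds cross-validation folds passed to [select_lambda()].
#' @param init optional [linear_rule()] used as `beta^(0)` instead of
#'   refitting the initializer.
#' @return a [linear_rule()]; attributes `lambda` (value used) and
#'   `objective` (final LP objective) are attached for the SCAD path.
#' @export
fit_rule <- function(x, contrast, scad = scad_spec(), n_lla_steps = 1L,
                     penalty = c("scad", "none"), cost = 1, folds = 5L,
                     init = NULL) {
  penalty <- match.arg(penalty)
  x <- as.matrix(x)
  w <- contrast$weight; z <- contrast$label
  stopifnot(length(w) == nrow(x))
  if (all(w <= 0)) return(linear_rule(0, rep(0, ncol(x))))
  std <- standardize_features(x)
  if (is.null(init)) {
    init_s <- init_rule_l2(std$x, z, w, cost = cost)
  } else {
    # re-express a data-scale initial rule on the standardized scale
    init_s <- linear_rule(init$intercept + sum(init$coefficients * std$center),
                          init$coefficients * std$scale)
  }
  if (penalty == "none")
    return(destandardize_rule(init_s, std))

  lambda <- scad$lambda
  if (is.null(lambda))
    lambda <- select_lambda(x, contrast, scad, folds = folds, cost = cost,
                            init = init_s)

  beta_cur <- init_s$coefficients
  n <- nrow(x)
  for (step in seq_len(max(1L, n_lla_steps))) {
    d <- n * scad_derivative(abs(beta_cur), lambda, scad$gamma)
    sol <- solve_weighted_l1_svm(std$x, z, w, d)
    beta_cur <- sol$rule$coefficients
  }
  out <- destandardize_rule(sol$rule, std)
  attr(out, "lambda") <- lambda
  attr(out, "objective") <- sol$objective
  out
}

#' Select the SCAD penalty level by cross-validated decision value
#'
#' Splits the data into `folds` folds; for each candidate `lambda` the rule
#' is fitted on the training folds (penalty weights linearized around the
#' full-data l2-SVM initializer) and scored on the held-out fold by the
#' weighted decision value `sum_i w_i I{Z_i == 2 g(H_i) - 1}` -- the
#' empirical value of following the fitted rule.  The selected `lambda` is
#' the largest one whose cross-validated value is within one standard error
#' (across folds) of the best, the usual parsimony rule; exact ties also
#' resolve toward the larger (sparser) `lambda`.
#'
#' @inheritParams fit_rule
#' @param folds number of cross-validation folds, `>= 2`.
#' @param init optional standardized-scale [linear_rule()] whose coefficient
#'   magnitudes fix the local linear approximation weights across folds (the
#'   full-data initializer); when `NULL` each training fold refits its own.
#' @param se_frac multiple of the paired fold-score standard error used by
#'   the parsimony step (0 disables it, leaving the plain maximizer).
#' @return the selected `lambda` (a positive scalar).
#' @export
select_lambda <- function(x, contrast, scad = scad_spec(), folds = 5L,
                          cost = 1, init = NULL, se_frac = 1) {
  stopifnot(folds >= 2L)
  x <- as.matrix(x)
  w <- contrast$weight; z <- contrast$label
  n <- nrow(x)
  grid <- scad$lambda_grid
  if (is.null(grid)) {
    grid <- default_lambda_grid(scale(x), w, z,
                                length_out = scad$grid_length %||% 20L)
    # the one-step local linear approximation is only trustworthy while the
    # strongest initializer coefficient escapes the penalty (derivative 0
    # beyond gamma*lambda); cap the default grid there so cross-validated
    # fold fits and the final refit stay on the same side of that boundary
    if (!is.null(init) && max(abs(init$coefficients)) > 0) {
      cap <- max(abs(init$coefficients)) / scad$gamma * 0.999
      if (any(grid <= cap)) grid <- c(grid[grid <= cap], cap)
      else grid <- cap
    }
  }
  grid <- sort(unique(grid))
  if (length(grid) == 1L) return(grid)
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  score <- matrix(0, folds, length(grid))
  for (kf in seq_len(folds)) {
    tr <- fold_id != kf
    if (length(unique(z[tr & w > 0])) < 2L) next
    std <- standardize_features(x[tr, , drop = FALSE])
    init_k <- if (is.null(init)) init_rule_l2(std$x, z[tr], w[tr], cost = cost)
              else init
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, std$center), 2, std$scale,
                 "/")
    for (g in seq_along(grid)) {
      d <- sum(tr) * scad_derivative(abs(init_k$coefficients), grid[g],
                                     scad$gamma)
      sol <- solve_weighted_l1_svm(std$x, z[tr], w[tr], d)
      dec <- ifelse(rule_f(sol$rule, xte) > 0, 1, -1)
      score[kf, g] <- sum(w[!tr] * (dec == z[!tr]))
    }
  }
  tot <- colSums(score)
  best <- max(which(tot >= max(tot) - 1e-12))  # argmax, exact ties -> larger
  # The weighted hinge loss can tie the true rule against the constant
  # classifier, leaving the LP free to return either vertex; identify which
  # grid values yield an intercept-only full-data refit so the parsimony
  # step never trades an informative rule for a degenerate one.
  null_fit <- rep(FALSE, length(grid))
  if (!is.null(init)) {
    std_full <- standardize_features(x)
    null_fit <- vapply(seq_along(grid), function(g) {
      d <- n * scad_derivative(abs(init$coefficients), grid[g], scad$gamma)
      all(solve_weighted_l1_svm(std_full$x, z, w, d)$rule$coefficients == 0)
    }, logical(1))
  }
  if (null_fit[best] || all(null_fit)) return(grid[best])
  # parsimony: the largest non-degenerate lambda whose deficit to the best
  # is within one standard error of the paired fold-score differences
  # (0 on the plateau where decisions coincide)
  ok <- vapply(seq_along(grid), function(g) {
    if (null_fit[g]) return(FALSE)
    d <- score[, best] - score[, g]
    se <- sd(d) * sqrt(folds) * se_frac
    if (!is.finite(se)) se <- 0
    sum(d) <= se + 1e-12
  }, logical(1))
  grid[max(which(ok))]
}
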