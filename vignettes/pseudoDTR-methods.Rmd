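---
title: "Penalized doubly-robust contrast learning for survival treatment regimes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized doubly-robust contrast learning for survival treatment regimes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoDTR)
```

# The problem

A dynamic treatment regime (DTR) is a sequence of decision rules
$g_1, \dots, g_K$, one per intervention stage, each mapping a patient's
accrued history $H_k$ to a treatment $A_k \in \{0, 1\}$.  With a
time-to-event endpoint the natural objectives are the $t$-year survival
probability $S(t) = P(T > t)$, to be maximized, or — under competing
risks — the $t$-year cause-1 cumulative incidence
$F_1(t) = P(T \le t, D = 1)$, to be minimized.  Censoring means the
outcome $s(T)$ is not observed for every subject, so standard
classification-based regime estimators cannot be applied directly.

This package combines three ingredients:

1. **Jackknife pseudo-observations** replace the unobservable per-subject
   outcome with $\hat\theta_i = n \hat\theta - (n-1) \hat\theta^{(-i)}$,
   where $\hat\theta$ is the Kaplan–Meier ($t$-year survival, restricted
   mean) or Aalen–Johansen ($t$-year CIF) estimate and
   $\hat\theta^{(-i)}$ its leave-one-out version.  Pseudo-values have the
   right conditional mean under independent censoring and can be fed to
   any complete-data learner.  They are deliberately *not* clipped to
   $[0,1]$.
2. **Doubly-robust treatment contrasts.**  The sign of
   $C(H) = \mu_1(H) - \mu_0(H)$ identifies the optimal action and its
   magnitude the cost of deciding wrongly.  $C$ is estimated per subject
   by inverse-probability weighting (IPW) or by the augmented (AIPW)
   estimator that combines a propensity model and an outcome (Q) model and
   remains consistent when either one is correct.
3. **A SCAD-penalized weighted support vector machine.**  The optimal rule
   minimizes the weighted misclassification error
   $E[\,|C(H)|\; 1\{ 1\{C(H) > 0\} \ne g(H) \}]$; replacing the 0–1 loss
   with the hinge loss and adding a smoothly clipped absolute deviation
   (SCAD) penalty on the linear coefficients gives
   $n^{-1} \sum_i w_i [1 - Z_i f(H_i)]_+ + \sum_j P_\lambda(|\beta_j|)$,
   with $w_i = |\hat C_i|$, $Z_i = \mathrm{sign}(\hat C_i)$ and
   $f(H) = \beta_0 + H^\top\beta$.  One local linear approximation (LLA)
   step turns the SCAD term into a weighted $\ell_1$ penalty with weights
   $P'_\lambda(|\beta_j^{(0)}|)$, and the resulting problem is an exact
   linear program.

Multi-stage regimes are estimated backward: set $\tilde V_{K+1} = Y$ (the
pseudo-response); at stage $k$ estimate the contrast of $\tilde V_{k+1}$,
fit the stage rule, and propagate
$\tilde V_k = \tilde V_{k+1} \pm \eta_k |\hat C_k| 1\{\hat g_k \ne A_k\}$
(`+` when maximizing survival, `-` when minimizing incidence), so that
$\tilde V_k$ estimates the outcome under optimal decisions from stage $k$
onward.  Subjects not at risk at stage $k$ ($\eta_k = 0$) are excluded
from stage-$k$ fitting and pass their value through unchanged.

For minimized objectives the product form of the recursion,
$\tilde V_{k+1} - \hat C_k(\hat g_k - A_k)$, carries a sign ambiguity
once $\hat g_k$ is the minimizing rule; the package therefore uses the
regret form throughout, which keeps
$\tilde V_k$ monotone in the direction of the objective (asserted at every
fit) and is the only reading under which the downstream stage contrasts
estimate the intended quantity.

# Assumptions

Consistency, sequential randomization (no unmeasured confounding given the
history), and coarsening at random for the censoring mechanism.  Plain
pseudo-values additionally require censoring independent of both event
time and covariates; `ipcw_pseudo_survival()` relaxes this to conditional
independence by reweighting with a censoring survivor model
(`fit_censoring_model()`: marginal Kaplan–Meier or Cox with Breslow
baseline).  Within the simulators, the two IPCW variants and the plain
estimator agree in mean to well under 0.03 (tested), mirroring the
experience that covariate adjustment of the pseudo-values changes little
under independent censoring.

# Estimators and numerical choices

**Survival convention.**  Right-continuous $P(T > t)$ throughout.  At tied
times deaths precede censorings (standard product-limit convention).  With
the continuous simulated times the $P(T \ge t)$ / $P(T > t)$ distinction is
measure-zero.

**Jackknife computation.**  The default path recomputes leave-one-out
estimates once per distinct `(time, status)` pair from updated risk tables
(`method = "grouped"`); an independent reference that refits
`survival::survfit()` $n$ times (`method = "naive"`) is kept in the
package, and their elementwise equality to $10^{-10}$ is part of the test
suite (100 random datasets, $n \le 50$).

**Truncations.**  Estimated censoring survivor values are floored at 0.05
before inversion and propensities truncated to $[0.01, 0.99]$; both are
positivity guards chosen once from common practice, and both tally their
activations (`pdtr_counters()`).  Zero contrasts get label $+1$; they
carry zero weight, so the convention is inert.

**The linear program.**  With split variables
$\beta_j = \beta_j^+ - \beta_j^-$ and slacks $\xi_i$, the LLA problem is
$\min \sum_i w_i \xi_i + \sum_j d_j (\beta_j^+ + \beta_j^-)$ subject to
$Z_i(\beta_0 + H_i^\top \beta) \ge 1 - \xi_i$, all variables nonnegative
and the intercept unpenalized.  No linear-programming package is available
in the target environment, so the package ships a small bounded-variable
revised simplex (C++), applied to the *dual*, which has only $2p + 1$ rows
regardless of $n$; the primal coefficients are recovered from the simplex
multipliers.  Solutions are validated in the test suite against
`boot::simplex()` applied to the primal constraint matrix (objective
agreement to $10^{-6}$ on 100 random instances).  Features are
standardized internally and coefficients back-transformed, so $\lambda$ is
comparable across covariates; the $1/n$ factor of the empirical risk is
absorbed into $\lambda$, so its values are per-sample.  Coefficients
below $10^{-9}$ (relative) are snapped to exact zero.  Decision rules use
the strict indicator $g(H) = 1\{f(H) > 0\}$, so $f = 0$ assigns action 0.

**The initializer.**  $\beta^{(0)}$ comes from the weighted soft-margin
$\ell_2$ SVM (ridge-penalized hinge), solved through its dual QP with
`kernlab::ipop()` on a jittered Gram matrix; the intercept is recovered by
exact one-dimensional minimization of the weighted hinge loss, which is
piecewise linear in $\beta_0$.  If the QP fails on a degenerate fold the
initializer falls back to the weighted least-squares direction — it only
seeds the penalty linearization.  The soft-margin cost (default 1) has
little influence: with overlapping classes the solution approaches the
unregularized hinge minimizer, whose scale is set by the data.

**Choosing $\lambda$** (`select_lambda()`).  The default grid is
data-driven: log-spaced points spanning $[10^{-4}, 1]$ times the largest
absolute weighted margin gradient at $\beta = 0$, capped at
$\max_j |\beta_j^{(0)}| / \gamma$ — beyond that point even the strongest
initializer coefficient would be penalized, the one-step linearization is
no longer local, and cross-validated fold fits and the final refit can
land on opposite sides of the elimination boundary.  Candidates are scored
by the held-out weighted decision value
$\sum w_i 1\{Z_i = 2 g(H_i) - 1\}$; the selected value is the largest
$\lambda$ within one standard error of the best, where the standard error
is computed from the *paired* fold-score differences (zero on the plateau
where decisions coincide, so genuinely equivalent sparser fits win).  Two
further safeguards address a real degeneracy of the weighted hinge: with
imbalanced labels the hinge objective can tie an informative
single-covariate rule against the constant classifier, and the LP may
return either vertex.  The parsimony step therefore never moves onto a
$\lambda$ whose full-data refit is intercept-only, unless the null model
is the outright cross-validation winner.  $\gamma = 3.7$ is the standard
SCAD recommendation; one LLA step is the default, more are allowed for
study.  The tuning criterion itself is a package design choice; no
canonical selection procedure exists for this weighted objective.

**Comparator configurations** (`fit_dtr(method = ...)`): `pdwl` = AIPW
contrast + SCAD rule (the proposed method); `powl` = IPW + SCAD;
`dwl` = AIPW + unpenalized; `owl` = IPW + unpenalized.  The unpenalized
methods return the weighted $\ell_2$-SVM rule itself: an LP with all-zero
penalty weights has badly non-unique solutions, and the classical
outcome-weighted learner *is* a weighted SVM.  A caveat for benchmark
comparisons: in the randomized survival design the IPW comparators are
strong here — the empirical propensity is exactly correct and the
unpenalized learner is a proper weighted SVM — so the doubly-robust
refinement shows mainly on the competing-risks endpoint, where the
penalized IPW learner often degenerates to a constant rule (under
IPW-weighted incidence labels the cross-validated tuner genuinely prefers
the null model) while the penalized doubly-robust learner does not.

**Multiple arms** (`fit_multiclass_rule()`).  Per-arm Q-values come from
arm-wise AIPW with multinomial propensities (or IPW, for comparison).
`ovo` fits all pairwise rules weighted by $|\mu_a - \mu_b|$ and votes;
the `bound_lower` / `bound_upper` schemes keep the pairwise sign labels
but weight each subject by its sub-optimality gap — best minus runner-up
(a lower bound on the loss from misallocation) or best minus worst (an
upper bound).  A literal "single binary rule" cannot emit three arms, so
the bound criteria are implemented through the same one-versus-one
decomposition; at $L = 2$ all schemes reduce exactly to the binary path.
Vote ties go to the lowest arm code; per-subject Q-value ties rank the
lower arm code lower, making an all-equal row pick the highest arm.

# The simulators

`sim_scenario()` implements three designs used throughout the tests.

**Two-stage survival** (`s1_survival`): ten i.i.d. Uniform$[-2,2]$
baseline covariates; the stage-2 covariate $x_2$ is uniform on the
*realized* range of the first baseline covariate (the literal reading of
its definition); Bernoulli(0.5) treatments; log-linear stage times
$T_1 = \exp\{1.5 + 0.5 x_{1,1} + A_1(x_{1,2} - 0.5) + \epsilon_1\}$ and
$T_2 = \exp\{\cdots + A_2(x_2 - 0.5) + \epsilon_2\}$ with
$e^\epsilon \sim \mathrm{Exp}(1)$; censoring $C \sim \mathrm{Exp}(c_0)$;
transfer $\eta_2 = 1\{T_1 < C\}$; and for non-transferred subjects the
counterfactual adjustment
$T = T_1 \exp\{(g_2^{\mathrm{opt}} - A_2)(x_2 - 0.5)\}$.  True rules: $g_1 = 1\{x_{1,2} \ge 0.484\}$,
$g_2 = 1\{x_2 \ge 0.5\}$.

Two facts about this design deserve a note.  First, a non-transferred
subject is *necessarily censored* (the adjustment factor is $\ge 1$, so
$T \ge T_1 \ge C$); hence $P(\text{censored}) \ge 1 - P(\eta_2 = 1)$ and a
15% censoring calibration forces transfer above 85% (about 0.90 here).
The design's reference transfer level of about 80% is attained at the
30% calibration, and that is where the package measures it.  Second, two value conventions
coexist: with the transfer mechanism active at the 15% calibration the
optimal two-stage value is $S(3) \approx 0.659$, while with every subject
reaching stage 2 it is $\approx 0.633$ — and the constant-rule reference
values ($S(3) = 0.50$ for $g \equiv 0$, $0.31$ for $g \equiv 1$) are
coherent only under the latter.  `evaluate_regime(transfer =)` exposes
both; benchmarks use the all-transfer convention, the optimal-value check
uses the mechanism.  Decision-agreement rates are identical under both.

**Two-stage competing risks** (`s1_competing`): cause-1 events follow a
two-parameter subdistribution
$F_1(t) = 1 - \{1 - q(1 - e^{-t})\}^{\psi_1}$ with a stage-dependent
linear model for $\log \psi_1$, cause-2 times are exponential with rate
$\psi_2$, and $P(D = 1) = 1 - (1-q)^{1/\psi_1}$ — note the *reciprocal*
exponent (a `d_prob_exponent` flag switches to the $\psi$ convention).
The mixed convention is what produces the design's reference cause-1
fractions (41–43% at 15% censoring, 36–38% at 30%) and
the direction of its optimal rules ($g_1 = 1\{x_{1,2} \le 0.250\}$,
$g_2 = 1\{x_2 \ge 0.294 = 0.5/1.7\}$; the stage-2 threshold is exactly the
sign change of the $\psi_1$ interaction).  A single uniform draw drives
both the stage-1 latent cause-1 time — whose being below 3 defines the
transfer indicator — and the final cause-1 inverse-CDF draw; this coupled
reading yields the design's reference optimal incidence
$F_1(3) \approx 0.223$.  Uncoupled variants give 0.21–0.25.

**Observational variants** (`s2_true`, `s2_false`): same outcome model,
with treatments assigned by fixed logistic models — `s2_true` has
main effects only (a main-effects logistic working model is correct),
`s2_false` adds quadratic terms (the working model is misspecified).

**Three-arm single stage** (`s3_multiarm`): multinomial treatment with the
fixed covariate-dependent probabilities and a log-linear survival time
whose arm effects make the optimal arm the pointwise argmax of three
linear predictors.

**Censoring calibration.**  `calibrate_censoring()` finds $c_0$ by root
finding against a 200,000-subject uncensored probe with censoring applied
through a fixed quantile transform, so the achieved fraction is smooth and
monotone in $c_0$; constants are cached per scenario and target and are
independent of the user's seed (fixed internal probe seeds).

**What the simulators do not emulate:** covariate-dependent censoring,
staggered entry, more than one terminal outcome per subject, and
time-varying per-stage horizons.  Passing tests therefore demonstrate
correctness of the estimators under the stated generative mechanisms, not
robustness to those features of real data.

# Evaluation metrics

`evaluate_regime()` draws a fresh test sample (50,000 subjects by
convention), reports the Monte Carlo value of the candidate regime by
*simulating* it inside the generator (potential-outcome evaluation, never
reweighting), the stage-1 correct decision rate (CDR1), and the fraction
of subjects whose decisions match the true rule at both stages (ACDR),
unconditional on transfer.  This definition reproduces the constant-rule
reference entries for the survival design ($g \equiv 0$: CDR1 0.62, ACDR
0.39; $g \equiv 1$: ACDR 0.14; competing $g \equiv 0$: CDR1 0.44) as
products of independent stage agreements.

# Problem sizes used in the checks

The replicated benchmark runs 50 replicates of $n = 500$ at 15% censoring
per endpoint, with 3-fold tuning over a 10-point data-driven grid —
compact by design; the selection study above showed the capped grid is
what matters, not its density.  Monte Carlo reference values use 200,000
draws; marginal checks 100,000; decision-rate grids 20,000–50,000.
Property tests (jackknife oracle, LP oracle) run 100 random instances
each.

# Limitations

Linear decision rules only (no kernelized or neural decision functions);
single-stage multi-arm fitting is demonstrated, and multi-stage multi-arm
composition, while mechanically supported through the bound weights, is an
untested extension; no variance estimation for pseudo-value regressions;
the LP returns one optimal vertex — degenerate optima mean coefficient
vectors are not unique, so all comparisons (including the package's own
tests) are on objectives and decisions, never raw coefficients.
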