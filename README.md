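# pseudoDTR

Estimation of optimal (dynamic) treatment regimes from censored survival
and competing-risks data, for biostatisticians analyzing multi-stage
randomized trials or observational cohorts with time-to-event endpoints.

Censored outcomes are replaced by jackknife **pseudo-observations** of a
survival functional — the *t*-year survival probability S(t) = P(T > t),
the *t*-year cause-specific cumulative incidence F₁(t) = P(T ≤ t, D = 1),
or the restricted mean survival time — via
θ̂ᵢ = n·θ̂ − (n−1)·θ̂⁽⁻ⁱ⁾ built on Kaplan–Meier / Aalen–Johansen
estimators (optionally IPCW-adjusted under covariate-dependent
censoring).  Per-subject treatment contrasts C(H) = μ₁(H) − μ₀(H) are
estimated by inverse-probability weighting or by the augmented (AIPW,
doubly-robust) estimator

    μ̂ₐᴰᴿ(H) = I(A=a)/π̂ₐ(H) · Y + {1 − I(A=a)/π̂ₐ(H)} · μ̂ₐ(H),

consistent when either the propensity model π̂ₐ or the outcome model μ̂ₐ
is correct.  The decision rule g(H) = I(β₀ + Hᵀβ > 0) is learned by
minimizing the weighted hinge risk

    n⁻¹ Σᵢ wᵢ [1 − Zᵢ f(Hᵢ)]₊ + Σⱼ P_λ(|βⱼ|),   wᵢ = |Ĉᵢ|, Zᵢ = sign(Ĉᵢ),

with a SCAD penalty (γ = 3.7) linearized by one local-linear-approximation
step around an ℓ₂-SVM initializer and solved exactly as a linear program.
Multi-stage regimes are estimated by backward induction with
value/regret propagation (Ṽₖ = Ṽₖ₊₁ ± ηₖ|Ĉₖ|·I{ĝₖ ≠ Aₖ}); for competing
risks the contrast sign is flipped so the rule targets the
incidence-lowering arm.  Three or more arms are handled by Q-value
ordering with one-versus-one decomposition and lower/upper-bound gap
weights.  Built-in simulators generate two-stage survival, two-stage
competing-risks (Fine–Gray-type subdistribution), observational, and
three-arm designs with calibrated censoring, and evaluate fitted regimes
by potential-outcome simulation (value, correct-decision rates).

## Worked example

Simulate a two-stage randomized trial with 15% censoring, compute
3-year-survival pseudo-observations, fit the penalized doubly-robust
regime, and evaluate it against the generative truth:

```r
library(pseudoDTR)

sim <- sim_scenario(scenario_spec("s1_survival", n = 500,
                                  censoring = 0.15, seed = 7))
y <- jackknife_pseudo(sim$data$time, sim$data$cause,
                      pseudo_target("survival", horizon = 3))
set.seed(1)  # cross-validation folds of the lambda selection
fit <- fit_dtr(sim$panel, objective = "maximize", method = "pdwl",
               response = y)
fit
#> dynamic treatment regime fit: PDWL, 2 stage(s), objective maximize
#>   stage 1: 500 at risk, 1/10 nonzero coefficients, lambda = 0.2498
#>   stage 2: 454 at risk, 1/12 nonzero coefficients, lambda = 0.2181

str(evaluate_regime(fit, "s1_survival", seed = 8, transfer = "none"))
#> List of 3
#>  $ value: num 0.633
#>  $ cdr1 : num 0.937
#>  $ acdr : num 0.886
```

Both stage rules retain a single covariate — the tailoring variable the
generative model actually uses.  `value` is the regime's true 3-year
survival probability, estimated by assigning treatments with the fitted
rules inside the generator on a fresh 50,000-subject draw (the optimal
regime attains about 0.633 under this evaluation convention, a constant
rule about 0.50); `cdr1` and `acdr` are the fractions of test subjects
whose stage-1 (respectively both-stage) decisions match the true optimal
rules.  `run_benchmark()` repeats this pipeline over replicates and also
reports the comparator configurations (OWL, DWL, POWL).

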