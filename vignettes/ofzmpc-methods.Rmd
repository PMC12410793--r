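---
title: "Offset-free impulsive zone MPC for automated insulin delivery: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offset-free impulsive zone MPC: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofzmpc)
```

# The physiological model and its assumptions

The package is built around a minimal five-compartment linear model of
glucose–insulin dynamics in a diabetic subject:

$$\dot x(t) = A x(t) + B_u u(t) + B_r r(t) + E, \qquad y = C x = x_1,$$

with glycemia $x_1$ (mg/dL), insulin delivery rates in the blood and
subcutaneous compartments $x_2, x_3$ (U/min), and carbohydrate delivery
rates in the gut and stomach $x_4, x_5$ (g/min). Six scalar parameters
define a subject:

| parameter | meaning | units | identified bounds |
|---|---|---|---|
| $p_0$ | endogenous glucose production | mg/dL/min | [0, 20] |
| $p_1$ | hepatic autoregulation | 1/min | [0, 0.1] |
| $p_2$ | insulin sensitivity | mg/dL/U | [0, 2000] |
| $p_3$ | carbohydrate bioavailability | mg/dL/g | fixed 9.5 |
| $p_4$ | time-to-max effective insulin | min | [0, 100] |
| $p_5$ | time-to-max glucose appearance | min | fixed 20.45 |

The model is linear and unbounded: it admits negative glycemia under
overdosing. Only the *simulated plant* clamps $x_1$ at 1 mg/dL (a
physical floor); the prediction model used by the controller and the
estimator is never clamped, so all linear-systems machinery stays exact.

Two packaged subjects (DR7, DR11) have $p_1$ reported as 0.00 at the
table's printed precision. We deliberately keep the printed zeros rather
than invent unrounded values. $p_1 = 0$ makes glycemia an integrator:
the zero-insulin rest level $p_0/p_1$ is unbounded, `I - Ad` is
singular, and — importantly — an *output*-bias disturbance becomes
structurally unobservable (a constant CGM bias cannot be told apart from
the integrator's state). All downstream code paths treat $p_1 = 0$ as a
first-class case: the artificial equilibrium is kept as a hard
constraint rather than solved by inversion, and the estimator's default
disturbance enters the state equation, which stays observable.

## Impulsive sampling

Insulin is delivered as discrete boluses every $T$ minutes (default 5,
the CGM cadence). Sampling the flow exactly gives

$$x(k+1) = A_d\,x(k) + B_{ud}\,u(k) + B_{rd}\,\tfrac{r(k)}{T} + E_d,$$

with $A_d = e^{AT}$, $B_{ud} = e^{AT}B_u$,
$B_{rd} = \bigl(\int_0^T e^{As}\,ds\bigr) B_r$ and
$E_d = \bigl(\int_0^T e^{As}\,ds\bigr) E$. The integral is computed by
the augmented block-exponential identity
$\exp\!\bigl(\begin{smallmatrix}A & I\\ 0 & 0\end{smallmatrix}\bigr)T =
\bigl(\begin{smallmatrix}e^{AT} & \int_0^T e^{As}ds\\ 0 &
I\end{smallmatrix}\bigr)$, which needs no invertibility of $A$ and is
verified in the tests against an independent Runge–Kutta oracle at
$10^{-6}$ relative error.

**Units of the impulse.** A delta-impulse $u(t) = D\,\delta(t)$ with $u$
in U/min delivers exactly $D$ units, so the impulse weight *is* the dose
in U, and a basal rate $u^\*$ U/min is equivalent to a periodic bolus
$D = T u^\*$. This convention conserves injected units and makes the
impulsive fixed point of the basal-equivalent bolus agree with the
continuous rest point (the suite checks agreement within 1%). Meals are
handled as a rate $g/T$ held over one period through the integral input
matrix, which conserves grams. The pump's 0–1 U restriction applies to
the bolus $D$.

# Offset-free estimation

The sampled model is augmented with an integrating disturbance
$d(k+1) = d(k)$ entering through $B_d$ (state side) and/or $C_d$
(output side). The default is $B_d = e_1$, $C_d = 0$: mismatch is
injected into the glycemia balance, where unannounced meals and
endogenous-production error act — and it remains observable for
$p_1 = 0$ subjects, unlike the output-bias alternative (available via
configuration for $p_1 > 0$ models). Observability of
$(\tilde A_d, \tilde C)$ is verified at construction; the estimator
refuses unobservable configurations.

A Kalman filter estimates $(\hat x, \hat d)$. Defaults (all
configuration, none asserted as in-vivo values, since those were never
disclosed): process noise $10^{-4}$ on the physiological states and $1$
on the disturbance — the filter trusts the model states and puts its
weight on the plant–model difference — measurement variance $25$
(mg/dL)$^2$ from the CGM error scale, initial state
$\hat x_1 = \text{first CGM sample}$, $\hat x_{2..5} = \hat d = 0$ with
a large initial variance on $d$. The gain is recomputed each step
(time-varying mode); a steady-state mode freezes it at the Riccati fixed
point for bit-reproducible long runs. Sensor dropouts trigger a
prediction-only step. Tests verify that any constant state- or
output-side mismatch is absorbed: the stationary innovation vanishes,
which is precisely the property the offset-free controller relies on.

# The zone MPC and its quadratic program

Every period the controller solves, over the free boluses
$u(0..H_u-1)$, an artificial equilibrium $(x_a, u_a)$ and zone slacks:

$$\min \sum_{j=0}^{H_p-1}\|x(j)-x_a\|_Q^2
      + \sum_{j=0}^{H_u-1} R\,(u(j)-u_a)^2
      + P\,(s_{lo}^2 + s_{hi}^2)$$

subject to the disturbance-corrected dynamics started at the current
estimate with $\hat d$ held constant, the bolus box $[0,1]$ U, the hard
terminal equality $x(H_p) = x_a$, the equilibrium equalities
$x_a = A_d x_a + B_{ud} u_a + B_{dd}\hat d + E_d$ and
$y_a = C x_a + C_d \hat d$, and the softened zone membership
$y_{lo} - s_{lo} \le y_a \le y_{hi} + s_{hi}$. The first bolus is
applied; the controller never sees meals ($r \equiv 0$ in prediction).

Design choices where the formulation is genuinely open:

* **Move blocking.** $H_u = 30 < H_p = 100$ free boluses; doses beyond
  $H_u$ are pinned to $u_a$, consistent with the terminal equality.
* **Zone as soft constraint.** Only the zone membership of $y_a$ is
  softened, through slacks penalized quadratically with weight $P$; the
  dynamics, terminal and equilibrium equalities stay hard. Under a large
  meal or estimator transient the optimizer can place $y_a$ marginally
  outside the zone (status `"zone-relaxed"`) instead of failing; the
  distance character of the terminal cost is thereby realized inside the
  same QP. A standalone `terminal_cost()` computes the exact
  set-distance version by projection QPs for post-hoc analysis, and the
  intra-period excursion check is deliberately left as such an optional
  diagnostic rather than a constraint (exact intra-sample containment
  would need the continuous flow).
* **Weights.** $Q = \mathrm{diag}(1,0,0,0,0)$ (penalize glycemia only),
  $R = 10$, $P = 10^4$. The magnitudes were chosen by running the same
  72-h tuning scenario the study describes (unannounced 1–5 g meals
  every 2–4 h from 400 mg/dL, parameter mismatch): glucose deviations
  are O(10–100) mg/dL against dose deviations O(0.1–1) U, so regulation
  is dominated by the glucose term; $R$ smooths transient dosing and
  $P$ makes slack use expensive relative to any in-zone solution.
* **Tie-breaking.** A ridge of $10^{-7}$ (relative, added in the
  equilibrated space — see below) makes the optimum unique.
* **Dose quantization** to a pump step is available and off by default.

## Numerical treatment

Two issues surface that the clean formulation hides, and both are dealt
with once, at controller construction:

1. *Rank-deficient equalities.* With move blocking, the free boluses
   reach $x(H_p)$ only through $A_d^{H_p-H_u}\!\ldots A_d^{H_p-1}$; the
   fast modes of $A_d$ (eigenvalues $\approx e^{-T/p_4}, e^{-T/p_5}$)
   decay below machine precision over 70 steps, so the stacked
   terminal-plus-equilibrium equality block has numerical rank ~6, not
   10. The block is row-reduced by SVD (keep
   $\sigma > 10^{-10}\sigma_{max}$, orthonormal rows); the dropped
   directions have near-zero coefficients for *every* decision vector,
   so their fixed residual is checked at solve time and triggers the
   fail-safe if it exceeds $10^{-4}$.
2. *Nine decades of curvature.* The Hessian carries glucose-squared
   curvature on the doses ($\sim 10^8$) and no curvature at all on
   $x_{a,2..5}$ (pinned only by equalities). The dual active-set solver
   reports spurious infeasibility on such scaling, so the QP is
   diagonally equilibrated to unit diagonal and the solution mapped
   back. The ridge is added *after* equilibration: an earlier variant
   that applied it to raw variables silently biased the artificial
   glycemia downward by penalizing $x_{a,1}^2$ — the closed loop settled
   half a mg/dL below the zone. The regression test for zone membership
   at equilibrium guards this.

On any solver failure the controller emits a zero bolus with status
`"failed-safe"` — never inject on an unreliable solution. The QP is
cross-checked against an exhaustive grid oracle on one-compartment
instances at $H_p \le 3$ (five-state instances at $H_p = 3$ are
*correctly* infeasible: three inputs cannot steer five states onto the
equilibrium manifold, and the suite asserts the fail-safe there).

# The virtual trial: what it emulates, what it does not

`run_trial()` closes the loop at 5-min cadence: read CGM → correct the
estimate → solve the QP → inject the first bolus → advance the true
plant (optionally parameter-perturbed) with the true, unannounced meal →
predict the estimate forward. A 72-h run makes exactly 864 dose
decisions. Scenario defaults are the stated experimental world: initial
glycemia 400 mg/dL, meal sizes uniform on [1, 5] g with gaps uniform on
[120, 240] min, and CGM artifacts (Gaussian noise SD 2 mg/dL, 1 mg/dL
quantization, 1% dropouts, 0.5% spike outliers of 75 mg/dL — our
documented choices for the artifact rates, since only the artifact
*kinds* are described). One seeded generator per run feeds named
substreams (meals, sensor), so components are independently
reproducible. Optional stress-induced glucose excursions are off by
default.

What a green simulated test does **not** establish: the virtual plant is
the same model family the controller uses (perturbed parameters, not
structural mismatch); the CGM has no interstitial lag — the measured
variable *is* glycemia, as in the model's output equation; there is no
circadian or intra-day parameter variation; and under a combined 30%
mismatch the transient descent from 400 mg/dL can undershoot into
hypoglycemia before the disturbance estimate converges, a transient the
animal protocol handled with a supervised tuning day. The offset-free
guarantee we do test is asymptotic: for every packaged subject with a
±30% plant-side perturbation of $p_0/p_2$, the closed-loop glucose ends
inside the 90–130 mg/dL zone with vanishing zone distance. For the
$p_1 = 0$ subjects this convergence is slow (the glucose drifts through
the zone toward the lower edge over days — DR7 reaches exactly 90.0
after ~12 simulated days), so the 72-h check asserts zone membership,
which is what "offset" means against a target *set*. One perturbed
subject (DR2 with $p_0 \times 0.7$) physically cannot reach the zone:
its zero-insulin ceiling is $p_0'/p_1 = 68.6$ mg/dL and insulin only
lowers glucose, so the target equilibrium set is empty — the hypothesis
of the offset-free property fails and the test instead asserts the best
achievable behavior (dose → 0, glucose → its ceiling).

# Parameter identification

The pipeline reproduces the bolus-response protocol: a 37–80 sample
window at 5-min cadence with one bolus and no meals.

* **Cleaning.** Missing samples are linearly interpolated; outliers are
  removed by a Hampel filter (window 7, 3 scaled-MAD — our concrete
  reading of "outliers are removed", configurable); then moving-median
  smoothing. The "smoothing factor 0.25" is interpreted as a window of
  `max(3, round(0.25 n))` forced odd, the convention of common
  smoothing tooling; it is labeled an interpretation and overridable.
* **Global stage.** The response is *conditionally linear*: with
  $(p_1, p_4)$ fixed, glycemia is affine in $(p_0, p_2)$. The global
  search therefore Latin-hypercube samples only $(p_1, p_4)$ — warped
  toward small values, where the physiological mass and the objective's
  sharpness live — and profiles $(p_0, p_2)$ out exactly by least
  squares from three basis simulations per sample (variable
  projection), all within the 200-simulation budget. The documented
  human-scale seed point (ours: $p_0=3$, $p_1=0.005$, $p_2=1200$,
  $p_4=50$; the source of the original seed prints no values) is always
  included.
* **Local stage.** Bounded Levenberg–Marquardt on the residuals with
  parameters scaled by their bound ranges and projected onto the box:
  function tolerance $10^{-3}$, step tolerance $10^{-3}$, at most 40
  iterations, $p_3, p_5$ untouched. On noise-free synthetic responses
  all 13 packaged subjects are recovered to well under the 5% acceptance
  bar; with 5 mg/dL CGM noise the median $p_2$ error over 50 seeded
  replicates stays under 15%. A deliberate negative control shows that
  an unannounced meal inside the fit window biases $p_0/p_2$ — the
  structural reason the in-vivo model error was left to the offset-free
  layer rather than to better fitting.

# Outcome metrics

Glycemic bands $<54$, $[54,70)$, $[70,180]$, $(180,250]$, $>250$ mg/dL
tile the positive axis; band boundaries 70 and 180 belong to the
normoglycemic band. An *event* is a maximal run of $\ge 15$ min in a
band, with runs separated by $< 30$ min merged — a documented
convention, configurable, and never used by a numeric acceptance
target. MedARD is the median of $|pred - ref|/ref \times 100$ with a
seeded percentile bootstrap CI (default 5000 replicates). The cohort
summary reports the sample SD ($n-1$) next to the mean and the
coefficient of variation under both the $n$ and $n-1$ conventions: the
packaged parameter table's printed CVs for $p_0, p_1, p_2$ match the
$n$ convention (its $p_4$ CV of 0.53 matches neither recomputation —
0.35 under $n$ — and is documented as a table-internal inconsistency).
Display rounding is half-up to two decimals; raw values are kept.

# Known limitations

Single-hormone control only; no insulin-on-board accounting, meal
announcement or bolus priming; empirical (not symbolic) stability
evidence; the virtual world shares the controller's model family; and
the equality-reduction threshold, equilibration, and LM tolerance
mappings are numerical interpretations, each pinned by a test rather
than proved.
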