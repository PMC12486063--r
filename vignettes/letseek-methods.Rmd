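---
title: "Methods: feasibility-seeking and superiorization for simultaneous dose and LET reoptimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feasibility-seeking and superiorization for simultaneous dose and LET reoptimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(letseek)
```

## The problem

Intensity-modulated proton therapy (IMPT) delivers dose as a sum of
thousands of individually weighted pencil beams ("spots"). The physical
dose alone does not capture biological effect: the relative biological
effectiveness of protons rises with the dose-averaged linear energy
transfer (LET\_d), which climbs steeply at the end of the proton range —
often just beyond the target, inside an abutting organ at risk (OAR) such
as the brainstem. A plan that is clinically acceptable in dose can
therefore concentrate high-LET damage exactly where it is least wanted.

`letseek` reoptimizes the spot weights of an existing plan so that the
target keeps its prescribed dose while the quantity

$$\mathrm{cDL}_i \;=\; c \cdot D_i \cdot \mathrm{LET}_{d,i},
\qquad c = 0.04\ \mu\mathrm{m/keV},$$

is pushed down in the OARs. The constant $c$ gives the product dose units
(Gy), so dose-space and cDL-space constraints are commensurable.

## Forward model: two-component influence matrices

All forward quantities are linear-algebraic. The sparse *dose influence
matrix* $D_{ij}$ maps unit fluence of beamlet $j$ to dose in voxel $i$.
LET\_d is a dose-weighted average and is **not** additive across beamlets,
but its numerator and denominator are; the package therefore stores a
second sparse component $N_{ij}$, the per-beamlet LET\_d *numerator*
(local LET\_d × local dose), and computes

$$\mathrm{LET}_d(x)_i = \frac{(Nx)_i}{(Dx)_i}$$

for voxels whose dose exceeds a reporting floor, and 0 elsewhere. The
denominator is taken to be the total dose — the standard simplification
that the proton-deposited dose is approximately the total deposited dose.
Its decisive consequence is that the cDL image is *linear* in the fluence,

$$\mathrm{cDL}(x)_i = c\,(Nx)_i \quad \text{wherever dose} > \text{floor},$$

which is what makes per-voxel cDL interval constraints projectable rows of
a linear system. The identity $c\,D_i\,\mathrm{LET}_{d,i} = c\,(Nx)_i$
holds to machine precision by construction and is verified in the test
suite. The exact two-component ratio is retained for evaluation and
reporting (an optional separately scored denominator component is
supported by the container and the file format).

## Constraints

* **Target (dose space).** Every planning-target (PTV) voxel receives the
  interval $[0.95, 1.07] \times$ prescription. The per-voxel lower bound
  at 95% of the prescription is a *sufficient* condition for the clinical
  coverage rule that at least 98% of the PTV receives 95% of the
  prescription; the rule itself is checked post hoc by `plan_metrics()`.
  The 107% ceiling is not prescribed by any protocol we reimplement; it is
  the common clinical homogeneity cap and is exposed in the configuration.
* **OARs (cDL space).** For each OAR, the cDL volume histogram of the
  *baseline* plan (the prescription-scaled uniform fluence) is computed
  and its 30%-volume percentile — cDL30, the cDL value received by 30% of
  the structure volume — becomes a per-voxel upper bound $[0,
  \mathrm{cDL30}]$. By the step-percentile definition at least 30% of the
  OAR voxels meet or exceed the bound at baseline, so the constraint
  actively compresses the high-LET tail.
* **Percentile convention.** `vh_percentile()` returns the largest value
  $v$ with $V(v) \ge$ fraction, evaluated on raw voxel values with no
  interpolation. This makes tests integer-exact and the cDL30 extraction
  reproducible to the bit.
* **Overlap.** A voxel inside both the target and an OAR keeps only its
  target row (target priority, configurable): target coverage is the
  binding clinical goal. In the phantom generator, a target/OAR overlap
  without declared priorities is an error rather than a silent choice.

## The AMS feasibility-seeking iteration

Feasibility-seeking looks for *any* fluence satisfying all interval rows,
with no objective function. Each row is a slab $L_i \le \langle a_i, x
\rangle \le U_i$ whose Euclidean projection has the closed form
implemented in `project_interval_row()`. One sweep of `ams_iteration()`
projects onto **all** rows simultaneously and combines the displacements:

$$x^{k+1} = \Big[x^k + \lambda \sum_{i \in V_k} \tilde w_i\, d_i(x^k)\Big]_+,$$

where $V_k$ is the violated set, $\tilde w$ the normalised weights,
$\lambda \in (0, 2]$ the relaxation parameter (enforced at construction),
and $[\,\cdot\,]_+$ the clamp onto the nonnegative orthant — fluences are
physical and must stay $\ge 0$; the clamp is itself a projection onto a
convex set containing every physical plan, so it does not disturb the
convergence argument. The simultaneous form is chosen because the
projections are independent and batch into two sparse matrix products per
sweep; a sequential sweep variant is deliberately not offered, keeping the
iteration order-free and deterministic.

**Weight normalisation.** Each relaxed single-row step $x + \lambda d_i$
is Fejér monotone with respect to the feasible intersection for $\lambda
< 2$, and any convex combination of such steps inherits the property. Two
normalisations therefore both converge: dividing by the weight sum over
*all* rows, or over the *violated* rows only. The package defaults to
violated-row normalisation (`normalize = "violated"`): with all-row
normalisation the effective step length decays proportionally to the
shrinking violated set, and on the bundled synthetic case the tail of the
iteration visibly stalls (97.4% vs 99.1% PTV V95 after 200 sweeps under
otherwise identical conditions). The all-row variant remains available as
`normalize = "all"`.

**Residual and stopping.** The weighted residual is
$\sqrt{\sum_i \tilde w_i\, v_i^2}$ with $v_i$ the distance of
$\langle a_i, x\rangle$ beyond its interval (Gy). Iteration stops at
`max_iterations` (default 200) or when the residual drops below `tol`
(default $10^{-4}\times$ prescription in the pipeline configuration). An
inconsistent system terminates at the budget with a residual plateau and
no exception — deliberately, since slightly infeasible clinical systems
are the norm and the compromise point is still useful.

## Superiorization

Feasibility-seeking returns *some* feasible point. Superiorization steers
it toward a *superior* one — feasible, with an equal or lower value of

$$\chi^2(x) = \sum_{i \in \mathrm{PTV}} w_i \big(\hat D_i - D(x)_i\big)^2
            + \sum_{i \in \mathrm{OAR}} w_i \big(\widehat{\mathrm{cDL}}_i -
              \mathrm{cDL}(x)_i\big)^2,$$

where the references are the prescription ($\hat D_i$) and the cDL30
bound ($\widehat{\mathrm{cDL}}_i$). Each outer iteration of
`superiorize()` does:

1. **Bounded perturbation** (×`n_perturb`): move along the normalised
   negative gradient $-\nabla \chi^2 / \lVert \nabla \chi^2 \rVert$ with
   step $\beta = \alpha^s$, incrementing $s$ on every trial until the
   objective does not increase, then accept (clamped to $x \ge 0$).
   Because $s$ starts at 1 and never resets, the total perturbation length
   is bounded by $\sum_{s\ge1} \alpha^s = \alpha/(1-\alpha)$ — this
   summability is what preserves convergence of the perturbed iterates to
   a feasible point (perturbation resilience). The acceptance rule uses
   $\le$, so a vanishing step always terminates the trial loop; a hard cap
   of 60 trials guards the floating-point floor.
2. **Weight decay**: the objective weights are multiplied by $\eta \in
   (0,1)$, carrying $\eta^k$ cumulatively after $k$ iterations, so the
   perturbations fade and feasibility dominates late iterations. The decay
   is interpreted as acting on the whole objective (both sums); an
   `"oar-only"` mode is exposed for the narrower reading.
3. **One AMS sweep**, unchanged.

With $\alpha \to 0$ the perturbations vanish and the trajectory reduces to
plain feasibility-seeking — a limit the test suite checks — and with the
gradient identically zero (all references met) the two algorithms
coincide exactly. Reported $\chi^2$ traces always use the *undecayed*
weights so AMS and superiorization runs are directly comparable.

Defaults $\alpha = \eta = 0.99$ keep perturbations active across a
200-iteration run ($0.99^{200} \approx 0.13$); smaller values make the
method collapse to AMS within a few dozen iterations.

## The synthetic beam model

The package replaces Monte Carlo particle transport with an analytic
pencil-beam model (`beam_model()`), because only the linear-algebraic
structure of the influence matrices matters to the optimizer. Its
parameters are synthetic, documented, and deliberately not a commissioned
clinical beam model:

| parameter | default | unit | role |
|---|---|---|---|
| `range_a`, `range_p` | 0.022, 1.77 | mm, – | power-law range $R_0(E) = a E^p$ (~76 mm at 100 MeV, the water value) |
| `peak_width_mm` | 5 | mm | distal Gaussian width of the Bragg-like peak |
| `rise_width_mm` | 14 | mm | width of the proximal rise into the peak |
| `entrance_ratio` | 0.35 | – | entrance-to-peak dose ratio (typical clinical Bragg curves sit near 0.3) |
| `sigma0_mm`, `sigma_k` | 4, 0.03 | mm, – | lateral spot sigma $\sigma(d) = \sigma_0 + k d$ |
| `let_entrance`, `let_distal` | 2, 10 | keV/µm | monotone LET\_d depth curve endpoints (entrance plateau ~2, end-of-range ~10) |
| `sparsity_floor` | $10^{-4}$ | – | per-column relative threshold for sparse storage |

The depth-dose curve is exact at its anchors by construction: value
`entrance_ratio` at depth 0, maximum 1 exactly at $R_0(E)$, 0 beyond $R_0
+ 3\times$`peak_width_mm`. The LET\_d depth curve is piecewise linear and
monotone from the entrance to the distal value with a knee at 75% of the
distal edge, concentrating the rise near the end of range — the feature
that creates the clinical problem. The numerator entries are defined as
$N_{ij} = \mathrm{LET}_d(\text{depth}) \times D_{ij}$, so
numerator/denominator additivity holds exactly, not approximately.

Fields are axis-aligned (gantry multiples of 90°, couch 0), which turns a
rigid patient shift into an exact lateral spot displacement plus a depth
offset and avoids a ray-tracing/rotation engine. Density perturbations
rescale depth as $\text{depth}/\rho$ before curve lookup; under this
convention a factor below 1 pulls the Bragg peak *proximally*. This is a
pure labelling convention on the robustness scenario (the opposite sign
convention would relabel the ±3.5% scenarios), chosen so that scenario
construction, simulator and tests share one definition.

What the generator does **not** emulate: nuclear interaction halos,
heterogeneity ray-tracing, CT calibration, scattering tails beyond a
single Gaussian, and statistical MC noise. Passing tests therefore
demonstrate the correctness of the optimization and analytics machinery on
exactly structured inputs, not dosimetric fidelity on patient anatomy.

## Numerical choices

* Violated-set membership uses plain inequality beyond the bounds; the
  projection formula is continuous at the boundary, so no tie-break
  tolerance is needed in the step itself.
* LET\_d reporting floor: $10^{-6}\times$ prescription in the pipeline;
  avoids noise-dominated ratios in effectively undosed voxels.
* Constraint rows whose influence row is entirely zero (a voxel no beam
  reaches) cannot be moved by any projection; they are kept but inert, with
  a warning when their interval excludes 0 (i.e. they are unreachable).
* All solver arithmetic is deterministic given the starting point; the
  only optional stochastic element is a multiplicative jitter of the
  starting fluence (`--jitter`, seeded by `--seed`).
* Sparse round trips print 17 significant digits, making the text format
  bit-exact for doubles.

## Problem sizes

The bundled study case is a $20^3$ voxel phantom at 3 mm spacing (8000
voxels), a spherical 18 mm target abutted by a 6 mm OAR sphere, two
opposed fields with 9 mm spot and layer spacing (~200 beamlets), AMS
$\lambda = 1$ for 200 iterations — small enough that the full pipeline
runs in seconds on one CPU while exercising every code path. Solver
property tests use planted-feasible toys (50 voxels × 10 beamlets) whose
feasible point is known by construction.

## Limitations

* The cDL constraints rely on the denominator ≈ dose linearisation;
  the evaluation module reports the exact ratio, but the *projections*
  act on the linear model.
* DVH-type percentile constraints are non-convex and are deliberately
  replaced by per-voxel sufficient conditions; the clinical DVH criterion
  is verified after the fact.
* The phantom simulator's geometry is axis-aligned; arbitrary gantry
  angles require an external influence matrix (the sparse text format is
  the interchange point).
* Feasibility of the combined target/OAR system is not guaranteed on
  arbitrary inputs; on inconsistent systems the iteration returns the
  budgeted compromise point and its residual trace.
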