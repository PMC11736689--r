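---
title: "Ensemble ABFE estimation: models, diagnostics and protocol planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble ABFE estimation: models, diagnostics and protocol planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abfetools)
```

# The problem

An absolute binding free energy (ABFE), $\Delta G_b$, is the free energy of
a ligand binding its protein relative to both species free in solution.
Alchemical methods compute it along a nonphysical path: a coupling
parameter $\lambda \in [0, 1]$ scales the ligand's interactions with its
environment, and the free energy of switching those interactions on or off
is estimated from simulations. Because a fully decoupled ligand would drift
out of the binding site, a set of restraints (one distance, two angles,
three dihedrals) bridges the decoupled state, giving the double-decoupling
cycle

$$\Delta G_b = \Delta G_{alch}^{com} - \Delta G_{restr}^{com}
  - \Delta G_{alch}^{lig} + \Delta G_{restr}^{lig}
  + \Delta G_{conf}^{prot},$$

where the superscripts denote the complex and the ligand-in-solvent legs,
$\Delta G_{restr}^{lig}$ is the analytic cost of restraining the decoupled
ligand at standard-state concentration, and $\Delta G_{conf}^{prot}$ is an
empirical term absorbing systematic errors dominated by apo/holo
conformational differences of the protein. `assemble_cycle()` implements
exactly this sign convention, and the convention is pinned by unit tests
and echoed in every report because sign mistakes in cycle assembly are a
classic failure mode.

This package is the *post-processing* side of such calculations: it takes
gradient and work samples (engine-agnostic TSV formats), estimates free
energies with quantified uncertainty, runs the reliability diagnostics
that decide whether a prediction can be trusted, and costs/escalates
protocols. It runs no molecular dynamics; instead it ships synthetic
generators with analytic ground truth so that every estimator can be
validated end to end.

# Equilibrium estimation (TI over replica ensembles)

The equilibrium route simulates fixed $\lambda$-windows and integrates the
ensemble-averaged gradient,

$$\Delta G = \int_0^1 \left\langle \frac{\partial H}{\partial \lambda}
  \right\rangle d\lambda .$$

Three built-in window schedules are provided (`builtin_schedule()`): 13
windows for ligand (de)coupling, 15 for the combined
coupling-plus-restraint-release leg in the complex (adding 0.95 and 0.99),
and 12 for a separate restraint-release leg. Windows crowd toward
$\lambda = 0$ where the gradient is steepest. `coupling_weights()` records
how the interaction groups enter: van der Waals linearly over all of
$\lambda$, electrostatics extinguished below $\lambda = 0.45$ and linear
above it, restraints as $1 - \lambda$ on the combined leg.

Single trajectories of a chaotic system are not reproducible observables;
replica ensembles are. The estimator therefore works on a *rectangular*
grid — every replica present at every window — and averages across
replicas. Uncertainty comes from a bootstrap that mirrors that structure
(`bootstrap_lambda_mean()`): within each bootstrap iteration, each
replica's samples are resampled with replacement, the replica mean is
taken, and replica means are averaged; the standard error at a window is
the standard deviation of those bootstrap ensemble means. We use block
length 1 (no block bootstrap): gradients recorded every couple of
picoseconds are treated as given, and no additional autocorrelation
correction is applied. Integration is trapezoidal (`ti_integrate()`) —
exact for per-window means affine in $\lambda$, appropriate for unevenly
spaced windows — and window errors are propagated as independent through
the trapezoid weights
($w_1 = (\lambda_2-\lambda_1)/2$, $w_K = (\lambda_K-\lambda_{K-1})/2$,
interior $w_k = (\lambda_{k+1}-\lambda_{k-1})/2$):
$\mathrm{SE}^2 = \sum_k w_k^2 \sigma_k^2$. Windows are separate
simulations, so independence across windows is exact; this propagation is
our chosen, fully testable reading of variance transport through the
quadrature.

Determinism: every bootstrap stream is derived from the user seed and
keyed to the window index and the replica's position in sorted-id order,
so rerunning with the same seed is bit-identical and reordering the input
series changes nothing.

```{r ti-example}
m <- harmonic_model(k0 = 1, k1 = 4)          # dG_true = kT/2 * ln(4)
sim <- harmonic_ti_ensemble(m, builtin_schedule("coupling13"),
                            ensemble_size = 10, n_samples = 200, seed = 1)
eq_free_energy(sim$gradients, n_boot = 400, seed = 1)
sim$dG_true
```

# Nonequilibrium estimation (Crooks/Bennett and Jarzynski)

The nonequilibrium route launches fast switching transitions from
equilibrated end-state conformations; the work of each transition obeys
the Crooks fluctuation theorem, and the maximum-likelihood (Bennett)
estimator extracts $\Delta G$ from the forward and reverse work samples.
`bar_mle()` solves the self-consistency equation

$$\sum_i \left[1 + \frac{n_f}{n_r} e^{(W_{f,i} - \Delta G)/kT}\right]^{-1}
 = \sum_j \left[1 + \frac{n_r}{n_f} e^{(W_{r,j} + \Delta G)/kT}\right]^{-1}$$

by bracketed root finding to $10^{-8}$ kcal/mol; the residual is strictly
monotone in $\Delta G$, so the root is unique when it exists. Work values
are stored with the sign of their own transition direction, so the Crooks
pairing compares $W_f$ against $-W_r$; with that convention the estimator
is exactly antisymmetric under exchanging the roles of the two directions.
When the distributions share no effective support the Fisher information
at the solution vanishes and `bar_mle()` raises a convergence error
pointing at the overlap diagnostics rather than returning a number with an
infinite error bar.

Coupling transitions in a protein environment occasionally produce extreme
forward work values; these are inevitable and poison both accuracy and
precision. `filter_extreme_work()` drops all works above 1000 kcal/mol
(idempotently, with exact removal counts) before estimation.

Uncertainty adapts the ensemble philosophy: the reported value is the
pooled Bennett estimate over all replicas, while the standard error is the
between-replica standard error of per-replica estimates
(`neq_free_energy()`). The per-replica estimates are bidirectional Bennett
solutions over matched replica indices: whether sub-estimates should be
bidirectional per replica pair or unidirectional per end-state is a
genuinely open design choice, and the bidirectional-per-pair reading is
adopted here (and flagged in reports) because it yields one ΔG per replica
with the same estimator as the pooled value. A replica with
fewer than two works in either direction is refused by name.

`jarzynski()` provides the unidirectional exponential average
$-kT \ln \langle e^{-W/kT} \rangle$ (log-sum-exp stabilized, delta-method
standard error). It is biased at finite $n$, bounded above by the mean
work (Jensen), and included mainly because bidirectional estimates
degenerate toward averaged unidirectional ones when overlap vanishes —
which is precisely when Jarzynski's outlier sensitivity makes predictions
unreliable.

# Reliability diagnostics

Nonzero overlap between the forward and negated-reverse work distributions
is necessary (not sufficient) for a trustworthy bidirectional estimate.
`overlap_coefficient()` computes the area of intersection of the two
normalized histograms on shared bins (Freedman–Diaconis width on the
pooled sample, minimum 10 bins): 0 means disjoint, 1 identical. A
histogram rather than a kernel estimator keeps the $[0,1]$ bounds and the
zero-overlap count exactly reproducible; the bin rule is recorded in
reports. The reverse distribution is negated onto the common axis —
otherwise "identical distributions in both directions" could never score
1. `work_distance()` complements it with
$\min(W_f) - \max(-W_r)$: a positive value is the gap between
non-overlapping distributions, a negative value means the ranges
interleave (outliers can produce negative distances even at zero overlap).

`moment_diagnostics()` reports skewness and excess kurtosis in population
form ($m_3/m_2^{3/2}$, $m_4/m_2^2 - 3$; a sample-adjusted variant is a
switch), since per-replica free-energy distributions from large ensembles
are often visibly non-Gaussian and fat-tailed. `reliability_flags()`
applies the two reliability criteria used throughout: ensemble standard
error at or below 0.5 kcal/mol and (for the nonequilibrium route) distance
at or below 0. Both thresholds are inclusive; the boundary convention is
ours and is stated rather than implied.

# Boresch restraint term

The analytic imposition free energy of the six-dimensional restraint set
in the stiff-spring regime is

$$\Delta G_{restr}^{lig} = -kT \ln\left[
  \frac{8\pi^2 V_0}{r_0^2 \sin\theta_{A0} \sin\theta_{B0}}
  \frac{\sqrt{K_r K_{\theta A} K_{\theta B} K_{\phi A} K_{\phi B}
  K_{\phi C}}}{(2\pi kT)^3}\right], \qquad V_0 = 1660\ \text{Å}^3 .$$

Because this closed form is easy to transcribe wrongly, the test suite
validates it against an independent numerical oracle: the full restrained
configurational integral
$\int r^2 \sin\theta_A \sin\theta_B\, e^{-U/kT}\,
d r\, d\theta_A\, d\theta_B\, d\phi_A\, d\phi_B\, d\phi_C$
evaluated by quadrature with no stiff-spring approximation (the integrand
factorizes, so the 6-D integral is an exact product of six 1-D
quadratures). Agreement is required to 0.05 kcal/mol for typical force
constants, and exact logarithmic identities (volume doubling shifts by
$-kT\ln 2$; scaling all six constants by 4 shifts by $-3kT\ln 4$) are
asserted to machine precision.

# Empirical adjustment and accuracy metrics

Systematic, system-wide offsets dominate raw ABFE errors. Where reference
values exist, `conf_correction()` estimates $\Delta G_{conf}^{prot}$ per
system as the mean signed error of raw predictions and subtracts it;
per-system mean signed error is zero after adjustment by construction and
ligand ranking is untouched. The adjustment needs reference data — it is
diagnostic, not prospective — and systems with fewer than two complexes
are left alone. `accuracy_metrics()` reports MUE, RMSE, Pearson $r$ and
Spearman $\rho$ with standard errors from a nonparametric bootstrap over
complexes — resampling complexes (rather than propagating per-complex
prediction errors) is the declared, configurable choice —
plus the percentage of complexes whose reported error bars exceed given
thresholds.

# Protocol cost and escalation

`protocol_cost()` prices one ABFE prediction from a `protocol_spec()`: an
equilibrium leg costs $n_\lambda \times$ ensemble $\times$ replica length;
a nonequilibrium leg costs its two end-state ensembles plus all
transitions, with the restraint leg priced like the complex leg. The
recommended parameter sets (`recommended_protocol()`) give 2.15/1.9 μs
per prediction for the standard equilibrium/nonequilibrium protocols and
0.7/0.55 μs for the minimum ones.

`escalation_step()` operationalizes the reliability-driven workflow: for
predictions failing the thresholds, adjust one parameter at a time in a
fixed order — transitions per replica ($50 \to 75 \to 100$; distances are
most sensitive to it), then transition length (800 ps $\to$ 1 ns $\to$ 2
ns forward, reverse at half with a 400 ps floor), then ensemble size (+5
to 100), then replica length (doubling to 100 ns). The adjustment order
and the 100-transitions / 2-ns caps follow the recommended workflow; the
intermediate step values and the 100 ns replica-length cap are this
package's interpolations, config-overridable and flagged as such.
Every step strictly increases cost, escalation always terminates, and
rerun transitions are priced from scratch — extended nonequilibrium
transitions cannot reuse earlier ones.

# Synthetic ground truth

The generators exist to give estimators a desk-scale test bed with exact
answers, not to imitate proteins:

* `harmonic_ti_ensemble()` — a 1-D particle with stiffness
  $k(\lambda) = (1-\lambda)k_0 + \lambda k_1$, the simplest system where
  TI, free-energy perturbation, Jarzynski and Crooks all have closed
  forms; $\Delta G = (kT/2)\ln(k_1/k_0)$, and
  $\langle \partial H/\partial\lambda \rangle = (k_1-k_0)kT/2k(\lambda)$.
* `gaussian_work_set()` — forward works
  $N(\Delta G + \sigma^2/2kT, \sigma^2)$, reverse
  $N(-\Delta G + \sigma^2/2kT, \sigma^2)$: Crooks-consistent by
  construction with dissipation $\sigma^2/2kT$.
* `ou_switching_work()` — overdamped Ornstein–Uhlenbeck dynamics in the
  instantaneous harmonic potential while $\lambda$ switches linearly; one
  parameter (`relax_time`, the relaxation time at the $\lambda = 0$
  stiffness) controls dissipation, and the friction is identical in both
  directions, as the Crooks theorem requires of the underlying dynamics.
  Single-step switching reproduces the free-energy-perturbation identity;
  quasi-static switching converges to $\Delta G$.
* `inject_extremes()` / `skewed_dg_ensemble()` — contamination above the
  extreme-work cutoff and skew-normal $\Delta G$ ensembles with analytic
  skewness, feeding the filter and moment diagnostics.

All generators are bit-reproducible and split deterministic sub-streams
across replicas and windows.

What the toy system does *not* emulate: protein conformational change
(apo/holo), water occupancy, multimodal binding, or force-field error.
Passing tests demonstrate estimator correctness — unbiasedness,
calibration of error bars, diagnostic behavior — not accuracy on real
complexes. One concrete divergence: the regime of *positive* distances
(fully separated work distributions, common for real coupling legs) is
unreachable for the 1-D harmonic system, whose forward work distribution keeps a soft lower tail;
the transition-length trend therefore manifests as the magnitude of the
(negative) distance shrinking toward zero while overlap grows, the same
physical statement that forward and reverse work values approach each
other as dissipation falls.

# Numerical choices and problem sizes

* Bennett root: bracket $\pm 10^4$ kcal/mol, tolerance $10^{-8}$; standard
  error from the asymptotic Fisher-information form with the
  $1/n_f + 1/n_r$ correction (pooled estimates), or between-replica SE
  (ensemble estimates).
* $\lambda$ matching between files and schedules: $10^{-9}$ absolute, safe
  for text round-trips; TSV writers emit 17 significant digits so
  write-then-read is the identity to $10^{-12}$.
* Bootstrap defaults: $n_{boot} = 1000$ in the API and CLI; the test and
  acceptance runs use 400 where 50-seed repetition is involved, which
  leaves the bootstrap SD estimate's own noise well below the quantities
  compared.
* Validation problem sizes (chosen to make Monte-Carlo noise negligible
  relative to the tested tolerances): TI recovery uses ensembles of 10
  replicas × 200 samples at 13 windows over 50 seeds; Bennett recovery
  uses $10^4$ works per direction; Jarzynski $10^5$; Gaussian overlap
  $10^5$ per direction; the switching sweep uses 200 transitions per
  direction at transition lengths 100–800 ps averaged over 20 seeds.
* Degenerate inputs have defined behavior: single-sample replicas,
  filtered-empty directions, zero-variance moment inputs and exhausted
  escalation states raise typed errors; an all-equal pooled work sample
  yields overlap 1 with a degeneracy flag.

# Limitations

The package post-processes; it cannot detect under-sampling that is
invisible in the gradients or works it is given (e.g. a binding mode never
visited). The empirical $\Delta G_{conf}^{prot}$ adjustment requires
reference data and transfers none of its benefit to prospective
predictions beyond ranking. The escalation model prices simulation time
only — no wall-clock or scheduler modeling — and its intermediate step
sizes are interpolations, not measured optima.
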