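---
title: "Estimating regional cardiac tissue properties with annealed adaptive multiple importance sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating regional cardiac tissue properties with annealed adaptive multiple importance sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardamis)
```

## The inference problem

Echocardiographic deformation imaging measures how much each ventricular
wall segment shortens over the cardiac cycle.  In right-ventricular
cardiomyopathies the earliest functional abnormalities are regional:
a basal segment activates late, shortens less, or stiffens while its
neighbours still look normal.  `cardamis` treats these measurements as the
observation $z$ of a Bayesian inverse problem: given five segmental
longitudinal strain traces (three RV free-wall segments, the LV free wall
and the septum) plus the global scalars EF, EDV and RV basal diameter, it
estimates the posterior distribution $p(\theta \mid z) \propto
p(z \mid \theta)\,p(\theta)$ of a 20-dimensional mechanical parameter
vector $\theta$, and propagates that posterior to four derived tissue
properties per RV segment (contractility, activation delay, compliance,
myocardial work density).

A point estimate would hide the fact that echo measurements are noisy and
several parameters trade off against each other; the posterior makes both
uncertainties explicit.

## Parameter space and transforms

The estimated subset holds, per segment, the active stress scaling factor
`SfAct` (kPa, range [0, 1000]), the passive stiffness exponent `k1`
([1, 100]) and the mechanical activation delay `dT` (ms, [-200, 800]);
per wall, the reference midwall area `AmRef` (cm², positive, unbounded
above); and globally the relative systole duration `RSD` and cardiac
output `Q0` (L/min), both positive.  That is 5 + 5 + 5 + 3 + 1 + 1 = 20
parameters.

Sampling happens in an unbounded space: bounded parameters map through
`logit((x - lower)/(upper - lower))`, positive parameters through
`ln(x)`.  The prior is uniform in these transformed coordinates (so
importance weights need no Jacobian term); a prior uniform in physical
units is available via `amis_estimate(..., prior = "physical")`, which
adds the transform Jacobian to the weights.  The transformed-coordinate
default was chosen because the sampling distributions attached to the
parameters (logit-uniform, log-uniform) are themselves statements about
those coordinates; with the likelihoods used here the two options give
very similar posteriors because the likelihood, not the prior, dominates.

Reference values (SfAct 120 kPa, k1 10, dT 0 ms, AmRef 80/45/100 cm²,
RSD 1.0, Q0 5.1 L/min) are ordinary textbook-scale resting values and are
all overridable.  The unbounded log-uniform parameters carry finite
practical clip ranges (AmRef [5, 400] cm², RSD [0.2, 5], Q0 [1, 15]
L/min) used only to place the initial proposal.

## The surrogate forward model

The full closed-loop cardiovascular models used clinically for this kind
of inference are large compiled codes.  `cardamis` ships a deliberately
small surrogate behind a pluggable interface
(`register_forward_backend()`), so the estimation machinery can drive an
external simulator unchanged while remaining testable on its own.  The
surrogate preserves the *semantics* of every estimated parameter —
amplitude, stiffness, timing, size, duration, flow — not the physiology of
any particular model:

* **Activation.** Each segment follows a smooth pulse
  $a(t) = \sin^2(\pi\tau/T_{act})$ with $\tau = t - t_{QRS} - dT$ and
  $T_{act} = 0.4\,RSD\sqrt{60/HR}$ s.
* **Constitutive law.** Total fibre stress is
  $\sigma = S_{fAct}\,a\,\max(0, 1 + 5\varepsilon) +
  \sigma_0(e^{k_1\varepsilon} - 1)$ with $\sigma_0 = 0.5$ kPa.  The slope
  of the active length-dependence is calibrated so that reference
  parameters under the prescribed loads yield physiological systolic
  strain (about $-0.2$) and EF (about 0.6); a shallower slope lets the
  fibre shorten far past physiological lengths before its force droops.
* **Load.** Each wall bears a prescribed load-stress waveform: diastolic
  baseline $B = P_{dia} \cdot Q_0/Q_{0,ref}$ ($P_{dia} = 1$ kPa), systolic
  plateau 12 kPa (LV, septum) or 4 kPa (RV free wall).  The plateau is
  scaled by $\min(1, \overline{S_{fAct}}_w/120)$ and floored at $B$: a
  wall generates systolic load only in proportion to its own contractile
  capacity, so a non-contracting heart carries a constant load and flat
  strain.  The gate opens with a slow cosine up-ramp (a quarter of
  $T_{act}$, emulating the isovolumic rise of pressure with activation so
  the fibre is never stretched above its diastolic length at systole
  onset) and closes with a fast 30 ms ramp at $0.85\,T_{act}$ (ejection
  ends while the fibre still contracts), which makes the stress–strain
  loop work-producing.
* **Strain.** At each time point the segment strain solves the pointwise
  stress balance by bisection on $[-0.5, 1]$ (unique root by
  monotonicity; a bracket without sign change marks the sample as
  non-physiological and the simulation as failed).  Strains are then
  re-referenced to end diastole, the instant of maximum LV cavity volume.
* **Global measures.** The LV is treated as a sphere of reference midwall
  area `AmRef_LVfw`: $V(t) \propto (1+\varepsilon_{LVfw})^3$, EDV is the
  maximum volume, EF the relative volume excursion.  The RV basal diameter
  is proportional to $\sqrt{AmRef_{RVfw}}$ at the ED instant (calibration
  10 mm/cm, a surrogate-only constant).

What the surrogate does *not* emulate: pressure–volume loop realism,
valves, atria, septal interaction geometry, multi-beat hemodynamic
settling, and measurement artifacts of speckle tracking (drift, smoothing,
segment averaging).  Passing tests therefore demonstrate the estimation
machinery end to end on data with the right structure and scales, not
clinical validity of the surrogate itself.  The time step is 2 ms over a
single steady cycle.

## The likelihood

The misfit between a simulated cycle and a measurement is the
dimensionless summed squared error
$$X^2 = \sum_{seg}\left(e^2_{\varepsilon,seg} +
e^2_{\dot\varepsilon,seg}\right) + \sum_{pair} e^2_{\Delta\varepsilon,pair}
+ e^2_{EF} + e^2_{EDV} + e^2_{RVD},$$
with each windowed term a mean squared residual over the systolic window
divided by its variance, and each scalar term a squared normalised error.
The systolic window runs from QRS onset until 100 ms after the latest
segmental peak shortening, because diastolic strain is dominated by
measurement drift.  Strain rates are central differences on the
measurement grid; inter-segmental terms cover the three RV segment pairs
(apex–mid, mid–base, apex–base), the pairs in which regional heterogeneity
expresses itself.  Model traces are linearly interpolated onto the
measurement grid, treating the cycle as periodic.

Default normalisation SDs: strain 0.02, strain rate 0.2 s⁻¹,
inter-segment 0.02, EF 0.05, EDV 20 mL, RVD 4 mm — magnitudes of typical
test–retest variability for each quantity; all are configuration values.

The tempered (annealed) likelihood is $p(z \mid \theta, T) \propto
e^{-X^2/T}$: temperature $T \ge 1$ flattens the target to aid global
search, and $T = 1$ recovers the posterior actually reported.

## The annealed AMIS loop

Each iteration draws a batch from the current proposal, evaluates the
forward model and $X^2$ for the new samples, and re-weights *every sample
ever drawn* against the deterministic mixture of all proposals used so
far,
$$q(\theta) = \frac{1}{N}\sum_c n_c\,\pi_c(\theta), \qquad
w(\theta) \propto \frac{e^{-X^2(\theta)/T}}{q(\theta)},$$
so expensive simulations are recycled and samples from poorly placed early
proposals are eroded by their low weights rather than discarded.

* **Initialisation.** A small uniform box (half-width 0.05 in transformed
  units) around the transformed reference vector, at $T = T_{max} = 10$.
* **Temperature schedule.** If the best $X^2$ improved during the last
  iteration, $T \leftarrow \min(10, T + \Delta)$ with $\Delta$ the size of
  the improvement; otherwise $T \leftarrow \max(1, 0.8\,T)$.  From 10,
  exactly 11 consecutive non-improving steps reach the floor.
* **Adaptation.** The next proposal is fitted to the current tempered
  weights: weighted mean and weighted covariance over all samples,
  eigendecomposed so that draws happen along the principal component axes
  of the weighted sample set.  Three safeguards matter in practice:
  eigenvalues are floored at 1e-8 (variance units); a quarter of the
  previous component's covariance is blended into the fit, so when the
  tempered weights degenerate onto a single sample the proposal contracts
  geometrically around it (a trust region) instead of collapsing, and
  re-expands to the posterior's width once several samples carry weight;
  and with fewer than two positively weighted samples the previous
  component is reused with scales inflated 1.5-fold.
* **Component family.** Adapted components are multivariate Student-t
  with 5 degrees of freedom along the fitted axes.  In 20 dimensions the
  posterior mass lies on a shell that light-tailed Gaussian components
  systematically under-cover; the mixture balance then hands most of the
  weight to a few lucky low-density samples and the effective sample size
  stalls.  Heavy tails keep the whole shell reachable.
* **Stopping.** The loop runs at least `min_iterations` iterations
  (default 500) and then stops once the Kish effective sample size
  $N_{eff} = 1/\sum w^2$ of the temperature-1 weights exceeds
  $10\,n_\theta$, or at `max_iterations` (default 1500, flagged
  non-converged).  Adaptation uses the current temperature; the reported
  posterior always re-weights all samples at $T = 1$.

Every run is fully reproducible from its seed; the seed is recorded in
the result.

A property worth noting for interpretation: for a well-converged sampler
in 20 dimensions the *minimum* $X^2$ in the sample set does not approach
zero even on noise-free data — posterior draws have $X^2$ of order
$n_\theta/2$ above the optimum, so the best-found $X^2$ typically lands
between roughly 0.5 and 2.  Judging convergence requires $N_{eff}$, not
the best misfit alone.

## Derived tissue properties

Per RV segment, from each posterior sample's simulation:

* **Contractility** (kPa/s): the maximum rate of rise of the isometric
  active-stress capacity $S_{fAct}\,a(t)$.  In a quasi-static force
  balance the *realised* active stress always equals load minus passive
  stress, so it carries no intrinsic contractile information; the capacity
  is the quantity analogous to $dP/dt_{max}$ at tissue level and is
  exactly linear in `SfAct`.
* **Activation delay** (ms): the sample's `dT` directly.
* **Compliance** (strain/kPa): the inverse slope of the end-diastolic
  passive stress–strain relation, $1/(\sigma_0 k_1 e^{k_1\varepsilon_{ED}})$,
  evaluated at the last grid point before the earliest segmental
  activation onset.  Reported as strain-per-stress (larger = more
  compliant) to match the clinical term; the inverse convention (a
  stiffness) contains the same information.
* **Work density** (kPa = kJ/m³): the signed shoelace area of the fibre
  stress–strain loop, positive for physiological loops that shorten under
  high stress; it is invariant to where on the cycle the trace starts.

Each property value carries its sample's temperature-1 weight, giving a
posterior distribution per property; `tissue_property_table()` summarises
weighted means, SDs and 2.5/50/97.5 weighted percentiles.

## Validation statistics

* **Overlap MI.** Reproducibility between two posterior estimates of the
  same quantity is measured by discretising both weighted sample sets on a
  shared 100-bin equal-width grid spanning the union of their ranges and
  computing $100\cdot\sum\min(h_A,h_B) / \sum\max(h_A,h_B)$ percent:
  100 for identical distributions, 0 for disjoint supports.  (This is an
  overlap-over-union statistic, not Shannon mutual information.)  Weighted
  histograms are the default; a resampled-unweighted variant is available
  via a flag.
* **HDI-containing-true.** Trueness against a known parameter value is the
  posterior mass in histogram bins *strictly* denser than the bin holding
  the true value (Freedman–Diaconis bin width `2·IQR·n^(-1/3)` with
  weighted quantiles).  0% means the truth sits in the modal bin; 100%
  means it is outside the distribution.  The strict inequality makes a
  true value at the mode yield exactly 0%.  A zero IQR degenerates to a
  single bin (0% if the truth is inside the range, 100% otherwise).
* **Correlation matrix.** `weighted_correlation_matrix()` gives the
  weighted Pearson correlations between all parameters and, optionally,
  the derived tissue properties — the standard identifiability diagnostic
  (strong off-diagonal structure marks parameter trade-offs).

## Virtual patients

`generate_virtual_patient()` runs the forward model at a known $\theta$
and packages the outputs verbatim as a measurement set, so
$X^2(\theta_{true}) = 0$ by construction and estimation trueness can be
scored.  Additive Gaussian strain noise exists as an extension but is off
by default: the uncertainty being quantified is the one the likelihood's
SDs encode, not synthetic noise.  Three presets represent disease stages
of an RV cardiomyopathy: `healthy` (reference tissue), `early` (a mildly
weakened, late-activated RV base) and `overt` (weakened and stiffened
basal and mid segments with a dilated RV).  The abnormality magnitudes are
deliberately early-stage — a few percent to a few tens of percent of the
reference values, producing datasets whose misfit from reference is on
the scale the likelihood SDs encode ($X^2$ of order $10^2$).  This is the
regime the annealed sampler is built for: the temperature cap bounds how
much misfit the annealed weights can see past, so per-iteration descent
is of order $T_{max}$, and the sampler resolves in a few hundred
iterations datasets whose starting misfit is a few hundred.  Far-advanced
disease (starting misfit in the thousands) is reachable but needs
proportionally more iterations.

## Problem sizes used by the test suite

The package's own validation runs at desk scale: the estimation protocol
in the acceptance tests uses the standard minimum of 500 iterations with
50 samples per iteration, capped at 600 iterations (up to 30 000 forward
evaluations, a few minutes per run at the 2 ms surrogate time step),
three virtual patients for trueness and two different-seed runs on one
virtual patient for reproducibility.  The toy-likelihood cross-check
against dense-grid quadrature uses 200 iterations of 50 samples in 2
dimensions, where quadrature is exact to plotting accuracy.  Batch size
50 (rather than 100) keeps the runs inside a desktop time budget; the
iteration minimum and the $N_{eff}$ stopping rule are kept at their
standard values because, as shown by the temperature-cap argument above,
halving the batch mainly slows posterior accumulation while halving the
iteration count breaks descent.

At this reduced batch size convergence is seed-dependent: some runs
satisfy $N_{eff} > 10\,n_\theta$ within the cap, others end at the cap
with an effective sample size of only a handful, and the trueness (HDI)
and reproducibility (MI) statistics of a capped run inherit that Monte
Carlo noise — a posterior represented by four effective samples has
essentially arbitrary per-parameter histograms.  The acceptance tests
report these statistics under the fixed protocol regardless, so their
outcomes should be read together with the per-run $N_{eff}$: they
demonstrate the machinery end to end and quantify what this budget buys,
not the asymptotic behaviour of the method, which the full-size protocol
(hundreds of samples per iteration, no cap) is designed for.

## Known limitations

* The surrogate's load waveforms are prescribed, not generated by a
  circulation; RVD is a geometric proxy; strain amplitudes, while in the
  physiological range, are not patient-calibrated.
* A 20-dimensional posterior explored with tens of thousands of samples
  retains Monte Carlo error: HDI and MI statistics on single runs are
  noisy, and identifiability of `SfAct` and `k1` degrades in segments
  whose traces the likelihood window barely constrains.
* Evaluation is sequential by design (deterministic order, bit-identical
  reruns); no parallel scheduler is included.
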