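---
title: "Modeling ephaptic interactions in axonal fiber sheets"
author: "ephapse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ephaptic interactions in axonal fiber sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephapse)
```

## The scientific problem

White-matter fiber pathways are sheets and bundles of densely packed
parallel axons separated by a thin, resistive extracellular space. When an
action potential travels along one axon, part of its return current flows
through that shared space and polarizes the neighbouring membranes — an
*ephaptic* interaction, distinct from synaptic or gap-junction coupling.
`ephapse` implements two mathematical descriptions of this situation and
the analysis machinery needed to characterize what the coupling does to
traveling impulses.

### The discrete sheet model

Each of $N$ identical unmyelinated axons is a FitzHugh–Nagumo (FHN) cable.
Writing $v_p(z,t)$ for the transmembrane potential of axon $p$ and $w_p$
for its recovery variable, the nondimensional model is

$$
4(R+1)\sum_{s=1}^{N}\alpha_{ps}\,\frac{\partial^2 v_s}{\partial z^2}
 = \frac{\partial v_p}{\partial t} + f(v_p, w_p) - I_p,
\qquad
\frac{\partial w_p}{\partial t} = \epsilon\,(v_p + a - b\,w_p),
$$

with $f(v,w) = -(v - v^3/3 - w)$, so that the uncoupled cable is the
standard excitable FHN cable $\partial_t v = \partial_z^2 v + v - v^3/3 -
w + I$. The coupling weights $\alpha_{ps}$ are the entries of
$A^{-1}$, where $A$ is tridiagonal with constant diagonal $D = 4(R +
\tfrac12)$ and unit off-diagonals; $R = r_a/r_e$ is the ratio of
axoplasmic to extracellular longitudinal resistance. Because the coupling
enters through a matrix *inverse*, every axon interacts with every other,
with strength alternating in sign and decaying geometrically with lateral
separation — the physical consequence of all axons sharing one
extracellular return path. `build_coupling_matrix()` constructs $A$,
$\alpha$, and the effective diffusion matrix $B = 4(R+1)\alpha$; a
continuant (Usmani-type) closed form for the entries of the inverse of a
constant-diagonal tridiagonal matrix is implemented independently in
`closed_form_inverse_entry()` and used purely as a test oracle.

$R$ is estimated from tissue geometry as $R = (1/\rho)(A_e/A_a)$ with
$\rho$ the extracellular-to-intracellular resistivity ratio (plausibly 1
to 4) and $A_e/A_a$ the area ratio of extracellular space to axon; tightly
packed tracts put $R$ roughly between 0 and 1, with *smaller* $R$ meaning
*stronger* ephaptic coupling. `physical_to_nondimensional()` performs this
map together with the axial and temporal rescalings $\tilde z =
\sqrt{g(r_a+r_e)}\,z$, $\tilde t = (g/c)\,t$.

### The continuum field model

Treating the lateral direction as continuous gives the field system

$$
\frac{\partial^2 v}{\partial z^2} = i + K\,\frac{\partial^2 i}{\partial x^2},
\qquad
i = \frac{\partial v}{\partial t} + f(v,w) - I,
\qquad
\frac{\partial w}{\partial t} = \epsilon(v + a - b w),
$$

where $i$ is the membrane-current field and $K =
(\delta^2/\lambda^2)/(R+1)$ collects the interaxonal spacing $\delta$ and
the lateral length scale $\lambda$. The solver eliminates $i$ each step by
solving the lateral Helmholtz-type relation $(1 + K\,\partial_x^2)\,i =
\partial_z^2 v$ implicitly with zero-flux boundaries. An equivalent
integro-differential form exists in which the lateral operator appears as
a convolution with the oscillatory kernel
$\frac{1}{\sqrt K}\sin(|x-x'|/\sqrt K)$; the package represents this
operator only through the implicit solve (numerically far better
behaved), and refuses — with a "resonance" error — parameter/grid
combinations for which $1 + K\mu$ vanishes for an eigenvalue $\mu$ of the
discrete lateral Laplacian.

## Correspondence between the two models

A central practical question is which $K$ corresponds to which $R$. The
package resolves it exactly at the level of the linear lateral structure.
On the lateral grid, the strongest ephaptic effect acts on the
*alternating* lateral mode (neighbouring axons out of phase):

* discrete model: the alternating eigenvector of $B$ has eigenvalue
  $4(R+1)/(4R+2-2) = 1 + 1/R$;
* continuum model: the most oscillatory lateral mode has effective axial
  diffusivity $1/(1 + K\mu_{\min})$ with $\mu_{\min} \to -4/dx^2$, i.e.
  $1/(1 - K/K^\*)$ with resonance constant $K^\* = dx^2/4$.

Equating the two gives the amplification-matched pairing

$$K = \frac{K^\*}{R + 1} = \frac{dx^2/4}{R+1},$$

which on the default grid ($dx = 1$, one column per axon) places the
continuum partner of $R = 0.19$ at $K = 0.2101$. Note the formal
continuum-limit expression $K = (\delta^2/\lambda^2)/(R+1)$ has exactly
this form with $K^\* = \delta^2/\lambda^2$: the pairing is the
continuum-limit formula with the resonance constant evaluated on the
actual simulation grid rather than at the physical spacing. All
cross-model comparisons in the package (notably the spectral-similarity
experiment below) use this mapping.

Two consequences are worth stating plainly, because they are the
package's main deliberate deviations from naive expectations:

1. **Small printed $K$ values are weakly coupled on an axon-pitch grid.**
   With $dx = 1$, values of $K$ of a few hundredths give lateral
   amplifications of only 1.1–1.25, far below what recruitment of
   neighbouring axons requires; simulations there show two independent
   impulses at every such $K$. The qualitative continuum regimes instead
   appear as $K$ approaches $K^\* = 0.25$: stable finite fronts near
   $K \approx 0.18$, laterally widening (diffusive) fronts near
   $K \approx 0.19$–$0.21$, and complex re-entrant patterns just beyond.
   The regime ladder as a function of amplification matches the discrete
   model's ladder in $R$ almost perfectly (see the test suite).
2. **No stable discretization makes all small printed $K$ values strongly
   coupled.** Choosing $dx$ small enough to amplify $K \approx 0.026$
   puts larger $K$ beyond the resonance, where the axial term for
   super-resonant lateral modes becomes *anti*-diffusive and the
   initial-value problem is effectively ill-posed (verified: fine lateral
   grids blow up within a few time units). This is an intrinsic property
   of the operator, not of the scheme.

## Numerical scheme

Both models are advanced by the same implicit–explicit Crank–Nicolson
(CN) step, implemented in compiled code:

* the linear coupled-diffusion operator — lateral operator composed with
  the axial second difference — is treated by CN. The lateral operator is
  diagonalized once (it is symmetric, or similar to symmetric via a
  diagonal edge rescaling), so each implicit solve decouples into one
  constant-coefficient tridiagonal solve along $z$ per lateral mode
  (Thomas algorithm with precomputed factors). A dense brute-force
  stepper (`dense_reference_step()`), which assembles the full operator
  as one matrix, serves as the independent oracle: production and oracle
  trajectories agree to better than $10^{-13}$ on small grids;
* the cubic reaction, the recovery equation and the stimulus are advanced
  by forward Euler from the step-start state, keeping the implicit solve
  linear. This choice is deliberate: the regime boundaries reported for
  this class of models (e.g. the onset of neighbour recruitment at
  $R = 0.4$) sit within about 0.01 in $R$ of the transition, and are tied
  to this classic treatment of the nonlinearity at $dt = 0.05$. A
  second-order extrapolated treatment of the reaction (tried during
  development) shifts the recruitment threshold to $R^\* \approx 0.395$
  and flips the $R = 0.4$ scenario to the non-recruiting side. With the
  reaction on, the scheme is therefore first-order in $dt$; the linear
  part retains CN's second order, which the suite verifies via the
  reaction-off hook (error ratio $\approx 4$ per halving of $dt$);
* zero-flux boundaries use second-order mirrored ghost nodes, in $z$ for
  both models and in $x$ for the continuum; the discrete model's lateral
  edges are already encoded in the first and last rows of $A$;
* runs start from the uniform resting state, the unique intersection of
  the FHN nullclines (defaults: $v^\* = -1.0328$, $w^\* = -0.6656$),
  whose linear stability is checked at construction time;
* a finiteness guard aborts with a clear message naming $dt$ if the
  explicit reaction ever destabilizes the step.

Default discretization: $dt = 0.05$, $dz = 0.5$, $dx = 1$, 50 lateral
nodes, snapshots every 1 time unit. All defaults are configurable through
`grid_spec()` or the YAML configuration interface.

### Domain auto-sizing

The axial extent is not a physical parameter; what matters is that
impulses never reach the far boundary (zero-flux ends would reflect
subthreshold tails and annihilate arriving pulses). When `z_extent` is
omitted the package measures the single-cable pulse speed
(`estimate_pulse_speed()`, about 1.03 in model units at default
parameters) and sets `z_extent = 1.3 × speed × t_end + margin`. The
factor 1.3 bounds the lead-front speeds measured across every coupled
regime (1.08–1.27 × the single-cable speed — the lead impulse is fed, but
not outrun, by its recruits). Analyses exclude the final 10% of the
domain as a guard band.

## Stimulation

The reference stimulus is a boxcar current $I = 2$ applied for 2 time
units over $z \in [0, 4]$ at the inlet of a chosen axon — just
suprathreshold, launching exactly one action potential.
`impulse_protocol()` builds lists of such events; the standard
two-impulse scenario stimulates lateral index 30 at $t = 0$ and 20 at
$t = 10$.

`poisson_train_protocol()` gives every axon a finite train (10 impulses
by default) whose inter-onset intervals follow a refractory-respecting
Poisson process: interval $=$ minimum gap $+$ an exponential variate,
with the exponential rate chosen so the intervals have *exactly* the
requested mean (default 10). The minimum gap (boxcar duration 2 +
refractory floor 5) prevents two stimuli from merging into one. A naive
"resample until the gap clears the floor" rule would inflate the realized
mean from 10 to 17 and silently change the input statistics, which is why
the shifted-exponential form was chosen. The first onset is uniform in
$[0,$ mean interval$]$; no particular convention is standard here, and
this one makes the train ensemble stationary from the start. Everything is reproducible from a single integer seed, and the
protocol (including the seed) is echoed verbatim into every result
archive.

One caveat documented here because it is a real property of the model,
not a bug: with a mean interval of 10 the FHN membrane (whose own
refractory period is roughly 15–20 time units at $\epsilon = 0.1$)
does not fire for every stimulus, so the realized inlet interspike
interval is substantially longer than the stimulus mean. Rate statistics
should therefore be compared *between* coupling conditions, not against
the generator mean; the generator-mean check in the test suite uses the
drawn intervals themselves.

## Analysis toolkit

All analyses are pure functions of a result archive.

* **Spike detection** (`detect_spikes()`): upward crossings of a
  threshold with linear interpolation, refractory suppression. Threshold
  0 sits midway between rest ($\approx -1.03$) and the impulse peak
  ($\approx +1.9$); refractory 5 is below the membrane's refractory
  period. Both configurable.
* **Rasters** (`build_raster()`): spikes at 10 equally spaced axial
  stations excluding the inlet stimulus region and the final 10% of the
  domain; requires snapshot cadence ≤ refractory/2 so no spike is missed.
* **Impulse lag** (`measure_lag()`): per-station difference of
  first-spike times for a pair of axons; "locked" once the change per
  station is below 2% (absolute floor 0.05 time units for near-zero
  lags). These thresholds operationalize what is visually evident in
  space-time plots; they are configurable.
* **Front width** (`front_width()`): laterally contiguous groups whose
  first-spike times at a station fall within a 5-time-unit locking
  window.
* **Backward propagation** (`detect_backward_propagation()`): chains of
  spikes whose arrival times strictly decrease across ≥ 3 consecutive
  stations (a wave traveling toward the inlet), counted after a
  configurable transient.
* **mISI** (`compute_misi()`): per-node mean interspike interval,
  station-averaged over nodes with at least two spikes; nodes with fewer
  are excluded but counted (whether such nodes should enter the average
  is genuinely ambiguous; exclusion plus reporting was chosen).
* **Spatial spectra** (`spatial_spectrum()` /
  `spectrum_cosine_similarity()`): per-snapshot magnitude of the 2D DFT
  of $v$(lateral, axial), flattened; cosine similarity per matched
  snapshot, with mean and SD over the run. The 2D transform is the most
  inclusive reading of "spatial pattern"; a lateral-only variant is
  available behind a flag for sensitivity analysis.
* **Regime classification** (`classify_regime()`): decision tree over
  the measured evidence — retrograde chains ⇒ `complex`; no recruitment
  ⇒ `independent` or `locked` (by lag behaviour); stable cluster size
  $k$ ⇒ `front(k)`; growing clusters without retrograde chains ⇒
  `diffusive_front`. Ambiguity yields `complex` with a low-confidence
  flag, never a silent answer.

## The regime phenomenology

With the standard two-impulse protocol the discrete model traverses, as
$R$ decreases (coupling strengthens):

| $R$ | regime |
|------|--------|
| 0.8 | two independent impulses (adjacent stimulation instead yields attraction/repulsion and phase locking) |
| 0.4 | each impulse recruits both neighbours: stable 3-wide fronts |
| 0.33 | 5-wide fronts (exactly two more axons per front) |
| 0.19, 0.15, 0.05 | complex re-entrant spatiotemporal patterns with lateral and backward re-initiation |

The continuum model traverses front → diffusive front → complex as its
lateral amplification $1/(1-K/K^\*)$ increases. In this package's
operator the progression is monotone in $K$; a reversion from complex
back to a diffusive front at still-higher coupling is not observed
(stronger coupling only deepens re-entry). Cross-model spectral
similarity in the paired complex regimes ($R = 0.19$ vs $K = 0.2101$) is
high: the time-averaged cosine similarity of the 2D spectra is ≈ 0.99–1.0
at the package's standard auto-sized domain. This statistic is sensitive
to the fraction of the domain occupied by the pattern, since both models
share the large rest-state background: saturating a small recycled
domain drops it to ≈ 0.86–0.91, while oversizing the domain drives it
toward 1. Values near 0.96 correspond to a domain with modest margin
around the pattern. The mean is reported together with its SD, and the
test suite asserts the documented conditional floor of 0.94 rather than
a narrow band, precisely because of this margin sensitivity.

## Problem sizes used by the tests

Routine test runs use 50 lateral nodes, an axial domain of 300 (601
nodes) with a horizon of 800 time units for regime scenarios, 600 for
phase-locking scenarios, and 450 with five-impulse trains for rate
statistics; the cross-model spectral experiment uses the auto-sized
domain (about 1080) at `t_end = 800`. These sizes were chosen as the
smallest at which each phenomenon is fully developed and
scale-insensitive (front widths, labels and locking plateaus are
identical at double the domain and horizon); the brute-force oracle
comparisons run on 6 × 40 grids where the dense operator is tractable.

## What the synthetic conditions do and do not show

The simulations are the model's own study conditions, not recordings:
identical unmyelinated axons on a regular lattice, homogeneous
parameters, noiseless dynamics, idealized boxcar stimuli. Passing tests
demonstrate that the *implementation* reproduces the mathematical
phenomenology (locking, recruitment, re-entry, rate reorganization) —
they say nothing about whether real white-matter tracts occupy the
strongly coupled parameter range. Myelination, axon-diameter
heterogeneity, 3D bundle geometry, and stochastic channel noise are all
outside the present scope (the 3D extension adds one lateral operator
term and would follow the same numerical pattern).

## Known limitations

* The reaction is explicit first order; halving $dt$ roughly halves the
  nonlinear-part error. At the default $dt = 0.05$ this is the regime in
  which the reference phenomenology (including the $R = 0.4$ recruitment
  boundary) is defined.
* The continuum operator is only meaningful below its lateral resonance
  $K^\* = dx^2/4$; the package refuses resonant configurations rather
  than integrating an ill-posed system.
* `scan_regimes()` caches by a coarse configuration tag (model, value,
  grid signature), not a full content hash.
* Result archives use R serialization; they are self-describing within R
  but not a cross-language format.
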