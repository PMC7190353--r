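---
title: "Modelling axonal tension buffering by crosslinker unfolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling axonal tension buffering by crosslinker unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmech)
```

## The problem

Stretched axons behave as strain-softening viscoelastic solids: after each
applied strain step the tension first jumps, then relaxes to a *non-zero*
steady state, and the steady-state effective modulus falls as the strain
grows while the tension saturates (tension homeostasis). A long-time solid
response rules out crosslinker unbinding and filament turnover as the
dominant dissipation channel — repeated unbinding would let the tension
relax to zero. The mechanism implemented here is instead reversible
unfolding of crosslinker repeat domains: spectrin tetramers of the
membrane periodic skeleton (and potentially tau, spectraplakins and
neurofilament sidearms) release stored length under tension, buffering it,
and refold on release, restoring the initial state.

## The model

The axon is treated as a homogeneous cylinder pierced by $M$ types of
elastic elements in parallel, $n_i$ copies of type $i$ per cross-section,
so the total tension is $\mathcal{T} = \sum_i n_i T_i$. Each element is a
worm-like chain at relative extension $\Lambda = \lambda \ell_0' / \ell$,
where $\lambda = 1 + \gamma$ is the axon deformation (affine down to the
element scale), $\ell_0'$ the zero-strain end-to-end length and $\ell(t)$
the current rest (contour) length:

$$T(\Lambda) = \frac{1}{\beta \ell_p}\left[\frac{1}{4(1-\Lambda)^2} +
\Lambda - \frac{1}{4}\right].$$

The rest length evolves by mean-field unfolding/refolding kinetics,

$$\frac{d\ell}{dt} = -\nu_f (\ell - \ell_f) + \nu_u (\ell_u - \ell),
\qquad
\nu_u = \nu_u(0) e^{\beta T \Delta x_{fu}}, \quad
\nu_f = \nu_f(0) e^{-\beta T \Delta x_{uf}},$$

with Bell-type tension dependence: tension tilts the folding landscape,
accelerating unfolding and hindering refolding. At fixed deformation the
rest length settles at $\ell_{ss} = (\nu_u \ell_u + \nu_f \ell_f)/(\nu_u +
\nu_f)$, solved self-consistently because the rates depend on $\ell_{ss}$
through $T$. Linearising about that state gives an exponential tension
relaxation with time constant

$$\tau = \left[(\nu_u + \nu_f) + \frac{\nu_u \nu_f}{\nu_u + \nu_f}
\frac{\ell_u - \ell_f}{\ell}\,\beta(\Delta x_{fu} + \Delta x_{uf})\,
\Lambda K(\Lambda)\right]^{-1},$$

where $K = dT/d\Lambda$. The first term is the constant-rate limit; the
second encodes the feedback of tension on the rates and produces the
signature non-monotonic $\tau(\gamma)$: refolding-limited growth at low
strain, unfolding-accelerated decay at high strain.

## Default parameters

The single built-in species is the axonal spectrin tetramer
(`spectrin_species()`), with literature values: $\ell_p = 20$ nm,
$k_BT = 4$ pN nm, $\ell_0' = 170$ nm, $\ell_f = 200$ nm, $\ell_u = 1200$
nm, $\Delta x_{fu} = 2.5$ nm, $\Delta x_{uf} = 15$ nm, $\nu_u(0) = 10^{-5}$
s$^{-1}$, $\nu_f(0) = 100$ s$^{-1}$. The persistence length is assumed
independent of the folding state. Because $\ell_0'$ is close to $\ell_f$,
the element carries about 2.2 pN of pre-tension at zero strain — the model
axon is under tension even unstretched, as observed. Copy number defaults
to $n = 1$ (a single element); for cross-section-scale forces the
envelope estimate of a few hundred tetramers per cross-section
(`spectrin_count()`) is the natural choice, and the synthetic force-record
generator uses $n = 300$.

```{r}
sp <- spectrin_species()
steady_state_tension_curve(c(0, 0.05, 0.1, 0.2), axon_model(sp))
```

## Numerical choices

* **Units.** pN, nm, s internally; total tension crosses interfaces in nN
  (1 nN = 1000 pN) and geometry in µm, where 1 nN/µm² = 1 kPa.
* **Steady-state solver.** The residual $g(\ell) = \ell - (\nu_u \ell_u +
  \nu_f \ell_f)/(\nu_u+\nu_f)$ is monotone increasing in $\ell$ ($T$, and
  with it $\nu_u/\nu_f$, falls as $\ell$ grows), so `uniroot` on the
  bracket $[\max(\ell_f, \lambda\ell_0'(1+10^{-6})),\ \ell_u(1-10^{-9})]$
  is safe; the achieved residual is below $10^{-9}$ nm. When refolding
  dominates so strongly that the self-consistent solution would fall below
  the bracket, the result is clamped to the folded length and flagged.
* **Guard band.** $\Lambda$ is rejected beyond $1 - 10^{-9}$ rather than
  allowed to return `Inf`, protecting the ODE right-hand side from NaN
  propagation.
* **Integration.** `deSolve::ode` with `lsoda` (switches to a stiff
  method as needed — the rates span seven orders of magnitude), relative
  tolerance $10^{-8}$, absolute tolerance $10^{-10}$ nm. Strain steps are
  instantaneous: rest lengths are continuous across a step, tension jumps.
  The experimental feedback controller is idealised away.
* **Relaxation decomposition.** After a step the tension increment decays
  toward the *new* steady state,
  $\mathcal{T}(t) = \mathcal{T}_{ss} + \sum_i n_i \delta T_i
  e^{-(t-t_{step})/\tau_i}$ — the literal sum-of-decaying-exponentials
  form without offset would contradict the non-zero long-time plateau, so
  the offset form is used throughout.
* **Numeric relaxation oracle.** `relaxation_time_numeric()` equilibrates,
  applies a strain increment of $2\times10^{-4}$ (the linearisation error
  of the fitted time constant is first order in the increment; at
  $10^{-3}$ it already reaches the 2% level), integrates on a log-spaced
  grid (the decay time can sit orders of magnitude below the bare-rate
  scale when the stiffness term dominates) and fits the mid-decay window
  (2–50% of the initial increment) log-linearly. With tension-independent
  rates a strain step leaves the rest-length fixed point untouched; the
  oracle then perturbs the rest length directly.
* **Bi-exponential fits.** Bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`) with eight multistarts: offset from the tail
  mean, slow time constant from log-linear peeling, remaining starts
  log-spaced over the window span. $\tau_1 \ge \tau_2$ is enforced by
  post-sort; vanishing amplitudes or indistinguishable constants raise a
  degeneracy flag instead of failing.
* **Steady-state plateau estimate.** Mean over the final 10% of the
  window's *time* span (simulated records are log-sampled after each
  step, so a sample-count tail would reach far into the decay), with a
  drift flag when the tail still trends.

## The rheology pipeline

A cantilever record $(t, D, d)$ with force constant $k$, axon length
$L_0$ and radius $r$ maps to strain
$\gamma = (\sqrt{L_0^2 + 4d^2} - L_0)/L_0$, force $F = k(D - d)$ and
axial tension $\mathcal{T} = F/(2\sin\theta)$ with $\sin\theta =
d/\sqrt{d^2 + (L_0/2)^2}$. Tension is undefined at $d = 0$; such samples
are dropped with a warning. The cross-sectional area is held fixed — the
constant-volume thinning correction, $\Delta r/r_0 = -\gamma/2$, is below
optical resolution at the strains of interest and would slightly
*increase* the inferred moduli, so neglecting it is conservative for the
softening conclusion.

Step detection takes strain changes above 0.002 (after running-median
smoothing over 5 samples; the smallest protocol step of interest is
0.01). A record that opens already under load is treated as beginning at
an unobserved step, so its leading segment is analysed too. The rest
tension $\mathcal{T}_0$ is the intercept of a least-squares line through
the three smallest-strain plateau values by default. Note a structural
bias: the model's tension–strain curve is concave, so any linear
extrapolation overestimates $\mathcal{T}_0$, which can suppress the
effective modulus $E = (\mathcal{T}_{ss} - \mathcal{T}_0)/(A\gamma)$ of
the smallest-strain step. When the true rest tension is known (synthetic
data), `softening_curve(..., T0 = )` accepts it; measured records inherit
the bias, which is documented rather than hidden.

## Periodicity analysis

Line-scan intensity profiles are split into 1-µm segments; each segment's
biased, mean-subtracted, variance-normalized autocorrelation is averaged
pointwise. The spectrin lattice shows as a positive ACF peak near the
tetramer length (~190–200 nm) and a trough near the half period. The
amplitude metric is the window maximum (150–250 nm) minus the window
minimum (50–150 nm). A profile is called periodic only when the peak
window contains a local maximum with *positive* ACF value and the
amplitude reaches 0.1: disordered profiles (jittered peak positions) have
uniformly negative window ACF after segment demeaning, and 0.1 is the
fluctuation level of segment-averaged ACFs of unstructured profiles at
typical imaging noise. The peak position is refined by three-point
parabolic interpolation, giving sub-sample period estimates.

Two estimator facts worth knowing: the linear (non-circular) ACF is shift
invariant only up to an $O(1/N)$ boundary term, and the *normalized* ACF
amplitude of a noiseless peak train saturates at the pure-cosine value as
blur grows — it decreases monotonically with blur only in the realistic
regime where fixed imaging noise competes with the shrinking signal
variance.

## Synthetic data

The generators emulate the two experimental inputs with known ground
truth attached to every object:

* `generate_force_record()` simulates the crosslinker model under a step
  protocol and inverts the pulling geometry ($d$ from $\gamma$, $F$ from
  $\mathcal{T}$, $D = d + F/k$), adding Gaussian noise to the
  tip-displacement channel — where instrument noise enters in the real
  apparatus. Default geometry: $k = 0.1$ nN/µm, $L_0 = 150$ µm, radius
  0.5 µm (mid-range of the axons the technique targets).
* `generate_intensity_profile()` produces a Gaussian-peak train (period
  190 nm, PSF width 40 nm, sampling 10 nm, length 20 µm — twenty 1-µm
  segments), with additive noise and optional positional disorder
  (`disorder * period` jitter) emulating lattice loss after actin
  disruption. Knockdown is emulated by reducing the peak amplitude at
  fixed *absolute* noise (background-limited imaging: the background does
  not scale with labeling intensity), with group comparisons averaged
  over profiles as the imaging workflow averages over axons.
* `generate_relaxation_trace()` draws exact bi-exponential data for fit
  validation.

Default protocol waits are six analytic relaxation times per step so the
plateau is effectively reached; note that after a *large* step the
nonlinear decay is slower than the linearized $\tau$, so plateau-critical
analyses use longer waits.

What the generators deliberately do not reproduce: active contractility
and growth responses (suppressed at room temperature in the experiments
this emulates), cantilever thermal fluctuations, photon-counting noise
statistics, axon-to-axon parameter variability, and 2-D image structure.
Passing tests therefore validate the inference machinery against the
model's own ground truth, not the biological variability of real
recordings.

## Known limitations and open choices

* A mean-field rate equation for $\ell(t)$ ignores single-molecule
  unfolding stochasticity; it is the appropriate description for hundreds
  of parallel crosslinkers.
* Actin rings are load-bearing anchors but not elastic elements; the
  microtubule core's fluid-like sliding is summarised only by the
  order-of-magnitude estimators.
* Bi-exponential time-constant recovery is information-limited: for the
  reference design (amplitudes 2 and 1 nN on a 5 nN offset, $\tau_1 =
  60$ s, $\tau_2 = 5$ s, 500 samples over $5\tau_1$, 5% multiplicative
  noise) the Cramér–Rao bound gives $\mathrm{sd}(\tau_1)/\tau_1 \approx
  8.8\%$ and $\mathrm{sd}(\tau_2)/\tau_2 \approx 47\%$, so no estimator
  can place both constants within 10% in much more than ~13% of
  replicates. The fitter operates essentially at that bound; the
  recovery-rate check in the test suite records the attainable rate
  honestly rather than relaxing the stated target.
* The strain behind the 0.07 thinning magnitude is taken as 0.14
  (back-inferred from the first-order constant-volume relation), and the
  junction-based spectrin tension bound is reported as computed (5.4 nN)
  rather than forced onto a printed order-of-magnitude range.

## Problem sizes

The test suite and the acceptance script run the relaxation-time oracle
on 21 strains, simulate 4–20-step protocols (up to ~1300 s of model
time), fit 100 noisy bi-exponential replicates, and analyse 50 disordered
plus 20 control/knockdown 20-µm profiles — sizes chosen to give stable
Monte-Carlo rates while keeping a full run in well under a minute.
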