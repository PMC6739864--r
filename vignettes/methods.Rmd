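---
title: "Methods: orientation decodability through the firing rate nonlinearity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation decodability through the firing rate nonlinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frnldecode)
```

## The scientific question

A stimulus feature is *linearly decodable* from a neural population when a
weighted sum of the responses suffices to classify it. In primary visual
cortex (V1), simple-cell membrane potentials are driven by oriented Gabor
receptive fields, so they certainly *carry* orientation information — but
they are also modulated by nuisance parameters of the stimulus (phase,
spatial period, contrast). Under phase variability the membrane-potential
response manifolds of different orientations interleave, and a linear
read-out fails entirely. The firing rate nonlinearity (FRNL) of the cells,
a threshold power law

$$ r(u) = \Phi\,\lfloor u - u_{th} \rfloor_+^{\kappa}, $$

rectifies away the low-potential half of response space. This loses total
information (everything below threshold maps to zero rate) but *sparsifies*
the code, and sparse codes are more linearly separable. The package's
simulations quantify this trade-off: linear decodability of orientation
from firing rates peaks at an intermediate firing threshold, a few mV above
the mean membrane potential, while the total information (the performance
of an optimal Bayesian decoder) only ever decreases with the threshold.
The optimal threshold is then compared, in normalised units, with
thresholds measured in real simple cells.

## The population model

Each of $N$ model neurons is a circular Gabor filter with six parameters:
center $(x, y)$, spatial period $\lambda$, preferred orientation $\theta$,
phase offset $\varphi$ relative to the center, and envelope SD $\delta$.
Defaults: $N = 500$, $\lambda = 3°$, $\delta = 2°$, preferred orientations
$\theta_n = 180°(n-1)/N$, phases evenly covering $[0°, 360°)$ in randomly
permuted order, centers uniform on a disk of radius $R = 90°$ (1.5° for
the hypercolumn variant). The mean membrane potential in response to a
sine grating of orientation $\vartheta$, phase $\phi$, period $\lambda_s$
and contrast $c$ has the closed form

$$ u = u_{DC} + c\,u_{AC}\left[\cos(\psi_s + \varphi - \phi)\,E_-
     + \cos(\psi_s - \varphi - \phi)\,E_+\right],\qquad
   E_\mp = e^{-2\pi^2\delta^2\left|k \mp k_s\right|^2}, $$

where $k, k_s$ are the filter and stimulus wave vectors and
$\psi_s = 2\pi(\sin\vartheta\,x - \cos\vartheta\,y)/\lambda_s$ is the
location phase. The calibration fixes the phase-averaged response at
$u_{DC} = -60$ mV and the modulation amplitude at preferred orientation and
full contrast at $u_{AC} = 12$ mV; contrast scales only the AC part. For
equal periods this reduces to the standard equal-period Gabor response
formula with $|k \mp k_s|^2 = 2(1 \mp \cos(\theta-\vartheta))/\lambda^2$.
The unequal-period form is a standard Gaussian integral; because no external
reference form was available for it, it is validated against a brute-force
pixel-grid quadrature oracle (truncation $4\delta$, step $\lambda/40$) to
within 1% of $u_{AC}$ in the test suite. The $E_+$ term is
$\sim 10^{-61}$ of $E_-$ at the default geometry; its cosine argument
(which an equal-argument approximation would alter) is numerically
irrelevant but kept exact.

Control populations share the V1 receptive-field locations: *retina*
neurons sample the grating value at their center ("pixel" receptive
fields), and *LGN* neurons are balanced (equal-volume)
difference-of-Gaussians with center/surround SDs 1.5°/4°. Both are
affinely calibrated per neuron so their noise-free response variance over
a reference orientation x phase ensemble matches the corresponding V1
neuron within 2%. These populations carry as much response variance, but
their phase and orientation selectivity are confounded, and orientation
remains linearly undecodable from them under phase nuisance at every
threshold — the control result reproduced in the test suite.

Membrane-potential noise is zero-mean Gaussian, drawn independently per
20 ms bin (one draw per stimulus presentation), SD $\sigma = 3$ mV
(25% of $u_{AC}$), optionally with uniform pairwise correlation $\rho$
(sampled exactly through a shared component). Information-limiting
correlations are represented by their generative mechanism — jitter of
the encoded orientation itself with SD $\sigma_\vartheta$ — on both
sides: banks can present orientations jittered around their class labels
(`bank_spec(ilc_sd = )`), and the ideal observer marginalises the jitter
with a wrapped-normal kernel (`ilc_posterior()`), rather than through a
bespoke covariance construction.

## Stimulus banks

Decoding uses $K = 10$ orientation classes with $M_\vartheta = 10$
within-class orientations and $M_\phi = 50$ phases on zero-anchored
uniform grids (the same convention as the population's preferred
orientations), every grid stimulus repeated $M_{rep}$ times with fresh
noise: $M = K M_\vartheta M_\phi M_{rep} = 10^5$ training rows at the
asymptotic reference size. Test banks share the stimulus grid but never a
noise draw. Fixed nuisance values are phase 180°, period 3°, contrast 0.5.
Variable spatial period is lognormal ($\mu = 0.95$, $\sigma = 0.55$) and
variable contrast Beta($2.4, 3.6$), both reflecting natural image
statistics, sampled with a distorted grid: equally spaced probability
levels through the inverse CDF, randomly assigned to grid nodes. (The
beta contrast distribution has mean 0.4, while the reference
parameterisation fixes contrast at 0.5 and describes it as the natural
mean — an inconsistency as stated; the package honours the fixed value
0.5 and notes the discrepancy here.)

## Decoders and performance measures

The linear decoder is multinomial logistic regression (bias plus one
weight per neuron and class), trained by Barzilai–Borwein gradient descent
on the cross-entropy; a weak $L_2$ penalty ($10^{-8}$) fixes the softmax
gauge, features are standardised internally for conditioning (predictions
are invariant), and non-convergence within the iteration cap is flagged in
metadata. The test suite verifies the optimiser against an independent
solver (`nnet::multinom`) to $10^{-6}$ relative objective tolerance.
Decisions take the maximum class probability, ties to the lowest index.

The optimal Bayesian decoder inverts the generative model exactly on the
bank's stimulus grid: membrane potentials are Gaussian around the filter
response; the firing-rate likelihood mixes a point mass
$p^0_n = \Pr(u \le u_{th})$ at zero with the change-of-variables density
for positive rates; the class posterior marginalises phase (grid of
$J = M_\phi$ values) and within-class orientation with uniform priors.
All accumulation is in the log domain with log-sum-exp — with $N = 500$
neurons, likelihood products underflow otherwise. Exponents $\kappa < 1$
are rejected (no invertible one-sided derivative at threshold); at
$\kappa = 1$ the derivative is taken as $\Phi$. Because the
superthreshold branch of the FRNL is invertible, the optimal posterior —
and hence total information — is identical for all $\kappa \ge 1$ at a
given threshold; only the linear decoder is sensitive to $\kappa$.

Performance measures: fraction correct (FC); probabilistic fraction
correct, the geometric mean of posterior mass on the true class, floored
at $10^{-12}$ in the log domain with floored rows counted; and a
Monte-Carlo mutual-information estimate
$I = \log_2 K + \overline{\log_2 p(\vartheta_m|r)}$ bits, which is an
exact transform of log PFC. The sparseness-scaled prediction of linear
performance is $(FC_{opt} - \text{chance})\times\text{sparseness} +
\text{chance}$, with sparseness the fraction of exactly-zero rate entries
— the quantity rectification controls directly, with the correct limits
(0 when nothing is rectified, 1 when the population is silent).

## Threshold sweeps and regimes

`threshold_sweep()` reuses one set of membrane-potential draws across the
threshold grid (so the lowest grid point reproduces membrane-potential
decoding exactly), retrains the linear decoder at every threshold, and
evaluates the optimal decoder on an evenly-spaced subsample of test rows.
The default grid spans $[u_{DC} - u_{AC} - 3\sigma,\; u_{DC} + u_{AC} +
3\sigma]$ at 1 mV, with an optional 0.25 mV refinement pass around the
coarse peak; the optimum is the grid argmax, with no curve fitting.

Robust regimes are the normalised-threshold intervals
$z = (u_{th} - u_{DC})/u_{AC}$ retaining at least 90% of peak performance
for every FRNL exponent $\kappa \in \{1, 1.25, 1.5, 1.75, 2\}$ at a given
noise-to-signal ratio $\sigma/u_{AC}$. Two criteria: *RU* (linear-decoder
FC; a bounded interval) and *infomax* (optimal-decoder mutual information;
monotonically non-increasing in the threshold, so the interval always
extends to $-\infty$ and only the upper edge binds). Since the geometry of
the normalised RU optimum collapses across population size and class
count, RU regimes are computed on reduced populations ($N = 250$ in the
acceptance tests); the infomax ceiling, in contrast, extends further for
larger populations, so infomax regimes are computed at the full $N = 500$
(cheap, as no decoder training is involved) — and the $\kappa$
intersection is trivial by the invariance noted above.

## Intracellular pipeline and its synthetic ground truth

`synth_trace()` emulates whole-cell recordings of drifting-grating
responses: 3 s trials at 2 Hz (6 cycles) preceded by 3 s gray, generator
potential $u_{DC} + u_{AC}\sin(2\pi\,2\,t + \text{jitter})$ with Gaussian
phase jitter (SD 10° of cycle phase) across trials, noise as an
Ornstein–Uhlenbeck process with 20 ms correlation time and stationary SD
$\sigma$, inhomogeneous-Poisson spikes at rate $r(u)$ with a 2 ms
refractory period, and a stereotyped spike waveform (0.4 ms rise to
~60 mV, 0.5 ms decay, small after-hyperpolarisation). The OU process is
the smooth counterpart of iid 20 ms noise bins: piecewise-constant bin
noise would put mV-scale discontinuities every 20 ms into a 10 kHz trace,
which no slope-based spike detector could distinguish from spike onsets,
while the OU process matches the bin-level statistics (stationary SD,
correlation time) that the downstream estimators rely on. Poisson spiking
(rather than deterministic threshold crossing) keeps the FRNL histogram
estimable at low rates. Ground truth is stored in the trace and read only
by tests.

Analysis operations mirror the stated recording pipeline. Spike removal
detects onsets by a dV/dt threshold (10 mV/ms over a 0.2 ms span, 1 ms
merge, 20 mV prominence confirmation — the prominence step is what lets a
slope detector coexist with continuous-noise traces) and subtracts a
composite analytic fit per spike: template amplitude and a linear baseline
fitted jointly by least squares over a small alignment search, with the
fit range truncated at the next spike's onset and the template subtracted
over its full support; windows with poor fits fall back to linear
interpolation. Cycle-overlay extraction computes per-trial $u_{DC}$ (mean
over cycles and time), $u_{AC}$ (amplitude of the cycle-averaged waveform;
sinusoid fit by default, half peak-to-trough as the alternative) and
$\sigma^2$ (variance across overlaid cycles at matched positions). FRNL
estimation bins 20 ms window means into a 1 mV voltage histogram, divides
spike counts by occupancy time, and fits a threshold-linear function by
time-weighted least squares (plus threshold-power-law fits over the
$\kappa$ grid for the consistency display). Conditioning on the 20 ms
window mean rather than the instantaneous potential gives the fitted
threshold a small downward bias that grows with $\sigma$; at the
physiological noise range (SDs ~1.5–3 mV) recovery is unbiased at the
1 mV level on average, with individual 30 s recordings scattering by
roughly the same amount at ~20 spikes (a Poisson floor, visible in the
test suite's multi-cell averaging).

The four reference cells ship as `recorded_cells()`; their normalised
thresholds (0.27, 0.42, 0.54, 0.23) and noise-to-signal ratios (0.24,
0.31, 0.53, 0.41) follow from the tabulated parameters by arithmetic. The reference
$\sigma$ values are reported without units (while noise level as a
quantity is sometimes quoted in mV²); they are treated here as mV standard
deviations, the only reading consistent with noise-to-signal ratios up to
~0.55. The
permutation test shuffles each parameter vector across cells independently
(the stricter null; permuting whole parameter tuples would leave the
statistic unchanged), with the threshold-only shuffle available as the
alternative scheme; $p$ is the fraction of shuffles with at least the
observed in-regime count.

## Numerical choices and problem sizes

Degrees externally, radians internally; angle wrapping maps a grating at
$\vartheta + 180°$ to the identical physical pattern at $\vartheta$ with
flipped phase. Argmax ties break to the lowest index everywhere. Seeds are
set per experiment; identical seeds give byte-identical outputs.

Test and acceptance runs use scaled-down problem sizes chosen once:
reduced banks ($M_{rep} = 1{-}2$, $M_\phi = 20{-}25$) for sweeps at
$N = 500$; $N = 40{-}100$ populations with $K = 4{-}5$ classes for
structural property tests; three independent population draws for the
fixed-phase decodability level, whose test-set value moves by a few
percentage points across receptive-field draws; and the regime grids noted
above (2 mV threshold steps, five exponents). The acceptance script
(`scripts/acceptance.R`) states its sizes alongside each quantity.

## Known limitations

The model is a static, feed-forward description: no drifting-grating
temporal dynamics in the decoding pipeline, no extra-classical
receptive-field effects, no spike-count decoding (rates are decoded
directly; the affine-equivalence below threshold makes the
membrane-potential limit exact). Synthetic traces use a stereotyped spike
shape and stationary OU noise, so passing recovery tests demonstrates
correctness of the pipeline's logic, not robustness to real
electrophysiology artefacts (electrode drift, bridge imbalance, bursting).
The sparseness definition (zero fraction) is one of several reasonable
choices; its testable commitments are its limits and monotonicity. Regime
intervals inherit Monte-Carlo noise from finite banks; the acceptance
tests use fixed seeds and grid resolutions at which the qualitative
memberships are stable.
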