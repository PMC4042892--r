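---
title: "Methods: time-varying cardiorespiratory coupling from two-channel recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-varying cardiorespiratory coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardioresp)
```

This vignette is the package's own account of the model, the algorithms,
the tunable parameters, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

The heartbeat and respiration are treated as two self-sustained oscillators
described only by their phases $\phi_h, \phi_r$:

$$\dot\phi_{h} = \omega_{h} + q_{h}(\phi_h,\phi_r,t) + \xi_{h}(t), \qquad
  \dot\phi_{r} = \omega_{r} + q_{r}(\phi_h,\phi_r,t) + \xi_{r}(t),$$

with natural frequencies $\omega_{h,r}$, coupling functions $q_{h,r}$ that
are $2\pi$-periodic in each phase, and white Gaussian noise
$\langle\xi_i(t)\xi_j(\tau)\rangle = \delta(t-\tau)E_{ij}$. Each coupling
function is split by its arguments into a *self* part (own phase only), a
*direct* part (other phase only), and an *indirect* part (both phases).
The direct part of the heart equation, $d_h(\phi_r,t)$, is the only term
that can sustain a stable respiratory modulation of the heart rate — it is
the respiratory sinus arrhythmia (RSA). Indirect terms absorb pathways in
which an intermediate system (e.g. arterial pressure via the baroreflex) is
driven by both rhythms. All terms may drift in time, which is why the
inference is windowed.

## Phase and frequency extraction

**Wavelet transform.** `compute_wt()` uses an analytic Morlet wavelet with
central angular frequency $\omega_0 = 2\pi$ and L1 normalization, so a scale
of $a$ seconds corresponds to a nominal frequency $1/a$ Hz and a
unit-amplitude tone has $|W| = 1$ at its ridge. Scales are log-spaced,
$a_j = 2^{j/n_v}(2/f_s)$ with $n_v = 64$ voices per octave, and capped at
$T/8.6$ so that any retained scale fits at least about eight oscillations
into the record. The cone of influence is $\pm 3$ Gaussian e-folding widths
($3\sqrt2\,a$); outside it the edge transient of the finite record
dominates and cells are flagged, not dropped.

**Synchrosqueezing.** Each cell's instantaneous frequency is the central
difference of its argument,
$\omega_f(a,t_i) = \arg[W(a,t_{i+1})\overline{W(a,t_{i-1})}]/(4\pi\,\Delta t)$,
valid for components below a quarter of the sampling rate. `synchrosqueeze()`
reassigns every cell to the equi-log-spaced frequency bin containing its
$\omega_f$:

$$T(\omega_l, t) = \Delta\omega_l^{-1} \sum_{a_k:\,\omega_f(a_k,t)\in[\omega_l,\omega_{l+1})}
  W(a_k,t)\,\frac{\ln 2}{n_v},$$

where $\ln 2 / n_v$ is the log-measure $da/a$ of the grid. The complex mass
$\sum_l T\,\Delta\omega_l$ is conserved by construction (tested to 1e-6),
and a tracked component is reconstructed as
$x(t) = \mathrm{Re}[(2/C_\psi)\sum_{\text{support}} T\,\Delta\omega]$ with
$C_\psi = \int_0^\infty \hat\psi(u)\,du/u$ evaluated once by quadrature.

**Ridge tracking.** `track_support()` follows the main curve with a window
of fixed width $n_v/2$ bins. At each time the window maximizes
Gaussian-centre-weighted mass times two multiplicative penalties:

$$F(i_c,t) = \Big[\sum_{|i-i_c|\le w/2} |T_{i,t}|\, e^{-(i-i_c)^2/2\sigma_g^2}\Big]
  \, e^{-\lambda\,\lvert\log(\omega_{i_c}/\omega_{\mathrm{prev}})\rvert}
  \, e^{-\kappa\,\lvert\log(\omega_{i_c}/\bar\omega)\rvert}.$$

Design choices here, made once: the centre weight's $\sigma_g$ is half the
window width, so edge bins receive weight $e^{-1/2}\approx 0.6$; the
penalties act on log-frequency (the natural metric of the grid) and are
multiplicative so that $F$ stays positive; $\omega_{\mathrm{prev}}$ is the
amplitude-weighted frequency of the previous window's support and is
initialized at the global amplitude-weighted mean $\bar\omega$ (no previous
window exists at $t=0$; starting at the global mean removes startup bias,
and `omega_init` can force a particular component instead); argmax ties
break toward the lower frequency. Defaults $\lambda=5,\kappa=0$ for the ECG
and $\lambda=10,\kappa=10$ for respiration, whose frequency wanders more.
The tracker is exactly the per-time maximization of $F$ (tested against an
independent exhaustive scoring).

**Phase/frequency.** The phase is the unwrapped argument of
$\sum_{\text{support}} T\,\Delta\omega$; the frequency is the
$|T|$-weighted mean of the bin frequencies over the support, which is more
robust than the ridge centre when the curve is non-uniformly broadened.
Both are sampled at the signal's rate. Because the phase comes from the
fundamental band only, it is invariant (up to a constant) under invertible
point transformations of the waveform — tested with $x$ vs $x^3 + x$.

**A measured limitation.** For a tone frequency-modulated at a quarter of
its own carrier rate ($f(t) = 1 + 0.1\sin(2\pi\,0.25\,t)$ Hz) the wavelet's
time resolution attenuates the recovered modulation: at the ridge scale the
coefficient argument is the Gaussian-smoothed phase (measured modulation
gain 0.30, matching $e^{-(2\pi\nu a)^2/2}$), and multi-scale reassignment
recovers the overall gain only to about 0.70. The frequency-tracking RMSE
for that test case is therefore ~0.021–0.022 Hz, with residual noise an
order of magnitude smaller; this is a resolution property of the Morlet
family at $\omega_0 = 2\pi$, not an implementation artefact. Slow
modulations (e.g. 0.1 Hz on a 1 Hz carrier) are tracked with little
attenuation.

## Wavelet phase coherence and intersubject surrogates

`wpc()` computes, per frequency, the modulus of the time-averaged unit
phasor of the phase difference between two wavelet transforms on a common
grid. Amplitudes cancel, so the measure is invariant to channel rescaling.
Averaging is restricted to the admissible interval of the *lowest*
frequency on the grid for every frequency, so that all frequencies are
averaged over the same window and the frequency profile is not biased by
unequal effective lengths.

Low frequencies have few cycles per record and therefore high coherence
under the null; significance must come from surrogates. The package uses
*intersubject surrogates*: channel A of subject $i$ paired with channel B
of subject $i+1$ (cyclically), which preserves all single-channel structure
while destroying any genuine interdependence; `pairing = "all"` uses all
$N(N-1)$ ordered pairs instead. The threshold is the rank-ordered 95th
percentile (no normality assumption). With $N$ cyclic surrogates the
exceedance probability of the threshold under exchangeability is
$(N - \lceil 0.95N\rceil + 1)/(N+1)$ — about 7% at $N=40$, approaching 5%
as $N$ grows; the calibration test accepts 3–8%. Fourier-type (FT/IAAFT)
surrogates are not implemented; the intersubject construction needs no
phase randomization and tests the hypothesis actually of interest
(absence of interdependence).

Band summaries default to the conventional physiological intervals
(cardiac I: 0.6–2 Hz, respiratory II: 0.145–0.6 Hz, myogenic III:
0.052–0.145 Hz, neurogenic IV: 0.021–0.052 Hz, endothelial V:
0.0095–0.021 Hz); the edges are configuration, not constants. Note that the
full range down to 0.0095 Hz requires roughly 900 s of data ($T \ge 8.6/f$);
the default cohort configuration restricts coherence to 0.145–2 Hz, which
250-s records admit.

## Windowed Bayesian inference

`build_basis()` expands each $q$ in a double Fourier series up to order 2
(constant + 24 sin/cos terms after collapsing the $(n,m)\sim(-n,-m)$
redundancy) plus one sin/cos pair per common locking ratio
(3:1, 4:1, 5:1, 6:1, 7:1, 7:2, 9:2, 10:3 — the term for $n{:}m$ has
argument $m\phi_h - n\phi_r$, the combination that drifts slowly near that
resonance), i.e. 41 terms per equation. Every term is tagged
self/direct/indirect per equation; these tags drive the coupling
decomposition later.

`infer_window()` implements the dynamical Bayesian scheme for time-evolving
coupled oscillators: phase velocities by forward difference, basis
functions at the midpoint of consecutive samples, and a Gaussian posterior
for the stacked coefficients $c$ given the noise matrix $E$, with the
drift-divergence correction $-\tfrac{h}{2}\sum_n \partial\Phi_k/\partial\phi_l$
in the linear term; $E$ is re-estimated from the weighted residuals,
$E = (h/N)\sum_n r_n r_n^\top$, and the two updates are alternated to a
fixed point (relative change $<10^{-6}$, cap 100 iterations; a $10^{-14}$
ridge keeps $E$ invertible on noise-free data). Ill-conditioned designs
(condition number above $10^{12}$) raise an error suggesting a longer
window or smaller basis.

`infer_sequence()` runs non-overlapping windows (default 50 s — at least
ten respiratory cycles, enough data for 82 coefficients) and carries
information forward: the next prior mean is the current posterior mean and
the prior covariance is inflated as
$\Sigma_{\mathrm{prior}} = \Sigma_{\mathrm{post}} + p_w^2\,
\mathrm{diag}(\Sigma_{\mathrm{post}})$. This one-constant rule reproduces
both stated limits exactly — identity at $p_w = 0$ (full propagation) and
flat-prior independence as $p_w \to \infty$ — and $p_w = 20$ is the
default; on stationary simulations the choice of $p_w$ in a wide range
changes time-averaged coefficients by a few percent only. The initial prior
is weakly informative (zero mean, variance $10^4$ per coefficient). Phases
are decimated to 10 Hz before inference: the dynamics of interest live at
or below ~2 Hz, and decimation cuts cost several-fold without touching the
estimates; it is configurable (`decimate_to = NULL` disables it).

## Derived measures

**Synchronization.** For a ratio $n{:}m$, `sync_map()` fixes
$\psi = \phi_h/n - \phi_r/m$ on the section $\phi_h/n + \phi_r/m = 0$,
integrates the *deterministic* inferred flow (noise off; classical RK4 with
a step of 1/200 of the nominal sum-coordinate cycle) until the sum
coordinate advances by $2\pi$, and returns the final $\psi$. Locking
corresponds to a stable fixed point: `detect_sync()` scans the wrapped
displacement $M(\psi)-\psi$ for sign changes between adjacent determinate
grid points (64-point grid by default), refines roots by bisection to
$10^{-6}$, and requires $|dM/d\psi| < 1$ by central difference. Trajectories
whose sum coordinate stops advancing, or which have not crossed within
three nominal cycles, are indeterminate — away from the region the data
explored the inferred flow is prior-dominated, and single-trajectory
failures there are expected; a window counts as synchronized only on the
evidence of the determinate part, and as indeterminate only if the map
fails everywhere. Detection agrees with a brute-force boundedness oracle
(long noise-free integration of the inferred flow) on the test battery.
Synchronization durations are quantized in window units; the overall
duration is the sum over ratios.

**Directionality and decomposition.** `coupling_norms()` takes the
Euclidean norm (the natural choice for Gaussian posteriors) of the
heart-equation coefficients on all $\phi_r$-dependent terms
($\varepsilon_{r\to h}$) and conversely ($\varepsilon_{h\to r}$);
$D = (\varepsilon_{r\to h} - \varepsilon_{h\to r}) /
(\varepsilon_{r\to h} + \varepsilon_{h\to r}) \in [-1, 1]$, flagged
undefined when both norms are below $10^{-8}$ rad/s. Self terms enter no
norm. The direct/indirect split follows the basis tags.

**RSA shape.** The direct term is written
$d_h(\phi_r,t) = A(t)\sin(\phi_r + \alpha(t)) + B(t)\sin(2\phi_r + \beta(t))$
(sine-reference convention: $c_{\sin}\sin\phi + c_{\cos}\cos\phi =
A\sin(\phi+\alpha)$ with $\alpha = \mathrm{atan2}(c_{\cos}, c_{\sin})$).
$B/A$ measures how non-sinusoidal the RSA waveform is; its mean and
standard deviation over windows, and the harmonic phase coherence
$\gamma = |\langle e^{i(2\alpha - \beta)}\rangle|$, summarize shape
stability. Windows with $A < 10^{-6}$ are excluded from the $B/A$ summary
and counted.

**Coupling surfaces.** `coupling_grid()` evaluates $q_h, q_r$ (constant
term excluded) on a uniform torus grid; because the map from coefficients
to surfaces is linear, the time-averaged surface equals the surface of the
time-averaged coefficients.

## The synthetic-data module

`simulate_phases()` integrates the phase model with an internal step of at
most $\min(1/(20 f_h), 1/f_{s,\mathrm{phase}})$. Each substep advances the
drift by classical RK4 and then adds the exact Gaussian increment
$\sqrt{dt}\,L z$ with $L$ the symmetric square root of $E$ — for additive
noise this increment is exact, and the fourth-order drift makes step-halving
change noise-free trajectories by less than $10^{-4}$ rad (a first-order
Euler drift misses that bound by more than an order of magnitude, which is
why the higher-order drift was adopted).

`synthesize_signals()` renders phases into observables: the ECG channel is
a $2\pi$-periodic template of von-Mises bumps imitating the P, Q, R, S, T
deflections with a dominant sharp R peak; respiration is a cosine; both get
independent Gaussian amplitude noise, and a fraction `artefact_level` of
the ECG template can leak into the respiration channel, imitating the
mechanical effect of heartbeats on a respiratory measuring belt. Sampling
below four times the cardiac rate is rejected.

`generate_cohort()` draws an age-graded population: ages uniform on the
range (default 16–90 years), per-subject natural frequencies jittered
around 1.1 Hz (cardiac) and 0.25 Hz (respiratory), and model parameters
following linear age trends with Gaussian scatter. The defaults encode the
ageing pattern the analysis is meant to detect: the direct RSA amplitude
declines with age (base 0.5 rad/s at the youngest age, −0.005 rad/s per
year, scatter 0.05), the indirect (both-phase) modulation declines more
slowly (−0.001/yr from 0.25), and the heart-to-respiration influence and
the heart self term are age-flat. Phase noise defaults to
$E = 0.01 I$ rad²/s and record length to 250 s at 25 Hz — long enough for
five 50-s windows and for coherence down to 0.145 Hz, small enough that a
100-subject cohort runs end-to-end in minutes. No value on this list was
revisited after the validation runs. The cohort is a pure function of its
spec (bit-reproducible given the seed).

What the generator does *not* emulate: real ECG morphology variability
(beat-to-beat waveform changes, ectopic beats), movement and electrode
artefacts, nonstationary natural frequencies within a record, amplitude
(as opposed to phase) respiratory modulation of the ECG, and any
hemodynamic or neural mechanism — the simulator is phase-level only.
Passing tests therefore demonstrate that the chain recovers what the phase
model contains, not that real recordings satisfy the model.

One emergent property worth noting: with the belt artefact switched on, the
respiration–IHF coherence develops a significant peak at each subject's own
cardiac frequency. The cardiac-locked content of the *extracted* IHF comes
from fundamental/second-harmonic interference cells that synchrosqueezing
reassigns into the tracked support — its power is tiny (of order $10^{-4}$
of the channel power), but phase coherence is amplitude-blind, which is
exactly why the artefact is detectable at all, and why the per-subject
measure is evaluated at the single bin nearest the subject's mean IHF (a
band-wide peak search would ride the low-frequency coherence bias and the
genuine respiratory-harmonic lines $k f_r$ instead).

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 120–200-s tones for the
extraction oracles; 600 s at 10 Hz (12 windows) for parameter-recovery and
directionality runs; 300 s for the locked/unlocked synchronization battery
(the unlocked control is detuned 25% from the tested 4:1 resonance — a
control closer to resonance than the windowed-inference noise floor, about
0.15 rad/s in the slow variable here, would not be a null system at all);
100 white-noise subject pairs for the coherence null calibration (the
rank-ordered threshold at $N=100$ has an exact null exceedance of
$6/101 \approx 5.9\%$); and a 100-subject cohort (250 s per subject at
25 Hz, `artefact_level = 0.2`, coherence over 0.145–2 Hz, respiration–IHF
products only, synchronization omitted from the cohort battery for runtime)
for the end-to-end ageing analysis. These sizes were chosen as the smallest
at which the tested effects are comfortably resolved.

## Known limitations

* The FM-tracking attenuation described above: frequency modulations at a
  substantial fraction of the carrier rate are recovered with gain ~0.7.
* Synchronization detection operates on the *inferred* flow; in a fully
  locked, essentially noise-free record the data do not constrain the flow
  off the locked line, and the map is determinate only near it. Detection
  still works (the locked region carries the fixed point) but relies on the
  phase noise exploring a neighbourhood of the attractor.
* Records must satisfy $T \ge 8.6/f_{\min}$ for every analysed band; with
  the default respiratory band this means at least 172 s.
* The intersubject-surrogate threshold needs a cohort; for a single subject
  no significance statement is made.
* `D` is undefined (and flagged) when both coupling norms vanish.
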