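---
title: "Models and methods behind unwindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind unwindr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

unwindr turns raw magnetic-tweezers bead recordings into helicase unwinding
statistics, and quantifies the mass-photometry and ensemble assays that
typically accompany such experiments. This vignette explains the models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer should know about.

## Tether elasticity and the extension-to-bp conversion

A nicked-flap tether (6.6 kbp of duplex carrying a 40-nt single-stranded
flap in the defaults) is held at constant force. As the enzyme unwinds,
duplex leaves the tether and single strand enters it; because double- and
single-stranded DNA have different specific extensions, the apparent tether
length reports unwinding. The signed extension change per unwound base pair
is

\[
\Delta(F) \;=\; n_{\mathrm{nt}}\; L_{ss}\, r_{ss}(F)\;-\;h_{ds}\, r_{ds}(F),
\]

with defaults \(n_{\mathrm{nt}} = 1\) nt gained per bp (the displaced strand
exits at the nick; configurable because the construct geometry decides this),
\(L_{ss} = 0.56\) nm/nt, \(h_{ds} = 0.338\) nm/bp.

* **dsDNA** uses the Marko–Siggia worm-like-chain interpolation
  \(F = \tfrac{k_BT}{P}\left[\tfrac{1}{4(1-r)^2} - \tfrac14 + r\right]\) with
  persistence length \(P = 45\) nm, inverted for \(r\) by bracketed root
  finding on \(r \in [0, 1-10^{-9}]\) at tolerance \(10^{-12}\). No enthalpic
  stretch term is included: the experiments provide no elasticity fit to
  constrain a stretch modulus, and below ~30 pN the interpolation error is
  small compared to bead noise.
* **ssDNA** uses the freely-jointed chain
  \(r = \coth(Fb/k_BT) - k_BT/(Fb)\) with Kuhn length \(b = 1.5\) nm,
  evaluated by series expansion below \(Fb/k_BT < 10^{-4}\) to avoid
  \(0/0\).

\(k_BT\) is derived from the temperature (298 K \(\to\) 4.114 pN nm) and
cross-checked to 0.1% when supplied explicitly. \(\Delta(F)\) changes sign
near ~7 pN with these defaults (collapsed ssDNA is shorter than the duplex
it replaces); `extension_to_unwound_bp()` refuses forces where
\(|\Delta(F)|\) is below a tolerance (default \(10^{-3}\) nm/bp) because
unwinding is then unobservable, and the division amplifies noise without
bound as the crossover is approached.

## Constant-velocity segmentation

Traces are divided into fragments of constant velocity by minimizing

\[
\sum_{\text{fragments}} \mathrm{RSS}(\text{independent OLS line})
  \;+\; \beta\cdot \#\text{breakpoints}
\]

exactly, over all partitions with fragments of at least 3 samples, by
dynamic programming with \(O(1)\) fragment costs from cumulative sums
(centered first for conditioning) and PELT-style candidate pruning in the
compiled kernel. Pruning preserves exactness: residual sums of squares are
subadditive across a split, and the implementation keeps a one-penalty
safety margin and never prunes recent candidates (the minimum-length
constraint makes the textbook pruning bound slightly too eager otherwise).
The test suite compares the DP cost against an exhaustive brute-force
enumeration on hundreds of random traces.

Fragments are *independent* lines — no continuity at breakpoints — because
pauses, slips and detachment make continuity physically wrong.

**Penalty.** The default is \(\beta = 3\hat\sigma^2\log n\), with
\(\hat\sigma = \mathrm{mad}(\Delta y)/\sqrt2\) estimated from first
differences so slopes and rare jumps do not inflate it. The factor 3 is the
BIC charge for the three parameters an extra segment buys (slope, intercept,
breakpoint location). A penalty of \(\hat\sigma^2\log n\) — the naive
single-parameter BIC — empirically lets the optimizer isolate short coherent
noise excursions as spurious steep fragments on 30 Hz traces (about 45
fragments with |velocities| in the thousands of bp/s where ~8 are real);
charging all three parameters suppresses this without affecting genuine
rate changes. The penalty is configurable everywhere it is used.

**Velocity statistics.** The condition mean is the unweighted mean of
fragment velocities with pause fragments (|v| below 5 bp/s by default)
excluded, and SEM \(= s/\sqrt n\). A threshold of 0 disables the exclusion.
The default excludes pauses because segmented traces contain long
detached/idle stretches whose near-zero fragments are not unwinding
velocities; for traces consisting only of active unwinding the two choices
agree. SEM of a single fragment is reported as `NA`, never 0.

## Event detection and processivity

An unwinding event is a maximal rise of the trace: from a local minimum to
the next local maximum on the median-smoothed signal, kept when the rise is
at least `min_processivity_bp` (default 100 bp). On noiseless staircases
the implementation is exactly this definition. Under bead noise a literal
local-extremum walk degenerates (noise creates extrema every few samples),
so "rising" is decided by the local slope (lag difference over 3 s of the
running median, window 15 samples) exceeding

\[
\max(\text{pause threshold},\; 4\,\sigma_{\text{slope}}),
\]

where \(\sigma_{\text{slope}}\) is the noise floor of that slope estimate
propagated analytically from \(\hat\sigma\). Without the adaptive floor, a
5 bp/s threshold sits inside the noise band of any local slope estimate at
30 Hz and stationary segments flicker "moving". Moving runs separated by
gaps shorter than `merge_gap_s` (default 8 s) are merged so that pauses do
not split an event; the rise is then measured between the smoothed minimum
and maximum of the run.

Two limitations follow directly from the observable. First, in a
non-reannealing trace a pause and a detachment-plus-reinitiation are both
plateaus — only the gap duration distinguishes them, so event splitting is
reliable only when pause durations and idle times are on separated time
scales (seconds versus minutes here). Second, rises separated by a plateau
shorter than the merge gap coalesce into one event.

**Censoring.** `analyze_condition()` excludes events still rising within
1 s of the end of their trace (right-censored: the enzyme had not
detached). Even so, a finite recording window length-biases the completed
events — long events are the ones that fail to finish — which is why the
simulator's default duration (300 s) is long compared with the ~52 s mean
event. With 120 s windows the completed-event mean is depressed by roughly
30% for these kinetics; no event detector can undo that.

The survival curve is the exceedance fraction
\(S(x) = \#\{p_i > x\}/n\), right-continuous, with
\(\int_0^{\max} S\,dx\) equal to the sample mean — an identity the tests
check numerically.

## Force calibration

Equipartition on the transverse bead coordinate:
\(F = k_BT\,L/\langle\delta x^2\rangle\) with the unbiased sample variance
and the tether extension \(L\). No camera-blur or aliasing correction is
applied; at 30 Hz video rates with corner frequencies of a few Hz this
underestimates the variance and so overestimates force — a known
limitation, flagged rather than modeled, since the correction requires the
full power spectrum.

## Mass photometry

Interferometric contrast is proportional to molecular mass. Calibration
fits a least-squares line through the per-standard **median** contrasts
(medians resist outlier landings) against the known marker masses; the
line is not forced through the origin, since small instrument offsets are
common. Spectra are fitted as 1-D Gaussian mixtures by EM with a
**deterministic** quantile initialization (means at evenly spaced sample
quantiles) so repeated fits agree bit-for-bit; `k = "auto"` picks the
component count by minimum BIC over 1..`k_max`. EM enforces a small sd
floor (\(10^{-6}\) of the data range) against component collapse, requires
50 events per requested component, and raises a convergence error (rather
than returning silently) after the iteration cap — overfit \(k\) converges
slowly, hence the generous 2000-iteration default.

Peak-to-complex assignment is exhaustive subset-sum over user-supplied
component masses (they are inputs, not constants, because published
component masses are typically only consistent to rounding level): the
subset minimizing |peak mean − mass sum| wins, ties to fewer components,
and a peak is reported unassigned when the best deviation exceeds the
tolerance (default: the peak's fitted sd).

## Binding, gel and ATPase quantification

* **Fraction product**: background-subtracted (clipped at 0) product
  intensity over total lane signal; invariant to uniform gain.
* **Apparent \(K_D\)**: the concentration at 50% binding. The default
  estimator is a Hill fit \(f = c^n/(c^n+K^n)\) with saturation fixed at 1,
  optimized over \((\log K, \log n)\) by Nelder–Mead with multistart over
  \(n_0 \in \{0.5, 1, 2, 4\}\); \(K\) is the 50% point for any \(n\). An
  interpolation mode reads the 50% crossing directly from the titration
  (linear in log-concentration) for exact replication of tabulated
  "50% binding" readings; which convention a published table used is often
  unstated, so both are provided. Data that never cross 50% give an
  extrapolation warning.
* **ATPase**: in a coupled assay each ATP hydrolyzed oxidizes one NADH, so
  the A340 slope converts as
  \(k_{cat} = |dA/dt|/(\varepsilon\,\ell\,[E])\), with
  \(\varepsilon = 6220\ \mathrm{M^{-1}cm^{-1}}\) and \(\ell = 1\) cm as
  standard defaults. A rising absorbance warns (wrong orientation); the
  linear window is user-selectable.

## The synthetic-data generator

`simulate_unwinding_trajectory()` draws a continuous-time single-enzyme
path: 1-bp steps at the stepping rate (default 44 bp/s), geometric per-step
detachment with mean 2300 bp (so processivity is approximately exponential
and independent of pausing), Poisson pause entry during active unwinding
(0.005 /s, mean pause 2 s), and Poisson re-initiation after detachment
(0.01 /s). Unwound bp is cumulative and capped at the duplex length (with a
truth flag): unwound DNA does not re-anneal, consistent with ssDNA-binding
protein coating the products, so events appear as rises separated by idle
plateaus. The staircase is boxcar-averaged per camera frame (30 Hz),
mapped to extension through the tether model at the applied force (20 pN
default), and Gaussian per-frame bead noise (5 nm) plus optional linear
drift are added.

Values the experiments report (stepping rate, processivity, tether
geometry, frame rate) are the generator defaults; values they do not
report were fixed once at realistic magnitudes and documented here:
applied force 20 pN and 5 nm/frame bead noise (typical for ~3 µm beads
under video tracking), second-scale transient pauses, and ~100 s mean
re-initiation delay at nanomolar enzyme. Two of these were revised during
development for identifiability rather than fit: overlapping pause/idle
time scales make plateau-based event splitting ill-posed (any gap
threshold misclassifies), and sub-duration recording windows length-bias
processivity; the revised world separates those scales (2 s vs 100 s;
300 s windows vs 52 s events).

What the generator does **not** emulate: bead–tether hydrodynamics and the
correlated (Ornstein–Uhlenbeck-like) character of real bead noise, camera
motion blur and aliasing, drift nonlinearity, sequence-dependent kinetics,
back-stepping or re-annealing, and multi-enzyme events. A green end-to-end
test therefore establishes that the estimators recover the parameters of
*this* stochastic world at the stated noise — not that they are unbiased on
any real recording.

All generators are pure functions of (config, seed): a single top-level
seed initializes one RNG stream (saved and restored around the draw), and
multi-trace conditions consume that stream sequentially.

## Numerical and interface conventions

Indices are 0-based half-open throughout the fragment/event tables; times
are seconds, lengths nm, masses kDa, concentrations nM. JSON outputs are
written with 12 significant digits so identical runs are byte-identical.
Trajectory files round-trip at full double precision (17 significant
digits). The run-configuration file is JSON validated against a fixed
schema (unknown keys are rejected before any computation); JSON was chosen
over TOML because the deployment environment guarantees a JSON parser but
no TOML parser.

## Known limitations

* Force calibration ignores motion blur/aliasing (see above).
* Mean fragment velocity retains a small downward bias (~1 bp/s at the
  default world) from pauses too short for the DP to resolve at 30 Hz
  noise; it is within one SEM at condition scale.
* Event detection requires pause/idle time-scale separation and a
  recording window long relative to event duration; neither can be
  recovered in post-processing.
* The Hill fit fixes saturation at 1; partially active protein preparations
  violate this and need external normalization first.
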