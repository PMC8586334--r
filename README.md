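# unwindr

Analysis toolkit for single-molecule magnetic-tweezers helicase experiments
and the ensemble biochemistry that accompanies them. It is written for
labs that record DNA-tethered bead trajectories while a helicase (or a
nuclease-dead helicase mutant exposing its motor) unwinds a duplex, measure
protein-complex masses by interferometric mass photometry, and quantify
binding, gel and coupled-ATPase assays.

## What it computes

**Tether model.** At force $F$, unwinding one base pair removes one bp of
duplex from the tether and adds `nt_gained_per_bp` nucleotides of single
strand, changing the tether extension by

$$\Delta(F) = n_{nt}\, L_{ss}\, r_{ss}(F) - h_{ds}\, r_{ds}(F)$$

where $r_{ds}$ is the worm-like-chain relative extension (Marko–Siggia
interpolation, persistence length 45 nm, rise 0.338 nm/bp) and $r_{ss}$
the freely-jointed-chain (Langevin) relative extension (Kuhn length 1.5 nm,
contour 0.56 nm/nt). Base pairs unwound follow as
$n(t) = (z(t) - z_0)/\Delta(F)$.

**Trace analysis.** Unwinding traces are divided into fragments of constant
velocity by exact penalized least-squares change-point detection
(dynamic programming with PELT pruning, penalty per breakpoint, minimum
fragment 3 samples); each fragment's velocity is its OLS slope. Unwinding
events are maximal rises of the median-smoothed trace; their sizes
(processivities, in bp) are summarized as mean ± SEM and as the survival
probability $S(x) = \Pr(\text{processivity} > x)$. Applied force is
calibrated from transverse bead fluctuations by equipartition,
$F = k_BT\,L/\langle\delta x^2\rangle$.

**Mass photometry.** Landing contrasts are calibrated against a protein
size marker (least-squares line through per-standard median contrasts),
mass spectra are fitted as Gaussian mixtures (EM, BIC model selection),
and peaks are assigned to complex compositions by exhaustive subset-sum
over user-supplied component masses.

**Quantification.** Fraction product from background-subtracted band
intensities; apparent $K_D$ as the concentration at 50% binding from a
Hill fit $f = c^n/(c^n + K^n)$ (interpolation mode available); apparent
ATP turnover from the NADH absorbance slope,
$k_{cat} = |dA/dt| / (\varepsilon\, \ell\, [E])$ with
$\varepsilon = 6220\ \mathrm{M^{-1}cm^{-1}}$ at 340 nm.

**Synthetic data.** A seeded generator produces every input the pipeline
reads: stochastic stepping trajectories (1-bp steps, geometric per-step
detachment, Poisson pauses, re-initiation, camera boxcar averaging, bead
noise), transverse fluctuations, mass-landing mixtures with standards,
binding titrations and NADH time courses — each with its ground truth.

## Worked example

```r
library(unwindr)

cfg  <- sim_config(seed = 7, n_traces = 10)       # 44 bp/s, 2300 bp events
sims <- simulate_unwinding_condition(cfg)
traces <- lapply(sims, function(s)
  extension_to_unwound_bp(s$trajectory, cfg$polymer,
                          baseline_nm = s$truth$baseline_nm))
analyze_condition(traces)
```

```
Condition summary
  velocity: 42.56 +/- 0.98 bp/s (n = 55 fragments)
  processivity: 1954 +/- 402 bp (n = 20 events)
```

The condition summary pools all constant-velocity fragments (pause
fragments below 5 bp/s excluded) and all completed unwinding events across
the ten simulated beads: the recovered mean velocity (42.6 ± 1.0 bp/s) and
mean processivity (1954 ± 402 bp) agree with the generating 44 bp/s and
2300 bp within 1.5 standard errors.

```r
ms  <- simulate_mass_events(
  data.frame(mass = c(115, 302), weight = c(.5, .5), sd = c(27, 67)),
  n = 2000, seed = 7)
cal <- calibrate_contrast(ms$standards$contrast, ms$standards$standard_mass_kDa)
pk  <- fit_mass_peaks(contrasts_to_masses(ms$events, cal)$masses_kDa, k = 2)
print(assign_species(pk, c(RPA = 114, Dna2 = 172, DNA = 25), tolerance_kDa = 20))
```

```
  114.5 kDa -> RPA (sum 114.0, off by 0.5 kDa)
  302.4 kDa -> RPA+Dna2+DNA (sum 311.0, off by 8.6 kDa)
```

A 302-kDa class of landings is identified as the ternary complex whose
theoretical component masses sum to 311 kDa.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "unwindr", package = "unwindr"))')
Rscript "$CLI" simulate --seed 1 --out runs/sim \
    --config "$(Rscript -e 'cat(system.file("extdata", "condition_default.json", package = "unwindr"))')"
Rscript "$CLI" analyze-trace --manifest runs/sim/manifest.csv --out runs/out
Rscript "$CLI" report --in runs/out --out runs/report.csv
```

Subcommands: `simulate`, `analyze-trace`, `calibrate-force`,
`mass-calibrate`, `mass-fit`, `kd-fit`, `quantify-gel`, `atpase`,
`report`; `--help` lists options. Identical seed and config give
byte-identical JSON outputs.

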