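---
title: "Profiling sodium channel inhibitors: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling sodium channel inhibitors: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciblock)
```

## The problem

A single IC50 says little about *how* a sodium channel inhibitor works.
Two drugs with identical potency at a holding potential can differ
radically in which channel conformation they bind, how fast they
equilibrate, whether block accumulates during repetitive firing, and
whether it washes out. These differences track therapeutic profile:
state-dependent inhibitors preferring the inactivated conformation
selectively silence pathologically active tissue, which is why the same
pharmacology serves epilepsy, arrhythmia and neuropathic pain.

`sciblock` turns two cheap, fixed patch-clamp protocols into an
eight-property biophysical profile per drug, and then does the
comparative statistics: correlation structure, hierarchical clustering
in the "biophysical space", rule-based typing, and the link to chemical
descriptors.

## The train protocol and its five properties

Five depolarizing pulses at 5 Hz, trains every 20 s; ten trains in
control, ten with drug, ten during washout. Five anchor amplitudes
summarize the experiment: first- and fifth-pulse amplitudes at control
steady state (A1, A2), the same at drug steady state (A3, A4), and the
first-pulse amplitude after washout (A5). From these:

* inhibited fraction `Inh = (A1 - A3)/A1`,
* single-point Hill potency `IC50 = (1 - Inh) * cc / Inh` (one-to-one
  binding assumed; `cc` is the tested concentration),
* reversibility `Rev = A5/A1`,
* use-dependence `UD = (A3/A4)/(A1/A2)`,
* onset and offset time constants from monoexponential fits to the
  first-pulse amplitude of successive trains.

Anchors are averaged over the last three trains of each phase. A
single-train read is what the protocol diagram suggests, but the average
is materially more noise-robust and collapses to the single-train read
when `n_anchor_trains = 1`.

The exponential fit profiles the time constant out of the linear
parameters: for a candidate tau the baseline and amplitude are solved by
linear least squares, and tau itself is found by a log-spaced grid
search refined by one-dimensional optimization. The usual free
three-parameter optimizer has a singular gradient exactly in the case
this protocol cannot avoid — an onset faster than the 20 s train
spacing, where the data are a step — while the profiled search
degrades gracefully: the sum of squares plateaus below the sampling
resolution and the smallest indistinguishable tau is reported, which
the clip rule then maps to the 3 s floor. Fitted values are clipped to
[3, 500] s (configurable): 3 s is the resolution floor of the train
spacing, 500 s the cap for drugs showing no recovery within the 200 s
washout. Clipping is flagged, never silent.

Per-cell values are computed first and aggregated across cells:
arithmetic mean with SEM for `Inh`, `Rev`, `UD` and time constants, and
the *geometric* mean for IC50. Affinity-like quantities are ratios;
their errors are multiplicative, and the geometric mean is the natural
location estimate. This convention also explains why an IC50 recomputed
from the *mean* inhibited fraction differs by a few percent from a
published per-cell aggregate — the package reproduces such values to
about 1%, not exactly, and that discrepancy is expected, not a defect.

## The availability protocol, Kr, Ki and state-dependence

A 10 ms test pulse follows a 400 ms pre-pulse stepped from -150 to
-30 mV. The fraction of available (non-inactivated) channels follows a
Boltzmann curve `h(V) = 1/(1 + exp((V - V1/2)/k))`. The analysis
assumes a four-state modulated-receptor scheme — resting and
inactivated channels, each drug-bound or free, with dissociation
constants `Kr` and `Ki` — whose equilibrium available fraction is

```
f(V, D) = 1 / (1 + D/Kr + exp((V - V1/2)/k) * (1 + D/Ki))
```

Three consequences drive the estimators:

1. At -150 mV essentially all channels rest, so the rearranged Hill
   equation applied to the inhibition there returns `Kr` directly.
2. The drug curve is a scaled Boltzmann with the *same* slope and a
   midpoint shifted by `dV1/2 = -k log[(1 + D/Ki)/(1 + D/Kr)]`;
   inverting this for Ki gives the shift estimator
   (`ki_from_shift()`).
3. At a partially inactivating potential with drug-free availability
   `h`, the apparent affinity mixes the two constants harmonically,
   `1/Kapp = h/Kr + (1 - h)/Ki`; inverting gives the apparent-affinity
   estimator (`ki_from_kapp()`, evaluated at -60 mV by default, a
   configurable choice).

State-dependence is `SD = Kr/Ki`, with Ki from the apparent-affinity
estimator — the one used for all downstream analyses, because it can be
cross-checked at several potentials. The two estimators agreeing (their
per-drug ratio averaging near 1) is itself a model-consistency check,
and the package's acceptance suite performs it on simulated cohorts.

Numerical choices worth knowing:

* Boltzmann fits fix the depolarized asymptote at zero and let the
  amplitude float, so the same parameterization serves control curves
  (amplitude near 1) and drug curves (amplitude depressed to
  `1/(1 + D/Kr)`); `k > 0` is enforced by bounds, fixing the sign
  convention (availability falls with depolarization, hyperpolarizing
  shifts are negative).
* Inhibition at -150 and -60 mV is read off the *fitted* curves, not
  single raw points: with 2% multiplicative noise a raw-point read
  costs roughly 12% error in a per-cell Kr, the fitted read a few
  percent.
* `ki_from_shift()` accepts any shift sign and errors only when the
  shift is infeasibly positive given `Kr` (flagged as "no resolvable
  inactivated-state preference"). Hard-rejecting positive shifts would
  systematically exclude non-state-dependent drugs, whose noisy shifts
  straddle zero, and bias cohort statistics.
* Per-cell affinities are aggregated by geometric mean; cells whose
  estimators are infeasible are excluded with a logged warning, not
  imputed. Measurements of one drug at several concentrations are
  combined the same way — the affinities are concentration-independent,
  so their agreement across concentrations is a consistency check.

## The synthetic-data generator

`simulate_availability()` and `simulate_train()` generate instrument-
shaped data from the four-state model, and `simulate_cohort()` adds
lognormal cell-to-cell scatter of the affinities with per-cell seeds
drawn from one master stream (reproducible, order-insensitive). The
generator emulates: monoexponential onset/offset of first-pulse
amplitudes, a configurable washout plateau (`rev_residual`; instrument
washout of lipophilic drugs is notoriously incomplete, so reversibility
is a parameter, not a derived quantity), phenomenological per-pulse
use-dependent block with between-train recovery, Boltzmann availability
with the drug-induced left shift, and multiplicative Gaussian
measurement noise applied last.

It deliberately does **not** solve within-sweep gating kinetics, a
Markov scheme for use-dependence at 5 Hz, membrane partitioning, or
non-equilibrium binding during the 400 ms pre-pulse. Passing recovery
tests on these simulations therefore validates the estimators against
the equilibrium model they assume — it does not certify behaviour on
real recordings of slow-binding drugs, where the pre-pulse may be too
short for equilibration.

The standard validation cohort (used by the test suite) is 20 drugs
with Kr log-uniform over [30, 3000] µM and SD log-uniform over [1, 200]
— the observed span of the 35-drug reference panel — tested at
`cc = Kr/3` (about 25% resting inhibition, mirroring how test
concentrations are chosen to land in the 25–75% window), 4 cells per
drug, 2% measurement noise and 10% cell scatter, availability sampled
every 10 mV from -150 to -30. On this cohort the pipeline recovers Kr
and Ki with median absolute relative error well under 10% and the two
Ki estimators' ratio averages within a few percent of 1. These problem
sizes run in seconds and are the package's chosen validation scale.

## Downstream statistics

* `build_matrix()` log10-transforms the declared columns (`Kr`, `Ki`,
  `IC50`, `SD`, `tau_off` by default — the correlation and z-score
  results are invariant to the log base, so base 10 is used for
  readability) and `zscore()` normalizes each property over the drug
  set.
* `correlation_matrix()` reports pairwise-complete Pearson r with
  two-sided t-test p-values flagged at 0.05 and 0.01. No
  multiple-testing correction is applied, matching the two-star
  convention of the comparative literature; the flags are descriptive,
  not confirmatory.
* `hcluster()` delegates to `stats::hclust` over Euclidean distances:
  `"wpgma"` (McQuitty's weighted pair-group average) for the
  biophysical clustering and `"ward"` (Ward.D2) for the chemical one.
  Both rules are monotone, so dendrograms have no inversions. The test
  suite checks the linkage against brute-force agglomeration oracles
  implemented from the definitions. Exact leaf order is not a stable
  analysis surface — different amalgamation rules give similar but not
  identical trees — so assertions are about partitions, not leaf
  sequences.
* `classify_types()` applies rule boxes whose default edges are the
  observed property ranges of the named types (Type 1:
  Ki 0.73–6.1 µM, IC50 14–43 µM, time constants 10–53 s, Rev 0.2–0.6,
  UD 1.09–1.66; Type 2: Ki 17–88 µM, IC50 > 95 µM, time constants
  < 27 s, Rev > 0.75, split at UD 1.1; Type 3: Rev < 0.05 with
  tau_off at the 500 s cap). A 1% relative tolerance absorbs the
  rounding of published range edges. Drugs matching parts of both the
  Type 1 and Type 2 boxes are labelled Type 4 (intermediate); drugs
  matching neither are left unclassified rather than forced.

## Chemical descriptors

Descriptors (logP, logD at pH 7.3, pKa, MW, PSA, aromatic atom count,
minimal projection area) are *ingested*, not computed from structure:
published values come from specific cheminformatics software and are
not bit-reproducible from first principles. The package derives only
the neutral fraction `N(pKa) = 10^pH/(10^pH + 10^pKa)` (a base-form
Henderson–Hasselbalch rearrangement; acids such as phenytoin and
diclofenac are flagged and their table values passed through untouched)
and, when a measured logD is missing, the flagged estimate
`logD = logP + log10 N(pKa)`. The packaged descriptor table is an
explicitly synthetic stand-in with literature-magnitude values; no
regression test asserts its contents.

## Dropout handling

Drugs causing under 10% inhibition at the highest tested concentration,
or with IC50 out of all proportion to their plasma concentration, carry
too little signal for the eight-property analysis and are marked
dropouts rather than profiled. Both thresholds are configurable; the
packaged reference table ships the 9 dropouts of the 44-drug panel as
data, and the package does not re-derive that exact exclusion set (the
published criteria do not reproduce it mechanically — one excluded drug
prints 14% inhibition).

## Known limitations

* Equilibrium assumptions throughout: slow-binding drugs violate the
  400 ms pre-pulse equilibration, and the single-point IC50 assumes a
  Hill coefficient of 1.
* Reversibility on planar-chip instruments partly reflects compound
  retention in the system, not pharmacology; `Rev` is informative but
  instrument-bound.
* The use-dependence model in the simulator is phenomenological; no
  kinetic scheme for within-train block is implied.
* The type rule boxes are descriptive summaries of one drug panel, not
  validated decision boundaries.

## Reproducing the packaged analysis

```{r fixture, eval = FALSE}
prof <- fixture_profiles()                      # 35 analyzed drugs
m <- zscore(build_matrix(
  prof,
  columns = c("Kr_uM", "Ki_kapp_uM", "IC50_uM", "SD", "UD", "Rev", "tau_off_s"),
  log_columns = c("Kr_uM", "Ki_kapp_uM", "IC50_uM", "SD", "tau_off_s")))
correlation_matrix(m)
cut_tree(hcluster(m, "wpgma"), n_clusters = 3)
classify_types(prof)
```

`run_pipeline()` orchestrates the same steps from raw CSV inputs, and
`scripts/acceptance.R` (repository root) recomputes the headline
reference quantities from the packaged tables.
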