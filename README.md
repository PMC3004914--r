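# sciblock

Multi-property profiling and classification of sodium channel
inhibitors (SCIs) from automated patch-clamp recordings.

Sodium channel inhibitors — local anesthetics, anticonvulsants, class I
antiarrhythmics, and a surprising fraction of antidepressants and
antipsychotics — are usually compared by a single IC50, which hides the
mechanistic differences that matter therapeutically. `sciblock`
extracts **eight biophysical properties of inhibition** per drug from
two simple protocols and runs the comparative statistics on top of
them. It is aimed at ion-channel pharmacologists and screening groups
who want mode-of-action information at concentration–response cost.

## The model

From a 5 Hz pulse-train protocol (5 pulses per train, trains every
20 s; control → drug → washout), five anchor amplitudes A1–A5 give

    Inh  = (A1 − A3)/A1              inhibited fraction
    IC50 = (1 − Inh)·cc / Inh        single-point Hill potency
    Rev  = A5/A1                     reversibility
    UD   = (A3/A4)/(A1/A2)           use-dependence

with τon and τoff from monoexponential fits of first-pulse amplitudes.

From steady-state availability curves (400 ms pre-pulses, −150 to
−30 mV), a four-state modulated-receptor model — channels resting (R)
or inactivated (I), drug-bound or free, with dissociation constants Kr
and Ki — predicts the available fraction

    f(V, D) = 1 / (1 + D/Kr + exp((V − V1/2)/k)·(1 + D/Ki))

Three estimators follow: Kr from the inhibition at −150 mV via the
rearranged Hill equation; Ki from the hyperpolarizing midpoint shift
ΔV1/2 = −k·ln[(1 + D/Ki)/(1 + D/Kr)]; and Ki from the apparent
affinity at a partially inactivating potential, 1/Kapp = h/Kr +
(1 − h)/Ki. State-dependence is SD = Kr/Ki — the property most linked
to therapeutic selectivity for hyperactive tissue.

Downstream: z-scored property matrices, pairwise Pearson correlation
with significance flags, WPGMA/Ward hierarchical clustering (Newick
export), rule-based classification into inhibition types, and min–max
radar exports. A four-state simulator with per-cell lognormal scatter
generates ground-truth cohorts so every estimator is validated by
parameter recovery. The per-drug reference tables of a 44-drug panel
(35 analyzed, 9 dropouts) ship as packaged CSV fixtures.

## Worked example

Simulate one cell of a strongly state-dependent drug (ground truth
Kr = 600 µM, Ki = 6 µM, 100 µM applied, 2% measurement noise) and
recover its affinities:

```r
library(sciblock)
p  <- four_state_params(Kr_uM = 600, Ki_uM = 6, drug_concentration_uM = 100,
                        noise_cv = 0.02, seed = 42)
av <- simulate_availability(p)
profile_availability(av, cc = 100)
#>   Inh_150 dV_half_mV  Kr_uM Ki_dV_uM Ki_kapp_uM    SD
#>      0.16     -22.18 543.11     5.29       7.13 76.21
```

One noisy cell lands within ~10–20% of the truth on every quantity
(the noiseless fit recovers Kr = 600, Ki = 6.00, shift −21.74 mV
exactly); averaging 4 cells brings the cohort median error under 10%.

The packaged reference tables reproduce the published analysis:

```r
fx  <- fixture_profiles()                    # 35 analyzed drugs
mrz <- fx[fx$drug_code == "MRZ", ]
ic50_single_point(mrz$Inh, mrz$cc_uM)
#> 132.56    # printed per-cell aggregate: 132.28 (0.2% apart)

m <- zscore(build_matrix(fx,
       c("Kr_uM","Ki_kapp_uM","IC50_uM","SD","UD","Rev","tau_off_s"),
       c("Kr_uM","Ki_kapp_uM","IC50_uM","SD","tau_off_s")))
cut_tree(hcluster(m, "wpgma"), n_clusters = 3)
#> cluster 3 = {FLR, LIF}: the irreversible, slow neuroprotectants
#> separate from everything else, as in the source analysis

table(classify_types(fx)$type)
#> Type1 Type2_nonUD Type2_UD Type3 Type4 unclassified
#>     9           7        4     2    11            2
```

The nine Type 1 drugs are exactly the published set (fluoxetine,
sertraline, paroxetine, amitriptyline, imipramine, desipramine,
maprotiline, haloperidol, ritanserin), and the Type 2 use-dependent /
non-use-dependent split matches drug for drug.

See `vignettes/profiling-methods.Rmd` for the estimators' derivations,
the simulator's scope, and every configurable default.

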