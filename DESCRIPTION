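Package: sciblock
Title: Profiling and Classification of Sodium Channel Inhibitors from
    Automated Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts eight biophysical properties of sodium channel
    inhibition from two automated patch-clamp protocols: a 5 Hz pulse-train
    protocol (inhibited fraction, single-point Hill IC50, reversibility,
    use-dependence, onset and offset time constants) and a steady-state
    inactivation protocol (resting affinity Kr, inactivated affinity Ki by
    two modulated-receptor estimators, and state-dependence Kr/Ki).
    Merges the biophysical profile with chemical descriptors, computes
    cross-correlation matrices with significance flags, performs WPGMA and
    Ward hierarchical clustering, and classifies drugs into inhibition
    types. Includes a four-state channel-drug equilibrium simulator so the
    whole pipeline can be validated by parameter recovery without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
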