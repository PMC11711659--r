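Package: aepkit
Title: Auditory Evoked-Potential Analysis for Mouse ABR and Cortical AEP Recordings
Version: 0.1.0
Authors@R:
    person("aepkit", "developers", email = "aepkit@example.org", role = c("aut", "cre"))
Description: Tools for analysing click- and tone-evoked auditory potentials in
    mice: zero-phase band-pass filtering and differential referencing of
    auditory brainstem response (ABR) signals, epoch averaging with
    time-dependent standard errors, artifact rejection, objective ABR hearing
    threshold detection, wave-1 feature extraction, cortical auditory evoked
    potential (AEP) P1/N1/P2 feature extraction, central-gain and
    level-/interval-dependent slope statistics, and cohort-level inference
    (Gaussian GLM with Wald tests, within- versus between-animal randomization
    tests, and nonparametric group comparisons). A synthetic waveform and
    cohort generator with known ground truth makes every stage testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
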