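---
title: "Methods: evoked-potential analysis and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked-potential analysis and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aepkit)
```

## What this package computes

aepkit implements a complete analysis chain for monaural evoked-potential
recordings in mice, of the kind used to study central auditory processing in
the Df1/+ model of the 22q11.2 deletion syndrome:

1. **Preprocessing.** ABR electrode signals (bulla and vertex) are band-pass
   filtered at 100–3000 Hz with a zero-phase Butterworth filter and subtracted
   (vertex − bulla) to form the differential ABR. Epochs are cut around
   stimulus onsets, baseline-corrected on the pre-stimulus interval, screened
   for artifacts, and averaged with a pointwise (time-dependent) standard
   error of the mean.
2. **Hearing threshold.** The click-evoked ABR threshold of an ear is the
   lowest click level eliciting a characteristic deflection at least twice the
   time-dependent SEM of the averaged waveform, required consistently at that
   level and every higher level. Ears are classified hearing-impaired (HI)
   when the threshold exceeds the wild-type mean by more than 2.5 wild-type
   standard deviations; with the conventional wild-type statistics
   (35.23 ± 4.64 dB SPL) the cutoff displays as 47 dB SPL.
3. **Cortical AEP features.** From the averaged cortical potential, P1 is the
   highest deflection in 15–30 ms, N1 the lowest in 25–60 ms, and P2 the
   highest in 60–120 ms (windows inclusive, earliest sample on ties). The
   amplitude complexes P1−N1 and N1−P2 are analysed rather than absolute
   amplitudes to cancel baseline fluctuations; by construction of the
   overlapping windows both complexes are non-negative.
4. **Derived statistics.** *Central gain* is the ratio of an amplitude complex
   to the tone-evoked ABR wave-1 amplitude for the same stimulus. The
   *level-dependent slope* (LDAEP) is the ordinary-least-squares slope of a
   feature against sound level in dB; the *interval-dependent slope* is the
   OLS slope against the natural logarithm of the inter-tone interval (ITI),
   because recovery from repetition suppression is expected to be
   exponential in ITI.
5. **Cohort inference.** A Gaussian GLM screens predictors (genotype, gender,
   age, contralateral and ipsilateral hearing threshold) of each AEP measure
   with Wald tests; a randomization test compares within-animal to
   between-animal correlation of paired ear measures; group contrasts use the
   Mann–Whitney U test (two groups) or Kruskal–Wallis with Dunn post-hoc
   comparisons (three groups), all two-tailed.

## The generative model behind the simulator

Animal recordings of this type are typically available only on request, so
every stage is validated against a synthetic generator with known ground
truth. Waveforms are sums of Gaussian-windowed monophasic deflections (ABR
waves 1–5; AEP P1, N1, P2) whose peak latency and amplitude are analytically
known — so feature extractors can be tested against closed forms.

For an ear with true threshold $T$ and stimulus level $L$ (dB SPL):

* ABR deflections scale with $g \cdot \max(0, L - T)$, where $g$ is the
  peripheral intensity gain (`level_gain`, default 0.05 per dB: wave 1 reaches
  ≈2.7 µV at 45 dB sensation level, typical of subdermal mouse recordings).
  ABR latencies increase linearly as sensation level falls.
* AEP deflections scale with
  $a \cdot \left(1 - e^{-\mathrm{ITI}/\tau}\right) \cdot
  \left(1 + s\,(L - 80)\right)$: a cortical response scale $a$
  (`aep_scale`), an exponential recovery from repetition suppression with
  time constant $\tau$ (`adaptation_tau`, default 150 ms, so the amplitude
  has recovered to 86% at the standard 300 ms ITI), and a linear cortical
  excitability term $s$ (`aep_level_slope`, default 0.02 per dB).
  N1 and P2 latencies can be delayed (`latency_shift`) and all AEP latencies
  shorten mildly with level and ITI.
* Noise is Gaussian per trial: 1.5 µV on the ABR electrode pair (the
  differential trace has this SD; after the 100–3000 Hz band it leaves a
  ≈0.05 µV SEM on 500-trial averages) and 20 µV on the cortical electrode
  (≈0.6 µV SEM at 1000 trials). An optional biphasic heartbeat artifact can
  be injected at a configurable rate and amplitude (default amplitude 0; the
  artifact-rejection stage exists to remove it when present).

The four stimulus protocols use the standard parameters: clicks 20–90 dB SPL
in 5 dB steps, 500 repetitions at 50 ms inter-onset interval; 16 kHz tones at
80 dB SPL, 1000 repetitions at 300 ms ITI; a level series at 70/80/90/100 dB
SPL; and an ITI series at 200/250/300/350/450 ms. ABR-bearing conditions are
rendered as continuous two-channel recordings at 20 kHz with event times;
AEP conditions as cortical epoch matrices at 2 kHz over −10…150 ms.

Simulated cohorts draw wild-type thresholds from N(35.23, 4.64²) dB SPL and
Df1/+ thresholds from a two-component mixture (59% impaired component,
N(65, 9²); 41% normal component, N(38, 5²)) with left and right ears sampled
independently — reproducing the bimodal, ear-uncorrelated threshold structure
reported for this model. The mixture parameters were chosen once so the
implied overall Df1/+ mean and SD (≈54 ± 15 dB SPL) match the published
summary statistics; they are not tuned further. Thresholds are rounded to the
5 dB stimulus grid, since only grid levels are presented and therefore only
grid thresholds are observable. Genotype effects are additive offsets on
Df1/+ ears: `aep_scale` +0.3, `aep_level_slope` +0.015, `adaptation_tau`
+80 ms, `latency_shift` +3 ms. Together with the threshold-linked wave-1
reduction these reproduce the qualitative group orderings of interest:
elevated central gain for impaired ears, steeper level-dependent growth for
Df1/+ ears regardless of hearing status, and steeper interval-dependent
growth for normally-hearing Df1/+ ears.

Two deliberate deviations from a naive reading of the brief are worth
flagging. First, the intensity-coding genotype effect is placed on the
*cortical* level term rather than the peripheral ABR gain, because the
empirical observation being emulated is steeper cortical growth alongside
wild-type-like wave-1 amplitudes in normally-hearing Df1/+ ears; a peripheral
gain offset would contradict the latter. Second, the simulator's ABR response
is exactly zero at and below threshold (the specified `max(0, ·)` floor), so
the detector's expected answer is the lowest *presented* level with a
response — one 5 dB step above the nominal threshold. Grid-aligned true
thresholds keep this discretization inside the one-step recovery tolerance.

### What the simulator does not emulate

Real recordings contain 1/f and line noise, non-Gaussian artifacts, drifting
anesthetic depth, frequency-dependent hearing loss, and genuine biological
covariance between measures. Green tests therefore establish that the
*analysis* is correct and well-calibrated under the stated statistical
structure — not that the generator is a faithful biophysical model, and not
that the published group differences are reproduced (those depend on the
unavailable animal dataset and are explicitly out of scope).

## Numerical and design choices

* **Filtering.** No DSP package is available in the target environment, so
  the Butterworth band-pass (second-order high-pass at 100 Hz cascaded with
  fourth-order low-pass at 3000 Hz) is designed in-package via the bilinear
  transform and applied forward–backward, giving zero phase so latency
  endpoints are unbiased. For long continuous traces an FFT path applies the
  identical $|H|^2$ response (interior agreement ≈1e-13); tests pin the
  response at 550 Hz (unity within 0.2%), DC and 10 kHz (stopband).
* **Threshold detection.** The "characteristic deflection" judgment is
  automated as an *anchored* rule: the candidate wave is located at the
  largest deflection of the highest-level average, and lower levels must show
  a same-sign crossing of 2×SEM near that latency (−0.5…+1.5 ms, allowing
  latency growth toward threshold). A purely pointwise rule (any sample in
  the 1–6 ms window) is available but has a high per-level false-positive
  rate on realistic averages; the anchored rule keeps one-step threshold
  recovery above 90% (the property-test criterion). Detection is inclusive
  at exactly 2×SEM and requires consistency at all higher levels.
* **Tie-breaking.** All extrema take the earliest sample on exact ties, for
  determinism.
* **Wald reference.** The GLM Wald p-values use the standard normal reference
  by default (large-sample GLM convention); a t reference on residual degrees
  of freedom is available. With ~100 rows the difference is negligible
  (rejection 0.050 vs 0.053 at nominal 0.05).
* **Dunn post-hoc p-values** are unadjusted by default, with a
  `p.adjust`-method flag, since no multiplicity convention is imposed.
* **Randomization scheme.** The null re-pairs the right-ear column across
  animals uniformly at random — the minimal scheme that produces
  "independent measures from different animals" while preserving both
  marginals. 10,000 permutations by default; calibration tests use 400–600
  to stay inside runtime budgets.
* **Degenerate inputs.** Fewer than two epochs flag the SEM invalid; an
  all-rejected artifact screen is flagged rather than silently averaged;
  all-tied group comparisons return a flagged non-rejection; constant vectors
  make rank correlations undefined rather than zero; a zero-residual GLM is
  flagged Wald-degenerate.
* **Runtime scaling in tests.** The acceptance suite runs threshold recovery
  at the full 500-repetition click protocol on 100 ears, but the full-cohort
  ordering check scales repetition counts to 35% (protocols, levels and ITIs
  unchanged) and Monte-Carlo calibrations use table-level simulation, to keep
  the whole suite within a ~25 minute single-CPU budget. Effect sizes are
  large relative to averaging noise at these settings, so the scaled checks
  test the same orderings.

## Worked example

```{r example, eval = FALSE}
library(aepkit)

# one hearing-impaired Df1-like ear
params <- ear_sim_params(true_threshold = 65, aep_scale = 1.3,
                         adaptation_tau = 230, latency_shift = 3)
session <- simulate_ear_session(params, seed = 1)

clicks <- lapply(session$protocols$click_series, preprocess_abr_condition)
detect_threshold(clicks)

tone <- session$protocols$tone_80db[[1]]
w1 <- wave1_features(preprocess_abr_condition(tone))
aep <- extract_aep_features(preprocess_aep_condition(tone))
central_gain(aep, w1)

# full cohort at reduced repetition counts
cfg <- run_config(cohort = cohort_sim_config(n_wt = 22, n_df1 = 29,
                                             rep_fraction = 0.25),
                  seed = 1)
run <- run_pipeline(cfg)
run
cat(make_report(run), sep = "\n")
```

## Known limitations

* Waveform morphology (latencies, widths, relative amplitudes) follows field
  conventions, not fitted data; no quantitative morphology was available.
* ABR waves 2–5 are rendered but not individually analysed (wave 1 only), and
  no binaural interaction or awake-state dynamics are modelled.
* Whether the cortical channel should be band-pass filtered is left
  configurable and off by default; the reference workflow is silent on it.
* The heartbeat-removal stage is a peak-to-peak rejection rule, a documented
  stand-in for the unpublished algorithm used in the original workflow.
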