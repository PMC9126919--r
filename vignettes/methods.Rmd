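---
title: "Models and methods: temporal compression in retelling and memory transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: temporal compression in retelling and memory transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retellr)
library(dplyr)
```

## The scientific problem

When people retell a long naturalistic experience — here, a movie watched
in the scanner and later recalled aloud — they compress it: some moments
are recounted in temporally precise detail, others are summarized in a
sentence that spans minutes of movie time. `retellr` implements a complete
pipeline for asking how this behavioral compression relates to how neural
event representations change between encoding (movie viewing) and
retrieval (spoken recall):

1. **Utterance coding.** Each recall utterance is mapped to a span of
   movie micro-segments; if the span's summed duration exceeds 10 s the
   utterance is *Summary*, otherwise *Temporally Precise*; speech without
   a mappable span is *Other* and excluded. A continuous companion
   measure, the temporal compression factor,
   $\mathrm{TCF} = 1 - \frac{\text{content words}}{\text{described seconds}}$,
   increases with compression. Per scene and subject, the *%Summary bias*
   is the proportion of content words about that scene coming from
   Summary utterances (Other words are tallied but excluded from the
   denominator).
2. **Text validation.** Utterances and micro-segment annotations are
   embedded; cosine similarity between an utterance and its covered
   segments (matched) should exceed similarity to uncovered segments
   (mismatched), and should be lower for Summary than for Precise
   utterances.
3. **Reinstatement.** Within subject, each described micro-segment's
   movie pattern is correlated with the average recall pattern of the
   utterances describing it, separately per recall type.
4. **Memory transformation.** Between subjects, at the scene level:
   $MR_{ik}$ correlates subject $i$'s movie pattern for scene $k$ with
   the average recall pattern of the *other* subjects who recalled $k$;
   $RR_{ik}$ does the same with subject $i$'s recall pattern on the left.
   If recall patterns are more similar between people than to the
   original encoding pattern ($T = RR - MR > 0$), the encoding-to-recall
   change is systematic rather than noise. Parcels are screened by a
   scene-label permutation test with BH-FDR (the reliability mask), and
   only mask parcels with $T > 0$ are carried forward.
5. **Linking.** Within each transformation parcel, every subject's
   scene-level %Summary bias is correlated with the group per-scene
   transformation value; the subject correlations enter a random-effects
   one-sample t-test versus zero, BH-FDR corrected across tested parcels.
   A control analysis checks that scene duration does not explain bias.

## The generative model behind the synthetic data

The generator encodes the two candidate accounts of encoding-to-recall
pattern change as one parametric family. For parcel features
(voxel-level activity), scene $k$:

* movie pattern of subject $i$: $x_{ik} = m_k + \eta_{ik}$, with a shared
  standard-normal scene pattern $m_k$ and idiosyncratic noise
  $\eta_{ik} \sim \mathcal N(0, \sigma_m^2)$;
* recall pattern of subject $i$:
  $y_{ik} = m_k + c_k\, s_k + \varepsilon_{ik}$, with a *shared*
  unit-normal shift direction $s_k$ drawn once per scene and parcel,
  shift scale $c_k$, and idiosyncratic noise
  $\varepsilon_{ik} \sim \mathcal N(0, \sigma_r^2)$.

With $c_k \equiv 0$ every encoding-to-recall change is noise or
subject-idiosyncratic (model 1); with $c_k > 0$ part of the change is
common across people and scene-specific (model 2). In "linked" parcels
$c_k = a + b \cdot \bar\beta_k$, where $\bar\beta_k$ is the group-mean
true summary bias of scene $k$ — this is the planted association the
linking analysis must recover; in all other parcels $c_k = a$.

Noise is drawn once per (subject, scene) and repeated across the TRs of
that scene, so scene-level TR averages equal the generative patterns
exactly and the between-subject statistics have a closed form. With $n$
recallers per scene:

$$MR = \frac{1}{\sqrt{(1+\sigma_m^2)\,(1+c^2+\sigma_r^2/(n-1))}},
\qquad
RR = \frac{1+c^2}{\sqrt{(1+c^2+\sigma_r^2)\,(1+c^2+\sigma_r^2/(n-1))}}.$$

At $\sigma_m = \sigma_r = 1$, $c = 1$, $n = 17$ this gives
$MR \approx 0.492$ and $RR \approx 0.804$, and algebraically $T > 0$ iff
$c > 0$ when $\sigma_m = \sigma_r$. The test suite verifies both the
closed form (50 replicates, 2000 features) and an exact straight-loop
oracle for $T$ on a tiny instance.

```{r closed-form, eval = FALSE}
cfg <- sim_config(n_subjects = 17, n_scenes = 10, n_parcels = 1,
                  features_per_parcel = 2000, p_recall = 1,
                  shift_base = 1, shift_slope = 0, summary_noise_mult = 1)
d <- simulate_dataset(cfg, seed = 1, neural = "patterns")
mean(between_subject_similarity(d$patterns, "MR")$r)  # ~0.492
mean(between_subject_similarity(d$patterns, "RR")$r)  # ~0.804
```

### Behavioral generator

Scene durations come from a log-normal whose *truncated* (11–180 s)
moments are solved numerically to match mean 57.7 s and SD 41.6 s;
micro-segment durations are likewise matched to mean ≈ 4 s (SD 2.2 s)
but truncated to [1, 9.5] s so that every single micro-segment can in
principle be described by a Temporally Precise utterance. Per subject
and scene a latent summary tendency is drawn: a mild shared scene-mean
(Beta(50, 50), SD ≈ 0.05 around 0.5) plus a dominant subject-specific
jitter (SD 0.3, clipped to [0, 1], so some subjects fully summarize or
fully detail a scene). Utterance spans are then constructed by
predictive dithering so Summary spans exceed the 10-s threshold, Precise
spans do not, and the realized share of content words from Summary
utterances tracks the tendency.

The split between shared and idiosyncratic bias variance is a
calibration with teeth. The linking analysis regresses every subject's
bias on the *same* group transformation map; if bias were dominated by a
shared scene-level component, all subjects' correlations would rise and
fall together with the noise in that common map, the random-effects t
would treat near-duplicate correlations as independent evidence, and
parcels with no planted association would be flagged far above the
nominal FDR level. With mostly idiosyncratic bias the test is calibrated
(verified by the parameter-recovery test: planted parcels recovered with
power ≥ 0.9, unplanted parcels flagged at most at the FDR level within
Monte-Carlo error), and the planted association is still recovered
because the shift magnitude tracks the group-mean bias. The converse —
that a strongly shared summarization profile across people would inflate
this style of random-effects inference — is a genuine property of the
method and is listed under limitations. Because short scenes (11–20 s)
structurally admit only shares near 0 or 1, the exported ground-truth
bias is the *realized* summary word share of the constructed plan (the
latent tendency is exported alongside as `target_bias`); the realized
share is the quantity any coder could recover from the transcript.
Content-word counts are Poisson(14), inflated ×1.5 for Summary
utterances; Other utterances (no segment span, filler text) are
interleaved to make up 23.6% of utterances; utterance durations are
normal (6.83 s, SD 1.6 s).

Annotation text uses disjoint per-scene vocabularies plus a small shared
pool, which makes the matched-versus-mismatched text property provable
with the built-in deterministic hashed bag-of-words embedder (512
dimensions, L2-normalized, signed feature hashing) — no model download is
involved, and a production sentence encoder can be plugged in behind the
same `embed()` contract.

Two behavioral-neural couplings are deliberate calibration choices, not
reported values: recall noise inside Summary utterances is doubled
(`summary_noise_mult = 2`), which reproduces the direction of the
reinstatement contrast (precise recall reinstates more), and the default
shift parameters are $a = 0$, $b = 1$, $\sigma_m = \sigma_r = 1$. The
magnitude of the shared shift relative to noise is not quantified by the
empirical literature; these defaults place the effects at comfortably
detectable but not trivial signal-to-noise.

## Numerical and design choices

* **Time conventions.** All on-disk times are seconds, 0-based,
  half-open `[onset, offset)`; TR index $j$ (0-based) samples
  stimulus/speech time $(j - \mathrm{lag})\,\mathrm{TR}$ with a default
  hemodynamic lag of 3 TRs (4.5 s at TR = 1.5 s). An interval covering no
  full TR falls back to the TR containing its midpoint.
* **10-s tie.** An utterance describing exactly 10 s codes Temporally
  Precise by default (`boundary_rule = "LE_PRECISE"`); the stricter
  reading is available as `"LT_PRECISE"`.
* **Averaging.** Reinstatement and similarity means are arithmetic means
  of raw correlations (the field's reporting convention); Fisher-z
  averaging is available via `fisher_z = TRUE` for sensitivity analyses.
* **Permutations.** The scene-label null applies *one common relabeling
  per draw to every subject*: the between-subject statistic couples
  subjects through shared scene patterns and overlapping leave-one-out
  averages, and independent per-subject relabelings under-disperse the
  null (verified by a KS-test calibration check that fails for the
  per-subject variant and passes for the common one). The reinstatement
  null instead shuffles, within each subject, which movie segment is
  paired with which utterance-averaged recall pattern — recall patterns
  are subject-specific, so no cross-subject alignment exists to
  preserve. Permutation p-values use the literal
  $\#\{null \ge obs\}/n$ rule; add-one smoothing is available
  (`perm_smoothing = TRUE`) for FDR stability when p = 0 is undesirable.
* **Degenerate inputs.** Zero-variance samples yield flagged results
  (`degenerate = TRUE`, capped $t = \pm\infty$), never exceptions, so
  parcel-wise loops do not abort. Correlations of constant vectors are
  `NA` and excluded by callers. Subjects need at least 3 contributing
  scenes for a linking correlation (a 2-point correlation is ±1
  degenerately); scenes need at least 5 recallers to enter
  between-subject analyses.
* **RR construction.** The leave-one-out averaged-others construction is
  applied to RR symmetrically with MR (the subject's recall pattern
  against the mean of the other recallers' patterns).
* **Exchange formats.** TSV with mandatory headers everywhere; NIfTI
  (via RNifti) as ingestion convenience for voxel data and optional
  rendering target for parcel maps; YAML for configurations. Empty
  fields are the missing-value sentinel.

## What the synthetic data does and does not emulate

The generator reproduces the statistical skeleton the analyses rely on:
shared scene patterns, event-specific shared recall shifts, idiosyncratic
noise, realistic scene/segment/utterance timing, label proportions, and a
plantable bias-transformation association with exported ground truth. It
does not emulate hemodynamic convolution, temporal autocorrelation, head
motion, physiological noise, inter-regional correlation structure, or
semantic structure in text beyond vocabulary overlap. Passing tests
therefore certify the pipeline's correctness and calibration under the
assumed generative family — not that real fMRI data satisfies those
assumptions. Within a scene the generated patterns are constant across
TRs and micro-segments; consequently micro-segments of one scene are
duplicated, non-exchangeable units, and the segment-shuffle calibration
check uses a one-segment-per-scene configuration where exchangeability
holds.

## Problem sizes used in the test suite

Simulation-based checks run at reduced sizes chosen for a single CPU:
closed-form recovery uses 50 replicates of 17 subjects x 10 scenes x
2000 features; linking recovery uses 50 replicates of the full 17 x 50
design at 100 features and 4 parcels with 200 permutations; permutation
calibration uses 40-50 replicates at 200 permutations; reinstatement
direction uses 100 replicates of 17 subjects x 6 scenes x 40 features.
The statistics scale as documented, and all sizes are explicit in the
tests.

## Known limitations

* Human Direct-Judgment labels and inter-rater consensus are inputs, not
  reproduced; the Automatic rule is enforced and validated against them.
* The stop-word list is a standard English function-word list shipped
  with the package and user-overridable; published supplementary lists
  can be substituted via `analysis_config(stopwords = ...)`.
* ROIs are user-supplied parcel sets; no voxel-wise searchlight is
  implemented.
* The mismatching comparison set in the text analysis defaults to all
  uncovered segments (a seeded subsample is available for large
  corpora).
* Subject-level linking correlations are Pearson by default; Spearman is
  available by configuration.
* The random-effects linking test assumes subject-level correlations are
  exchangeable across subjects. Because all subjects are correlated
  against one common group transformation map, any strongly shared
  component in the bias scores makes those correlations co-vary and
  inflates the t-statistic; interpret linking results cautiously when
  summarization profiles are highly consistent across participants.
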