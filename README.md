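# retellr

Temporal compression in verbal retelling and encoding-to-recall pattern
transformation — an analysis pipeline for naturalistic free-recall fMRI
studies, with a calibrated synthetic-data generator for end-to-end
validation.

## The problem

Participants watch a continuous movie in the scanner and later retell it
aloud. Their speech compresses the experience: some moments are recounted
in temporally precise detail, others are summarized in one sentence
spanning minutes of movie time. `retellr` quantifies that compression from
transcripts and asks how it relates to the way neural event
representations change between encoding and recall:

- **Utterance coding.** Each utterance maps to a span of movie
  micro-segments; spans describing more than 10 s of movie time are
  *Summary*, shorter spans *Temporally Precise*, unmappable speech
  *Other*. The temporal compression factor is
  `TCF = 1 - content_words / described_seconds`. Per scene and subject,
  the %Summary bias is the share of content words coming from Summary
  utterances.
- **Text validation.** Sentence-embedding cosine similarity between
  utterances and the movie annotations they cover (matched) versus the
  rest (mismatched), split by recall type.
- **Reinstatement.** Within subject, the correlation between each
  described micro-segment's movie pattern and the averaged recall pattern
  of the utterances describing it, split by recall type.
- **Memory transformation.** Between subjects, per parcel and scene:
  movie-to-recall similarity `MR` (a subject's movie scene pattern vs the
  average recall pattern of the *other* subjects who recalled the scene)
  and recall-to-recall similarity `RR` (the subject's own recall pattern
  vs the same leave-one-out average). If recall patterns are more similar
  between people than to the original encoding pattern, the
  encoding-to-recall change is systematic rather than noise:
  `T = RR - MR > 0`. Parcels are screened by a scene-label permutation
  test with Benjamini–Hochberg FDR (the reliability mask).
- **Linking.** In each transformation parcel, every subject's scene-level
  %Summary bias is correlated with the group per-scene transformation
  value; subject correlations enter a random-effects t-test versus zero,
  FDR-corrected across parcels. A control analysis checks scene duration.

The synthetic generator implements the underlying generative family: per
scene `k`, movie patterns `m_k + eta_ik` and recall patterns
`m_k + c_k * s_k + eps_ik`, where `s_k` is an event-specific shift shared
across subjects and `c_k` scales with the scene's group-mean summary bias
in designated parcels. With `n` recallers,

    MR = 1 / sqrt((1 + sm^2) (1 + c^2 + sr^2/(n-1)))
    RR = (1 + c^2) / sqrt((1 + c^2 + sr^2) (1 + c^2 + sr^2/(n-1)))

so the test suite can hold the pipeline to a closed form (at
`sm = sr = 1, c = 1, n = 17`: `MR ≈ 0.492`, `RR ≈ 0.804`) and to an
independent straight-loop oracle. See `vignettes/methods.Rmd` for the
full model, calibration choices and limitations.

## Worked example

Simulate a 17-subject, 50-scene study in which parcels 1–2 carry a
bias-linked shared recall shift and parcels 3–4 do not, then run the
whole pipeline:

```r
library(retellr)

cfg <- sim_config(n_subjects = 17, n_scenes = 50, n_parcels = 4,
                  features_per_parcel = 100, linked_parcel_ids = c(1, 2))
dat <- simulate_dataset(cfg, seed = 42, neural = "patterns")
res <- run_pipeline(dat, analysis_config(n_perm = 1000), seed = 43)

res$transformation
#> <transformation_result> 4 parcels
#>   reliability mask: 4/4; positive transformation: 4
#>   mean MR = 0.648, mean RR = 0.698

tidy(res$link)[, c("parcel_id", "mean_r", "t", "p", "q_value", "significant")]
#> # A tibble: 4 × 6
#>   parcel_id  mean_r      t           p     q_value significant
#>   <chr>       <dbl>  <dbl>       <dbl>       <dbl> <lgl>
#> 1 1          0.223   6.45  0.00000807  0.0000161   TRUE
#> 2 2          0.274   8.65  0.000000199 0.000000798 TRUE
#> 3 3         -0.0620 -1.57  0.135       0.181       FALSE
#> 4 4         -0.0211 -0.466 0.648       0.648       FALSE
```

All four parcels pass the reliability screen (the shared movie component
makes between-subject similarity highly non-random) and show `RR > MR`;
only the two parcels where the generator tied the shift magnitude to
summary bias come out significant in the linking test, with mean
subject-level correlations around 0.22–0.27. The text validation on the
same data gives a matched-minus-mismatched cosine difference of 0.72 for
Precise and 0.31 for Summary utterances (Summary retellings paraphrase,
so their text diverges from the annotations), and the duration control
finds no reliable duration–bias correlation (t(16) = 1.51, p = 0.15).

Each stage is also exposed on its own (`scene_summary_bias()`,
`matched_vs_mismatched()`, `segment_reinstatement()`,
`transformation_scores()`, `link_bias_transformation()`), results carry
`tidy()` / `glance()` methods, and `autoplot()` /
`plot_summary_bias()` draw the standard figures. On-disk exchange is
plain TSV (`read_segmentation()`, `read_transcript()`,
`read_timeseries()`, `write_parcel_map()`), with NIfTI ingestion via
`read_timeseries_nifti()` and YAML configs via `read_config()`.

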