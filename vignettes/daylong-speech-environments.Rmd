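---
title: "Quantifying daylong home speech environments of preschoolers with cochlear implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying daylong home speech environments of preschoolers with cochlear implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daylongr)
```

## The problem

Children acquire spoken language from the speech around them, and for
children who hear through cochlear implants (CIs) the home environment is
both harder to access (pre-activation auditory absence, post-activation
signal degradation) and a prime target for intervention. Daylong
child-worn recorders (LENA and similar) produce speaker-diarized segment
streams — clips tagged *target child* (CHN), *female/male adult near*
(FAN/MAN), or other — from which quantity, consistency, and contingency
measures of the environment can be derived. `daylongr` implements that
post-diarization analysis as a tested pipeline: clip filtering, hourly
normalized metrics, conversational-turn detection, and the statistical
layer used to compare a CI group against chronological-age (CA) and
hearing-age (HA) matched peers with typical hearing. A calibrated
synthetic-cohort generator stands in for raw recordings, which are never
publicly deposited in studies of this kind.

## The measures

All timestamps are integer milliseconds from recording start; intervals
are half-open `[onset, offset)`, which removes double-counting ambiguity
at bin boundaries.

**Filtering.** Before any metric: CHN clips containing cries, FAN/MAN
clips containing any non-speech, and FAN/MAN clips strictly longer than
10 s (a diarizer-mislabel heuristic) are removed. "Longer than 10 s" is
implemented as `> 10000` ms (a clip of exactly 10 s survives). An adult
clip that is both contaminated and over-long is counted once, under
non-speech — a declared convention; published analyses report only a
pooled removal count, so precedence had to be fixed here. CHN clips
flagged as non-speech (but not crying) are retained, mirroring the
published rule, and OTHER-tagged clips pass through untouched.

**Quantity.** Adult words/hr (AWC), adult speech minutes (and seconds)
per hour, child vocalizations/hr (CVC), and conversational turns/hr
(CTC), each computed as a total divided by the actual recording duration
rather than a mean over hourly bins — exact for a shortened recording
(one study family recorded 12.83 h instead of 16 h).

**Consistency.** The proportion of fixed bins (minutes for words and
vocalizations; 5-minute epochs for turns) containing at least one
qualifying event. A minute "contains" adult speech when it overlaps an
adult clip carrying at least one estimated word: word estimates are
clip-level in diarizer output, so the whole clip carries its words, and
bin membership is by interval overlap rather than onset (onset-only
undercounts clips spanning a boundary). Trailing partial bins are dropped
from the denominator so a short recording is not deflated. Consistency is
deliberately independent of quantity — the same number of words spread
through the day scores high, clustered into one burst scores low.

**Conversational turns.** A turn is a target-child utterance and an adult
utterance within 5 s of each other, in either order; adult–adult and
child–child adjacencies never count. Adjacency is evaluated on the stream
restricted to CHN/FAN/MAN: an intervening OTHER clip does not break a
pair, an intervening same-side clip does. Two boundary decisions are
declared rather than inherited: the window is inclusive (`gap <= 5000`
ms), and overlapping child/adult clips (negative gap) count — overlap is
stronger evidence of contingency than a short silence. A clip can
participate in at most two turns (as second of one pair, first of the
next), which is what consecutive-pair scanning yields. Commercial
diarizers compute their turn counts with unpublished internal rules;
this detector implements the stated definition, and exact equality with
proprietary counts is not claimed.

## The statistical layer

Hearing group (CI / CA match / HA match) is treatment-coded with CI as
the reference, so match-group coefficients read as deviations from the CI
group. Continuous predictors are mean-centered. Hourly outcomes (words,
minutes, vocalization counts) are modeled with random intercepts by child
and by hour of recording; repeated segment-level outcomes (vocalization
duration) with random intercepts by child only. Model comparisons are
likelihood-ratio tests after refitting by maximum likelihood (REML
log-likelihoods are not comparable across fixed-effect structures).
Because `lmerTest` is not assumed available, fixed-effect p values for
mixed fits use a normal approximation on t, recorded as
`p_method = "normal"` in every result; the LRTs that carry the inferential
weight do not depend on that approximation.

Cross-sectional age slopes are per-group OLS fits of a per-child metric
on age in months, reported with the Pearson correlation; the hearing-age
basis applies only to CI children with at least 12 months of hearing
experience (hearing age = chronological age minus activation age).
Vocalization duration, being a repeated measure, gets its age slope from
a segment-level mixed model with child intercepts while its correlation
is still computed on per-child means. Whether word/second slopes should
be fit on per-child averages or hour-level data is genuinely open in the
source description; per-child averages are the default here (the
published figures plot one point per child), and the hour-level route is
available through `fit_group_model()` on the hourly table.

The vocal-productivity model regresses hourly child vocalizations on
hourly turns with a turns-by-group interaction, controlling for
chronological age; per-group slopes are the CI slope plus the group's
interaction deviation (`derive_group_slopes()`), and the interaction is
tested by ML likelihood ratio. `sensitivity_rerun()` refits the slope
tables and productivity model with configured children excluded — the
analysis used in the source study to confirm robustness to an
activation-age outlier (activated at 45 months, 8 months of hearing
experience).

## The synthetic world

The generator emulates the structure the analysis assumes — it is a
stated world, not a fit to data (the study is observational and provides
no generative model). A child-day is a sequence of well-separated events
on a 16 h clock:

* **adult bursts** at 40/hr, each a short run of adult clips (lognormal
  durations, median 3 s, capped at 10 s; FAN:MAN 85:15) carrying Poisson
  word counts;
* **exchanges**: a burst whose last clip elicits a child reply within the
  5 s window, with per-child probability `p_i`; the reply may extend into
  a volley (mean 1.5 child vocalizations) and is closed by an adult reply
  with probability 0.15. An exchange with `V` child vocalizations and
  closing-reply indicator `R` contributes exactly `2V - 1 + R` detectable
  turns;
* **solo bouts**: runs of child vocalizations placed more than 5 s from
  any adult clip (vocal play out of caregiver earshot), which therefore
  never create turns;
* **OTHER clips** (siblings, TV) that the analysis ignores.

Events are separated by more than the turn window, so planted contingency
maps one-to-one onto detected turns and every rate has a closed-form
expectation (`expected_rates()`), which the tests verify by Monte Carlo.
This is the deliberate deviation from a literal
"respond-after-every-adult-clip" reading: attaching responses to bursts
and exiling solo vocalizations from adult neighborhoods is what makes the
planted contingency *identifiable* by the 5 s rule, so that recovery
tests exercise the estimator rather than an uncontrolled overlap
geometry. Real diarized days are messier — overlapping speech, chance
adjacencies, cry bouts near caregivers — and a green recovery test
establishes correctness of the pipeline on this stated world, not
validity of the 5 s rule on real audio.

Defaults are calibrated once to the published cohort's printed values:
group mean ages (47.72 / 46.28 / 35 months), ~1217/1081/1106 adult
words/hr, ~282 s of adult speech/hr, ~272/308/255 vocalizations/hr,
~62–68 turns/hr, vocalization-duration means near 940–1000 ms with age
slopes 3.16/0.59/6.59 ms/month, word-rate age slopes 0/20.7/16.49
words/hr/month (zero for the CI group, mirroring the qualitative
finding), and vocs-per-turn productivity slopes 2.22/3.66/3.53.
Between-child spreads come from the printed SDs (lognormal word-rate
spread 0.38; response-probability SD 0.3, clamped to [0.05, 0.98]).
Input consistency emerges near the printed 0.5–0.6; turn consistency
emerges higher than printed (~0.9 vs ~0.6) because real turns cluster
into conversational sessions the generator does not model — a known,
accepted infidelity, as consistency levels are not an acceptance surface.

Two technical points matter for parameter recovery. First, the
productivity targets are regression slopes of *measured* hourly
vocalizations on *measured* hourly turns; over a finite day both carry
compound-Poisson measurement noise, correlated through the volley size.
Planting the target as a latent error-free slope would therefore generate
cohorts whose measured-scale regression slope is attenuated by a few
percent. The solo-rate link instead solves the errors-in-variables
identity in closed form (see `synth_links`), so the population regression
slope of measured-on-measured equals the target exactly. Second, the
solo-rate noise factor is a capped, mean-renormalized lognormal: the cap
(2.5) prevents a heavy-tailed draw from overfilling the day, and the
renormalization keeps `expected_rates()` exact.

Cohort construction mirrors the matching protocol: chronological-age
matches within 3 months, hearing-age matches within 3 months of the CI
child's *hearing* age (only when hearing age is at least 12 months; by
default 2 of 18 CI children fall below the floor, giving the published
18/18/16 design), equal gender within pairs, and maternal education
(7-level scale) within 1 level.

## Numerical and degenerate-input choices

* Tie-breaks: segments sort by (onset, offset, tag); bins and epochs are
  half-open, so an event at an exact boundary belongs to the later bin.
* A recording shorter than one bin is a domain error for consistency; an
  empty recording yields all-zero quantities and flows through the
  pipeline with models flagged `degenerate` rather than failing.
* Constant outcomes fall back from a mixed to a fixed-effects fit with a
  recorded note instead of crashing.
* `compare_models()` allows a zero-df comparison (identical models) and
  returns `chi2 = 0` with `p = NA`; negative chi-square from numerical
  noise is clamped to zero.
* Groups with fewer than 3 children are flagged `available = FALSE` in
  slope tables rather than fit.
* Output files never embed wall-clock time, so identical inputs, config
  and seed reproduce outputs byte-for-byte; `report.json` stores output
  basenames for the same reason.
* Runtime scale-downs in the test suite are declared in place: the
  segment-level duration model subsamples at most 150 clips per child in
  the recovery harness (unbiased, only less precise), and the
  Monte-Carlo rate check uses 80 four-hour days rather than 500 full
  days (expectations are duration-invariant).

## Limitations

The package consumes diarizer output and inherits its errors; no claim is
made about diarization accuracy, and, as in the source study, comparisons
are meaningful *across* groups rather than as absolute rates. The
generator omits conversational-session clustering, sibling speech beyond
the OTHER tag, day-to-day within-child variation (one recording per
child, as in the study design), and any linguistic content. Type-I-error
calibration simulates at the metrics level under the fitted models' own
null; it does not probe misspecification of the mixed-model variance
structure. Reproducing the study's actual coefficients would require the
real recordings, which are not deposited; printed values serve as
calibration anchors and structural targets only.
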