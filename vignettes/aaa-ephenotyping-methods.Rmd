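---
title: "Methods: rule-based AAA ePhenotyping, validation statistics, and the synthetic-EHR generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based AAA ePhenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaapheno)
```

## The classification model

`aaapheno` labels every subject of a coded-EHR extract as an abdominal
aortic aneurysm (AAA) **case**, a **control**, or **excluded** with one of
five reasons, using only four inputs per subject: dated ICD-9 diagnosis
events, dated CPT procedure events, the clinic attributed to each event,
and the subject's age at each event. The design goal is positive
predictive value in both the case and the control group, not sensitivity:
a subject who cannot be confidently placed is excluded rather than forced
into either group.

The cascade applies nine rules in a fixed order and stops at the first
match. Exclusions for phenocopies (heritable connective-tissue disease,
thoracic aneurysm, dissection) and for age precede case typing, so that a
Marfan patient with a genuine repair procedure is still excluded — these
subjects have aneurysms, but of an aetiology the case definition is
designed to avoid. The three case types are ordered by decreasing
certainty: a repair procedure (Type 1) is stronger evidence than a
ruptured-AAA diagnosis at a specialty clinic (Type 2), which is stronger
than repeated unruptured-AAA diagnoses at specialty clinics (Type 3). The
two control filters run last: any residual `441.*` code — typically a
single working or referral diagnosis that was never confirmed — bars a
subject from the control group, and so does the absence of any encounter
within the lookback window, since an untouched record cannot attest
AAA-freedom.

Assumptions worth making explicit:

* **Coded data only.** No clinical notes, no imaging. A pre-aneurysmal
  aorta coded as AAA is indistinguishable from a true case; this is the
  documented false-positive mode the validation statistics quantify.
* **Clinic attribution is meaningful.** Types 2 and 3 require encounters
  at clinics configured as responsible for AAA (vascular surgery by
  default; cardiology or interventional radiology at some institutions).
  Clinic names are compared exactly after trimming and case-folding — no
  fuzzy matching, because clinic vocabularies are site-specific and a
  near-miss should be fixed in configuration, not guessed at run time.
  A blank clinic is a non-specialty clinic: specialty attribution is a
  positive requirement.
* **Age is carried by events.** The input contract has age-at-event, not
  birth dates. Age at the reference date is reconstructed as the age at
  the subject's most recent event plus whole elapsed years. Subjects with
  no events cannot be age-assessed and fall through to the
  no-recent-encounter exclusion.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `specialty_clinics` | `"vascular surgery"` | clinics whose AAA diagnoses count for Types 2–3 |
| `min_age` | 40 years | lower age bound at the reference date; also the onset bound (first AAA evidence at ≤ 40 excludes) |
| `max_age` | 89 years | upper age bound at the reference date (inclusive band [40, 89]) |
| `lookback_years` | 5 years | encounter recency a control must satisfy |
| `reference_date` | `"auto"` | anchor for age/recency; `auto` = latest event date in the data |
| `min_type3_dates` | 2 | distinct specialty AAA-diagnosis dates for Type 3 |
| `require_specialty_type2` | `TRUE` | whether the ruptured-AAA encounter needs a specialty clinic |

The age band excludes the young because controls under 40 may yet develop
AAA and cases at or under 40 are likely traumatic or syndromic; the upper
bound avoids the heavily comorbid very old. Two readings of the age rules
are implemented as *separate* rules on purpose: a reference-date age band
(rule 2) and an onset-age bound (rule 3). They overlap but are not
redundant — a 70-year-old whose first AAA code appeared at 38 passes the
band and is caught by the onset rule.

Two boundary decisions the rule statements do not pin down were resolved
conservatively and are configurable: the band is inclusive ([40, 89]
survive), and the onset bound excludes at exactly 40 (`<=`). The recency
rule is interpreted as *encounter recency* (latest visit within 5 years of
the reference date), not minimum record duration, and it applies only to
would-be controls: case evidence is definitional regardless of when the
last visit happened, whereas a control's AAA-freedom decays with absence.

All ruptured-AAA logic keys on ICD-9 441.3 (abdominal aortic aneurysm,
ruptured); 444.3 (embolism of peripheral arteries) is *not* an AAA code
and is not in any default set. The default repair-procedure list covers
the standard open (35081–35103) and endovascular (34800–34832) families
and is deliberately exposed as a configurable placeholder: procedure lists
are maintained per site, and the engine only ever uses the list as a
membership test.

## Code normalization and matching

Extracts mix dotted (`441.4`) and undotted (`4414`) ICD-9 dialects; all
codes are normalized on ingestion to the dotted canonical form (3-character
category, optional 1–2 digit subcode; `V`/`E` prefixes preserved), and the
normalizer is idempotent. Matching is exact string equality, plus one
wildcard form: `441.*` matches the bare category `441` and every 1–2 digit
subcode. The bare category is matched deliberately — a sloppily coded bare
`441` must keep a subject out of the control group, which is the
conservative direction of error for a control-purity filter.

## Validation statistics

Review sampling draws equal numbers of predicted cases and controls
uniformly without replacement (capped at the stratum size with a warning),
shuffles the blinded listing, and keeps the label key separate. PPV is
`100 * confirmed / reviewed` per stratum. Confidence intervals are exact
Clopper–Pearson via beta quantiles, with the closed-form endpoints at
`x = 0` and `x = n`; the Wilson score interval is available as an option.
The exact interval was chosen because it is conservative (coverage at
least nominal for every `n` and `p`), which suits small review samples of
25–50 charts per stratum. Multi-site pooling sums confirmed and reviewed
counts per stratum across sites — equivalently, the reviewed-count-weighted
mean of site PPVs — never the unweighted mean, which would mis-state the
evidence when sites review different numbers of charts.

## The synthetic-EHR generator

The generator emulates the three input streams with ten per-subject
archetypes, one per engine outcome: the three case types, the five
exclusion modes (phenocopy, early onset, single unconfirmed code,
non-specialty-only codes, stale record), and two control variants (with
and without benign code noise). Each recipe is constructed so that, under
the default configuration, the engine's label is *implied*, which is what
makes exact ground-truth recovery a meaningful test: on mixed cohorts the
engine must recover 100% of labels, case types and exclusion reasons.

Realism choices: case ages are drawn from 55–85 (typical clinical AAA
ages); each subject has one latent birth date so age-at-event stays
arithmetically consistent with event dates, which the engine's age
reconstruction relies on; events fall uniformly in a five-year observation
window (2008-01-01 to 2012-12-31 by default) except the stale archetype,
whose last event is forced more than the lookback before the window end;
benign filler codes (hypertension, diabetes, COPD, ...) are added at a
Poisson rate of 2 per subject. The early-onset archetype pins its first
AAA code at age 37–40 and its anchor age just past 41, so the onset rule —
not the age band — fires.

What the generator does **not** emulate: longitudinal disease progression,
code co-occurrence structure, visit-frequency patterns, inter-site coding
habits, or free text. Passing the round-trip tests therefore demonstrates
that the engine implements its rules exactly, not that the rules achieve
any particular PPV on real EHR data — that number can only come from chart
review, which is why the validation module exists.

`perturb_to_false_positive()` converts `k` clean controls into subjects
the engine must label Type 3 cases while their ground truth stays
non-case, mimicking the known failure mode of aortic ectasia coded as AAA.
Full review of such a cohort has analytic PPV `(n - k) / n`, giving an
end-to-end check that classification, sampling and PPV computation compose
correctly.

## Numerical and degenerate-input choices

* Years convert to days as 365.25 × years; dates compare at calendar-day
  granularity, and two events on the same day are one "date" for the
  distinct-dates rule.
* Whole elapsed years use `floor()`, matching how age is stated clinically.
* If several events share the latest date with different recorded ages,
  the maximum age is used (deterministic tie-break).
* Percentages and CI bounds are reported to 1 decimal.
* Zero classified cases yields a case-type table with zero counts and `NA`
  percentages — no division by zero.
* `reference_date = "auto"` with zero events is an error, as is an empty
  subject table, a duplicated subject id, an unparseable date or age, or a
  config that breaks a registry invariant (e.g. the ruptured and
  unruptured sets must partition the AAA diagnosis set, and every AAA code
  must be barred from controls).
* Classification is fully deterministic: identical inputs and
  configuration produce byte-identical result files. All sampling and
  simulation randomness flows from explicit integer seeds and never leaks
  into the caller's RNG state.

## Test problem sizes

The bundled suite exercises: exhaustive oracle agreement for the exact
interval at all `(x, n ≤ 50)` against tail-sum bisection, plus empirical
coverage at `n = 125, p = 0.9` over 10,000 draws; engine-vs-oracle
agreement on 200 independently generated 50-subject random cohorts (an
unordered-predicate brute-force classifier written separately from the
cascade); exact ground-truth recovery on 1,000-subject archetype cohorts;
and the planted-false-positive round trips at `k ∈ {0, 2, 3, 6}`. These
sizes keep the whole suite under a couple of minutes on one CPU while
covering every rule interaction the cascade admits.

## Known limitations

* ICD-9 only; no ICD-10/SNOMED translation, by design.
* PPV is the only performance statistic obtainable from the blinded-review
  design; sensitivity and NPV would require reviewing algorithm-negative
  subjects and are not offered.
* The default repair-code and phenocopy lists are reconstructions and must
  be confirmed per site (see the README caveat).
* Aneurysm size is invisible in coded data; ectasia-coded-as-AAA false
  positives are quantified by validation, not prevented.
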