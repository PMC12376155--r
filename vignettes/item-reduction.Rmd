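---
title: "Classification rules, item reduction, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification rules, item reduction, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the rules it implements, the
choices that were genuinely open, and what the synthetic-data results do and
do not establish.

## The classification model

An examination scores 134 items: light touch (LT) and pinprick (PP) at 28
dermatomes per side on a 0/1/2 scale, ten key muscle functions per side on
the 0–5 manual muscle testing scale, and two binary anorectal findings (deep
anal pressure, DAP; voluntary anal contraction, VAC). "Not testable" scores
are rejected at validation: the package models clean exams only, and cohorts
containing NT items must be filtered upstream.

Levels live on a single rostral-to-caudal ladder of 28 segments (C2 … S4-5,
with S4 and S5 examined as one row), extended by two sentinels that occur
only as results: `C1` (even C2 is abnormal) and `INT` (intact throughout).
Level arithmetic is integer arithmetic on this ladder.

**Sensory level** — the most caudal dermatome with both modalities scored 2
at that dermatome and at every dermatome rostral to it, per side.

**Motor level** — computed by a rostral-to-caudal walk. A segment is
motor-intact when its key muscle grades 5; segments without key muscles
(above C5, T2–L1, below S1) take their status from their own dermatome
("motor follows sensory"). The walk stops at the first non-intact segment;
if that segment carries a key muscle graded 3 or 4 it becomes the motor
level itself (the standard's lowest-key-muscle ≥ 3 allowance), otherwise the
level is the last intact segment.

One corner of the standard's prose is ambiguous: a sensory level resting in
a non-key region *rostral to* fully intact key muscles (say, sensory level
C4 with 5/5 arms). The walk resolves it by letting the motor level run
caudally through the intact muscles — motor level T1 in that example, as the
published computerized classification algorithms do — rather than pinning
the motor level to the sensory level. This reading is normative for this
package; it is also the reason the item-reduced algorithm can determine
motor levels without extra sensory testing in those segments.

**NLI** — the most rostral of the four side levels; ties simply share the
level. **Sacral sparing** — sensory: any S4-5 score above 0 or DAP present;
motor: VAC present. **Grades** — A when no sparing; motor-incomplete (C/D)
when VAC is present or sensory sparing coexists with key-muscle activity
more than three *ladder* levels below the ipsilateral motor level (key
muscles only; non-key muscles are out of scope); B when sensory-spared but
not motor-incomplete; D when at least half of the key muscle functions
strictly below the single NLI (both sides pooled) grade ≥ 3, else C; E only
for a fully maximal exam. When **zero** key muscles lie below the NLI the
half-condition is treated as vacuously satisfied (grade D): the convention
makes the C/D split total, and it is why grade C is infeasible at NLI S1–S3.
For the three-way grouping used in evaluation, C and D merge to `CD`; the
degenerate grade E also maps to `CD` (incomplete), though generated cohorts
never contain it.

## The item-reduction policy

The reduced exam interrogates a responder (a complete exam record) in four
phases:

1. **All 20 key muscles.** Full motor testing is retained deliberately: it
   has clinical utility of its own, and upper-extremity weakness is too
   common in cases with caudal sensory levels for arm testing to be safely
   skipped.
2. **Galloping sensory search per side** (right, then left — a fixed order
   chosen for reproducibility; it cannot affect results). Both modalities
   are tested together at each visited dermatome. From C2 the search
   strides 4 levels while the visited dermatome is normal (C2, C6, T2, T6,
   T10, L2, S1); at the first abnormal visit it back-fills linearly from
   the last all-normal visit. The stride of 4 balances economy against the
   width of spans inside which a deficit can hide; it visits 7 dermatomes
   (14 items) on a fully normal side.
3. **Sacral confirmation.** S4-5 LT and PP on both sides, always (4 items —
   cheap, and indispensable for sparing). If a side reached S1 normal but
   S4-5 is abnormal, S2 and S3 are back-filled so the level can still be
   bracketed exactly.
4. **Anorectal items only when they can change the grade.** DAP is needed
   when all observed S4-5 scores are 0 (it could still establish sparing) —
   and also when every observed item is maximal, because DAP then separates
   grade E from D. VAC is needed unless sensory sparing plus qualifying
   motor sparing have already fixed the motor-incomplete status (the C/D
   split never consults VAC). The rule is conservative by construction: an
   anorectal item is only ever skipped when no attainable value could
   change the grade, given the observed items.

Classification then runs on the observed items, imputing every skipped
dermatome rostral to the first observed abnormality as normal (those are
exactly the dermatomes inside stride spans whose endpoints were observed
normal). Dermatomes caudal to the first abnormality stay untested; in the
effective exam they are scored 0, where they can influence neither levels
(the level logic stops at the abnormality) nor the grade (sacral and motor
items are all observed when relevant).

**Failure mode.** Imputation is the single source of error: an isolated
abnormal dermatome hidden inside a skipped span is assumed normal, and the
NLI can come out caudal to the truth — never rostral. The package's tests
construct these cases deliberately and verify the error is confined to
them. The AIS grouping survives even then: sensory sparing, DAP, VAC and
all muscle grades are observed directly, the imputed motor level can only
move caudally (never inventing motor sparing), and qualifying sparing in
generated cohorts never hinges on the one side carrying the deficit (see
below).

## The synthetic cohort model

`cohort_config()` defaults describe the emulated population:

| parameter | default | meaning |
|---|---|---|
| `nli_mixture` | 0.609 / 0.274 / 0.117 | cervical (C2–C8) / thoracic (T1–T12) / lumbosacral (L1–S3) NLI bands |
| `ais_mixture` | 0.335 / 0.115 / 0.159 / 0.392 | grades A / B / C / D |
| `asymmetry_prob` | 0.10 | left sensory level displaced caudally (up to `asymmetry_max_offset` = 6 levels) |
| `isolated_deficit_prob` | 0.02 | a single abnormal dermatome followed by a normal span, hidden on the NLI-determining side |
| `zpp_span` | 0–3 levels | partially impaired transition band below the level |
| `diffuse_sparing_prob` | 0.6 | patchy impaired sensation below the band (incomplete grades only) |

The band and grade mixtures are quoted from a published registry
population; quoted percentages carry rounding (the grade mixture sums to
1.001), so mixtures are renormalized after a tolerance check. No
within-band level distribution is published; uniform-within-band is a
modeling choice, not an empirical claim. Asymmetry magnitude (up to 6
levels) and the 2% deficit rate mirror the reported morphology and rate of
the cases that defeat striding searches; the diffuse-sparing rate and the
ZPP span are clinical-plausibility choices fixed once.

Construction is deterministic-by-verification: scores are laid down
(normal above the level, a monotone transition band, absent or patchily
spared below, sacral items per grade), then the full engine classifies the
result and the generator resamples — dropping the irregular features after
repeated failures — until the target is recovered; genuinely infeasible
targets (grade C at S1–S3) raise an error rather than silently shifting.
Three structural choices deserve note:

* A key muscle *at* a key-segment NLI draws grade 3 or 4. Grades 1–2 there
  would pull the motor level, and hence the NLI, one segment rostral, so
  they cannot occur at the level that defines a key-segment NLI; the
  partially innervated 0–2 grades live in the muscles just below instead.
* Motor-incomplete cases without VAC are built with qualifying motor
  sparing on **both** sides, reflecting that motor sparing strong enough to
  define incompleteness without anal contraction is typically bilateral.
  A consequence: the grade of such a case never depends on the single side
  where an isolated deficit may hide.
* The injected isolated deficit sits on the side whose sensory level
  determines the NLI, with normal dermatomes caudal to it — the morphology
  reported for real striding-search failures. NLI errors therefore arise
  when (and only when) that deficit coexists with contralateral asymmetry
  and no key-muscle anchor at the level.

With asymmetry, deficits and diffuse sparing all at probability 0,
generated exams are exactly side-symmetric and monotone, which is the
regime in which the item-reduced NLI is provably exact.

**What the generator does not emulate:** "not testable" items, examiner
error and inter-rater noise, non-SCI confounders, non-key muscles, zones of
partial preservation in the formal sense, longitudinal recovery, or any
empirical within-band level distribution. Passing tests therefore show that
the algorithms are exact with respect to the *rules* on clean,
plausibly-shaped exams — not that real registry accuracy or item counts
would be numerically identical. In particular, reduced-exam item counts
depend on the search protocol and the cohort's level mix; the package
asserts their direction (every case under 134 items; cervical cases
cheapest; a sizeable fraction of cases with no anorectal exam), never a
specific mean.

## Numerical and reporting conventions

* Reported percentages are rounded to one decimal, **half away from zero**,
  matching the convention of the published tables they are compared
  against (base `round()` rounds half to even).
* Recall/precision for an empty row or column is `NA` (undefined), never
  0%; levels with no cases are absent from per-level outputs, not 0%.
* Sample standard deviations use n − 1; a single observation reports `NA`.
* The cohort generator threads one seeded RNG through all sampling via
  `withr::with_seed`, leaving global RNG state untouched; identical
  configurations reproduce identical cohorts across platforms.
* Test and verification problem sizes — 5,000 cases for the item-reduction
  properties, 100,000 for mixture checks, a few hundred for per-module
  properties — were chosen so that binomial error on checked fractions is
  far below the asserted tolerances while the whole suite stays
  interactive.

## Known limitations

* The sensory search protocol is this package's own reconstruction of the
  published description (full motor first, limited sensory testing, one
  anorectal item for the typical case); exact per-case item counts from
  other implementations of the idea are not comparable.
* The motor-level corner case above is resolved by fiat; a clinician
  applying the "presumed same as sensory level" phrasing literally would
  report a more rostral motor level in the all-muscles-intact case (the
  NLI is unaffected).
* The E-versus-D distinction relies on DAP, so a fully normal responder
  still requires both anorectal items.
* `ais_group()` maps grade E to `CD`; callers comparing groupings on
  cohorts that may contain grade E should treat that explicitly.
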