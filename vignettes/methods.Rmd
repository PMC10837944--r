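---
title: "Methods: AKI staging, comorbidity mining and crosstalk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AKI staging, comorbidity mining and crosstalk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(akicomorbid)
```

This vignette is the package's account of its own science: the models and
procedures it implements, the parameters that matter, the choices we made
where the published definitions leave room, and what a green test suite
does and does not establish.

## 1. KDIGO detection and staging

AKI is defined operationally from two streams charted during an ICU stay:
serum creatinine (Scr, mg/dl) and urine output (Uo, ml).

**Creatinine criterion.** For each measurement at time $t$ the baseline is
the minimum Scr in the window $(t-168\,\mathrm{h},\, t]$ — a rolling-minimum
reading of "known or presumed to have occurred within the prior 7 days".
The published wording fixes only the 7-day horizon; the rolling minimum is
the deterministic convention used by the widely copied MIMIC code
concepts, and we adopt it. A measurement qualifies as AKI when it reaches
1.5× baseline or exceeds the minimum of the preceding 48 h by
≥ 0.3 mg/dl. Stage bands: 1.5–1.9× (or the 0.3 mg/dl rule) → stage 1,
2.0–2.9× → stage 2, ≥ 3.0× → stage 3; a value ≥ 4.0 mg/dl following a
qualifying rise is also stage 3 (a chronically high but flat creatinine is
not AKI). The stay's stage is the highest band attained; onset is the
first qualifying time. All band comparisons are inclusive at their printed
boundary (1.5, 2.0, 3.0, 0.3, 4.0): the printed numbers are treated as
attainable values, not open limits.

**Urine-output criterion.** Charted volumes are bucketed into clock hours
(`hour = ceiling(time)`) and converted to ml/kg/h with the recorded
weight. A low-output episode is a run of qualifying hours; runs tolerate
charting gaps of at most 2 h (the bridged hours count toward the
duration) but are broken by any charted non-qualifying hour or a longer
gap — the gap rule prevents declaring anuria across an uncharted
afternoon. Bands: < 0.5 ml/kg/h sustained 6–12 h → stage 1, ≥ 12 h →
stage 2 (the boundary at exactly 12 h is stage 2, reading "for ≥ 12
hours" as inclusive); < 0.3 ml/kg/h for ≥ 24 h or anuria (zero charted
volume) for ≥ 12 h → stage 3. A missing or non-positive weight skips the
criterion with a warning rather than imputing: imputation would fabricate
stage evidence.

**Combination.** The published criteria list both streams without saying
how they combine when they disagree; we take the worse (maximum) stage —
the KDIGO convention — and record which stream(s) attained it. Onset is
the earliest qualifying time across criteria. Both streams empty gives
stage 0 with a warning.

## 2. ICD processing

Codes are canonicalised to undotted uppercase (MIMIC stores undotted
codes; dotted input is accepted). ICD-9 codes are expanded through a
GEM-style two-column table; unmapped ICD-9 codes are dropped and counted.
Categories in V01–Y98 (external causes) and Z00–Z99 (health-status
contacts) are removed, both ranges inclusive and read lexicographically
on 3-character categories — note V00 and Y99 fall outside the excluded
block. Remaining codes are truncated to the 3-character category (ID-3;
ID-4 and ID-5 denote the 4-character and full detail levels), and each
patient becomes one deduplicated itemset; patients with fewer than
`min_codes = 2` disease items are dropped, since a single code carries no
pairwise information.

The mined AKI item is a **pseudo-item derived from the KDIGO label**, not
the raw N17 code: raw N17/N17.x codes are removed when the pseudo-item is
in use. Keeping both would manufacture a spurious (AKI, N17) self-pair
and make the mined hub reflect coding practice rather than the staging
definition. A flag (`use_pseudo_item = FALSE`) restores the raw-code
behaviour for users who want it.

## 3. Apriori mining and the three measures

Counting is per patient, never per diagnosis row. For items $A, B$ over
$N$ transactions:

$$\mathrm{sup} = P(A \cap B), \qquad
  \mathrm{kulc} = \tfrac12\left(P(A|B) + P(B|A)\right), \qquad
  \mathrm{lift} = \frac{P(A \cap B)}{P(A)\,P(B)}.$$

The support equation is sometimes printed with a union symbol; only the
joint-occurrence reading makes the lift identity coherent, and that is
what we implement. Candidate pairs are generated from frequent 1-itemsets
only (Apriori pruning); the result is proven equal, counts and measures,
to brute-force double-loop enumeration in the test suite.

The headline threshold setting `(sup: 8; kulc: 0; lift: 1)` does not pin
down units or strictness. We read it as `min_sup = 0.08` (8%, compared
inclusively: a support of exactly 8% survives) with kulc and lift
compared strictly (`> 0`, `> 1`); all three values and both strictness
conventions are configurable in `mining_thresholds()` and the default is
documented as a reading, not asserted as the source's intent. Output
order is `sup · kulc` descending with a lexicographic tie-break on the
partner code, so output files are reproducible byte for byte.

## 4. Verification

Two reference mechanisms, both offline:

* **Membership** in an externally mined pair list (the eICU role). Pairs
  are canonicalised to sorted order, so confirmation is order-insensitive
  and monotone in the reference set.
* **Chi-square** on a local 2×2 co-occurrence table keyed by a concept
  map (the COHD role, replayed from CSV snapshots). Pearson statistic
  without continuity correction, 1 df, significance at p < 0.05, no
  multiple-testing adjustment — mirroring the single-pair decision rule
  of the original design. A zero marginal leaves the statistic undefined
  and the pair unconfirmed.

**Fallback.** A partner category that fails concept mapping is retried:
transactions are rebuilt with that category replaced by each patient's
observed ID-4 subcategories, mining is re-run with the *same* thresholds
(the procedure says "performed again", naming no new thresholds), and
every resulting finer-level AKI pair that maps is chi-square-checked; one
confirmed subcategory confirms the category. Subcategories that still
fail mapping trigger the same step at ID-5. A partner that maps at ID-3
is never replaced. Because the fallback re-mines at the same support
threshold, a rare subcategory can fall below `min_sup` and the category
can remain unconfirmed even though a finer code would have verified — a
property of the published procedure itself, not of this implementation.

## 5. Network, risk factors, crosstalk

The disease network is a star centred on AKI: every printed edge
attribute (kulc width, lift shade, verification colour) is a property of
an AKI pair, so disease–disease edges have no data to carry; the star
topology is our design decision. Node importance is `sup · kulc`; the
selection rule behind a fixed-size published network is unstated, so we
take the top-K pairs by importance (K configurable, default 284) with the
same lexicographic tie-break. The hub is assigned the genitourinary
chapter (the chapter of N17, the condition the pseudo-item stands for).
GraphML and node-link JSON exports round-trip all attributes.

Stage-stratified mining grants the pseudo-item to patients at **exactly**
stage $s$ (not ≥ s): risk factors for severe AKI are defined as partner
codes unique to the stage-3 list, which requires disjoint stage groups to
be meaningful. Severe-AKI risk factors are a plain set difference
`stage3 \ (stage1 ∪ stage2)`.

Organ crosstalk: $\mathrm{score}_u = \sum_{j \in u}
\mathrm{sup}(AKI,j)\cdot\mathrm{kulc}(AKI,j)$, so the score grows with
frequency, reliability and the number of comorbidities in the class.
The bundled organ table is a **stand-in**: the original classification
table is not public. Our ranges — heart I05–I52 excluding the
hypertensive block I10–I15; lung J00–J99; liver K70–K77; brain G00–G99
and I60–I69; gut K20–K63 — cover the organ diseases named in published
crosstalk discussions (atrial fibrillation I48, ischaemic heart disease
I25, heart failure I50, respiratory failure, COPD, pneumonia) while
staying transparent and fully user-overridable
(`organ_classes("your.csv")`). Whether hypertension belongs to "heart"
is genuinely open; we exclude it, and users who disagree edit one CSV
row. Ranges must not overlap, so each category maps to exactly one
class.

## 6. The synthetic cohort: a stated world

The original analysis ran on credentialed databases with no public
generative model, so every distributional choice below is a stand-in,
stated once and not tuned:

* **Stage mix** default `(0.435, 0.399, 0.141, 0.025)` — an adult ICU
  population with 56.5% AKI and the within-AKI stage proportions of a
  large published cohort (stage 1 ≈ 71%, stage 2 ≈ 25%, stage 3 ≈ 4% of
  AKI). When pairs are planted at lift 2.0 the feasibility constraint
  `lift · P(AKI) ≤ 1` forces `P(AKI) ≤ 0.5`; tests use
  `(0.55, 0.3177, 0.1125, 0.0198)` (45% AKI, same within-AKI
  proportions).
* **Creatinine** baseline uniform on 0.6–1.2 mg/dl, charted 6-hourly
  over a 72 h stay; staged patients step at a random onset to a
  mid-band multiple (1.7×, 2.5×, 3.5×). Pre-onset values are charted
  noise-free and post-onset noise is Gaussian truncated at ±2 sd
  (default sd 0.05 mg/dl), which keeps every trajectory strictly inside
  its band: with baseline ≥ 0.6 the stage-1 plateau lies in
  [1.53, 1.87]× and cannot cross 2.0×, so stage recovery is exact by
  construction, and the same bound shows stage-0 noise (max ratio
  ≈ 1.4, max 48-h rise 0.2) can never cross an AKI trigger.
* **Urine output** hourly at 1.0 ml/kg/h; a configurable fraction of
  staged patients (default 0.3) express their stage through Uo instead:
  0.35 ml/kg/h for 8 h (stage 1), 0.35 for 14 h (stage 2), 0.20 for
  26 h (stage 3), volumes charted exactly. Both criteria are therefore
  exercised independently.
* **Diagnoses**: catalogue codes are independent Bernoulli draws at
  their marginal prevalence. A planted pair `(A, B, lift)` fixes the
  joint at $p_{AB} = \mathrm{lift}\cdot p_A p_B$ and samples B
  conditional on A, after checking that all four 2×2 cells lie in
  [0, 1] (violations raise an error naming the pair). Pairs sharing an
  item are planted sequentially, conditioning on the already realised
  item, which preserves each pair's target lift in expectation. The AKI
  margin comes from the truth stage, so planted AKI associations and
  KDIGO labels agree.
* **Randomness**: a single root seed drives one generation stream in
  fixed order. The original design sketch called for per-patient
  substreams to allow parallel generation; generation is fast enough in
  R that we kept one vectorised stream — determinism (byte-identical
  cohorts per seed) is what matters and is tested.

What the generator does **not** emulate: correlation between
demographics and stage, multi-admission structure, chapter-level code
co-occurrence beyond the planted pairs, charting irregularity, unit
mixups. A green recovery test therefore establishes that the pipeline is
*correct on its definitions* and recovers known signal — not that it
reproduces any real cohort's headline counts, which depend on
credentialed data and database versions and are out of scope by design.

## 7. Numerical conventions and degenerate inputs

* Support comparisons use `count ≥ min_sup · N − 1e−9` to keep exact
  fractions (8 of 100 at 8%) inside the threshold despite floating
  arithmetic; kulc and lift identities hold to machine precision and are
  asserted at 1e−14.
* Empty series, empty cohorts, hub-only networks, all-zero consistency
  tables and zero-patient stages all return well-formed empty objects
  (with warnings where information was expected), never errors.
* Code-range comparisons (V01–Y98, chapter and organ lookups) use
  C-collation string comparison on 3-character categories, which is
  exact for uppercase alphanumerics.
* Ties anywhere in ranking (network cut, output order, top-3 crosstalk
  pairs) break lexicographically on the partner code so that repeated
  runs serialise identically.

## 8. Known limitations

* The ICD-9 mapping ignores GEM approximate/combination flags; it is a
  plain expansion table.
* The urine bucketing assumes each charted row is the volume accumulated
  in its clock hour; true event-time integration over irregular
  intervals is not attempted.
* Creatinine units are mg/dl only; `scr_umol_to_mgdl()` converts SI-unit
  series (constant 88.4), but there is no auto-detection.
* The stage-3 risk-factor rule inherits the instability of set
  differences near mining thresholds: a pair hovering at `min_sup` can
  enter or leave the stage-1 list and flip a "unique to stage 3"
  verdict. This is inherent to the published definition.
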