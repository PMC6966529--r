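---
title: "Methods: the somatic variant classification workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the somatic variant classification workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoclassify)
```

## The problem and the model

Targeted NGS of a tumour sample yields calls whose relevance spans the
whole range from sequencing artefact to established driver. The package
implements a two-level classification: a tumour-independent *biological*
class on the five-level ACMG scale, assigned by a deterministic rule
pipeline, and a tumour-dependent *clinical* tier on the four-level ACMG/AMP
scale, constrained by the biological class. The design premise is that the
biological step can and should be mechanised: every decision is a
threshold, a set-membership test, or a table lookup, so two laboratories
running the same inputs must get the same classes. Consequently the engine
is written as a pure function of (record, evidence snapshot, knowledge
tables, configuration) with an ordered rule trail in every result.

The pipeline order is fixed: technical filter, population frequency,
gene-specific exceptions, hotspot match, clear-LoF routing, scoring table.
The first stage that produces a class ends the run. Two properties are
maintained across all stages and checked property-style in the tests: a
variant matching a consensus-pathogenic-variant (CPV) entry is always
finally Pathogenic (no exception handler may demote it), and evidence
absence never moves a variant *toward* pathogenicity.

## Parameters that matter

All thresholds live in `lab_config()`, are echoed into decision details and
the run manifest, and are fractions in [0, 1] internally (reports render
percentages — keeping one internal unit avoids double-scaling bugs).

* `vaf_min = 0.05`, `depth_min = 500` — the validated detection limits of a
  typical panel ("down to 5% with at least several hundred reads").
  `site_overrides` relaxes them per validated target; the packaged fixture
  configuration carries the classic example, BRAF V600E down to 1% on 300
  reads for hairy cell leukaemia.
* `maf_likely_benign = 0.001`, `maf_benign = 0.01`,
  `min_allele_number = 2000` — the ethnic-specific population-frequency
  rule. The bounds are deliberately asymmetric: MAF strictly above 0.1% in
  an eligible population (≥ 2000 interrogated alleles) is Likely Benign,
  ≥ 1% Benign. A MAF of exactly 0.1% is *not* benign; the lower bound is
  encoded strictly and tested at the boundary.
* `germline_vaf_bands = [0.40, 0.60] and [0.90, 1.00]` — "close to 50% /
  100%" is nowhere quantified in the consensus rules, so the bands are
  configuration with these defaults. They feed only a review flag and the
  regional-benign rescue; they never change a class on their own.
* `recurrence_fraction = 0.10`, `recurrence_blacklist` — the recurrent
  artefact heuristic ("seen in ≥ 10% of samples") is panel-specific, so it
  is implemented as a lab-maintained blacklist plus a run-scoped fraction;
  hotspot-listed variants are exempt.
* `str_stutter_thresholds` — per-site validated stutter VAFs; a call at or
  below its site threshold is an artefact, above it a true variant that
  then follows the normal workflow (ASXL1 c.1934dup being the canonical
  case: stutter up to ~10%, true Likely Pathogenic variant above).
* `cebpa_bzip_interval = [278, 358]` — the source rules name the CEBPA
  bZIP domain without coordinates. The default covers the basic region
  plus leucine zipper of the CEBPA protein on its reference transcript and
  is configurable; labs using a different domain annotation can replace it.
* `brca_last_exon = (BRCA1: 24, BRCA2: 27)` — records do not carry
  transcript exon counts, so last-exon detection for the BRCA handler
  compares the annotated exon against these configured transcript last
  exons.

## The scoring table

Non-clear-LoF variants (missense, in-frame indels — plus clear-LoF variants
in genes whose tumour-suppressor/oncogene role is unknown, which are routed
here with a review flag) are scored on four parameters in half-unit
arithmetic with no rounding: COSMIC entry count of the exact amino-acid
change (0/1/2 with tumour-category-specific bands, because solid tumours
dominate COSMIC), both in-silico predictors damaging (+0.5 or 0),
functional-study verdict (+0.5/0/−1) and genomic-database verdict
(+0.5/0/−1). The COSMIC band boundaries follow the explicit printed
thresholds (solid: +2 at ≥ 50, 0 at ≤ 10; haematological: +2 at ≥ 10, 0 at
≤ 5), making the +1 bands strictly open intervals. Total ≥ 2 is Likely
Pathogenic, < 2 VUS; the maximal 3.5 upgrades to Pathogenic only for genes
absent from the CPV lists (for listed genes, the lists themselves are the
authority on Pathogenic). Unknown evidence always scores 0. Strongly
negative totals (≤ −1) still yield VUS, not Likely Benign: the published
rule defines only the ≥ 2 boundary, and we do not extrapolate a benign
boundary it never states.

`enumerate_scoring_grid()` closes the table over all 3 × 2 × 3 × 3 = 54
combinations per tumour category and is the brute-force oracle for the
score-algebra tests (max 3.5, min −2, boundary exactly at 2,
monotonicity).

## Exceptions and their ordering

Handlers run after the population step and before the hotspot box, with
gene-specific rules beating consequence-generic ones. Ordering subtleties
that were genuinely open, and how they were decided:

* *CPV precedence.* The TP53 handler and the regional-benign rescue check
  the CPV list first and stand aside on a hit, so no handler can demote a
  hotspot. The CALR/NPM1/MET handlers return Pathogenic themselves — the
  same class their CPV entries would produce — so precedence is moot there.
* *TP53 clear LoF.* Frameshift and nonsense TP53 variants take the general
  tumour-suppressor LoF route (Likely Pathogenic) without a review flag;
  the dedicated-database consensus route is reserved for the plethora of
  non-evident TP53 changes (missense, in-frame, synonymous). Core splice
  TP53 variants are Likely Pathogenic directly — deliberately not
  Pathogenic, since they are functionally equivalent to frameshifts.
* *TP53 database disagreement.* When the two dedicated databases disagree,
  or either verdict is missing, there is no published tie rule; the
  handler falls through to the general workflow with `manual_review`
  rather than guessing.
* *TP53 synonymous.* Synonymous TP53 changes are exempt from the Box-1
  synonymous drop so the handler can consult the databases; with no
  verdicts available they end as VUS with `manual_review`.
* *BRCA1/2.* Clear LoF is Pathogenic outright except in the configured
  last exon, where — like all other BRCA variants — the dedicated database
  verdict decides (mapped conservatively: pathogenic-like verdicts give
  Likely Pathogenic, benign-like Likely Benign, absent verdicts fall
  through with review).

## Hotspot matching semantics

CPV cells are transcribed into typed entries: exact residue + allowed
alternates, protein region (`X-Y`: the whole reported change must lie
inside the closed interval) or exact span (`X_Y`: start and end must match
exactly), exon-level events (keyed on annotated exon and event class,
following the listed transcript's exon numbering), blanket clear-LoF
entries, and splice events. When several entries match, specificity wins
in the fixed order exact > region > exon event > clear LoF > splice, making
the result independent of file order. An `any missense` position matches
any substitution but not a nonsense change at that position — the list
names missense variants only, and a stop at the position would be a
different biological event. Genes listed with no consensus variants
(`none` rows) contribute no entries but count as CPV-listed, which matters
for the scoring table's Pathogenic upgrade rule.

## Numerical and degenerate-input choices

Half-unit score arithmetic is exact in floating point (all values are
multiples of 0.5), so score equality tests are exact, not
tolerance-based. All interval checks are closed unless stated otherwise;
the two strict bounds in the system (MAF > 0.1%, COSMIC +1 bands) are
strict because the printed rules make them so. Empty population snapshots,
unknown genes in the role table, and variants absent from the evidence
snapshot all degrade toward VUS plus flags — never an error and never a
pathogenic default. Records missing VAF or depth are hard errors at the
technical filter: quality gates are mandatory. A record whose annotation
cannot be joined is skipped and counted in the manifest, because one bad
row must not abort a diagnostic run.

## The synthetic fixture generator

`generate_fixtures()` emulates what a lab's annotation pipeline would hand
the engine: annotated calls, per-variant ethnic population frequencies,
and offline database evidence (COSMIC counts, predictor verdicts,
functional and database verdicts, TP53/BRCA database classes), plus the
lab-side observation log and override table. Fifty branches cover every
rule the engine can emit; each branch contributes its canonical example
with the exact published numbers and seeded randomized copies drawn
uniformly inside the branch-legal interval (VAF, depth, and where the
branch turns on them, MAF/allele number/COSMIC count). Expected classes
are fixed by construction, never by running the engine, so fixture tests
cannot self-confirm. The default batch is 250 cases and classifies in a
few seconds; the test suite uses 1–5 cases per branch depending on what a
test needs.

What the generator does *not* emulate — and therefore what passing fixture
tests cannot show — includes: read-level artefact structure (strand bias,
alignment error), realistic mutational signatures and co-occurrence
patterns, annotation disagreement between pipelines (one HGVS string per
variant is assumed correct), transcript-version drift between knowledge
tables and annotations, and the judgement embedded in curated evidence
(COSMIC counts and database verdicts are inputs, not re-derived). Genomic
coordinates are synthetic and internally consistent only.

## Known limitations

* The CPV lists and role table are snapshots transcribed from the
  consensus tables; real deployments must version and extend them
  (replacement TSVs with the same schema are accepted everywhere).
* Splice assessment covers only the −2/−1/+1/+2 core positions (plus the
  MET exon-14 and BRCA special cases); no in-silico splice prediction.
* Clinical evidence levels (A–D) are curation input; the package enforces
  only the hard tier constraints and the declarative co-occurrence rules.
* The classification store is a local, single-lab history; cross-lab
  repository federation is out of scope.
* HGVS support covers the small-variant grammar that panel reporting
  produces (substitutions, indels, dup, frameshift); no inversions,
  extensions, or allele syntax.
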