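# oncoclassify

Deterministic, auditable classification of somatic variants from targeted
NGS panels, for molecular diagnostic laboratories reporting on solid and
haematological tumours.

Diagnostic labs receive, per sample, a list of variant calls that must be
classified before anything can be reported to a clinician. That happens at
two levels. The **biological** level asks, independently of the tumour type,
whether the variant can contribute to tumorigenesis; it uses the five ACMG
classes *Benign < Likely Benign < VUS < Likely Pathogenic < Pathogenic*. The
**clinical** level then asks what the variant means for *this* patient's
tumour, using the four-tier ACMG/AMP system (Tier I strong, Tier II
potential, Tier III unknown clinical significance, Tier IV benign). Done by
hand, the biological step is notoriously subjective; this package implements
it as a fixed rule engine so the same variant always gets the same class,
with a complete audit trail of every rule that fired.

## The workflow

Each call runs through a fixed pipeline; the first stage that yields a class
terminates it:

1. **Technical filter** — drop intronic calls outside the AG/GT core splice
   positions (−2, −1, +1, +2), stand-alone synonymous changes (kept for
   TP53), recurrent technical artefacts, STR/homopolymer calls at or below
   their validated stutter VAF, and calls under the validated gates
   (defaults: VAF ≥ 5%, depth ≥ 500; per-site overrides for validated
   low-frequency targets such as BRAF V600E in hairy cell leukaemia).
   Sub-threshold hotspot candidates are flagged for re-analysis rather than
   silently lost.
2. **Population frequency** — a variant whose ethnic-specific minor allele
   frequency exceeds 0.1% in any population with ≥ 2000 interrogated
   alleles is Likely Benign; ≥ 1% is Benign. Population-negative calls at
   VAF ≈ 50%/100% are flagged as germline suspects.
3. **Exceptions** — gene-specific rules that bypass the general workflow:
   TP53 (dedicated database consensus; core splice → Likely Pathogenic),
   BRCA1/2 (clear LoF → Pathogenic; last-exon LoF and everything else by
   database verdict), CALR exon-9 and NPM1 exon-11 out-of-frame indels and
   MET exon-14 splice variants (consensus pathogenic variants → Pathogenic),
   CEBPA bZIP in-frame indels (→ Likely Pathogenic), and a
   regional-rare-benign rescue based on the lab's own observation history.
4. **Hotspot (CPV) match** — variants on the curated consensus pathogenic
   variant lists (packaged, per tumour category) are Pathogenic. Matching is
   by exact residue/alternate set for point changes and structural
   (region containment, exact span, or exon + event class) for indels.
5. **Clear LoF routing** — frameshift, nonsense, and core splice variants
   are Likely Pathogenic in a tumour suppressor, VUS in an oncogene.
6. **Scoring table** — everything else is scored on four parameters:
   COSMIC entry count (solid: ≥50 → +2, 10 < n < 50 → +1, ≤10 → 0;
   haematological: ≥10 → +2, 5 < n < 10 → +1, ≤5 → 0), SIFT +
   MutationTaster (+0.5 only if both damaging), functional studies
   (+0.5 / 0 / −1), and genomic databases (+0.5 / 0 / −1). Total ≥ 2 →
   Likely Pathogenic, otherwise VUS; the maximal 3.5 upgrades to Pathogenic
   for genes not on a CPV list. Curated overrides may raise (never lower) a
   class.

Tiering then enforces the hard clinical constraints: (Likely) Benign ⇒ Tier
IV and never reported; VUS ⇒ Tier III, reported only in a segregated,
disclaimed annex; (Likely) Pathogenic ⇒ Tier I/II/III according to the
curated evidence level (A–D) supplied per tumour type.

## Worked example

```r
library(oncoclassify)

rec <- variant_record(
  sample_id = "P-001", chrom = "chr7", pos = 55191822, ref = "T", alt = "G",
  vaf = 0.22, depth = 1460, gene = "EGFR", transcript = "NM_005228.4",
  cdna_hgvs = "c.2573T>G", protein_hgvs = "p.(Leu858Arg)",
  consequence = "missense", exon = 21, tumour_category = "solid",
  tumour_type = "lung adenocarcinoma")

classify_record(rec, kb = load_kb())
#> <classification_result> EGFR c.2573T>G p.(Leu858Arg)
#>   class: Pathogenic
#>   BOX1-FILTER          pass               VAF 0.220 >= 0.050, depth 1460 >= 500
#>   BOX2-POPFREQ         none               no eligible population above the Likely Benign bound
#>   BOX3-CPV             Pathogenic         matches CPV entry 'L858R'
```

The call passed the technical gates, is absent from the population
databases, and matches the EGFR L858R hotspot entry, so it is biologically
Pathogenic. With level-A clinical evidence in lung adenocarcinoma it becomes
Tier I:

```r
assign_tier("Pathogenic", "A")$tier
#> [1] "I"
```

A non-hotspot variant is scored instead — EGFR S768I with 265 COSMIC
entries and both predictors damaging:

```r
score_variant(evidence_bundle(cosmic_count = 265, sift_damaging = "yes",
                              mutationtaster_damaging = "yes"), "solid")
#> <score_breakdown> COSMIC +2, in-silico +0.5, functional +0, genomic db +0 => total +2.5
```

2.5 ≥ 2, so the scoring table classifies it Likely Pathogenic.

Batch runs over TSV (or minimal VCF) inputs, with results, review queue,
re-analysis candidates and a reproducibility manifest, go through
`classify_batch()`; `inst/cli/classify.R` is a thin command-line wrapper.
`generate_fixtures()` builds a fully synthetic annotated batch (250 cases
covering every rule, with construction-time truth labels) for offline
testing and validation.

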