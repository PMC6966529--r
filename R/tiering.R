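# Clinical four-tier mapping (ACMG/AMP) over biological classes. The
# evidence level (A-D) of a variant in a tumour type is clinical curation and
# arrives as input; only the hard consistency constraints are enforced here.

TIERS <- c("I", "II", "III", "IV")
EVIDENCE_LEVELS <- c("A", "B", "C", "D", "none")

#' Assign the clinical tier of a variant
#'
#' The constrained mapping: a (Likely) Benign variant is always Tier IV and
#' cannot carry clinical evidence; a VUS is always Tier III; a (Likely)
#' Pathogenic variant is Tier I with level A/B evidence, Tier II with level
#' C/D, and Tier III (unknown clinical significance) without evidence for
#' the tumour type.
#'
#' @param bio_class one of the five biological class labels.
#' @param evidence_level `"A"`, `"B"`, `"C"`, `"D"` or `"none"` — the
#'   curated clinical evidence level of the variant in the tumour type.
#' @return list of class `tier_assignment`: `tier` (`"I"`..`"IV"`),
#'   `evidence_level`, `rationale`.
#' @export
assign_tier <- function(bio_class, evidence_level = "none") {
  if (!is_bio_class(bio_class)) stop("unknown biological class: ", bio_class)
  evidence_level <- match.arg(evidence_level, EVIDENCE_LEVELS)
  if (bio_class %in% c("Benign", "LikelyBenign")) {
    if (evidence_level != "none") {
      stop("a (Likely) Benign variant cannot carry clinical evidence level ",
           evidence_level)
    }
    tier <- "IV"
    rationale <- "(Likely) Benign variants are Tier IV and are not reported"
  } else if (bio_class == "VUS") {
    tier <- "III"
    rationale <- "a VUS is always Tier III"
  } else if (evidence_level %in% c("A", "B")) {
    tier <- "I"
    rationale <- sprintf("level %s evidence: strong clinical significance",
                         evidence_level)
  } else if (evidence_level %in% c("C", "D")) {
    tier <- "II"
    rationale <- sprintf("level %s evidence: potential clinical significance",
                         evidence_level)
  } else {
    tier <- "III"
    rationale <- "no clinical evidence in this tumour type: unknown clinical significance"
  }
  structure(list(tier = tier, evidence_level = evidence_level,
                 rationale = rationale), class = "tier_assignment")
}

#' Load conditional tier rules
#'
#' Declarative co-occurrence rules: some variants (e.g. a resistance variant)
#' are Tier I only in the presence of a co-occurring CPV hit in the same
#' gene, else Tier III.
#'
#' @param path TSV with columns `gene`, `change` (one-letter shorthand or
#'   cDNA HGVS), `condition` (currently `co_occurring_cpv_same_gene`),
#'   `tier_if_true`, `tier_if_false`.
#' @return data frame of class `tier_rules`.
#' @export
load_tier_rules <- function(path) {
  tab <- read_kb_tsv(path)
  need <- c("gene", "change", "condition", "tier_if_true", "tier_if_false")
  stopifnot(all(need %in% names(tab)))
  ok <- tab$condition == "co_occurring_cpv_same_gene" &
    tab$tier_if_true %in% TIERS & tab$tier_if_false %in% TIERS
  if (!all(ok)) stop("malformed conditional tier rule rows: ",
                     paste(which(!ok), collapse = ", "))
  class(tab) <- c("tier_rules", "data.frame")
  tab
}

#' Path to the packaged conditional tier rules
#' @return TSV path (ships with the EGFR resistance-variant example rule).
#' @export
default_tier_rules_path <- function() {
  system.file("extdata", "kb", "tier_rules.tsv", package = "oncoclassify",
              mustWork = TRUE)
}

#' Apply conditional tier rules to a sample's tiered results
#'
#' For each rule matching a variant in the sample, the tier is set to
#' `tier_if_true` when the same sample carries another variant of the same
#' gene whose deciding rule was a CPV hit, else `tier_if_false`.
#'
#' @param tiered data frame with at least `sample_id`, `gene`, `cdna_hgvs`,
#'   `protein_shorthand`, `deciding_rule`, `tier`.
#' @param rules a `tier_rules` table.
#' @return `tiered` with adjusted `tier` and a `tier_condition` note column.
#' @export
apply_tier_rules <- function(tiered, rules) {
  tiered$tier_condition <- tiered$tier_condition %||% ""
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    hit <- tiered$gene == r$gene &
      (tiered$cdna_hgvs == r$change |
         (!is.na(tiered$protein_shorthand) &
            tiered$protein_shorthand == r$change))
    for (j in which(hit)) {
      co <- tiered$sample_id == tiered$sample_id[j] &
        tiered$gene == r$gene &
        tiered$cdna_hgvs != tiered$cdna_hgvs[j] &
        grepl("CPV|EXC-MET|EXC-CALR|EXC-NPM1", tiered$deciding_rule)
      cond <- any(co)
      tiered$tier[j] <- if (cond) r$tier_if_true else r$tier_if_false
      tiered$tier_condition[j] <- sprintf(
        "conditional: co-occurring CPV in %s %s", r$gene,
        if (cond) "present" else "absent")
    }
  }
  tiered
}

`%||%` <- function(a, b) if (is.null(a)) b else a
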