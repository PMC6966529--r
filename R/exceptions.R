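# Gene-specific exception handlers. A small set of genes and variants must
# not go through the general workflow because it would misclassify them;
# these handlers run before the hotspot/LoF/scoring boxes. Gene-specific
# rules beat consequence-generic ones, and no handler ever demotes a variant
# that matches a CPV entry (handlers that could interfere check the CPV list
# first and stand aside).

exception_outcome <- function(class, rule_id, detail, flags = character()) {
  list(class = class, rule_id = rule_id, detail = detail, flags = flags)
}

#' Apply the exception handlers
#'
#' Evaluates, in order: CALR exon-9 out-of-frame indels and NPM1 exon-11
#' out-of-frame insertions (consensus pathogenic variants, not ordinary
#' frameshifts — Pathogenic); MET exon-14 splice variants (CPV — Pathogenic);
#' the TP53 handler (CPV hotspots stand aside for Box 3; core splice
#' variants are Likely Pathogenic; frameshift/nonsense take the ordinary
#' tumour-suppressor LoF route; otherwise the consensus of the two
#' dedicated TP53 databases is used when both agree, and disagreement or
#' missing verdicts fall through to the general workflow with a
#' manual-review flag); the BRCA1/2 handler (clear LoF is always Pathogenic,
#' except in the configured last exon where — like all other BRCA variants —
#' the dedicated database verdict decides, with manual review when absent);
#' CEBPA in-frame indels in the bZIP domain (Likely Pathogenic); and the
#' regional rare-benign rescue (Likely Benign with a follow-up flag, never
#' for CPV matches).
#'
#' @param record a [variant_record()] that passed the technical filter.
#' @param evidence the record's [evidence_bundle()].
#' @param kb a `knowledge_base` ([load_kb()]).
#' @param config a [lab_config()].
#' @param observation_log optional lab observation history (for the regional
#'   benign check).
#' @return `NULL` when no handler applies, otherwise a list with `class` (a
#'   biological class label, or `NULL` for flag-only fall-through),
#'   `rule_id`, `detail` and `flags`.
#' @export
apply_exceptions <- function(record, evidence, kb, config = lab_config(),
                             observation_log = NULL) {
  stopifnot(inherits(record, "variant_record"),
            inherits(evidence, "evidence_bundle"))
  cpv <- kb_for(kb, record$tumour_category)
  ch <- record$protein_change

  # (c) CALR exon 9 out-of-frame indel: the typical type I (52-bp del) and
  # type II (5-bp ins) driver events — CPVs, not frameshifts
  if (record$gene == "CALR" && identical(record$exon, 9L) &&
      record$consequence == "frameshift") {
    return(exception_outcome("Pathogenic", "EXC-CALR-EX9",
                             "out-of-frame indel in CALR exon 9 is a CPV"))
  }
  # (d) NPM1 exon 11 out-of-frame insertion
  if (record$gene == "NPM1" && identical(record$exon, 11L) &&
      record$consequence == "frameshift" && indel_direction(record) == "ins") {
    return(exception_outcome("Pathogenic", "EXC-NPM1-EX11",
                             "out-of-frame insertion in NPM1 exon 11 is a CPV"))
  }
  # (f) MET exon 14 splice variants are CPVs
  if (record$gene == "MET" && record$consequence == "splice_core" &&
      identical(record$exon, 14L)) {
    return(exception_outcome("Pathogenic", "EXC-MET-EX14",
                             "MET exon 14 splice variant (exon skipping CPV)"))
  }
  # (a) TP53
  if (record$gene == "TP53") {
    if (!is.null(match_cpv(record, cpv))) return(NULL)  # Box 3 decides
    if (record$consequence == "splice_core") {
      return(exception_outcome(
        "LikelyPathogenic", "EXC-TP53-SPLICE",
        "TP53 core splice variant; treated like frameshift, Likely Pathogenic"))
    }
    # frameshift/nonsense are clear LoF in a tumour suppressor; the general
    # Box 4 route classifies them — the database consensus is for the
    # plethora of non-evident TP53 changes
    if (record$consequence %in% c("frameshift", "nonsense")) return(NULL)
    iarc <- evidence$tp53_iarc_class
    seshat <- evidence$tp53_seshat_class
    if (!is.na(iarc) && !is.na(seshat) && identical(iarc, seshat)) {
      return(exception_outcome(iarc, "EXC-TP53-DB",
                               sprintf("consensus class of both TP53 databases: %s",
                                       iarc)))
    }
    detail <- if (is.na(iarc) || is.na(seshat)) {
      "TP53 database class missing"
    } else {
      sprintf("TP53 databases disagree (%s vs %s)", iarc, seshat)
    }
    return(exception_outcome(NULL, "EXC-TP53-DB",
                             paste0(detail, "; general workflow with review"),
                             flags = "manual_review"))
  }
  # (b) BRCA1 / BRCA2
  if (record$gene %in% c("BRCA1", "BRCA2")) {
    last_exon <- config$brca_last_exon[[record$gene]]
    in_last_exon <- !is.na(record$exon) && !is.null(last_exon) &&
      record$exon == last_exon
    if (is_clear_lof(record) && !in_last_exon) {
      return(exception_outcome("Pathogenic", "EXC-BRCA-LOF",
                               "clear LoF in BRCA1/2 is always Pathogenic"))
    }
    verdict <- evidence$brca_db_verdict
    if (!is.na(verdict) && verdict != "not_described") {
      cls <- if (verdict == "likely_pathogenic_or_pathogenic") {
        "LikelyPathogenic"
      } else "LikelyBenign"
      return(exception_outcome(cls, "EXC-BRCA-DB",
                               sprintf("BRCA database verdict: %s", verdict)))
    }
    return(exception_outcome(NULL, "EXC-BRCA-DB",
                             "no BRCA database verdict; general workflow with review",
                             flags = "manual_review"))
  }
  # (e) CEBPA bZIP in-frame indel
  if (record$gene == "CEBPA" && !is.null(ch) && is_indel_kind(ch$kind)) {
    span <- c(ch$position,
              if (is.na(ch$end_position)) ch$position else ch$end_position)
    bzip <- config$cebpa_bzip_interval
    if (span[1L] >= bzip[1L] && span[2L] <= bzip[2L]) {
      return(exception_outcome(
        "LikelyPathogenic", "EXC-CEBPA-BZIP",
        sprintf("in-frame indel within CEBPA bZIP domain (AA %d-%d)",
                bzip[1L], bzip[2L])))
    }
  }
  # (g) regional rare benign variant (never demotes a CPV match)
  if (!is.null(observation_log) && is.null(match_cpv(record, cpv)) &&
      regional_benign_check(variant_key(record), observation_log, config)) {
    return(exception_outcome(
      "LikelyBenign", "EXC-REGIONAL-BENIGN",
      sprintf("seen in >= %d region-specific samples at heterozygous VAF",
              config$regional_benign_min_samples),
      flags = "regional_benign_candidate"))
  }
  NULL
}
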