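# The four-parameter scoring table for non-clear-LoF variants (workflow
# Box 5), in half-unit arithmetic: COSMIC entry count (0/1/2), in-silico
# predictions (0/0.5), functional studies (-1/0/0.5), genomic databases
# (-1/0/0.5). Total >= 2 is Likely Pathogenic, < 2 is VUS; the maximal total
# of 3.5 upgrades to Pathogenic for genes not on a CPV list.

#' COSMIC-entry parameter score
#'
#' Entry counts of the exact amino-acid change, thresholded by tumour
#' category because solid tumours are heavily over-represented in COSMIC:
#' solid scores +2 at >= 50 entries, 0 at <= 10, +1 in between;
#' haematological scores +2 at >= 10, 0 at <= 5, +1 in between. An unknown
#' count scores 0 — absent evidence is never rewarded.
#'
#' @param count non-negative entry count, or `NA` for unknown.
#' @param tumour_category `"solid"` or `"haematological"`.
#' @return 0, 1 or 2.
#' @export
cosmic_score <- function(count, tumour_category) {
  tumour_category <- match.arg(tumour_category, TUMOUR_CATEGORIES)
  if (is.na(count)) return(0)
  if (count < 0) stop("cosmic count must be non-negative")
  th <- if (tumour_category == "solid") c(hi = 50, lo = 10) else c(hi = 10, lo = 5)
  if (count >= th[["hi"]]) 2 else if (count > th[["lo"]]) 1 else 0
}

#' In-silico prediction parameter score
#'
#' +0.5 only when *both* tools (SIFT and MutationTaster) predict a damaging
#' or deleterious effect; any other combination — including one tool missing
#' — scores 0. There is no negative score for this parameter.
#'
#' @param sift,mutationtaster `"yes"`, `"no"` or `"unknown"`.
#' @return 0 or 0.5.
#' @export
insilico_score <- function(sift, mutationtaster) {
  sift <- match.arg(sift, TRI_STATE)
  mutationtaster <- match.arg(mutationtaster, TRI_STATE)
  if (sift == "yes" && mutationtaster == "yes") 0.5 else 0
}

functional_score <- function(functional_evidence) {
  switch(match.arg(functional_evidence, FUNCTIONAL_LEVELS),
         harmful = 0.5, not_reported = 0, shown_benign = -1)
}

genomicdb_score <- function(genomic_db_verdict) {
  switch(match.arg(genomic_db_verdict, GENOMICDB_LEVELS),
         likely_pathogenic_or_pathogenic = 0.5, not_described = 0,
         likely_benign_or_benign = -1)
}

#' Score a variant on the four-parameter table
#'
#' Applies the four parameter scorers to an evidence bundle and sums them
#' exactly (half-unit arithmetic, no rounding). Intended for non-clear-LoF
#' variants (missense, in-frame indels) and for clear-LoF variants in genes
#' of unknown role.
#'
#' @param evidence an [evidence_bundle()].
#' @param tumour_category `"solid"` or `"haematological"`.
#' @return object of class `score_breakdown` with the four component scores
#'   and `total` in `[-2, 3.5]`.
#' @export
score_variant <- function(evidence, tumour_category) {
  stopifnot(inherits(evidence, "evidence_bundle"))
  parts <- c(
    cosmic = cosmic_score(evidence$cosmic_count, tumour_category),
    insilico = insilico_score(evidence$sift_damaging,
                              evidence$mutationtaster_damaging),
    functional = functional_score(evidence$functional_evidence),
    genomicdb = genomicdb_score(evidence$genomic_db_verdict))
  structure(list(cosmic_score = parts[["cosmic"]],
                 insilico_score = parts[["insilico"]],
                 functional_score = parts[["functional"]],
                 genomicdb_score = parts[["genomicdb"]],
                 total = sum(parts)),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<score_breakdown> COSMIC %+g, in-silico %+g, ",
                     "functional %+g, genomic db %+g => total %+g\n"),
              x$cosmic_score, x$insilico_score, x$functional_score,
              x$genomicdb_score, x$total))
  invisible(x)
}

#' Class from a scoring-table total
#'
#' Total >= 2 is Likely Pathogenic; below 2 is VUS. For genes *not* on a CPV
#' list, the maximal total of 3.5 upgrades the class to Pathogenic. A curated
#' override record may raise (never lower) the class further.
#'
#' @param score a `score_breakdown`.
#' @param gene_is_cpv_listed is the gene on a CPV list (incl. `none` rows)?
#' @param override optional override record (list with at least `new_class`)
#'   from a curated override table; only upward overrides are accepted.
#' @return a list: `class` (biological class label) and `overruled`
#'   (logical).
#' @export
scoring_class <- function(score, gene_is_cpv_listed = TRUE, override = NULL) {
  stopifnot(inherits(score, "score_breakdown"))
  cls <- if (score$total >= 2) "LikelyPathogenic" else "VUS"
  if (!gene_is_cpv_listed && score$total == 3.5) cls <- "Pathogenic"
  overruled <- FALSE
  if (!is.null(override)) {
    new_class <- override$new_class
    if (!is_bio_class(new_class)) stop("override has no valid new_class")
    if (bio_class(new_class) < bio_class(cls)) {
      stop("overrides may only raise a class: ", cls, " -> ", new_class,
           " rejected")
    }
    if (bio_class(new_class) > bio_class(cls)) {
      cls <- new_class
      overruled <- TRUE
    }
  }
  list(class = cls, overruled = overruled)
}

#' Is a variant a clear loss-of-function change? (workflow Box 4 gate)
#'
#' Clear LoF means frameshift, nonsense, or AG/GT core splice-site variant.
#' Missense and in-frame indels are "non-evident" and go to the scoring
#' table instead.
#'
#' @param record a [variant_record()].
#' @return logical.
#' @export
is_clear_lof <- function(record) {
  stopifnot(inherits(record, "variant_record"))
  record$consequence %in% c("frameshift", "nonsense", "splice_core")
}

#' Classify a clear LoF variant by gene role (workflow Box 4)
#'
#' A clear LoF change in a tumour suppressor causes haploinsufficiency and is
#' Likely Pathogenic — including in the last exon, since the impact of
#' nonsense-mediated decay on cancer genes is currently unpredictable. A
#' clear LoF change in an oncogene cannot activate it and is a VUS. Never
#' returns Pathogenic (driver status of LoF variants is rarely functionally
#' proven) or Benign.
#'
#' @param record a [variant_record()] with [is_clear_lof()] `TRUE`.
#' @param role `"tumour_suppressor"` or `"oncogene"` (from [lookup_role()]).
#' @return `"LikelyPathogenic"` or `"VUS"`.
#' @export
classify_lof <- function(record, role) {
  stopifnot(is_clear_lof(record))
  role <- match.arg(role, c("tumour_suppressor", "oncogene"))
  if (role == "tumour_suppressor") "LikelyPathogenic" else "VUS"
}

#' Hotspot classification (workflow Box 3)
#'
#' A variant matching a CPV entry is Pathogenic, full stop. Returns the class
#' with the matched entry, or `NULL` when no entry matches.
#'
#' @param record a [variant_record()].
#' @param kb a `knowledge_base` (or a single `cpv_list`).
#' @return `NULL`, or a list `class = "Pathogenic"`, `entry` (matched row),
#'   `label` (the source cell text).
#' @export
classify_cpv <- function(record, kb) {
  cpv <- if (inherits(kb, "knowledge_base")) {
    kb_for(kb, record$tumour_category)
  } else kb
  stopifnot(inherits(cpv, "cpv_list"))
  entry <- match_cpv(record, cpv)
  if (is.null(entry)) return(NULL)
  list(class = "Pathogenic", entry = entry, label = entry$label)
}
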