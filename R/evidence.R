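# Offline evidence snapshots: population frequencies and curated database
# verdicts, one row per variant. All evidence is supplied as flat tables; no
# live database query is ever made, so classification degrades to VUS (never
# crashes) when a variant has no coverage in the snapshot.

TRI_STATE <- c("yes", "no", "unknown")
FUNCTIONAL_LEVELS <- c("harmful", "not_reported", "shown_benign")
GENOMICDB_LEVELS <- c("likely_pathogenic_or_pathogenic", "not_described",
                      "likely_benign_or_benign")

#' Offline evidence bundle for one variant
#'
#' Snapshot of what the curated databases say about a variant: COSMIC entry
#' count, the two in-silico predictors, functional-study verdicts and genomic
#' database verdicts, plus the two TP53-specific database classes and the
#' BRCA1/2 database verdict used by the exception handlers. Every field
#' defaults to its unknown/not-described state — absence of evidence is never
#' read as evidence of pathogenicity.
#'
#' @param cosmic_count entries of the exact amino-acid change in COSMIC
#'   (`NA` = unknown).
#' @param sift_damaging,mutationtaster_damaging `"yes"`, `"no"` or
#'   `"unknown"`.
#' @param functional_evidence `"harmful"`, `"not_reported"` or
#'   `"shown_benign"` (functional studies in the literature databases).
#' @param genomic_db_verdict `"likely_pathogenic_or_pathogenic"`,
#'   `"not_described"` or `"likely_benign_or_benign"` (somatic verdict in at
#'   least one curated genomic database).
#' @param tp53_iarc_class,tp53_seshat_class biological class assigned by the
#'   two dedicated TP53 databases, or `NA`.
#' @param brca_db_verdict as `genomic_db_verdict`, for the BRCA1/2 databases,
#'   or `NA`.
#' @return object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(cosmic_count = NA_integer_,
                            sift_damaging = "unknown",
                            mutationtaster_damaging = "unknown",
                            functional_evidence = "not_reported",
                            genomic_db_verdict = "not_described",
                            tp53_iarc_class = NA_character_,
                            tp53_seshat_class = NA_character_,
                            brca_db_verdict = NA_character_) {
  if (!is.na(cosmic_count) && cosmic_count < 0) {
    stop("cosmic_count must be non-negative")
  }
  sift_damaging <- match.arg(sift_damaging, TRI_STATE)
  mutationtaster_damaging <- match.arg(mutationtaster_damaging, TRI_STATE)
  functional_evidence <- match.arg(functional_evidence, FUNCTIONAL_LEVELS)
  genomic_db_verdict <- match.arg(genomic_db_verdict, GENOMICDB_LEVELS)
  for (cl in c(tp53_iarc_class, tp53_seshat_class)) {
    if (!is.na(cl) && !cl %in% BIO_CLASSES) {
      stop("unknown biological class in TP53 evidence: ", cl)
    }
  }
  if (!is.na(brca_db_verdict) && !brca_db_verdict %in% GENOMICDB_LEVELS) {
    stop("unknown brca_db_verdict: ", brca_db_verdict)
  }
  structure(
    list(cosmic_count = as.integer(cosmic_count),
         sift_damaging = sift_damaging,
         mutationtaster_damaging = mutationtaster_damaging,
         functional_evidence = functional_evidence,
         genomic_db_verdict = genomic_db_verdict,
         tp53_iarc_class = tp53_iarc_class,
         tp53_seshat_class = tp53_seshat_class,
         brca_db_verdict = brca_db_verdict),
    class = "evidence_bundle")
}

#' Load an evidence snapshot table
#'
#' TSV keyed by `gene` + `cdna_hgvs` with one column per
#' [evidence_bundle()] field (`.` for absent).
#'
#' @param path TSV path.
#' @return data frame of class `evidence_table`.
#' @export
load_evidence <- function(path) {
  tab <- read_kb_tsv(path)
  need <- c("gene", "cdna_hgvs", "cosmic_count", "sift_damaging",
            "mutationtaster_damaging", "functional_evidence",
            "genomic_db_verdict", "tp53_iarc_class", "tp53_seshat_class",
            "brca_db_verdict")
  if (!all(need %in% names(tab))) {
    stop("evidence table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  tab$cosmic_count <- dot_na_int(tab$cosmic_count)
  for (col in setdiff(need, c("gene", "cdna_hgvs", "cosmic_count"))) {
    tab[[col]] <- dot_na_chr(tab[[col]])
  }
  class(tab) <- c("evidence_table", "data.frame")
  tab
}

#' Evidence bundle for one variant, all-unknown when not covered
#'
#' @param evidence an `evidence_table` (or `NULL`).
#' @param gene,cdna_hgvs variant key.
#' @return an `evidence_bundle`.
#' @export
get_evidence <- function(evidence, gene, cdna_hgvs) {
  if (is.null(evidence)) return(evidence_bundle())
  i <- which(evidence$gene == gene & evidence$cdna_hgvs == cdna_hgvs)
  if (!length(i)) return(evidence_bundle())
  r <- evidence[i[1L], ]
  or_default <- function(x, d) if (is.na(x)) d else x
  evidence_bundle(
    cosmic_count = r$cosmic_count,
    sift_damaging = or_default(r$sift_damaging, "unknown"),
    mutationtaster_damaging = or_default(r$mutationtaster_damaging, "unknown"),
    functional_evidence = or_default(r$functional_evidence, "not_reported"),
    genomic_db_verdict = or_default(r$genomic_db_verdict, "not_described"),
    tp53_iarc_class = r$tp53_iarc_class,
    tp53_seshat_class = r$tp53_seshat_class,
    brca_db_verdict = r$brca_db_verdict)
}

#' Per-population frequency snapshot for one variant
#'
#' Emulates the ethnic-specific minor allele frequencies (with interrogated
#' allele numbers) reported by the large population databases, plus whether
#' the variant is listed in dbSNP.
#'
#' @param populations data frame with columns `population`, `maf` (fraction),
#'   `allele_number` (non-negative integer); may have zero rows.
#' @param dbsnp_listed `"yes"`, `"no"` or `"unknown"`.
#' @return object of class `population_snapshot`.
#' @export
population_snapshot <- function(populations = data.frame(
                                  population = character(),
                                  maf = numeric(),
                                  allele_number = integer()),
                                dbsnp_listed = "unknown") {
  stopifnot(all(c("population", "maf", "allele_number") %in%
                  names(populations)))
  if (anyDuplicated(populations$population)) {
    stop("populations must be unique within a snapshot")
  }
  if (any(populations$maf < 0 | populations$maf > 1)) {
    stop("maf must be a fraction in [0,1]")
  }
  if (any(populations$allele_number < 0)) {
    stop("allele_number must be non-negative")
  }
  dbsnp_listed <- match.arg(dbsnp_listed, TRI_STATE)
  structure(list(populations = populations, dbsnp_listed = dbsnp_listed),
            class = "population_snapshot")
}

#' Load a population-frequency snapshot table
#'
#' TSV with one row per (variant, population): columns `gene`, `cdna_hgvs`,
#' `population`, `maf`, `allele_number`, `dbsnp_listed`.
#'
#' @param path TSV path.
#' @return data frame of class `popfreq_table`.
#' @export
load_popfreq <- function(path) {
  tab <- read_kb_tsv(path)
  need <- c("gene", "cdna_hgvs", "population", "maf", "allele_number",
            "dbsnp_listed")
  if (!all(need %in% names(tab))) {
    stop("population table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  tab$maf <- suppressWarnings(as.numeric(ifelse(tab$maf == ".", NA, tab$maf)))
  tab$allele_number <- dot_na_int(tab$allele_number)
  tab$dbsnp_listed <- dot_na_chr(tab$dbsnp_listed)
  class(tab) <- c("popfreq_table", "data.frame")
  tab
}

#' Snapshot for one variant, empty when not covered
#' @param popfreq a `popfreq_table` (or `NULL`).
#' @param gene,cdna_hgvs variant key.
#' @return a `population_snapshot`.
#' @export
get_snapshot <- function(popfreq, gene, cdna_hgvs) {
  if (is.null(popfreq)) return(population_snapshot())
  rows <- popfreq[popfreq$gene == gene & popfreq$cdna_hgvs == cdna_hgvs, ,
                  drop = FALSE]
  if (!nrow(rows)) return(population_snapshot())
  dbsnp <- rows$dbsnp_listed[1L]
  population_snapshot(
    populations = data.frame(population = rows$population, maf = rows$maf,
                             allele_number = rows$allele_number),
    dbsnp_listed = if (is.na(dbsnp)) "unknown" else dbsnp)
}
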