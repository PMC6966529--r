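# Clinical report rendering. Content rules enforced here: (Likely) Benign
# variants never appear anywhere in the document; VUS are segregated into
# their own disclaimed section; every reported gene carries a versioned
# transcript accession; regions that failed analysis are enumerated; and the
# report always states that the assay cannot discriminate somatic from
# germline variants.

SAMPLE_FIELDS <- c("sample_id", "sampling_date", "received_date",
                   "tumoral_stage", "anatomic_site", "sample_type",
                   "sample_procedure", "neoplastic_cell_pct",
                   "sample_quality")

VUS_DISCLAIMER <- paste(
  "The variants below are of unknown biological significance (VUS).",
  "Their contribution to the malignancy is currently unclear; they must",
  "not be used to guide clinical management.")

GERMLINE_DISCLAIMER <- paste(
  "This test cannot discriminate between somatic and germline variants.")

#' Render a clinical report from classified, tiered results
#'
#' Builds the structured report document for one sample: sample information
#' block, test results (gene, versioned transcript, cDNA and three-letter
#' protein HGVS, VAF as a percentage, optional one-letter shorthand, failed
#' regions), conclusion and interpretation (each Pathogenic / Likely
#' Pathogenic variant with its clinical tier), a segregated VUS annex with
#' disclaimer, the method block and the sign-off block.
#'
#' @param sample_info named list covering the mandatory sample fields
#'   (`sample_id`, `sampling_date`, `received_date`, `tumoral_stage`,
#'   `anatomic_site`, `sample_type`, `sample_procedure`,
#'   `neoplastic_cell_pct`, `sample_quality`).
#' @param results a `batch_result` (or its results data frame) for a single
#'   sample.
#' @param evidence_levels named character vector, variant key -> clinical
#'   evidence level (`"A"`..`"D"`); variants not named get `"none"`.
#' @param tier_rules optional `tier_rules` for conditional co-occurrence
#'   tiers.
#' @param failed_regions character vector of regions/exons/genes that could
#'   not be interpreted (always listed, even if empty the section states
#'   none).
#' @param method_info named list for the method block (sequencer, panel,
#'   reference genome, validated thresholds, consistently failing regions).
#' @param absence_statements character vector of clinically relevant negative
#'   findings (e.g. absence of a resistance variant).
#' @param validators names of the persons who interpreted and validated the
#'   report.
#' @param report_date validation date string.
#' @return object of class `report_document`.
#' @export
render_report <- function(sample_info, results, evidence_levels = NULL,
                          tier_rules = NULL, failed_regions = character(),
                          method_info = list(),
                          absence_statements = character(),
                          validators = "unsigned",
                          report_date = as.character(Sys.Date())) {
  missing_fields <- setdiff(SAMPLE_FIELDS, names(sample_info))
  if (length(missing_fields)) {
    stop("missing mandatory sample field(s): ",
         paste(missing_fields, collapse = ", "))
  }
  if (inherits(results, "batch_result")) results <- results$results
  if (length(unique(results$sample_id)) > 1L) {
    stop("a clinical report covers exactly one sample; got ",
         length(unique(results$sample_id)))
  }

  kept <- results[results$kept & results$biological_class != ".", ,
                  drop = FALSE]
  # hard content rule: (Likely) Benign variants are not reported, anywhere
  kept <- kept[!kept$biological_class %in% c("Benign", "LikelyBenign"), ,
               drop = FALSE]

  kept$protein_shorthand <- vapply(kept$protein_hgvs, function(p) {
    if (is.na(p) || p == ".") return(NA_character_)
    ch <- tryCatch(parse_protein_change(p), error = function(e) NULL)
    if (!is.null(ch) && ch$kind %in% c("substitution", "nonsense")) {
      shorthand(ch)
    } else NA_character_
  }, character(1), USE.NAMES = FALSE)

  level_of <- function(key) {
    if (!is.null(evidence_levels) && key %in% names(evidence_levels)) {
      evidence_levels[[key]]
    } else "none"
  }
  tiers <- lapply(seq_len(nrow(kept)), function(i) {
    assign_tier(kept$biological_class[i], level_of(kept$variant_key[i]))
  })
  kept$tier <- vapply(tiers, `[[`, character(1), "tier")
  kept$evidence_level <- vapply(tiers, `[[`, character(1), "evidence_level")
  kept$tier_rationale <- vapply(tiers, `[[`, character(1), "rationale")
  if (!is.null(tier_rules) && nrow(kept)) {
    kept <- apply_tier_rules(kept, tier_rules)
  }

  is_vus <- kept$biological_class == "VUS"
  structure(
    list(sample = sample_info,
         test_results = kept[, c("gene", "transcript", "cdna_hgvs",
                                 "protein_hgvs", "protein_shorthand", "vaf",
                                 "biological_class", "tier"),
                             drop = FALSE],
         failed_regions = failed_regions,
         conclusion = kept[!is_vus, , drop = FALSE],
         absence_statements = absence_statements,
         vus_annex = list(disclaimer = VUS_DISCLAIMER,
                          variants = kept[is_vus, , drop = FALSE]),
         method = method_info,
         germline_disclaimer = GERMLINE_DISCLAIMER,
         sign_off = list(validators = validators, date = report_date)),
    class = "report_document")
}

#' Render a report document as Markdown
#' @param doc a `report_document`.
#' @param path optional output file.
#' @return the Markdown text, invisibly when written to `path`.
#' @export
report_markdown <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "report_document"))
  fmt_var <- function(d, with_tier = TRUE) {
    if (!nrow(d)) return("- none")
    vapply(seq_len(nrow(d)), function(i) {
      sprintf("- %s %s: %s; %s%s — VAF %.1f%%%s",
              d$gene[i], d$transcript[i], d$cdna_hgvs[i], d$protein_hgvs[i],
              if (!is.na(d$protein_shorthand[i]))
                sprintf(" (%s)", d$protein_shorthand[i]) else "",
              100 * d$vaf[i],
              if (with_tier) sprintf(" — %s, Tier %s", d$biological_class[i],
                                     d$tier[i]) else "")
    }, character(1))
  }
  s <- doc$sample
  lines <- c(
    sprintf("# Molecular pathology report — sample %s", s$sample_id),
    "", "## Sample information",
    sprintf("- %s: %s", gsub("_", " ", SAMPLE_FIELDS),
            vapply(SAMPLE_FIELDS, function(f) as.character(s[[f]]),
                   character(1))),
    "", "## Test results", fmt_var(doc$test_results),
    "", "### Regions not analysed or not interpretable",
    if (length(doc$failed_regions)) paste0("- ", doc$failed_regions) else
      "- none",
    "", "## Conclusion and interpretation",
    fmt_var(doc$conclusion),
    vapply(seq_len(nrow(doc$conclusion)), function(i)
      sprintf("  - %s", doc$conclusion$tier_rationale[i]), character(1)),
    if (length(doc$absence_statements)) c("", paste0("- ", doc$absence_statements)),
    "", "## Variants of unknown significance (annex)",
    paste0("> ", doc$vus_annex$disclaimer),
    fmt_var(doc$vus_annex$variants, with_tier = FALSE),
    "", "## NGS method",
    if (length(doc$method)) sprintf("- %s: %s", names(doc$method),
                                    vapply(doc$method, as.character,
                                           character(1))) else "- see lab guide",
    paste0("> ", doc$germline_disclaimer),
    "", "## Validation",
    sprintf("Interpreted and validated by %s on %s.",
            paste(doc$sign_off$validators, collapse = ", "),
            doc$sign_off$date))
  text <- paste(unlist(lines), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Render a report document as JSON
#' @param doc a `report_document`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
report_json <- function(doc, path) {
  stopifnot(inherits(doc, "report_document"))
  jsonlite::write_json(unclass(doc), path, dataframe = "rows",
                       auto_unbox = TRUE, na = "null", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.report_document <- function(x, ...) {
  cat(report_markdown(x), "\n")
  invisible(x)
}
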