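# End-to-end orchestration of the classification workflow over single
# records and batches. The pipeline order is fixed: technical filter (Box 1),
# population frequency (Box 2, then the germline-suspect flag), exception
# handlers, CPV hotspot match (Box 3), clear-LoF routing (Box 4), scoring
# table (Box 5). The first stage that returns a class terminates the
# pipeline; a full ordered rule trail is always emitted.

new_trail <- function() {
  data.frame(rule_id = character(), outcome = character(),
             detail = character(), stringsAsFactors = FALSE)
}

add_rule <- function(trail, rule_id, outcome, detail = "") {
  rbind(trail, data.frame(rule_id = rule_id, outcome = outcome,
                          detail = detail, stringsAsFactors = FALSE))
}

new_result <- function(record, biological_class, filter, score, trail,
                       flags) {
  stopifnot(nrow(trail) >= 1L)
  structure(
    list(sample_id = record$sample_id, variant_key = variant_key(record),
         gene = record$gene, transcript = record$transcript,
         cdna_hgvs = record$cdna_hgvs, protein_hgvs = record$protein_hgvs,
         consequence = record$consequence, vaf = record$vaf,
         depth = record$depth, tumour_category = record$tumour_category,
         biological_class = biological_class, filter = filter,
         score = score, rule_trail = trail, flags = unique(flags)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s %s %s\n", x$gene, x$cdna_hgvs,
              if (is.na(x$protein_hgvs)) "" else x$protein_hgvs))
  cat(sprintf("  class: %s%s\n",
              if (is.na(x$biological_class)) "(filtered out)" else
                x$biological_class,
              if (length(x$flags))
                paste0("  [", paste(x$flags, collapse = ", "), "]") else ""))
  for (i in seq_len(nrow(x$rule_trail))) {
    cat(sprintf("  %-20s %-18s %s\n", x$rule_trail$rule_id[i],
                x$rule_trail$outcome[i], x$rule_trail$detail[i]))
  }
  invisible(x)
}

#' Load a curated override table
#'
#' Overrides record strong published evidence that overrules a scoring-table
#' VUS to a higher class; they are only ever applied upward and always leave
#' an `overruled` flag plus trail entry.
#'
#' @param path TSV with columns `gene`, `cdna_hgvs`, `new_class`,
#'   `justification`, `source`.
#' @return data frame of class `override_table`.
#' @export
load_overrides <- function(path) {
  tab <- read_kb_tsv(path)
  need <- c("gene", "cdna_hgvs", "new_class", "justification", "source")
  if (!all(need %in% names(tab))) {
    stop("override table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  bad <- !tab$new_class %in% BIO_CLASSES
  if (any(bad)) {
    stop("override rows with unknown class: ",
         paste(which(bad), collapse = ", "))
  }
  class(tab) <- c("override_table", "data.frame")
  tab
}

get_override <- function(overrides, gene, cdna_hgvs) {
  if (is.null(overrides)) return(NULL)
  i <- which(overrides$gene == gene & overrides$cdna_hgvs == cdna_hgvs)
  if (!length(i)) return(NULL)
  as.list(overrides[i[1L], ])
}

#' Classify one variant record through the full workflow
#'
#' Runs the fixed pipeline and returns the biological class with a complete
#' audit trail. Records dropped by the technical filter get `NA` as their
#' class (with the drop reason in the trail); sub-threshold calls that would
#' have been (Likely) Pathogenic are flagged `reanalysis_suggested` so they
#' can be re-tested with an alternative method.
#'
#' @param record a [variant_record()].
#' @param snapshot the variant's [population_snapshot()].
#' @param evidence the variant's [evidence_bundle()].
#' @param kb a `knowledge_base` from [load_kb()].
#' @param config a [lab_config()].
#' @param observation_log optional lab history for the regional-benign rule.
#' @param overrides optional `override_table`.
#' @return a `classification_result`: `biological_class` (one of the five
#'   classes, or `NA` if filtered out), `score` (a `score_breakdown` iff the
#'   scoring table was consulted), `rule_trail`, `flags`.
#' @export
classify_record <- function(record, snapshot = population_snapshot(),
                            evidence = evidence_bundle(), kb = load_kb(),
                            config = lab_config(), observation_log = NULL,
                            overrides = NULL) {
  stopifnot(inherits(record, "variant_record"))
  trail <- new_trail()
  flags <- character()
  cpv <- kb_for(kb, record$tumour_category)
  cpv_hit <- classify_cpv(record, cpv)

  # Box 1 — technical filter (hotspot matches are exempt from the
  # recurrence heuristic)
  fd <- technical_filter(record, config, cpv_listed = !is.null(cpv_hit))
  trail <- add_rule(trail, "BOX1-FILTER",
                    if (fd$keep) "pass" else fd$reason, fd$detail)
  if (!fd$keep) {
    if (fd$reason %in% c("low_vaf", "low_depth")) {
      candidate <- !is.null(cpv_hit) ||
        (is_clear_lof(record) &&
           identical(lookup_role(kb$roles, record$gene,
                                 record$tumour_category),
                     "tumour_suppressor"))
      if (candidate) flags <- c(flags, "reanalysis_suggested")
    }
    return(new_result(record, NA_character_, fd, NULL, trail, flags))
  }

  # Box 2 — population frequency
  pc <- population_classify(snapshot, config)
  if (!is.null(pc)) {
    trail <- add_rule(trail, "BOX2-POPFREQ", pc,
                      sprintf("max eligible ethnic MAF %.4f%%",
                              100 * max_eligible_maf(snapshot, config)))
    return(new_result(record, pc, fd, NULL, trail, flags))
  }
  trail <- add_rule(trail, "BOX2-POPFREQ", "none",
                    "no eligible population above the Likely Benign bound")
  if (germline_suspect(record, snapshot, config)) {
    flags <- c(flags, "germline_suspect")
    trail <- add_rule(trail, "BOX2-GERMLINE-FLAG", "flag",
                      sprintf("VAF %.2f in a germline band, dbSNP %s",
                              record$vaf, snapshot$dbsnp_listed))
  }

  # exception handlers
  exc <- apply_exceptions(record, evidence, kb, config, observation_log)
  if (!is.null(exc)) {
    flags <- c(flags, exc$flags)
    trail <- add_rule(trail, exc$rule_id,
                      if (is.null(exc$class)) "fall-through" else exc$class,
                      exc$detail)
    if (!is.null(exc$class)) {
      return(new_result(record, exc$class, fd, NULL, trail, flags))
    }
  }

  # Box 3 — CPV hotspot
  if (!is.null(cpv_hit)) {
    trail <- add_rule(trail, "BOX3-CPV", "Pathogenic",
                      sprintf("matches CPV entry '%s'", cpv_hit$label))
    return(new_result(record, "Pathogenic", fd, NULL, trail, flags))
  }

  # Box 4 — clear LoF routed by gene role
  route_to_scoring <- TRUE
  if (is_clear_lof(record)) {
    role <- lookup_role(kb$roles, record$gene, record$tumour_category)
    if (is.na(role)) {
      flags <- c(flags, "manual_review")
      trail <- add_rule(trail, "BOX4-ROLE-UNKNOWN", "fall-through",
                        sprintf("no role on record for %s; scoring table with review",
                                record$gene))
    } else {
      cls <- classify_lof(record, role)
      rule <- if (role == "tumour_suppressor") "BOX4-TS-LOF" else
        "BOX4-ONCO-LOF"
      trail <- add_rule(trail, rule, cls,
                        sprintf("clear LoF in %s (%s)", record$gene, role))
      return(new_result(record, cls, fd, NULL, trail, flags))
    }
  }

  # Box 5 — scoring table
  if (route_to_scoring) {
    score <- score_variant(evidence, record$tumour_category)
    override <- get_override(overrides, record$gene, record$cdna_hgvs)
    sc <- scoring_class(score, cpv_listed_gene(cpv, record$gene), override)
    trail <- add_rule(trail, "BOX5-SCORE", sc$class,
                      sprintf("total %+g (COSMIC %+g, in-silico %+g, functional %+g, genomic db %+g)",
                              score$total, score$cosmic_score,
                              score$insilico_score, score$functional_score,
                              score$genomicdb_score))
    if (sc$overruled) {
      flags <- c(flags, "overruled")
      trail <- add_rule(trail, "BOX5-OVERRIDE", sc$class,
                        sprintf("curated override (%s)", override$source))
    }
    return(new_result(record, sc$class, fd, score, trail, flags))
  }
}
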