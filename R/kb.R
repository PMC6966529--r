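# Knowledge base: consensus pathogenic variant (CPV) lists, gene roles and
# per-variant offline evidence snapshots.
#
# The CPV tables ship with the package as versioned TSV files transcribed from
# the consensus hotspot lists for solid and myeloid tumours; a lab may pass
# replacements with the same schema. Cells are kept verbatim in `label`; the
# positional grammar of the source cells is: "X-Y" a closed region that must
# contain the whole reported change, "X_Y" the exact start/end of the change.

MATCH_KINDS <- c("exact_aa", "aa_region", "exon_event", "any_clear_lof",
                 "splice_event")
# specificity order for tie-breaking, most specific first
MATCH_SPECIFICITY <- MATCH_KINDS

EVENT_CLASSES <- c("substitution", "inframe_del", "inframe_ins",
                   "inframe_indel", "out_of_frame_del", "out_of_frame_ins",
                   "duplication", "skipping", "any_missense", "clear_lof")

read_kb_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = character(0),
                    check.names = FALSE)
}

dot_na_int <- function(x) suppressWarnings(as.integer(ifelse(x == ".", NA, x)))
dot_na_chr <- function(x) ifelse(x == ".", NA_character_, x)

#' Load a consensus pathogenic variant (CPV) list
#'
#' Reads one curated hotspot table (TSV with columns `gene`, `transcript`,
#' `match_kind`, `position`, `end_position`, `exon`, `allowed_alts`,
#' `event_class`, `label`; `.` for absent). Rows with `match_kind` `none`
#' contribute no match entries but mark the gene as CPV-listed (which matters
#' for the scoring rule that reserves the Pathogenic top score for non-listed
#' genes). A `see_solid` alias row pulls that gene's entries from the solid
#' list in the same directory.
#'
#' @param path TSV file path.
#' @param tumour_category `"solid"` or `"haematological"` (recorded on the
#'   returned object).
#' @return an object of class `cpv_list`: list with `entries` (data frame of
#'   match entries, one per hotspot rule), `listed_genes` (all genes on the
#'   list, including `none` rows) and `table` (the file verbatim).
#' @export
load_cpv_list <- function(path, tumour_category = c("solid", "haematological")) {
  tumour_category <- match.arg(tumour_category)
  tab <- read_kb_tsv(path)
  need <- c("gene", "transcript", "match_kind", "position", "end_position",
            "exon", "allowed_alts", "event_class", "label")
  if (!identical(names(tab), need)) {
    stop("CPV table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  entries <- tab
  entries$position <- dot_na_int(tab$position)
  entries$end_position <- dot_na_int(tab$end_position)
  entries$exon <- dot_na_int(tab$exon)
  entries$allowed_alts <- dot_na_chr(tab$allowed_alts)
  entries$event_class <- dot_na_chr(tab$event_class)
  # "X_Y" labels pin the exact span; "X-Y" labels delimit a region
  entries$span_exact <- grepl("[A-Z][0-9]+_[A-Z]", entries$label)

  listed_genes <- unique(entries$gene)

  # resolve alias rows against the companion solid table
  alias <- entries$match_kind == "see_solid"
  if (any(alias)) {
    solid_path <- file.path(dirname(path), "cpv_solid.tsv")
    if (!file.exists(solid_path)) {
      stop("alias row ('see_solid') but no cpv_solid.tsv next to ", path)
    }
    solid <- load_cpv_list(solid_path, "solid")
    pulled <- solid$entries[solid$entries$gene %in% entries$gene[alias], ]
    entries <- rbind(entries[!alias, ], pulled)
  }
  entries <- entries[entries$match_kind != "none", ]

  bad <- !entries$match_kind %in% MATCH_KINDS
  if (any(bad)) {
    stop("unknown match_kind in row(s) ",
         paste(which(bad), collapse = ", "), " of ", path)
  }
  # structural validation per match kind
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    ok <- switch(e$match_kind,
      exact_aa = !is.na(e$position) &&
        (!is.na(e$allowed_alts) || identical(e$event_class, "any_missense")),
      aa_region = !is.na(e$position) && !is.na(e$end_position) &&
        e$end_position >= e$position,
      exon_event = !is.na(e$exon) && !is.na(e$event_class),
      any_clear_lof = TRUE,
      splice_event = !is.na(e$exon))
    if (!ok) stop("malformed CPV row ", i, " (", e$gene, " '", e$label,
                  "') in ", path)
  }
  dup <- duplicated(entries[entries$match_kind == "exact_aa",
                            c("gene", "position", "allowed_alts")])
  if (any(dup)) stop("duplicate exact_aa entries in ", path)

  rownames(entries) <- NULL

  structure(list(entries = entries, listed_genes = listed_genes,
                 tumour_category = tumour_category, table = tab,
                 path = path),
            class = "cpv_list")
}

#' Write a CPV list back to TSV
#'
#' Emits the verbatim table the list was loaded from; a loaded-then-written
#' packaged table is byte-identical to the shipped file.
#'
#' @param cpv a `cpv_list`.
#' @param path output TSV path.
#' @export
write_cpv_list <- function(cpv, path) {
  stopifnot(inherits(cpv, "cpv_list"))
  utils::write.table(cpv$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Is a gene on the CPV list (including `none` rows)?
#' @param cpv a `cpv_list`.
#' @param gene HGNC symbol.
#' @return logical.
#' @export
cpv_listed_gene <- function(cpv, gene) {
  stopifnot(inherits(cpv, "cpv_list"))
  gene %in% cpv$listed_genes
}

entry_ref_aa <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])[0-9]+", label))[[1]]
  if (length(m)) m[2] else NA_character_
}

indel_direction <- function(record) {
  if (nchar(record$ref) > nchar(record$alt)) "del" else "ins"
}

# map a record onto the indel event classes a CPV cell can name
event_matches <- function(event_class, record) {
  ch <- record$protein_change
  kind <- if (!is.null(ch)) ch$kind else NA_character_
  switch(event_class,
    inframe_del = identical(kind, "inframe_del"),
    inframe_ins = kind %in% c("inframe_ins", "duplication"),
    inframe_indel = is_indel_kind(kind),
    duplication = identical(kind, "duplication"),
    out_of_frame_del = record$consequence == "frameshift" &&
      indel_direction(record) == "del",
    out_of_frame_ins = record$consequence == "frameshift" &&
      indel_direction(record) == "ins",
    skipping = record$consequence == "splice_core",
    FALSE)
}

#' Match a variant against a CPV list
#'
#' Finds the hotspot entry a variant satisfies, if any. When several entries
#' apply, the most specific wins, in the fixed order `exact_aa` > `aa_region`
#' > `exon_event` > `any_clear_lof` > `splice_event`; the result is therefore
#' independent of the file order of the entries. Point changes are matched by
#' residue and position against the allowed alternate residues; indels are
#' matched structurally (span containment for `X-Y` region cells, exact span
#' for `X_Y` cells, exon + event class for exon-level cells). `any_missense`
#' cells match any substitution at the position, but not a nonsense change.
#' Absence of a match is a normal outcome, not an error.
#'
#' @param record a `variant_record`.
#' @param cpv a `cpv_list` loaded for the record's tumour category.
#' @return a one-row data frame (the matched entry) or `NULL`.
#' @export
match_cpv <- function(record, cpv) {
  stopifnot(inherits(record, "variant_record"), inherits(cpv, "cpv_list"))
  entries <- cpv$entries[cpv$entries$gene == record$gene, , drop = FALSE]
  if (!nrow(entries)) return(NULL)
  ch <- record$protein_change

  hit <- function(e) {
    switch(e$match_kind,
      exact_aa = {
        if (is.null(ch) || ch$kind != "substitution") return(FALSE)
        if (ch$position != e$position) return(FALSE)
        ref <- entry_ref_aa(e$label)
        if (!is.na(ref) && ch$ref_aa != ref) return(FALSE)
        if (identical(e$event_class, "any_missense")) return(TRUE)
        ch$alt_aa %in% strsplit(e$allowed_alts, "/", fixed = TRUE)[[1]]
      },
      aa_region = {
        if (is.null(ch) || !is_indel_kind(ch$kind)) return(FALSE)
        if (!event_matches(e$event_class, record)) return(FALSE)
        cs <- ch$position
        ce <- if (is.na(ch$end_position)) ch$position else ch$end_position
        if (e$span_exact) {
          cs == e$position && ce == e$end_position
        } else {
          cs >= e$position && ce <= e$end_position
        }
      },
      exon_event = {
        if (is.na(record$exon) || record$exon != e$exon) return(FALSE)
        event_matches(e$event_class, record)
      },
      any_clear_lof = record$consequence %in%
        c("nonsense", "frameshift", "splice_core"),
      splice_event = record$consequence == "splice_core" &&
        !is.na(record$exon) && record$exon == e$exon,
      FALSE)
  }

  matched <- vapply(seq_len(nrow(entries)), function(i) hit(entries[i, ]),
                    logical(1))
  if (!any(matched)) return(NULL)
  cand <- entries[matched, , drop = FALSE]
  ord <- order(match(cand$match_kind, MATCH_SPECIFICITY))
  cand[ord[1L], , drop = FALSE]
}

#' Load the tumour-suppressor / oncogene role table
#'
#' @param path TSV with columns `gene`, `role`
#'   (`tumour_suppressor`/`oncogene`), `tumour_category`
#'   (`solid`/`haematological`/`both`). Dual-role genes carry one row per
#'   category so the role can be resolved by the tumour type screened.
#' @return data frame of class `gene_roles`.
#' @export
load_gene_roles <- function(path) {
  tab <- read_kb_tsv(path)
  stopifnot(identical(names(tab), c("gene", "role", "tumour_category")))
  bad <- !tab$role %in% c("tumour_suppressor", "oncogene")
  if (any(bad)) stop("unknown role in rows ", paste(which(bad), collapse = ","))
  key <- paste(tab$gene, tab$tumour_category)
  if (anyDuplicated(key)) stop("duplicate (gene, tumour_category) rows in ", path)
  class(tab) <- c("gene_roles", "data.frame")
  tab
}

#' Resolve the role of a gene for a tumour category
#'
#' Clear loss-of-function variants are routed by this role: haploinsufficiency
#' of a tumour suppressor is Likely Pathogenic, while an inactivating change
#' in an oncogene is a VUS. An unknown gene returns `NA`; the engine then
#' falls back to the scoring table with a manual-review flag rather than
#' guessing a role.
#'
#' @param roles a `gene_roles` table.
#' @param gene HGNC symbol.
#' @param tumour_category `"solid"` or `"haematological"`.
#' @return `"tumour_suppressor"`, `"oncogene"`, or `NA_character_`.
#' @export
lookup_role <- function(roles, gene, tumour_category) {
  stopifnot(inherits(roles, "gene_roles"))
  i <- roles$gene == gene &
    (roles$tumour_category == tumour_category | roles$tumour_category == "both")
  if (!any(i)) return(NA_character_)
  roles$role[which(i)[1L]]
}

#' Path to the packaged knowledge-base directory
#' @return directory containing `cpv_solid.tsv`, `cpv_haematological.tsv`,
#'   `gene_roles.tsv`.
#' @export
default_kb_dir <- function() {
  system.file("extdata", "kb", package = "oncoclassify", mustWork = TRUE)
}

#' Load the full knowledge base from a directory
#'
#' @param dir directory with `cpv_solid.tsv`, `cpv_haematological.tsv` and
#'   `gene_roles.tsv`; defaults to the packaged tables.
#' @return list of class `knowledge_base` with elements `cpv` (one `cpv_list`
#'   per tumour category) and `roles`.
#' @export
load_kb <- function(dir = default_kb_dir()) {
  structure(
    list(cpv = list(
           solid = load_cpv_list(file.path(dir, "cpv_solid.tsv"), "solid"),
           haematological = load_cpv_list(
             file.path(dir, "cpv_haematological.tsv"), "haematological")),
         roles = load_gene_roles(file.path(dir, "gene_roles.tsv")),
         dir = dir,
         versions = vapply(
           c("cpv_solid.tsv", "cpv_haematological.tsv", "gene_roles.tsv"),
           function(f) unname(tools::md5sum(file.path(dir, f))), character(1))),
    class = "knowledge_base")
}

kb_for <- function(kb, tumour_category) kb$cpv[[tumour_category]]
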