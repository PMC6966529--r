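# Batch classification: file I/O, joining calls to annotations and evidence,
# deterministic result tables and the run manifest.

read_table_arg <- function(x, loader = read_kb_tsv) {
  if (is.null(x) || is.data.frame(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) stop("cannot read input file: ", x)
  loader(x)
}

#' Read a calls table (annotated TSV, or minimal VCF)
#'
#' The primary input is a TSV of calls with columns `sample_id`, `chrom`,
#' `pos`, `ref`, `alt`, `vaf` (fraction), `depth`, `tumour_category`,
#' `tumour_type`. A minimal VCF path (`.vcf`) is also accepted: CHROM, POS,
#' REF, ALT are taken from the fixed columns and per-sample depth/VAF from
#' the `DP` and `AF` FORMAT fields (one row per sample with a called ALT);
#' tumour category/type must then be supplied because a VCF does not carry
#' them.
#'
#' @param path TSV or VCF file.
#' @param tumour_category,tumour_type required for VCF input.
#' @return data frame of calls.
#' @export
read_calls <- function(path, tumour_category = NULL, tumour_type = NA) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF input requires the vcfR package")
    }
    if (is.null(tumour_category)) {
      stop("tumour_category must be given for VCF input")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)  # single-variant VCF drops dims
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    af <- vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)
    out <- do.call(rbind, lapply(colnames(dp), function(s) {
      data.frame(sample_id = s, chrom = fix$CHROM,
                 pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                 vaf = af[, s], depth = as.integer(dp[, s]),
                 tumour_category = tumour_category,
                 tumour_type = tumour_type, stringsAsFactors = FALSE)
    }))
    out[!is.na(out$vaf), , drop = FALSE]
  } else {
    tab <- read_kb_tsv(path)
    tab$pos <- as.integer(tab$pos)
    tab$vaf <- as.numeric(tab$vaf)
    tab$depth <- as.integer(tab$depth)
    tab
  }
}

join_annotations <- function(calls, annotations) {
  if (is.null(annotations)) return(calls)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  i <- match(key(calls), key(annotations))
  ann_cols <- setdiff(names(annotations), c("chrom", "pos", "ref", "alt"))
  cbind(calls, annotations[i, ann_cols, drop = FALSE])
}

record_from_row <- function(row) {
  variant_record(
    sample_id = row$sample_id, chrom = row$chrom, pos = row$pos,
    ref = row$ref, alt = row$alt, vaf = row$vaf, depth = row$depth,
    gene = row$gene, transcript = row$transcript,
    cdna_hgvs = row$cdna_hgvs,
    protein_hgvs = if (is.null(row$protein_hgvs) || is.na(row$protein_hgvs) ||
                       row$protein_hgvs == ".") NA_character_ else
      row$protein_hgvs,
    consequence = row$consequence,
    exon = if (is.null(row$exon) || is.na(row$exon) ||
               identical(row$exon, ".")) NA_integer_ else
      as.integer(row$exon),
    tumour_category = row$tumour_category,
    tumour_type = if (is.null(row$tumour_type)) NA_character_ else
      row$tumour_type)
}

result_row <- function(res) {
  final <- res$rule_trail[nrow(res$rule_trail), ]
  data.frame(
    sample_id = res$sample_id, gene = res$gene, transcript = res$transcript,
    cdna_hgvs = res$cdna_hgvs,
    protein_hgvs = ifelse(is.na(res$protein_hgvs), ".", res$protein_hgvs),
    consequence = res$consequence, vaf = res$vaf, depth = res$depth,
    tumour_category = res$tumour_category, variant_key = res$variant_key,
    kept = res$filter$keep, filter_reason = res$filter$reason,
    biological_class = ifelse(is.na(res$biological_class), ".",
                              res$biological_class),
    score_total = if (is.null(res$score)) NA_real_ else res$score$total,
    deciding_rule = final$rule_id,
    flags = if (length(res$flags)) paste(sort(res$flags), collapse = ",") else ".",
    rule_trail = paste(sprintf("%s=%s", res$rule_trail$rule_id,
                               res$rule_trail$outcome), collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Classify a batch of variant calls
#'
#' Joins calls to annotations, population snapshots and evidence bundles,
#' classifies every record through [classify_record()], and returns a
#' deterministic results table (sorted by sample, gene and cDNA change, so
#' permuting input rows changes nothing) plus a run manifest echoing every
#' threshold source (config digest, knowledge-base table checksums). Records
#' with no matching annotation are skipped and counted in the manifest; a
#' gene mismatch between annotation and a keyed evidence row cannot occur
#' because evidence is joined by (gene, cdna_hgvs).
#'
#' @param calls calls table or file ([read_calls()] columns).
#' @param annotations annotation table or file keyed by
#'   `chrom`,`pos`,`ref`,`alt` with columns `gene`, `transcript`,
#'   `cdna_hgvs`, `protein_hgvs`, `consequence`, `exon`; `NULL` if `calls`
#'   is already annotated.
#' @param popfreq population snapshot table or file ([load_popfreq()]).
#' @param evidence evidence table or file ([load_evidence()]).
#' @param kb a `knowledge_base` or a directory for [load_kb()].
#' @param config a [lab_config()] or a YAML path for [read_lab_config()].
#' @param observation_log optional observation log (table or file).
#' @param overrides optional override table or file ([load_overrides()]).
#' @param out_dir if given, writes `results.tsv`, `results.json`,
#'   `manifest.json`, `review_queue.tsv` (flagged records) and
#'   `reanalysis.tsv` (sub-threshold (Likely) Pathogenic candidates) there.
#' @param run_id identifier echoed into the manifest.
#' @return list of class `batch_result`: `results` (data frame), `details`
#'   (list of `classification_result`), `manifest`.
#' @export
classify_batch <- function(calls, annotations = NULL, popfreq = NULL,
                           evidence = NULL, kb = load_kb(),
                           config = lab_config(), observation_log = NULL,
                           overrides = NULL, out_dir = NULL,
                           run_id = "run") {
  calls <- read_table_arg(calls, read_calls)
  annotations <- read_table_arg(annotations)
  popfreq <- read_table_arg(popfreq, load_popfreq)
  evidence <- read_table_arg(evidence, load_evidence)
  observation_log <- read_table_arg(observation_log, load_observation_log)
  overrides <- read_table_arg(overrides, load_overrides)
  if (is.character(kb)) kb <- load_kb(kb)
  if (is.character(config)) config <- read_lab_config(config)

  joined <- join_annotations(calls, annotations)
  skipped <- 0L
  details <- list()
  for (i in seq_len(nrow(joined))) {
    row <- as.list(joined[i, ])
    if (is.null(row$gene) || is.na(row$gene)) {
      skipped <- skipped + 1L
      next
    }
    rec <- record_from_row(row)
    res <- classify_record(
      rec,
      snapshot = get_snapshot(popfreq, rec$gene, rec$cdna_hgvs),
      evidence = get_evidence(evidence, rec$gene, rec$cdna_hgvs),
      kb = kb, config = config, observation_log = observation_log,
      overrides = overrides)
    details[[length(details) + 1L]] <- res
  }

  results <- if (length(details)) {
    do.call(rbind, lapply(details, result_row))
  } else {
    result_row_template()
  }
  ord <- order(results$sample_id, results$gene, results$cdna_hgvs,
               results$variant_key)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  details <- details[ord]

  manifest <- list(
    run_id = run_id,
    config_digest = config_digest(config),
    kb_versions = as.list(kb$versions),
    records_in = nrow(joined),
    records_skipped = skipped,
    records_kept = sum(results$kept),
    records_classified = sum(results$kept))

  out <- structure(list(results = results, details = details,
                        manifest = manifest), class = "batch_result")
  if (!is.null(out_dir)) write_batch_outputs(out, out_dir)
  out
}

result_row_template <- function() {
  data.frame(sample_id = character(), gene = character(),
             transcript = character(), cdna_hgvs = character(),
             protein_hgvs = character(), consequence = character(),
             vaf = numeric(), depth = integer(),
             tumour_category = character(), variant_key = character(),
             kept = logical(), filter_reason = character(),
             biological_class = character(), score_total = numeric(),
             deciding_rule = character(), flags = character(),
             rule_trail = character(), stringsAsFactors = FALSE)
}

write_batch_outputs <- function(batch, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) {
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  w(batch$results, "results.tsv")
  jsonlite::write_json(batch$results, file.path(out_dir, "results.json"),
                       dataframe = "rows", na = "null", digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(batch$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  w(batch$results[batch$results$flags != ".", , drop = FALSE],
    "review_queue.tsv")
  reana <- vapply(batch$details,
                  function(r) "reanalysis_suggested" %in% r$flags, logical(1))
  w(batch$results[reana, , drop = FALSE], "reanalysis.tsv")
  invisible(out_dir)
}

#' @export
print.batch_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<batch_result> %d records in, %d kept and classified, %d skipped\n",
              m$records_in, m$records_kept, m$records_skipped))
  kept <- x$results[x$results$kept, , drop = FALSE]
  if (nrow(kept)) print(table(class = kept$biological_class))
  invisible(x)
}
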