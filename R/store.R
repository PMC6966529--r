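# Local classification store: an append-only TSV history of the class
# assigned to each variant, enabling fast standardized categorisation of
# previously encountered variants and follow-up of class switches.

empty_store <- function() {
  data.frame(variant_key = character(), biological_class = character(),
             date = character(), run_id = character(),
             stringsAsFactors = FALSE)
}

#' Load a classification store
#' @param path TSV with columns `variant_key`, `biological_class`, `date`,
#'   `run_id`; a missing file is an empty store.
#' @return data frame of class `classification_store` (append-only history;
#'   the current class of a variant is its last entry).
#' @export
load_store <- function(path) {
  tab <- if (file.exists(path)) read_kb_tsv(path) else empty_store()
  stopifnot(all(c("variant_key", "biological_class", "date", "run_id") %in%
                  names(tab)))
  class(tab) <- c("classification_store", "data.frame")
  tab
}

#' @rdname load_store
#' @param store a `classification_store`.
#' @export
write_store <- function(store, path) {
  utils::write.table(store, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

current_classes <- function(store) {
  if (!nrow(store)) return(stats::setNames(character(), character()))
  last <- !duplicated(store$variant_key, fromLast = TRUE)
  stats::setNames(store$biological_class[last], store$variant_key[last])
}

#' Class-switch report against the store
#'
#' Compares a batch's classes with the stored current class per variant.
#' Downgrades (new class lower than stored) are flagged for expert review.
#'
#' @param store a `classification_store`.
#' @param results a `batch_result` or its `results` data frame.
#' @return data frame with `variant_key`, `old_class`, `new_class`,
#'   `direction` (`upgrade`/`downgrade`) and `review` (logical); zero rows
#'   when nothing switched.
#' @export
diff_store <- function(store, results) {
  if (inherits(results, "batch_result")) results <- results$results
  cur <- current_classes(store)
  kept <- results[results$kept & results$biological_class != ".", ,
                  drop = FALSE]
  kept <- kept[!duplicated(kept$variant_key), , drop = FALSE]
  old <- unname(cur[kept$variant_key])
  changed <- !is.na(old) & old != kept$biological_class
  out <- data.frame(variant_key = kept$variant_key[changed],
                    old_class = old[changed],
                    new_class = kept$biological_class[changed],
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(bio_class(out$new_class) > bio_class(out$old_class),
                          "upgrade", "downgrade")
  out$review <- out$direction == "downgrade"
  out
}

#' Append a batch's classes to the store
#'
#' Appends one history row per classified variant whose class is new or
#' switched; unchanged variants are not re-recorded.
#'
#' @param store a `classification_store`.
#' @param results a `batch_result` or its `results` data frame.
#' @param date date string recorded with the entries.
#' @param run_id run identifier recorded with the entries.
#' @return the updated store.
#' @export
update_store <- function(store, results, date = as.character(Sys.Date()),
                         run_id = "run") {
  if (inherits(results, "batch_result")) {
    run_id <- results$manifest$run_id
    results <- results$results
  }
  cur <- current_classes(store)
  kept <- results[results$kept & results$biological_class != ".", ,
                  drop = FALSE]
  kept <- kept[!duplicated(kept$variant_key), , drop = FALSE]
  old <- unname(cur[kept$variant_key])
  new_rows <- is.na(old) | old != kept$biological_class
  add <- data.frame(variant_key = kept$variant_key[new_rows],
                    biological_class = kept$biological_class[new_rows],
                    date = date, run_id = run_id, stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(store), add)
  class(out) <- c("classification_store", "data.frame")
  out
}
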