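#' Biological variant classes
#'
#' The five tumour-independent biological classes, as an ordered factor:
#' `Benign < LikelyBenign < VUS < LikelyPathogenic < Pathogenic`. The order is
#' the one used by every "higher class" comparison in the package (overrides,
#' class-switch direction, monotonicity checks).
#'
#' @param x character vector of class labels.
#' @return an ordered factor with the five biological class levels.
#' @examples
#' bio_class("VUS") < bio_class("Pathogenic")
#' @export
bio_class <- function(x) {
  out <- factor(x, levels = BIO_CLASSES, ordered = TRUE)
  if (anyNA(out) && !anyNA(x)) {
    bad <- setdiff(unique(x), BIO_CLASSES)
    stop("unknown biological class label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' @rdname bio_class
#' @export
BIO_CLASSES <- c("Benign", "LikelyBenign", "VUS", "LikelyPathogenic",
                 "Pathogenic")

is_bio_class <- function(x) {
  length(x) == 1L && !is.na(x) && as.character(x) %in% BIO_CLASSES
}
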