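CONSEQUENCES <- c("missense", "nonsense", "frameshift", "inframe_deletion",
                  "inframe_insertion", "inframe_delins", "synonymous",
                  "splice_core", "intronic", "other")

TUMOUR_CATEGORIES <- c("solid", "haematological")

#' One observed somatic variant call joined to its annotation
#'
#' The unit record the whole workflow operates on: a VCF-level call (position,
#' alleles, VAF, depth) joined to its transcript-level annotation (gene, HGVS
#' at cDNA and protein level, consequence, exon). VAF is carried internally as
#' a fraction in `[0, 1]`; only reports render percentages. Positions are
#' 1-based (VCF and HGVS convention).
#'
#' @param sample_id,chrom,pos,ref,alt call-level fields; `pos` is 1-based.
#' @param vaf variant allele fraction in `[0, 1]`.
#' @param depth read depth at the position (non-negative integer).
#' @param gene HGNC symbol.
#' @param transcript accession with explicit version, e.g. `"NM_005228.4"`.
#' @param cdna_hgvs HGVS c. description (carried through, not parsed).
#' @param protein_hgvs HGVS p. description (three-letter) or `NA` — e.g. a
#'   pure splice-site variant has none.
#' @param consequence one of missense, nonsense, frameshift, inframe_deletion,
#'   inframe_insertion, inframe_delins, synonymous, splice_core, intronic,
#'   other. `splice_core` means the intronic -2/-1/+1/+2 positions carrying
#'   the AG/GT motif.
#' @param exon exon number on `transcript`, or `NA`.
#' @param tumour_category `"solid"` or `"haematological"`.
#' @param tumour_type free-text tumour type.
#' @return an object of class `variant_record`.
#' @export
variant_record <- function(sample_id, chrom, pos, ref, alt, vaf, depth,
                           gene, transcript, cdna_hgvs,
                           protein_hgvs = NA_character_,
                           consequence, exon = NA_integer_,
                           tumour_category, tumour_type = NA_character_) {
  stopifnot(is.numeric(pos), pos >= 1)
  # vaf/depth may arrive missing (e.g. a VCF without AF); the technical
  # filter treats that as a hard error, since the quality gates are mandatory
  if (!is.na(vaf) && (vaf < 0 || vaf > 1)) {
    stop("vaf must be a fraction in [0,1], got: ", vaf)
  }
  if (!is.na(depth) && depth < 0) stop("depth must be a non-negative integer")
  if (!grepl("\\.[0-9]+$", transcript)) {
    stop("transcript accession must carry an explicit version: ", transcript)
  }
  consequence <- match.arg(consequence, CONSEQUENCES)
  tumour_category <- match.arg(tumour_category, TUMOUR_CATEGORIES)
  change <- if (!is.na(protein_hgvs) && nzchar(protein_hgvs)) {
    parse_protein_change(protein_hgvs)
  } else NULL
  structure(
    list(sample_id = as.character(sample_id), chrom = as.character(chrom),
         pos = as.integer(pos), ref = ref, alt = alt, vaf = vaf,
         depth = as.integer(depth), gene = gene, transcript = transcript,
         cdna_hgvs = cdna_hgvs, protein_hgvs = protein_hgvs,
         protein_change = change, consequence = consequence,
         exon = as.integer(exon), tumour_category = tumour_category,
         tumour_type = tumour_type),
    class = "variant_record"
  )
}

#' Stable key of a variant for stores, evidence joins and artefact lists
#'
#' Keys are `(gene, transcript, cdna_hgvs)`: HGVS on a versioned transcript is
#' preferred over genomic coordinates, which are carried but never used as a
#' join key.
#'
#' @param record a `variant_record`, or the three components.
#' @return a single string key.
#' @export
variant_key <- function(record) {
  stopifnot(inherits(record, "variant_record"))
  make_variant_key(record$gene, record$transcript, record$cdna_hgvs)
}

make_variant_key <- function(gene, transcript, cdna_hgvs) {
  paste(gene, transcript, cdna_hgvs, sep = "|")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s %s:%s %s>%s  %s %s %s (%s)\n",
              x$sample_id, x$chrom, x$pos, x$ref, x$alt,
              x$gene, x$cdna_hgvs,
              if (is.na(x$protein_hgvs)) "" else x$protein_hgvs,
              x$consequence))
  cat(sprintf("  VAF %.1f%%, depth %d, %s tumour%s\n", 100 * x$vaf, x$depth,
              x$tumour_category,
              if (is.na(x$exon)) "" else sprintf(", exon %d", x$exon)))
  invisible(x)
}

is_indel_kind <- function(kind) {
  kind %in% c("inframe_del", "inframe_ins", "inframe_delins", "duplication")
}
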