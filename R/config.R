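#' Laboratory configuration
#'
#' All lab-tunable thresholds of the workflow in one validated object. The
#' defaults are the consensus values: variants are validated down to 5% VAF on
#' at least 500 reads; a variant seen in at least 10% of a run's samples
#' (outside hotspots) is treated as a recurrent artefact; an ethnic-specific
#' MAF above 0.1% in a population with at least 2000 interrogated alleles is
#' Likely Benign and 1% or above is Benign; germline-suspect VAF bands are
#' [0.40, 0.60] and [0.90, 1.00] ("close to 50% / 100%", which the source
#' rules leave unquantified); a rare regional benign variant needs at least
#' three region-specific samples in the heterozygous band. Fractions
#' throughout (VAF and MAF in [0,1]); reports render percentages.
#'
#' @param vaf_min minimum VAF to keep a call (fraction; default 0.05).
#' @param depth_min minimum read depth (default 500).
#' @param site_overrides data frame `gene`, `change` (one-letter shorthand or
#'   cDNA HGVS), `vaf_min`, `depth_min`: per-site relaxed thresholds for
#'   validated low-frequency targets.
#' @param recurrence_fraction run-level fraction of samples above which a
#'   non-hotspot variant is treated as a technical artefact (default 0.10).
#' @param recurrence_blacklist character vector of variant keys
#'   ([variant_key()]) known to be artefacts.
#' @param str_stutter_thresholds named numeric vector, variant key ->
#'   validated stutter VAF threshold for STR/homopolymer sites.
#' @param maf_likely_benign strict lower MAF bound for Likely Benign
#'   (default 0.001).
#' @param maf_benign inclusive MAF bound for Benign (default 0.01).
#' @param min_allele_number minimum interrogated alleles for a population to
#'   be eligible (default 2000).
#' @param germline_vaf_bands 2x2 matrix of closed VAF intervals around 0.5
#'   and 1.0.
#' @param regional_benign_min_samples distinct heterozygous-band samples
#'   needed to call a regional benign variant (default 3).
#' @param synonymous_keep_genes genes whose synonymous variants are not
#'   dropped by the technical filter (default `"TP53"`, whose synonymous
#'   changes must still be checked in the dedicated databases).
#' @param cebpa_bzip_interval protein interval of the CEBPA bZIP domain used
#'   by the in-frame-indel exception (default c(278, 358)).
#' @param brca_last_exon named integer vector giving the last exon number of
#'   the BRCA1/BRCA2 reference transcripts; clear LoF variants in the last
#'   exon are routed to the database verdict instead of automatic Pathogenic.
#' @return object of class `lab_config`.
#' @export
lab_config <- function(vaf_min = 0.05,
                       depth_min = 500L,
                       site_overrides = NULL,
                       recurrence_fraction = 0.10,
                       recurrence_blacklist = character(),
                       str_stutter_thresholds = numeric(),
                       maf_likely_benign = 0.001,
                       maf_benign = 0.01,
                       min_allele_number = 2000L,
                       germline_vaf_bands = rbind(het = c(0.40, 0.60),
                                                  hom = c(0.90, 1.00)),
                       regional_benign_min_samples = 3L,
                       synonymous_keep_genes = "TP53",
                       cebpa_bzip_interval = c(278L, 358L),
                       brca_last_exon = c(BRCA1 = 24L, BRCA2 = 27L)) {
  stopifnot(vaf_min > 0, vaf_min < 1,
            0 < maf_likely_benign, maf_likely_benign < maf_benign,
            maf_benign <= 1,
            depth_min >= 0, min_allele_number >= 0,
            regional_benign_min_samples >= 1,
            is.matrix(germline_vaf_bands), ncol(germline_vaf_bands) == 2)
  if (is.null(site_overrides)) {
    site_overrides <- data.frame(gene = character(), change = character(),
                                 vaf_min = numeric(), depth_min = integer())
  }
  stopifnot(all(c("gene", "change", "vaf_min", "depth_min") %in%
                  names(site_overrides)))
  structure(
    list(vaf_min = vaf_min, depth_min = as.integer(depth_min),
         site_overrides = site_overrides,
         recurrence_fraction = recurrence_fraction,
         recurrence_blacklist = recurrence_blacklist,
         str_stutter_thresholds = str_stutter_thresholds,
         maf_likely_benign = maf_likely_benign, maf_benign = maf_benign,
         min_allele_number = as.integer(min_allele_number),
         germline_vaf_bands = germline_vaf_bands,
         regional_benign_min_samples = as.integer(regional_benign_min_samples),
         synonymous_keep_genes = synonymous_keep_genes,
         cebpa_bzip_interval = as.integer(cebpa_bzip_interval),
         brca_last_exon = brca_last_exon),
    class = "lab_config")
}

#' Read a lab configuration from a YAML file
#'
#' Keys mirror the [lab_config()] argument names; unknown keys are an error so
#' that typos cannot silently fall back to defaults. `site_overrides` is a
#' list of mappings; `germline_vaf_bands` a list of two `[lo, hi]` pairs.
#'
#' @param path YAML file.
#' @return a `lab_config`.
#' @export
read_lab_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(lab_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown lab_config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$site_overrides)) {
    raw$site_overrides <- do.call(rbind, lapply(raw$site_overrides,
                                                as.data.frame))
  }
  if (!is.null(raw$germline_vaf_bands)) {
    raw$germline_vaf_bands <- do.call(rbind, raw$germline_vaf_bands)
  }
  if (!is.null(raw$str_stutter_thresholds)) {
    raw$str_stutter_thresholds <- unlist(raw$str_stutter_thresholds)
  }
  if (!is.null(raw$brca_last_exon)) {
    raw$brca_last_exon <- unlist(raw$brca_last_exon)
  }
  do.call(lab_config, raw)
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config)[order(names(config))], f)
  unname(tools::md5sum(f))
}
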