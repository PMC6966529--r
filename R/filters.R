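# Technical filtering and population-frequency classification: the first two
# boxes of the workflow. Everything here is deliberately boring and literal —
# filters quote the thresholds they applied in the decision detail so runs
# are auditable.

FILTER_REASONS <- c("pass", "technical_artifact", "recurrent_artifact",
                    "intronic", "synonymous", "low_vaf", "low_depth",
                    "str_stutter")

filter_decision <- function(keep, reason, detail = "") {
  stopifnot(reason %in% FILTER_REASONS, identical(keep, reason == "pass"))
  structure(list(keep = keep, reason = reason, detail = detail),
            class = "filter_decision")
}

site_thresholds <- function(record, config) {
  ov <- config$site_overrides
  vaf_min <- config$vaf_min
  depth_min <- config$depth_min
  if (nrow(ov)) {
    sh <- tryCatch(
      if (!is.null(record$protein_change) &&
          record$protein_change$kind %in% c("substitution", "nonsense"))
        shorthand(record$protein_change) else NA_character_,
      error = function(e) NA_character_)
    i <- which(ov$gene == record$gene &
                 (ov$change == record$cdna_hgvs |
                    (!is.na(sh) & ov$change == sh)))
    if (length(i)) {
      vaf_min <- ov$vaf_min[i[1L]]
      depth_min <- ov$depth_min[i[1L]]
    }
  }
  list(vaf_min = vaf_min, depth_min = depth_min)
}

#' Technical filter (workflow Box 1)
#'
#' Selects the high-quality, protein-altering calls: drops intronic variants
#' outside the AG/GT core splice positions, stand-alone synonymous changes
#' (except in genes configured for synonymous follow-up, TP53 by default),
#' known recurrent technical artefacts (unless the variant is hotspot-listed,
#' which exempts it from the recurrence heuristic), STR/homopolymer calls at
#' or below their validated stutter VAF, and calls under the VAF or depth
#' gate. Per-site overrides can relax the gates for validated low-frequency
#' targets (e.g. BRAF V600E in hairy cell leukaemia).
#'
#' @param record a [variant_record()].
#' @param config a [lab_config()].
#' @param cpv_listed does the variant match a CPV entry (hotspot exemption
#'   from the recurrence filter)?
#' @return a `filter_decision`: `keep` (logical), `reason`, `detail`. `keep`
#'   is `TRUE` iff `reason == "pass"`.
#' @export
technical_filter <- function(record, config, cpv_listed = FALSE) {
  stopifnot(inherits(record, "variant_record"), inherits(config, "lab_config"))
  if (is.na(record$vaf) || is.na(record$depth)) {
    stop("vaf and depth are mandatory quality gates; missing for ",
         variant_key(record))
  }
  if (record$consequence == "intronic") {
    return(filter_decision(FALSE, "intronic",
                           "intronic outside AG/GT core splice positions"))
  }
  if (record$consequence == "synonymous" &&
      !record$gene %in% config$synonymous_keep_genes) {
    return(filter_decision(FALSE, "synonymous", "stand-alone silent change"))
  }
  key <- variant_key(record)
  thr <- config$str_stutter_thresholds
  if (key %in% names(thr) && record$vaf <= thr[[key]]) {
    return(filter_decision(FALSE, "str_stutter",
                           sprintf("VAF %.3f <= stutter threshold %.3f",
                                   record$vaf, thr[[key]])))
  }
  if (key %in% config$recurrence_blacklist && !cpv_listed) {
    return(filter_decision(FALSE, "recurrent_artifact",
                           "on lab recurrent-artefact blacklist"))
  }
  gate <- site_thresholds(record, config)
  if (record$vaf < gate$vaf_min) {
    return(filter_decision(FALSE, "low_vaf",
                           sprintf("VAF %.3f < %.3f", record$vaf,
                                   gate$vaf_min)))
  }
  if (record$depth < gate$depth_min) {
    return(filter_decision(FALSE, "low_depth",
                           sprintf("depth %d < %d", record$depth,
                                   gate$depth_min)))
  }
  filter_decision(TRUE, "pass",
                  sprintf("VAF %.3f >= %.3f, depth %d >= %d", record$vaf,
                          gate$vaf_min, record$depth, gate$depth_min))
}

#' Population-frequency classification (workflow Box 2)
#'
#' A variant is (Likely) Benign when its minor allele frequency exceeds 0.1%
#' in any ethnic population in which at least 2000 alleles were interrogated:
#' strictly above 0.1% and below 1% is Likely Benign, 1% or above is Benign.
#' A MAF of exactly 0.1% is *not* benign (the bound is strict) and a
#' population below the allele-number floor is ineligible regardless of its
#' MAF. Variants absent from the snapshot continue through the workflow.
#'
#' @param snapshot a [population_snapshot()]; may be empty.
#' @param config a [lab_config()].
#' @return `"Benign"`, `"LikelyBenign"`, or `NULL` (no call — variant
#'   continues).
#' @export
population_classify <- function(snapshot, config) {
  stopifnot(inherits(snapshot, "population_snapshot"),
            inherits(config, "lab_config"))
  pop <- snapshot$populations
  eligible <- pop[!is.na(pop$allele_number) &
                    pop$allele_number >= config$min_allele_number, ,
                  drop = FALSE]
  if (!nrow(eligible)) return(NULL)
  m <- max(eligible$maf)
  if (m >= config$maf_benign) return("Benign")
  if (m > config$maf_likely_benign) return("LikelyBenign")
  NULL
}

#' Maximum MAF over eligible populations
#'
#' The statistic [population_classify()] thresholds: the highest ethnic MAF
#' among populations with at least `min_allele_number` interrogated alleles.
#'
#' @inheritParams population_classify
#' @return a fraction, or `NA` if no population is eligible.
#' @export
max_eligible_maf <- function(snapshot, config = lab_config()) {
  pop <- snapshot$populations
  eligible <- pop[!is.na(pop$allele_number) &
                    pop$allele_number >= config$min_allele_number, ,
                  drop = FALSE]
  if (!nrow(eligible)) return(NA_real_)
  max(eligible$maf)
}

in_band <- function(vaf, band) vaf >= band[1L] && vaf <= band[2L]

#' Germline-suspect flag
#'
#' Population-database-negative variants with VAFs close to 50% or 100% may
#' be germline changes missed because of transcript-ID mismatches; they must
#' be checked in dbSNP with critical review. This check only raises a flag —
#' it never changes the biological class by itself.
#'
#' @param record a [variant_record()].
#' @param snapshot the variant's [population_snapshot()].
#' @param config a [lab_config()].
#' @return logical flag.
#' @export
germline_suspect <- function(record, snapshot, config = lab_config()) {
  bands <- config$germline_vaf_bands
  in_any <- any(apply(bands, 1L, function(b) in_band(record$vaf, b)))
  in_any && snapshot$dbsnp_listed != "no"
}

#' Regional rare benign variant check
#'
#' A population-specific very rare benign variant that population databases
#' miss can be recognised from the lab's own history: seen in at least three
#' region-specific samples at VAFs close to 50%, irrespective of tumour
#' content or type. The engine assigns Likely Benign with a follow-up flag
#' when this fires.
#'
#' @param key variant key ([variant_key()]).
#' @param observation_log data frame with columns `variant_key`, `sample_id`,
#'   `vaf` (the lab's historical observations).
#' @param config a [lab_config()].
#' @return logical.
#' @export
regional_benign_check <- function(key, observation_log,
                                  config = lab_config()) {
  if (is.null(observation_log) || !nrow(observation_log)) return(FALSE)
  stopifnot(all(c("variant_key", "sample_id", "vaf") %in%
                  names(observation_log)))
  het <- config$germline_vaf_bands[1L, ]
  obs <- observation_log[observation_log$variant_key == key &
                           observation_log$vaf >= het[1L] &
                           observation_log$vaf <= het[2L], , drop = FALSE]
  length(unique(obs$sample_id)) >= config$regional_benign_min_samples
}

#' Load an observation log
#' @param path TSV with columns `variant_key`, `sample_id`, `vaf` (and
#'   optionally `date`).
#' @return data frame.
#' @export
load_observation_log <- function(path) {
  tab <- read_kb_tsv(path)
  stopifnot(all(c("variant_key", "sample_id", "vaf") %in% names(tab)))
  tab$vaf <- as.numeric(tab$vaf)
  tab
}
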