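# Deterministic generator of synthetic annotated-variant batches with
# construction-time truth labels. Every branch of the workflow is covered by
# at least one branch of the generator, and the expected class of each case
# is dictated by the branch that built it — never by running the engine — so
# the fixture suite cannot self-confirm. Genomic coordinates are synthetic;
# gene, transcript and HGVS strings are real-world plausible and include the
# canonical worked examples of each rule (ALK P1599H, EGFR S768I/L858R/
# L747P, KRAS D57N/G115*, TET2 S1870*/T822P, BRAF V600E/V600M/L597R, SF3B1
# K666N/G740E, SRSF2 P107H, TP53 S149fs, CALR type I/II, ASXL1 c.1934dup).

#' Lab configuration used by the fixture batches
#'
#' The default thresholds plus the site-specific entries the branches
#' exercise: a validated low-VAF override for BRAF V600E (down to 1% on 300
#' reads, the hairy-cell-leukaemia setting), a 10% stutter threshold for the
#' ASXL1 c.1934dup homopolymer site, and one blacklisted recurrent artefact.
#'
#' @return a [lab_config()].
#' @export
fixture_lab_config <- function() {
  lab_config(
    site_overrides = data.frame(gene = "BRAF", change = "V600E",
                                vaf_min = 0.01, depth_min = 300L,
                                stringsAsFactors = FALSE),
    str_stutter_thresholds = c("ASXL1|NM_015338.5|c.1934dup" = 0.10),
    recurrence_blacklist = "GNAS|NM_000516.5|c.393C>A")
}

#' Rule identifiers the engine can emit
#' @return character vector of all rule ids that can appear in a rule trail.
#' @export
engine_rule_ids <- function() {
  c("BOX1-FILTER", "BOX2-POPFREQ", "BOX2-GERMLINE-FLAG",
    "EXC-TP53-SPLICE", "EXC-TP53-DB", "EXC-BRCA-LOF", "EXC-BRCA-DB",
    "EXC-CALR-EX9", "EXC-NPM1-EX11", "EXC-CEBPA-BZIP", "EXC-MET-EX14",
    "EXC-REGIONAL-BENIGN", "BOX3-CPV", "BOX4-TS-LOF", "BOX4-ONCO-LOF",
    "BOX4-ROLE-UNKNOWN", "BOX5-SCORE", "BOX5-OVERRIDE")
}

# one branch definition: the canonical variant, the legal numeric intervals,
# evidence/popfreq templates, and the truth label dictated by construction
fx_branches <- function() {
  v <- function(gene, transcript, cdna, protein, consequence, chrom, pos,
                ref, alt, cat, type, exon = NA_integer_) {
    list(gene = gene, transcript = transcript, cdna_hgvs = cdna,
         protein_hgvs = protein, consequence = consequence, chrom = chrom,
         pos = pos, ref = ref, alt = alt, tumour_category = cat,
         tumour_type = type, exon = exon)
  }
  ev <- function(...) list(...)
  pf <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(population = r[[1]], maf = as.numeric(r[[2]]),
                 allele_number = as.integer(r[[3]]),
                 stringsAsFactors = FALSE)))
  }

  list(
    # ---- Box 1 drops -----------------------------------------------------
    list(name = "box1_intronic", expected = "Filtered", rule = "BOX1-FILTER",
         vaf = 0.30, vaf_range = c(0.10, 0.45),
         note = "deep intronic change outside the AG/GT core positions",
         variant = v("BRAF", "NM_004333.5", "c.1909-15T>C", NA, "intronic",
                     "chr7", 140100015L, "A", "G", "solid", "melanoma")),
    list(name = "box1_synonymous", expected = "Filtered", rule = "BOX1-FILTER",
         vaf = 0.30, vaf_range = c(0.10, 0.45),
         note = "stand-alone silent change",
         variant = v("KRAS", "NM_004985.4", "c.519T>C", NA, "synonymous",
                     "chr12", 25201000L, "A", "G", "solid",
                     "colorectal adenocarcinoma")),
    list(name = "box1_low_vaf", expected = "Filtered", rule = "BOX1-FILTER",
         vaf = 0.02, vaf_range = c(0.005, 0.045),
         note = "below the validated VAF gate, no site override",
         variant = v("ESR1", "NM_000125.3", "c.1138G>A", "p.(Glu380Lys)",
                     "missense", "chr6", 152098800L, "G", "A", "solid",
                     "breast carcinoma")),
    list(name = "box1_low_depth", expected = "Filtered", rule = "BOX1-FILTER",
         vaf = 0.30, vaf_range = c(0.10, 0.45), depth_range = c(20L, 499L),
         depth = 120L,
         note = "coverage below the validated depth gate",
         variant = v("GNAS", "NM_000516.5", "c.601C>T", "p.(Arg201Cys)",
                     "missense", "chr20", 58909365L, "C", "T", "solid",
                     "pancreatic carcinoma")),
    list(name = "box1_stutter", expected = "Filtered", rule = "BOX1-FILTER",
         vaf = 0.04, vaf_range = c(0.005, 0.095),
         note = "ASXL1 homopolymer dup at stutter-level VAF",
         variant = v("ASXL1", "NM_015338.5", "c.1934dup",
                     "p.(Gly646Trpfs*12)", "frameshift", "chr20", 32434638L,
                     "C", "CG", "haematological", "AML")),
    list(name = "box1_recurrent", expected = "Filtered", rule = "BOX1-FILTER",
         vaf = 0.30, vaf_range = c(0.10, 0.45),
         note = "blacklisted recurrent artefact, not hotspot-listed",
         variant = v("GNAS", "NM_000516.5", "c.393C>A", NA, "other",
                     "chr20", 58903000L, "C", "A", "solid",
                     "pancreatic carcinoma")),
    list(name = "box1_reanalysis_flag", expected = "Filtered",
         rule = "BOX1-FILTER", flags = "reanalysis_suggested",
         vaf = 0.02, vaf_range = c(0.005, 0.045),
         note = "sub-threshold hotspot: dropped but flagged for re-analysis",
         variant = v("EGFR", "NM_005228.4", "c.2573T>G", "p.(Leu858Arg)",
                     "missense", "chr7", 55191822L, "T", "G", "solid",
                     "lung adenocarcinoma")),
    # ---- validated low-VAF hotspot via site override ---------------------
    list(name = "box1_site_override", expected = "Pathogenic",
         rule = "BOX3-CPV", vaf = 0.02, vaf_range = c(0.011, 0.045),
         depth_range = c(300L, 2000L), depth = 800L,
         note = "BRAF V600E at validated low VAF (hairy cell leukaemia)",
         variant = v("BRAF", "NM_004333.5", "c.1799T>A", "p.(Val600Glu)",
                     "missense", "chr7", 140453136L, "A", "T", "solid",
                     "hairy cell leukaemia")),
    # ---- Box 2 -----------------------------------------------------------
    list(name = "box2_benign", expected = "Benign", rule = "BOX2-POPFREQ",
         vaf = 0.52, vaf_range = c(0.35, 0.65),
         note = "common polymorphism, ethnic MAF >= 1%",
         variant = v("TP53", "NM_000546.5", "c.215C>G", "p.(Pro72Arg)",
                     "missense", "chr17", 7579472L, "G", "C", "solid",
                     "lung adenocarcinoma"),
         popfreq = pf(list("European", 0.30, 120000L),
                      list("African", 0.55, 24000L)),
         popfreq_random = list(maf_range = c(0.01, 0.60),
                               an_range = c(2000L, 250000L))),
    list(name = "box2_likely_benign", expected = "LikelyBenign",
         rule = "BOX2-POPFREQ",
         vaf = 0.48, vaf_range = c(0.35, 0.65),
         note = "ALK P1599H: African MAF 0.25% on 24,968 alleles",
         variant = v("ALK", "NM_004304.4", "c.4796C>A", "p.(Pro1599His)",
                     "missense", "chr2", 29415640L, "G", "T", "solid",
                     "lung adenocarcinoma"),
         popfreq = pf(list("Total", 0.0002, 251262L),
                      list("African", 0.0025, 24968L)),
         popfreq_random = list(maf_range = c(0.0012, 0.0095),
                               an_range = c(2000L, 250000L))),
    list(name = "box2_ineligible_population", expected = "VUS",
         rule = "BOX5-SCORE",
         vaf = 0.22, vaf_range = c(0.10, 0.38),
         note = "raised MAF only in an under-sampled population: no benign call",
         variant = v("KIT", "NM_000222.2", "c.2586G>C", "p.(Glu862Asp)",
                     "missense", "chr4", 55599300L, "G", "C", "solid",
                     "GIST", exon = 18L),
         popfreq = pf(list("African", 0.005, 1500L)),
         popfreq_random = list(maf_range = c(0.0012, 0.0095),
                               an_range = c(100L, 1999L))),
    list(name = "box2_germline_flag", expected = "VUS", rule = "BOX5-SCORE",
         flags = "germline_suspect",
         vaf = 0.49, vaf_range = c(0.41, 0.59),
         note = "population-negative at heterozygous VAF: flag for dbSNP review",
         variant = v("ESR1", "NM_000125.3", "c.1000G>A", "p.(Ala334Thr)",
                     "missense", "chr6", 152094700L, "G", "A", "solid",
                     "breast carcinoma")),
    # ---- exceptions ------------------------------------------------------
    list(name = "exc_tp53_consensus", expected = "Pathogenic",
         rule = "EXC-TP53-DB",
         vaf = 0.35, vaf_range = c(0.10, 0.60),
         note = "both dedicated TP53 databases agree on Pathogenic",
         variant = v("TP53", "NM_000546.5", "c.451C>T", "p.(Pro151Ser)",
                     "missense", "chr17", 7578500L, "G", "A", "solid",
                     "ovarian carcinoma"),
         evidence = ev(tp53_iarc_class = "Pathogenic",
                       tp53_seshat_class = "Pathogenic")),
    list(name = "exc_tp53_disagree", expected = "VUS", rule = "BOX5-SCORE",
         flags = "manual_review",
         vaf = 0.35, vaf_range = c(0.10, 0.60),
         note = "TP53 databases disagree: general workflow with review",
         variant = v("TP53", "NM_000546.5", "c.638G>A", "p.(Arg213Gln)",
                     "missense", "chr17", 7578210L, "C", "T", "solid",
                     "ovarian carcinoma"),
         evidence = ev(tp53_iarc_class = "Pathogenic",
                       tp53_seshat_class = "VUS", cosmic_count = 30L)),
    list(name = "exc_tp53_splice", expected = "LikelyPathogenic",
         rule = "EXC-TP53-SPLICE",
         vaf = 0.30, vaf_range = c(0.10, 0.60),
         note = "TP53 -1 core splice position",
         variant = v("TP53", "NM_000546.5", "c.673-1G>A", NA, "splice_core",
                     "chr17", 7578100L, "C", "T", "solid",
                     "ovarian carcinoma", exon = 7L)),
    list(name = "exc_tp53_synonymous", expected = "VUS", rule = "BOX5-SCORE",
         flags = "manual_review",
         vaf = 0.30, vaf_range = c(0.10, 0.60),
         note = "TP53 synonymous change kept for database check; none available",
         variant = v("TP53", "NM_000546.5", "c.672G>A", NA, "synonymous",
                     "chr17", 7578177L, "C", "T", "solid",
                     "ovarian carcinoma")),
    list(name = "exc_tp53_cpv_hotspot", expected = "Pathogenic",
         rule = "BOX3-CPV",
         vaf = 0.40, vaf_range = c(0.10, 0.60),
         note = "TP53 hotspot on the myeloid CPV list beats the handler",
         variant = v("TP53", "NM_000546.5", "c.524G>A", "p.(Arg175His)",
                     "missense", "chr17", 7578406L, "C", "T",
                     "haematological", "MDS")),
    list(name = "exc_brca_lof", expected = "Pathogenic", rule = "EXC-BRCA-LOF",
         vaf = 0.42, vaf_range = c(0.15, 0.60),
         note = "clear LoF in BRCA2: always Pathogenic",
         variant = v("BRCA2", "NM_000059.3", "c.5857G>T", "p.(Glu1953*)",
                     "nonsense", "chr13", 32912700L, "G", "T", "solid",
                     "ovarian carcinoma", exon = 11L)),
    list(name = "exc_brca_last_exon", expected = "LikelyPathogenic",
         rule = "EXC-BRCA-DB",
         vaf = 0.38, vaf_range = c(0.15, 0.60),
         note = "BRCA1 last-exon LoF routed to the database verdict",
         variant = v("BRCA1", "NM_007294.3", "c.5503C>T", "p.(Arg1835*)",
                     "nonsense", "chr17", 41201200L, "G", "A", "solid",
                     "ovarian carcinoma", exon = 24L),
         evidence = ev(brca_db_verdict = "likely_pathogenic_or_pathogenic")),
    list(name = "exc_brca_db_missing", expected = "VUS", rule = "BOX5-SCORE",
         flags = "manual_review",
         vaf = 0.30, vaf_range = c(0.10, 0.60),
         note = "BRCA2 missense without a database verdict: review + scoring",
         variant = v("BRCA2", "NM_000059.3", "c.1114A>C", "p.(Asn372His)",
                     "missense", "chr13", 32906700L, "A", "C", "solid",
                     "breast carcinoma", exon = 10L)),
    list(name = "exc_calr_type1", expected = "Pathogenic",
         rule = "EXC-CALR-EX9",
         vaf = 0.41, vaf_range = c(0.15, 0.55),
         note = "CALR type I 52-bp exon 9 deletion",
         variant = v("CALR", "NM_004343.3", "c.1092_1143del",
                     "p.(Leu367Thrfs*46)", "frameshift", "chr19", 13054555L,
                     "CAGAGGACAAGTTGTCAGAGGACAAGTTGTCAGAGGACAAGTTGTCAGAGGA",
                     "C", "haematological", "MPN", exon = 9L)),
    list(name = "exc_calr_type2", expected = "Pathogenic",
         rule = "EXC-CALR-EX9",
         vaf = 0.39, vaf_range = c(0.15, 0.55),
         note = "CALR type II 5-bp exon 9 insertion",
         variant = v("CALR", "NM_004343.3", "c.1154_1155insTTGTC",
                     "p.(Lys385Asnfs*47)", "frameshift", "chr19", 13054617L,
                     "A", "ATTGTC", "haematological", "MPN", exon = 9L)),
    list(name = "exc_npm1_ex11", expected = "Pathogenic",
         rule = "EXC-NPM1-EX11",
         vaf = 0.37, vaf_range = c(0.15, 0.55),
         note = "NPM1 type A 4-bp exon 11 insertion",
         variant = v("NPM1", "NM_002520.6", "c.860_863dup",
                     "p.(Trp288Cysfs*12)", "frameshift", "chr5", 170837543L,
                     "C", "CTCTG", "haematological", "AML", exon = 11L)),
    list(name = "exc_cebpa_bzip", expected = "LikelyPathogenic",
         rule = "EXC-CEBPA-BZIP",
         vaf = 0.33, vaf_range = c(0.15, 0.55),
         note = "in-frame duplication inside the CEBPA bZIP domain",
         variant = v("CEBPA", "NM_004364.3", "c.937_939dup",
                     "p.(Lys313dup)", "inframe_insertion", "chr19",
                     33792740L, "C", "CTTG", "haematological", "AML")),
    list(name = "exc_met_ex14", expected = "Pathogenic", rule = "EXC-MET-EX14",
         vaf = 0.28, vaf_range = c(0.10, 0.50),
         note = "MET exon 14 donor splice variant (exon skipping)",
         variant = v("MET", "NM_001127500.3", "c.3028+1G>T", NA,
                     "splice_core", "chr7", 116412044L, "G", "T", "solid",
                     "lung adenocarcinoma", exon = 14L)),
    list(name = "exc_regional_benign", expected = "LikelyBenign",
         rule = "EXC-REGIONAL-BENIGN", flags = "regional_benign_candidate",
         vaf = 0.50, vaf_range = c(0.42, 0.58),
         note = "rare regional germline variant seen in 3+ local samples near 50%",
         variant = v("ALK", "NM_004304.4", "c.3735C>G", "p.(Phe1245Leu)",
                     "missense", "chr2", 29432600L, "G", "C", "solid",
                     "neuroblastoma"),
         observation_log = data.frame(
           sample_id = c("H001", "H002", "H003"),
           vaf = c(0.47, 0.51, 0.53), stringsAsFactors = FALSE)),
    # ---- Box 3: CPV hotspots --------------------------------------------
    list(name = "box3_braf_v600m", expected = "Pathogenic", rule = "BOX3-CPV",
         vaf = 0.31, vaf_range = c(0.06, 0.60),
         note = "BRAF V600M exact hotspot",
         variant = v("BRAF", "NM_004333.5", "c.1798G>A", "p.(Val600Met)",
                     "missense", "chr7", 140453137L, "C", "T", "solid",
                     "melanoma")),
    list(name = "box3_egfr_l858r", expected = "Pathogenic", rule = "BOX3-CPV",
         vaf = 0.22, vaf_range = c(0.06, 0.60),
         note = "EGFR L858R exact hotspot",
         variant = v("EGFR", "NM_005228.4", "c.2573T>G", "p.(Leu858Arg)",
                     "missense", "chr7", 55191822L, "T", "G", "solid",
                     "lung adenocarcinoma")),
    list(name = "box3_sf3b1_k666n", expected = "Pathogenic", rule = "BOX3-CPV",
         vaf = 0.35, vaf_range = c(0.06, 0.60),
         note = "SF3B1 K666N exact hotspot",
         variant = v("SF3B1", "NM_012433.3", "c.1998G>T", "p.(Lys666Asn)",
                     "missense", "chr2", 198266834L, "C", "A",
                     "haematological", "MDS")),
    list(name = "box3_jak2_v617f", expected = "Pathogenic", rule = "BOX3-CPV",
         vaf = 0.45, vaf_range = c(0.06, 0.60),
         note = "JAK2 V617F exact hotspot",
         variant = v("JAK2", "NM_004972.3", "c.1849G>T", "p.(Val617Phe)",
                     "missense", "chr9", 5073770L, "G", "T",
                     "haematological", "MPN")),
    list(name = "box3_mpl_w515", expected = "Pathogenic", rule = "BOX3-CPV",
         vaf = 0.27, vaf_range = c(0.06, 0.60),
         note = "MPL W515 any-missense hotspot",
         variant = v("MPL", "NM_005373.2", "c.1544G>T", "p.(Trp515Leu)",
                     "missense", "chr1", 43815009L, "G", "T",
                     "haematological", "MPN")),
    list(name = "box3_kit_region_del", expected = "Pathogenic",
         rule = "BOX3-CPV",
         vaf = 0.30, vaf_range = c(0.06, 0.60),
         note = "KIT exon-11 in-frame deletion inside the K550-V560 region",
         variant = v("KIT", "NM_000222.2", "c.1669_1674del",
                     "p.(Trp557_Lys558del)", "inframe_deletion", "chr4",
                     55593600L, "TTGGAAG", "T", "solid", "GIST", exon = 11L)),
    list(name = "box3_egfr_ex19del", expected = "Pathogenic",
         rule = "BOX3-CPV",
         vaf = 0.26, vaf_range = c(0.06, 0.60),
         note = "EGFR exon-19 in-frame deletion",
         variant = v("EGFR", "NM_005228.4", "c.2235_2249del",
                     "p.(Glu746_Ala750del)", "inframe_deletion", "chr7",
                     55174772L, "GGAATTAAGAGAAGCA", "G", "solid",
                     "lung adenocarcinoma", exon = 19L)),
    list(name = "box3_srsf2_span_del", expected = "Pathogenic",
         rule = "BOX3-CPV",
         vaf = 0.32, vaf_range = c(0.06, 0.60),
         note = "SRSF2 exact-span P95_R102 deletion",
         variant = v("SRSF2", "NM_003016.4", "c.284_307del",
                     "p.(Pro95_Arg102del)", "inframe_deletion", "chr17",
                     74732959L, "GGGGCGGTGGTGGCGGGGCGGACCG", "G",
                     "haematological", "MDS", exon = 1L)),
    list(name = "box3_flt3_itd", expected = "Pathogenic", rule = "BOX3-CPV",
         vaf = 0.34, vaf_range = c(0.06, 0.60),
         note = "FLT3 internal tandem duplication in exon 14",
         variant = v("FLT3", "NM_004119.2", "c.1800_1832dup",
                     "p.(Leu601_Lys611dup)", "inframe_insertion", "chr13",
                     28608250L, "A", "ACCTTTGGATTGGCTCGAGATTTCAGAGAATAT",
                     "haematological", "AML", exon = 14L)),
    # ---- Box 4: clear LoF routed by role --------------------------------
    list(name = "box4_tet2_nonsense", expected = "LikelyPathogenic",
         rule = "BOX4-TS-LOF",
         vaf = 0.36, vaf_range = c(0.06, 0.60),
         note = "TET2 S1870* nonsense in a tumour suppressor",
         variant = v("TET2", "NM_001127208.2", "c.5609C>G", "p.(Ser1870*)",
                     "nonsense", "chr4", 106197834L, "C", "G",
                     "haematological", "AML")),
    list(name = "box4_tp53_frameshift", expected = "LikelyPathogenic",
         rule = "BOX4-TS-LOF",
         vaf = 0.33, vaf_range = c(0.06, 0.60),
         note = "TP53 S149fs frameshift takes the Ts LoF route",
         variant = v("TP53", "NM_000546.5", "c.445dup",
                     "p.(Ser149Phefs*32)", "frameshift", "chr17", 7578440L,
                     "C", "CT", "haematological", "AML")),
    list(name = "box4_asxl1_true_dup", expected = "LikelyPathogenic",
         rule = "BOX4-TS-LOF",
         vaf = 0.30, vaf_range = c(0.15, 0.45),
         note = "ASXL1 c.1934dup above the stutter threshold: true variant",
         variant = v("ASXL1", "NM_015338.5", "c.1934dup",
                     "p.(Gly646Trpfs*12)", "frameshift", "chr20", 32434638L,
                     "C", "CG", "haematological", "AML")),
    list(name = "box4_kras_nonsense", expected = "VUS",
         rule = "BOX4-ONCO-LOF",
         vaf = 0.24, vaf_range = c(0.06, 0.60),
         note = "KRAS G115* nonsense cannot activate an oncogene",
         variant = v("KRAS", "NM_004985.4", "c.343G>T", "p.(Gly115*)",
                     "nonsense", "chr12", 25215440L, "C", "A", "solid",
                     "colorectal adenocarcinoma")),
    list(name = "box4_role_unknown", expected = "VUS", rule = "BOX5-SCORE",
         flags = "manual_review",
         vaf = 0.29, vaf_range = c(0.06, 0.60),
         note = "LoF in a gene without a recorded role: scoring with review",
         variant = v("STAG2", "NM_001042749.2", "c.3097C>T",
                     "p.(Arg1033*)", "nonsense", "chrX", 123196750L, "C",
                     "T", "haematological", "AML")),
    # ---- Box 5: scoring table -------------------------------------------
    list(name = "box5_egfr_s768i", expected = "LikelyPathogenic",
         rule = "BOX5-SCORE",
         vaf = 0.25, vaf_range = c(0.06, 0.60),
         note = "EGFR S768I: 265 COSMIC entries (solid +2) + both in silico",
         variant = v("EGFR", "NM_005228.4", "c.2303G>T", "p.(Ser768Ile)",
                     "missense", "chr7", 55181370L, "G", "T", "solid",
                     "lung adenocarcinoma", exon = 20L),
         evidence = ev(cosmic_count = 265L, sift_damaging = "yes",
                       mutationtaster_damaging = "yes"),
         cosmic_range = c(50L, 3000L)),
    list(name = "box5_egfr_l747p", expected = "LikelyPathogenic",
         rule = "BOX5-SCORE",
         vaf = 0.23, vaf_range = c(0.06, 0.60),
         note = "EGFR L747P resistance variant reaches 2 on the table",
         variant = v("EGFR", "NM_005228.4", "c.2239_2240delinsCC",
                     "p.(Leu747Pro)", "missense", "chr7", 55174776L, "TT",
                     "CC", "solid", "lung adenocarcinoma", exon = 19L),
         evidence = ev(cosmic_count = 30L, sift_damaging = "yes",
                       mutationtaster_damaging = "yes",
                       functional_evidence = "harmful"),
         cosmic_range = c(11L, 49L)),
    list(name = "box5_sf3b1_g740e", expected = "LikelyPathogenic",
         rule = "BOX5-SCORE",
         vaf = 0.38, vaf_range = c(0.06, 0.60),
         note = "SF3B1 G740E: 15 COSMIC entries (haematological +2)",
         variant = v("SF3B1", "NM_012433.3", "c.2219G>A", "p.(Gly740Glu)",
                     "missense", "chr2", 198266466L, "C", "T",
                     "haematological", "MDS"),
         evidence = ev(cosmic_count = 15L), cosmic_range = c(10L, 500L)),
    list(name = "box5_braf_l597r", expected = "LikelyPathogenic",
         rule = "BOX5-SCORE",
         vaf = 0.27, vaf_range = c(0.06, 0.60),
         note = "BRAF L597R: 35 entries (+1) + in silico + functional = 2.0",
         variant = v("BRAF", "NM_004333.5", "c.1790T>G", "p.(Leu597Arg)",
                     "missense", "chr7", 140453145L, "A", "C", "solid",
                     "melanoma"),
         evidence = ev(cosmic_count = 35L, sift_damaging = "yes",
                       mutationtaster_damaging = "yes",
                       functional_evidence = "harmful"),
         cosmic_range = c(11L, 49L)),
    list(name = "box5_kras_d57n", expected = "VUS", rule = "BOX5-SCORE",
         vaf = 0.21, vaf_range = c(0.06, 0.60),
         note = "KRAS D57N: 7 solid entries score 0",
         variant = v("KRAS", "NM_004985.4", "c.169G>A", "p.(Asp57Asn)",
                     "missense", "chr12", 25227300L, "C", "T", "solid",
                     "colorectal adenocarcinoma"),
         evidence = ev(cosmic_count = 7L), cosmic_range = c(0L, 10L)),
    list(name = "box5_tet2_t822p", expected = "VUS", rule = "BOX5-SCORE",
         vaf = 0.31, vaf_range = c(0.06, 0.60),
         note = "TET2 T822P: 2 haematological entries score 0",
         variant = v("TET2", "NM_001127208.2", "c.2464A>C", "p.(Thr822Pro)",
                     "missense", "chr4", 106164900L, "A", "C",
                     "haematological", "AML"),
         evidence = ev(cosmic_count = 2L), cosmic_range = c(0L, 5L)),
    list(name = "box5_srsf2_p107h", expected = "VUS", rule = "BOX5-SCORE",
         vaf = 0.29, vaf_range = c(0.06, 0.60),
         note = "SRSF2 P107H: 7 haematological entries (+1) alone stay below 2",
         variant = v("SRSF2", "NM_003016.4", "c.320C>A", "p.(Pro107His)",
                     "missense", "chr17", 74732935L, "G", "T",
                     "haematological", "MDS"),
         evidence = ev(cosmic_count = 7L), cosmic_range = c(6L, 9L)),
    list(name = "box5_nonlisted_max", expected = "Pathogenic",
         rule = "BOX5-SCORE",
         vaf = 0.40, vaf_range = c(0.06, 0.60),
         note = "maximal 3.5 in a gene outside the CPV lists: Pathogenic",
         variant = v("PTPN11", "NM_002834.4", "c.215C>T", "p.(Ala72Val)",
                     "missense", "chr12", 112450390L, "C", "T",
                     "haematological", "AML"),
         evidence = ev(cosmic_count = 60L, sift_damaging = "yes",
                       mutationtaster_damaging = "yes",
                       functional_evidence = "harmful",
                       genomic_db_verdict = "likely_pathogenic_or_pathogenic"),
         cosmic_range = c(10L, 500L)),
    list(name = "box5_listed_gene_max", expected = "LikelyPathogenic",
         rule = "BOX5-SCORE",
         vaf = 0.35, vaf_range = c(0.06, 0.60),
         note = "maximal 3.5 in a CPV-listed gene stays Likely Pathogenic",
         variant = v("SF3B1", "NM_012433.3", "c.1988C>T", "p.(Thr663Ile)",
                     "missense", "chr2", 198266844L, "G", "A",
                     "haematological", "MDS"),
         evidence = ev(cosmic_count = 40L, sift_damaging = "yes",
                       mutationtaster_damaging = "yes",
                       functional_evidence = "harmful",
                       genomic_db_verdict = "likely_pathogenic_or_pathogenic"),
         cosmic_range = c(10L, 500L)),
    list(name = "box5_override", expected = "LikelyPathogenic",
         rule = "BOX5-OVERRIDE", flags = "overruled",
         vaf = 0.26, vaf_range = c(0.06, 0.60),
         note = "curated strong evidence overrules a scoring-table VUS upward",
         variant = v("DNMT3A", "NM_175629.2", "c.2207G>A", "p.(Arg736His)",
                     "missense", "chr2", 25234373L, "C", "T",
                     "haematological", "AML"),
         evidence = ev(cosmic_count = 4L), cosmic_range = c(0L, 5L),
         override = list(new_class = "LikelyPathogenic",
                         justification = "functional studies demonstrate GoF",
                         source = "curated-panel-2019"))
  )
}

#' Generate a synthetic fixture batch with truth labels
#'
#' Produces, for every workflow branch, `n_per_branch` cases: the first is
#' the canonical (often literature) example of the branch with its exact
#' printed numbers; the rest re-draw the call-level quantities (VAF, depth,
#' and where the branch turns on them, MAF/allele number/COSMIC count)
#' uniformly inside the branch-legal interval from a seeded generator. The
#' expected class and deciding rule of every case are fixed by the branch
#' that constructed it. Output is reproducible: the same seed yields
#' identical tables and files.
#'
#' @param seed integer seed for the randomized copies.
#' @param n_per_branch cases per branch (default 5; 50 branches, so the
#'   default batch has 250 cases).
#' @param out_dir if given, writes `calls.tsv`, `annotations.tsv`,
#'   `popfreq.tsv`, `evidence.tsv`, `truth.tsv`, `observation_log.tsv`,
#'   `overrides.tsv` there.
#' @return list of class `fixture_batch` with the component tables plus
#'   `config` ([fixture_lab_config()]) and `cases` (per-case metadata).
#' @export
generate_fixtures <- function(seed = 1L, n_per_branch = 5L, out_dir = NULL) {
  stopifnot(n_per_branch >= 1L)
  set.seed(seed)
  branches <- fx_branches()

  calls <- list(); annotations <- list(); popfreq <- list()
  evidence <- list(); truth <- list(); obs <- list(); overrides <- list()
  case_id <- 0L

  for (b in branches) {
    vd <- b$variant
    for (k in seq_len(n_per_branch)) {
      case_id <- case_id + 1L
      canonical <- k == 1L
      vaf <- if (canonical) b$vaf else
        round(stats::runif(1, b$vaf_range[1], b$vaf_range[2]), 4)
      depth <- if (canonical) (b$depth %||% 1000L) else if (!is.null(b$depth_range))
        sample(seq(b$depth_range[1], b$depth_range[2]), 1L) else
          sample(500:2500, 1L)
      sample_id <- sprintf("S%04d", case_id)

      calls[[case_id]] <- data.frame(
        sample_id = sample_id, chrom = vd$chrom, pos = vd$pos, ref = vd$ref,
        alt = vd$alt, vaf = vaf, depth = depth,
        tumour_category = vd$tumour_category, tumour_type = vd$tumour_type,
        stringsAsFactors = FALSE)
      annotations[[case_id]] <- data.frame(
        chrom = vd$chrom, pos = vd$pos, ref = vd$ref, alt = vd$alt,
        gene = vd$gene, transcript = vd$transcript,
        cdna_hgvs = vd$cdna_hgvs,
        protein_hgvs = if (is.na(vd$protein_hgvs)) "." else vd$protein_hgvs,
        consequence = vd$consequence,
        exon = if (is.na(vd$exon)) "." else as.character(vd$exon),
        stringsAsFactors = FALSE)

      if (!is.null(b$popfreq)) {
        p <- b$popfreq
        if (!canonical && !is.null(b$popfreq_random)) {
          pr <- b$popfreq_random
          p$maf <- round(stats::runif(nrow(p), pr$maf_range[1],
                                      pr$maf_range[2]), 6)
          p$allele_number <- sample(seq(pr$an_range[1], pr$an_range[2]),
                                    nrow(p), replace = TRUE)
          # keep the canonical variant's snapshot: randomized copies share
          # the variant only when the branch does not randomize its snapshot
        }
        if (canonical || !is.null(b$popfreq_random)) {
          cdna <- if (canonical) vd$cdna_hgvs else
            sprintf("%s;case%d", vd$cdna_hgvs, case_id)
          popfreq[[length(popfreq) + 1L]] <- data.frame(
            gene = vd$gene, cdna_hgvs = cdna, population = p$population,
            maf = p$maf, allele_number = p$allele_number,
            dbsnp_listed = "yes", stringsAsFactors = FALSE)
        }
      }
      # randomized copies that need their own snapshot/evidence become their
      # own variant (suffixing the cDNA keeps the per-variant keying honest)
      own_variant <- !canonical &&
        (!is.null(b$popfreq_random) || !is.null(b$cosmic_range))
      if (own_variant) {
        cdna <- sprintf("%s;case%d", vd$cdna_hgvs, case_id)
        annotations[[case_id]]$cdna_hgvs <- cdna
        pos2 <- vd$pos + case_id
        annotations[[case_id]]$pos <- pos2
        calls[[case_id]]$pos <- pos2
      }

      if (!is.null(b$evidence) || !is.null(b$cosmic_range)) {
        e <- b$evidence %||% list()
        if (!canonical && !is.null(b$cosmic_range)) {
          e$cosmic_count <- sample(seq(b$cosmic_range[1], b$cosmic_range[2]),
                                   1L)
        }
        evidence[[length(evidence) + 1L]] <- data.frame(
          gene = vd$gene,
          cdna_hgvs = annotations[[case_id]]$cdna_hgvs,
          cosmic_count = e$cosmic_count %||% NA_integer_,
          sift_damaging = e$sift_damaging %||% NA_character_,
          mutationtaster_damaging = e$mutationtaster_damaging %||%
            NA_character_,
          functional_evidence = e$functional_evidence %||% NA_character_,
          genomic_db_verdict = e$genomic_db_verdict %||% NA_character_,
          tp53_iarc_class = e$tp53_iarc_class %||% NA_character_,
          tp53_seshat_class = e$tp53_seshat_class %||% NA_character_,
          brca_db_verdict = e$brca_db_verdict %||% NA_character_,
          stringsAsFactors = FALSE)
      }
      key <- make_variant_key(vd$gene, vd$transcript,
                              annotations[[case_id]]$cdna_hgvs)
      if (!is.null(b$observation_log)) {
        obs[[length(obs) + 1L]] <- data.frame(
          variant_key = key, sample_id = b$observation_log$sample_id,
          vaf = b$observation_log$vaf, stringsAsFactors = FALSE)
      }
      if (!is.null(b$override)) {
        overrides[[length(overrides) + 1L]] <- data.frame(
          gene = vd$gene, cdna_hgvs = annotations[[case_id]]$cdna_hgvs,
          new_class = b$override$new_class,
          justification = b$override$justification,
          source = b$override$source, stringsAsFactors = FALSE)
      }
      truth[[case_id]] <- data.frame(
        sample_id = sample_id, variant_key = key, branch = b$name,
        expected_class = b$expected, expected_rule = b$rule,
        expected_flags = if (is.null(b$flags)) "." else
          paste(b$flags, collapse = ","),
        note = b$note, stringsAsFactors = FALSE)
    }
  }

  dedupe <- function(lst, keys) {
    if (!length(lst)) return(NULL)
    d <- do.call(rbind, lst)
    d[!duplicated(d[, keys, drop = FALSE]), , drop = FALSE]
  }
  out <- structure(list(
    calls = do.call(rbind, calls),
    annotations = dedupe(annotations, c("chrom", "pos", "ref", "alt")),
    popfreq = dedupe(popfreq, c("gene", "cdna_hgvs", "population")),
    evidence = dedupe(evidence, c("gene", "cdna_hgvs")),
    truth = do.call(rbind, truth),
    observation_log = dedupe(obs, c("variant_key", "sample_id")),
    overrides = dedupe(overrides, c("gene", "cdna_hgvs")),
    config = fixture_lab_config(),
    seed = seed, n_per_branch = n_per_branch), class = "fixture_batch")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(d, f) {
      if (is.null(d)) d <- data.frame()
      utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE, na = ".")
    }
    w(out$calls, "calls.tsv"); w(out$annotations, "annotations.tsv")
    w(out$popfreq, "popfreq.tsv"); w(out$evidence, "evidence.tsv")
    w(out$truth, "truth.tsv"); w(out$observation_log, "observation_log.tsv")
    w(out$overrides, "overrides.tsv")
  }
  out
}

#' Exhaustive closure of the scoring table
#'
#' Enumerates, per tumour category, every combination of the four parameter
#' levels (3 COSMIC bands x 2 in-silico states x 3 functional states x 3
#' genomic-database states = 54), computes the breakdown through the scoring
#' functions and attaches the resulting class. Used as the brute-force
#' oracle for the score-algebra properties (max total 3.5, min total -2,
#' class boundary exactly at 2).
#'
#' @return data frame with 108 rows.
#' @export
enumerate_scoring_grid <- function() {
  bands <- list(solid = c(low = 7L, mid = 35L, high = 265L),
                haematological = c(low = 2L, mid = 7L, high = 15L))
  grid <- expand.grid(tumour_category = TUMOUR_CATEGORIES,
                      cosmic_band = c("low", "mid", "high"),
                      insilico = c("both", "other"),
                      functional = FUNCTIONAL_LEVELS,
                      genomicdb = GENOMICDB_LEVELS,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    eb <- evidence_bundle(
      cosmic_count = bands[[g$tumour_category]][[g$cosmic_band]],
      sift_damaging = if (g$insilico == "both") "yes" else "no",
      mutationtaster_damaging = if (g$insilico == "both") "yes" else "unknown",
      functional_evidence = g$functional,
      genomic_db_verdict = g$genomicdb)
    s <- score_variant(eb, g$tumour_category)
    cbind(g, data.frame(cosmic_score = s$cosmic_score,
                        insilico_score = s$insilico_score,
                        functional_score = s$functional_score,
                        genomicdb_score = s$genomicdb_score,
                        total = s$total,
                        class = scoring_class(s)$class,
                        stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
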