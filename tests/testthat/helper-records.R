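# Shared test constructors: a compact way to build annotated records for the
# genes the suite exercises, with call-level defaults that pass the
# technical filter.

TX <- c(ALK = "NM_004304.4", BRAF = "NM_004333.5", BRCA1 = "NM_007294.3",
        BRCA2 = "NM_000059.3", EGFR = "NM_005228.4", ESR1 = "NM_000125.3",
        GNAS = "NM_000516.5", KIT = "NM_000222.2", KRAS = "NM_004985.4",
        MET = "NM_001127500.3", CALR = "NM_004343.3", CEBPA = "NM_004364.3",
        NPM1 = "NM_002520.6", SF3B1 = "NM_012433.3", SRSF2 = "NM_003016.4",
        TET2 = "NM_001127208.2", TP53 = "NM_000546.5", JAK2 = "NM_004972.3",
        MPL = "NM_005373.2", ASXL1 = "NM_015338.5", DNMT3A = "NM_175629.2",
        STAG2 = "NM_001042749.2", PTPN11 = "NM_002834.4")

mk_record <- function(gene, cdna, protein = NA_character_,
                      consequence = "missense", category = "solid",
                      vaf = 0.30, depth = 1000L, exon = NA_integer_,
                      ref = "A", alt = "T", sample_id = "S1",
                      chrom = "chr1", pos = 1000L) {
  variant_record(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, vaf = vaf, depth = depth, gene = gene,
                 transcript = TX[[gene]], cdna_hgvs = cdna,
                 protein_hgvs = protein, consequence = consequence,
                 exon = exon, tumour_category = category,
                 tumour_type = "test")
}

test_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- load_kb()
    kb
  }
})

# ALK c.4796C>A snapshot as printed: MAF Total 0.02%, African 0.25% on
# 24,968 alleles
alk_snapshot <- function() {
  population_snapshot(
    data.frame(population = c("Total", "African"),
               maf = c(0.0002, 0.0025),
               allele_number = c(251262L, 24968L)),
    dbsnp_listed = "yes")
}
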