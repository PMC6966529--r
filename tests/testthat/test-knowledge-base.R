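# CPV list loading, validation, matching semantics and gene roles.

test_that("packaged CPV tables load with full coverage of non-empty cells", {
  solid <- test_kb()$cpv$solid
  hemato <- test_kb()$cpv$haematological
  # every gene row contributes entries unless its cell is 'none'
  expect_true(all(c("ALK", "BRAF", "BRCA1", "EGFR", "KIT", "KRAS", "MET",
                    "NRAS", "PDGFRA") %in% solid$entries$gene))
  none_genes <- c("ASXL1", "CEBPA", "RUNX1", "TET2", "WT1")
  expect_equal(sum(hemato$entries$gene %in% none_genes), 0L)
  expect_true(all(none_genes %in% hemato$listed_genes))
  expect_true(all(vapply(none_genes, cpv_listed_gene, logical(1),
                         cpv = hemato)))
  # the haematological KIT row aliases the solid entries
  expect_equal(nrow(hemato$entries[hemato$entries$gene == "KIT", ]),
               nrow(solid$entries[solid$entries$gene == "KIT", ]))
})

test_that("written CPV tables are byte-identical to the packaged files", {
  for (f in c("cpv_solid.tsv", "cpv_haematological.tsv")) {
    src <- file.path(default_kb_dir(), f)
    cpv <- load_cpv_list(src, if (f == "cpv_solid.tsv") "solid" else
                           "haematological")
    out <- file.path(tempdir(), f)
    write_cpv_list(cpv, out)
    expect_identical(readLines(out), readLines(src), label = f)
  }
})

test_that("exact hotspot matching respects the allowed alternate set", {
  kb <- test_kb()
  v600m <- mk_record("BRAF", "c.1798G>A", "p.(Val600Met)")
  expect_equal(match_cpv(v600m, kb$cpv$solid)$label, "V600E/K/M/R")
  # A is not an allowed alternate at V600
  v600a <- mk_record("BRAF", "c.1799_1800delinsCT", "p.(Val600Ala)")
  expect_null(match_cpv(v600a, kb$cpv$solid))
  # wrong reference residue at the position cannot match
  wrong_ref <- mk_record("BRAF", "c.1798G>A", "p.(Ala600Met)")
  expect_null(match_cpv(wrong_ref, kb$cpv$solid))
  # nonsense at an any-missense position does not match
  w515l <- mk_record("MPL", "c.1544G>T", "p.(Trp515Leu)",
                     category = "haematological")
  expect_equal(match_cpv(w515l, kb$cpv$haematological)$label, "W515any ms")
  w515x <- mk_record("MPL", "c.1544G>A", "p.(Trp515*)",
                     consequence = "nonsense", category = "haematological")
  hit <- match_cpv(w515x, kb$cpv$haematological)
  expect_true(is.null(hit) || hit$match_kind != "exact_aa")
})

test_that("region cells use containment and exact-span cells exact bounds", {
  kb <- test_kb()
  # interval-containment oracle over the KIT K550-V560 region: every
  # in-frame deletion span inside [550, 560] matches, any span leaving the
  # region does not
  for (start in c(550L, 555L, 558L)) {
    for (end in c(start, 560L)) {
      prot <- sprintf("p.(Lys%d_Val%ddel)", start, end)
      rec <- mk_record("KIT", sprintf("c.%d_%ddel", start * 3, end * 3),
                       prot, consequence = "inframe_deletion", exon = 11L,
                       ref = "TTTT", alt = "T")
      expect_equal(match_cpv(rec, kb$cpv$solid)$label, "K550-V560 if-indel",
                   label = prot)
    }
  }
  outside <- mk_record("KIT", "c.1750_1755del", "p.(Lys558_Gly561del)",
                       consequence = "inframe_deletion", exon = 11L,
                       ref = "TTTT", alt = "T")
  hit <- match_cpv(outside, kb$cpv$solid)
  expect_true(is.null(hit) || hit$match_kind != "aa_region")
  # SRSF2 P95_R102del is an exact span: the full span matches ...
  exact <- mk_record("SRSF2", "c.284_307del", "p.(Pro95_Arg102del)",
                     consequence = "inframe_deletion",
                     category = "haematological", ref = "GGGG", alt = "G")
  expect_equal(match_cpv(exact, test_kb()$cpv$haematological)$label,
               "P95_R102del")
  # ... a strict sub-span does not
  partial <- mk_record("SRSF2", "c.290_301del", "p.(Pro97_Arg100del)",
                       consequence = "inframe_deletion",
                       category = "haematological", ref = "GGGG", alt = "G")
  expect_null(match_cpv(partial, test_kb()$cpv$haematological))
})

test_that("exon events, splice events and clear-LoF entries match", {
  kb <- test_kb()
  ex19 <- mk_record("EGFR", "c.2235_2249del", "p.(Glu746_Ala750del)",
                    consequence = "inframe_deletion", exon = 19L,
                    ref = "GGAATTAAGAGAAGCA", alt = "G")
  expect_equal(match_cpv(ex19, kb$cpv$solid)$label, "ex19if-del/ins")
  met <- mk_record("MET", "c.3028+1G>T", NA, consequence = "splice_core",
                   exon = 14L, ref = "G", alt = "T")
  expect_equal(match_cpv(met, kb$cpv$solid)$label, "ex14 skipping")
  brca <- mk_record("BRCA1", "c.5503C>T", "p.(Arg1835*)",
                    consequence = "nonsense")
  expect_equal(match_cpv(brca, kb$cpv$solid)$match_kind, "any_clear_lof")
  # specificity: EGFR T790M (exact) wins over the exon-20 insertion cell
  t790m <- mk_record("EGFR", "c.2369C>T", "p.(Thr790Met)", exon = 20L)
  expect_equal(match_cpv(t790m, kb$cpv$solid)$label, "T790M")
})

test_that("matching is independent of entry order", {
  kb <- test_kb()
  cpv <- kb$cpv$solid
  rec <- mk_record("EGFR", "c.2369C>T", "p.(Thr790Met)", exon = 20L)
  set.seed(42)
  for (i in 1:5) {
    shuffled <- cpv
    shuffled$entries <- cpv$entries[sample(nrow(cpv$entries)), ]
    expect_equal(match_cpv(rec, shuffled)$label, "T790M")
  }
})

test_that("malformed knowledge tables are load errors", {
  bad <- file.path(tempdir(), "bad_cpv.tsv")
  writeLines(c("gene\ttranscript\tmatch_kind\tposition\tend_position\texon\tallowed_alts\tevent_class\tlabel",
               "BRAF\tNM_004333.5\texact_aa\t.\t.\t.\tE\tsubstitution\tV600E"),
             bad)
  expect_error(load_cpv_list(bad, "solid"), "malformed CPV row")
  dup <- file.path(tempdir(), "dup_cpv.tsv")
  writeLines(c("gene\ttranscript\tmatch_kind\tposition\tend_position\texon\tallowed_alts\tevent_class\tlabel",
               "BRAF\tNM_004333.5\texact_aa\t600\t.\t.\tE\tsubstitution\tV600E",
               "BRAF\tNM_004333.5\texact_aa\t600\t.\t.\tE\tsubstitution\tV600E"),
             dup)
  expect_error(load_cpv_list(dup, "solid"), "duplicate exact_aa")
})

test_that("gene roles resolve by tumour category, unknown genes return NA", {
  roles <- test_kb()$roles
  expect_equal(lookup_role(roles, "TET2", "haematological"),
               "tumour_suppressor")
  expect_equal(lookup_role(roles, "KRAS", "solid"), "oncogene")
  expect_equal(lookup_role(roles, "BRCA2", "solid"), "tumour_suppressor")
  expect_true(is.na(lookup_role(roles, "NOT_A_GENE", "solid")))
})

test_that("evidence lookups degrade to all-unknown, never to pathogenic", {
  eb <- get_evidence(NULL, "EGFR", "c.1A>T")
  expect_true(is.na(eb$cosmic_count))
  expect_equal(eb$sift_damaging, "unknown")
  expect_equal(eb$functional_evidence, "not_reported")
  expect_equal(eb$genomic_db_verdict, "not_described")
  expect_error(evidence_bundle(cosmic_count = -1), "non-negative")
  snap <- get_snapshot(NULL, "EGFR", "c.1A>T")
  expect_equal(nrow(snap$populations), 0L)
})
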