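# Gene-specific exception handlers.

exc <- function(record, evidence = evidence_bundle(), log = NULL,
                config = lab_config()) {
  apply_exceptions(record, evidence, test_kb(), config, log)
}

test_that("CALR exon-9 out-of-frame indels are consensus pathogenic", {
  type1 <- mk_record("CALR", "c.1092_1143del", "p.(Leu367Thrfs*46)",
                     consequence = "frameshift", category = "haematological",
                     exon = 9L,
                     ref = "CAGAGGACAAGTTGTCAGAGGACAAGTTGTCAGAGGACAAGTTGTCAGAGGA",
                     alt = "C")
  out <- exc(type1)
  expect_equal(out$class, "Pathogenic")
  expect_equal(out$rule_id, "EXC-CALR-EX9")
  type2 <- mk_record("CALR", "c.1154_1155insTTGTC", "p.(Lys385Asnfs*47)",
                     consequence = "frameshift", category = "haematological",
                     exon = 9L, ref = "A", alt = "ATTGTC")
  expect_equal(exc(type2)$class, "Pathogenic")
  # an out-of-frame CALR indel outside exon 9 is not covered by the handler
  other <- mk_record("CALR", "c.500del", "p.(Leu167fs)",
                     consequence = "frameshift", category = "haematological",
                     exon = 5L, ref = "CT", alt = "C")
  expect_null(exc(other))
})

test_that("NPM1 exon-11 insertion and MET exon-14 splice are pathogenic", {
  npm1 <- mk_record("NPM1", "c.860_863dup", "p.(Trp288Cysfs*12)",
                    consequence = "frameshift", category = "haematological",
                    exon = 11L, ref = "C", alt = "CTCTG")
  expect_equal(exc(npm1)$rule_id, "EXC-NPM1-EX11")
  expect_equal(exc(npm1)$class, "Pathogenic")
  # a deletion in exon 11 is not the NPM1 exception
  del11 <- mk_record("NPM1", "c.860del", "p.(Trp288fs)",
                     consequence = "frameshift",
                     category = "haematological", exon = 11L, ref = "CT",
                     alt = "C")
  expect_null(exc(del11))
  met <- mk_record("MET", "c.3028+1G>T", NA, consequence = "splice_core",
                   exon = 14L)
  expect_equal(exc(met)$class, "Pathogenic")
  expect_equal(exc(met)$rule_id, "EXC-MET-EX14")
})

test_that("TP53: splice LP, database consensus, disagreement falls through", {
  spl <- mk_record("TP53", "c.673-1G>A", NA, consequence = "splice_core",
                   exon = 7L)
  out <- exc(spl)
  expect_equal(out$class, "LikelyPathogenic")
  expect_equal(out$rule_id, "EXC-TP53-SPLICE")
  mis <- mk_record("TP53", "c.451C>T", "p.(Pro151Ser)")
  both_p <- evidence_bundle(tp53_iarc_class = "Pathogenic",
                            tp53_seshat_class = "Pathogenic")
  expect_equal(exc(mis, both_p)$class, "Pathogenic")
  both_lb <- evidence_bundle(tp53_iarc_class = "LikelyBenign",
                             tp53_seshat_class = "LikelyBenign")
  expect_equal(exc(mis, both_lb)$class, "LikelyBenign")
  disagree <- evidence_bundle(tp53_iarc_class = "Pathogenic",
                              tp53_seshat_class = "VUS")
  out2 <- exc(mis, disagree)
  expect_null(out2$class)
  expect_true("manual_review" %in% out2$flags)
  missing <- exc(mis, evidence_bundle())
  expect_null(missing$class)
  expect_true("manual_review" %in% missing$flags)
  # frameshift/nonsense TP53 take the general Ts LoF route
  fs <- mk_record("TP53", "c.445dup", "p.(Ser149Phefs*32)",
                  consequence = "frameshift", ref = "C", alt = "CT")
  expect_null(exc(fs))
})

test_that("TP53 CPV hotspots are never demoted by the handler", {
  r175h <- mk_record("TP53", "c.524G>A", "p.(Arg175His)",
                     category = "haematological")
  # even with a benign database consensus, the handler stands aside
  ev <- evidence_bundle(tp53_iarc_class = "LikelyBenign",
                        tp53_seshat_class = "LikelyBenign")
  expect_null(exc(r175h, ev))
  res <- classify_record(r175h, evidence = ev, kb = test_kb())
  expect_equal(res$biological_class, "Pathogenic")
  expect_true("BOX3-CPV" %in% res$rule_trail$rule_id)
})

test_that("BRCA clear LoF is Pathogenic; last exon routes to the database", {
  nons <- mk_record("BRCA2", "c.5857G>T", "p.(Glu1953*)",
                    consequence = "nonsense", exon = 11L)
  out <- exc(nons)
  expect_equal(out$class, "Pathogenic")
  expect_equal(out$rule_id, "EXC-BRCA-LOF")
  last <- mk_record("BRCA1", "c.5503C>T", "p.(Arg1835*)",
                    consequence = "nonsense", exon = 24L)
  lp <- exc(last, evidence_bundle(
    brca_db_verdict = "likely_pathogenic_or_pathogenic"))
  expect_equal(lp$class, "LikelyPathogenic")
  expect_equal(lp$rule_id, "EXC-BRCA-DB")
  lb <- exc(last, evidence_bundle(brca_db_verdict = "likely_benign_or_benign"))
  expect_equal(lb$class, "LikelyBenign")
  none <- exc(last, evidence_bundle())
  expect_null(none$class)
  expect_true("manual_review" %in% none$flags)
  # non-LoF BRCA variants also take the database route
  mis <- mk_record("BRCA2", "c.1114A>C", "p.(Asn372His)", exon = 10L)
  expect_true("manual_review" %in% exc(mis, evidence_bundle())$flags)
})

test_that("CEBPA in-frame indels fire only inside the bZIP domain", {
  bzip <- mk_record("CEBPA", "c.937_939dup", "p.(Lys313dup)",
                    consequence = "inframe_insertion",
                    category = "haematological", ref = "C", alt = "CTTG")
  out <- exc(bzip)
  expect_equal(out$class, "LikelyPathogenic")
  expect_equal(out$rule_id, "EXC-CEBPA-BZIP")
  nterm <- mk_record("CEBPA", "c.100_102del", "p.(Lys34del)",
                     consequence = "inframe_deletion",
                     category = "haematological", ref = "CTTG", alt = "C")
  expect_null(exc(nterm))
})

test_that("regional rare benign rescue fires on history, never on hotspots", {
  rec <- mk_record("ALK", "c.3735C>G", "p.(Phe1245Leu)", vaf = 0.5)
  log <- data.frame(variant_key = variant_key(rec),
                    sample_id = c("a", "b", "c"), vaf = c(0.47, 0.5, 0.53))
  out <- exc(rec, log = log)
  expect_equal(out$class, "LikelyBenign")
  expect_true("regional_benign_candidate" %in% out$flags)
  expect_null(exc(rec, log = log[1:2, ]))
  # a CPV hotspot with the same history is not rescued
  hot <- mk_record("BRAF", "c.1799T>A", "p.(Val600Glu)", vaf = 0.5)
  hotlog <- data.frame(variant_key = variant_key(hot),
                       sample_id = c("a", "b", "c"), vaf = 0.5)
  expect_null(exc(hot, log = hotlog))
  expect_equal(classify_record(hot, kb = test_kb(),
                               observation_log = hotlog)$biological_class,
               "Pathogenic")
})
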