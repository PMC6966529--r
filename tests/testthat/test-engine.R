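# End-to-end record and batch classification, stores, and I/O.

test_that("worked examples route through the documented boxes", {
  kb <- test_kb()
  # EGFR L858R: hotspot, Pathogenic via Box 3
  l858r <- classify_record(mk_record("EGFR", "c.2573T>G", "p.(Leu858Arg)",
                                     vaf = 0.22), kb = kb)
  expect_equal(l858r$biological_class, "Pathogenic")
  expect_equal(l858r$rule_trail$rule_id[nrow(l858r$rule_trail)], "BOX3-CPV")
  expect_null(l858r$score)
  # ALK P1599H with the printed snapshot: Likely Benign via Box 2
  alk <- classify_record(mk_record("ALK", "c.4796C>A", "p.(Pro1599His)",
                                   vaf = 0.48),
                         snapshot = alk_snapshot(), kb = kb)
  expect_equal(alk$biological_class, "LikelyBenign")
  expect_equal(alk$rule_trail$rule_id[nrow(alk$rule_trail)], "BOX2-POPFREQ")
  # EGFR L747P with strong evidence: Likely Pathogenic via the scoring table
  l747p <- classify_record(
    mk_record("EGFR", "c.2239_2240delinsCC", "p.(Leu747Pro)", exon = 19L,
              ref = "TT", alt = "CC"),
    evidence = evidence_bundle(cosmic_count = 30L, sift_damaging = "yes",
                               mutationtaster_damaging = "yes",
                               functional_evidence = "harmful"),
    kb = kb)
  expect_equal(l747p$biological_class, "LikelyPathogenic")
  expect_false(is.null(l747p$score))
  expect_identical(l747p$score$total, 2)
})

test_that("every result carries a non-empty ordered rule trail", {
  kb <- test_kb()
  res <- classify_record(mk_record("KRAS", "c.519T>C",
                                   consequence = "synonymous"), kb = kb)
  expect_true(is.na(res$biological_class))
  expect_gte(nrow(res$rule_trail), 1L)
  expect_equal(res$rule_trail$rule_id[1], "BOX1-FILTER")
  # dropped hotspot below the gate is flagged for re-analysis
  low <- classify_record(mk_record("EGFR", "c.2573T>G", "p.(Leu858Arg)",
                                   vaf = 0.02), kb = kb)
  expect_true(is.na(low$biological_class))
  expect_true("reanalysis_suggested" %in% low$flags)
})

test_that("role-unknown LoF goes to the scoring table with review", {
  res <- classify_record(mk_record("STAG2", "c.3097C>T", "p.(Arg1033*)",
                                   consequence = "nonsense",
                                   category = "haematological"),
                         kb = test_kb())
  expect_equal(res$biological_class, "VUS")
  expect_true("manual_review" %in% res$flags)
  expect_true("BOX4-ROLE-UNKNOWN" %in% res$rule_trail$rule_id)
  expect_false(is.null(res$score))
})

test_that("batch runs are idempotent and order-invariant", {
  fx <- generate_fixtures(seed = 11, n_per_branch = 2)
  kb <- test_kb()
  run <- function(calls, dir) {
    classify_batch(calls, fx$annotations, fx$popfreq, fx$evidence, kb = kb,
                   config = fx$config,
                   observation_log = fx$observation_log,
                   overrides = fx$overrides, out_dir = dir)
  }
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  b1 <- run(fx$calls, d1)
  b2 <- run(fx$calls[rev(seq_len(nrow(fx$calls))), ], d2)
  expect_identical(b1$results, b2$results)
  for (f in c("results.tsv", "results.json", "manifest.json",
              "review_queue.tsv", "reanalysis.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # every kept record got exactly one of the five classes
  kept <- b1$results[b1$results$kept, ]
  expect_true(all(kept$biological_class %in% BIO_CLASSES))
  expect_equal(b1$manifest$records_classified, nrow(kept))
})

test_that("empty batches and per-sample duplicates are handled", {
  kb <- test_kb()
  empty <- classify_batch(
    data.frame(sample_id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               vaf = numeric(), depth = integer(),
               tumour_category = character(), tumour_type = character()),
    annotations = data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             gene = character(), transcript = character(),
                             cdna_hgvs = character(),
                             protein_hgvs = character(),
                             consequence = character(), exon = character()),
    kb = kb)
  expect_equal(nrow(empty$results), 0L)
  expect_equal(empty$manifest$records_in, 0L)
  # the same variant in two samples yields two independent results
  calls <- data.frame(sample_id = c("P1", "P2"), chrom = "chr7",
                      pos = 55191822L, ref = "T", alt = "G",
                      vaf = c(0.22, 0.4), depth = 1000L,
                      tumour_category = "solid", tumour_type = "lung")
  ann <- data.frame(chrom = "chr7", pos = 55191822L, ref = "T", alt = "G",
                    gene = "EGFR", transcript = "NM_005228.4",
                    cdna_hgvs = "c.2573T>G",
                    protein_hgvs = "p.(Leu858Arg)", consequence = "missense",
                    exon = "21")
  two <- classify_batch(calls, ann, kb = kb)
  expect_equal(nrow(two$results), 2L)
  expect_equal(unique(two$results$biological_class), "Pathogenic")
  # unannotated calls are skipped, not fatal
  calls2 <- rbind(calls,
                  data.frame(sample_id = "P3", chrom = "chr1", pos = 5L,
                             ref = "A", alt = "T", vaf = 0.3, depth = 900L,
                             tumour_category = "solid",
                             tumour_type = "lung"))
  three <- classify_batch(calls2, ann, kb = kb)
  expect_equal(three$manifest$records_skipped, 1L)
  expect_equal(nrow(three$results), 2L)
})

test_that("minimal VCF input is read through vcfR", {
  vcf <- file.path(tempdir(), "mini.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1",
    "chr7\t55191822\t.\tT\tG\t.\tPASS\t.\tGT:DP:AF\t0/1:1200:0.22"),
    vcf)
  calls <- read_calls(vcf, tumour_category = "solid", tumour_type = "lung")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$vaf, 0.22)
  expect_equal(calls$depth, 1200L)
  expect_equal(calls$pos, 55191822L)
})

test_that("the store records switches and flags downgrades for review", {
  fx <- generate_fixtures(seed = 3, n_per_branch = 1)
  kb <- test_kb()
  b <- classify_batch(fx$calls, fx$annotations, fx$popfreq, fx$evidence,
                      kb = kb, config = fx$config,
                      observation_log = fx$observation_log,
                      overrides = fx$overrides)
  store <- update_store(load_store(file.path(tempdir(), "no_such_store.tsv")),
                        b, date = "2019-01-01")
  # identical run: no switches
  expect_equal(nrow(diff_store(store, b)), 0L)
  # force one upgrade and one downgrade
  res2 <- b$results
  i_vus <- which(res2$biological_class == "VUS")[1]
  i_path <- which(res2$biological_class == "Pathogenic")[1]
  res2$biological_class[i_vus] <- "LikelyPathogenic"
  res2$biological_class[i_path] <- "VUS"
  d <- diff_store(store, res2)
  expect_equal(nrow(d), 2L)
  up <- d[d$variant_key == res2$variant_key[i_vus], ]
  down <- d[d$variant_key == res2$variant_key[i_path], ]
  expect_equal(up$direction, "upgrade")
  expect_false(up$review)
  expect_equal(down$direction, "downgrade")
  expect_true(down$review)
  # history is append-only: the switch adds a row, the old row remains
  store2 <- update_store(store, res2, date = "2019-06-01")
  expect_gt(nrow(store2), nrow(store))
  expect_equal(unname(current_classes(store2)[res2$variant_key[i_vus]]),
               "LikelyPathogenic")
  # round-trip through disk
  p <- file.path(tempdir(), "store_rt.tsv")
  write_store(store2, p)
  expect_equal(nrow(load_store(p)), nrow(store2))
})
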