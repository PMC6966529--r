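# Scoring table (Box 5) and LoF routing (Boxes 3-4).

test_that("COSMIC parameter reproduces the printed worked examples", {
  # solid: EGFR S768I 265 entries +2; BRAF L597R 35 entries +1;
  # KRAS D57N 7 entries 0
  expect_identical(cosmic_score(265L, "solid"), 2)
  expect_identical(cosmic_score(35L, "solid"), 1)
  expect_identical(cosmic_score(7L, "solid"), 0)
  # haematological: SF3B1 G740E 15 entries +2; SRSF2 P107H 7 entries +1;
  # TET2 T822P 2 entries 0
  expect_identical(cosmic_score(15L, "haematological"), 2)
  expect_identical(cosmic_score(7L, "haematological"), 1)
  expect_identical(cosmic_score(2L, "haematological"), 0)
})

test_that("COSMIC bands have the stated boundaries", {
  expect_identical(cosmic_score(10L, "solid"), 0)
  expect_identical(cosmic_score(11L, "solid"), 1)
  expect_identical(cosmic_score(49L, "solid"), 1)
  expect_identical(cosmic_score(50L, "solid"), 2)
  expect_identical(cosmic_score(5L, "haematological"), 0)
  expect_identical(cosmic_score(6L, "haematological"), 1)
  expect_identical(cosmic_score(9L, "haematological"), 1)
  expect_identical(cosmic_score(10L, "haematological"), 2)
  expect_identical(cosmic_score(NA_integer_, "solid"), 0)
  expect_error(cosmic_score(-1L, "solid"), "non-negative")
})

test_that("in-silico parameter: +0.5 only when both tools are damaging", {
  states <- c("yes", "no", "unknown")
  for (s in states) for (m in states) {
    expect_identical(insilico_score(s, m),
                     if (s == "yes" && m == "yes") 0.5 else 0,
                     label = paste(s, m))
  }
})

test_that("score totals match the printed examples", {
  # EGFR S768I, solid, 265 entries + both tools damaging
  s <- score_variant(evidence_bundle(cosmic_count = 265L,
                                     sift_damaging = "yes",
                                     mutationtaster_damaging = "yes"),
                     "solid")
  expect_identical(s$total, 2.5)
  # TET2 T822P, haematological, two entries, nothing else
  s0 <- score_variant(evidence_bundle(cosmic_count = 2L), "haematological")
  expect_identical(s0$total, 0)
  # intermediate count with negative functional and database evidence
  sneg <- score_variant(evidence_bundle(
    cosmic_count = 35L, sift_damaging = "yes",
    mutationtaster_damaging = "no", functional_evidence = "shown_benign",
    genomic_db_verdict = "likely_benign_or_benign"), "solid")
  expect_identical(sneg$total, -1)
})

# Independent brute-force oracle: the four parameter level sets written out
# literally, summed with plain arithmetic — no scoring function involved.
oracle_grid <- function() {
  g <- expand.grid(cosmic = c(0, 1, 2), insilico = c(0, 0.5),
                   functional = c(0.5, 0, -1), genomicdb = c(0.5, 0, -1))
  g$total <- g$cosmic + g$insilico + g$functional + g$genomicdb
  g
}

test_that("exhaustive enumeration: extremes and the class boundary at 2", {
  g <- oracle_grid()
  expect_equal(nrow(g), 54L)
  expect_equal(max(g$total), 3.5)
  expect_equal(min(g$total), -2)
  # cross-check against the engine's own enumeration, per tumour category
  grid <- enumerate_scoring_grid()
  expect_equal(nrow(grid), 108L)
  for (cat in c("solid", "haematological")) {
    sub <- grid[grid$tumour_category == cat, ]
    expect_equal(sort(sub$total), sort(g$total))
    expect_equal(min(sub$total[sub$class == "LikelyPathogenic"]), 2)
    expect_equal(max(sub$total[sub$class == "VUS"]), 1.5)
    # classifier agrees with the plain threshold on all 54 cells
    expect_equal(sub$class, ifelse(sub$total >= 2, "LikelyPathogenic",
                                   "VUS"))
  }
})

test_that("upgrading any parameter never lowers the class", {
  grid <- enumerate_scoring_grid()
  pole <- list(cosmic_band = c("low", "mid", "high"),
               insilico = c("other", "both"),
               functional = c("shown_benign", "not_reported", "harmful"),
               genomicdb = c("likely_benign_or_benign", "not_described",
                             "likely_pathogenic_or_pathogenic"))
  rank <- function(x) match(x, c("VUS", "LikelyPathogenic"))
  for (param in names(pole)) {
    lv <- pole[[param]]
    for (i in seq_len(length(lv) - 1L)) {
      lo <- grid[grid[[param]] == lv[i], ]
      hi <- grid[grid[[param]] == lv[i + 1L], ]
      others <- setdiff(c("tumour_category", names(pole)), param)
      key <- function(d) do.call(paste, d[others])
      m <- match(key(lo), key(hi))
      expect_true(all(rank(hi$class[m]) >= rank(lo$class)),
                  label = param)
    }
  }
})

test_that("scoring class upgrades to Pathogenic only off the CPV lists", {
  max_ev <- evidence_bundle(cosmic_count = 60L, sift_damaging = "yes",
                            mutationtaster_damaging = "yes",
                            functional_evidence = "harmful",
                            genomic_db_verdict =
                              "likely_pathogenic_or_pathogenic")
  s <- score_variant(max_ev, "haematological")
  expect_identical(s$total, 3.5)
  expect_equal(scoring_class(s, gene_is_cpv_listed = FALSE)$class,
               "Pathogenic")
  expect_equal(scoring_class(s, gene_is_cpv_listed = TRUE)$class,
               "LikelyPathogenic")
  mid <- score_variant(evidence_bundle(cosmic_count = 265L,
                                       sift_damaging = "yes",
                                       mutationtaster_damaging = "yes"),
                       "solid")
  expect_equal(scoring_class(mid, gene_is_cpv_listed = TRUE)$class,
               "LikelyPathogenic")
  low <- score_variant(evidence_bundle(cosmic_count = 35L), "solid")
  expect_equal(scoring_class(low)$class, "VUS")
})

test_that("overrides only raise classes", {
  low <- score_variant(evidence_bundle(cosmic_count = 2L), "haematological")
  up <- scoring_class(low, TRUE,
                      override = list(new_class = "LikelyPathogenic"))
  expect_equal(up$class, "LikelyPathogenic")
  expect_true(up$overruled)
  expect_error(
    scoring_class(score_variant(evidence_bundle(cosmic_count = 265L,
                                                sift_damaging = "yes",
                                                mutationtaster_damaging = "yes"),
                                "solid"),
                  TRUE, override = list(new_class = "VUS")),
    "only raise")
})

test_that("clear LoF definition and role routing", {
  fs <- mk_record("TET2", "c.419del", "p.(Asn140Metfs*5)",
                  consequence = "frameshift", category = "haematological",
                  ref = "CA", alt = "C")
  expect_true(is_clear_lof(fs))
  expect_true(is_clear_lof(mk_record("MET", "c.3028+1G>T", NA,
                                     consequence = "splice_core",
                                     exon = 14L)))
  expect_false(is_clear_lof(mk_record("KIT", "c.1669_1674del",
                                      "p.(Trp557_Lys558del)",
                                      consequence = "inframe_deletion",
                                      ref = "TTTT", alt = "T")))
  # TET2 S1870* -> Likely Pathogenic; KRAS G115* -> VUS
  tet2 <- mk_record("TET2", "c.5609C>G", "p.(Ser1870*)",
                    consequence = "nonsense", category = "haematological")
  expect_equal(classify_lof(tet2, "tumour_suppressor"), "LikelyPathogenic")
  kras <- mk_record("KRAS", "c.343G>T", "p.(Gly115*)",
                    consequence = "nonsense")
  expect_equal(classify_lof(kras, "oncogene"), "VUS")
  # never Pathogenic or Benign, for either role
  for (role in c("tumour_suppressor", "oncogene")) {
    expect_true(classify_lof(tet2, role) %in% c("LikelyPathogenic", "VUS"))
  }
})

test_that("CPV classification returns Pathogenic with the matched label", {
  kb <- test_kb()
  k666n <- mk_record("SF3B1", "c.1998G>T", "p.(Lys666Asn)",
                     category = "haematological")
  hit <- classify_cpv(k666n, kb)
  expect_equal(hit$class, "Pathogenic")
  expect_equal(hit$label, "K666N/R/T")
  l747p <- mk_record("EGFR", "c.2239_2240delinsCC", "p.(Leu747Pro)",
                     exon = 19L, ref = "TT", alt = "CC")
  expect_null(classify_cpv(l747p, kb))
})
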