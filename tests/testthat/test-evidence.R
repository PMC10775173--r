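test_that("PS4 strength bands match exhaustive enumeration of case counts", {
  # independent oracle: band membership from the stated cutpoints 1/2/4/16
  oracle <- function(k) {
    if (k >= 16) "very_strong" else if (k >= 4) "strong"
    else if (k >= 2) "moderate" else if (k >= 1) "supporting" else NA_character_
  }
  for (k in 0:20) {
    got <- assign_ps4(k)
    if (k == 0) expect_equal(nrow(got), 0L)
    else expect_equal(got$strength, oracle(k), label = paste("count", k))
  }
  expect_error(assign_ps4(-1), "non-negative")
})

test_that("PS4 strength is non-decreasing in the reported case count", {
  lev <- c(none = 0, supporting = 1, moderate = 2, strong = 3, very_strong = 4)
  ranks <- vapply(0:20, function(k) {
    es <- assign_ps4(k)
    if (nrow(es) == 0) lev[["none"]] else lev[[es$strength]]
  }, numeric(1))
  expect_false(is.unsorted(ranks))
})

test_that("REVEL bands partition the score axis with at most one code firing", {
  grid <- seq(0, 1, by = 0.0005)
  for (r in grid) {
    es <- assign_pp3_bp4_missense(r)
    expect_lte(nrow(es), 1L)
    if (r > 0.290 && r < 0.644) expect_equal(nrow(es), 0L)
  }
  expect_equal(assign_pp3_bp4_missense(0.845)$strength, "moderate")
  expect_equal(assign_pp3_bp4_missense(0.946)$strength, "moderate")  # capped
  expect_equal(assign_pp3_bp4_missense(0.946)$code, "PP3")
  expect_equal(assign_pp3_bp4_missense(0.696),
               tibble::tibble(code = "PP3", strength = "supporting"))
  expect_equal(assign_pp3_bp4_missense(0.242),
               tibble::tibble(code = "BP4", strength = "supporting"))
  expect_equal(assign_pp3_bp4_missense(0.1)$strength, "moderate")
  expect_equal(assign_pp3_bp4_missense(0.01)$strength, "strong")
  expect_equal(assign_pp3_bp4_missense(0.001)$strength, "very_strong")
  # band edges
  expect_equal(assign_pp3_bp4_missense(0.644)$strength, "supporting")
  expect_equal(assign_pp3_bp4_missense(0.733)$strength, "moderate")
  expect_equal(assign_pp3_bp4_missense(0.290)$code, "BP4")
})

test_that("SpliceAI gates yield PP3 above 0.2 and BP7 below 0.01, never both", {
  grid <- seq(0, 1, by = 0.001)
  for (s in grid) {
    es <- assign_splice_pp3_bp7(s)
    expect_lte(nrow(es), 1L)
  }
  expect_equal(assign_splice_pp3_bp7(0.73)$code, "PP3")
  expect_equal(assign_splice_pp3_bp7(0.36)$code, "PP3")
  expect_equal(assign_splice_pp3_bp7(0.005)$code, "BP7")
  expect_equal(nrow(assign_splice_pp3_bp7(0.2)), 0L)   # exclusive bounds
  expect_equal(nrow(assign_splice_pp3_bp7(0.01)), 0L)
  expect_equal(nrow(assign_splice_pp3_bp7(0.1)), 0L)
})

test_that("PVS1 strength tracks NMD prediction and deletion extent", {
  f8 <- gene_model("F8")
  expect_equal(assign_pvs1("nonsense", f8, ptc_cdna_pos = 208)$strength,
               "very_strong")
  expect_equal(assign_pvs1("indel", f8, ptc_cdna_pos = 7150)$strength,
               "strong")  # frameshift terminating in the last exon
  expect_equal(assign_pvs1("canonical_splice", f8)$strength, "very_strong")
  expect_equal(assign_pvs1("gross_deletion", f8, exons_del_from = 26,
                           exons_del_to = 26)$strength, "strong")
  expect_equal(assign_pvs1("gross_deletion", f8, exons_del_from = 15,
                           exons_del_to = 26)$strength, "very_strong")
  expect_equal(assign_pvs1("gross_deletion", f8, exons_del_from = 1,
                           exons_del_to = 1)$strength, "very_strong")
  expect_equal(nrow(assign_pvs1("missense", f8)), 0L)
  expect_error(assign_pvs1("gross_deletion", f8), "deleted-exon range")
})

test_that("computed PVS1 strengths agree with the printed loss-of-function column", {
  v <- hem_fixture("variants")
  cl <- fixture_classified()
  rows <- !is.na(v$autopvs1_printed)
  expected <- c(`Very Strong` = "very_strong", Strong = "strong")[v$autopvs1_printed[rows]]
  got <- vapply(parse_criteria(cl$criteria[rows]), function(es) {
    i <- match("PVS1", es$code)
    if (is.na(i)) NA_character_ else es$strength[i]
  }, character(1))
  expect_equal(unname(got), unname(expected))
})

test_that("PM1 requires a functional domain and excludes the F8 B domain", {
  f8 <- gene_model("F8"); f9 <- gene_model("F9")
  expect_equal(assign_pm1("missense", f8, 67)$code, "PM1")
  expect_equal(nrow(assign_pm1("missense", f8, 845)), 0L)   # B domain
  expect_equal(nrow(assign_pm1("missense", f8, 355)), 0L)   # inter-domain
  expect_equal(assign_pm1("missense", f9, 43)$code, "PM1")  # F9 has no exclusion
  expect_equal(nrow(assign_pm1("nonsense", f8, 67)), 0L)
})

test_that("PM2 is always supporting; PP4 gates on the activity bound", {
  expect_equal(assign_pm2(TRUE)$strength, "supporting")
  expect_equal(nrow(assign_pm2(FALSE)), 0L)
  expect_equal(assign_pp4(parse_activity("<1")$bound)$code, "PP4")
  expect_equal(nrow(assign_pp4(NA_real_)), 0L)
  expect_equal(assign_pp4(39.9)$code, "PP4")
  expect_equal(nrow(assign_pp4(40)), 0L)
  expect_equal(assign_pp4(c(NA, 50, 12))$code, "PP4")  # any linked patient
})

test_that("criteria strings round-trip through the compact notation", {
  s <- c("PVS1, PS4-M, PM2-PP, PP4", "BS2, BP2, BP4", "PS4-VS, PM1, PM2-PP, PP3, PP4")
  expect_equal(vapply(parse_criteria(s), format_criteria, character(1)), s)
  # suffix synonyms normalize
  expect_equal(norm_criteria("PVS1-PS, PS4-PP, PM2-PP, PP4"),
               "PVS1-S, PS4-PP, PM2-PP, PP4")
  expect_equal(norm_criteria("PM1, PM2-PP, PP3-PM, PP4"),
               "PM1, PM2-PP, PP3-M, PP4")
  expect_error(parse_criteria("PX9"), "unknown criterion")
})

test_that("co-occurrence with a pathogenic variant adds BP2 and withholds PM1/PP4", {
  variants <- tibble::tibble(
    gene = "F8",
    nucleotide = c("c.871G>A", "c.2535C>A"),
    protein = c("p.Glu291Lys", "p.Asp845Glu"),
    revel = c(0.828, 0.242),
    absent_from_population = c(TRUE, FALSE),
    reported_case_count = c(4L, 0L),
    bs2 = c(FALSE, TRUE)
  )
  patients <- tibble::tibble(
    patient_id = c("A", "B"), gene = "F8",
    variants = c("c.871G>A;c.2535C>A", "c.871G>A"),
    activity = c("4.7", "5")
  )
  cl <- classify_variants(variants, patients)
  expect_equal(cl$criteria[1], "PS4, PM1, PM2-PP, PP3-M, PP4")
  expect_equal(cl$classification[1], "P")
  expect_equal(cl$criteria[2], "BS2, BP2, BP4")
  expect_equal(cl$classification[2], "LB")
  # a lone benign variant gets no BP2
  lone <- classify_variants(variants[2, ], patients[1, ])
  expect_false(grepl("BP2", lone$criteria))
})

test_that("evidence overrides replace the computed set and are flagged", {
  v <- tibble::tibble(gene = "F8", nucleotide = "c.1649G>A", protein = "p.Arg550His",
                      revel = 0.738, absent_from_population = TRUE,
                      reported_case_count = 4L,
                      override_criteria = "PS4, PM1, PM2-PP, PP3, PP4")
  p <- tibble::tibble(patient_id = "X", gene = "F8", variants = "c.1649G>A",
                      activity = "19.1")
  cl <- classify_variants(v, p)
  expect_true(cl$overridden)
  expect_equal(cl$criteria, "PS4, PM1, PM2-PP, PP3, PP4")
  expect_equal(cl$classification, "LP")
  cl2 <- classify_variants(dplyr::select(v, -"override_criteria"), p)
  expect_equal(cl2$criteria, "PS4, PM1, PM2-PP, PP3-M, PP4")
  expect_equal(cl2$classification, "P")
})

test_that("no benign code exceeds strong except banded BP4", {
  cl <- fixture_classified()
  for (es in parse_criteria(cl$criteria[!is.na(cl$classification)])) {
    ben <- es[es$code %in% c("BS2", "BP2", "BP7"), ]
    expect_true(all(ben$strength %in% c("strong", "supporting")))
  }
})
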