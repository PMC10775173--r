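es_of <- function(s) parse_criteria(s)[[1]]

test_that("points mode sums signed strength points into tiers", {
  expect_equal(combine_points(es_of("PVS1, PM2-PP")),
               list(classification = "LP", score = 9))
  expect_equal(combine_points(es_of("PVS1, PS4, PM2-PP, PP4")),
               list(classification = "P", score = 14))
  expect_equal(combine_points(es_of("BS2, BP2, BP4")),
               list(classification = "LB", score = -6))
  expect_equal(combine_points(tibble::tibble(code = character(),
                                             strength = character())),
               list(classification = "VUS", score = 0))
  # tier boundaries
  expect_equal(combine_points(es_of("PVS1, PM2-PP, PP4"))$classification, "P")   # 10
  expect_equal(combine_points(es_of("PM1, PM2-PP, PP3-M, PP4"))$classification, "LP") # 6
  expect_equal(combine_points(es_of("PM1, PM2-PP, PP3-M"))$classification, "VUS")     # 5
  expect_equal(combine_points(es_of("BS2, BS2"))$classification, "B")                  # -8
  expect_equal(combine_points(es_of("BP4"))$classification, "LB")                      # -1
})

test_that("categorical mode applies the published combinations", {
  expect_equal(combine_categorical(es_of("PS4, PM1, PM2-PP, PP3-M, PP4"))$classification,
               "P")    # 1S + 2M + 2P
  expect_equal(combine_categorical(es_of("PS4-PP, PM1, PM2-PP, PP3-M, PP4"))$classification,
               "LP")   # 2M + 3P
  expect_equal(combine_categorical(es_of("PM1, PM2-PP, PP4"))$classification,
               "VUS")  # 1M + 2P matches nothing
  expect_equal(combine_categorical(es_of("PVS1, PM2-PP"))$classification,
               "VUS")  # 1VS + 1P is not a published combination
  expect_equal(combine_categorical(es_of("PVS1, PS4-M, PM2-PP, PP4"))$classification,
               "P")    # 1VS + 1M + 2P
  expect_equal(combine_categorical(es_of("BP2, BP4"))$classification, "LB")
  expect_equal(combine_categorical(es_of("BS2, BP2, BP4"))$classification, "LB")
  # conflicting evidence returns uncertain
  expect_equal(combine_categorical(es_of("PM1, PM2-PP, PP3-M, PP4, BS2"))$classification,
               "VUS")
})

test_that("points mode is monotone in added evidence", {
  tiers <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  base_sets <- list(
    es_of("PM2-PP"), es_of("PS4-M, PM1"), es_of("PVS1, PM2-PP"),
    es_of("BS2, BP4"), es_of("PM1, PM2-PP, PP3-M, PP4")
  )
  adds_path <- list(es_of("PP3"), es_of("PM1"), es_of("PS4"), es_of("PVS1"))
  adds_ben <- list(es_of("BP4"), es_of("BS2"))
  for (b in base_sets) {
    t0 <- tiers[[combine_points(b)$classification]]
    for (a in adds_path) {
      t1 <- tiers[[combine_points(dplyr::bind_rows(b, a))$classification]]
      expect_gte(t1, t0)
    }
    for (a in adds_ben) {
      t1 <- tiers[[combine_points(dplyr::bind_rows(b, a))$classification]]
      expect_lte(t1, t0)
    }
  }
})

test_that("classify_evidence reports both modes and their agreement", {
  out <- classify_evidence(es_of("PVS1, PM2-PP"))
  expect_equal(out$classification, "LP")          # points is the default mode
  expect_equal(out$classification_categorical, "VUS")
  expect_false(out$modes_agree)
  out2 <- classify_evidence(es_of("PVS1, PM2-PP"),
                            combiner_config(mode = "categorical"))
  expect_equal(out2$classification, "VUS")
})

test_that("the two modes disagree on exactly the single-supporting LoF rows", {
  cl <- fixture_classified()
  disagree <- cl$nucleotide[!is.na(cl$modes_agree) & !cl$modes_agree]
  expect_setequal(disagree, c("c.3235dup", "c.3348del"))
})

test_that("points mode reproduces every printed fixture classification", {
  v <- hem_fixture("variants")
  cl <- fixture_classified()
  expect_equal(cl$classification_points, v$classification_printed)
})
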