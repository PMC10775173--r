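#' Packaged cohort fixtures
#'
#' Transcriptions of the published southern-Chinese hemophilia A/B cohort
#' tables shipped with the package: the per-variant detail tables for *F8*
#' (83 distinct variants) and *F9* (24), a patient-level expansion
#' (193 patients, including inversion carriers and patients without a
#' detectable variant), the prenatal-diagnosis fetus table (40 fetuses), the
#' printed cohort summary (counts and percentages with
#' `rounding_discrepancy` flags where the printed percentage differs from
#' recomputation), and the mildly/moderately affected truncating-variant
#' carriers.
#'
#' Printed strings are stored untouched; normalization happens here at load
#' time. For the variant tables that adds the evidence *inputs* that the
#' source tables do not print but imply: `reported_case_count` (minimum of
#' the PS4 band named in the criteria string, 0 when PS4 is absent),
#' `absent_from_population` (PM2 present in the criteria), and `bs2` (BS2
#' present). Rows whose printed criteria contradict the stated scoring bands
#' are flagged `inconsistent` and carry `override_criteria`. In the patient
#' table, inhibitor titers of inversion carriers are synthetic placeholders
#' (BU = 1 for positives; only positive/tested counts are published).
#'
#' @param table One of `"f8"`, `"f9"`, `"variants"` (both genes),
#'   `"patients"`, `"fetuses"`, `"table1"`, `"table4"`.
#' @return A tibble.
#' @examples
#' nrow(hem_fixture("f8"))   # 83
#' nrow(hem_fixture("f9"))   # 24
#' @export
hem_fixture <- function(table = c("f8", "f9", "variants", "patients", "fetuses",
                                  "table1", "table4")) {
  table <- match.arg(table)
  path <- function(f) system.file("extdata", f, package = "hemvar", mustWork = TRUE)
  if (table == "variants") {
    return(dplyr::bind_rows(hem_fixture("f8"), hem_fixture("f9")))
  }
  if (table %in% c("f8", "f9")) {
    raw <- readr::read_tsv(path(paste0(table, "_variants.tsv")),
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character())
    return(normalize_variant_fixture(raw))
  }
  if (table == "patients") {
    return(readr::read_tsv(path("patients.tsv"),
                           col_types = readr::cols(.default = readr::col_character()),
                           na = "NA"))
  }
  if (table == "fetuses") {
    return(readr::read_tsv(path("fetuses.tsv"),
                           col_types = readr::cols(carries_variant = readr::col_logical(),
                                                   .default = readr::col_character())))
  }
  if (table == "table4") {
    return(readr::read_tsv(path("table4_severity.tsv"),
                           col_types = readr::cols(.default = readr::col_character())))
  }
  readr::read_tsv(path("table1_printed.tsv"),
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    variant_class = readr::col_character(),
                    flags = readr::col_character(),
                    .default = readr::col_double()
                  ), na = "NA")
}

normalize_variant_fixture <- function(raw) {
  num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c("-", "NA", ""), NA, x)))
  crit_sets <- parse_criteria(raw$criteria)
  has_code <- function(code) vapply(crit_sets, function(es) code %in% es$code, logical(1))
  strength_of <- function(code) {
    vapply(crit_sets, function(es) {
      i <- match(code, es$code)
      if (is.na(i)) NA_character_ else es$strength[i]
    }, character(1))
  }
  ps4_min_count <- c(supporting = 1L, moderate = 2L, strong = 4L, very_strong = 16L)
  ps4 <- strength_of("PS4")
  tibble::tibble(
    gene = raw$gene,
    class_printed = raw$variant_class,
    nucleotide = raw$nucleotide,
    protein = ifelse(raw$protein %in% c("-", "?"), NA_character_, raw$protein),
    exon_printed = ifelse(raw$exon == "-", NA_character_, raw$exon),
    domain_printed = ifelse(raw$domain == "-", NA_character_, raw$domain),
    autopvs1_printed = ifelse(raw$autopvs1 == "-", NA_character_, raw$autopvs1),
    revel = num(raw$revel),
    spliceai = num(raw$spliceai),
    novel = raw$novel == "Novel",
    activity_printed = ifelse(raw$activity == "NA", NA_character_, raw$activity),
    criteria_printed = raw$criteria,
    classification_printed = raw$classification,
    n_patients = as.integer(raw$n_patients),
    severity_printed = raw$severity,
    inhibitor_printed = raw$inhibitor,
    origin_printed = raw$origin,
    reported_case_count = dplyr::coalesce(
      suppressWarnings(as.integer(raw$case_count)),
      unname(dplyr::coalesce(ps4_min_count[ps4], 0L))
    ),
    absent_from_population = has_code("PM2"),
    bs2 = has_code("BS2"),
    inconsistent = raw$inconsistent == "yes",
    override_criteria = ifelse(raw$override_criteria == "", NA_character_,
                               raw$override_criteria),
    note = raw$note
  )
}
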