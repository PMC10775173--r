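#' Read the three cohort input tables
#'
#' Tab-delimited UTF-8 files with a header row; the token `NA` marks missing
#' values and censored activities are kept as strings (`"<1"`). Unknown
#' columns are kept with a warning; a missing required column fails naming
#' it.
#'
#' @param path Path to a TSV file.
#' @return A tibble of typed records.
#' @name read_tables
NULL

read_checked <- function(path, required, col_types) {
  x <- readr::read_tsv(path, col_types = col_types, na = "NA")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(x), c(required, OPTIONAL_COLS))
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  x
}

OPTIONAL_COLS <- c(
  "protein", "revel", "spliceai", "absent_from_population",
  "reported_case_count", "novel", "bs2", "override_criteria", "exon",
  "domain", "severity", "inhibitor", "origin", "variant_class", "note"
)

#' @rdname read_tables
#' @export
read_variant_table <- function(path) {
  x <- read_checked(path, required = c("gene", "nucleotide"),
                    col_types = readr::cols(.default = readr::col_character()))
  convert <- list(revel = as.numeric, spliceai = as.numeric,
                  absent_from_population = as.logical,
                  reported_case_count = as.integer,
                  novel = as.logical, bs2 = as.logical)
  for (col in intersect(names(convert), names(x))) {
    x[[col]] <- convert[[col]](x[[col]])
  }
  x
}

#' @rdname read_tables
#' @export
read_patient_table <- function(path) {
  read_checked(path, required = c("patient_id", "gene", "variants", "activity"),
               col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_tables
#' @export
read_fetus_table <- function(path) {
  read_checked(path, required = c("variant_class", "sex", "carries_variant"),
               col_types = readr::cols(carries_variant = readr::col_logical(),
                                       .default = readr::col_character()))
}

#' Write a table in the package's TSV dialect
#'
#' Tab separator, no quoting, `NA` for missing; logical columns are written
#' as `TRUE`/`FALSE`. Write-then-read round-trips tables bit-identically
#' modulo line endings.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hem_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Run a full classify-and-summarize pass over input tables
#'
#' Convenience wrapper chaining [classify_variants()], [spectrum_table()],
#' [inhibitor_incidence()], [inheritance_summary()] and, when a fetus table
#' is given, [prenatal_summary()].
#'
#' @param variants,patients,fetuses Input tibbles (fetuses optional).
#' @param rules A [rule_config()].
#' @param combiner A [combiner_config()].
#' @return A list: `classified`, `spectrum`, `inhibitor`, `inheritance`,
#'   `prenatal` (`NULL` without fetuses).
#' @export
run_cohort_analysis <- function(variants, patients, fetuses = NULL,
                                rules = rule_config(),
                                combiner = combiner_config()) {
  classified <- classify_variants(variants, patients, rules, combiner)
  list(
    classified = classified,
    spectrum = spectrum_table(classified, patients),
    inhibitor = inhibitor_incidence(classified, patients),
    inheritance = inheritance_summary(patients),
    prenatal = if (!is.null(fetuses)) prenatal_summary(fetuses) else NULL
  )
}
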