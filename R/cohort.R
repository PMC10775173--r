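#' Parse possibly-censored factor activity values
#'
#' Clinical activity measurements (FVIII:C / FIX:C, % of normal) may be
#' reported as a detection-limit bound such as `"<1"`. The censoring bound is
#' retained as the usable upper bound.
#'
#' @param x Character or numeric vector; `"NA"`, `""` and `NA` are missing.
#' @return A tibble with `value` (numeric, `NA` when censored or missing),
#'   `bound` (upper bound: the value itself, or the censoring limit) and
#'   `censored` (logical).
#' @export
parse_activity <- function(x) {
  x <- as.character(x)
  x <- trimws(x)
  x[x %in% c("", "NA", "?")] <- NA_character_
  censored <- !is.na(x) & grepl("^<", x)
  num <- suppressWarnings(as.numeric(sub("^<", "", x)))
  tibble::tibble(
    value = ifelse(censored, NA_real_, num),
    bound = num,
    censored = censored
  )
}

#' Severity band from factor activity
#'
#' Severe below 1% of normal, moderate 1-5% (both bounds inclusive), mild
#' above 5% up to 40%. Above 40% is not hemophilia. Censored values (`"<1"`)
#' classify by their upper bound; an activity of exactly 0 (below detection)
#' is severe. Negative activities error.
#'
#' @param activity Numeric or character vector (censored values allowed).
#' @return Character vector: `severe`, `moderate`, `mild`,
#'   `not_hemophilia`, or `NA` for missing input.
#' @export
severity_from_activity <- function(activity) {
  a <- parse_activity(activity)
  if (any(a$bound < 0, na.rm = TRUE)) {
    stop("activity must be non-negative", call. = FALSE)
  }
  # censored "<x" means activity strictly below x, so band edges are strict
  dplyr::case_when(
    is.na(a$bound) ~ NA_character_,
    a$bound < 1 | (a$censored & a$bound <= 1) ~ "severe",
    a$bound <= 5 ~ "moderate",
    a$bound <= 40 ~ "mild",
    TRUE ~ "not_hemophilia"
  )
}

#' Bethesda units from residual factor activity
#'
#' One Bethesda unit is the amount of inhibitor leaving 50% residual
#' FVIII:C/FIX:C in the assay mixture, so the titer is log2(100 / residual%).
#'
#' @param residual_activity_pct Residual activity in (0, 100\].
#' @return Numeric BU titer.
#' @export
bethesda_units <- function(residual_activity_pct) {
  if (any(residual_activity_pct <= 0, na.rm = TRUE)) {
    stop("residual activity must be positive", call. = FALSE)
  }
  log2(100 / residual_activity_pct)
}

#' Residual activity from a Bethesda titer (inverse of [bethesda_units()])
#' @param bu Numeric BU titer (>= 0).
#' @return Residual activity in % of normal.
#' @export
bethesda_inverse <- function(bu) 100 / 2^bu

#' Round half up at a fixed number of decimals
#'
#' Cohort-table percentages use commercial (half-up) rounding, not banker's
#' rounding: 6.25 renders as 6.3 at one decimal.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

SEVERITY_LEVELS <- c("severe", "moderate", "mild", "unknown")
CLASS_LEVELS <- c("IVS22_inversion", "IVS1_inversion", "missense", "nonsense",
                  "indel", "gross_deletion", "canonical_splice",
                  "noncanonical_splice", "none")

# spectrum class of a patient: from the linked classified variants
patient_class <- function(patient_variants, classified) {
  refs <- split_variants(patient_variants)
  if (!length(refs) || all(is.na(refs))) return("none")
  if (any(grepl("^IVS\\s*22", refs))) return("IVS22_inversion")
  if (any(grepl("^IVS\\s*1\\b", refs))) return("IVS1_inversion")
  hit <- classified[classified$nucleotide %in% refs, ]
  if (nrow(hit) == 0) return("none")
  # a patient with several variants counts once, keyed by the P/LP variant
  plp <- hit[hit$classification %in% c("P", "LP"), ]
  use <- if (nrow(plp)) plp else hit
  use$variant_class[[1]]
}

#' Patient-level table with spectrum class and severity attached
#'
#' @param patients Patient table (`patient_id`, `gene`, `variants`,
#'   `activity`, optional `severity`, `inhibitor`, `origin`).
#' @param classified An `acmg_tbl` from [classify_variants()] for the same
#'   cohort's variants.
#' @return The patient tibble plus `variant_class`, `severity` (printed one,
#'   or derived from activity when absent), `inhibitor_tested`,
#'   `inhibitor_positive`.
#' @export
annotate_patients <- function(patients, classified) {
  p <- tibble::as_tibble(patients)
  refs <- unlist(lapply(p$variants[!is.na(p$variants)], split_variants))
  refs <- refs[nzchar(refs) & !grepl("^IVS", refs)]
  missing_refs <- setdiff(refs, classified$nucleotide)
  if (length(missing_refs)) {
    stop("patient variant_ref not in the classified table: ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  }
  cls <- vapply(ifelse(is.na(p$variants), "", p$variants),
                patient_class, character(1), classified = classified)
  sev <- if ("severity" %in% names(p)) p$severity else rep(NA_character_, nrow(p))
  derived <- severity_from_activity(if ("activity" %in% names(p)) p$activity
                                    else rep(NA, nrow(p)))
  sev <- dplyr::coalesce(sev, derived, "unknown")
  sev[sev %in% c("?", "")] <- "unknown"
  bu <- if ("inhibitor" %in% names(p)) suppressWarnings(as.numeric(p$inhibitor))
        else rep(NA_real_, nrow(p))
  dplyr::mutate(
    p,
    variant_class = factor(cls, levels = CLASS_LEVELS),
    severity = factor(sev, levels = SEVERITY_LEVELS),
    inhibitor_tested = !is.na(bu),
    inhibitor_positive = !is.na(bu) & bu > 0
  )
}

#' Variant-spectrum summary table
#'
#' Per gene and variant class: patient counts split by severity (with
#' percentages of each severity column's total), inhibitor
#' positives/tested, origin counts, distinct-variant and novel-variant
#' counts. Mirrors the layout of cohort characteristic tables; percentages
#' are round-half-up at one decimal. Patients carrying several variants
#' count once, keyed by their P/LP variant.
#'
#' @param classified An `acmg_tbl` from [classify_variants()].
#' @param patients Patient table (see [annotate_patients()]).
#' @return A tibble, one row per gene x class plus per-gene totals
#'   (`variant_class == "total"`).
#' @export
spectrum_table <- function(classified, patients) {
  ap <- annotate_patients(patients, classified)
  ap$origin <- if ("origin" %in% names(ap)) ap$origin else NA_character_

  per_class <- ap |>
    dplyr::group_by(.data$gene, .data$variant_class, .drop = FALSE) |>
    dplyr::summarise(
      severe_n = sum(.data$severity == "severe"),
      moderate_n = sum(.data$severity == "moderate"),
      mild_n = sum(.data$severity == "mild"),
      unknown_n = sum(.data$severity == "unknown"),
      total_n = dplyr::n(),
      inhibitor_positive = sum(.data$inhibitor_positive),
      inhibitor_tested = sum(.data$inhibitor_tested),
      de_novo = sum(.data$origin == "de_novo", na.rm = TRUE),
      inherited = sum(.data$origin == "inherited", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$total_n > 0 | !.data$variant_class %in%
                    c("IVS22_inversion", "IVS1_inversion", "noncanonical_splice"))

  cl <- tibble::as_tibble(classified)
  if (!"novel" %in% names(cl)) cl$novel <- FALSE
  cl <- cl |>
    dplyr::filter(!is.na(.data$classification)) |>
    dplyr::group_by(.data$gene, variant_class = factor(.data$variant_class,
                                                       levels = CLASS_LEVELS)) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_novel = sum(.data$novel %in% c(TRUE, "Novel", "novel")),
      .groups = "drop"
    )

  out <- dplyr::left_join(per_class, cl, by = c("gene", "variant_class")) |>
    dplyr::mutate(dplyr::across(c("n_variants", "n_novel"),
                                ~ tidyr::replace_na(.x, 0L)))

  totals <- out |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum), .groups = "drop") |>
    dplyr::mutate(variant_class = "total")
  out <- dplyr::bind_rows(dplyr::mutate(out, variant_class = as.character(.data$variant_class)),
                          totals)

  tot <- out |>
    dplyr::filter(.data$variant_class == "total") |>
    dplyr::select("gene", sev_tot = "severe_n", mod_tot = "moderate_n",
                  mild_tot = "mild_n", unk_tot = "unknown_n", all_tot = "total_n",
                  var_tot = "n_variants")
  out |>
    dplyr::left_join(tot, by = "gene") |>
    dplyr::mutate(
      severe_pct = round_half_up(100 * .data$severe_n / .data$sev_tot),
      moderate_pct = round_half_up(100 * .data$moderate_n / .data$mod_tot),
      mild_pct = round_half_up(100 * .data$mild_n / .data$mild_tot),
      unknown_pct = round_half_up(100 * .data$unknown_n / .data$unk_tot),
      total_pct = round_half_up(100 * .data$total_n / .data$all_tot),
      inhibitor_pct = round_half_up(100 * .data$inhibitor_positive /
                                      .data$inhibitor_tested),
      variants_pct = round_half_up(100 * .data$n_variants / .data$var_tot)
    ) |>
    dplyr::select(-"sev_tot", -"mod_tot", -"mild_tot", -"unk_tot", -"all_tot",
                  -"var_tot")
}

#' Inhibitor incidence per group
#'
#' Denominators count only inhibitor-tested patients. `group_by = "class"`
#' groups by variant class; `group_by = "b_domain"` splits one class
#' (default nonsense, F8) into B-domain vs non-B-domain carriers by the
#' variant's protein residue.
#'
#' @param classified An `acmg_tbl`.
#' @param patients Patient table.
#' @param group_by `"class"` or `"b_domain"`.
#' @param class_filter Variant class used for the B-domain split.
#' @return A tibble with `group`, `positive`, `tested`, `percent`
#'   (`NA`, flagged by `undefined`, when no patient was tested).
#' @export
inhibitor_incidence <- function(classified, patients, group_by = c("class", "b_domain"),
                                class_filter = "nonsense") {
  group_by <- match.arg(group_by)
  ap <- annotate_patients(patients, classified)
  if (group_by == "class") {
    grouped <- ap |> dplyr::mutate(group = as.character(.data$variant_class))
  } else {
    cl <- tibble::as_tibble(classified)
    in_b <- function(refs) {
      hit <- cl[cl$nucleotide %in% split_variants(refs) &
                  cl$variant_class == class_filter, ]
      if (nrow(hit) == 0) return(NA_character_)
      if (any(!is.na(hit$domain) & hit$domain == "B")) "B_domain" else "non_B_domain"
    }
    grouped <- ap |>
      dplyr::filter(.data$gene == "F8",
                    as.character(.data$variant_class) == class_filter) |>
      dplyr::mutate(group = vapply(.data$variants, in_b, character(1)))
  }
  grouped |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      positive = sum(.data$inhibitor_positive),
      tested = sum(.data$inhibitor_tested),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent = ifelse(.data$tested > 0,
                       round_half_up(100 * .data$positive / .data$tested), NA_real_),
      undefined = .data$tested == 0
    )
}

#' Inheritance summary
#'
#' Counts patients whose variant was maternally inherited vs de novo
#' (among those with a tested mother) and those of unknown origin.
#'
#' @param patients Patient table with an `origin` column
#'   (`inherited`/`de_novo`/`unknown` or `NA`).
#' @return A one-row tibble with counts and the inherited fraction among
#'   patients of known origin.
#' @export
inheritance_summary <- function(patients) {
  o <- patients$origin
  inh <- sum(o == "inherited", na.rm = TRUE)
  dn <- sum(o == "de_novo", na.rm = TRUE)
  unk <- sum(is.na(o) | o == "unknown")
  tibble::tibble(
    inherited = inh, de_novo = dn, unknown = unk,
    pct_inherited = ifelse(inh + dn > 0,
                           round_half_up(100 * inh / (inh + dn)), NA_real_)
  )
}

#' Prenatal-diagnosis summary
#'
#' Per variant class: male/female x variant-positive/negative fetus counts
#' (a positive male is a hemizygote, a positive female a heterozygote), plus
#' the overall sex ratio (males / total) and hemizygote-or-heterozygote
#' fraction.
#'
#' @param fetuses Fetus table: `variant_class`, `sex` (`male`/`female`),
#'   `carries_variant` (logical).
#' @return A list with `by_class` (tibble) and `overall` (one-row tibble
#'   with `n`, `males`, `positive`, `sex_ratio`, `pct_positive`).
#' @export
prenatal_summary <- function(fetuses) {
  f <- tibble::as_tibble(fetuses)
  by_class <- f |>
    dplyr::group_by(.data$variant_class) |>
    dplyr::summarise(
      male_positive = sum(.data$sex == "male" & .data$carries_variant),
      male_negative = sum(.data$sex == "male" & !.data$carries_variant),
      female_positive = sum(.data$sex == "female" & .data$carries_variant),
      female_negative = sum(.data$sex == "female" & !.data$carries_variant),
      total = dplyr::n(),
      .groups = "drop"
    )
  overall <- tibble::tibble(
    n = nrow(f),
    males = sum(f$sex == "male"),
    positive = sum(f$carries_variant),
    sex_ratio = ifelse(nrow(f) > 0, sum(f$sex == "male") / nrow(f), NA_real_),
    pct_positive = ifelse(nrow(f) > 0,
                          round_half_up(100 * sum(f$carries_variant) / nrow(f)),
                          NA_real_)
  )
  list(by_class = by_class, overall = overall)
}

#' Size of a deletion from its flanking breakpoints
#'
#' The breakpoints are the genomic coordinates of the last retained bases on
#' either side of the deletion (upstream > downstream for a minus-strand
#' gene), so the deleted length is the count of integers strictly between
#' them.
#'
#' @param upstream_bp,downstream_bp Genomic coordinates (1-based).
#' @return Deleted length in bp.
#' @export
deletion_size <- function(upstream_bp, downstream_bp) {
  if (any(upstream_bp <= downstream_bp)) {
    stop("upstream breakpoint must exceed downstream breakpoint", call. = FALSE)
  }
  upstream_bp - downstream_bp - 1
}

#' Count distinct arginine nonsense variants
#'
#' CGA arginine codons are deamination hotspots for stop gains; this counts
#' the distinct nonsense rows whose protein change is Arg -> Ter.
#'
#' @param classified An `acmg_tbl` (needs `variant_class` and `protein`).
#' @return Integer count.
#' @export
arginine_nonsense_count <- function(classified) {
  cl <- tibble::as_tibble(classified)
  ns <- cl[cl$variant_class == "nonsense" & !is.na(cl$protein), ]
  if (nrow(ns) == 0) return(0L)
  pr <- parse_protein(ns$protein)
  sum(pr$ref_residue == "Arg" & pr$alt == "Ter", na.rm = TRUE)
}
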