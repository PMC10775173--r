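#' Combiner configuration
#'
#' Evidence-combination settings. In points mode (the default) each item
#' contributes very strong = 8, strong = 4, moderate = 2, supporting = 1
#' points, positive for pathogenic codes and negative for benign codes, and
#' the summed score maps to P >= 10, LP 6..9, VUS 0..5, LB -6..-1, B <= -7.
#' In categorical mode the published combining rules are applied literally
#' and conflicting evidence yields VUS.
#'
#' @param points Named numeric vector of per-strength point values.
#' @param thresholds Named numeric vector: minimum score of P, LP, VUS, LB
#'   (B is everything below the LB minimum).
#' @param mode `"points"` or `"categorical"`.
#' @return A list of class `combiner_config`.
#' @export
combiner_config <- function(points = c(very_strong = 8, strong = 4,
                                       moderate = 2, supporting = 1),
                            thresholds = c(P = 10, LP = 6, VUS = 0, LB = -6),
                            mode = c("points", "categorical")) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(rev(thresholds)), all(points > 0))
  structure(list(points = points, thresholds = thresholds, mode = mode),
            class = "combiner_config")
}

evidence_score <- function(es, config = combiner_config()) {
  if (nrow(es) == 0) return(0)
  sign <- ifelse(es$code %in% BENIGN_CODES, -1, 1)
  sum(sign * config$points[es$strength])
}

#' Combine evidence by summed points
#'
#' @param es An evidence tibble (columns `code`, `strength`).
#' @param config A [combiner_config()].
#' @return A list with `classification` (P/LP/VUS/LB/B) and `score`.
#' @export
combine_points <- function(es, config = combiner_config()) {
  score <- evidence_score(es, config)
  th <- config$thresholds
  cls <- if (score >= th[["P"]]) "P"
    else if (score >= th[["LP"]]) "LP"
    else if (score >= th[["VUS"]]) "VUS"
    else if (score >= th[["LB"]]) "LB"
    else "B"
  list(classification = cls, score = score)
}

#' Combine evidence by the categorical ACMG/AMP rules
#'
#' Counts items per strength on each side and applies the published
#' combinations. A set with both pathogenic and benign evidence that matches
#' a rule on each side (or on neither) is conflicting and returns VUS.
#'
#' @param es An evidence tibble (columns `code`, `strength`).
#' @return A list with `classification` and the per-side rule matches.
#' @export
combine_categorical <- function(es) {
  path <- es[!es$code %in% BENIGN_CODES, ]
  ben <- es[es$code %in% BENIGN_CODES, ]
  nvs <- sum(path$strength == "very_strong")
  ns <- sum(path$strength == "strong")
  nm <- sum(path$strength == "moderate")
  np <- sum(path$strength == "supporting")
  nbs <- sum(ben$strength %in% c("very_strong", "strong"))
  nbp <- sum(ben$strength %in% c("moderate", "supporting"))

  path_call <- if (
    (nvs >= 1 && ns >= 1) || (nvs >= 1 && nm >= 2) ||
    (nvs >= 1 && nm >= 1 && np >= 1) || (nvs >= 1 && np >= 2) ||
    (ns >= 2) || (ns >= 1 && nm >= 3) || (ns >= 1 && nm >= 2 && np >= 2) ||
    (ns >= 1 && nm >= 1 && np >= 4)
  ) "P" else if (
    (nvs >= 1 && nm >= 1) || (ns >= 1 && nm >= 1) || (ns >= 1 && np >= 2) ||
    (nm >= 3) || (nm >= 2 && np >= 2) || (nm >= 1 && np >= 4)
  ) "LP" else NA_character_

  ben_call <- if (nbs >= 2) "B"
    else if ((nbs >= 1 && nbp >= 1) || nbp >= 2) "LB"
    else NA_character_

  # conflicting evidence: a rule fires on one side while the other side is
  # non-empty -> uncertain
  cls <- if (!is.na(path_call) && nrow(ben) > 0) "VUS"
    else if (!is.na(ben_call) && nrow(path) > 0) "VUS"
    else if (!is.na(path_call)) path_call
    else if (!is.na(ben_call)) ben_call
    else "VUS"
  list(classification = cls, pathogenic_rule = path_call, benign_rule = ben_call)
}

#' Classify one evidence set
#'
#' Runs the configured mode and records both modes' answers and whether they
#' agree (the points system can reach LP from a single very strong plus one
#' supporting item, which no categorical combination covers).
#'
#' @param es An evidence tibble.
#' @param config A [combiner_config()].
#' @return A one-row tibble: `classification`, `score`,
#'   `classification_points`, `classification_categorical`, `modes_agree`.
#' @export
classify_evidence <- function(es, config = combiner_config()) {
  pts <- combine_points(es, config)
  cat_ <- combine_categorical(es)
  final <- if (config$mode == "points") pts$classification else cat_$classification
  tibble::tibble(
    classification = final,
    score = pts$score,
    classification_points = pts$classification,
    classification_categorical = cat_$classification,
    modes_agree = pts$classification == cat_$classification
  )
}

#' Classify a table of annotated variants
#'
#' The main pipeline entry point. Takes a variant annotation table and an
#' optional patient table, assigns the strength-modulated evidence codes to
#' each variant, and combines them into a five-tier classification.
#'
#' The variant table needs columns `gene` and `nucleotide` (HGVS-style c.
#' description, an exon-deletion label, or an inversion label) and may carry
#' `protein`, `revel`, `spliceai`, `absent_from_population`,
#' `reported_case_count`, `novel`, `bs2`, and `override_criteria`. Inversions
#' are categorical findings outside the sequence-evidence framework and are
#' passed through unclassified. Patient linkage (for the activity-gated PP4
#' and the co-occurrence rule BP2) uses `patients$variants`, a
#' semicolon-separated list of the patient's variant descriptions, and
#' `patients$activity` (censored values like `"<1"` allowed). BP2 is assigned
#' in a second pass: a variant gets BP2 when some carrier also harbors a
#' variant classified P/LP in the first pass, and its PM1/PP4 are then
#' withheld.
#'
#' @param variants Data frame of annotated variants.
#' @param patients Optional data frame of patient records.
#' @param rules A [rule_config()].
#' @param combiner A [combiner_config()].
#' @return A tibble of class `acmg_tbl`: the input annotation plus
#'   `variant_class`, `exon`, `residue`, `domain`, `criteria`, `score`,
#'   `classification`, `classification_categorical`, `modes_agree`,
#'   `overridden`.
#' @examples
#' v <- tibble::tibble(
#'   gene = "F8", nucleotide = "c.6496C>T", protein = "p.Arg2166*",
#'   absent_from_population = TRUE, reported_case_count = 16
#' )
#' p <- tibble::tibble(patient_id = "HA5", gene = "F8",
#'                     variants = "c.6496C>T", activity = "1.2")
#' classify_variants(v, p)
#' @export
classify_variants <- function(variants, patients = NULL,
                              rules = rule_config(),
                              combiner = combiner_config()) {
  stopifnot(is.data.frame(variants), all(c("gene", "nucleotide") %in% names(variants)))
  v <- tibble::as_tibble(variants)
  n <- nrow(v)
  if (n == 0) {
    out <- dplyr::bind_cols(v, tibble::tibble(
      variant_class = character(), exon = integer(), residue = integer(),
      domain = character(), criteria = character(), overridden = logical(),
      classification = character(), score = double(),
      classification_points = character(),
      classification_categorical = character(), modes_agree = logical()
    ))
    class(out) <- c("acmg_tbl", class(out))
    return(out)
  }
  opt <- function(col, default) if (col %in% names(v)) v[[col]] else rep(default, n)
  protein_raw <- opt("protein", NA_character_)
  revel <- opt("revel", NA_real_)
  spliceai <- opt("spliceai", NA_real_)
  absent <- opt("absent_from_population", FALSE)
  cases <- opt("reported_case_count", 0L)
  bs2 <- opt("bs2", FALSE)
  override <- opt("override_criteria", NA_character_)
  cases[is.na(cases)] <- 0L
  absent[is.na(absent)] <- FALSE
  bs2[is.na(bs2)] <- FALSE

  cd <- parse_cdna(v$nucleotide)
  pr <- parse_protein(protein_raw)
  cls <- infer_variant_class(cd, pr)
  ptc <- ptc_position(pr)

  exon <- purrr::map2_int(v$gene, seq_len(n), function(g, i) {
    pos <- cd$start_cdna[i]
    if (is.na(pos) || !is.na(cd$start_offset[i])) return(NA_integer_)
    map_cdna_to_exon(gene_model(g), pos)
  })
  residue <- pr$position
  domain <- purrr::map2_chr(v$gene, residue, function(g, r) {
    if (is.na(r)) NA_character_ else domain_of(gene_model(g), r)
  })

  # linked-patient activities
  activity_by_variant <- function(i) {
    if (is.null(patients)) return(NA_real_)
    idx <- carrier_index(patients, v$gene[i], v$nucleotide[i])
    if (!length(idx)) return(NA_real_)
    parse_activity(patients$activity[idx])$bound
  }

  eval_once <- function(i, bp2) {
    evaluate_evidence(
      gene = v$gene[i], variant_class = cls[i], residue = residue[i],
      ptc_cdna_pos = ptc[i],
      exons_del_from = cd$exons_del_from[i], exons_del_to = cd$exons_del_to[i],
      revel = revel[i], spliceai = spliceai[i],
      absent_from_population = isTRUE(absent[i]),
      reported_case_count = cases[i], bs2_flag = isTRUE(bs2[i]), bp2 = bp2,
      activity = activity_by_variant(i),
      override_criteria = if (bp2) NA_character_ else override[i],
      config = rules
    )
  }

  keep <- cls != "inversion"
  # first pass: no BP2
  sets <- purrr::map(seq_len(n), function(i) {
    if (!keep[i]) return(no_evidence())
    eval_once(i, bp2 = FALSE)
  })
  first <- purrr::map_chr(sets, ~ combine_points(.x, combiner)$classification)
  plp <- first %in% c("P", "LP") & keep

  # second pass: BP2 for variants co-occurring with a P/LP variant
  if (!is.null(patients) && "variants" %in% names(patients)) {
    for (i in seq_len(n)) {
      if (!keep[i] || plp[i]) next
      idx <- carrier_index(patients, v$gene[i], v$nucleotide[i])
      if (!length(idx)) next
      has_plp_partner <- any(vapply(idx, function(j) {
        others <- setdiff(split_variants(patients$variants[j]), v$nucleotide[i])
        any(others %in% v$nucleotide[v$gene == v$gene[i]][
          plp[v$gene == v$gene[i]]])
      }, logical(1)))
      if (has_plp_partner) {
        es <- eval_once(i, bp2 = TRUE)
        if (!is.na(override[i]) && nzchar(override[i])) {
          es <- parse_criteria(override[i])[[1]]
          attr(es, "overridden") <- TRUE
        }
        sets[[i]] <- es
      }
    }
  }

  calls <- purrr::map(sets, classify_evidence, config = combiner)
  calls <- dplyr::bind_rows(calls)
  computed_cols <- c("variant_class", "exon", "residue", "domain", "criteria",
                     "overridden", "classification", "score",
                     "classification_points", "classification_categorical",
                     "modes_agree")
  out <- dplyr::bind_cols(
    v[, setdiff(names(v), computed_cols), drop = FALSE],
    tibble::tibble(
      variant_class = cls, exon = exon, residue = residue, domain = domain,
      criteria = purrr::map_chr(sets, format_criteria),
      overridden = purrr::map_lgl(sets, ~ isTRUE(attr(.x, "overridden")))
    ),
    calls
  )
  out$classification[!keep] <- NA_character_
  out$classification_points[!keep] <- NA_character_
  out$classification_categorical[!keep] <- NA_character_
  out$modes_agree[!keep] <- NA
  class(out) <- c("acmg_tbl", class(out))
  out
}

split_variants <- function(x) trimws(strsplit(x, ";", fixed = TRUE)[[1]])

carrier_index <- function(patients, gene, nucleotide) {
  which(patients$gene == gene &
          vapply(patients$variants, function(s) {
            !is.na(s) && nucleotide %in% split_variants(s)
          }, logical(1)))
}

#' @export
print.acmg_tbl <- function(x, ...) {
  cat(sprintf("# ACMG classification of %d variants\n", nrow(x)))
  cnt <- table(factor(x$classification, levels = c("P", "LP", "VUS", "LB", "B")))
  cat("#", paste(sprintf("%s: %d", names(cnt), cnt), collapse = "  "), "\n")
  NextMethod()
}

#' Tidy a classification table
#'
#' One row per variant with the essential call columns, broom-style.
#'
#' @param x An `acmg_tbl` from [classify_variants()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.acmg_tbl <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), dplyr::any_of(c(
    "gene", "nucleotide", "protein", "variant_class", "exon", "domain",
    "criteria", "score", "classification", "classification_categorical",
    "modes_agree"
  )))
}

#' Summarize a classification table
#'
#' One-row summary: variant counts per tier, mode agreement, override count.
#'
#' @param x An `acmg_tbl` from [classify_variants()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.acmg_tbl <- function(x, ...) {
  cl <- x$classification
  tibble::tibble(
    n_variants = nrow(x),
    n_P = sum(cl == "P", na.rm = TRUE),
    n_LP = sum(cl == "LP", na.rm = TRUE),
    n_VUS = sum(cl == "VUS", na.rm = TRUE),
    n_LB = sum(cl == "LB", na.rm = TRUE),
    n_B = sum(cl == "B", na.rm = TRUE),
    n_unclassified = sum(is.na(cl)),
    modes_agreement = mean(x$modes_agree, na.rm = TRUE),
    n_overridden = sum(x$overridden, na.rm = TRUE)
  )
}
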