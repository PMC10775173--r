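#' Evidence-rule configuration
#'
#' Thresholds for the strength-modulated ACMG evidence rules. Defaults are
#' the study rules:
#' * PS4 case-count bands 1 / 2-3 / 4-15 / >=16 reported cases mapping to
#'   supporting / moderate / strong / very strong;
#' * REVEL pathogenic bands >=0.932 (strong, capped to moderate),
#'   \[0.733, 0.932) moderate, \[0.644, 0.733) supporting; benign bands
#'   <=0.003 very strong, (0.003, 0.016\] strong, (0.016, 0.183\] moderate,
#'   (0.183, 0.290\] supporting;
#' * SpliceAI: PP3 supporting above 0.2, BP7 supporting below 0.01;
#' * PP4 when factor activity is below 40% of normal.
#'
#' @param ps4_thresholds Named integer vector: minimum reported-case count
#'   for each PS4 strength.
#' @param revel_pp3 Lower bounds of the three pathogenic REVEL bands.
#' @param revel_bp4 Upper bounds of the four benign REVEL bands.
#' @param pp3_missense_cap Maximum strength for missense PP3 (`"moderate"`:
#'   the strong band is deliberately down-weighted).
#' @param spliceai_pp3_min PP3 fires when SpliceAI score exceeds this.
#' @param spliceai_bp7_max BP7 fires when SpliceAI score is below this.
#' @param pp4_activity_max PP4 fires when activity (upper bound for censored
#'   values) is strictly below this percentage of normal.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(ps4_thresholds = c(supporting = 1L, moderate = 2L,
                                           strong = 4L, very_strong = 16L),
                        revel_pp3 = c(supporting = 0.644, moderate = 0.733,
                                      strong = 0.932),
                        revel_bp4 = c(very_strong = 0.003, strong = 0.016,
                                      moderate = 0.183, supporting = 0.290),
                        pp3_missense_cap = "moderate",
                        spliceai_pp3_min = 0.2,
                        spliceai_bp7_max = 0.01,
                        pp4_activity_max = 40) {
  stopifnot(
    !is.unsorted(ps4_thresholds), !is.unsorted(revel_pp3),
    !is.unsorted(revel_bp4), revel_bp4[["supporting"]] < revel_pp3[["supporting"]]
  )
  structure(
    list(ps4_thresholds = ps4_thresholds, revel_pp3 = revel_pp3,
         revel_bp4 = revel_bp4, pp3_missense_cap = pp3_missense_cap,
         spliceai_pp3_min = spliceai_pp3_min, spliceai_bp7_max = spliceai_bp7_max,
         pp4_activity_max = pp4_activity_max),
    class = "rule_config"
  )
}

STRENGTH_LEVELS <- c("supporting", "moderate", "strong", "very_strong")

# default strength of each code (used when printing the compact notation)
CODE_DEFAULTS <- c(
  PVS1 = "very_strong", PS4 = "strong", PM1 = "moderate", PM2 = "moderate",
  PP3 = "supporting", PP4 = "supporting",
  BS2 = "strong", BP2 = "supporting", BP4 = "supporting", BP7 = "supporting"
)
BENIGN_CODES <- c("BS2", "BP2", "BP4", "BP7")

evidence_item <- function(code, strength) {
  tibble::tibble(code = code, strength = strength)
}
no_evidence <- function() {
  tibble::tibble(code = character(), strength = character())
}

#' PVS1: predicted loss of function, NMD-modulated
#'
#' Nonsense and frameshift variants get very strong when the premature stop
#' is NMD-predicted and strong when it escapes (last exon / final 50 nt of
#' the penultimate exon). Canonical +/-1,2 splice variants get very strong.
#' Exon-level deletions get strong when confined to the last exon, otherwise
#' very strong. Other classes get nothing.
#'
#' @param variant_class One of the spectrum classes.
#' @param model The gene's [gene_model()].
#' @param ptc_cdna_pos cDNA position of the predicted stop ([ptc_position()]);
#'   ignored for splice and gross-deletion classes.
#' @param exons_del_from,exons_del_to Deleted-exon range for gross deletions.
#' @return One-row evidence tibble, or an empty one.
#' @export
assign_pvs1 <- function(variant_class, model, ptc_cdna_pos = NA,
                        exons_del_from = NA, exons_del_to = NA) {
  if (variant_class == "canonical_splice") {
    return(evidence_item("PVS1", "very_strong"))
  }
  if (variant_class == "gross_deletion") {
    if (is.na(exons_del_from) || is.na(exons_del_to)) {
      stop("gross deletion without a deleted-exon range", call. = FALSE)
    }
    last_only <- exons_del_from == model$n_exons && exons_del_to == model$n_exons
    return(evidence_item("PVS1", if (last_only) "strong" else "very_strong"))
  }
  if (variant_class %in% c("nonsense", "indel")) {
    if (is.na(ptc_cdna_pos)) {
      if (variant_class == "nonsense") {
        stop("nonsense variant without a computable stop position", call. = FALSE)
      }
      return(no_evidence())  # in-frame indel without a stop: no LoF claim
    }
    nmd <- is_nmd_predicted(model, ptc_cdna_pos)
    return(evidence_item("PVS1", if (nmd) "very_strong" else "strong"))
  }
  no_evidence()
}

#' PS4: strength banded by previously reported case count
#' @param reported_case_count Non-negative integer.
#' @param config A [rule_config()].
#' @return One-row evidence tibble, or an empty one for a count of zero.
#' @export
assign_ps4 <- function(reported_case_count, config = rule_config()) {
  if (is.na(reported_case_count) || reported_case_count < 0) {
    stop("reported_case_count must be a non-negative integer", call. = FALSE)
  }
  th <- config$ps4_thresholds
  band <- findInterval(reported_case_count, th)
  if (band == 0L) return(no_evidence())
  evidence_item("PS4", names(th)[band])
}

#' PM1: missense in a functional domain (F8 B domain excluded)
#'
#' The central B domain of factor VIII is largely spliced off the mature
#' protein and is not treated as a mutational hotspot, so missense variants
#' there get no PM1.
#'
#' @param variant_class Spectrum class; only missense is eligible.
#' @param model The gene's [gene_model()].
#' @param residue Protein residue index.
#' @return One-row evidence tibble, or an empty one.
#' @export
assign_pm1 <- function(variant_class, model, residue) {
  if (!identical(variant_class, "missense") || is.na(residue)) return(no_evidence())
  dom <- domain_of(model, residue)
  if (is.na(dom)) return(no_evidence())
  if (model$gene_id == "F8" && dom == "B") return(no_evidence())
  evidence_item("PM1", "moderate")
}

#' PM2 at supporting strength: absent from population databases
#' @param absent_from_population Logical input flag (database lookup result).
#' @return One-row evidence tibble, or an empty one.
#' @export
assign_pm2 <- function(absent_from_population) {
  if (isTRUE(absent_from_population)) evidence_item("PM2", "supporting") else no_evidence()
}

#' PP3/BP4 from a REVEL score (missense)
#'
#' The strong pathogenic band is capped to moderate; scores between the
#' benign and pathogenic bands (0.290, 0.644) yield no evidence.
#'
#' @param revel REVEL score in \[0, 1\].
#' @param config A [rule_config()].
#' @return One-row evidence tibble (PP3 or BP4), or an empty one.
#' @export
assign_pp3_bp4_missense <- function(revel, config = rule_config()) {
  if (is.na(revel)) return(no_evidence())
  stopifnot(revel >= 0, revel <= 1)
  pp3 <- config$revel_pp3
  if (revel >= pp3[["supporting"]]) {
    strength <- if (revel >= pp3[["strong"]]) "strong"
      else if (revel >= pp3[["moderate"]]) "moderate"
      else "supporting"
    cap <- match(config$pp3_missense_cap, STRENGTH_LEVELS)
    if (match(strength, STRENGTH_LEVELS) > cap) strength <- config$pp3_missense_cap
    return(evidence_item("PP3", strength))
  }
  bp4 <- config$revel_bp4
  if (revel <= bp4[["supporting"]]) {
    strength <- if (revel <= bp4[["very_strong"]]) "very_strong"
      else if (revel <= bp4[["strong"]]) "strong"
      else if (revel <= bp4[["moderate"]]) "moderate"
      else "supporting"
    return(evidence_item("BP4", strength))
  }
  no_evidence()
}

#' PP3/BP7 from a SpliceAI score (splice-region variants)
#' @param spliceai SpliceAI delta score in \[0, 1\].
#' @param config A [rule_config()].
#' @return One-row evidence tibble (PP3 or BP7 at supporting), or empty.
#' @export
assign_splice_pp3_bp7 <- function(spliceai, config = rule_config()) {
  if (is.na(spliceai)) return(no_evidence())
  stopifnot(spliceai >= 0, spliceai <= 1)
  if (spliceai > config$spliceai_pp3_min) return(evidence_item("PP3", "supporting"))
  if (spliceai < config$spliceai_bp7_max) return(evidence_item("BP7", "supporting"))
  no_evidence()
}

#' PP4: phenotype specific for hemophilia (factor activity below 40%)
#'
#' Activity may be censored ("<1"); the censoring bound is used. With several
#' linked patients, PP4 fires if any measured activity is below the gate.
#'
#' @param activity Numeric vector of activity upper bounds (% of normal);
#'   `NA` for unmeasured patients.
#' @param config A [rule_config()].
#' @return One-row evidence tibble, or an empty one.
#' @export
assign_pp4 <- function(activity, config = rule_config()) {
  activity <- activity[!is.na(activity)]
  if (length(activity) && any(activity < config$pp4_activity_max)) {
    return(evidence_item("PP4", "supporting"))
  }
  no_evidence()
}

#' BS2: observed in healthy adults (input flag)
#' @param bs2_flag Logical input flag.
#' @return One-row evidence tibble, or an empty one.
#' @export
assign_bs2 <- function(bs2_flag) {
  if (isTRUE(bs2_flag)) evidence_item("BS2", "strong") else no_evidence()
}

#' Parse a compact criteria string into an evidence set
#'
#' Reads the comma-joined notation used in clinical variant tables, e.g.
#' `"PVS1, PS4-M, PM2-PP, PP4"`. A suffix overrides the code's default
#' strength: `-VS` very strong; `-S`/`-PS` strong; `-M`/`-PM` moderate;
#' `-PP` supporting. Unsuffixed codes carry their default strength (PM2 is
#' conventionally written `PM2-PP` since its applied strength is supporting).
#'
#' @param x Character vector of criteria strings (may be `NA` or empty).
#' @return A list of evidence tibbles (columns `code`, `strength`).
#' @export
parse_criteria <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(no_evidence())
    toks <- trimws(strsplit(s, ",")[[1]])
    toks <- toks[nzchar(toks)]
    items <- purrr::map(toks, function(tok) {
      parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
      code <- trimws(parts[1])
      if (!code %in% names(CODE_DEFAULTS)) {
        stop("unknown criterion code '", code, "' in: ", s, call. = FALSE)
      }
      strength <- if (length(parts) > 1) {
        switch(toupper(trimws(parts[2])),
               VS = "very_strong", S = "strong", PS = "strong",
               M = "moderate", PM = "moderate", PP = "supporting",
               stop("unknown strength suffix in '", tok, "'", call. = FALSE))
      } else {
        CODE_DEFAULTS[[code]]
      }
      evidence_item(code, strength)
    })
    dplyr::bind_rows(items)
  })
}

#' Format an evidence set in the compact criteria notation
#'
#' Inverse of [parse_criteria()] up to suffix synonyms: a strength suffix is
#' printed only when the applied strength differs from the code's default
#' (`-VS`, `-S`, `-M`, `-PP`).
#'
#' @param es An evidence tibble (columns `code`, `strength`).
#' @return A single string.
#' @export
format_criteria <- function(es) {
  if (nrow(es) == 0) return("")
  ord <- order(match(es$code, names(CODE_DEFAULTS)))
  es <- es[ord, ]
  suff <- c(very_strong = "-VS", strong = "-S", moderate = "-M", supporting = "-PP")
  lab <- ifelse(es$strength == CODE_DEFAULTS[es$code], es$code,
                paste0(es$code, suff[es$strength]))
  paste(lab, collapse = ", ")
}

#' Assemble the full evidence set for one annotated variant
#'
#' Runs every rule in turn. When `bp2` is set (the patient carries another
#' P/LP variant in the same gene), the phenotype-linked pathogenic evidence
#' PM1 and PP4 is withheld, since the phenotype is attributed to the
#' co-occurring variant. Overrides, if given as a criteria string, replace
#' the computed set entirely.
#'
#' @param gene `"F8"` or `"F9"`.
#' @param variant_class Spectrum class.
#' @param residue Protein residue index (missense), or `NA`.
#' @param ptc_cdna_pos Predicted stop position, or `NA`.
#' @param exons_del_from,exons_del_to Gross-deletion exon range, or `NA`.
#' @param revel,spliceai In-silico scores, or `NA`.
#' @param absent_from_population,bs2_flag,bp2 Logical input flags.
#' @param reported_case_count Previously reported cases (PS4 input).
#' @param activity Linked patients' activity upper bounds (% of normal).
#' @param override_criteria Optional criteria string replacing the computed
#'   set (used for fixture rows whose printed criteria contradict the rules).
#' @param config A [rule_config()].
#' @return An evidence tibble with attribute `"overridden"`.
#' @export
evaluate_evidence <- function(gene, variant_class, residue = NA,
                              ptc_cdna_pos = NA,
                              exons_del_from = NA, exons_del_to = NA,
                              revel = NA, spliceai = NA,
                              absent_from_population = FALSE,
                              reported_case_count = 0L,
                              bs2_flag = FALSE, bp2 = FALSE,
                              activity = NA_real_,
                              override_criteria = NA_character_,
                              config = rule_config()) {
  model <- gene_model(gene)
  es <- dplyr::bind_rows(
    assign_pvs1(variant_class, model, ptc_cdna_pos, exons_del_from, exons_del_to),
    assign_ps4(reported_case_count, config),
    if (!bp2) assign_pm1(variant_class, model, residue) else no_evidence(),
    assign_pm2(absent_from_population),
    if (variant_class == "missense") assign_pp3_bp4_missense(revel, config)
      else no_evidence(),
    if (variant_class %in% c("canonical_splice", "noncanonical_splice"))
      assign_splice_pp3_bp7(spliceai, config) else no_evidence(),
    if (!bp2) assign_pp4(activity, config) else no_evidence(),
    assign_bs2(bs2_flag),
    if (bp2) evidence_item("BP2", "supporting") else no_evidence()
  )
  overridden <- FALSE
  if (!is.na(override_criteria) && nzchar(override_criteria)) {
    es <- parse_criteria(override_criteria)[[1]]
    overridden <- TRUE
  }
  attr(es, "overridden") <- overridden
  es
}
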