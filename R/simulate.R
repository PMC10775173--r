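#' Parameters for a synthetic hemophilia cohort
#'
#' Defaults are the observed cohort conditions: the patient-level variant
#' class mixture, the severity distribution conditional on class, the
#' per-class inhibitor-positive rates among tested patients, the fraction of
#' maternally inherited variants (0.95), and the prenatal parameters
#' (male-fetus fraction 0.85, transmission probability 0.5). Annotation
#' samplers draw REVEL scores per evidence band, SpliceAI scores, and
#' reported-case counts for known variants.
#'
#' @param n_patients Number of patients to simulate.
#' @param gene_mix Named probabilities for F8 vs F9 patients.
#' @param class_mix Named list (per gene) of variant-class probabilities.
#' @param severity_given_class Named list: per class, probabilities over
#'   severe/moderate/mild.
#' @param inhibitor_rate Named list (per gene) of per-class inhibitor
#'   positive rates among tested patients.
#' @param p_inhibitor_tested Probability a patient has an inhibitor result.
#' @param p_inherited Probability an origin-tested variant is inherited.
#' @param p_origin_tested Probability the mother was tested.
#' @param p_novel Probability a variant is previously unreported.
#' @param n_fetuses Number of fetuses for the prenatal arm.
#' @param p_male Male-fetus fraction.
#' @param p_transmission Probability a fetus carries the familial variant.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(
    n_patients = 200,
    gene_mix = c(F8 = 161, F9 = 32) / 193,
    class_mix = list(
      F8 = c(IVS22_inversion = 52, IVS1_inversion = 4, missense = 40,
             nonsense = 24, indel = 25, gross_deletion = 6,
             canonical_splice = 2, none = 8) / 161,
      F9 = c(missense = 21, nonsense = 3, indel = 1, gross_deletion = 2,
             canonical_splice = 1, noncanonical_splice = 2, none = 2) / 32
    ),
    severity_given_class = list(
      IVS22_inversion = c(severe = 49, moderate = 1, mild = 2) / 52,
      IVS1_inversion = c(severe = 3, moderate = 0, mild = 1) / 4,
      missense = c(severe = 24, moderate = 19, mild = 13) / 56,
      nonsense = c(severe = 23, moderate = 1, mild = 0) / 24,
      indel = c(severe = 23, moderate = 1, mild = 0) / 24,
      gross_deletion = c(severe = 8, moderate = 0, mild = 0) / 8,
      canonical_splice = c(severe = 3, moderate = 0, mild = 0) / 3,
      noncanonical_splice = c(severe = 1, moderate = 0, mild = 1) / 2,
      none = c(severe = 3, moderate = 1, mild = 6) / 10
    ),
    inhibitor_rate = list(
      F8 = c(IVS22_inversion = 4 / 34, IVS1_inversion = 0, missense = 0,
             nonsense = 4 / 19, indel = 3 / 21, gross_deletion = 2 / 6,
             canonical_splice = 1 / 2, none = 0),
      F9 = c(missense = 0, nonsense = 1 / 3, indel = 0, gross_deletion = 1 / 2,
             canonical_splice = 0, noncanonical_splice = 0, none = 0)
    ),
    p_inhibitor_tested = 142 / 193,
    p_inherited = 0.95,
    p_origin_tested = 103 / 193,
    p_novel = 26 / 107,
    n_fetuses = 40,
    p_male = 0.85,
    p_transmission = 0.5,
    seed = 1L) {
  stopifnot(
    n_patients >= 0,
    abs(sum(gene_mix) - 1) < 1e-8,
    all(vapply(class_mix, function(m) abs(sum(m) - 1) < 1e-8, logical(1))),
    all(vapply(severity_given_class, function(m) abs(sum(m) - 1) < 1e-8, logical(1))),
    all(unlist(inhibitor_rate) >= 0), all(unlist(inhibitor_rate) <= 1),
    p_inherited >= 0, p_inherited <= 1, p_male >= 0, p_male <= 1
  )
  structure(
    list(n_patients = n_patients, gene_mix = gene_mix, class_mix = class_mix,
         severity_given_class = severity_given_class,
         inhibitor_rate = inhibitor_rate,
         p_inhibitor_tested = p_inhibitor_tested, p_inherited = p_inherited,
         p_origin_tested = p_origin_tested, p_novel = p_novel,
         n_fetuses = n_fetuses, p_male = p_male,
         p_transmission = p_transmission, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

sample_activity <- function(severity) {
  vapply(severity, function(s) {
    switch(s,
      severe = "<1",
      moderate = format(round(stats::runif(1, 1, 5), 1)),
      mild = format(round(stats::runif(1, 5.1, 40), 1)),
      "NA"
    )
  }, character(1))
}

# REVEL drawn from the band consistent with a pathogenic or benign missense
sample_revel <- function(n, pathogenic) {
  ifelse(pathogenic, stats::runif(n, 0.733, 0.99), stats::runif(n, 0.02, 0.29))
}

#' Generate a synthetic hemophilia cohort
#'
#' Draws a patient table, a matching variant annotation table, and a fetus
#' table with the statistical structure of the real cohort, plus a
#' ground-truth ledger of the generating parameters for recovery tests.
#' One seeded random stream drives the whole cohort; the same seed
#' reproduces it exactly.
#'
#' Variants are synthetic but structurally valid: each non-inversion patient
#' gets a private variant whose coding description, protein consequence and
#' in-silico scores are drawn to match its class (e.g. nonsense variants get
#' NMD-informative stop positions, missense variants get in-domain residues
#' and band-consistent REVEL scores).
#'
#' @param params A [cohort_params()].
#' @return A list of class `hem_cohort`: `variants`, `patients`, `fetuses`,
#'   `truth` (list), `params`.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_patients = 50, seed = 42))
#' nrow(cohort$patients)
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients

  if (n == 0) {
    return(structure(list(
      variants = tibble::tibble(gene = character(), nucleotide = character(),
                                protein = character(), revel = double(),
                                spliceai = double(),
                                absent_from_population = logical(),
                                reported_case_count = integer(),
                                novel = logical(), bs2 = logical()),
      patients = tibble::tibble(patient_id = character(), gene = character(),
                                variants = character(), activity = character(),
                                severity = character(), variant_class = character(),
                                inhibitor = character(), origin = character()),
      fetuses = tibble::tibble(variant_class = character(), sex = character(),
                               carries_variant = logical()),
      truth = list(params = params), params = params), class = "hem_cohort"))
  }

  gene <- sample(names(params$gene_mix), n, replace = TRUE, prob = params$gene_mix)
  cls <- vapply(gene, function(g) {
    m <- params$class_mix[[g]]
    sample(names(m), 1, prob = m)
  }, character(1))
  severity <- vapply(cls, function(cl) {
    m <- params$severity_given_class[[cl]]
    sample(names(m), 1, prob = m)
  }, character(1))
  tested <- stats::runif(n) < params$p_inhibitor_tested
  pos_rate <- mapply(function(g, cl) params$inhibitor_rate[[g]][[cl]], gene, cls)
  positive <- tested & (stats::runif(n) < pos_rate)
  titer <- ifelse(!tested, "NA",
                  ifelse(positive, format(round(stats::runif(n, 0.6, 40), 1)), "0"))
  origin_tested <- stats::runif(n) < params$p_origin_tested
  origin <- ifelse(!origin_tested, NA_character_,
                   ifelse(stats::runif(n) < params$p_inherited,
                          "inherited", "de_novo"))

  variant <- synth_variant(gene, cls, severity, params)
  patients <- tibble::tibble(
    patient_id = sprintf("S%04d", seq_len(n)),
    gene = gene,
    variants = variant$nucleotide,
    activity = sample_activity(severity),
    severity = severity,
    variant_class = unname(cls),
    inhibitor = titer,
    origin = origin
  )
  patients$activity[cls == "none" & severity == "severe"] <- "<1"

  variants <- variant[!is.na(variant$nucleotide) &
                        !grepl("^IVS", variant$nucleotide), ]
  variants <- variants[!duplicated(paste(variants$gene, variants$nucleotide)), ]

  nf <- params$n_fetuses
  fet_cls <- if (nf > 0) sample(names(params$class_mix$F8), nf, replace = TRUE,
                                prob = params$class_mix$F8) else character()
  fetuses <- tibble::tibble(
    variant_class = fet_cls,
    sex = ifelse(stats::runif(nf) < params$p_male, "male", "female"),
    carries_variant = stats::runif(nf) < params$p_transmission
  )

  truth <- list(
    class_mix = params$class_mix, inhibitor_rate = params$inhibitor_rate,
    p_inherited = params$p_inherited, p_male = params$p_male,
    p_transmission = params$p_transmission,
    class_counts = table(gene, cls), seed = params$seed
  )
  structure(list(variants = variants, patients = patients, fetuses = fetuses,
                 truth = truth, params = params), class = "hem_cohort")
}

# build structurally valid synthetic variant descriptions per class
synth_variant <- function(gene, cls, severity, params) {
  n <- length(gene)
  models <- list(F8 = gene_model("F8"), F9 = gene_model("F9"))
  nuc <- character(n); prot <- rep(NA_character_, n)
  revel <- rep(NA_real_, n); sai <- rep(NA_real_, n)
  novel <- stats::runif(n) < params$p_novel
  cases <- ifelse(novel, 0L, stats::rpois(n, 3))
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    m <- models[[gene[i]]]
    if (cls[i] == "none") { nuc[i] <- NA_character_; next }
    if (cls[i] == "IVS22_inversion") { nuc[i] <- "IVS 22 inversion"; next }
    if (cls[i] == "IVS1_inversion") { nuc[i] <- "IVS 1 inversion"; next }
    if (cls[i] == "gross_deletion") {
      from <- sample(seq_len(m$n_exons), 1)
      to <- min(m$n_exons, from + sample(0:2, 1))
      nuc[i] <- if (from == to) paste0("Exon ", from, " deletion")
                else paste0("Exon ", from, "-", to, " deletion")
      next
    }
    if (cls[i] %in% c("canonical_splice", "noncanonical_splice")) {
      anchor <- sample(m$exon_ends_cdna[-m$n_exons], 1)
      off <- if (cls[i] == "canonical_splice") sample(1:2, 1) else sample(3:8, 1)
      b <- sample(bases, 2)
      nuc[i] <- sprintf("c.%d+%d%s>%s", anchor, off, b[1], b[2])
      sai[i] <- if (cls[i] == "canonical_splice") stats::runif(1, 0.8, 1)
                else stats::runif(1, 0.21, 0.9)
      next
    }
    res <- sample(seq_len(m$protein_length - 60L), 1)
    pos <- codon_start(res)
    aa <- sample(AA3[AA3 != "Met"], 2)
    if (cls[i] == "missense") {
      b <- sample(bases, 2)
      nuc[i] <- sprintf("c.%d%s>%s", pos, b[1], b[2])
      prot[i] <- sprintf("p.%s%d%s", aa[1], res, aa[2])
      revel[i] <- sample_revel(1, pathogenic = severity[i] != "mild" ||
                                 stats::runif(1) < 0.5)
    } else if (cls[i] == "nonsense") {
      b <- sample(bases, 2)
      nuc[i] <- sprintf("c.%d%s>%s", pos, b[1], b[2])
      prot[i] <- sprintf("p.%s%d*", aa[1], res)
    } else { # small indel, frameshift
      nuc[i] <- sprintf("c.%ddel", pos)
      prot[i] <- sprintf("p.%s%d%sfs*%d", aa[1], res, aa[2], sample(2:40, 1))
    }
  }
  tibble::tibble(
    gene = gene, nucleotide = nuc, protein = prot, revel = revel,
    spliceai = sai, absent_from_population = novel | stats::runif(n) < 0.6,
    reported_case_count = as.integer(cases), novel = novel,
    bs2 = FALSE
  )
}

#' @export
print.hem_cohort <- function(x, ...) {
  cat(sprintf(
    "<hem_cohort> %d patients, %d distinct variants, %d fetuses (seed %d)\n",
    nrow(x$patients), nrow(x$variants), nrow(x$fetuses), x$params$seed))
  invisible(x)
}
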