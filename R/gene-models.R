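#' Transcript and protein-domain models for F8 and F9
#'
#' `gene_model()` returns the packaged transcript model for one of the two
#' hemophilia genes: coagulation factor VIII (*F8*, transcript NM_000132.3,
#' protein NP_000123.1, 26 exons, minus strand of chrX) or factor IX (*F9*,
#' NM_000133.3, NP_000124.1, 8 exons, plus strand). Coding coordinates are
#' 1-based with +1 the A of the ATG initiation codon; protein coordinates
#' include the signal peptide, matching the reference-protein numbering used
#' in clinical reports.
#'
#' Exon boundaries are stored as the cDNA coordinate of the last coding base
#' of each exon. The boundary table was transcribed from the published exon
#' structure of each gene and is consistent with the canonical splice-donor
#' positions of known splice variants (e.g. F8 c.1443+1, c.5815+1;
#' F9 c.252+3, c.723+1).
#'
#' @param gene `"F8"` or `"F9"`.
#'
#' @return A list of class `transcript_model` with elements `gene_id`,
#'   `n_exons`, `exon_ends_cdna`, `cds_length`, `protein_length`,
#'   `chromosome_strand`, and `domains` (a tibble with columns `name`,
#'   `start_residue`, `end_residue`).
#' @examples
#' f8 <- gene_model("F8")
#' map_cdna_to_exon(f8, 201)   # exon 2
#' domain_of(f8, 845)          # B domain
#' @export
gene_model <- function(gene = c("F8", "F9")) {
  gene <- match.arg(gene)
  if (gene == "F8") {
    model <- list(
      gene_id = "F8",
      n_exons = 26L,
      # last coding base of each exon, cDNA coordinates
      exon_ends_cdna = c(
        143L, 265L, 389L, 601L, 670L, 787L, 1009L, 1271L, 1443L, 1537L,
        1752L, 1903L, 2113L, 5219L, 5373L, 5586L, 5815L, 5998L, 6115L,
        6187L, 6273L, 6429L, 6574L, 6723L, 6982L, 7056L
      ),
      cds_length = 7056L,
      protein_length = 2351L,
      chromosome_strand = "-",
      domains = tibble::tribble(
        ~name, ~start_residue, ~end_residue,
        "A1",    20L,   351L,
        "A2",   392L,   729L,
        "B",    760L,  1667L,
        "A3",  1709L,  2038L,
        "C1",  2039L,  2191L,
        "C2",  2192L,  2351L
      )
    )
  } else {
    model <- list(
      gene_id = "F9",
      n_exons = 8L,
      exon_ends_cdna = c(88L, 252L, 277L, 392L, 520L, 723L, 881L, 1386L),
      cds_length = 1386L,
      protein_length = 461L,
      chromosome_strand = "+",
      domains = tibble::tribble(
        ~name, ~start_residue, ~end_residue,
        "Signal peptide",   1L,  28L,
        "Gla",             29L,  92L,
        "EGF1",            93L, 129L,
        "EGF2",           130L, 171L,
        "Linker",         172L, 226L,
        "SP",             227L, 461L
      )
    )
  }
  structure(model, class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s: %d exons, CDS %d nt, protein %d aa, strand %s\n",
    x$gene_id, x$n_exons, x$cds_length, x$protein_length, x$chromosome_strand
  ))
  print(x$domains)
  invisible(x)
}

#' Map a coding cDNA position to its exon
#'
#' Intronic offsets are handled by the caller: a variant with an intronic
#' offset belongs to the intron adjoining its anchor (exonic) position.
#'
#' @param model A [gene_model()].
#' @param cdna_pos Integer vector of 1-based coding positions.
#' @return Integer vector of exon numbers.
#' @export
map_cdna_to_exon <- function(model, cdna_pos) {
  stopifnot(inherits(model, "transcript_model"))
  cdna_pos <- as.integer(cdna_pos)
  if (any(is.na(cdna_pos)) || any(cdna_pos < 1L) || any(cdna_pos > model$cds_length)) {
    stop("cdna_pos out of coding range 1..", model$cds_length, " for ", model$gene_id,
         call. = FALSE)
  }
  findInterval(cdna_pos, model$exon_ends_cdna, left.open = TRUE) + 1L
}

#' Residue index of a coding position
#'
#' Standard codon arithmetic: residue = ceiling(position / 3).
#'
#' @param cdna_pos Integer vector of coding positions (>= 1).
#' @return Integer vector of 1-based residue indices.
#' @export
codon_of <- function(cdna_pos) {
  if (any(cdna_pos < 1, na.rm = TRUE)) stop("cdna_pos must be >= 1", call. = FALSE)
  as.integer(ceiling(cdna_pos / 3))
}

#' First coding base of a residue's codon
#' @param residue Integer vector of residue indices.
#' @return Integer vector of cDNA positions.
#' @export
codon_start <- function(residue) 3L * as.integer(residue) - 2L

#' Protein domain containing a residue
#'
#' @param model A [gene_model()].
#' @param residue Integer vector of residue indices.
#' @return Character vector of domain names; `NA` for inter-domain residues.
#' @export
domain_of <- function(model, residue) {
  stopifnot(inherits(model, "transcript_model"))
  residue <- as.integer(residue)
  if (any(is.na(residue)) || any(residue < 1L) || any(residue > model$protein_length)) {
    stop("residue out of range 1..", model$protein_length, " for ", model$gene_id,
         call. = FALSE)
  }
  d <- model$domains
  vapply(residue, function(r) {
    hit <- which(d$start_residue <= r & r <= d$end_residue)
    if (length(hit) == 0L) NA_character_ else d$name[hit[1L]]
  }, character(1))
}

#' Is a premature termination codon predicted to trigger NMD?
#'
#' Nonsense-mediated decay is predicted unless the premature termination
#' codon (PTC) lies in the last exon or within the 3'-most 50 nucleotides of
#' the penultimate exon (the classic 50-bp rule). Positions beyond the CDS
#' end (frameshifts terminating in 3'UTR sequence) count as last-exon and
#' therefore escape NMD.
#'
#' @param model A [gene_model()].
#' @param ptc_cdna_pos Integer vector: cDNA coordinate of the first base of
#'   the stop codon.
#' @return Logical vector: `TRUE` if NMD is predicted.
#' @export
is_nmd_predicted <- function(model, ptc_cdna_pos) {
  stopifnot(inherits(model, "transcript_model"))
  ends <- model$exon_ends_cdna
  n <- length(ends)
  penult_end <- ends[n - 1L]
  escape_from <- penult_end - 50L + 1L  # 50-nt window, inclusive
  ptc_cdna_pos < escape_from
}
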