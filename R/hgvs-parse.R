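#' Parse an HGVS-style coding (c.) description
#'
#' Tolerant parser for the coding-variant dialects seen in clinical
#' hemophilia reports: substitutions (`c.6496C>T`), deletions (`c.209_212del`,
#' `c.252delA`), duplications (`c.6988dup`), insertions (`c.4052_4053ins10`,
#' `c.4342_4343ins`), delins (`c.5818_5820delinsCACAT`), intronic offsets with
#' optional spaces (`c.1443 + 1G>A`, `c.253-6T>G`), exon-level gross deletions
#' (`Exon 5-6 deletion`), and the recurrent F8 inversion labels
#' (`IVS 22 inversion`, `IVS 1 inversion`). Whitespace and a redundant inner
#' `c.` prefix (as in `c.252+3_c.252+6delGAGT`) are ignored.
#'
#' @param raw Character vector of descriptions.
#' @return A tibble with one row per input: `raw`, `kind` (substitution,
#'   deletion, duplication, insertion, delins, gross_deletion, inversion),
#'   `start_cdna`, `end_cdna`, `start_offset`, `end_offset` (signed intronic
#'   offsets, `NA` when exonic), `ref_bases`, `alt_bases`, `ins_length`,
#'   `exons_del_from`, `exons_del_to`, `inversion_label`.
#' @examples
#' parse_cdna("c.5818_5820delinsCACAT")
#' parse_cdna("c.1443 + 1G>A")
#' @export
parse_cdna <- function(raw) {
  if (length(raw) == 0) return(parse_cdna_one("c.1A>G")[0, ])
  dplyr::bind_rows(purrr::map(raw, parse_cdna_one))
}

parse_cdna_one <- function(raw) {
  out <- tibble::tibble(
    raw = raw, kind = NA_character_,
    start_cdna = NA_integer_, end_cdna = NA_integer_,
    start_offset = NA_integer_, end_offset = NA_integer_,
    ref_bases = NA_character_, alt_bases = NA_character_,
    ins_length = NA_integer_,
    exons_del_from = NA_integer_, exons_del_to = NA_integer_,
    inversion_label = NA_character_
  )
  s <- gsub("[[:space:]]+", "", raw)

  # inversion labels
  if (grepl("^IVS", s, ignore.case = TRUE)) {
    m <- regmatches(s, regexec("^IVS([0-9]+)", s, ignore.case = TRUE, perl = TRUE))[[1]]
    if (length(m) < 2) stop("cannot parse inversion label: ", raw, call. = FALSE)
    out$kind <- "inversion"
    out$inversion_label <- paste0("IVS", m[2])
    return(out)
  }
  # exon-level gross deletions: "Exon 1 deletion", "Exon 5-6 deletion"
  if (grepl("^Exon", s, ignore.case = TRUE)) {
    s <- gsub(intToUtf8(0x2013L), "-", s, fixed = TRUE)  # tolerate an en dash
    m <- regmatches(s, regexec("^Exon([0-9]+)(?:-([0-9]+))?deletion$", s,
                               ignore.case = TRUE, perl = TRUE))[[1]]
    if (length(m) == 0) stop("cannot parse gross-deletion label: ", raw, call. = FALSE)
    out$kind <- "gross_deletion"
    out$exons_del_from <- as.integer(m[2])
    out$exons_del_to <- if (m[3] == "") as.integer(m[2]) else as.integer(m[3])
    return(out)
  }

  if (!grepl("^c\\.", s)) stop("expected a c.-prefixed description: ", raw, call. = FALSE)
  body <- sub("^c\\.", "", s)
  body <- gsub("c\\.", "", body)  # tolerate redundant inner c. prefixes

  pos_re <- "([0-9]+)([+-][0-9]+)?"

  # substitution: pos[offset]REF>ALT
  m <- regmatches(body, regexec(paste0("^", pos_re, "([ACGT])>([ACGT])$"), body, perl = TRUE))[[1]]
  if (length(m)) {
    out$kind <- "substitution"
    out$start_cdna <- out$end_cdna <- as.integer(m[2])
    off <- if (m[3] == "") NA_integer_ else as.integer(m[3])
    out$start_offset <- out$end_offset <- off
    out$ref_bases <- m[4]; out$alt_bases <- m[5]
    return(out)
  }

  # range or single position followed by del/dup/ins/delins
  m <- regmatches(body, regexec(
    paste0("^", pos_re, "(?:_", pos_re, ")?",
           "(delins|del|dup|ins)([ACGT]*|[0-9]*)$"), body, perl = TRUE))[[1]]
  if (length(m)) {
    out$start_cdna <- as.integer(m[2])
    out$start_offset <- if (m[3] == "") NA_integer_ else as.integer(m[3])
    if (m[4] != "") {
      out$end_cdna <- as.integer(m[4])
      out$end_offset <- if (m[5] == "") NA_integer_ else as.integer(m[5])
    } else {
      out$end_cdna <- out$start_cdna
      out$end_offset <- out$start_offset
    }
    op <- m[6]; tail <- m[7]
    if (op == "del") {
      out$kind <- "deletion"
      if (grepl("^[ACGT]+$", tail)) out$ref_bases <- tail
    } else if (op == "dup") {
      out$kind <- "duplication"
      if (grepl("^[ACGT]+$", tail)) out$ref_bases <- tail
    } else if (op == "ins") {
      out$kind <- "insertion"
      if (grepl("^[ACGT]+$", tail) && nzchar(tail)) {
        out$alt_bases <- tail
        out$ins_length <- nchar(tail)
      } else if (grepl("^[0-9]+$", tail) && nzchar(tail)) {
        out$ins_length <- as.integer(tail)  # length-only insertion, sequence unknown
      }
    } else {
      out$kind <- "delins"
      if (grepl("^[ACGT]+$", tail) && nzchar(tail)) out$alt_bases <- tail
      else if (grepl("^[0-9]+$", tail) && nzchar(tail)) out$ins_length <- as.integer(tail)
    }
    if (!is.na(out$end_cdna) && is.na(out$end_offset) && is.na(out$start_offset) &&
        out$end_cdna < out$start_cdna) {
      stop("range end precedes start in: ", raw, call. = FALSE)
    }
    return(out)
  }
  stop("cannot parse c. description: ", raw, call. = FALSE)
}

#' Format a parsed c. description back to HGVS-style text
#'
#' Canonical inverse of [parse_cdna()]: round-trips every supported dialect
#' modulo whitespace and redundant inner `c.` prefixes.
#'
#' @param v A tibble as returned by [parse_cdna()].
#' @return Character vector.
#' @export
format_cdna <- function(v) {
  fmt_pos <- function(p, off) {
    paste0(p, ifelse(is.na(off), "", sprintf("%+d", off)))
  }
  vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    switch(r$kind,
      inversion = paste(sub("IVS", "IVS ", r$inversion_label), "inversion"),
      gross_deletion = if (r$exons_del_from == r$exons_del_to) {
        paste0("Exon ", r$exons_del_from, " deletion")
      } else {
        paste0("Exon ", r$exons_del_from, "-", r$exons_del_to, " deletion")
      },
      substitution = paste0("c.", fmt_pos(r$start_cdna, r$start_offset),
                            r$ref_bases, ">", r$alt_bases),
      {
        range <- if (r$start_cdna == r$end_cdna &&
                     identical(r$start_offset, r$end_offset)) {
          fmt_pos(r$start_cdna, r$start_offset)
        } else {
          paste0(fmt_pos(r$start_cdna, r$start_offset), "_",
                 fmt_pos(r$end_cdna, r$end_offset))
        }
        op <- switch(r$kind, deletion = "del", duplication = "dup",
                     insertion = "ins", delins = "delins")
        tail <- ""
        if (r$kind %in% c("deletion", "duplication") && !is.na(r$ref_bases)) {
          tail <- r$ref_bases
        } else if (r$kind %in% c("insertion", "delins")) {
          if (!is.na(r$alt_bases)) tail <- r$alt_bases
          else if (!is.na(r$ins_length)) tail <- as.character(r$ins_length)
        }
        paste0("c.", range, op, tail)
      }
    )
  }, character(1))
}

AA3 <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)

#' Parse an HGVS-style protein (p.) description
#'
#' Handles missense (`p.Lys67Asn`), nonsense (`p.Arg2166*`), and frameshift
#' with new-stop offset (`p.Glu1988Glyfs*3`); parenthesized descriptions
#' (`p.(Gly266Trpfs*19)`) are marked predicted. Internal spaces are ignored.
#'
#' @param raw Character vector of p.-prefixed descriptions.
#' @return A tibble: `raw`, `ref_residue` (3-letter), `position`, `alt`
#'   (3-letter code, `"Ter"`, or `"fs"`), `fs_new_stop` (offset N of `fs*N`,
#'   `NA` otherwise), `predicted`.
#' @export
parse_protein <- function(raw) {
  if (length(raw) == 0) return(parse_protein_one(NA_character_)[0, ])
  dplyr::bind_rows(purrr::map(raw, parse_protein_one))
}

parse_protein_one <- function(raw) {
  if (is.na(raw) || raw %in% c("", "-", "?")) {
    return(tibble::tibble(raw = raw, ref_residue = NA_character_,
                          position = NA_integer_, alt = NA_character_,
                          fs_new_stop = NA_integer_, predicted = NA))
  }
  s <- gsub("[[:space:]]+", "", raw)
  if (!grepl("^p\\.", s)) stop("expected a p.-prefixed description: ", raw, call. = FALSE)
  body <- sub("^p\\.", "", s)
  predicted <- grepl("^\\(.*\\)$", body)
  body <- gsub("^\\(|\\)$", "", body)
  aa <- "([A-Z][a-z]{2})"
  m <- regmatches(body, regexec(
    paste0("^", aa, "([0-9]+)(?:", aa, "fs\\*([0-9]+)|", aa, "|\\*|Ter)$"), body, perl = TRUE))[[1]]
  if (length(m) == 0) stop("cannot parse p. description: ", raw, call. = FALSE)
  ref <- m[2]; pos <- as.integer(m[3])
  if (!ref %in% AA3) stop("unknown amino acid '", ref, "' in: ", raw, call. = FALSE)
  if (m[4] != "") {           # frameshift
    alt <- "fs"; fs <- as.integer(m[5])
    if (fs < 1) stop("frameshift new-stop offset must be >= 1 in: ", raw, call. = FALSE)
    if (!m[4] %in% AA3) stop("unknown amino acid '", m[4], "' in: ", raw, call. = FALSE)
  } else if (m[6] != "") {    # missense
    alt <- m[6]; fs <- NA_integer_
    if (!alt %in% AA3) stop("unknown amino acid '", alt, "' in: ", raw, call. = FALSE)
  } else {                    # nonsense
    alt <- "Ter"; fs <- NA_integer_
  }
  tibble::tibble(raw = raw, ref_residue = ref, position = pos, alt = alt,
                 fs_new_stop = fs, predicted = predicted)
}

#' Infer the variant class used in cohort spectrum tables
#'
#' Precedence: inversion > exon-level gross deletion > splice (canonical for
#' offsets +/-1 or +/-2, noncanonical for any other intronic offset) >
#' protein-consequence typing (direct stop gain is nonsense even when caused
#' by a small indel; frameshifts and other small del/dup/ins/delins are
#' indels; single-base exonic substitutions are missense unless stop gain).
#'
#' @param v A tibble from [parse_cdna()].
#' @param p Optional tibble from [parse_protein()] aligned row-wise with `v`.
#' @return Character vector with levels `missense`, `nonsense`, `indel`,
#'   `canonical_splice`, `noncanonical_splice`, `gross_deletion`, `inversion`.
#' @export
infer_variant_class <- function(v, p = NULL) {
  n <- nrow(v)
  alt_prot <- if (is.null(p)) rep(NA_character_, n) else p$alt
  fs <- if (is.null(p)) rep(NA_integer_, n) else p$fs_new_stop
  vapply(seq_len(n), function(i) {
    r <- v[i, ]
    if (r$kind == "inversion") return("inversion")
    if (r$kind == "gross_deletion") return("gross_deletion")
    offs <- c(r$start_offset, r$end_offset)
    offs <- offs[!is.na(offs)]
    if (length(offs)) {
      if (any(abs(offs) <= 2L)) return("canonical_splice")
      return("noncanonical_splice")
    }
    if (identical(alt_prot[i], "Ter") && is.na(fs[i])) return("nonsense")
    if (r$kind == "substitution") {
      return("missense")
    }
    "indel"
  }, character(1))
}

#' cDNA position of the first base of a predicted premature stop codon
#'
#' For a direct stop gain (`p.X123*`) this is the start of codon 123; for a
#' frameshift (`p.X123Yfs*N`) the new stop is the (N-1)th codon downstream of
#' the first altered residue. Returns `NA` when no termination is implied.
#'
#' @param p A tibble from [parse_protein()].
#' @return Integer vector of cDNA positions (may exceed the CDS length when
#'   a frameshift terminates in 3'UTR-derived sequence).
#' @export
ptc_position <- function(p) {
  res <- ifelse(
    !is.na(p$alt) & p$alt == "Ter" & is.na(p$fs_new_stop),
    p$position,
    ifelse(!is.na(p$fs_new_stop), p$position + p$fs_new_stop - 1L, NA_integer_)
  )
  ifelse(is.na(res), NA_integer_, codon_start(res))
}
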