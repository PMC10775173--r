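---
title: "Strength-modulated ACMG/AMP interpretation of F8 and F9 variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strength-modulated ACMG/AMP interpretation of F8 and F9 variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemvar)
library(dplyr)
```

## The problem

Hemophilia A and B are X-linked bleeding disorders caused by variants in
*F8* and *F9*. Diagnostic laboratories classify each observed variant into
the five ACMG/AMP tiers — pathogenic (P), likely pathogenic (LP), uncertain
(VUS), likely benign (LB), benign (B) — by assigning standardized evidence
codes and combining them. In a hemophilia cohort the evidence is strongly
strength-modulated: loss-of-function weight depends on whether the premature
stop triggers nonsense-mediated decay (NMD), case-count evidence is banded
because individual variants are too rare for formal case-control statistics,
and in-silico scores (REVEL for missense, SpliceAI for splice-region
variants) map to banded strengths. `hemvar` implements this rule set as a
reusable tibble-in/tibble-out pipeline, together with the cohort-level
summaries a genetics clinic reports: variant spectrum by severity, inhibitor
incidence, inheritance, and prenatal outcomes.

## Gene models

The package embeds transcript models for *F8* (NM_000132.3 / NP_000123.1,
26 exons, CDS 7056 nt, 2351 residues including the 19-residue signal
peptide) and *F9* (NM_000133.3 / NP_000124.1, 8 exons, CDS 1386 nt,
461 residues). Coding coordinates are 1-based with +1 at the A of the ATG;
protein numbering includes the signal peptide, matching clinical p.
descriptions.

Exon boundaries are stored as the cDNA coordinate of the last coding base of
each exon. They were transcribed from the published exon structure of each
gene and reconciled against the exon assignments printed in the cohort's
variant tables, which this package treats as its validation surface (the
boundary table is regression-tested against every coding variant's printed
exon). The boundaries are consistent with the classic splice-donor anchors
(F8 c.1443+1 and c.5815+1; F9 c.252+3 and c.723+1 sit exactly on exon ends).

Protein-domain spans (F8: A1, A2, B, A3, C1, C2; F9: signal peptide, Gla,
EGF1, EGF2, activation linker, serine-protease domain) use the standard
mature-protein boundaries shifted by the signal peptide. Two placement
choices were genuinely open and were fixed against the printed Domain
column: the A1 domain ends at residue 351 so that p.Arg355* is inter-domain
while p.Leu326Val is A1, and the F9 Gla span starts at residue 29 so that
the classic propeptide hotspot p.Arg43 reports as Gla, as hemophilia B
tables conventionally print it. The fixture row p.Arg449Gln carries the
printed label "Signal peptide" with an `inconsistent` flag; residue 449 is
in the protease domain and no span placement can reproduce that cell.

NMD is predicted by the standard heuristic: a premature termination codon
escapes NMD when it lies in the last exon or within the 3'-most 50
nucleotides of the penultimate exon (window measured in cDNA coordinates,
inclusive). Frameshift stops beyond the CDS end (read-through into 3'UTR
sequence) count as last-exon. The rule is monotone along the transcript,
which the tests assert as a property.

## Evidence rules and their tunables

All thresholds live in `rule_config()` and are documented defaults rather
than constants:

* **PVS1** — nonsense and frameshift variants: very strong if the predicted
  stop triggers NMD, strong if it escapes. Canonical (+/-1,2) splice
  variants: very strong. Exon-level deletions: strong when confined to the
  last exon, very strong otherwise. The frameshift stop position is computed
  from the `fs*N` offset (`residue + N - 1`).
* **PS4** — reported-case bands 1 / 2–3 / 4–15 / >=16 mapping to supporting
  / moderate / strong / very strong. Case counts are *inputs* (database
  lookups), not computed.
* **PM1** — missense in an annotated functional domain, except the F8 B
  domain, which is largely spliced off the mature protein and is not a
  constraint hotspot.
* **PM2** — population absence (an input flag), applied at supporting
  strength per current recommendation.
* **PP3/BP4 (missense, REVEL)** — pathogenic bands >=0.932 (strong, capped
  to moderate to avoid over-weighting a single in-silico line), [0.733,
  0.932) moderate, [0.644, 0.733) supporting; benign bands <=0.003 very
  strong, (0.003, 0.016] strong, (0.016, 0.183] moderate, (0.183, 0.290]
  supporting. Scores in (0.290, 0.644) yield nothing; the bands partition
  the axis, asserted over a grid.
* **PP3/BP7 (splice, SpliceAI)** — supporting PP3 above 0.2, supporting BP7
  below 0.01, both exclusive.
* **PP4** — phenotype gate: factor activity below 40% of normal in a linked
  patient. Censored activities ("<1") are carried as an upper bound and
  "<x" is read as strictly below x, so "<1" is severe and satisfies PP4.
* **BS2** — a pass-through input flag: the cohort tables apply it to three
  variants without stating the underlying healthy-carrier observation, so
  there is nothing to compute.
* **BP2** — assigned in a second pass: a variant in a patient who also
  carries a P/LP variant (classified in the first pass) in the same gene
  gets BP2, and its PM1/PP4 are withheld because the phenotype is
  attributed to the co-occurring variant. This reproduces both printed
  co-occurrence rows, including the absence of PM1 on the A1-domain
  missense co-occurring with an exon 1 deletion.

Every computed criterion is emitted in the compact clinical notation
(`"PVS1, PS4-M, PM2-PP, PP4"`); a suffix appears only when the applied
strength differs from the code's default. The parser tolerates the suffix
synonyms seen in print (`-PS` for strong, `-PM` for moderate).

## Combining evidence

`combiner_config()` supports two modes. Points mode (default) scores very
strong/strong/moderate/supporting as 8/4/2/1, positive for pathogenic and
negative for benign codes, with tiers P >= 10, LP 6..9, VUS 0..5, LB -6..-1,
B <= -7. Categorical mode applies the published combining rules literally
and returns VUS when a rule fires on one side while evidence exists on the
other (conflict).

Points mode is the default because the categorical combinations cannot
produce LP from {PVS1, PM2-supporting} — one very strong plus a single
supporting item matches no rule — yet that pairing is a natural LP under
points (score 9), and it is the call the cohort tables print for the two
novel B-domain frameshifts. On the packaged tables the two modes agree on
105 of 107 rows; the divergence set is exactly those two rows
(`c.3235dup`, `c.3348del`), asserted as such in the tests. Both modes'
answers and their agreement are reported on every row.

```{r}
classify_variants(
  tibble::tibble(gene = "F8", nucleotide = "c.3235dup",
                 protein = "p.(Arg1079Lysfs*8)", absent_from_population = TRUE)
) |> tidy()
```

## The packaged cohort tables

`hem_fixture()` loads transcriptions of the source cohort's tables: 83
distinct *F8* variants, 24 *F9* variants, a 193-patient expansion, 40
fetuses, and the printed summary table. Printed strings are stored
untouched; load-time normalization adds the evidence inputs the tables
imply but do not print (case counts from the printed PS4 band, population
absence from PM2, BS2 flags). Seven rows whose printed criteria contradict
the stated bands are flagged `inconsistent` and carry recorded overrides;
the regression asserts the remaining 100 rows byte-for-byte against the
printed criteria and classification, and the flagged rows under their
overrides. Cells of the printed summary whose percentage differs from
recomputation (round-half-up, one decimal) carry `rounding_discrepancy`
flags rather than a bent rounding rule; the prenatal table's per-sex cells
are transcribed as printed even though their grand total disagrees with the
printed one by one carrier.

```{r}
res <- run_cohort_analysis(hem_fixture("variants"), hem_fixture("patients"),
                           hem_fixture("fetuses"))
glance(res$classified)
res$spectrum |> filter(variant_class == "total")
res$inhibitor |> filter(group %in% c("nonsense", "gross_deletion"))
res$prenatal$overall
```

## Patient-level derivations

Severity bands follow the clinical definition: severe below 1% factor
activity, moderate 1–5% (both ends inclusive), mild above 5% up to 40%;
above 40% is flagged as not hemophilia. An activity of exactly 0 (below
detection) is accepted as severe rather than rejected. Inhibitor titers use
the Bethesda definition — one BU leaves 50% residual activity — so
`bethesda_units(residual) = log2(100 / residual)`, with an exact inverse
used in round-trip tests. Gross-deletion sizes are computed from flanking
breakpoints as the count of bases strictly between them.

## Synthetic cohorts

`simulate_cohort()` draws patient, variant and fetus tables from
`cohort_params()`, whose defaults are the observed cohort conditions: the
per-gene class mixture, severity conditional on class (inversions and
truncating classes almost all severe), per-class inhibitor rates among
tested patients, 95% maternal inheritance, 85% male fetuses, and 50%
transmission. A single seeded stream drives each cohort; the seed is
recorded in the ground-truth ledger. Where the source tables do not pin a
value the generator uses one fixed, realistic choice: inhibitor testing
coverage and maternal-testing coverage are set to the cohort's observed
fractions (142/193 and 103/193), activities are drawn uniformly within the
severity band, and positive titers uniformly in 0.6–40 BU.

Synthetic variants are structurally valid (nonsense stops at
NMD-informative positions, missense in plausible residues with
band-consistent REVEL scores) but they are not mutational-spectrum
realistic: there are no hotspot codons, no poly-A slippage clustering, no
linkage between REVEL and true effect beyond the band draw, and activity
noise is a uniform draw. Passing recovery tests therefore demonstrate that
the pipeline's estimators recover the generating rates — not that the
generator reproduces real mutational biology.

The recovery checks use cohorts of 500 patients and 100 seeded replicates
(problem sizes chosen to keep each per-class denominator informative while
the whole suite stays interactive), asserting that exact binomial intervals
around the per-class inhibitor estimates cover the generating rate in at
least 93% of replicates.

## Numerical and degenerate-input choices

Percentages are rendered with round-half-up at one decimal (6.25 prints as
6.3), matching the dominant convention of the printed tables; flagged cells
record where print deviates. Rates over zero tested patients are returned
as `NA` with an `undefined` flag, never 0. Empty inputs yield empty, typed
tables. Censored activities compare by their bound with strict band edges.
The classification of an inversion is out of the sequence-evidence
framework's scope: inversions pass through with `NA` classification and are
counted as their own spectrum classes.

## Known limitations

* Exon boundaries and domain spans are package data reconciled to the
  validation tables, not live RefSeq/UniProt queries; transcript liftover
  and alternative transcripts are out of scope.
* Database-derived evidence (case counts, population absence, BS2 grounds,
  REVEL, SpliceAI) must be supplied as inputs; the package neither queries
  gnomAD/HGMD-style resources nor computes in-silico scores.
* The categorical combiner implements only the published combinations plus
  a conservative conflict rule; gene-specific expert-panel rule sets are
  not modeled.
* Age and diagnostic-delay statistics are not reproducible from published
  data (raw ages are unpublished) and are deliberately not implemented.
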