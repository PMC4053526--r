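---
title: "Methods: in-silico multiplex PCR subtyping of KIR3DL1/KIR3DS1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico multiplex PCR subtyping of KIR3DL1/KIR3DS1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kir3dl1typer)
```

## The problem and the model

KIR3DL1 is the most polymorphic inhibitory receptor of human NK cells; its
locus also encodes the activating lineage KIR3DS1. Alleles fall into six
functional subtype groups defined by surface expression and HLA-Bw4 binding
behaviour: a null group (canonical allele \*004, retained intracellularly),
two low-expression groups (\*005-group and \*007-group), two high-expression
groups (\*001-group and \*002-group), and KIR3DS1 (\*013). Medium-resolution
typing to the group level is sufficient for most immunogenetic questions
(e.g. compound KIR3DL1/HLA-Bw4 genotype effects), and can be achieved with
sequence-specific-primer (PCR-SSP) chemistry: primers whose 3' termini sit on
diagnostic SNPs, so that amplification itself is the genotype call.

This package re-implements the computational logic of that assay:

1. **SNP decision table.** Four diagnostic coding-sequence sites — positions
   193 and 202 (exon 3), 607 (exon 4) and the dinucleotide 1021/1022
   (exon 7), 1-based from the A of the initiator ATG — partition alleles into
   the six groups. Rules fire in order: 193G → null; 202A+607T → \*005-low;
   202A+607C → \*001-high; 202G+607C+CG → \*007-low; 202G+607C+CA →
   \*002-high or KIR3DS1; anything else is `UNCLASSIFIED`. The null rule has
   precedence because the null group shares 202A/607T with the \*005-group;
   the wet assay realises this precedence with a primer footprint spanning
   position 193, the classifier realises it as rule order.
2. **Virtual multiplex PCR.** Five reactions (R1–R5) plus an HLA-DR internal
   control are simulated by IUPAC-aware primer matching: a site qualifies if
   the 3'-terminal `three_prime_anchor` bases (default 3) match exactly and
   the remaining positions carry at most `max_internal_mismatches`
   (default 0) mismatches. Strict full-length matching stands in for the
   annealing-temperature optimisation of the wet protocol, which is not
   modelled; the published cycling metadata is carried in the panel config as
   inert provenance. The \*002-group and KIR3DS1 share all typed SNPs and
   both amplify in R4; they are separated by product size, because KIR3DS1
   intron 3 is 360 bp longer (1933 vs 1573 bp).
3. **Pattern decoding.** All 21 unordered group pairs are forward-simulated
   and the map inverted. Exactly one collision exists by design: a \*007-group
   homozygote and a \*007/\*002-group heterozygote both show the small R4
   product plus the R5 band. Decoding reports both hypotheses; supplying
   exon-7 dinucleotide reads (CG vs CA) resolves the collision, the in-silico
   counterpart of sequencing exon 7.
4. **Pedigree logic.** A child's typing is consistent when some hypothesis
   can be split into one transmissible unit from each parent; a unit is a
   single group or, under extended transmission, a linked pair of groups (a
   duplicated haplotype carrying both KIR3DS1 and a null allele is the
   published example, producing three-allele individuals).
5. **Population arithmetic.** Group frequencies aggregate the packaged
   426-donor allele-frequency table via the published group membership;
   Hardy-Weinberg genotype frequencies are `p^2` / `2pq` after explicit
   renormalisation (the printed table sums to 99.98%); the population
   ambiguity rate is `q^2 + 2pq` with `q` the \*007-group and `p` the
   \*002-group frequency; group frequencies are recoverable from ambiguous
   typings by gene-counting EM.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_internal_mismatches` | 0 | mismatches tolerated outside the 3' anchor |
| `three_prime_anchor` | 3 nt | 3'-terminal bases requiring an exact match |
| `max_product` | 5000 bp | largest product considered (covers all designed products) |
| `gel_tolerance` | 25 bp | bands closer than this merge into one; 1573/1933 stay distinct under any sane value |
| `coordinate_offset` | 0 | 0 = 1021/1022 dinucleotide convention; −1 for the alternative 1020/1021 reading, which the source description leaves ambiguous |
| `bootstrap_reps` | 100 | NJ bootstrap replicates; replicate `r` is seeded `seed + r` |

## What the synthetic fixtures emulate — and what they do not

No sequence database download is required: `make_template()` builds synthetic
genomic templates (nine exons with realistic KIR3DL1 coding lengths — CDS
1281 nt, diagnostic sites in exons 3/4/7 — plus UTRs and introns) whose
spliced CDS carries each group's diagnostic states and whose primer
footprints are written base-exact for the group's designed reactions only.
Intron lengths are calibrated so the five designed amplicons reproduce the
published sizes (2019 / 1573 / 1573 / 1573–1933 / 1408 bp). Two calibration
facts deserve emphasis:

* With every primer 3'-anchored exactly on its SNP, reactions 3 and 4 —
  which share the reverse primer `607C-R` but have forward primers differing
  by 6 nt in length — could not both produce 1573 bp. Since primer genomic
  offsets are not published, the scaffold anchors the R2/R3 primers on their
  SNPs (intron 3 = 1122 bp) and places the shared `607C-R` footprint 6 nt
  downstream of the SNP on \*002-group/\*007-group/KIR3DS1 templates. All
  five printed sizes are then reproduced by construction. Absolute size
  reproduction on *real* genomic sequence would be the authoritative check
  and is supported but deliberately not required.
* Non-diagnostic sequence is seeded uniform background, shared across groups
  at equal seed, so the KIR3DS1 template differs from the inhibitory
  template only by its 360 bp intron-3 insertion. Off-target primer sites in
  random background are astronomically unlikely (≤ 4^-15 per position) and
  are asserted empirically by the signature tests.

A green test therefore establishes that the *engine arithmetic and decision
logic* are correct on sequences with the assay's designed structure. It does
**not** establish performance on real IPD-KIR sequences (real intron-length
variation within groups, rare alleles with footprint polymorphisms), nor
wet-lab failure modes (weak bands, temperature sensitivity, primer dimers).

The phylogeny fixture plants 12 group-specific marker substitutions (~1% of
the CDS) per group plus ≤2% per-member background noise. The markers are
essential realism, not convenience: \*002-group and KIR3DS1 share all four
diagnostic states, so without lineage-specific divergence (which real
KIR3DS1 amply shows) no distance method could separate them into clades.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout (Bioconductor idiom);
  amplicon size is `end − start + 1`, inclusive of both primer footprints —
  this convention reproduces the published product sizes.
* **Control product size** is recorded as 607 bp from the primer table; the
  running text twice says 650 bp. The config carries 607 and flags the
  discrepancy; nothing downstream depends on which is true.
* **Band merging** reports the smallest member of each ≤25 bp cluster
  (deterministic; only relevant for near-comigrating products, which the
  designed panel never produces).
* **NJ trees**: p-distance with pairwise deletion of N/gap columns; negative
  branch-length estimates clamped to 0; bootstrap support = percentage of
  replicate trees containing each internal bipartition.
* **Nearest reference**: percent identity over ungapped columns of a global
  alignment; ties break to the lowest numeric allele designation.
* **Suballele collapsing** reduces any designation longer than three digits
  to its three-digit canonical allele (\*0040101 → \*004); collapsing twice
  equals collapsing once.
* **Joint table rows** (\*001/\*016) are aggregated wholly to their common
  group; the unpublished split is not invented. The unknown \*073 row's mass
  (0.12%) is reported as unassigned, never redistributed.
* **Homozygote vs heterozygote within one group** is indistinguishable by
  design (single-band signatures); genotype hypotheses are group pairs,
  never allele pairs. Extended-haplotype search is capped at three groups,
  the published maximum.
* **EM** (`estimate_group_frequencies`) uses gene counting: ambiguous
  samples contribute fractionally by their current Hardy-Weinberg posterior;
  the observed-data log-likelihood is non-decreasing and returned.
* The source description's "<0.01%" figure for \*007-group homozygosity
  conflicts with naive Hardy-Weinberg arithmetic on the printed table
  (0.027² ≈ 0.073%); its basis is unstated, so it is not asserted anywhere.
* One published allele (\*042) is listed both within the \*002-group and as
  an unknown whose SNP states match no reaction; the decision table returns
  `UNCLASSIFIED` for those states, while the membership table retains the
  group listing with a comment.

## Worked example

```{r example}
# classify the synthetic high-frequency reference set
refs <- make_reference_alleles(seed = 42)
cls <- classify_sequence(refs[["KIR3DS1*013"]], refs)
cls$group

# type a simulated heterozygous donor
panel <- kir_panel()
donor <- list(make_template("HIGH1", seed = 1), make_template("NULL", seed = 1))
pat <- run_panel(donor, panel, sample_id = "demo")
decode_pattern(pat, panel)

# the documented ambiguity and its resolution
hom007 <- run_panel(rep(list(make_template("LOW2", seed = 1)), 2), panel)
length(decode_pattern(hom007, panel)$hypotheses)        # 2 hypotheses
decode_pattern(hom007, panel, exon7_reads = "CG")$hypotheses
```

## Known limitations

* Fixtures are structurally, not literally, faithful: no real KIR intron
  sequence is reproduced, and per-allele intron-length variation within a
  group (beyond the 360 bp KIR3DS1 insertion) is assumed absent.
* The CLI `type` subcommand accepts band-pattern TSV only; typing from
  arbitrary genomic FASTA would require an exon/intron annotation that plain
  FASTA does not carry (use `run_panel()` programmatically instead).
* No melting-temperature, secondary-structure or primer-dimer modelling; no
  electrophoresis mobility simulation beyond the size tolerance; no
  maximum-likelihood phylogenetics; no linkage analysis beyond transmission
  consistency.
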