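Package: kir3dl1typer
Title: In-Silico Multiplex PCR Subtyping of KIR3DL1 and KIR3DS1 Alleles
Version: 0.1.0
Authors@R:
    person("KIR Typing", "Maintainers", email = "kir3dl1typer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for medium-resolution functional subtyping of KIR3DL1 and
    KIR3DS1 alleles. Classifies coding sequences into six functional subtype
    groups (null, two low-expression, two high-expression, and the activating
    KIR3DS1 lineage) using a SNP decision table over coding positions 193, 202,
    607 and 1021/1022; simulates the five-reaction sequence-specific-primer
    multiplex PCR panel with IUPAC-degenerate primer matching and amplicon size
    prediction; decodes band patterns back to genotype hypotheses including the
    documented *002-group/*007 ambiguity and extended (polyallelic) haplotypes;
    checks Mendelian consistency in pedigrees; and provides population-genetic
    arithmetic (cumulative allele frequencies, Hardy-Weinberg genotype
    frequencies, typing-ambiguity rates, and EM estimation of group frequencies
    from ambiguous typings). A deterministic synthetic-fixture generator
    produces allele sequences, genomic templates with the KIR3DL1/KIR3DS1
    intron structure, diploid cohorts and multi-generation pedigrees so the
    entire toolkit is testable without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
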