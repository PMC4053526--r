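#' Functional subtype groups of KIR3DL1/KIR3DS1 alleles
#'
#' The toolkit recognises six typed functional groups plus the pseudo-group
#' `UNCLASSIFIED`. Group labels, their canonical (most common) allele, and the
#' surface-expression class they imply:
#'
#' | label   | canonical allele | expression class |
#' |---------|------------------|------------------|
#' | NULL    | KIR3DL1*004      | null             |
#' | LOW1    | KIR3DL1*005      | low              |
#' | LOW2    | KIR3DL1*007      | low              |
#' | HIGH1   | KIR3DL1*001      | high             |
#' | HIGH2   | KIR3DL1*002      | high             |
#' | S1      | KIR3DS1*013      | activating       |
#'
#' @return A data frame with columns `label`, `canonical_allele`,
#'   `expression_class`, one row per typed group plus `UNCLASSIFIED`.
#' @export
kir_groups <- function() {
  data.frame(
    label = c("NULL", "LOW1", "LOW2", "HIGH1", "HIGH2", "S1", "UNCLASSIFIED"),
    canonical_allele = c("KIR3DL1*004", "KIR3DL1*005", "KIR3DL1*007",
                         "KIR3DL1*001", "KIR3DL1*002", "KIR3DS1*013", NA),
    expression_class = c("null", "low", "low", "high", "high", "activating",
                         "unknown"),
    stringsAsFactors = FALSE
  )
}

#' @rdname kir_groups
#' @export
kir_group_labels <- function() {
  c("NULL", "LOW1", "LOW2", "HIGH1", "HIGH2", "S1")
}

.assert_group <- function(group, allow_unclassified = FALSE) {
  ok <- kir_group_labels()
  if (allow_unclassified) ok <- c(ok, "UNCLASSIFIED")
  if (!(is.character(group) && length(group) == 1L && group %in% ok)) {
    stop("unknown subtype group: ", paste(group, collapse = ","), call. = FALSE)
  }
  invisible(group)
}

#' Expected NK-cell surface phenotype for a subtype group
#'
#' Maps a functional subtype group to the NK surface phenotype expected from
#' staining with the DX9 (binds KIR3DL1 only) and Z27 (binds KIR3DL1 and
#' KIR3DS1) monoclonal antibodies: high-expression groups give a high-density
#' double-positive population, low-expression groups a low-density
#' double-positive population, the null group no surface staining, and the
#' activating KIR3DS1 lineage a Z27-single-positive population.
#'
#' @param group A subtype group label (see [kir_groups()]); `UNCLASSIFIED`
#'   is an error since no phenotype is defined for it.
#' @return One of `"DX9+Z27+ high"`, `"DX9+Z27+ low"`, `"surface-negative"`,
#'   `"Z27+DX9-"`.
#' @export
expected_phenotype <- function(group) {
  if (identical(group, "UNCLASSIFIED")) {
    stop("no phenotype defined for UNCLASSIFIED", call. = FALSE)
  }
  .assert_group(group)
  switch(group,
    "HIGH1" = ,
    "HIGH2" = "DX9+Z27+ high",
    "LOW1"  = ,
    "LOW2"  = "DX9+Z27+ low",
    "NULL"  = "surface-negative",
    "S1"    = "Z27+DX9-"
  )
}

#' Diagnostic SNP states of the subtype groups
#'
#' The four diagnostic coding-sequence sites used by the typing panel:
#' positions 193 and 202 (exon 3), 607 (exon 4) and the dinucleotide at
#' 1021/1022 (exon 7), 1-based from the A of the initiator ATG. Groups whose
#' published dinucleotide state is polymorphic ("C/A or T/G") are recorded
#' with both admissible dinucleotides separated by `|`; the typing rules never
#' consult the dinucleotide for those groups.
#'
#' Two published low-frequency alleles carry SNP combinations matched by no
#' reaction and are retained here as `UNCLASSIFIED` exemplars (*042: A/G/T/CA;
#' *073: A/A/A/CA).
#'
#' @return Data frame with columns `group`, `allele`, `p193`, `p202`, `p607`,
#'   `dinuc`.
#' @export
kir_snp_states <- function() {
  data.frame(
    group  = c("NULL", "LOW1", "HIGH1", "HIGH2", "LOW2", "S1",
               "UNCLASSIFIED", "UNCLASSIFIED"),
    allele = c("KIR3DL1*004", "KIR3DL1*005", "KIR3DL1*001", "KIR3DL1*002",
               "KIR3DL1*007", "KIR3DS1*013", "KIR3DL1*042", "KIR3DL1*073"),
    p193   = c("G", "A", "A", "A", "A", "A", "A", "A"),
    p202   = c("A", "A", "A", "G", "G", "G", "G", "A"),
    p607   = c("T", "T", "C", "C", "C", "C", "T", "A"),
    dinuc  = c("TG", "CA|TG", "CA|TG", "CA", "CG", "CA", "CA", "CA"),
    stringsAsFactors = FALSE
  )
}

#' Allele-to-group membership table
#'
#' Reads the packaged membership table mapping every published KIR3DL1/KIR3DS1
#' allele designation (high- and low-frequency) to its functional subtype
#' group.
#'
#' @param path Path to a membership TSV; defaults to the packaged table.
#' @return Data frame with columns `allele`, `group`, `tier`
#'   (`high_frequency` or `low_frequency`).
#' @export
kir_group_membership <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "group_membership.tsv",
                        package = "kir3dl1typer", mustWork = TRUE)
  }
  m <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("allele", "group", "tier") %in% names(m)))
  m
}

# Resolve an allele designation (possibly lacking a gene prefix, possibly a
# joint label like "KIR3DL1*001/*016") to its subtype group via the
# membership table. Returns NA_character_ when unknown or when a joint label
# spans two groups.
.lookup_group <- function(name, membership = kir_group_membership()) {
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  grp <- vapply(parts, function(p) {
    hit <- membership$group[membership$allele == p]
    if (length(hit) == 0L && !grepl("^KIR3D", p)) {
      # bare "*049"-style designation: match the numeric part against either
      # gene, tolerating a trailing expression suffix (*049 ~ KIR3DS1*049N)
      bare <- sub("N$", "", sub("^KIR3D[LS]1", "", membership$allele))
      hit <- membership$group[bare == sub("N$", "", p)]
    }
    if (length(hit) == 0L) NA_character_ else hit[[1]]
  }, character(1))
  grp <- unique(grp[!is.na(grp)])
  if (length(grp) == 1L) grp else NA_character_
}
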