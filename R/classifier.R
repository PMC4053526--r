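#' Classify a SNP profile into a functional subtype group
#'
#' Applies the SNP decision table over the diagnostic sites. Rules fire in
#' order; the null rule has precedence because the null group shares its
#' 202A/607T states with the *005-group (the wet assay achieves the same
#' precedence through a primer footprint spanning position 193):
#'
#' 1. `193 = G` -> `NULL`
#' 2. `202 = A & 607 = T` -> `LOW1`
#' 3. `202 = A & 607 = C` -> `HIGH1`
#' 4. `202 = G & 607 = C & 1021/1022 = CG` -> `LOW2`
#' 5. `202 = G & 607 = C & 1021/1022 = CA` -> `HIGH2` or `S1` (the typed SNPs
#'    are identical between the two; `needs_gene_disambiguation` is set)
#' 6. otherwise `UNCLASSIFIED`
#'
#' Any consulted site reading `N` yields `UNCLASSIFIED` rather than a forced
#' call. An incomplete dinucleotide is only an obstacle when rules 4/5 are
#' reached (202G/607C), in which case the result is `UNCLASSIFIED` with an
#' explanatory note; incomplete 193/202/607 is an error.
#'
#' @param profile A `kir_snp_profile`.
#' @param gene Optional `"KIR3DL1"`/`"KIR3DS1"` (or `"3DL1"`/`"3DS1"`) gene
#'   annotation used to resolve the shared HIGH2/S1 rule.
#' @return A `kir_classification`: list with `group`, `rule_fired`,
#'   `needs_gene_disambiguation`, `nearest` (filled by [classify_sequence()]),
#'   `note`.
#' @export
classify_snp_profile <- function(profile, gene = NULL) {
  stopifnot(inherits(profile, "kir_snp_profile"))
  if (!all(profile$complete[c("p193", "p202", "p607")])) {
    stop("SNP profile incomplete at positions 193/202/607: cannot classify",
         call. = FALSE)
  }
  res <- function(group, rule, needs = FALSE, note = NA_character_) {
    structure(list(group = group, rule_fired = rule,
                   needs_gene_disambiguation = needs, nearest = NULL,
                   note = note),
              class = "kir_classification")
  }
  b <- c(profile$p193, profile$p202, profile$p607)
  if (any(b == "N")) {
    return(res("UNCLASSIFIED", "rule6_no_match",
               note = "diagnostic site reads N"))
  }
  if (profile$p193 == "G") return(res("NULL", "rule1_193G"))
  if (profile$p202 == "A" && profile$p607 == "T") {
    return(res("LOW1", "rule2_202A_607T"))
  }
  if (profile$p202 == "A" && profile$p607 == "C") {
    return(res("HIGH1", "rule3_202A_607C"))
  }
  if (profile$p202 == "G" && profile$p607 == "C") {
    dinuc <- profile$p1021_1022
    if (!profile$complete[["p1021_1022"]] || grepl("N", dinuc)) {
      return(res("UNCLASSIFIED", "rule6_no_match",
                 note = "202G/607C but exon-7 dinucleotide unreadable"))
    }
    if (dinuc == "CG") return(res("LOW2", "rule4_202G_607C_CG"))
    if (dinuc == "CA") {
      gene <- .normalize_gene(gene)
      if (identical(gene, "KIR3DS1")) {
        return(res("S1", "rule5_202G_607C_CA"))
      }
      if (identical(gene, "KIR3DL1")) {
        return(res("HIGH2", "rule5_202G_607C_CA"))
      }
      return(res("HIGH2", "rule5_202G_607C_CA", needs = TRUE,
                 note = "typed SNPs identical between HIGH2 and S1"))
    }
  }
  res("UNCLASSIFIED", "rule6_no_match")
}

.normalize_gene <- function(gene) {
  if (is.null(gene) || length(gene) == 0L || is.na(gene)) return(NULL)
  if (grepl("3DS1", gene)) return("KIR3DS1")
  if (grepl("3DL1", gene)) return("KIR3DL1")
  NULL
}

#' @export
print.kir_classification <- function(x, ...) {
  cat(sprintf("<kir_classification> %s (%s)%s%s\n", x$group, x$rule_fired,
              if (isTRUE(x$needs_gene_disambiguation)) " [HIGH2/S1 unresolved]" else "",
              if (!is.null(x$nearest))
                sprintf("  nearest %s (%.2f%%)", x$nearest$allele,
                        x$nearest$identity) else ""))
  invisible(x)
}

#' Classify a full coding sequence
#'
#' Extracts the SNP profile and applies [classify_snp_profile()]. The shared
#' HIGH2/S1 decision-table row is resolved by (a) the gene carried in the
#' allele name when present, else (b) the gene of the nearest reference
#' coding sequence; if neither resolves, the disambiguation flag is left set.
#' `UNCLASSIFIED` results always carry a nearest-reference suggestion.
#'
#' @param allele A `kir_allele` (or plain coding sequence).
#' @param references Named list of `kir_allele` reference sequences; must be
#'   non-empty whenever disambiguation or a nearest suggestion is needed.
#'   Defaults to the synthetic high-frequency reference set.
#' @param coordinate_offset Passed to [extract_snp_profile()].
#' @return A `kir_classification` (see [classify_snp_profile()]).
#' @export
classify_sequence <- function(allele, references = NULL,
                              coordinate_offset = 0L) {
  if (!inherits(allele, "kir_allele")) {
    allele <- .new_allele("query", allele)
  }
  prof <- extract_snp_profile(allele, coordinate_offset)
  gene <- .normalize_gene(regmatches(allele$name,
                                     regexpr("KIR3D[LS]1", allele$name)))
  cls <- classify_snp_profile(prof, gene = gene)
  need_nearest <- isTRUE(cls$needs_gene_disambiguation) ||
    cls$group == "UNCLASSIFIED"
  if (need_nearest) {
    if (is.null(references)) references <- make_reference_alleles()
    if (length(references) == 0L) {
      stop("empty reference set: cannot resolve HIGH2/S1 or suggest nearest",
           call. = FALSE)
    }
    nn <- nearest_reference(allele$cds, references)
    cls$nearest <- nn
    if (isTRUE(cls$needs_gene_disambiguation)) {
      ref_gene <- .normalize_gene(nn$allele)
      if (!is.null(ref_gene)) {
        cls$group <- if (ref_gene == "KIR3DS1") "S1" else "HIGH2"
        cls$needs_gene_disambiguation <- FALSE
        cls$note <- paste0("HIGH2/S1 resolved by nearest reference ",
                           nn$allele)
      }
    }
  }
  cls
}

#' Nearest reference coding sequence by global-alignment identity
#'
#' Percent identity is computed over the ungapped aligned positions of a
#' global (Needleman-Wunsch) alignment of the query against each reference
#' coding sequence; the reference with maximal identity is returned. Ties are
#' broken deterministically by the lowest numeric allele designation
#' (KIR3DL1 before KIR3DS1 at equal numbers).
#'
#' @param query Nucleotide string.
#' @param references Non-empty named list of `kir_allele` objects.
#' @return List with `allele` (name) and `identity` (percent).
#' @export
nearest_reference <- function(query, references) {
  if (!nzchar(query)) stop("empty query sequence", call. = FALSE)
  if (length(references) == 0L) stop("empty reference set", call. = FALSE)
  ids <- vapply(references, function(ref) {
    if (identical(ref$cds, toupper(query))) return(100)
    aln <- pairwiseAlignment(DNAString(toupper(query)), DNAString(ref$cds),
                             type = "global")
    100 * nmatch(aln) / (nmatch(aln) + nmismatch(aln))
  }, numeric(1))
  nms <- vapply(references, `[[`, character(1), "name")
  num <- suppressWarnings(as.integer(sub("N$", "",
                                         sub("^KIR3D[LS]1\\*", "", nms))))
  gene_rank <- ifelse(grepl("3DS1", nms), 1L, 0L)
  ord <- order(-ids, num, gene_rank, nms)
  best <- ord[[1]]
  list(allele = nms[[best]], identity = unname(ids[[best]]))
}

#' Pairwise p-distance matrix of an alignment
#'
#' Proportion of differing columns among columns where neither sequence reads
#' `N` or a gap (pairwise deletion).
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return A symmetric numeric matrix.
#' @export
p_distance <- function(alignment) {
  n <- length(alignment)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("alignment sequences must have equal length",
                            call. = FALSE)
  if (L == 0L) stop("zero-length alignment", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !(mat[i, ] %in% c("N", "-")) & !(mat[j, ] %in% c("N", "-"))
      nok <- sum(ok)
      d[i, j] <- d[j, i] <- if (nok == 0L) 0 else
        sum(mat[i, ok] != mat[j, ok]) / nok
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds an unrooted neighbor-joining tree on the p-distance matrix of a
#' multiple alignment, with nonparametric bootstrap support computed by
#' resampling alignment columns with replacement. Support for each internal
#' edge is the percentage of replicate trees containing the same bipartition,
#' stored as internal node labels. Negative NJ branch-length estimates are
#' clamped to zero. Deterministic for a given seed: replicate `r` draws its
#' columns under `seed + r`.
#'
#' @param alignment Named character vector of >= 3 equal-length sequences.
#' @param bootstrap_reps Number of bootstrap replicates (0 disables).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with `node.label` bootstrap percentages.
#' @export
build_nj_tree <- function(alignment, bootstrap_reps = 100L, seed = 1L) {
  if (length(alignment) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    stop("alignment must have unique names", call. = FALSE)
  }
  tree_from <- function(seqs) {
    tr <- ape::nj(p_distance(seqs))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }
  main <- tree_from(alignment)
  if (bootstrap_reps > 0L) {
    L <- nchar(alignment[[1]])
    mat <- do.call(rbind, strsplit(alignment, ""))
    reps <- vector("list", bootstrap_reps)
    for (r in seq_len(bootstrap_reps)) {
      set.seed(seed + r)
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      names(res) <- names(alignment)
      reps[[r]] <- tree_from(res)
    }
    counts <- ape::prop.clades(main, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    main$node.label <- as.character(round(100 * counts / bootstrap_reps))
  }
  main
}

#' Test whether a set of taxa forms a clade of an unrooted tree
#'
#' True when the taxon set (or its complement) is a monophyletic bipartition
#' of the unrooted topology.
#'
#' @param tree An [ape::phylo] tree.
#' @param taxa Character vector of tip labels.
#' @return Logical.
#' @export
is_clade <- function(tree, taxa) {
  tips <- tree$tip.label
  stopifnot(all(taxa %in% tips))
  if (length(taxa) <= 1L || length(taxa) >= length(tips) - 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  want <- sort(match(taxa, tips))
  comp <- sort(setdiff(seq_along(tips), want))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, want) || identical(sp, comp)) return(TRUE)
  }
  # prop.part on unrooted trees enumerates clades relative to an arbitrary
  # root; check bipartitions of the rooted representation's complement too.
  FALSE
}

#' Write a classification report as TSV
#'
#' @param results Named list of `kir_classification` objects (names = allele
#'   names).
#' @param path Output path, or `""` for stdout.
#' @export
write_classification_report <- function(results, path = "") {
  lines <- c("allele\tgroup\trule\tnearest\tidentity",
             vapply(names(results), function(nm) {
               r <- results[[nm]]
               sprintf("%s\t%s\t%s\t%s\t%s", nm, r$group, r$rule_fired,
                       if (is.null(r$nearest)) "." else r$nearest$allele,
                       if (is.null(r$nearest)) "." else
                         sprintf("%.2f", r$nearest$identity))
             }, character(1)))
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
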