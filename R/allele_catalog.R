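#' @importFrom Biostrings readDNAStringSet DNAString DNAStringSet
#'   writeXStringSet reverseComplement matchPattern pairwiseAlignment nmatch
#'   nmismatch
NULL

.new_allele <- function(name, cds, genomic = NULL, group = NA_character_,
                        frequency = NA_real_) {
  cds <- toupper(cds)
  if (!nzchar(cds) || grepl("[^ACGTN]", cds)) {
    stop("allele ", name, ": coding sequence must be non-empty over A,C,G,T,N",
         call. = FALSE)
  }
  structure(
    list(name = name, cds = cds, genomic = genomic, group = group,
         frequency = frequency),
    class = "kir_allele"
  )
}

#' @export
print.kir_allele <- function(x, ...) {
  cat(sprintf("<kir_allele> %s  cds %d nt%s%s\n", x$name, nchar(x$cds),
              if (!is.null(x$genomic)) sprintf("  genomic %d nt", nchar(x$genomic)) else "",
              if (!is.na(x$group)) paste0("  group ", x$group) else ""))
  invisible(x)
}

# Collapse an IPD-style designation to its 3-digit canonical allele:
# "KIR3DL1*0040101" -> "KIR3DL1*004". Expression suffixes (trailing N) are
# dropped when collapsing since they are not defined for the truncated
# designation. Idempotent.
.collapse_name <- function(name) {
  m <- regmatches(name, regexec("^(KIR3D[LS]1)\\*(\\d+)(N?)$", name))[[1]]
  if (length(m) == 0L) return(name)
  digits <- m[3]
  if (nchar(digits) <= 3L) return(name)
  paste0(m[2], "*", substr(digits, 1, 3))
}

# Pull an IPD-style allele name out of a FASTA header. Headers may carry
# extra tokens ("KIR3DL1*004 some description") or IPD-style accession
# prefixes ("KIR:KIR00001 KIR3DL1*0010101 1345 bp").
.parse_allele_name <- function(header) {
  m <- regmatches(header, regexpr("KIR3D[LS]1\\*\\d+N?", header))
  if (length(m) == 0L || !nzchar(m)) NA_character_ else m
}

#' Read KIR3DL1/KIR3DS1 allele sequences from a FASTA file
#'
#' Parses a multi-record FASTA of coding sequences whose headers carry
#' IPD-style allele names (e.g. `KIR3DL1*00401`). With
#' `collapse_suballeles = TRUE`, designations longer than three digits are
#' collapsed to their canonical three-digit allele (suballeles differ only in
#' intronic/synonymous positions and type identically); when two records
#' collapse to the same canonical name the first-seen sequence is kept and a
#' message is emitted.
#'
#' @param path FASTA file path.
#' @param collapse_suballeles Collapse suballele designations (default `TRUE`).
#' @return Named list of `kir_allele` objects (names are allele names).
#' @export
read_allele_fasta <- function(path, collapse_suballeles = TRUE) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path, call. = FALSE)
  }
  seqs <- tryCatch(readDNAStringSet(path, format = "fasta"),
                   error = function(e) stop("cannot parse FASTA ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  out <- list()
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    nm <- .parse_allele_name(header)
    if (is.na(nm)) {
      stop("FASTA record ", i, " has no parsable allele name in header: '",
           header, "'", call. = FALSE)
    }
    if (collapse_suballeles) {
      canon <- .collapse_name(nm)
      if (canon != nm) nm <- canon
    }
    if (!is.null(out[[nm]])) {
      message("duplicate canonical allele ", nm,
              ": keeping first-seen sequence (record ", i, " ignored)")
      next
    }
    out[[nm]] <- .new_allele(nm, as.character(seqs[[i]]))
  }
  out
}

#' Write alleles to a FASTA file
#'
#' @param alleles Named list of `kir_allele` objects.
#' @param path Output file path.
#' @param what Write the `"cds"` (default) or `"genomic"` sequence.
#' @export
write_allele_fasta <- function(alleles, path, what = c("cds", "genomic")) {
  what <- match.arg(what)
  seqs <- vapply(alleles, function(a) {
    s <- a[[what]]
    if (is.null(s)) stop("allele ", a$name, " has no ", what, " sequence")
    s
  }, character(1))
  names(seqs) <- vapply(alleles, `[[`, character(1), "name")
  writeXStringSet(DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Extract the diagnostic SNP profile of a coding sequence
#'
#' Reads the bases at 1-based CDS positions 193, 202 and 607, and the
#' dinucleotide at 1021-1022, counted from the A of the initiator ATG. The
#' published description of the exon-7 site is ambiguous between a 1020/1021
#' and a 1021/1022 convention; `coordinate_offset = -1` shifts all four reads
#' to the alternative convention instead of silently picking one.
#'
#' Sites beyond the end of the sequence are flagged incomplete (read as `N`),
#' never guessed.
#'
#' @param allele A `kir_allele`, or a plain character coding sequence.
#' @param coordinate_offset `0` (default, 1021/1022 convention) or `-1`.
#' @return A `kir_snp_profile`: list with `p193`, `p202`, `p607`,
#'   `p1021_1022` and a logical `complete` flag per site.
#' @export
extract_snp_profile <- function(allele, coordinate_offset = 0L) {
  stopifnot(coordinate_offset %in% c(0L, -1L))
  cds <- if (inherits(allele, "kir_allele")) allele$cds else toupper(allele)
  n <- nchar(cds)
  if (n < 193 + coordinate_offset) {
    stop("sequence too short for typing (", n, " nt)", call. = FALSE)
  }
  at <- function(pos) {
    pos <- pos + coordinate_offset
    if (pos > n) "N" else substr(cds, pos, pos)
  }
  prof <- list(
    p193 = at(193), p202 = at(202), p607 = at(607),
    p1021_1022 = paste0(at(1021), at(1022))
  )
  prof$complete <- c(
    p193 = 193 + coordinate_offset <= n,
    p202 = 202 + coordinate_offset <= n,
    p607 = 607 + coordinate_offset <= n,
    p1021_1022 = 1022 + coordinate_offset <= n
  )
  class(prof) <- "kir_snp_profile"
  prof
}

#' Construct a SNP profile directly
#'
#' @param p193,p202,p607 Single bases in `A,C,G,T,N`.
#' @param dinuc Two-base string for positions 1021/1022.
#' @return A `kir_snp_profile`.
#' @export
snp_profile <- function(p193, p202, p607, dinuc) {
  stopifnot(nchar(dinuc) == 2L)
  bases <- c(p193, p202, p607, substr(dinuc, 1, 1), substr(dinuc, 2, 2))
  if (!all(bases %in% c("A", "C", "G", "T", "N"))) {
    stop("SNP profile bases must be in {A,C,G,T,N}", call. = FALSE)
  }
  structure(
    list(p193 = p193, p202 = p202, p607 = p607, p1021_1022 = dinuc,
         complete = c(p193 = TRUE, p202 = TRUE, p607 = TRUE,
                      p1021_1022 = TRUE)),
    class = "kir_snp_profile"
  )
}

#' @export
print.kir_snp_profile <- function(x, ...) {
  cat(sprintf("<kir_snp_profile> 193=%s 202=%s 607=%s 1021/1022=%s%s\n",
              x$p193, x$p202, x$p607, x$p1021_1022,
              if (all(x$complete)) "" else "  [incomplete]"))
  invisible(x)
}

#' Load an allele population-frequency table
#'
#' Reads a tab-separated table of allele frequencies (percent) such as the
#' packaged 426-donor reference table. Lines starting with `#` are comments; a
#' directive line `# source_n: <int>` records the donor count, from which the
#' allele observation count (2 per diploid donor) is derived. Joint rows
#' (e.g. `KIR3DL1*001/*016`, whose split is not published) carry an
#' `n_alleles` column counting the printed alleles in the row.
#'
#' @param path TSV path; defaults to the packaged reference table.
#' @return A `kir_freq_table`: data frame with columns `allele`, `frequency`
#'   (percent), `n_alleles`, and attributes `source_n` and
#'   `allele_observations`.
#' @export
load_frequency_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_frequencies.tsv",
                        package = "kir3dl1typer", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("cannot read frequency table: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  source_n <- NA_integer_
  dir <- grep("^#\\s*source_n\\s*:", lines, value = TRUE)
  if (length(dir) > 0L) {
    source_n <- as.integer(sub("^#\\s*source_n\\s*:\\s*", "", dir[[1]]))
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body_idx) < 2L) stop("frequency table has no data rows: ", path,
                                  call. = FALSE)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!all(c("allele", "frequency") %in% header)) {
    stop("frequency table must have 'allele' and 'frequency' columns",
         call. = FALSE)
  }
  rows <- lapply(body_idx[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < length(header)) {
      stop("malformed frequency-table row at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    }
    stats::setNames(as.list(f[seq_along(header)]), header)
  })
  tab <- data.frame(
    allele = vapply(rows, `[[`, character(1), "allele"),
    frequency = suppressWarnings(
      as.numeric(vapply(rows, `[[`, character(1), "frequency"))),
    stringsAsFactors = FALSE
  )
  tab$n_alleles <- if ("n_alleles" %in% header) {
    suppressWarnings(as.integer(vapply(rows, `[[`, character(1), "n_alleles")))
  } else 1L
  bad <- which(is.na(tab$frequency) | is.na(tab$n_alleles))
  if (length(bad) > 0L) {
    stop("malformed frequency-table row at line ", body_idx[-1][bad[1]],
         call. = FALSE)
  }
  if (any(tab$frequency < 0)) {
    stop("negative allele frequency in table: ",
         tab$allele[tab$frequency < 0][1], call. = FALSE)
  }
  if (sum(tab$frequency) > 100.1) {
    stop("allele frequencies sum to ", sum(tab$frequency),
         "% (> 100.1%): invalid table", call. = FALSE)
  }
  structure(tab,
            source_n = source_n,
            allele_observations = if (is.na(source_n)) NA_integer_
                                  else 2L * source_n,
            class = c("kir_freq_table", "data.frame"))
}

#' Write a frequency table back to TSV (round-trip companion of
#' [load_frequency_table()])
#'
#' @param table A `kir_freq_table`.
#' @param path Output path.
#' @export
write_frequency_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- attr(table, "source_n")
  if (!is.null(n) && !is.na(n)) writeLines(paste0("# source_n: ", n), con)
  writeLines("allele\tfrequency\tn_alleles", con)
  writeLines(sprintf("%s\t%.2f\t%d", table$allele, table$frequency,
                     table$n_alleles), con)
  invisible(path)
}

#' Export alleles, profiles or typing results as JSON
#'
#' @param x A package object (`kir_allele`, `kir_snp_profile`,
#'   `kir_band_pattern`, `kir_decode_result`, ...).
#' @param ... Passed to [jsonlite::toJSON()].
#' @return A JSON string.
#' @export
kir_to_json <- function(x, ...) {
  strip <- function(o) {
    if (is.list(o)) {
      o <- lapply(unclass(o), strip)
    }
    o
  }
  jsonlite::toJSON(strip(x), auto_unbox = TRUE, null = "null", digits = NA, ...)
}
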