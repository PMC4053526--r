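# canonical string key of a band pattern (reactions with bands only)
.pattern_key <- function(pattern) {
  parts <- character(0)
  for (id in paste0("R", 1:5)) {
    sz <- pattern$bands[[id]]
    if (length(sz) > 0L) {
      parts <- c(parts, paste0(id, ":", paste(sort(sz), collapse = ",")))
    }
  }
  if (length(parts) == 0L) "(empty)" else paste(parts, collapse = ";")
}

# do two patterns agree within gel tolerance?
.patterns_match <- function(a, b, tolerance = 25L) {
  for (id in paste0("R", 1:5)) {
    x <- sort(a$bands[[id]])
    y <- sort(b$bands[[id]])
    if (length(x) != length(y)) return(FALSE)
    if (length(x) > 0L && any(abs(x - y) > tolerance)) return(FALSE)
  }
  TRUE
}

#' Band signature of a homozygous subtype group
#'
#' The per-reaction band set produced by running the panel on a homozygous
#' synthetic template of the group: the forward simulation that defines each
#' group's designed signature (null: reaction 1 only; *005-group: reaction 2;
#' *001-group: reaction 3; *002-group: the small reaction-4 product;
#' *007-group: small reaction-4 product plus reaction 5; activating: the
#' large reaction-4 product).
#'
#' @param group Typed subtype group label (not `UNCLASSIFIED`).
#' @param panel A `kir_panel`.
#' @param template_seed,scaffold Template generation controls.
#' @return A `kir_band_pattern`.
#' @export
subtype_signature <- function(group, panel = kir_panel(),
                              template_seed = 1000L,
                              scaffold = kir_scaffold()) {
  if (identical(group, "UNCLASSIFIED")) {
    stop("UNCLASSIFIED has no band signature", call. = FALSE)
  }
  .assert_group(group)
  tpl <- make_template(group, scaffold = scaffold, seed = template_seed,
                       panel = panel)
  run_panel(list(tpl, tpl), panel = panel, sample_id = paste0("hom_", group))
}

#' Enumerate the pattern-to-genotype lookup table
#'
#' Forward-simulates all 21 unordered pairs of the six typed groups and
#' inverts the map from genotype to band pattern. Colliding genotypes are
#' preserved as multi-hypothesis entries; with the designed panel the single
#' collision is *007-group homozygote vs *007-group/*002-group heterozygote
#' (both show the small reaction-4 product plus the reaction-5 band), the
#' documented ambiguity of the assay.
#'
#' @param panel A `kir_panel`.
#' @param template_seed,scaffold Template generation controls.
#' @return A `kir_pattern_table`: list of entries, each with `key`, `bands`
#'   (a representative `kir_band_pattern`), `hypotheses` (list of sorted
#'   group pairs).
#' @export
enumerate_pattern_table <- function(panel = kir_panel(),
                                    template_seed = 1000L,
                                    scaffold = kir_scaffold()) {
  groups <- kir_group_labels()
  sigs <- stats::setNames(lapply(groups, function(g) {
    make_template(g, scaffold = scaffold, seed = template_seed, panel = panel)
  }), groups)
  entries <- list()
  for (i in seq_along(groups)) {
    for (j in seq(i, length(groups))) {
      pair <- sort(c(groups[i], groups[j]))
      pat <- run_panel(list(sigs[[pair[1]]], sigs[[pair[2]]]), panel = panel,
                       sample_id = paste(pair, collapse = "+"))
      key <- .pattern_key(pat)
      if (is.null(entries[[key]])) {
        entries[[key]] <- list(key = key, bands = pat,
                               hypotheses = list(pair))
      } else {
        entries[[key]]$hypotheses <- c(entries[[key]]$hypotheses, list(pair))
      }
    }
  }
  structure(entries, class = "kir_pattern_table")
}

# cached pattern table per (panel fingerprint, template seed)
.pattern_table_cache <- new.env(parent = emptyenv())

.get_pattern_table <- function(panel, template_seed = 1000L,
                               scaffold = kir_scaffold()) {
  key <- paste(paste(vapply(panel$reactions, function(r)
    paste0(r$forward$seq, r$reverse$seq), character(1)), collapse = "|"),
    template_seed, sep = "#")
  if (is.null(.pattern_table_cache[[key]])) {
    .pattern_table_cache[[key]] <- enumerate_pattern_table(panel,
                                                           template_seed,
                                                           scaffold)
  }
  .pattern_table_cache[[key]]
}

#' Decode a band pattern into genotype hypotheses
#'
#' Looks the pattern up in the enumerated genotype table (within gel size
#' tolerance). When no two-group genotype reproduces the pattern and
#' `allow_extended` is set, unordered triples of groups are searched and the
#' minimal-cardinality fits are returned flagged as extended (polyallelic)
#' haplotype carriers. An empty pattern yields no call (possible novel or
#' unclassified allele). The documented *002/*007 ambiguity can be resolved
#' by supplying exon-7 dinucleotide reads (`"CG"` for *007-group, `"CA"` for
#' *002-group chromosomes) — the in-silico counterpart of sequencing exon 7.
#'
#' @param pattern A `kir_band_pattern` with all controls passing.
#' @param panel A `kir_panel`.
#' @param allow_extended Search 3-group hypotheses when no pair fits.
#' @param exon7_reads Optional character vector of observed exon-7
#'   dinucleotides used to resolve the *002/*007 collision.
#' @param gel_tolerance Band size matching tolerance (bp).
#' @param template_seed,scaffold Template generation controls for the lookup
#'   table.
#' @return A `kir_decode_result`: list with `pattern`, `hypotheses` (list of
#'   sorted group multisets), `extended`, `ambiguous`, `notes`.
#' @export
decode_pattern <- function(pattern, panel = kir_panel(),
                           allow_extended = TRUE, exon7_reads = NULL,
                           gel_tolerance = 25L, template_seed = 1000L,
                           scaffold = kir_scaffold()) {
  stopifnot(inherits(pattern, "kir_band_pattern"))
  if (!all(pattern$control_ok)) {
    stop("sample invalid (control failure), cannot decode", call. = FALSE)
  }
  n_bands <- sum(lengths(pattern$bands))
  result <- function(hyps, extended = FALSE, notes = character(0)) {
    structure(list(pattern = pattern, hypotheses = hyps,
                   extended = extended, ambiguous = length(hyps) > 1L,
                   notes = notes),
              class = "kir_decode_result")
  }
  if (n_bands == 0L) {
    return(result(list(), notes =
      "no call: no bands observed (possible novel or unclassified allele)"))
  }
  tab <- .get_pattern_table(panel, template_seed, scaffold)
  hit <- NULL
  for (e in tab) {
    if (.patterns_match(pattern, e$bands, gel_tolerance)) {
      hit <- e
      break
    }
  }
  if (!is.null(hit)) {
    hyps <- hit$hypotheses
    notes <- character(0)
    if (length(hyps) > 1L) {
      notes <- paste("ambiguous pattern: sequencing of exon 7 (positions",
                     "1021/1022) distinguishes *007 homozygosity from",
                     "*002-group/*007 heterozygosity")
      if (!is.null(exon7_reads)) {
        reads <- sort(unique(toupper(exon7_reads)))
        keep <- Filter(function(h) {
          expect <- sort(unique(vapply(h, function(g)
            .template_states(g)$dinuc, character(1))))
          identical(expect, reads)
        }, hyps)
        if (length(keep) > 0L) {
          hyps <- keep
          notes <- paste("ambiguity resolved by exon-7 reads:",
                         paste(reads, collapse = "/"))
        }
      }
    }
    return(result(hyps, notes = notes))
  }
  if (allow_extended) {
    groups <- kir_group_labels()
    sig <- stats::setNames(lapply(groups, function(g)
      subtype_signature(g, panel, template_seed, scaffold)), groups)
    fits <- list()
    for (i in seq_along(groups)) {
      for (j in seq(i, length(groups))) {
        for (k in seq(j, length(groups))) {
          trio <- sort(c(groups[i], groups[j], groups[k]))
          synth <- band_pattern(stats::setNames(lapply(paste0("R", 1:5),
            function(id) {
              .merge_bands(unlist(lapply(trio, function(g)
                sig[[g]]$bands[[id]])), gel_tolerance)
            }), paste0("R", 1:5)))
          if (.patterns_match(pattern, synth, gel_tolerance)) {
            fits <- c(fits, list(trio))
          }
        }
      }
    }
    if (length(fits) > 0L) {
      return(result(fits, extended = TRUE,
                    notes = "extended (polyallelic) haplotype hypothesis"))
    }
  }
  result(list(), notes = "no genotype hypothesis reproduces this pattern")
}

#' @export
print.kir_decode_result <- function(x, ...) {
  cat("<kir_decode_result>", .pattern_key(x$pattern), "\n")
  if (length(x$hypotheses) == 0L) {
    cat("  no call\n")
  } else {
    for (h in x$hypotheses) cat("  ", paste(h, collapse = " + "), "\n")
  }
  if (isTRUE(x$ambiguous)) cat("  [ambiguous]\n")
  if (isTRUE(x$extended)) cat("  [extended haplotype]\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Read a pedigree file
#'
#' Four-column TSV: `id`, `father`, `mother` (empty or `.` when unknown) and
#' `call` — either a genotype (`"NULL+HIGH2"`, 2 or 3 `+`-separated group
#' labels) or a band pattern (`"R1:2019;R4:1573"`). `#` lines are comments.
#'
#' @param path TSV path.
#' @return A `kir_pedigree` (with `calls` in place of simulated patterns).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("cannot read pedigree file: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "father", "mother", "call")
  if (!all(need %in% names(tab))) {
    stop("pedigree file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$father[tab$father %in% c("", ".", "NA")] <- NA_character_
  tab$mother[tab$mother %in% c("", ".", "NA")] <- NA_character_
  for (k in seq_len(nrow(tab))) {
    for (p in c("father", "mother")) {
      v <- tab[[p]][k]
      if (!is.na(v) && !(v %in% tab$id)) {
        stop("pedigree row ", k, ": unknown ", p, " id '", v, "'",
             call. = FALSE)
      }
    }
  }
  calls <- stats::setNames(lapply(seq_len(nrow(tab)), function(k) {
    .parse_call(tab$call[k], k)
  }), tab$id)
  structure(list(individuals = tab[c("id", "father", "mother")],
                 calls = calls),
            class = "kir_pedigree")
}

# parse "NULL+HIGH2" or "R1:2019;R4:1573,1933" into hypotheses or pattern
.parse_call <- function(s, row = NA) {
  s <- trimws(s)
  if (grepl("^R[1-5]:", s)) {
    bands <- list()
    for (part in strsplit(s, ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(part, ":", fixed = TRUE)[[1]]
      bands[[kv[1]]] <- as.integer(strsplit(kv[2], ",")[[1]])
    }
    return(band_pattern(bands))
  }
  gs <- sort(strsplit(s, "+", fixed = TRUE)[[1]])
  if (!all(gs %in% kir_group_labels()) || !(length(gs) %in% c(2L, 3L))) {
    stop("pedigree row ", row, ": unparsable call '", s, "'", call. = FALSE)
  }
  gs
}

# hypothesis sets for one individual: list of sorted group multisets
.individual_hypotheses <- function(ped, id, panel, ...) {
  call <- if (!is.null(ped$calls)) ped$calls[[id]] else ped$patterns[[id]]
  if (is.null(call)) return(NULL)
  if (inherits(call, "kir_band_pattern")) {
    decode_pattern(call, panel = panel, ...)$hypotheses
  } else if (inherits(call, "kir_decode_result")) {
    call$hypotheses
  } else {
    list(sort(as.character(call)))
  }
}

# transmissible units of a parent hypothesis
.units_of <- function(hyp, allow_extended) {
  units <- lapply(unique(hyp), function(g) g)
  if (allow_extended && length(hyp) >= 2L) {
    for (i in seq_len(length(hyp) - 1L)) {
      for (j in seq(i + 1L, length(hyp))) {
        units <- c(units, list(sort(c(hyp[i], hyp[j]))))
      }
    }
  }
  unique(units)
}

# multiset difference helper: child groups minus one unit; NULL if not subset
.minus_unit <- function(child, unit) {
  rest <- child
  for (g in unit) {
    k <- match(g, rest)
    if (is.na(k)) return(NULL)
    rest <- rest[-k]
  }
  rest
}

#' Check Mendelian consistency of a typed pedigree
#'
#' A child is consistent when some genotype hypothesis of the child can be
#' partitioned into one transmissible unit from each available parent. Units
#' are single groups or — when extended transmission is enabled — a linked
#' pair of groups (a duplicated haplotype carrying two genes, which typing
#' cannot exclude even for a parent showing only two groups). Parents with
#' missing calls are unconstrained and logged. The hypothesis space is tiny,
#' so the search is exhaustive and reports a witness assignment for each
#' consistent child.
#'
#' @param ped A `kir_pedigree` (from [read_pedigree()] or
#'   [simulate_pedigree()]).
#' @param allow_extended Allow linked-pair transmission (default `TRUE`).
#' @param panel Panel used to decode band-pattern calls.
#' @param ... Passed to [decode_pattern()].
#' @return A `kir_pedigree_report`: data frame with one row per child
#'   (`id`, `consistent`, `witness`, `note`) plus summary attributes.
#' @export
check_pedigree <- function(ped, allow_extended = TRUE, panel = kir_panel(),
                           ...) {
  stopifnot(inherits(ped, "kir_pedigree"))
  ind <- ped$individuals
  # cycle detection: parents must precede children in some topological order
  .check_acyclic(ind)
  children <- ind[!is.na(ind$father) | !is.na(ind$mother), , drop = FALSE]
  if (nrow(children) == 0L) {
    stop("pedigree has no parent-child relation", call. = FALSE)
  }
  hyp_cache <- new.env(parent = emptyenv())
  hyps <- function(id) {
    if (is.null(hyp_cache[[id]])) {
      h <- .individual_hypotheses(ped, id, panel, ...)
      hyp_cache[[id]] <- if (is.null(h)) list(NULL) else h
    }
    hyp_cache[[id]]
  }
  rows <- list()
  for (k in seq_len(nrow(children))) {
    id <- children$id[k]
    fa <- children$father[k]
    mo <- children$mother[k]
    note <- character(0)
    if (is.na(fa) || is.null(ped$calls[[fa]] %||% ped$patterns[[fa]])) {
      note <- c(note, "father unconstrained")
    }
    if (is.na(mo) || is.null(ped$calls[[mo]] %||% ped$patterns[[mo]])) {
      note <- c(note, "mother unconstrained")
    }
    f_hyps <- if (is.na(fa)) list(NULL) else hyps(fa)
    m_hyps <- if (is.na(mo)) list(NULL) else hyps(mo)
    witness <- NA_character_
    consistent <- FALSE
    for (ch in hyps(id)) {
      if (is.null(ch)) next
      if (length(ch) > 2L && !allow_extended) next
      for (fh in f_hyps) {
        f_units <- if (is.null(fh)) NULL else .units_of(fh, allow_extended)
        for (mh in m_hyps) {
          m_units <- if (is.null(mh)) NULL else .units_of(mh, allow_extended)
          w <- .find_witness(ch, f_units, m_units, allow_extended)
          if (!is.null(w)) {
            consistent <- TRUE
            witness <- sprintf("%s | father->%s | mother->%s",
                               paste(ch, collapse = "+"),
                               paste(w$father, collapse = "+"),
                               paste(w$mother, collapse = "+"))
          }
          if (consistent) break
        }
        if (consistent) break
      }
      if (consistent) break
    }
    rows[[k]] <- data.frame(id = id, consistent = consistent,
                            witness = witness,
                            note = paste(note, collapse = "; "),
                            stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  structure(rep,
            n_children = nrow(rep),
            n_consistent = sum(rep$consistent),
            class = c("kir_pedigree_report", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.find_witness <- function(child, f_units, m_units, allow_extended) {
  # unconstrained parent: any unit of the right residual size is allowed
  cand_f <- if (is.null(f_units)) "any" else f_units
  for (fu in cand_f) {
    rest <- if (identical(fu, "any")) NULL else .minus_unit(child, fu)
    if (identical(fu, "any")) {
      # father free: residual after mother must have size 1 or 2
      cand_m <- if (is.null(m_units)) "any" else m_units
      for (mu in cand_m) {
        if (identical(mu, "any")) return(list(father = "?", mother = "?"))
        r2 <- .minus_unit(child, mu)
        if (!is.null(r2) && length(r2) %in% c(1L, 2L) &&
            (length(r2) == 1L || allow_extended)) {
          return(list(father = r2, mother = mu))
        }
      }
      next
    }
    if (is.null(rest)) next
    if (is.null(m_units)) {
      if (length(rest) %in% c(1L, 2L) &&
          (length(rest) == 1L || allow_extended)) {
        return(list(father = fu, mother = rest))
      }
      next
    }
    for (mu in m_units) {
      if (identical(sort(rest), sort(unlist(mu)))) {
        return(list(father = fu, mother = mu))
      }
    }
  }
  NULL
}

.check_acyclic <- function(ind) {
  ids <- ind$id
  if (anyDuplicated(ids)) stop("duplicate individual ids in pedigree",
                               call. = FALSE)
  parents <- stats::setNames(lapply(seq_len(nrow(ind)), function(k)
    stats::na.omit(c(ind$father[k], ind$mother[k]))), ids)
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) stop("cyclic pedigree at individual ", id,
                                call. = FALSE)
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (p in parents[[id]]) if (p %in% ids) visit(p)
    state[[id]] <<- 2L
  }
  for (id in ids) visit(id)
  invisible(TRUE)
}

#' @export
print.kir_pedigree_report <- function(x, ...) {
  cat(sprintf("<kir_pedigree_report> %d/%d children consistent\n",
              attr(x, "n_consistent"), attr(x, "n_children")))
  print.data.frame(x)
  invisible(x)
}
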