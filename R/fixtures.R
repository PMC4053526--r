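#' Scaffold specification for synthetic KIR3DL1/KIR3DS1 genomic templates
#'
#' Describes the synthetic gene model used by [make_template()]: nine exons
#' with realistic KIR3DL1 coding lengths (CDS total 1281 nt, so the
#' diagnostic sites 193/202 fall in exon 3, 607 in exon 4 and 1021/1022 in
#' exon 7), flanking UTRs, and intron lengths calibrated so that the five
#' designed reactions reproduce the published amplicon sizes on synthetic
#' templates (2019 / 1573 / 1573 / 1573-1933 / 1408 bp; the authoritative
#' check for absolute sizes would be real IPD-KIR genomic sequence, which the
#' toolkit deliberately does not require). The KIR3DS1 scaffold differs from
#' the KIR3DL1 scaffold only by a 360 bp insertion in intron 3.
#'
#' @param intron3 Intron-3 length of the inhibitory-gene scaffold (1122 bp;
#'   calibrated so SNP-anchored exon3/exon4 primer pairs span 1573 bp).
#' @param s1_intron3_extra Extra intron-3 length of the activating-gene
#'   scaffold (default 360 bp).
#' @return A `kir_scaffold` list.
#' @export
kir_scaffold <- function(intron3 = 1122L, s1_intron3_extra = 360L) {
  structure(list(
    utr5 = 1800L,
    exon_lengths = c(34L, 36L, 285L, 300L, 300L, 51L, 102L, 53L, 120L),
    intron_lengths = c(600L, 600L, intron3, 250L, 250L, 1450L, 180L, 180L),
    utr3 = 700L,
    s1_intron3_extra = as.integer(s1_intron3_extra),
    control_offset = 20L,      # control cassette offset into the 3' UTR
    control_size = 607L        # recorded product size of the HLA-DR control
  ), class = "kir_scaffold")
}

.template_cache <- new.env(parent = emptyenv())

# genomic position (1-based) of a 1-based CDS coordinate under a scaffold
.cds_to_genomic <- function(scaffold, cds_pos, intron3 = NULL) {
  ex <- scaffold$exon_lengths
  introns <- scaffold$intron_lengths
  if (!is.null(intron3)) introns[3] <- intron3
  cum <- cumsum(ex)
  k <- which(cds_pos <= cum)[1]
  if (is.na(k)) stop("CDS position ", cds_pos, " beyond CDS length")
  within <- cds_pos - if (k == 1L) 0L else cum[k - 1L]
  scaffold$utr5 + sum(ex[seq_len(k - 1L)]) +
    sum(introns[seq_len(k - 1L)]) + within
}

# exon/intron feature map (genomic + CDS coordinates, 1-based inclusive)
.feature_map <- function(scaffold, intron3) {
  ex <- scaffold$exon_lengths
  introns <- scaffold$intron_lengths
  introns[3] <- intron3
  feats <- data.frame(type = character(0), name = character(0),
                      start = integer(0), end = integer(0),
                      cds_start = integer(0), cds_end = integer(0))
  pos <- scaffold$utr5
  cds <- 0L
  for (i in seq_along(ex)) {
    feats <- rbind(feats, data.frame(
      type = "exon", name = paste0("exon", i),
      start = pos + 1L, end = pos + ex[i],
      cds_start = cds + 1L, cds_end = cds + ex[i]))
    pos <- pos + ex[i]
    cds <- cds + ex[i]
    if (i < length(ex)) {
      feats <- rbind(feats, data.frame(
        type = "intron", name = paste0("intron", i),
        start = pos + 1L, end = pos + introns[i],
        cds_start = NA_integer_, cds_end = NA_integer_))
      pos <- pos + introns[i]
    }
  }
  feats
}

.rc <- function(s) as.character(reverseComplement(DNAString(s)))

# Diagnostic CDS states written into each group's template. Groups whose
# published dinucleotide is polymorphic get the first listed state (C/A).
.template_states <- function(group) {
  switch(group,
    "NULL"  = list(p193 = "G", p202 = "A", p607 = "T", dinuc = "TG"),
    "LOW1"  = list(p193 = "A", p202 = "A", p607 = "T", dinuc = "CA"),
    "HIGH1" = list(p193 = "A", p202 = "A", p607 = "C", dinuc = "CA"),
    "HIGH2" = list(p193 = "A", p202 = "G", p607 = "C", dinuc = "CA"),
    "LOW2"  = list(p193 = "A", p202 = "G", p607 = "C", dinuc = "CG"),
    "S1"    = list(p193 = "A", p202 = "G", p607 = "C", dinuc = "CA"),
    stop("no template states for group ", group)
  )
}

#' Build a synthetic genomic template for a subtype group
#'
#' Generates a full-length synthetic gene (UTRs, nine exons, introns) whose
#' spliced coding sequence carries the group's diagnostic SNP states, and
#' whose primer footprints are engineered so the group amplifies in exactly
#' its designed reactions and in no other: designed footprints are written
#' base-exact (3'-anchored on the diagnostic SNP wherever the primer
#' chemistry is SNP-anchored), while every other reaction's footprint region
#' is either absent (random background) or carries the natural blocking
#' mismatches — e.g. on null-group templates the footprint of the *005-group
#' forward primer is occupied by the null-specific reverse-primer site, the
#' in-silico analogue of the 193-linked mismatch that blocks reaction 2 on
#' null alleles in the wet assay.
#'
#' Every template carries the conserved 5'-UTR forward-primer site and an
#' HLA-DR control cassette in the 3' UTR. The activating-gene (S1) template
#' differs from the inhibitory-gene template with the same seed only by the
#' 360 bp intron-3 insertion. Deterministic per seed; non-diagnostic sequence
#' is seeded uniform background.
#'
#' @param group Subtype group label (not `UNCLASSIFIED`).
#' @param scaffold A `kir_scaffold`.
#' @param seed Integer seed for the background sequence.
#' @param panel Panel whose primer sequences are written into the template.
#' @param allele_name Optional name stamped on the template (defaults to the
#'   group's canonical allele).
#' @return A `kir_genomic_template`: list with `allele_name`, `seq`,
#'   `features`, `group`, `cds`, `seed`, `uid`.
#' @export
make_template <- function(group, scaffold = kir_scaffold(), seed = 1L,
                          panel = kir_panel(), allele_name = NULL) {
  .assert_group(group)
  # templates are pure functions of their arguments; memoize on a full
  # fingerprint so repeated cohort/pedigree simulation is cheap
  cache_key <- paste(group, seed, allele_name %||% ".",
                     paste(unlist(scaffold[c("utr5", "exon_lengths",
                                             "intron_lengths", "utr3",
                                             "s1_intron3_extra")]),
                           collapse = ","),
                     paste(vapply(panel$reactions, function(r)
                       paste0(r$forward$seq, r$reverse$seq), character(1)),
                       collapse = ","),
                     sep = "|")
  cached <- .template_cache[[cache_key]]
  if (!is.null(cached)) return(cached)
  st <- .template_states(group)
  intron3 <- scaffold$intron_lengths[3] +
    if (group == "S1") scaffold$s1_intron3_extra else 0L
  feats <- .feature_map(scaffold, intron3)
  total <- max(feats$end) + scaffold$utr3

  # background: common to all groups at a given seed; the S1 insertion is
  # drawn afterwards so the first `total_3dl1` draws coincide across genes
  base_len <- max(.feature_map(scaffold, scaffold$intron_lengths[3])$end) +
    scaffold$utr3
  set.seed(seed)
  bg <- sample(c("A", "C", "G", "T"), base_len, replace = TRUE)
  if (group == "S1") {
    ins <- sample(c("A", "C", "G", "T"), scaffold$s1_intron3_extra,
                  replace = TRUE)
    i3 <- feats[feats$name == "intron3", ]
    mid <- .feature_map(scaffold, scaffold$intron_lengths[3])
    mid3 <- mid[mid$name == "intron3", ]
    at <- mid3$start + (mid3$end - mid3$start) %/% 2L
    bg <- c(bg[1:at], ins, bg[(at + 1L):base_len])
  }
  seqc <- bg
  stopifnot(length(seqc) == total)

  gp <- function(cds_pos) .cds_to_genomic(scaffold, cds_pos, intron3)
  put <- function(seqc, start, s) {
    chars <- strsplit(s, "")[[1]]
    stopifnot(start >= 1L, start + length(chars) - 1L <= length(seqc))
    seqc[start:(start + length(chars) - 1L)] <- chars
    seqc
  }
  rxs <- panel$reactions

  # diagnostic states first; designed footprints below must agree with them
  seqc[gp(193)] <- st$p193
  seqc[gp(202)] <- st$p202
  seqc[gp(607)] <- st$p607
  seqc[gp(1021)] <- substr(st$dinuc, 1, 1)
  seqc[gp(1022)] <- substr(st$dinuc, 2, 2)

  # conserved 5'-UTR forward primer (reaction 1) on every template,
  # positioned so the null product spans exactly its published size
  consF <- rxs$R1$forward
  r1_end <- gp(193) + nchar(rxs$R1$reverse$seq) - 1L
  consF_start <- r1_end - rxs$R1$expected_sizes[["KIR3DL1"]] + 1L
  seqc <- put(seqc, consF_start, consF$seq)

  if (group == "NULL") {
    # null-specific reverse primer, 3'-anchored on the G at CDS 193; its
    # footprint occupies 193..217 and thereby blocks the *005-group forward
    # primer (the engineered 193-linked mismatch)
    seqc <- put(seqc, gp(193), .rc(rxs$R1$reverse$seq))
  }
  if (group == "LOW1") {
    fw <- rxs$R2$forward$seq            # 3' on the A at CDS 202
    seqc <- put(seqc, gp(202) - nchar(fw) + 1L, fw)
    rv <- .rc(rxs$R2$reverse$seq)       # 3' on the T at CDS 607; Y -> C
    rv <- gsub("Y", "C", rv, fixed = TRUE)
    seqc <- put(seqc, gp(607), rv)
  }
  if (group == "HIGH1") {
    fw <- rxs$R3$forward$seq            # 3' on the A at CDS 202
    seqc <- put(seqc, gp(202) - nchar(fw) + 1L, fw)
    seqc <- put(seqc, gp(607), .rc(rxs$R3$reverse$seq))  # 3' on the C at 607
  }
  if (group %in% c("HIGH2", "S1", "LOW2")) {
    fw <- rxs$R4$forward$seq            # 3' on the G at CDS 202
    seqc <- put(seqc, gp(202) - nchar(fw) + 1L, fw)
    # shared 607C-R footprint sits 6 nt downstream of the SNP here so the
    # reaction-4 product matches its published size despite the shorter
    # forward primer (primer genomic offsets are not published; see vignette)
    seqc <- put(seqc, gp(607) + 6L, .rc(rxs$R4$reverse$seq))
  }
  if (group == "LOW2") {
    # exon-7 reverse primer 3'-anchored on the C/G dinucleotide
    seqc <- put(seqc, gp(1021), .rc(rxs$R5$reverse$seq))
    r5_end <- gp(1021) + nchar(rxs$R5$reverse$seq) - 1L
    int6_start <- r5_end - rxs$R5$expected_sizes[["KIR3DL1"]] + 1L
    i6 <- feats[feats$name == "intron6", ]
    if (int6_start < i6$start ||
        int6_start + nchar(rxs$R5$forward$seq) - 1L > i6$end) {
      stop("scaffold intron 6 too short for the exon-7 reaction footprint",
           call. = FALSE)
    }
    seqc <- put(seqc, int6_start, rxs$R5$forward$seq)
  }

  # HLA-DR control cassette in the 3' UTR (present on every template)
  ctrl <- panel$control
  c_start <- max(feats$end) + scaffold$control_offset
  seqc <- put(seqc, c_start, ctrl$forward$seq)
  c_end <- c_start + scaffold$control_size - 1L
  rcr <- .rc(ctrl$reverse$seq)
  seqc <- put(seqc, c_end - nchar(rcr) + 1L, rcr)

  seq <- paste(seqc, collapse = "")
  cds <- paste(vapply(which(feats$type == "exon"), function(i) {
    substr(seq, feats$start[i], feats$end[i])
  }, character(1)), collapse = "")

  # construction check: the spliced CDS must read back the intended states
  prof <- extract_snp_profile(cds)
  got <- c(prof$p193, prof$p202, prof$p607, prof$p1021_1022)
  want <- c(st$p193, st$p202, st$p607, st$dinuc)
  if (!identical(got, want)) {
    stop("template construction error for ", group,
         ": footprint overlaps a diagnostic SNP inconsistently (",
         paste(got, collapse = "/"), " vs ", paste(want, collapse = "/"), ")",
         call. = FALSE)
  }

  if (is.null(allele_name)) {
    allele_name <- kir_groups()$canonical_allele[kir_groups()$label == group]
  }
  out <- structure(list(
    allele_name = allele_name, seq = seq, features = feats, group = group,
    cds = cds, seed = as.integer(seed),
    uid = sprintf("%s|%s|s%d|n%d", group, allele_name, seed, nchar(seq))
  ), class = "kir_genomic_template")
  .template_cache[[cache_key]] <- out
  out
}

#' @export
print.kir_genomic_template <- function(x, ...) {
  cat(sprintf("<kir_genomic_template> %s (%s)  %d nt, CDS %d nt\n",
              x$allele_name, x$group, nchar(x$seq), nchar(x$cds)))
  invisible(x)
}

# CDS positions safe for neutral allele-marker edits: outside every primer
# footprint written by make_template and away from the diagnostic sites.
.safe_cds_positions <- function() {
  c(5:170, 240:590, 660:1000, 1050:1281)
}

#' Synthetic reference alleles for the eleven high-frequency alleles
#'
#' Builds one `kir_allele` (with both genomic and coding sequence) per
#' high-frequency allele by adding a few neutral, allele-specific marker
#' substitutions to the group template, at positions outside all primer
#' footprints and diagnostic sites. The activating-gene allele receives a
#' larger marker set, mimicking the substantial coding divergence of the real
#' activating lineage, so that nearest-reference gene assignment is
#' informative. These are synthetic stand-ins for database sequences (no
#' download required), not real alleles.
#'
#' @param seed Integer seed.
#' @param scaffold,panel Passed to [make_template()].
#' @return Named list of `kir_allele` objects with a `template` attribute on
#'   each element.
#' @export
make_reference_alleles <- function(seed = 42L, scaffold = kir_scaffold(),
                                   panel = kir_panel()) {
  spec <- list(
    "KIR3DL1*004" = list(group = "NULL",  k = 3L),
    "KIR3DL1*005" = list(group = "LOW1",  k = 3L),
    "KIR3DL1*001" = list(group = "HIGH1", k = 3L),
    "KIR3DL1*016" = list(group = "HIGH1", k = 3L),
    "KIR3DL1*002" = list(group = "HIGH2", k = 3L),
    "KIR3DL1*015" = list(group = "HIGH2", k = 3L),
    "KIR3DL1*008" = list(group = "HIGH2", k = 3L),
    "KIR3DL1*009" = list(group = "HIGH2", k = 3L),
    "KIR3DL1*020" = list(group = "HIGH2", k = 3L),
    "KIR3DL1*007" = list(group = "LOW2",  k = 3L),
    "KIR3DS1*013" = list(group = "S1",    k = 12L)
  )
  safe <- .safe_cds_positions()
  out <- list()
  for (i in seq_along(spec)) {
    nm <- names(spec)[i]
    g <- spec[[i]]$group
    tpl <- make_template(g, scaffold = scaffold, seed = seed, panel = panel,
                         allele_name = nm)
    set.seed(seed + 1000L * i)
    pos <- sample(safe, spec[[i]]$k)
    seqc <- strsplit(tpl$seq, "")[[1]]
    ex <- tpl$features[tpl$features$type == "exon", ]
    for (p in pos) {
      grow <- ex[p >= ex$cds_start & p <= ex$cds_end, ]
      gpos <- grow$start + (p - grow$cds_start)
      seqc[gpos] <- sample(setdiff(c("A", "C", "G", "T"), seqc[gpos]), 1L)
    }
    tpl$seq <- paste(seqc, collapse = "")
    tpl$cds <- paste(vapply(which(tpl$features$type == "exon"), function(j) {
      substr(tpl$seq, tpl$features$start[j], tpl$features$end[j])
    }, character(1)), collapse = "")
    tpl$uid <- paste0(tpl$uid, "|ref", i)
    al <- .new_allele(nm, tpl$cds, genomic = tpl$seq, group = g)
    attr(al, "template") <- tpl
    out[[nm]] <- al
  }
  out
}

#' Synthetic multi-group coding-sequence alignment
#'
#' Generates an equal-length CDS alignment with `members_per_group` sequences
#' per typed group. Each group carries its diagnostic SNP states plus
#' `n_markers` group-specific marker substitutions (the in-silico analogue of
#' lineage-specific coding divergence — the activating lineage shares all four
#' diagnostic states with the *002-group, so only lineage markers can
#' separate them phylogenetically); each member additionally receives
#' independent background substitutions at `noise_rate` (default 0.5%, within
#' the intended "at most 2% background" regime).
#'
#' @param members_per_group Sequences per group (default 3).
#' @param noise_rate Per-site substitution probability per member.
#' @param n_markers Group-specific marker substitutions per group.
#' @param seed Integer seed.
#' @return Named character vector of sequences (`GROUP_i`).
#' @export
make_group_alignment <- function(members_per_group = 3L, noise_rate = 0.005,
                                 n_markers = 12L, seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate <= 0.02)
  groups <- kir_group_labels()
  L <- 1281L
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  diag_pos <- c(193L, 202L, 607L, 1021L, 1022L)
  marker_pool <- setdiff(seq_len(L), diag_pos)
  marker_sites <- sample(marker_pool, n_markers * length(groups))
  out <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    st <- .template_states(g)
    proto <- anc
    proto[diag_pos] <- c(st$p193, st$p202, st$p607,
                         substr(st$dinuc, 1, 1), substr(st$dinuc, 2, 2))
    sites <- marker_sites[seq((gi - 1L) * n_markers + 1L, gi * n_markers)]
    for (p in sites) {
      proto[p] <- setdiff(c("A", "C", "G", "T"), anc[p])[
        1L + (p %% 3L)]
    }
    for (m in seq_len(members_per_group)) {
      set.seed(seed + 100L * gi + m)
      mem <- proto
      noisy <- setdiff(which(stats::runif(L) < noise_rate),
                       c(diag_pos, marker_sites))
      for (p in noisy) {
        mem[p] <- sample(setdiff(c("A", "C", "G", "T"), mem[p]), 1L)
      }
      out[[paste0(g, "_", m)]] <- paste(mem, collapse = "")
    }
  }
  out
}

#' Simulate a diploid typing cohort
#'
#' Draws `2n` independent group alleles from a group frequency table (paired
#' per donor, emulating the diploid structure of the reference cohort) and
#' attaches the per-group genomic templates.
#'
#' @param groups A `kir_group_freq` table (see [group_frequencies()]), or a
#'   named numeric vector of proportions.
#' @param n Number of donors.
#' @param seed Integer seed.
#' @param template_seed Seed for the shared per-group templates.
#' @param scaffold,panel Passed to [make_template()].
#' @return List of donors: each a list with `id`, `genotype` (sorted pair of
#'   group labels) and `templates` (list of 2 templates).
#' @export
simulate_cohort <- function(groups, n, seed = 1L, template_seed = 1000L,
                            scaffold = kir_scaffold(), panel = kir_panel()) {
  stopifnot(n >= 1L)
  p <- .as_proportions(groups)
  tpls <- stats::setNames(lapply(names(p), function(g) {
    make_template(g, scaffold = scaffold, seed = template_seed, panel = panel)
  }), names(p))
  set.seed(seed)
  draws <- sample(names(p), 2L * n, replace = TRUE, prob = p)
  lapply(seq_len(n), function(i) {
    pair <- sort(draws[c(2L * i - 1L, 2L * i)])
    list(id = sprintf("donor%04d", i), genotype = pair,
         templates = list(tpls[[pair[1]]], tpls[[pair[2]]]))
  })
}

.as_proportions <- function(groups) {
  p <- if (inherits(groups, "kir_group_freq")) groups$proportion else groups
  nm <- if (inherits(groups, "kir_group_freq")) groups$group else names(groups)
  if (is.null(nm) || any(!nm %in% kir_group_labels())) {
    stop("group frequency table must be named by typed group labels",
         call. = FALSE)
  }
  if (any(p < 0) || sum(p) <= 0) stop("unnormalizable group frequencies",
                                      call. = FALSE)
  stats::setNames(p / sum(p), nm)
}

#' Simulate a typed multi-generation pedigree
#'
#' Founder genotypes are lists of two transmissible haplotype units; a unit
#' is a single group label, or a linked pair of labels for a duplicated
#' (extended) haplotype. Each child inherits one unit drawn uniformly from
#' each parent. Generations beyond the first are formed by marrying the first
#' child of each couple to a newly drawn founder spouse. Band patterns are
#' produced by [run_panel()] on each individual's templates.
#'
#' @param founders List of founder genotypes (each a list of 2 units); names
#'   become individual ids. At least 2 founders.
#' @param generations Number of generations (>= 2).
#' @param children_per_couple Children per couple.
#' @param duplicated_haplotype Optional `list(carrier = <founder id>,
#'   pair = c(<group>, <group>))` replacing one unit of the carrier with a
#'   linked pair (as in the published family carrying an activating + null
#'   haplotype).
#' @param seed Integer seed.
#' @param spouse_pool Groups from which founder-spouse haplotypes are drawn
#'   (default: uniform over the six groups).
#' @param template_seed,scaffold,panel Template generation controls.
#' @return A `kir_pedigree`: list with `individuals` (data frame `id`,
#'   `father`, `mother`), `truth` (id -> list of units), `patterns`
#'   (id -> `kir_band_pattern`).
#' @export
simulate_pedigree <- function(founders, generations = 2L,
                              children_per_couple = 2L,
                              duplicated_haplotype = NULL, seed = 1L,
                              spouse_pool = kir_group_labels(),
                              template_seed = 1000L,
                              scaffold = kir_scaffold(),
                              panel = kir_panel()) {
  if (length(founders) < 2L) stop("need at least 2 founders", call. = FALSE)
  if (is.null(names(founders))) {
    names(founders) <- paste0("F", seq_along(founders))
  }
  truth <- lapply(founders, function(g) {
    stopifnot(length(g) == 2L)
    lapply(g, as.character)
  })
  if (!is.null(duplicated_haplotype)) {
    id <- duplicated_haplotype$carrier
    if (is.null(truth[[id]])) {
      stop("duplicated_haplotype names a non-founder: ", id, call. = FALSE)
    }
    truth[[id]][[1]] <- as.character(duplicated_haplotype$pair)
  }
  individuals <- data.frame(id = names(truth), father = NA_character_,
                            mother = NA_character_, stringsAsFactors = FALSE)
  set.seed(seed)
  couples <- list()
  fo <- names(founders)
  for (k in seq_len(length(fo) %/% 2L)) {
    couples[[k]] <- c(fo[2L * k - 1L], fo[2L * k])
  }
  next_id <- 1L
  for (gen in seq_len(generations - 1L)) {
    new_couples <- list()
    for (cp in couples) {
      kids <- character(0)
      for (ci in seq_len(children_per_couple)) {
        id <- sprintf("G%d_%03d", gen + 1L, next_id)
        next_id <- next_id + 1L
        u1 <- truth[[cp[1]]][[sample.int(2L, 1L)]]
        u2 <- truth[[cp[2]]][[sample.int(2L, 1L)]]
        truth[[id]] <- list(u1, u2)
        individuals <- rbind(individuals, data.frame(
          id = id, father = cp[1], mother = cp[2], stringsAsFactors = FALSE))
        kids <- c(kids, id)
      }
      if (gen < generations - 1L && length(kids) > 0L) {
        sp <- sprintf("S%d_%03d", gen + 1L, next_id)
        next_id <- next_id + 1L
        truth[[sp]] <- list(sample(spouse_pool, 1L), sample(spouse_pool, 1L))
        individuals <- rbind(individuals, data.frame(
          id = sp, father = NA_character_, mother = NA_character_,
          stringsAsFactors = FALSE))
        new_couples[[length(new_couples) + 1L]] <- c(kids[1], sp)
      }
    }
    couples <- new_couples
  }
  tpl_cache <- new.env(parent = emptyenv())
  get_tpl <- function(g) {
    if (is.null(tpl_cache[[g]])) {
      tpl_cache[[g]] <- make_template(g, scaffold = scaffold,
                                      seed = template_seed, panel = panel)
    }
    tpl_cache[[g]]
  }
  patterns <- lapply(stats::setNames(nm = individuals$id), function(id) {
    gs <- unlist(truth[[id]])
    run_panel(lapply(gs, get_tpl), panel = panel, sample_id = id)
  })
  structure(list(individuals = individuals, truth = truth,
                 patterns = patterns),
            class = "kir_pedigree")
}

#' Drop bands from a pattern at random (decoder robustness testing)
#'
#' Each band is dropped independently with probability `dropout_prob`;
#' control flags are never touched. Deterministic per seed.
#'
#' @param pattern A `kir_band_pattern`.
#' @param dropout_prob In `[0, 1]`.
#' @param seed Integer seed.
#' @return A `kir_band_pattern`.
#' @export
add_band_noise <- function(pattern, dropout_prob, seed = 1L) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1)
  set.seed(seed)
  for (id in names(pattern$bands)) {
    sz <- pattern$bands[[id]]
    if (length(sz) > 0L) {
      keep <- stats::runif(length(sz)) >= dropout_prob
      pattern$bands[[id]] <- sz[keep]
    }
  }
  pattern
}
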