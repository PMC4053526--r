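test_that("decision table reproduces the published group rows", {
  st <- kir_snp_states()
  for (k in seq_len(nrow(st))) {
    dinuc <- strsplit(st$dinuc[k], "|", fixed = TRUE)[[1]][1]
    prof <- snp_profile(st$p193[k], st$p202[k], st$p607[k], dinuc)
    gene <- sub("\\*.*$", "", st$allele[k])
    cls <- classify_snp_profile(prof, gene = gene)
    expect_equal(cls$group, st$group[k], info = st$allele[k])
  }
  # spot checks straight from the published states
  expect_equal(classify_snp_profile(snp_profile("G", "A", "T", "TG"))$group,
               "NULL")
  expect_equal(classify_snp_profile(snp_profile("A", "G", "C", "CG"))$group,
               "LOW2")
  expect_equal(classify_snp_profile(snp_profile("A", "A", "A", "CA"))$group,
               "UNCLASSIFIED")  # *073 states
  expect_equal(classify_snp_profile(snp_profile("A", "G", "T", "CA"))$group,
               "UNCLASSIFIED")  # *042 states
})

test_that("HIGH2/S1 row needs gene disambiguation; N reads never force a call", {
  cls <- classify_snp_profile(snp_profile("A", "G", "C", "CA"))
  expect_equal(cls$group, "HIGH2")
  expect_true(cls$needs_gene_disambiguation)
  expect_equal(classify_snp_profile(snp_profile("A", "G", "C", "CA"),
                                    gene = "KIR3DS1")$group, "S1")
  expect_false(classify_snp_profile(snp_profile("A", "G", "C", "CA"),
                                    gene = "3DL1")$needs_gene_disambiguation)

  expect_equal(classify_snp_profile(snp_profile("N", "A", "T", "TG"))$group,
               "UNCLASSIFIED")
  # unreadable dinucleotide only matters when rules 4/5 are reached
  expect_equal(classify_snp_profile(snp_profile("A", "G", "C", "NN"))$group,
               "UNCLASSIFIED")
  expect_equal(classify_snp_profile(snp_profile("A", "A", "T", "NN"))$group,
               "LOW1")
  # incomplete obligatory sites are an error
  short <- extract_snp_profile(substr(test_templates[["LOW1"]]$cds, 1, 400))
  expect_error(classify_snp_profile(short), "incomplete")
})

test_that("decision table is total and mutually exclusive (brute force)", {
  bases <- c("A", "C", "G", "T")
  n_by_group <- c()
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    for (d1 in bases) for (d2 in bases) {
      cls <- classify_snp_profile(snp_profile(b1, b2, b3, paste0(d1, d2)),
                                  gene = "KIR3DL1")
      expect_true(cls$group %in% c(kir_group_labels(), "UNCLASSIFIED"))
      prev <- if (cls$group %in% names(n_by_group))
        n_by_group[[cls$group]] else 0
      n_by_group[cls$group] <- prev + 1
    }
  }
  expect_equal(sum(n_by_group), 4^3 * 16)
  # independent closed-form counts for each rule over the 1024 profiles:
  # rule 1 fires for 193=G: 4*4*16 = 256
  expect_equal(unname(n_by_group[["NULL"]]), 256)
  # rules 2/3: 193 in {A,C,T}, 202=A, 607 in {T}/{C}: 3*1*1*16 = 48 each
  expect_equal(unname(n_by_group[["LOW1"]]), 48)
  expect_equal(unname(n_by_group[["HIGH1"]]), 48)
  # rules 4/5: 193 in {A,C,T}, 202=G, 607=C, one dinucleotide: 3 each
  expect_equal(unname(n_by_group[["LOW2"]]), 3)
  expect_equal(unname(n_by_group[["HIGH2"]]), 3)
})

test_that("classify_sequence resolves gene by name or nearest reference", {
  # canonical fixtures classify to their groups
  for (nm in names(test_refs)) {
    cls <- classify_sequence(test_refs[[nm]], test_refs)
    expect_equal(cls$group, test_refs[[nm]]$group, info = nm)
  }
  # gene carried in the name wins (rule 5 disambiguation)
  s1 <- classify_sequence(test_refs[["KIR3DS1*013"]], test_refs)
  expect_equal(s1$group, "S1")
  expect_equal(s1$rule_fired, "rule5_202G_607C_CA")

  # anonymous activating-lineage sequence resolves via nearest reference
  q <- test_refs[["KIR3DS1*013"]]
  q$name <- "query"
  cls <- classify_sequence(q, test_refs)
  expect_equal(cls$group, "S1")
  expect_equal(cls$nearest$allele, "KIR3DS1*013")
  expect_equal(cls$nearest$identity, 100)

  # substitution outside diagnostic sites and footprints leaves the call
  low1 <- test_refs[["KIR3DL1*005"]]$cds
  substr(low1, 300, 300) <- setdiff(c("A", "C", "G", "T"),
                                    substr(low1, 300, 300))[1]
  expect_equal(classify_sequence(low1, test_refs)$group, "LOW1")

  # UNCLASSIFIED results carry a nearest suggestion
  un <- test_refs[["KIR3DL1*002"]]$cds
  substr(un, 607, 607) <- "T"   # 202G/607T: the *042-like unknown states
  cls_un <- classify_sequence(un, test_refs)
  expect_equal(cls_un$group, "UNCLASSIFIED")
  expect_false(is.null(cls_un$nearest))

  expect_error(classify_sequence(q, list()), "empty reference")
})

test_that("nearest_reference identity arithmetic and tie-breaking", {
  refs <- list(a = kir3dl1typer:::.new_allele("KIR3DL1*002",
                                              strrep("ACGT", 250)),
               b = kir3dl1typer:::.new_allele("KIR3DL1*001",
                                              strrep("ACGT", 250)))
  # identical query: 100%, tie broken by lowest allele number
  hit <- nearest_reference(strrep("ACGT", 250), refs)
  expect_equal(hit$allele, "KIR3DL1*001")
  expect_equal(hit$identity, 100)
  # 1 mismatch in 1000 aligned positions = 99.9%
  q <- strrep("ACGT", 250)
  substr(q, 501, 501) <- "T"   # the A at position 501 becomes a mismatch
  expect_equal(nearest_reference(q, refs["a"])$identity, 99.9)
  expect_error(nearest_reference("", refs), "empty query")
})

test_that("p-distance ignores N columns and build_nj_tree handles 3 taxa", {
  aln <- c(a = "AAAA", b = "AATA", c = "ANTT")
  d <- p_distance(aln)
  expect_equal(d["a", "b"], 1 / 4)
  expect_equal(d["a", "c"], 2 / 3)  # N column dropped pairwise
  expect_equal(d["b", "c"], 1 / 3)

  # 3 taxa: unique unrooted topology, closed-form branch lengths
  aln3 <- c(a = strrep("A", 100),
            b = paste0(strrep("A", 90), strrep("C", 10)),
            c = paste0(strrep("G", 20), strrep("A", 80)))
  tr <- build_nj_tree(aln3, bootstrap_reps = 0)
  expect_s3_class(tr, "phylo")
  dmat <- p_distance(aln3)
  # leaf edge for a: (d_ab + d_ac - d_bc)/2
  la <- (dmat["a", "b"] + dmat["a", "c"] - dmat["b", "c"]) / 2
  ea <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(ea, la, tolerance = 1e-12)

  expect_error(build_nj_tree(aln3[1:2]), "3 taxa")
  expect_error(p_distance(c(a = "", b = "", c = "")), "zero-length")
})

test_that("NJ recovers the 4-taxon topology certified by least squares", {
  # additive distances favouring ((A,B),(C,D)): built from a known tree
  seqs <- c(
    A = paste0(strrep("A", 60), strrep("C", 5),  strrep("A", 35)),
    B = paste0(strrep("A", 60), strrep("G", 5),  strrep("A", 35)),
    C = paste0(strrep("T", 20), strrep("A", 75), strrep("C", 5)),
    D = paste0(strrep("T", 20), strrep("A", 75), strrep("G", 5))
  )
  d <- p_distance(seqs)

  # independent oracle: exhaustive least-squares fit of the 3 unrooted
  # 4-taxon topologies, each parameterised by 5 branch lengths
  topo_paths <- list(
    "AB|CD" = function(x) c(AB = x[1] + x[2], AC = x[1] + x[5] + x[3],
                            AD = x[1] + x[5] + x[4], BC = x[2] + x[5] + x[3],
                            BD = x[2] + x[5] + x[4], CD = x[3] + x[4]),
    "AC|BD" = function(x) c(AB = x[1] + x[5] + x[2], AC = x[1] + x[3],
                            AD = x[1] + x[5] + x[4], BC = x[3] + x[5] + x[2],
                            BD = x[2] + x[4], CD = x[3] + x[5] + x[4]),
    "AD|BC" = function(x) c(AB = x[1] + x[5] + x[2], AC = x[1] + x[5] + x[3],
                            AD = x[1] + x[4], BC = x[2] + x[3],
                            BD = x[2] + x[5] + x[4], CD = x[4] + x[5] + x[3])
  )
  obs <- c(AB = d["A", "B"], AC = d["A", "C"], AD = d["A", "D"],
           BC = d["B", "C"], BD = d["B", "D"], CD = d["C", "D"])
  rss <- vapply(topo_paths, function(f) {
    fit <- stats::optim(rep(0.05, 5), function(x) sum((f(pmax(x, 0)) - obs)^2),
                        method = "BFGS")
    fit$value
  }, numeric(1))
  expect_equal(names(which.min(rss)), "AB|CD")

  tr <- build_nj_tree(seqs, bootstrap_reps = 50, seed = 3)
  expect_true(is_clade(tr, c("A", "B")))
  expect_true(is_clade(tr, c("C", "D")))
  # clean signal: full bootstrap support on the internal edge
  expect_true(any(as.numeric(tr$node.label) == 100, na.rm = TRUE))
})

test_that("identical sequences give a zero-length tree with full support", {
  aln <- c(a = strrep("ACGT", 30), b = strrep("ACGT", 30),
           c = strrep("ACGT", 30), d = strrep("ACGT", 30))
  tr <- build_nj_tree(aln, bootstrap_reps = 20, seed = 1)
  expect_true(all(tr$edge.length == 0))
  expect_true(all(as.numeric(tr$node.label) == 100, na.rm = TRUE))
})

test_that("build_nj_tree is deterministic for a fixed seed", {
  aln <- make_group_alignment(members_per_group = 2, seed = 9)
  t1 <- build_nj_tree(aln, bootstrap_reps = 10, seed = 4)
  t2 <- build_nj_tree(aln, bootstrap_reps = 10, seed = 4)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("group clades emerge from fixture alignments (seeded property)", {
  hits <- 0L
  for (s in 1:3) {
    aln <- make_group_alignment(members_per_group = 3, seed = s)
    tr <- build_nj_tree(aln, bootstrap_reps = 0)
    ok <- all(vapply(kir_group_labels(), function(g) {
      is_clade(tr, grep(paste0("^", g, "_"), names(aln), value = TRUE))
    }, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 2L)
})
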