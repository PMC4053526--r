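test_that("enumerate_pattern_table matches the hand-derived design table", {
  tab <- enumerate_pattern_table(test_panel)
  groups <- kir_group_labels()

  # oracle: union the hand-coded design signatures over all 21 pairs
  oracle <- list()
  for (i in seq_along(groups)) {
    for (j in seq(i, length(groups))) {
      pair <- sort(c(groups[i], groups[j]))
      key <- design_pattern_key(pair)
      oracle[[key]] <- c(oracle[[key]], list(pair))
    }
  }
  expect_length(oracle, 20L)          # 21 pairs, exactly one collision
  expect_length(tab, 20L)
  expect_setequal(names(oracle), vapply(tab, `[[`, character(1), "key"))
  for (e in tab) {
    expect_setequal(lapply(e$hypotheses, paste, collapse = "+"),
                    lapply(oracle[[e$key]], paste, collapse = "+"))
  }

  # the single collision is the documented *007-group ambiguity
  coll <- Filter(function(e) length(e$hypotheses) > 1L, tab)
  expect_length(coll, 1L)
  expect_setequal(lapply(coll[[1]]$hypotheses, paste, collapse = "+"),
                  list("LOW2+LOW2", "HIGH2+LOW2"))

  # a clean two-reaction pattern decodes uniquely
  r2r3 <- Filter(function(e) e$key == design_pattern_key(c("HIGH1", "LOW1")),
                 tab)
  expect_equal(r2r3[[1]]$hypotheses, list(c("HIGH1", "LOW1")))
})

test_that("decode_pattern: unambiguous, ambiguous and empty patterns", {
  hom_null <- run_panel(list(test_templates[["NULL"]],
                             test_templates[["NULL"]]), test_panel)
  d <- decode_pattern(hom_null)
  expect_false(d$ambiguous)
  expect_equal(d$hypotheses, list(c("NULL", "NULL")))

  amb <- run_panel(list(test_templates[["LOW2"]], test_templates[["LOW2"]]),
                   test_panel)
  da <- decode_pattern(amb)
  expect_true(da$ambiguous)
  expect_length(da$hypotheses, 2L)
  expect_match(paste(da$notes, collapse = " "), "exon 7")

  # exon-7 reads resolve the collision both ways
  dh <- decode_pattern(amb, exon7_reads = "CG")
  expect_equal(dh$hypotheses, list(c("LOW2", "LOW2")))
  het <- run_panel(list(test_templates[["LOW2"]], test_templates[["HIGH2"]]),
                   test_panel)
  dhet <- decode_pattern(het, exon7_reads = c("CG", "CA"))
  expect_equal(dhet$hypotheses, list(c("HIGH2", "LOW2")))

  dempty <- decode_pattern(band_pattern(list()))
  expect_length(dempty$hypotheses, 0L)
  expect_match(dempty$notes, "no call")
})

test_that("decoding is a pure lookup: identical patterns, identical results", {
  p1 <- run_panel(list(test_templates[["HIGH1"]], test_templates[["S1"]]),
                  test_panel, sample_id = "a")
  p2 <- run_panel(list(test_templates[["S1"]], test_templates[["HIGH1"]]),
                  test_panel, sample_id = "b")
  expect_equal(p1$bands, p2$bands)
  expect_equal(decode_pattern(p1)$hypotheses, decode_pattern(p2)$hypotheses)
})

test_that("extended haplotypes decode as minimal triples", {
  tri <- run_panel(list(test_templates[["NULL"]], test_templates[["HIGH1"]],
                        test_templates[["S1"]]), test_panel)
  d <- decode_pattern(tri, allow_extended = TRUE)
  expect_true(d$extended)
  expect_true(any(vapply(d$hypotheses, identical, logical(1),
                         sort(c("NULL", "HIGH1", "S1")))))
  d2 <- decode_pattern(tri, allow_extended = FALSE)
  expect_length(d2$hypotheses, 0L)
})

test_that("round trip: decode contains the truth for all 21 pairs", {
  groups <- kir_group_labels()
  ambiguous_keys <- design_pattern_key(c("LOW2", "LOW2"))
  for (i in seq_along(groups)) {
    for (j in seq(i, length(groups))) {
      pair <- sort(c(groups[i], groups[j]))
      pat <- run_panel(list(test_templates[[pair[1]]],
                            test_templates[[pair[2]]]), test_panel)
      d <- decode_pattern(pat)
      expect_true(any(vapply(d$hypotheses, identical, logical(1), pair)),
                  info = paste(pair, collapse = "+"))
      # equality (unambiguous) except for the documented collision
      if (!identical(kir3dl1typer:::.pattern_key(pat), ambiguous_keys)) {
        expect_equal(d$hypotheses, list(pair),
                     info = paste(pair, collapse = "+"))
      }
    }
  }
})

test_that("pedigree TSV parsing and error reporting", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfather\tmother\tcall",
               "dad\t.\t.\tNULL+HIGH2",
               "mum\t.\t.\tLOW1+S1",
               "kid\tdad\tmum\tR1:2019;R2:1573"), tmp)
  ped <- read_pedigree(tmp)
  expect_equal(nrow(ped$individuals), 3L)
  expect_equal(ped$calls$dad, c("HIGH2", "NULL"))
  expect_s3_class(ped$calls$kid, "kir_band_pattern")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfather\tmother\tcall",
               "kid\tghost\t.\tNULL+NULL"), bad)
  expect_error(read_pedigree(bad), "unknown father id 'ghost'")

  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfather\tmother\tcall",
               "kid\t.\t.\tNULL+WAT"), bad2)
  expect_error(read_pedigree(bad2), "row 1")
})

test_that("check_pedigree verdicts: transmission, violation, extended", {
  mk <- function(calls, rel) {
    structure(list(
      individuals = data.frame(id = names(calls),
                               father = rel$father, mother = rel$mother,
                               stringsAsFactors = FALSE),
      calls = calls), class = "kir_pedigree")
  }
  rel <- list(father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"))

  ok <- mk(list(dad = c("HIGH2", "NULL"), mum = c("LOW1", "S1"),
                kid = c("LOW1", "NULL")), rel)
  rep_ok <- check_pedigree(ok)
  expect_true(all(rep_ok$consistent))
  expect_match(rep_ok$witness[1], "father->NULL")

  bad <- mk(list(dad = c("HIGH2", "NULL"), mum = c("LOW1", "S1"),
                 kid = c("HIGH1", "HIGH1")), rel)
  expect_false(any(check_pedigree(bad)$consistent))

  # child with three groups is consistent only under extended transmission
  ext <- mk(list(dad = c("HIGH1", "HIGH1"), mum = c("LOW1", "NULL", "S1"),
                 kid = c("HIGH1", "NULL", "S1")), rel)
  expect_true(all(check_pedigree(ext, allow_extended = TRUE)$consistent))
  expect_false(any(check_pedigree(ext, allow_extended = FALSE)$consistent))

  # missing parents are unconstrained and logged
  orphan <- structure(list(
    individuals = data.frame(id = c("mum", "kid"),
                             father = c(NA, NA), mother = c(NA, "mum"),
                             stringsAsFactors = FALSE),
    calls = list(mum = c("LOW1", "LOW1"), kid = c("LOW1", "HIGH2"))),
    class = "kir_pedigree")
  rep_o <- check_pedigree(orphan)
  expect_true(rep_o$consistent[1])
  expect_match(rep_o$note[1], "father unconstrained")

  # structural errors
  cyc <- structure(list(
    individuals = data.frame(id = c("a", "b"), father = c("b", "a"),
                             mother = c(NA, NA), stringsAsFactors = FALSE),
    calls = list(a = c("NULL", "NULL"), b = c("NULL", "NULL"))),
    class = "kir_pedigree")
  expect_error(check_pedigree(cyc), "cyclic")
  no_rel <- structure(list(
    individuals = data.frame(id = "a", father = NA_character_,
                             mother = NA_character_,
                             stringsAsFactors = FALSE),
    calls = list(a = c("NULL", "NULL"))), class = "kir_pedigree")
  expect_error(check_pedigree(no_rel), "no parent-child")
})

test_that("simulated Mendelian trios always check out; injected groups fail", {
  n_trios <- 60L
  groups <- kir_group_labels()
  set.seed(20)
  founder_draws <- matrix(sample(groups, 4L * n_trios, replace = TRUE),
                          ncol = 4L)
  for (s in seq_len(n_trios)) {
    ped <- simulate_pedigree(
      list(F1 = list(founder_draws[s, 1], founder_draws[s, 2]),
           F2 = list(founder_draws[s, 3], founder_draws[s, 4])),
      generations = 2L, children_per_couple = 1L, seed = s)
    rep <- check_pedigree(ped)
    expect_true(all(rep$consistent), info = paste("seed", s))

    # corrupt the child call with a group neither parent carries
    absent <- setdiff(groups, unlist(ped$truth))
    if (length(absent) > 0L) {
      kid <- ped$individuals$id[!is.na(ped$individuals$father)][1]
      calls <- lapply(ped$truth, function(u) sort(unlist(u)))
      calls[[kid]] <- sort(c(absent[1], calls[[kid]][1]))
      ped_bad <- structure(list(individuals = ped$individuals,
                                calls = calls), class = "kir_pedigree")
      rep_bad <- check_pedigree(ped_bad)
      expect_false(rep_bad$consistent[rep_bad$id == kid],
                   info = paste("seed", s))
    }
  }
})

test_that("duplicated-haplotype families propagate three-allele typings", {
  ped <- simulate_pedigree(
    list(F1 = list("HIGH1", "LOW1"), F2 = list(c("S1", "NULL"), "HIGH2")),
    generations = 3L, children_per_couple = 2L,
    duplicated_haplotype = list(carrier = "F2", pair = c("S1", "NULL")),
    seed = 5L)
  n_alleles <- vapply(ped$truth, function(u) length(unlist(u)), integer(1))
  expect_true(any(n_alleles == 3L))
  # typing the three-allele members shows three band-pattern groups
  tri_ids <- names(n_alleles)[n_alleles == 3L]
  d <- decode_pattern(ped$patterns[[tri_ids[1]]])
  expect_true(d$extended)
  expect_true(all(check_pedigree(ped)$consistent))
  expect_error(simulate_pedigree(
    list(F1 = list("HIGH1", "LOW1"), F2 = list("S1", "HIGH2")),
    duplicated_haplotype = list(carrier = "nobody", pair = c("S1", "NULL")),
    seed = 1L), "non-founder")
})
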