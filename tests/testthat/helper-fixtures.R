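# Shared fixtures, built once per test run. Everything is generated in code;
# no binary files.

test_panel <- kir_panel()

# per-group homozygous templates at the canonical fixture seed
test_templates <- local({
  tpls <- lapply(kir_group_labels(), make_template, seed = 1000L)
  names(tpls) <- kir_group_labels()
  tpls
})

test_refs <- make_reference_alleles(seed = 42L)

# hand-coded design signatures (reaction id -> which groups band there, and
# at what size class); used as the independent oracle for enumeration tests
design_signature <- list(
  "NULL"  = c(R1 = "2019"),
  "LOW1"  = c(R2 = "1573"),
  "HIGH1" = c(R3 = "1573"),
  "HIGH2" = c(R4 = "1573"),
  "LOW2"  = c(R4 = "1573", R5 = "1408"),
  "S1"    = c(R4 = "1933")
)

# union of two design signatures as a canonical string, oracle-side
design_pattern_key <- function(pair) {
  bands <- list()
  for (g in pair) {
    s <- design_signature[[g]]
    for (rx in names(s)) bands[[rx]] <- union(bands[[rx]], s[[rx]])
  }
  paste(vapply(sort(names(bands)), function(rx)
    paste0(rx, ":", paste(sort(bands[[rx]]), collapse = ",")),
    character(1)), collapse = ";")
}

# tiny FASTA writer for parser tests
write_tmp_fasta <- function(records, width = 60L) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(records)) {
    writeLines(paste0(">", nm), con)
    s <- records[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  path
}
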