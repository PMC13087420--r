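test_that("the HGVS grammar parses the recurrent exon-7 variants", {
  v <- parse_hgvs_c(c("c.855_858delAGAA", "c.861_862insT", "c.863G>T",
                      "c.855del", "c.10_12dup", "c.10_12delinsAT"))
  expect_equal(v$kind, c("deletion", "insertion", "substitution",
                         "deletion", "duplication", "delins"))
  expect_equal(v$start_c, c(855L, 861L, 863L, 855L, 10L, 10L))
  expect_equal(v$end_c, c(858L, 862L, 863L, 855L, 12L, 12L))
  expect_equal(v$ref_allele[1], "AGAA")
  expect_equal(v$alt_allele[2], "T")
  expect_equal(v$ref_allele[3], "G")
  expect_equal(v$alt_allele[3], "T")
  expect_identical(v$raw[1], "c.855_858delAGAA")
})

test_that("unsupported or inconsistent HGVS syntax is rejected by name", {
  expect_error(parse_hgvs_c("c.100+3A>G"), "intronic")
  expect_error(parse_hgvs_c("c.10_12inv"), "cannot parse")
  expect_error(parse_hgvs_c("c.855_858delAGA"), "length does not match")
  expect_error(parse_hgvs_c("c.861_863insT"), "flanking")
  expect_error(parse_hgvs_c("c.10A>A"), "identical")
})

test_that("apply_variant edits correctly and defends the reference allele", {
  m <- toy_model()
  # substitution is an involution
  once <- apply_variant(m, "c.8G>A")
  m2 <- transcript_model("t", once, m$cds_start, m$cds_end, m$exons)
  expect_identical(apply_variant(m2, "c.8A>G"), m$sequence)
  # length bookkeeping
  expect_identical(nchar(apply_variant(m, "c.7_10delAGAA")),
                   nchar(m$sequence) - 4L)
  expect_identical(nchar(apply_variant(m, "c.7_8insTT")),
                   nchar(m$sequence) + 2L)
  expect_identical(nchar(apply_variant(m, "c.7_10dup")),
                   nchar(m$sequence) + 4L)
  # stated reference must match the transcript
  expect_error(apply_variant(m, "c.7_10delAGAG"),
               "expected 'AGAG'.*has 'AGAA'")
  expect_error(apply_variant(m, "c.8C>T"), "expected 'C'")
})

test_that("translate_cds follows the standard code and flags missing stops", {
  expect_equal(translate_cds("ATGTAA"), list(peptide = "M", stop_found = TRUE))
  expect_equal(translate_cds("ATGGCTAGAAGGCATTGA"),
               list(peptide = "MARRH", stop_found = TRUE))
  expect_equal(translate_cds("ATGGCA"),
               list(peptide = "MA", stop_found = FALSE))
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
})

test_that("consequence calls on the toy transcript match hand computation", {
  m <- toy_model()
  fs <- protein_consequence(m, "c.7_10delAGAA")
  expect_equal(fs$kind, "frameshift")
  expect_equal(fs$first_residue, 3L)
  expect_equal(fs$ref_aa, "Arg")
  expect_equal(fs$alt_aa, "Gly")
  expect_equal(fs$ter_offset, 4L)
  expect_equal(fs$hgvs_p, "p.Arg3GlyfsTer4")

  expect_equal(protein_consequence(m, "c.8G>A")$hgvs_p, "p.Arg3Lys")
  expect_equal(protein_consequence(m, "c.9A>G")$kind, "synonymous")
  expect_equal(protein_consequence(m, "c.4_6delGCT")$hgvs_p, "p.Ala2del")
})

test_that("the demo SMN1-like transcript reproduces the published calls", {
  m <- smn_transcript_demo()
  d1 <- protein_consequence(m, "c.855_858delAGAA")
  d2 <- protein_consequence(m, "c.861_864delAAGG")
  expect_equal(d1$hgvs_p, "p.Arg288AlafsTer5")
  expect_identical(d1$hgvs_p, d2$hgvs_p)
  # mutual consistency: codon 288 must be AGG for these to hold together
  expect_equal(protein_consequence(m, "c.863G>T")$hgvs_p, "p.Arg288Met")
  expect_equal(protein_consequence(m, "c.861_862insT")$hgvs_p, "p.Arg288Ter")
})

test_that("format_p is a pure function of the consequence fields", {
  expect_equal(format_p("frameshift", "Arg", 288, "Ala", 5),
               "p.Arg288AlafsTer5")
  expect_equal(format_p("nonsense", "Arg", 288), "p.Arg288Ter")
  expect_equal(format_p("missense", "Arg", 288, "Met"), "p.Arg288Met")
  expect_equal(format_p("synonymous", "Gly", 287), "p.Gly287=")
  expect_equal(format_p("no_stop_found", "Lys", 10, "Asn"), "p.Lys10AsnfsTer?")
})

test_that("consequence engine agrees with the brute-force oracle", {
  skip_if_not_installed("seqinr")
  withr::local_seed(424L)
  for (rep in 1:300) {
    m <- random_model()
    h <- random_variant(m)
    got <- protein_consequence(m, h)
    want <- oracle_consequence(m, h)
    expect_equal(got$kind, want$kind, info = paste(h, m$sequence))
    if (!is.na(want$first_residue))
      expect_equal(got$first_residue, want$first_residue,
                   info = paste(h, m$sequence))
    if (!is.na(want$ter_offset))
      expect_equal(got$ter_offset, want$ter_offset,
                   info = paste(h, m$sequence))
  }
})

test_that("frame-preserving variants never yield a frameshift call", {
  withr::local_seed(77L)
  for (rep in 1:150) {
    m <- random_model()
    cds_len <- m$cds_end - m$cds_start + 1
    p <- sample(4:(cds_len - 12), 1)
    h <- sample(c(paste0("c.", p, "_", p + 2, "del"),
                  paste0("c.", p, "_", p + 1, "ins",
                         random_dna(3)),
                  paste0("c.", p, "_", p + 2, "dup")), 1)
    res <- protein_consequence(m, h)
    expect_false(res$kind == "frameshift", info = h)
    expect_false(grepl("fsTer", res$hgvs_p), info = h)
  }
})

test_that("identical inputs give byte-identical consequence strings", {
  m <- smn_transcript_demo()
  a <- protein_consequence(m, "c.855_858delAGAA")$hgvs_p
  b <- protein_consequence(m, "c.855_858delAGAA")$hgvs_p
  expect_identical(a, b)
})

test_that("predict_consequences annotates a variant table row-wise", {
  tab <- tibble::tibble(variant_id = c("a", "b"),
                        hgvs_c = c("c.855_858delAGAA", "c.863G>T"))
  out <- predict_consequences(tab, smn_transcript_demo())
  expect_equal(nrow(out), 2L)
  expect_equal(out$hgvs_p, c("p.Arg288AlafsTer5", "p.Arg288Met"))
  expect_true(all(c("variant_id", "kind", "ter_offset") %in% names(out)))
})

test_that("variant tables round-trip through TSV with invariant checks", {
  tab <- make_variant_table(11)
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, f)
  back <- read_variant_table(f)
  expect_equal(back$hgvs_c, tab$hgvs_c)
  bad <- tab
  bad$allele_count[1] <- bad$carrier_count[1] - 1L
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, f2)
  expect_error(read_variant_table(f2), "carrier_count <= allele_count")
})
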