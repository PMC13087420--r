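test_that("paralog pairs are reproducible and differ only as declared", {
  p1 <- make_paralog_pair(42)
  p2 <- make_paralog_pair(42)
  expect_identical(p1$a$sequence, p2$a$sequence)
  expect_identical(p1$b$sequence, p2$b$sequence)
  p3 <- make_paralog_pair(43)
  expect_false(identical(p1$a$sequence, p3$a$sequence))

  # Hamming distance equals the number of discriminating positions
  mism <- sum(strsplit(p1$a$sequence, "")[[1]] !=
                strsplit(p1$b$sequence, "")[[1]])
  expect_equal(mism, nrow(default_discriminating()))

  # the exon-8 window has a DdeI site in the second paralog only
  win <- p1$exon8_window
  cuts_a <- find_cut_sites(p1$a$sequence, dde_i())
  cuts_b <- find_cut_sites(p1$b$sequence, dde_i())
  expect_false(any(cuts_a >= win[1] & cuts_a < win[2]))
  expect_true(any(cuts_b >= win[1] & cuts_b < win[2]))

  # both are valid transcript models with identical exon structure
  expect_identical(p1$a$exons, p1$b$exons)
  expect_error(make_paralog_pair(1, discriminating = tibble::tibble(
    exon = c(7L, 8L), offset = c(30L, 27L),
    base_a = c("C", "C"), base_b = c("C", "G"))), "must differ")
})

test_that("the demo transcript is deterministic and SMN-shaped", {
  m1 <- smn_transcript_demo()
  m2 <- smn_transcript_demo()
  expect_identical(m1$sequence, m2$sequence)
  expect_equal(nrow(m1$exons), 8L)
  expect_equal((m1$cds_end - m1$cds_start + 1) / 3, 295)  # 294 aa + stop
  expect_equal(exon_of(m1, 835), 7L)
  expect_equal(exon_of(m1, 885), 7L)  # stop codon inside exon 7
  expect_equal(substr(cds_sequence(m1), 855, 858), "AGAA")
  expect_equal(substr(cds_sequence(m1), 861, 864), "AAGG")
  expect_equal(substr(cds_sequence(m1), 862, 864), "AGG")  # Arg288
})

test_that("variant tables carry the designated deletions and stay in range", {
  tab <- make_variant_table(7, n_variants = 15,
                            carrier_count_range = c(13L, 47L))
  expect_equal(nrow(tab), 15L)
  expect_equal(tab$hgvs_c[1:2], c("c.855_858delAGAA", "c.861_864delAAGG"))
  expect_false(any(duplicated(tab$hgvs_c)))
  expect_true(all(tab$carrier_count >= 13 & tab$carrier_count <= 47))
  expect_identical(tab$allele_count, tab$carrier_count)  # all heterozygous
  expect_identical(make_variant_table(7, n_variants = 15,
                                      carrier_count_range = c(13L, 47L)),
                   tab)

  # every generated variant anneals under the demo assay
  rep <- screen_variants(tab, demo_assay())
  expect_equal(rep$summary$n[rep$summary$classification == "no_overlap"], 0L)
  expect_length(rep$annealing_region_ids, 15L)

  # the two designated deletions share one frameshift consequence
  cons <- predict_consequences(tab[1:2, ], smn_transcript_demo())
  expect_equal(cons$hgvs_p[1], cons$hgvs_p[2])
  expect_equal(cons$kind, c("frameshift", "frameshift"))

  expect_error(make_variant_table(1, region = c(850L, 855L)),
               "too small")
})

test_that("cohort simulation computes screening results mechanistically", {
  # no variant alleles -> nobody screens positive
  none <- simulate_newborn_cohort(1, 5000, 0, 0)
  expect_equal(sum(none$n[none$screen_positive]), 0L)
  expect_equal(sum(none$n), 5000L)

  # a VUS the assay does not cover still amplifies: compound hets are
  # screen-NEGATIVE
  far_assay <- assay_definition("elsewhere", tibble::tibble(
    role = "reverse_primer", start_c = 100, end_c = 126))
  sim <- simulate_newborn_cohort(2, 20000, 0.05, 0.04, assay = far_assay)
  dv <- sim[sim$genotype == "del/vus", ]
  expect_gt(dv$n, 0)
  expect_false(dv$screen_positive)
  expect_equal(dv$category, "screen_negative")
  # del/del remains a true positive regardless of the assay
  expect_equal(sim$category[sim$genotype == "del/del"], "true_positive")

  # with the demo assay the VUS drops out and del/vus screens positive
  sim2 <- simulate_newborn_cohort(2, 20000, 0.05, 0.04)
  dv2 <- sim2[sim2$genotype == "del/vus", ]
  expect_true(dv2$screen_positive)
  expect_equal(dv2$category, "compound_het_dropout")

  expect_error(simulate_newborn_cohort(1, 100, 0.2, 0.2), "< 0.1")
  expect_identical(simulate_newborn_cohort(3, 10000, 1 / 70, 1 / 500),
                   simulate_newborn_cohort(3, 10000, 1 / 70, 1 / 500))
})

test_that("observed genotype frequencies track Hardy-Weinberg expectations", {
  # moderate n, several seeds: del/vus count ~ Binomial(n, 2 p q)
  n <- 2e5; p_del <- 1 / 50; p_vus <- 1 / 400
  counts <- vapply(1:8, function(s) {
    sim <- simulate_newborn_cohort(s, n, p_del, p_vus)
    sim$n[sim$genotype == "del/vus"]
  }, integer(1))
  mu <- n * 2 * p_del * p_vus
  se <- sqrt(mu / length(counts))
  expect_lt(abs(mean(counts) - mu), 4 * se)
})

test_that("scenario directories regenerate bit-identically from a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- make_scenario(5, d1)
  s2 <- make_scenario(5, d2)
  for (f in basename(s1$paths)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_s3_class(s1, "synthetic_scenario")
  expect_true(all(file.exists(s1$paths)))
})
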