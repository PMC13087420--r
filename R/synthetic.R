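# Codons other than TAA/TAG/TGA, used when generating stop-free filler CDS.
non_stop_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)),
                                bases, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove every occurrence of a motif from a sequence by rewriting one
# matched base to something outside that motif position's IUPAC set
# (re-scanning until clean). The ambiguous N position is useless for
# this, so the least ambiguous motif position is rewritten.
scrub_motif <- function(seq, motif = "CTNAG") {
  codes <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(motif, "")[[1]]], "")
  widths <- lengths(codes)
  if (min(widths) == 4L)
    stop("cannot scrub a motif of all-N positions", call. = FALSE)
  at <- which.min(widths)
  repl <- setdiff(c("A", "C", "G", "T"), codes[[at]])[1]
  repeat {
    hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                     fixed = FALSE)
    if (length(hits) == 0L) return(seq)
    i <- Biostrings::start(hits)[1] + at - 1L
    substr(seq, i, i) <- repl
  }
}

#' Synthetic SMN1-like demonstration transcript
#'
#' A 1,048-nt transcript with a 60-nt 5'UTR, an 885-nt CDS (295 codons
#' including the stop) and 8 exons, built so that its exon 7 matches the
#' published SMN1 exon-7 coding region (c.835-885). That region is fully
#' determined by the four recurrent exon-7 variants this package
#' handles: the reference alleles of c.855_858delAGAA and
#' c.861_864delAAGG, codon 288 = AGG (so c.863G>T gives Met and
#' c.861_862insT an immediate stop), and the frameshift reading frame
#' that places the new stop five codons in. Everything outside exon 7 is
#' deterministic synthetic filler; this object is a synthetic
#' reconstruction, not the GenBank transcript record.
#'
#' @return A [transcript_model()] with id `"SMN1demo"` and the
#'   SMN1/SMN2-discriminating c.840 position annotated.
#' @examples
#' protein_consequence(smn_transcript_demo(), "c.855_858delAGAA")
#' @export
smn_transcript_demo <- function() {
  exon7_coding <- "GGTTTCAGACAAAATCAAAAAGAAGGAAGGTGCTCACATTCCTTAAATTAA"
  withr::with_seed(2861L, {
    utr5 <- random_bases(60L)
    filler <- paste(sample(non_stop_codons(), 277L, replace = TRUE),
                    collapse = "")
    utr3_in_exon7 <- random_bases(3L)
    exon8 <- scrub_motif(random_bases(100L))
    seq <- paste0(utr5, "ATG", filler, exon7_coding, utr3_in_exon7, exon8)
    exons <- rbind(cbind(149L * (0:5) + 1L, 149L * (1:6)),
                   c(895L, 948L), c(949L, 1048L))
    transcript_model(
      "SMN1demo", seq, cds_start = 61L, cds_end = 945L, exons = exons,
      discriminating_positions = tibble::tibble(c_pos = "840", base = "C"))
  })
}

#' Default discriminating positions for a synthetic paralog pair
#'
#' Two differences, echoing the real SMN1/SMN2 pair: a translationally
#' silent exon-7 substitution (the c.840 C/T analogue) and an exon-8
#' (3'UTR) substitution that creates a DdeI site (CTNAG) in the second
#' paralog only.
#'
#' @return Tibble with columns `exon`, `offset`, `base_a`, `base_b`.
#' @export
default_discriminating <- function() {
  tibble::tibble(exon = c(7L, 8L), offset = c(30L, 27L),
                 base_a = c("C", "C"), base_b = c("T", "G"))
}

#' Generate a synthetic paralog transcript pair
#'
#' Two transcript models identical except at the declared discriminating
#' positions -- the toy analogue of SMN1/SMN2. Exons tile the transcript
#' (`n_exons` of `exon_len` nt each); the CDS starts at position 1 and
#' its stop codon is placed inside exon 7, so exon 8 is entirely 3'UTR,
#' mirroring the SMN gene layout. One discriminating change must create a
#' cut-site motif for `enzyme` in the second paralog's exon 8; exon 8 is
#' otherwise scrubbed of the motif in both paralogs so the digest-based
#' gene call has exactly one informative site.
#'
#' @param seed Integer seed; the pair is bit-reproducible from it.
#' @param n_exons,exon_len Exon count and length (defaults 8 x 111 nt =
#'   an 888-nt transcript, the scale of the real SMN transcripts).
#' @param discriminating Tibble as in [default_discriminating()].
#' @param enzyme Enzyme whose motif the exon-8 discriminating change
#'   creates (default [dde_i()]).
#' @return List with elements `a` and `b` ([transcript_model()]s,
#'   ids `SMN1like`/`SMN2like`), `exon7_tag` (a subsequence shared by
#'   both full-length paralogs and absent from their exon-7-skipped
#'   forms) and `exon8_window` (transcript-space interval around the
#'   paralogous cut site).
#' @export
make_paralog_pair <- function(seed, n_exons = 8L, exon_len = 111L,
                              discriminating = default_discriminating(),
                              enzyme = dde_i()) {
  stopifnot(n_exons >= 8L, exon_len >= 40L)
  discriminating <- tibble::as_tibble(discriminating)
  if (any(discriminating$base_a == discriminating$base_b))
    stop("discriminating bases must differ between paralogs", call. = FALSE)
  n <- n_exons * exon_len
  exons <- cbind(exon_len * (seq_len(n_exons) - 1L) + 1L,
                 exon_len * seq_len(n_exons))
  ex7_start <- exons[7L, 1L]; ex8_start <- exons[8L, 1L]
  # stop codon two codons before the end of exon 7
  cds_end <- (ex7_start + exon_len %/% 2L) %/% 3L * 3L
  withr::with_seed(as.integer(seed), {
    body <- paste(sample(non_stop_codons(), cds_end %/% 3L - 2L,
                         replace = TRUE), collapse = "")
    seq_a <- paste0("ATG", body, "TAA", random_bases(n - cds_end))
    # silent-substitution context for the exon-7 discriminating position:
    # make it the third base of a glycine codon (GGC <-> GGT)
    pos7 <- ex7_start + discriminating$offset[discriminating$exon == 7L][1] - 1L
    pos7 <- (pos7 + 2L) %/% 3L * 3L  # snap to a codon's third base
    substr(seq_a, pos7 - 2L, pos7) <- "GGC"
    # exon 8: scrub the motif, then plant a fixed context block holding an
    # almost-site (CTAAC) that the second paralog's discriminating base
    # completes to CTAAG; the flanking block bases are chosen so no other
    # CTNAG can arise across the block junctions
    exon8 <- scrub_motif(substr(seq_a, ex8_start, n), enzyme$recognition)
    seq_a <- paste0(substr(seq_a, 1L, ex8_start - 1L), exon8)
    pos8 <- ex8_start + discriminating$offset[discriminating$exon == 8L][1] - 1L
    stopifnot(pos8 - 7L >= ex8_start, pos8 + 7L <= n)
    substr(seq_a, pos8 - 7L, pos8 + 7L) <- "AACCTAACCAACCAA"
    seq_b <- seq_a
    substr(seq_b, pos8, pos8) <- "G"             # CTAAG: DdeI site in B only
    substr(seq_b, pos7, pos7) <- "T"             # GGC -> GGT, silent
    dp <- function(model_pos) {
      vapply(model_pos, function(p)
        if (p <= cds_end) as.character(p) else paste0("*", p - cds_end),
        character(1))
    }
    a <- transcript_model("SMN1like", seq_a, 1L, cds_end, exons,
                          tibble::tibble(c_pos = dp(c(pos7, pos8)),
                                         base = c("C", "C")))
    b <- transcript_model("SMN2like", seq_b, 1L, cds_end, exons,
                          tibble::tibble(c_pos = dp(c(pos7, pos8)),
                                         base = c("T", "G")))
    # exon-7 tag: a subsequence both FL paralogs share, clear of the
    # discriminating base, and not recurring elsewhere in either transcript
    tag <- NULL
    for (off in seq(5L, exon_len - 20L, by = 3L)) {
      cand_start <- ex7_start + off
      if (cand_start <= pos7 && pos7 <= cand_start + 14L) next
      cand <- substr(seq_a, cand_start, cand_start + 14L)
      n_a <- sum(gregexpr(cand, seq_a, fixed = TRUE)[[1]] > 0)
      n_b <- sum(gregexpr(cand, seq_b, fixed = TRUE)[[1]] > 0)
      if (n_a == 1L && n_b == 1L) { tag <- cand; break }
    }
    if (is.null(tag))
      stop("could not place a unique exon-7 tag; try another seed",
           call. = FALSE)
    list(a = a, b = b, exon7_tag = tag,
         exon8_window = c(pos8 - 10L, pos8 + 10L))
  })
}

#' Amplicons of the exon 5-8 region for a paralog pair
#'
#' The four species visible on the diagnostic digest: each paralog's
#' full-length and exon-7-skipped (Delta7) transcript, restricted to the
#' exon 5-8 amplicon.
#'
#' @param pair Result of [make_paralog_pair()].
#' @return Named character vector of 4 amplicons
#'   (`<id>_FL`, `<id>_Delta7`).
#' @export
paralog_amplicons <- function(pair) {
  out <- character(0)
  for (m in list(pair$a, pair$b)) {
    from <- m$exons[5L, 1L]; to <- m$exons[8L, 2L]
    fl <- substr(m$sequence, from, to)
    ex7 <- m$exons[7L, ]
    d7 <- paste0(substr(m$sequence, from, ex7["start"] - 1L),
                 substr(m$sequence, ex7["end"] + 1L, to))
    out[paste0(m$id, "_FL")] <- fl
    out[paste0(m$id, "_Delta7")] <- d7
  }
  out
}

#' Generate a synthetic variant table
#'
#' `n_variants` distinct small variants (a mix of 4-bp deletions, 1-bp
#' insertions and substitutions) placed in `region`, each observed only
#' in heterozygotes (`allele_count == carrier_count`), with carrier
#' counts drawn uniformly from `carrier_count_range`. The first two rows
#' are always the two recurrent 4-bp deletions (c.855_858delAGAA and
#' c.861_864delAAGG on the default model), which both fall in the demo
#' assay's reverse-primer interval and share one frameshift consequence.
#'
#' @param seed Integer seed.
#' @param model Transcript model supplying reference alleles (default
#'   [smn_transcript_demo()]).
#' @param region Closed c. interval in which to place variants (default
#'   the demo assay's reverse-primer interval, c.850-876).
#' @param n_variants Total variants (>= 2).
#' @param n_individuals Population sample size recorded on each row.
#' @param carrier_count_range Inclusive range for carrier counts.
#' @return Tibble with the variant-table columns (`variant_id`, `hgvs_c`,
#'   `population`, `allele_count`, `carrier_count`, `n_individuals`,
#'   `annotation_flags`).
#' @export
make_variant_table <- function(seed, model = smn_transcript_demo(),
                               region = c(850L, 876L), n_variants = 15L,
                               n_individuals = 589724L,
                               carrier_count_range = c(1L, 50L)) {
  stopifnot(n_variants >= 2L, region[1] < region[2],
            region[2] <= model$cds_end - model$cds_start + 1L)
  if (region[2] - region[1] + 1L < 8L)
    stop("region too small to place distinct variants", call. = FALSE)
  ref_at <- function(i, j) substr(model$sequence, c_to_index(model, i),
                                  c_to_index(model, j))
  designated <- c(paste0("c.855_858del", ref_at(855, 858)),
                  paste0("c.861_864del", ref_at(861, 864)))
  withr::with_seed(as.integer(seed), {
    hgvs <- designated
    guard <- 0L
    while (length(hgvs) < n_variants) {
      guard <- guard + 1L
      if (guard > 1000L) stop("region too small for ", n_variants,
                              " distinct variants", call. = FALSE)
      kind <- sample(c("sub", "ins", "del4"), 1L, prob = c(0.6, 0.2, 0.2))
      cand <- switch(kind,
        sub = {
          p <- sample(region[1]:region[2], 1L)
          ref <- ref_at(p, p)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
          paste0("c.", p, ref, ">", alt)
        },
        ins = {
          p <- sample(region[1]:(region[2] - 1L), 1L)
          paste0("c.", p, "_", p + 1L, "ins",
                 sample(c("A", "C", "G", "T"), 1L))
        },
        del4 = {
          p <- sample(region[1]:(region[2] - 3L), 1L)
          paste0("c.", p, "_", p + 3L, "del", ref_at(p, p + 3L))
        })
      if (!cand %in% hgvs) hgvs <- c(hgvs, cand)
    }
    carriers <- sample(carrier_count_range[1]:carrier_count_range[2],
                       n_variants, replace = TRUE)
    tibble::tibble(
      variant_id = sprintf("var%02d", seq_len(n_variants)),
      hgvs_c = hgvs,
      population = "EUR",
      allele_count = as.integer(carriers),
      carrier_count = as.integer(carriers),
      n_individuals = as.integer(n_individuals),
      annotation_flags = "")
  })
}

#' Simulate a screened newborn cohort
#'
#' Each newborn draws two alleles independently from {wild-type, SMN1
#' deletion, primer-site VUS} at the given allele frequencies
#' (Hardy-Weinberg random mating). The screening result is then computed
#' mechanistically, not assigned: an allele contributes an amplification
#' signal unless it is the deletion (no template) or a VUS allele whose
#' dropout call against `assay` is dropout-level; a newborn screens
#' positive when neither allele yields signal. del/del newborns are true
#' positives; del/VUS newborns with a dropout-level VUS are the
#' false-positive-like compound heterozygotes this package exists to
#' quantify.
#'
#' @param seed Integer seed.
#' @param n_newborns Cohort size.
#' @param del_allele_freq,vus_allele_freq Allele (not carrier)
#'   frequencies; their sum must be < 0.1.
#' @param assay Assay the VUS is evaluated against.
#' @param model Transcript model for the VUS.
#' @param vus_hgvs The VUS (default the c.855 deletion).
#' @return Tibble with one row per genotype: `genotype`, `n`,
#'   `screen_positive`, `category` (`true_positive`,
#'   `compound_het_dropout`, `other_positive`, `screen_negative`).
#' @export
simulate_newborn_cohort <- function(seed, n_newborns, del_allele_freq,
                                    vus_allele_freq, assay = demo_assay(),
                                    model = smn_transcript_demo(),
                                    vus_hgvs = "c.855_858delAGAA") {
  stopifnot(n_newborns >= 1L, del_allele_freq >= 0, vus_allele_freq >= 0,
            del_allele_freq + vus_allele_freq < 0.1)
  cls <- classify_variant_vs_assay(vus_hgvs, assay)$classification
  vus_drops <- startsWith(cls, "likely_dropout")
  # signal per allele code: 1 wt, 2 del, 3 vus
  signal <- c(TRUE, FALSE, !vus_drops)
  prob <- c(1 - del_allele_freq - vus_allele_freq, del_allele_freq,
            vus_allele_freq)
  withr::with_seed(as.integer(seed), {
    a1 <- sample.int(3L, n_newborns, replace = TRUE, prob = prob)
    a2 <- sample.int(3L, n_newborns, replace = TRUE, prob = prob)
  })
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  allele_names <- c("wt", "del", "vus")
  counts <- table(factor(paste0(allele_names[lo], "/", allele_names[hi]),
                         levels = c("wt/wt", "wt/del", "wt/vus", "del/del",
                                    "del/vus", "vus/vus")))
  tab <- tibble::tibble(genotype = names(counts), n = as.integer(counts))
  geno_alleles <- strsplit(tab$genotype, "/", fixed = TRUE)
  tab$screen_positive <- vapply(geno_alleles, function(g) {
    !any(signal[match(g, allele_names)])
  }, logical(1))
  tab$category <- dplyr::case_when(
    tab$genotype == "del/del" ~ "true_positive",
    tab$genotype == "del/vus" & tab$screen_positive ~ "compound_het_dropout",
    tab$screen_positive ~ "other_positive",
    TRUE ~ "screen_negative")
  tab
}

#' Generate a complete demo scenario on disk
#'
#' Writes every input the pipeline reads -- transcript FASTA and JSON
#' annotations (demo transcript plus the synthetic paralog pair), the
#' demo assay configuration, a seeded variant table, the cohort
#' configuration, and the four exon 5-8 amplicon species -- into `dir`,
#' plus a `scenario.json` manifest recording the seed.
#'
#' @param seed Integer seed; the scenario is reproducible from it.
#' @param dir Output directory (created if needed).
#' @param n_variants Variants in the table (default 15).
#' @return Invisibly, a `synthetic_scenario` list: `seed`, `model`,
#'   `pair`, `assay`, `variant_table`, `cohort`, `paths`.
#' @export
make_scenario <- function(seed, dir, n_variants = 15L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- smn_transcript_demo()
  pair <- make_paralog_pair(seed)
  assay <- demo_assay()
  variants <- make_variant_table(seed, model, n_variants = n_variants)
  cohort <- cohort_preset("eu")
  p <- function(f) file.path(dir, f)
  write_fasta(stats::setNames(
    c(model$sequence, pair$a$sequence, pair$b$sequence),
    c(model$id, pair$a$id, pair$b$id)), p("transcripts.fasta"))
  write_transcript_json(model, p("transcript_SMN1demo.json"))
  write_transcript_json(pair$a, p("transcript_SMN1like.json"))
  write_transcript_json(pair$b, p("transcript_SMN2like.json"))
  write_assay_config(assay, p("assay.tsv"))
  readr::write_tsv(variants, p("variants.tsv"))
  jsonlite::write_json(unclass(cohort), p("cohort.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  write_fasta(paralog_amplicons(pair), p("amplicons.fasta"))
  manifest <- list(seed = as.integer(seed),
                   exon7_tag = pair$exon7_tag,
                   exon8_window = pair$exon8_window,
                   files = c("transcripts.fasta", "transcript_SMN1demo.json",
                             "transcript_SMN1like.json",
                             "transcript_SMN2like.json", "assay.tsv",
                             "variants.tsv", "cohort.json",
                             "amplicons.fasta"))
  jsonlite::write_json(manifest, p("scenario.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(structure(list(seed = as.integer(seed), model = model,
                           pair = pair, assay = assay,
                           variant_table = variants, cohort = cohort,
                           paths = vapply(manifest$files, p, character(1))),
                      class = "synthetic_scenario"))
}
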