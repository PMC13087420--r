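#' Parse HGVS c. descriptions of small coding variants
#'
#' Supports the small-variant grammar used throughout the package:
#' substitutions (`c.863G>T`), deletions (`c.855_858delAGAA`, `c.855del`),
#' insertions with the flanking-pair convention (`c.861_862insT`),
#' duplications (`c.10_12dup`) and deletion-insertions
#' (`c.10_12delinsAT`). Positions are coding (`c.`) positions; intronic
#' offsets, inversions and repeat notation are rejected with an error
#' naming the offending token. No normalisation is performed: variants
#' are represented exactly as written.
#'
#' @param text Character vector of HGVS c. descriptions.
#' @return A tibble with one row per description and columns `raw`,
#'   `kind` (substitution/deletion/insertion/duplication/delins),
#'   `start_c`, `end_c`, `ref_allele`, `alt_allele`.
#' @examples
#' parse_hgvs_c(c("c.855_858delAGAA", "c.861_862insT", "c.863G>T"))
#' @export
parse_hgvs_c <- function(text) {
  rows <- lapply(text, parse_hgvs_c_one)
  dplyr::bind_rows(rows)
}

parse_hgvs_c_one <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  t <- trimws(text)
  if (grepl("[+-]", sub("^c\\.", "", t)))
    stop("unsupported HGVS position with intronic offset in '", t, "'",
         call. = FALSE)
  row <- function(kind, start_c, end_c, ref = "", alt = "") {
    tibble::tibble(raw = t, kind = kind,
                   start_c = as.integer(start_c), end_c = as.integer(end_c),
                   ref_allele = ref, alt_allele = alt)
  }
  m <- regmatches(t, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", t))[[1]]
  if (length(m)) {
    if (m[3] == m[4]) stop("substitution ref and alt are identical in '",
                           t, "'", call. = FALSE)
    return(row("substitution", m[2], m[2], m[3], m[4]))
  }
  m <- regmatches(t, regexec("^c\\.([0-9]+)(_([0-9]+))?delins([ACGT]+)$", t))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[4])) m[4] else m[2]
    return(row("delins", m[2], end, alt = m[5]))
  }
  m <- regmatches(t, regexec("^c\\.([0-9]+)(_([0-9]+))?del([ACGT]*)$", t))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[4])) m[4] else m[2]
    v <- row("deletion", m[2], end, ref = m[5])
    if (nzchar(m[5]) &&
        nchar(m[5]) != v$end_c - v$start_c + 1L)
      stop("deleted allele '", m[5], "' length does not match span ",
           v$start_c, "_", v$end_c, " in '", t, "'", call. = FALSE)
    if (v$start_c > v$end_c) stop("start > end in '", t, "'", call. = FALSE)
    return(v)
  }
  m <- regmatches(t, regexec("^c\\.([0-9]+)_([0-9]+)ins([ACGT]+)$", t))[[1]]
  if (length(m)) {
    v <- row("insertion", m[2], m[3], alt = m[4])
    if (v$end_c != v$start_c + 1L)
      stop("insertion must use flanking positions n_(n+1) in '", t, "'",
           call. = FALSE)
    return(v)
  }
  m <- regmatches(t, regexec("^c\\.([0-9]+)(_([0-9]+))?dup([ACGT]*)$", t))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[4])) m[4] else m[2]
    v <- row("duplication", m[2], end, ref = m[5])
    if (v$start_c > v$end_c) stop("start > end in '", t, "'", call. = FALSE)
    return(v)
  }
  stop("cannot parse HGVS description '", t,
       "' (supported: sub, del, ins, dup, delins on c. coding positions)",
       call. = FALSE)
}

variant_row <- function(var) {
  if (is.character(var)) var <- parse_hgvs_c_one(var)
  var <- tibble::as_tibble(var)
  stopifnot(nrow(var) == 1L)
  var
}

#' Apply a small variant to a transcript sequence
#'
#' Edits the transcript of `model` according to an HGVS c. variant.
#' When the description states a reference allele (e.g. the `AGAA` in
#' `c.855_858delAGAA`) the transcript bases at those positions must match
#' it exactly; a mismatch raises an error reporting expected vs observed
#' bases. This is the primary defence against coordinate bugs.
#'
#' @param model A [transcript_model()].
#' @param var An HGVS string or a one-row tibble from [parse_hgvs_c()].
#' @return The full mutated transcript string.
#' @export
apply_variant <- function(model, var) {
  var <- variant_row(var)
  seq <- model$sequence
  i <- c_to_index(model, var$start_c)
  j <- c_to_index(model, var$end_c)
  segment <- substr(seq, i, j)
  check_ref <- function(expected) {
    if (nzchar(expected) && segment != expected)
      stop("reference mismatch at c.", var$start_c, "_", var$end_c,
           ": expected '", expected, "', transcript has '", segment, "'",
           call. = FALSE)
  }
  switch(var$kind,
    substitution = {
      check_ref(var$ref_allele)
      paste0(substr(seq, 1L, i - 1L), var$alt_allele,
             substr(seq, i + 1L, nchar(seq)))
    },
    deletion = {
      check_ref(var$ref_allele)
      paste0(substr(seq, 1L, i - 1L), substr(seq, j + 1L, nchar(seq)))
    },
    insertion = {
      # flanking convention: insert between start_c and end_c = start_c + 1
      paste0(substr(seq, 1L, i), var$alt_allele,
             substr(seq, i + 1L, nchar(seq)))
    },
    duplication = {
      check_ref(var$ref_allele)
      paste0(substr(seq, 1L, j), segment, substr(seq, j + 1L, nchar(seq)))
    },
    delins = {
      paste0(substr(seq, 1L, i - 1L), var$alt_allele,
             substr(seq, j + 1L, nchar(seq)))
    },
    stop("unknown variant kind '", var$kind, "'", call. = FALSE))
}

# net length change of a variant (len(alt) - len(ref))
variant_length_change <- function(var) {
  var <- variant_row(var)
  span <- var$end_c - var$start_c + 1L
  switch(var$kind,
         substitution = 0L,
         deletion = -span,
         insertion = nchar(var$alt_allele),
         duplication = span,
         delins = nchar(var$alt_allele) - span)
}

# Translate consecutive codons into a single-letter amino-acid vector
# (stops as "*"); standard genetic code from Biostrings. Trailing partial
# codons are dropped.
translate_codons <- function(seq) {
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return(character(0))
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1]
    stop("codon ", bad, " ('", codons[bad], "') contains non-ACGT bases",
         call. = FALSE)
  }
  aa
}

#' Translate a CDS with the standard genetic code
#'
#' Translation starts at position 1 and stops at (and excludes) the first
#' stop codon.
#'
#' @param cds Nucleotide string, length >= 3.
#' @return A list with `peptide` (single-letter amino-acid string) and
#'   `stop_found` (logical).
#' @examples
#' translate_cds("ATGGCTAGAAGGCATTGA")  # MARRH, stop found
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) >= 3L)
  aa <- translate_codons(cds)
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) list(peptide = paste(aa, collapse = ""),
                           stop_found = FALSE)
  else list(peptide = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
            stop_found = TRUE)
}

aa3 <- function(aa1) {
  ifelse(aa1 == "*", "Ter", unname(Biostrings::AMINO_ACID_CODE[aa1]))
}

#' Format a protein consequence as an HGVS p. string
#'
#' Pure function of the consequence fields: `p.` + reference residue +
#' position, then the alternate residue for missense, `Ter` for nonsense,
#' `<alt>fsTer<offset>` for frameshift (`fsTer?` when no new stop is
#' reached before the transcript ends) and `=` for synonymous.
#' Three-letter amino-acid codes throughout.
#'
#' @param kind One of `synonymous`, `missense`, `nonsense`, `frameshift`,
#'   `no_stop_found`.
#' @param ref_aa,alt_aa Three-letter residue codes.
#' @param first_residue 1-based codon ordinal of the first affected residue.
#' @param ter_offset For frameshift, ordinal of the new stop counting the
#'   first changed residue as 1.
#' @return HGVS p. string.
#' @examples
#' format_p("frameshift", "Arg", 288, "Ala", 5)  # "p.Arg288AlafsTer5"
#' @export
format_p <- function(kind, ref_aa, first_residue, alt_aa = NA_character_,
                     ter_offset = NA_integer_) {
  head <- paste0("p.", ref_aa, first_residue)
  switch(kind,
         synonymous = paste0(head, "="),
         missense = paste0(head, alt_aa),
         nonsense = paste0(head, "Ter"),
         frameshift = paste0(head, alt_aa, "fsTer", ter_offset),
         no_stop_found = paste0(head, alt_aa, "fsTer?"),
         stop("cannot format consequence kind '", kind, "'", call. = FALSE))
}

#' Derive the protein consequence of a coding variant
#'
#' The consequence call is made by direct comparison of translated
#' proteins, not by case analysis on the variant description: (1) apply
#' the variant to the transcript; (2) translate the reference CDS;
#' (3) translate the mutated sequence from the start codon through the end
#' of the transcript, so a shifted frame reads into the 3'UTR; (4) locate
#' the first differing residue. A frame-preserving change is synonymous,
#' missense/nonsense (single residue) or an in-frame indel; a
#' frame-shifting change is reported with fsTer nomenclature, where the
#' new stop is counted with the first changed residue as position 1. A
#' shifted frame whose first changed codon is already a stop is reported
#' as nonsense (`p.XxxNTer`), per HGVS convention. If the shifted frame
#' reaches the end of the transcript without a stop, the kind is
#' `no_stop_found`.
#'
#' @inheritParams apply_variant
#' @return One-row tibble: `kind`, `first_residue`, `ref_aa`, `alt_aa`,
#'   `ter_offset`, `hgvs_p`.
#' @examples
#' toy <- transcript_model("toy", "ATGGCTAGAAGGCATTGAATAAGG",
#'                         cds_start = 1, cds_end = 18,
#'                         exons = rbind(c(1, 24)))
#' protein_consequence(toy, "c.7_10delAGAA")  # p.Arg3GlyfsTer4
#' @export
protein_consequence <- function(model, var) {
  var <- variant_row(var)
  mutated <- apply_variant(model, var)
  ref_aa_full <- translate_codons(cds_sequence(model))
  mut_tail <- substr(mutated, model$cds_start, nchar(mutated))
  mut_aa_full <- translate_codons(mut_tail)
  mut_stop <- which(mut_aa_full == "*")[1]
  mut_aa <- if (is.na(mut_stop)) mut_aa_full
            else mut_aa_full[seq_len(mut_stop)]

  len <- max(length(ref_aa_full), length(mut_aa))
  pad <- function(x) c(x, rep("", len - length(x)))
  diffs <- which(pad(ref_aa_full) != pad(mut_aa))

  out <- function(kind, first_residue, ref_aa = NA_character_,
                  alt_aa = NA_character_, ter_offset = NA_integer_,
                  hgvs_p = NULL) {
    if (is.null(hgvs_p))
      hgvs_p <- format_p(kind, ref_aa, first_residue, alt_aa, ter_offset)
    tibble::tibble(kind = kind, first_residue = as.integer(first_residue),
                   ref_aa = ref_aa, alt_aa = alt_aa,
                   ter_offset = as.integer(ter_offset), hgvs_p = hgvs_p)
  }

  delta <- variant_length_change(var)
  if (length(diffs) == 0L) {
    pos <- (var$start_c - 1L) %/% 3L + 1L
    pos <- min(pos, length(ref_aa_full))
    return(out("synonymous", pos, ref_aa = aa3(ref_aa_full[pos])))
  }
  i <- diffs[1]
  if (i > length(ref_aa_full))
    stop("variant alters translation only beyond the reference stop; ",
         "extension nomenclature is not supported", call. = FALSE)
  ref_i <- ref_aa_full[i]
  mut_i <- if (i <= length(mut_aa)) mut_aa[i] else ""

  if (delta %% 3L == 0L) {
    if (mut_i == "*")
      return(out("nonsense", i, ref_aa = aa3(ref_i), alt_aa = "Ter"))
    if (length(diffs) == 1L && length(ref_aa_full) == length(mut_aa))
      return(out("missense", i, ref_aa = aa3(ref_i), alt_aa = aa3(mut_i)))
    return(inframe_indel_consequence(ref_aa_full, mut_aa, i))
  }

  # frame-shifting change
  if (mut_i == "*")
    return(out("nonsense", i, ref_aa = aa3(ref_i), alt_aa = "Ter"))
  if (is.na(mut_stop))
    return(out("no_stop_found", i, ref_aa = aa3(ref_i), alt_aa = aa3(mut_i)))
  out("frameshift", i, ref_aa = aa3(ref_i), alt_aa = aa3(mut_i),
      ter_offset = mut_stop - i + 1L)
}

# In-frame multi-residue change: name by trimming the common prefix and
# suffix (p.del / p.ins / p.delins forms). Kept distinct from frameshift
# so frame-preserving variants never carry fsTer nomenclature.
inframe_indel_consequence <- function(ref_aa_full, mut_aa, i) {
  nr <- length(ref_aa_full); nm <- length(mut_aa)
  s <- 0L
  while (s < min(nr, nm) - i + 1L &&
         ref_aa_full[nr - s] == mut_aa[nm - s]) s <- s + 1L
  j <- nr - s          # last changed ref residue
  k <- nm - s          # last changed mut residue
  ref_span <- if (j >= i) ref_aa_full[i:j] else character(0)
  mut_span <- if (k >= i) mut_aa[i:k] else character(0)
  label <- function(idx) paste0(aa3(ref_aa_full[idx]), idx)
  hgvs_p <-
    if (length(mut_span) == 0L) {
      if (i == j) paste0("p.", label(i), "del")
      else paste0("p.", label(i), "_", label(j), "del")
    } else if (length(ref_span) == 0L) {
      paste0("p.", label(i - 1L), "_", label(i), "ins",
             paste(aa3(mut_span), collapse = ""))
    } else {
      left <- if (i == j) paste0("p.", label(i))
              else paste0("p.", label(i), "_", label(j))
      paste0(left, "delins", paste(aa3(mut_span), collapse = ""))
    }
  tibble::tibble(kind = "inframe_indel", first_residue = as.integer(i),
                 ref_aa = aa3(ref_aa_full[min(i, nr)]),
                 alt_aa = if (length(mut_span)) aa3(mut_span[1]) else NA_character_,
                 ter_offset = NA_integer_, hgvs_p = hgvs_p)
}

#' Annotate a variant table with protein consequences
#'
#' Data-frame-first verb: takes any tibble with an `hgvs_c` column and
#' returns it with consequence columns appended, one row per input row.
#'
#' @param variants Tibble with at least an `hgvs_c` column.
#' @param model A [transcript_model()].
#' @return The input tibble with `kind`, `first_residue`, `ref_aa`,
#'   `alt_aa`, `ter_offset`, `hgvs_p` columns added.
#' @export
predict_consequences <- function(variants, model) {
  stopifnot("hgvs_c" %in% names(variants))
  cons <- dplyr::bind_rows(lapply(variants$hgvs_c, function(h)
    protein_consequence(model, h)))
  dplyr::bind_cols(tibble::as_tibble(variants), cons)
}

#' Read a variant frequency table
#'
#' Tab-separated with columns `variant_id`, `hgvs_c`, `population`,
#' `allele_count`, `carrier_count`, `n_individuals` and free-text
#' `annotation_flags` (e.g. `exon7_skipping_reported` for variants whose
#' splice impact is known from experiment; the package never predicts
#' splice effects).
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_variant_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           variant_id = readr::col_character(),
                           hgvs_c = readr::col_character(),
                           population = readr::col_character(),
                           allele_count = readr::col_integer(),
                           carrier_count = readr::col_integer(),
                           n_individuals = readr::col_integer(),
                           annotation_flags = readr::col_character()))
  required <- c("variant_id", "hgvs_c", "population", "allele_count",
                "carrier_count", "n_individuals")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("variant table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(tab$carrier_count > tab$allele_count |
                 tab$allele_count > 2L * tab$n_individuals)
  if (length(bad))
    stop("variant table row ", bad[1],
         ": need carrier_count <= allele_count <= 2 * n_individuals",
         call. = FALSE)
  tab
}
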