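#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition motif, written 5'->3'.
#' @param cut_offset Bases after the motif start at which the strand is
#'   cut (0 to motif length).
#' @return Object of class `restriction_enzyme`.
#' @examples
#' dde_i()  # C^TNAG
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  stopifnot(nzchar(recognition),
            cut_offset >= 0, cut_offset <= nchar(recognition))
  if (!all(strsplit(recognition, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)))
    stop("recognition motif must use IUPAC nucleotide codes", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  motif <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                  substr(x$recognition, x$cut_offset + 1,
                         nchar(x$recognition)))
  cat(sprintf("<restriction_enzyme> %s (%s)\n", x$name, motif))
  invisible(x)
}

#' DdeI: C^TNAG
#'
#' The enzyme used to tell SMN1 from SMN2 transcripts: SMN2 carries a
#' paralogous DdeI site in exon 8 that SMN1 lacks, so digestion cuts
#' SMN2-derived amplicons specifically.
#'
#' @return A [restriction_enzyme()].
#' @export
dde_i <- function() restriction_enzyme("DdeI", "CTNAG", 1L)

# Is a motif its own reverse complement (IUPAC-aware)? If so a
# single-strand scan finds every site.
motif_is_palindromic <- function(recognition) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(recognition)))
  identical(rc, recognition)
}

#' Find cut positions of an enzyme in a sequence
#'
#' Matches the IUPAC motif (overlapping matches included) and returns cut
#' positions as 0-based indices: a cut at position `k` separates the
#' first `k` bases from the rest. Palindromic motifs (DdeI's CTNAG is its
#' own reverse complement) need only a single-strand scan; asymmetric
#' motifs are additionally scanned on the reverse complement strand and
#' the cuts mapped back to top-strand coordinates.
#'
#' @param seq Uppercase ACGT string.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of 0-based cut positions.
#' @examples
#' find_cut_sites("AACTGAGTT", dde_i())  # 3
#' @export
find_cut_sites <- function(seq, enzyme) {
  stopifnot(is.character(seq), length(seq) == 1L)
  subject <- Biostrings::DNAString(seq)
  hit_starts <- Biostrings::start(Biostrings::matchPattern(
    enzyme$recognition, subject, fixed = FALSE))
  cuts <- hit_starts - 1L + enzyme$cut_offset
  if (!motif_is_palindromic(enzyme$recognition)) {
    w <- nchar(enzyme$recognition)
    rc_hits <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(enzyme$recognition)),
      subject, fixed = FALSE))
    # cut_offset bases after motif start on the bottom strand = that many
    # before the motif end in top-strand coordinates
    cuts <- c(cuts, rc_hits - 1L + (w - enzyme$cut_offset))
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < nchar(seq)]
}

#' Digest a sequence in silico
#'
#' @inheritParams find_cut_sites
#' @return Object of class `digest_result`: `input_length`,
#'   `cut_positions` (0-based) and `fragments` (ordered lengths summing
#'   to the input length).
#' @examples
#' digest_sequence("AACTGAGTT", dde_i())$fragments  # 3 6
#' @export
digest_sequence <- function(seq, enzyme) {
  cuts <- find_cut_sites(seq, enzyme)
  n <- nchar(seq)
  fragments <- diff(c(0L, cuts, n))
  structure(list(input_length = n, cut_positions = cuts,
                 fragments = as.integer(fragments),
                 enzyme = enzyme$name),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s: %d nt -> %d fragment(s): %s\n",
              x$enzyme, x$input_length, length(x$fragments),
              paste(x$fragments, collapse = ", ")))
  invisible(x)
}

#' Digest a set of sequences into a fragment table
#'
#' @param seqs Named character vector (e.g. from [read_fasta()]).
#' @param enzyme A [restriction_enzyme()].
#' @return Tibble with one row per fragment: `record`, `fragment`,
#'   `length`, plus `n_cuts` per record.
#' @export
digest_table <- function(seqs, enzyme) {
  purrr::imap_dfr(seqs, function(s, id) {
    d <- digest_sequence(s, enzyme)
    tibble::tibble(record = id, fragment = seq_along(d$fragments),
                   length = d$fragments, n_cuts = length(d$cut_positions))
  })
}

#' Gel-style plot of digest fragments
#'
#' One lane per record, fragments drawn as bands by length -- the in
#' silico analogue of the agarose gel read-out used to score
#' full-length vs exon-7-skipped SMN transcripts after DdeI digestion.
#'
#' @param object A tibble from [digest_table()] or a single
#'   `digest_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.digest_result <- function(object, ...) {
  tab <- tibble::tibble(record = "input", length = object$fragments)
  plot_digest_lanes(tab)
}

#' @rdname autoplot.digest_result
#' @param table Fragment tibble from [digest_table()].
#' @export
plot_digest_lanes <- function(table) {
  plot_digest_lanes_impl(table)
}

plot_digest_lanes_impl <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$record, y = .data$length)) +
    ggplot2::geom_tile(width = 0.6, height = 4) +
    ggplot2::labs(x = NULL, y = "fragment length (nt)") +
    ggplot2::theme_minimal()
}

#' Classify an SMN-like amplicon by gene and isoform
#'
#' Reproduces the digestion read-out logic: the gene call is made by the
#' enzyme (a cut falling inside the paralogous exon-8 window means the
#' SMN2-like paralog; no cut means SMN1-like), and the isoform call by
#' presence of an exon-7 tag subsequence (present = full length, absent =
#' the exon-7-skipped Delta7 isoform). The amplicon must match one of the
#' four candidate templates (each paralog, full-length or with the
#' exon-7 segment spliced out) as an exact substring up to
#' `max_mismatch` mismatches; otherwise it is unclassifiable.
#'
#' @param amplicon Nucleotide string spanning the exon 5-8 region of one
#'   of the paralogs.
#' @param smn1_model,smn2_model [transcript_model()] paralogs; `exons`
#'   must include an exon 7 to splice out.
#' @param exon7_tag Subsequence present in exon 7 of both paralogs.
#' @param exon8_window Length-2 vector: closed transcript-space interval
#'   (on the full-length models) containing the paralogous cut site.
#' @param enzyme A [restriction_enzyme()], default [dde_i()].
#' @param max_mismatch Allowed mismatches when locating the amplicon on a
#'   template (default 0, exact).
#' @return One-row tibble: `gene` (`SMN1`/`SMN2`), `isoform`
#'   (`FL`/`Delta7`), `template`, `cut_in_window`.
#' @export
classify_transcript <- function(amplicon, smn1_model, smn2_model,
                                exon7_tag, exon8_window, enzyme = dde_i(),
                                max_mismatch = 0L) {
  amplicon <- toupper(amplicon)
  templates <- list()
  for (m in list(smn1_model, smn2_model)) {
    ex7 <- m$exons[7L, ]
    d7 <- paste0(substr(m$sequence, 1L, ex7["start"] - 1L),
                 substr(m$sequence, ex7["end"] + 1L, nchar(m$sequence)))
    templates[[paste0(m$id, ":FL")]] <- list(seq = m$sequence, d7 = FALSE,
                                             ex7 = ex7)
    templates[[paste0(m$id, ":Delta7")]] <- list(seq = d7, d7 = TRUE,
                                                 ex7 = ex7)
  }
  hit <- NULL
  for (nm in names(templates)) {
    t <- templates[[nm]]
    mt <- Biostrings::matchPattern(amplicon, Biostrings::DNAString(t$seq),
                                   max.mismatch = max_mismatch)
    if (length(mt) > 0L) {
      hit <- c(t, list(name = nm, offset = Biostrings::start(mt)[1]))
      break
    }
  }
  if (is.null(hit))
    stop("amplicon matches neither paralog template within ",
         max_mismatch, " mismatch(es); unclassifiable", call. = FALSE)
  # map the exon-8 window (full-length transcript coords) onto the amplicon
  win <- as.integer(exon8_window)
  if (hit$d7) {
    ex7_len <- hit$ex7["end"] - hit$ex7["start"] + 1L
    if (win[1] <= hit$ex7["end"])
      stop("exon8_window must lie downstream of exon 7", call. = FALSE)
    win <- win - ex7_len
  }
  win_local <- win - hit$offset + 1L
  cuts <- find_cut_sites(amplicon, enzyme)
  # a 0-based cut at k severs bases k and k+1; count it as inside the
  # window when the bond lies within [start, end]
  cut_in_window <- any(cuts >= win_local[1] & cuts < win_local[2])
  tibble::tibble(
    gene = if (cut_in_window) "SMN2" else "SMN1",
    isoform = if (grepl(exon7_tag, amplicon, fixed = TRUE)) "FL" else "Delta7",
    template = hit$name,
    cut_in_window = cut_in_window)
}

#' Read an enzyme table
#'
#' TSV with columns `name`, `motif`, `cut_offset`. A table with DdeI is
#' bundled at `system.file("extdata", "enzymes.tsv", package =
#' "smnscreen")`.
#'
#' @param path TSV path; default the bundled table.
#' @return Named list of [restriction_enzyme()] objects.
#' @export
read_enzyme_table <- function(path = system.file("extdata", "enzymes.tsv",
                                                 package = "smnscreen")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("name", "motif", "cut_offset") %in% names(tab)))
  enz <- lapply(seq_len(nrow(tab)), function(i)
    restriction_enzyme(tab$name[i], tab$motif[i], tab$cut_offset[i]))
  stats::setNames(enz, tab$name)
}
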