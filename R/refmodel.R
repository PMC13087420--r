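#' Construct a transcript model
#'
#' A `transcript_model` is the coordinate authority for every other
#' operation in the package: a spliced transcript sequence (5'->3',
#' uppercase ACGT), the CDS bounds within it, an exon tiling, and an
#' optional set of paralog-discriminating positions (the bases that tell
#' this transcript apart from its near-identical copy gene, as SMN1 and
#' SMN2 differ at a handful of positions).
#'
#' All HGVS-facing positions are 1-based closed coding (`c.`) positions;
#' internal transcript positions are 1-based as well, and the conversion
#' between the two frames happens only in [c_to_index()] and
#' [index_to_c()].
#'
#' @param id Transcript identifier.
#' @param sequence Nucleotide string, transcript space, 5'->3'. Lowercase
#'   input is uppercased.
#' @param cds_start 1-based transcript position of the A of the start codon.
#' @param cds_end 1-based transcript position of the last base of the stop
#'   codon.
#' @param exons Two-column matrix or data frame of 1-based closed
#'   `(start, end)` intervals in transcript space; must tile
#'   `[1, nchar(sequence)]` contiguously with no gaps or overlaps.
#' @param discriminating_positions Optional tibble/data frame with columns
#'   `c_pos` (HGVS `c.` position as character, e.g. `"840"` or `"*239"`)
#'   and `base` (the base this transcript carries there).
#'
#' @return An object of class `transcript_model`.
#' @examples
#' m <- transcript_model("toy", "AAATGGCTAGATGATT", cds_start = 3,
#'                       cds_end = 14, exons = rbind(c(1, 8), c(9, 16)))
#' exon_of(m, 10)
#' @export
transcript_model <- function(id, sequence, cds_start, cds_end, exons,
                             discriminating_positions = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (is.null(discriminating_positions)) {
    discriminating_positions <- tibble::tibble(c_pos = character(),
                                               base = character())
  } else {
    discriminating_positions <- tibble::as_tibble(discriminating_positions)
    discriminating_positions$c_pos <- as.character(discriminating_positions$c_pos)
  }
  model <- structure(
    list(id = id, sequence = sequence,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         exons = exons,
         discriminating_positions = discriminating_positions),
    class = "transcript_model")
  validate_transcript_model(model)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d nt, CDS %d..%d (%d codons), %d exons\n",
              x$id, nchar(x$sequence), x$cds_start, x$cds_end,
              (x$cds_end - x$cds_start + 1L) %/% 3L, nrow(x$exons)))
  if (nrow(x$discriminating_positions) > 0) {
    cat("  discriminating positions: ",
        paste0("c.", x$discriminating_positions$c_pos,
               x$discriminating_positions$base, collapse = ", "), "\n")
  }
  invisible(x)
}

validate_transcript_model <- function(model) {
  n <- nchar(model$sequence)
  if (grepl("[^ACGT]", model$sequence))
    stop("transcript '", model$id, "' contains non-ACGT characters",
         call. = FALSE)
  cds_len <- model$cds_end - model$cds_start + 1L
  if (cds_len <= 0L || cds_len %% 3L != 0L)
    stop("CDS length must be a positive multiple of 3 (got ", cds_len, ")",
         call. = FALSE)
  if (model$cds_start < 1L || model$cds_end > n)
    stop("CDS bounds outside transcript", call. = FALSE)
  if (substr(model$sequence, model$cds_start, model$cds_start + 2L) != "ATG")
    stop("CDS must begin with ATG", call. = FALSE)
  last_codon <- substr(model$sequence, model$cds_end - 2L, model$cds_end)
  if (!last_codon %in% c("TAA", "TAG", "TGA"))
    stop("CDS must end with a stop codon (got ", last_codon, ")",
         call. = FALSE)
  ex <- model$exons
  if (nrow(ex) < 1L || any(ex[, "start"] > ex[, "end"]))
    stop("invalid exon intervals", call. = FALSE)
  if (ex[1L, "start"] != 1L || ex[nrow(ex), "end"] != n ||
      (nrow(ex) > 1L && any(ex[-1L, "start"] != ex[-nrow(ex), "end"] + 1L)))
    stop("exons must tile [1, ", n, "] contiguously", call. = FALSE)
  if (nrow(model$discriminating_positions) > 0) {
    idx <- vapply(model$discriminating_positions$c_pos,
                  function(p) c_to_index(model, p), integer(1))
    stopifnot(all(idx >= 1L), all(idx <= n))
  }
  model
}

# Parse an HGVS c.-style position token: "855" (coding) or "*12" (3'UTR).
# Intronic offsets (855+3, 856-2) and 5'UTR positions are rejected loudly
# rather than silently mis-mapped.
parse_c_pos <- function(c_pos) {
  c_pos <- as.character(c_pos)
  if (grepl("^\\*[0-9]+$", c_pos)) {
    list(utr3 = TRUE, n = as.integer(sub("^\\*", "", c_pos)))
  } else if (grepl("^[0-9]+$", c_pos)) {
    n <- as.integer(c_pos)
    if (n < 1L) stop("coding position must be >= 1", call. = FALSE)
    list(utr3 = FALSE, n = n)
  } else if (grepl("[+-]", c_pos)) {
    stop("intronic offset positions (", c_pos,
         ") are not supported in transcript space", call. = FALSE)
  } else {
    stop("cannot parse c. position '", c_pos, "'", call. = FALSE)
  }
}

#' Convert an HGVS c. position to a transcript position
#'
#' Accepts coding positions (`"855"`, `855`) and 3'UTR positions
#' (`"*12"`). Intronic offsets are rejected: the model is spliced
#' transcript space and has no introns to offset into.
#'
#' @param model A [transcript_model()].
#' @param c_pos A single c. position (number or character).
#' @return 1-based transcript index.
#' @export
c_to_index <- function(model, c_pos) {
  p <- parse_c_pos(c_pos)
  idx <- if (p$utr3) model$cds_end + p$n else model$cds_start + p$n - 1L
  if (idx > nchar(model$sequence))
    stop("position c.", c_pos, " lies beyond the end of transcript '",
         model$id, "'", call. = FALSE)
  as.integer(idx)
}

#' Convert a transcript position back to an HGVS c. position
#'
#' Inverse of [c_to_index()] for positions at or after the start codon;
#' positions in the 3'UTR are returned in `*n` form.
#'
#' @inheritParams c_to_index
#' @param index 1-based transcript position.
#' @return Character c. position.
#' @export
index_to_c <- function(model, index) {
  index <- as.integer(index)
  stopifnot(index >= 1L, index <= nchar(model$sequence))
  if (index > model$cds_end) paste0("*", index - model$cds_end)
  else if (index >= model$cds_start) as.character(index - model$cds_start + 1L)
  else stop("position ", index, " lies in the 5'UTR; no c. form supported",
            call. = FALSE)
}

#' Exon ordinal containing a c. position
#'
#' @inheritParams c_to_index
#' @return 1-based exon ordinal.
#' @export
exon_of <- function(model, c_pos) {
  idx <- c_to_index(model, c_pos)
  unname(which(model$exons[, "start"] <= idx &
                 model$exons[, "end"] >= idx)[1L])
}

iupac_chars <- function() {
  c(names(Biostrings::IUPAC_CODE_MAP), "-")
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around Biostrings parsing that uppercases sequences,
#' validates them against the IUPAC nucleotide alphabet, and reports the
#' offending record and offset on failure. Ambiguity codes are kept but
#' flagged with a message.
#'
#' @param path Path to a FASTA file (possibly multi-record, line-wrapped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file '", path, "'",
                              call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  ok_chars <- iupac_chars()
  for (i in seq_along(seqs)) {
    letters_i <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!letters_i %in% ok_chars)
    if (length(bad) > 0)
      stop("record '", names(seqs)[i], "' has non-nucleotide character '",
           letters_i[bad[1]], "' at offset ", bad[1], call. = FALSE)
    amb <- which(!letters_i %in% c("A", "C", "G", "T"))
    if (length(amb) > 0)
      message("record '", names(seqs)[i], "' contains ", length(amb),
              " IUPAC ambiguity base(s)")
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write a transcript model as JSON
#'
#' The on-disk annotation holds everything except the sequence itself:
#' `{id, cds_start, cds_end, exons: [[s,e],...],
#'   discriminating_positions: [[c_pos, base],...]}`.
#' The sequence is supplied separately (FASTA) and joined by id.
#'
#' @param model A [transcript_model()].
#' @param path JSON path.
#' @param sequences Named character vector (e.g. from [read_fasta()])
#'   holding the sequence for the annotated id.
#' @return For the reader, a [transcript_model()]; for the writer, `path`.
#' @export
write_transcript_json <- function(model, path) {
  dp <- model$discriminating_positions
  obj <- list(id = model$id,
              cds_start = model$cds_start, cds_end = model$cds_end,
              exons = unname(lapply(seq_len(nrow(model$exons)), function(i)
                c(model$exons[i, "start"], model$exons[i, "end"]))),
              discriminating_positions = unname(lapply(
                seq_len(nrow(dp)), function(i) list(dp$c_pos[i], dp$base[i]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transcript_json
#' @export
read_transcript_json <- function(path, sequences) {
  obj <- jsonlite::read_json(path)
  if (!obj$id %in% names(sequences))
    stop("no sequence named '", obj$id, "' supplied for annotation '",
         path, "'", call. = FALSE)
  exons <- do.call(rbind, lapply(obj$exons, function(e)
    c(as.integer(e[[1]]), as.integer(e[[2]]))))
  dp <- if (length(obj$discriminating_positions) > 0) {
    tibble::tibble(
      c_pos = vapply(obj$discriminating_positions, function(d)
        as.character(d[[1]]), character(1)),
      base = vapply(obj$discriminating_positions, function(d)
        as.character(d[[2]]), character(1)))
  } else NULL
  transcript_model(obj$id, sequences[[obj$id]],
                   cds_start = obj$cds_start, cds_end = obj$cds_end,
                   exons = exons, discriminating_positions = dp)
}

#' Extract the CDS of a transcript model
#'
#' @inheritParams c_to_index
#' @return Nucleotide string from start codon through stop codon.
#' @export
cds_sequence <- function(model) {
  substr(model$sequence, model$cds_start, model$cds_end)
}
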