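# Shared fixtures and independent oracles. The oracles deliberately take
# a different route from the package: translation via seqinr, motif
# search via regex expansion, and variant application via direct string
# surgery on the parsed fields.

# The 24-nt toy transcript: CDS 1-18 (protein MARRH), 6-nt 3'UTR.
toy_model <- function() {
  transcript_model("toy", "ATGGCTAGAAGGCATTGAATAAGG",
                   cds_start = 1, cds_end = 18, exons = rbind(c(1, 24)))
}

# A random valid transcript model: UTRs, a stop-free CDS body, one exon.
random_model <- function(n_codons = sample(12:40, 1), utr3_len = NULL) {
  ok <- setdiff(as.vector(outer(as.vector(outer(
    c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0)), c("TAA", "TAG", "TGA"))
  utr5 <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), replace = TRUE),
                collapse = "")
  if (is.null(utr3_len)) utr3_len <- sample(0:20, 1)
  utr3 <- paste(sample(c("A", "C", "G", "T"), utr3_len, replace = TRUE),
                collapse = "")
  cds <- paste0("ATG", paste(sample(ok, n_codons - 2, replace = TRUE),
                             collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  seq <- paste0(utr5, cds, utr3)
  transcript_model("rnd", seq, cds_start = nchar(utr5) + 1,
                   cds_end = nchar(utr5) + 3 * n_codons,
                   exons = rbind(c(1, nchar(seq))))
}

# Random small variant inside the CDS, away from the start and stop
# codons so consequences stay within supported nomenclature.
random_variant <- function(model) {
  cds_len <- model$cds_end - model$cds_start + 1
  lo <- 4
  hi <- cds_len - 9
  kind <- sample(c("sub", "del", "ins", "dup"), 1)
  base_at <- function(p) substr(model$sequence,
                                c_to_index(model, p), c_to_index(model, p))
  switch(kind,
    sub = {
      p <- sample(lo:hi, 1)
      ref <- base_at(p)
      paste0("c.", p, ref, ">", sample(setdiff(c("A", "C", "G", "T"), ref), 1))
    },
    del = {
      w <- sample(1:4, 1)
      p <- sample(lo:(hi - w + 1), 1)
      if (w == 1) paste0("c.", p, "del")
      else paste0("c.", p, "_", p + w - 1, "del")
    },
    ins = {
      p <- sample(lo:hi, 1)
      paste0("c.", p, "_", p + 1, "ins",
             paste(sample(c("A", "C", "G", "T"), sample(1:2, 1),
                          replace = TRUE), collapse = ""))
    },
    dup = {
      w <- sample(1:4, 1)
      p <- sample(lo:(hi - w + 1), 1)
      if (w == 1) paste0("c.", p, "dup")
      else paste0("c.", p, "_", p + w - 1, "dup")
    })
}

# Brute-force consequence oracle: apply the parsed variant by direct
# string surgery, translate reference and mutant with seqinr, scan for
# the first differing residue.
oracle_consequence <- function(model, hgvs) {
  v <- parse_hgvs_c(hgvs)
  seq <- model$sequence
  i <- model$cds_start + v$start_c - 1
  j <- model$cds_start + v$end_c - 1
  mut <- switch(v$kind,
    substitution = paste0(substr(seq, 1, i - 1), v$alt_allele,
                          substr(seq, i + 1, nchar(seq))),
    deletion = paste0(substr(seq, 1, i - 1), substr(seq, j + 1, nchar(seq))),
    insertion = paste0(substr(seq, 1, i), v$alt_allele,
                       substr(seq, i + 1, nchar(seq))),
    duplication = paste0(substr(seq, 1, j), substr(seq, i, j),
                         substr(seq, j + 1, nchar(seq))),
    delins = paste0(substr(seq, 1, i - 1), v$alt_allele,
                    substr(seq, j + 1, nchar(seq))))
  tr <- function(s) {
    n <- nchar(s) %/% 3
    if (n == 0) return(character(0))
    seqinr::translate(strsplit(substr(s, 1, 3 * n), "")[[1]])
  }
  p_ref <- tr(substr(seq, model$cds_start, model$cds_end))
  p_mut <- tr(substr(mut, model$cds_start, nchar(mut)))
  stop_at <- which(p_mut == "*")[1]
  if (!is.na(stop_at)) p_mut <- p_mut[seq_len(stop_at)]
  len <- max(length(p_ref), length(p_mut))
  pad <- function(x) c(x, rep(".", len - length(x)))
  d <- which(pad(p_ref) != pad(p_mut))
  delta <- switch(v$kind, substitution = 0,
                  deletion = -(v$end_c - v$start_c + 1),
                  insertion = nchar(v$alt_allele),
                  duplication = v$end_c - v$start_c + 1,
                  delins = nchar(v$alt_allele) - (v$end_c - v$start_c + 1))
  if (length(d) == 0)
    return(list(kind = "synonymous", first_residue = NA, ter_offset = NA))
  i1 <- d[1]
  mut_i <- if (i1 <= length(p_mut)) p_mut[i1] else "."
  if (delta %% 3 == 0) {
    if (mut_i == "*")
      return(list(kind = "nonsense", first_residue = i1, ter_offset = NA))
    if (length(d) == 1 && length(p_ref) == length(p_mut))
      return(list(kind = "missense", first_residue = i1, ter_offset = NA))
    return(list(kind = "inframe_indel", first_residue = i1, ter_offset = NA))
  }
  if (mut_i == "*")
    return(list(kind = "nonsense", first_residue = i1, ter_offset = NA))
  if (is.na(stop_at))
    return(list(kind = "no_stop_found", first_residue = i1, ter_offset = NA))
  list(kind = "frameshift", first_residue = i1,
       ter_offset = stop_at - i1 + 1)
}

# Regex oracle for enzyme cut sites: expand IUPAC codes, scan top strand
# and (for non-palindromic motifs) the reverse complement.
oracle_cut_sites <- function(seq, motif, cut_offset) {
  expand <- function(m) paste0(vapply(strsplit(m, "")[[1]], function(ch) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
  scan <- function(s, pat) {
    hits <- integer(0)
    w <- nchar(motif)
    for (k in seq_len(nchar(s) - w + 1))
      if (grepl(paste0("^", pat), substr(s, k, k + w - 1))) hits <- c(hits, k)
    hits
  }
  cuts <- scan(seq, expand(motif)) - 1 + cut_offset
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  if (rc(motif) != motif) {
    w <- nchar(motif)
    cuts <- c(cuts, scan(seq, expand(rc(motif))) - 1 + (w - cut_offset))
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0 & cuts < nchar(seq)]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
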