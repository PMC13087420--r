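#' Define a PCR/qPCR assay by its annealing intervals
#'
#' An assay is a set of components (forward primer, reverse primer,
#' probe), each with a 1-based closed interval in transcript `c.`
#' coordinate space. For primers, the 3' terminus matters: a mismatch
#' near the extending end is far more likely to abolish amplification
#' than one mid-oligo. In transcript orientation the forward primer's 3'
#' end is the right boundary of its interval and the reverse primer's 3'
#' end is the left boundary; probes have no 3' polarity.
#'
#' @param name Assay name (metadata only).
#' @param components Tibble/data frame with columns `role`
#'   (`forward_primer`, `reverse_primer`, `probe`), `start_c`, `end_c`.
#' @return Object of class `assay_definition`.
#' @examples
#' demo_assay()
#' @export
assay_definition <- function(name, components) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("role", "start_c", "end_c") %in% names(components)))
  ok_roles <- c("forward_primer", "reverse_primer", "probe")
  if (!all(components$role %in% ok_roles))
    stop("component role must be one of: ",
         paste(ok_roles, collapse = ", "), call. = FALSE)
  components$start_c <- as.integer(components$start_c)
  components$end_c <- as.integer(components$end_c)
  if (any(components$start_c > components$end_c))
    stop("component intervals must satisfy start_c <= end_c", call. = FALSE)
  components$three_prime_c <- dplyr::case_when(
    components$role == "forward_primer" ~ components$end_c,
    components$role == "reverse_primer" ~ components$start_c,
    TRUE ~ NA_integer_)
  structure(list(name = name, components = components),
            class = "assay_definition")
}

#' @export
print.assay_definition <- function(x, ...) {
  cat(sprintf("<assay_definition> %s (%d components)\n", x$name,
              nrow(x$components)))
  print(x$components)
  invisible(x)
}

#' Bundled demonstration SMN NBS-style assay
#'
#' An illustrative exon-7 amplicon assay whose reverse-primer interval
#' (c.850-876) contains both recurrent 4-bp deletions handled by this
#' package. The genomic primer coordinates of commercial newborn-screening
#' kits are proprietary and unpublished; this assay reproduces the
#' mechanism (primer-site overlap), not any kit's true coordinates.
#'
#' @return An [assay_definition()].
#' @export
demo_assay <- function() {
  assay_definition("demo-smn-exon7-nbs", tibble::tibble(
    role = c("forward_primer", "probe", "reverse_primer"),
    start_c = c(780L, 815L, 850L),
    end_c = c(804L, 840L, 876L)))
}

#' Overlap length of two closed intervals
#'
#' `max(0, min(ends) - max(starts) + 1)`; adjacency is not overlap.
#' Vectorised over all arguments.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds (1-based closed).
#' @return Integer vector of overlap lengths.
#' @examples
#' overlap_bases(855, 858, 850, 876)  # 4
#' @export
overlap_bases <- function(a_start, a_end, b_start, b_end) {
  stopifnot(all(a_start <= a_end), all(b_start <= b_end))
  as.integer(pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L))
}

# c.-space footprint of a variant for overlap purposes; insertions use
# their flanking pair.
variant_span <- function(var) {
  var <- variant_row(var)
  c(var$start_c, var$end_c)
}

#' Classify a variant's predicted effect on one assay
#'
#' Rule cascade, applied in order: (1) a variant overlapping no component
#' is `no_overlap`; (2) any indel (deletion, insertion, duplication,
#' delins) overlapping any component is `likely_dropout_indel` -- an
#' indel under a primer or probe distorts annealing along its whole
#' footprint; (3) a substitution within `three_prime_window` bases of a
#' primer's 3' terminus (terminal base included) is
#' `likely_dropout_3prime_substitution`; (4) any other overlapping
#' substitution, including probe hits, is `at_risk_substitution` --
#' single internal mismatches often still amplify/report. The component
#' reported is the one with maximal overlap; ties resolve
#' forward_primer, then reverse_primer, then probe.
#'
#' @param var HGVS string or one-row variant tibble.
#' @param assay An [assay_definition()].
#' @param three_prime_window Number of 3'-terminal primer bases treated as
#'   dropout-critical for substitutions (default 5, a standard PCR rule
#'   of thumb).
#' @param variant_id Identifier carried into the call.
#' @return One-row tibble (a dropout call): `variant_id`, `assay_name`,
#'   `component_hit`, `overlap_bases`, `classification`, `rationale`.
#' @export
classify_variant_vs_assay <- function(var, assay, three_prime_window = 5L,
                                      variant_id = NULL) {
  var <- variant_row(var)
  if (is.null(variant_id)) variant_id <- var$raw
  span <- variant_span(var)
  comp <- assay$components
  ov <- overlap_bases(span[1], span[2], comp$start_c, comp$end_c)
  role_rank <- match(comp$role, c("forward_primer", "reverse_primer", "probe"))
  hit <- order(-ov, role_rank)[1]
  call_row <- function(classification, component_hit, overlap, rationale) {
    tibble::tibble(variant_id = variant_id, assay_name = assay$name,
                   component_hit = component_hit,
                   overlap_bases = as.integer(overlap),
                   classification = classification, rationale = rationale)
  }
  if (all(ov == 0L))
    return(call_row("no_overlap", "none", 0L,
                    "variant footprint outside all annealing intervals"))
  is_indel <- var$kind %in% c("deletion", "insertion", "duplication", "delins")
  if (is_indel)
    return(call_row("likely_dropout_indel", comp$role[hit], ov[hit],
                    sprintf("%s overlaps %s by %d base(s)", var$kind,
                            comp$role[hit], ov[hit])))
  # substitution: check 3'-proximity on any overlapped primer
  overlapped <- which(ov > 0L & !is.na(comp$three_prime_c))
  d3 <- abs(var$start_c - comp$three_prime_c[overlapped])
  near <- overlapped[d3 < three_prime_window]
  if (length(near) > 0L) {
    best <- near[order(abs(var$start_c - comp$three_prime_c[near]))[1]]
    return(call_row("likely_dropout_3prime_substitution", comp$role[best],
                    ov[best],
                    sprintf("substitution %d base(s) from %s 3' terminus",
                            abs(var$start_c - comp$three_prime_c[best]),
                            comp$role[best])))
  }
  call_row("at_risk_substitution", comp$role[hit], ov[hit],
           sprintf("substitution within %s, away from any 3' terminus",
                   comp$role[hit]))
}

dropout_classifications <- c("no_overlap", "at_risk_substitution",
                             "likely_dropout_3prime_substitution",
                             "likely_dropout_indel")

#' Screen a variant table against one or more assays
#'
#' Produces one dropout call per variant x assay, plus per-classification
#' summary counts. The subset of variants with any non-`no_overlap` call
#' is the "annealing-region variant set" that feeds the population model.
#'
#' @param variants Tibble with `hgvs_c` (and ideally `variant_id`)
#'   columns; frequency columns are carried through untouched.
#' @param assays An [assay_definition()] or list of them.
#' @inheritParams classify_variant_vs_assay
#' @return Object of class `screen_report`: list with `calls` (tibble),
#'   `summary` (classification counts) and `annealing_region_ids`.
#' @export
screen_variants <- function(variants, assays, three_prime_window = 5L) {
  if (inherits(assays, "assay_definition")) assays <- list(assays)
  variants <- tibble::as_tibble(variants)
  if (!"variant_id" %in% names(variants))
    variants$variant_id <- variants$hgvs_c
  empty_calls <- tibble::tibble(variant_id = character(),
                                assay_name = character(),
                                component_hit = character(),
                                overlap_bases = integer(),
                                classification = character(),
                                rationale = character())
  calls <- purrr::map_dfr(assays, function(assay) {
    purrr::map2_dfr(variants$hgvs_c, variants$variant_id,
                    function(h, id) classify_variant_vs_assay(
                      h, assay, three_prime_window, variant_id = id))
  })
  if (nrow(calls) == 0L) calls <- empty_calls
  summary <- tibble::tibble(classification = dropout_classifications) |>
    dplyr::left_join(dplyr::count(calls, .data$classification),
                     by = "classification") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  annealing <- unique(calls$variant_id[calls$classification != "no_overlap"])
  structure(list(calls = calls, summary = summary,
                 annealing_region_ids = annealing,
                 variants = variants),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d call(s), %d variant(s) in annealing region\n",
              nrow(x$calls), length(x$annealing_region_ids)))
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a screening report into one row per dropout call
#' @param x A `screen_report`.
#' @param ... Unused.
#' @export
tidy.screen_report <- function(x, ...) x$calls

#' One-row summary of a screening report
#' @param x A `screen_report`.
#' @param ... Unused.
#' @export
glance.screen_report <- function(x, ...) {
  counts <- stats::setNames(as.list(x$summary$n), x$summary$classification)
  tibble::tibble(n_calls = nrow(x$calls),
                 n_variants = nrow(x$variants),
                 n_annealing_region = length(x$annealing_region_ids),
                 !!!counts)
}

#' Plot dropout classifications of a screening report
#'
#' Bar chart of call counts per classification, split by assay.
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  calls <- object$calls
  calls$classification <- factor(calls$classification,
                                 levels = dropout_classifications)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$classification,
                                      fill = .data$component_hit)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$assay_name)) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "dropout classification", y = "variants",
                  fill = "component") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Read an assay configuration table
#'
#' TSV with columns `assay_name`, `role`, `start_c`, `end_c`. Intervals
#' are 1-based closed in c. space (not BED half-open; stated here to
#' avoid the usual off-by-one confusion).
#'
#' @param path TSV path.
#' @return List of [assay_definition()] objects, one per `assay_name`.
#' @export
read_assay_config <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("assay_name", "role", "start_c", "end_c") %in% names(tab)))
  lapply(split(tab, tab$assay_name), function(d)
    assay_definition(d$assay_name[1],
                     d[, c("role", "start_c", "end_c")]))
}

#' Write an assay configuration table
#' @param assays List of [assay_definition()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assay_config <- function(assays, path) {
  if (inherits(assays, "assay_definition")) assays <- list(assays)
  tab <- purrr::map_dfr(assays, function(a)
    dplyr::mutate(a$components[, c("role", "start_c", "end_c")],
                  assay_name = a$name, .before = 1))
  readr::write_tsv(tab, path)
  invisible(path)
}
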