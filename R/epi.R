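#' Carrier frequency from carrier counts
#'
#' Carrier frequency is computed over carrier *individuals* (persons with
#' at least one variant allele), not alleles: heterozygote counts are the
#' observable that matters for compound-het risk. The displayed
#' reciprocal ("1 in N") truncates toward zero.
#'
#' @param carrier_count Number of carrier individuals (vectorised).
#' @param n_individuals Population sample size.
#' @return Tibble: `carrier_count`, `n_individuals`, `fraction`,
#'   `reciprocal` (exact), `reciprocal_display` (truncated integer;
#'   `Inf` when there are zero carriers).
#' @examples
#' carrier_frequency(13 + 47, 589724)  # 1 in 9,828
#' @export
carrier_frequency <- function(carrier_count, n_individuals) {
  stopifnot(all(carrier_count >= 0), all(carrier_count <= n_individuals),
            all(n_individuals > 0))
  fraction <- carrier_count / n_individuals
  reciprocal <- ifelse(carrier_count == 0, Inf, n_individuals / carrier_count)
  tibble::tibble(carrier_count = carrier_count,
                 n_individuals = n_individuals,
                 fraction = fraction,
                 reciprocal = reciprocal,
                 reciprocal_display = trunc(reciprocal))
}

#' Compound-heterozygote frequency under random mating
#'
#' Expected frequency of individuals carrying a gene deletion on one
#' allele and a candidate variant on the other, from the two carrier
#' frequencies: `del_carrier_freq x vus_carrier_freq x 1/4` (each parent
#' a carrier of one allele class, each transmitting it with probability
#' 1/2). Assumes Hardy-Weinberg proportions, random mating, no
#' consanguinity and no fitness effects. Setting
#' `count_parent_orders = TRUE` doubles the estimate to count both
#' assignments of the two allele classes to the two parents; the default
#' keeps the single-order convention.
#'
#' The display reciprocal follows one rule for all magnitudes: at or
#' above one million it is expressed in millions truncated to two
#' decimals (and `reciprocal_for_chain` is that value scaled back up);
#' below one million it is rounded to the nearest integer.
#'
#' @param del_carrier_freq Deletion carrier frequency (e.g. 1/35 in
#'   Europeans).
#' @param vus_carrier_freq Carrier frequency of the candidate variant(s).
#' @param count_parent_orders Double for unordered parental assignment
#'   (default `FALSE`).
#' @return Tibble: `fraction`, `reciprocal` (exact),
#'   `reciprocal_millions_display`, `reciprocal_display`,
#'   `reciprocal_for_chain` (the display value downstream steps use).
#' @examples
#' compound_het_frequency(1 / 35, 60 / 589724)  # ~1 in 1.37 million
#' @export
compound_het_frequency <- function(del_carrier_freq, vus_carrier_freq,
                                   count_parent_orders = FALSE) {
  stopifnot(del_carrier_freq > 0, del_carrier_freq <= 1,
            vus_carrier_freq > 0, vus_carrier_freq <= 1)
  fraction <- del_carrier_freq * vus_carrier_freq / 4
  if (count_parent_orders) fraction <- 2 * fraction
  reciprocal <- 1 / fraction
  in_millions <- reciprocal >= 1e6
  millions_display <- trunc(reciprocal / 1e6 * 100) / 100
  reciprocal_display <- round(reciprocal)
  tibble::tibble(
    fraction = fraction,
    reciprocal = reciprocal,
    reciprocal_millions_display = ifelse(in_millions, millions_display, NA_real_),
    reciprocal_display = reciprocal_display,
    reciprocal_for_chain = ifelse(in_millions, millions_display * 1e6,
                                  reciprocal_display))
}

#' Expected number of existing compound heterozygotes
#'
#' `floor(population_size x freq)`.
#'
#' @param population_size Number of individuals in the population of
#'   interest (e.g. 1.13e9 of European descent).
#' @param freq Compound-het frequency (possibly display-rounded; the
#'   caller's provenance records which).
#' @return Integer count.
#' @examples
#' expected_individuals(1.13e9, 1 / 1.37e6)  # 824
#' @export
expected_individuals <- function(population_size, freq) {
  stopifnot(population_size > 0, freq >= 0, freq <= 1)
  as.integer(floor(population_size * freq))
}

#' Expected affected-genotype births per year
#'
#' `births_per_year x freq x coverage`. The display value truncates to
#' one decimal below 3 and rounds to the nearest integer at 3 or above
#' (the convention that renders 2.678... as 2.6 and 4.93 as 5). Screening
#' coverage defaults to 1: the headline birth expectation is over all
#' births, with coverage applied only when explicitly asked.
#'
#' @param births_per_year Annual births in the cohort (e.g. 3.67e6 in the
#'   EU27).
#' @param freq Genotype frequency.
#' @param coverage Fraction of newborns screened, in `[0, 1]`.
#' @return Tibble: `raw`, `display`.
#' @examples
#' expected_annual_births(3.67e6, 1 / 1.37e6)  # 2.6 per year
#' @export
expected_annual_births <- function(births_per_year, freq, coverage = 1) {
  stopifnot(births_per_year > 0, freq >= 0, coverage >= 0, coverage <= 1)
  raw <- births_per_year * freq * coverage
  display <- ifelse(raw >= 3, round(raw), trunc(raw * 10) / 10)
  tibble::tibble(raw = raw, display = display)
}

#' Cohort parameters for risk projection
#'
#' @param population_size Individuals in the ancestry-matched population.
#' @param births_per_year Annual births in the screened region.
#' @param screening_coverage Fraction of newborns screened.
#' @param deletion_carrier_freq SMN1-deletion carrier frequency.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(population_size, births_per_year,
                        screening_coverage = 1,
                        deletion_carrier_freq = 1 / 35) {
  stopifnot(population_size > 0, births_per_year > 0,
            screening_coverage >= 0, screening_coverage <= 1,
            deletion_carrier_freq > 0, deletion_carrier_freq <= 1)
  structure(list(population_size = population_size,
                 births_per_year = births_per_year,
                 screening_coverage = screening_coverage,
                 deletion_carrier_freq = deletion_carrier_freq),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> population %.3g, births/yr %.3g, ",
                     "coverage %.0f%%, deletion carrier freq 1/%.0f\n"),
              x$population_size, x$births_per_year,
              100 * x$screening_coverage, 1 / x$deletion_carrier_freq))
  invisible(x)
}

#' Named cohort presets
#'
#' `"eu"`: ~1.13 billion individuals of European descent (13.88% of a
#' world population of 8.2 billion), 3.67 million annual EU27 births,
#' 64% SMA-NBS coverage (2024), SMN1-deletion carrier frequency 1/35 in
#' Europeans.
#'
#' @param name Preset name (currently `"eu"`).
#' @return A [cohort_spec()].
#' @export
cohort_preset <- function(name = "eu") {
  switch(name,
         eu = cohort_spec(population_size = 1.13e9,
                          births_per_year = 3.67e6,
                          screening_coverage = 0.64,
                          deletion_carrier_freq = 1 / 35),
         stop("unknown cohort preset '", name, "'", call. = FALSE))
}

#' Full compound-heterozygote risk projection
#'
#' Runs the whole chain -- carrier frequency (combined over variants by
#' summing carrier individuals), compound-het frequency, expected
#' existing individuals, expected annual births -- both per variant and
#' combined. Two labelled arithmetic paths are reported:
#' `rounding = "display"` feeds each step the previous step's displayed
#' (truncated/rounded) value, the convention used when quoting headline
#' numbers; `rounding = "exact"` carries full precision end-to-end. Every
#' rounding step is recorded in the provenance.
#'
#' @param records Tibble of variant frequency records (`variant_id`,
#'   `carrier_count`, `n_individuals`, optionally `population`); all rows
#'   must share one population stratum.
#' @param cohort A [cohort_spec()].
#' @param rounding `"display"` or `"exact"`.
#' @param count_parent_orders Passed to [compound_het_frequency()].
#' @param apply_coverage Multiply the annual-births expectation by the
#'   cohort's screening coverage (default `FALSE`).
#' @return Object of class `risk_estimate` with `by_variant` and
#'   `combined` tibbles and a `provenance` list. [tidy()] returns the
#'   per-variant rows, [glance()] the combined one-row summary.
#' @examples
#' recs <- tibble::tibble(variant_id = c("855del4", "861del4"),
#'                        carrier_count = c(13L, 47L),
#'                        n_individuals = 589724L)
#' glance(risk_report(recs, cohort_preset("eu")))
#' @export
risk_report <- function(records, cohort, rounding = c("display", "exact"),
                        count_parent_orders = FALSE,
                        apply_coverage = FALSE) {
  rounding <- match.arg(rounding)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("carrier_count", "n_individuals") %in% names(records)),
            nrow(records) >= 1L)
  if ("population" %in% names(records) &&
      length(unique(records$population)) > 1L)
    stop("records mix population strata; stratify before calling ",
         "risk_report()", call. = FALSE)
  if (length(unique(records$n_individuals)) > 1L)
    stop("records disagree on n_individuals within one stratum",
         call. = FALSE)
  if (!"variant_id" %in% names(records))
    records$variant_id <- paste0("v", seq_len(nrow(records)))

  chain <- function(carrier_count, label) {
    cf <- carrier_frequency(carrier_count, records$n_individuals[1])
    vus_freq <- if (rounding == "display") 1 / cf$reciprocal_display
                else cf$fraction
    ch <- compound_het_frequency(cohort$deletion_carrier_freq, vus_freq,
                                 count_parent_orders = count_parent_orders)
    chain_freq <- if (rounding == "display") 1 / ch$reciprocal_for_chain
                  else ch$fraction
    coverage <- if (apply_coverage) cohort$screening_coverage else 1
    births <- expected_annual_births(cohort$births_per_year, chain_freq,
                                     coverage)
    tibble::tibble(
      group = label,
      carrier_count = carrier_count,
      n_individuals = records$n_individuals[1],
      carrier_fraction = cf$fraction,
      carrier_reciprocal_display = cf$reciprocal_display,
      compound_het_fraction = ch$fraction,
      compound_het_reciprocal = ch$reciprocal,
      compound_het_reciprocal_display = ch$reciprocal_display,
      compound_het_reciprocal_millions = ch$reciprocal_millions_display,
      expected_individuals = expected_individuals(cohort$population_size,
                                                  chain_freq),
      expected_births_per_year = births$raw,
      expected_births_display = births$display)
  }

  by_variant <- purrr::map2_dfr(records$carrier_count, records$variant_id,
                                chain)
  combined <- chain(sum(records$carrier_count), "combined")
  structure(list(
    by_variant = by_variant, combined = combined,
    provenance = list(
      rounding = rounding,
      count_parent_orders = count_parent_orders,
      apply_coverage = apply_coverage,
      cohort = unclass(cohort),
      n_variants = nrow(records),
      rounding_rules = c(
        "carrier reciprocal: truncate toward zero for display",
        "compound-het reciprocal: >= 1e6 -> millions truncated to 2 dp; else rounded to integer",
        "expected individuals: floor",
        "annual births: < 3 -> truncate to 1 dp; >= 3 -> round to integer"))),
    class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  c <- x$combined
  cat(sprintf("<risk_estimate> (%s arithmetic, %d variant(s))\n",
              x$provenance$rounding, x$provenance$n_variants))
  cat(sprintf("  combined carrier frequency: 1 in %s\n",
              format(c$carrier_reciprocal_display, big.mark = ",")))
  rec <- if (!is.na(c$compound_het_reciprocal_millions))
    paste0(c$compound_het_reciprocal_millions, " million")
  else format(c$compound_het_reciprocal_display, big.mark = ",")
  cat(sprintf("  compound-het frequency:     1 in %s\n", rec))
  cat(sprintf("  expected individuals:       %s\n",
              format(c$expected_individuals, big.mark = ",")))
  cat(sprintf("  expected births per year:   %s\n",
              format(c$expected_births_display)))
  invisible(x)
}

#' Tidy a risk estimate into one row per variant plus the combined row
#' @param x A `risk_estimate`.
#' @param ... Unused.
#' @export
tidy.risk_estimate <- function(x, ...) {
  dplyr::bind_rows(x$by_variant, x$combined)
}

#' One-row combined summary of a risk estimate
#' @param x A `risk_estimate`.
#' @param ... Unused.
#' @export
glance.risk_estimate <- function(x, ...) {
  dplyr::mutate(x$combined, rounding = x$provenance$rounding)
}

#' Plot expected counts across risk groups
#'
#' @param object A `risk_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_estimate <- function(object, ...) {
  tab <- tidy(object) |>
    dplyr::select("group", "expected_individuals",
                  "expected_births_per_year") |>
    tidyr::pivot_longer(-"group", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "expected count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
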