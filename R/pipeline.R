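#' Run the full variant-to-risk report
#'
#' One call from inputs (typically a scenario directory written by
#' [make_scenario()], or an equivalent set of user files) to a combined
#' report: per-variant protein consequences and dropout classifications,
#' and the population-level risk chain (combined carrier reciprocal,
#' compound-het reciprocal, expected existing individuals, expected
#' annual births). The report is a pure function of its inputs: rerunning
#' on identical files yields an identical report.
#'
#' @param config Either a path to a scenario directory containing
#'   `scenario.json` (as written by [make_scenario()]) or a named list
#'   with elements `model` ([transcript_model()]), `variants` (tibble or
#'   TSV path), `assays` ([assay_definition()] or list/TSV path),
#'   `cohort` ([cohort_spec()] or JSON path).
#' @param rounding Passed to [risk_report()] (default `"display"`).
#' @param three_prime_window Passed to [screen_variants()].
#' @return Object of class `smn_report`: list with `variants` (annotated
#'   tibble), `screen` (a `screen_report`), `risk` (a `risk_estimate`,
#'   absent when the variant table is empty) and `provenance`.
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "scen")
#' make_scenario(1, dir)
#' rep <- run_report(dir)
#' glance(rep$risk)
#' }
#' @export
run_report <- function(config, rounding = "display",
                       three_prime_window = 5L) {
  if (is.character(config) && length(config) == 1L) {
    config <- load_scenario_config(config)
  }
  stopifnot(is.list(config),
            all(c("model", "variants", "assays", "cohort") %in% names(config)))
  model <- config$model
  variants <- if (is.character(config$variants))
    read_variant_table(config$variants) else tibble::as_tibble(config$variants)
  assays <- if (is.character(config$assays))
    read_assay_config(config$assays) else config$assays
  cohort <- if (is.character(config$cohort)) {
    cj <- jsonlite::read_json(config$cohort)
    cohort_spec(cj$population_size, cj$births_per_year,
                cj$screening_coverage, cj$deletion_carrier_freq)
  } else config$cohort

  if (nrow(variants) == 0L) {
    return(structure(list(
      variants = variants, screen = NULL, risk = NULL,
      provenance = report_provenance(model, rounding, three_prime_window)),
      class = "smn_report"))
  }
  annotated <- predict_consequences(variants, model)
  screen <- screen_variants(annotated, assays, three_prime_window)
  first_assay <- if (inherits(assays, "assay_definition")) assays
                 else assays[[1]]
  calls1 <- screen$calls[screen$calls$assay_name == first_assay$name, ]
  annotated$dropout_classification <-
    calls1$classification[match(annotated$variant_id, calls1$variant_id)]
  annealing <- annotated[annotated$variant_id %in%
                           screen$annealing_region_ids, ]
  risk <- if (nrow(annealing) > 0L &&
              all(c("carrier_count", "n_individuals") %in% names(annealing)))
    risk_report(annealing, cohort, rounding = rounding)
  else NULL
  structure(list(variants = annotated, screen = screen, risk = risk,
                 provenance = report_provenance(model, rounding,
                                                three_prime_window)),
            class = "smn_report")
}

report_provenance <- function(model, rounding, three_prime_window) {
  list(transcript_id = model$id,
       tool = "smnscreen",
       version = as.character(utils::packageVersion("smnscreen")),
       rounding = rounding,
       three_prime_window = three_prime_window)
}

load_scenario_config <- function(dir) {
  manifest_path <- file.path(dir, "scenario.json")
  if (!file.exists(manifest_path))
    stop("no scenario.json in '", dir, "'", call. = FALSE)
  seqs <- read_fasta(file.path(dir, "transcripts.fasta"))
  model <- read_transcript_json(file.path(dir, "transcript_SMN1demo.json"),
                                seqs)
  list(model = model,
       variants = file.path(dir, "variants.tsv"),
       assays = file.path(dir, "assay.tsv"),
       cohort = file.path(dir, "cohort.json"))
}

#' @export
print.smn_report <- function(x, ...) {
  cat(sprintf("<smn_report> %d variant(s) on %s\n", nrow(x$variants),
              x$provenance$transcript_id))
  if (!is.null(x$screen)) print(x$screen$summary)
  if (!is.null(x$risk)) print(x$risk)
  invisible(x)
}

#' Write a report to JSON and TSV
#'
#' `report.json` carries the per-variant rows, the risk chain and the
#' provenance (including the rounding ledger); `report.tsv` the
#' per-variant table alone. Output is byte-stable across reruns on
#' identical inputs: no timestamps enter the files.
#'
#' @param report An `smn_report` from [run_report()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  tsv_path <- file.path(dir, "report.tsv")
  obj <- list(
    provenance = report$provenance,
    variants = report$variants,
    screen_summary = if (!is.null(report$screen)) report$screen$summary,
    risk = if (!is.null(report$risk))
      list(by_variant = report$risk$by_variant,
           combined = report$risk$combined,
           provenance = report$risk$provenance))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  readr::write_tsv(report$variants, tsv_path)
  invisible(c(json = json_path, tsv = tsv_path))
}
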