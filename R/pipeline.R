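#' Run the full pipeline: quality control, normalization, analysis
#'
#' Chains the three stages on an interchange CSV (or an in-memory dataset)
#' and writes every intermediate as a CSV so stages compose identically to
#' running them one at a time: `qc.csv` (classified records),
#' `normalized.csv`, `factors.csv`, `abundance.csv`, `stoichiometry.csv`,
#' `validation.csv` (when findings exist) and `run_log.json` (parameters and
#' per-stage record counts). For modes that keep a standard channel
#' (`equimolar`, `isotopologue`), analysis runs on the analyte channels
#' only.
#'
#' @param input Path to an interchange CSV, or a [quant_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param ptm Modification of interest.
#' @param mode Normalization mode: `"none"`, `"equimolar"`,
#'   `"isotopologue"`, `"tic"`, `"internal-reference"`.
#' @param standard_channel Spike-in channel for the isotopologue modes (and
#'   excluded from TIC sums when present in the roster).
#' @param reference_sample Reference sample override (default: the
#'   dataset's).
#' @param reference_proteins Loading-control protein ids
#'   (`internal-reference` mode).
#' @param proxy_policy Passed to [run_analysis()].
#' @param strict Raise on the first validation finding instead of reporting.
#' @return Invisibly, a list with the classified dataset, normalization
#'   result, analysis results and the validation report.
#' @export
run_pipeline <- function(input, out_dir, ptm = "phospho",
                         mode = c("none", "equimolar", "isotopologue", "tic",
                                  "internal-reference"),
                         standard_channel = "heavy", reference_sample = NULL,
                         reference_proteins = NULL,
                         proxy_policy = c("mean", "sum", "single"),
                         strict = FALSE) {
  mode <- match.arg(mode)
  proxy_policy <- match.arg(proxy_policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dataset <- if (is_quant_dataset(input)) input else {
    read_quant_csv(input, reference_sample = reference_sample, ptm = ptm)
  }
  if (!is.null(reference_sample)) {
    dataset <- set_reference_sample(dataset, reference_sample)
  }
  n_input <- nrow(dataset)

  report <- validate_dataset(dataset, strict = strict)
  if (nrow(report) > 0) {
    readr::write_csv(report, file.path(out_dir, "validation.csv"), progress = FALSE)
  }
  dataset <- classify_peptides(dataset)
  dataset <- drop_unquantified_proteins(dataset)
  write_quant_csv(dataset, file.path(out_dir, "qc.csv"))

  has_standard <- standard_channel %in% channel_roster(dataset)
  norm <- switch(mode,
    none = NULL,
    equimolar = normalize_equimolar_isotopologue(dataset, standard_channel),
    isotopologue = normalize_isotopologue(dataset, standard_channel),
    tic = normalize_tic(dataset,
                        standard_channel = if (has_standard) standard_channel),
    `internal-reference` = {
      if (is.null(reference_proteins)) {
        abort("internal-reference mode needs reference_proteins")
      }
      normalize_internal_reference(dataset, reference_proteins,
                                   standard_channel = if (has_standard) standard_channel)
    })
  normalized <- if (is.null(norm)) dataset else norm$dataset
  write_quant_csv(normalized, file.path(out_dir, "normalized.csv"))
  if (!is.null(norm)) {
    fac <- norm$factors
    fac$mode <- attr(norm$factors, "mode")
    readr::write_csv(fac, file.path(out_dir, "factors.csv"), progress = FALSE)
  }

  analyte <- if (has_standard) {
    setdiff(channel_roster(normalized), standard_channel)
  } else NULL
  results <- run_analysis(normalized, channels = analyte,
                          proxy_policy = proxy_policy)
  readr::write_csv(results$abundance, file.path(out_dir, "abundance.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(results$stoichiometry, file.path(out_dir, "stoichiometry.csv"),
                   na = "", progress = FALSE)

  log <- list(
    package_version = as.character(utils::packageVersion("ptmquant")),
    parameters = list(ptm = ptm, mode = mode,
                      standard_channel = standard_channel,
                      reference_sample = reference_sample(dataset),
                      proxy_policy = proxy_policy),
    counts = list(records_in = n_input,
                  records_after_qc = nrow(dataset),
                  validation_findings = nrow(report),
                  abundance_results = nrow(results$abundance),
                  stoichiometry_results = nrow(results$stoichiometry)),
    summary = results$summary
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = dataset, normalization = norm,
                 results = results, validation = report))
}
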