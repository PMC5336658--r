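# Normalization: four selectable corrections for technical variation. Every
# mode returns list(dataset, factors) with the same interchange schema, so
# stages downstream are mode-agnostic. Missing intensities are excluded from
# every sum and never imputed.

norm_result <- function(dataset, factors, mode) {
  attr(factors, "mode") <- mode
  list(dataset = dataset, factors = factors)
}

# standard-channel intensities per chemoform x sample
std_table <- function(rec, standard_channel) {
  std <- rec[rec$channel == standard_channel, , drop = FALSE]
  std[c(qd_chemoform_cols, "sample", "intensity")]
}

#' Equimolar-isotopologue normalization
#'
#' For experiments spiked with synthetic heavy-isotope standards at
#' equimolar concentration: since every standard is present at the same
#' molarity in every sample, differences in its recorded signal across
#' samples are technical. The correction equalizes each chemoform's
#' standard to its intensity in the reference sample: for chemoform *c* in
#' sample *s*, factor = standard(*c*, reference) / standard(*c*, *s*),
#' applied to all channels of *c* in *s*. The reference sample is left
#' numerically untouched (factors exactly 1). Because factors are scoped
#' per chemoform, the mode also corrects chemoform-specific molarity
#' alterations such as those produced by enrichment of chemically modified
#' peptides.
#'
#' Chemoforms whose standard is missing or zero where needed are flagged in
#' the factor table and their analyte records pass through unscaled.
#'
#' @inheritParams sample_roster
#' @param standard_channel Label channel holding the spiked standards.
#' @return `list(dataset, factors)`; `factors` has one row per chemoform x
#'   sample with columns `factor` and `flagged`.
#' @export
normalize_equimolar_isotopologue <- function(dataset, standard_channel = "heavy") {
  qd_assert(dataset)
  if (!standard_channel %in% attr(dataset, "channels")) {
    abort(paste0("standard channel '", standard_channel, "' not in roster"))
  }
  rec <- tibble::as_tibble(dataset)
  ref <- attr(dataset, "reference_sample")
  std <- std_table(rec, standard_channel)
  target <- std[std$sample == ref, c(qd_chemoform_cols, "intensity")]
  names(target)[names(target) == "intensity"] <- "target"

  grid <- distinct(rec[c(qd_chemoform_cols, "sample")])
  fac <- left_join(grid, rename(std, std_int = "intensity"),
                   by = c(qd_chemoform_cols, "sample"))
  fac <- left_join(fac, target, by = qd_chemoform_cols)
  fac$factor <- fac$target / fac$std_int
  fac$flagged <- !is.finite(fac$factor) | fac$factor <= 0
  fac$factor[fac$flagged] <- NA_real_

  joined <- left_join(rec, fac[c(qd_chemoform_cols, "sample", "factor", "target", "flagged")],
                      by = c(qd_chemoform_cols, "sample"))
  scale <- ifelse(is.na(joined$factor), 1, joined$factor)
  new_int <- joined$intensity * scale
  # standards map onto their target exactly, so the equalized standard has
  # zero range across samples in floating point too
  is_std <- joined$channel == standard_channel & !is.na(joined$factor)
  new_int[is_std] <- joined$target[is_std]
  rec$intensity <- new_int
  norm_result(qd_rebuild(rec, dataset),
              fac[c(qd_chemoform_cols, "sample", "factor", "flagged")],
              "equimolar_isotopologue")
}

#' Ratio-to-isotopologue normalization
#'
#' Expresses every intensity relative to its own chemoform's
#' standard-channel intensity within the same sample (dimensionless ratio
#' units). No cross-sample equalization of the standard is assumed, so
#' non-equimolar labeled references -- e.g. a SILAC-labeled proteome used as
#' the heavy channel -- are legal; any sample-wide multiplicative distortion
#' hitting both channels cancels. With equimolar standards the ratios are on
#' a common molar scale, which the analysis stage's approximate modes rely
#' on. Standard-channel records become 1 (their ratio to themselves).
#'
#' @inheritParams normalize_equimolar_isotopologue
#' @return `list(dataset, factors)`; `factors` rows are per chemoform x
#'   sample with `factor` = 1 / standard intensity.
#' @export
normalize_isotopologue <- function(dataset, standard_channel = "heavy") {
  qd_assert(dataset)
  if (!standard_channel %in% attr(dataset, "channels")) {
    abort(paste0("standard channel '", standard_channel, "' not in roster"))
  }
  rec <- tibble::as_tibble(dataset)
  std <- std_table(rec, standard_channel)
  grid <- distinct(rec[c(qd_chemoform_cols, "sample")])
  fac <- left_join(grid, rename(std, std_int = "intensity"),
                   by = c(qd_chemoform_cols, "sample"))
  fac$factor <- 1 / fac$std_int
  fac$flagged <- !is.finite(fac$factor) | fac$factor <= 0
  fac$factor[fac$flagged] <- NA_real_

  joined <- left_join(rec, fac[c(qd_chemoform_cols, "sample", "factor")],
                      by = c(qd_chemoform_cols, "sample"))
  scale <- ifelse(is.na(joined$factor), 1, joined$factor)
  rec$intensity <- joined$intensity * scale
  norm_result(qd_rebuild(rec, dataset),
              fac[c(qd_chemoform_cols, "sample", "factor", "flagged")],
              "isotopologue")
}

#' Total ion current (TIC) normalization
#'
#' For experiments with no isotopically encoded standard: each sample's TIC
#' (sum of all non-missing analyte intensities) is scaled to the reference
#' sample's, with factor = TIC(reference) / TIC(sample) applied to all of
#' the sample's records. Spiked standard channels, when present, are
#' excluded from the TIC sum (they are constant by design and would damp
#' real loading differences) but still rescaled.
#'
#' @inheritParams sample_roster
#' @param standard_channel Optional channel to exclude from the TIC sum
#'   (`NULL` when no standard is present).
#' @export
normalize_tic <- function(dataset, standard_channel = NULL) {
  qd_assert(dataset)
  rec <- tibble::as_tibble(dataset)
  analyte <- rec
  if (!is.null(standard_channel)) {
    analyte <- analyte[analyte$channel != standard_channel, , drop = FALSE]
  }
  samples <- attr(dataset, "samples")
  tic <- vapply(samples, function(s) {
    sum(analyte$intensity[analyte$sample == s], na.rm = TRUE)
  }, numeric(1))
  bad <- samples[!is.finite(tic) | tic <= 0]
  if (length(bad) > 0) {
    abort(paste0("zero or undefined total ion current in sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  ref <- attr(dataset, "reference_sample")
  fac <- tibble::tibble(sample = samples, factor = unname(tic[[ref]] / tic))
  fac$factor[fac$sample == ref] <- 1
  rec$intensity <- rec$intensity * fac$factor[match(rec$sample, fac$sample)]
  norm_result(qd_rebuild(rec, dataset), fac, "tic")
}

#' Internal-reference normalization
#'
#' Corrects for variation in total protein content per cell using a roster
#' of reference (loading-control) proteins assumed constant across samples:
#' factor = (summed reference-peptide intensity in the reference sample) /
#' (summed reference-peptide intensity in the sample), applied to all
#' records. Unlike TIC normalization, genuine changes of non-reference
#' proteins are preserved rather than diluted.
#'
#' @inheritParams normalize_tic
#' @param reference_proteins Protein ids of the loading controls; each must
#'   contribute at least one non-missing intensity in every sample.
#' @export
normalize_internal_reference <- function(dataset, reference_proteins,
                                         standard_channel = NULL) {
  qd_assert(dataset)
  if (length(reference_proteins) == 0) abort("no reference proteins given")
  rec <- tibble::as_tibble(dataset)
  refrec <- rec[rec$protein %in% reference_proteins, , drop = FALSE]
  if (!is.null(standard_channel)) {
    refrec <- refrec[refrec$channel != standard_channel, , drop = FALSE]
  }
  samples <- attr(dataset, "samples")
  for (p in reference_proteins) {
    for (s in samples) {
      hit <- refrec$protein == p & refrec$sample == s & !is.na(refrec$intensity)
      if (!any(hit)) {
        abort(paste0("reference protein '", p,
                     "' has no quantified peptide in sample '", s, "'"))
      }
    }
  }
  sums <- vapply(samples, function(s) {
    sum(refrec$intensity[refrec$sample == s], na.rm = TRUE)
  }, numeric(1))
  ref <- attr(dataset, "reference_sample")
  fac <- tibble::tibble(sample = samples, factor = unname(sums[[ref]] / sums))
  fac$factor[fac$sample == ref] <- 1
  rec$intensity <- rec$intensity * fac$factor[match(rec$sample, fac$sample)]
  norm_result(qd_rebuild(rec, dataset), fac, "internal_reference")
}
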