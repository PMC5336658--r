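# Column layout of the interchange table. `site` holds one token per modified
# residue ("S5"), ";"-joined for multiply modified chemoforms, aligned with the
# ";"-joined `ptm_type` tokens. `intensity` NA means "not detected" -- a
# recorded zero signal stays 0 and the two are never conflated.
qd_record_cols <- c("protein", "peptide", "ptm_type", "site",
                    "channel", "sample", "intensity", "class")
qd_key_cols <- c("protein", "peptide", "ptm_type", "site", "channel", "sample")
qd_chemoform_cols <- c("protein", "peptide", "ptm_type", "site")
qd_classes <- c("Q", "M", "NM", "unassigned")

#' Construct a peptide-level quantification dataset
#'
#' A `quant_dataset` is a tibble of one row per intensity measurement
#' (protein, peptide sequence, modification state, label channel, sample,
#' intensity), carrying as attributes the ordered sample roster, the
#' designated reference sample, the label-channel roster and the
#' modification of interest. All pipeline stages consume and produce this
#' container, so stages chain freely (in memory or via CSV files).
#'
#' @param records A data frame with columns `protein`, `peptide`, `sample`,
#'   `intensity`, and optionally `ptm_type` (default `"none"`), `site`
#'   (default `NA`), `channel` (default `"light"`), `class` (default
#'   `"unassigned"`). `intensity` must be numeric; `NA` marks a measurement
#'   that was not detected (distinct from a recorded 0).
#' @param reference_sample Sample id every abundance ratio is taken against.
#'   Defaults to the first sample in first-appearance order, the convention
#'   used throughout for "sample #1".
#' @param ptm Controlled token naming the modification of interest for this
#'   run (default `"phospho"`). Records bearing other modification types are
#'   kept and classified relative to this one.
#' @param samples,channels Optional explicit rosters; default to
#'   first-appearance order of the records.
#' @return A `quant_dataset` (tibble subclass).
#' @export
quant_dataset <- function(records, reference_sample = NULL, ptm = "phospho",
                          samples = NULL, channels = NULL) {
  rec <- tibble::as_tibble(records)
  required <- c("protein", "peptide", "sample", "intensity")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    abort(paste0("records lack required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"ptm_type" %in% names(rec)) rec$ptm_type <- "none"
  if (!"site" %in% names(rec)) rec$site <- NA_character_
  if (!"channel" %in% names(rec)) rec$channel <- "light"
  if (!"class" %in% names(rec)) rec$class <- "unassigned"

  rec$protein <- as.character(rec$protein)
  rec$peptide <- as.character(rec$peptide)
  rec$ptm_type <- as.character(rec$ptm_type)
  rec$ptm_type[is.na(rec$ptm_type) | rec$ptm_type == ""] <- "none"
  rec$site <- as.character(rec$site)
  rec$site[!is.na(rec$site) & rec$site == ""] <- NA_character_
  rec$channel <- as.character(rec$channel)
  rec$sample <- as.character(rec$sample)
  rec$intensity <- as.double(rec$intensity)
  rec$class <- as.character(rec$class)
  rec$class[is.na(rec$class) | rec$class == ""] <- "unassigned"
  rec <- rec[qd_record_cols]

  if (any(!rec$class %in% qd_classes)) {
    bad <- unique(rec$class[!rec$class %in% qd_classes])
    abort(paste0("unknown peptide class value(s): ", paste(bad, collapse = ", ")))
  }
  if (any(nzchar(rec$protein) == FALSE) || any(nzchar(rec$peptide) == FALSE)) {
    abort("protein and peptide identifiers must be non-empty")
  }
  if (any(!is.na(rec$intensity) & rec$intensity < 0)) {
    abort("intensities must be non-negative (NA marks a missing measurement)")
  }

  samples <- samples %||% unique(rec$sample)
  channels <- channels %||% unique(rec$channel)
  if (length(samples) == 0) abort("dataset has no samples")
  reference_sample <- reference_sample %||% samples[[1]]
  if (!reference_sample %in% samples) {
    abort(paste0("reference sample '", reference_sample,
                 "' is not in the sample roster"))
  }
  off <- setdiff(unique(rec$sample), samples)
  if (length(off) > 0) {
    abort(paste0("record sample(s) off roster: ", paste(off, collapse = ", ")))
  }
  off <- setdiff(unique(rec$channel), channels)
  if (length(off) > 0) {
    abort(paste0("record channel(s) off roster: ", paste(off, collapse = ", ")))
  }

  new_quant_dataset(rec, samples = samples, reference_sample = reference_sample,
                    channels = channels, ptm = ptm)
}

# low-level constructor: no checks, attaches metadata
new_quant_dataset <- function(rec, samples, reference_sample, channels, ptm) {
  structure(
    tibble::as_tibble(rec),
    samples = samples,
    reference_sample = reference_sample,
    channels = channels,
    ptm = ptm,
    class = c("quant_dataset", class(tibble::tibble()))
  )
}

# rebuild after a dplyr verb stripped the subclass/attributes
qd_rebuild <- function(rec, template, samples = NULL, channels = NULL) {
  new_quant_dataset(
    tibble::as_tibble(rec)[qd_record_cols],
    samples = samples %||% attr(template, "samples"),
    reference_sample = attr(template, "reference_sample"),
    channels = channels %||% attr(template, "channels"),
    ptm = attr(template, "ptm")
  )
}

#' @export
#' @rdname quant_dataset
is_quant_dataset <- function(x) inherits(x, "quant_dataset")

qd_assert <- function(x) {
  if (!is_quant_dataset(x)) abort("expected a quant_dataset; see quant_dataset()")
  invisible(x)
}

#' Dataset metadata accessors
#'
#' @param dataset A [quant_dataset()].
#' @return `sample_roster()` and `channel_roster()` return character vectors in
#'   roster order; `reference_sample()` and `ptm_of_interest()` return single
#'   strings.
#' @export
sample_roster <- function(dataset) {
  qd_assert(dataset)
  attr(dataset, "samples")
}

#' @rdname sample_roster
#' @export
channel_roster <- function(dataset) {
  qd_assert(dataset)
  attr(dataset, "channels")
}

#' @rdname sample_roster
#' @export
reference_sample <- function(dataset) {
  qd_assert(dataset)
  attr(dataset, "reference_sample")
}

#' @rdname sample_roster
#' @export
ptm_of_interest <- function(dataset) {
  qd_assert(dataset)
  attr(dataset, "ptm")
}

#' Re-designate the reference sample
#'
#' @inheritParams sample_roster
#' @param sample A sample id from the roster.
#' @export
set_reference_sample <- function(dataset, sample) {
  qd_assert(dataset)
  if (!sample %in% attr(dataset, "samples")) {
    abort(paste0("'", sample, "' is not in the sample roster"))
  }
  attr(dataset, "reference_sample") <- sample
  dataset
}

#' Restrict a dataset to selected label channels
#'
#' Typical use is dropping the spike-in standard channel before analysis.
#' The channel roster shrinks accordingly; sample roster, reference sample
#' and modification of interest are unchanged.
#'
#' @inheritParams sample_roster
#' @param channels Channels to keep.
#' @export
filter_channels <- function(dataset, channels) {
  qd_assert(dataset)
  bad <- setdiff(channels, attr(dataset, "channels"))
  if (length(bad) > 0) {
    abort(paste0("channel(s) not in roster: ", paste(bad, collapse = ", ")))
  }
  rec <- tibble::as_tibble(dataset)
  rec <- rec[rec$channel %in% channels, , drop = FALSE]
  qd_rebuild(rec, dataset, channels = channels)
}

#' Remove records of given peptide classes
#'
#' Emulates non-detection of whole peptide classes (e.g. Q peptides lost to
#' affinity enrichment): records whose class is listed are deleted in every
#' sample and channel. The dataset must already be classified with
#' [classify_peptides()]. Remaining class labels stay valid: removing Q
#' peptides or NM chemoforms never changes the class of a surviving record.
#'
#' @inheritParams sample_roster
#' @param classes Subset of `c("Q", "M", "NM")`.
#' @export
withhold_classes <- function(dataset, classes) {
  qd_assert(dataset)
  classes <- match.arg(classes, c("Q", "M", "NM"), several.ok = TRUE)
  rec <- tibble::as_tibble(dataset)
  if (any(rec$class == "unassigned")) {
    abort("dataset is not classified; run classify_peptides() first")
  }
  qd_rebuild(rec[!rec$class %in% classes, , drop = FALSE], dataset)
}

# canonical row order used by write_quant_csv and equality comparisons
qd_canonical_sort <- function(rec) {
  ord <- order(rec$protein, rec$peptide, rec$ptm_type,
               ifelse(is.na(rec$site), "", rec$site),
               rec$channel, rec$sample, method = "radix")
  rec[ord, , drop = FALSE]
}

#' @export
print.quant_dataset <- function(x, ...) {
  cat(sprintf(
    "<quant_dataset> %d records | %d proteins | %d samples (reference: %s) | channels: %s | PTM of interest: %s\n",
    nrow(x), length(unique(x$protein)), length(attr(x, "samples")),
    attr(x, "reference_sample"), paste(attr(x, "channels"), collapse = ", "),
    attr(x, "ptm")
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# TRUE where a ";"-joined ptm_type token list contains the PTM of interest
ptm_carries <- function(ptm_type, ptm) {
  vapply(strsplit(ptm_type, ";", fixed = TRUE),
         function(tok) ptm %in% tok, logical(1))
}

# sites (one per token) at which a chemoform bears `ptm`; NA_character_ when
# the chemoform bears it without positional information
ptm_sites <- function(ptm_type, site, ptm) {
  types <- strsplit(ptm_type, ";", fixed = TRUE)[[1]]
  hit <- which(types == ptm)
  if (length(hit) == 0) return(character(0))
  if (is.na(site)) return(NA_character_)
  sites <- strsplit(site, ";", fixed = TRUE)[[1]]
  if (length(sites) == length(types)) sites[hit] else rep(NA_character_, length(hit))
}
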