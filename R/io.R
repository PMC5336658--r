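#' Canonical interchange columns
#'
#' The column map ties schema fields to CSV header names. The canonical
#' header is `protein, peptide, ptm_type, site, channel, sample, intensity,
#' class`; vendor dialects remap onto it. Override entries to read any CSV
#' whose columns carry the same content under different names.
#'
#' @param ... Named overrides, e.g. `protein = "Protein Name"`.
#' @return Named character vector mapping schema field -> column name.
#' @export
quant_columns <- function(...) {
  map <- c(protein = "protein", peptide = "peptide", ptm_type = "ptm_type",
           site = "site", channel = "channel", sample = "sample",
           intensity = "intensity", class = "class")
  dots <- c(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad) > 0) {
      abort(paste0("unknown schema field(s): ", paste(bad, collapse = ", ")))
    }
    map[names(dots)] <- dots
  }
  map
}

#' Read a peptide-level intensity CSV
#'
#' Parses the interchange CSV (RFC-4180, UTF-8, mandatory header) produced by
#' every pipeline stage, or any equivalently-shaped export via `column_map`.
#' Empty intensity cells become explicitly missing measurements (`NA`), never
#' zero; a literal `0` is kept as a recorded zero signal.
#'
#' @param path CSV file path.
#' @param column_map Schema-field to column-name map, see [quant_columns()].
#'   Fields `protein`, `peptide`, `sample`, `intensity` must resolve to
#'   existing columns; the others are optional and default when absent.
#' @param reference_sample Reference sample id; defaults to the first sample
#'   in file order.
#' @param ptm Modification of interest for downstream classification.
#' @return A [quant_dataset()].
#' @export
read_quant_csv <- function(path, column_map = quant_columns(),
                           reference_sample = NULL, ptm = "phospho") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  required <- c("protein", "peptide", "sample", "intensity")
  for (field in required) {
    if (!column_map[[field]] %in% names(raw)) {
      abort(paste0("mapped column '", column_map[[field]], "' (field '", field,
                   "') is missing from the header"))
    }
  }
  get_col <- function(field, default) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  intensity_chr <- trimws(raw[[column_map[["intensity"]]]])
  intensity <- suppressWarnings(as.double(intensity_chr))
  bad <- which(!is.na(intensity_chr) & intensity_chr != "" & is.na(intensity))
  if (length(bad) > 0) {
    abort(paste0("non-numeric intensity at data row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  intensity[intensity_chr == ""] <- NA_real_

  rec <- tibble::tibble(
    protein = get_col("protein", NA_character_),
    peptide = get_col("peptide", NA_character_),
    ptm_type = get_col("ptm_type", "none"),
    site = get_col("site", NA_character_),
    channel = get_col("channel", "light"),
    sample = get_col("sample", NA_character_),
    intensity = intensity,
    class = get_col("class", "unassigned")
  )
  dup <- duplicated(rec[qd_key_cols])
  if (any(dup)) {
    k <- rec[which(dup)[1], qd_key_cols]
    abort(paste0("duplicate record key (first: ",
                 paste(unlist(k), collapse = "/"), "); ",
                 sum(dup), " duplicate row(s)"))
  }
  quant_dataset(rec, reference_sample = reference_sample, ptm = ptm)
}

#' Write a dataset as an interchange CSV
#'
#' Rows are written in canonical order (protein, peptide, modification,
#' channel, sample) so equal datasets always produce byte-identical files.
#' Missing intensities are written as empty cells; `read_quant_csv()` of the
#' output reproduces the dataset field-for-field.
#'
#' @inheritParams sample_roster
#' @param path Output file path.
#' @export
write_quant_csv <- function(dataset, path) {
  qd_assert(dataset)
  rec <- qd_canonical_sort(tibble::as_tibble(dataset))
  rec$class[rec$class == "unassigned"] <- NA_character_
  readr::write_csv(rec, path, na = "", progress = FALSE)
  invisible(path)
}

# mass-shift tokens accepted in Skyline-style bracket annotations
skyline_mod_masses <- list(
  phospho = c("+80", "+79.966331", "+79.9663", "+79.97", "+79.966"),
  acetyl = c("+42", "+42.010565", "+42.0106", "+42.01"),
  oxidation = c("+16", "+15.994915", "+15.9949", "+15.99")
)

# "AST[+80]PEK" -> list(peptide, ptm_type, site) with protein coordinates
# when `start` (1-based peptide start within the protein) is given
parse_bracket_sequence <- function(modseq, start = NA_integer_, row = NA_integer_) {
  stripped <- gsub("^_|_$", "", modseq)
  plain <- character(0)
  types <- character(0)
  sites <- character(0)
  rest <- stripped
  while (nchar(rest) > 0) {
    open <- regexpr("[", rest, fixed = TRUE)
    if (open == -1L) {
      plain <- c(plain, rest)
      break
    }
    plain <- c(plain, substr(rest, 1, open - 1))
    close <- regexpr("]", rest, fixed = TRUE)
    if (close == -1L) abort(paste0("unterminated modification bracket in '",
                                   modseq, "' (row ", row, ")"))
    token <- substr(rest, open + 1, close - 1)
    type <- NA_character_
    for (nm in names(skyline_mod_masses)) {
      if (token %in% skyline_mod_masses[[nm]]) type <- nm
    }
    if (is.na(type)) {
      abort(paste0("unknown modification token '[", token, "]' in '", modseq,
                   "' (row ", row, ")"))
    }
    seq_so_far <- paste(plain, collapse = "")
    pep_pos <- nchar(seq_so_far)
    if (pep_pos == 0) {
      abort(paste0("modification bracket precedes any residue in '", modseq,
                   "' (row ", row, ")"))
    }
    residue <- substr(seq_so_far, pep_pos, pep_pos)
    pos <- if (is.na(start)) pep_pos else start + pep_pos - 1L
    types <- c(types, type)
    sites <- c(sites, paste0(residue, pos))
    rest <- substr(rest, close + 1, nchar(rest))
  }
  list(
    peptide = paste(plain, collapse = ""),
    ptm_type = if (length(types) == 0) "none" else paste(types, collapse = ";"),
    site = if (length(types) == 0) NA_character_ else paste(sites, collapse = ";")
  )
}

# "(ph)" style tokens used in MaxQuant modified sequences
maxquant_mod_tokens <- c(ph = "phospho", ac = "acetyl", ox = "oxidation")

parse_paren_sequence <- function(modseq, start = NA_integer_, row = NA_integer_) {
  stripped <- gsub("^_|_$", "", modseq)
  plain <- character(0)
  types <- character(0)
  sites <- character(0)
  rest <- stripped
  while (nchar(rest) > 0) {
    open <- regexpr("(", rest, fixed = TRUE)
    if (open == -1L) {
      plain <- c(plain, rest)
      break
    }
    plain <- c(plain, substr(rest, 1, open - 1))
    close <- regexpr(")", rest, fixed = TRUE)
    if (close == -1L) abort(paste0("unterminated modification token in '",
                                   modseq, "' (row ", row, ")"))
    token <- substr(rest, open + 1, close - 1)
    if (!token %in% names(maxquant_mod_tokens)) {
      abort(paste0("unknown modification token '(", token, ")' in '", modseq,
                   "' (row ", row, ")"))
    }
    seq_so_far <- paste(plain, collapse = "")
    pep_pos <- nchar(seq_so_far)
    if (pep_pos == 0) {
      abort(paste0("modification token precedes any residue in '", modseq,
                   "' (row ", row, ")"))
    }
    residue <- substr(seq_so_far, pep_pos, pep_pos)
    pos <- if (is.na(start)) pep_pos else start + pep_pos - 1L
    types <- c(types, maxquant_mod_tokens[[token]])
    sites <- c(sites, paste0(residue, pos))
    rest <- substr(rest, close + 1, nchar(rest))
  }
  list(
    peptide = paste(plain, collapse = ""),
    ptm_type = if (length(types) == 0) "none" else paste(types, collapse = ";"),
    site = if (length(types) == 0) NA_character_ else paste(sites, collapse = ";")
  )
}

#' Import a vendor quantification report
#'
#' Maps exporter-specific column layouts and in-sequence modification
#' grammars onto the interchange schema.
#'
#' Dialects:
#' \describe{
#'   \item{`generic`}{identity pass-through of [read_quant_csv()].}
#'   \item{`skyline`}{customized 'Export Report' columns: `Protein Name`,
#'     `Peptide Modified Sequence` (bracket mass annotations such as
#'     `[+80]`), `Isotope Label Type`, `Replicate Name`, `Total Area`, and
#'     optionally `Begin Pos` (1-based start of the peptide in the protein)
#'     to place modification sites in protein coordinates. Without
#'     `Begin Pos`, site positions are peptide-internal.}
#'   \item{`maxquant`}{evidence-style columns: `Proteins`, `Modified
#'     sequence` (tokens `(ph)`, `(ac)`, `(ox)`), `Experiment`, and either a
#'     single `Intensity` column (label-free, imported as the light channel)
#'     or `Intensity L` / `Intensity H` pairs, which yield one light and one
#'     heavy record per row. Optional `Start position` supplies protein
#'     coordinates.}
#' }
#'
#' @param path Report file path (CSV).
#' @param dialect One of `"generic"`, `"skyline"`, `"maxquant"`.
#' @inheritParams read_quant_csv
#' @return A [quant_dataset()].
#' @export
import_vendor_report <- function(path, dialect = c("generic", "skyline", "maxquant"),
                                 reference_sample = NULL, ptm = "phospho") {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort(paste0(
                        "unknown dialect '", dialect[1],
                        "'; use generic, skyline or maxquant")))
  if (dialect == "generic") {
    return(read_quant_csv(path, reference_sample = reference_sample, ptm = ptm))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())

  if (dialect == "skyline") {
    need <- c("Protein Name", "Peptide Modified Sequence", "Replicate Name",
              "Total Area")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      abort(paste0("Skyline report lacks column(s): ", paste(miss, collapse = ", ")))
    }
    start <- if ("Begin Pos" %in% names(raw)) {
      suppressWarnings(as.integer(raw[["Begin Pos"]]))
    } else rep(NA_integer_, nrow(raw))
    parsed <- lapply(seq_len(nrow(raw)), function(i) {
      parse_bracket_sequence(raw[["Peptide Modified Sequence"]][i], start[i], i)
    })
    channel <- if ("Isotope Label Type" %in% names(raw)) {
      tolower(raw[["Isotope Label Type"]])
    } else rep("light", nrow(raw))
    area <- trimws(raw[["Total Area"]])
    intensity <- suppressWarnings(as.double(area))
    bad <- which(area != "" & is.na(intensity))
    if (length(bad) > 0) {
      abort(paste0("non-numeric Total Area at data row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    intensity[area == ""] <- NA_real_
    rec <- tibble::tibble(
      protein = raw[["Protein Name"]],
      peptide = vapply(parsed, `[[`, character(1), "peptide"),
      ptm_type = vapply(parsed, `[[`, character(1), "ptm_type"),
      site = vapply(parsed, `[[`, character(1), "site"),
      channel = channel,
      sample = raw[["Replicate Name"]],
      intensity = intensity
    )
    return(quant_dataset(rec, reference_sample = reference_sample, ptm = ptm))
  }

  # maxquant
  need <- c("Proteins", "Modified sequence", "Experiment")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("MaxQuant report lacks column(s): ", paste(miss, collapse = ", ")))
  }
  silac <- all(c("Intensity L", "Intensity H") %in% names(raw))
  if (!silac && !"Intensity" %in% names(raw)) {
    abort("MaxQuant report needs 'Intensity' or 'Intensity L'/'Intensity H' columns")
  }
  start <- if ("Start position" %in% names(raw)) {
    suppressWarnings(as.integer(raw[["Start position"]]))
  } else rep(NA_integer_, nrow(raw))
  parsed <- lapply(seq_len(nrow(raw)), function(i) {
    parse_paren_sequence(raw[["Modified sequence"]][i], start[i], i)
  })
  num <- function(col) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.double(v))
    bad <- which(v != "" & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("non-numeric ", col, " at data row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    out[v == ""] <- NA_real_
    out
  }
  base <- tibble::tibble(
    protein = raw[["Proteins"]],
    peptide = vapply(parsed, `[[`, character(1), "peptide"),
    ptm_type = vapply(parsed, `[[`, character(1), "ptm_type"),
    site = vapply(parsed, `[[`, character(1), "site"),
    sample = raw[["Experiment"]]
  )
  rec <- if (silac) {
    bind_rows(
      mutate(base, channel = "light", intensity = num("Intensity L")),
      mutate(base, channel = "heavy", intensity = num("Intensity H"))
    )
  } else {
    mutate(base, channel = "light", intensity = num("Intensity"))
  }
  quant_dataset(rec, reference_sample = reference_sample, ptm = ptm)
}
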