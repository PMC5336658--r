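#' Classify peptides as Q / M / NM
#'
#' For every (protein, peptide sequence) group -- exact sequence match, so
#' peptides with different termini from incomplete or nonspecific proteolysis
#' form separate groups -- the rule is: if no chemoform in the group bears
#' the modification of interest, the whole group is usable for protein
#' quantification and every record is labeled `Q`; otherwise each record is
#' labeled `M` if its own modification state bears the modification of
#' interest and `NM` if not. Chemoforms bearing only *other* modification
#' types do not modify-qualify their group. Classification depends only on
#' the chemoform roster, so it is identical across samples and channels, and
#' re-running it simply overwrites (idempotent).
#'
#' @inheritParams sample_roster
#' @return The dataset with its `class` column (re)assigned.
#' @export
classify_peptides <- function(dataset) {
  qd_assert(dataset)
  ptm <- attr(dataset, "ptm")
  rec <- tibble::as_tibble(dataset)
  if (nrow(rec) == 0) return(dataset)
  carries <- ptm_carries(rec$ptm_type, ptm)
  grp <- paste(rec$protein, rec$peptide, sep = "\r")
  group_modified <- as.logical(ave(carries, grp, FUN = any))
  rec$class <- ifelse(!group_modified, "Q", ifelse(carries, "M", "NM"))
  qd_rebuild(rec, dataset)
}

#' Validate dataset formatting
#'
#' Checks the formatting contract of the interchange table and reports every
#' violation: duplicate record keys, negative intensities, samples or
#' channels off their rosters, and malformed modification states (a site
#' annotation on an unmodified record, or site tokens not of the form
#' residue-letter + 1-based position, e.g. `S5`). An empty report means the
#' dataset passes.
#'
#' @inheritParams sample_roster
#' @param strict If `TRUE`, raise an error on the first finding instead of
#'   reporting.
#' @return A tibble with columns `check`, `row`, `detail` (zero rows when
#'   clean).
#' @export
validate_dataset <- function(dataset, strict = FALSE) {
  qd_assert(dataset)
  rec <- tibble::as_tibble(dataset)
  findings <- list()
  add <- function(check, row, detail) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      check = check, row = as.integer(row), detail = detail)
  }

  key <- do.call(paste, c(rec[qd_key_cols], sep = "\r"))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    rows <- which(key == k)
    add("duplicate_key", rows[1],
        paste0("rows ", paste(rows, collapse = ","), " share key ",
               gsub("\r", "/", k, fixed = TRUE)))
  }
  neg <- which(!is.na(rec$intensity) & rec$intensity < 0)
  for (i in neg) {
    add("negative_intensity", i,
        paste0(rec$protein[i], "/", rec$peptide[i], " in ", rec$sample[i],
               ": intensity ", rec$intensity[i]))
  }
  off <- which(!rec$sample %in% attr(dataset, "samples"))
  for (i in off) add("sample_off_roster", i, rec$sample[i])
  off <- which(!rec$channel %in% attr(dataset, "channels"))
  for (i in off) add("channel_off_roster", i, rec$channel[i])

  site_ok <- function(site) {
    all(grepl("^[A-Z][0-9]+$", strsplit(site, ";", fixed = TRUE)[[1]]))
  }
  for (i in seq_len(nrow(rec))) {
    unmodified <- rec$ptm_type[i] == "none"
    if (unmodified && !is.na(rec$site[i])) {
      add("site_on_unmodified", i,
          paste0(rec$peptide[i], ": site '", rec$site[i],
                 "' on an unmodified record"))
    } else if (!unmodified && !is.na(rec$site[i]) && !site_ok(rec$site[i])) {
      add("malformed_site", i, paste0(rec$peptide[i], ": '", rec$site[i], "'"))
    }
  }

  report <- if (length(findings) == 0) {
    tibble::tibble(check = character(), row = integer(), detail = character())
  } else {
    bind_rows(findings)
  }
  if (strict && nrow(report) > 0) {
    abort(paste0("validation failed: ", report$check[1], " (row ",
                 report$row[1], "): ", report$detail[1]))
  }
  report
}

#' Drop proteins with no quantified peptides
#'
#' A protein is unquantified when every one of its records carries a missing
#' intensity in every sample and channel; such proteins are removed.
#' "Quantified" is read permissively -- a single non-missing intensity
#' anywhere retains the protein (a recorded zero counts as a measurement).
#' Removed protein ids are reported via a message and attached as the
#' `dropped_proteins` attribute of the result.
#'
#' @inheritParams sample_roster
#' @export
drop_unquantified_proteins <- function(dataset) {
  qd_assert(dataset)
  rec <- tibble::as_tibble(dataset)
  quantified <- as.logical(ave(!is.na(rec$intensity), rec$protein, FUN = any))
  dropped <- unique(rec$protein[!quantified])
  out <- qd_rebuild(rec[quantified, , drop = FALSE], dataset)
  if (length(dropped) > 0) {
    inform(paste0("dropped ", length(dropped),
                  " protein(s) with no quantified peptides: ",
                  paste(dropped, collapse = ", ")))
  }
  attr(out, "dropped_proteins") <- dropped
  out
}
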