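# small hand-built fixtures used across test files

# hypothetical protein: peptide A detected phosphorylated and plain, peptide
# B detected plain only; plus a loading-control protein
toy_records <- function() {
  tibble::tibble(
    protein = c(rep("PROT1", 9), rep("CTL1", 3)),
    peptide = c(rep("AVSLDK", 6), rep("ELGTYR", 3), rep("GLLDNK", 3)),
    ptm_type = c(rep("phospho", 3), rep("none", 9)),
    site = c(rep("S3", 3), rep(NA_character_, 9)),
    channel = "light",
    sample = rep(c("S1", "S2", "S3"), 4),
    intensity = c(30, 60, 20, 70, 40, 80, 100, 250, 100, 50, 50, 50)
  )
}

toy_dataset <- function(ptm = "phospho") {
  quant_dataset(toy_records(), ptm = ptm)
}

# write records to a temp CSV in canonical interchange layout
write_fixture_csv <- function(records, path = tempfile(fileext = ".csv")) {
  readr::write_csv(records, path, na = "", progress = FALSE)
  path
}

# strip dataset to a comparable, canonically ordered tibble
canonical_records <- function(dataset) {
  rec <- tibble::as_tibble(dataset)
  rec <- rec[order(rec$protein, rec$peptide, rec$ptm_type,
                   ifelse(is.na(rec$site), "", rec$site),
                   rec$channel, rec$sample), ]
  attr(rec, "samples") <- NULL
  attr(rec, "reference_sample") <- NULL
  attr(rec, "channels") <- NULL
  attr(rec, "ptm") <- NULL
  class(rec) <- class(tibble::tibble())
  tibble::remove_rownames(rec)
}

expect_dataset_equal <- function(a, b) {
  expect_equal(canonical_records(a), canonical_records(b),
               ignore_attr = TRUE)
  expect_identical(sample_roster(a), sample_roster(b))
  expect_identical(reference_sample(a), reference_sample(b))
}
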