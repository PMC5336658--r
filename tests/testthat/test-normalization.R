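# one peptide measured light/heavy across three samples
std_fixture <- function(light = c(10, 20, 5), heavy = c(100, 200, 50)) {
  quant_dataset(tibble::tibble(
    protein = "P1", peptide = "AVSLDK", ptm_type = "none", site = NA_character_,
    channel = rep(c("light", "heavy"), each = 3),
    sample = rep(c("S1", "S2", "S3"), 2),
    intensity = c(light, heavy)
  ))
}

test_that("equimolar equalization forces standards onto the reference target", {
  out <- normalize_equimolar_isotopologue(std_fixture(), "heavy")
  expect_equal(out$factors$factor[order(out$factors$sample)], c(1, 0.5, 2))
  std <- out$dataset$intensity[out$dataset$channel == "heavy"]
  expect_identical(unique(std), 100)            # zero range, exactly
  light <- out$dataset$intensity[out$dataset$channel == "light"]
  expect_equal(light, c(10, 10, 10))

  # already equalized: identity with all factors 1
  eq <- std_fixture(heavy = c(100, 100, 100))
  out2 <- normalize_equimolar_isotopologue(eq, "heavy")
  expect_true(all(out2$factors$factor == 1))
  expect_equal(out2$dataset$intensity, eq$intensity)
})

test_that("equimolar mode recovers ground truth after instrument drift", {
  sim <- simulate_preset("esi_decay")
  ds <- classify_peptides(sim$dataset)
  out <- normalize_equimolar_isotopologue(ds, "heavy")
  got <- dplyr::inner_join(
    tibble::as_tibble(out$dataset), sim$truth$intensity,
    by = c("protein", "peptide", "ptm_type", "site", "channel", "sample"),
    suffix = c("", "_true"))
  expect_equal(got$intensity, got$intensity_true, tolerance = 1e-9)
  # per-chemoform standards have zero range across samples
  std <- got[got$channel == "heavy", ]
  ranges <- tapply(std$intensity,
                   paste(std$protein, std$peptide, std$ptm_type, std$site),
                   function(x) diff(range(x)))
  expect_true(all(ranges == 0))
})

test_that("missing or zero standards are flagged and analytes pass unscaled", {
  ds <- std_fixture(heavy = c(100, 0, NA))
  out <- normalize_equimolar_isotopologue(ds, "heavy")
  fac <- out$factors[order(out$factors$sample), ]
  expect_equal(fac$flagged, c(FALSE, TRUE, TRUE))
  light <- out$dataset$intensity[out$dataset$channel == "light"]
  expect_equal(light, c(10, 20, 5))             # S2/S3 untouched
})

test_that("ratio-to-isotopologue normalization is a per-sample ratio", {
  ds <- std_fixture(light = c(300, 40, 25), heavy = c(100, 200, 50))
  out <- normalize_isotopologue(ds, "heavy")
  light <- out$dataset$intensity[out$dataset$channel == "light"]
  expect_equal(light, c(3, 0.2, 0.5))
  heavy <- out$dataset$intensity[out$dataset$channel == "heavy"]
  expect_equal(heavy, c(1, 1, 1))               # standard over itself

  same <- std_fixture(light = c(100, 200, 50))
  expect_true(all(normalize_isotopologue(same, "heavy")$dataset$intensity == 1))
})

test_that("ratio mode cancels any per-sample distortion of both channels", {
  for (seed in c(21L, 22L, 23L)) {
    set.seed(seed)
    mult <- rlnorm(3, 0, 1)
    base <- std_fixture(light = c(30, 60, 15), heavy = c(120, 80, 40))
    rec <- tibble::as_tibble(base)
    rec$intensity <- rec$intensity * mult[match(rec$sample, c("S1", "S2", "S3"))]
    distorted <- quant_dataset(rec)
    r1 <- normalize_isotopologue(base, "heavy")$dataset$intensity
    r2 <- normalize_isotopologue(distorted, "heavy")$dataset$intensity
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("TIC normalization equalizes totals and recovers loading errors", {
  one <- toy_records()[toy_records()$sample == "S1", ]
  rec <- dplyr::bind_rows(lapply(c("S1", "S2", "S3"), function(s) {
    r <- one
    r$sample <- s
    r
  }))
  doubled <- rec
  doubled$intensity <- ifelse(doubled$sample == "S2", 2, 1) * doubled$intensity
  out <- normalize_tic(quant_dataset(doubled))
  expect_equal(out$factors$factor[out$factors$sample == "S2"], 0.5)
  expect_equal(canonical_records(out$dataset)$intensity,
               canonical_records(quant_dataset(rec))$intensity)

  single <- quant_dataset(rec[rec$sample == "S1", ])
  out1 <- normalize_tic(single)
  expect_equal(out1$factors$factor, 1)
  expect_equal(out1$dataset$intensity, rec$intensity[rec$sample == "S1"])

  sim <- simulate_preset("loading_error")
  ds <- classify_peptides(sim$dataset)
  out <- normalize_tic(ds)
  got <- dplyr::inner_join(
    tibble::as_tibble(out$dataset), sim$truth$intensity,
    by = c("protein", "peptide", "ptm_type", "site", "channel", "sample"),
    suffix = c("", "_true"))
  expect_equal(got$intensity, got$intensity_true, tolerance = 1e-9)

  zero <- rec
  zero$intensity[zero$sample == "S3"] <- 0
  expect_error(normalize_tic(quant_dataset(zero)), "S3")
})

test_that("TIC normalization conserves within-sample rank order", {
  sim <- simulate_dataset(sim_config(n_proteins = 4, noise_cv = 0.3, seed = 31L))
  out <- normalize_tic(sim$dataset, standard_channel = "heavy")
  before <- tibble::as_tibble(sim$dataset)
  after <- tibble::as_tibble(out$dataset)
  for (s in sample_roster(sim$dataset)) {
    expect_identical(order(before$intensity[before$sample == s]),
                     order(after$intensity[after$sample == s]))
  }
})

test_that("internal-reference normalization scales by loading-control sums", {
  rec <- toy_records()
  # CTL1 sums are (50, 50, 50); rescale S2/S3 to make them (50, 100, 25)
  rec$intensity <- rec$intensity * c(S1 = 1, S2 = 2, S3 = 0.5)[rec$sample]
  out <- normalize_internal_reference(quant_dataset(rec), "CTL1")
  expect_equal(out$factors$factor, c(1, 0.5, 2))
  expect_equal(canonical_records(out$dataset)$intensity,
               canonical_records(quant_dataset(toy_records()))$intensity)

  # reference roster = all proteins reduces to TIC
  ds <- quant_dataset(toy_records())
  via_ref <- normalize_internal_reference(ds, unique(ds$protein))
  via_tic <- normalize_tic(ds)
  expect_equal(via_ref$dataset$intensity, via_tic$dataset$intensity)

  missing <- toy_records()
  missing$intensity[missing$protein == "CTL1" & missing$sample == "S2"] <- NA
  expect_error(normalize_internal_reference(quant_dataset(missing), "CTL1"),
               "CTL1.*S2")
})

test_that("genuine protein variation survives internal-reference but not TIC", {
  sim <- simulate_preset("protein_variation")
  ds <- classify_peptides(sim$dataset)
  out <- normalize_internal_reference(ds, c("CTL1", "CTL2"),
                                      standard_channel = "heavy")
  got <- dplyr::inner_join(
    tibble::as_tibble(out$dataset)[out$dataset$channel == "light", ],
    sim$truth$intensity,
    by = c("protein", "peptide", "ptm_type", "site", "channel", "sample"),
    suffix = c("", "_true"))
  expect_equal(got$intensity, got$intensity_true, tolerance = 1e-9)
  # the doubling of P001 in S2 is preserved
  ab <- exact_abundance(classify_peptides(out$dataset), channels = "light")
  expect_equal(ab$relative_abundance[ab$protein == "P001" & ab$sample == "S2"],
               2, tolerance = 1e-9)
  # TIC would dilute it toward 1
  tic <- normalize_tic(ds, standard_channel = "heavy")
  ab_tic <- exact_abundance(classify_peptides(tic$dataset), channels = "light")
  expect_lt(ab_tic$relative_abundance[ab_tic$protein == "P001" &
                                        ab_tic$sample == "S2"], 2)
})

test_that("all four modes are idempotent on their own output", {
  sim <- simulate_dataset(sim_config(n_proteins = 3, noise_cv = 0.2, seed = 41L))
  ds <- classify_peptides(sim$dataset)
  rerun_factors <- list(
    equimolar = function(d) normalize_equimolar_isotopologue(d, "heavy"),
    isotopologue = function(d) normalize_isotopologue(d, "heavy"),
    tic = function(d) normalize_tic(d, standard_channel = "heavy"),
    internal = function(d) normalize_internal_reference(d, "CTL1",
                                                        standard_channel = "heavy")
  )
  for (f in rerun_factors) {
    once <- f(ds)
    twice <- f(once$dataset)
    expect_equal(twice$factors$factor, rep(1, nrow(twice$factors)),
                 tolerance = 1e-9)
  }
})
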