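# single-protein fixture with explicit classes via classify_peptides
abundance_fixture <- function(q_intensity = c(100, 250, 100)) {
  classify_peptides(quant_dataset(tibble::tibble(
    protein = "P1", peptide = "ELGTYR", ptm_type = "none", site = NA_character_,
    channel = "light", sample = c("S1", "S2", "S3"), intensity = q_intensity
  )))
}

test_that("exact abundance is the paired ratio to the reference sample", {
  ab <- exact_abundance(abundance_fixture())
  expect_equal(ab$relative_abundance[order(ab$sample)], c(1, 2.5, 1))
  expect_true(all(ab$method == "exact"))
  expect_identical(ab$relative_abundance[ab$sample == "S1"], 1)

  only_ref <- abundance_fixture(100)
  ds <- quant_dataset(tibble::as_tibble(only_ref)[only_ref$sample == "S1", ])
  ab1 <- exact_abundance(classify_peptides(ds))
  expect_equal(nrow(ab1), 1)
  expect_identical(ab1$relative_abundance, 1)
})

test_that("paired aggregation skips peptides missing from one side", {
  rec <- tibble::tibble(
    protein = "P1",
    peptide = rep(c("ELGTYR", "GTIDNK"), each = 2),
    ptm_type = "none", site = NA_character_, channel = "light",
    sample = rep(c("S1", "S2"), 2),
    intensity = c(100, 200, 50, NA)   # GTIDNK undetected in S2
  )
  ab <- exact_abundance(classify_peptides(quant_dataset(rec)))
  # S2 ratio from the shared peptide only: 200/100, not (200)/(150)
  expect_equal(ab$relative_abundance[ab$sample == "S2"], 2)
  expect_equal(ab$n_peptides_used[ab$sample == "S2"], 1)
  expect_equal(ab$n_peptides_used[ab$sample == "S1"], 2)
})

test_that("zero reference intensity is flagged undefined, not a number", {
  ab <- exact_abundance(abundance_fixture(c(0, 10, 20)))
  expect_true(all(ab$flag == "undefined"))
  expect_true(all(is.na(ab$relative_abundance)))
})

test_that("approximate abundance sums all chemoforms of modified peptides", {
  rec <- tibble::tibble(
    protein = "P1", peptide = "AVSLDK",
    ptm_type = rep(c("phospho", "none"), each = 3),
    site = rep(c("S3", NA), each = 3),
    channel = "light", sample = rep(c("S1", "S2", "S3"), 2),
    intensity = c(100, 300, 150, 300, 500, 250)   # sums 400, 800, 400
  )
  ab <- approximate_abundance(classify_peptides(quant_dataset(rec)))
  expect_equal(ab$relative_abundance[order(ab$sample)], c(1, 2, 1))
  expect_true(all(ab$method == "approximate"))
})

test_that("exact stoichiometry is modified over total chemoform intensity", {
  rec <- tibble::tibble(
    protein = "P1", peptide = "AVSLDK",
    ptm_type = c("phospho", "none"), site = c("S3", NA),
    channel = "light", sample = "S1", intensity = c(3, 1)
  )
  st <- exact_stoichiometry(classify_peptides(quant_dataset(rec)))
  expect_equal(st$stoichiometry, 0.75)

  rec$intensity <- c(0, 5)
  st0 <- exact_stoichiometry(classify_peptides(quant_dataset(rec)))
  expect_equal(st0$stoichiometry, 0)   # boundary: nothing modified

  rec$intensity <- c(0, 0)
  stu <- exact_stoichiometry(classify_peptides(quant_dataset(rec)))
  expect_identical(stu$flag, "undefined")
})

test_that("two singly modified chemoforms conserve total occupancy", {
  rec <- tibble::tibble(
    protein = "P1", peptide = "ASTLDK",
    ptm_type = c("phospho", "phospho", "none"),
    site = c("S2", "T3", NA),
    channel = "light", sample = "S1", intensity = c(2, 3, 5)
  )
  st <- exact_stoichiometry(classify_peptides(quant_dataset(rec)))
  expect_equal(st$stoichiometry[st$site == "S2"], 0.2)
  expect_equal(st$stoichiometry[st$site == "T3"], 0.3)
  unmodified_fraction <- 5 / 10
  expect_equal(sum(st$stoichiometry) + unmodified_fraction, 1, tolerance = 1e-12)
})

test_that("doubly modified chemoforms count per site and once in the total", {
  rec <- tibble::tibble(
    protein = "P1", peptide = "ASTLDK",
    ptm_type = c("phospho;phospho", "phospho", "none"),
    site = c("S2;T3", "S2", NA),
    channel = "light", sample = "S1", intensity = c(4, 2, 4)
  )
  st <- exact_stoichiometry(classify_peptides(quant_dataset(rec)))
  expect_equal(st$stoichiometry[st$site == "S2"], 0.6)  # (4 + 2) / 10
  expect_equal(st$stoichiometry[st$site == "T3"], 0.4)  # 4 / 10
})

test_that("approximate stoichiometry divides by the Q proxy per policy", {
  rec <- tibble::tibble(
    protein = "P1",
    peptide = c("AVSLDK", "ELGTYR", "GTIDNK"),
    ptm_type = c("phospho", "none", "none"),
    site = c("S3", NA, NA),
    channel = "light", sample = "S1",
    intensity = c(50, 200, 100)        # no NM partner for AVSLDK
  )
  ds <- classify_peptides(quant_dataset(rec))
  expect_equal(approximate_stoichiometry(ds, proxy_policy = "mean")$stoichiometry,
               50 / 150)
  expect_equal(approximate_stoichiometry(ds, proxy_policy = "sum")$stoichiometry,
               50 / 300)
  expect_equal(approximate_stoichiometry(ds, proxy_policy = "single")$stoichiometry,
               50 / 200)               # lexicographically first Q peptide

  # values above 1 are reported and flagged, never clipped
  hot <- rec
  hot$intensity[1] <- 500
  st <- approximate_stoichiometry(classify_peptides(quant_dataset(hot)))
  expect_gt(st$stoichiometry, 1)
  expect_identical(st$flag, "out_of_range")

  # no Q proxy: the site is skipped with a logged reason
  orphan <- rec[1, ]
  got <- suppressMessages(
    approximate_stoichiometry(classify_peptides(quant_dataset(orphan))))
  expect_equal(nrow(got), 0)
})

test_that("run_analysis dispatches exact and approximate per availability", {
  sim <- simulate_dataset(sim_config(n_proteins = 3, seed = 51L))
  ds <- classify_peptides(sim$dataset)
  complete <- run_analysis(ds, channels = "light")
  expect_true(all(complete$abundance$method == "exact"))
  expect_true(all(complete$stoichiometry$method == "exact"))

  # withhold Q for one protein only
  rec <- tibble::as_tibble(ds)
  sparse <- quant_dataset(rec[!(rec$protein == "P002" & rec$class == "Q"), ],
                          reference_sample = "S1")
  res <- run_analysis(sparse, channels = "light")
  method_by_protein <- tapply(res$abundance$method, res$abundance$protein, unique)
  expect_identical(method_by_protein[["P002"]], "approximate")
  expect_true(all(unlist(method_by_protein[names(method_by_protein) != "P002"]) ==
                    "exact"))
  expect_equal(res$summary$n_abundance_approximate, 3)

  empty <- quant_dataset(rec[0, ], samples = "S1")
  res0 <- run_analysis(empty)
  expect_equal(nrow(res0$abundance), 0)
  expect_equal(nrow(res0$stoichiometry), 0)
})

test_that("rescaling a non-reference sample moves abundance, not stoichiometry", {
  sim <- simulate_dataset(sim_config(n_proteins = 2, noise_cv = 0.1, seed = 61L))
  ds <- classify_peptides(sim$dataset)
  base <- run_analysis(ds, channels = "light")
  rec <- tibble::as_tibble(ds)
  rec$intensity[rec$sample == "S2"] <- rec$intensity[rec$sample == "S2"] * 7
  scaled <- run_analysis(quant_dataset(rec, reference_sample = "S1"),
                         channels = "light")
  expect_equal(scaled$stoichiometry$stoichiometry,
               base$stoichiometry$stoichiometry, tolerance = 1e-12)
  s2 <- base$abundance$sample == "S2"
  expect_equal(scaled$abundance$relative_abundance[s2],
               7 * base$abundance$relative_abundance[s2], tolerance = 1e-12)
  expect_equal(scaled$abundance$relative_abundance[!s2],
               base$abundance$relative_abundance[!s2], tolerance = 1e-12)
})
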