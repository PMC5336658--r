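# Simulator of peptide-level quantitative MS experiments: ground-truth
# molarities and site occupancies, peptide-specific ionization efficiencies,
# spike-in isotopologue standards, injected technical artifacts, selective
# withholding of peptide classes, and multiplicative log-normal measurement
# noise. Signal model per analyte measurement:
#
#   intensity = molarity x chemoform fraction x ionization efficiency
#               x artifact multiplier x noise draw
#
# Standards: standard molarity x efficiency x artifact multiplier x noise,
# where instrument- and loading-level artifacts (esi_decay, loading_error,
# enrichment) hit both channels -- standards are spiked before acquisition --
# while the loading distortion induced by genuine per-protein variation
# (protein_variation) hits the analyte channel only.

sim_artifact_types <- c("none", "esi_decay", "loading_error", "enrichment",
                        "protein_variation")

#' Configure a simulated experiment
#'
#' Defaults describe the canonical design used throughout: a hypothetical
#' phosphorylated protein producing four peptides, two of which bear the
#' modification (one site each), plus unmodified loading-control proteins,
#' across three samples with equimolar heavy-isotope standards.
#'
#' @param n_conditions Number of biological conditions (default 3); sample 1
#'   of condition 1 is the reference sample.
#' @param n_replicates Replicate measurements per condition (default 1);
#'   replicates share ground truth and differ by noise.
#' @param n_proteins Hypothetical modified proteins (`P001`, ...).
#' @param n_control_proteins Loading-control proteins (`CTL1`, ...), all
#'   peptides unmodified, molarity constant across conditions.
#' @param n_peptides,n_modified Peptides per modified protein and how many of
#'   them carry the PTM (one site each, detected as modified + unmodified
#'   chemoform pairs).
#' @param n_control_peptides Peptides per control protein.
#' @param molarity Optional `n_proteins x n_conditions` matrix of true
#'   molarities (arbitrary molar units). Default: 100 in condition 1,
#'   `100 * lognormal(0, molarity_sdlog)` fold changes elsewhere.
#' @param control_molarity Constant molarity of control proteins.
#' @param molarity_sdlog Log-sd of drawn fold changes (default `log(2)`).
#' @param stoichiometry Optional `n_proteins x n_modified x n_conditions`
#'   array of true site occupancies in (0, 1).
#' @param stoich_range Range of drawn base occupancies.
#' @param stoich_variation `"independent"` draws each condition's occupancy
#'   independently; `"jitter"` draws one base occupancy per site and shifts
#'   it by up to `stoich_jitter` per condition (modest signaling-scale
#'   changes); `"constant"` holds occupancies fixed across conditions.
#' @param stoich_jitter Absolute occupancy shift bound for `"jitter"`.
#' @param efficiency_cv Coefficient of variation of per-chemoform ionization
#'   efficiencies (log-normal, mean 1); 0 gives unit efficiency everywhere.
#'   Both isotopic channels of a chemoform share its efficiency.
#' @param spike_standard Whether heavy-isotopologue standards are spiked.
#' @param standard_equimolar If `TRUE`, all standards at `standard_molarity`;
#'   if `FALSE`, per-chemoform molarities drawn log-normally around it
#'   (non-equimolar labeled reference, SILAC-style).
#' @param standard_molarity Spike-in molarity (same units as `molarity`).
#' @param analyte_channel,standard_channel Channel tokens.
#' @param artifact Injected technical artifact:
#'   `list(type = "none")`;
#'   `list(type = "esi_decay", multipliers =)` per-sample instrument drift;
#'   `list(type = "loading_error", multipliers =)` per-sample loading;
#'   `list(type = "enrichment", multipliers =)` per-sample enrichment of
#'   PTM-bearing chemoforms;
#'   `list(type = "protein_variation", proteins =, multipliers =)` genuine
#'   per-protein molarity changes (rows = proteins, cols = samples) followed
#'   by equalize-total-protein loading of the analyte channel.
#' @param withhold Peptide design classes (`"Q"`, `"NM"`, `"M"`) whose
#'   records are deleted after generation, emulating non-detection.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   measurement noise (0 = deterministic).
#' @param ptm Modification-of-interest token.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_conditions = 3, n_replicates = 1,
                       n_proteins = 1, n_control_proteins = 2,
                       n_peptides = 4, n_modified = 2, n_control_peptides = 2,
                       molarity = NULL, control_molarity = 100,
                       molarity_sdlog = log(2),
                       stoichiometry = NULL, stoich_range = c(0.1, 0.9),
                       stoich_variation = c("independent", "jitter", "constant"),
                       stoich_jitter = 0.05,
                       efficiency_cv = 0,
                       spike_standard = TRUE, standard_equimolar = TRUE,
                       standard_molarity = 100,
                       analyte_channel = "light", standard_channel = "heavy",
                       artifact = list(type = "none"),
                       withhold = character(), noise_cv = 0,
                       ptm = "phospho", seed = 1L) {
  stoich_variation <- match.arg(stoich_variation)
  stopifnot(n_conditions >= 1, n_replicates >= 1, n_proteins >= 0,
            n_control_proteins >= 0, n_peptides >= 1,
            n_modified >= 0, n_modified <= n_peptides,
            control_molarity > 0, standard_molarity > 0,
            noise_cv >= 0, efficiency_cv >= 0,
            stoich_range[1] > 0, stoich_range[2] < 1,
            stoich_range[1] <= stoich_range[2])
  n_samples <- n_conditions * n_replicates
  if (!is.null(molarity)) {
    molarity <- as.matrix(molarity)
    if (!all(dim(molarity) == c(n_proteins, n_conditions))) {
      abort("molarity must be an n_proteins x n_conditions matrix")
    }
    if (any(molarity <= 0)) abort("molarities must be positive")
  }
  if (!is.null(stoichiometry)) {
    stoichiometry <- array(stoichiometry,
                           dim = c(n_proteins, n_modified, n_conditions))
    if (any(stoichiometry <= 0 | stoichiometry >= 1)) {
      abort("stoichiometries must lie strictly in (0, 1)")
    }
  }
  if (!artifact$type %in% sim_artifact_types) {
    abort(paste0("unknown artifact type '", artifact$type, "'"))
  }
  if (artifact$type %in% c("esi_decay", "loading_error", "enrichment")) {
    if (length(artifact$multipliers) != n_samples || any(artifact$multipliers <= 0)) {
      abort("artifact multipliers must be positive, one per sample")
    }
  }
  if (artifact$type == "protein_variation") {
    artifact$multipliers <- matrix(artifact$multipliers,
                                   nrow = length(artifact$proteins))
    if (ncol(artifact$multipliers) != n_samples || any(artifact$multipliers <= 0)) {
      abort("protein_variation multipliers must be positive, proteins x samples")
    }
  }
  if (length(withhold) > 0) {
    withhold <- match.arg(withhold, c("Q", "M", "NM"), several.ok = TRUE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# deterministic unique peptide sequences; alphabet omits S so the single
# phospho-acceptor serine sits at peptide position 4 of modified peptides
sim_peptide <- function(protein_index, peptide_index, modified) {
  alpha <- strsplit("ACDEFGHIKLMNPQTVWY", "")[[1]]
  n <- length(alpha)
  i <- protein_index - 1L
  paste0(alpha[(i %/% n) %% n + 1L], alpha[i %% n + 1L],
         alpha[(peptide_index - 1L) %% n + 1L],
         if (modified) "S" else "L", "GELVK")
}

# chemoform design table for a config (no RNG)
sim_chemoforms <- function(config) {
  rows <- list()
  all_proteins <- c(
    if (config$n_proteins > 0) sprintf("P%03d", seq_len(config$n_proteins)),
    if (config$n_control_proteins > 0) sprintf("CTL%d", seq_len(config$n_control_proteins))
  )
  for (pi in seq_along(all_proteins)) {
    p <- all_proteins[[pi]]
    is_control <- pi > config$n_proteins
    n_pep <- if (is_control) config$n_control_peptides else config$n_peptides
    for (j in seq_len(n_pep)) {
      modified <- !is_control && j <= config$n_modified
      pep <- sim_peptide(pi, j, modified)
      start <- (j - 1L) * 20L + 1L
      if (modified) {
        site <- paste0("S", start + 3L)
        rows[[length(rows) + 1]] <- tibble::tibble(
          protein = p, peptide = pep,
          ptm_type = c("none", config$ptm), site = c(NA_character_, site),
          design_class = c("NM", "M"),
          protein_index = pi, site_index = j, control = is_control)
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          protein = p, peptide = pep,
          ptm_type = "none", site = NA_character_,
          design_class = "Q",
          protein_index = pi, site_index = NA_integer_, control = is_control)
      }
    }
  }
  bind_rows(rows)
}

#' Simulate a peptide-level quantification experiment
#'
#' Generates measured intensities from the configured ground truth (see
#' [sim_config()] for the signal model) and returns both the observable
#' dataset and the truth tables needed to score any downstream calculation.
#'
#' @param config A [sim_config()].
#' @return A list:
#' \describe{
#'   \item{`dataset`}{[quant_dataset()] of observed records (classes
#'     unassigned; run [classify_peptides()]).}
#'   \item{`truth`}{list of tibbles: `abundance` (true fold change vs. the
#'     reference sample per protein x sample), `stoichiometry` (true site
#'     occupancy per site x sample), `intensity` (noiseless, artifact-free
#'     intensities per record, both channels).}
#'   \item{`config`}{the configuration used.}
#' }
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  nc <- config$n_conditions
  nr <- config$n_replicates
  n_samples <- nc * nr
  cond_of <- rep(seq_len(nc), each = nr)
  samples <- if (nr == 1) paste0("S", seq_len(nc)) else
    paste0("S", rep(seq_len(nc), each = nr), "_r", rep(seq_len(nr), nc))

  set.seed(config$seed)

  # ground-truth molarities (hypothetical proteins x conditions)
  molarity <- config$molarity
  if (is.null(molarity) && config$n_proteins > 0) {
    molarity <- matrix(100, config$n_proteins, nc)
    if (nc > 1) {
      molarity[, -1] <- 100 * rlnorm(config$n_proteins * (nc - 1),
                                     0, config$molarity_sdlog)
    }
  }

  # ground-truth occupancies
  st <- config$stoichiometry
  if (is.null(st) && config$n_proteins > 0 && config$n_modified > 0) {
    st <- array(NA_real_, c(config$n_proteins, config$n_modified, nc))
    base <- matrix(runif(config$n_proteins * config$n_modified,
                         config$stoich_range[1], config$stoich_range[2]),
                   config$n_proteins, config$n_modified)
    for (k in seq_len(nc)) {
      st[, , k] <- switch(config$stoich_variation,
        independent = matrix(runif(length(base), config$stoich_range[1],
                                   config$stoich_range[2]), nrow(base)),
        jitter = pmin(pmax(base + matrix(runif(length(base), -config$stoich_jitter,
                                               config$stoich_jitter), nrow(base)),
                           0.02), 0.98),
        constant = base)
    }
  }

  chemo <- sim_chemoforms(config)
  n_chemo <- nrow(chemo)

  chemo$efficiency <- if (config$efficiency_cv > 0) {
    s <- sqrt(log(1 + config$efficiency_cv^2))
    rlnorm(n_chemo, -s^2 / 2, s)
  } else rep(1, n_chemo)

  chemo$std_molarity <- if (!config$spike_standard) {
    NA_real_
  } else if (config$standard_equimolar) {
    rep(config$standard_molarity, n_chemo)
  } else {
    rlnorm(n_chemo, log(config$standard_molarity), log(2))
  }

  # long grid: chemoform x sample
  grid <- chemo[rep(seq_len(n_chemo), each = n_samples), ]
  grid$sample <- rep(samples, n_chemo)
  grid$condition <- rep(cond_of, n_chemo)

  grid$molarity <- rep(config$control_molarity, nrow(grid))
  hyp <- !grid$control
  if (any(hyp)) {
    grid$molarity[hyp] <- molarity[cbind(grid$protein_index[hyp],
                                         grid$condition[hyp])]
  }
  occ <- rep(NA_real_, nrow(grid))
  has_site <- !is.na(grid$site_index)
  if (any(has_site)) {
    occ[has_site] <- st[cbind(grid$protein_index[has_site],
                              grid$site_index[has_site],
                              grid$condition[has_site])]
  }
  grid$fraction <- ifelse(grid$design_class == "M", occ,
                          ifelse(grid$design_class == "NM", 1 - occ, 1))

  # genuine per-protein variation enters the ground truth
  art <- config$artifact
  if (art$type == "protein_variation") {
    idx <- match(grid$protein, art$proteins)
    smp <- match(grid$sample, samples)
    hit <- !is.na(idx)
    grid$molarity[hit] <- grid$molarity[hit] * art$multipliers[cbind(idx[hit], smp[hit])]
  }

  grid$true_analyte <- grid$molarity * grid$fraction * grid$efficiency
  grid$true_std <- grid$std_molarity * grid$efficiency

  # technical artifact multipliers
  smp <- match(grid$sample, samples)
  art_analyte <- rep(1, nrow(grid))
  art_std <- rep(1, nrow(grid))
  if (art$type %in% c("esi_decay", "loading_error")) {
    art_analyte <- art$multipliers[smp]
    art_std <- art$multipliers[smp]
  } else if (art$type == "enrichment") {
    m <- ifelse(grid$design_class == "M", art$multipliers[smp], 1)
    art_analyte <- m
    art_std <- m
  } else if (art$type == "protein_variation") {
    # equalize total protein loaded (analyte only; standards spiked after)
    prot <- distinct(grid[c("protein", "sample", "molarity")])
    tot <- vapply(samples, function(s) sum(prot$molarity[prot$sample == s]),
                  numeric(1))
    art_analyte <- (tot[[1]] / tot)[smp]
  }

  noise <- function(n) {
    if (config$noise_cv == 0) return(rep(1, n))
    s <- sqrt(log(1 + config$noise_cv^2))
    rlnorm(n, -s^2 / 2, s)
  }
  obs_analyte <- grid$true_analyte * art_analyte * noise(nrow(grid))
  obs_std <- if (config$spike_standard) {
    grid$true_std * art_std * noise(nrow(grid))
  } else NULL

  analyte_rec <- tibble::tibble(
    protein = grid$protein, peptide = grid$peptide, ptm_type = grid$ptm_type,
    site = grid$site, channel = config$analyte_channel, sample = grid$sample,
    intensity = obs_analyte, class = "unassigned",
    design_class = grid$design_class)
  rec <- if (config$spike_standard) {
    bind_rows(analyte_rec,
              mutate(analyte_rec, channel = config$standard_channel,
                     intensity = obs_std))
  } else analyte_rec

  if (length(config$withhold) > 0) {
    rec <- rec[!rec$design_class %in% config$withhold, , drop = FALSE]
  }
  channels <- if (config$spike_standard) {
    c(config$analyte_channel, config$standard_channel)
  } else config$analyte_channel
  dataset <- quant_dataset(rec[qd_record_cols], reference_sample = samples[1],
                           ptm = config$ptm, samples = samples,
                           channels = channels)

  # truth tables
  all_prot <- unique(chemo[c("protein", "protein_index", "control")])
  truth_ab <- tidyr::expand_grid(all_prot, sample = samples)
  truth_ab$condition <- cond_of[match(truth_ab$sample, samples)]
  truth_ab$mol <- rep(config$control_molarity, nrow(truth_ab))
  hyp <- !truth_ab$control
  if (any(hyp)) {
    truth_ab$mol[hyp] <- molarity[cbind(truth_ab$protein_index[hyp],
                                        truth_ab$condition[hyp])]
  }
  if (art$type == "protein_variation") {
    idx <- match(truth_ab$protein, art$proteins)
    hit <- !is.na(idx)
    truth_ab$mol[hit] <- truth_ab$mol[hit] *
      art$multipliers[cbind(idx[hit], match(truth_ab$sample, samples)[hit])]
  }
  ref_mol <- truth_ab$mol[match(paste(truth_ab$protein, samples[1]),
                                paste(truth_ab$protein, truth_ab$sample))]
  truth_abundance <- tibble::tibble(protein = truth_ab$protein,
                                    sample = truth_ab$sample,
                                    fold_change = truth_ab$mol / ref_mol)

  msub <- grid[grid$design_class == "M", , drop = FALSE]
  truth_stoich <- tibble::tibble(protein = msub$protein, peptide = msub$peptide,
                                 site = msub$site, sample = msub$sample,
                                 stoichiometry = msub$fraction)

  truth_int <- tibble::tibble(
    protein = grid$protein, peptide = grid$peptide, ptm_type = grid$ptm_type,
    site = grid$site, channel = config$analyte_channel, sample = grid$sample,
    intensity = grid$true_analyte)
  if (config$spike_standard) {
    truth_int <- bind_rows(truth_int,
                           mutate(truth_int, channel = config$standard_channel,
                                  intensity = grid$true_std))
  }

  list(dataset = dataset,
       truth = list(abundance = truth_abundance,
                    stoichiometry = truth_stoich,
                    intensity = truth_int),
       config = config)
}

#' Named preset simulated datasets
#'
#' Eleven scenarios covering the designs used to exercise every stage:
#' a complete baseline; four "identical samples + injected artifact"
#' datasets matched to the four normalization modes; an enrichment
#' distortion; and five analysis scenarios (complete and
#' class-withheld variants of the four-peptide worked design measured in
#' triplicate, plus a 50-protein correlation benchmark with variable
#' ionization efficiencies). `preset_names()` lists them; each preset
#' documents its parameters through the returned `config`.
#'
#' @param name One of `preset_names()`.
#' @param seed Optional seed overriding the preset's documented default.
#' @return `simulate_preset()`: the [simulate_dataset()] result for the
#'   scenario.
#' @export
simulate_preset <- function(name, seed = NULL) {
  name <- match.arg(name, preset_names())
  identical3 <- function(n_prot) matrix(100, n_prot, 3)
  cfg <- switch(name,
    baseline_complete = sim_config(seed = 101L),
    esi_decay = sim_config(
      molarity = identical3(1), stoich_variation = "constant",
      artifact = list(type = "esi_decay", multipliers = c(1, 0.7, 0.4)),
      seed = 102L),
    silac_nonequimolar = sim_config(
      molarity = identical3(1), stoich_variation = "constant",
      standard_equimolar = FALSE,
      artifact = list(type = "loading_error", multipliers = c(1, 1.3, 0.8)),
      seed = 103L),
    loading_error = sim_config(
      molarity = identical3(1), stoich_variation = "constant",
      spike_standard = FALSE,
      artifact = list(type = "loading_error", multipliers = c(1, 1.3, 0.8)),
      seed = 104L),
    protein_variation = sim_config(
      molarity = identical3(1), stoich_variation = "constant",
      artifact = list(type = "protein_variation", proteins = "P001",
                      multipliers = c(1, 2, 0.5)),
      seed = 105L),
    modified_enrichment = sim_config(
      molarity = identical3(1), stoich_variation = "constant",
      artifact = list(type = "enrichment", multipliers = c(1, 3, 0.5)),
      seed = 106L),
    analysis_complete = sim_config(
      n_replicates = 3, molarity = matrix(c(100, 200, 50), 1, 3),
      stoich_variation = "jitter", efficiency_cv = 0.3, noise_cv = 0.05,
      seed = 107L),
    abundance_q_withheld = sim_config(
      n_replicates = 3, molarity = matrix(c(100, 200, 50), 1, 3),
      stoich_variation = "jitter", efficiency_cv = 0.3, noise_cv = 0.05,
      withhold = "Q", seed = 108L),
    stoichiometry_nm_withheld = sim_config(
      n_replicates = 3, molarity = matrix(c(100, 200, 50), 1, 3),
      stoich_variation = "jitter", efficiency_cv = 0.3, noise_cv = 0.05,
      withhold = "NM", seed = 109L),
    sparse_q_nm_withheld = sim_config(
      n_replicates = 3, molarity = matrix(c(100, 200, 50), 1, 3),
      stoich_variation = "jitter", efficiency_cv = 0.3, noise_cv = 0.05,
      withhold = c("Q", "NM"), seed = 110L),
    correlation_benchmark = sim_config(
      n_proteins = 50, n_control_proteins = 5,
      efficiency_cv = 0.3, noise_cv = 0.05, seed = 111L)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  simulate_dataset(cfg)
}

#' @rdname simulate_preset
#' @export
preset_names <- function() {
  c("baseline_complete", "esi_decay", "silac_nonequimolar", "loading_error",
    "protein_variation", "modified_enrichment", "analysis_complete",
    "abundance_q_withheld", "stoichiometry_nm_withheld",
    "sparse_q_nm_withheld", "correlation_benchmark")
}

#' Write preset fixtures to disk
#'
#' Writes, per preset, the interchange data CSV plus companion ground-truth
#' CSVs (`<name>.csv`, `<name>_truth_abundance.csv`,
#' `<name>_truth_stoichiometry.csv`, `<name>_truth_intensity.csv`).
#'
#' @param dir Output directory (created if needed).
#' @param names Presets to write (default all).
#' @param seed Optional seed override passed to every preset.
#' @export
write_presets <- function(dir, names = preset_names(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names) {
    sim <- simulate_preset(nm, seed = seed)
    write_quant_csv(sim$dataset, file.path(dir, paste0(nm, ".csv")))
    readr::write_csv(sim$truth$abundance,
                     file.path(dir, paste0(nm, "_truth_abundance.csv")),
                     progress = FALSE)
    readr::write_csv(sim$truth$stoichiometry,
                     file.path(dir, paste0(nm, "_truth_stoichiometry.csv")),
                     progress = FALSE)
    readr::write_csv(sim$truth$intensity,
                     file.path(dir, paste0(nm, "_truth_intensity.csv")),
                     na = "", progress = FALSE)
  }
  invisible(dir)
}
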