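# Analysis: relative protein abundance and per-site PTM stoichiometry,
# exact when the chemoform coverage allows it, approximate otherwise.
# Formulas are channel-agnostic: they consume whatever the normalization
# stage emitted (raw intensities or ratio units); restrict `channels` to the
# analyte channel(s) when a standard channel is still present.

analysis_records <- function(dataset, channels) {
  qd_assert(dataset)
  rec <- tibble::as_tibble(dataset)
  if (nrow(rec) > 0 && any(rec$class == "unassigned")) {
    abort("dataset has unclassified records; run classify_peptides() first")
  }
  if (!is.null(channels)) rec <- rec[rec$channel %in% channels, , drop = FALSE]
  rec
}

abundance_cols <- function() {
  tibble::tibble(protein = character(), sample = character(),
                 relative_abundance = double(), method = character(),
                 n_peptides_used = integer(), flag = character())
}

stoichiometry_cols <- function() {
  tibble::tibble(protein = character(), peptide = character(),
                 site = character(), sample = character(),
                 stoichiometry = double(), method = character(),
                 flag = character())
}

# paired ratio-to-reference over a set of records: for each sample, sum over
# the (peptide, modification, channel) keys observed non-missing in both the
# sample and the reference sample, then ratio the sums. Pairing avoids
# composition bias when peptides drop out of single samples.
paired_abundance <- function(rec, ref, method) {
  rec <- rec[!is.na(rec$intensity), , drop = FALSE]
  if (nrow(rec) == 0) return(abundance_cols())
  keys <- c("peptide", "ptm_type", "site", "channel")
  refrec <- rec[rec$sample == ref, c("protein", keys, "intensity")]
  names(refrec)[names(refrec) == "intensity"] <- "ref_int"
  paired <- inner_join(rec, refrec, by = c("protein", keys))
  if (nrow(paired) == 0) return(abundance_cols())
  res <- paired |>
    group_by(.data$protein, .data$sample) |>
    summarise(num = sum(.data$intensity), den = sum(.data$ref_int),
              n_peptides_used = n_distinct(.data$peptide), .groups = "drop")
  res$flag <- ifelse(res$den > 0, "ok", "undefined")
  res$relative_abundance <- ifelse(res$den > 0, res$num / res$den, NA_real_)
  res$relative_abundance[res$sample == ref & res$flag == "ok"] <- 1
  res$method <- method
  res[c("protein", "sample", "relative_abundance", "method",
        "n_peptides_used", "flag")]
}

#' Exact relative protein abundance
#'
#' For proteins with quantification (`Q`) peptides: relative abundance is
#' the ratio of aggregate Q-peptide intensity in each sample to that in the
#' reference sample. Aggregation sums over the Q-peptide chemoforms observed
#' (non-missing) in both the sample and the reference sample, so a peptide
#' missing from one sample never distorts the ratio. Proteins with no usable
#' Q peptide in the reference sample are simply absent from the result
#' (route them to [approximate_abundance()]); a zero reference aggregate is
#' flagged `"undefined"` rather than emitted as a number. The reference
#' sample's abundance is exactly 1.
#'
#' @inheritParams sample_roster
#' @param channels Channels to use; `NULL` (default) uses all. Pass the
#'   analyte channel(s) when a spike-in standard channel is still present.
#' @return Tibble: `protein`, `sample`, `relative_abundance`, `method`,
#'   `n_peptides_used`, `flag`.
#' @export
exact_abundance <- function(dataset, channels = NULL) {
  rec <- analysis_records(dataset, channels)
  q <- rec[rec$class == "Q", , drop = FALSE]
  paired_abundance(q, reference_sample(dataset), "exact")
}

#' Approximate relative protein abundance
#'
#' For proteins whose Q peptides were not detected: under the model
#' assumption that the total molarity of all chemoforms of a peptide equals
#' that of the unmodified peptide (and hence of the protein), the summed
#' intensity of all chemoforms of the modified-peptide groups (`M` and `NM`
#' records) is a proxy for protein amount. Abundance is that sum expressed
#' as a paired ratio to the reference sample, flagged `method =
#' "approximate"`.
#'
#' @inheritParams exact_abundance
#' @export
approximate_abundance <- function(dataset, channels = NULL) {
  rec <- analysis_records(dataset, channels)
  grp <- paste(rec$protein, rec$peptide, sep = "\r")
  in_modified_group <- as.logical(ave(rec$class == "M", grp, FUN = any))
  chemoforms <- rec[in_modified_group, , drop = FALSE]
  paired_abundance(chemoforms, reference_sample(dataset), "approximate")
}

# per-(protein, peptide, sample): denominator over all detected chemoforms of
# the group, NM availability, and per-site modified intensity for the PTM of
# interest. Multiply modified chemoforms count toward every site they carry
# and once in the denominator.
stoich_components <- function(rec, ptm) {
  grp <- paste(rec$protein, rec$peptide, sep = "\r")
  in_modified_group <- as.logical(ave(rec$class == "M", grp, FUN = any))
  g <- rec[in_modified_group & !is.na(rec$intensity), , drop = FALSE]
  if (nrow(g) == 0) {
    return(list(denom = tibble::tibble(protein = character(), peptide = character(),
                                       sample = character(), den = double(),
                                       has_nm = logical()),
                num = tibble::tibble(protein = character(), peptide = character(),
                                     site = character(), sample = character(),
                                     num = double())))
  }
  denom <- g |>
    group_by(.data$protein, .data$peptide, .data$sample) |>
    summarise(den = sum(.data$intensity), has_nm = any(.data$class == "NM"),
              .groups = "drop")
  m <- g[g$class == "M", , drop = FALSE]
  site_rows <- lapply(seq_len(nrow(m)), function(i) {
    sites <- ptm_sites(m$ptm_type[i], m$site[i], ptm)
    if (length(sites) == 0) return(NULL)
    tibble::tibble(protein = m$protein[i], peptide = m$peptide[i],
                   site = sites, sample = m$sample[i],
                   intensity = m$intensity[i])
  })
  num <- bind_rows(site_rows) |>
    group_by(.data$protein, .data$peptide, .data$site, .data$sample) |>
    summarise(num = sum(.data$intensity), .groups = "drop")
  list(denom = denom, num = num)
}

#' Exact PTM stoichiometry
#'
#' For each modified site (or whole modified peptide when positional
#' information is absent), stoichiometry in a sample is the intensity of the
#' chemoforms modified at that site divided by the summed intensity of all
#' detected chemoforms of that exact peptide sequence. Values lie in [0, 1].
#' The calculation is emitted as exact only where the unmodified (`NM`)
#' chemoform is detected in that sample -- otherwise the denominator cannot
#' represent the peptide's total molarity and the site is left to
#' [approximate_stoichiometry()]. A zero denominator is flagged
#' `"undefined"`.
#'
#' @inheritParams exact_abundance
#' @return Tibble: `protein`, `peptide`, `site`, `sample`, `stoichiometry`,
#'   `method`, `flag`.
#' @export
exact_stoichiometry <- function(dataset, channels = NULL) {
  rec <- analysis_records(dataset, channels)
  parts <- stoich_components(rec, ptm_of_interest(dataset))
  if (nrow(parts$num) == 0) return(stoichiometry_cols())
  res <- inner_join(parts$num, parts$denom, by = c("protein", "peptide", "sample"))
  res <- res[res$has_nm, , drop = FALSE]
  if (nrow(res) == 0) return(stoichiometry_cols())
  res$flag <- ifelse(res$den > 0, "ok", "undefined")
  res$stoichiometry <- ifelse(res$den > 0, res$num / res$den, NA_real_)
  res$method <- "exact"
  res[c("protein", "peptide", "site", "sample", "stoichiometry", "method", "flag")]
}

# Q-peptide proxy for total protein amount, per protein x sample.
# policy "mean": mean over Q peptides of their per-peptide chemoform sums
# (each peptide's molar amount equals the protein's, so the mean stays on
# the protein's scale); "sum": plain sum over Q records; "single": the
# lexicographically first Q peptide's sum (deterministic single-peptide
# proxy).
q_proxy <- function(rec, policy) {
  q <- rec[rec$class == "Q" & !is.na(rec$intensity), , drop = FALSE]
  if (nrow(q) == 0) {
    return(tibble::tibble(protein = character(), sample = character(),
                          proxy = double()))
  }
  pep <- q |>
    group_by(.data$protein, .data$peptide, .data$sample) |>
    summarise(total = sum(.data$intensity), .groups = "drop")
  if (policy == "single") {
    pep <- pep |>
      group_by(.data$protein, .data$sample) |>
      filter(.data$peptide == min(.data$peptide)) |>
      ungroup()
  }
  pep |>
    group_by(.data$protein, .data$sample) |>
    summarise(proxy = if (policy == "sum") sum(.data$total) else mean(.data$total),
              .groups = "drop")
}

#' Approximate PTM stoichiometry via a Q-peptide proxy
#'
#' When a modified peptide's unmodified (`NM`) partner is undetected in a
#' sample, the total-chemoform denominator is unavailable. Under the model
#' assumptions, the protein's Q-peptide intensity stands in for total
#' peptide amount: stoichiometry is approximated as the modified-site
#' intensity divided by the Q proxy. Because proxy and modified peptide have
#' different ionization efficiencies, values can exceed 1; they are emitted
#' flagged `"out_of_range"` rather than clipped, since clipping would hide
#' the artifact. The approximation is quantitative only after normalization
#' against equimolar standards; otherwise it tracks relative biological
#' differences. Sites whose protein has no Q proxy in the sample are skipped
#' and listed in the `skipped` attribute of the result.
#'
#' @inheritParams exact_abundance
#' @param proxy_policy `"mean"` (default) averages the per-peptide chemoform
#'   sums of all Q peptides, `"sum"` adds them, `"single"` uses the
#'   lexicographically first Q peptide.
#' @export
approximate_stoichiometry <- function(dataset, channels = NULL,
                                      proxy_policy = c("mean", "sum", "single")) {
  proxy_policy <- match.arg(proxy_policy)
  rec <- analysis_records(dataset, channels)
  parts <- stoich_components(rec, ptm_of_interest(dataset))
  if (nrow(parts$num) == 0) return(stoichiometry_cols())
  nm_present <- parts$denom[parts$denom$has_nm,
                            c("protein", "peptide", "sample"), drop = FALSE]
  cand <- anti_join(parts$num, nm_present, by = c("protein", "peptide", "sample"))
  if (nrow(cand) == 0) return(stoichiometry_cols())
  proxy <- q_proxy(rec, proxy_policy)
  res <- left_join(cand, proxy, by = c("protein", "sample"))
  skipped <- res[is.na(res$proxy) | res$proxy <= 0, , drop = FALSE]
  res <- res[!is.na(res$proxy) & res$proxy > 0, , drop = FALSE]
  res$stoichiometry <- res$num / res$proxy
  res$method <- "approximate"
  res$flag <- ifelse(res$stoichiometry > 1, "out_of_range", "ok")
  out <- res[c("protein", "peptide", "site", "sample", "stoichiometry",
               "method", "flag")]
  if (nrow(skipped) > 0) {
    inform(paste0(nrow(skipped),
                  " site/sample combination(s) skipped: no Q-peptide proxy"))
    attr(out, "skipped") <- skipped[c("protein", "peptide", "site", "sample")]
  }
  out
}

#' Run the full analysis with per-protein exact/approximate dispatch
#'
#' Abundance: proteins with a usable Q peptide in the reference sample get
#' the exact calculation; remaining proteins with modified-peptide groups
#' get the approximate one. Stoichiometry: each site x sample is exact where
#' the NM chemoform is detected and approximate (Q proxy) where it is not.
#' Every result row carries its `method` flag and the summary counts exact
#' vs. approximate results.
#'
#' @inheritParams approximate_stoichiometry
#' @return `list(abundance, stoichiometry, summary)`.
#' @export
run_analysis <- function(dataset, channels = NULL,
                         proxy_policy = c("mean", "sum", "single")) {
  proxy_policy <- match.arg(proxy_policy)
  ab_exact <- exact_abundance(dataset, channels)
  ab_approx <- approximate_abundance(dataset, channels)
  ab_approx <- ab_approx[!ab_approx$protein %in% unique(ab_exact$protein), ,
                         drop = FALSE]
  abundance <- arrange(bind_rows(ab_exact, ab_approx), .data$protein, .data$sample)

  st_exact <- exact_stoichiometry(dataset, channels)
  st_approx <- approximate_stoichiometry(dataset, channels, proxy_policy)
  stoichiometry <- arrange(bind_rows(st_exact, st_approx),
                           .data$protein, .data$peptide, .data$site, .data$sample)

  summary <- list(
    n_abundance_exact = sum(abundance$method == "exact"),
    n_abundance_approximate = sum(abundance$method == "approximate"),
    n_stoichiometry_exact = sum(stoichiometry$method == "exact"),
    n_stoichiometry_approximate = sum(stoichiometry$method == "approximate")
  )
  list(abundance = abundance, stoichiometry = stoichiometry, summary = summary)
}
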