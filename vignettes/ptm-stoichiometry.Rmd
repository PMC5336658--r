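---
title: "Quantifying protein abundance and PTM stoichiometry from peptide intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein abundance and PTM stoichiometry from peptide intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmquant)
```

## The measurement model

A bottom-up experiment observes, for each peptide chemoform $c$ of protein
$p$ in sample $s$, an intensity

$$I_{c,s} = m_{p,s} \cdot f_{c,s} \cdot \eta_c \cdot a_{c,s} \cdot \varepsilon,$$

where $m_{p,s}$ is the protein's molar amount, $f_{c,s}$ the chemoform's
molar fraction (the site occupancy for a modified chemoform, one minus the
summed occupancies for its unmodified partner, and 1 for a peptide with a
single chemoform), $\eta_c$ the peptide-specific ionization efficiency,
$a_{c,s}$ an artifact multiplier collecting technical distortions, and
$\varepsilon$ multiplicative measurement noise. Because $\eta_c$ differs
between peptides, raw intensities are not molar quantities; the package's
job is to cancel $\eta_c$ and $a_{c,s}$ and then separate $m$ from $f$.

Three assumptions underpin the quantitative interpretation: (i) samples are
spiked with synthetic heavy-isotopologue standards at equimolar
concentration; (ii) signal response is linear with slope close to one
(confirmed upstream, as is routine for absolute quantitation); (iii) all or
most chemoforms of each peptide are quantified, so the total molarity of a
peptide's chemoforms equals that of the unmodified peptide and of the
protein. When an assumption fails the calculations still run, but their
output tracks relative biological differences rather than molar fractions —
which is why every result row carries an `exact`/`approximate` method flag
and out-of-range approximate stoichiometries are flagged rather than
clipped: clipping would hide exactly the ionization-efficiency artifact the
flag is there to expose.

## Peptide classification

Classification is performed per (protein, peptide sequence) group using
exact sequence identity — peptides with different termini produced by
incomplete or nonspecific proteolysis are distinct groups, because their
chemoform accounting is distinct. If no chemoform of a group bears the
modification of interest the group is labeled `Q` and feeds protein
quantification; otherwise each record is `M` or `NM` according to its own
modification state. A chemoform carrying only some *other* PTM does not
modify-qualify its group: the rule is defined relative to one modification
of interest per run, and other PTM types simply ride along as additional
chemoforms. The operation is a pure annotation and idempotent.

## Normalization modes

All four modes rescale intensities by explicit factors, return the factor
table for audit, and leave the schema unchanged. Missing intensities are
excluded from every sum and never imputed. The reference sample always
carries factor 1, so it is numerically untouched — chosen so that
downstream ratios "to the reference sample" are unaffected by the
normalization itself.

* **Equimolar isotopologue** — per chemoform and sample, the factor maps the
  observed standard intensity onto that chemoform's standard intensity in
  the reference sample. Since the standards are equimolar by design, any
  cross-sample spread of a standard is technical, and the per-chemoform
  scoping also corrects chemoform-specific distortions such as variable
  recovery of enriched phosphopeptides. The standard-channel value is set
  to the target directly (not multiplied by the factor), so equalized
  standards have exactly zero range in floating point as well as in exact
  arithmetic. Chemoforms whose standard is missing or zero are flagged and
  passed through unscaled rather than silently dropped.
* **Isotopologue (ratio)** — every intensity is divided by its own
  chemoform's standard in the same sample. No equimolarity is assumed, so a
  SILAC-labeled proteome can serve as the reference channel; any
  multiplicative distortion hitting both channels cancels identically. With
  equimolar standards, ratio units are a common molar scale — this is the
  normalization the approximate analysis routes rely on.
* **Total ion current** — per-sample factors equalize the summed non-missing
  analyte intensity to the reference sample's, for designs without
  isotopically encoded standards. Spiked standard channels are excluded
  from the sum (they are constant by design and would damp real loading
  differences) but are still rescaled.
* **Internal reference** — per-sample factors equalize the summed intensity
  of designated loading-control proteins, correcting variable total protein
  content per cell while preserving genuine changes of other proteins that
  TIC normalization would dilute.

Chaining modes is possible (each run is logged with its factors) but the
pipeline applies a single explicit mode by default, since the right choice
is a property of the experimental design.

## Exact and approximate analysis

With a usable `Q` peptide in the reference sample, relative abundance is
the paired ratio of aggregate Q intensities: sums run over the Q chemoforms
observed non-missing in *both* the sample and the reference, which keeps
the ratio unbiased when peptides drop out of single samples. Aggregation
across multiple Q peptides is a sum; ratios cancel the peptide count.

Exact stoichiometry of site $k$ is $I_{M,k} / \sum_c I_c$ over all detected
chemoforms of that peptide sequence; multiply modified chemoforms count in
the numerator of every site they carry and once in the denominator. The
calculation is emitted as exact only where the `NM` chemoform is detected —
otherwise the denominator cannot represent total peptide amount. Without
positional information the value is reported per modified peptide instead
of per site.

When coverage is incomplete, the missing quantity is inferred rather than
imputed. Abundance without Q peptides: under assumption (iii) the summed
intensity of all chemoforms of the modified peptide groups is proportional
to protein amount. Stoichiometry without the NM partner: a Q peptide of the
same protein proxies total protein amount. The default proxy is the *mean*
of the per-peptide chemoform sums across the protein's Q peptides: each
peptide's molar amount equals the protein's, so the mean stays on the
protein scale, and in the noiseless equimolar-normalized limit the
approximation reproduces the exact value elementwise — a property a summed
proxy cannot have with more than one Q peptide, which is why `sum` (and
`single`, the deterministic lexicographically-first peptide variant) are
offered as alternatives rather than as the default.

`run_analysis()` dispatches per protein (abundance) and per site and sample
(stoichiometry), so a single dataset can mix both routes; the summary
counts how often each was used.

## The simulator

`simulate_dataset()` draws data directly from the measurement model above,
which makes every stage testable against ground truth with no external
data. The canonical design is one hypothetical phosphorylated protein
producing four peptides, two bearing one phospho-site each, plus unmodified
loading-control proteins, across three samples with equimolar heavy
standards. Where a study value was not prescribed, the defaults were fixed
once at field-realistic magnitudes and not revisited: reference molarity
100 (arbitrary units), per-protein fold changes lognormal with
$\sigma_{\log} = \log 2$, site occupancies uniform on $[0.1, 0.9]$,
standard spike at 100, measurement noise multiplicative lognormal
(`noise_cv = 0.05` in the noisy presets), and per-chemoform ionization
efficiencies lognormal with CV 0.3 in the benchmark presets. Both isotopic
channels of a chemoform share its efficiency, as co-eluting isotopologues
do.

Technical artifacts are injected explicitly: instrument drift and loading
error multiply both channels (standards are spiked before acquisition);
enrichment multiplies PTM-bearing chemoforms in both channels; per-protein
variation is genuine biology (it enters the ground truth) followed by an
equalize-total-protein loading factor on the analyte channel only, with
standards spiked per sample afterwards. Each artifact has a matched
normalization mode that restores the noiseless ground truth to floating
point accuracy, and the artifact presets use biologically identical samples
so that the recovery is well defined.

Eleven named presets (`preset_names()`) cover: the complete baseline, the
four artifact/normalization pairings plus the enrichment distortion, the
triplicate single-protein analysis scenario and its Q-, NM- and
Q+NM-withheld variants, and a 50-protein correlation benchmark
(`noise_cv = 0.05`, efficiency CV 0.3, five loading controls). The
single-protein presets use three conditions measured in triplicate with
molarity folds (1, 2, 0.5) and modest occupancy shifts across conditions
(±0.05 absolute, signaling-scale changes); the benchmark draws occupancies
independently per condition.

What the simulator does *not* emulate: peak detection and integration,
retention-time alignment, charge states, interference/co-isolation,
identification and site-localization error, and intensity-dependent
missingness (withholding is by design class, not at random). Passing tests
therefore demonstrate the correctness of the accounting and inference given
correctly extracted intensities, not robustness to upstream processing
errors.

## Numerical choices and degenerate inputs

* Missing is `NA`, never 0; a recorded 0 participates in sums and can make
  a denominator zero, which is flagged `undefined` rather than emitted.
* Zero or missing standards flag the chemoform and leave it unscaled;
  zero TIC or a loading-control protein absent from a sample are hard
  errors naming the sample (the correction is undefined, not approximate).
* Idempotence of every normalization mode holds to 1e-9 relative; the
  noiseless end-to-end inversion (simulate, normalize, analyze, compare to
  truth) holds to 1e-12 relative, and per-site occupancies plus the
  unmodified fraction sum to 1 at the same tolerance.
* Canonical row order (protein, peptide, modification, channel, sample)
  makes equal datasets produce byte-identical CSVs, and fixed seeds make
  simulation runs byte-identical.
* Problem sizes in the test-suite and acceptance benchmarks (50 proteins ×
  3 samples; triplicate single-protein scenarios; 20-seed noise sweeps at
  10 proteins) were chosen as the smallest designs at which the
  correlations of interest are stable to the third decimal.

## Known limitations

One modification of interest per run; records of other PTM types are
carried and counted as chemoforms but not assigned their own occupancies in
the same pass (run twice with a different `ptm` to analyze two
modifications). Protein inference is out of scope — peptide-to-protein
annotation is taken as given. Statistical testing of the resulting fold
changes and occupancies is deliberately left to downstream tools; the
output CSVs are designed to feed them.
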