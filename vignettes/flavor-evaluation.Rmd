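---
title: "Evaluating tomato flavor from volatiles, taste chemistry and sensory panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating tomato flavor from volatiles, taste chemistry and sensory panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomatoflavor)
library(dplyr)
```

## The problem

Tomato flavor is a joint product of taste chemistry (sugars and organic
acids perceived on the tongue) and odor chemistry (volatile compounds
perceived retronasally). Panels of accessions -- distinct genetic lines --
are screened for both: taste compounds by liquid chromatography, volatiles
by headspace GC-MS, and hedonic impressions by a trained sensory panel.
The analytical question this package answers is how to turn those three
heterogeneous measurements into a single defensible flavor ranking, and
which compounds drive it.

The pipeline has four stages, each usable on its own:

1. **GC-MS quantification** (`kovats_ri()`, `filter_identifications()`,
   `relative_concentration()`, `apply_calibration()`, `fit_calibration()`,
   `quantify_peaks()`): peak tables to concentrations.
2. **Flavor metrics** (`odor_activity_value()`, `odor_category_oav()`,
   `sugar_acid_ratio()`, `aggregate_by_class()`, `descriptive_stats()`):
   concentrations to interpretable scores.
3. **Multi-criteria ranking** (`zscore_standardize()`, `topsis()`,
   `evaluate_flavor()`, `assign_classes()`): scores to a ranked partition.
4. **Association statistics** (`pearson_with_flags()`,
   `correlation_table()`, `anova_by_type()`): which compounds track which
   sensory impressions.

A synthetic-data generator (`sim_config()`, `generate_panel()`) forward-
simulates all of the inputs with known ground truth, so each stage is
testable end to end without instrument data.

## Quantification model

**Retention index.** Compound identity on a chromatographic column is
anchored by the Kovats retention index: each n-alkane with $z$ carbons
scores $100z$, and a query eluting between alkanes $z$ and $z+1$ is
interpolated. `kovats_ri()` implements the classical logarithmic form

$$RI = 100z + 100\,\frac{\log t_x - \log t_z}{\log t_{z+1} - \log t_z}$$

as the default, with a `"linear"` option that replaces the logarithms with
raw retention times. The log form is the textbook definition and is kept
as the default; the linear form is conventional for temperature-programmed
runs, and both are exposed because published index tables do not always
say which was used. Two deliberate edge rules: a query exactly equal to a
ladder alkane's retention time returns exactly $100z$ (the alkane identity),
and a query outside the ladder span returns `NA` rather than an
extrapolation -- an index extrapolated beyond its anchors is not a Kovats
index.

**Identification filtering.** A peak is accepted only when both the
forward and reverse spectral match scores strictly exceed 800 of 1000.
The inequality is strict: a score of exactly 800 is rejected. Rejected
peaks are never silently dropped; they are carried with a reason string
(`rejected_peaks()`).

**Internal-standard quantification.** With 3-nonanone spiked at a known
working concentration $m_t$ (default 65.68 in units of $10^{-9}$ kg
L$^{-1}$, the concentration produced by adding $10^{-5}$ L of a
$3.284\times10^{-5}$ kg L$^{-1}$ stock to about 0.005 kg of homogenate),
the relative concentration of compound $n$ is

$$m_n = \frac{S_n \, m_t}{S_t \, m_0}$$

where $S_n$ and $S_t$ are the analyte and internal-standard areas and
$m_0$ is the sample mass in kg. The convention that 1 L of tomato
homogenate weighs about 1 kg makes the units close dimensionally with
$m_0 = 1$.

**Calibration correction.** Headspace partitioning and fiber affinity
differ per compound, so relative concentrations are corrected through a
per-compound calibration line. The package's axis convention is that the
fitted line maps true concentration ($x$) to measured relative
concentration ($y = ax + b$); correction inverts it, $x = (y-b)/a$. This
orientation is a design choice -- reference tables rarely state it -- and
it is the one under which "correction" is a well-defined inversion.
Because fitted intercepts can be negative, small signals can invert to
negative concentrations; these are floored at zero and counted
(`attr(, "n_floored")`) rather than passed through or erred on.
`fit_calibration()` computes the OLS fit and flags any series with
$r^2 < 0.99$, the quality bar every curve in the shipped reference meets.

## Odor and taste metrics

**OAV.** The odor activity value is concentration divided by olfactory
threshold. An absent threshold leaves the OAV *undefined*, not zero:
undefined OAVs never enter category sums. The reporting form
(`oav_report()`) rounds half-up to an integer and prints `"<1"` when the
rounded value is zero. That exact rule was recovered by machine-checking
the shipped 60-compound reference: it is the only simple rule consistent
with every printed row (e.g. a raw OAV of 0.65 prints as 1, while 0.43
prints as `"<1"`); the suite asserts it row by row.

**Odor categories.** Accession-level odor is summarized over six
categories -- green, floral, fruity, vegetable, fatty, irritant -- by
matching each volatile's free-text descriptors against an editable keyword
table (`default_category_map()`) and summing member OAVs per category. Two
choices here are configuration, not ground truth. First, the keyword map
itself: no complete descriptor-to-category enumeration is published, so
the shipped map is built from the descriptor vocabulary of the reference
table, including `cinnamon -> irritant` so that all five volatiles
conventionally treated as irritant-odor carriers (2-hydroxy-ethyl
benzoate, methyl salicylate, 2,4-bis(1,1-dimethylethyl)-phenol,
4-allyl-2-methoxyphenol, 2-methoxyphenol) land in that category. Second,
a volatile whose descriptors span categories contributes its *full* OAV
to each matched category; no fractional splitting is attempted, because
any split ratio would be invented. Sums, not means, aggregate the member
OAVs: accession-level totals in the hundreds are only consistent with
summation.

**Taste metrics.** The sugar-acid ratio is
$(\mathrm{fructose}+\mathrm{glucose})/(\mathrm{citric}+\mathrm{malic})$,
reported to two decimals. `aggregate_by_class()` totals per-volatile mean
concentrations within functional classes (alcohols, aldehydes, ketones,
esters, phenols, other) or metabolic-precursor classes (lipid-,
carotenoid-, Phe-, Ile/Leu-derived). Against the shipped reference the
alcohol, aldehyde, ester and other-volatile totals reconcile with the
published group table to ±0.02, while the ketone and phenol rows disagree
with the direct sums by about 122.4 and 101.5 units respectively; the
package reproduces the direct sums and the test suite asserts the
discrepancy *is present*, because silently "correcting" either side would
hide a real inconsistency in the source table. The precursor-class column
of the shipped reference is a chemistry-based curation (the published
table prints only class totals, 31/17/8/4), so precursor totals are not
asserted against it.

## Multi-criteria ranking

Sensory criteria are first Z-score standardized per column (sample SD;
a zero-SD column maps to zeros with a warning). `topsis()` then scores
each accession by closeness to the ideal flavor:

$$S_i^{\pm} = \sqrt{\sum_j w_j^2 \left(R_{ij} - X_j^{\pm}\right)^2},
\qquad C_i = \frac{S_i^-}{S_i^+ + S_i^-}$$

where $X_j^+$ is the column maximum for a benefit criterion and the
column minimum for a cost criterion ($X_j^-$ the opposite). Sourness and
irritant odor are the two cost criteria; every other criterion is a
benefit. Directions are handled through the ideal/anti-ideal selection
rather than by sign-flipping the data -- the result is identical and the
audit trail clearer. Canonical closeness lies in $[0,1]$ and equals 1
exactly when an accession attains the ideal on every criterion; the suite
verifies the implementation against an independently coded brute-force
evaluation of the closed form to $10^{-12}$ on small matrices.

Three design points were genuinely open:

* **Weights.** No criterion weights are published for this analysis;
  the default is uniform and weights are user-configurable. Uniform
  weights reproduce the unweighted formulation exactly (tested).
* **Score scale.** Published composite flavor scores for this kind of
  analysis have been reported on ranges extending below zero, which is
  impossible for canonical closeness; the likeliest explanation is a
  post-hoc standardization of $C_i$. The package therefore reports both
  the canonical $C_i \in [0,1]$ and a Z-scored `closeness_z`, and asserts
  numeric properties only of the canonical score.
* **Class boundaries.** The four flavor classes (I--IV) can be formed
  either from fixed cut points or from fixed class sizes;
  `assign_classes()` supports both, with ties broken deterministically by
  input order. The fixed-size mode with sizes (10, 20, 28, 13) reproduces
  the published partition cardinalities of a 71-accession panel -- the
  cardinalities only, since the underlying per-accession score matrix is
  not published.

`evaluate_flavor()` runs three independent rankings -- taste block, odor
block, concatenated block -- because taste and odor are known to be nearly
uncorrelated at the accession level and a single blended ranking would
obscure which modality drives an accession's standing.

## Association statistics

`correlation_table()` computes all compound-by-sensory Pearson
correlations with two-sided t-test p-values, starred `*` ($p<0.05$) and
`**` ($p<0.01$) per cell. Per-cell starring without multiplicity
correction mirrors the convention of printed correlation tables in this
literature; a Benjamini-Hochberg option (`adjust = "BH"`) is provided and
off by default -- fidelity first, rigor available. `anova_by_type()` is a
plain one-way F-test across fruit types; groups smaller than 2 are
excluded with a warning, and a zero within-group sum of squares is
reported as an infinite F with $p = 0$ rather than an error, since that is
the correct limit of the statistic.

## What the generator simulates -- and what it does not

`generate_panel()` forward-simulates the full study design. Its defaults
*are* the study conditions: 71 accessions in the 8/11/15/37 split over
pink-cherry, red-cherry, pink-large and red-large types; 60 volatiles;
concentration CVs drawn from 0.3--2.5; calibration slopes from 0.02--4.85
(a slope range containing zero is rejected as non-invertible); olfactory
thresholds log-uniform over 3.5 to $4\times10^6$ in $10^{-9}$ kg L$^{-1}$;
a 50-panelist hedonic panel on a 0--8 scale.

Concentrations are log-normal per volatile, parameterized by a mean
(log-uniform over 7--3100, the span of the reference means) and a CV from
the configured range: concentrations are positive and span two to three
orders of magnitude, which only a heavy-tailed positive distribution
reproduces. Peak areas are the exact forward image of the quantification
model -- $S_n = (a\,m_n + b)\,S_t\,m_0/m_t$ -- times multiplicative
log-normal noise of configurable CV (default 1%), so the quantification
stage inverts them exactly at zero noise; true concentrations are floored
at the level where the forward signal stays positive, so the forward model
is always invertible. Sensory scores are per-factor truths (sweetness
planted on fructose+glucose, sourness on total acid, the remaining factors
on a latent accession-level flavor scalar) averaged over panelists with
Gaussian noise, truncated to $[0, 8]$ and snapped to the quarter-point
grid hedonic panels actually report on. The Gaussian panelist-noise model
is a stand-in: no distributional statement about panelist variability is
available for this design, and nothing downstream depends on its shape.
All randomness derives from one root seed through per-stage sub-streams,
so any single stage can be reproduced without regenerating the rest.

What passing tests on synthetic data do **not** show: real chromatograms
have co-elution, baseline drift and censoring at the detection limit, none
of which are simulated (peaks enter as already-integrated areas); real
panelists drift, fatigue and correlate; and real descriptor vocabularies
are messier than the keyword map. The synthetic checks validate the
*arithmetic* of the pipeline, not the instrument model.

## Numerical choices and degenerate inputs

* Half-up integer rounding (`round_half_up()`) is used wherever a printed
  table convention requires it; base R's banker's rounding does not
  reproduce those tables.
* Zero internal-standard area is a hard error (the run is invalid);
  zero-slope calibrations are configuration errors; negative corrected
  concentrations floor at zero with a count.
* Identical alternatives in a decision matrix make closeness undefined
  ($S^+ + S^- = 0$) and raise an error rather than returning 0/0.
* Ties in class assignment break by input order, which makes partitions
  reproducible given a documented accession order.
* Test and example problem sizes: full 71-accession, 60-volatile panels
  are used where study-scale structure matters (type counts, planted
  correlations, recovery at 1% noise); 10--12-accession panels elsewhere.

## Limitations

The pipeline starts at integrated peak tables: no raw-spectrum parsing,
deconvolution or library search is performed (match scores are inputs).
Odor-mixture psychophysics is out of scope -- category OAV sums are an
additive convenience, not a perceptual model. The correlation surface is
descriptive; no causal claims about compounds and liking follow from
starred cells. And the shipped reference tables carry their source's own
inconsistencies (the ketone/phenol totals), which this package flags but
cannot resolve.
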