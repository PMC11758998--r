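---
title: "Reconstructing organic-aerosol composition from an ice-core NTS record"
author: "iceNTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing organic-aerosol composition from an ice-core NTS record}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nontarget screening (NTS) by liquid chromatography coupled to high-resolution
mass spectrometry detects every ionisable molecule in a sample rather than a
predefined list. Applied to a dated glacier ice core, the result is a feature
table — one molecular profile per row, characterised by m/z, retention time,
an assigned elemental formula and one intensity per dated sample — from which
the history of atmospheric water-soluble organic aerosol can be
reconstructed: which compound classes dominate, how their intensities changed
across industrialisation, and whether the average oxidation state of the
organic material shifted.

iceNTS implements the post-processing that turns such a feature table into
those answers. Everything upstream (peak picking, alignment, formula
assignment from isotope patterns) is assumed done by the vendor software;
everything downstream of the statistics (geochemical interpretation) is out
of scope.

```{r, eval = FALSE}
library(iceNTS)
report <- runPipeline(generatorConfig(seed = 1))
```

## Molecular descriptors

For a formula with counts C, H, N, O, S (halogens X):

* **DBE** (double-bond equivalent): $\mathrm{DBE} = C - (H + X)/2 + N/2 + 1$.
  Halogens are counted with hydrogen. The value is an integer when $H + X$
  and $N$ have equal parity, otherwise a half-integer. No clamping: exotic
  inputs may be negative.
* **Aromaticity equivalent** $\chi_c$: with
  $d = \mathrm{DBE} - (m\,O + n\,S)$,
  $\chi_c = (3d - 2)/d$ clamped to 0 when negative. $m$ and $n$ are the
  fractions of oxygen and sulfur assumed to sit in pi-bonded structures;
  the defaults $m = n = 0.5$ suit carboxylic acids and esters, which
  dominate negative-mode electrospray records. A molecule is called aromatic
  when $\chi_c \ge 2.5$. **Convention:** when $d \le 0$ the expression is
  undefined or negative; we return 0 there too, which keeps $\chi_c$ total
  and non-negative. The index is conservative — C8H8O3 scores 2.4 (just
  below threshold) although it is compatible with aromatic structures such
  as vanillin.
* **Average carbon oxidation state**: $\mathrm{OS}_C = 2\,O/C - H/C$.
* **Region annotations**: the Van Krevelen split calls a molecule aliphatic
  when $H/C \ge 1.5$; Kroll-diagram bands are *closed, overlapping*
  OS$_C$ intervals (monoterpene oxidation $[-1, -0.5]$, isoprene + OH
  $[-0.8, -0.2]$, SVOC $[-0.5, 0]$, LVOC $[0, 0.9]$, hydrocarbon-like
  $[-1.7, -1.6]$), so the annotation is a set, not a single label.

Descriptors are stored at full precision; rounding is for display only.
Elements beyond CHNOS enter only the DBE (via halogens) and force the
compound class to `other`; classes `CHO`, `CHNO`, `CHNOS` and `CHOS` are
exact element sets.

## Quality-control filter

Six predicates, applied jointly; a profile is kept only if all pass:
(i) not background, (ii) peak rating $\ge 7.0$, (iii) replicate group CV
$\le 15\%$, (iv) formula assigned, (v) maximum sample intensity
$\ge 5\times 10^6$, (vi) sample-to-blank intensity ratio $\ge 3$. Rejections
are tallied by the *first* failing predicate in this order, so the tally and
the kept count always add up to the input count.

Two conventions the predicate list leaves open: the sample-to-blank ratio is
taken as max(sample intensities)/max(blank intensities) — the conservative
reading — and an all-zero blank passes (ratio $+\infty$). Missing intensity
cells are read as 0 (below detection), not as errors.

## Homolog series

Two formulas are CH$_2$ homologs when they differ only by an integer number
of CH$_2$ units: identical heteroatom content and identical hydrogen offset
$k = H - 2C$ (the series notation C$_n$H$_{2n+k}$O$_o$). Grouping by this
key is exactly the connected-components computation on the CH$_2$-difference
graph, which the tests verify against a brute-force oracle. DBE is constant
within a series by arithmetic. The default minimum series size is 3 —
observed records report series of 5–7 members, and 3 suppresses accidental
pairs while keeping small test sets meaningful. Gaps in the carbon ladder
are allowed. Retention time should increase with chain length; the Spearman
correlation of RT against $n_C$ is reported per series as a diagnostic but
never used as a membership criterion, since no RT rule is part of the
series definition.

## Time binning and weighted records

Sample intensities are averaged into half-open 5-year bins
$[\mathrm{start}, \mathrm{start}+5)$ anchored at 1800 CE, smoothing
year-to-year variability of atmospheric transport and snow deposition. A
sample dated exactly on a boundary belongs to the bin starting there. Bins
without samples are missing, never zero.

The intensity-weighted mean of a descriptor over a molecule subset,
$\sum_i I_i x_i / \sum_i I_i$ per bin, yields the weighted O/C, OS$_C$,
$n_C$, DBE and $\chi_c$ records. To track atmospheric oxidation these are
computed over the molecules with a biogenic source (clusters 1A and 2);
purely anthropogenic molecules (cluster 1B) are excluded because their
appearance would change the record for reasons unrelated to oxidation
chemistry. The spread quoted for a window (e.g. pre- vs post-change mean
$\pm$ SD) is the standard deviation across bins within the window.

## Clustering

Each molecule's binned series is standardised to mean 0, SD 1 (sample SD,
$n-1$; the convention is stated because it is not forced by the method).
Constant rows cannot be standardised; they are excluded from clustering and
reported separately. Clustering is agglomerative with Euclidean distance
and Ward linkage (`ward.D2`, the Ward criterion on Euclidean distances).

The tree is cut at $k = 2$; the branch whose mean z-score series correlates
more positively with a monotone ramp is labelled anthropogenic (cluster 1),
the other natural (cluster 2). This proxy-free rule reflects that the
anthropogenic cluster is ultimately recognised by its rise — change point
and proxy correlations are computed downstream of labelling and would be
circular as labelling criteria. The anthropogenic members are then
clustered again and cut at $k = 2$; the subcluster with the lower mean
z-score over the first half of the record is 1B (purely industrial
molecules sit far below their own mean before onset), the other 1A. Whether
the original two-level split came from a fixed-height cut or visual
selection of the dendrogram is not determinable; re-clustering the branch
is one consistent, reproducible choice.

## Change points, trends, correlations

The change-point detector evaluates **every** split of a series into two
contiguous segments and minimises the total within-segment sum of squared
deviations — the exhaustive single-change-point criterion of standard
mean-shift detectors, implemented via cumulative sums (the tests hold it
against an explicit brute-force loop). The reported year is the start year
of the first post-change bin, since single calendar years like "1950 CE"
do not pin down a convention. A constant series yields an SSE drop of 0
and is flagged not significant. Only a single change point is detected per
series; recursive segmentation for multi-change series is deliberately out
of scope because one abrupt change per record is the phenomenon of
interest here.

Fold changes divide the post-change mean by the pre-change mean, windows
defaulting to (record start, change point) and (change point, record end).
Trends are ordinary least squares of value on bin year with the two-sided
slope t-test ($n-2$ df, significance 0.05). Group contrasts (e.g. O/C of
cluster 1A versus 2) use the Welch unequal-variance t-test — the
unequal-variance form is the safer default when only "t test" is
specified. Proxy series (nitrate, sulfate, ozone, OH) are linearly
interpolated onto the ice-core bin years — not vice versa — and compared
by Pearson correlation.

## Identification confidence

Levels follow the five-tier confidence scale: 5 = exact mass only, 4 =
formula only, 3 = several library spectra score at or above the match
threshold (ambiguous structures), 2 = exactly one does, 1 = a reference
standard with the same formula matches within 0.1 min of retention time.
A standard match confirms level 1 on its own (the in-house database
route). The level-2/level-3 boundary has no universal numeric criterion;
unique-above-threshold versus multiple-above-threshold is our convention.
The spectral score is a cosine on square-root-scaled intensities after
greedy closest-pair matching within 0.01 Da (Orbitrap-class accuracy); the
library threshold defaults to 0.6, consistent with accepting commercial
library matches down to about 60 on a 0–100 scale. Proprietary library
scores present in inputs are annotations, never recomputed.

## The synthetic generator

No machine-readable ice-core feature table is publicly deposited, so the
package ships a generator that emulates the *statistical structure* the
analysis assumes, making every stage testable end-to-end:

* 398 molecules at class count proportions 75/18/3/2/2% (largest-remainder
  allocation, so counts are deterministic), with formulas drawn per class
  and per cluster from realistic ranges ($n_C$ 4–20, most DBE < 4, most
  CHO with $0.25 \le O/C < 0.75$) and rejected when chemically impossible
  ($H > 2C + 2 + N$ or DBE < 0). Cluster-1A molecules are drawn more
  oxidised (higher O/C, OS$_C$) and shorter-chained than cluster-2
  molecules, so that the weighted records shift in the observed directions
  when cluster 1A gains intensity share.
* 53 unevenly spaced samples over 1800–1980 CE with a monotone depth scale
  and enrichment factors near 92.
* Cluster shapes: natural molecules decline by 35% over the record (a
  clearly expressed version of the observed significant decreasing trend;
  chosen once at design time so the natural population has a coherent
  shape), 1A molecules ramp from 1925, 1B molecules are exactly zero
  before their onset (1950; 1960 for CHNOS, whose class-aggregate change
  point is planted at 1960).
* Deterministic calibration: the ramp amplitude is solved in closed form so
  the cluster-1A aggregate fold is 1.4; step multipliers on the
  anthropogenic members of CHNO and CHNOS make the class-aggregate folds
  exactly 1.4 (1950) and 1.9 (1960) at the template level; class intensity
  shares are scaled in one exact pass to 95/4/0.4/0.3/0.3%; proxy noise is
  rescaled so the sample correlation of each coupled proxy with the planted
  anthropogenic mean equals its target (0.70 nitrate, 0.72 sulfate, 0.66
  ozone) exactly.
* Lognormal multiplicative noise at CV 0.15 — electrospray intensity
  variation is multiplicative, and no explicit noise model is available
  to copy; intensities are scaled so every true profile clears the QC
  intensity floor; an extra set of reject profiles violates exactly one QC
  predicate each, exercising the filter.

What the generator does **not** emulate: mass accuracy and formula
mis-assignment, chromatographic drift, co-elution and matrix effects in
ionisation, dating uncertainty, and any atmospheric-chemistry mechanism.
Passing recovery tests therefore shows that the pipeline's inference is
correct *given* the assumed statistical structure — not that a real record
satisfies those assumptions.

## Problem sizes and runtimes

The shipped tests run the full generator at its default size (398 molecules
x 53 samples, 37 bins), 100-seed cluster-recovery and 200-seed
change-point suites, a 1000-simulation type-I-error check of the trend
test, and a 5000-molecule law-of-large-numbers check of the intensity-share
calibration. The complete suite takes on the order of a minute on a single
CPU.

## Known limitations

* One change point per series; no recursive segmentation.
* $\chi_c$ may under-count aromatics; no second aromaticity index is
  provided.
* Cluster-count reproduction of any specific real record (e.g. exact
  member counts per cluster) is out of reach without that record's feature
  table; the generator is calibrated to proportions and dynamics, not to
  the identities of individual molecules.
* The QC filter consumes the vendor-computed group CV; `recomputeGroupCV()`
  exists for tables that ship replicate columns instead.
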