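# iceNTS

Post-processing for nontarget-screening (NTS) LC-HRMS feature tables from
glacier ice cores: from a molecules × dated-samples intensity table to a
reconstruction of how atmospheric water-soluble organic aerosol changed
across industrialisation.

It is written for analytical and atmospheric chemists who already have a
vendor-processed feature table (m/z, retention time, assigned formula,
per-sample intensities, QC fields) for a dated ice core, plus optional
co-registered proxy series (nitrate, sulfate, ozone, OH), and want the
downstream statistics reproducible outside point-and-click tools.

## What it computes

**Per-molecule descriptors.** For a formula with counts C, H, N, O, S and
halogens X:

- double-bond equivalent `DBE = C − (H + X)/2 + N/2 + 1` (halogens counted
  with hydrogen);
- aromaticity equivalent, with `d = DBE − (m·O + n·S)` and `m = n = 0.5`:
  `χc = (3d − 2)/d`, clamped to 0 when negative or when `d ≤ 0`; molecules
  with `χc ≥ 2.5` are flagged aromatic;
- average carbon oxidation state `OSc = 2·O/C − H/C`;
- compound class (CHO / CHNO / CHNOS / CHOS / other, exact element sets),
  Van Krevelen region (aliphatic iff `H/C ≥ 1.5`) and Kroll-diagram
  volatility/precursor bands (closed, overlapping OSc intervals).

**The record pipeline.** Six-predicate QC filtering (background, peak
rating ≥ 7, group CV ≤ 15 %, formula present, max intensity ≥ 5×10⁶,
sample-to-blank ratio ≥ 3); CH₂ homolog-series detection; 5-year binned
intensity records; z-scored molecule series clustered by Ward/Euclidean
into a natural cluster (2) and an anthropogenic cluster split into 1A
(biogenic + anthropogenic) and 1B (purely industrial, absent early);
exhaustive single-split change-point detection; fold changes, OLS trend
tests, Welch group contrasts and proxy correlations after linear
interpolation onto the ice-core bins; intensity-weighted O/C, OSc, nC, DBE
and χc records over the biogenic subset (clusters 1A ∪ 2); identification
confidence levels 1–5 from reference standards and MSP spectral libraries.

A synthetic generator (`simulateIceCore()`) emulates the statistical
structure of a dated 1800–1980 CE alpine record — 398 molecules at class
proportions 75/18/3/2/2 %, CHO carrying 95 % of total intensity, an
anthropogenic ramp from 1925, class-aggregate folds of 1.4 (CHNO, 1950 CE)
and 1.9 (CHNOS, 1960 CE), proxies coupled to the anthropogenic cluster
mean at r ≈ 0.7 — with the planted truth returned for recovery scoring, so
the entire pipeline is testable without any external data.

## Worked example

```r
library(iceNTS)

computeDescriptors(c(succinic = "C4H6O4", vanillin = "C8H8O3",
                     pinic = "C9H14O4", pnitrophenol = "C6H5NO3"))
#>            id formula nC oc_ratio hc_ratio dbe chi_c    osc compound_class
#>      succinic  C4H6O4  4    1.000    1.500   2  0.00  0.500            CHO
#>      vanillin  C8H8O3  8    0.375    1.000   5  2.43 -0.250            CHO
#>         pinic C9H14O4  9    0.444    1.556   3  1.00 -0.667            CHO
#>  pnitrophenol C6H5NO3  6    0.500    0.833   5  2.43  0.167           CHNO
```

Succinic acid is fully oxidised for its size (OSc +0.5), pinic acid is a
typical monoterpene-oxidation product (OSc −0.67), and vanillin sits just
below the χc = 2.5 aromaticity threshold at 2.43 — the index is
deliberately conservative.

A full synthetic run:

```r
report <- runPipeline(generatorConfig(seed = 1))
#> simulate: 438 profiles x 53 samples
#> filter: kept 398 of 438 profiles
#> descriptors: 398 molecules, 13.6% aromatic
#> homologs: 33 series, 132 member molecules
#> bin: 36 bins of 5 yr
#> cluster: 1A n=116, 1B n=55, 2 n=227
#> identify: levels L1=6 L2=3 L3=0 L4=389 L5=0

round(report$recordShare[["CHO"]], 1)        # 95   (% of total intensity)
report$classChangePoints$CHNO$year           # 1950 (CE)
round(report$classFolds$CHNO, 2)             # 1.37 (post/pre mean ratio)
report$classChangePoints$CHNOS$year          # 1960
round(report$classFolds$CHNOS, 2)            # 1.87
report$anthroChangePoint$year                # 1950
round(report$proxyCorrelations$nitrate, 2)   # 0.66
```

The 40 reject profiles the generator plants are removed by the QC filter;
the 398 true molecules split into the natural cluster (227) and the
anthropogenic clusters; the CHNO and CHNOS aggregates recover their
planted change points exactly and their planted folds (1.4, 1.9) within a
few percent; the anthropogenic cluster mean correlates with the coupled
nitrate proxy near the planted r = 0.70. The weighted oxidation-state
record shifts upward across 1950 (e.g. OSc −0.449 ± 0.009 before to
−0.412 ± 0.012 after in this run), mirroring the increase in oxidised
cluster-1A material. `recoveryReport(report, report$truth)` scores all of
this against the planted truth.

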