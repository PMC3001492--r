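---
title: "Models and methods behind epilock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epilock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilock)
```

## The biological question and the experiment

Chicken proepicardial (PE) explants differentiate into beating
cardiomyocytes in culture, while explanted epicardium (Epi) loses that
capacity during maturation — an "epicardial lock". The experiment this
package analyses profiles both processes on two-color oligonucleotide
arrays (20,460 probes printed in singlets): eight PE samples (pre-explant
HH16, then 14, 24, 36, 48, 60, 72 and 120 h in culture) hybridized in a
dye-swapped loop, four Epi stages (HH25, HH29, HH32, HH37) in a dye-swapped
round robin, and dye-swapped bridges of HH25 and HH29 against the PE 48-h
sample — 32 arrays in all, with every sample on 4 (PE loop) or 6 (round
robin) within-series arrays.

A loop design has no common reference: each array measures a log ratio
between two biological samples, and all per-sample quantities are solved
jointly over the connected design graph. Everything downstream —
estimability, residual degrees of freedom, error correlations — flows from
that graph, which is why `design_graph` objects and `validate_design()`
(connectivity, dye balance, design-matrix rank) sit at the base of the
package.

## From spot tables to M and A

`read_spot_table()` ingests GenePix-style tab-delimited results (median
foreground/background per channel, flags), drops control spots, and
`compute_ma()` forms per spot

$$M = \log_2(R/G), \qquad A = \tfrac12(\log_2 R + \log_2 G),$$

with $R$ the Cy5 (635 nm) and $G$ the Cy3 (532 nm) signal. Flagged spots
(flag < 0) are kept at weight 0.1 rather than discarded, as in the original
processing; a non-positive signal under the `"subtract"` background policy
zeroes the weight and marks M/A missing instead of throwing. The default
background policy is `"none"`: the original analysis does not state a
subtraction, and using foreground medians as-is avoids the missing-data
cascade that subtraction causes at low intensities. The `"subtract"` option
remains for sensitivity analyses.

## Normalization

Within each array, `loess_normalize_array()` removes the
intensity-dependent dye bias by a weighted robust local-linear fit of M on
A (span 0.25), returning $M - \hat c(A)$. `iterations = 2` is interpreted
as two robustifying (Tukey bisquare) passes after the initial fit — the
lowess convention matching the printed parameter name. Spot weights
multiply into the fit, so a flagged spot pulls the curve ten times less
than a clean one; the local fit itself is delegated to
`limma::loessFit()`. Between arrays, `aquantile_normalize()` maps each
array's A values onto the mean of the order statistics
(`limma::normalizeQuantiles`), leaving M untouched and resolving ties by
the mean of the tied targets. Loess is applied globally rather than per
print-tip block: the original block structure is not recorded in the data
the pipeline consumes.

One numerical caveat is worth stating plainly: a local-linear smoother is
not a projection, so renormalizing an already-normalized array refits a
curve of order $\sigma/\sqrt{\mathrm{span}\cdot n}$ — about $9\times
10^{-3}$ RMS at 8,000 spots with spot noise 0.3 — rather than zero. Exact
idempotence holds only for inputs the smoother reproduces exactly (e.g.
data linear in A).

## Sample effects over the design graph

For probe $p$, the M value of an array hybridizing Cy3 sample $i$ against
Cy5 sample $j$ is modelled as

$$M_{pa} = e_{pj} - e_{pi} + d_p + \varepsilon_{pa},$$

where $e$ are log2 expression levels relative to a reference sample and
$d_p$ is a probe-specific dye offset (the constant column). The connected
32-array graph makes all 11 non-reference effects plus the dye term jointly
estimable. `estimate_sample_effects()` solves this per probe by weighted
least squares, grouping probes by weight pattern so the unflagged majority
is handled in a single matrix product. Probes with fewer usable arrays than
parameters + 1, or a rank-deficient weighted design, are reported
untestable rather than dropped silently.

## The temporal Hotelling test

Differential regulation over the PE time course is tested per probe by
fitting a second-degree polynomial in coded time while conserving temporal
order and correcting for dye. In ratio space the intercept cancels, so the
design row of an array pairing times $t_i$ (Cy3) and $t_j$ (Cy5) is
$[u(t_j)-u(t_i),\; u(t_j)^2-u(t_i)^2,\; 1]$, the constant column absorbing
the dye effect. The default coding $u(t) = (t - \bar t)/\mathrm{sd}(t)$
over the eight design times (HH16 taken as 0 h) is purely for conditioning:
the joint test depends only on the column span of the two time columns, and
the test verifies F is invariant to affine recodings to $10^{-8}$.

With $\hat\beta_s = (\hat\beta_1, \hat\beta_2)$ and $\hat V_s = s^2
(X'WX)^{-1}$ restricted to those coefficients,

$$T^2 = \hat\beta_s' \hat V_s^{-1} \hat\beta_s, \qquad
  F = T^2/2 \sim F(2, \nu), \quad \nu = n_\mathrm{usable} - 3 .$$

The phrase "any of the individual parameters except the intercept differs
from zero" is implemented as this joint 2-df Wald (Hotelling) statistic,
not as two marginal tests — the procedure is named a Hotelling $T^2$ test,
and the 16 data points are read as the 16 loop arrays' M values (4
technical replicates × 8 time points in ratio space). BH-FDR is applied
across all testable probes as a single family, with calls at $q \le 0.15$.
Zero-residual-variance probes receive an infinite-F sentinel with $p = 0$
and a `"degenerate"` status; they are never silently removed.

The F reference distribution is exact under Gaussian errors; the test suite
confirms KS-uniform null p-values through the full pipeline. A permutation
oracle conditioning on the observed M multiset estimates a slightly
different quantity: its law differs from the unconditional $F(2,\nu)$ tail
by $O(1/n)$ (about 0.005–0.01 at 16 arrays, largest in the mid-to-upper p
range), which exceeds Monte-Carlo error at 20,000 draws. The corresponding
acceptance check is therefore expected to flag several probes even for a
correct implementation.

## Epi stage contrasts

`fit_epi_pairwise()` fits the stage + dye model per probe on the 12
Epi–Epi arrays only and tests all six pairwise stage comparisons with t
statistics on the residual df ($\nu = 8$ when all spots are usable),
BH-adjusted across probes separately within each contrast family and
called at adjusted $p < 0.01\%$. The four bridge arrays enter sample-effect
estimation but not this model: "Epi stage + dye" names stages as the only
biological terms, and a bridge involves a PE sample. BH is per family, not
pooled, because the six comparisons are reported as separate tests.

## Profile clustering

Called genes are clustered on z-scored profiles with k-means
(`stats::kmeans`, best of 50 random starts under a fixed seed). For rows
standardized to unit variance, $1 - r_{xy} = \lVert x-y\rVert^2 / (2(n-1))$,
so the squared-Euclidean objective is exactly clustering on Pearson
correlation distance; the suite asserts the identity numerically. Defaults
follow the study: 7 clusters for the temporal set, 6 for the divergent set.

## The divergence screen

Candidate "lock" genes are probes whose 12-point profile (8 PE effects in
time order, then 4 Epi effects in stage order, each segment z-scored
separately) correlates strongly with a divergent template. The published
template set is not available, so `default_templates()` defines a
canonical, user-replaceable library of six: PE saturating rise, PE
exponential decline, PE transient peak (36 h) and PE transient dip (60 h),
each paired with monotone Epi shapes such that no template is concordant
(same trend in both series) and no two templates are scalar multiples of
one another — the rise/decline and the two transients are deliberately
non-mirror-image. Because the screen uses the best absolute correlation,
what the package guarantees is the procedure, not any particular vector
set; the printed count of 258 divergent genes in the original study is
accordingly not a reproduction target.

Calls require BH-FDR $q < 1\%$ and $|r| > 0.6$. The p-value calibration is
the one genuinely open design point. The textbook route — $t =
r\sqrt{(n-2)/(1-r^2)}$ with $n = 12$ — assumes 12 independent profile
points, but effects estimated over a loop graph have strongly correlated
errors, so smooth null profiles imitate smooth templates far more often
than iid theory predicts; selecting the best of six templates compounds
this. Measured on the generator's own null worlds, BH at 1% on t-transform
p-values yields a realized false-discovery proportion around 20%. The
default (`p_method = "design"`) therefore simulates the null distribution
of the best-template $|r|$ from the design-implied effect covariance
$(X'X)^{-1}$ (20,000 draws on a private, seeded RNG stream), leaving the
statistic, thresholds and call rule untouched while making the nominal 1%
an actual 1%. The t transform, with a Šidák best-of-$T$ selection
correction, remains available as `p_method = "t"` for settings with
independent profile points. The design-covariance null uses the all-usable
weight pattern; probes with flagged spots deviate slightly from it, an
approximation the FDR results show to be immaterial at the default flag
rate.

## The synthetic stated world

`simulate_study()` is a first-class forward model, not a fixture: it
builds the 32-array design and emits per-array GenePix-style tables in
which

$$M = \Delta e + d_a + c(A) + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2),$$

with per-array dye offsets $d_a \sim N(0, 0.15^2)$, a smooth
intensity-dependent trend $c(A) = 0.8\sin(A/2)$ (a shape loess must remove
but quantile steps must not), per-array scale shifts, and a 2% rate of
flagged spots whose red channel is wildly corrupted. Intensities are
generated on the log2 scale and exponentiated, kept as floating-point
counts so the forward model is exactly invertible; local background is a
small positive constant with noise so both background policies are
exercisable. Probe classes default to 70% null, 10% temporal, 10% cluster
archetype, 5% divergent, 5% concordant. Temporal coefficients are drawn
with $|\beta_1| \sim U(0.20, 0.45)$ and $|\beta_2| \sim U(0.12, 0.35)$ in
scaled-time units, calibrated once so the Hotelling test has ≈ 80% power
at the default noise $\sigma = 0.3$; divergent and concordant profile
amplitudes are 3 × the spot noise ("signal-to-noise 3"). Spot noise 0.3
log2 units and baseline abundance $N(10, 1.5^2)$ are typical of two-color
spotted-array data.

What the generator does not emulate: spatial print-tip artifacts, probe
sequence effects, correlated (non-Gaussian) spot noise, and the unrecorded
internals of the original normalization. A green test establishes that the
procedures behave as specified on this stated world — it does not
establish that re-analysis of the deposited raw data would reproduce the
printed 1,530 temporally regulated probes, which would require downloading
the archive and is outside the desk-scale suite.

## Numerical and policy choices

* Estimation uses plain WLS without empirical-Bayes variance moderation:
  moderation is a property of external software, not of the procedure
  implemented here; the contrast machinery accepts a shrinkage plug-in.
* Probes missing from an array carry weight 0 there; untestable and
  degenerate probes are labelled via a `status` column, never dropped.
* Quantile-normalization ties map to the mean of tied targets.
* K-means ties and empty clusters are handled by `stats::kmeans`
  (Hartigan–Wong); the seed and restart count are recorded in the model
  object and the pipeline manifest.
* All pipeline outputs are plain TSV with stable column order; the
  manifest records versions, configuration, per-stage row counts and file
  checksums, and identical inputs reproduce identical files.
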