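---
title: "Models and methods behind rnaptrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnaptrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaptrack)
```

rnaptrack analyses single-particle-tracking PALM data of RNA polymerase
(RNAP) in rod-shaped bacteria: where RNAPs are in the cell, how mobile they
are, how strongly they cluster, and whether the clusters sit on ribosomal RNA
(rrn) operons. Because raw localization data of this kind are rarely
deposited, the package ships a fully specified synthetic-data generator whose
defaults encode the study conditions; every analysis routine is exercised
against data whose ground truth is known. This vignette explains the models,
the defaults and the judgement calls.

## Cell and nucleoid geometry

The cell boundary is a spherocylinder of pole-to-pole length $L$ and width
$W$ (cylinder of length $L-W$ with hemispherical caps of radius $W/2$);
physical coordinates are in micrometres with the origin at the cell centre
and $x$ along the long axis. The nucleoid is a prolate spheroid with long
semi-axis $a = L/2 - g$ and short semi-axis $b = 0.75\,W/2$, where
$g = 150$ nm is the nucleoid-to-pole gap. The data behind the geometry fix
only the pole gap and a separate "shrink the cell by 75% in length and width"
rule used to estimate the nucleoid *area*; the short semi-axis is not stated
anywhere, so we set it to $0.75\,W/2$ to make the 3D spheroid consistent
with the 2D shrink rule. This is a declared convention, not a measured value.

Normalized coordinates are $l = (x + L/2)/L$ and $w = (y + W/2)/W$, both in
$[0,1]$. Pole-proximity statistics use the folded coordinate
$l_f = \min(l, 1-l)$, which pools the two cell halves; under a uniform axial
distribution exactly half the mass has $l_f \le 0.25$, so the "exterior-25%
fraction" reads directly as pole enrichment (above 0.5) or depletion (below).

Uniform sampling in the cell volume or nucleoid uses rejection sampling in
the region's bounding box (for the spheroid the acceptance rate is
$\pi/6$, which the tests verify). Projection to 2D drops the $z$ coordinate
and leaves $x$ untouched.

## The four-population cell simulator

`simulate_cell()` draws one cell of the Monte-Carlo model used for
fixed-cell analyses. $n$ molecules (1800 for the wild-type and $\Delta$5
configurations, 1200 for $\Delta$6) are split into:

* an immobile fraction $f_{\mathrm{imm}} = 0.48$, of which a fraction
  $f_{rrn} = 0.60$ (plausible range 0.30–0.80) is bound in clusters at rrn
  operon sites and the remainder in small clusters spread through the
  nucleoid;
* a mobile remainder, uniform in the nucleoid, of which a fraction
  `noise_fraction` (default 0.10, unstated in the source data; chosen as a
  realistic localization-artifact level) is diverted to uniform "noise" in
  the whole cell volume.

Counts are exact by construction (rounded once, then conserved), which the
tests assert for every configuration.

Small-cluster sizes follow a truncated exponential fitted to experimental
cluster-size histograms, $y = a e^{-bx}$, sampled by the inverse transform
$X = -(1/b)\ln(1 - bu/a)$ with rejection of draws where $bu/a \ge 1$,
rounded and clamped to $\ge 1$ molecule. The fitted $(a, b)$ of the original
data are not available; the default `cluster_size_model(0.1, 0.1)` is a plain
exponential with mean 10 molecules per small cluster, consistent with "small"
clusters being well below the 35-molecule scale of the large-cluster
censuses. Cluster members are isotropic 3D Gaussians of sd `cluster_sigma`
(default 40 nm, giving 100–200 nm cluster diameters in line with reported
50–300 nm cluster sizes); members falling outside the cell volume are
redrawn until inside.

rrn operon sites sit on the nucleoid surface. Their long-axis position
comes from a linear genomic-distance map: oriC maps to the pole-proximal
nucleoid tip, the terminus to mid-cell, and an operon `offset_kb` from oriC
on a 2320 kb replication arm sits at distance $(\mathrm{offset}/2320)\,a$
from the tip. The azimuth around the resulting surface ring is uniform
(no imaging-plane bias is assumed), proposals are rejected until all
pairwise separations exceed 70 nm, and all sites of one nucleoid share an
ori pole drawn at random per cell. Operon offsets 42 (rrnC), 265 (rrnB) and
306 kb (rrnE) are the values used in the occupancy analysis; the remaining
operons (rrnA 110, rrnD 497, rrnH 940, rrnG 1196 kb) carry standard
MG1655-annotation distances.

The linear map is an idealization. It reproduces the qualitative spatial
phenotype — deletion strains concentrate immobile RNAP in the exterior
quarter of the cell, wild type stays flatter and more interior — but it
places the $\Delta$5 profile peak at $l_f \approx 0.06$–0.10 of cell length,
somewhat more polar than the $\approx 0.15$ seen in real cells, where the
ori region does not sit hard against the nucleoid tip. Tests therefore
assert the ordering and exterior-quarter statistics, not the exact peak
position.

Simulated cells use a single nucleoid in a 3.0 × 1.0 μm cell; longer
double-nucleoid cells can be composed by tiling two single-nucleoid cells
end-to-end.

## Tracks, D* and the two-gamma mixture

`simulate_tracks()` generates two-species Brownian tracks at the imaging
frame interval $\Delta t = 15$ ms: per-axis step variance $2D\Delta t$, plus
independent Gaussian localization error (default sd 35 nm) on every
localization, no species switching within a track. The apparent diffusion
coefficient of a species is $D^* = D + \sigma_{loc}^2/\Delta t$; an immobile,
chromosome-bound molecule ($D = 0$) therefore shows
$D^* \approx 0.082\ \mu m^2/s$, inside the 0.08–0.10 band measured for
immobile controls.

Tracking (`link_tracks()`) is greedy nearest-neighbour linking within a
search radius (default 0.48 μm, about five diffusion standard deviations of
a 0.36 μm²/s molecule in one frame; the value used on the original data is
not recorded). A molecule absent from exactly one frame is bridged; longer
gaps terminate the track. Ties are broken deterministically by index.

`apparent_D()` uses **exactly the first four** single-frame displacement
intervals: $D^* = \sum_{i=1}^{4}(\Delta x_i^2 + \Delta y_i^2)/(16\,\Delta t)$.
Displacements across a bridged blink gap span two frame intervals and are
excluded. Fixing the step count makes the sampling distribution of $D^*$ an
exact Gamma with shape 4 and mean equal to the apparent coefficient, so the
population model for a mixture of immobile and mobile molecules is a
two-gamma mixture with shape 4. `fit_two_gamma()` maximizes that mixture
likelihood on unbinned $D^*$ values — not least squares on histogram bins,
which would make the result depend on bin width — with the immobile
coefficient fixed (default 0.09 μm²/s, configurable in the 0.08–0.10 band)
and the mobile coefficient free. Five fixed initializations make the fit
deterministic and order-invariant; a grid-search oracle in the tests
confirms the optimizer finds the global optimum.

One caveat the tests document: when tracks are generated with an explicit
localization error, consecutive displacements share error terms and are
negatively correlated, so $D^*$ is no longer exactly gamma; at the study's
parameter values this biases the recovered immobile fraction by about half
a point. Recovery tests therefore parameterize the generator directly by
apparent coefficients (zero localization error), the regime in which the
mixture model is exact. Real data carry the correlated-error bias.

Track classification uses a threshold of 0.16 μm²/s, boundary inclusive
(immobile iff $D^* \le 0.16$).

## Heatmaps and pole statistics

`build_heatmap()` pools normalized positions across cells inside a
cell-length window (defaults follow the double-nucleoid windows 3.2–4.0 μm
in minimal and 3.5–4.5 μm in rich medium) on a 50 × 25 grid; the grid size
is a display choice, not data-driven. For track data one spatial sample per
track (its first localization) is used so long tracks are not over-weighted
— the same convention the clustering analysis applies. Difference maps
normalize the immobile and mobile heatmaps to unit mass *before*
subtracting; without that, unequal track counts dominate the sign. The
exterior-25% fraction computed from a heatmap weights boundary-straddling
bins by their overlap with the exterior region, so the statistic is
consistent with the point-wise definition.

## Clustering and pair correlation

`cluster_rnap()` is DBSCAN with the classical core / directly-reachable /
noise semantics, neighbourhood counts inclusive of the point itself, and
defaults $\epsilon = 20$ nm, MinPts = 4 (a calibration inherited from the
original Monte-Carlo parameter study; the package does not re-derive it).
Border points reachable from two clusters go to the cluster discovered
first in index order — the classical ambiguity, fixed for reproducibility;
the partition of core points is order-invariant and is checked against a
brute-force neighbourhood-enumeration + connected-components oracle.
Large-cluster fractions use strict thresholds (size $> 35$, $> 70$,
$> 100$) with clustered molecules (noise excluded) as the denominator.

The pair-correlation function $g(r)$ bins all pairwise 2D distances in a
cell (default 10 nm bins to 1 μm) and normalizes by the mean histogram of
uniform draws of the same number of points in the 3D volume of revolution
of the cell boundary, projected to 2D — this cancels the confining-geometry
artefact, so uniform input gives $g \equiv 1$. The default of 20 null draws
balances null noise (sub-percent per bin at 2000 points) against cost;
per-cell curves are averaged unweighted across cells, and bins with an
empty null are reported NA and skipped per-bin in averages. A population
confined to the nucleoid but otherwise uniform shows $g > 1$ against the
whole-cell null purely through confinement; for such populations the
function accepts `null_region = "nucleoid"`, under which an unclustered
nucleoid population is flat at 1.

Co-localization with rrn foci uses the fraction of query items (points or
cluster centroids) within 200 nm of the nearest focus. The random baseline
replaces the queries by uniform draws in the nucleoid *area* — the cell
outline with length and width scaled to 75%. Axial focus positions in
reference geometries are interpreted in normalized coordinates of that
shrunk nucleoid region (foci of nascent-rRNA signal are nucleoid
structures); with a 3.0 × 1.0 μm cell and foci at folded positions 0.15,
0.15 (opposite pole) and 0.30 this baseline is ≈ 23–24%, which the tests
verify against direct numerical area integration. Interpreting the same
positions in whole-cell coordinates would push the pole foci half outside
the nucleoid and lower the baseline to ≈ 19%.

## The occupancy bookkeeping model

The occupancy module asks whether the rrn operons remaining in a deletion
strain can physically carry the RNAP traffic its growth rate demands.

*Gene dosage.* A gene at relative map position $m'$ (0 at oriC, 1 at the
terminus) is present at $2^{(C(1-m') + D)/\tau}$ copies per cell, with
replication period $C$, division period $D$ and doubling time $\tau$. $C$
and $D$ are not tabulated for these strains; the package inverts
$C + D = \tau \log_2(\text{oriC copies})$ from the measured origin copy
number and splits $C{:}D = 2{:}1$, a split that reproduces all six
tabulated per-cell rrn copy numbers within 5%, the model's own consistency
check.

*rRNA-engaged RNAPs.* The per-cell count $N_r$ of RNAPs transcribing rrn
(defined as overall rRNA synthesis rate over the 85 nt/s elongation speed)
is interpolated across growth rates by a single exponential in
$\ln \mu$ (with $\mu = 60/\tau$ doublings/h), i.e. a power law
$N_r = \alpha\,\mu^\beta$. On this axis the six calibration points are
collinear to about 1% and leave-one-out predictions land within 1.3%; a
fit linear in $\mu$ instead misses held-out points by over 30%, so the
log-growth-rate axis is the one the calibration data actually support.

*Occupancy.* RNAPs per operon is $N_r$ over rrn copies; fractional
occupancy is that loading relative to the 72 RNAPs/operon observed at the
maximal growth rate. Ratios are kept unrounded internally and rounded
half-away-from-zero only in report columns. The physical ceiling,
`floor(5400 bp / 40 bp) = 135` RNAPs, uses a default operon length of
5.4 kb (16S + 23S + 5S plus spacers) and a 40 bp elongating footprint, both
configurable. qPCR ori:ter ratios use plain $2^{\Delta Ct}$ arithmetic.
Plasmid-complemented strains are not modelled: their plasmid copy number is
too uncertain to support the same bookkeeping.

## Problem sizes and determinism

Every stochastic routine takes an integer seed and is bit-reproducible
given one. The test suite sizes simulations to keep the full run in a few
minutes while leaving comfortable statistical margins: 10⁴ tracks per
mobility replicate with 100 replicates for recovery statistics, 2000
simulated cells per strain configuration for mean pair-correlation
orderings, 150 cells per configuration for heatmap statistics, and 10⁵–10⁶
points for uniform-null and co-localization baselines. Tolerances in tests
are 3-standard-error bands where a sampling distribution is known, and
analytic bounds elsewhere.

## Known limitations

* The simulator draws positions, not movies: localization error enters the
  track generator but there is no photophysics beyond Poisson shot noise in
  the frame renderer, and no blinking model in the fixed-cell point
  patterns beyond the consecutive-frame merge rule (100 nm radius).
* Cell geometry is parametric; real segmented outlines (curved or dividing
  cells) are out of scope, so passing tests demonstrate correctness of the
  estimators under the model, not robustness to segmentation error.
* The two-gamma model assumes static species membership over a track's
  first four steps; molecules binding or unbinding within that window blur
  the mixture.
* The genomic-distance map is linear and single-nucleoid; replication-
  driven multi-copy chromosome organization in fast growth is only
  approximated by tiling.
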