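---
title: "Quantifying DNA double-strand breaks from fragment-length distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA double-strand breaks from fragment-length distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbfrag)
```

## The measurement model

Ionising radiation severs circular plasmid DNA by double-strand breaks
(DSBs). On a circular molecule the bookkeeping is exact: one DSB linearises
the plasmid into a single full-length fragment, and $k$ DSBs cut it into
exactly $k$ fragments whose contour lengths sum to the intact length $L$.
Atomic force microscopy (AFM) measures each deposited fragment's contour
length individually, so a sample of measured lengths carries everything
needed to count breaks:

* **Molecules.** Cutting conserves total length, so the number of plasmid
  equivalents in a sample is $M = \sum_i x_i / L$, summing *all* records —
  intact circles included.
* **DSB per DNA molecule.** Fragment count equals break count, so
  $\mathrm{DSB/DNA} = N_\mathrm{lin} / M$ with $N_\mathrm{lin}$ the number
  of linear fragments. Intact circles enter the denominator only.
* **DSB per broken DNA.** The same ratio with the denominator restricted to
  the plasmid equivalents of the linear material,
  $N_\mathrm{lin} / (\sum_{\mathrm{linear}} x_i / L)$; it is $\ge 1$
  whenever a fragment exists and $\ge$ DSB/DNA whenever circles are present.
* **Spatial DSB profile.** Binning fragment lengths into $w = 50$ nm bins
  over $(0, L]$ and dividing each bin count by $M$ attributes DSBs to
  inter-break distances. Mass in the shortest bin means breaks arrived
  close together on the molecule — the signature of clustered damage from
  densely ionising (high-LET) particles.
* **RBE.** The relative biological effectiveness of a test radiation for
  DSB induction is the ratio of its DSB/DNA to that of the Co-60 reference,
  with the uncertainty of the ratio propagated in quadrature from the two
  standard deviations (`compute_rbe()`); the bundled five-radiation
  reference table is reproduced cell-for-cell at two decimals by
  `reproduce_table1()`.

The default target is the pUC19 plasmid: 2686 bp with a measured intact
contour length of 850 nm. That implies 0.3165 nm/bp — below the canonical
B-DNA rise of 0.34 nm/bp; we deliberately use the measured calibration,
since surface deposition is known to compress apparent contour length, and
all conversions (`bp_to_nm()`, `nm_to_bp()`) scale by the measured factor.

### Binning convention

Bins are left-open/right-closed, $(0,50], (50,100], \dots, (800,850]$, so a
fragment measuring exactly a bin edge falls in the lower bin and a
full-length 850 nm linear fragment lands in the last bin. Intact circles
are not fragments and are never binned. Lengths above $L$ by at most 2%
(measurement noise) are clamped to $L$ with a warning; larger excursions
are reported and excluded. Topology is required input, never guessed: a
full-length linear fragment and an intact circle have identical lengths but
opposite meanings, and records without a valid `linear`/`circular` flag are
rejected.

## The uniform random-breakage null

Low-LET radiation deposits energy sparsely, so breaks are well modelled as
a Poisson process uniform on the circle: $K \sim \mathrm{Poisson}(\mu)$
breaks per plasmid, positions i.i.d. uniform on $[0, L)$. Conditional on
$K = k \ge 2$, each circular spacing has density
$f(x \mid k) = \frac{k-1}{L}\left(1 - \frac{x}{L}\right)^{k-2}$ on $(0,L)$,
and $k = 1$ contributes a point mass at $L$. The expected fragments per
plasmid per bin $(a, b]$ mix over $k$:

$$E[(a,b]] \;=\; \sum_{k\ge1} P(K=k)\,k\,\bigl[F(b\mid k) - F(a\mid k)\bigr],
\qquad F(x \mid k) = 1 - (1 - x/L)^{k-1},$$

computed in closed form by `uniform_null_bin_expectation()` with the
Poisson sum truncated where the remaining tail mass drops below $10^{-12}$.
Summed over bins the expectation is exactly $\mu$ (each break makes one
fragment), which doubles as a self-check.

A pleasant identity falls out of the mixture: since
$\sum_k P(K=k)\,k\,t^{k-1} = \mu\,e^{\mu(t-1)}$, the per-bin expectation is
*exactly* $\mu\,(e^{-\mu a/L} - e^{-\mu b/L})$ in every bin except the
last, which carries the extra single-break atom $P(K=1)$. The familiar
"near-exponential" low-LET fragment-size distribution is therefore not an
asymptotic approximation at the level of bin expectations but an identity;
the test suite asserts it both exactly and as the (trivially satisfied) 5%
band in the first five bins.

`estimate_break_rate()` inverts the DSB/DNA definition as a
method-of-moments estimator of $\mu$; its error at $n$ plasmids is
$O(\sqrt{\mu/n})$ and the suite checks recovery within three standard
errors at $n = 10^3 \dots 10^5$.

## The clustered (high-LET) model

The experimental observation this package makes testable is a spike of
fragments in the shortest bin after heavy-ion irradiation. The generator's
clustered model is the simplest two-scale process producing it: plasmid
hits by particle tracks are $\mathrm{Poisson}(\lambda)$; each track draws a
cluster size $S \ge 1$ (breaks per track) from a configurable law — by
default a geometric law truncated at 100 with mean `mean_size` — and
places its breaks uniformly in a window of width `cluster_span_nm`
(default 50 nm, the shortest bin) centred at a uniform track position,
wrapped on the circle. Mean breaks per plasmid is
$\lambda\,E[S]$, so models are matched to a uniform $\mu$ by
$\lambda = \mu / E[S]$. With $S \equiv 1$ the model reduces exactly to the
uniform one — a reduction the suite verifies distributionally.

No track-structure physics is implied: cluster parameters are free knobs
emulating the qualitative two-scale geometry, not fitted constants (the
underlying experiment reports no intra-cluster distances). The
`clustering_index()` quantifies the short-bin excess as observed first-bin
DSB density over the uniform-null expectation *at the sample's own
DSB/DNA*; it sits near 1 for uniform breakage and well above 1.5 for mean
cluster sizes $\ge 3$ at 50 nm span. A multi-bin variant (`bins > 1`) is
available but non-default, matching the emphasis on the shortest interval.

## The synthetic-data generator as a stated world

`simulate_sample()` emulates one irradiated, imaged and measured aliquot:
`n_plasmids` circles, breaks from either model, then an optional
measurement layer (`detection_model()`): additive Gaussian contour-length
noise (resampled until positive — lengths can never become non-positive)
followed by a hard detection floor. Both default to **off**, because the
experiment states no length-error model and no minimum measurable length;
the ~10 nm AFM tip radius motivates a floor of that order when one is
explored. Dose enters through a linear response $\mu = \alpha D$ with
$\alpha$ calibrated per radiation so the 6 kGy analysis dose reproduces the
bundled reference DSB/DNA (no dose–response curve is available to fit
beyond that single point).

What a green test establishes: the statistical machinery — conservation
bookkeeping, binning, estimators, null expectations, uncertainty — is
correct on data with the assumed structure. What it does not establish:
anything about real AFM artefacts (tip convolution, surface-induced length
bias, overlapping molecules, non-uniform deposition), which the generator
does not emulate.

### Reproducibility contract

One master seed; each plasmid draws from its own deterministic sub-stream
(a fixed integer hash of seed and plasmid index), so enlarging a sample
extends it without reshuffling earlier plasmids, identical configuration
gives bit-identical output tables, and the caller's RNG state is never
touched.

## Numerical choices

* **Exact conservation.** Circular spacings are computed as sorted
  differences plus the wrap-around gap, with the floating-point residual (a
  few ulps) folded into the largest fragment so per-plasmid lengths sum to
  $L$ bit-exactly. `count_molecules()` sums with a chunked long-double +
  Neumaier compensation, so a noise-free $n$-plasmid sample counts exactly
  $n$ molecules. These choices make the conservation tests exact rather
  than tolerance-based.
* **Bootstrap uncertainty.** The reference experiment reports standard
  deviations without stating their method; we use a nonparametric bootstrap
  over fragment records ($B = 1000$, seeded). Against 200 independent
  simulated replicates it tracks the true sampling deviation within ~12%
  (slightly high, because resampling also perturbs the molecule
  denominator). With $\ge 1000$ fragments the relative uncertainty of
  DSB/DNA stays below the 5% design target.
* **RBE rounding.** Computation at full precision; reporting and the
  reference-table comparison round to 2 decimals, the table's convention.
* **Monte-Carlo acceptance check.** The analytic null is compared to a
  brute-force vectorised simulation of $10^6$ plasmids bin-by-bin at 3
  Monte-Carlo standard errors (batch-based SE, floored by the Poisson SE
  $\sqrt{p/n}$ where bins are near-empty). Because 51 simultaneous
  3-sigma comparisons fail by chance for about one seed in eight even for
  an exact implementation, a flagged bin gets one independent confirmation
  draw and the check fails only if the exceedance replicates; a genuine
  bias would.
* **Dose constant.** $1\,\mathrm{keV} = 1.602176634\times10^{-16}$ J over
  the mass of a $1\,\mathrm{cm^2}\times1\,\mu\mathrm{m}$ element at
  density $\rho$ gives
  $D[\mathrm{Gy}] = 1.602\times10^{-9}\,\Phi\,[\mathrm{cm^{-2}}]\;
  \mathrm{LET}\,[\mathrm{keV/\mu m}] / \rho\,[\mathrm{g/cm^3}]$.

## Worked example

```{r example}
# Co-60-like aliquot: 6 kGy at the bundled calibration
mu <- dose_to_break_rate(6000, dose_calibration_from_reference("Co-60"))
co60 <- simulate_sample(uniform_break_model(mu), pUC19(), 2000, seed = 42)
co60
dsb_stats(co60, 850, B = 500, seed = 1)

# A heavy-ion-like aliquot at matched DSB/DNA, and its clustering index
ion <- simulate_sample(clustered_break_model(mu / 3, cluster_size_geometric(3), 50),
                       pUC19(), 2000, seed = 42)
fit_breakage(ion, 850)$clustering_index
fit_breakage(co60, 850)$clustering_index

# RBE table regression
reproduce_table1()
```

## Known limitations

* The clustered model is phenomenological; its parameters are not
  identifiable from pooled fragment lengths alone, and no maximum-likelihood
  fit of the full clustered model is attempted.
* The bootstrap treats fragments as exchangeable units; plasmid-level
  resampling is not offered because real AFM data do not record which
  fragments share a parent molecule.
* Heavy-tail behaviour of high-LET spectra beyond the first bin is left
  qualitative — no tail statistic is claimed beyond the clustering index.
* Dose response is assumed linear through the single calibrated point;
  saturation or quadratic components are out of scope.
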