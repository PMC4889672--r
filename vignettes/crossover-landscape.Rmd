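---
title: "Crossover landscapes from nested NIL panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover landscapes from nested NIL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilscape)
```

## The experimental design the package models

A nested near-isogenic line (NIL) panel localizes meiotic crossovers at
high resolution: each sub-NIL strain carries exactly one crossover within
a focal interval that is heterozygous for two divergent genetic
backgrounds, and dense SNP genotyping places that crossover between two
consecutive markers. Two features of such designs shape every statistic
in this package:

1. **One crossover per strain.** Counts per inter-marker interval are
   sums of independent single events, so a Poisson model with the
   physical interval length as exposure is natural.
2. **Side-sorted sampling.** Strains are first typed at a central indel
   and then genotyped only on the side carrying the crossover, with
   *equal numbers of strains genotyped per side* even though the
   underlying crossover totals differ between sides and between the two
   reciprocal crosses. The left/right side label is therefore part of the
   sampling design, not a biological effect, and enters every model as a
   covariate. Simulation nulls likewise condition on the observed
   per-side totals.

## The count model

For unmasked intervals $i$ with length $L_i$, side indicator $s_i$ and
optional features $x_i$, crossover counts are modelled as

$$y_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \log L_i + \beta_0 + \beta_s s_i + \beta^\top x_i .$$

`fit_poisson()` fits this by maximum likelihood through `stats::glm.fit`.
Two accounting conventions matter:

* **Deviance explained** is always computed against the offset+side base
  model, so the design covariate is never credited to a feature.
* **Feature covariates are per-bp densities** (occurrences divided by
  interval length), decoupling a feature's effect from exposure; raw
  counts can be supplied instead by passing them directly as covariates.

The residual deviance of the offset+side model is the package's
heterogeneity statistic: under a uniform landscape it should look like
the deviance of tables where each side's total is thrown multinomially
across intervals in proportion to length
(`simulate_uniform_null()` / `uniformity_test()`). The Monte-Carlo
p-value uses the add-one convention $p = (1 + \#\{D^\ast \ge D\}) /
(n_{\rm sims} + 1)$, which keeps p-values in $(0,1]$ and super-uniform
under the null.

The scan modules refit this same model thousands of times inside
permutation loops; they use an internal minimal IRLS solver whose
coefficients and deviances agree with `glm.fit` to $10^{-7}$ (enforced by
tests), while user-facing fits go through `glm.fit` itself.

## Heterogeneity: Lorenz curves and the Gini coefficient

Intervals are sorted by per-bp rate (ascending, ties in physical order);
plotting cumulative physical fraction against cumulative genetic fraction
gives a Lorenz curve, and the Gini coefficient is twice the area between
the curve and the diagonal (trapezoid rule). $G = 0$ means every
location recombines at the same rate; $G \to 1$ means all crossovers
concentrate in one point. The Gini is invariant to rescaling of counts or
lengths and non-decreasing under mean-preserving concentration — both
enforced as property tests.

Because Gini values depend on sample size, `gini_downsample_compare()`
compares maps at equal footing: the denser reference map is repeatedly
subsampled (without replacement) to the event count the target map
yields per window of a stated physical size, and the target Gini is
located within the subsampled distribution (two-sided add-one p).

## Constant-rate domains by exact dynamic programming

To ask how many constant-rate domains a side needs, `fit_segmentation()`
maximizes the Poisson log-likelihood of pooled counts over all placements
of $K-1$ knots at marker boundaries. Within a domain the ML rate is
pooled count over pooled length, so the inner objective is closed-form
and the outer optimization is solved exactly by dynamic programming in
$O(Kn^2)$. This choice — exact ML segmentation rather than a smoothing
or spline approximation of the cumulative map — was made because it
optimizes the stated model class directly, is deterministic, and lets the
test suite verify the optimum against brute-force enumeration. A
consequence is that domain counts from smoothing-based fits of the same
data are comparable only approximately.

Adequacy of $K$ domains is judged by the likelihood-ratio statistic
against the saturated (per-interval rate) model, calibrated by a
parametric bootstrap: tables are drawn from the fitted $K$-domain model
(multinomial, conditioned on the side total) and refitted at the same
$K$. `min_adequate_domains()` reports the smallest $K$ whose add-one p
is at least $\alpha$ (default 0.05, $K \le 40$ examined). The
saturated-model comparison is the default; a $K$ vs $K{+}1$ comparison
can be assembled from successive fits if preferred.

## Gamma rate landscapes and hotspot compatibility

Hotspot-like and near-uniform landscapes are spanned by one family:
per-kilobase rates drawn i.i.d. from a gamma distribution with shape $k$
(CV $= 1/\sqrt{k}$; $k = 1$ is exponential), rescaled to a target total,
with crossovers placed uniformly within bins and then binned into the
marker intervals. For a given shape, `gini_envelope()` simulates the
distribution of the resulting Gini (defaulting to 5000 simulations;
tests use fewer), and `fit_shape_to_gini()` inverts the monotone
shape→mean-Gini map by bisection (on a log-scale bracket, tolerance
0.002 in Gini) with a grid-scan 95% CI: shapes whose simulated 2.5–97.5%
interval covers the observed Gini. `max_rate_multiple()` converts a
shape into the expected fold of the hottest of $n$ kilobases over the
mean rate — the practical meaning of "hotspot-compatible". The expected
fold is the Monte-Carlo mean of the max (not a quantile). Simulations
condition on the observed crossover totals, mirroring the design.

Bin counts default to one bin per kilobase of the span being modelled
(e.g. 820 and 590 bins for sides of 820 kb and 590 kb).

## Motif scans with GC-preserving permutation control

Double-strand k-mers are canonicalized to the lexicographic minimum of
motif and reverse complement (so a $k$-mer catalog has $4^k/2$ entries
plus half the palindromes). Occurrences are counted greedily left to
right in a single pass over both strands: a match of the motif or its
reverse complement consumes $k$ bases; `N` never matches. The greedy
single-pass convention is a deliberate, oracle-tested choice among
several defensible non-overlap definitions.

Each motif's per-bp density enters the count model; the selection effect
of scanning thousands of motifs is controlled by `permutation_null()`:
the sequence of every unmasked interval is shuffled within the interval
(preserving the interval's exact base composition, hence its GC), all
motifs are recounted and refitted, and the minimum residual deviance per
motif-length class is recorded. A motif's permutation p is the add-one
fraction of permutations whose class minimum beats it; the mean
best-motif deviance explained across permutations is the "expected"
baseline that the observed value must exceed (the *additional* deviance
explained). Note the expected baseline is well above zero even under the
null — that is the selection effect, not a bug.

The default scan range is 4–6 bp; 7–8 bp catalogs are supported but cost
multiplies by 16 per extra base. Pairs of motifs (`scan_motif_pairs()`)
fit two densities jointly over a user-bounded subset; identical pairs
collapse to single fits and are flagged collinear.

## Genomic correlates

`aggregate_track()` reduces BED/bedGraph tracks (read via `rtracklayer`,
converted to 1-based half-open coordinates at the boundary) to
per-interval covariates: length-weighted means for signals, prorated
counts per bp for annotations, coverage fractions for span features.
`univariate_scan()` reports per-feature coefficients, deviance explained
and nominal 1-df chi-square p-values, uncorrected (a Bonferroni column is
appended for convenience); a named control covariate (e.g. an IgG binding
control for nucleosome occupancy) can be partialled out so only the
feature's increment is credited. `correlation_cluster()` gives the
average-linkage clustering of the feature correlation matrix with
significance stars from the univariate scan.

## The synthetic-data generator

`synth_scenario()` defaults describe the study conditions the package
is built around: a 1.48 Mb span genotyped at 277 markers whose lognormal
spacing yields a ~4.4 kb median against a ~5.4 kb mean gap; a sorting
indel at 55.6% of the span; per-cross, per-side crossover totals of
387/243 (FaxNIL) and 244/241 (LonNIL), reproducing the design's sampling
skew; 36% GC (typical of a *C. elegans* chromosome arm); and per-side
gamma landscapes with shapes 1.70 (left) and 3.57 (right). Noise rates
default to 1% double-recombinant strains (the rate at which such plates
arise in practice) and 0.2% missing and heterozygous-contamination
rates, chosen as small-but-nonzero values that exercise QC without
dominating it.

The generator writes a truth record for every strain, so tests can check
exact recovery (zero noise) and exact QC flagging (injected noise). What
it does **not** emulate: real linkage disequilibrium or polymorphism
structure, genotyping-intensity artifacts, segmental duplications or
length polymorphism between backgrounds, or any correlation between the
genome sequence and the rate landscape unless a motif effect is
explicitly planted. Passing tests therefore demonstrate the statistical
machinery is correct under the stated design — not that any particular
biological conclusion transfers to a real panel.

## Numerical and edge-case conventions

* Coordinates are 1-based; an interval between consecutive markers at
  $p_i < p_{i+1}$ is $[p_i, p_{i+1})$ with length $p_{i+1} - p_i$.
* A breakpoint spanning several intervals (missing calls) is booked to
  the interval containing the span midpoint; setting
  `missing_rule = "drop"` excludes such strains as
  `ambiguous_at_breakpoint` instead. Midpoints falling in the gap
  straddling the indel go to the terminal interval of their side (the
  case is degenerate when strains are indel-sorted before genotyping).
* 25 kb binning is greedy by length within contiguous unmasked runs,
  trailing short bins merged backward, then bins below the event minimum
  merged into their smaller neighbour. A pre-binned table can be read
  directly, bypassing `rebin_25kb()`.
* Strains with any heterozygous call are excluded (`het_stretch`);
  `max_missing` defaults to 2.
* GLM convergence: relative deviance change $<10^{-10}$ or 100
  iterations; non-convergence is flagged, never silent.
* KS comparisons place interval-censored events at interval right
  boundaries and use the asymptotic two-sided p (sample sizes are in the
  hundreds); ties are inherent to binning and the exact p would be
  invalid anyway.
* All Monte-Carlo p-values use the add-one convention; every stochastic
  stage derives its own seed deterministically from the master seed, so
  whole-pipeline reruns are byte-identical.

## Problem sizes used by the test suite

The suite exercises every stage at sizes chosen for quick desk runs while
keeping each check informative: panels of 180–1,115 strains, 25–277
markers, permutation and bootstrap nulls of 99–1,000 replicates,
segmentation brute-force cross-checks at up to 12 intervals and $K \le
4$, and the dense-limit Gini check at 500 one-kb bins with $10^6$
crossovers. The gamma shape-recovery check averages the observed Gini
over 12 simulated panels because the shape→Gini map is shallow near
shape 1.7 — a precision choice about the *observation*, with the
estimator itself run at 1,000 simulations per evaluation.

## Known limitations

* The exact-ML segmentation count is not directly comparable to
  spline-smoothed domain fits of the same data (see above); treat domain
  numbers as model-class-specific.
* The motif scan's permutation control is per length class; combining
  classes (e.g. best motif overall) needs an extra max across classes.
* `scan_motif_pairs()` over the full 4–8 bp pair space is intentionally
  out of scale; bound the subset.
* The correlates module aggregates signal tracks by length-weighted
  mean; if a track's biology calls for maxima or enrichment-call
  fractions, aggregate externally and pass the covariate directly.
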