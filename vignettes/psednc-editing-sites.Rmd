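---
title: "Pseudo dinucleotide composition for A-to-I editing site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo dinucleotide composition for A-to-I editing site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adared)
```

## The problem and the unit of prediction

A-to-I editing converts specific adenosines in double-stranded RNA into
inosines, which the cell reads as guanosine. `adared` treats site
identification as binary classification of a fixed-length window centered
on the candidate adenosine. The window convention is 51 nt with the A at
1-based position 26: window length is a tunable of the upstream data
preparation, and 51 nt is the length at which this kind of predictor has
been reported to perform best on the fly editing-site benchmark. The
library layer is strict — a window whose center is not A, or that would
run past the end of its source sequence, is an error — while the CLI skips
such records with a logged warning so one bad record does not abort a
batch.

Coordinates are 1-based and inclusive everywhere in the public interface.
DNA input is accepted and silently converted T→U, since editing sites are
often reported against genomic coordinates; ambiguity codes are rejected
rather than randomly resolved, because the property lookup that drives the
encoding is undefined for them. No strand handling is attempted: input is
assumed to be the transcript strand.

## The encoding

The pseudo dinucleotide composition of a window of length $L$ is

$$d_u = \frac{f_u}{\sum_{i=1}^{16} f_i + w\sum_{j=1}^{\lambda}\theta_j}
\quad (u \le 16), \qquad
d_{16+j} = \frac{w\,\theta_j}{\sum_{i=1}^{16} f_i + w\sum_{j=1}^{\lambda}\theta_j},$$

with $f_u$ the 16 dinucleotide frequencies (fixed lexicographic order AA,
AC, ..., UU) and

$$\theta_j = \frac{1}{L-1-j}\sum_{i=1}^{L-1-j}\Theta(T_i, T_{i+j}), \qquad
\Theta(T_a, T_b) = \frac{1}{6}\sum_{u=1}^{6}\left[P_u(T_a)-P_u(T_b)\right]^2,$$

where $T_i$ is the overlapping dinucleotide starting at position $i$ and
$P_u$ ranges over six local structural parameters of the dinucleotide
step: the translational Shift, Slide, Rise (nm) and the angular Tilt,
Roll, Twist (degrees). Every feature vector is non-negative and sums to 1,
and its dimension $16+\lambda$ is independent of $L$.

### Parameters

* `w` (weight factor, unitless, in $[0,1]$; default **0.3**) balances
  composition against the pseudo components. At $w=0$ the encoding reduces
  to plain dinucleotide composition.
* `lambda` (tier count, default **4**) sets how far along the window the
  structural correlation reaches; the feature dimension is $16+\lambda$,
  so large values risk over-fitting small training sets. The defaults are
  the values at which a 5-fold cross-validated sweep of the fly benchmark
  peaks; `parameter_sweep()` reruns that sweep (default grid $w \in
  \{0, 0.1, \dots, 1\}$, $\lambda \in \{1, \dots, 10\}$, 110 cells) on any
  dataset.
* `counting_mode` (default **overlapping**). The composition part counts
  either all $L-1$ adjacent dinucleotides or the $\lfloor L/2\rfloor$
  disjoint ones. The literature describing this encoding uses the phrase
  "non-overlapping" for $f_u$ while defining the correlation factors over
  overlapping dinucleotides; the two readings cannot both be literal, and
  canonical PseDNC implementations count overlapping dinucleotides, so
  that is our default — the non-overlapping mode is retained as an option
  so either reading is testable. Tier correlations always use the
  overlapping dinucleotide sequence.

### Standardization

Property columns are z-scored over the 16 dinucleotides before use. The
SD is the **population** standard deviation (divisor 16): the 16
dinucleotides are the entire population, not a sample from one, and this
matches reference PseDNC implementations. `standardize_properties(...,
sd = "sample")` exposes the divisor-15 convention for sensitivity
analysis; it rescales every column by a common factor
$\sqrt{16/15}$ and therefore changes $\Theta$ only by a constant factor.
A constant property column cannot be standardized and is an error. Users
may supply their own table via `read_property_table()` (CSV/TSV, 16 rows,
named property columns).

## The classifier and the evaluation protocol

Feature vectors are classified by a C-SVM with RBF kernel, using the
libsvm solver through `e1071` — the solver is infrastructure here, not the
contribution; the encoding and protocol are implemented in this package.
Features are not rescaled before fitting (they already live in $[0,1]$ and
sum to 1). `grid_search()` evaluates every $(C,\gamma)$ pair on the
standard libsvm lattice $C = 2^{-5}, 2^{-3}, \dots, 2^{15}$, $\gamma =
2^{-15}, 2^{-13}, \dots, 2^{3}$ by stratified $k$-fold accuracy, with the
fold assignment derived from an explicit seed and shared across cells so
cells are comparable. Ties are broken toward smaller $C$, then smaller
$\gamma$, which makes the result invariant to grid ordering and
duplication.

Evaluation pools confusion counts across folds before computing Sn, Sp,
Acc and MCC. Pooling (rather than averaging per-fold metrics) is the only
convention that also covers the jackknife, where each fold holds a single
sample; `jackknife()` is exactly `kfold_cv()` with $k = n$, and the test
suite asserts the equivalence. Degenerate reports follow documented
conventions: Sn or Sp is NaN (with a warning) when its class is absent,
and MCC is reported as 0 when any confusion marginal is zero. Percentages
are reported to two decimals, matching the precision such predictors are
usually quoted at.

Hyperparameters are selected once on the full training set and held fixed
across jackknife rounds, mirroring the usual protocol in which a 5-fold
parameter optimization precedes the jackknife. This is optimistically
biased — the left-out sample influenced the selected $(C,\gamma)$ — and a
fully nested re-search per round is the honest but far more expensive
alternative; we document the bias rather than hide the cheap protocol,
since it is the one headline numbers in this literature are produced by.

## The synthetic benchmark

The editing-site benchmark this method was developed on (125 positive /
119 negative 51-nt fly windows, plus 300 independent positives) was
distributed from a webserver that is no longer reachable, so the package
generates size- and shape-matched synthetic data instead.
`synthetic_spec()` draws windows from a first-order Markov chain over
{A, C, G, U}: transition weights are $b^{s}$ where $b$ is the class's
dinucleotide bias and $s \in [0,1]$ the separation, so $s=0$ makes the
classes exchangeable and $s=1$ applies the full bias. A first-order chain
(rather than i.i.d. bases) is used because dinucleotide composition is
exactly what PseDNC measures, which makes recovery tests meaningful. The
defaults match the benchmark's shape: 125/119 windows of 51 nt; the bias
maps favor CG/GC in positives and AU/UA in negatives with weight 8 —
strong enough that full separation is unambiguously learnable, which is
what a positive-control harness needs. The central position is overwritten
with A after generation; the slight composition distortion this introduces
is shared by both classes and accepted.

What passing tests on this data do show: the encoder, the SVM wiring, and
the evaluation protocol correctly recover a dinucleotide-composition
signal of known strength, and stay at chance when there is none. What they
do not show: performance on real editing sites, which differ from the
generator in every biological respect (ADAR neighbor preference, secondary
structure, non-stationarity along the window). The generator is a test
harness, not a biological simulator, and accuracy numbers obtained on it
must never be quoted as editing-site performance.

## Numerical choices and problem sizes

All arithmetic is double precision. The feature-sum invariant is asserted
at $10^{-9}$, encoder-versus-oracle agreement at $10^{-12}$ per component,
and standardization at $10^{-10}$ — comfortably above accumulation error
at these sizes, far below any meaningful signal. The test suite and the
acceptance script run the full pipeline at the benchmark's own scale
(244 windows, 5-fold CV, 110-cell grid search, 244-round jackknife),
which completes in seconds; property-style checks use 100–1000 random
windows under fixed seeds.

## Known limitations

* Only dinucleotides ($k=2$) and type-I (series) correlation are
  implemented; no PseKNC generalization.
* No probability calibration and no ROC analysis — the classifier reports
  hard calls (optionally with decision values), and the metrics are
  threshold metrics.
* Class weighting is not applied; the intended training sets are nearly
  balanced.
* Model files are R serializations with a version tag and a
  property-table fingerprint; they are not portable to other SVM
  toolchains (use the libsvm-format feature export for that).
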