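---
title: "Nearest-neighbour models of DNA duplex free energy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nearest-neighbour models of DNA duplex free energy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexnn)
```

## The model

The stability of a short DNA duplex — two strands hybridized over their
full length — is dominated by the stacking interactions of adjacent
Watson–Crick base pairs.  The thermodynamic nearest-neighbour (NN)
picture turns this into a linear model: the hybridization free energy
of a perfect-match duplex with top strand $s$ is

$$\Delta G^\circ(s) \;=\; \sum_{m} n_m(s)\, x_m ,$$

where $m$ ranges over *motif classes* (stacks of $k$ adjacent base
pairs), $n_m(s)$ counts the overlapping $k$-windows of $s$ falling in
class $m$, and $x_m$ is the class's free-energy weight in kcal/mol.
The classical model uses doublets ($k=2$); the extended model uses
triplets ($k=3$), so that each base pair is seen together with its two
neighbours and more sequence context reaches the energy.

A stack read 5'→3' on one strand is the same physical object as its
reverse complement read on the other strand.  Partitioning all $4^k$
$k$-mers by this *rotational identity* leaves 10 doublet classes (four
doublets are their own reverse complement) and 32 triplet classes (no
odd-length word is).  `enumerate_classes()` builds the partition and
`canonical_class()` names each class `"TOP/BOTTOM"`, where TOP is the
lexicographically smaller member and BOTTOM its base-wise complement
written 3'→5'.  Counting is done on the top strand only; by class
symmetry the complementary strand adds no information, and counting
both strands would merely halve every weight.

Deliberately absent from the model: initiation/symmetry penalties,
mismatch, loop and dangling-end terms, and any explicit temperature or
salt dependence.  Environmental breadth is supposed to come from
training on measurements that span those conditions, not from extra
terms.  This is the model's defining simplification and its main
limitation.

## Fitting

For $N$ duplexes the counts form an $N \times K$ design matrix $F$
($K = 10$ or $32$) with experimental energies $R$, and
`tnn_fit()` solves $\min_X \lVert F X - R \rVert^2$.  The solver is an
SVD-based *minimum-norm* least squares (singular values below
$10^{-10}$ of the largest are treated as zero).  That contract matters:
random 67% training subsets can miss rare motifs entirely, making $F$
rank-deficient.  Rather than failing, the fit gives unseen classes
weight 0 and lists them in `unseen_classes`; the design rank and
residual norm are always reported.  On full-rank noise-free data the
fit is an exact interpolator (the test suite checks recovery to
1e-9 kcal/mol), and the test suite also cross-checks the solver against
an independent pseudo-inverse oracle on a thousand random systems.

`tnn_fit()` returns a classed model object, so the usual verbs work:
`coef()` (an `nn_params` vector), `predict()` on new sequences,
`residuals()`, `plot()` (observed versus fitted energies), and
`simulate()`, which draws new synthetic datasets governed by the fitted
parameters.

## Evaluation protocol

`tnn_evaluate()` implements a repeated random-split design.  Each
iteration samples `round(0.67 N)` records (half-up rounding — for
$N = 340$ that is 228 training / 112 testing, for $N = 197$ it is
132/65) uniformly without replacement, fits on the training part, and
scores the *whole* test set with the Pearson correlation and RMSE
between estimated and experimental energies.  Per-test-set (rather
than per-record) metrics are the only coherent reading: a correlation
of a single data point is undefined.  A test set with zero energy
variance records `NA` correlation with a warning while its RMSE is
kept.

Randomness policy: one master seed; iteration $i$ runs on a derived
stream `derive_seed(seed, i)`, so the whole run is bit-reproducible and
any single iteration can be replayed in isolation.  The "best"
parameter set across iterations is chosen by highest test correlation,
ties broken by lowest test RMSE, then lowest iteration index.
Summaries use the seven statistics min / q1 / median / mean / q3 /
max / stddev, with type-7 (linear interpolation) quantiles — the
default convention of common statistical software, stated here because
quartile conventions differ.

## Structure comparison

Duplex secondary structures are pairs of dot-parenthesis strings; base
pairs are extracted by nested matching over the concatenation of the
two strands (0-based indices internally; serialized reports are
1-based).  Pseudoknots cannot be expressed in this dialect and are
rejected at parse time.

Two families of measures are provided.  **SSSI** is the percentage of
string positions at which two annotations agree, normalized by the sum
of the strand lengths.  Because it is character-level, it needs no
pair extraction (even unparseable annotations can be scored) and it
automatically grants one point per correctly placed pairing *end*: a
predicted pair sharing only its start or only its end with the
reference earns half the credit of a fully correct pair, with no
separate half-credit bookkeeping.  **Sensitivity / PPV / F** compare
exact $(i, j)$ pair sets: $\mathrm{SENS} = TP/(TP+FN)$,
$\mathrm{PPV} = TP/(TP+FP)$, F their harmonic mean.  Degenerate inputs
are defined, not errors: two structures with no pairs at all agree
perfectly (all three measures 1); an empty prediction against a paired
reference — or any prediction with no true positive — scores 0 on all
three.  `stratified_metrics()` averages the three measures per
sequence-length bin and per 10-point GC bin.

## Synthetic data

`generate_duplexes()` draws perfect-match duplexes of configurable
length range (default 4–30 nt, the short-oligo regime the model
targets) and GC bias (per-base Bernoulli at the target rate, so
realized GC content spreads around the target instead of collapsing to
a point mass), and assigns each duplex the energy of a known
ground-truth parameter set plus i.i.d. Gaussian noise.  Defaults: the
bundled reference triplet parameters as truth and 0.5 kcal/mol noise, a
mid-range value between reported measurement reproducibility and model
error for short oligos.

`synthetic_benchmark()` goes further and emulates the *composition* of
the 695-duplex experimental collection the reference parameters come
from: 29 literature sources with their record counts, per-source
sequence-length ranges, temperatures (24.85–50 °C), sodium (0.1–1 M)
and sequence concentrations, 340 perfect matches of which 197 sit at
25 °C/1 M Na⁺ and 143 at 37 °C/1 M Na⁺, mismatch duplexes carrying
one to three unpaired positions, and a length histogram peaking at 8-
and 9-mers.  Its noise default is 2.2 kcal/mol — the triplet model's
observed deviation from experiment on the real collection, i.e. the
natural residual scale for an emulation whose ground truth *is* that
model.

What the emulation does **not** carry, and hence what passing tests do
and do not show: real measurements contain inter-laboratory
systematics, initiation and environmental effects, and designed (not
random) sequence panels.  In particular, the emulation's energies are
*exactly* triplet-model values plus isotropic noise, and the bundled
triplet parameters happen to be closely approximable by a doublet
model: a doublet fit to noise-free triplet-model energies leaves well
under 1 kcal/mol RMS (a fact the test suite computes).  Consequently,
on emulated data the doublet and triplet models evaluate almost
identically, and the substantial doublet-versus-triplet gap seen on
real measurements is *not* reproduced — reproducing it would require
the real data, not a stand-in generated from the printed parameters.
Tests on the emulation therefore validate the machinery (counting,
fitting, protocol, metrics, I/O) and the triplet model's self-
consistency, not the empirical superiority of triplets over doublets.

## Problem sizes and numerical choices

The test suite runs the repeated-split protocol at 400 iterations and
the recovery studies at up to 100 seeds × 1000 duplexes, sizes at which
every Monte-Carlo statistic asserted is stable to well inside its
tolerance; `scripts/acceptance.R` runs the full 10,000-iteration
design.  Other fixed choices: SVD rank tolerance 1e-10 (relative);
temperature filtering at ±0.01 °C (so 24.85 °C sources never leak into
a 25 °C subset); missing numeric fields parse as `NA`, never 0;
energies keep their printed sign convention (negative = stable, no unit
conversion); derived per-iteration seeds stay below $2^{31}$.

## Known limitations

* Perfect matches only: no mismatch, bulge, loop or dangling-end
  energetics, hence no applicability to imperfect duplexes beyond
  storing and filtering them.
* No initiation or symmetry terms; absolute energies of very short or
  self-complementary duplexes inherit that bias.
* No explicit temperature/salt model: a parameter set is only as broad
  as the conditions it was trained on.
* The bundled exclusion mechanism (`exclude_ids=`) supports curated
  removals, but no curated id list ships with the package.
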