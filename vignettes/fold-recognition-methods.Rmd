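---
title: "Methods: evolutionary-feature fold recognition in pssmfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary-feature fold recognition in pssmfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pssmfold` predicts a protein's fold class from its PSI-BLAST
position-specific scoring matrix (PSSM): the $L \times 20$ matrix $P$
whose entry $P_{j,i}$ is the log-odds substitution score of amino acid
$i$ at sequence position $j$. The working assumption is that proteins
sharing a fold share statistical regularities of $P$ that survive the loss
of sequence alignment: per-column autocorrelation along the chain, and
residue-pair propensities at short separations. Two transforms convert the
variable-length matrix into a fixed-length vector.

**Auto-cross-covariance (ACC).** With $\bar P_i$ the mean of column $i$
over all $L$ positions,

$$AC(i, lg) = \frac{1}{L-lg} \sum_{j=1}^{L-lg}
  (P_{j,i}-\bar P_i)(P_{j+lg,i}-\bar P_i), \qquad
CC(i_1, i_2, lg) = \frac{1}{L-lg} \sum_{j=1}^{L-lg}
  (P_{j,i_1}-\bar P_{i_1})(P_{j+lg,i_2}-\bar P_{i_2})$$

for lags $lg = 1,\dots,LG$ and ordered pairs $i_1 \neq i_2$ (CC is
asymmetric and both orderings are emitted). The block sizes are
$20\,LG$ and $380\,LG$; at the default $LG = 4$, 1600 features total.
Being mean-centered, ACC is exactly invariant to adding a constant to any
column — it measures fluctuation structure, not composition.

**Separated dimer (SD).** $F_{m,n}(k) = \sum_{i=1}^{L-k} P_{i,m}
P_{i+k,n}$ over all 400 ordered pairs $(m, n)$, default $k = 4$. SD sums
*raw* products: it responds to composition (column means) as well as to
lag-$k$ co-occurrence, which is precisely what ACC discards. Fusing the
two blocks (1600 + 400 = 2000 features) therefore adds information rather
than redundancy; the package's acceptance suite demonstrates the
complementarity directly on synthetic data.

One convention deserves note: the SD sum is taken over $i = 1..L-k$
($L-k$ terms), matching the range convention of the covariance sums. A
sum starting at a zeroth position is not well defined for 1-based matrix
rows, and the choice is fixed identically in the production code and in
the naive test oracle.

**Information-gain selection.** Each feature is discretized by equal-width
binning (default 10 bins over the observed range, right-closed intervals)
and scored against the fold label $Y$ by
$IG(X|Y) = I(X) - I(X|Y)$ in bits, with
$I(X) = -\sum_i p(x_i)\log_2 p(x_i)$. Features in the closed band
$[\tfrac12 \max IG,\ \max IG]$ are retained; boundary ties are kept and
the maximum always qualifies. Because IG is mutual information, the
implementation is checked against symmetry ($IG(X|Y) = IG(Y|X)$) and the
bound $0 \le IG \le \min(I(X), I(Y))$ on randomized inputs.

**Classifier.** A soft-margin SVM,
$\min_w \tfrac12\lVert w\rVert^2 + C\sum_i \xi_i$, with RBF kernel
$\exp(-\Gamma \lVert x - x'\rVert^2)$, trained one-vs-one: one binary
machine per class pair, majority vote at prediction, vote ties broken by
the largest summed pairwise decision margin and then lexicographic label
order. $(C, \Gamma) = (2^a, 2^b)$ are tuned by stratified $k$-fold
cross-validation over integer exponent grids (classical range
$-14..14$); grid ties go to the smaller $C$, then smaller $\Gamma$.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `LG` | 4 | lag, residues | largest ACC lag; fixes ACC length at 400·LG |
| `k` | 4 | separation, residues | SD dimer gap; 400 features per k |
| `normalization` | `"raw"` | — | ACC/SD consume raw log-odds; `"sigmoid"` squashes to (0,1) |
| `n_bins` | 10 | bins | equal-width discretization for IG |
| `band_fraction` | 0.5 | fraction of max IG | lower edge of the closed selection band |
| `folds` | 10 | — | stratified CV folds for tuning |
| `c/gamma exponents` | −14..14 | $\log_2$ | the classical SVM grid; 841 pairs |
| `noise_sd` | 2 | log-odds units | synthetic per-entry noise, matching typical PSSM spread |

The source method is silent on whether the transforms consume raw or
normalized scores; raw is the default here because the covariance algebra
is defined on the substitution scores themselves, and the `mode` switch
exposes the alternative without endorsing it. It is likewise silent on
how real-valued features become discrete for the entropy formulas;
equal-width binning is the simplest defensible choice, is recorded in
every ranking object, and is configurable.

Scaling is min–max to $[-1, 1]$ per feature, fit on training rows only;
constant training features map to 0 everywhere. Inside cross-validation
both the scaler and the IG selection are re-fit on each training fold —
selecting on the full dataset before CV would leak label information into
the folds and inflate accuracy. A `leaky` flag reproduces the
whole-dataset reading for comparison, but it is off by default.

## The synthetic generator: what a green test establishes

`generate_dataset()` emulates the *statistical structure the features
detect*, not protein evolution. Each class draws:

* **signature autocorrelated columns** — 6 columns follow an AR(1)
  process with class-specific coefficient $\rho$ (preset `high`:
  $\rho \approx 0.7$, `medium` 0.45, `low` 0). This is the ACC-visible
  signal: lagged covariances scale as $\sigma^2\rho^{lg}$, while column
  means are untouched.
* **signed dimer-pair offsets** — 5 column pairs $(m, n)$ receive mean
  offsets $\pm c$ in a class-specific sign pattern (preset `high`:
  $c = 2$ score units, `medium` 1, `low` 0). Mean shifts are invisible to
  the mean-centered ACC transform but move the raw SD products.

Noise is i.i.d. Gaussian (sd 2) around a background mean of −1; scores
are rounded to integers and clamped to $[-10, 12]$, the typical printed
PSI-BLAST range, so fixtures re-enter through the real ASCII parser.
Sequence letters are i.i.d. and carry no signal. A design note: one could
instead have made class-specific *column means* the ACC signal — but ACC
is provably shift-invariant per column, so composition alone cannot
separate classes through it; autocorrelation can, and that is what the
generator encodes. (Rounding and clamping leak a small amount of
mean-pattern signal into ACC; the complementarity tests tolerate and
quantify this.)

Consequently a green pipeline test establishes that the implementation
recovers planted covariance and dimer structure at realistic lengths
(50–150 residues) and sample sizes (tens per class), and that the two
feature families are complementary in the designed directions. It does
*not* establish benchmark-level accuracy on real fold datasets, which
depend on PSI-BLAST profiles against a large sequence database and on
fold-class imbalance that the generator does not model.

## Numerical choices

* **SMO solver** (`src/smo.cpp`): maximal-violating-pair working-set
  selection, stopping when the KKT violation gap is below $10^{-3}$
  (the LibSVM default), hard cap $10^6$ iterations; bias from free
  support vectors, else the violation-interval midpoint. No R package in
  the deployment environment provides an SVM or QP solver, so the dual
  solver is compiled into the package and verified by KKT property tests
  (box and equality constraints, margin conditions at free and bounded
  support vectors) on randomized problems.
* **IG negative-zero guard**: values in $(-10^{-12}, 0)$ from floating
  cancellation are clipped to 0.
* **Degenerate inputs**: profiles with $L \le \max(LG, k)$ are rejected
  fail-fast, listing every offending protein, rather than zero-padded —
  silent zeros would masquerade as legitimate low-IG features. Constant
  features discretize to a single bin (IG 0) and scale to 0.
* **Determinism**: fold assignment and the generator consume an explicit
  seed through an isolated RNG scope; identical spec + seed gives
  bit-identical datasets, grids and reports (the CLI reproduces report
  files byte for byte).
* **Tie-breaks** are total and documented: grid (accuracy, then smaller
  $C$, then smaller $\Gamma$), votes (margin sum, then lexicographic).

## Scaling of the shipped tests

The unit and acceptance suites run on one CPU in a few minutes. The
acceptance pipeline uses the reduced exponent grid $-6..2$ at the stated
dataset size (3 classes × 40 proteins, seed 7); unit tests use single-pair
grids. These reductions change runtime, not code paths: the full
$-14..14$ grid remains the CLI default. The null-separation acceptance
check compares the tuned model's CV accuracy against the 95% binomial
interval of chance at $n = 120$; the winner-over-grid optimism is visible
(0.367 vs 1/3) but well inside the interval at this grid size.

## Known limitations

* Real PSSMs have position-dependent score distributions (conservation
  gradients, gap-rich termini) that the homogeneous generator does not
  imitate; IG thresholds tuned on synthetic data should not be assumed
  transferable.
* The IG band (and so the selected-feature count) depends on the
  discretization; published selected-feature counts on external datasets
  are not reproducible without the original discretization choice.
* One-vs-one voting scales quadratically in the number of folds; with the
  27-fold datasets of the field this is 351 machines, still tractable at
  hundreds of proteins but untested here beyond synthetic scale.
* `read_fold_model()` restores a model from JSON exactly, but archives
  are not portable across changes to the feature-id scheme.
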