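---
title: "Atom-pair property descriptors and the frequency-matched pseudo-distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-pair property descriptors and the frequency-matched pseudo-distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairprop)
```

# The model

`pairprop` describes a molecule as the multiset of its ordered heavy-atom
pairs. Each pair (i, j), i ≠ j, is a 19-feature row: the 8 atom-type
features of atom i, the same 8 for atom j, a common-ring flag, the
bond-count of the shortest i→j path, and a cis/trans flag. Identical rows
are grouped; the group size (frequency) is carried as a 20th column but is
never a feature. A molecule with n heavy atoms therefore always satisfies
Σ frequencies = n(n − 1); pyridine gives 30 ordered pairs in 9 grouped rows,
any 20-heavy-atom molecule gives 380.

The intent of the design is to keep every feature *numerically comparable*
(periods, bond counts, path lengths, a shifted pKa) rather than categorical,
so that similar-but-not-identical atom environments remain close in feature
space — the property-descriptor virtue — while the pairwise layout retains
positional information — the fingerprint virtue.

## Atom-type features

For each atom: periodic period; main-group family (1–8; transition elements
are out of scope and molecules containing them are skipped with a warning);
the number of single, double, triple and aromatic bonds to *heavy*
neighbours; a flag for membership in any ring; and pKa − 7 where a pKa is
available, 0 otherwise. Shifting by 7 centres the scale at neutral so
"no value" and "neutral" coincide, which is the conservative reading when a
value is missing.

pKa prediction engines are proprietary, so the pKa feature is pluggable: a
CSV table `mol_id,atom_index,pka` (0-based indices in input atom order) is
attached with `set_pka()`, and the all-absent fallback makes the feature
vanish entirely. Any published numbers that depended on a specific vendor
engine are therefore provider-dependent by construction.

## Relationship and isomerism features

Two atoms get a common-ring flag of 1 when they lie on a common cycle. The
reading of "common ring" was genuinely open; we use *shared cyclic
biconnected block*, which is equivalent to "some cycle passes through both
atoms", is cheap (biconnected components), and is verified in the tests
against a brute-force enumeration of all simple cycles on every fixture
graph. A spiro atom therefore shares a ring with members of both of its
rings, while two atoms in different rings of a spiro system do not.

The cis/trans flag is evaluated on the shortest path only when (1) the path
has ≥ 3 bonds, (2) its *first* three bonds are single, double, single, and
(3) none of the first four path atoms is aromatic. We read the four-atom
window as anchored at the path start (the natural reading of the
source's indices); windows further along the path are ignored. The
configuration is judged from 2D coordinates: the sign of the cross products
of path atoms 1 and 4 against the double-bond axis — same side → cis (−1),
opposite → trans (+1), |cross| < 1e−6 → degenerate (0). SDF coordinates are
used verbatim; SMILES input gets a deterministic 120° zigzag layout in which
directional bonds (`/`, `\`) are honoured by reflecting the far subtree of a
double bond when the encoded configuration requires cis. This is not a
structure-diagram generator: ring geometry is distorted (harmless — aromatic
atoms are excluded from the cis/trans test, and ring-internal configurations
are not stereo-labile in the inputs we target), but local double-bond
geometry is exact and reproducible.

## Grouping and canonical order

Grouping compares integer features exactly. The pKa column is continuous;
we round it to 0.01 *once, at row construction*, so grouping keys and stored
features are identical and the grouped descriptor expands exactly to the raw
pair enumeration. 0.01 pKa units is far below the accuracy of any provider.
Rows are sorted lexicographically over the 19-tuple, making serialized
descriptors bit-stable across runs and machines.

# The pseudo-distance

Let A have grouped rows a_i with frequencies n_{a_i} and total pair count
n_A. Row distances are weighted Euclidean: d(a, b) = ‖w ⊙ (a − b)‖₂, the
frequency never participating. The weights multiply the differences *inside*
the square — the source never states where weights enter; this choice keeps
the Euclidean form and makes the whole distance positively homogeneous in
the weights (d(c·w) = c·d(w)), a property the GA search and the tests rely
on.

`f(a_i, B)` is computed by greedy frequency matching: initialize n′ = n_{a_i};
repeatedly take the nearest remaining row b_m of B; if n′ ≤ n_{b_m}, add
n′·d and stop; otherwise add n_{b_m}·d, decrement n′, and remove b_m. If B
runs out first, scale the accumulated sum by n_{a_i}/n_B. Ties for "nearest"
are broken by the canonical row order, so results are independent of input
row order. B's frequency pool is reset for every a_i: letting one source row
consume from another's pool would make the result depend on the iteration
order over A's rows and destroy determinism.

Then

d_{AB→} = sqrt( Σ_i f(a_i, B)² / n_A ),  d_AB = sqrt(d_{AB→}² + d_{BA→}²).

Two deliberate as-printed choices:

* The symmetrization omits the ÷2 that the phrase "root mean square" would
  imply; the printed formula is primary and `pseudo_distance(..., rms = TRUE)`
  provides the RMS variant.
* The directed distance divides by n_A (total pairs) while summing over
  *grouped* rows whose f values already carry frequency factors. This makes
  grouping granularity of the *source* side semantically meaningful: a row
  of frequency n contributes (n·d̄)², not n·d̄². Expanding the *consumed*
  side B to frequency-1 rows, by contrast, provably changes nothing, and the
  test suite asserts exactly that invariant (to 1e−9; the tolerance absorbs
  the different floating-point summation order). Source-side expansion
  invariance does *not* hold — it is a different quantity by design — and
  the suite documents the distinction.

The result is a *pseudo*-distance: symmetric, non-negative, zero on
identity, but the triangle inequality is not guaranteed and is deliberately
not asserted anywhere.

# Kernel and SVM

Distances become kernels via f(d) = exp(−d²/γ). γ is taken from a 10-point
log-uniform grid adapted to the data: t = min(−3, min ln d),
s = (max(3, max ln d) − t)/9, γ_i = e^{s·i+t}, i = 0..9, so the default
span [e⁻³, e³] widens when the observed distances fall outside it. Zero
off-diagonal distances (duplicate molecules) are excluded from the grid
statistics with a classed warning; a fully degenerate (all-zero) matrix is
an error.

The classifier is a C-SVC on the precomputed kernel, solved by SMO with
maximal-violating-pair working-set selection (tolerance 1e−3, the standard
LIBSVM stopping rule) implemented in Rcpp; it was validated against
scikit-learn's `SVC(kernel="precomputed")` during development and a frozen
reference case lives in the tests. Because a pseudo-distance can produce
indefinite kernels, the quadratic step uses the usual τ guard and an
iteration cap; kernels are passed to the solver as-is, matching the original
procedure. (γ, C) are chosen by exhaustive search over the 10 × 11 grid
C ∈ {2⁻⁵, …, 2⁵} scored by k-fold CV accuracy — k = 10 by default; the
source never states k for the grid search, and 10 matches its tie-breaking
CV. Ties are broken toward smaller C (the more regularized model), then
smaller γ. Folds are assigned once per
search from a dedicated seed, so all 110 grid points see identical folds.

AUC uses the rank-sum (midrank) formulation: invariant under monotone score
transforms, 0.5 for constant scores, NA (with a warning) for single-class
test sets.

# GA weight optimization

The 19 column weights are tied to 11 free parameters: one set of 8
atom-type weights applied to both atoms, plus ring-pair, path-bonds and
cis/trans weights. Defaults are the published initial values (period 0.927,
family 0.400, single 0.370, double 0.013, triple 0.504, aromatic 0.931,
ring atom 0.340, pKa 0.688, ring pair 0.264, path bonds 0.013, cis/trans
0.925).

Fitness of a weight vector is mean out-of-bag accuracy over bootstrap bags:
each bag trains a full grid-searched SVM on the in-bag distances and scores
the out-of-bag molecules. The distance matrix is computed once per genome
and sub-indexed per bag — the expensive part is the matching, not the SVM.
Single-class bags are redrawn (≤ 10 times) then skipped with a log message.

The published configuration fixes population 32, mutation 0.15, crossover
0.8, 20 generations, 1000 bags, and a per-step weight change bounded by
±0.1. Selection scheme, crossover type and elitism were unstated; we use
the simplest canonical GA consistent with those probabilities:
fitness-proportional (roulette) selection, single-point crossover on the
11-gene vector, per-gene uniform mutation within ±0.1 (we read the ±0.1
bound as a *mutation-step* bound, not a cumulative drift bound), clipping
at 0, and one elite carried unchanged — which makes best-so-far fitness
provably non-decreasing, a property the tests assert. Everything is driven
by one R RNG seed, so whole trajectories are bit-reproducible.

GA runs routinely end with several weight sets at identical fitness; the
winner is chosen by full k-fold CV grid-search accuracy on the original
training set, residual ties by lexicographic order of the weight vector.
Per-bag "prediction accuracy" is plain accuracy, not AUC, following the
stated evaluation function.

Desk-scale settings for tests are population 8, generations 5, bags 20; the
full configuration (reported at 1.5–3.3 days per data set in the original
work) is reachable through `ga_config()` but is not exercised in CI.

# Synthetic data

External benchmark sets (MUTAG, PTC, BBB, …) were obtained privately by the
original study and are neither bundled nor downloaded; users can supply any
set as SDF + two-column label TSV. For testing, `synthetic_labeled_set()`
generates small valid structures whose class is determined *exactly* (no
label noise) by one structural rule: ring presence (cycloalkanes/heterocycles
vs decorated chains), halogen position (ortho vs meta F/Cl benzenes with
varying tails), or N–N path length in chains. These sets emulate the
*format* and the separability structure of a QSAR task, not its chemistry:
molecules are small (≤ ~10 heavy atoms), classes are perfectly separable by
construction, and there is no activity cliff, no class imbalance beyond ±1,
and no measurement noise. A green end-to-end test therefore establishes that
the pipeline is wired correctly and that the descriptor exposes the planted
signal — it says nothing about accuracy on real assay data, which the
original evaluation showed to be competitive but not superior at the
affordable number of GA generations.

The 90/10 × 20 split protocol is plain random (the source says "randomly
split" with no stratification), so small test splits are occasionally
single-class; those repeats report a missing AUC and are flagged, mirroring
the original report of scores "not calculated normally" on some sets.

# Numerical and degenerate-input choices

* Shortest paths: BFS; among equal-length paths the lexicographically
  smallest atom-index sequence is returned (deterministic tie-break).
* Multi-fragment molecules are rejected — the distance between fragments is
  undefined under a bond-path feature.
* Single-atom molecules yield an empty descriptor; distances involving an
  empty descriptor are errors rather than 0 (no pairs to match).
* Kernel underflow: exp(−d²/γ) may round to exactly 0 for d² ≫ γ; entries
  are mathematically in (0, 1] and the tests accept the underflowed 0.
* Grouping rounds pKa to 2 decimals; all other features are integers.
* Hydrogens are suppressed at parse time everywhere; all bond counts refer
  to heavy neighbours only (H handling was unstated; heavy-only is the
  self-consistent choice for a hydrogen-suppressed graph).

# Known limitations

* No chirality feature (explicitly out of scope in the source's
  conclusions); no R/S perception, no 3D.
* Aromaticity is taken from the input (lowercase SMILES, SDF bond order 4),
  not perceived by a Hückel rule; Kekulé-form inputs stay Kekulé.
* The SMILES grammar covers main-group organics (organic subset + brackets,
  ring closures incl. `%nn`, directional bonds); exotic notation (reaction
  SMILES, wildcard atoms, explicit aromatic bond perception) is rejected
  loudly rather than guessed.
* The 2D layout is a zigzag embedding, adequate for double-bond geometry but
  not for depiction; cis/trans inside non-aromatic rings follows the layout
  and is deterministic but not chemically meaningful.
* `train_select` accepts indefinite kernels as-is; an eigenvalue-clipping
  option was considered and rejected for the default path to stay faithful
  to the original procedure.
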