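---
title: "Finding mutually exclusive cancer driver gene sets by quadratic penalty minimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding mutually exclusive cancer driver gene sets by quadratic penalty minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutexquad)
```

## The problem

Tumors are driven by a small number of somatic *driver* mutations against a
large background of functionally inert *passengers*. Drivers scatter across
patients: different patients disrupt the same cellular pathway through
different member genes, so within a functionally related gene set one
expects each patient to carry **one** mutation — full *coverage* with
*mutual exclusivity*. Deviations occur in both directions: missed calls and
unmutated pathways reduce coverage, while mutator phenotypes and
slow-growing tumors add excess hits.

`mutexquad` searches a binary patient-by-gene matrix \(G\)
(\(G_{ij}=1\) if patient \(i\) has a non-silent mutation in gene \(j\)) for
an indicator vector \(x\) over genes minimizing a penalty that scores how
far the selected set is from the ideal one-hit-per-patient pattern.

## The model

Writing \(m_i = G_i x\) for the number of selected-gene mutations in
patient \(i\), each patient contributes

\[
L(m_i) = \frac{1+k}{2}\,(m_i - 1)\Bigl(m_i - \frac{2}{1+k}\Bigr),
\]

a quadratic in \(m_i\) with \(L(1) = 0\), \(L(0) = 1\) and \(L(2) = k\).
The single parameter \(k \ge 0\) is the *ratio of the two-hit penalty to
the no-hit penalty*: it arbitrates the coverage / exclusivity trade-off.
Low \(k\) tolerates multiple hits (appropriate for hypermutated or
slow-evolving tumors); high \(k\) demands strict exclusivity. At \(k=1\)
the penalty is exactly \((m_i-1)^2\), and the quadratic growth — unlike a
linear overlap penalty — charges progressively more for each additional
excess mutation, matching the decreasing odds of re-hitting an already
disrupted pathway.

The total objective adds an \(L_0\) size penalty with price \(C\) per gene:

\[
L(G, x) = \sum_{i=1}^n L(G_i x) + C\,\lVert x \rVert_0 .
\]

Expanding the square shows this is an unconstrained binary quadratic
program (BQP),

\[
L(G,x) = x^T Q x - f^T x + n, \qquad
Q = \tfrac{k+1}{2}\, G^T G, \qquad
f = \tfrac{k+3}{2}\, G^T \mathbf 1_n - C\,\mathbf 1_p ,
\]

which `bqp_coefficients()` materializes. The constant \(n\) is carried
explicitly so solver objectives equal the penalty itself, never a shifted
value. \(Q\) is a scaled Gram matrix, hence positive semidefinite with
nonnegative entries.

## The optimizer

BQP minimization is NP-hard, but instances restricted to a few dozen genes
solve exactly in well under a second. `mutex_search()` exploits this with
a Markov-chain search over *which* genes to consider, delegating *which of
those to keep* to an exact solver:

1. **Propose** (`propose_gene_set()`): grow or perturb the current
   solution to exactly \(\nu\) genes. A full solution swaps one uniformly
   chosen member for one gene drawn from the proposal distribution
   \(\Gamma\) restricted to non-members; a smaller solution is expanded by
   weighted sampling without replacement. The default \(\Gamma\) is
   proportional to \(\log(1 + c_j)\) with \(c_j\) the per-gene mutation
   count: monotone in frequency, yet keeping genes mutated in a single
   patient proposable — rare drivers are precisely the interesting catch.
   (Weights proportional to the raw log frequency would assign such genes
   weight \(\log 1 = 0\) and silence them.)
2. **Improve** (`local_improve()`): solve the BQP restricted to the
   \(\nu\) candidate genes to *global* optimality, pruning the candidate
   to its best subset. The solver (`solve_bqp_exact()`) is a compiled
   depth-first branch-and-bound: variables are ordered by decreasing
   \(|f_j|\); at each node the remaining quadratic is bounded below by
   clamping each term at its coordinate-wise minimum (for Gram-structured
   \(Q\) the pairwise terms are nonnegative and the bound tightens to the
   linear part alone). An independent vectorized enumeration oracle
   (`solve_bqp_enumerate()`, up to 20 variables) verifies the solver in
   the test suite; the two must agree exactly, including tie-breaking.
3. **Accept**: the Metropolis rule — always accept an improvement, accept
   a worsening of \(\Delta\) with probability \(e^{-\Delta/\tau}\). A
   constant temperature \(\tau\) (default 1, no annealing schedule) is the
   simplest rule consistent with acceptance "depending on the difference
   in quality"; \(\tau \to 0\) recovers strict hill climbing and the
   parameter is exposed for tuning.

The chain starts from the empty set (so the first proposal is a weighted
\(\nu\)-gene draw), runs `iterations` steps (default 10,000), and reports
the best locally-improved candidate ever evaluated, accepted or not.
Degenerate cases are kept total: if local improvement prunes a candidate
to the empty set, the empty set is a legal state and the next proposal
re-expands it.

### Determinism and tie-breaking

Equal-objective optima are resolved deterministically everywhere:
the solvers prefer fewer selected genes, then the lexicographically
smallest indicator (reading 0 before 1 from the first variable);
best-solution tracking inside the search prefers fewer genes, then the
smaller leading gene index. Objective comparisons use an absolute
tolerance of \(10^{-9}\) — objectives are short sums of products of small
integers with \(k\) and \(C\), so this is far below any genuine gap.
Identically seeded runs are bit-identical; the seed is stored in the
result, and seeded calls restore the caller's RNG state on exit.

### Multiple gene sets

One run returns one near-exclusive set — a single-pathway query.
`mutex_iterate()` reruns the search, deleting each round's genes from the
working matrix, and pools the disjoint per-round sets; it shrinks \(\nu\)
when fewer proposable genes remain and stops early (with a warning) when
the matrix is exhausted.

## Significance

`permutation_test()` permutes the entries of each gene column
independently — preserving every gene's mutation count while destroying
within-patient structure — reruns the full search on each of `n_perm`
permuted matrices with the same settings and fresh sub-seeds, and reports
the add-one estimator

\[
p = \frac{1 + \#\{\text{null} \le \text{observed}\}}{1 + N_{\text{perm}}},
\]

counting ties as successes ("\(\le\)" because lower penalty is better), so
\(p \in [1/(N_{\text{perm}}+1),\, 1]\) and never 0.

A subtlety worth knowing: when the penalty spectrum is coarse — e.g.
\(k = C = 1\) on a small cohort makes every objective an integer in a
narrow range — ties between observed and null objectives are massive, and
the tie-counting estimator is then *valid but conservative*: null
p-values lump on few atoms and shift right rather than being uniform.
The calibration study in the test suite therefore uses conditions with a
fine-grained spectrum (60 patients, heterogeneous gene margins,
\(k=0.85\), \(C=1.15\)), where the null p-value distribution is
indistinguishable from uniform (Kolmogorov–Smirnov over 200 replicate
cohorts at reduced search effort \(T=200\), \(N_{\text{perm}}=99\)).
Conservatism under coarse spectra never inflates significance claims.

## Synthetic cohorts

`simulate_mutations()` generates the ground-truth fixtures used
throughout: for each patient and each planted set, a uniformly chosen
member gene is mutated with probability `coverage_prob`, a second distinct
member with probability `excess_prob` (at most one extra hit per set per
patient — higher-order excess is left to the background), and every cell
outside the planted columns is mutated with `passenger_rate`. The default
fixture — 60 patients, 40 genes, one planted 5-gene set, coverage 0.95,
excess 0.05, passengers 0.02 — mimics a small exome cohort with a single
strongly exclusive pathway: near-complete coverage, occasional double
hits, and a sparse passenger background, while staying small enough that
exhaustive subset enumeration can certify optima.

What the generator does *not* emulate: gene-length and replication-timing
effects on passenger rates, patient-specific mutation burdens,
copy-number events, and correlated passengers. Recovery of planted sets
here therefore demonstrates correctness of the optimization and
calibration machinery, not robustness to every artifact of real cohorts —
on real data the gene filter (`apply_gene_filter()`) and the `k` knob
exist precisely because backgrounds are not homogeneous.

## Parameters at a glance

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | two-hit / no-hit penalty ratio | 1 | dimensionless; lower it for mutator phenotypes |
| `C` | penalty per selected gene | 1 | in penalty units; roughly "patients a gene must newly cover to pay for itself" |
| `nu` | subproblem size | 30 | exact solver cap is 50 |
| `iterations` | search steps `T` | 10,000 | each step solves one exact subproblem |
| `tau` | acceptance temperature | 1 | penalty units |
| `n_perm` | permuted datasets | 1000 | p-value floor is `1/(n_perm+1)` |

## Verification scales

The test suite certifies the implementation against independent oracles
at sizes where those oracles are exact: closed-form penalty identities on
the full `k` grid; the quadratic-form identity on 1,000 random matrices
plus exhaustive all-subset checks; branch-and-bound vs enumeration on 500
random instances up to 15 variables; search vs exhaustively enumerated
global optima on 30-patient, 12-gene cohorts; exact recovery of the
default fixture's planted set across 20 seeded runs; monotone response of
solution size to `C` and of coverage/excess to `k`; and the permutation
calibration described above. These sizes were chosen so that every claim
has a brute-force certificate; the algorithm itself has no
size-dependent switches, so behavior at cohort scale differs only in
runtime (the default `T = 10,000` handles hundreds of patients and
thousands of genes in minutes).

## Known limitations

- The search is stochastic; on large cohorts different seeds can return
  different near-optimal sets. Use several seeds and/or
  `mutex_iterate()`.
- Matrices are strictly binary: mutation multiplicity, variant type and
  functional impact scores are out of scope.
- The permutation null preserves gene margins but not patient mutation
  burdens; heavily hypermutated patients can make it anti-conservative,
  which is one reason the hypermutated-gene filter exists.
- `nu` caps the size of any single discovered set at 50 (the exact-solver
  capacity).
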