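---
title: "Nonlinear chordal distances for Pythagorean fuzzy sets: models, conventions, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear chordal distances for Pythagorean fuzzy sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfdist)
```

## The model

A Pythagorean fuzzy set (PFS) over a finite universe $U = \{x_1, \dots,
x_n\}$ assigns each element a membership grade $\mu_i$ and a
non-membership grade $\nu_i$, both in $[0,1]$, with $\mu_i^2 + \nu_i^2
\le 1$. The residual $\pi_i = \sqrt{1 - \mu_i^2 - \nu_i^2}$ is the
hesitancy. The intuitionistic family (IFS) is the sub-family with
$\mu_i + \nu_i \le 1$ and hesitancy $1 - \mu_i - \nu_i$; every IFS is a
PFS. `pfset()` validates either constraint with a tolerance of $10^{-9}$,
enough to absorb decimal round-trip noise but nothing more.

The package's central objects are two nonlinear distances between PFSs on
a shared universe, built from scalar kernels applied separately to the
membership and non-membership channels.

**Generalized chordal distance.** The scalar kernel is the chordal
(stereographic-sphere) metric restricted to $[0,1]$,
$d(x,y) = |x-y| / (\sqrt{1+x^2}\sqrt{1+y^2})$, bounded by $1/\sqrt 2$.
The set distance is
$$D_p(P,Q) = \Big(\tfrac{1}{2^{1-p/2}\,n}\sum_i
  \big[d(\mu_{P,i},\mu_{Q,i})^p + d(\nu_{P,i},\nu_{Q,i})^p\big]\Big)^{1/p},
\qquad p > 0.$$
The prefactor's power applies to 2 only. Two facts pin this parse down:
the crisp opposite singletons $(1,0)$ and $(0,1)$ attain exactly 1 at
$p=1$, and the bound $D_p \le 1$ is tight for every $p$ because each
kernel is at most $1/\sqrt 2$. The distance is bounded, separable and
symmetric, attains 1 against the complement exactly on crisp sets, is
monotone under set containment, and commutes with complementation.

**Non-Archimedean chordal distance.** The kernel is the valuation-style
$d_\lambda(x,y) = |x-y| / (\max(\lambda,x)\max(\lambda,y))$ with floor
$\lambda \in [0,1]$; the set distance is
$$D^\lambda_p(P,Q) = \Big(\sum_i \big[(d_\lambda(\mu)/20n)^p +
  (d_\lambda(\nu)/20n)^p\big]\Big)^{1/p}.$$
At $n=1$, $p=1$, $\lambda=0.1$ the crisp opposite pair again gives
exactly 1. No unit bound holds for small $\lambda$ (the kernel can reach
$1/\lambda^2$), so the value is deliberately not clamped.

## Tunable parameters

* `p` (both families, default 1, any positive real): Minkowski-like
  exponent. Small `p` aggregates evenly; large `p` approaches a
  worst-element criterion, so rankings can legitimately reverse along
  `p` (see `pf_sweep()`; the suite constructs such a reversal).
* `lam` ($\lambda$, non-Archimedean only, default 0.5): pessimism floor.
  Distances decrease monotonically in $\lambda$; small values magnify
  disagreement on weakly graded elements. At $\lambda = 0$ the kernel is
  undefined whenever exactly one argument is zero; the package raises a
  classed degeneracy error and `pf_sweep()` marks such cells degenerate
  instead of inventing numbers.
* `tol` (discrimination diagnostic, default `5e-5`): two distances are
  "identical" when they agree to better than half of the last printed
  decimal of four-decimal reporting.

## Replication conventions for the sixteen competitor measures

The sixteen established measures are printed in squared-grade
(Pythagorean) form, but the published comparison tables they travel with
were computed under mixed dialects. We audited every table cell by
brute-force dialect search (first-power vs squared grades crossed with
intuitionistic/Pythagorean/no hesitancy, plus alternative normalizers)
and froze the result in `pf_conventions()`:

* pattern-recognition and diagnosis tables: first-power grades with the
  intuitionistic hesitancy $1-\mu-\nu$ for the Hamming/Euclidean/max-type
  measures;
* medicine-selection table: first-power grades with the Pythagorean
  hesitancy;
* `ren` and `mahanta_panda`: squared grades everywhere;
* `peng`: a $1/(2n)$-normalized absolute-difference sum over squared
  grades (the printed $1/(4n)$ squared-term formula is available as
  `as_printed`);
* `ba_sq1` and `song` operate on first powers by construction;
  `ejegwa_awolola` likewise, with Pythagorean hesitancy.

Three rows resist replication and are documented rather than "fixed":
`sarkar_biswas` (no dialect reproduces any of its table rows),
`ejegwa_awolola` outside the pattern table (its diagnosis row matches a
reversed-argument evaluation in two cells and nothing in the rest — the
measure is asymmetric and sign-indefinite, and the published medicine row
implies a winner its raw minimiser does not produce), and the
medicine-table `song` row (printed values equal the magnitudes of the
computed — negative — values with two cells transposed).

Two structural caveats about `song`, visible only outside the IFS
sub-family: its five-term certainty decomposition sums to the constant 3
only when $\mu + \nu + \pi = 1$, so under the Pythagorean hesitancy its
self-distance is not zero and values can be negative; and intuitionistic
hesitancies of non-IFS pairs are negative, making $\sqrt{\pi_P\pi_Q}$
undefined — the package clamps only floating-point-negative products
(within $10^{-9}$) and lets genuine negatives propagate as `NaN`.

## Decision pipelines

`pf_classify()` is nearest-prototype assignment: least distance wins,
exact ties (within $10^{-12}$) break toward the earlier prototype and
set an `is_tie` flag, since the source material never defines a
tie-break. `pf_ideal()` builds the ideal alternative of a decision
matrix from polarity-oriented column extrema — benefit criteria take
$(\max_i \mu_{ij}, \min_i \nu_{ij})$, cost criteria the dual — and
`pf_rank()` orders alternatives by distance to it. `pf_sweep()` re-runs
either pipeline over parameter grids (defaults $p \in \{1,2,5,10,50\}$,
$\lambda \in \{0, 0.4, 0.6, 0.8, 1\}$, the published grid) and flags
rank stability across non-degenerate cells. `pf_discriminate()` computes
each measure's distance on a list of single-element profile pairs and
groups profiles with equal values — the standard drawback diagnostic for
distance measures.

On the packaged case studies the chordal family elects the same winners
as all sixteen competitors under their table conventions (P2; malaria;
Tocilizumab), and the pattern-problem ranking $P_2 < P_1 < P_3$ is
stable across the whole grid. The medicine problem, by contrast, is
*not* rank-stable beyond the winner under the as-written formulas:
positions 2–6 shuffle with $p$ and $\lambda$. The tests assert only what
the formulas actually deliver.

## Known limitations and documented discrepancies

* **Exponent ordering.** With the unit-attaining prefactor, the chordal
  distance satisfies $D_2 \ge D_1$ (Cauchy–Schwarz; equality iff the two
  channel kernels coincide), not $D_2 \le D_1$: a published claim of the
  reverse inequality implicitly drops the $p$-dependent prefactor. The
  non-Archimedean family, which has no such prefactor, does satisfy
  $D^1_2 \le D^1_1$. The acceptance suite states the published claim
  verbatim, so its chordal half fails there by design; the main suite
  asserts the direction the formula implies.
* **Published values for the proposed measures.** The case-study rows
  printed for the two chordal distances are not derivable from their
  defining formulas under any dialect we tried; only the induced winners
  replicate. All competitor-measure replication claims in this package
  are therefore cell-verified, while proposed-measure claims are
  order-verified.
* **Mirror blindness.** Being a sum of two symmetric channel terms, the
  generalized chordal distance assigns equal values to a profile pair
  and its mirrored pair (e.g. $(0.4,0.4)\!-\!(0.5,0.5)$ vs
  $(0.4,0.5)\!-\!(0.5,0.4)$); `pf_discriminate()` reports this honestly.
* **Print truncation.** A few published cells are truncated rather than
  rounded; replication tests accept a value when it matches to
  $5\times10^{-5}$ or after truncation to four decimals.

## Synthetic data and what the tests show

`pf_random()` samples $(\mu,\nu)$ uniformly on the quarter disk by
rejection from the unit square (acceptance $\pi/4$; simplicity over
cleverness at these sizes), uniformly on the IFS triangle, or as nested
triples $P \subseteq Q \subseteq R$ built per element by sorting three
membership draws ascending against the non-membership draws descending —
each resulting pair is dominated by one of the original valid draws, so
validity holds by construction. Identical seeds give identical sets and
the caller's RNG state is preserved. Property suites run on 500 seeded
pairs (metric axioms, complement identities), 200 nested triples
(containment), 1000 ordered triples (the chordal triangle lemma) and 200
pairs of oracle-equivalence checks at $10^{-12}$ — sizes chosen so the
whole suite runs in well under a minute while leaving the sampling error
of a violated invariant negligible. Uniform quarter-disk sampling has no
claim to represent real elicitation data: passing tests certify the
algebraic properties of the measures, not field performance of the
decision pipelines.

## Numerical choices

Grades are stored as decimal strings in JSON fixtures so files round-trip
exactly. Sums run in universe order with plain summation ($n$ is at most
dozens; compensated summation would be noise here). The ratio-type
measure (`mahanta_panda`) defines $0/0$ element terms as 0, the
continuous extension that keeps self-distance at zero. Discrimination
grouping is single-linkage on sorted values, which at the default
tolerance is exact-agreement grouping for four-decimal data.
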