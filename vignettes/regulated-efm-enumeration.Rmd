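---
title: "Regulated elementary flux mode enumeration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulated elementary flux mode enumeration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regefm)
```

## The model

A metabolic network is described by its internal stoichiometric matrix
$S$ (rows: internal metabolites, columns: reactions) and a reversibility
flag per reaction. External metabolites act as open sources and sinks and
are omitted, so steady state is simply $S v = 0$. The elementary flux
modes (EFMs) are the support-minimal solutions of

$$S v = 0, \qquad v_i \ge 0 \text{ for irreversible } i,$$

equivalently the extreme rays of the flux cone. `regefm` computes them
with the binary nullspace variant of the double description method and
applies Boolean transcriptional-regulatory constraints during the
computation.

### Binary double description iteration

Each reversible reaction is split into a forward/backward pair (backward
column $=$ negated forward column, placed directly after it), which makes
the cone pointed. The crucial consequence: combining two modes never
clears a set flux bit, so intermediate modes can be stored as a *binary
support prefix* over processed reactions plus an exact numeric tail over
unprocessed ones.

The initial mode matrix is a kernel basis $K$ with
$S_{\mathrm{ext}} K = 0$. Rows without negative entries binarize before
the iteration starts (a zero entry stays zero, a positive entry is flux);
the remaining rows are processed one per iteration:

* modes with nonnegative pivot entries survive (bit 1 for positive, 0 for
  zero);
* every negative $\times$ positive pair whose combined support is not a
  superset of a third mode's support (the adjacency test) spawns a child
  with support $=$ bitwise OR and tail entries
  $v^{\mathrm{new}}_r = (v_1^+ v_r^- - v_1^- v_r^+) / (v_1^+ - v_1^-)$,
  which is exactly zero at the pivot;
* negative modes are discarded.

After the last row the matrix is fully binary. Futile 2-cycles (the
forward+backward pair of one split reaction) are removed, split pairs are
merged by OR, and numeric fluxes are recovered: the kernel rows of the
reactions *inactive* in a mode span a homogeneous system whose solution
space is one-dimensional exactly when the support is elementary; $K$
times that solution is the flux ray.

### Three-valued regulatory rules

Rules are Boolean equations `OUTPUT = EXPR` over reaction ids with
`NOT`/`AND`/`OR`. Every atom carries an activity tag: `0X` (defined only
when `X` carries no flux), `1X` (only when it does), `fX` (always; the
default). Connectives follow strong Kleene three-valued semantics; a rule
whose output atom or expression is undefined is not consulted. A mode
*violates* a rule when both sides are defined and disagree.

A rule qualifies for the **iteration phase** when its output must be
inactive while all inputs are active (expression at all-ones evaluates to
a defined false, and the output atom is defined at 1). Such a violation is
permanent under OR-combination, so matching modes are deleted at every
iteration — this is the package's central performance device and is
provably lossless. Compiled patterns set one bit per involved reaction;
reversible reactions contribute one pattern per direction (the cartesian
product), because either direction makes the merged reaction active.
All rules, iteration-phase or not, are re-checked on the final merged
modes; multiple rules combine conjunctively.

## Parameters that matter

* `rule_sort` (default `FALSE`): moves kernel rows of rule-involved
  reactions directly behind the nonnegative block, so patterns become
  applicable in the earliest possible iterations. It never changes the
  result (order invariance is a tested property), only the intermediate
  mode counts; it pays off when rules kill many modes.
* `normalize` (default `TRUE`): recovered fluxes are scaled by the
  maximum absolute entry, the conventional display scale for worked
  examples. The underlying object is a ray; the scale carries no
  information.
* `max_reactions` of the brute-force enumerator (default 16): exhaustive
  support enumeration is $2^n$; the cap keeps the oracle honest about its
  scope.
* Generator defaults (`reversible_fraction = 0.2`,
  `coef_pool = c(1, 2)`): small integer stoichiometries with a minority
  of reversible reactions, typical of toy pathway models, and small
  enough that exact arithmetic never strains.

## Numerical choices

All matrix arithmetic is exact rational (reduced integer pairs held in
doubles, overflow-guarded far below $2^{53}$). This removes the usual
epsilon-tuning in rank and sign decisions: a tail entry is negative,
zero, or positive, with no tolerance. Kernel computation and all
nullspace solves use Gauss–Jordan elimination with a fixed first-nonzero
pivot rule, so every run is deterministic. Ties in the
adjacency-candidate sort are broken by the incoming row position (stable
sort); children are appended in (negative-parent, positive-parent)
lexicographic order. These conventions fix the full intermediate trace,
not just the final set.

Numeric recovery must re-split a merged support; the stored bits do not
say which direction a reversible reaction ran. The directions are
searched (forward first) for the assignment that yields a one-dimensional,
sign-consistent solution — at most $2^k$ trials for $k$ active
reversibles, and $k$ is tiny in practice. A second recovery route through
the restricted columns of $S_{\mathrm{ext}}$ is implemented and asserted
equal in the tests.

## Design decisions taken where the design was open

* **Pruning position within a step.** Patterns are applied after child
  creation in every iteration (and once to the initial matrix). Pruning
  before pairing would also be correct — by the monotone-OR argument the
  final sets coincide — and the tests assert exactly that equivalence
  against post-hoc filtering.
* **Bit convention.** 1 means flux-carrying. Some established tools use
  the inverse convention internally; this package standardizes on the
  presentation convention everywhere.
* **Adjacency search.** A naive pairwise superset scan. Bit-pattern tree
  indexes accelerate large networks but do not change semantics; the
  contract of `adjacency_test()` would absorb such an index unchanged.
* **"Nonnegative" vs "positive" leading rows.** Rows with zeros but no
  negatives are binarizable (a zero entry simply stays zero), so the
  leading block is defined by *no negative entry*; the stricter all-positive
  reading would forfeit binarizable rows.
* **Post-processing rules on merged reactions.** Rule evaluation after
  the merge treats a reversible reaction as active when either direction
  is (matching the split semantics used for patterns).
* **Output order.** EFM columns are sorted lexicographically by support
  bits; any fixed order would do, this one needs no extra state.

## The worked example and the synthetic generator

The bundled 11-reaction example is anchored by its fixed 12×6 reference
kernel (`toy_kernel()`); since a nullspace basis is not unique, starting
from this kernel is what makes the intermediate matrices reproducible
entry by entry. The stoichiometric matrix behind it is reconstructed as
an exact left-annihilator of that kernel, padded to 12 metabolite rows
(`toy_network()`); it is *synthetic* in the sense that only its nullspace
— which determines every EFM quantity — is meaningful, not the individual
metabolite rows. The reordering fixture (`reorder_example()`) is likewise
synthetic down to its sign patterns, which are all the ordering logic
consults.

`generate_network()` emulates small connected pathway networks: an
uptake, a conversion backbone, a secretion, and random two-metabolite
conversions. What it does **not** emulate: compartments, cofactor
coupling, enzyme subsets, dead ends, or genome-scale sparsity patterns.
Passing tests on generated networks therefore demonstrate algorithmic
correctness (agreement with exhaustive enumeration, invariants), not
performance or biological realism at scale.

Problem sizes used by the test-suite and the acceptance script — networks
of 4 metabolites × 7 reactions (9–10 extended columns, 20 seeded
instances, 10 seeded rule sets) — were chosen so the exhaustive oracle
(which scales as $2^n$ rank tests) stays comfortable while still
exercising reversible splits, futile cycles, both rule classes, and
pattern pruning.

## Known limitations

* No network compression (dead-end removal, enzyme-subset merging); rule
  remapping onto compressed reactions is documented as requiring a
  bijective activity correspondence but no compressor is shipped.
* Single-threaded; no bit-pattern-tree adjacency index — desk-scale
  networks only.
* Only the all-inputs-active implication of a rule is compiled to
  iteration patterns; implications forced by partial input assignments
  are left to post-processing.
* The SBML reader covers the core subset (species, boundary condition,
  reversibility, stoichiometry); kinetic laws, function definitions and
  flux bounds are ignored. The tsv format is the canonical interchange.
* Continuous or time-dependent regulatory models are out of scope: the
  iteration sees only bits.
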