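---
title: "Prediction-driven MMP analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction-driven MMP analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the synthetic data emulate,
the numerical choices, and the limits of what the tests demonstrate.

## The method

### Matched pairs by fragment-and-index

Two molecules form a matched molecular pair (MMP) when they are identical
except for one localized fragment replacement. Operationally, every molecule
is fragmented at its *breakable bonds* — acyclic single bonds between two
heavy atoms; rings are never opened — with one, two, or three simultaneous
cuts. Each cut-set splits the molecule into a *variable* part (the fragment
that may be replaced) and a *scaffold* (the unaffected context). A split is
kept when the variable part is a single connected component touching every
cut bond, has at most `max_variable_atoms` (default 10) heavy atoms, and is
strictly smaller than the scaffold. For multi-cut splits the variable part
is the central linker and the scaffold is the two or three peripheral
pieces, written dot-separated; removing k acyclic bonds from a connected
molecule always yields k+1 components, so this is the only shape a two-sided
split can take. Additionally, one single-cut record per symmetry-distinct
hydrogen position is emitted with the explicit-hydrogen fragment `[*:1][H]`
as the variable part, so hydrogen-to-group replacements are first-class
transformations. Molecules with more than `max_breakable_bonds` (default 40)
breakable bonds are skipped outright — the cut-set count grows
combinatorially and such molecules contribute disproportionately little
pair information per unit cost.

Records are keyed by canonical scaffold notation; molecules sharing a
scaffold with different variable fragments form a pair, subject to a
whole-molecule similarity filter (ECFP fingerprints, Tanimoto at least
`min_similarity`, default 0.5) that suppresses pairs whose shared scaffold
is a coincidence of two otherwise dissimilar structures. Pairs are grouped
into *transformations* — canonical directed fragment replacements
`left >> right` with `left <= right` lexicographically; a pair realizing
the replacement right-to-left carries sign −1. When one molecule pair
matches on several nested scaffolds it is emitted once per scaffold but
tagged with a shared pair-group id, and the statistics count each molecule
pair once per transformation.

### Significance

For a continuous endpoint the test statistic is the exact binomial sign
test `P[Bin(N, 0.5) <= min(n_pos, n_neg)]` over the `N` non-tied pairs of a
transformation; for binary endpoints it is the minimum of the two binomial
lower tails at the observed after-counts, with success rates set by the
before-counts. Both are computed by exact summation of binomial terms — no
normal approximation — and reported also as `-log10(p)`. All tested
transformations of an endpoint are corrected with Holm–Bonferroni at
`alpha` (default 0.05). Transformations with fewer than `min_pairs`
(default 5) pairs are reported untested: 5 is the smallest N at which the
sign test can reach 0.05 (`0.5^5 ≈ 0.031`).

### Predictions, the bootstrap, and amplification

Endpoint values may be experimental or predicted. Experimental values
always win where both exist; predictions only fill gaps, and a pair counts
as experimental evidence only when both sides are experimental. Predicted
values carry an uncertainty (for continuous endpoints, the estimated
standard error, e.g. the spread of an ensemble model; for binary ones, an
estimated misclassification probability) and an in/out applicability-domain
flag; out-of-domain predictions are excluded by default.

Wherever predictions contribute to a significant transformation, the pair
set is re-sampled `n_replicas` (default 1,000) times, perturbing each
predicted value with independent Gaussian noise at its uncertainty (binary
labels flip with their misclassification probability) and recomputing the
p-value. The replicas are summarised by their **median** p-value, compared
against `alpha`. The median was chosen over alternatives (mean, quantile
envelopes) because it is monotone in the noise level, insensitive to the
handful of extreme replicas a heavy-tailed perturbation can produce, and
reduces exactly to the unperturbed p-value when all uncertainties are zero.
Perturbations are drawn per pair side; the correlation induced by one
molecule appearing in several pairs of the same transformation is ignored,
which makes the replicas slightly conservative for star-shaped pair sets.

Every transformation is assigned a provenance class: `experimental` if
significant on its experimental pairs alone, `amplified` if not (or
untestable alone) but significant on the combined evidence with at least
one experimental pair, `predicted` if significant with no experimental
pairs at all, `none` otherwise. "Too few experimental pairs to test" counts
as not-significant-alone, so a transformation with 4 measured and 100
concordant predicted pairs is classified amplified.

### Optimization

Given an endpoint goal (decrease/increase a continuous value,
deactivate/activate a binary one), the optimizer selects the significant
transformations whose effect serves the goal at a practical magnitude —
`|mean_delta|` of at least `practical_threshold` (default 1.0 log unit) for
continuous endpoints, a deactivation (or activation) ratio of at least 0.55
for binary ones — and applies each in the serving direction at every
severable embedding of its source fragment: the fragment's atoms must
connect to the rest of the molecule only through acyclic single bonds at
its attachment atoms, exactly one per attachment point, mirroring how the
fragmenter cuts. Products are standardized, deduplicated per transformation
on their InChIKey, counted as *generated*, filtered to *kept* by Tanimoto
similarity to the start molecule, and scored by the predictor: a *hit* is a
kept product whose prediction moves in the desired direction (any
improvement for continuous endpoints — the practical threshold governs
transformation selection, not per-product hits); *effectiveness* is
hits/kept. Products with impossible valences or disconnected skeletons are
discarded silently, and predictor failures leave a product generated but
not kept.

## Chemistry substrate and numerical choices

Structure perception is delegated to OpenBabel (via ChemmineOB): canonical
SMILES, InChIKeys for uniqueness (duplicate structures under different ids
are indexed once and aliased), ECFP fingerprints (radius 2, folded to 2,048
bits by default). Choices the package makes on top:

- **Attachment labels.** Fragment notation is canonical SMILES with
  labelled wildcards `[*:1]..[*:3]`; internally the label rides in the
  wildcard's isotope field, the one annotation that survives SMILES and
  molblock round-trips. Labels are assigned from the scaffold side: each
  scaffold attachment point is characterised by the canonical SMILES of the
  scaffold with a probe isotope on that point, and label 1 goes to the
  lexicographically smallest environment. Two attachment points get equal
  environment strings exactly when a graph automorphism exchanges them; the
  tie is broken by choosing the assignment that minimises the variable
  fragment's notation. This makes scaffold keys and pair orientation
  deterministic for any input atom order.
- **Transformation identity.** The two fragments of a replacement share
  scaffold-consistent labels; the canonical identity minimises the
  `left>>right` string over joint relabellings, so the attachment pairing
  is preserved while label permutations collapse.
- **Ties.** Continuous pair deltas with `|delta| < 1e-9` are excluded from
  both direction counts and reported separately; the sign test is otherwise
  biased by floating-point ties.
- **Degenerate classification tails.** With a degenerate before-rate (0 or
  1), an all-flip after-count has literal tail probability 0; it is floored
  at the smallest positive normalized double so the log-scale level stays
  finite.
- **Aromatic matching.** Substructure embedding colours atoms by (element,
  charge, aromaticity) and bonds by order, with all aromatic ring bonds
  sharing one colour. Aromaticity is read back from OpenBabel's canonical
  output, so a phenyl fragment matches an aromatic ring regardless of which
  kekulé rendering either side happens to carry, and never matches a
  saturated ring.
- **Salts and stereo.** Multi-component inputs are rejected, not stripped —
  silently keeping one component would make pair semantics ambiguous.
  Stereo descriptors are retained in canonical keys by default
  (`ignore_stereo` collapses stereoisomers), so enantiomers are distinct
  molecules unless the caller says otherwise.

## The synthetic data

`generate_library()` emulates a small combinatorial series: decorated
drug-like cores (12–16 heavy atoms, one open aromatic substitution site)
crossed with a vocabulary of small common substituents (H, methyl,
hydroxyl, chloro, bromo, amino, carboxyl). The endpoint is additive —
core baseline (uniform in 4–6 log units) + substituent contribution +
Gaussian noise (default sd 0.1) — so every transformation's true effect is
known: a planted methyl→hydroxyl effect of +1.0 log units (the default)
makes every hydroxyl-introducing swap a true positive and every
equal-contribution swap a true control. A binary companion endpoint
thresholds the continuous value. Cores are sized so that same-core
substituent swaps stay above the default 50% similarity filter; decorated
cores can additionally pair *across* cores through shared linker
fragments — genuine MMPs that carry their own transformations and make the
multiple-testing family realistically larger than the vocabulary grid
alone.

What the generator does **not** emulate: activity cliffs and non-additive
context effects (every planted effect is perfectly context-free),
assay-dependent noise structure, correlated prediction errors, chemistry
beyond one substitution site per core, and any realistic property model.
Passing tests therefore demonstrate the statistical machinery —
recovery, error control, amplification, bookkeeping — not predictive
validity on real assay data.

Test and acceptance problem sizes were chosen to exercise the full default
configuration at desk scale: the reference library is 10 cores × 7
substituents (70 molecules, ~340 pair records), the family-wise error
simulation uses 500 seeded runs of a structure-independent endpoint over
that library's fixed pair structure, the bootstrap demonstrations use 1,000
replicas, and the binomial test is checked against exhaustive enumeration
for all N ≤ 20.

## Known limitations

- Transformation effects are averaged over all chemical contexts; the
  method does not distinguish an alcohol hydroxyl from a carboxyl hydroxyl
  (chemistry-aware fragmentation is out of scope), and the additive toy
  predictor makes the consequence visible: a carboxyl product scores its
  embedded hydroxyl fragment.
- Products of the optimizer are not screened for synthetic feasibility,
  stability, or retained potency; counting a product as a hit means only
  that the predictor's value moved the right way.
- The binomial tests use sign information only; effect-size modelling
  beyond the mean pair delta, and FDR-style corrections, are out of scope.
- Pair similarity uses one global fingerprint/threshold; no per-series
  calibration.
- The index is rebuilt per run (a portable tabular store; no incremental
  updates or distributed fragmentation).
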