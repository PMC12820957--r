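---
title: "Methods: consensus rescoring, threshold classification and interaction fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus rescoring, threshold classification and interaction fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockconsensus)
```

This vignette documents the statistical model behind each stage of the
package, the tunable parameters and their defaults, the numerical and
design choices made where conventions diverge, and what the synthetic
study generator does and does not emulate.

## Relative ranks and consensus schemes

Docking scores are not comparable across scoring functions: scales differ
by orders of magnitude (a docking score near −9, an IFD composite score
near −3170, a fitness near 80), units differ, and — crucially — direction
differs: docking scores, IFD scores and binding-energy estimates improve
downwards, while GOLD's genetic-algorithm fitness functions improve
upwards. All consensus computation therefore happens on *relative ranks*:
per function, rank 1 is the most favorable ligand under that function's
declared direction. Directions are mandatory metadata
(`scoring_functions()`); there is no default, because a silently wrong
direction inverts every downstream result.

**Tie policy.** Tied scores receive average (fractional) ranks. This
preserves the column sum of every rank vector, which keeps Borda counts
comparable across functions, and matches the convention of standard rank
statistics (`rank(ties.method = "average")`, Spearman).

**Missing scores.** A docking failure leaves a ligand without scores for
one program. Two policies are offered. The default, `worst_rank`, assigns
rank `n_ranked + 1`: a ligand that could not be docked must not be rewarded
relative to ligands that docked poorly. The alternative, `omit`, drops the
(ligand, function) pair; a ligand losing *all* its ranks this way is
excluded from aggregation with a warning. `worst_rank` is the default
because omission quietly shrinks a failed ligand's Borda count towards
favorability.

**Borda / aggregated rank.** `B_i = Σ_j r_ij`, and the aggregated rank is
the average-tie ranking of `B_i` ascending. It weights all functions
equally and is invariant to any strictly monotone, direction-respecting
transform of each function's scores (a property the test suite asserts).

**Exponential consensus rank.** `ECR_i = Σ_j c · exp(−r_ij/σ)` over the
functions that ranked ligand *i*. The exponential decay means a compound
ranked near the top by a few functions can outscore one ranked middling by
all — ECR "takes the best from each program". The scale is `σ = 10`
(results are nearly insensitive to it, and 10 is the conventional choice).
The prefactor `c = 1/σ` (the normalised form, bounding a single function's
contribution by `(1/σ)e^{−1/σ}`) is included by default; `prefactor =
FALSE` gives the unnormalised sum, `c = 1`, since reported ECR magnitudes
in the literature are sometimes on that larger scale. The prefactor is a
positive constant, so it never changes any ordering — only the printed
magnitude.

Consensus ranks are computed within one target's docking campaign; there
is no cross-target pooling, because rank 1 at one target and rank 1 at
another are not the same evidence.

## KDE-intersection threshold classification

Given the scores of a positive class (inhibitors of the docked target)
and a negative class (everything else), each class density is estimated
with a Gaussian kernel. The default bandwidth is Scott's rule
`h = s·n^(−1/5)` (sample standard deviation `s`), the default of the
common KDE plotting stacks; Silverman's rule and a fixed bandwidth are
available. The curve is evaluated on a uniform grid of 512 points spanning
`[min − 3h, max + 3h]`, which captures >99% of the kernel mass at the
extremes; the trapezoid integral of a returned curve is within ±2% of 1,
and this is asserted rather than renormalised.

The decision threshold is a crossing of the two densities. Numerically,
both KDEs are evaluated on one shared grid, sign changes of
`f_pos − f_neg` are located, and each crossing is refined by linear
interpolation between the bracketing grid points (error `O(Δx²)`, far
below the sampling noise of any realistic ligand panel). Multiple
crossings are the rule, not the exception — Gaussian KDE tails always
cross again far from the data. The crossing *between the two class
medians* is selected, falling back to the crossing nearest the midpoint of
the medians; this is the decision boundary a reader takes from a
two-class KDE figure. All crossings are retained in the model object for
audit, so a near-degenerate pair of distributions is visible as a pile of
crossings rather than silently reduced to one number. If the curves never
cross on the grid the operation errors ("no intersection"): the
classification criterion is simply inapplicable, and fabricating a cutoff
would be worse than failing.

Classification is a strict inequality on the positive side; a score
exactly at the threshold is negative, matching the reading of a cutoff
phrased as "scores lower than t". Ligands with missing scores are labeled
negative with a warning: absence of a score cannot constitute evidence of
favorable binding. Thresholds can also be built directly from a published
cutoff via `threshold_model()`, with the same classification semantics;
`domain` records whether the threshold lives in score or rank units, since
densities are sometimes estimated on ranks while published cutoffs are in
score units.

**Metrics.** MCC and BAC are the primary metrics because ligand panels of
this kind are small and mildly imbalanced (e.g. 11 positives vs 17
negatives), where raw accuracy flatters the majority class. MCC is defined
as 0 when any denominator factor vanishes (the standard total-metric
convention); per-class precision/recall/F1 are reported alongside. The
test suite verifies every metric against an independent oracle that
rebuilds explicit label vectors and computes MCC as the Pearson
correlation of 0/1 labels, over exhaustive enumerations of small
confusion tables.

## Consensus interaction fingerprints

Contacts reported by PLIP for the poses of two different docking programs
are intersected per ligand on the exact key (interaction type, residue
number, residue type, chain). Only the intersection — never the union —
forms the consensus: a contact supported by a single placement algorithm
is treated as unconfirmed. Water bridges and salt bridges remain distinct
types (they are not folded into hydrogen bonds), because the merge key
operates on the interaction type verbatim. Within a (ligand, program) set
the key has set semantics: several atoms contacting the same residue with
the same interaction type collapse to one key, since the fingerprint
encodes presence/absence.

Bits are named `type@resnum@restype@chain` and ordered lexicographically
by (chain, residue number, residue type, interaction type) — no ordering
is canonical in the field, and a deterministic one is required for stable
serialization. Ligands whose consensus is empty keep an all-zero row.
Tanimoto similarity is `|A∩B|/|A∪B|` with the convention `T = 0` when the
union is empty, *including the diagonal*: an empty consensus fingerprint
means no consistent binding mode at the site, and such ligands must not
appear maximally similar to each other. Affected ligands are flagged via
the `empty_ligands` attribute.

Clustering is agglomerative on `d = 1 − T` (`stats::hclust`), average
linkage by default — the common choice for binary-fingerprint heatmaps;
complete and single linkage are available. The tests validate the
clustering against an exhaustive pairwise-minimum agglomeration oracle via
cophenetic distances, which is invariant to the merge-order ambiguities of
equivalent dendrograms.

## Activity correlation

Spearman (Pearson on average-tie ranks) and Pearson coefficients are both
reported: rank agreement is the robust prioritisation measure, while the
linear coefficient is what a regression plot displays. p-values are not
computed — on panels of ~7 ligands they would be noise dressed as
inference. Pairing is by strict ligand-ID intersection with dropped
ligands reported. The OLS confidence band is the 95% interval for the
conditional mean, `t`-based with `n − 2` degrees of freedom, evaluated on
a uniform abscissa grid for plotting. Sign conventions are deliberately
left to the data: ECR correlates positively with pIC50, aggregated rank
negatively (low rank = potent), and the tests pin both directions.

## The synthetic study generator

`generate_study()` emulates the *tabulated outputs* of a two-program
cross-docking campaign; it generates no poses and no chemistry. One latent
affinity `a_it` per (ligand, target) drives everything — scores,
interaction records and activity — which is exactly the coupling a
score-to-activity correlation analysis implicitly assumes.

Default conditions mirror a two-target mitochondrial inhibitor panel:

| parameter | default | meaning |
|---|---|---|
| `n_ci`, `n_ciii`, `n_unc` | 14, 11, 3 | class sizes (28 ligands) |
| functions | 11 | 5 Glide-side (lower-is-better), 3 GOLD fitness (higher), 3 GOLD rescoring (lower) |
| `binder_mean`, `binder_sd` | 2.5, 1 | latent affinity of a target's binders |
| `nonbinder_mean`, `nonbinder_sd` | 0, 1 | latent affinity of nonbinders |
| `program_sd` | 0.5 | ligand noise shared within a program |
| `p_fail` | 0.05 | whole-program docking failure per (ligand, program) |
| `core_size` | 21 | interaction keys in a target's binder core |
| `p_core` | 0.8 | per-program core-key detection probability |
| `nonbinder_core_prob` | 0.05 | nonbinder core-key rate |
| `lambda_spur` | 2 | Poisson mean of spurious keys per (ligand, program) |
| `gamma0`, `gamma1`, `activity_sd` | 6, 0.8, 0.3 | pIC50 model for binders of the activity target |

Scores follow `raw = gain·a + offset + target_offset + u + ε` with
`u ~ N(0, program_sd)` shared across one program's functions — inducing
the within-program block correlation seen in real rank heatmaps — and the
emitted score is `raw` or `−raw` per direction. The default latent
separation (2.5 pooled sds) makes single functions good but imperfect
classifiers, the regime in which consensus methods are interesting;
per-function gains and noise vary so that function quality is
heterogeneous. Docking failures are drawn per (ligand, program): a
protocol fails as a whole, not one scoring function at a time.

Interaction records cover each core key per program with probability
`p_core` independently, so a binder's consensus fingerprint retains a core
key with probability ≈ `p_core²` (expected consensus size
`21 × 0.64 ≈ 13.4` under defaults, an invariant the tests check against
its binomial standard error). Spurious keys are drawn from a 200-key pool
disjoint from all cores; surviving the two-program intersection requires
the same spurious key twice, which is rare — mirroring how consensus
fingerprints suppress placement noise.

What the generator does *not* emulate: realistic score magnitudes (offsets
are modest; nothing tries to land near −3170), correlated errors between
functions beyond the program block, chemistry-driven similarity between
ligands of one class, binding-site geometry or interactions driven by it,
and any pose-level detail. Passing tests on synthetic data therefore
demonstrate that the *analysis machinery* is correct under a known
generative model, not that the method will perform identically on real
docking output.

**Parameter recovery conditions.** The recovery property — the
KDE-threshold classifier reaching BAC ≥ 0.9 — is evaluated at a score-level
class separation of d′ ≥ 3 (`binder_mean = 4`, `program_sd = 0.3`,
`p_fail = 0`), selecting the best-separating function per replicate as a
real study would, and averaging over seeds at the study's own panel size
(28 ligands). Failures are disabled there because the property isolates
the threshold machinery; failure handling is tested separately.

**Problem sizes.** The statistical suites use 50 seeds for the
ECR/aggregated-rank agreement rate, 20 for threshold recovery, 40
replicates for fingerprint coverage, 100 replicates for the
consensus-vs-single-function comparison on 7-ligand activity panels, and
Monte Carlo samples of 2,000–20,000 points for the Gaussian-crossing
checks — sizes at which the asserted margins are several standard errors
wide.

## Known limitations

- The KDE threshold depends on bandwidth; published cutoffs from other
  stacks are generally not bit-reproducible, and are better supplied as
  fixed `threshold_model()` inputs than re-derived.
- On panels of ~28 ligands, a KDE intersection is a coarse estimator;
  `crossings` should be inspected whenever class separation is weak.
- Consensus intersection is conservative by design: a genuine contact
  found by only one program is discarded.
- The activity-correlation stage assumes a single latent potency axis;
  multi-mechanism panels violate this silently.
- Three-way mechanism classes are evaluated as one-vs-rest binary tasks;
  there is no multi-class classifier.
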