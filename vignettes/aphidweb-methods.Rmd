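---
title: "Methods: host-range indices, specialist advantage and trait analysis in aphid-parasitoid webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-range indices, specialist advantage and trait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidweb)
```

## The data and the scientific question

The package analyses a quantitative bipartite rearing web: a matrix of
counts of parasitoid individuals reared from mummified aphids, with aphid
species as rows and parasitoid species as columns, together with a ranked
taxonomy of the aphids and ten categorical aphid traits (colony
concealment, aggregation, ant attendance, mobility, wax production, body
size, life cycle, diet breadth, habitat specialization, habitat
disturbance). The question is bottom-up: which host traits are associated
with (i) a *specialist advantage* — relatively specialized parasitoids
outnumbering relative generalists on shared hosts — and (ii) a more
specialized parasitoid assemblage on average.

Interactions documented by fewer than five reared individuals are removed
before analysis (`filter_rare_interactions()`): such records contribute
little to autecology and are where misidentifications concentrate. The
boundary is strict — a count of exactly five is kept — and rows/columns
left empty are dropped from all downstream stages, so species counts
always describe the analysed web. Whether a deposited matrix was already
filtered cannot generally be known, so the threshold is an explicit
argument (`min_count = 1` disables the stage).

## Host-range indices on a taxonomy

Two indices describe a parasitoid's host range: host species richness
(`SR`), and the phylogenetic species variability of its hosts (`PSV`),

$$\mathrm{PSV} = \frac{n\,\mathrm{tr}(C_s) - \Sigma C_s}{n(n-1)}
              = 1 - \overline{c}_{\text{off-diag}},$$

computed presence-only on the `n` hosts' submatrix of a host correlation
matrix `C`. Without a dated phylogeny, `C` is built from the ranked
lineages: the correlation of two species is the fraction of shared
leading lineage segments out of `L + 1` equal segments, where `L` is the
number of ranks and the extra terminal segment belongs to the species
itself. Under the default four ranks (family / subfamily / tribe /
genus), congeners correlate at 4/5 and members of different families at
0. This is the natural equal-branch-length ultrametric convention: it is
monotone in the number of shared ranks, reaches 1 only on the diagonal,
and reduces to `PSV = 1` (a star phylogeny) when all hosts are in
different families. Because the true segment lengths are unknowable from
a taxonomy, the per-segment weights are an argument of
`taxonomic_correlation()`; any reproduction of published values computed
under a different convention is therefore tolerance-based, not exact.

Two conventions need fixing where the formula is undefined or arbitrary:

* a single-host parasitoid has no host pairs; it is assigned `PSV = 0`
  (maximally specialized, the natural limit of "one or a few closely
  related hosts"). `single_host = "exclude"` returns `NA` instead, for
  sensitivity analyses;
* `SR` and `PSV` are always computed on the full filtered web, never on a
  trait subset — host range is a species property defined before any
  stratification.

A false "obvious" property is worth recording: adding a host whose
lineage duplicates an existing host does *not* always decrease PSV. If
the duplicated host is a taxonomic outlier, duplicating it dilutes the
mean pairwise correlation and PSV rises. The test suite therefore asserts
the true properties (bounds, `PSV = 1` iff all pairwise correlations are
zero, abundance invariance, equality with a brute-force double loop)
rather than monotonicity.

## Specialist advantage

All unordered parasitoid pairs that share at least one host and have
strictly different index values are enumerated; the smaller-index member
is the relative specialist. Ties are excluded under either index; for PSV
equality is judged after rounding to 12 decimals, so representation noise
cannot manufacture a pair. For a pair on a set of shared hosts, each
host contributes the specialist's count share
$p_h = n_{S,h}/(n_{S,h}+n_{G,h})$, and

* the pair's score is the unweighted mean over shared hosts, and
* a trait level's *mean score* is the unweighted mean over all pairs that
  still share a host after restricting rows to that level.

Both means are deliberately unweighted — each shared host, and each pair,
counts once regardless of abundance — matching the definition of the
mean score as a mean over pairwise comparisons. Because each parasitoid
of a pair enters the ratio with its own counts, the score is insensitive
to aphid sampling intensity.

One genuinely open design point is whether specialist/generalist labels
should be recomputed within each trait subset. The package keeps
designation on the full web (`designation = "full"`), so a pair keeps one
consistent orientation across the levels of a trait and across traits;
`designation = "subset"` is available for sensitivity analysis. Species
with a missing value for the focal trait are excluded from that trait's
analysis only.

A level in which no pair retains a shared host yields a sentinel
(`n_pairs = 0`, score `NA`), not an error: an empty stratum is a fact of
the data, not a misuse of the function.

## Bootstrap inference

Trait-level differences (in mean score, or in mean assemblage
specialization $W_i = \sum_j S_j A_j$) are tested by a nonparametric
bootstrap that preserves category sizes: each replicate draws, with
replacement from the full aphid row pool, $n_a$ rows assigned to the
first level and $n_b$ to the second, then recomputes the statistic. This
breaks the trait–score association while holding the per-level species
counts fixed, which is what makes the replicate distribution a null for
the observed difference. The literal alternative — resampling rows
*within* each category — is implemented as
`null_mode = "distribution_bootstrap"` for comparison, but its replicates
centre on the observed difference and cannot calibrate a test, so it is
not the default.

The p-value counts replicates at least as extreme as the observed
difference and divides by the number of evaluable replicates (no +1
correction; ties count as exceedances, the conservative choice).
Replicates on which a statistic is undefined (no applicable pair
survives the resampling) are dropped and reported; if more than half of
the replicates are undefined the test aborts with the failure rate.

Tail choice deserves care. The default `tail = "auto"` follows the sign
of the observed difference, which is how directional findings are
usually reported — but under the null either sign can be drawn, so the
*effective* size of the auto rule is about twice the nominal one-tailed
level. Calibration statements (e.g. the type-I checks in the test suite)
therefore evaluate a fixed tail; `tail = "greater"`, `"less"` and
`"two_sided"` (doubled smaller tail) are all available and the tail
actually used is recorded in the result.

`run_all_trait_tests()` runs one primary contrast per trait (two-level
traits use their two levels; the three-level traits use pooled contrasts:
not-ant-attended vs ant-attended, monophagous vs polyphagous, large vs
medium-and-small) plus all pairwise level contrasts of three-level traits
as supplementary rows. Per-test replicate streams are derived from the
master seed by hashing the test label, so adding or removing tests from a
batch never perturbs the others, and a failed contrast becomes a flagged
row rather than aborting the batch. `B = 4999` replicates by default;
the examples and tests scale `B` down (49–999) where only the machinery,
not the resolution of the p-value, is under study.

## Trait associations: MCA, imputation, v.tests

The ten traits are analysed jointly by multiple correspondence analysis:
a correspondence analysis of the species × category indicator matrix
(relative frequencies centred on the product of row and column masses,
standardized, decomposed by SVD). Eigenvalues are squared singular
values; for a complete indicator matrix with `J` categories over `Q`
traits the total inertia is exactly `J/Q − 1`, which the tests verify to
1e-10. The indicator-matrix formulation (not the Burt matrix, no
eigenvalue correction) is used because categories should sit at the
rescaled barycentre of their species. Unobserved levels are dropped so
no column has zero mass; a table with no variation at all is refused.
(A rank-1 solution — e.g. two perfectly associated binary traits — is
returned, not refused: its single axis carries 100% of the inertia.)

Missing trait values are imputed by the regularized iterative MCA
algorithm: initialize missing indicator cells at the observed level
proportions of their trait; then alternate (i) CA of the completed
matrix, (ii) reconstruction from the first `ncp` dimensions with singular
values shrunk by the mean of the discarded eigenvalues, overwriting only
the missing cells, clipped to [0, 1] and renormalized within each trait
block, until the largest change drops below `tol = 1e-6` (cap 1000
iterations, warning on non-convergence). Observed cells are never
touched, and the tests compare them bitwise before and after. `ncp = 2`
by default, matching the two dimensions used for interpretation; note
that on a table whose centred rank is ≤ `ncp` the iteration can fix the
initialization in place (nothing is discarded, so nothing is
regularized) — imputation is only informative when the trait structure
has more dimensions than `ncp`. Each imputed cell is finally
hard-assigned to its trait's maximum-weight level (first level wins
ties), because the downstream v.tests operate on categories, not on
fuzzy weights.

Pairwise trait-level association uses the hypergeometric v.test: with
`n` species, `n_k` carrying the tested category, `n_l` the conditioning
category and `n_kl` both, the two-sided p doubles the smaller
hypergeometric tail (each tail including the observed overlap, capped at
1) and $v = \mathrm{sign}(n_{kl}/n_l - n_k/n)\,\Phi^{-1}(1 - p/2)$. The
test is asymmetric by construction — testing k among l is not testing l
among k — and `all_pairwise_vtests()` reports every ordered cross-trait
pair. Under this convention "complete containment" at small n can fall
marginally short of |v| = 2 (e.g. n = 10, n_k = 5, n_l = 4, n_kl = 4
gives p = 2·5/210 and v = 1.98): the doubled-tail definition is kept in
preference to the rule of thumb. V.tests are computed on the
hard-assigned completed table.

## The synthetic-data generator

`simulate_study()` draws the three inputs with known ground truth. Its
defaults are the study conditions the package is built around: 142 aphid
species in a 4-rank taxonomy (4 families × 5 genera, one subfamily per
family, two genera per tribe), 75 parasitoid species, an even mix of
narrow, taxonomically clustered specialists (host ranges 1–2, chosen
within a genus, widened only when the genus is too small) and broad
generalists (Poisson-distributed ranges, mean 8, uniform host choice),
zero-truncated Poisson counts with mean 20 per realized link (so the
default filter removes only a small tail), and 2% of trait cells missing
completely at random — MCAR being the assumption under which the
imputation is unbiased. Trait marginals are roughly uniform with
optional pairwise odds tilts to inject associations.

The specialist-advantage mechanism multiplies the counts of
below-median-PSV parasitoids on hosts at a focal trait level by
`delta ≥ 1` (rounded, floored at 1 for realized links). Multiplying
counts rather than adding links keeps every host set — hence SR and PSV,
hence *who* is the specialist — identical with and without the effect:
identity and performance stay orthogonal, which is exactly the
confound the pairwise design is meant to avoid. The generator is fully
deterministic given the spec's seed; sub-generators use fixed offsets of
it.

What the generator does *not* emulate: spatial or temporal structure,
phylogenetic signal in traits (traits are drawn independently of the
taxonomy), non-random missingness, and abundance differences among
aphids beyond what host-range draws induce. Passing tests on synthetic
webs therefore demonstrate correctness of the machinery and
detectability of injected effects under these idealized conditions — not
that real webs satisfy them.

## Numerical and testing choices

* PSV tie rule for pairing: exact equality after rounding to 12 decimals.
* Imputation: `tol = 1e-6` on the largest imputed-cell change; inertia
  identities asserted to 1e-10; oracle equivalences (brute-force PSV,
  triple-loop pair scores, enumerated hypergeometric p) to 1e-12 or
  exact.
* Degenerate inputs: a web that filters to nothing returns an empty table
  flagged "no interactions survive filtering"; an all-missing or
  ≥ 50%-missing trait refuses imputation; an aphid present in the web but
  absent from the taxonomy is a hard, named error.
* Report CSVs round to 6 decimals with fixed column order so reruns diff
  cleanly; full precision stays in the returned objects.
* Problem sizes in the test suite: oracle sweeps use webs of ≤ 8 hosts ×
  ≤ 6 parasitoids (1000 / 100 replicates); calibration uses 200 null
  webs of 60 aphids with `B = 499` at a fixed tail; power uses 100
  seeded webs of 60 aphids with `delta = 3`. These sizes give stable
  Monte Carlo rates while keeping the default suite fast.

## Limitations

* Rank-based correlations are a coarse stand-in for divergence times;
  conclusions sensitive to the segment-weight convention should be
  checked with `weights`.
* Pairs are not independent (one parasitoid joins many pairs); the
  bootstrap addresses sampling variability of species, not pair
  pseudo-replication, and no multiple-testing correction is applied
  across the trait battery.
* The auto tail doubles the effective test size, as discussed above.
* MCA coordinates depend on the imputation dimensionality `ncp`; only
  signs and orderings of strong associations should be interpreted, not
  exact coordinates.
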