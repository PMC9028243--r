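---
title: "Models and methods behind phyloccs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyloccs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phyloccs implements a comparative-genomics workflow for a seven-species
bird phylogeny in which three independently evolved tactile-foraging
lineages (kiwi, mallard, crested ibis) form a foreground group, their
non-tactile relatives (tinamou, chicken, little egret) the background,
and the ostrich the outgroup. This vignette explains the models, the
defaults and the numerical choices; it states no result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The species tree

`make_default_tree()` fixes the topology
`((ostrich,(kiwi,tinamou)),((chicken,mallard),(egret,ibis)))`. In
`"time"` mode it is ultrametric with a default root depth of 111 time
units and internal node ages (73, 60, 88, 80, 45 in the same units)
chosen once as round palaeognath/neognath-scale values; in `"sequence"`
mode every branch defaults to 0.1 expected substitutions per site. Both
are fixture defaults, configurable, and carry no inferential weight.
Foreground tips and the outgroup ride along as attributes so that every
downstream function agrees on the grouping.

## JTT + discrete gamma, pruning, and ancestral states

Protein likelihoods use the JTT empirical exchangeability matrix and
stationary frequencies (embedded as package constants), scaled to one
expected substitution per unit branch length. Among-site rate variation
uses K equal-probability discrete-gamma categories with category-mean
rates (`discrete_gamma_rates()`; mean exactly 1); the default K = 4 and
the fixture shape α = 0.7 are conventional choices — nothing in the
study design pins them down, so both are exposed as arguments.

`protein_loglik()` is Felsenstein pruning with per-node rescaling,
pattern compression, and the site likelihood averaged over categories.
The inner loop (transition matrices via the reversible
eigendecomposition, and the postorder partial-likelihood recursion) is
compiled RcppArmadillo; tip edges use a column gather rather than a
matrix product. The same kernel serves the 20-state amino-acid model,
the 61-state codon model, and the birth–death count model.

`fit_protein_model()` maximises the likelihood coordinate-wise: each
branch length on [1e-8, 10], the shape α on [0.05, 50] (log scale),
sweeping until the log-likelihood gains less than `tol` (default 1e-4).
Coordinate sweeps are deterministic, monotone (the per-sweep trace is
returned and tested), and robust for the small fixed topologies this
package targets; no topology search is attempted.

`marginal_ancestral_states()` combines each node's downward partial
likelihood with the likelihood of the rest of the tree (computed by a
preorder sweep), mixes categories by their per-site posterior weight,
and records the MAP residue and its posterior. Sites where the MAP
state of the outgroup's attachment node differs from the observed
outgroup residue are flagged; the convergence caller skips flagged
sites by default (audit-as-filter, the conservative reading), but the
flag is exposed so users can treat it as an audit only.

Gap handling: columns containing any character outside the 20 standard
residues are removed up front (`strip_gap_columns()`); the index map is
threaded through so all site calls are reported in original
coordinates.

## Convergence at conserved sites

`detect_convergent_sites()` calls a column iff (1) all foreground tips
share one residue X; (2) all background tips and the MAP states of
every checked ancestor equal one residue Y; (3) X ≠ Y. Two genuinely
open points are resolved conservatively and exposed as options:

* *Which ancestors?* Default `"all"`: every internal node must match Y.
  `"parents"` relaxes this to the parents of the foreground branches.
* *Posterior floor.* A reconstructed ancestral state is only trusted at
  MAP posterior ≥ 0.8 (configurable); a site with any weaker ancestor
  is not called.

This trades recall for precision deliberately: in the packaged
simulations (`inject_convergent_sites()` plants foreground-only
substitutions at columns where background and true ancestors are
uniform), about 90–98% of planted sites are recovered while false calls
on 10,000 null columns stay in single digits — the suite measures both.

`random_trio_control()` re-runs detection with an arbitrary
non-outgroup trio as surrogate foreground and reports gene-level and
site-level overlap separately, because two runs can flag the same gene
at entirely different loci.

## Codon models

`codon_log_likelihood()` implements the GY94 61-sense-codon model:
single-nucleotide changes at rate π_target, times κ for transitions,
times ω for nonsynonymous changes; multi-nucleotide changes are
forbidden. Codon frequencies are F3x4 from the analysed alignment
(zero-count nucleotide frequencies floored at 1e-6 and renormalised).

**Normalisation convention.** All site classes of a mixture share one
time scale per branch: the branch is normalised so its expected
substitution rate, averaged over site classes, is one per unit length.
Classes with larger ω therefore genuinely evolve faster, as in codeml;
for single-class models this reduces to the usual per-matrix scaling.
The simulator (`simulate_codon_alignment()`, `site_classes` argument)
uses the identical convention, so planted and fitted regimes share one
definition of branch length. Branch lengths are taken from the input
tree and are not re-estimated by the codon fits.

`branch_site_lrt()` fits Model A (classes 0, 1, 2a, 2b; background ω0
∈ (0,1), ω1 = 1, foreground ω2 ≥ 1 free) against the null with ω2 = 1,
and tests 2Δℓ (clamped at 0) against χ²₁ — the conservative convention,
not the 50:50 mixture. `group_omega_difference()` realises "average ω
per group" as a two-ratio ML fit with a one-ratio null and a χ²₁ LRT:
free-ratio averaging is unstable on short branches, and the two-ratio
LRT gives the significance machinery a definite, testable form.

Optimisation: parameters are transformed to an unconstrained scale
(log κ, softmax proportions, logit ω0, log(ω2 − 1)), then maximised by
bounded quasi-Newton from three fixed starts screened at loose
tolerance, with the best start polished to ~1e-8 on the log-likelihood.
The null optimum is always included among the alternative's starts, so
nesting (lnL_alt ≥ lnL_null) holds by construction.

`ng86_pairwise()` follows Nei–Gojobori (1986): fractional
synonymous-site counting per codon (mutations to stop codons count as
nonsynonymous, keeping N + S = 3), pathway-averaged difference counts
with stop-passing paths discarded (falling back to all paths when every
path is blocked), and the Jukes–Cantor correction; dS = 0 or a
saturated correction yields an `NA` sentinel rather than a number.

## Birth–death gene-family model

Family sizes evolve as a linear birth–death chain with equal per-gene
birth and death rate λ. The transition probability from s to c in time
t uses the classical closed form with α = λt/(1+λt); for λt > 1 the
(1 − 2α) factor is negative and is carried with an explicit sign in log
space. `fit_lambda()` maximises the summed pruning likelihood over
count states 0..C (C = 2× the largest observed count, minimum 16), with
the root marginalised over a uniform prior on 1..max_root (max_root =
2× the largest observed count) and each family conditioned on leaving
at least one surviving gene; the non-extinction probability has a
closed form through the geometric offspring law.

The family-wide p-value statistic is the conditional log-likelihood
*profiled over the root size*: it is compared against null families
simulated (by the same exact Gillespie machinery that generates the
synthetic data — the simulator doubles as the model's oracle) from the
family's own best-supported root. Conditioning the null on the root
size keeps the statistic from being confounded by family size, which is
how the CAFE-style test behaves. The add-one estimator keeps p in
[1/(n+1), 1].

Per-branch calls use a max-product (Viterbi) reconstruction of
ancestral counts, ties broken toward the smaller count for determinism;
the branch p-value is the one-sided tail probability of a change at
least as extreme as the reconstructed one, and expansion/contraction is
called at p < 0.05 jointly with a family-wide p < 0.05, mirroring the
two-threshold rule of the study design.

## Orthology

MCL follows the textbook loop — column normalisation, expansion by
squaring, inflation 1.5, pruning below 1e-6, convergence at 1e-8 max
entry change, 200-iteration cap with diagnostics on failure — on a
graph weighted by −log10(e-value) capped at 200 and averaged over the
two hit directions (bit-score weighting behind a flag). Self-loops
equal each gene's maximum incident weight. Clusters are the connected
components of the limit matrix's support. "Other" genes are defined as
the complement of the four explicit categories — the study never
defines the category, so the complement definition is declared here and
enforced by the partition invariant (per species, the five tallies sum
to the kept gene count).

## Synthetic data: what it does and does not emulate

The simulators generate every input with known ground truth: protein
alignments under exactly the inference model, planted convergent
columns that satisfy the three criteria by construction (foreground
tips overwritten, true ancestors untouched), codon alignments under
branch or branch-site ω regimes, family counts by exact event-driven
simulation with optional deterministic jumps, and similarity graphs
whose noise edges sit above the e-value cutoff. Defaults follow the
study design where it speaks (7 species, 3 foreground lineages,
inflation 1.5, e-value 1e-5, thresholds 0.05/0.01) and declared
fixture values elsewhere (tree depth 111, α = 0.7, K = 4, λ = 0.002,
root sizes 5–15).

Passing tests on these data show the machinery is correct and
calibrated *under its own model*. They do not show robustness to what
real data add: indels and alignment error, heterotachy, assembly and
annotation artefacts, codon-usage bias beyond F3x4, or gene-tree
discordance. The pipeline's problem sizes (6 analysis genes of 300
aa / 300 codons, 40 families, 500 Monte-Carlo draws per p-value) are
fixture-scale choices that keep a full run in the low minutes while
leaving every statistical property measurable; all are configurable
through `pipeline_config()`.

## Known limitations

* No joint (max-joint) ancestral reconstruction, topology search, or
  codon-level ASR.
* No Bayes Empirical Bayes site identification in the branch-site
  machinery; the test is gene-level.
* Single global λ with no per-branch rate classes or error model.
* Enrichment is flat hypergeometric: no GO-graph propagation or
  topology-aware weighting; results on user term maps are labelled by
  method so they are not mistaken for any external tool's output.
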