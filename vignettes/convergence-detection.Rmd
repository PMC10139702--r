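---
title: "Detecting convergent and parallel amino acid substitutions on focal branches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent and parallel amino acid substitutions on focal branches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaconv)
```

## The question the package answers

When distantly related lineages evolve the same specialized phenotype —
here, the ant- and termite-eating (myrmecophagous) habit that arose
independently in anteaters (Xenarthra), echidnas (Monotremata) and
pangolins (Pholidota) — one molecular signature worth scanning for is
*sequence convergence*: alignment sites at which the focal lineages
independently acquired the same derived amino acid. `aaconv` implements
the classical scan over single-copy ortholog protein alignments on a fixed
species tree:

1. reconstruct ancestral protein sequences at every internal node by
   marginal (empirical Bayes) reconstruction under a reversible empirical
   amino acid model;
2. compare extant sequences with the reconstructed ancestor at the parent
   of each focal branch, calling a substitution wherever they differ;
3. classify sites where every focal branch (or a branch pair) acquired the
   same derived residue as **parallel** (identical ancestral residues) or
   **convergent** (different ancestral residues);
4. compare the observed count against the count expected under the same
   substitution model, treating the observed count as Poisson with the
   expected count as its mean, and testing both directions: an *excess*
   on the focal branches and, as a specificity control, a *deficit or
   plain null behavior* on the non-myrmecophagous sister branches (dog,
   cat, giant panda, elephant, platypus).

The package also contains a seeded simulator that generates ortholog
datasets with full ground truth (ancestral sequences, per-branch
substitution histories, and optionally injected convergent sites), which
is how every statistical claim in the test suite is validated.

## The model

All computations use a 20-state general time-reversible substitution
model. From symmetric exchangeabilities $s_{ij}$ and equilibrium
frequencies $\pi$, the rate matrix is $Q_{ij} = s_{ij}\pi_j$ ($i \ne j$),
diagonal set so rows sum to zero, rescaled so
$-\sum_i \pi_i Q_{ii} = 1$; branch lengths are then expected
substitutions per site. Transition probabilities $P(t) = e^{Qt}$ are
computed by the symmetric similarity transform
$\mathrm{diag}(\sqrt{\pi})\,Q\,\mathrm{diag}(1/\sqrt{\pi})$ and a
symmetric eigendecomposition, which is numerically stable for reversible
models; rows are renormalized only when within $10^{-8}$ of 1, larger
deviations raise an error rather than being masked.

JTT, WAG and LG are shipped as plain-text files in the classic PAML
layout (lower-triangular exchangeabilities, then 20 frequencies) under
`inst/extdata/models/`, so the matrices are inspectable and replaceable;
`aa_model("JTT", frequencies = alignment)` gives the +F variant with
observed alignment frequencies (one pseudo-count per residue keeps them
strictly positive). JTT is the default because it is the common default
for protein-level ancestral reconstruction pipelines; the choice is
configurable (`"WAG"`, `"LG"`, `"EQ"`, or a file path). Among-site rate
variation is deliberately not modeled: the simulator and the detector
share a single uniform-rate model, so the analysis is internally
consistent, and the expected-count null sees exactly the process that
generated the data it is calibrated against. With real data this means
rate-heterogeneous genes are analyzed slightly conservatively on slow
sites and anticonservatively on fast ones; a gamma extension would slot
in at the transition-matrix layer.

## Likelihoods, branch lengths, ancestors

Site likelihoods use Felsenstein pruning with per-node rescaling (column
maxima, accumulated in log space), so alignments of any practical length
cannot underflow. Gaps and ambiguity codes (`-`, `X`, `?`, `*`, `.`) are
missing data — an all-ones tip partial — never a 21st state. Columns with
no data at all have likelihood 1 and contribute nothing.

Branch lengths can be taken from the input tree (`branch_lengths =
"fixed"`) or re-estimated per gene on the fixed species topology
(`"estimate"`, the default in the batch pipeline, mirroring how ancestral
reconstruction is usually run in practice: per-gene rates vary). The
estimator sweeps the branches with Brent one-dimensional optimization on
$[0, 10]$ substitutions/site until the per-sweep log-likelihood gain
falls below $10^{-6}$ (at most 50 sweeps). Under a reversible model the
two branches meeting at a bifurcating root are identifiable only through
their sum, so they are optimized jointly on the sum with the split kept
proportional to the input tree — this removes a spurious optimizer degree
of freedom rather than letting it wander.

Marginal posteriors at every internal node come from the standard
two-pass (post-order + pre-order) decomposition and are exact for the
given tree, lengths and model; the test suite checks them against
brute-force enumeration over all internal-state assignments at $10^{-10}$.
The MAP (posterior mode) residue is reported per node and site. Ties are
resolved to the alphabetically first one-letter code; "tie" means within
`tie_delta = 1e-9` of the maximum, because exactly symmetric
configurations differ at the $10^{-16}$ level after an eigendecomposition
and a bit-exact tie rule would be unreachable. Reconstructions with MAP
probability below 0.8 are flagged low-confidence in output but never
filtered: the expected-count null integrates over the full posterior, so
filtering observed calls by confidence would bias the comparison.

## Counting events and the expected-count null

A focal branch set names $k \ge 2$ disjoint branches (no branch ancestral
to another — violating this is a hard error, because the null model
multiplies posteriors across branches and that requires the focal
subtrees to be separated). On terminal branches the child state is the
*observed tip residue* — extant sequences are data and are never replaced
by a reconstruction. Sites with missing data in any focal tip are
unusable for the entire branch set, and exactly the same usable-site
ledger drives the expected counts, so observed and expected are always
computed on the same sites.

In `"all"` mode an event requires a call to the same derived residue on
every branch of the set (used for the three-species analysis); in
`"pairwise"` mode every unordered branch pair with a shared derived
residue contributes an event (used for the two-species comparisons, and
for the five-sister control alongside the all-branches version). With
identical ancestral states the event is parallel, otherwise convergent;
pooled ("combined") counts are reported alongside the split because the
headline quantities in this literature are pooled.

The expected count per usable site and branch pair, with parent
posteriors $q_1, q_2$ and transition matrices $P_1, P_2$, is

$$E_{\mathrm{par}} = \sum_x q_1(x)q_2(x) \sum_{j \ne x} P_1(x,j)P_2(x,j),
\qquad
E_{\mathrm{conv}} = \sum_{x_1 \ne x_2} q_1(x_1)q_2(x_2)
\sum_{j \ne x_1, x_2} P_1(x_1,j)P_2(x_2,j),$$

extended in all-branches mode to a single shared derived residue $j$
distinct from every ancestral state, with the product over all $k$
branches. Two deliberate asymmetries deserve emphasis:

* expectations integrate over the full ancestral posterior while observed
  counts use MAP ancestors — this mirrors standard practice, and the test
  suite verifies empirically that on null simulations the genome-wide
  observed count tracks the expectation within 10%;
* posteriors at distinct focal parents are treated as independent, which
  the disjointness requirement makes structurally legal (for two sister
  control branches sharing a parent node the factorization is an
  approximation, as it is in the standard procedure).

Observed counts are tested as Poisson draws with the expected count as
mean, using exact tail sums in both directions: `p_upper` ($P(X \ge
\mathrm{obs})$, the focal-excess direction) and `p_lower` ($P(X \le
\mathrm{obs})$, the sister-deficit direction). Expectations are additive
over independent genes, so the genome-wide test sums observed and
expected across genes — this is the headline test. Per-gene upper-tail
p-values get Benjamini–Hochberg q-values for reporting only; no per-gene
threshold is applied anywhere.

## The simulator and what passing tests demonstrate

`sim_config()` defaults describe the study design the package targets: a
13-tip mammal tree with the three focal lineages in three disjoint
subtrees and their five designated sister species, JTT, 300-site genes,
and branch lengths at magnitudes typical of mammalian ortholog protein
divergence (terminal branches 0.07–0.24 substitutions/site). Sequences
are evolved root-to-tips by direct sampling from transition-matrix rows,
with the complete substitution history recorded. Convergence is injected
by overwriting the focal tips at selected sites with a shared derived
residue distinct from each focal parent's true state — bookkeeping is
exact and the intended category (parallel/convergent) is recorded — rather
than by re-simulating histories; this keeps the ground truth exactly
controllable. The derived residue is drawn uniformly among legal residues
by default; a biased policy (one fixed target residue) exists for stress
tests. Gene lengths can be drawn uniformly from a range to emulate
ortholog length variation.

The simulator emulates: site-independent evolution under the reversible
model, missing-data handling, and focal-branch convergence of tunable
strength. It does not emulate indels, alignment error, orthology error,
among-site rate variation, or selection elsewhere on the tree. Green
tests therefore demonstrate internal statistical correctness (the
detector finds what was planted, at the rate the null predicts, with
calibrated type-I behavior); they do not certify behavior under
misalignment or model misspecification on real data.

Two empirical properties of the default design are worth knowing. First,
MAP reconstruction accuracy at the focal parents exceeds 90% and decays
as branch lengths grow. Second, recall of true (neutral) focal-branch
substitutions is limited by the echidna branch: its parent, the monotreme
ancestor, is anchored only by platypus and the root path, so a fraction
of echidna substitutions is absorbed into reconstruction error (~86–90%
recall there, against 94–100% for anteater and pangolin; ~92–94%
overall). Injected convergent sites are easier than the average neutral
substitution — the shared derived residue on three branches leaves the
parents well anchored — and per-gene recall of injected sites averages
above 0.9 (at least 4 of 5 in every tested replicate).

## Numerical and design choices

* Transition matrices: symmetric-eigendecomposition exponentials,
  validated against scaling-and-squaring; entries clamped at 0 and rows
  renormalized only within $10^{-8}$.
* Optimizer: Brent (via `stats::optimize`) per branch, bracketed on
  $[0, 10]$; deterministic given inputs; non-convergence after 50 sweeps
  returns the best tree with a warning flag rather than failing.
* Poisson tails: exact via `stats::ppois`; the degenerate
  $\lambda = 0$ case is handled explicitly (`p_upper = 1` iff the
  observed count is 0, `p_lower = 1`).
* Determinism: every simulation consumes a seed derived from
  `(master seed, gene index, salt)`, all below $2^{31}$; identical
  configs give byte-identical FASTA and TSV outputs, and batches can be
  split and concatenated without changing per-gene rows (Benjamini–
  Hochberg q-values are batch-wide by definition).
* Per-gene isolation in `run_batch()`: a malformed gene is quarantined
  into the failures manifest; it never aborts the batch.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script exercise, as the package's
own standard experiment sizes: enumeration oracles on 3–4-tip trees;
branch-length recovery on a 6-tip, 1000-site gene; a 200,000-replicate
Monte-Carlo check of the expectation formulas; type-I calibration on 50
replicates of 200 null genes × 300 sites; and designed-recovery runs of
20 genes with 5 injected convergent sites each, repeated over 50 seeds.

## Known limitations

* Uniform rates across sites; no codon-level modeling (protein only).
* The expected-count null conditions on one fixed tree and the estimated
  branch lengths; uncertainty in either is not propagated.
* The independence factorization across focal parents is exact only for
  parents in disjoint subtrees; same-parent control pairs use it as an
  approximation.
* Joint (rather than marginal) ancestral reconstruction, sampling of
  ancestral histories, and alternative nulls (site permutation,
  posterior-predictive) are out of scope; the simulator provides an
  indirect posterior-predictive route.
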