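---
title: "Methods: mapping ecdysone-receptor loss and screening molting regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping ecdysone-receptor loss and screening molting regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Molting in ecdysozoans is canonically triggered by ecdysteroid hormones
acting through the ECR/USP nuclear-receptor heterodimer, yet the model
nematode *Caenorhabditis elegans* molts without an ecdysone receptor.
moltloss packages the inference machinery needed to ask how widespread
such loss is and what might buffer it: mapping minimal gene-loss events on
a species phylogeny, reconstructing how nuclear-receptor (NR) orthogroup
repertoires grew along that phylogeny, screening molting-cycle
transcriptomes for regulators whose expression peaks just before ecdysis,
and comparing the ligand-binding-domain (LBD) structures of expanded NRs
against a reference receptor panel.

This vignette explains each model, its assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data generators
do and do not emulate.

# Loss mapping by Dollo parsimony

## Model and assumptions

A gene family is assumed to be gained **once** and lost any number of
times (Dollo's law is a good approximation for complex protein-coding
genes: re-evolving a lost receptor is far less likely than losing it
twice). Under that assumption the most parsimonious history is fully
determined by the observation pattern:

* the **origin** is the most recent common ancestor (MRCA) of the leaves
  where the family is present;
* the **loss edges** are the stems of the maximal subtrees, inside the
  origin's subtree, that contain no present leaf and at least one absent
  leaf.

Missing observations (`?`) are compatible with either state, and subtrees
containing only missing leaves contribute **no** loss edge. Two
consequences follow. First, the loss count is a *lower bound* — "lost at
least N times" — which is the scientifically safe direction when absence
of evidence is entangled with evidence of absence. Second, ambiguous
internal states resolve toward presence, deferring losses tipward; the
test suite verifies against an independent dynamic-programming oracle
(and, on tiny trees, exhaustive edge-subset enumeration) that the
resulting count equals the true minimum over all single-gain labelings.

## The reliability rule

Draft-genome absence is often annotation dropout. Before mapping,
`apply_reliability_rule()` keeps an absence only when **every** leaf of
the same group (by default each leaf is its own group; in practice a
genus or family tag) is absent; otherwise the cell is demoted to missing.
"Closely related species" is operationalized as the configured group tag
because no formal definition exists at this granularity; the
`min_group_size` knob (default 1) lets users require corroboration from
at least *k* congeners.

## Per-clade attribution

`losses_by_clade()` counts a loss edge toward a named clade only when the
edge lies strictly inside the clade's subtree; an edge on the clade's own
stem is attributable to the clade's ancestor, not its interior, and falls
under `"other"`. For disjoint clades the per-clade counts plus `"other"`
always sum to the total.

## The packaged fixture

The package ships a taxon-level tree (14 tips; named clades Tylenchina,
Rhabditina, Rhabditina_Tylenchina, Rhabditida, Nematoda) and the
*ecr*/*usp*/*hr3* presence pattern: *ecr* absent exactly in
Caenorhabditis, Tylenchomorpha, Strongyloididae and Alloionematidae, *usp*
absent in those plus Panagrolaimidae, Cephalobomorpha and Strongylida.
Dollo mapping gives three independent *ecr* losses (two inside
Tylenchina, one inside Rhabditina), and every *ecr*-lacking taxon also
lacks *usp* — the joint pattern motivating the hypothesis that *usp* loss
precedes *ecr* loss.

# Ancestral orthogroup content

## The coverage rule

`assign_og_origin()` places an orthogroup at the named ancestor whose set
of major taxa **exactly** matches the taxa represented in it (one gene
suffices to represent a taxon). This mirrors the all-taxa criterion used
with OrthoFinder outputs: an orthogroup with members from all five major
nematode taxa existed in the nematode common ancestor. Orthogroups whose
coverage matches no named node are **patchy**; they are excluded from
multi-taxon ancestors and counted per taxon, preserving the lower-bound
reading of ancestral contents. Whether patchiness reflects loss or
orthology-inference error cannot be resolved at this level, which is why
we do not attempt a parsimony correction here.

`reconstruct_node_content()` evaluates content at every named node
(within-taxon "ancestral" content requires only one gene from that
taxon), and reports gains/losses **along the chain of named ancestors**
(root → Rhabditida → Rhabditina+Tylenchina → taxon → species) rather than
against the immediate topological parent; with coverage-based content the
named-ancestor chain is nested, so losses appear only at the species
level, where content means "has at least one gene".

# Homolog screening

The screen consumes precomputed tabular search results; no sequence
search runs in-process. Thresholds follow the screening protocol the
package automates: forward hits strictly below e-value 1e-20, reciprocal
hits strictly below 1e-10 ("less than" is implemented as strict
inequality). Best hits are ordered by e-value, then higher bitscore, then
lexicographic subject ID, making results deterministic; mutual-best logic
enforces one-to-one pairs. `iterative_screen()` reuses genes accepted in
round *r−1* as queries against species still lacking an accepted gene,
stopping when a round adds nothing or after `max_rounds` (default 3 —
both stopping rules are active because empirically a third round adds
little, but new families may behave differently). Clade validation
accepts a candidate only if it descends from the smallest gene-tree node
containing all reference members and that node's bootstrap support
reaches `min_support` (default 70; "high support" is never quantified in
practice, so it is a knob). If the references only resolve at the root,
validation degrades to accept-all and is flagged low-confidence rather
than silently passing.

# Expression clustering and pre-molt selection

## Preprocessing

Replicates at one stage are arithmetically averaged; split gene models
are summed per time point (`collapse_replicates_and_merge()`).
`smooth_windows()` replaces each interior time point with the mean of the
w-point window centred on it (default w = 3) and drops the endpoints —
e.g. points at 0, 1, 3 h yield a smoothed value anchored at 1 h. This
damps the developmental-timing jitter of independently staged samples and
commutes with affine rescaling of the values.

## Fuzzy c-means

`fuzzy_cmeans()` implements the standard alternating updates
(memberships `u_ik = 1/Σ_j (d_ik/d_jk)^{2/(m−1)}`, centers
`v_k = Σ u_ik^m x_i / Σ u_ik^m`) with fuzzifier m = 2, convergence when
the objective changes by less than 1e-6, and a 500-iteration cap —
matching common package defaults so results are comparable with e1071
usage (the test suite cross-checks against `e1071::cmeans` on separable
blobs). Points at zero distance from a center take membership 1 there.
Rows are z-scored before clustering (exposed as a flag, default on):
clustering raw abundances would group genes by expression level, while
the biological signal here is profile *shape*. Cluster counts of 5–7 are
the practical range for molting time courses; genes are assigned crisply
by maximum membership before candidate extraction because downstream
counts are per-gene.

## Selecting pre-molt clusters

Cluster selection was historically visual; `select_premolt_clusters()`
makes it algorithmic. A cluster is selected when its z-scored center
*peaks* in the pre-molt window `(molt − delta × preceding intermolt
interval, molt]` (delta = 0.25) for more than `majority` = 0.5 of the
molt events. "Peaks" is evaluated per molt cycle: the center's maximum
over the cycle must fall inside the window and exceed the center's mean.
This is deliberately stronger than requiring *any* local maximum in the
window: centers of clusters that collect incoherent genes shrink toward
the grand mean, and after z-scoring their residual noise wiggle has local
maxima almost everywhere, which would select them spuriously. For the
same reason a **coherence guard** requires a selected cluster's center to
retain at least `min_coherence` = 0.3 of its members' median profile SD;
empty clusters are never selected. With these two choices the planted
pre-molt genes in the synthetic benchmark (30% planted, noise SD = 0.1 of
amplitude, c = 6) are recovered with mean recall ≥ 0.9 and contamination
≤ 0.1 over ten seeds, which the acceptance suite asserts.

# Regulator screen

Per-species candidate sets are intersected through orthogroups: an
orthogroup survives only if it holds a candidate gene from **every**
species, so adding a species can only shrink the set (monotonicity is
property-tested). The representative species' genes in surviving
orthogroups are filtered to transcription factors by a fixed Pfam panel
(34 DNA-binding/TF domains including Hormone_recep PF00104 and zf-C4
PF00105) at e-value < 1e-5; Pfam version suffixes are ignored when
matching since annotation pipelines mix versioned and unversioned
accessions. Nuclear receptors are counted as distinct genes after isoform
collapse (default: strip a trailing `.N`/`.tN`/letter suffix; an explicit
isoform map overrides the heuristic) so that alternative transcripts do
not inflate counts.

# Structural comparison

## Superposition and TM-score

`kabsch_superpose()` computes the least-squares proper rotation via SVD,
excluding reflections even for degenerate noise configurations.
`tm_score()` uses the standard length-normalized form
`TM = (1/L_norm) Σ 1/(1 + (d_i/d0)²)` with
`d0 = 1.24 (L_norm − 15)^{1/3} − 1.8` clamped below at 0.5 Å (the clamp is
active for all L ≤ 21), and maximizes over superpositions by refining on
close-pair subsets at growing distance cutoffs. Exact numeric agreement
with external TM-align binaries is **not** promised — the contract is
self-score 1, rigid-motion invariance, and rank agreement (same fold
scores above different fold), all asserted in the tests.

## Alignment heuristic

`align_structures()` is a deliberate simplification of full TM-align:
correspondences are seeded from gapless sliding offsets and fragment
superpositions (fragment length min(L, 40)), then refined by alternating
superposition, per-pair similarity `1/(1 + (d_ij/d0)²)`, and a monotone
dynamic-programming alignment with a flat gap penalty of 0.6 (free end
gaps; ties resolve toward the diagonal so the traceback is
deterministic), up to 20 iterations per seed; the best TM over seeds is
reported. The DP inner loop is implemented in C++ for speed. Gap penalty
and fragment length are exposed but fixed defaults; they were chosen once
as round values in the range used by fragment-based aligners, and the
synthetic-fold benchmark (below) is insensitive to them.

Normalization defaults to the **reference** chain length, reflecting
classification against a fixed receptor panel; `norm = "query"` is
available because per-query normalization is the other defensible
reading when chains differ in length. Length filtering removes LBDs of
150 residues or fewer (min_len = 151) before comparison, excluding
truncated domains.

## Classification

`classify_against_references()` computes the full query × reference score
matrix, assigns each query to its argmax reference (ties break to the
lexicographically first reference ID and are flagged), and bins per-query
scores against a designated reference at a fixed width of 0.02. Failed
alignments leave `NA` cells which are excluded from the argmax.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* each stage assumes,
with ground truth attached:

* `gen_presence_matrix()` — single-gain, no-regain evolution with
  per-edge loss probability and missing-data corruption of absences. A
  `regain_rate` knob exists purely to probe the Dollo assumption's
  failure mode. Default study conditions in the analysis drivers: 500
  families, loss rate 0.08/edge, 10% hidden absences.
* `gen_orthogroups()` — origins drawn over named ancestors, members
  thinned per species; "clean" orthogroups keep each descendant taxon
  covered so the planted origin is recoverable by construction.
* `gen_expression_timecourse()` — Gaussian expression bumps peaking at a
  fixed offset before each molt (sharp pre-molt peaks rather than
  sinusoids, matching observed molting-cycle profiles), additive Gaussian
  noise (SD as a fraction of amplitude), values clipped at zero.
  Background genes are flat or peak at random phases.
* `gen_structure_pair()` — noisy rigid copies of idealized Cα folds (a
  three-helix bundle and a β-meander, 160 residues), random proper
  rotations, isotropic coordinate noise.
* `gen_hit_tables()` — reciprocal best e-values below 1e-25 for planted
  ortholog pairs, decoys a fixed factor worse; e-values are reported to
  two significant digits as in tabular search output, so near-equal
  decoys can tie with true hits and steal the rank deterministically —
  this is what makes recall degrade measurably as the decoy factor
  approaches 1.

What passing these benchmarks does **not** show: real genomes violate the
single-gain assumption through horizontal transfer and deep paralogy;
real absence calls are correlated with assembly quality rather than
independent per cell; real expression noise is heteroscedastic, phase
jitter between individuals stretches time rather than adding amplitude
noise, and molt timing itself varies; real protein folds differ by
flexible loops and domain motions, not isotropic jitter. The synthetic
results validate the *inference machinery*, not the biological
conclusions on any particular dataset.

# Determinism and problem sizes

Every stochastic routine takes an explicit integer seed and restores the
caller's RNG state; identical configuration and seed give byte-identical
pipeline outputs (asserted in the tests). The test and acceptance suites
run at desk scale by design: Dollo oracle checks on 500 random trees of
4–12 leaves, clustering benchmarks at 300 genes × 41 time points with
c = 6, hit-table screens at 10–20 genes with tens of decoys, and
structure benchmarks at 160-residue chains with 100 seeded trials —
sizes chosen so the full statistical contract is exercised in minutes
while remaining faithful to the regimes the methods target.

# Known limitations

* Dollo mapping cannot see a loss that is "rescued" by missing data
  covering the whole lost clade, and merges losses on sister edges into
  one event — both are consequences of reporting the minimum.
* The coverage rule for ancestral content ignores within-orthogroup gene
  counts; expansions inside one taxon do not move origins.
* The iterative screen trusts the hit tables it is given; it cannot
  rescue orthologs absent from them (e.g. from a better assembly of the
  same species).
* Fuzzy c-means converges to local optima; the packaged seeds give
  reproducible, not globally optimal, partitions.
* The structural aligner is sequence-order-dependent (no non-sequential
  alignments) and its TM-scores should be compared within this package,
  not mixed with scores from other implementations.
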