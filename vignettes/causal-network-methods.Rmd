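---
title: "Methods: eQTL-anchored causal gene network reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL-anchored causal gene network reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

causanet reconstructs a directed gene regulatory network from paired
genome-wide genotypes and expression profiles measured on the same
individuals, for a binary phenotype contrast (e.g. metastatic vs
non-metastatic tumors). Orienting gene–gene edges from observational
expression data alone is fundamentally limited: many directed structures are
likelihood equivalent. The package's central idea is to use naturally
occurring DNA variation as a causal anchor — germline genotype can influence
transcript abundance but never the reverse — and to keep the search tractable
by working on small, phenotype-relevant subproblems whose local conclusions
are then reassembled globally.

The pipeline has four steps, each exposed as ordinary functions and run
end-to-end by `run_pipeline()`.

## Step 1: discriminative module discovery

A module is a connected gene set on a molecular interactome (pooled
protein–protein/protein–gene interactions supplied as an edge list). Each
interaction between genes $x_1$ and $x_2$ receives two statistics:
$r_1 = |\mathrm{cor}(x_1, x_2)|$ over all samples (cooperative potential) and
$r_2 = |\mathrm{cor}_1 - \mathrm{cor}_2|$, the absolute difference of the
within-group Pearson correlations (condition-specific rewiring). Both are
converted to percentile ranks $q_1, q_2$ over all interactions (fraction of
values $\le$ the value, so the maximum is 1), and the *bonding score* is
$\max(q_1, q_2)$: an interaction is interesting if it either coexpresses
strongly overall or changes its coexpression between phenotype groups.

From every seed gene, `expand_module()` grows a module greedily: frontier
interactions are sorted by decreasing bonding (ties broken lexicographically
by gene id, for determinism), only candidates above the bonding cutoff
`r_cut` (default the 0.90 percentile) are eligible, and a candidate joins iff
the two-sample Hotelling $T^2$ test of the enlarged member set separates the
phenotype groups at `alpha` (default 0.05). Expansion stops when no eligible
candidate passes, or at `size_cap` (default 10) members. The cap matters
twice: large modules rarely share driving eQTLs, and Step 3's cost grows
quickly with subnetwork size. Note the gate tests the *joint* member set, not
the candidate's marginal contribution, so strongly discriminative modules can
absorb a few neutral neighbors before the cap; this is intentional — those
genes are carried along and sorted out later by the network stages.
Singleton results are dropped and identical member sets deduplicated;
overlapping modules are kept (they create the repeated pairwise evaluations
Step 3 relies on).

Numerical details: $T^2 = \frac{n_1 n_2}{n_1+n_2} d' S^{-1} d$ with the
pooled covariance $S$; $p$-values use the exact $F$ transform on
$(p,\, n_1+n_2-p-1)$ degrees of freedom, which requires $p < n_1+n_2-1$
(candidates violating it are ineligible). A computationally singular $S$ gets
a ridge of $10^{-6}\,\mathrm{tr}(S)/p$ — rare with the size cap and
reasonable sample sizes.

## Step 2: module-level eQTL mapping

Each module's expression submatrix $Y$ (samples × members) is regressed on
candidate SNP dosages. Candidates are the union over members of SNPs within 1
Mb of the gene's transcription start or stop; because module members spread
across the genome, one member's cis SNPs act as trans candidates for the
others. Selection uses sparse partial least squares (SPLS): direction
surrogates are soft-thresholded first singular vectors of $X'Y_{res}$,
$c_j = \mathrm{sign}(z_j)(|z_j| - \eta \max|z|)_+$, the active set is the
union of surrogate supports over $K$ components, and a plain PLS refit on the
active set gives coefficients (rows outside the active set exactly zero).
SPLS is preferred over the LASSO here because it selects whole groups of
collinear SNPs — linked markers enter together instead of one arbitrary
representative.

Selection is two-staged to keep design matrices small: per-chromosome SPLS
first, then a combined SPLS on the union of stage-1 selections. $\eta \in
[0,1)$ and $K$ are tuned by 5-fold cross-validated prediction error
(tie-breaks toward larger $\eta$, then smaller $K$ — the sparser model);
$\kappa$ is fixed at the standard 0.5, which is what the singular-vector
surrogate corresponds to. Monomorphic SNPs are dropped before fitting.
Genotypes enter SPLS numerically (additive 0/1/2 coding).

Because linked SNPs distort network topology downstream, selected SNPs are
grouped into linkage blocks by complete-linkage hierarchical clustering on
basepair distance, cut at 500 kb (the conventional linkage-block scale), and
each block is reduced to the member with the strongest module association by
one-way MANOVA on genotype groups (Wilks' lambda; ordinary ANOVA when the
module has one gene; monomorphic members get $p = 1$; ties resolve to the
smaller position).

## Step 3: eQTL-anchored Bayesian subnetworks

For every *pair* of modules, a Bayesian network is learned over the union of
their genes plus their eQTL representatives. All nodes are scored as Gaussian
(dosages keep their additive 0/1/2 coding) with the BGe marginal likelihood:
a conjugate normal–Wishart prior with $\alpha_\mu = 1$, $\alpha_w = d + 2$,
prior mean at the sample mean, and scale $t I$ with
$t = \alpha_\mu(\alpha_w - d - 1)/(\alpha_\mu + 1)$. This score is
*score-equivalent* — Markov-equivalent DAGs tie exactly — so expression data
alone cannot orient a chain. The genetics enters as a structural blacklist:
no edge may point into an eQTL node, and eQTLs may not connect to each other.
Conditional on an anchored genotype parent, previously equivalent
orientations now differ (reversing a downstream edge creates a new collider),
which is precisely how the anchors propagate orientation down the graph.
Module membership and the physical interactions themselves are deliberately
not encoded as constraints.

Search is greedy hill climbing over add/delete/reverse moves (acyclicity
checked incrementally, parent sets capped at 4, equal-scoring moves resolved
in a fixed lexicographic order), from the empty graph plus 5 random restarts
drawn under the constraints. Local scores are memoised by (node, parent set)
across restarts and module pairs. Every learned directed gene–gene edge
$i \to j$ increments a causation matrix entry $c_{ij}$; with $n$ overlapping
modules a within-module pair is re-evaluated in many different contexts, so
$c_{ij}$ accumulates the reproducibility of that local causal call. Pairs are
processed with per-pair seeds derived from the master seed, so results are
identical for any processing order or worker count.

## Step 4: Beta-random-field ranking and assembly

The causation matrix is read as a round-robin of pairwise contests, and genes
are ranked the way dominance hierarchies are inferred in social-network
analysis. Each supported pair ($c_{ij} + c_{ji} \ge 1$) gets a control
potential with conjugate posterior $P_{ij} \sim
\mathrm{Beta}(1 + c_{ij},\, 1 + c_{ji})$, $P_{ji} = 1 - P_{ij}$. Pairs with
no causation record carry no orientation evidence and are pinned at the
neutral 0.5 (a sampled Uniform potential for the vast majority of
never-evaluated pairs would otherwise flood the rank objective with random
constraints and drown the real ones). Direct odds $O_{ij} =
P_{ij}/(1-P_{ij})$ are augmented with transitive information through each
common support-graph neighbor $h$: the path odds $T_{ihj} =
P_{ih}P_{hj}/(1 - P_{ih}P_{hj})$ are kept only when $> 1$ (weak transitive
evidence is not followed; only one intermediate, $R = 1$, is supported), and
the overall odds are $W_{ij} = \max(O_{ij}, \max_h T_{ihj})$. The enhanced
potential $P^*_{ij} = W_{ij}/(W_{ij} + W_{ji})$ restores the antisymmetry the
ranking step needs; with no transitive input it is a strictly monotone,
0.5-fixing transform of $P_{ij}$, so it induces exactly the same rankings.

A rank order is scored by the number of lower-triangle entries of the
permuted $P^*$ exceeding 0.5 (a lower-ranked gene claiming to regulate a
higher-ranked one). `anneal_rank()` minimizes this count by simulated
annealing over random transpositions starting from a seeded random
permutation (the input row order must not leak information), with Metropolis
acceptance, geometric cooling ($T_0 = 1$, factor 0.9995, up to 20 000
proposals) and early stopping after 5 000 non-improving proposals or at cost
zero. The schedule was chosen so the annealer reproduces the exhaustive
minimum on small instances (see the oracle tests); the slower 0.9995 cooling
is needed on rugged random fields where a fast schedule freezes early.
Uncertainty is handled by repetition: `K = 100` fields are sampled from the
Beta posteriors, each is enhanced and annealed (per-replicate seeds), and
genes get consensus coordinates — mean and SD of their positions — with the
final integer order by ascending mean (ties by gene id). Every supported pair
becomes a global edge oriented from the higher- to the lower-ranked gene.
Unlike the simple majority rule ($c_{ij} > c_{ji}$, ties unresolvable), the
ranking can orient tied pairs from the transitive context; the majority-rule
network is also returned as a baseline.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a tumor genetical-genomics
study at desk scale: two phenotype groups; genotypes in Hardy–Weinberg
proportions (default MAF 0.3) organized in tight linkage blocks (non-anchor
SNPs copy their block anchor with a 5% per-sample redraw), blocks separated
by more than the 500-kb cut; expression generated from a linear-Gaussian
structural equation model over a known DAG — per module a chain
$g_1 \to \cdots \to g_5$ with effect 0.8, one cis-eQTL driving the head gene
with effect 1, a phenotype shift of 0.5 on the head gene (about one residual
SD, propagating down the chain; this is what makes modules discriminative),
residual SD 0.5 — plus background noise genes and decoy SNP blocks inside the
cis windows. Optional condition-gated edges (active in one group only)
emulate disease-specific rewiring for the differential-coexpression score.
Gene labels are assigned by a seeded random permutation so that, as with real
gene symbols, alphabetical order carries no causal information — several
deterministic tie-breaks in the pipeline are lexicographic, and with ordered
labels they would silently reconstruct the truth. The interactome is the
undirected truth skeleton plus random decoy pairs (default 300, so genuine
interactions populate the top bonding decile the way a small fraction of a
real interactome would).

Defaults follow the study conditions the package is validated under: 6
modules × 5 genes, 30 background genes, n = 200 samples. At these sizes the
full pipeline (two runs: eQTL-anchored and expression-only) completes in a
few minutes on one CPU; the test suite uses smaller instances for everything
except the end-to-end recovery check.

What the generator does *not* emulate: array-level measurement noise and
normalization artifacts, realistic linkage-disequilibrium decay, population
structure, copy-number effects, feedback loops (the truth is a DAG), or
hub-like interactome topology. Passing the recovery tests therefore shows the
machinery is sound under its own assumptions — linear effects, Gaussian
noise, faithful cis anchors — not that real tumor data will reach the same
concordance.

## Design choices on genuinely open points

* **Bonding combination**: `max(q1, q2)` operationalizes "high overall
  coexpression OR large between-group disparity"; a product or mean would
  require both signals at once, which contradicts the disjunctive intent.
* **Beta field scope**: only pairs with causation records are sampled;
  unsupported pairs stay at 0.5 (rationale above).
* **$P^*$ normalization**: $W_{ij}/(W_{ij}+W_{ji})$, the unique choice here
  that restores antisymmetry after the asymmetric max-combination of
  transitive odds; it preserves all 0.5-threshold comparisons.
* **Missing genotypes**: per-SNP rounded-mean imputation at load keeps
  dosages in {0,1,2}; anything more elaborate (EM, haplotype-aware) is out of
  scope and can be done upstream.
* **Sample order**: canonicalized to the expression file; all stages assume
  aligned columns thereafter.
* **Chromosome names**: matched verbatim as strings across files; a naming
  mismatch surfaces as an explicit error rather than a silently empty join.
* **Search and priors in Step 3** (the score family is standard but the
  search is unstated territory): hill climbing with 5 restarts and parent cap
  4 keeps the ~40-node worst case tractable while exhausting small problems;
  the exhaustive-search tests pin the score's behavior independently.
* **One DAG per pair**: only the single best-scoring DAG of each module pair
  contributes counts; pooling several high-scoring DAGs would blur the
  Beta-posterior interpretation of $c_{ij}$ as repeated-contest outcomes.

## Known limitations

Orientation quality degrades when modules share no eQTL support (the
expression-only mode exists exactly to quantify that gap); the Hotelling gate
admits neutral genes into strongly discriminative modules (see Step 1); the
BGe-with-blacklist treatment of dosages as Gaussian is an approximation to a
proper conditional-Gaussian mixed score; and the rank consensus can flip
weakly supported pairs when the causation matrix contains contradictory
cycles. The concordance evaluation only judges orientation of edges present
in both networks — it deliberately says nothing about edge discovery
sensitivity.
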