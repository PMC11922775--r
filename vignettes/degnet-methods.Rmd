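---
title: "degnet methods: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{degnet methods: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

## 1. Scientific setting and model

`degnet` analyzes a differential expression experiment through a
heterogeneous gene–pathway network. The motivating setting is ciliary
cell biology: knockdown of a primary-cilium receptor perturbs many
transcripts, and the question is how that perturbation relates to a
specific anchor process — autophagy — through the pathway annotation
structure.

The model has four layers:

1. **Membership graph** M: an undirected bipartite graph whose nodes are
   the significant genes (adjusted *P* < α) plus every pathway that
   contains at least one of them, with an edge for each membership.
   Pathways left with no significant member are dropped; genes belonging
   to no retained pathway are dropped and reported.
2. **Pathway projection**: pathways joined by edges weighted by the
   number of shared significant genes.
3. **Ranked gene list**: genes ordered by a network statistic (here,
   node-removal centrality).
4. **Protein layer**: VxPx ciliary-targeting motifs in the anchor
   receptor's sequence, independent of the network.

### Connectedness

Connectedness is global efficiency:
$$E(M) = \frac{1}{\binom{n}{2}} \sum_{u < v} \frac{1}{d(u, v)},$$
with $1/d = 0$ for unreachable pairs. Unlike average path length, this is
well defined on disconnected graphs — important because node removal is
exactly the operation that disconnects them. A graph with fewer than two
nodes has efficiency 0 by convention.

### Node-removal gene centrality

The score of gene $g$ is $E(M - g) - E(M)$, deleting only the gene node
(a pathway emptied of significant members stays in the graph as an
isolated node, so the node set shrinks by exactly one). Negative scores
mark **central** genes: removing them lowers efficiency. Genes are
ranked ascending by score, ties broken by higher degree, then
alphabetically — a deterministic total order.

### Ordered enrichment

For a ranked list of $L$ genes in a universe of size $N$ and a pathway
with $K$ members, let $x_k$ be the overlap within the top $k$. The
pathway's *P* value is
$$p = \min_{1 \le k \le L} \Pr\big(X \ge x_k\big), \quad X \sim
\mathrm{Hypergeom}(N, K, k),$$
computed via `stats::phyper(x_k - 1, K, N - K, k, lower.tail = FALSE)`,
with the minimizing depth reported as `k_star` and Benjamini–Hochberg
correction across pathways (`stats::p.adjust`). Taking the minimum over
prefixes rewards pathways whose members concentrate at the top of the
ranking; it is a scan statistic, so *p* is anti-conservative as a pure
hypergeometric tail — the BH-adjusted `q` should be read comparatively,
not as a calibrated error rate.

### Pathway prioritization

Three parameters per pathway, each in $[0, 1]$:

- **Impact similarity.** Pathway impact is
  $\mathrm{mean}_g\big((-\text{score}_g)\cdot|\log_2\mathrm{FC}_g|\big)$
  over significant members, so central (negative-score) genes with large
  expression changes dominate. Similarity is
  $1 - \text{minmax}(|{\rm impact} - {\rm impact}_{\rm anchor}|)$ with
  the min–max taken over non-anchor pathways; the anchor itself is 1 by
  convention, and a degenerate (constant) divergence vector maps to all
  1s.
- **Connection strength.** Raw strength is
  $0.5\,\mathrm{Ochiai}(P, A) + 0.5\,/(1 + \mathrm{hops}(P, A))$, where
  Ochiai is $|P \cap A| / \sqrt{|P||A|}$ over significant members and
  hops is the membership-graph distance to the anchor (pathways in other
  components score 0). Values are min–max normalized excluding the
  anchor; the anchor is fixed at 1.
- **Key-regulator index.** Eigenvector centrality of the weighted
  pathway projection, computed per connected component and rescaled so a
  component's maximum equals its dominant eigenvalue divided by the
  global maximum eigenvalue; isolated pathways score 0.

The **combined coefficient** is the weighted mean (default weights 1/3
each, required to sum to 1 within $10^{-9}$). Pathways are ranked by
descending combined coefficient, ties by descending similarity then
name; the anchor is excluded from the ranking, and `passes_threshold`
requires the coefficient to be **strictly greater** than 0.35.

### Gene–anchor chains

`min_node_distance()` runs BFS in the membership graph from the target
pathway and reports the minimum hop count over the supplied source
genes, plus one explicit chain. When several chains tie, the
lexicographically smallest is returned: the smallest-named source gene
among those at minimum distance, then at every step the smallest-named
neighbor whose distance to the target decreases by one. This makes the
output deterministic and stable across igraph versions.

### Coordinated-expression scan

Walking a ranked gene list, each gene contributes
$\mathrm{sign}(\log_2\mathrm{FC})$ (genes with zero fold change
contribute 0 but still advance the position). A **zone** is a maximal
run of window start positions $i$ where the windowed slope
$(S_{i+w} - S_i)/w$ satisfies $|{\rm slope}| \ge s_{\min}$ with constant
sign; runs of the same sign separated by a gap shorter than $w/2$ are
merged. A run over starts $i_1..i_2$ is reported as trace span
$[i_1,\; i_2 + w]$ with strength
$|S_{\rm end} - S_{\rm start}| / (\text{end} - \text{start})$, sorted by
descending strength.

### VxPx motifs

`scan_vxpx()` matches `V.P.` with a look-ahead regular expression so
**overlapping** occurrences are all reported (positions are 1-based,
end = start + 3). In this implementation "x" is unrestricted — it may
itself be V or P — because the biological motif definition constrains
only positions 1 and 3. `design_mutant()` applies a plan mapping V→A and
P→A by default, with optional tetramer-keyed overrides (e.g.
`c(VLPG = "ALQG")`), refuses plans whose replacement still matches
`V.P.`, detects conflicting substitutions at the same position, and
re-scans the mutant to verify every targeted motif is gone.

## 2. Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `alpha_deg` | 0.05 | standard adjusted-*P* significance cut; strict `<` |
| `anchor_name` | `"autophagy"` | the anchor process of the study design |
| `weights` | (1/3, 1/3, 1/3) | no a priori reason to favor a component |
| `combined_threshold` | 0.35 | listing cut for reported pathways; strict `>` |
| `overlap_weight` | 0.5 | equal blend of gene overlap and hop proximity |
| `scan_window` | 10 | resolves zones ≥ ~10 genes without tracking noise |
| `scan_slope` | 0.6 | ≥ 8 of 10 genes moving the same way |
| `seed` | 1 | full determinism of any stochastic step |

Synthetic-generator defaults (`synthetic_spec()`): 500 genes, 40
pathways of 10–30 members, background overlap rate 0.25, 30% of genes
significant with effect size 1.5, a near pathway built from half the
anchor's members, an anchor-disjoint far pathway, a regulator gene
inserted into ~70% of pathways, and a planted coordinated block of 30
genes starting at rank 41 of the significant-gene reference ordering.
These are fixed study conditions, not tuning knobs.

## 3. What the generator emulates — and what it does not

The generator emulates the *structural* signals the pipeline is meant to
detect: a pathway that is genuinely close to the anchor (half-shared
membership), one that is genuinely remote (no shared genes, hence
membership distance ≥ 4), a high-membership hub gene, and a
rank-localized stretch of same-direction expression. Adjusted *P* values
are drawn uniformly below α for significant genes and above α otherwise,
so `filter_significant()` recovers the generator's significance flags
exactly.

It does **not** emulate realistic expression distributions
(no negative-binomial counts, no *P*-value histograms from real tests),
pathway ontology structure, gene–gene correlation, or batch effects. The
planted zone is defined relative to a recorded *reference ordering* of
the significant genes (`truth$zone$order`), not the pipeline's
centrality ordering — a generator cannot dictate where genes land in a
computed ranking, so zone recovery is evaluated by scanning the
reference ordering.

## 4. Numerical choices

- **Unreachable pairs** contribute 0 to efficiency rather than being
  excluded from the average, so fragmenting the graph always lowers the
  statistic.
- **Power iteration with diagonal shift.** Eigenvector centrality is
  computed by power iteration on $B = A + \sigma I$ with
  $\sigma = \max_i \sum_j A_{ij}$, converged to $10^{-10}$ in the
  max-norm, and the eigenvalue recovered as $\lambda = v_{\max} -
  \sigma$. The shift is required: on bipartite-like projections the
  unshifted iteration oscillates with period 2 and never converges. The
  shift changes eigenvalues but not eigenvectors. The test suite
  cross-checks against `igraph::eigen_centrality` as an independent
  implementation.
- **Deterministic tie-breaking everywhere**: gene ranking (score, then
  degree, then name), pathway ranking (combined, then similarity, then
  name), enrichment (q, then p, then name), chains (lexicographic).
  Outputs are byte-identical across runs with the same seed.
- **Strict inequalities** at both thresholds (`p_adj < alpha`,
  `combined > 0.35`) as stated, so boundary values are excluded.
- **Exact hypergeometric tails** via `phyper` rather than normal
  approximation; the tests verify against exhaustive subset enumeration
  up to $N = 12$.

## 5. Design decisions on open points

- The ±1 scan is run over the full centrality-ranked significant gene
  list (not the central-only subset), so peripheral genes can form
  detectable down-zones; any ordering can be supplied explicitly.
- Similarity to the anchor is a single min–max quantity of absolute
  impact divergence, not a signed two-sided measure, because the blend
  needs a $[0,1]$ component and the sign is recoverable from the raw
  impacts.
- The anchor pathway is excluded from the ranked output: its three
  components are 1 by convention, so including it would only report the
  convention back.
- Default mutagenesis is V→A and P→A at motif positions 1 and 3 only;
  overrides exist because some constructs (e.g. VLPG→ALQG) also change
  "x" positions.

## 6. Problem sizes and limitations

The package is designed for universes of order $10^2$–$10^4$ genes and
tens to hundreds of pathways. Node-removal centrality recomputes
all-pairs BFS per gene, so it is $O(G \cdot n \cdot m)$; at the default
synthetic size (≈ 160 network nodes) a full run takes a few seconds, and
it remains practical to a few thousand significant genes.

**Known limitation of the zone detector.** The windowed-slope rule with
its fixed constants (window 10, slope 0.6, merge gap < 5) has a
per-window false-fire probability of about 11% under random ±1
background ($\Pr(|2\,\mathrm{Bin}(10, \tfrac12) - 10| \ge 6)$). When a
chance 8-of-10 same-sign run in the flank directly adjoins a genuine
zone, the merged detection extends past the true boundary. On simulated
studies at the default size this blurs a detected boundary by more than
one window in roughly 10% of runs, even though the median boundary error
is only ~4 ranks. Zone spans should therefore be read as approximate;
shrinking the window sharpens boundaries but raises the false-fire rate
further. The detector implements the stated rule verbatim rather than
adding post-hoc boundary refinement.

Enrichment *P* values are scan statistics (see §1) and the generator's
simplifications (§3) mean recovery rates measured on synthetic data are
upper bounds on what real, correlated expression data would yield.
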