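---
title: "Methods: meta-path scoring, cluster hierarchies and link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-path scoring, cluster hierarchies and link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hclink)
```

## The problem

Experimentally validated ncRNA-disease associations are sparse: databases
record a few thousand links among hundreds of ncRNAs and thousands of
diseases, and contain only positives - an absent link means *unknown*, not
*absent*. hclink ranks the unknown ncRNA-disease pairs of an attributed
heterogeneous network by how strongly the network's structure and node
attributes support them, so that laboratory validation can concentrate on
the top of the ranking.

The input is a network with typed nodes (ncRNAs, diseases, and any number
of *task-relevant* types such as genes or proteins), typed undirected
edges, and per-type attributes (numeric or categorical). Two node types are
designated *targets*; links are predicted only between them, and only among
nodes present in the input (a transductive setting - no generalization to
unseen nodes is attempted).

## Stage 1: degree of certainty via meta-path similarity

A *meta-path* is a sequence of node types joined by declared edge types,
running from the ncRNA type to the disease type; its instances are concrete
node sequences ("path sequences"). For a pair $(n, d)$ and a meta-path $P$
the score is

* 1 if some sequence of $P$ runs from $n$ to $d$ (the pair is connected
  along $P$; in particular every directly linked pair scores 1), and
* otherwise the maximum similarity between any sequence starting at $n$
  and any sequence ending at $d$.

Sequence similarity is the mean, over every attribute of every node
position of $P$, of a per-attribute similarity: for numeric attributes
$1 - |v_1 - v_2| / (\max_x - \min_x)$ with the range taken over the whole
network, for categorical attributes 1 if equal else 0. The pair's overall
degree of certainty $s(n, d)$ is the **maximum** over all meta-paths - a
fuzzy-OR: one confirming meta-path suffices. The assumption doing the work
here is network autocorrelation (guilt by association): nodes with similar
neighborhood attribute profiles tend to share interactions.

Node types that no meta-path touches would be invisible to the similarity,
so their attributes are first propagated: each on-path node receives the
mean (numeric) or mode (categorical) of the attributes of off-path nodes
reachable within `depth` hops through off-path nodes, appended as new
attributes (`<type>.<attr>_mean` / `_mode`). `depth = 0` disables
propagation; the default `depth = 2` confines the aggregation to nodes
close to the meta-path structure.

### Numerical and policy choices

* **Missing values** are never imputed; a comparison with a missing value
  is dropped from both numerator and denominator of the similarity mean
  (pairwise deletion). A sequence pair with no comparable attribute at all
  has similarity 0. This avoids penalizing sparsely annotated nodes.
* **Constant numeric attributes** (zero range) compare as 1 when both
  values are present: identical values are maximally similar, and the
  degenerate denominator never materializes.
* **Meta-path enumeration** is cycle-free at the type level and bounded by
  `max_len` edges (default 3). Both bounds guarantee termination and keep
  the instance count finite; realistic schemas put 1-2 intermediate types
  between the targets.
* **Sequence materialization** enumerates all simple paths per meta-path,
  depth-first with neighbors in lexicographic ID order, capped at
  `seq_cap` sequences per starting node (default 1000). The cap bounds the
  worst-case exponential blow-up; the lexicographic order makes any
  truncation deterministic, and a warning reports it.
* **Mode ties** during propagation resolve to the lexicographically
  smallest label, again for determinism.
* Whether the two sequences of a comparison may be the *same* sequence
  only matters when a sequence connects $n$ to $d$ - and then the score is
  1 by the direct-connection rule anyway, which is how the implementation
  treats it.

## Stage 2: a hierarchy of overlapping multi-type clusters

Pairs with $s \ge \beta$ (default grid values 0.3/0.4) are the *extracted
relationships*. Level 1 starts from one $1 \times 1$ cluster per retained
pair and greedily merges clusters in *cohesiveness order*: the cohesiveness
of a cluster $C$ is

$$h(C) = \frac{\sum_{(n,d) \in \text{retained}(C)} s(n,d)}
             {|\text{ncRNAs}(C)| \cdot |\text{diseases}(C)|},$$

the retained scores averaged over **all possible** pairs of the cluster
(absent pairs contribute 0 to the numerator but count in the denominator).
A level-1 merge is valid only if the union is a *biclique*: every pair of
the union must be retained. The scan repeatedly merges the best cluster
with its first valid partner, re-sorts, and stops at a fixpoint.

Higher levels drop the biclique constraint: a merge is valid when the
union's cohesiveness exceeds $\alpha$ (default grid values 0.1/0.2). One
pass over the sorted list defines one level - each cluster merges at most
once per level, unmerged clusters carry over - so every level-$i{+}1$
cluster contains a level-$i$ cluster and level sizes strictly decrease,
guaranteeing termination. Duplicated clusters (overlapping merges can
create them) are removed after each pass.

Where the ordering relation leaves ties ($h$ equal), they are broken by
fewer possible pairs, then by the lexicographically smallest member set:
the order is total, so the hierarchy is a deterministic function of the
scores and parameters.

Small $\alpha$ admits more merges per pass and deeper hierarchies of
larger, looser clusters; large $\beta$ admits fewer, purer bicliques.

## Stage 3: prediction

Each level $w$ is a predictor: a pair co-occurring in at least one cluster
of $L_w$ receives the aggregate of the cohesiveness values of its
containing clusters, ordered best-first:

* **max**, **min**, **avg** - as named;
* **ec** (evidence combination), $ec_1 = h_1$,
  $ec_m = ec_{m-1} + (1 - ec_{m-1}) \cdot h_m$, which rewards membership
  in several cohesive clusters and never falls below the maximum.

Pairs contained in no cluster get no row (evaluation treats them as score
0): the predictor is only defined through clusters. By default
already-known pairs are excluded from the ranked output, since the object
of interest is *new* associations; `exclude_known = FALSE` re-includes
them. Equal scores rank in (ncRNA, disease) lexicographic order so that
top-$k$ metrics are reproducible.

## Evaluation protocol

`make_folds()` partitions the known positive pairs (not nodes - the
setting is transductive) into seeded folds; each training network drops
the fold's direct target edges while keeping all nodes. Rankings are
assessed with:

* **TPR@k** - the fraction of held-out positives in the top $k$;
* **AUTPR@k** - the trapezoidal area under TPR@k for $k = 1..k_{max}$
  (default 5000), normalized by $k_{max} - 1$ so a single positive at
  rank 1 scores exactly 1. The normalization constant is a package choice;
  only comparisons computed with the same constant are meaningful.
* **ROC / PR with unknowns as negatives** - every non-positive candidate
  is assumed negative, ties are grouped into single steps (a constant
  ranking gives AUROC 0.5). Because the assumption is wrong for the
  unknown-but-true pairs, these areas support *relative* comparison only,
  and the return value carries that caveat.

Candidates missing from a ranking are appended with score 0 in
lexicographic order, so all metrics are defined for any $k$.

## The synthetic generator

`generate_network()` plants multi-type clusters: blocks of ncRNAs,
diseases and genes with dense intra-block connectivity (`p_gene = 1`,
`p_direct = 0.8` by default), sparse cross-block noise edges
(`p_noise = 0.02`), and correlated attributes - a numeric attribute per
type centered on the block index (spacing 1, noise `attr_sd = 0.1`) and a
categorical attribute equal to the block label (`flip_prob = 0.05`). The
defaults describe a clearly clustered regime in which block membership is
recoverable: attribute agreement inside blocks drives intra-block
similarity near 1 while the spaced means and distinct labels hold
cross-block similarity well below typical $\beta$ values. Generation is a
pure function of the seed.

What the generator does **not** emulate: the heavy-tailed degree
distributions of curated association databases, correlated annotation
missingness, multiple ncRNA subtypes with shared interactions, or edge
attributes. Passing recovery tests therefore demonstrate algorithmic
correctness under the stated planted model, not expected accuracy on
curated datasets.

## Problem sizes and test design

The test suite exercises the full pipeline on networks of roughly 10-60
nodes: large enough for multi-level hierarchies and non-trivial meta-path
structure, small enough that a brute-force reimplementation (enumerating
every simple path and evaluating the similarity definitions naively) can
serve as an oracle - the package's vectorized scorer is required to match
it exactly, not approximately. Invariants (direct pairs score 1, biclique
and nesting constraints, aggregator ordering, TPR@k monotonicity) are
checked property-style across a hundred seeded networks each.

## Known limitations

* Scoring all pairs is quadratic in the number of targets times the cost
  of the pairwise sequence-similarity matrices; the implementation is
  intended for networks up to a few thousand target nodes, not for
  genome-scale all-vs-all scans.
* Any pair connected to the other target type within `max_len` edges
  scores 1, so on densely connected networks the score distribution
  saturates at 1 and $\beta$ loses resolution; the clustering stage then
  carries the burden of discrimination.
* Edge attributes are loaded and preserved but do not enter the
  similarity, which is defined over node attributes only.
* The greedy, order-driven merging commits to its first valid merge; it
  is deterministic but not optimal, and no cluster-quality measure beyond
  cohesiveness is computed.
* Aggregated $\psi$ scores are rank scores, not calibrated probabilities.
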