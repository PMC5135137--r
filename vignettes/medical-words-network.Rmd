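---
title: "Word co-occurrence networks and community evolution: methods"
author: "medwordnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word co-occurrence networks and community evolution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medwordnet)
```

## The model

medwordnet treats a literature corpus as a sequence of time-binned
document collections and asks how the vocabulary's community structure
evolves. The unit of counting is always the document (abstract): a word
"occurs" in a document if it appears at least once, so all statistics are
document frequencies, and token multiplicity within a document is
deliberately discarded.

For one time bin holding $N$ documents, with $f(A)$ the number of
documents containing word $A$ and $f(A,B)$ the number containing both $A$
and $B$, the weight of the association between $A$ and $B$ is the
pointwise mutual information in bits:

$$\mathrm{PMI}(A,B) \;=\; \log_2 \frac{p(A,B)}{p(A)\,p(B)}
 \;=\; \log_2 \frac{f(A,B)\, N}{f(A)\, f(B)}.$$

PMI is zero when the words are independent and rises to the
self-information $-\log_2 p(A)$ when the two words always appear
together; because it is a ratio of probabilities it is insensitive to how
fashionable a topic is in absolute terms, which makes bins of very
different sizes comparable. When $f(A,B) = 0$ the quantity is undefined;
the package returns `NA` ("no edge") rather than $-\infty$, since edge
thresholding makes the distinction immaterial and non-finite weights
would poison downstream arithmetic.

The per-bin network keeps the words whose document frequency *strictly*
exceeds `min_word_count` and the edges between surviving words whose PMI
*strictly* exceeds `pmi_threshold_bits`. The corpus-scale defaults (2000
documents; 2.8 bits, with 4.0 as a sparser overview resolution) are tuned
to collections of millions of abstracts; for the synthetic corpora used
throughout the tests the thresholds are derived from the generator design
(below). We read the word threshold as a *document* count because every
other count in the construction is a document count; a raw-occurrence
reading would require token multiplicities the model never uses, but the
knob is exposed so either interpretation can be configured.

## Overlapping communities by clique percolation

Communities are extracted with the k-clique percolation method: a
k-clique is a set of $k$ pairwise-adjacent nodes, two k-cliques are
neighbors when they share $k-1$ nodes, and a community is the union of
all k-cliques connected through chains of neighbors. Unlike partitioning
methods, the covers produced this way may overlap — a word such as a
shared disease term can belong to two fields at once — which is the
property that motivates the method here.

Rather than enumerating every k-clique, `cpm_communities()` enumerates
maximal cliques once (igraph's Bron–Kerbosch) and joins two maximal
cliques of size $\ge k$ whenever they share $\ge k-1$ nodes; connected
components of that overlap relation yield exactly the percolation
communities. The equivalence holds in both directions: neighboring
k-cliques lie inside maximal cliques that inherit their $k-1$ shared
nodes, and two maximal cliques sharing $s \ge k-1$ nodes are bridged by a
pair of neighboring k-cliques built from those shared nodes. The naive
construction (enumerate all k-subsets, test cliqueness, BFS over the
adjacency relation) is retained in the test suite as an independent
oracle and the two agree exactly on hundreds of random graphs.

Edge weights never enter the percolation step: thresholding during
network construction is the single place where weights act, so the PMI
threshold plays the role of a resolution control and $k$ of a stringency
control.

### Choosing the critical k

Percolation theory motivates the selection rule: below a critical $k$ a
single giant community swallows most of the network and smears out its
structure. `select_critical_k()` scans $k$ upward from `k_min` (default
3; $k=2$ reduces to connected components and is rarely informative) and
returns the smallest $k$ at which communities exist but none reaches
`giant_fraction` of the graph's nodes. Two degenerate outcomes are
reported as statuses rather than numbers: `"giant_at_all_k"` (every $k$
that yields communities yields a giant one — e.g. a complete graph) and
`"no_communities"` (no $k$ in range yields anything — e.g. an edgeless
graph). A $k$ whose cover is empty is never selected, since choosing a
resolution at which nothing is visible would be vacuous. The giant
fraction is a genuine free parameter of the method; we default to 0.5
(a community is "giant" when it holds at least half the nodes, ties
counting as giant) and expose it in every interface.

In the multi-bin pipeline with `k = "auto"`, a critical $k$ is selected
per bin and the maximum across bins is applied to all of them: one
stringency for the whole timeline keeps communities comparable across
bins, and taking the maximum respects every interval's own resolution
requirement.

## Life-cycle events

Covers in consecutive bins are matched by Jaccard overlap
$|A \cap B| / |A \cup B|$, keeping pairs at or above `overlap_threshold`
(default 0.1). The match relation is then resolved greedily — best score
first, with a deterministic tie-break on the member sets that is
invariant under time reversal — into a forest of stars, so that each
component is one-to-one, one-to-many, or many-to-one. Events follow
mechanically: unmatched predecessors disappear, unmatched successors
appear, one-to-many is a split, many-to-one a merge, and one-to-one pairs
are classified by the size ratio $|B_{t+1}|/|A_t|$: growth above
$1 + \tau$, contraction below $1/(1+\tau)$, otherwise continuation, with
`growth_tolerance` $\tau = 0.25$ by default. The contraction bound is the
reciprocal of the growth bound (not $1 - \tau$) so that reversing the
direction of time maps growth to contraction exactly; the test suite
checks this mirror symmetry, along with merge/split and
appearance/disappearance, on random instances.

The matcher is one defensible instantiation of community tracking — the
event taxonomy itself is standard, but no single matching procedure is
canonical — so all of its thresholds are configuration, not constants.

## The synthetic generator

`generate_corpus()` draws bag-of-words documents from planted topics:
each document belongs to one topic and includes each of that topic's
member words independently with probability `p_in`, plus each background
word with probability `p_bg`; an optional mixing probability lets a
document draw from a second topic, creating genuinely shared words.
Bernoulli presence (rather than a document-length model) is the minimal
generative model faithful to the analysis, because every statistic the
pipeline computes depends only on document-level presence. Generation is
reproducible from a stated RNG (Mersenne-Twister, inversion,
rejection sampling) so corpora are byte-identical across platforms under
a fixed seed.

For two equal-share topics the expected within-topic PMI is
$\approx -\log_2(\text{topic share})$ (1 bit at half share) and
cross-topic PMI is negative, which the suite verifies by Monte Carlo
against these closed forms.

The preset scenarios (`preset_scenarios()`) script the event taxonomy:
two static topics; a merge of two six-word topics into their union; the
reverse split; a disappearance; and two topics overlapping in exactly one
shared word. Defaults — 250 documents per topic per bin, `p_in = 0.9`,
`p_bg = 0.01`, a 40-word background vocabulary, two five-year bins — are
chosen so that member words are near-saturated within their topic
(expected document frequency $\approx 225$, standard deviation $\approx
5$) while background words stay far below any sensible node threshold.
Every preset also carries two stable ten-word *context* topics besides
its focal ones. This is a deliberate design constraint: with only two
equal topics the larger community necessarily holds half the graph, which
the $\ge$-giant rule flags at every $k$, and critical-$k$ selection —
which presumes a many-community network, as real corpora are — would
degenerate.

For scenario-derived corpora, `scenario_pipeline_config()` sets the node
threshold to one fifth of the smallest per-topic document count (well
below the expected member frequency $p_{\text{in}} \cdot
n_{\text{docs}}$, far above expected background frequency $p_{\text{bg}}
\cdot N$) and the edge threshold to 0.5 bits, between the within-topic
(~1–2 bits) and cross-topic (negative) PMI regimes. These follow from
the generator's parameters, not from any particular realization.

What passing the recovery tests does and does not show: the generator
plants near-clique topics with sharp PMI contrast and no polysemy,
Zipfian frequency structure, vocabulary drift, or length variation.
Recovery of planted communities and events at Jaccard 1 under these
conditions validates the machinery — counting, weighting, percolation,
tracking — not the harder claim that any particular real corpus resolves
into clean communities; on real data the thresholds and the giant
fraction must be chosen with the resolution trade-off in mind.

## Numerical and determinism choices

* PMI is computed in double precision straight from the count ratio; the
  suite checks it against an exact reduced-fraction evaluation to
  $10^{-12}$. Serialized edge lists round to 6 decimals so files are
  byte-comparable.
* All orderings are total and deterministic: vertices sorted by word,
  edges by word pair, communities by size (descending) then by sorted
  membership, events by community index with a reversal-invariant
  tie-break. Two runs of the same configuration produce byte-identical
  outputs, recorded as MD5 checksums in the run manifest.
* Degenerate inputs are defined, not errors: empty corpora yield empty
  networks and covers with a warning; an empty graph yields a zero
  connectivity report with an `NA` mean distance; a single-node largest
  component likewise has `NA` distance.
* Pair counting restricts the quadratic pair space to the words that
  already passed the node threshold before counting, which bounds memory
  on wide corpora.

## Problem sizes in the test suite

Property tests run at sizes where independent brute-force oracles are
exact and fast: maximal-clique covers are cross-checked by subset
enumeration on graphs up to 13 nodes, percolation covers by direct
k-clique enumeration up to 25 nodes (200 random graphs), connectivity
reports by Floyd–Warshall up to 40 nodes (100 random graphs), counting
tables by double-loop recounts on bins up to 500 documents and 60 words,
and end-to-end recovery on all five presets across 20 seeds. These sizes
are the package's own validation design: large enough to exercise every
code path and overlap pattern, small enough that the oracles themselves
are beyond doubt.

## Known limitations

* Tokens are unigrams; multi-word terms are out of scope, as is
  lemmatization, named-entity recognition, or MeSH mapping. Tokenization
  is configurable (case folding, punctuation stripping, minimum length,
  stopwords) precisely because no single convention is canonical.
* No smoothed or shifted PMI variants (PPMI, PMI$^k$) and no
  within-document proximity windows; associations are document-level.
* No weighted clique percolation; weights act only through the edge
  threshold.
* The tracker offers no community age/survival statistics beyond the
  event list, and no joint-network matching variant.
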