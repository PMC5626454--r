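---
title: "Predicate-pattern topics in RDF knowledge graphs: model and methods"
author: "predtopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicate-pattern topics in RDF knowledge graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predtopics)
```

## The problem

Clinical and biomedical text pipelines increasingly emit RDF triples
`<subject, predicate, object>`, with each triple tagged by the domain
(e.g. a postsurgical complication) whose reports it came from. For any
given domain the number of distinct *predicates* is far smaller than the
number of concepts, so the predicate layer is a natural place to look for
structure: predicates that relate the same groups of concepts, in the same
or in different domains, tend to describe one clinical theme. `predtopics`
partitions the predicates of one or more such graphs into hierarchical
"topics", summarises each topic, validates topic composition against an
external gold standard, and turns each topic into an executable SPARQL
query by crawling its similarity graph.

## Predicate profiles and neighbouring patterns

Every predicate $P_i$ is profiled by the exact subject set $S_i$ and
object set $O_i$ observed in the graph, together with its degree (the
number of triples using it). Two predicates are *neighbours* when they
exhibit at least one of five patterns:

* **Share patterns** — $S_i \cap S_j \neq \emptyset$ (subject share),
  $O_i \cap O_j \neq \emptyset$ (object share), or both
  (subject–object share).
* **Connection patterns** — a concept that is object of one predicate and
  subject of the other (path connectivity), possibly closing back so that
  $(x, P_i, y)$ and $(y, P_j, x)$ both exist (cycle connectivity). A cycle
  always implies a path, and both are read as non-empty set intersections,
  not whole-set equality: a single linking concept is a connection.

The similarity of a pair combines the two families:

$$ s(P_i, P_j) \;=\; \max\!\big(s_\text{share},\; s_\text{conn}\big), $$

where $s_\text{share} = w_{so}\,\tfrac{J(S_i,S_j) + J(O_i,O_j)}{2}$ when
both subject and object sets overlap, $w_s J(S_i,S_j)$ or $w_o J(O_i,O_j)$
for a single-sided share, and $s_\text{conn}$ is $w_\text{cycle}$ or
$w_\text{path}$ for connection-only pairs ($J$ is the Jaccard index). The
default weights $w_{so}=1$, $w_s=w_o=0.8$, $w_\text{cycle}=0.6$,
$w_\text{path}=0.5$ order the evidence: overlapping both concept sets is
stronger than one-sided overlap, which in turn beats mere chaining. The
similarity is symmetric, bounded in $[0,1]$, equals 1 for identical
profiles, and never decreases when a shared concept is added. Collecting
all pairs gives the symmetric predicate similarity matrix with unit
diagonal that drives everything downstream.

This weighted-maximum form is this package's own definition: the pattern
families themselves are standard, but published descriptions of this
pipeline defer the numeric combination to earlier work without printing
it, so a concrete, configurable rule was fixed here once
(`pnp_config()`).

## Hierarchical fuzzy c-means

Each predicate is represented by its row of the similarity matrix
restricted to the node being split, and fuzzy c-means (Bezdek updates,
fuzzifier $m = 2$) clusters these profile rows under Euclidean distance.
Silhouette width over the hardened (argmax) assignment selects the number
of clusters: $k$ is scanned from 2 to `k_max` (default
$\min(10, n-1)$), the best silhouette wins with ties to the smaller $k$,
and the node is not split at all when even the best silhouette falls below
the acceptance threshold $\delta$ (default 0.4; splits on real cohort-scale
runs typically score 0.45–0.65, so 0.4 admits them with margin).

The recursion stops at a node when (a) the triples carried by its
predicates number at most the machine-capacity threshold $\alpha$, (b) no
candidate split clears $\delta$, or (c) a split fails to separate the
items. The package default for $\alpha$ is one third of the total triple
count. Note an arithmetic consequence of rule (a): three first-level
clusters can never *all* exceed $\lceil T/3\rceil$, so a three-way first
split can recurse into at most two of its children at that default.
$\alpha$ is a per-cluster capacity an operator chooses; analyses that
expect every intermediate cluster to be revisited should set it at the
scale of the intended *topics*, which is why the bundled cohort-scale
fixture records $\alpha = \lceil T/6 \rceil$ as part of its analysis
protocol.

Numerical choices worth knowing:

* FCM restarts 5 random initialisations (all derived deterministically
  from the seed) and keeps the best final objective; the objective is
  non-increasing within every run and the winning run's initial membership
  matrix is stored, so the trajectory can be replayed independently.
* Items at zero distance from a centroid receive all their membership
  there (split evenly over exact ties).
* Hardening is argmax with ties to the lowest cluster index; silhouette
  uses the convention that singleton-cluster items contribute 0.
* "Fuzzy predicates" — items whose membership reaches $\beta$ (default
  0.3) in two or more clusters — are recorded on every split; they mark
  predicates bridging topics and are excluded from crawling by default.
* Whether silhouette should be computed on profile-row distances or on
  $1 - s$ directly is genuinely open; profile rows were chosen because
  they give FCM and the silhouette the same geometry, and the choice is
  confined to one helper.

## Topic signatures and gold-standard validation

Each leaf topic is summarised by the domains its predicates span, its top
5 predicates by degree, and up to 2 predicates unique to it (appearing in
no other leaf). Composition is validated against a binary
subject-by-domain indicator table: Pearson correlation on binary columns
(the phi coefficient) gives a domain–domain correlation matrix, each
domain's top-3 partners are extracted, and a topic is called *supported*
when every pair of domains it covers is a top-3 partner pair in either
direction. "Correlation" is not further specified in the source
literature; phi is the standard choice for binary co-occurrence and
reproduces the top-3-partner reading. The concordance flag is a reporting
aid, not a hypothesis test. Gold standards whose domain granularity
differs from the analysis (e.g. an abscess column and a separate leak
column) are reconciled through an explicit `domain_map` rather than any
guessed merge.

## Query generation

Every leaf induces a cluster graph: its predicates as nodes, edges
weighted by similarity. The crawler starts at the predicate with the
highest degree (ties lexicographic), visits all unvisited neighbours of
the current node in descending similarity, then moves to the just-visited
neighbour of highest similarity that still has unvisited neighbours. The
narrative this follows leaves the "move on" rule after a hub is exhausted
open; the fallback here — the earliest-visited node with unvisited
neighbours — guarantees deterministic full-component coverage. Traversed
edges with similarity $\ge t$ survive; kept nodes are those incident to a
kept edge plus the start node, so raising $t$ never enlarges the query
graph.

Each kept predicate becomes one triple pattern `?s <p> ?o`. Variables are
unified along the kept edges' patterns — subject share merges subject
variables, object share merges object variables, path connectivity chains
the upstream object into the downstream subject, with share taking
precedence over chaining on the same edge. Pattern evidence is pairwise
and marginal, so a chain of merges can demand a joint solution the data
does not contain; each candidate merge is therefore applied only if the
joined query still has at least one solution on the source graph (checked
with the package's brute-force matcher). Emitted queries are plain
conjunctive `SELECT DISTINCT` — no `OPTIONAL` or `FILTER` — and are
satisfiable on their source graph by construction. A `strict` mode unifies
instead on raw concept-label equality across all kept pairs, for users who
want instance-level joins.

## Concept ranking front end

Upstream of the graph work, concepts are ranked per domain by smoothed
pointwise mutual information over case counts:
$\log_2\!\big(((N_{co} + \varepsilon)\,N) / (N_c N_o)\big)$ with
$\varepsilon = 0.01$, and triples are kept only when subject or object is
a top-$K$ concept (default $K = 60$) of the triple's own domain. The score
is zero under independence (up to smoothing), strictly increasing in
$N_{co}$, and with $\varepsilon = 0$ returns $-\infty$ for never-co-occurring
pairs, which sort last. Published worked values for this quantity do not
always reproduce from their printed inputs (typesetting of the formula and
counts that exceed their own marginals); the implementation scores
whatever counts it is given, warning when $N_{co} > \min(N_c, N_o)$.

## The synthetic generator

`synth_spec()` / `synth_kg()` generate multi-domain graphs with a planted
two-level predicate hierarchy, plus matching co-occurrence counts and a
gold-standard indicator table, so the whole pipeline is testable without
any external data. The design separates the two levels of structure:

* **Objects carry topic identity.** Each triple's object comes from its
  leaf topic's pool with probability `p_share` (covering draws: the pool
  is cycled through before repeating), from the super-cluster pool with a
  small fixed weight, else it is a fresh private concept. With
  `p_share = 1` every within-topic pair shares objects.
* **Subjects carry super-cluster cohesion.** Subjects come from the
  super-cluster pool with probability `p_share_super`, binding all of a
  super's topics together.
* **Connections.** Cross-topic pairs within a super are chained through a
  bridge concept with probability `p_conn`, planting path-connectivity
  patterns.
* **Noise.** At rate `noise_rate`, a private object of one predicate is
  reused as the subject of a single extra triple on a predicate of a
  *different* super-cluster. Each such unit creates exactly one spurious
  cross-super path while barely perturbing either profile. This blurs
  fine partition structure at the whole-graph level (where all predicates
  compete) but vanishes when clustering recurses inside a super-cluster,
  which is what makes a two-level hierarchy — rather than one flat
  partition — the detectable signal, mirroring how heterogeneous
  real cohorts behave.

`cohort_fixture()` is the canned cohort-scale spec: 6 domains with 13,
13, 10, 21, 12 and 14 predicates (83 in all), a planted hierarchy of 3
super-clusters splitting 3/3/2 into 8 topics, a per-predicate draw count
chosen so the unique-triple total centres on 1210, and a recorded capacity
$\alpha = \lceil T/6\rceil$. Indicator tables are drawn from a
probit-threshold Gaussian copula whose latent correlation follows how
strongly two domains share planted topics, so the gold-standard machinery
has a known target. What the generator does *not* emulate: the heavy
per-domain skew of real cohorts (one domain dominating the triple count),
OWL schema axioms, and extraction noise in the triples themselves — so
passing recovery tests show the clustering works on cleanly planted
share/connection structure, not that any particular clinical corpus would
yield eight tidy topics.

## A worked run

```{r example, eval = FALSE}
gen <- synth_kg(cohort_fixture(seed = 1))
sim <- similarity_matrix(gen$graph)
fit <- hfcm(sim, gen$graph, alpha = gen$spec$alpha, seed = 1)
fit          # 3 intermediate clusters, 8 leaf topics
summary(fit)
sigs <- topic_signatures(fit, gen$graph)
rep_ <- gold_correlation(gen$indicators)
concordance_check(sigs, rep_)
q <- generate_sparql(crawl(cluster_graph(fit$leaves[[1]], sim, gen$graph),
                           t = 0), gen$graph)
cat(q$text)
```

Test and acceptance runs use exactly these problem sizes: pattern oracles
on random graphs of up to 200 triples and 20 predicates, fuzzy c-means
against an independent textbook implementation on 12-item instances,
silhouette against brute force at $n \le 10$, and hierarchy recovery on
20 cohort-scale fixture seeds.

## Known limitations

* The similarity definition is one defensible member of a family; weights
  are configurable but results in this package are reported at the
  defaults.
* Silhouette-based model selection inherits silhouette's bias toward
  well-separated spherical groups in the profile-row geometry.
* The crawler explores one connected component (the start predicate's);
  isolated predicates of a topic appear in the query only when $t = 0$
  keeps their edges.
* The RDF readers cover N-Triples, a practical Turtle subset and basic
  RDF/XML; no OWL reasoning or subclass closure is performed, and blank
  node property lists / collections are not parsed.
* Literal datatypes and language tags are dropped on ingest; only the
  lexical form is kept.
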