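---
title: "Mining multipartite co-occurrence networks from biomedical full text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multipartite co-occurrence networks from biomedical full text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnet)
```

## The problem and the model

A large body of literature on a biological system -- here, the genetics and
pharmacology of *Cannabis sativa* -- contains thousands of scattered
statements connecting genes to the chemicals they synthesize and chemicals
to the therapeutic properties they influence. `litnet` condenses a full-text
corpus into an undirected, weighted, multipartite network over four node
types (gene, chemical, therapeutic property, strain) in which an edge
records that two entities co-occur in the same paragraph more often than
chance, with the supporting paragraphs retained as edge provenance.

The paragraph is the unit of evidence. Authors group related statements
into paragraphs, so two entities named in one paragraph are far more likely
to stand in a real relationship than two entities merely sharing an
article. For entities $a$ and $g$, presence/absence over the $N$ corpus
paragraphs gives the 2x2 table $(k_{11}, k_{12}, k_{21}, k_{22})$: both
present, only $a$, only $g$, neither.

**Association test.** Candidate edges are validated with the Dunning
log-likelihood-ratio collocation statistic. With $n_1 = k_{11}+k_{21}$
paragraphs containing $g$ and $n_2 = k_{12}+k_{22}$ without, and
$\ell(x,n,q) = x\log q + (n-x)\log(1-q)$ (taking $0\log 0 = 0$),

$$\mathrm{LLR} = 2\left[\ell(x_1,n_1,p_1) + \ell(x_2,n_2,p_2)
  - \ell(x_1,n_1,p) - \ell(x_2,n_2,p)\right]$$

with $x_1 = k_{11}$, $x_2 = k_{12}$, $p_i = x_i/n_i$ and $p$ the pooled
rate. The statistic is zero exactly at independence, symmetric in the two
entities, and asymptotically $\chi^2_1$ under the null, which supplies the
significance cut-off (3.8415 at $\alpha = 0.05$). Compared to Pearson's
chi-square, the likelihood-ratio form degrades gracefully in the sparse
regime that dominates co-occurrence data, which is why it is the standard
collocation statistic in corpus linguistics.

**Edge weight.** Each co-occurring paragraph contributes the product of the
two entities' in-paragraph mention counts; the edge weight is the sum of
these products over its provenance paragraphs. Multiplicity therefore
enters the weight only -- the contingency table sees presence/absence, so
one obsessively repetitive paragraph cannot manufacture statistical
significance, but repeated joint mention does raise the weight.

**Direction classes.** The ratio $r_a = k_{11}/(k_{11}+k_{12})$ is the
fraction of $a$'s paragraphs that also contain $g$. With a threshold
$\tau$: both ratios $\ge \tau$ is *bidirectional*, only $r_a$ is
$a \to g$, only $r_g$ is $g \to a$, neither is *undirected*. The graph
itself stays undirected; the class is an edge annotation. We chose
$\tau = 0.8$ ("most paragraphs mentioning $a$ also mention $g$") as the
operational reading of the conditional near-equality
$p(a) \approx p(a,g)$; it is exposed in the configuration because no
uniquely correct value exists.

**Admissible relations.** Mined edges exist only between gene-chemical and
chemical-property pairs. Same-type pairs and gene-property pairs are never
scored: the chemical layer mediates gene-to-property inference by design.
Strain-chemical edges are not mined at all; they enter through a curated
table of cultivar constituents (`add_strain_edges()`), carry weight 1 and
no association attributes. The installed
`extdata/strains_synthetic.tsv` is a synthetic nine-strain stand-in panel
for such a table, not measured chemical profiles.

## Entity recognition

The default tagger is a dictionary matcher over typed lexicons
(surface form, canonical name, entity type). Matching is greedy
longest-match, left-to-right and non-overlapping on the normalized token
sequence, so the gene name "cannabidiolic acid synthase" consumes its
tokens before the embedded chemical "cannabidiolic acid" can match. Ties
at equal length break by the fixed priority gene > chemical > property >
strain (rarer, more specific vocabularies win). Normalization lowercases,
maps hyphens to spaces and strips edge punctuation; there is no stemming
-- inflected property forms are stored as separate surfaces instead,
which keeps matching exact and auditable.

Model-based taggers (e.g. biomedical NER models running out of process)
plug in through `external_tagger_adapter()`, which routes any
span-producing function through the same normalization and canonical
lookup, so the dictionary matcher and an external model are
interchangeable behind one interface. The package deliberately bundles no
trained models: everything it ships is reproducible from text files.

**Language filter.** Non-English documents are dropped by a stopword-ratio
heuristic: at least 15% of the alphabetic tokens of title plus abstract
must be English function words. English prose is saturated with such words
(typically 30-60%), while other languages share essentially none of the
list, so the two populations separate cleanly; the threshold is
configurable (`stopword_ratio_min`). We use this in place of a
language-identification model because it is deterministic,
dependency-free and inspectable.

## Lexicon expansion by word embeddings

Therapeutic-property vocabularies are open-ended; a manually curated seed
list misses synonyms the literature actually uses. `train_skipgram()`
learns skip-gram vectors with negative sampling on the corpus itself, and
`expand_terms()` returns, for each seed, the vocabulary terms within a
cosine-similarity radius. Defaults: dimension 100, window 5, `min_count`
5, 5 epochs, similarity threshold 0.7, top 10 neighbors per seed. These
are conventional word2vec settings; on corpus-linguistic grounds none is
sharply identified, so all are configuration parameters.

Two design choices matter more than the numeric defaults. First,
training is single-threaded with a seeded generator: identical inputs give
bit-identical vectors (parallel word2vec trades this away; we do not).
Second, adjacent token pairs occurring at least `bigram_min_count` times
(default 20) are merged into single tokens before training, so multi-word
properties like "anti inflammatory" embed as units. The expansion output
is a review file, not an automatic lexicon update -- a human accepts or
rejects candidates before they are matched, preserving the curation step
that keeps the property vocabulary honest.

## The synthetic corpus generator

`synthetic_spec()`/`generate_corpus()` produce corpora with exact ground
truth so every stage is testable offline. Per paragraph, each entity is
included by an independent Bernoulli draw at its base rate; a designated
dependent pair instead draws from a 2x2 joint distribution whose
both-present cell is `joint_boost` times the independence product (capped
at the smaller marginal). Included entities receive mention counts from a
fixed-count or shifted-geometric model and are embedded, shuffled, in
filler text whose vocabulary is disjoint from every lexicon surface -- so
the dictionary matcher recovers the planted mention stream exactly, and
edge weights can be checked to equality rather than approximately.

Defaults emulate entity statistics at realistic density: base rate 0.1
per paragraph, geometric mention counts on $\{1,2,\dots\}$ with $q=0.5$
(mean 2), ~12 filler tokens per paragraph. What the generator does *not*
emulate is language: there is no syntax, no ambiguous surface forms, no
near-miss strings unless requested. Passing tests therefore establish the
counting, testing and graph machinery exactly, and the matcher's contract
on clean input -- they say nothing about NER accuracy on real prose,
which is governed by the lexicon (or external tagger) a user supplies.

## Numerical and degenerate-input choices

* $0 \log 0 = 0$ throughout the LLR; the statistic is clamped at zero
  against floating-point undershoot. A zero marginal (an entity in no
  paragraph) is an error, not a zero score.
* Independence-structured tables evaluate to exactly 0 up to double
  precision; agreement with an independent `dbinom`-based oracle is
  maintained to 1e-9 relative (with a unit floor for near-zero scores,
  where ratios are ill-posed).
* Ties in matching break by surface length first, then type priority;
  matching is deterministic.
* Counting is order-independent: any permutation of paragraphs yields an
  identical, deterministically sorted counts object, and rebuilds produce
  byte-identical exports.
* Empty paragraphs advance the paragraph total $N$ (they are evidence of
  absence); documents with no body yield no paragraphs but survive
  ingestion.
* Degree filtering is single-pass by deliberate choice: nodes below the
  threshold are removed, then local degrees are recomputed, so survivors
  may fall below the threshold afterwards -- reproducing the progressive
  manual-filter workflow in which the analyst raises the threshold
  stepwise and watches local degrees shrink. `iterate = TRUE` gives the
  k-core-style fixed point instead. Queried anchors are protected by
  default so a query can never delete its own subject.
* The heatmap reports edge weights by default; `values = "degree"`
  fills existing-edge cells with the product of endpoint local degrees,
  covering the node-degree reading of such plots.

## Permissive versus strict edge retention

By default every scored pair becomes an edge, carrying its significance
flag, LLR and direction as attributes (`mode = "permissive"`); weight-1
edges are genuine literature signals worth inspecting, and pruning is a
display decision. `mode = "significant_only"` builds the pruned graph for
users who want the test to gate the topology. No multiple-testing
correction is applied by default; Bonferroni over the scored pairs is
available (`correction = "bonferroni"`). These mirror the two defensible
readings of how a permissively built literature network should treat its
own validation statistic.

## Problem sizes used by the test suite

The shipped tests run entirely on generated data: LLR oracle agreement on
1,000 random tables; type-I calibration on 500 null corpora of 2,000
paragraphs (statistical stages driven from the generator's ground-truth
mention streams, whose exactness the full-text tests establish
separately); planted-pair recovery through the complete text pipeline on a
5,000-paragraph corpus with joint-occurrence boost 8; and structural
invariants on repeated random builds. These sizes give the calibration
check roughly +-2.5 percentage points of binomial resolution at the 99%
level and saturating power for the planted pairs.

## Known limitations

* Co-occurrence is not causation, and no relation semantics ("precursor",
  "inhibits") are extracted; the provenance paragraphs exist precisely so
  a reader can judge each edge.
* Dictionary NER misses surface forms absent from the lexicon and cannot
  disambiguate polysemous names; the adapter seam exists for stronger
  taggers.
* Paragraph granularity misses cross-paragraph relationships and dilutes
  very long paragraphs.
* The significance test assumes paragraphs are exchangeable units;
  heavily templated corpora (e.g. many near-duplicate abstracts) violate
  this and inflate co-occurrence.
* Embedding expansion on small corpora is noisy; the human review step is
  not optional in practice.

## A minimal worked run

```{r, eval = FALSE}
library(litnet)
spec <- synthetic_spec(
  entities = data.frame(
    canonical = c("cbdas1", "cbd", "thc", "analgesic"),
    etype = c("gene", "chemical", "chemical", "property"),
    base_rate = 0.1),
  n_docs = 20, paras_per_doc = 30,
  dependent_pairs = data.frame(e1 = "cbd", e2 = "analgesic",
                               joint_boost = 8),
  seed = 9)
gen <- generate_corpus(spec)
net <- mine_network(gen$corpus, gen$lexicon)
summary(net)
planted_recovery_report(gen$truth, net$associations)
sub <- query_network(net, "cbd")
heatmap_matrix(sub, "chemical", "property")
```
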