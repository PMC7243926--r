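---
title: "Methods: POS-weighted MRF retrieval over dataset metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: POS-weighted MRF retrieval over dataset metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Dataset discovery portals describe each dataset by short unstructured
metadata — a title and a description. Queries are natural-language requests
("Find data on T-cell homeostasis related to multiple sclerosis …"), and
relevance is graded: a record is *relevant* (2) when it covers all key
concepts of the query with a relationship between them, *partially relevant*
(1) when the key terms appear without such a relationship, and *not relevant*
(0) otherwise. `posmrf` implements retrieval, expansion, entity-based
re-ranking and evaluation for this setting.

# The retrieval model

All language-model scorers use Dirichlet smoothing,
$f(t, D) = \frac{tf(t,D) + \mu P(t\mid C)}{|D| + \mu}$, over a per-field
collection model. The MRF family scores

$$ r(Q,D) = \sum_{c \in \{F,O,U\}} \theta_c \sum_{q \in c} \lambda(q)\, w(q)\,
\log f(c, q, D), $$

with unigram cliques $F$, adjacent ordered-pair cliques $O$ and unordered
pair cliques $U$ over the query terms. The POS-MRF weights each term by a
constant $\lambda$ per part-of-speech class (nouns 0.5970, plural nouns
0.2265, past-participle verbs 0.3065, past-tense verbs 0.2260, adjectives
0.3730, adverbs 0.1040, singular proper nouns 0.8930, all other classes 0).
Two exact reductions anchor the implementation and are asserted by the test
suite: with $\lambda \equiv 1$ the POS-MRF is the plain MRF, and with
$\theta = (1,0,0)$ the MRF is Dirichlet query likelihood.

## Parameters and defaults

| parameter | default | rationale |
|---|---|---|
| $\theta_F, \theta_O, \theta_U$ | 0.8, 0.1, 0.1 | the model's stated heuristic setting |
| $\mu$ | 2500 | the standard Dirichlet LM default; the source system does not state one |
| ordered window | 1 | adjacent bigram, the practical instantiation of sequential dependence |
| unordered window | 8 | the conventional full-dependence window |
| field weights | 0.5 / 0.5 | both fields queried simultaneously; whether the original system summed or maximized is unknowable, so the combination is a config choice and the default is an even sum |
| $\lambda$ of a pair clique | mean of member $\lambda$s | $\lambda$ attaches to terms; the mean is the symmetric lift to pairs |
| out-of-collection floor | $P(t\mid C) = 1/(L+1)$ | keeps every potential finite while preserving order |
| expansion weights | 0.9 / 0.1 | the stated original/expanded query weighting; they enter as per-term multiplicative weights on clique contributions, and expansion terms participate only in $F$ cliques (they arrive as an unordered bag) |

Verb base/gerund forms deliberately fall into the "other" class
($\lambda = 0$): the weight table defines values only for the seven classes
listed, and this materially changes scores for queries phrased imperatively.

## The POS tagger

No Penn-Treebank tagger is available in the supported dependency set, and the
tagger is by design a pluggable component (`pos_tag(tokens, tagger = …)`).
The shipped reference tagger is a compact lexicon + suffix-rule tagger that
reproduces the documented behaviours the model's error analysis relies on:
the bare imperative "search" tags NN (queries are not full sentences),
"obese" tags JJ, "data" NNS, "related" VBN. It is *not* a general-purpose
tagger; users wanting one can plug in any function from tokens to tags.

# Preprocessing and indexing

Indexing lowercases, splits on non-alphanumerics while **retaining
intra-token hyphens** ("t-cell" stays one token, matching how biomedical
query terms are used at retrieval time), removes a frozen base English
stopword list, and records 0-based positions over the post-stopword token
sequence. Stopword removal before positional indexing is a recorded decision,
not an inference. In query mode the stoplist additionally contains "find"
and "search". No stemming is performed. The embedding-training corpus uses a
*different*, minimal normalization — lowercase, all punctuation including
hyphens removed, stopwords kept — and the whole collection is merged into a
single token stream.

# Query expansion

Skip-gram embeddings with negative sampling are trained locally on the
collection (dimension 100; window 5, k = 5 negatives, 5 epochs, minimum
count 1 — hyperparameters the source method leaves unstated, frozen here for
reproducibility). Training is single-threaded with its own deterministic
generator, so a seed fully determines the vectors. Each extracted medical
entity contributes its individual word tokens as expansion seeds; each
in-vocabulary seed adds its five cosine-nearest neighbours (ties broken
lexicographically), deduplicated and with original query tokens removed, at
weight 0.1. An expansion colliding with an original term is dropped rather
than double-weighted.

# Entity extraction and re-ranking

Extraction is dictionary-based: surfaces are normalized (lowercase, hyphens
to spaces, a space at letter–digit boundaries, parentheses stripped keeping
content, whitespace collapsed) and matched greedily longest-first over token
n-grams (n ≤ 8, comfortably above the longest realistic entity phrase).
"Surface similarity" is realized entirely by this normalization — it is what
makes "Gialpha(1)" and "Gi alpha(1)" the same key — with no edit-distance
matching. Acronyms are detected Schwartz–Hearst-style from "long form
(ACRONYM)" patterns and inherit the long form's dictionary entry within the
unit. External annotator files (e.g. gene/chemical/disease taggers) merge
under priority rules: for GENE/CHEM/DISO types `pubtator > becas >
dictionary`, otherwise `becas > dictionary`; exact dictionary hits beat
partial ones; survivors never overlap. Entity identifiers are namespaced
(`source:id`) so cross-vocabulary id collisions cannot manufacture false
overlaps.

Re-ranking rescores the top-10 000 list by $s'_D = s_{max} n_D + s_D$ with
$n_D$ the count of unique entities shared with the query, then keeps the top
1000. Log-domain scorers produce negative $s_D$, for which the formula loses
its intended dominance (more shared entities ⇒ higher rank); scores are
therefore shifted per query (subtract the minimum, add 1) before the formula
whenever any score is non-positive. The shift is order-preserving within
each $n_D$ stratum and restores the dominance property, which the test suite
asserts on fuzzed inputs. Documents without extracted entities get
$n_D = 0$, not an error: metadata-poor records must remain rankable.

# Evaluation

Classical measures follow their textbook definitions (MAP counts grade ≥ 1
as relevant by default — configurable, since the threshold is a community
convention; NDCG uses linear gains and $1/\log_2(r+1)$ discounts). Unjudged
retrieved documents are non-relevant for classical measures but *unjudged*
for the inferred ones — that distinction is the point of inferred measures.

infAP estimates, for each sampled relevant document at rank $k$,
$E[P@k] = 1/k + \frac{k-1}{k}\cdot\frac{\text{judged above}}{k-1}\cdot
\frac{\text{rel above} + \epsilon}{\text{judged above} + 2\epsilon}$
($\epsilon = 10^{-5}$), averaged over sampled relevant documents and scaled
by the estimated total relevant. With stratified sampling metadata
(pool/sample sizes per stratum) judged counts and the total-relevant
estimate are inflated per stratum by pool/sample, the standard extended
estimator. Two numerical choices are deliberate: the $\epsilon$ smoothing is
applied only to *incomplete* strata (a complete stratum needs no smoothing),
which makes the complete-judgment reduction to AP exact rather than
$O(\epsilon)$-approximate; and the estimated relevant-above count is capped
at $k-1$ so single-query estimates stay in $[0,1]$. infNDCG inflates judged
gains in the ranking by inverse sampling rate and builds the ideal DCG from
inflated per-grade counts, poured fractionally over ranks so non-integer
estimated counts interpolate smoothly. Both estimators reduce exactly to
their classical forms under complete judgments and are checked for
approximate unbiasedness (±0.02 / ±0.03 at 50% sampling over 500 draws) by
the acceptance suite.

# The synthetic benchmark

`generate_collection()` builds the world every module is tested against:

* **topics** — five Zipf-shaped topic vocabularies mixed (55/45) with a
  Zipf-shaped shared background vocabulary; document lengths are negative
  binomial (mean 80, dispersion 20), titles 8 tokens;
* **synonym families** — ten pairs of interchangeable entity tokens. Each
  occurrence is wrapped in an "episode" of context words drawn from a block
  of mid-frequency *background* words dedicated to the family. Both members
  therefore share a near-identical context distribution while the context
  words keep mostly generic contexts, so skip-gram embeddings pull member
  pairs together — this is the planted structure that makes five-nearest
  expansion recover synonyms, and it is the property the acceptance suite
  measures;
* **graded relevance** — per query, 15 grade-2 documents contain both
  required entities co-mentioned adjacently (half phrase the first entity as
  its synonym partner, so a query phrased with member A has relevant
  documents phrased with member B); 20 grade-1 documents contain a strict
  subset of the combo, scattered without co-mention; 100 judged
  non-relevant documents complete the pool.

Default scale is 5000 background documents and 10 queries, chosen so
embedding training stays under a minute on one CPU. Everything is
deterministic given the seed.

What a green test does establish: the scorers implement their formulas
exactly (oracle equivalence), the reductions hold, the estimators are
calibrated, expansion recovers planted synonymy, and the pipeline composes.
What it does not establish: performance on real biomedical language — the
generator makes no attempt to emulate morphology, real entity nomenclature,
annotator noise, or the collection-scale frequency structure of a real
metadata corpus, and absolute metric values on the synthetic benchmark are
not comparable to values on any real collection.

# Known limitations

* The reference tagger is rule-based; POS-MRF behaviour with a full
  statistical tagger will differ in the weights assigned, though the scoring
  machinery is identical (and pluggable).
* External annotation services are out of scope; their outputs enter via
  annotation files only.
* The indexer holds postings in memory; the intended scale is the desk-scale
  benchmark (~10⁴ documents), not a production corpus.
* Score ties are broken by ascending document id everywhere, a reproducibility
  choice, not an IR judgement.
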