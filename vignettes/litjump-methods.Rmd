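---
title: "Scoring literature relevance and detecting rank jumps with litjump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring literature relevance and detecting rank jumps with litjump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litjump)
library(data.table)
```

## The problem

Early drug discovery depends on noticing, quickly, when the literature
starts treating a protein as relevant to a disease. Keyword searches have
two failure modes: they drown the reader in articles that name the disease
without touching its molecular biology (case reports, care guidelines), and
they miss articles about the relevant biology that never name the disease —
because the association is not yet established, or is understood from
context. `litjump` implements a data-driven scoring scheme that addresses
both: it learns the field's own vocabulary from the corpus, scores every
abstract by that vocabulary, turns article scores into weekly protein
rankings, and flags proteins whose rank improves by more than historical
experience can explain.

The pipeline has five stages, each exposed as ordinary functions and as a
staged command-line tool.

## Core proteins: anchoring the disease

Named-entity recognition with a curated synonym dictionary
(`corpus_mentions()`) finds protein and disease mentions at the document
level. For every protein a 2×2 contingency table of document counts (both /
protein only / disease only / neither) is tested with the one-sided
Fisher's exact test (`fisher_exact_p()`): the alternative is
over-co-mentioning, because a *positive* literature association is what
makes a protein disease-linked. The `K = 100` proteins with the smallest
p-values form the **core set** (`select_core_proteins()`); ranking uses raw
p-values (no multiple-testing correction) because only the order matters,
and ties break by protein id so the selection is reproducible.

Tokenization lowercases, strips punctuation at token edges, and preserves
Greek letters, digits, and internal hyphens (`"HOMA-IR"` → `"homa-ir"`).
Matching is longest-match, leftmost, non-overlapping, so `"insulin
receptor"` yields the receptor, not the hormone. Matching is
case-insensitive at the dictionary level; because the normalizer lowercases
the token stream, a per-synonym case flag would have nothing to act on, so
case sensitivity is offered only as a whole-dictionary switch.

## Semantic concepts: learning the vocabulary

All token windows of 2–6 words that occur in at least `min_df = 5`
documents, and that neither start nor end with a stopword, become candidate
n-grams (`extract_ngrams()`). Unigrams are excluded by default: single
words are covered by the entity dictionaries and mostly add noise.
Counting is by document presence, matching every downstream statistic.
An n-gram is kept when it is **over-represented** among disease-mentioning
documents (`disease_overrepresented()`): co-document count ≥ 3,
over-representation ratio

$$\mathrm{ratio} = \frac{\mathrm{co} \cdot D}{\mathrm{df} \cdot \mathrm{df}_{disease}} \ge 2,$$

and one-sided Fisher p ≤ 0.01. The supplement-level thresholds of the
original method are not public; these defaults are configurable and chosen
so that clearly disease-linked phrases pass with a wide margin while
independent phrases (ratio ≈ 1) are excluded.

Surviving n-grams are clustered into **semantic concepts** using two
similarity measures simultaneously:

* **String similarity** (`string_similarity()`) absorbs spelling variants
  and word rearrangement: tokens match when equal after roman/arabic
  numeral normalization (`"ii"` ↔ `"2"`) or within one edit for tokens of
  ≥ 4 characters; the score is the maximum one-to-one token matching
  divided by the longer phrase length. `"type 2 diabetes"` and
  `"diabetes type ii"` score 1.
* **Context similarity** (`context_similarity()`) captures phrases used in
  the same company: cell $(i,j)$ of the co-occurrence matrix holds the
  pairwise over-representation ratio $\mathrm{co}_{ij} D / (\mathrm{df}_i
  \mathrm{df}_j)$, and two n-grams are compared by the cosine of their
  `log1p`-transformed rows, excluding columns $i$ and $j$ themselves. The
  exclusion matters: two phrases that are never co-mentioned with *each
  other* (like a treatment phrase and a measurement phrase for the same
  hormone) can still be perfectly context-similar through shared third
  parties. The `log1p` damps the heavy right tail of ratios so that a few
  high cells do not dominate the cosine.

"Simultaneously" is realized as a union rule: an edge exists when either
string similarity ≥ 0.8 **or** context similarity ≥ 0.5, and carries the
convex combination $w = \lambda w_{string} + (1-\lambda) w_{context}$ with
$\lambda = 0.5$ (`build_similarity_graph()`). The combination rule is a
design choice of this package — the union keeps the two signals
independent routes into a cluster, and the mixture gives the flow
simulation a single weight.

The graph is clustered with the Markov cluster algorithm
(`mcl_cluster()`): self-loops equal to each node's maximum incident weight
(1 for isolated nodes), column normalization, then alternating expansion
(matrix squaring) and inflation (entry-wise power, default 2.0, followed by
re-normalization) until the maximum entry change falls below `1e-6` or 200
iterations pass; after every normalization the column sums are 1 to within
1e-9 and the final support components define a hard partition. Singleton
n-grams stay as one-member concepts rather than being dropped — a phrase
without variants is still a usable signal. Each concept is represented by
its most frequent member (ties break lexicographically). Note that
antonymic phrases legitimately share a concept (increased/decreased forms
of the same quantity): concepts capture *topical* relevance, not polarity.

## Weights and article scores

Each concept is weighted by how much more than chance it is co-mentioned
with the core proteins (`concept_weights()`). For core protein $p$,

$$\mathrm{pmi}_p = \log_{10}\frac{\mathrm{obs}_p}{\mathrm{df}_c\,
\mathrm{df}_p / D},$$

and the concept weight is the arithmetic mean over all $K$ core proteins.
Base 10 makes weights readable: weight 1 means co-mentioned ten times as
often as expected. A zero observed count is floored at $c_0 = 0.5$
documents — half the smallest observable count — so the logarithm stays
finite while still penalizing absence.

An article's score is the sum of the weights of the *distinct* concepts
whose member n-grams occur in it (`score_articles()`); a concept counts
once however many of its members match. The score is therefore exactly
explainable: `explain_article()` lists the matched members, each concept's
weight, and their sum.

## Protein relevance over time

A protein's weekly score is the **highest** score among that week's
articles mentioning it (`weekly_protein_scores()`) — one strong paper
matters more than many weak ones. The combined relevance at week $w$
(`combined_relevance()`) looks at the `W = 260` weekly scores ending at
$w$ (five years; missing weeks count 0), takes the `M = 40` largest, and
forms their weighted sum with linearly decreasing weights
$u_i = (M+1-i)/\sum_j (M+1-j)$, which sum to one. The highest week
contributes most ($u_1 = 40/820 \approx 4.9\%$), but no single week — a
conference's proceedings, say — can carry a protein alone: contributions
must be spread over time. Whether the original weighting was linear or
geometric is not public; linear is the default here and the scheme is
configurable. Proteins are ranked each week (rank 1 = most relevant, ties
by id), and the ratio of two ranks is reported as a fold change rounded
half-up to one decimal.

Benchmark recovery is evaluated with ROC curves whose AUC uses the
rank-sum (Mann–Whitney) formulation with midranks for ties
(`evaluate_roc()`).

## High-jumpers

A rank jump is `initial_rank − new_rank` (positive = improvement). Whether
a jump is surprising depends on where it starts: near the top a 3-place
jump is rare; at rank 15,000, jumps of thousands of places happen. The
null distribution is therefore *empirical and conditional on the initial
rank* (`build_jump_distribution()`): every consecutive-week rank change
before the evaluation week is an observation, and the null for initial
rank $r$ pools observations with initial rank within $\pm h(r)$,
$h(r) = \max(5, 0.1r)$ — tight at the top, wide down the list, smoothing
ranks with few direct observations. The evaluation week never contributes
to its own null. The one-sided p-value uses the add-one convention,

$$p = \frac{1 + \#\{\text{pooled jumps} \ge \text{observed}\}}{1 + N},$$

so no jump gets $p = 0$ and the estimator is valid (never
anti-conservative) under exchangeable noise — a property the test suite
checks directly on simulated histories. Only upward jumps are tested
(`weekly_high_jumpers()`); the modal weekly change is a 1-place slip
caused by someone else's jump and is reported descriptively, not tested.
P-values are not corrected across the weekly protein universe by default;
the weekly report is a short list for human triage, and the α level is
configurable.

## The synthetic corpus generator

Real corpora have no ground truth, so every recovery claim is validated on
generated corpora (`generate_corpus()`) with planted structure:

* **Documents** come in weekly batches: filler tokens from an arbitrary
  vocabulary, with phrases, protein mentions, and disease mentions
  inserted at controlled rates. Defaults: 60 weeks × 50 documents,
  500-word vocabulary, 20–35 filler tokens per document.
* **Phrase families** (6 disease-topic, 3 filler) each contain four member
  phrases built with the two variation operators the string similarity
  must absorb — word-order permutation and numeral aliasing / one-letter
  edits — plus one longer member reachable only through context, and
  partner phrases that provide shared third-party context. Members 3 and 4
  of each family never share a document: they are context-similar but
  never co-mentioned, which is precisely the case context similarity
  exists for.
* **Proteins**: 10 disease-linked core proteins appear in topic documents
  (30% of documents, one family each, 65% of which mention the disease;
  filler documents mention it at 3%). Core affinities vary only two-fold:
  a planted "core" protein whose association is indistinguishable from
  background would contradict what core means. 90 background proteins
  appear at low, log-spaced topic rates, giving the ranking a realistic
  middle class whose occasional first hits create ordinary historical
  jumps.
* **The hub protein** is mentioned weekly in one document carrying one
  member and one partner from each of two families — the single-phrase-
  per-family choice avoids planting systematic cross-family co-occurrence,
  which would blur the family structure the clustering must recover. The
  **jumper protein** is quiet until its week, when one document loaded
  with phrases from `boost = 6` families mentions it. Neither hub nor
  jumper documents mention the disease explicitly: they are the
  implicit-relevance cases the method claims to catch, and they must not
  leak into the Fisher-selected core set.

What the generator does *not* emulate: real English (filler is arbitrary
tokens), realistic synonym ambiguity (each protein has one synonym),
abstract-length and citation dynamics, or vocabulary drift over time.
Passing the recovery tests therefore shows the pipeline's statistics do
what they claim under controlled conditions — not that curated
dictionaries or real PubMed text would pose no additional NER and
phrase-mining challenges.

## Numerical choices and degenerate inputs

* Fisher tails come from the hypergeometric distribution
  (`stats::phyper`), verified in the tests against direct enumeration to
  1e-12; degenerate margins (an entity never mentioned) give p = 1 with a
  message.
* MCL convergence: max entry change < 1e-6, cap 200 iterations (a warning
  and the current partition on hitting the cap); entries below 1e-12 are
  pruned and columns re-normalized.
* An all-zero context row has no direction: its similarity to anything is
  0, with a message.
* Empty pooled jump history gives p = 1 with a warning; fewer than two
  weeks of rank history is an error instructing a burn-in.
* Ties: protein ranking and core selection break by ascending id;
  representatives by descending document frequency then lexicographic;
  weekly top articles by ascending doc id.
* Week indices derive from dates by ISO-8601 weeks since Monday
  1970-01-05 when a corpus supplies dates instead of week numbers.

## Problem sizes in the test suite

The validation suite runs the full pipeline on twenty 3,000-document
corpora (seeds 0–19, 60 weeks) for the recovery properties, a
140-week × 80-protein exchangeable-noise history (>10,000 observations)
for p-value calibration, and brute-force oracle comparisons on fixtures of
up to 50 documents and 200 proteins; these sizes keep each property's
check sharp while the whole suite stays fast enough to run on every
change.

## Known limitations

* Concepts are disease-conditional: the n-gram filter keeps only phrases
  over-represented with the target disease, so the clustering must be
  redone per disease.
* Dictionary NER has false positives on short ambiguous symbols; the
  explanation report exists partly to make those visible.
* Clustering artifacts happen at the margins: synonyms split across
  concepts, or non-equivalent phrases grouped. Because article scores sum
  a handful of weights, such artifacts perturb scores only mildly, but
  they do affect concept-level interpretation.
* The jump test conditions only on initial rank, not on protein identity;
  a protein with intrinsically volatile coverage is judged against the
  same null as a stable one at the same rank.
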