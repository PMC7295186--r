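# litjump

Data-driven literature relevance scoring and rank-jump detection for
drug-target surveillance.

## What problem this solves, and for whom

Teams running weekly literature surveys for a disease area face two
complementary failure modes of keyword search: articles that *name* the
disease without touching its molecular biology (case reports, care
guidelines) dilute the survey, while articles about the relevant biology
that *never name* the disease — because the association is not yet
established — are missed entirely. `litjump` is for computational
biologists and text-mining engineers who want a corpus-driven relevance
score for abstracts, weekly protein rankings derived from it, and a
statistically grounded alert when a protein suddenly starts being
discussed in a disease-relevant context.

## The method

1. **Core proteins.** Dictionary NER finds protein and disease mentions
   per abstract; each protein's document-level co-mentioning with the
   disease is tested with a one-sided Fisher's exact test, and the K most
   significant proteins form the *core set*.
2. **Semantic concepts.** All 2–6-word n-grams occurring in ≥ 5 documents
   (no stopword at either edge) are filtered for over-representation with
   the disease (ratio `co·D/(df·df_dis) ≥ 2`, Fisher p ≤ 0.01), then
   clustered with the Markov cluster algorithm (inflation 2) on a graph
   whose edges combine two similarities: order-invariant token matching
   with numeral aliasing and single-edit tolerance (string), and the
   cosine of `log1p`-transformed rows of the pairwise over-representation
   matrix, excluding the pair's own columns (context).
3. **Weights and scores.** Concept `c` gets weight
   `mean_p log10(obs_cp / (df_c · df_p / D))` over the K core proteins —
   weight 1 ⇔ co-mentioned 10× more than chance. An article's score is
   the sum of the weights of the distinct concepts it contains, which
   makes every score exactly explainable.
4. **Protein relevance.** A protein's weekly score is the best article
   mentioning it that week; its combined relevance is the weighted sum of
   the top M = 40 weekly scores in a W = 260-week sliding window, with
   linearly decreasing weights summing to 1 (u₁ = 40/820). Proteins are
   ranked weekly; rank 1 is most relevant.
5. **High-jumpers.** A week-over-week jump `initial − new` is compared
   with the empirical distribution of historical jumps pooled over
   initial ranks within `±max(5, 0.1·r)`; the add-one one-sided p-value
   `(1 + #{jumps ≥ observed}) / (1 + N)` flags proteins suddenly
   mentioned in high-relevance articles.

See `vignettes/litjump-methods.Rmd` for assumptions, parameter rationale,
numerical choices, and limitations.

## Worked example

The package ships a seeded synthetic-corpus generator with planted ground
truth (phrase families with spelling/word-order variants, disease-linked
core proteins, a steadily relevant "hub" protein, and a planted jumper),
so the whole pipeline can be exercised without any external data:

```r
library(litjump)
cfg <- pipeline_config(K = 10L, generator = generator_config(seed = 5L))
dir <- "artifacts"
for (st in c("simulate", "core-proteins", "mine-ngrams", "cluster-concepts",
             "weight-concepts", "score-articles", "score-proteins",
             "detect-jumps", "evaluate-roc"))
  run_stage(st, cfg, dir)
```

```
simulate: 3000 documents over 60 weeks
core-proteins: 10 selected (K = 10)
mine-ngrams: 146 frequent n-grams, 72 disease over-represented
cluster-concepts: 6 concepts from 72 n-grams (403 edges)
weight-concepts: 6 concepts weighted against 10 core proteins
score-articles: 3000 articles scored, 948 with a positive score
score-proteins: 102 proteins over 60 weeks
detect-jumps: 17 significant weekly jumps
evaluate-roc: AUC 0.9891 against the planted core set
```

The funnel reads: 3,000 abstracts yield 146 frequent n-grams, 72 of which
are over-represented with the disease; they cluster into exactly the 6
planted phrase families; the planted core proteins are recovered and the
final ranking finds them with AUC 0.99. The jump report shows the planted
jumper (`PJUMP`) at its planted week (50), moved by a single document:

```r
jumps <- data.table::fread(file.path(dir, "high_jumpers.tsv"))
head(jumps[order(p_value)], 3)
#>     week protein_id initial_rank new_rank  jump     p_value top_doc
#> 1:    50    PROT049           59       18    41 0.001600000  D02500
#> 2:    46     CORE08           10        6     4 0.004123711  D02260
#> 3:    50      PJUMP           82       28    54 0.004895961  D02500
```

`PJUMP` rose 54 places (rank 82 → 28) in week 50; no historical jump from
that starting region comes close, so p ≈ 0.005. (`PROT049` happened to be
co-mentioned in the same loaded abstract and rode along — exactly the kind
of secondary hit a human reviewer triages.) Every score decomposes into
its concepts:

```r
ex <- explain_article("D02500", dir)
ex$score
#> [1] 2.651526
ex$contributions
#>    concept_id    weight                                        matched
#> 1:      C0002 0.4566045               ketone spillover|oxidation lipid
#> 2:      C0004 0.4551319        adipocyte signalling|insulin resistance
#> 3:      C0006 0.4544873             glucose homeostasis|hepatic output
#> ...
```

The triggering abstract touches six disease-biology concepts at once —
without mentioning the disease itself — and its score 2.65 is the sum of
the six weights. The same pipeline is scriptable from a shell via the
installed front-end:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","litjump",package="litjump"))')" \
    all --dir artifacts --seed 5
```

Real corpora enter through the `ingest` stage: a MEDLINE/PubMed XML file
or a line-delimited JSON record format (`doc_id`, `week`, `title`,
`abstract`), plus TSV entity dictionaries (`entity_id`, `entity_class`,
`synonym`); set `corpus_path`/`dictionary_path` in `pipeline_config()`.

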