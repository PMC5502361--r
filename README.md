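# litriage

Ranking-based literature triage for biocuration. `litriage` prioritises
MEDLINE abstracts for the curation of **protein–protein interactions
(PPI)** and **post-translational modifications (PTM)** — two annotation
axes where relevance hinges on *relationships* (binding, phosphorylation)
that no ontology term captures directly, so curators cannot triage with
plain keyword search. The package is aimed at curation teams and text-mining
researchers who want a transparent, fully offline triage pipeline:
corpus ingestion, dictionary annotation, ranked retrieval, score fusion
and TREC-style evaluation.

## Method

Documents are ranked for a (gene, axis) query in three stages:

1. **Vector-space retrieval.** An Okapi BM25 score over the query terms
   (gene + synonyms, optionally refined with axis trigger keywords —
   *binds*, *interacts*, *associates* for PPI; *phosphorylates* for PTM):

   `s(d, q) = Σ_t idf(t) · tf · (k1+1) / (tf + k1 · (1 − b + b · dl/avgdl))`

   with `idf(t) = ln(1 + (N − df + 0.5)/(df + 0.5))`, `k1 = 1.2`,
   `b = 0.75`. A Boolean mode ranked by recency (most recent first)
   serves as the baseline.
2. **Concept annotation.** Axis descriptors are marked up by stem
   matching: a token matches a concept when it begins with one of its
   lowercase stems (`phosphorylat` covers *phosphorylated,
   phosphorylates, phosphorylating, phosphorylation*); multi-word method
   names match as exact token phrases. Sentence index and character
   offsets are recorded. Per document this yields the number of distinct
   concepts `D`, per-concept term frequencies `tf_c` and descriptor
   lengths `len_c`.
3. **Score fusion.** The ranked list is re-scored with a linear
   combination of engine score and concept density:

   | preset        | formula                                      |
   |---------------|----------------------------------------------|
   | `PPI_base`    | `0.9·s + 1.5·D`                              |
   | `PTM_base`    | `0.9·s + 1.7·D`                              |
   | `PPI_refined` | `1.0·s + 0.1·Σ_c ln(1 + len_c·tf_c)`         |
   | `PTM_refined` | `1.4·s + 1.3·D`                              |

Runs are evaluated against TREC-style qrels with P@1 (the precision of
the top-returned document), MRR, MAP and P@k, plus relative improvement
over a baseline. A seeded synthetic corpus generator emulates the key
statistics of a triage benchmark so the whole pipeline is testable
without any downloads.

## Worked example

```r
library(litriage)

# annotate an abstract with the bundled PTM vocabulary
annotate_document(list(title = "BTK phosphorylated PLCG2 in vitro",
                       abstract = ""), default_thesaurus("PTM"))
#>            concept_id sentence_index char_start char_end        surface
#> 1 PTM:phosphorylation              0          4       18 phosphorylated

# benchmark the ranking strategies on a synthetic corpus
gen <- generate_corpus(synth_params(n_docs = 200, n_queries = 10, seed = 3))
run_benchmark(gen$docs, gen$queries, gen$qrels,
              configs = list(fused = fusion_preset("PPI_base")), axis = "PPI")
#> <triage_benchmark>
#>            system p_at_1    mrr    map improvement_p_at_1
#> 1 boolean_recency    0.1 0.2207 0.1501              +0.0%
#> 2          engine    1.0 1.0000 0.9018            +900.0%
#> 3           fused    0.3 0.4412 0.3701            +200.0%
```

The annotation reports the matched concept with its sentence and
0-based half-open character offsets. The benchmark rows give, per
ranking strategy, the share of queries whose top-ranked document is a
planted relevant one (P@1), mean reciprocal rank, mean average
precision, and the P@1 improvement over the Boolean recency baseline.
On synthetic corpora of this size the BM25 gene-frequency signal is
close to noise-free, so the engine row dominates; see the methods
vignette (`vignettes/triage-methods.Rmd`) for why fusion behaves
differently at this scale than on a full MEDLINE mirror.

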