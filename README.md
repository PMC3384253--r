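# bioevents

Biomedical event extraction from sentence-level text, for text-mining
researchers and practitioners working with BioNLP-style standoff corpora.
The package extracts typed, possibly nested events — gene expression,
transcription, protein catabolism, phosphorylation, localization, binding,
and the three regulation types — anchored on trigger words, with protein
or event arguments.

## The model

Extraction is decomposed into three classification stages plus a
rule-based construction step: **trigger recognition** (10-way token
labeling over nouns/verbs/adjectives), **Theme assignment** and **Cause
assignment** (accept/reject classification of trigger–argument pairs,
processed in order of increasing dependency-path length), and **event
construction** (one event per Theme for Simple and Regulation triggers,
first-dependency-label grouping with cross-products for nominal Binding
triggers, plus a dictionary for stacked regulation events such as
*overexpression*).

The stage classifiers are trained either independently or jointly with
**SEARN** (search-based structured prediction): prediction of a sentence
is a sequence of actions ŷ₁…ŷ_T; training interpolates stochastically
between an optimal policy π derived from the gold standard (used with
probability (1−β)^iteration) and the ensemble of learned hypotheses, and
turns every action into a cost-sensitive example whose per-label costs
come from policy rollouts under the event-level loss
w_FP·|FP| + w_FN·|FN| — restricted, under *focused costing*, to the part
of the output graph connected with the action.  The cost-sensitive
classifier is a multiclass passive-aggressive learner (PA-II,
prediction-based updates, loss margin √cost, averaged weights over
shuffled rounds).  Setting β = 1 with 0/1 costs and no structural
features recovers a pipeline of independently trained classifiers, which
serves as the baseline.  Feature-augmentation domain adaptation
(abstract vs. full-paper copies of every feature) and
recall/precision control through loss weights or per-stage score offsets
are included.

Because shared-task corpora cannot be shipped, the package contains a
synthetic corpus generator (`generate_corpus()`) producing standoff
documents (text, proteins, nested gold events, consistent dependency
parses, two domains) on which every component is testable end to end.

## Worked example

```r
library(bioevents)

## the built-in demonstration document: three nested gold events
doc <- demo_document()
sent <- prepare_sentence(doc$sentences[[1]], doc$domain)
paste(sent$tokens$surface, collapse = " ")
#> [1] "SQ 22536 suppressed gp41 - induced IL-10 production in monocytes"
gold_event_signatures(sent)
#> [1] "Gene_expression@7(T=P:T2)"
#> [2] "Positive_regulation@5(T=Gene_expression@7(T=P:T2))<C=P:T1>"
#> [3] "Negative_regulation@2(T=Positive_regulation@5(T=Gene_expression@7(T=P:T2))<C=P:T1>)"

## train jointly with SEARN on a synthetic corpus and evaluate held-out
train <- generate_corpus(generator_config(n_docs = 30, sentences_per_doc = 10,
                                          seed = 1, p_nested = 0.5))
test <- generate_corpus(generator_config(n_docs = 10, sentences_per_doc = 10,
                                         seed = 2, p_nested = 0.5))
policy <- searn_train(train, searn_config(beta = 0.3, iterations = 4,
                                          C = 1, rounds = 5, seed = 3))
report <- score_corpus(test, predict_corpus(test, policy))
report[report$type %in% c("Simple (TOTAL)", "Binding",
                          "Regulation (TOTAL)", "TOTAL"), ]
#>                type  TP FP FN recall precision fscore
#>             Binding  13  0  0 100.00    100.00 100.00
#>      Simple (TOTAL)  72  0  0 100.00    100.00 100.00
#>  Regulation (TOTAL)  54  0  0 100.00    100.00 100.00
#>               TOTAL 139  0  0 100.00    100.00 100.00
```

The signatures read as `type@trigger-token(T=themes)<C=cause>`: IL-10
production is a `Gene_expression` event, gp41 induces it
(`Positive_regulation` with a protein Cause), and SQ 22536's suppression
is a `Negative_regulation` over that event.  The evaluation table counts
an event as correct only when its trigger head token, type, Themes and
Cause all match, recursively; recall/precision/F are on a 0–100 scale.
On this clean 300-sentence synthetic grammar the joint model recovers the
held-out annotation perfectly — synthetic corpora show the machinery
works, not shared-task performance.

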