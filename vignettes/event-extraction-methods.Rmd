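---
title: "Joint biomedical event extraction: model, training, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint biomedical event extraction: model, training, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioevents)
```

## The task and its decomposition

A biomedical *event* is a typed relation anchored on a *trigger* word, with
one or more *Theme* arguments and, for regulation events, an optional
*Cause*.  Nine event types fall into three classes: **Simple** events
(`Gene_expression`, `Transcription`, `Protein_catabolism`,
`Phosphorylation`, `Localization`) take exactly one protein Theme;
**Binding** takes one or more protein Themes; the **Regulation** class
(`Regulation`, `Positive_regulation`, `Negative_regulation`) takes one
Theme and optionally a Cause, each of which may itself be a protein or
another event — giving nested structures.  Protein mentions are annotated
in advance (the `.a1` file); the system predicts the rest as a directed
acyclic graph over trigger tokens and proteins.

`bioevents` decomposes prediction per sentence into a sequence of
multiclass *actions*:

1. **Trigger recognition** — each noun, verb or adjective token is labeled
   with one of the nine types or `No_trigger`, left to right (modifiers
   appearing before a noun inform its label).
2. **Theme assignment** — candidate trigger–argument pairs (every
   predicted trigger crossed with every protein; Regulation triggers
   further paired with any trigger that has just received a Theme) are
   accepted or rejected, in order of increasing dependency-path length,
   agenda insertion order on ties.  Pairs that would close a directed
   cycle are discarded.
3. **Cause assignment** — Regulation-class triggers with at least one
   Theme are paired with all proteins and all other themed triggers; at
   most one Cause is accepted per trigger.
4. **Event construction** (rule-based) — Simple triggers emit one event
   per Theme; nominal Binding triggers group Themes by the first label of
   the trigger–Theme dependency path and emit the cross-product of the
   groups (`interactions of A and B with C` → two two-Theme events), with
   three exceptions collapsing to a single multi-Theme event (Themes on
   one token, Theme sharing the trigger's token, or the lemma *bind*);
   Regulation triggers emit one event per Theme with the Cause attached
   to each; a *regulation dictionary* (built from training data) stacks a
   Regulation event over the Simple event of lemmas such as
   *overexpression* that are consistently dual-annotated.

The built-in demonstration document shows the decomposition end to end:

```{r demo}
doc <- demo_document()
sent <- prepare_sentence(doc$sentences[[1]], doc$domain)
paste(sent$tokens$surface, collapse = " ")
gold_event_signatures(sent)
```

## Features

All features are binary indicators, namespaced by stage; conjunctions are
realized by string concatenation, and features unseen in training
contribute nothing at prediction time.  Trigger features: token lemma,
lemma×PoS, lemma×surrounding lemmas, lemma×dependency-neighbour lemmas.
Theme/Cause features are built from the shortest *unlexicalized*
dependency path between the pair (computed over the dependency graph in
either edge direction), conjoined with the trigger's lemma, PoS and
assigned event type, the argument type, and the first/last lemmas on the
path; the textual string between the pair (lemmas, capped at 10 tokens to
bound sparsity) serves as a fallback that survives parse errors.  Cause
features add the conjunction of the pair's path with the path(s) to the
trigger's assigned Theme(s).

*Structural* features read earlier predictions: neighbouring trigger
labels during trigger recognition; undirected-Theme-cycle, mixed
protein/event argument, shared-argument and three-Theme indicators during
Theme assignment; protein-Cause and event-argument indicators during
Cause assignment.  They are what joint learning can exploit and are
switched off in the independent baseline.

Domain adaptation (optional) duplicates every feature with a
domain-conjoined copy (`abstract` / `fullpaper`), so shared and
domain-specific behaviour receive separate weights; exactly two of the
three versions of a feature are active for any token.

## Learning

### Cost-sensitive classification with passive-aggressive updates

Each stage classifier is a linear multiclass model trained from examples
that carry a *cost vector* rather than a single label.  For an example
$x$ with costs $c$, the learner predicts
$\hat y = \arg\max_k w^{(k)} \cdot x$; if $c(\hat y) > 0$ it suffers

$$\ell = w^{(\hat y)} \cdot x - w^{(y)} \cdot x + \sqrt{c(\hat y)},
  \qquad y = \arg\min_k c(k),$$

sets the learning rate $\tau = \ell / (\lVert x \rVert^2 + \tfrac{1}{2C})$
(the PA-II variant with prediction-based updates; the aggressiveness
parameter $C$ damps updates on noisy data) and moves $w^{(y)}$ by
$+\tau x$ and $w^{(\hat y)}$ by $-\tau x$.  Training runs $R$ rounds with
a seeded shuffle per round, and prediction uses the average of the weight
snapshots after every example visit, as in the averaged perceptron.  Ties
in both argmax and argmin break towards the lowest label index; label 1
is always the negative class, so an untrained classifier abstains.

### SEARN

The stage classifiers are learned jointly by search-based structured
prediction.  The *optimal policy* derived from the gold standard picks,
at every action, the choice that minimizes the final event-level loss
assuming all later actions are optimal: gold type for true triggers,
`No_trigger` otherwise; a Theme only when the trigger carries its gold
type, the edge is in the gold decomposition and an event-valued
argument's own Themes are already correct; a Cause additionally requires
one correct Theme on the acting trigger.  Consequently a mislabeled
trigger receives no arguments — avoiding the false positive it would
create.

Training runs for a fixed number of iterations.  In iteration $i$, each
action is taken by the optimal policy with probability
$(1-\beta)^{i-1}$ and otherwise by a hypothesis sampled from the learned
ensemble; every action becomes a cost-sensitive example whose per-label
costs are estimated by *rollouts*: force the label, complete the sentence
with the same interpolated policy, construct events, and measure
$w_{FP}\cdot|FP| + w_{FN}\cdot|FN|$ against gold (averaged over
`samples_per_action` rollouts, then shifted to minimum 0; all-zero
examples are dropped).  Under **focused costing** the loss is restricted
to the gold and predicted events whose connected component — over the
union of both graphs — touches the action site, which shields the
estimate from unrelated events elsewhere in the sentence.  The rollout
uses the interpolated policy rather than an optimal-policy approximation:
a learned hypothesis makes mistakes the optimal policy would never make,
and it is precisely those mistakes the costs must reflect.

After each iteration a new classifier triple is trained on that
iteration's examples alone and appended to the ensemble; unrolling
$h \leftarrow \beta h_{new} + (1-\beta) h$ gives hypothesis $j$ of $I$
the mixture weight $\beta(1-\beta)^{I-j}$ (normalized), so early
hypotheses fade.  The returned policy predicts without the optimal
policy; test-time prediction combines per-label scores as the
mixture-weighted sum (deterministic, the default) or samples one
hypothesis per action (`stochastic = TRUE`).

Setting $\beta = 1$, disabling structural features and using 0/1 costs
against the optimal policy degenerates SEARN into a pipeline of
independently trained classifiers (`train_independent()`), which is the
comparison baseline throughout.

### Controlling recall versus precision

Two mechanisms trade recall against precision.  At prediction time,
per-stage score offsets added to the negative class
(`sweep_offsets()`) move each classifier's operating point without
retraining.  At training time, the loss weights $w_{FP}$ and $w_{FN}$
reweight the rollout costs, so all three classifiers adapt jointly to
the preferred operating point.

## Key parameters

| parameter | meaning | default |
|---|---|---|
| `beta` | per-iteration interpolation toward learned hypotheses | 0.3 |
| `iterations` | SEARN iterations; final optimal-policy probability is $(1-\beta)^{I}$ (0.3/12 gives ≈ 0.01) | 12 |
| `C` | PA-II aggressiveness (larger = more aggressive updates) | 1 |
| `rounds` | PA rounds with per-round shuffling | 5 |
| `w_fp`, `w_fn` | loss weights on false-positive / false-negative events | 1, 1 |
| `samples_per_action` | rollouts averaged per candidate label | 1 |
| `focused` | focused costing | TRUE |

## The synthetic corpus

Real shared-task corpora cannot be redistributed with the package, so
every end-to-end behaviour is exercised on a synthetic corpus
(`generate_corpus()`) whose sentences come from hand-built templates
with consistent dependency parses: Simple nominal/passive-verbal
patterns, grouped and verbal Binding (including the *bind*-lemma
exception), flat and nested Regulation with protein or event Causes, the
ambiguous *positive/negative regulation* construction (type decided by
context), the dictionary *overexpression* pattern, and trigger-free
distractors that reuse trigger lemmas in non-trigger contexts.  Protein
names are `PROT<k>` tokens; some trigger lemmas are reserved to one
domain when `domain_specific_vocab` is set.

`p_nested` selects the Regulation family, `p_binding_multi` the Binding
family (so at 0/0 every event is Simple with one Theme, by
construction), `p_cause` the fraction of nested sentences carrying a
Cause, and `parse_noise` relabels that fraction of dependency edges to
emulate parser errors — with noise the Binding grouping is no longer
guaranteed to reconstruct gold, so decomposition-compatibility holds
only at `parse_noise = 0`.  Every generated corpus at noise 0 satisfies
the central oracle property: running the optimal policy and constructing
events reproduces the gold annotation with zero loss on every sentence.

What the generator does **not** emulate: real biomedical vocabulary
growth, multi-token triggers (gold triggers are single tokens; the
head-reduction rule is exercised on separate fixtures), intersentence
structure, annotation noise, and the long sentences (100+ tokens) that
motivate focused costing at corpus scale.  Passing tests on this corpus
therefore demonstrate the machinery's correctness and the qualitative
behaviour of joint learning, not performance on GENIA-scale text.

## Numerical and design choices

* Character offsets are 0-based half-open; token indices 0-based.
* Dijkstra tie-breaks among equal-length paths pick the lexicographically
  smallest label/direction string, making path features deterministic.
* Multi-token gold triggers reduce to the span token whose dependency
  head lies outside the span (rightmost if several).
* Candidate triggers are tokens with PoS starting `N`, `V` or `J`.
* Disconnected trigger–argument pairs stay on the agenda (between-string
  features still apply) and sort after all finite paths.
* The cycle filter checks the union of Theme and Cause edges.
* The PA gold label is the cost argmin, ties to the lowest index; weight
  averaging covers all $T \times R$ post-step snapshots.
* Classifiers are trained per iteration on that iteration's examples
  only.
* A Regulation trigger's single Cause is attached to every per-Theme
  event it emits.
* Event identity (for the loss and the evaluator) is the canonical
  signature: type, trigger head token, Theme set and Cause, recursively —
  so approximate trigger matching is head-token equality, both sides
  being head-reduced.
* Event ids in emitted `.a2` files are assigned in sentence order, then
  construction order, making prediction output byte-reproducible under a
  fixed seed.
* Randomness is drawn from R's generator seeded per (iteration, sentence,
  purpose) from the master seed; the caller's RNG state is restored.

## Problem sizes used by the test suite

The suite trains on deliberately small corpora chosen to exercise each
claim: the joint-versus-independent comparison uses 400 training and 100
held-out sentences at `p_nested = 0.5` with 6 SEARN iterations; the
degeneration-equivalence check uses 200 sentences; the weighted-loss
scans train on 100 sentences with 3 iterations per weight setting and
evaluate on 400 held-out sentences at `parse_noise = 0.15` (the noise
keeps the systems off the accuracy ceiling so the trade-off has room to
move, and the enlarged held-out set makes the per-event quantum of
recall/precision small relative to the shifts being measured).

## Known limitations

* Binding event construction is heuristic (grouping + exceptions), not
  learned; sentences whose gold grouping contradicts the first-label rule
  cannot be reproduced.
* Under extreme loss weights ($w_{FP} = 64$) the $\sqrt{\text{cost}}$
  margin reaches 8 and passive-aggressive updates on a small corpus
  become unstable: on the synthetic scans precision improves through
  $w_{FP} \le 16$ but collapses at 64, while the $w_{FN}$/recall
  direction behaves monotonically.  On corpus-scale data with real
  headroom the trade-off is expected to be smoother; at desk scale the
  package documents this as a measured boundary of the mechanism.
* The evaluator implements head-token approximate matching only, not the
  official shared-task evaluator's span-extension rules.
* Sentence segmentation, parsing and lemmatization are inputs, not
  components; parse quality directly bounds Theme/Cause accuracy, with
  only the between-string features degrading gracefully.
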