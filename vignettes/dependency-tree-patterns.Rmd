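---
title: "Classifying opinionated sentences with dependency-tree patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying opinionated sentences with dependency-tree patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtclass)
```

## The problem

Aspect-based analysis of service reviews — here, patient reviews of
doctors — asks, per sentence and per *opinion class* (wait time, staff,
bedside manner, ...), one of three things: does the sentence affirm the
aspect (`x`), deny it (`y`), or not address it at all (`neutral`)? Two
features of this problem defeat plain bag-of-words sentiment analysis.
First, aspects are complex: "visit time" may surface as *spends time with
me*, *not rushed*, or *in and out within 20 minutes*. Second, the two
non-neutral values are not positive/negative sentiment: a long visit is
good for some patients and bad for others, so the labels are arbitrary
poles of the aspect, not valence. Syntax matters too: *"there are never
long wait times"* contains the words *long* and *wait* yet asserts a
short wait, and only the negation's position in the dependency tree
reveals that.

The classifier in this package therefore learns *dependency-tree matching
patterns*. Each training sentence comes with its dependency tree (nodes =
words with optional lemma and part-of-speech attributes; edges = typed
governor→dependent relations; a single root). Learned knowledge is a list
of patterns in a subset of the semgrex language, each paired with a label
and a score.

## The pattern language and matcher

A pattern node is `{}` (any node) or `{attr:value;...}` with attributes
`word`, `lemma`, `pos` and values that are exact strings or `/regex/`
forms. `A > B` requires a direct edge from A to B (any relation),
`A >rel B` requires relation `rel`, and `A >> B` requires B anywhere in
A's subtree. Relations chain onto the leading node of their group;
parentheses open a subgroup. A pattern matches a tree if its nodes can be
mapped to tree nodes satisfying every constraint; the pattern root may map
anywhere, and the mapping need not be injective (the permissive reading of
"matches any part of the tree"; nothing in extraction ever produces a
pattern whose meaning depends on injectivity). Attribute comparison is
case-insensitive, regexes must match the whole attribute, and relation
labels compare by exact string equality. Only the governor-direction
operators are implemented, because pattern extraction only emits those;
`<` and `<<` are rejected with a clear parse error.

The matcher is validated property-style against an independent
brute-force oracle that enumerates every assignment of pattern nodes to
tree nodes (500 random tree/pattern pairs per run); monotonicity (removing
a constraint never breaks a match) and the typed→untyped implication are
checked the same way.

## Training

For one opinion class the trainer:

1. **Selects words.** For each label L in {x, y}, labels are binarized
   (L vs rest) and each lowercased word type is scored by Shannon
   information gain of its presence indicator: IG(w) = H(c) − H(c | w).
   The top `n_x` (or `n_y`) words are kept; ties break lexicographically
   so training is deterministic. Presence/absence (not counts) is used
   because patterns test occurrence, not frequency; the token unit is the
   lowercased surface word, matching the prefix semantics below.
2. **Extracts patterns** from every tree of label L. `prune()` repeatedly
   removes leaves whose word does not start with any selected word
   (case-insensitive prefix — *wait* covers *waited*, *waiting*, mirroring
   the `/wait.*/` constraints the patterns print) and whose incoming
   relation is not the negation label; surviving unselected nodes become
   wildcards. `collapse()` then descends the root past single-child
   wildcards and replaces interior single-child wildcards with indirect
   edges. Every combination of `min(|W|, m)` selected words seeds this
   reduction; each new pattern's sub-combinations (two or more of its
   surviving words) are reduced in turn. Negation edges are preserved
   verbatim (`>neg`); all other directs become `>`. Patterns consisting
   solely of wildcards are suppressed — they match every tree and carry no
   information. Sub-combinations are pushed only for patterns not seen
   before, which both matches the de-duplicating set semantics and bounds
   the recursion.
3. **Scores and ranks.** Each distinct (pattern, label) pair is scored on
   the full class training set — neutral sentences included — by weighted
   accuracy: for each of the three label values, the fraction of its
   sentences the pattern handles correctly (match ⟺ sentence has the
   pattern's label), averaged unweighted. A label with no instances
   contributes accuracy 1, the vacuous truth that the pattern cannot err
   on absent instances; this keeps scores in [0, 1] with no special cases.
   Ties in the ranking go to the longer serialized pattern first (more
   specific), then lexicographic — deterministic, and consistent with
   preferring the most specific rule at classification time.

Defaults are `n_x = n_y = 30` — more than enough distinct discriminative
words for one aspect — and `m = 4`, beyond which the combination
enumeration becomes prohibitively expensive for no observed gain.

Classification scans the ranked list and returns the first match's label.
When nothing matches, the sentence is classified by the fallback: the
majority training label (ties broken neutral, then x, then y — neutral is
the natural default since in real review corpora the overwhelming majority
of sentences do not mention any given aspect), or a user-supplied backup
classifier through a text-in/label-out function interface. The heavier
neural/forest backups studied alongside this classifier are intentionally
out of scope; the interface accepts any R function.

### Enumeration and caching

Two algebraic facts keep training fast without changing its output.
Pruning with a word combination depends only on the combination's
intersection with the words actually present (as prefixes) in the tree, so
the seed enumeration visits each distinct present-word subset once instead
of all `choose(30, 4)` combinations. And any unselected single-child chain
above the first "interesting" node is discarded by every subsequent
prune+collapse, so it is stripped up front; this canonicalization lets an
extraction cache be shared across trees (and cross-validation folds) that
reduce to the same working tree. Scoring similarly pre-filters (pattern,
tree) pairs with an inverted word-prefix index — a pattern constraining
*wait* cannot match a tree with no word starting *wait* — and caches
matcher results across folds. Canonical pattern serialization (attributes
in word/lemma/pos order; direct children before indirect, then
lexicographic, C locale) is the identity used for deduplication
everywhere.

## Evaluation

`dtc_evaluate()` reports, per gold label, the classification accuracy
(the weighted accuracy is their unweighted mean — rare labels matter as
much as neutral), and for each non-neutral label the predicted-correct
ratio: among sentences *predicted* `x` (or `y`), the fraction whose gold
label agrees. The two views are deliberately different: a classifier can
reach decent per-label accuracy while flooding the non-neutral labels
with false positives, and the predicted-correct ratio exposes exactly
that failure mode. A label absent from an evaluation set is reported `NA`
and excluded from the mean, with a warning.

`dtc_cross_validate()` performs stratified k-fold evaluation (default
k = 10): each label's sentences are shuffled with the given seed and dealt
to the currently least-loaded folds, so fold sizes differ by at most one
and every fold is populated when n ≥ k. Whether the original experimental
protocol stratified its folds is not stated anywhere; stratification with
a recorded seed was chosen because it is reproducible and keeps rare
labels represented in every fold, and the report records the seed and the
choice.

## The synthetic corpus generator

Real labeled review corpora of this kind are not redistributable, so the
generator builds gold-standard corpora in which the *truth is known by
construction*: for each class, `x` and `y` sentences embed that label's
planted **motif** — a small dependency fragment, by default a negated
long-wait construction for `x` (collapsing to
`{} >neg {} >> ({word:/wait.*/} > {word:/long.*/})`) and a
waiting-room/hour construction for `y` — under random filler structure,
and an equal number of neutral sentences contain filler only.
`planted_pattern()` returns each motif's collapsed pattern as recovery
ground truth. Filler relations are drawn from a fixed UD-like inventory
with the negation label reserved for motifs; `label_noise` flips labels,
`motif_dropout` omits motifs while keeping labels.

Two generator choices deserve explanation:

* **Unique filler tokens by default.** With `vocab = NULL`, filler tokens
  are unique placeholder types with *randomly drawn* ids. Uniqueness makes
  the planted motifs the only repeating discriminative structure — the
  intended "mutually exclusive planted subtrees" condition — and random
  (rather than sequential) ids keep the lexicographic tie-break of word
  selection from correlating with generation order. Supplying a finite
  `vocab` reintroduces recurring filler words and with them the spurious
  low-scoring patterns that real corpora induce — useful for studying the
  classifier's known precision weakness, which is exactly what the
  predicted-correct ratio measures.
* **Gold trees, no parser.** The generator emits trees directly. A real
  pipeline parses raw text and inherits parser errors; generating gold
  trees isolates the learning algorithm under test from parser variance.
  Sentence text is just the token join, for traceability only.

Consequently, passing tests on synthetic data demonstrate correctness of
the algorithm — recovery of planted structure, exact metric arithmetic,
determinism — and do **not** predict accuracy on real reviews, where
aspects overlap lexically, negation attaches ambiguously and parsers err.

## Numerical and format conventions

* Token indices are 1-based (CoNLL-U convention); sibling order is
  preserved through round trips but carries no matching semantics.
* Words are stored verbatim; all matching-time comparisons lowercase.
  The dependency label inventory is deliberately uninterpreted (plain
  strings): trees in the wild may use `neg` or a newer scheme's label, so
  the negation label is a configuration knob (default `"neg"`).
* A record whose annotations assign both `x` and `y` to one class (which
  a union-of-annotators rule can produce) is dropped *for that class*
  (label `NA`, with a warning) and excluded from training and evaluation
  denominators; a missing class entry means neutral. Neither convention
  loses the record for other classes.
* Model files are plain text (header + `score<TAB>label<TAB>pattern`
  lines, scores at full `%.17g` precision) and round-trip byte-exactly;
  repeated training runs on identical input are byte-identical because
  nothing in training is random.
* Problem sizes in the shipped tests: property suites use 200–500 random
  cases; recovery and cross-validation checks use 100 sentences per label
  with 10 folds — large enough for the binomial noise bounds they assert,
  small enough to run comfortably on one CPU.

## Limitations

* Patterns carry no semantic role information: a negation anywhere above
  the motif words can satisfy `>neg` even when it does not semantically
  scope over them, a known source of false positives.
* Lexically similar aspects (e.g. praise for a doctor vs for staff)
  produce overlapping patterns; the classifier has no mechanism to
  require the aspect's holder.
* The matcher is the brute-force-verified reference subset of semgrex:
  no named nodes, no negated or optional relations, no regex over
  relation types.
* Sentence splitting, tokenization and parsing are upstream concerns:
  the package consumes per-sentence trees (CoNLL-U, the bracketed
  dialect, or generated), and no test depends on an external parser.
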