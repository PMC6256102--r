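# dtclass: dependency-tree pattern classification of opinionated sentences

`dtclass` classifies review sentences by *aspect-specific opinion* rather
than plain sentiment. In patient reviews of doctors, an opinion class such
as **wait time** takes one of three values per sentence: `x` ("yes" — the
wait is short), `y` ("no" — the wait is long) or `neutral` (the sentence is
not about wait time at all). A sentence like *"there are never long wait
times"* is positive in sentiment but, more usefully, it is `x` for wait
time — and getting that right requires the sentence's *syntax* (the
negation over "long wait"), not just its words.

The package implements a dependency-tree pattern classifier:

1. **Word selection.** For each non-neutral label, the top *n* words by
   information gain — IG(w) = H(c) − H(c | w) on the one-vs-rest
   binarization of the class label against word presence — are selected
   (defaults n<sub>x</sub> = n<sub>y</sub> = 30).
2. **Pattern extraction.** Every training tree with that label is pruned to
   the selected words: leaves that start with no selected word and are not
   in a negation relation are removed recursively, remaining unselected
   nodes become wildcards `{}`, and single-child wildcards collapse into
   indirect (`>>`) relations. Every combination of up to *m* = 4 selected
   words seeds this reduction, and sub-combinations of each result are
   reduced in turn, yielding a set of semgrex-style patterns such as

   ```
   {} >neg {} >> ({word:/wait.*/} > {word:/long.*/})
   ```

   ("some node has a direct negation dependent and, somewhere below it, a
   word starting with *wait* whose direct dependent starts with *long*").
3. **Ranking.** Every (pattern, label) pair is scored by **weighted
   accuracy**: the unweighted mean of its per-label accuracy over the three
   label values, so rare opinion labels count as much as the dominant
   neutral class. The model is the ranked list.
4. **Classification.** A new sentence gets the label of the highest-ranked
   pattern matching its dependency tree; if none matches, a fallback
   applies (majority training label, or a pluggable backup classifier).

The package also ships the matching engine for the governor-direction
semgrex subset (`>`, `>rel`, `>>`, verified against brute-force assignment
enumeration), readers/writers for CoNLL-U, a bracketed tree dialect and a
JSON-lines corpus format, stratified cross-validated evaluation with
per-label and predicted-correct ratios, a synthetic gold-tree corpus
generator with planted discriminative motifs, and a command-line interface
(`inst/cli/dtc`) with `train` / `classify` / `eval` / `synth` /
`extract-patterns` subcommands.

## Worked example

```r
library(dtclass)

tree <- parse_bracketed_tree(
  "[are/VBP expl>there/EX neg>never/RB nsubj>[times/NNS compound>[wait/NN amod>long/JJ]]]"
)
semgrex_matches("{} >neg {} >> ({word:wait} > {word:long})", tree)
#> [1] TRUE

# a synthetic corpus with planted motifs: 30 sentences per label for the
# "wait_time" class (x = negated long wait, y = waiting-room/hour)
corpus <- generate_corpus(synth_config(n_per_label = 30, seed = 1))
model  <- dtc(corpus, "wait_time")
model
#> Dependency-tree pattern classifier
#>   class:          wait_time
#>   ranked patterns: 1816
#>   fallback:       majority (majority label: neutral)
#>   top patterns:
#>     1.0000  y  {word:/wait.*/} > ({word:/hour.*/} > {word:/over.*/}) > ({word:/room.*/} > {word:/wait.*/})
#>     1.0000  x  {} > ({word:/times.*/} > ({word:/wait.*/} > {word:/long.*/})) > {word:/there.*/} >neg {}
#>     ...
```

The top-ranked patterns score a weighted accuracy of 1.0: each matches all
and only the training sentences of its label. Evaluation and
cross-validation report the per-label measures:

```r
dtc_evaluate(model, corpus)
#> Evaluation for class 'wait_time'
#>   weighted accuracy: 1.0000
#>    label  n accuracy predicted_correct
#>        x 30   1.0000            1.0000
#>        y 30   1.0000            1.0000
#>  neutral 30   1.0000                NA

dtc_cross_validate(corpus, "wait_time", k = 10, seed = 1)
#> 10-fold cross-validation for class 'wait_time' (seed 1)
#>   mean weighted accuracy: 1.0000
```

Here `accuracy` is the fraction of each gold label classified correctly
(its mean is the weighted accuracy) and `predicted_correct` is, among
sentences *predicted* `x` or `y`, the fraction whose gold label agrees.
Fitted models are tibble-friendly: `tidy(model)` returns the ranked
pattern list, `tidy(dtc_evaluate(...))` the per-label table, and
`autoplot()` draws it.

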