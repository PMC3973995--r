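---
title: "Knowledge-based extraction of adverse drug event relations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based extraction of adverse drug event relations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Pharmacovigilance text mining asks, sentence by sentence, whether a drug
mention and a disorder mention describe an adverse drug event (ADE).
Machine-learning relation extractors need large annotated corpora;
`aderex` implements the alternative: a knowledge-based pipeline that needs
almost no training data because the relational evidence comes from a
medical concept graph rather than from learned sentence features.

The pipeline has two halves.

**Concept identification.** Sentences are matched against a lexicon that
maps surface terms to concept unique identifiers (CUIs), each carrying a
coarse semantic group — `CHEMICALS_AND_DRUGS` or `DISORDERS`. Matching is
leftmost-longest over normalized token n-grams (case folding, possessive
removal, punctuation-to-space, final-token plural stripping), so
`"Angiotensin-Converting Enzyme inhibitors"` and
`"angiotensin converting enzyme inhibitor"` are the same key. Five
rule submodules then post-process the dictionary output using a bundled
part-of-speech tagger and noun-phrase chunker:

1. *coordination resolution* — `"A and B H"` is rewritten as `"A H"` /
   `"B H"`, re-matched, and a hit is anchored on the minimal original span
   covering the conjunct (so `"magnesium"` in
   `"magnesium and aluminium hydroxide"` receives the magnesium-hydroxide
   concept);
2. *abbreviation expansion* — parenthesis-anchored short-form/long-form
   detection in the classic right-to-left character-matching style; when
   the long form is a known concept, later occurrences of the short form
   inherit its CUI, and a short form with an unknown long form is blocked
   from dictionary matching for the rest of the document;
3. *term variation* — unmatched noun phrases are retried after determiner
   dropping, `"H of M"` inversion, and premodifier stripping;
4. *boundary correction* — trim-only removal of determiners, pronouns, and
   punctuation at mention edges;
5. *concept filtering* — a mention is dropped when it overlaps no noun
   phrase (partial overlap is enough to keep it) or when its CUI or
   normalized surface is on a configurable filter list.

**Relation decision.** The knowledge base is a three-tier graph (terms →
concepts → semantic types); queries use only the concept tier, whose typed
edges (`"is-a"`, `"cause-of"`, ...) are traversed undirected. For every
within-sentence drug × disorder candidate pair, the shortest-path distance
between the two concepts decides the relation: accept iff
`distance <= distance_threshold`. On top of that sits a trainable
relation-type filter: on a labeled training split, every distance-accepted
candidate is marked true positive (boundary-exact match to gold) or false
positive, and each relation type occurring on the hops of the enumerated
shortest paths increments the corresponding count. A type is discarded
when

```
(fp + 1) / (tp + 1) > type_ratio_threshold   (strictly)
```

and at extraction time a pair survives the filter when at least one of its
shortest paths contains no discarded type on any hop.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `distance_threshold` | 4 | maximum shortest-path length (edges) between drug and disorder concepts; `Inf` gives the co-occurrence baseline |
| `type_ratio_threshold` | 7 | strict cutoff on `(fp+1)/(tp+1)` for discarding a relation type |
| `horizon` | threshold + 1 | BFS depth cap; pairs beyond it count as unreachable, which bounds cost on hub concepts |
| `path_cap` | 64 | maximum number of shortest paths enumerated per pair, in deterministic lexicographic order, with a truncation flag |
| `filter_mode` | `any_path_survives` | a pair is rejected only when *every* shortest path carries a discarded type; `all_paths_clean` implements the stricter reading |
| `count_mode` | `occurrence` | a type counts once per hop occurrence across all enumerated paths; `per_pair` counts each type once per labeled candidate |

The defaults for the two thresholds are the operating point the method is
known to work at; both are exposed so a user can re-tune on their own
training split (`train_relation_type_filter` plus a grid over the two
values).

Design points that were genuinely open, and the choices made:

* *Direction of traversal.* Concept-relation tables store each relation
  together with its inverse, so undirected traversal is the faithful
  reading; this is recorded prominently because it changes distances.
* *Path-level vs pair-level filtering.* Discarding "any path containing
  that relation type" is read as filtering paths, not pairs; the pair
  survives if a clean path remains. The stricter alternative is behind
  `filter_mode`.
* *Parallel edges.* A hop contributes the set of types of all parallel
  edges; a path "contains" a discarded type if any hop's set does.
* *Ambiguous mentions.* A term mapping to several CUIs keeps all of them;
  candidate distance is the minimum over CUI combinations and the
  lexicographically first minimizing pair feeds the filter. Word-sense
  disambiguation is deliberately out of scope.
* *Span conflicts after the rule stage.* Overlapping mentions with
  different spans resolve to the longer span; ties prefer dictionary
  provenance. Same-span multi-CUI copies all survive.
* *Offset conventions.* Annotated relation files are read with
  auto-detection over eight conventions (sentence- vs document-relative ×
  0/1-based × half-open/closed), checked by surface/slice agreement on the
  first parsable records; the detected convention is recorded in the
  corpus' provenance so a run log can state it.

## Evaluation

Scoring is boundary-exact and micro-averaged: a prediction is a true
positive only when both entity spans coincide exactly with a gold
relation in the same document; duplicates (same spans, different CUIs)
collapse before counting, so `tp + fn` equals the number of distinct gold
relations and `tp + fp` the number of distinct predictions. Precision,
recall, and F (harmonic mean) are reported in percent.
`categorize_errors()` partitions all errors into four kinds: false
positives with both entity spans matching gold entity annotations
(relation wrong), false positives from wrongly recognized entities, false
negatives whose entities were found but whose pair was rejected, and false
negatives with a missed entity. Because the gold standard annotates only
entities participating in relations, the "entities correct" reading
under-counts correctly recognized entities; reports say so.
`build_comparison_subset()` reproduces the balanced-pair construction used
when comparing against sentence classifiers: nested gold annotations
dropped, positive sentences only, and negatives sampled to a 1.26 : 1
positive-to-negative ratio.

## What the synthetic fixture emulates

Real resources for this task (a licensed vocabulary release and the ADE
corpus download) cannot be bundled, so the `fixture_spec()` generator
builds a seeded toy world in which every stage has something to do and the
planted ground truth is known:

* **true pairs** are wired into the graph at distance 3 through clean
  relation types — under the threshold of 4;
* **far decoys** sit at distance 6 — beyond the threshold, so only the
  distance rule can reject them;
* **trap decoys** sit at distance 2 but every hop of every one of their
  shortest paths carries a planted noise relation type
  (`"co-reported-with"`), so only the trained relation-type filter can
  reject them;
* the corpus renders positive sentences from simple, coordinated
  (`"<w1> and <w2> chloride-induced <effect>"`), and abbreviation
  define/use templates, and negative sentences that co-mention trap or far
  pairs or no pair at all. Gold offsets are computed from the rendered
  strings and checked at emission.

Defaults: 200 documents of 3–5 sentences, 20 drugs (three shared-head
families for coordination), 20 disorders (six with usable short forms),
25 trap and 25 far decoy pairs, negative-sentence fraction 0.64 (echoing
the composition of the corpus this emulates), coordination and
abbreviation rates 0.15, and a 10% chance of rendering a two-word disorder
hyphenated. These sizes keep the whole test suite desk-scale (the full
suite runs in about two minutes) while leaving every planted effect
measurable: dictionary-only recognition misses exactly the coordinated
first conjuncts and the short forms, the distance rule removes exactly the
far decoys, and filter training recovers exactly the noise type.

What passing on this fixture does **not** show: template sentences are
deliberately simple and auditable, so the tagger, chunker, and rule
modules face none of the variability of real prose; lexicon coverage is
perfect by construction; and the graph has no dense hubs. Absolute scores
on the fixture (the full pipeline typically reaches F ≈ 100 on the test
split, about 45 points over the co-occurrence baseline) therefore say
nothing about absolute performance on real corpora — they demonstrate the
machinery, the orderings (recall never rises under filtering; prediction
sets nest across thresholds), and the recoverability of planted structure.

## Numerical and degenerate-input choices

* BFS treats unknown concepts and disconnected pairs as infinitely
  distant — a rejection, never an error.
* Shortest-path enumeration visits neighbors in lexicographic CUI order
  and caps at `path_cap` paths, setting a truncation flag that decision
  traces carry; decisions are then made on the enumerated subset.
* `f_score(0, 0)` is 0; metrics with empty denominators are 0.
* Empty training input yields an empty filter (nothing discarded) with a
  warning, and an empty discard set behaves exactly like no filter.
* Train/test splitting sorts document ids lexicographically before seeded
  sampling, so the split is independent of storage order.
* Sentence segmentation of plain abstracts is rule-based (terminal
  punctuation + abbreviation exception list) and pluggable; annotated
  corpora arrive pre-sentencized and never pass through it.

## A worked example

```{r}
library(aderex)

spec <- fixture_spec(n_documents = 60, seed = 42)
res <- generate_fixture_resources(spec)
corpus <- generate_fixture_corpus(spec, res)
split <- split_corpus(corpus, 15, seed = 1)

mentions <- apply_nlp_rules(
  recognize_corpus(split$train, res$lexicon), split$train, res$lexicon)
filter <- train_relation_type_filter(
  split$train, mentions, res$graph, extraction_config())
filter$stats

stage_report(split$test, res$lexicon, res$graph,
             extraction_config(), filter)[, 1:7]
```

## Known limitations

* The rule inventory of the five NLP submodules is a minimal, explicit
  reconstruction (each rule individually switchable); the bundled tagger
  is a closed-class + suffix heuristic sufficient for fixtures and simple
  abstracts, not a trained model. Any tagger with the
  `analyze_sentence()` signature can be plugged in.
* Adverse-event and treatment relations are not distinguished: a drug
  close to a disorder it treats will be extracted too.
* Relation types are unweighted and path plausibility is not scored.
* The coordination rewrite handles one conjunction per noun phrase with a
  single-token second conjunct.
* The comparison-subset builder can run out of negatives on corpora whose
  positive sentences contain no spurious co-occurrences (it then warns
  and reports the achieved ratio).
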