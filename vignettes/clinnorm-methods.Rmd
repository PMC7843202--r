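---
title: "Normalizing clinical terms with learned edit patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing clinical terms with learned edit patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(clinnorm)
```

## The task

Clinical notes mention conditions, drugs, procedures and findings in forms
that rarely coincide with how a terminology lists them: an extra plural
"s", a British spelling ("tumour" for "tumor"), a swapped word ("heart" for
"cardiac"), a dropped trailing marker ("nos"), or a compositional paraphrase
("nasal o2" for "oxygen administration by nasal cannula"). *Clinical term
normalization* maps each such mention to the concept unique identifier
(CUI) of the concept it denotes in a synonym lexicon — in practice a
UMLS/SNOMED CT/RxNorm extract — or to the reserved output `"CUI-less"` when
no concept corresponds.

`clinnorm` implements a normalizer that is learned entirely from the
lexicon's own synonym structure plus (optionally) a set of annotated
training mentions. Fitting is done by `term_normalizer()`; the fitted
object normalizes new terms through `predict()` and is scored with
`evaluate()`.

## The stage cascade

A term is preprocessed and then passed through three matching stages; the
first stage that produces candidates wins, and a disambiguation step picks
a single CUI when several candidates remain:

1. **Exact matching** against the preprocessed lexicon synonyms and the
   annotated training mention texts (both hashed, so lookup is
   constant-time).
2. **Learned edit patterns**: every retained pattern is applied to the
   term; each rewrite that is itself a lexicon synonym contributes that
   concept's CUI.
3. **Subconcept matching**: the term's n-gram subterms are resolved to
   concepts, and a concept with the same subconcept profile is sought.
4. Otherwise the output is `"CUI-less"`.

Stage short-circuiting follows the system design: later stages run only
when earlier ones return nothing. The cascade order encodes a confidence
ordering — exact evidence beats a learned rewrite, which beats a
compositional reconstruction.

## Preprocessing

Everything downstream works on lowercased strings. Preprocessing removes a
fixed list of common words swept into mention spans by noun-phrase
annotation conventions ("a", "an", "the", "his", "her", "patient",
"patient's", "any", "your", "this", "that", "these") and the character
sequences `'s`, `'d`, `-`, `'`, `>`, `<`, then collapses whitespace.

Three decisions here were genuinely open:

* **Order of operations.** Character stripping runs before stopword
  removal, so "patient's" is reduced to "patient" by the `'s` rule and then
  removed as a stopword; keeping "patient" in the stopword list makes both
  routes converge.
* **Apostrophe variants.** Curly apostrophes are normalized to `'` before
  any rule, so source encoding does not matter.
* **Hyphen removal splits tokens.** Removing `-` joins its neighbours with
  a space ("asthma-cardiac" becomes "asthma cardiac"), not by
  concatenation. Splitting preserves word tokenization for word-level
  patterns; `preprocess_config(hyphen_splits = FALSE)` selects the joining
  behaviour instead. En and em dashes are treated as hyphens.

Preprocessing is idempotent, and may legitimately produce an empty string
(such synonyms are dropped from the lexicon).

## Edit patterns

For every ordered pair of distinct preprocessed synonyms within a concept,
the package computes a minimal Levenshtein alignment and stores it as an
*edit pattern*: an anchored sequence of `SAME`, `INSERT`, `DELETE` and
`SUBSTITUTE` operations, e.g.

```{r}
render_pattern(extract_edit_pattern("anemic", "anemias"))
```

Minimal alignments are not unique, so the dynamic-programming traceback
uses a fixed tie-break — diagonal (`SAME`/`SUBSTITUTE`) over vertical
(`DELETE`) over horizontal (`INSERT`) — making extraction deterministic.
Units are either characters or whitespace-separated word tokens; the same
machinery serves both levels. In rendered form a literal space unit is
written `_space_` (and a literal pipe `_pipe_`) so pattern files stay one
line per pattern; `parse_pattern()` inverts `render_pattern()` exactly.

A pattern anchored on both sides only reproduces the pair it came from, so
patterns are **generalized**: the generalization of two patterns is the
longest contiguous common pattern that still contains all the edit
operations, generalizing over `SAME` context and the `BEGIN`/`END`
anchors. Two patterns are compatible only when their edit-operation
subsequences are identical and the `SAME` context *between* edit
operations agrees; the shared context before the first and after the last
edit operation is trimmed to the common part, and an anchor survives only
when it bounds the common run in both inputs. Under this formulation the
result is unique, so no tie-breaking is needed, and generalization is
commutative. The closure (`generalize_patterns()`) works over an agenda
with canonical-form deduplication, grouped by edit-operation signature;
it terminates because every generalization is a contiguous sub-run of its
inputs and there are finitely many sub-runs.

```{r}
g <- generalize_pattern(extract_edit_pattern("glycemic", "glycemias"),
                        extract_edit_pattern("anemic", "anemias"))
render_pattern(g)
apply_pattern(parse_pattern("SAME m SAME i INSERT a SUBSTITUTE c|s END"),
              "arrhythmic")
```

Because synonym pairs are enumerated in both directions, the candidate
pool is closed under reversal: a pattern that inserts a trailing "s"
always comes with one that deletes it.

### Scoring

Generalization left unchecked produces absurdly general rules ("change
every c to s"), so every candidate is scored against the concepts it was
learned from. Applying a pattern to a synonym of concept `c` yields
rewrites; a rewrite that is itself a synonym of `c` counts as a positive,
one that is a term of a different concept only counts as a negative, and a
rewrite matching nothing counts as neither. The score is the m-estimate
style quantity

$$\mathrm{score} = \frac{p}{p + n + 1},$$

always in `[0, 1)`. The `+1` makes broader patterns win among equally
clean ones: with `n = 0`, `p = 10` scores 0.909 while `p = 1` scores 0.5.
Only patterns scoring above the threshold (default **0.9**) are retained —
so a zero-negative pattern needs at least 10 positive instances, which is
why the synthetic generator plants at least that many per rule. Scoring
counts only over the sampled learning scope by default
(`learn_config(scope = "full")` widens it to the whole lexicon); each
direction of a synonym pair is counted once, and duplicate synonyms are
collapsed first so a term repeated across source vocabularies cannot
inflate `p`.

### Learning regimes

* **Per semantic type** (`learn_by_semantic_type()`): variation is
  type-specific (laboratory procedures swap "assay"/"measurement", drugs
  swap routes), so seeds, generalization and scoring run separately per
  semantic-type label, on up to `max_concepts_per_type` sampled concepts
  (default 5000 — enough for common variations; more only adds rare
  patterns). Retained patterns carry the type as provenance, but at
  prediction time patterns of *all* types are applied, because an input
  term's type is unknown. Concepts carrying several types participate in
  each of them.
* **From training data** (`learn_from_training()`): annotated mention
  texts are first added as synonyms of their gold concepts
  (`augment_with_training()`); learning then runs over those concepts plus
  `extra_random_concepts` (default 3000) randomly sampled others, which
  drive generalization and provide negative evidence. No type split is
  used — training sets are too small per type. Provenance is `"training"`.

Sampling uses a seed recorded in the configuration, so a rerun reproduces
the same pattern set bit for bit.

## Subconcept matching

The term's *subconcept profile* is computed by enumerating all contiguous
token subsequences, keeping those that are lexicon terms, and recording
each with its full candidate CUI set. Two profile-construction choices are
deliberate:

* **Maximal subterms only.** A matched subterm nested inside a longer
  matched subterm is suppressed; otherwise "breast biopsy" would
  contribute "breast", "biopsy" *and* "breast biopsy" and profile equality
  would rarely hold.
* **A synonym's own full-span match is excluded from its concept's
  profile.** Every lexicon synonym trivially matches itself, and without
  this exclusion a multi-word synonym's profile would collapse to the
  concept itself rather than its constituents. A synonym contributing
  nothing after the exclusion — in particular any single-word synonym —
  falls back to its full-span set, so atomic concepts keep well-defined
  profiles.

A concept's profile is the union of its synonyms' profiles with duplicate
CUI sets collapsed. A term matches a concept when the two profiles have
the same number of CUI sets and can be paired one-to-one such that every
paired couple of sets intersects (computed by augmenting-path bipartite
matching; profiles are tiny). Intersection is what lets "o2" meet
"oxygen": the strings differ, but they share a CUI. Strict equality of
profile cardinality is required — tolerating concept-side supersets is a
plausible relaxation but makes "exactly these subconcepts" vacuous, so it
was not adopted.

## Disambiguation

When a stage returns several candidates, the system uses rules learned
from the training data: for every training mention with two or more
candidates (gold among them), the combination of semantic types across
candidates is recorded, and a rule `combination -> winning type` is
emitted when, in every supporting mention, the gold concept bears one type
that *no competing candidate bears*. The identifiability requirement is
this package's tightening of "the correct concept was always of one
particular type": it guarantees that applying a rule back to the mentions
it was learned from can never select a wrong concept, even though concepts
may carry several semantic types (a candidate's "type" is its full type
set, and the combination is the union across candidates). `min_support`
(default 1) optionally guards against one-off rules.

Unresolved ambiguity falls back to the first candidate in canonical
(lexicographic CUI) order — an arbitrary but reproducible stand-in for
"effectively random". The same ordering breaks ties among candidates
bearing a winning type.

Exact matching consults the training index only for mentions annotated
with a real CUI; `"CUI-less"` annotations are not indexed, since the
candidate machinery traffics in CUIs only.

## The synthetic benchmark

Licensed terminologies cannot ship with the package, so `synth_generate()`
builds lexicons whose statistical structure exercises every stage:

* Four lexicon variation families (analogues of commonly learned rules):
  trailing-"s" pluralization, an "or"→"our" spelling family, a whole-word
  substitution pair, and a trailing "nos" marker token — each instantiated
  in `instances_per_rule` concepts (default 12: comfortably above the
  10-instance floor imposed by the 0.9 threshold, without tuning to it).
* A training-only substitution family whose variant form occurs solely in
  annotated mentions, so its pattern is learnable only from training data.
* A planted *ambiguous* rewrite (a final-vowel swap that lands on a
  different concept as often as on a synonym), which scoring must reject.
* Ambiguity injections (one term under two concepts of different types,
  with training resolving half) to exercise rule learning.
* Compositional host concepts ("x u" where "u"/"v" are synonyms of a
  component concept) reachable only through subconcept matching.
* 60 single-synonym distractor concepts spread over the semantic types as
  negative-evidence pool and exact-match targets.

Vocabulary is built from pronounceable consonant-vowel syllables over a
fixed alphabet; because generated words end in vowels while derived
variants end in consonants, cross-family string collisions are
structurally excluded and every positive or negative count is attributable
to a planted cause. The manifest records, for every evaluation mention,
its gold CUI, reachability class (`exact`, `pattern`, `subconcept`,
`cuiless`) and, for pattern-reachable mentions, the lexicon synonym its
rewrite must land on — so tests can assert stage accounting exactly
rather than approximately.

What the generator does **not** emulate: real UMLS frequency and ambiguity
distributions, abbreviation conventions, token reorderings
("asthma–cardiac" vs "cardiac asthma"), misspellings outside the planted
families, and the long tail of near-miss negatives a 200k-concept
vocabulary supplies. Passing on this benchmark demonstrates that the
machinery is correct and that learning recovers plantable regularities; it
does not predict accuracy on clinical corpora, which depends on licensed
resources out of scope here.

## Numerical and degenerate-input choices

* Ties in the alignment DP and among disambiguation candidates are broken
  deterministically (see above); all set-valued outputs are returned
  sorted, so whole-pipeline runs are byte-reproducible.
* A pattern consisting solely of `SAME` operations performs no edit and is
  never constructed; extraction refuses identical inputs.
* Insertion-only patterns have an empty source sequence and match at
  insertion points (`BEGIN` pins them to the start, `END` to the end).
* Rewrites equal to the input term are discarded defensively, although the
  pattern algebra cannot produce them from minimal alignments.
* Scoring prefilters terms by the pattern's contiguous source run
  (`INSERT`s do not interrupt source contiguity, so the whole source is
  one literal), which keeps candidate screening linear in practice.
* Empty preprocessed mentions can match nothing and normalize to
  `"CUI-less"`.

## Problem sizes

The shipped test-suite and acceptance-script workloads were chosen as the
smallest sizes at which every claim is exercised meaningfully: exhaustive
distance-oracle equivalence over all ~10.8M string pairs up to length 7 on
a 3-letter alphabet, 1000 random extract/apply round trips, and a
synthetic benchmark of about 180 concepts with an 89-mention evaluation
set. Fitting the benchmark normalizer takes a few seconds on one core.

## Limitations

Edit patterns capture contiguous sequential edits only: no transpositions,
no word reordering, no context outside the mention, no abbreviation
expansion beyond what exact matching or learned patterns happen to cover,
and no use of terminology hierarchy or postcoordination. The pattern file
notation reserves `_space_` and `_pipe_`, so units may not contain those
literal strings themselves.
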