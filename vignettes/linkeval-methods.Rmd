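---
title: "Scoring and error analysis for clinical entity linking with linkeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and error analysis for clinical entity linking with linkeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkeval)
```

## The problem

Clinical entity linking takes free-text notes (for example hospital
discharge summaries) and produces *annotations*: contiguous character spans,
each linked to one concept in a hierarchical clinical terminology such as
SNOMED CT. Evaluating such systems requires a metric that is sensitive both
to *where* a system draws span boundaries and to *which* concept it links,
and — because performance varies enormously across concepts — tooling to
diagnose *why* particular concepts are hard.

linkeval provides that tooling: the character-level IoU scoring function
with bootstrap uncertainty, a five-way error taxonomy, a concept-difficulty
feature suite, a majority-vote ensemble combiner, and a seeded synthetic
benchmark generator so that every stage can be exercised, end to end,
without access to restricted clinical corpora.

## Data model and conventions

Annotations are rows of `(doc_id, start, end, concept_id)` attributed to one
*source* (the gold standard, a system, or an annotator). Offsets are
**0-based, half-open** `[start, end)`, indexing the decoded character
sequence of the note (not bytes), so span length is always `end - start`.
Empty spans are rejected at construction, and annotations from one source
may never overlap within a document — annotation guidelines for this task
preclude overlapping spans, and the no-overlap invariant is what makes the
character-level view well defined (at most one concept per character per
source). Overlap means a non-empty intersection of half-open intervals in
the same document; the touching spans `[0,5)` and `[5,9)` do not overlap.

The exchange formats are deliberately plain: a UTF-8 CSV with header
`note_id,start,end,concept_id` for annotation sets, one text file per note
(or a `note_id,text` CSV) for documents, and two TSVs (`concept_id,term`
synonyms; `child_id,parent_id` is-a edges) for a desk-scale terminology
snapshot. Full terminology release formats are out of scope.

## The scoring model

For a concept $c$, let $G$ and $P$ be the sets of (document, position)
characters that the gold standard and the prediction link to $c$. The
per-concept score is the intersection-over-union of those character sets:

$$\mathrm{IoU}_c \;=\; \frac{|P \cap G|}{|P| + |G| - |P \cap G|}.$$

With character-level precision $\mathrm{Pr}_c = |P \cap G|/|P|$ and recall
$\mathrm{Re}_c = |P \cap G|/|G|$ this is equivalent to

$$\mathrm{IoU}_c \;=\;
\frac{\mathrm{Pr}_c\,\mathrm{Re}_c}
     {\mathrm{Pr}_c + \mathrm{Re}_c - \mathrm{Pr}_c\,\mathrm{Re}_c},$$

an identity the test suite verifies to $10^{-12}$ on random corpora. The
implementation never materializes character sets: because spans within one
source are disjoint, $|P \cap G|$ is the sum of pairwise interval-overlap
lengths between same-document, same-concept spans, which is exact and fast.
(`char_assignment()` exposes the materialized per-character view for
consumers that want it, and the test suite uses explicit character-set
enumeration as an independent oracle against the interval arithmetic.)

Worked example on the sentence `"CT head revealed no internal
hemorrhage."` with gold linking `"CT head"` (7 characters) to concept
`303653007`:

```{r worked}
docs <- corpus("n1", "CT head revealed no internal hemorrhage.")
gold <- annotation_set(
  data.frame(doc_id = "n1", start = 0, end = 7, concept_id = "303653007"),
  "gold")

# prediction covers only "CT": 2 of 7 characters
concept_iou(gold, annotation_set(
  data.frame(doc_id = "n1", start = 0, end = 2, concept_id = "303653007"),
  "sys"), "303653007")

# prediction links the right span to the wrong concept: 0
concept_iou(gold, annotation_set(
  data.frame(doc_id = "n1", start = 0, end = 7, concept_id = "72970002"),
  "sys"), "303653007")
```

A note on the union denominator: a plain-sum denominator $|P| + |G|$
(without subtracting the intersection) is inconsistent with both the
$2/7$ example above and the precision/recall identity, so linkeval uses the
union form throughout. One consequence is that an over-long prediction
covering `"CT head revealed"` (16 characters) scores $7/16 = 0.4375$, the
value the identity demands ($\mathrm{Pr} = 7/16$, $\mathrm{Re} = 1$), rather
than the smaller plain-sum value $2/16$ sometimes quoted for this example.

### Aggregation

`score_submission()` averages $\mathrm{IoU}_c$ over the **union** of
concepts appearing in the gold standard or the prediction. Including
predicted-only concepts matters: a hallucinated concept scores 0 and must
enter the mean, otherwise a system could invent concepts without penalty.
The class-weighted variant weights each concept by its number of gold
annotation instances (concepts absent from gold get weight 0), reflecting
that missing 100 of 100 instances is worse than missing 1 of 1. A perfect
submission scores 1 under both aggregates regardless of weights. Concepts
with no gold and no predicted characters are simply absent from the table;
no 0/0 ratio is ever formed.

### Bootstrap confidence intervals

`bootstrap_ci()` resamples the per-concept IoU vector with replacement
(default 1000 replicates, seed mandatory) and reports the 2.5%/97.5%
percentiles of the resampled mean — or of the resampled class-weighted mean,
each resampled concept carrying its own instance weight. The resampling unit
is the concept because the mean itself is a per-concept average. A
single-concept unweighted report yields a degenerate interval and a warning.
The suite checks calibration directly: over 200 repetitions of 500
Uniform(0,1) per-concept scores, the 95% interval covers the true mean 0.5
at close to the nominal rate.

### Inter-annotator agreement

`iaa_jaccard()` asks a coarser question than IoU: did two annotators find
the same entities and link them to the same concepts, ignoring boundary
variation? Candidate matches are same-document, overlapping, same-concept
pairs; they are ranked by overlap length (ties broken by earlier position,
then input order, so the result is deterministic) and matched greedily
one-to-one; the score is $|M| / (|A| + |B| - |M|)$. Whether a one-to-one or
many-to-many matching is preferable is genuinely open; one-to-one was chosen
because it cannot count one annotation as agreeing with two conflicting
partners. When every predicted boundary exactly equals a gold boundary and
all instances of a concept have the same span length, per-concept IoU
reduces exactly to this instance-level Jaccard score — the property test
uses constant-length spans per concept because with unequal lengths the
character-weighted and instance-weighted ratios legitimately differ.

## The error taxonomy

`classify_errors()` compares the gold standard with the *bag union* of one
or more systems' predictions (duplicates preserved) and assigns each
annotation one of five categories per overlapping pair:

| situation | gold-side record | prediction-side record |
|---|---|---|
| overlap, same concept | Correct | — |
| overlap, different concept | False-Negative Link | False-Positive Link |
| gold span overlapped by nothing | False-Negative Span | — |
| prediction overlapping nothing | — | False-Positive Span |

The nested pairwise loops are applied literally: a gold span overlapped by
$k$ predictions yields $k$ records. This double counting is intentional (it
is what the pairwise definition says), and a `dedupe = TRUE` variant that
collapses to one record per annotation — Correct winning over
False-Negative Link — is available for consumers who want per-annotation
rather than per-pair accounting. Each record is weighted by its own span
length in characters; `error_table()` then reports, within each difficulty
class, the percentage of character weight per category, so each row sums
to 100. Per-record span-length weighting is the simplest defensible reading
of "number of characters affected"; an alternative (weighting by the
overlap length of the pair) would underweight span errors and is not used.

`partition_hard_easy()` splits concepts at an IoU threshold (default 0.1):
a concept is *hard* only if it falls below the threshold in **every**
report, with absence from a report counting as 0. The 0.1 default reflects
the strongly bimodal per-concept score distributions this task produces,
where scores pile up below 0.1 and above 0.9.

`feature_associations()` (Kendall's tau, tau-b tie handling via
`stats::cor`) and `system_correlation()` (Spearman's rho) quantify how
difficulty features track per-concept scores and how similar two systems'
difficulty profiles are; constant vectors yield `NA` with a warning rather
than a spurious coefficient.

## Concept difficulty features

`feature_table()` computes, per concept:

* **mean_span_length** (characters) — short spans tend to be abbreviations
  and are harder to detect; pooled over both splits.
* **concept_entropy** (bits) — Shannon entropy of the bag of normalized
  span strings linked to the concept: 0 when the concept is always written
  one way, $\log_2 k$ for $k$ equally common surface forms.
* **annotation_entropy** (bits) — for concept $C$, collect the distinct
  normalized strings $A$ linked to $C$, then the bag $B$ of all concepts
  linked anywhere to any string in $A$ (with multiplicity), and take the
  entropy of $B$. It measures how many plausible targets a linker faces
  when it sees one of $C$'s surface forms. Each distinct string contributes
  its corpus-wide concept counts once; an option (`weight_by_span = TRUE`)
  additionally weights by the string's multiplicity under $C$, since both
  readings of "the bag of concepts linked to the spans" are defensible.
* **depth** — shortest is-a chain (in edges) to the terminology root, root
  depth 0; in a multi-hierarchy the shortest chain wins. Deeper concepts are
  more clinically specific.
* **n_examples**, **n_notes** — training-split annotation count and distinct
  training-note count. Counting on the training split only is deliberate:
  these features proxy how much signal a model had available at training
  time, and test-only concepts should show 0.

Span strings are normalized (lowercase, trim, collapse internal whitespace)
before bagging; without this, trivial casing variants inflate both
entropies. Entropy base 2 is a convention — any fixed base preserves every
ordering used downstream.

```{r entropy}
entropy_bits(c(15, 1, 1, 2, 1))  # one dominant surface form + 4 rare ones
entropy_bits(c(9, 1))            # a string linked 9:1 between two concepts
```

## Majority voting

`majority_vote()` combines systems at the granularity the metric is defined
on: the character. Each system votes per character (not annotating counts
as a "no annotation" vote); a character receives a concept only when a
strict majority (votes $> n/2$) agrees, which makes the winner unique by
construction; ties and sub-quorum pluralities abstain, which is the
conservative choice — the combiner never fabricates a link that most
systems did not make. Maximal runs of identical winning concepts are then
reassembled into spans. The rule is idempotent and order-invariant, and on
synthetic data with independent low-rate corruptions the voted set's mean
IoU is at least each individual system's (up to sampling noise).

## The synthetic benchmark generator

Real gold-standard corpora for this task are access-restricted, so linkeval
ships a generator whose outputs have the statistical structure the analysis
machinery assumes:

* `gen_terminology()` — a rooted acyclic is-a multi-hierarchy
  (`n_concepts`, default 300, root included; `max_depth` 6; a
  `multi_parent_frac` of 0.15 gives second parents that are strictly
  shallower, so acyclicity holds by construction). Synonyms are
  pseudo-clinical phrases ("acute chest pain", "effusion of knee"); an
  `ambiguity` fraction (default 0.2) of strings is also assigned to a
  sibling concept, producing the many-to-many span/concept ambiguity that
  drives annotation entropy.
* `gen_corpus()` — `n_docs` (default 40) notes, each structured into a
  fixed 7-section layout with headers, with 20–40 gold mentions per note.
  Concepts are drawn under a Zipf law (`rank^-s`, default exponent 1.1), so
  example counts are heavy-tailed: a few very frequent concepts, a long
  tail of rare ones. Gold offsets exactly cover the embedded synonym
  strings and never overlap.
* `perturb()` — four independent noise channels, each aligned with one
  error category: drop a span with `p_miss` (False-Negative Span), re-link
  a survivor to a *sibling* concept with `p_confuse` (link confusion among
  semantically adjacent concepts, the realistic failure mode — uniform
  random relinking would make link errors trivially detectable), jitter
  boundaries by up to `jitter` characters (clamped so spans stay disjoint
  and in bounds; an infeasible jitter is skipped and logged), and add
  `Poisson(spur_rate)` spurious spans per note, each reusing a real synonym
  string placed on unannotated text so False-Positive Spans are
  string-plausible. Every event goes into a truth log from which expected
  error totals are recomputable exactly.

Defaults were chosen once as a desk-scale emulation of a real annotation
exercise (hundreds of concepts, tens of notes, tens of annotations per
note, heavy-tailed frequencies, moderate noise); the parameter-recovery
tests run the miss/confuse/spurious channels at rate 0.3 (or 2 spans/note)
over roughly 15–40k gold characters, where binomial sampling error is well
inside the tolerances checked.

What the generator does **not** emulate: real clinical language (filler
text is random words), deidentification artifacts, section-dependent
concept usage, annotator drift over time, and the scale of real
terminologies. Passing tests on synthetic data therefore demonstrate the
*correctness of the machinery* — scoring, taxonomy, features, voting — not
the performance any real system would achieve on clinical text.

```{r bundle}
cfg <- sim_config(seed = 7, n_concepts = 80, n_docs = 10,
                  anns_per_doc = c(10, 20))
b <- simulate_bundle(cfg, n_systems = 3)
r <- score_submission(b$gold, b$preds$sys1, n_boot = 200, seed = 1)
r
```

## Numerical and degenerate-input choices

* All randomness is funneled through explicit seeds; seeded code saves and
  restores the caller's RNG state, and identical (config, seed) pairs give
  byte-identical files through the writers.
* Scoring two sets with disjoint document universes is a likely user error:
  it warns but still returns the (all-zero) scores.
* An empty prediction set scores 0 for every gold concept; scoring two
  empty sets is an error (there is nothing to average).
* Entropy of an empty bag is an error; a single-element bag is 0 bits.
* `error_table()` on a class with no records returns `NA` percentages with
  a warning rather than dividing by zero.
* Greedy IAA matching breaks ties deterministically (overlap length, then
  start positions, then input order).
* Percentile CIs use `stats::quantile` defaults (type 7).

## Pipeline and command line

`run_pipeline()` sequences everything — per-system scores with CIs, the
voted ensemble, the hard/easy partition, the error ledger and table, the
feature table, rank associations — and writes JSON/CSV outputs plus a
manifest (package version, seeds, MD5 digests of file inputs; no
timestamps, so reruns are byte-identical). Any stage failure aborts with
the stage name. A thin command-line wrapper over these functions ships at
`inst/cli/linkeval.R` with subcommands `score`, `errors`, `features`,
`vote`, `simulate`, and `run`.

## Known limitations

* The union-averaging domain and the class-weighted formula are reasoned
  choices where the metric's prose description is ambiguous; both are
  documented above and isolated in `score_submission()`.
* The literal pairwise error taxonomy double-counts multiply-overlapped
  annotations; use `dedupe = TRUE` when per-annotation accounting matters.
* `iaa_jaccard()`'s greedy matching is not guaranteed maximum-cardinality
  in adversarial overlap patterns (a maximum bipartite matching could
  differ); on non-overlapping annotation sets, where each annotation
  overlaps few partners, the greedy result is essentially always maximal.
* The generator's documents are statistically, not linguistically,
  realistic; do not use it to estimate absolute system performance.
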