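---
title: "Structuring free-text nursing notes: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structuring free-text nursing notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notestructr)
```

## The problem

Nursing documentation standards organize daily care notes into paragraphs,
each filed under a *subject heading* drawn from a large care-classification
taxonomy (hundreds of headings, split into nursing *diagnoses* and nursing
*interventions*, each with a three-level hierarchy). Writing this way is
laborious: the nurse must pick headings from the taxonomy and sort sentences
under them. `notestructr` implements the opposite workflow — the nurse
writes a free narrative and the system structures it:

1. **Segment** the narrative into sentences (rule-based, with protections
   for decimal numbers and abbreviations — clinical text is full of doses
   and timestamps).
2. **Classify** each sentence into a heading, keeping the classifier's full
   probability distribution over headings (the sentence's *confidence
   profile*).
3. **Group** same-heading sentences into paragraphs (first-occurrence
   order).
4. **Merge** (optionally) paragraphs the model considers near-duplicates,
   using the asymmetric similarity score below.

Stopping after step 3 is the *NoMerging* variant; adding step 4 gives
*WithMerging*. Merging exists because per-sentence classification tends to
shatter a note into more paragraphs than a nurse would write; collapsing
near-synonymous paragraphs brings the count back toward human practice.

## The paragraph similarity score

For a source paragraph $A$ and target paragraph $B$ with headings $h_A \ne
h_B$ in a note of $N$ sentences, the directed score is

$$
S(A \to B) \;=\; \underbrace{\frac{1}{|A|}\sum_{s \in A}
\bigl[\,c_s(h_B) - (c_s(h_A) - c_s(h_B))\,\bigr]}_{\text{confidence term}
\;\in\; [-1,\,2]}
\;+\; \underbrace{\mathrm{headsim}(h_A, h_B)}_{\in\; [-1,\,0]}
\;+\; \underbrace{\frac{|B|}{N}}_{\in\; (0,\,1]}
$$

where $c_s(\cdot)$ is the classifier confidence of sentence $s$ and
$\mathrm{headsim}(h_A,h_B) = -\tfrac{1}{2}\bigl(1 -
\cos(v_{h_A}, v_{h_B})\bigr)$ over the learned heading vectors. The first
term asks how well $A$'s sentences would sit under $B$'s heading, penalized
by how much they prefer their own; the second rewards semantically similar
headings; the third prefers keeping the headings of large paragraphs. The
score is asymmetric and spans the range **3 down to −2**; `score_range()`
derives both bounds by driving each term to its extreme through the
implementation itself, and neither bound is attained (the target paragraph
can never be the entire note).

A note on the heading term's sign and scale: stated verbally, the score
"adds the cosine distance", yet more similar headings must score *higher*.
Adding a raw cosine distance would do the opposite, and no affine placement
of a raw distance in $[0,2]$ reproduces the stated $[-2, 3]$ total range.
Rescaling to $-\tfrac{1}{2}(1-\cos) \in [-1, 0]$ is the unique choice among
the natural sign/scale candidates that both rewards similarity and yields
exactly that range (confidence term $[-1,2]$, heading term $[-1,0]$,
relative size $(0,1]$), so the package adopts it.

### The merge loop

While any pair of paragraphs exceeds the threshold **in both directions**,
the pair with the largest *mutual similarity* — defined as
$\min\{S(A \to B),\, S(B \to A)\}$, consistent with the both-directions
requirement — is merged, and the matrix is recomputed. Two wordings in the
procedure's description are underdetermined, and the package fixes them
explicitly:

* *"the two most similar paragraphs"*: largest mutual (minimum) directed
  score; exact ties go to the lexicographically first paragraph-index pair.
* *"keeping the heading of the paragraph with the lowest score"*: the
  member with the **lower outgoing score** keeps its heading — it is the
  one less inclined to adopt the other's heading, so its own heading
  survives. Ties keep the earlier paragraph's heading.

The merged paragraph's sentences stay in note order, and each merge reduces
the paragraph count by one, so at most $p-1$ merges happen per note
(`max_iterations` is a pure safety net). The relative-size denominator is
the whole note's sentence count, matching the phrase "compared against the
whole nursing note". Sentences keep their original confidence profiles
after a merge; nothing is re-classified.

### Threshold calibration

The threshold is not a free parameter: it is tuned so that the system
produces roughly as many paragraphs as the reference versions of a
calibration sample. `calibrate_threshold()` sweeps a grid over $[-2, 3]$
(default step 0.05), counts the total paragraphs produced at each
threshold, and returns the grid point minimizing the absolute gap to the
reference **total** (not the per-note mean — with totals, large notes weigh
more, which matches how a corpus-level paragraph count is reported). Ties
go to the larger threshold, i.e. the least merging that achieves the best
match. Produced totals are a non-decreasing step function of the threshold,
which the test suite exercises across the grid.

## The classifier

Every sentence is one training example; its heading is the target class.
Two interchangeable backends sit behind one interface, and the whole
downstream pipeline is backend-agnostic (this is tested by running the
structurer under both):

* **`bow_softmax`** — multinomial softmax regression on bag-of-words
  counts, trained full-batch with Adam (learning rate 0.5, ridge penalty
  `1e-4`). Convex, fast, deterministic from a zero start. Its output
  weight matrix has one row per heading of width `|vocabulary|`.
* **`recurrent`** — a bidirectional recurrent encoder: pretrained word
  embeddings feed tanh recurrent units run in both directions; the final
  states are concatenated (width `2 × hidden_dim_per_direction`) into a
  softmax output layer, trained by backpropagation through time with Adam
  on minibatches of 16 with gradient-norm clipping at 5. The reference
  architecture for this design uses 300-d embeddings and 600 units per
  direction (1200-d heading vectors); the package default mirrors those
  dimensions, while tests run far smaller ones. Gated units (LSTM/GRU)
  would be the production choice for long sentences; at the 7-token
  sentence lengths this pipeline targets, plain tanh units learn the same
  separable structure and keep the implementation dependency-free, which is
  why the package uses them.

Both backends stop early on development-set top-1 accuracy with a patience
in epochs (the monitoring metric had to be fixed somewhere; top-1 accuracy
is what the pipeline ultimately consumes) and keep the best-scoring
parameters. Training is deterministic on CPU at a fixed seed.

Word embeddings are pretrained from the training corpus itself with a
count-based distributional method: sentence-internal co-occurrence counts
in a symmetric 2-token window, positive pointwise mutual information, and a
sign-fixed truncated SVD. This gives the same "same context ⇒ nearby
vector" behaviour as a sampled skip-gram trainer while being exactly
reproducible. Embeddings are fine-tuned during recurrent training by
default (`freeze_embeddings = FALSE`) — with trainable embeddings the toy
corpora converge faster, and a flag preserves the frozen alternative.

Sentences with no tokens (blank lines, stray punctuation) get a uniform
confidence profile plus a warning rather than an error: real narratives
contain such lines and a pipeline must survive them. Sentences of only
unknown tokens reduce to the reserved `<unk>` token.

## Heading vectors and taxonomy analysis

The rows of the trained classifier's output weight matrix serve as learned
semantic representations of the headings (the bias is excluded — it encodes
class frequency, not content). `build_rankings()` compares this learned
geometry against the taxonomy: cosine distances between heading vectors on
one side, shortest-path edge counts in the taxonomy tree on the other
(diagnoses and interventions joined under an artificial root, so two
deepest-level leaves in different categories sit 8 edges apart), each
ranked ascending over all heading pairs. Tree distances are small integers,
so ties are pervasive; fractional (average) ranks keep the two rankings
comparable, and `spearman_rho()` is tie-corrected accordingly.
`conflict_pairs()` sorts pairs by signed rank difference in either
direction — both directions are exposed because "furthest apart" can be
read signed or absolute; the signed form with a direction argument
subsumes both readings. Headings are mapped onto taxonomy nodes by strict
string matching; unmapped headings are dropped and reported rather than
fuzzily matched.

`cluster_headings()` provides the dendrogram view (agglomerative clustering
under cosine distance, Newick export). Average linkage is the default: the
clustering is illustrative, and average linkage is the least
outlier-sensitive of the three offered.

## The synthetic generator

No clinical corpus can ship with the package, so `generate_corpus()` /
`generate_unstructured_notes()` emulate the statistical structure the
pipeline assumes:

* a two-category taxonomy of configurable branching, depth ≤ 4 with the
  root at 0;
* one multinomial topic per **leaf** heading, drawn from a symmetric
  Dirichlet (concentration 0.05 over a 500-token vocabulary by default —
  sparse, well-separated topics). Internal nodes are structural only:
  in practice the headings actually used in documentation are the specific
  ones, and giving only leaves content keeps gold partitions unambiguous;
* sentence length `1 + Poisson(6)` (mean 7 tokens, minimum 1) and
  sentences-per-paragraph `1 + Geometric` with mean 2.1 — the shifted
  geometric is the simplest ≥ 1 count distribution matching a stated mean;
* 3–8 distinct headings per note, 400 notes by default (≈ 210 sentences
  per heading across 20 leaf headings);
* optional **conflated pairs**: a diagnosis leaf and an intervention leaf
  assigned the *identical* topic distribution, emulating heading twins
  such as a condition and the intervention monitoring it, under which the
  same content is documented.

Every output is a pure function of (config, seed). What the generator does
*not* emulate: morphology and spelling variation, multi-topic sentences,
dictation noise, label noise in gold headings, and realistic heading
frequency skew. Passing the recovery tests therefore shows the pipeline's
machinery is correct and that separable content is recovered — it does not
predict clinical-corpus accuracy, where reported sentence-level top-1
figures sit near 54%, not the ≥ 90% these clean topics allow.

## Numerical choices and degenerate inputs

* Softmax rows are max-shifted before exponentiation; cross-entropy clamps
  probabilities at `1e-300`.
* Mutual-similarity comparisons use a `1e-15` slack so that floating-point
  noise cannot flip a tie-break.
* Zero heading vectors make cosine undefined; every cosine path errors with
  the offending heading named.
* Empty notes structure to zero paragraphs; single-paragraph notes skip
  merging entirely.
* Percentage summaries round half away from zero at two decimals, matching
  how such tables are conventionally printed (base `round()` is
  half-to-even).
* `split_corpus` assigns whole notes to splits, never sentences — wards
  write near-duplicate sentences, and sentence-level splitting would leak
  them across train/test.

## Problem sizes in the shipped tests

The test and acceptance suites run the full study loop at desk scale: the
default generator (20 leaf headings, ≈ 4 800 sentences), a 60/20/20
note-level split, a 50-note calibration/evaluation sample, 101-point
calibration grids, 100 random trees for the distance oracle, and
2 000-draw admissibility samples for the score range. These sizes were
chosen so the whole suite completes in a couple of minutes on one CPU while
still exercising every moving part; all of them scale up linearly through
`generator_config()` if heavier runs are wanted.

## Known limitations

* Sentence segmentation is rule-based and ships a generic abbreviation
  list; a deployment would extend the rule table to its language and ward
  conventions.
* One heading per sentence: multi-topic sentences are assigned to a single
  paragraph, never split.
* The merge step never introduces headings outside the inventory and never
  splits paragraphs; an over-merged paragraph stays merged.
* The recurrent backend is pure R and meant for desk-scale corpora;
  training millions of sentences would require a compiled implementation
  and gated units.
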