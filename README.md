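# notestructr

Automatic structuring of free-text nursing notes.

Nursing documentation standards expect daily care notes to be organized as
paragraphs filed under *subject headings* from a care-classification
taxonomy — a tree of nursing diagnoses and interventions, hundreds of
headings deep. Writing that way by hand is slow. `notestructr` lets the
narrative be written freely and structures it afterwards: it segments the
text into sentences, classifies every sentence into a heading (keeping the
classifier's full confidence profile), groups same-heading sentences into
paragraphs, and optionally merges near-duplicate paragraphs. It also ships
the analysis tooling for auditing the heading taxonomy against how headings
are actually used, and a synthetic corpus generator so the entire pipeline
is testable without access to clinical data.

The package is aimed at clinical-NLP researchers and engineers building or
evaluating note-structuring systems.

## The method

**Pipeline.** (1) rule-based sentence segmentation (decimal numbers and
abbreviations protected); (2) a multiclass sentence classifier — softmax
regression on bag-of-words, or a bidirectional recurrent encoder — trained
with Adam, early-stopped on dev accuracy; (3) grouping by predicted
heading; (4) iterative paragraph merging.

**The merge score.** For source paragraph *A* and target paragraph *B* in a
note of *N* sentences, with classifier confidences *c_s(·)* and heading
vectors *v_h* (rows of the classifier's output weight matrix):

    S(A→B) = mean_{s∈A} [ 2·c_s(h_B) − c_s(h_A) ]        ∈ [−1, 2]
           − (1 − cos(v_{h_A}, v_{h_B})) / 2              ∈ [−1, 0]
           + |B| / N                                      ∈ (0, 1]

The score is asymmetric with attainable range (−2, 3). Two paragraphs merge
when both directed scores exceed a threshold; the qualifying pair with the
largest mutual score min{S(A→B), S(B→A)} merges first, the member with the
lower outgoing score keeps its heading, and the matrix is recomputed until
no pair qualifies. The threshold is calibrated on a sample of notes so the
produced paragraph total matches the reference total.

**Taxonomy audit.** Heading pairs are ranked twice — by cosine distance of
their learned vectors and by shortest-path distance in the taxonomy tree
(diagnoses and interventions joined under an artificial root). Fractional
ranks, tie-corrected Spearman's rho, and signed rank differences surface
*conflict pairs*: headings the model finds interchangeable but the taxonomy
keeps far apart (typically diagnosis/intervention twins documented with
identical content).

## Worked example

Everything below runs in a few seconds on one CPU; all data is synthetic.

```r
library(notestructr)

cfg    <- generator_config(seed = 1)        # 20 leaf headings, 400 notes
tax    <- generate_taxonomy(cfg)
corpus <- generate_corpus(tax, cfg)
splits <- split_corpus(corpus, seed = 1)    # 60/20/20 by note

model <- train_classifier(splits$train, splits$dev, classifier_config(seed = 1))
glance(model)
#> # A tibble: 1 × 6
#>   backend     n_headings vocab_size vector_width epochs_trained best_dev_accuracy
#>   <chr>            <int>      <int>        <int>          <int>             <dbl>
#> 1 bow_softmax         20        484          484             24             0.997

top_k_accuracy(model, splits$test, k = 1)
#> [1] 0.9929648
```

Structure unseen free-text notes, calibrating the merge threshold against
the reference paragraph counts:

```r
notes <- generate_unstructured_notes(tax, generator_config(seed = 1, n_notes = 50))
vec   <- heading_vectors(model)
thr   <- calibrate_threshold(notes[, c("text", "ref_paragraphs")], model, vec)
thr
#> <threshold_calibration> threshold 3 -> total paragraphs 270 (reference 270)
```

With fully separable synthetic topics the step-3 output already matches the
reference counts, so calibration selects the top of the grid (no merging
needed) and recovery is exact:

```r
structured <- lapply(seq_len(nrow(notes)), function(i)
  structure_note(notes$text[i], model, vec, threshold = thr,
                 note_id = notes$note_id[i]))
evaluate_structuring(notes$gold, structured)
#> # A tibble: 1 × 6
#>   n_notes heading_accuracy precision recall    f1 total_paragraphs
#>     <int>            <dbl>     <dbl>  <dbl> <dbl>            <int>
#> 1      50                1         1      1     1              270
```

`heading_accuracy` is the fraction of sentences assigned their gold
heading; `precision`/`recall`/`f1` score unordered same-paragraph sentence
pairs against the gold partition; `total_paragraphs` is the corpus-wide
paragraph count after structuring.

The analytic range of the merge score is available directly:

```r
score_range()[, 1:3]
#> # A tibble: 2 × 3
#>   bound    value attained
#>   <chr>    <dbl> <lgl>
#> 1 infimum     -2 FALSE
#> 2 supremum     3 FALSE
```

Planting conflated cross-category heading pairs
(`generator_config(n_conflated_pairs = 3)`) and rerunning the training
makes those pairs surface as the top `conflict_pairs()` of
`build_rankings(heading_vectors(model), tax)` — the taxonomy-audit use
case.

A thin command-line front end over the same functions lives at
`inst/cli/notestructr.R` (subcommands `generate`, `train`, `structure`,
`calibrate`, `evaluate`).

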