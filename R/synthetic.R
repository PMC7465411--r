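#' Synthetic-corpus generator configuration
#'
#' The generator emulates the statistical shape of heading-annotated nursing
#' narratives without any clinical content: a two-category taxonomy
#' (diagnoses and interventions, three levels under each category beneath an
#' artificial root), one multinomial topic per leaf heading drawn from a
#' sparse Dirichlet, short heading-conditioned sentences, and notes composed
#' of a few headings with a couple of sentences each. Conflated pairs — one
#' diagnosis leaf and one intervention leaf sharing the *same* topic
#' distribution — plant the kind of cross-category heading twins that
#' conflict analysis should rediscover.
#'
#' Defaults follow the corpus statistics the pipeline targets: mean sentence
#' length 7 tokens, mean 2.1 sentences per paragraph, and 20 leaf headings
#' with roughly 200 sentences each at `n_notes = 400`.
#'
#' @param n_level1,n_level2,n_level3 branching counts per category at each
#'   level; leaves are the level-3 nodes (`n_level1*n_level2*n_level3` per
#'   category).
#' @param vocab_size abstract vocabulary size (tokens `w001`, `w002`, ...).
#' @param topic_concentration Dirichlet concentration for leaf topics; small
#'   values give sparse, well-separated topics.
#' @param mean_sentence_tokens mean tokens per sentence
#'   (`1 + Poisson(mean - 1)`, so always >= 1).
#' @param mean_sentences_per_paragraph mean sentences a heading contributes
#'   to a note (`1 + Geometric`, support >= 1).
#' @param headings_per_note_min,headings_per_note_max uniform range of
#'   distinct headings per note.
#' @param n_notes number of notes to generate.
#' @param n_conflated_pairs cross-category heading pairs assigned identical
#'   topic distributions.
#' @param seed integer; every generator output is a pure function of
#'   (config, seed).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_level1 = 2L, n_level2 = 5L, n_level3 = 1L,
                             vocab_size = 500L,
                             topic_concentration = 0.05,
                             mean_sentence_tokens = 7,
                             mean_sentences_per_paragraph = 2.1,
                             headings_per_note_min = 3L,
                             headings_per_note_max = 8L,
                             n_notes = 400L,
                             n_conflated_pairs = 0L,
                             seed = 1L) {
  stopifnot(is_count(n_level1), is_count(n_level2), is_count(n_level3),
            is_count(vocab_size), is_count(n_notes),
            topic_concentration > 0, mean_sentence_tokens > 0,
            mean_sentences_per_paragraph >= 1,
            headings_per_note_min >= 1,
            headings_per_note_max >= headings_per_note_min,
            n_conflated_pairs >= 0)
  structure(
    list(
      n_level1 = as.integer(n_level1), n_level2 = as.integer(n_level2),
      n_level3 = as.integer(n_level3), vocab_size = as.integer(vocab_size),
      topic_concentration = topic_concentration,
      mean_sentence_tokens = mean_sentence_tokens,
      mean_sentences_per_paragraph = mean_sentences_per_paragraph,
      headings_per_note_min = as.integer(headings_per_note_min),
      headings_per_note_max = as.integer(headings_per_note_max),
      n_notes = as.integer(n_notes),
      n_conflated_pairs = as.integer(n_conflated_pairs),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Generate a two-category heading taxonomy
#'
#' Builds the synthetic analogue of a care-classification tree: an
#' artificial root joining a diagnosis and an intervention category, each
#' carrying a three-level hierarchy per the branching counts. Node depth is
#' therefore at most 4 (root at 0). The structure is fully determined by the
#' config.
#'
#' @param config a [generator_config()].
#' @return a [heading_taxonomy()].
#' @export
generate_taxonomy <- function(config = generator_config()) {
  cat_nodes <- function(prefix, category) {
    l1 <- paste0(prefix, seq_len(config$n_level1))
    l2 <- as.vector(t(outer(l1, seq_len(config$n_level2), paste, sep = ".")))
    l3 <- as.vector(t(outer(l2, seq_len(config$n_level3), paste, sep = ".")))
    tibble(
      id = c(l1, l2, l3),
      parent = c(rep(category, length(l1)),
                 rep(l1, each = config$n_level2),
                 rep(l2, each = config$n_level3)),
      category = category
    )
  }
  nodes <- dplyr::bind_rows(
    tibble(id = "root", parent = NA_character_, category = NA_character_),
    tibble(id = c("diagnosis", "intervention"), parent = "root",
           category = c("diagnosis", "intervention")),
    cat_nodes("D", "diagnosis"),
    cat_nodes("I", "intervention")
  )
  heading_taxonomy(nodes)
}

# leaf ids of one category, in id order
category_leaves <- function(tax, category) {
  sort(tax$id[tax$is_leaf & !is.na(tax$category) & tax$category == category])
}

# Dirichlet-drawn topic per leaf; conflated pairs share one distribution.
# Must be called inside a seeded RNG context.
draw_topics <- function(tax, config) {
  dia <- category_leaves(tax, "diagnosis")
  int <- category_leaves(tax, "intervention")
  leaves <- c(dia, int)
  if (config$n_conflated_pairs > min(length(dia), length(int))) {
    abort("`n_conflated_pairs` exceeds the available cross-category leaves")
  }
  V <- config$vocab_size
  topics <- t(vapply(leaves, function(l) {
    g <- stats::rgamma(V, shape = config$topic_concentration)
    g / sum(g)
  }, numeric(V)))
  rownames(topics) <- leaves
  pairs <- NULL
  if (config$n_conflated_pairs > 0L) {
    a <- resample(dia, config$n_conflated_pairs)
    b <- resample(int, config$n_conflated_pairs)
    topics[b, ] <- topics[a, , drop = FALSE]
    pairs <- tibble(a = a, b = b)
  }
  list(topics = topics, conflated_pairs = pairs, leaves = leaves)
}

# one sentence: token count 1 + Poisson(mean-1), tokens i.i.d. from the topic
draw_sentence <- function(topic, config) {
  n <- 1L + stats::rpois(1L, config$mean_sentence_tokens - 1)
  paste(sprintf("w%03d", sample.int(config$vocab_size, n, replace = TRUE, prob = topic)),
        collapse = " ")
}

# sample() that never falls into the scalar-expansion trap
resample <- function(x, size) x[sample.int(length(x), size)]

# one note: a few distinct headings, 1 + Geometric sentences each
draw_note <- function(topics, config) {
  leaves <- rownames(topics)
  k <- resample(seq.int(config$headings_per_note_min,
                        min(config$headings_per_note_max, length(leaves))), 1L)
  heads <- resample(leaves, k)
  p_stop <- 1 / config$mean_sentences_per_paragraph
  purrr::map_dfr(heads, function(h) {
    ns <- 1L + stats::rgeom(1L, p_stop)
    tibble(heading = h,
           text = vapply(seq_len(ns), function(i) draw_sentence(topics[h, ], config),
                         character(1)))
  })
}

#' Generate a labeled training corpus
#'
#' Draws `n_notes` heading-structured notes and flattens them into sentence
#' records. The leaf topic distributions (and any conflated pairs) are
#' attached as attributes `"topics"` and `"conflated_pairs"`.
#'
#' @param tax a taxonomy from [generate_taxonomy()].
#' @param config a [generator_config()].
#' @return a labeled-corpus tibble (`note_id`, `index`, `text`, `heading`).
#' @export
generate_corpus <- function(tax, config = generator_config()) {
  topics <- withr::with_seed(config$seed, draw_topics(tax, config))
  recs <- withr::with_seed(config$seed + 1L, {
    purrr::map_dfr(seq_len(config$n_notes), function(i) {
      note <- draw_note(topics$topics, config)
      note$note_id <- sprintf("note%05d", i)
      note
    })
  })
  out <- labeled_corpus(recs$note_id, recs$text, recs$heading)
  attr(out, "topics") <- topics$topics
  attr(out, "conflated_pairs") <- topics$conflated_pairs
  out
}

#' Generate unstructured notes with gold structure
#'
#' Emulates notes written as free narrative — no paragraphs, no headings:
#' the sentences of each note are emitted as one plain-text block (in
#' shuffled order unless `shuffle = FALSE`), while the gold heading
#' partition is retained for scoring. Topic distributions are shared with
#' [generate_corpus()] at equal config, so a classifier trained on the
#' corpus transfers.
#'
#' @param tax a taxonomy from [generate_taxonomy()].
#' @param config a [generator_config()]; `n_notes` controls how many notes.
#' @param shuffle shuffle sentence order within each note (default TRUE).
#' @return tibble with columns `note_id`, `text` (the raw narrative),
#'   `ref_paragraphs` (gold paragraph count) and `gold` (list column of
#'   tibbles `index`, `text`, `heading` aligned with the emitted sentence
#'   order).
#' @export
generate_unstructured_notes <- function(tax, config = generator_config(), shuffle = TRUE) {
  topics <- withr::with_seed(config$seed, draw_topics(tax, config))
  withr::with_seed(config$seed + 2L, {
    purrr::map_dfr(seq_len(config$n_notes), function(i) {
      note <- draw_note(topics$topics, config)
      ord <- if (shuffle) sample(nrow(note)) else seq_len(nrow(note))
      note <- note[ord, ]
      gold <- tibble(
        index = seq_len(nrow(note)) - 1L,
        text = paste0(note$text, "."),
        heading = note$heading
      )
      tibble(
        note_id = sprintf("unote%05d", i),
        text = paste(gold$text, collapse = " "),
        ref_paragraphs = dplyr::n_distinct(gold$heading),
        gold = list(gold)
      )
    })
  })
}
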