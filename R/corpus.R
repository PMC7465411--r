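#' Sentence segmentation rules
#'
#' The segmenter is rule-driven: a sentence boundary is a run of terminal
#' punctuation (`.`, `!`, `?`) followed by whitespace or end of text, unless a
#' suppression rule fires. The default rules keep decimal numbers (a period
#' between digits) and a configurable abbreviation list intact. Clinical text
#' is full of timestamps, doses and shorthand, so the rule table is exposed
#' rather than hard-coded.
#'
#' @param abbreviations character vector of abbreviations (matched without the
#'   trailing period, case-insensitively) after which a period never ends a
#'   sentence.
#' @return an object of class `segmenter_rules`.
#' @export
segmenter_rules <- function(abbreviations = c(
                              "e.g", "i.e", "dr", "mr", "mrs", "ms",
                              "vs", "etc", "approx", "cf", "resp"
                            )) {
  structure(list(abbreviations = tolower(abbreviations)), class = "segmenter_rules")
}

#' Split a note into sentences
#'
#' Splits raw note text at terminal punctuation, suppressing boundaries inside
#' decimal numbers and after known abbreviations. The concatenation of the
#' returned spans reconstructs the input up to surrounding whitespace, and
#' indices are consecutive from 0.
#'
#' @param text a single character string (one note).
#' @param rules a [segmenter_rules()] object.
#' @return a tibble with columns `index` (0-based), `text` (the raw sentence
#'   span, trimmed) and `tokens` (list column of lower-cased tokens). Empty or
#'   whitespace-only input yields a zero-row tibble.
#' @examples
#' segment_sentences("Patient slept well. No pain.")
#' @export
segment_sentences <- function(text, rules = segmenter_rules()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble(index = integer(), text = character(), tokens = list())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  term <- chars %in% c(".", "!", "?")
  cuts <- integer(0)
  i <- 1L
  while (i <= n) {
    if (term[i]) {
      j <- i
      while (j < n && term[j + 1L]) j <- j + 1L # absorb runs like "?!" or "..."
      followed <- j == n || grepl("^\\s$", chars[j + 1L])
      if (followed && !suppress_boundary(chars, i, rules)) cuts <- c(cuts, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  keep <- starts <= ends
  spans <- purrr::map2_chr(starts[keep], ends[keep], function(s, e) {
    paste(chars[s:e], collapse = "")
  })
  spans <- trimws(spans)
  spans <- spans[nzchar(spans)]
  if (length(spans) == 0L) return(empty)
  tibble(
    index = seq_along(spans) - 1L,
    text = spans,
    tokens = purrr::map(spans, tokenize)
  )
}

# TRUE when the terminal char at position i must not end a sentence:
# a period squeezed between digits, or following a listed abbreviation
suppress_boundary <- function(chars, i, rules) {
  if (chars[i] != ".") return(FALSE)
  n <- length(chars)
  prev_digit <- i > 1L && grepl("[0-9]", chars[i - 1L])
  next_digit <- i < n && grepl("[0-9]", chars[i + 1L])
  if (prev_digit && next_digit) return(TRUE)
  # word immediately before the period
  j <- i - 1L
  while (j >= 1L && grepl("[[:alnum:].]", chars[j])) j <- j - 1L
  word <- tolower(paste(chars[seq.int(j + 1L, length.out = i - 1L - j)], collapse = ""))
  word <- sub("\\.$", "", word)
  nzchar(word) && word %in% rules$abbreviations
}

#' Tokenize a sentence
#'
#' Lower-cases and extracts tokens: runs of letters/digits, with decimal
#' numbers (`38.5`, `1,5`) kept as single tokens. Punctuation is dropped.
#'
#' @param text a character string.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  m <- stringr::str_extract_all(
    tolower(text),
    "\\p{N}+(?:[.,]\\p{N}+)+|[\\p{L}\\p{N}]+"
  )[[1]]
  m
}

#' Build a labeled corpus
#'
#' A labeled corpus is a tibble of sentence records — one row per sentence —
#' with columns `note_id`, `index` (0-based position within the note), `text`
#' and `heading`. All corpus-level operations take and return this shape.
#'
#' @param note_id,text,heading equal-length vectors.
#' @param index optional 0-based within-note indices; computed per note in
#'   input order when absent.
#' @return a labeled-corpus tibble.
#' @export
labeled_corpus <- function(note_id, text, heading, index = NULL) {
  out <- tibble(
    note_id = as.character(note_id),
    text = as.character(text),
    heading = as.character(heading)
  )
  if (is.null(index)) {
    out <- out %>%
      dplyr::group_by(.data$note_id) %>%
      dplyr::mutate(index = dplyr::row_number() - 1L) %>%
      dplyr::ungroup()
  } else {
    out$index <- as.integer(index)
  }
  dplyr::relocate(out, "note_id", "index", "text", "heading")
}

#' Heading inventory of a corpus
#'
#' @param corpus a labeled-corpus tibble.
#' @return sorted character vector of distinct headings.
#' @export
heading_inventory <- function(corpus) sort(unique(corpus$heading))

#' Drop rare headings
#'
#' Removes every record whose heading occurs fewer than `min_count` times,
#' keeping record order. Mirrors the usual minimum-frequency filter applied to
#' heading inventories before training ("used less than `min_count` times"
#' excluded, so a heading at exactly `min_count` survives).
#'
#' @param corpus a labeled-corpus tibble.
#' @param min_count positive integer; default 100.
#' @return the filtered corpus tibble.
#' @export
filter_min_frequency <- function(corpus, min_count = 100) {
  if (!is_count(min_count)) abort("`min_count` must be a positive integer")
  counts <- table(corpus$heading)
  keep <- names(counts)[counts >= min_count]
  out <- dplyr::filter(corpus, .data$heading %in% keep)
  if (nrow(out) == 0L) abort("filtering removed every record; lower `min_count`")
  out
}

#' Split a corpus into train / dev / test by note
#'
#' Notes (not sentences) are assigned to splits, so sentences of one note
#' never straddle a split boundary; this avoids leakage of near-duplicate
#' sentences between training and evaluation. The default 60/20/20 split is
#' the usual choice for this pipeline.
#'
#' @param corpus a labeled-corpus tibble.
#' @param fractions three non-negative proportions summing to 1.
#' @param seed integer seed; equal seeds give equal partitions.
#' @return named list of tibbles `train`, `dev`, `test`.
#' @export
split_corpus <- function(corpus, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1")
  notes <- unique(corpus$note_id)
  if (length(notes) < sum(fractions > 0)) {
    abort("fewer notes than non-zero split fractions")
  }
  shuffled <- withr::with_seed(seed, sample(notes))
  n <- length(shuffled)
  bounds <- round(cumsum(fractions) * n)
  sizes <- diff(c(0L, bounds))
  assign <- rep(c("train", "dev", "test"), times = sizes)
  split_of <- stats::setNames(assign, shuffled)
  out <- split(corpus, factor(split_of[corpus$note_id], levels = c("train", "dev", "test")))
  lapply(out, as_tibble)
}

#' Read / write labeled corpora
#'
#' TSV files carry columns `note_id`, `sentence_text`, `heading`; JSONL files
#' carry one object per line with keys `note_id`, `sentence_text`, `heading`.
#'
#' @param path file path.
#' @param corpus a labeled-corpus tibble.
#' @return `read_corpus_*` return a labeled-corpus tibble; writers return
#'   `path` invisibly.
#' @name corpus_io
NULL

#' @rdname corpus_io
#' @export
read_corpus_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  labeled_corpus(df$note_id, df$sentence_text, df$heading)
}

#' @rdname corpus_io
#' @export
write_corpus_tsv <- function(corpus, path) {
  readr::write_tsv(
    tibble(note_id = corpus$note_id, sentence_text = corpus$text, heading = corpus$heading),
    path
  )
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_corpus_jsonl <- function(path) {
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  labeled_corpus(
    purrr::map_chr(recs, "note_id"),
    purrr::map_chr(recs, "sentence_text"),
    purrr::map_chr(recs, "heading")
  )
}

#' @rdname corpus_io
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- purrr::pmap_chr(
    list(corpus$note_id, corpus$text, corpus$heading),
    function(n, t, h) {
      jsonlite::toJSON(list(note_id = n, sentence_text = t, heading = h), auto_unbox = TRUE)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write raw notes as JSONL
#'
#' One object per line: `{"note_id": ..., "text": ...}`.
#'
#' @param path file path.
#' @param notes tibble with columns `note_id`, `text`.
#' @return `read_notes_jsonl` returns that tibble; the writer returns `path`
#'   invisibly.
#' @export
read_notes_jsonl <- function(path) {
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  tibble(
    note_id = purrr::map_chr(recs, "note_id"),
    text = purrr::map_chr(recs, "text")
  )
}

#' @rdname read_notes_jsonl
#' @export
write_notes_jsonl <- function(notes, path) {
  lines <- purrr::map2_chr(notes$note_id, notes$text, function(n, t) {
    jsonlite::toJSON(list(note_id = n, text = t), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}
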