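#' Top-k heading accuracy
#'
#' Fraction of test sentences whose gold heading is among the classifier's
#' `k` most confident suggestions (ties broken by heading id, matching
#' [top_k()]).
#'
#' @param model a trained `heading_classifier`.
#' @param test a labeled-corpus tibble.
#' @param k suggestion budget, between 1 and the inventory size.
#' @return proportion in `[0, 1]`.
#' @export
top_k_accuracy <- function(model, test, k = 1L) {
  if (nrow(test) == 0L) abort("`test` is empty")
  if (!is_count(k) || k > length(model$headings)) {
    abort("`k` must be an integer between 1 and the inventory size")
  }
  P <- predict_profiles(model, test$text)
  hit <- vapply(seq_len(nrow(test)), function(i) {
    ord <- order(-P[i, ], model$headings)
    gold <- match(test$heading[i], model$headings)
    !is.na(gold) && gold %in% ord[seq_len(k)]
  }, logical(1))
  mean(hit)
}

#' Pairwise grouping precision, recall and F1
#'
#' Partition-agreement over unordered same-paragraph sentence pairs: a pair
#' counts as predicted (resp. gold) when the two sentences share a predicted
#' (resp. gold) paragraph. Precision and recall default to 1 when the
#' corresponding pair set is empty, so two all-singleton partitions agree
#' perfectly. This is the automated proxy for a human judgment of whether
#' grouped sentences belong together.
#'
#' @param gold,predicted partitions over one sentence set: either tibbles
#'   with columns `index` and a grouping column (`heading` or `paragraph` —
#'   `paragraph` preferred when both are present), or `structured_note`
#'   objects.
#' @return one-row tibble: `precision`, `recall`, `f1`.
#' @export
pairwise_grouping_f1 <- function(gold, predicted) {
  g <- partition_of(gold)
  p <- partition_of(predicted)
  if (!setequal(g$index, p$index)) abort("gold and predicted cover different sentence sets")
  g <- g[order(g$index), ]
  p <- p[order(p$index), ]
  tab <- table(g$group, p$group)
  pairs2 <- function(n) n * (n - 1) / 2
  n_gold <- sum(pairs2(rowSums(tab)))
  n_pred <- sum(pairs2(colSums(tab)))
  n_both <- sum(pairs2(tab))
  precision <- if (n_pred == 0) 1 else n_both / n_pred
  recall <- if (n_gold == 0) 1 else n_both / n_gold
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1)
}

partition_of <- function(x) {
  if (inherits(x, "structured_note")) {
    return(tibble(index = x$sentences$index, group = as.character(x$sentences$paragraph)))
  }
  col <- if ("paragraph" %in% names(x)) "paragraph" else "heading"
  tibble(index = x$index, group = as.character(x[[col]]))
}

#' Paragraph-count reduction percentage
#'
#' `100 * (before - after) / before`: how much the merging step shrinks the
#' paragraph total.
#'
#' @param total_before,total_after paragraph counts before and after
#'   merging.
#' @return percentage (0-100 scale).
#' @export
paragraph_reduction <- function(total_before, total_after) {
  if (!(total_before > 0)) abort("`total_before` must be positive")
  if (total_after < 0 || total_after > total_before) {
    abort("`total_after` must lie in [0, total_before]")
  }
  100 * (total_before - total_after) / total_before
}

#' Paragraph-count summary over notes
#'
#' @param counts integer vector of paragraphs per note.
#' @return one-row tibble: `n_notes`, `total`, `mean`, `min`, `max`.
#' @export
paragraph_stats <- function(counts) {
  stopifnot(length(counts) > 0)
  tibble(
    n_notes = length(counts), total = sum(counts),
    mean = sum(counts) / length(counts),
    min = min(counts), max = max(counts)
  )
}

#' Rating tables
#'
#' Human evaluations of system output enter the package only as count
#' tables: per system variant, how many paragraphs fell in each rating class
#' (heading classes 1-4: from "heading suits the text" down; grouping
#' classes a-d: from "sensible grouping" down; and joint classes such as
#' "1&a"). The package does the summary arithmetic, not the judging.
#'
#' @param counts tibble with columns `variant`, `scale` (e.g. `"heading"`,
#'   `"grouping"`, `"joint"`), `class`, `count`.
#' @param totals named vector of paragraph totals per variant; derived from
#'   the per-scale sums when absent.
#' @return object of class `rating_table`.
#' @export
rating_table <- function(counts, totals = NULL) {
  stopifnot(all(c("variant", "scale", "class", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("negative counts")
  if (is.null(totals)) {
    sums <- counts %>%
      dplyr::filter(.data$scale != "joint") %>%
      dplyr::group_by(.data$variant, .data$scale) %>%
      dplyr::summarise(total = sum(.data$count), .groups = "drop")
    if (any(tapply(sums$total, sums$variant, function(x) length(unique(x))) > 1)) {
      abort("per-scale class counts disagree on the variant total; pass `totals`")
    }
    tot <- tapply(sums$total, sums$variant, unique)
    totals <- stats::setNames(as.numeric(tot), dimnames(tot)[[1L]])
  }
  bad <- counts$count > totals[counts$variant]
  if (any(bad)) abort("class count exceeds its variant total")
  structure(list(counts = as_tibble(counts), totals = totals), class = "rating_table")
}

#' Summarize a rating table
#'
#' Percentage per class (`100 * count / variant total`, two decimals, half
#' away from zero) plus a combined `1+2` row per variant when heading
#' classes 1 and 2 are present (the "heading at least related" share).
#'
#' @param table a [rating_table()].
#' @return tibble with columns `variant`, `scale`, `class`, `count`, `pct`.
#' @export
summarize_ratings <- function(table) {
  counts <- table$counts
  combined <- counts %>%
    dplyr::filter(.data$scale == "heading", .data$class %in% c("1", "2")) %>%
    dplyr::group_by(.data$variant) %>%
    dplyr::filter(dplyr::n() == 2L) %>%
    dplyr::summarise(scale = "heading", class = "1+2",
                     count = sum(.data$count), .groups = "drop")
  out <- dplyr::bind_rows(counts, combined)
  out$pct <- round_half_up(100 * out$count / as.numeric(table$totals[out$variant]), 2)
  dplyr::arrange(out, .data$variant, .data$scale, .data$class)
}

#' Read a rating table from CSV
#'
#' Columns: `variant`, `scale`, `class`, `count`.
#'
#' @param path file path.
#' @return a [rating_table()].
#' @export
read_rating_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    variant = readr::col_character(), scale = readr::col_character(),
    class = readr::col_character(), count = readr::col_double()
  ))
  rating_table(df)
}

#' End-to-end evaluation report
#'
#' Compares predicted structured notes against gold partitions: per-note
#' pairwise grouping scores, sentence-level heading accuracy, and paragraph
#' totals for both pipeline variants when given.
#'
#' @param gold list of gold tibbles (`index`, `text`, `heading`), one per
#'   note.
#' @param predicted list of `structured_note` objects aligned with `gold`.
#' @return one-row tibble: `n_notes`, `heading_accuracy`, `precision`,
#'   `recall`, `f1` (pair counts pooled over notes), `total_paragraphs`.
#' @export
evaluate_structuring <- function(gold, predicted) {
  stopifnot(length(gold) == length(predicted))
  acc_n <- 0L; acc_hit <- 0L
  n_gold <- 0; n_pred <- 0; n_both <- 0
  pairs2 <- function(n) n * (n - 1) / 2
  for (i in seq_along(gold)) {
    g <- gold[[i]]
    pn <- predicted[[i]]
    s <- pn$sentences[order(pn$sentences$index), ]
    gg <- g[order(g$index), ]
    acc_hit <- acc_hit + sum(s$heading == gg$heading)
    acc_n <- acc_n + nrow(gg)
    tab <- table(gg$heading, s$paragraph)
    n_gold <- n_gold + sum(pairs2(rowSums(tab)))
    n_pred <- n_pred + sum(pairs2(colSums(tab)))
    n_both <- n_both + sum(pairs2(tab))
  }
  precision <- if (n_pred == 0) 1 else n_both / n_pred
  recall <- if (n_gold == 0) 1 else n_both / n_gold
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(
    n_notes = length(gold),
    heading_accuracy = acc_hit / acc_n,
    precision = precision, recall = recall, f1 = f1,
    total_paragraphs = sum(vapply(predicted, n_paragraphs, integer(1)))
  )
}
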