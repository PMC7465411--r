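# hand-crafted classifier whose confidence ordering is fully controlled:
# token "u" ranks gold heading A first, token "v" ranks it second
stub_model <- function() {
  W <- rbind(A = c(u = 2, v = 1, `<unk>` = 0),
             B = c(u = 1, v = 2, `<unk>` = 0),
             C = c(u = 0, v = 0, `<unk>` = 0))
  structure(
    list(
      config = classifier_config(max_epochs = 1),
      vocabulary = c("u", "v", "<unk>"),
      headings = c("A", "B", "C"),
      params = list(W_out = W, b_out = c(A = 0, B = 0, C = 0)),
      history = tibble::tibble(epoch = integer(), train_loss = numeric(),
                               dev_accuracy = numeric())
    ),
    class = "heading_classifier"
  )
}

test_that("top-k accuracy counts gold headings within the suggestion budget", {
  m <- stub_model()
  test <- labeled_corpus(
    note_id = paste0("n", 1:4),
    text = c("u", "u", "v", "v"),
    heading = rep("A", 4)
  )
  expect_equal(top_k_accuracy(m, test, 1), 0.5) # gold 2nd for the "v" half
  expect_equal(top_k_accuracy(m, test, 2), 1.0)
  expect_equal(top_k_accuracy(m, test, 3), 1.0) # k = inventory size
  expect_error(top_k_accuracy(m, test, 4), "inventory")
  expect_error(top_k_accuracy(m, test[0, ], 1), "empty")

  perfect <- labeled_corpus("n1", c("u", "v"), c("A", "B"))
  expect_equal(top_k_accuracy(m, perfect, 1), 1.0)
})

test_that("pairwise grouping F1 follows the pair-counting conventions", {
  gold <- tibble::tibble(index = 0:2, heading = c("X", "X", "Y"))

  same <- tibble::tibble(index = 0:2, paragraph = c(1, 1, 2))
  expect_equal(pairwise_grouping_f1(gold, same),
               tibble::tibble(precision = 1, recall = 1, f1 = 1))

  singletons <- tibble::tibble(index = 0:2, paragraph = 1:3)
  block_gold <- tibble::tibble(index = 0:2, heading = c("X", "X", "X"))
  r <- pairwise_grouping_f1(block_gold, singletons)
  expect_equal(r$precision, 1) # zero predicted pairs
  expect_equal(r$recall, 0)
  expect_equal(r$f1, 0)

  lumped <- tibble::tibble(index = 0:2, paragraph = c(1, 1, 1))
  r2 <- pairwise_grouping_f1(gold, lumped)
  expect_equal(r2$precision, 1 / 3)
  expect_equal(r2$recall, 1)
  expect_equal(r2$f1, 1 / 2)

  # both all-singletons agree by convention; F1 symmetric in its arguments
  expect_equal(pairwise_grouping_f1(singletons, singletons)$f1, 1)
  expect_equal(pairwise_grouping_f1(lumped, gold)$f1, r2$f1)

  expect_error(pairwise_grouping_f1(gold, tibble::tibble(index = 0:1, paragraph = 1:2)),
               "different sentence sets")
})

test_that("paragraph reduction and per-note statistics do the printed arithmetic", {
  expect_equal(paragraph_reduction(396, 305), 100 * 91 / 396)
  expect_equal(round(paragraph_reduction(396, 305)), 23)
  expect_equal(paragraph_reduction(200, 150), 25)
  expect_equal(paragraph_reduction(17, 17), 0)
  expect_error(paragraph_reduction(0, 0), "positive")
  expect_error(paragraph_reduction(10, 11), "total_before")

  counts <- c(rep(10, 36), rep(9, 4)) # 40 notes, 396 paragraphs
  st <- paragraph_stats(counts)
  expect_equal(st$total, 396)
  expect_equal(st$mean, 9.9)
  expect_equal(st$n_notes, 40)
})

test_that("rating summaries reproduce the published percentage arithmetic", {
  counts <- tibble::tibble(
    variant = rep(c("NoMerging", "WithMerging"), each = 9),
    scale = rep(c(rep("heading", 4), rep("grouping", 4), "joint"), 2),
    class = rep(c("1", "2", "3", "4", "a", "b", "c", "d", "1&a"), 2),
    count = c(279, 58, 56, 3, 315, 62, 15, 4, 264,
              217, 51, 36, 1, 241, 37, 26, 1, 210)
  )
  tab <- rating_table(counts)
  expect_equal(unname(tab$totals[c("NoMerging", "WithMerging")]), c(396, 305))
  s <- summarize_ratings(tab)
  pct <- function(v, sc, cl) s$pct[s$variant == v & s$scale == sc & s$class == cl]
  expect_equal(pct("WithMerging", "heading", "1"), 71.15)
  expect_equal(pct("NoMerging", "heading", "1"), 70.45)
  expect_equal(pct("WithMerging", "heading", "1+2"), 87.87)
  expect_equal(pct("NoMerging", "heading", "1+2"), 85.10)
  expect_equal(pct("WithMerging", "joint", "1&a"), 68.85)
  expect_equal(pct("NoMerging", "joint", "1&a"), 66.67)

  # exhaustive classes sum to ~100 within rounding slack
  for (v in c("NoMerging", "WithMerging")) {
    hsum <- sum(s$pct[s$variant == v & s$scale == "heading" & s$class %in% c("1", "2", "3", "4")])
    expect_lt(abs(hsum - 100), 0.05)
  }

  zero <- rating_table(tibble::tibble(variant = "V", scale = "heading",
                                      class = c("1", "2"), count = c(10, 0)))
  sz <- summarize_ratings(zero)
  expect_equal(sz$pct[sz$class == "2"], 0)

  expect_error(
    rating_table(counts, totals = c(NoMerging = 100, WithMerging = 100)),
    "exceeds"
  )

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(counts, csv)
  expect_equal(summarize_ratings(read_rating_csv(csv)), s)
})

test_that("structuring evaluation pools pairs over notes", {
  fx <- mini_fixture()
  notes <- generate_unstructured_notes(fx$tax, mini_config(n_notes = 5L))
  structured <- lapply(seq_len(nrow(notes)), function(i) {
    structure_note(notes$text[i], fx$model, note_id = notes$note_id[i])
  })
  rep <- evaluate_structuring(notes$gold, structured)
  expect_equal(rep$n_notes, 5L)
  expect_gte(rep$f1, 0)
  expect_lte(rep$f1, 1)
  expect_equal(rep$total_paragraphs, sum(vapply(structured, n_paragraphs, integer(1))))
})
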