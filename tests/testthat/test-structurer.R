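test_that("grouping pools same-heading sentences in first-occurrence order", {
  s <- tibble::tibble(index = 0:2, text = c("s0", "s1", "s2"),
                      heading_pred = c("A", "B", "A"))
  note <- group_into_paragraphs(s, "n1")
  expect_equal(note$paragraphs$heading, c("A", "B"))
  expect_equal(note$sentences$paragraph, c(1L, 2L, 1L))
  flat <- tibble::as_tibble(note)
  expect_equal(flat$text[flat$heading == "A"], c("s0", "s2"))

  all_same <- group_into_paragraphs(
    tibble::tibble(index = 0:3, text = paste0("s", 0:3), heading_pred = rep("X", 4))
  )
  expect_equal(n_paragraphs(all_same), 1L)

  all_diff <- group_into_paragraphs(
    tibble::tibble(index = 0:3, text = paste0("s", 0:3), heading_pred = c("D", "C", "B", "A"))
  )
  expect_equal(n_paragraphs(all_diff), 4L)
  expect_equal(all_diff$paragraphs$heading, c("D", "C", "B", "A"))

  expect_equal(n_paragraphs(group_into_paragraphs(NULL)), 0L)
})

test_that("paragraph_score reproduces the three-term arithmetic", {
  # hand oracle: sentence terms (2*0.3-0.6, 2*0.4-0.5) = (0.0, 0.3), mean 0.15;
  # cosine 0.8 -> heading term -0.1; target 3 of 5 sentences -> 0.6; total 0.65
  profiles <- mk_profiles(c(src = 0.6, tgt = 0.3), c(src = 0.5, tgt = 0.4))
  vectors <- rbind(src = c(1, 0), tgt = c(0.8, 0.6)) # cosine exactly 0.8
  src <- list(heading = "src", profiles = profiles, size = 2)
  tgt <- list(heading = "tgt", profiles = profiles, size = 3)
  expect_equal(paragraph_score(src, tgt, vectors, note_size = 5), 0.65, tolerance = 1e-12)

  # extremal construction: identical vectors, full target confidence,
  # dominant target paragraph -> approaches the supremum 3
  big <- list(heading = "tgt", profiles = profiles, size = 1e6)
  sure <- list(heading = "src", profiles = mk_profiles(c(src = 0, tgt = 1)), size = 1)
  same_vec <- rbind(src = c(1, 1), tgt = c(1, 1))
  s <- paragraph_score(sure, big, same_vec, note_size = 1e6 + 1)
  expect_gt(s, 3 - 1e-5)
  expect_lt(s, 3)

  expect_error(paragraph_score(src, src, vectors, 5), "share one heading")
  expect_error(paragraph_score(list(heading = "src"), tgt, vectors, 5), "no confidence")
  expect_error(paragraph_score(src, tgt, vectors, 3), "smaller than")
})

test_that("the attainable score range is the supremum 3 and infimum -2", {
  rng <- score_range(n_samples = 500, seed = 4)
  expect_equal(rng$value[rng$bound == "supremum"], 3)
  expect_equal(rng$value[rng$bound == "infimum"], -2)
  expect_false(any(rng$attained))
  sampled <- attr(rng, "sampled_range")
  expect_gte(sampled[1], -2)
  expect_lte(sampled[2], 3)
})

test_that("similarity matrices match pairwise paragraph_score calls", {
  fx <- random_note_fixture(21, max_paragraphs = 4)
  S <- similarity_matrix(fx$note, fx$vectors)
  p <- n_paragraphs(fx$note)
  expect_equal(sum(!is.na(S)), p * (p - 1L))
  note_size <- nrow(fx$note$sentences)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      expect_equal(
        S[i, j],
        paragraph_score(note_paragraph(fx$note, i), note_paragraph(fx$note, j),
                        fx$vectors, note_size),
        tolerance = 1e-12
      )
    }
  }

  one <- random_note_fixture(3, max_paragraphs = 2)
  single <- group_into_paragraphs(
    tibble::tibble(index = 0:1, text = c("a", "b"), heading_pred = c("H1", "H1")),
    conf = matrix(c(0.6, 0.6, 0.4, 0.4), 2, 2, dimnames = list(NULL, c("H1", "H2")))
  )
  expect_equal(sum(!is.na(similarity_matrix(single, one$vectors))), 0L)
})

test_that("merging at an unattainable threshold is the identity", {
  fx <- random_note_fixture(7)
  merged <- merge_paragraphs(fx$note, fx$vectors, merge_config(threshold = 3))
  expect_equal(note_partition(merged), note_partition(fx$note))

  single <- group_into_paragraphs(
    tibble::tibble(index = 0, text = "a", heading_pred = "H1"),
    conf = matrix(1, 1, 1, dimnames = list(NULL, "H1"))
  )
  expect_equal(n_paragraphs(merge_paragraphs(single, matrix(1, 1, 2, dimnames = list("H1", NULL)),
                                             merge_config(threshold = -2))), 1L)
})

test_that("a constructed three-paragraph note merges exactly the close pair", {
  # paragraphs A and B share confidence mass and identical heading vectors;
  # C is far from both, so only {A, B} exceeds the threshold mutually
  conf <- mk_profiles(
    c(A = 0.55, B = 0.43, C = 0.02), # A sentence
    c(A = 0.45, B = 0.52, C = 0.03), # B sentence
    c(A = 0.05, B = 0.05, C = 0.90)  # C sentence
  )
  s <- tibble::tibble(index = 0:2, text = c("a1", "b1", "c1"),
                      heading_pred = c("A", "B", "C"))
  note <- group_into_paragraphs(s, "n", conf = conf)
  vectors <- rbind(A = c(1, 0), B = c(1, 0), C = c(-1, 0))
  S <- similarity_matrix(note, vectors)
  thr <- 0.5
  expect_true(S["A", "B"] > thr && S["B", "A"] > thr)
  expect_true(S["A", "C"] < thr && S["C", "A"] < thr)

  merged <- merge_paragraphs(note, vectors, merge_config(threshold = thr))
  expect_equal(n_paragraphs(merged), 2L)
  # A's outgoing score (towards B) vs B's (towards A): the lower one keeps
  # its heading
  expected_heading <- if (S["A", "B"] <= S["B", "A"]) "A" else "B"
  expect_equal(sort(merged$paragraphs$heading), sort(c(expected_heading, "C")))
  ab <- which(merged$paragraphs$heading == expected_heading)
  expect_equal(merged$sentences$paragraph[1:2], rep(merged$paragraphs$paragraph[ab], 2))
})

test_that("the merge loop equals the brute-force greedy oracle", {
  thresholds <- c(-0.5, 0, 0.25, 0.5, 1)
  for (seed in 1:40) {
    fx <- random_note_fixture(seed, max_paragraphs = 4)
    for (thr in thresholds) {
      got <- note_partition(merge_paragraphs(fx$note, fx$vectors, merge_config(threshold = thr)))
      want <- oracle_merge(fx$note, fx$vectors, thr)
      expect_equal(got, want,
                   info = sprintf("seed %d threshold %.2f", seed, thr))
    }
  }
})

test_that("merging conserves sentences and only coarsens the partition", {
  for (seed in 41:60) {
    fx <- random_note_fixture(seed)
    merged <- merge_paragraphs(fx$note, fx$vectors, merge_config(threshold = 0))
    expect_identical(merged$sentences$index, fx$note$sentences$index)
    expect_identical(merged$sentences$text, fx$note$sentences$text)
    expect_lte(n_paragraphs(merged), n_paragraphs(fx$note))
    # every merged paragraph is a union of original paragraphs
    orig <- note_partition(fx$note)
    for (pg in note_partition(merged)) {
      covering <- Filter(function(o) all(o$rows %in% pg$rows), orig)
      expect_equal(sort(unlist(lapply(covering, `[[`, "rows"))), pg$rows)
    }
  }
})

test_that("calibration picks the top of the grid when no merging is needed", {
  fx <- mini_fixture()
  notes <- generate_unstructured_notes(fx$tax, mini_config(n_notes = 10L))
  cal <- calibrate_threshold(notes[, c("text", "ref_paragraphs")], fx$model, fx$vectors)
  expect_equal(as.numeric(cal), 3)
  grid <- attr(cal, "grid")
  expect_false(is.unsorted(grid$total_paragraphs))
  expect_error(calibrate_threshold(notes[0, ], fx$model), "empty")
  bad <- notes
  bad$ref_paragraphs[1] <- 0L
  expect_error(calibrate_threshold(bad, fx$model), ">= 1")
})

test_that("structure_note runs the four-step pipeline end to end", {
  fx <- mini_fixture()
  expect_equal(n_paragraphs(structure_note("", fx$model)), 0L)

  notes <- generate_unstructured_notes(fx$tax, mini_config(n_notes = 8L))
  for (i in seq_len(nrow(notes))) {
    nomerge <- structure_note(notes$text[i], fx$model)
    withmerge <- structure_note(notes$text[i], fx$model, fx$vectors, threshold = 0.5)
    # merging only coarsens
    expect_lte(n_paragraphs(withmerge), n_paragraphs(nomerge))
    # output partitions the segmented sentences
    segs <- segment_sentences(notes$text[i])
    expect_setequal(nomerge$sentences$index, segs$index)
    expect_setequal(withmerge$sentences$index, segs$index)
  }

  # deterministic given model and threshold
  a <- structure_note(notes$text[1], fx$model, fx$vectors, threshold = 0.5)
  b <- structure_note(notes$text[1], fx$model, fx$vectors, threshold = 0.5)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("separable topics are recovered as their planted paragraphs", {
  fx <- mini_fixture()
  cfg3 <- mini_config(n_notes = 6L, headings_per_note_min = 3L, headings_per_note_max = 3L)
  notes <- generate_unstructured_notes(fx$tax, cfg3)
  for (i in seq_len(nrow(notes))) {
    sn <- structure_note(notes$text[i], fx$model, fx$vectors,
                         threshold = as.numeric(calibrate_threshold(
                           notes[i, c("text", "ref_paragraphs")], fx$model, fx$vectors)))
    f1 <- pairwise_grouping_f1(notes$gold[[i]], sn)
    expect_equal(f1$f1, 1.0)
    expect_equal(n_paragraphs(sn), 3L)
  }
})

test_that("structured notes round-trip through JSONL", {
  fx <- mini_fixture()
  notes <- generate_unstructured_notes(fx$tax, mini_config(n_notes = 3L))
  structured <- lapply(seq_len(nrow(notes)), function(i) {
    structure_note(notes$text[i], fx$model, note_id = notes$note_id[i])
  })
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_structured_jsonl(structured, path)
  back <- read_structured_jsonl(path)
  expect_equal(unique(back$note_id), notes$note_id)
  expect_equal(
    vapply(structured, n_paragraphs, integer(1)),
    as.integer(table(factor(back$note_id, levels = notes$note_id)))
  )
  expect_true(all(back$mean_confidence >= 0 & back$mean_confidence <= 1))
})
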