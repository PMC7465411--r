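#' Structured notes
#'
#' A structured note is the system's end-to-end output: the note's sentences,
#' in original order, partitioned into paragraphs that each carry one subject
#' heading. Internally it is a list with a `sentences` tibble (`index`,
#' `text`, `heading`, `paragraph`), a `paragraphs` tibble (`paragraph`,
#' `heading`, in display order), and an optional per-sentence confidence
#' matrix `conf` (rows aligned with `sentences`, columns the heading
#' inventory) used by the merging step.
#'
#' @param note_id note identifier.
#' @param sentences tibble with columns `index`, `text`, `heading`,
#'   `paragraph`.
#' @param paragraphs tibble with columns `paragraph`, `heading`.
#' @param conf optional confidence matrix.
#' @return an object of class `structured_note`.
#' @export
structured_note <- function(note_id, sentences, paragraphs, conf = NULL) {
  structure(
    list(note_id = note_id, sentences = sentences, paragraphs = paragraphs, conf = conf),
    class = "structured_note"
  )
}

#' @export
print.structured_note <- function(x, ...) {
  cat("<structured_note>", x$note_id, "—", nrow(x$sentences), "sentences in",
      nrow(x$paragraphs), "paragraph(s)\n")
  for (p in seq_len(nrow(x$paragraphs))) {
    ids <- x$sentences$paragraph == x$paragraphs$paragraph[p]
    cat("  [", x$paragraphs$heading[p], "] ",
        paste(x$sentences$text[ids], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Flatten a structured note
#'
#' @param x a `structured_note`.
#' @param ... unused.
#' @return tibble with columns `note_id`, `paragraph`, `heading`, `index`,
#'   `text` (one row per sentence, paragraph display order).
#' @exportS3Method tibble::as_tibble
as_tibble.structured_note <- function(x, ...) {
  if (nrow(x$sentences) == 0L) {
    return(tibble(note_id = character(), paragraph = integer(), heading = character(),
                  index = integer(), text = character()))
  }
  ord <- order(match(x$sentences$paragraph, x$paragraphs$paragraph), x$sentences$index)
  s <- x$sentences[ord, ]
  tibble(
    note_id = x$note_id,
    paragraph = match(s$paragraph, x$paragraphs$paragraph),
    heading = x$paragraphs$heading[match(s$paragraph, x$paragraphs$paragraph)],
    index = s$index,
    text = s$text
  )
}

#' Number of paragraphs in a structured note
#' @param note a `structured_note`.
#' @return integer count.
#' @export
n_paragraphs <- function(note) nrow(note$paragraphs)

#' Group labeled sentences into paragraphs
#'
#' Step three of the pipeline: sentences sharing an assigned subject heading
#' are pooled into one paragraph. Paragraphs appear in order of each
#' heading's first occurrence; sentences keep note order within a paragraph.
#'
#' @param sentences tibble with columns `index`, `text` and an assigned
#'   heading in `heading_pred` (or `heading`).
#' @param note_id note identifier.
#' @param conf optional confidence matrix (one row per sentence, columns
#'   named by the heading inventory), required later for merging.
#' @return a [structured_note()]; empty input gives zero paragraphs.
#' @export
group_into_paragraphs <- function(sentences, note_id = "note", conf = NULL) {
  empty <- tibble(index = integer(), text = character(),
                  heading = character(), paragraph = integer())
  if (is.null(sentences) || nrow(sentences) == 0L) {
    return(structured_note(note_id, empty, tibble(paragraph = integer(), heading = character())))
  }
  heading <- if ("heading_pred" %in% names(sentences)) sentences$heading_pred else sentences$heading
  if (any(is.na(heading))) abort("every sentence needs an assigned heading")
  ord <- order(sentences$index)
  s <- tibble(index = sentences$index[ord], text = sentences$text[ord], heading = heading[ord])
  if (!is.null(conf)) conf <- conf[ord, , drop = FALSE]
  first_occ <- unique(s$heading)
  s$paragraph <- match(s$heading, first_occ)
  structured_note(
    note_id, s,
    tibble(paragraph = seq_along(first_occ), heading = first_occ),
    conf
  )
}

# ---- the asymmetric paragraph similarity score ----------------------------
#
# S(src -> tgt) = mean over src sentences of [2 c(tgt) - c(src)]
#               + headsim(src, tgt)
#               + |tgt| / note_size
#
# where c(.) are the classifier confidences of the sentence, and
# headsim = -(1 - cos(v_src, v_tgt)) / 2 in [-1, 0]. The three terms range
# over [-1, 2], [-1, 0] and (0, 1], so S ranges over (-2, 3]-closure: the
# printed bounds are 3 (supremum) and -2 (infimum), approached but not
# attained.

# per-sentence affinity term, averaged over the source paragraph
sentence_affinity <- function(profiles, src_heading, tgt_heading) {
  mean(2 * profiles[, tgt_heading] - profiles[, src_heading])
}

# semantic closeness of two heading vectors, rescaled so that identical
# headings contribute 0 and opposite ones -1 (more similar => higher score)
heading_affinity <- function(v_src, v_tgt, label_src = "src", label_tgt = "tgt") {
  -(1 - cosine_sim(v_src, v_tgt, label_src, label_tgt)) / 2
}

# preference for retaining the heading of large target paragraphs
relative_size <- function(tgt_size, note_size) tgt_size / note_size

#' Directed paragraph-to-paragraph similarity
#'
#' Scores how inclined a source paragraph is towards adopting the heading of
#' a target paragraph in the same note. Three terms are summed: (1) for each
#' source sentence, the classifier's confidence in the target heading minus
#' the gap between its source- and target-heading confidences (i.e.
#' `2*c_tgt - c_src`), averaged over the paragraph; (2) a heading-similarity
#' term derived from the cosine of the two heading vectors, scaled to
#' `[-1, 0]` so that more similar headings score higher; (3) the target
#' paragraph's share of the note's sentences. The score is asymmetric and
#' takes values in the range 3 down to -2.
#'
#' @param src,tgt paragraph objects: lists with elements `heading`,
#'   `profiles` (matrix of confidence rows for the paragraph's sentences,
#'   columns named by heading) and optionally `size` (sentence count;
#'   defaults to `nrow(profiles)`). See [note_paragraph()].
#' @param vectors a `heading_vectors` matrix (rownames = heading ids).
#' @param note_size total sentences in the note; must be at least
#'   `|src| + |tgt|`.
#' @return a single numeric score.
#' @export
paragraph_score <- function(src, tgt, vectors, note_size) {
  if (identical(src$heading, tgt$heading)) {
    abort("source and target paragraphs share one heading; nothing to score")
  }
  if (is.null(src$profiles)) abort("source paragraph has no confidence profiles")
  src_size <- src$size %||% nrow(src$profiles)
  tgt_size <- tgt$size %||% nrow(tgt$profiles)
  if (note_size < src_size + tgt_size) {
    abort("`note_size` smaller than the two paragraphs combined")
  }
  if (!all(c(src$heading, tgt$heading) %in% colnames(src$profiles))) {
    abort("confidence profiles lack a column for the source or target heading")
  }
  sentence_affinity(src$profiles, src$heading, tgt$heading) +
    heading_affinity(vectors[src$heading, ], vectors[tgt$heading, ], src$heading, tgt$heading) +
    relative_size(tgt_size, note_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one paragraph of a structured note as a scoring object
#'
#' @param note a `structured_note` carrying a confidence matrix.
#' @param p paragraph id (row of `note$paragraphs`).
#' @return list with `heading`, `profiles`, `size`, usable with
#'   [paragraph_score()].
#' @export
note_paragraph <- function(note, p) {
  if (is.null(note$conf)) abort("note carries no confidence profiles")
  rows <- which(note$sentences$paragraph == note$paragraphs$paragraph[p])
  list(
    heading = note$paragraphs$heading[p],
    profiles = note$conf[rows, , drop = FALSE],
    size = length(rows)
  )
}

#' Attainable range of the paragraph similarity score
#'
#' Determines the least upper bound and greatest lower bound of
#' [paragraph_score()] over admissible inputs by driving each of its three
#' terms to its extreme: the per-sentence term is evaluated at the vertices
#' of the probability simplex (all mass on the target heading, or all on the
#' source), the heading term at perfectly aligned and perfectly opposed
#' heading vectors, and the relative-size term at its boundary values (a
#' vanishing target paragraph, and a target paragraph approaching the whole
#' note). Neither bound is attained — the target paragraph can never be the
#' entire note — so both are reported with `attained = FALSE`. A random
#' sample of admissible inputs is drawn as a containment check and its
#' observed range attached as attribute `"sampled_range"`.
#'
#' @param n_samples random admissible score evaluations for the containment
#'   check.
#' @param seed RNG seed for that sample.
#' @return tibble with columns `bound` (`"infimum"`, `"supremum"`), `value`
#'   and `attained`.
#' @export
score_range <- function(n_samples = 1000, seed = 1L) {
  hs <- c("src", "tgt")
  unit <- function(h) matrix(as.numeric(hs == h), 1, 2, dimnames = list(NULL, hs))
  s_max <- sentence_affinity(unit("tgt"), "src", "tgt") # all mass on target
  s_min <- sentence_affinity(unit("src"), "src", "tgt") # all mass on source
  v <- c(1, 0)
  h_max <- heading_affinity(v, v)   # identical heading vectors
  h_min <- heading_affinity(v, -v)  # opposed heading vectors
  r_sup <- relative_size(1, 1)      # target -> whole note (closure point)
  r_inf <- relative_size(1, Inf)    # target share -> 0

  sup <- s_max + h_max + r_sup
  inf <- s_min + h_min + r_inf

  sampled <- withr::with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      k <- sample(2:6, 1L)
      heads <- paste0("h", seq_len(k))
      ns <- sample(1:4, 1L)
      pr <- matrix(stats::rexp(ns * k), ns, k, dimnames = list(NULL, heads))
      pr <- pr / rowSums(pr)
      vec <- matrix(stats::rnorm(k * 5), k, 5, dimnames = list(heads, NULL))
      tgt_size <- sample(1:8, 1L)
      note_size <- ns + tgt_size + sample(0:8, 1L)
      paragraph_score(
        list(heading = heads[1L], profiles = pr, size = ns),
        list(heading = heads[2L], profiles = pr, size = tgt_size),
        vec, note_size
      )
    }, numeric(1))
  })
  out <- tibble(
    bound = c("infimum", "supremum"),
    value = c(inf, sup),
    attained = c(FALSE, FALSE)
  )
  attr(out, "sampled_range") <- range(sampled)
  out
}

# ---- similarity matrices and the merge loop -------------------------------

# full heading-by-heading affinity matrix from the vector space
headsim_matrix <- function(vectors) {
  V <- unclass(vectors)
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) {
    abort(paste0("zero vector for heading '", rownames(V)[which(nrm == 0)[1L]], "'"))
  }
  Vn <- V / nrm
  -(1 - Vn %*% t(Vn)) / 2
}

# internal merge state: per-paragraph mean profiles M, headings, sizes,
# member sentence rows, plus the note-level constants
note_merge_state <- function(note, headsim) {
  if (is.null(note$conf)) abort("note carries no confidence profiles; cannot merge")
  p <- nrow(note$paragraphs)
  members <- lapply(note$paragraphs$paragraph, function(id) which(note$sentences$paragraph == id))
  M <- do.call(rbind, lapply(members, function(rows) colMeans(note$conf[rows, , drop = FALSE])))
  list(
    M = M,
    heads = note$paragraphs$heading,
    sizes = lengths(members),
    members = members,
    note_size = nrow(note$sentences),
    headsim = headsim
  )
}

# vectorized directed score matrix for the current state; diagonal NA
state_similarity <- function(st) {
  p <- length(st$heads)
  if (p < 2L) return(matrix(NA_real_, p, p))
  own <- st$M[cbind(seq_len(p), match(st$heads, colnames(st$M)))]
  sent <- 2 * st$M[, st$heads, drop = FALSE] - matrix(own, p, p)
  hs <- st$headsim[st$heads, st$heads, drop = FALSE]
  rel <- matrix(st$sizes / st$note_size, p, p, byrow = TRUE)
  S <- sent + hs + rel
  diag(S) <- NA_real_
  S
}

#' Paragraph-to-paragraph similarity matrix
#'
#' Evaluates the directed [paragraph_score()] for every ordered paragraph
#' pair of a note. The matrix is asymmetric in general; the diagonal is
#' undefined (`NA`).
#'
#' @param note a `structured_note` carrying confidence profiles.
#' @param vectors a `heading_vectors` matrix.
#' @return a matrix of class `paragraph_similarity` with one row/column per
#'   paragraph (dimnames = paragraph headings).
#' @export
similarity_matrix <- function(note, vectors) {
  hs <- headsim_matrix(vectors)
  st <- note_merge_state(note, hs)
  S <- state_similarity(st)
  dimnames(S) <- list(st$heads, st$heads)
  structure(S, class = c("paragraph_similarity", class(S)))
}

# one pass of the greedy rule: among pairs above threshold in both
# directions, merge the pair with the largest mutual (min) similarity
merge_engine <- function(st, threshold, max_iterations = 1000L) {
  iter <- 0L
  repeat {
    p <- length(st$heads)
    if (p < 2L) break
    iter <- iter + 1L
    if (iter > max_iterations) abort("merge loop exceeded `max_iterations`")
    S <- state_similarity(st)
    best <- NULL
    for (i in seq_len(p - 1L)) {
      for (j in seq.int(i + 1L, p)) {
        if (is.na(S[i, j]) || is.na(S[j, i])) next
        if (S[i, j] > threshold && S[j, i] > threshold) {
          m <- min(S[i, j], S[j, i])
          if (is.null(best) || m > best$m + 1e-15) best <- list(i = i, j = j, m = m)
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    # the member with the lower outgoing score is less inclined to adopt the
    # other's heading, so its heading survives; ties keep the earlier one
    winner <- if (S[i, j] <= S[j, i]) st$heads[i] else st$heads[j]
    w <- st$sizes[c(i, j)]
    st$M[i, ] <- (w[1L] * st$M[i, ] + w[2L] * st$M[j, ]) / sum(w)
    st$heads[i] <- winner
    st$sizes[i] <- sum(w)
    st$members[[i]] <- sort(c(st$members[[i]], st$members[[j]]))
    st$M <- st$M[-j, , drop = FALSE]
    st$heads <- st$heads[-j]
    st$sizes <- st$sizes[-j]
    st$members[[j]] <- NULL
  }
  st
}

#' Merge configuration
#'
#' @param threshold merge threshold in `[-2, 3]`; both directed scores must
#'   exceed it for a pair to merge.
#' @param grid_step calibration grid resolution over `[-2, 3]`; default 0.05.
#' @param max_iterations safety cap on merge iterations per note.
#' @return object of class `merge_config`.
#' @export
merge_config <- function(threshold = NULL, grid_step = 0.05, max_iterations = 1000L) {
  if (!is.null(threshold)) stopifnot(threshold >= -2, threshold <= 3)
  stopifnot(grid_step > 0)
  structure(list(threshold = threshold, grid_step = grid_step,
                 max_iterations = as.integer(max_iterations)),
            class = "merge_config")
}

#' Iteratively merge similar paragraphs
#'
#' Step four of the pipeline. While some paragraph pair exceeds the threshold
#' in both directions, the pair with the largest mutual similarity (the
#' minimum of its two directed scores) is merged; the merged paragraph keeps
#' the heading of the member with the lower outgoing score, the similarity
#' matrix is recomputed, and the process repeats until no pair qualifies.
#' Sentences are never created, dropped or reordered; the paragraph count
#' never increases.
#'
#' @param note a `structured_note` with confidence profiles.
#' @param vectors a `heading_vectors` matrix.
#' @param config a [merge_config()] with a non-`NULL` threshold.
#' @return the merged `structured_note`.
#' @export
merge_paragraphs <- function(note, vectors, config) {
  if (is.null(config$threshold)) abort("`config$threshold` is required for merging")
  if (nrow(note$paragraphs) < 2L) return(note)
  st <- note_merge_state(note, headsim_matrix(vectors))
  st <- merge_engine(st, config$threshold, config$max_iterations)
  rebuild_note(note, st)
}

rebuild_note <- function(note, st) {
  p <- length(st$heads)
  paragraphs <- tibble(paragraph = seq_len(p), heading = st$heads)
  sentences <- note$sentences
  for (k in seq_len(p)) {
    sentences$paragraph[st$members[[k]]] <- k
    sentences$heading[st$members[[k]]] <- st$heads[k]
  }
  # paragraph display order follows first occurrence in the note
  first_row <- vapply(st$members, min, integer(1))
  ord <- order(first_row)
  paragraphs <- paragraphs[ord, ]
  remap <- stats::setNames(seq_len(p), ord)
  sentences$paragraph <- as.integer(remap[as.character(sentences$paragraph)])
  paragraphs$paragraph <- seq_len(p)
  structured_note(note$note_id, sentences, paragraphs, note$conf)
}

#' Calibrate the merge threshold against reference paragraph counts
#'
#' Sweeps a grid over `[-2, 3]` and, for every candidate threshold, counts
#' the paragraphs the merging step would produce on a sample of notes. The
#' returned threshold minimizes the absolute gap between the produced total
#' and the reference total (the paragraph counts of the original, structured
#' versions of the sample notes); ties go to the larger threshold (least
#' merging). The produced total is a non-decreasing step function of the
#' threshold.
#'
#' @param sample tibble with columns `text` (raw note) and `ref_paragraphs`
#'   (paragraph count of the reference version).
#' @param model a trained `heading_classifier`.
#' @param vectors a `heading_vectors` matrix; defaults to
#'   [heading_vectors()] of `model`.
#' @param config a [merge_config()]; its `grid_step` sets the resolution.
#' @return the selected threshold (numeric scalar of class
#'   `threshold_calibration`) with the full grid curve in attribute `"grid"`
#'   (tibble: `threshold`, `total_paragraphs`).
#' @export
calibrate_threshold <- function(sample, model, vectors = NULL, config = merge_config()) {
  if (is.null(sample) || nrow(sample) == 0L) abort("`sample` is empty")
  if (!all(sample$ref_paragraphs >= 1)) abort("reference paragraph counts must be >= 1")
  vectors <- vectors %||% heading_vectors(model)
  hs <- headsim_matrix(vectors)
  states <- lapply(seq_len(nrow(sample)), function(i) {
    note <- structure_note(sample$text[i], model, note_id = paste0("cal", i))
    if (nrow(note$paragraphs) == 0L) NULL else note_merge_state(note, hs)
  })
  states <- states[!vapply(states, is.null, logical(1))]
  grid <- seq(-2, 3, by = config$grid_step)
  totals <- vapply(grid, function(thr) {
    sum(vapply(states, function(st) {
      length(merge_engine(st, thr, config$max_iterations)$heads)
    }, numeric(1)))
  }, numeric(1))
  ref_total <- sum(sample$ref_paragraphs)
  gap <- abs(totals - ref_total)
  best <- max(which(gap == min(gap))) # ties -> larger threshold
  out <- grid[best]
  attr(out, "grid") <- tibble(threshold = grid, total_paragraphs = totals)
  attr(out, "reference_total") <- ref_total
  class(out) <- "threshold_calibration"
  out
}

#' @export
print.threshold_calibration <- function(x, ...) {
  g <- attr(x, "grid")
  sel <- g$total_paragraphs[g$threshold == as.numeric(x)]
  cat("<threshold_calibration> threshold", format(as.numeric(x)),
      "-> total paragraphs", sel, "(reference", attr(x, "reference_total"), ")\n")
  invisible(x)
}

#' Structure one raw note end to end
#'
#' Runs the full pipeline on a free-text note: (1) sentence segmentation,
#' (2) per-sentence heading classification, (3) grouping of same-heading
#' sentences into paragraphs, and — when a threshold is supplied — (4)
#' iterative paragraph merging. Without a threshold the pipeline stops after
#' step 3 (the NoMerging variant); with one it applies step 4 (WithMerging).
#'
#' @param text raw note text.
#' @param model a trained `heading_classifier`.
#' @param vectors optional `heading_vectors`; derived from the model when
#'   merging is requested and they are absent.
#' @param threshold optional merge threshold (numeric, or a
#'   [calibrate_threshold()] result).
#' @param note_id note identifier.
#' @param rules segmentation rules.
#' @return a [structured_note()].
#' @export
structure_note <- function(text, model, vectors = NULL, threshold = NULL,
                           note_id = "note", rules = segmenter_rules()) {
  sents <- segment_sentences(text, rules)
  if (nrow(sents) == 0L) return(group_into_paragraphs(NULL, note_id))
  P <- predict_profiles(model, sents$tokens)
  top <- apply(P, 1L, function(p) order(-p, model$headings)[1L])
  sents$heading_pred <- model$headings[top]
  note <- group_into_paragraphs(sents[, c("index", "text", "heading_pred")], note_id, conf = P)
  if (!is.null(threshold)) {
    vectors <- vectors %||% heading_vectors(model)
    note <- merge_paragraphs(note, vectors, merge_config(threshold = as.numeric(threshold)))
  }
  note
}

#' Write / read structured notes as JSONL
#'
#' One object per line:
#' `{"note_id", "paragraphs": [{"heading", "sentences": [...], "mean_confidence"}]}`.
#' `mean_confidence` is the mean classifier confidence of the paragraph's
#' sentences for the paragraph's assigned heading — surfaced because low
#' values flag paragraphs worth a manual look.
#'
#' @param notes list of `structured_note` objects.
#' @param path file path.
#' @return the writer returns `path` invisibly; the reader returns a tibble
#'   with columns `note_id`, `paragraph`, `heading`, `sentences` (list),
#'   `mean_confidence`.
#' @export
write_structured_jsonl <- function(notes, path) {
  lines <- vapply(notes, function(note) {
    paras <- lapply(seq_len(nrow(note$paragraphs)), function(p) {
      rows <- which(note$sentences$paragraph == note$paragraphs$paragraph[p])
      h <- note$paragraphs$heading[p]
      mc <- if (!is.null(note$conf)) mean(note$conf[rows, h]) else NA_real_
      list(heading = h, sentences = as.list(note$sentences$text[rows]), mean_confidence = mc)
    })
    as.character(jsonlite::toJSON(list(note_id = note$note_id, paragraphs = paras),
                                  auto_unbox = TRUE, digits = NA, na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_structured_jsonl
#' @export
read_structured_jsonl <- function(path) {
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON, simplifyVector = FALSE)
  purrr::map_dfr(recs, function(r) {
    purrr::imap_dfr(r$paragraphs, function(p, i) {
      tibble(
        note_id = r$note_id, paragraph = i, heading = p$heading,
        sentences = list(unlist(p$sentences)),
        mean_confidence = if (is.null(p$mean_confidence)) NA_real_ else p$mean_confidence
      )
    })
  })
}
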