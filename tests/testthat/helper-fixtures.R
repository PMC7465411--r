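# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures are trained once per session and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# small, fully separable world: 8 leaf headings, fast to train (~2 s)
mini_config <- function(seed = 42L, ...) {
  args <- list(
    n_level2 = 2L, vocab_size = 80L, n_notes = 80L,
    headings_per_note_min = 2L, headings_per_note_max = 4L, seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

mini_fixture <- function() {
  cached("mini", function() {
    cfg <- mini_config()
    tax <- generate_taxonomy(cfg)
    corpus <- generate_corpus(tax, cfg)
    sp <- split_corpus(corpus, seed = 1L)
    model <- train_classifier(sp$train, sp$dev,
                              classifier_config(max_epochs = 100L, seed = 1L))
    list(cfg = cfg, tax = tax, corpus = corpus, split = sp,
         model = model, vectors = heading_vectors(model))
  })
}

# the recovery configuration: 20 separable leaf headings, ~200 sentences each
recovery_fixture <- function() {
  cached("recovery", function() {
    cfg <- generator_config(seed = 1L)
    tax <- generate_taxonomy(cfg)
    corpus <- generate_corpus(tax, cfg)
    sp <- split_corpus(corpus, seed = 1L)
    model <- train_classifier(sp$train, sp$dev, classifier_config(seed = 1L))
    notes <- generate_unstructured_notes(tax, generator_config(seed = 1L, n_notes = 50L))
    list(cfg = cfg, tax = tax, corpus = corpus, split = sp,
         model = model, vectors = heading_vectors(model), notes = notes)
  })
}

conflated_fixture <- function() {
  cached("conflated", function() {
    cfg <- generator_config(seed = 1L, n_conflated_pairs = 3L)
    tax <- generate_taxonomy(cfg)
    corpus <- generate_corpus(tax, cfg)
    sp <- split_corpus(corpus, seed = 1L)
    model <- train_classifier(sp$train, sp$dev, classifier_config(seed = 1L))
    list(cfg = cfg, tax = tax, corpus = corpus,
         planted = attr(corpus, "conflated_pairs"),
         model = model, vectors = heading_vectors(model))
  })
}

# profile matrix from rows of named confidences
mk_profiles <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) r[sort(names(rows[[1]]))]))
  colnames(m) <- sort(names(rows[[1]]))
  m
}

# random structured note with p paragraphs and simplex confidence rows
random_note_fixture <- function(seed, max_paragraphs = 4L) {
  withr::with_seed(seed, {
    p <- sample(2:max_paragraphs, 1L)
    heads <- paste0("H", seq_len(p))
    n_per <- sample(1:3, p, replace = TRUE)
    assign_h <- rep(heads, n_per)
    n <- length(assign_h)
    ord <- sample(n)
    sentences <- tibble::tibble(
      index = seq_len(n) - 1L,
      text = paste0("s", seq_len(n)),
      heading_pred = assign_h[ord]
    )
    conf <- matrix(stats::rexp(n * p), n, p, dimnames = list(NULL, heads))
    conf <- conf / rowSums(conf)
    vec <- matrix(stats::rnorm(p * 6), p, 6, dimnames = list(heads, NULL))
    list(note = group_into_paragraphs(sentences, "fx", conf = conf), vectors = vec)
  })
}

# --- independent oracles ---------------------------------------------------

# brute-force greedy merge: re-derives every step with scalar paragraph_score
# calls and explicit pair enumeration
oracle_merge <- function(note, vectors, threshold) {
  paras <- lapply(seq_len(nrow(note$paragraphs)), function(p) {
    rows <- which(note$sentences$paragraph == note$paragraphs$paragraph[p])
    list(heading = note$paragraphs$heading[p], rows = rows)
  })
  note_size <- nrow(note$sentences)
  as_scored <- function(pg) {
    list(heading = pg$heading,
         profiles = note$conf[pg$rows, , drop = FALSE],
         size = length(pg$rows))
  }
  repeat {
    p <- length(paras)
    if (p < 2L) break
    best <- NULL
    for (i in seq_len(p - 1L)) {
      for (j in seq.int(i + 1L, p)) {
        sij <- paragraph_score(as_scored(paras[[i]]), as_scored(paras[[j]]), vectors, note_size)
        sji <- paragraph_score(as_scored(paras[[j]]), as_scored(paras[[i]]), vectors, note_size)
        if (sij > threshold && sji > threshold) {
          m <- min(sij, sji)
          if (is.null(best) || m > best$m + 1e-15) {
            best <- list(i = i, j = j, m = m, sij = sij, sji = sji)
          }
        }
      }
    }
    if (is.null(best)) break
    keep <- if (best$sij <= best$sji) paras[[best$i]]$heading else paras[[best$j]]$heading
    paras[[best$i]] <- list(heading = keep,
                            rows = sort(c(paras[[best$i]]$rows, paras[[best$j]]$rows)))
    paras[[best$j]] <- NULL
  }
  paras <- paras[order(vapply(paras, function(pg) min(pg$rows), integer(1)))]
  lapply(paras, function(pg) list(heading = pg$heading, rows = pg$rows))
}

note_partition <- function(note) {
  lapply(seq_len(nrow(note$paragraphs)), function(p) {
    list(heading = note$paragraphs$heading[p],
         rows = which(note$sentences$paragraph == note$paragraphs$paragraph[p]))
  })
}

# breadth-first search distance over an undirected adjacency list
bfs_distance <- function(adj, from, to) {
  if (from == to) return(0L)
  dist <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  dist[from] <- 0L
  queue <- from
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        if (w == to) return(unname(dist[w]))
        queue <- c(queue, w)
      }
    }
  }
  NA_integer_
}

random_tree_nodes <- function(seed, max_nodes = 50L) {
  withr::with_seed(seed, {
    n <- sample(2:max_nodes, 1L)
    ids <- paste0("n", seq_len(n))
    parent <- c(NA_character_, vapply(2:n, function(i) ids[sample.int(i - 1L, 1L)], character(1)))
    tibble::tibble(id = ids, parent = parent, category = NA_character_)
  })
}

adjacency_of <- function(nodes) {
  adj <- stats::setNames(vector("list", nrow(nodes)), nodes$id)
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (!is.na(p)) {
      adj[[p]] <- c(adj[[p]], nodes$id[i])
      adj[[nodes$id[i]]] <- c(adj[[nodes$id[i]]], p)
    }
  }
  adj
}

# fractional ranks and the plain Pearson formula, written out by hand
oracle_fractional_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_fractional_ranks(x)
  ry <- oracle_fractional_ranks(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
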