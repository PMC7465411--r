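#' Classifier configuration
#'
#' Settings for the sentence-level subject-heading classifier. Two backends
#' share one interface:
#'
#' * `"bow_softmax"` — multinomial softmax regression on bag-of-words counts.
#'   Fast, convex, and its output weight matrix has one row per heading of
#'   width `|vocabulary|`; the workhorse for tests and desk-scale runs.
#' * `"recurrent"` — a bidirectional recurrent encoder over pretrained word
#'   embeddings; the final hidden states of both directions are concatenated
#'   (width `2 * hidden_dim_per_direction`) and fed to a softmax output
#'   layer. The reference configuration for this architecture uses 300-d
#'   embeddings and 600 units per direction, giving 1200-d heading vectors.
#'
#' Both are trained with Adam on categorical cross-entropy and stop early
#' when dev-set top-1 accuracy fails to improve for `patience` epochs.
#'
#' @param backend `"bow_softmax"` or `"recurrent"`.
#' @param embedding_dim word-embedding width (recurrent backend).
#' @param hidden_dim_per_direction recurrent state width per direction.
#' @param max_epochs,patience training-length and early-stopping controls.
#' @param learning_rate Adam step size; backend default when `NULL`
#'   (0.5 for `bow_softmax`, 0.02 for `recurrent`).
#' @param l2 ridge penalty on the output weights.
#' @param freeze_embeddings keep pretrained embeddings fixed during recurrent
#'   training (default: fine-tune them).
#' @param seed integer seed; training is deterministic on CPU at a fixed seed.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(backend = c("bow_softmax", "recurrent"),
                              embedding_dim = 300L,
                              hidden_dim_per_direction = 600L,
                              max_epochs = 200L,
                              patience = 15L,
                              learning_rate = NULL,
                              l2 = 1e-4,
                              freeze_embeddings = FALSE,
                              seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(is_count(embedding_dim), is_count(hidden_dim_per_direction),
            is_count(max_epochs), is_count(patience))
  if (is.null(learning_rate)) {
    learning_rate <- if (backend == "bow_softmax") 0.5 else 0.02
  }
  structure(
    list(
      backend = backend,
      embedding_dim = as.integer(embedding_dim),
      hidden_dim_per_direction = as.integer(hidden_dim_per_direction),
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience),
      learning_rate = learning_rate,
      l2 = l2,
      freeze_embeddings = isTRUE(freeze_embeddings),
      seed = as.integer(seed)
    ),
    class = "classifier_config"
  )
}

#' Train the subject-heading classifier
#'
#' Fits the configured backend on the training corpus, monitoring top-1
#' accuracy on the development corpus after every epoch and keeping the
#' best-scoring parameters (early stopping). Every sentence is a training
#' example with its heading as the target class.
#'
#' @param train,dev labeled-corpus tibbles sharing one heading inventory;
#'   every dev heading must occur in train.
#' @param config a [classifier_config()].
#' @return an object of class `heading_classifier` with elements `config`,
#'   `vocabulary`, `headings`, `params` (backend parameters; the output
#'   weight matrix is `params$W_out`), and `history` (per-epoch loss and dev
#'   accuracy).
#' @export
train_classifier <- function(train, dev, config = classifier_config()) {
  stopifnot(nrow(train) > 0L)
  missing_h <- setdiff(unique(dev$heading), unique(train$heading))
  if (length(missing_h) > 0L) {
    abort(paste0("dev headings absent from train: ", paste(missing_h, collapse = ", ")))
  }
  headings <- heading_inventory(train)
  toks_train <- lapply(train$text, tokenize)
  vocab <- sort(unique(unlist(toks_train)))
  vocabulary <- c(vocab, "<unk>")

  fit <- withr::with_seed(config$seed, {
    if (config$backend == "bow_softmax") {
      fit_bow_softmax(toks_train, train$heading, dev, vocabulary, headings, config)
    } else {
      fit_recurrent(toks_train, train$heading, train$text, dev, vocabulary, headings, config)
    }
  })

  structure(
    list(
      config = config,
      vocabulary = vocabulary,
      headings = headings,
      params = fit$params,
      history = fit$history
    ),
    class = "heading_classifier"
  )
}

#' @export
print.heading_classifier <- function(x, ...) {
  cat("<heading_classifier>", x$config$backend, "backend;",
      length(x$headings), "headings;", length(x$vocabulary), "vocabulary tokens\n")
  if (nrow(x$history) > 0L) {
    cat("  trained", max(x$history$epoch), "epochs; best dev accuracy",
        sprintf("%.4f", max(x$history$dev_accuracy)), "\n")
  }
  invisible(x)
}

# token list -> sparse count matrix over the model vocabulary, OOV -> <unk>
bow_counts <- function(token_list, vocabulary) {
  v <- length(vocabulary)
  unk <- v
  n <- length(token_list)
  lens <- lengths(token_list)
  if (sum(lens) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, v)))
  }
  j <- match(unlist(token_list), vocabulary)
  j[is.na(j)] <- unk
  i <- rep(seq_len(n), lens)
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, v))
}

fit_bow_softmax <- function(toks_train, y_train, dev, vocabulary, headings, config) {
  K <- length(headings)
  V <- length(vocabulary)
  X <- bow_counts(toks_train, vocabulary)
  y <- match(y_train, headings)
  n <- nrow(X)
  Xd <- bow_counts(lapply(dev$text, tokenize), vocabulary)
  yd <- match(dev$heading, headings)

  W <- matrix(0, K, V) # convex problem: zero init, deterministic
  b <- numeric(K)
  adam <- adam_state(list(W = W, b = b))
  best <- list(W = W, b = b, acc = -Inf, epoch = 0L)
  history <- vector("list", config$max_epochs)
  wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    Z <- sweep(as.matrix(X %*% t(W)), 2L, b, `+`)
    P <- softmax_rows(Z)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-300)))
    G <- P
    G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] - 1
    G <- G / n
    grads <- list(W = as.matrix(t(G) %*% X) + config$l2 * W, b = colSums(G))
    upd <- adam_step(adam, list(W = W, b = b), grads, config$learning_rate)
    adam <- upd$state
    W <- upd$params$W
    b <- upd$params$b

    Pd <- softmax_rows(sweep(as.matrix(Xd %*% t(W)), 2L, b, `+`))
    acc <- mean(max.col(Pd, ties.method = "first") == yd)
    history[[epoch]] <- tibble(epoch = epoch, train_loss = loss, dev_accuracy = acc)
    if (acc > best$acc + 1e-12) {
      best <- list(W = W, b = b, acc = acc, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  rownames(best$W) <- headings
  colnames(best$W) <- vocabulary
  list(
    params = list(W_out = best$W, b_out = stats::setNames(best$b, headings)),
    history = dplyr::bind_rows(history)
  )
}

# One Adam optimizer state per named parameter tensor
adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

#' Confidence profile for one sentence
#'
#' Runs the classifier on a single sentence and returns its full probability
#' distribution over the heading inventory (the sentence's confidence
#' profile). A sentence with no tokens gets a uniform profile with a warning:
#' free narratives contain such lines and they should not crash a pipeline.
#'
#' @param model a trained `heading_classifier`.
#' @param sentence a character string, or a character vector of tokens.
#' @return a tibble with columns `heading` and `prob` (one row per heading,
#'   inventory order; probabilities sum to 1).
#' @export
predict_confidences <- function(model, sentence) {
  tokens <- if (length(sentence) == 1L && !identical(attr(sentence, "tokenized"), TRUE)) {
    tokenize(sentence)
  } else {
    as.character(sentence)
  }
  P <- predict_profiles(model, list(tokens))
  tibble(heading = model$headings, prob = as.numeric(P[1L, ]))
}

#' Batch confidence profiles
#'
#' @param model a trained `heading_classifier`.
#' @param sentences character vector of sentence texts, or a list of token
#'   vectors.
#' @return numeric matrix, one row per sentence, one column per heading
#'   (colnames = inventory); rows sum to 1. Token-less sentences get uniform
#'   rows (with one warning).
#' @export
predict_profiles <- function(model, sentences) {
  token_list <- if (is.list(sentences)) sentences else lapply(sentences, tokenize)
  K <- length(model$headings)
  n <- length(token_list)
  empty <- lengths(token_list) == 0L
  if (any(empty)) {
    warn(paste0(sum(empty), " sentence(s) with no tokens: assigning uniform confidence profiles"))
  }
  if (model$config$backend == "bow_softmax") {
    X <- bow_counts(token_list, model$vocabulary)
    Z <- sweep(as.matrix(X %*% t(model$params$W_out)), 2L, model$params$b_out, `+`)
    P <- softmax_rows(Z)
  } else {
    P <- matrix(0, n, K)
    for (i in seq_len(n)) {
      if (empty[i]) next
      P[i, ] <- recurrent_forward(model, token_list[[i]])$probs
    }
  }
  P[empty, ] <- 1 / K
  colnames(P) <- model$headings
  P
}

#' Predict headings for a corpus
#'
#' Assigns each sentence its top-confidence heading.
#'
#' @param model a trained `heading_classifier`.
#' @param corpus a labeled-corpus tibble (gold `heading` column optional) or
#'   character vector of sentences.
#' @return the input tibble with columns `heading_pred` and `confidence`
#'   appended (ties broken by heading id).
#' @export
predict_headings <- function(model, corpus) {
  if (!is.data.frame(corpus)) corpus <- tibble(text = as.character(corpus))
  P <- predict_profiles(model, corpus$text)
  top <- apply(P, 1L, function(p) {
    ord <- order(-p, model$headings)
    ord[1L]
  })
  corpus$heading_pred <- model$headings[top]
  corpus$confidence <- P[cbind(seq_len(nrow(P)), top)]
  corpus
}

#' Top-k headings from a confidence profile
#'
#' @param profile a tibble with columns `heading` and `prob` (as returned by
#'   [predict_confidences()]).
#' @param k number of headings to return, between 1 and the inventory size.
#' @return tibble of `k` rows sorted by decreasing probability, ties broken
#'   by heading id.
#' @export
top_k <- function(profile, k) {
  if (!is_count(k) || k > nrow(profile)) {
    abort("`k` must be an integer between 1 and the inventory size")
  }
  dplyr::slice_head(dplyr::arrange(profile, dplyr::desc(.data$prob), .data$heading), n = k)
}

#' Heading vectors from the trained classifier
#'
#' The rows of the fully connected output layer's weight matrix, one per
#' subject heading, read as learned semantic representations of the headings:
#' headings used over similar content get similar rows. The output bias is
#' excluded — it encodes class frequency, not content. Width is
#' `2 * hidden_dim_per_direction` for the recurrent backend and the
#' vocabulary size for `bow_softmax`.
#'
#' @param model a trained `heading_classifier`.
#' @return numeric matrix of class `heading_vectors`; rownames are heading
#'   ids.
#' @export
heading_vectors <- function(model) {
  W <- model$params$W_out
  structure(W, class = c("heading_vectors", class(W)))
}

#' Export heading vectors as TSV
#'
#' Columns: `heading_id`, `v1` ... `vd`.
#'
#' @param vectors a `heading_vectors` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_heading_vectors <- function(vectors, path) {
  df <- as.data.frame(unclass(vectors))
  names(df) <- paste0("v", seq_len(ncol(df)))
  df <- cbind(heading_id = rownames(vectors), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Save / load a trained classifier
#'
#' The model is stored as a directory of plain-text files: `config.json`,
#' `vocabulary.txt`, `headings.txt` and `params.json` (full-precision
#' numbers), plus `history.tsv`.
#'
#' @param model a `heading_classifier`.
#' @param dir directory path (created if missing).
#' @return `save_classifier` returns `dir` invisibly; `load_classifier`
#'   returns the restored `heading_classifier`.
#' @export
save_classifier <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(model$vocabulary, file.path(dir, "vocabulary.txt"))
  writeLines(model$headings, file.path(dir, "headings.txt"))
  params <- lapply(model$params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p)) else list(data = as.numeric(p))
  })
  jsonlite::write_json(params, file.path(dir, "params.json"), digits = NA)
  readr::write_tsv(model$history, file.path(dir, "history.tsv"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- classifier_config(
    backend = cfg$backend, embedding_dim = cfg$embedding_dim,
    hidden_dim_per_direction = cfg$hidden_dim_per_direction,
    max_epochs = cfg$max_epochs, patience = cfg$patience,
    learning_rate = cfg$learning_rate, l2 = cfg$l2,
    freeze_embeddings = cfg$freeze_embeddings, seed = cfg$seed
  )
  vocabulary <- readLines(file.path(dir, "vocabulary.txt"))
  headings <- readLines(file.path(dir, "headings.txt"))
  raw <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- lapply(raw, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L]) else p$data
  })
  if (!is.null(params$W_out)) {
    rownames(params$W_out) <- headings
    if (ncol(params$W_out) == length(vocabulary)) colnames(params$W_out) <- vocabulary
  }
  if (!is.null(params$b_out)) names(params$b_out) <- headings
  if (!is.null(params$E)) rownames(params$E) <- vocabulary
  structure(
    list(
      config = config, vocabulary = vocabulary, headings = headings,
      params = params,
      history = readr::read_tsv(file.path(dir, "history.tsv"), show_col_types = FALSE)
    ),
    class = "heading_classifier"
  )
}
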