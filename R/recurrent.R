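# Bidirectional recurrent backend: pretrained embeddings -> tanh recurrent
# encoders run left-to-right and right-to-left -> final states concatenated
# -> softmax output layer. Trained by backpropagation through time with Adam
# on minibatches; pure R, intended for desk-scale corpora.

fit_recurrent <- function(toks_train, y_train, train_text, dev, vocabulary, headings, config) {
  d <- config$embedding_dim
  h <- config$hidden_dim_per_direction
  K <- length(headings)
  V <- length(vocabulary)

  emb <- pretrain_embeddings(train_text, dim = d, seed = config$seed)
  E <- matrix(0, V, d)
  rownames(E) <- vocabulary
  common <- intersect(rownames(emb), vocabulary)
  E[common, ] <- emb[common, ]
  # unit-scale rows keep recurrent activations in range
  sc <- max(sqrt(rowSums(E^2)))
  if (sc > 0) E <- E / sc

  ginit <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  params <- list(
    E = E,
    W_f = ginit(h, d), U_f = ginit(h, h) * 0.5, b_f = numeric(h),
    W_b = ginit(h, d), U_b = ginit(h, h) * 0.5, b_b = numeric(h),
    W_out = matrix(0, K, 2L * h), b_out = numeric(K)
  )

  idx_train <- lapply(toks_train, function(tk) {
    ix <- match(tk, vocabulary)
    ix[is.na(ix)] <- V
    ix
  })
  y <- match(y_train, headings)
  keep <- lengths(idx_train) > 0L
  idx_train <- idx_train[keep]
  y <- y[keep]
  n <- length(idx_train)

  toks_dev <- lapply(dev$text, tokenize)
  idx_dev <- lapply(toks_dev, function(tk) {
    ix <- match(tk, vocabulary)
    ix[is.na(ix)] <- V
    ix
  })
  yd <- match(dev$heading, headings)

  trainable <- c(if (!config$freeze_embeddings) "E",
                 "W_f", "U_f", "b_f", "W_b", "U_b", "b_b", "W_out", "b_out")
  adam <- adam_state(params[trainable])
  best <- list(params = params, acc = -Inf)
  history <- list()
  wait <- 0L
  batch_size <- 16L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    total_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      acc_grads <- NULL
      for (i in batch) {
        fb <- rnn_forward_backward(params, idx_train[[i]], y[i], config$freeze_embeddings)
        total_loss <- total_loss + fb$loss
        acc_grads <- if (is.null(acc_grads)) fb$grads else {
          purrr::map2(acc_grads, fb$grads, `+`)
        }
      }
      grads <- lapply(acc_grads, function(g) g / length(batch))
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (gn > 5) grads <- lapply(grads, function(g) g * 5 / gn) # clip
      if (!is.null(grads$W_out)) grads$W_out <- grads$W_out + config$l2 * params$W_out
      upd <- adam_step(adam, params[trainable], grads[trainable], config$learning_rate)
      adam <- upd$state
      params[trainable] <- upd$params
    }

    acc <- rnn_accuracy(params, idx_dev, yd, K)
    history[[epoch]] <- tibble(epoch = epoch, train_loss = total_loss / n, dev_accuracy = acc)
    if (acc > best$acc + 1e-12) {
      best <- list(params = params, acc = acc)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  p <- best$params
  rownames(p$W_out) <- headings
  names(p$b_out) <- headings
  rownames(p$E) <- vocabulary
  list(params = p, history = dplyr::bind_rows(history))
}

# forward pass for one token-index sequence; returns hidden trajectories
rnn_states <- function(params, idx) {
  X <- params$E[idx, , drop = FALSE]
  Tn <- length(idx)
  h <- nrow(params$W_f)
  Hf <- matrix(0, Tn, h)
  Hb <- matrix(0, Tn, h)
  hprev <- numeric(h)
  for (t in seq_len(Tn)) {
    hprev <- tanh(params$W_f %*% X[t, ] + params$U_f %*% hprev + params$b_f)[, 1L]
    Hf[t, ] <- hprev
  }
  hprev <- numeric(h)
  for (t in rev(seq_len(Tn))) {
    hprev <- tanh(params$W_b %*% X[t, ] + params$U_b %*% hprev + params$b_b)[, 1L]
    Hb[t, ] <- hprev
  }
  feat <- c(Hf[Tn, ], Hb[1L, ])
  z <- (params$W_out %*% feat + params$b_out)[, 1L]
  zs <- z - max(z)
  probs <- exp(zs) / sum(exp(zs))
  list(X = X, Hf = Hf, Hb = Hb, feat = feat, probs = probs)
}

rnn_forward_backward <- function(params, idx, y, freeze_embeddings) {
  st <- rnn_states(params, idx)
  Tn <- length(idx)
  h <- nrow(params$W_f)
  loss <- -log(max(st$probs[y], 1e-300))

  dz <- st$probs
  dz[y] <- dz[y] - 1
  gW_out <- outer(dz, st$feat)
  gb_out <- dz
  dfeat <- as.numeric(crossprod(params$W_out, dz))

  gW_f <- matrix(0, h, ncol(st$X)); gU_f <- matrix(0, h, h); gb_f <- numeric(h)
  gW_b <- matrix(0, h, ncol(st$X)); gU_b <- matrix(0, h, h); gb_b <- numeric(h)
  dX <- matrix(0, Tn, ncol(st$X))

  dh <- dfeat[seq_len(h)] # gradient enters at the last forward state
  for (t in rev(seq_len(Tn))) {
    da <- dh * (1 - st$Hf[t, ]^2)
    hprev <- if (t > 1L) st$Hf[t - 1L, ] else numeric(h)
    gW_f <- gW_f + outer(da, st$X[t, ])
    gU_f <- gU_f + outer(da, hprev)
    gb_f <- gb_f + da
    dX[t, ] <- dX[t, ] + as.numeric(crossprod(params$W_f, da))
    dh <- as.numeric(crossprod(params$U_f, da))
  }
  dh <- dfeat[h + seq_len(h)] # and at the first backward state
  for (t in seq_len(Tn)) {
    da <- dh * (1 - st$Hb[t, ]^2)
    hnext <- if (t < Tn) st$Hb[t + 1L, ] else numeric(h)
    gW_b <- gW_b + outer(da, st$X[t, ])
    gU_b <- gU_b + outer(da, hnext)
    gb_b <- gb_b + da
    dX[t, ] <- dX[t, ] + as.numeric(crossprod(params$W_b, da))
    dh <- as.numeric(crossprod(params$U_b, da))
  }

  grads <- list(
    W_f = gW_f, U_f = gU_f, b_f = gb_f,
    W_b = gW_b, U_b = gU_b, b_b = gb_b,
    W_out = gW_out, b_out = gb_out
  )
  if (!freeze_embeddings) {
    gE <- matrix(0, nrow(params$E), ncol(params$E))
    for (t in seq_len(Tn)) gE[idx[t], ] <- gE[idx[t], ] + dX[t, ]
    grads$E <- gE
  }
  list(loss = loss, grads = grads)
}

rnn_accuracy <- function(params, idx_list, y, K) {
  pred <- vapply(seq_along(idx_list), function(i) {
    if (length(idx_list[[i]]) == 0L) return(1L)
    which.max(rnn_states(params, idx_list[[i]])$probs)
  }, integer(1))
  mean(pred == y)
}

# single-sentence inference used by predict_profiles for this backend
recurrent_forward <- function(model, tokens) {
  idx <- match(tokens, model$vocabulary)
  idx[is.na(idx)] <- length(model$vocabulary)
  st <- rnn_states(model$params, idx)
  list(probs = st$probs)
}
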