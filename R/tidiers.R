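#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained heading classifier
#'
#' One row per heading: its training support is not stored on the model, so
#' the row reports the heading-vector norm and output bias — a quick view of
#' which headings the model has a strong representation for.
#'
#' @param x a `heading_classifier`.
#' @param ... unused.
#' @return tibble with columns `heading`, `vector_norm`, `bias`.
#' @exportS3Method generics::tidy
tidy.heading_classifier <- function(x, ...) {
  W <- x$params$W_out
  tibble(
    heading = x$headings,
    vector_norm = sqrt(rowSums(W^2)),
    bias = as.numeric(x$params$b_out)
  )
}

#' One-row summary of a trained heading classifier
#'
#' @param x a `heading_classifier`.
#' @param ... unused.
#' @return tibble: `backend`, `n_headings`, `vocab_size`, `vector_width`,
#'   `epochs_trained`, `best_dev_accuracy`.
#' @exportS3Method generics::glance
glance.heading_classifier <- function(x, ...) {
  tibble(
    backend = x$config$backend,
    n_headings = length(x$headings),
    vocab_size = length(x$vocabulary),
    vector_width = ncol(x$params$W_out),
    epochs_trained = if (nrow(x$history)) max(x$history$epoch) else 0L,
    best_dev_accuracy = if (nrow(x$history)) max(x$history$dev_accuracy) else NA_real_
  )
}

#' Training-history plot for a classifier
#'
#' @param object a `heading_classifier`.
#' @param ... unused.
#' @return a ggplot: dev accuracy and training loss per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.heading_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "dev_accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Classifier training history")
}

#' Heatmap of a paragraph similarity matrix
#'
#' @param object a `paragraph_similarity` matrix.
#' @param ... unused.
#' @return a ggplot tile map of the directed scores (source rows, target
#'   columns).
#' @exportS3Method ggplot2::autoplot
autoplot.paragraph_similarity <- function(object, ...) {
  S <- unclass(object)
  df <- tidyr::expand_grid(src = rownames(S), tgt = colnames(S))
  df$score <- S[cbind(df$src, df$tgt)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tgt, y = .data$src, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$score), "",
                                                   sprintf("%.2f", .data$score))), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-2, 3), low = "steelblue",
                                  mid = "white", high = "firebrick", na.value = "grey90") +
    ggplot2::labs(x = "target paragraph", y = "source paragraph",
                  title = "Directed paragraph similarity")
}

#' Calibration-curve plot
#'
#' @param object a `threshold_calibration` result.
#' @param ... unused.
#' @return a ggplot: produced paragraph total as a step function of the
#'   threshold, with the reference total and selected threshold marked.
#' @exportS3Method ggplot2::autoplot
autoplot.threshold_calibration <- function(object, ...) {
  g <- attr(object, "grid")
  ggplot2::ggplot(g, ggplot2::aes(x = .data$threshold, y = .data$total_paragraphs)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = attr(object, "reference_total"), linetype = 2) +
    ggplot2::geom_vline(xintercept = as.numeric(object), colour = "firebrick") +
    ggplot2::labs(x = "merge threshold", y = "total paragraphs produced",
                  title = "Threshold calibration")
}

#' Model-vs-taxonomy rank scatter
#'
#' @param object a `pair_ranking`.
#' @param ... unused.
#' @return a ggplot of `rank_model` against `rank_tree`; points far off the
#'   diagonal are conflict candidates.
#' @exportS3Method ggplot2::autoplot
autoplot.pair_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank_model, y = .data$rank_tree)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "rank by model (cosine) distance",
                  y = "rank by taxonomy (tree) distance",
                  title = "Learned vs taxonomy heading similarity")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
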