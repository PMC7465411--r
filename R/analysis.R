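#' Pairwise cosine distances between heading vectors
#'
#' Cosine distance (`1 - cosine similarity`) for every unordered pair of the
#' selected headings.
#'
#' @param vectors a `heading_vectors` matrix (rownames = heading ids).
#' @param ids subset of heading ids; defaults to all rows.
#' @return tibble with columns `a`, `b` (with `a < b`) and `distance`.
#' @export
cosine_pair_distances <- function(vectors, ids = rownames(vectors)) {
  missing_ids <- setdiff(ids, rownames(vectors))
  if (length(missing_ids) > 0L) {
    abort(paste0("no vector for heading(s): ", paste(missing_ids, collapse = ", ")))
  }
  if (length(ids) < 2L) abort("need at least two headings")
  V <- unclass(vectors)[ids, , drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) {
    abort(paste0("zero vector for heading '", ids[which(nrm == 0)[1L]], "'"))
  }
  C <- (V / nrm) %*% t(V / nrm)
  pairs <- utils::combn(sort(ids), 2L)
  tibble(
    a = pairs[1L, ],
    b = pairs[2L, ],
    distance = 1 - C[cbind(pairs[1L, ], pairs[2L, ])]
  )
}

#' Rank heading pairs by model distance and taxonomy distance
#'
#' Maps headings onto the taxonomy by strict string matching on identifiers
#' (unmapped headings are dropped and reported via the `"unmapped"`
#' attribute), computes the cosine distance and the tree distance for every
#' unordered pair of mapped headings, and ranks the pairs under each
#' distance (ascending, fractional ranks for ties — tree distances are small
#' integers, so ties are pervasive).
#'
#' @param vectors a `heading_vectors` matrix.
#' @param tax a [heading_taxonomy()].
#' @param ids headings to analyse; defaults to all vector rows.
#' @return a tibble of class `pair_ranking` with columns `a`, `b`,
#'   `d_model`, `d_tree`, `rank_model`, `rank_tree`.
#' @export
build_rankings <- function(vectors, tax, ids = rownames(vectors)) {
  mapped <- intersect(ids, tax$id)
  unmapped <- setdiff(ids, mapped)
  if (length(mapped) < 2L) abort("fewer than two headings map onto the taxonomy")
  pr <- cosine_pair_distances(vectors, mapped)
  D <- tree_distance_matrix(tax, mapped)
  pr$d_tree <- as.integer(D[cbind(pr$a, pr$b)])
  out <- tibble(
    a = pr$a, b = pr$b,
    d_model = pr$distance, d_tree = pr$d_tree,
    rank_model = rank(pr$distance, ties.method = "average"),
    rank_tree = rank(pr$d_tree, ties.method = "average")
  )
  attr(out, "unmapped") <- unmapped
  class(out) <- c("pair_ranking", class(out))
  out
}

#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of fractional ranks; equals the classical
#' `1 - 6*sum(d^2)/(n(n^2-1))` formula when there are no ties.
#'
#' @param r1,r2 numeric vectors over the same pair set (raw values or
#'   ranks), or a single `pair_ranking` passed as `r1` (its two rankings are
#'   correlated).
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(r1, r2 = NULL) {
  if (inherits(r1, "pair_ranking") && is.null(r2)) {
    r2 <- r1$rank_tree
    r1 <- r1$rank_model
  }
  if (length(r1) != length(r2)) abort("rankings cover different pair sets")
  if (length(r1) < 2L) abort("need at least two pairs")
  stats::cor(r1, r2, method = "spearman")
}

#' Conflict pairs between learned and taxonomy similarity
#'
#' Heading pairs the classifier treats as close but the taxonomy places far
#' apart (or vice versa) betray discrepancies between how headings are used
#' and how the taxonomy organizes them — the typical finding being
#' diagnosis/intervention twins documented with identical content. Pairs are
#' ordered by the signed rank difference: `rank_tree - rank_model` for
#' `model_close_tree_far` (large when the model ranks a pair near and the
#' tree ranks it far), and the negation for the opposite direction.
#'
#' @param ranking a [build_rankings()] result.
#' @param direction `"model_close_tree_far"` or `"tree_close_model_far"`.
#' @param top_n how many pairs to return (0 allowed).
#' @return tibble of `top_n` rows: `a`, `b`, `rank_model`, `rank_tree`,
#'   `difference`, sorted by decreasing difference, ties broken by pair ids.
#' @export
conflict_pairs <- function(ranking,
                           direction = c("model_close_tree_far", "tree_close_model_far"),
                           top_n = 10L) {
  direction <- match.arg(direction)
  stopifnot(top_n >= 0)
  diff <- ranking$rank_tree - ranking$rank_model
  if (direction == "tree_close_model_far") diff <- -diff
  out <- tibble(
    a = ranking$a, b = ranking$b,
    rank_model = ranking$rank_model, rank_tree = ranking$rank_tree,
    difference = diff
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$difference), .data$a, .data$b)
  dplyr::slice_head(out, n = top_n)
}

#' Write conflict pairs as TSV
#'
#' @param conflicts a [conflict_pairs()] tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_conflicts_tsv <- function(conflicts, path) {
  readr::write_tsv(conflicts, path)
  invisible(path)
}

#' Hierarchical clustering of heading vectors
#'
#' Agglomerative clustering of the headings under cosine distance; useful as
#' a dendrogram view of the learned heading space (clusters of headings used
#' over similar content).
#'
#' @param vectors a `heading_vectors` matrix.
#' @param ids headings to cluster; defaults to all.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return an [ape::as.phylo()] tree (class `phylo`) with the headings as
#'   tips; merge heights become branch lengths.
#' @export
cluster_headings <- function(vectors, ids = rownames(vectors),
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (length(ids) < 2L) abort("need at least two headings")
  pd <- cosine_pair_distances(vectors, ids)
  ids <- sort(ids)
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  D[cbind(pd$a, pd$b)] <- pd$distance
  D <- D + t(D)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  ape::as.phylo(hc)
}

#' Export a heading dendrogram as Newick
#'
#' @param tree a `phylo` tree from [cluster_headings()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
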