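#' Heading taxonomies
#'
#' A heading taxonomy is a rooted tree over heading identifiers: an
#' artificial root joins the top-level categories (typically nursing
#' diagnoses and nursing interventions), each of which carries its own
#' hierarchy. Node depth counts edges from the root (`depth(root) = 0`).
#'
#' @param nodes tibble with columns `id`, `parent` (`NA` for the root) and
#'   `category` (the top-level category a node belongs to; `NA` for the
#'   root).
#' @return an object of class `heading_taxonomy`: the node tibble with a
#'   `depth` and `is_leaf` column and an igraph representation attached.
#' @export
heading_taxonomy <- function(nodes) {
  stopifnot(all(c("id", "parent") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  roots <- nodes$id[is.na(nodes$parent)]
  if (length(roots) != 1L) abort("taxonomy must have exactly one root")
  if (!all(stats::na.omit(nodes$parent) %in% nodes$id)) abort("unknown parent id")
  if (!"category" %in% names(nodes)) nodes$category <- NA_character_

  g <- igraph::graph_from_data_frame(
    data.frame(from = stats::na.omit(nodes$parent),
               to = nodes$id[!is.na(nodes$parent)]),
    directed = FALSE,
    vertices = data.frame(name = nodes$id)
  )
  if (!igraph::is_tree(g) && igraph::vcount(g) > 1L) abort("taxonomy edges do not form a tree")
  depth <- as.integer(igraph::distances(g, v = roots)[1L, nodes$id])
  out <- tibble(
    id = nodes$id, parent = nodes$parent, category = nodes$category,
    depth = depth, is_leaf = !(nodes$id %in% nodes$parent)
  )
  attr(out, "graph") <- g
  attr(out, "root") <- roots
  class(out) <- c("heading_taxonomy", class(out))
  out
}

#' Shortest-path distance between two taxonomy nodes
#'
#' The number of edges on the unique tree path between two headings: 0 for a
#' node and itself, 2 for siblings, and up to twice the maximum depth for
#' leaves in different categories (the path runs through the artificial
#' root). A simple but effective semantic distance on concept hierarchies.
#'
#' @param tax a [heading_taxonomy()].
#' @param a,b node ids.
#' @return non-negative integer edge count.
#' @export
tree_distance <- function(tax, a, b) {
  unknown <- setdiff(c(a, b), tax$id)
  if (length(unknown) > 0L) {
    abort(paste0("unknown taxonomy node(s): ", paste(unknown, collapse = ", ")))
  }
  g <- attr(tax, "graph")
  as.integer(igraph::distances(g, v = a, to = b)[1L, 1L])
}

# full pairwise tree-distance matrix over a node subset
tree_distance_matrix <- function(tax, ids) {
  unknown <- setdiff(ids, tax$id)
  if (length(unknown) > 0L) {
    abort(paste0("unknown taxonomy node(s): ", paste(unknown, collapse = ", ")))
  }
  D <- igraph::distances(attr(tax, "graph"), v = ids, to = ids)
  storage.mode(D) <- "integer"
  D
}

#' Read / write a taxonomy as JSON
#'
#' Format: `{"nodes": [{"id", "parent", "category"}, ...]}` with `null`
#' parent for the root.
#'
#' @param tax a `heading_taxonomy`.
#' @param path file path.
#' @return the reader returns a `heading_taxonomy`; the writer returns
#'   `path` invisibly.
#' @export
read_taxonomy_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)$nodes
  heading_taxonomy(tibble(
    id = purrr::map_chr(raw, "id"),
    parent = purrr::map_chr(raw, function(n) n$parent %||% NA_character_),
    category = purrr::map_chr(raw, function(n) n$category %||% NA_character_)
  ))
}

#' @rdname read_taxonomy_json
#' @export
write_taxonomy_json <- function(tax, path) {
  nodes <- lapply(seq_len(nrow(tax)), function(i) {
    list(id = tax$id[i],
         parent = if (is.na(tax$parent[i])) NULL else tax$parent[i],
         category = if (is.na(tax$category[i])) NULL else tax$category[i])
  })
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
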