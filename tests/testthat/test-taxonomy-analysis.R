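test_that("taxonomy construction validates tree shape", {
  nodes <- tibble::tibble(
    id = c("root", "diagnosis", "intervention", "D1", "D1.1"),
    parent = c(NA, "root", "root", "diagnosis", "D1"),
    category = c(NA, "diagnosis", "intervention", "diagnosis", "diagnosis")
  )
  tax <- heading_taxonomy(nodes)
  expect_equal(tax$depth, c(0L, 1L, 1L, 2L, 3L))
  expect_true(tax$is_leaf[tax$id == "D1.1"])
  expect_error(heading_taxonomy(dplyr::mutate(nodes, parent = dplyr::if_else(id == "diagnosis", NA_character_, parent))),
               "exactly one root")
  expect_error(heading_taxonomy(tibble::tibble(id = c("a", "a"), parent = c(NA, "a"))),
               "duplicate")
})

test_that("tree distance counts edges on the unique path", {
  tax <- generate_taxonomy(generator_config())
  expect_equal(tree_distance(tax, "D1.1.1", "D1.1.1"), 0L)
  # two leaves under one parent
  expect_equal(tree_distance(tax, "D1.1.1", "D1.2.1"), 4L) # via D1
  sibs <- tax$id[!is.na(tax$parent) & tax$parent == "D1"]
  expect_equal(tree_distance(tax, sibs[1], sibs[2]), 2L)
  # depth-4 diagnosis leaf to depth-4 intervention leaf crosses the root: 8
  expect_equal(max(tax$depth), 4L)
  expect_equal(tree_distance(tax, "D1.1.1", "I1.1.1"), 8L)
  expect_error(tree_distance(tax, "D1.1.1", "nope"), "unknown")
})

test_that("tree distance matches breadth-first search on random trees", {
  for (seed in 1:100) {
    nodes <- random_tree_nodes(seed, max_nodes = 50)
    tax <- heading_taxonomy(nodes)
    adj <- adjacency_of(nodes)
    ids <- withr::with_seed(seed + 1000, {
      n_check <- min(6L, nrow(nodes))
      nodes$id[sample.int(nrow(nodes), n_check)]
    })
    for (a in ids) {
      for (b in ids) {
        expect_identical(tree_distance(tax, a, b), bfs_distance(adj, a, b),
                         info = sprintf("seed %d: %s-%s", seed, a, b))
      }
    }
  }
})

test_that("tree distance is a metric", {
  nodes <- random_tree_nodes(7, max_nodes = 20)
  tax <- heading_taxonomy(nodes)
  D <- withr::with_seed(8, {
    ids <- nodes$id[sample.int(nrow(nodes), min(8, nrow(nodes)))]
    outer(ids, ids, Vectorize(function(a, b) tree_distance(tax, a, b)))
  })
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  n <- nrow(D)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    expect_lte(D[i, j], D[i, k] + D[k, j])
  }
})

test_that("cosine pair distances follow the geometry", {
  V <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1))
  pd <- cosine_pair_distances(V)
  get <- function(x, y) pd$distance[pd$a == min(x, y) & pd$b == max(x, y)]
  expect_equal(get("a", "b"), 0)
  expect_equal(get("a", "c"), 1)
  expect_equal(get("a", "d"), 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(nrow(pd), choose(4, 2))

  Vz <- rbind(a = c(1, 0), z = c(0, 0))
  expect_error(cosine_pair_distances(Vz), "zero vector for heading 'z'")
  expect_error(cosine_pair_distances(V, "a"), "at least two")
})

test_that("pair rankings cover all pairs with fractional ranks", {
  tax <- generate_taxonomy(generator_config())
  V <- withr::with_seed(5, matrix(rnorm(12), 3, 4,
                                  dimnames = list(c("D1.1.1", "D1.2.1", "I1.1.1"), NULL)))
  rk <- build_rankings(V, tax)
  expect_equal(nrow(rk), 3L)
  expect_setequal(rk$rank_model, 1:3)

  # all tree distances equal -> every tree rank is the mean rank
  V2 <- withr::with_seed(6, matrix(rnorm(12), 3, 4,
                                   dimnames = list(c("D1.1.1", "D1.3.1", "D1.5.1"), NULL)))
  rk2 <- build_rankings(V2, tax)
  expect_equal(rk2$rank_tree, rep(2, 3))

  # unmapped headings are dropped and reported
  V3 <- rbind(V, elsewhere = rnorm(4))
  rk3 <- build_rankings(V3, tax)
  expect_equal(nrow(rk3), 3L)
  expect_equal(attr(rk3, "unmapped"), "elsewhere")
  expect_error(build_rankings(V3, tax, ids = c("elsewhere", "D1.1.1")), "fewer than two")
})

test_that("hand-set four-heading rankings match exhaustive enumeration", {
  # vectors on the unit circle at 0, 10, 90, 180 degrees
  ang <- c(A = 0, B = 10, C = 90, D = 180) * pi / 180
  V <- cbind(cos(ang), sin(ang))
  rownames(V) <- names(ang)
  nodes <- tibble::tibble(
    id = c("root", "cat1", "cat2", "A", "B", "C", "D"),
    parent = c(NA, "root", "root", "cat1", "cat1", "cat2", "cat2"),
    category = c(NA, "cat1", "cat2", "cat1", "cat1", "cat2", "cat2")
  )
  tax <- heading_taxonomy(nodes)
  rk <- build_rankings(V, tax, ids = c("A", "B", "C", "D"))
  # model distances ascending: AB (~0.015) < BC < AC=1 < BD < CD < AD=2
  expect_equal(rk$rank_model[rk$a == "A" & rk$b == "B"], 1)
  expect_equal(rk$rank_model[rk$a == "A" & rk$b == "D"], 6)
  # tree: siblings AB, CD at 2; cross pairs at 4 -> fractional ranks
  expect_equal(rk$rank_tree[rk$a == "A" & rk$b == "B"], 1.5)
  expect_equal(rk$rank_tree[rk$a == "C" & rk$b == "D"], 1.5)
  expect_equal(rk$rank_tree[rk$a == "A" & rk$b == "C"], 4.5)
})

test_that("spearman correlation matches the closed form and a naive oracle", {
  expect_equal(spearman_rho(1:4, 1:4), 1)
  expect_equal(spearman_rho(1:4, 4:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8) # 1 - 6*2/60
  expect_error(spearman_rho(1:3, 1:4), "different pair sets")
  expect_error(spearman_rho(1, 1), "at least two")

  for (seed in 1:100) {
    xy <- withr::with_seed(seed, {
      n <- sample(5:40, 1)
      list(x = sample(1:8, n, replace = TRUE), y = sample(1:8, n, replace = TRUE))
    })
    if (stats::var(xy$x) == 0 || stats::var(xy$y) == 0) next
    expect_equal(spearman_rho(xy$x, xy$y), oracle_spearman(xy$x, xy$y),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("conflict pairs order by signed rank difference, both directions", {
  tax <- generate_taxonomy(generator_config())
  V <- withr::with_seed(9, matrix(rnorm(5 * 6), 5, 6,
                                  dimnames = list(c("D1.1.1", "D1.2.1", "D2.1.1", "I1.1.1", "I2.1.1"), NULL)))
  rk <- build_rankings(V, tax)
  expect_equal(nrow(conflict_pairs(rk, top_n = 0)), 0L)

  up <- conflict_pairs(rk, "model_close_tree_far", top_n = nrow(rk))
  down <- conflict_pairs(rk, "tree_close_model_far", top_n = nrow(rk))
  key <- function(d) paste(d$a, d$b)
  expect_equal(
    up$difference[match(key(down), key(up))],
    -down$difference
  )
  expect_false(is.unsorted(rev(up$difference)))

  # identical rankings -> all differences zero
  rk0 <- rk
  rk0$rank_tree <- rk0$rank_model
  expect_true(all(conflict_pairs(rk0, top_n = 5)$difference == 0))
})

test_that("heading clustering produces a Newick-exportable dendrogram", {
  V <- rbind(a = c(1, 0, 0), b = c(0, 1, 0))
  tr <- cluster_headings(V)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b"))
  # the single merge happens at their cosine distance
  expect_equal(sum(tr$edge.length), 1, tolerance = 1e-9)

  V2 <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0), d = c(0.1, 0.9, 0))
  tr2 <- cluster_headings(V2, linkage = "average")
  coph <- ape::cophenetic.phylo(tr2)
  expect_equal(coph["a", "b"], 0, tolerance = 1e-12) # duplicated vector merges first

  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tr2, path)
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), sort(rownames(V2)))
  expect_equal(ape::Ntip(back), 4L)
})
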