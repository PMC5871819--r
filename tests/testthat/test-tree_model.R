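test_that("SWC parsing handles records, comments, and malformed input", {
  p <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# a comment header",
               "1 0 0 0 0 1 -1",
               "2 0 0 0 -5 1 1",
               "3 0 0 0 -10 1 2"), p)
  tr <- read_tree(p)
  expect_equal(tree_length(tr), 3)
  expect_equal(tr$nodes$id[is.na(tr$nodes$parent)], 1L)
  expect_equal(sum(!is.na(tr$nodes$parent)), 2)  # 2 edges
  expect_true(any(grepl("a comment header", tr$provenance)))

  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 2"), p)  # self-parent
  expect_error(read_tree(p), "cycle")

  writeLines(c("1 0 0 0 0 1 -1", "1 0 1 0 0 1 1"), p)  # duplicate id
  expect_error(read_tree(p), "line 2")

  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 9"), p)  # missing parent
  expect_error(read_tree(p), "missing parent")
})

test_that("read/write round trip is the identity on nodes, edges, generations", {
  tr <- generate_airway_tree(tree_gen_params(generations = 4L, seed = 11,
                                             node_spacing_mm = 1))
  p <- withr::local_tempfile(fileext = ".swc")
  write_tree(tr, p)
  back <- read_tree(p)
  expect_equal(back$nodes$id, tr$nodes$id)
  expect_equal(back$nodes$parent, tr$nodes$parent)
  expect_equal(back$nodes$generation, tr$nodes$generation)
  expect_equal(back$nodes[, c("x", "y", "z")], tr$nodes[, c("x", "y", "z")],
               tolerance = 1e-15)
  # second trip is byte-identical
  p2 <- withr::local_tempfile(fileext = ".swc")
  write_tree(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("branch_csv dialect reads generations and rejects bad files", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(node_id = 1:3, x = 0, y = 0, z = c(0, -1, -2),
                              parent_id = c(NA, 1, 2), generation = c(0, 0, 1)),
                   p, row.names = FALSE)
  tr <- read_tree(p, dialect = "branch_csv")
  expect_equal(tr$nodes$generation, c(0L, 0L, 1L))
  utils::write.csv(data.frame(a = 1), p, row.names = FALSE)
  expect_error(read_tree(p, dialect = "branch_csv"), "parse error")
})

test_that("write_tree refuses empty trees", {
  tr <- airway_tree(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                               z = numeric(0), parent = integer(0)))
  expect_error(write_tree(tr, tempfile()), "no nodes")
})

test_that("rotate_tree follows the right-hand rule about fixed axes", {
  tr <- airway_tree(data.frame(id = 1:2, x = 0, y = c(0, 1), z = 0,
                               parent = c(NA, 1)))
  expect_equal(as.matrix(rotate_tree(tr, c(0, 0, 0))$nodes[, c("x", "y", "z")]),
               as.matrix(tr$nodes[, c("x", "y", "z")]))
  r <- rotate_tree(tr, c(90, 0, 0))   # (0,1,0) -> (0,0,1)
  expect_equal(unlist(r$nodes[2, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 1), tolerance = 1e-12)
  twice <- rotate_tree(rotate_tree(tr, c(180, 0, 0)), c(180, 0, 0))
  expect_equal(as.matrix(twice$nodes[, c("x", "y", "z")]),
               as.matrix(tr$nodes[, c("x", "y", "z")]), tolerance = 1e-12)
})

test_that("rotation preserves counts and pairwise distances", {
  tr <- generate_airway_tree(tree_gen_params(generations = 4L, seed = 5,
                                             node_spacing_mm = 1))
  rot <- rotate_tree(tr, c(10, 220, 35))
  expect_equal(tree_length(rot), tree_length(tr))
  expect_equal(branch_point_count(rot), branch_point_count(tr))
  i <- seq(1, tree_length(tr), by = 17)
  d0 <- dist(as.matrix(tr$nodes[i, c("x", "y", "z")]))
  d1 <- dist(as.matrix(rot$nodes[i, c("x", "y", "z")]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("branch point and length counts match generator ground truth", {
  for (seed in c(2, 9)) {
    tr <- generate_airway_tree(tree_gen_params(generations = 5L, seed = seed,
                                               node_spacing_mm = 1))
    log <- attr(tr, "event_log")
    expect_equal(branch_point_count(tr), log$n_bifurcations)
    expect_equal(tree_length(tr), sum(log$nodes_per_generation))
  }
  y <- airway_tree(data.frame(id = 1:4, x = c(0, 0, -1, 1), y = 0,
                              z = c(0, -1, -2, -2), parent = c(NA, 1, 2, 2)))
  expect_equal(branch_point_count(y), 1)           # one bifurcation
  expect_equal(branch_point_count(path_tree(0:-5)), 0)  # path graph
})

test_that("prune_to_generation matches bookkeeping and is monotone", {
  tr <- generate_airway_tree(tree_gen_params(generations = 6L, seed = 3,
                                             node_spacing_mm = 1))
  log <- attr(tr, "event_log")
  expect_equal(tree_length(prune_to_generation(tr, 0)), tree_length(tr))
  for (g in 1:5)
    expect_equal(tree_length(prune_to_generation(tr, g)),
                 sum(log$nodes_per_generation[(g + 1):6]))
  expect_equal(tree_length(prune_to_generation(tr, 99)), 0)
  # idempotent and monotone
  p2 <- prune_to_generation(tr, 2)
  expect_equal(prune_to_generation(p2, 2)$nodes, p2$nodes)
  lens <- vapply(0:6, function(g) tree_length(prune_to_generation(tr, g)), 1L)
  expect_true(all(diff(lens) <= 0))
  # unlabeled tree errors
  ul <- airway_tree(data.frame(id = 1:2, x = 0, y = 0, z = c(0, -1),
                               parent = c(NA, 1)))
  expect_error(prune_to_generation(ul, 1), "generation labels")
})

test_that("structural validation rejects cycles and bad generations", {
  expect_error(airway_tree(data.frame(id = 1:2, x = 0, y = 0, z = 0,
                                      parent = c(2, 1))), "cycle")
  expect_error(airway_tree(data.frame(id = 1:2, x = 0, y = 0, z = 0,
                                      parent = c(NA, 1),
                                      generation = c(0, 3))), "generation")
  # multi-root forests are accepted
  f <- airway_tree(data.frame(id = 1:4, x = 0:3, y = 0, z = 0,
                              parent = c(NA, 1, NA, 3)))
  expect_equal(length(unique(lungtda:::tree_component_ids(f))), 2)
})
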