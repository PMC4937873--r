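test_that("edge lists load into simple graphs with dedup and loop removal", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  g <- load_edges(f)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(igraph::ecount(load_edges(empty)), 0)

  # malformed rows are skipped with a message naming the line
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "oops", "C\tD"), bad)
  expect_message(g2 <- load_edges(bad), "line")
  expect_equal(igraph::ecount(g2), 2)

  # a 10-edge fixture with hand-counted nodes and edges
  fx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc", "c\td", "d\ta", "a\tc", "b\td",
               "e\tf", "f\tg", "g\te", "h\ti"), fx)
  g3 <- load_edges(fx)
  expect_equal(igraph::vcount(g3), 9)
  expect_equal(igraph::ecount(g3), 10)
})

test_that("one-bridge extraction handles the worked toy and degenerate cases", {
  g <- edges_to_graph(rbind(c("A", "B"), c("A", "X"), c("X", "C"),
                            c("X", "Y"), c("Y", "D")))
  res <- extract_subnetwork(g, c("A", "B", "C"))
  expect_setequal(res$nodes$node, c("A", "B", "C", "X"))
  expect_equal(edge_keys(res$edges), c("A B", "A X", "C X"))
  expect_equal(res$intermediates, "X")
  expect_equal(res$largest_cluster_size, 4)
  expect_equal(dplyr::n_distinct(res$nodes$component), 1)

  # candidates with no edges among or through them: empty subnetwork
  none <- extract_subnetwork(g, c("B", "D"))
  expect_equal(none$largest_cluster_size, 0)
  expect_equal(nrow(none$edges), 0)

  # candidate set = every node: the rule degenerates to the identity
  all_nodes <- igraph::V(g)$name
  full <- extract_subnetwork(g, all_nodes)
  expect_equal(nrow(full$edges), igraph::ecount(g))

  # unmapped candidates are recorded, not an error
  um <- extract_subnetwork(g, c("A", "Z9"))
  expect_equal(um$unmapped, "Z9")
})

test_that("extraction equals brute-force path enumeration (exhaustive + random)", {
  # exhaustive: every graph on 4 labelled nodes x every candidate subset
  nodes4 <- c("a", "b", "c", "d")
  prs <- t(utils::combn(nodes4, 2))
  for (mask in 0:(2^nrow(prs) - 1)) {
    E <- prs[bitwAnd(mask, 2^(seq_len(nrow(prs)) - 1)) > 0, , drop = FALSE]
    g <- edges_to_graph(E)
    for (cmask in 0:15) {
      cand <- nodes4[bitwAnd(cmask, c(1, 2, 4, 8)) > 0]
      got <- extract_subnetwork(g, cand)
      want <- brute_subnetwork(E, cand)
      expect_identical(edge_keys(got$edges), want$edges)
      expect_identical(sort(got$intermediates), want$intermediates)
    }
  }

  # random 7-node graphs with random candidate sets
  withr::with_seed(55, {
    for (i in 1:100) {
      nodes7 <- letters[1:7]
      prs7 <- t(utils::combn(nodes7, 2))
      E <- prs7[runif(nrow(prs7)) < 0.3, , drop = FALSE]
      g <- edges_to_graph(E)
      cand <- sample(nodes7, sample(0:7, 1))
      cand <- intersect(cand, if (nrow(E)) unique(c(E)) else character(0))
      got <- extract_subnetwork(g, cand)
      want <- brute_subnetwork(E, cand)
      expect_identical(edge_keys(got$edges), want$edges)
      expect_identical(sort(got$intermediates), want$intermediates)
    }
  })
})

test_that("extraction is order-independent and monotone in the candidate set", {
  withr::with_seed(56, {
    prs <- t(utils::combn(letters[1:12], 2))
    E <- prs[runif(nrow(prs)) < 0.25, , drop = FALSE]
  })
  g <- edges_to_graph(E)
  cand <- c("a", "d", "f", "k")
  r1 <- extract_subnetwork(g, cand)
  r2 <- extract_subnetwork(g, rev(cand))
  expect_identical(edge_keys(r1$edges), edge_keys(r2$edges))

  # adding a candidate never shrinks the retained edge set
  r3 <- extract_subnetwork(g, c(cand, "b"))
  expect_true(all(edge_keys(r1$edges) %in% edge_keys(r3$edges)))
})

test_that("randomization test tails, boundaries and determinism behave", {
  # edgeless graph: observed largest is 0; no draw can exceed it
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  g0 <- igraph::set_vertex_attr(g0, "name", value = letters[1:5])
  r0 <- randomization_test(g0, c("a", "b"), n_randomizations = 50, seed = 1)
  expect_equal(r0$permutation$p_strict, 0)
  expect_equal(r0$permutation$p_inclusive, 1)

  g <- edges_to_graph(rbind(c("A", "B"), c("A", "X"), c("X", "C"),
                            c("X", "Y"), c("Y", "D")))
  r <- randomization_test(g, c("A", "B", "C"), n_randomizations = 200, seed = 9)
  pm <- r$permutation
  expect_lte(pm$p_strict, pm$p_inclusive)
  expect_equal(pm$p_strict,
               mean(pm$null_sizes > r$largest_cluster_size))
  expect_equal(pm$p_inclusive,
               mean(pm$null_sizes >= r$largest_cluster_size))

  # same seed reproduces; add-one estimator shifts both tails
  r2 <- randomization_test(g, c("A", "B", "C"), n_randomizations = 200, seed = 9)
  expect_identical(r$permutation, r2$permutation)
  r3 <- randomization_test(g, c("A", "B", "C"), n_randomizations = 200, seed = 9,
                           add_one = TRUE)
  expect_equal(r3$permutation$p_strict,
               (sum(pm$null_sizes > r$largest_cluster_size) + 1) / 201)

  expect_error(randomization_test(g, igraph::V(g)$name, seed = 1,
                                  n_randomizations = 0), "n_randomizations")
})

test_that("ortholog overlay reports the mapped fraction", {
  g <- edges_to_graph(rbind(c("A", "B"), c("A", "X"), c("X", "C")))
  res <- extract_subnetwork(g, c("A", "B", "C"))

  empty <- overlay_orthologs(res, tibble::tibble(node = character(0),
                                                 ortholog = character(0)))
  expect_equal(empty$ortholog_fraction, 0)

  full <- overlay_orthologs(res, tibble::tibble(
    node = res$nodes$node, ortholog = paste0("HS_", res$nodes$node)
  ))
  expect_equal(full$ortholog_fraction, 1)

  # 3 of 4 nodes mapped; one-to-many rows count once
  part <- overlay_orthologs(res, tibble::tibble(
    node = c("A", "A", "B", "X"), ortholog = c("H1", "H2", "H3", "H4")
  ))
  expect_equal(part$ortholog_fraction, 0.75)
  expect_equal(part$orthologs$orthologs[part$orthologs$node == "A"], "H1,H2")
})
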