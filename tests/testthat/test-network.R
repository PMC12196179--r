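test_that("target intersection counts the Venn overlap after symbol cleanup", {
  res <- intersect_targets(list(c1 = c("A", "B"), c2 = c("b", "C")), c("B", "C", "D"))
  expect_equal(unlist(res$counts), c(n_compound_union = 3L, n_disease = 3L, n_overlap = 2L))
  expect_equal(res$overlap, c("B", "C"))
  all_disease <- intersect_targets(list(c1 = c("A", "B", "C")), LETTERS)
  expect_equal(all_disease$overlap, c("A", "B", "C"))
  expect_error(intersect_targets(list(), "A"), class = "phytonet_validation_error")
})

test_that("network construction filters strictly, handles dialects, drops isolates", {
  edges <- tibble::tibble(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g1"),
    s = c(0.39, 0.40, 0.41))
  net <- build_ppi_network(edges, min_confidence = 0.4)
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$confidence, 0.41)
  lax <- build_ppi_network(edges, min_confidence = 0.4, strict = FALSE)
  expect_equal(n_edges(lax), 2)
  string_style <- tibble::tibble(a = "g1", b = "g2", s = 700)
  expect_equal(build_ppi_network(string_style)$edges$confidence, 0.7)
  # star plus a detached pair: the detached pair's edge survives, but a node
  # whose every edge is filtered out disappears
  star <- tibble::tibble(
    a = c("h", "h", "h", "x"), b = c("l1", "l2", "l3", "y"),
    s = c(0.9, 0.9, 0.9, 0.2)
  )
  net2 <- build_ppi_network(star)
  expect_equal(n_nodes(net2), 4)
  expect_equal(n_edges(net2), 3)
  expect_false(any(c("X", "Y") %in% net2$nodes))
  big <- build_ppi_network(star, largest_component = TRUE)
  expect_equal(n_nodes(big), 4)
  bad <- tibble::tibble(a = "g1", b = "g2", s = "not-a-number")
  expect_error(build_ppi_network(bad), "row")
})

test_that("centralities match hand-enumerable graphs", {
  path <- ppi_network(tibble::tibble(from = c("a", "b"), to = c("b", "c"), confidence = 1))
  tab <- centralities(path)
  expect_equal(tab$dc[tab$node == "b"], 2L)
  expect_equal(tab$bc[tab$node == "b"], 1)
  expect_equal(tab$cc[tab$node == "b"], 1)
  expect_equal(tab$cc[tab$node == "a"], 2 / 3)
  star <- ppi_network(tibble::tibble(from = "h", to = c("a", "b", "c"), confidence = 1))
  stab <- centralities(star)
  expect_equal(stab$dc[stab$node == "h"], 3L)
  expect_equal(stab$bc[stab$node == "h"], 3)
  expect_equal(stab$cc[stab$node == "h"], 1)
  expect_equal(stab$cc[stab$node != "h"], rep(0.6, 3))
})

test_that("centralities agree with the exhaustive path-counting oracle", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(4:10, 1)
    net <- random_test_network(n, p = runif(1, 0.2, 0.7), seed = s + 1000)
    got <- centralities(net)
    want <- oracle_centralities(net)
    expect_equal(got$dc, want$dc)
    expect_equal(got$bc, want$bc, tolerance = 1e-10)
    expect_equal(got$cc, want$cc, tolerance = 1e-10)
  }
})

test_that("centrality invariants hold on random graphs", {
  for (s in 1:10) {
    net <- random_test_network(8, 0.4, seed = s)
    tab <- centralities(net)
    expect_equal(sum(tab$dc), 2 * n_edges(net))
    expect_true(all(tab$bc[tab$dc == 1] == 0))
    # cc == 1 exactly for nodes adjacent to all others (connected graphs)
    if (length(largest <- phytonet:::largest_component_nodes(net)) == n_nodes(net)) {
      expect_equal(tab$cc == 1, tab$dc == n_nodes(net) - 1)
    }
  }
})

test_that("tier-1 screen keeps nodes at twice the median degree", {
  # degrees (5, 5, 2, 2, 2, 2): median 2, threshold 4 keeps the two hubs
  edges <- tibble::tibble(
    from = c("h1", rep("h1", 4), rep("h2", 4)),
    to = c("h2", c("c", "d", "e", "f"), c("c", "d", "e", "f")),
    confidence = 1
  )
  net <- ppi_network(edges)
  tab <- centralities(net)
  expect_equal(sort(unique(tab$dc)), c(2, 5))
  expect_equal(median(tab$dc), 2)
  t1 <- tier1_screen(net, multiplier = 2)
  expect_setequal(t1$network$nodes, c("h1", "h2"))
  expect_equal(t1$dc_threshold, 2 * median(tab$dc))
  ident <- tier1_screen(net, multiplier = 0)
  expect_setequal(ident$network$nodes, net$nodes)
})

test_that("tier-1 screens are nested in the multiplier and idempotent", {
  net <- gen_ppi_network(120, 3, seed = 21)
  t_a <- tier1_screen(net, multiplier = 1.5)$network$nodes
  t_b <- tier1_screen(net, multiplier = 2.5)$network$nodes
  expect_true(all(t_b %in% t_a))
  # idempotence at fixed thresholds: re-applying the recorded tier-2
  # thresholds to the core table retains the whole core
  hs <- tier2_screen(tier1_screen(net, 2)$network)
  again <- apply_hub_thresholds(hs$core, hs$thresholds$bc_min,
    hs$thresholds$cc_min, hs$thresholds$dc_min)
  expect_equal(again, hs$core)
})

test_that("tier-2 screen retains nodes meeting all three recomputed medians", {
  # complete graph: every node equals every median, all retained
  k5 <- ppi_network(tibble::tibble(
    from = utils::combn(letters[1:5], 2)[1, ],
    to = utils::combn(letters[1:5], 2)[2, ],
    confidence = 1
  ))
  res <- tier2_screen(k5)
  expect_equal(nrow(res$core), 5)
  # a dominant center survives
  wheel <- ppi_network(tibble::tibble(
    from = c(rep("hub", 5), "a", "b"),
    to = c("a", "b", "c", "d", "e", "b", "c"),
    confidence = 1
  ))
  res2 <- tier2_screen(wheel)
  expect_true("hub" %in% res2$core$node)
  expect_equal(res2$core$node[1], "hub")
  single <- ppi_network(tibble::tibble(from = "a", to = "b", confidence = 1))
  expect_error(tier2_screen(phytonet:::induce_subnetwork(single, "a")),
    class = "phytonet_validation_error")
})

test_that("planted mega-hubs survive both screening tiers", {
  for (s in 1:20) {
    net <- gen_ppi_network(300, 5, seed = s, n_hubs = 5)
    hubs <- attr(net, "planted_hubs")
    hs <- hub_screen(net)
    expect_true(all(hubs %in% hs$tier1$network$nodes))
    expect_gte(mean(hubs %in% hs$tier2$core$node), 0.9)
  }
})

test_that("compound degree ranking uses the median cutoff with core at or above", {
  single <- ct_degree_rank(tibble::tibble(compound = "a", target = c("T1", "T2")))
  expect_equal(single$cutoff, 2)
  expect_equal(single$core, "a")
  # odd number of distinct degrees: at least ceiling(n/2) compounds reach the median
  for (s in 1:10) {
    set.seed(s)
    n <- 2 * sample(2:6, 1) + 1
    scores <- tibble::tibble(compound = sprintf("c%02d", 1:n),
      score = sample(1:100, n))
    r <- ct_degree_rank(scores)
    expect_gte(length(r$core), ceiling(n / 2))
    expect_true(all(r$ranking$score[r$ranking$core] >= r$cutoff))
    expect_equal(r$ranking$score, sort(r$ranking$score, decreasing = TRUE))
  }
  # edge-list input counts distinct targets
  edges <- tibble::tibble(
    compound = c("a", "a", "a", "b", "b", "b"),
    target = c("T1", "T2", "T2", "T1", "T2", "T3")
  )
  r2 <- ct_degree_rank(edges)
  expect_equal(r2$ranking$score[r2$ranking$compound == "a"], 2L)
  expect_equal(r2$ranking$score[r2$ranking$compound == "b"], 3L)
})

test_that("networks export to SIF", {
  net <- ppi_network(tibble::tibble(from = "a", to = "b", confidence = 0.8))
  tmp <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, tmp)
  expect_equal(readLines(tmp), "a\tpp\tb")
})
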