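test_that("cycle detection finds barrels and ignores forests", {
  p <- toy_protein(rep("VIVIV", 4))
  tri <- mk_edge_topology(p, rbind(c(1, 2), c(2, 3), c(1, 3)))
  cyc <- find_cycles(tri)
  expect_equal(length(cyc), 1L)
  expect_equal(sort(cyc[[1]]), 1:3)
  path <- mk_edge_topology(p, rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(find_cycles(path), list())
})

test_that("cycle existence agrees with an igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (trial in 1:50) {
    n <- sample(4:8, 1)
    p <- toy_protein(rep("VIVIV", n))
    all_pairs <- t(combn(n, 2))
    pick <- sample(nrow(all_pairs), sample(2:min(8, nrow(all_pairs)), 1))
    edges <- all_pairs[pick, , drop = FALSE]
    topo <- mk_edge_topology(p, edges)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    has_cycle_oracle <- igraph::ecount(g) >
      igraph::vcount(g) - igraph::components(g)$no
    expect_equal(length(find_cycles(topo)) > 0, has_cycle_oracle)
  }
})

test_that("two-colorability: base cases and odd-cycle witnesses", {
  p <- toy_protein(rep("VIVIVIVI", 4))
  single <- mk_edge_topology(p, rbind(c(1, 2)))
  expect_true(is_two_colorable(single)$ok)

  # three contacts on one long strand with pairwise-overlapping footprints:
  # mutually incompatible, odd cycle of length 3
  long <- toy_protein(c("VIVIVIVIVIVI", "VIV", "IVI", "VAV"))
  cts <- list(manual_contact(long, 1, 2, "A", 1:3, 3:1),
              manual_contact(long, 1, 3, "A", 2:4, 3:1),
              manual_contact(long, 1, 4, "A", 3:5, 3:1))
  bad <- sheet_topology(cts, n_strands = 4L)
  res <- is_two_colorable(bad)
  expect_false(res$ok)
  expect_equal(sort(res$witness), 1:3)

  # result invariant under contact relabeling
  res2 <- is_two_colorable(sheet_topology(rev(cts), n_strands = 4L))
  expect_false(res2$ok)
})

test_that("two-colorability agrees with exhaustive coloring on random cases", {
  set.seed(123)
  for (trial in 1:150) {
    n <- sample(4:8, 1)
    p <- toy_protein(rep("VIVIVIVIVI", n))
    all_pairs <- t(combn(n, 2))
    m <- sample(2:min(10, nrow(all_pairs)), 1)
    pick <- sample(nrow(all_pairs), m)
    ors <- sample(c("A", "P"), m, replace = TRUE)
    cts <- lapply(seq_len(m), function(r) {
      i <- all_pairs[pick[r], 1]; j <- all_pairs[pick[r], 2]
      a0 <- sample(1:6, 1); len <- sample(2:4, 1)
      a <- a0:(a0 + len - 1)
      manual_contact(p, i, j, ors[r], a, if (ors[r] == "P") a else rev(a))
    })
    topo <- sheet_topology(cts, n_strands = n)
    edges <- incompatibility_graph(topo)
    res <- is_two_colorable(topo)
    expect_equal(res$ok, oracle_bipartite(m, edges))
    if (res$ok && nrow(edges)) {
      expect_true(all(res$coloring[edges[, 1]] != res$coloring[edges[, 2]]))
    } else if (!res$ok) {
      w <- res$witness
      expect_equal(length(w) %% 2, 1)      # odd cycle
      ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
      ring <- cbind(w, c(w[-1], w[1]))
      expect_true(all(paste(pmin(ring[, 1], ring[, 2]),
                            pmax(ring[, 1], ring[, 2])) %in% ek))
    }
  }
})

test_that("the validator passes planted fixtures and localizes violations", {
  cfg <- default_config()
  fx <- suppressWarnings(make_fixture(4, seed = 3, config = cfg))
  rep_ok <- validate_topology(fx$planted, fx$protein, cfg, fx$scored_pairs)
  expect_true(rep_ok$pass)
  expect_true(all(vapply(rep_ok$checks, `[[`, logical(1), "pass")))

  # zero-contact strand fails exactly the minimum-degree requirement
  cfg_rel <- relaxed_config()
  p <- toy_protein(rep("VIVIV", 4))
  topo <- mk_edge_topology(p, rbind(c(1, 2), c(2, 3)))
  rep1 <- suppressWarnings(validate_topology(topo, p, cfg_rel))
  expect_false(rep1$pass)
  failing <- names(Filter(function(ck) !ck$pass, rep1$checks))
  expect_equal(failing, "strand_degree_min")
  expect_true(4 %in% rep1$checks$strand_degree_min$witnesses)
})
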