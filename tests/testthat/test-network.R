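test_that("link selection keeps moderate and high pairs only", {
  # all-weak matrix: every node isolated
  weakm <- sym_from_upper(4, rep(0.1, 6))
  net <- build_network(toy_corr(weakm))
  expect_equal(nrow(net$links), 0)
  expect_equal(nrow(net$nodes), 4)
  expect_true(all(net$C == 0))

  # pairwise c = 0.8, 0.5, 0.1 -> two links, weights 1 and 0.625
  tri <- sym_from_upper(3, c(0.8, 0.5, 0.1))
  net3 <- build_network(toy_corr(tri))
  expect_equal(nrow(net3$links), 2)
  expect_equal(sort(net3$links$weight), c(0.625, 1))
  expect_equal(as.character(sort(net3$links$strength)), c("moderate", "high"))
})

test_that("free-model networks keep all 18 nodes whatever the link pattern", {
  for (s in c(1, 2)) {
    tab <- generate_athletes(free_model_preset(), n = 8, seed = 400 + s)
    net <- build_network(correlate_athletes(tab))
    expect_equal(nrow(net$nodes), 18)
    expect_equal(net$nodes$name, sprint_variables("free")$name)
  }
})

test_that("weight normalization divides by the max over retained links", {
  single <- tibble::tibble(a = "x", b = "y", c_raw = 0.42)
  expect_equal(normalize_weights(single)$weight, 1.0)

  two <- tibble::tibble(a = c("x", "x"), b = c("y", "z"), c_raw = c(0.8, -0.4))
  expect_equal(normalize_weights(two)$weight, c(1.0, 0.5))

  # ratio invariance under global rescaling of coefficients
  for (k in c(0.2, 0.5, 1)) {
    scaled <- dplyr::mutate(two, c_raw = c_raw * k)
    expect_equal(normalize_weights(scaled)$weight, c(1.0, 0.5))
  }

  empty <- tibble::tibble(a = character(), b = character(), c_raw = numeric())
  expect_equal(nrow(normalize_weights(empty)), 0)
})

test_that("the connection matrix is symmetric, hollow, and unit-max", {
  net <- edge_network(2, matrix(c(1, 2), ncol = 2))
  expect_equal(unname(net$C), matrix(c(0, 1, 1, 0), 2))

  for (s in 1:10) {
    net <- random_network(8, seed = 700 + s)
    C <- connection_matrix(net)
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(0, 8))
    if (nrow(net$links) > 0) expect_equal(max(C), 1)
    m <- nrow(net$links)
    expect_true(m >= 0 && m <= choose(8, 2))
    # isolated nodes have all-zero rows and columns
    iso <- setdiff(net$nodes$name, c(net$links$a, net$links$b))
    for (v in iso) {
      expect_true(all(C[v, ] == 0) && all(C[, v] == 0))
    }
  }
})

test_that("candidate pair counts match the published network sizes", {
  free <- build_network(correlate_athletes(
    generate_athletes(free_model_preset(), n = 8, seed = 1)
  ))
  expect_equal(glance(free)$candidate_pairs, 153)
  expect_gt(glance(free)$candidate_pairs, 100)

  # tethered registry: 23 nodes, 253 candidate pairs (structural count only;
  # the tethered preset has a deliberately degenerate mean R margin)
  expect_equal(choose(nrow(sprint_variables("tethered")), 2), 253)
  expect_gt(253, 200)
})

test_that("edge-list export round-trips to a bit-identical connection matrix", {
  tab <- generate_athletes(free_model_preset(), n = 8, seed = 77)
  net <- build_network(correlate_athletes(tab))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  rebuilt <- read_edge_list(f, attr(tab, "registry"))
  expect_identical(rebuilt$C, net$C)
})

test_that("corr/registry mismatch and bad thresholds are rejected", {
  cm <- toy_corr(sym_from_upper(3, c(0.8, 0.5, 0.1)))
  expect_error(build_network(cm, registry = toy_registry(4)),
               class = "sprintnet_error_mismatch")
  expect_error(build_network(cm, weak = 0.9, high = 0.7),
               class = "sprintnet_error_bad_input")
})

test_that("removing a link only changes C through renormalization", {
  net <- build_network(toy_corr(sym_from_upper(3, c(0.8, 0.5, 0.4))))
  # drop the weakest link and rebuild from raw coefficients
  kept <- net$links[-which.min(abs(net$links$c_raw)), ]
  r2 <- diag(1, 3)
  dimnames(r2) <- list(net$nodes$name, net$nodes$name)
  for (k in seq_len(nrow(kept))) {
    r2[kept$a[k], kept$b[k]] <- r2[kept$b[k], kept$a[k]] <- kept$c_raw[k]
  }
  net2 <- build_network(toy_corr(r2, registry = net$nodes))
  denom <- max(abs(kept$c_raw))
  for (k in seq_len(nrow(kept))) {
    expect_equal(net2$C[kept$a[k], kept$b[k]], abs(kept$c_raw[k]) / denom)
  }
})

test_that("GraphML export carries weights and categories", {
  skip_if_not_installed("igraph")
  net <- build_network(correlate_athletes(
    generate_athletes(free_model_preset(), n = 8, seed = 13)
  ))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 18)
  expect_equal(igraph::ecount(g), nrow(net$links))
  expect_setequal(igraph::vertex_attr(g, "category"), unique(net$nodes$category))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::ecount(g2), nrow(net$links))
})
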