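star_network <- function(k) {
  edge_network(k + 1, cbind(1, 2:(k + 1)))
}

test_that("degree counts links per node with the handshake identity", {
  complete4 <- edge_network(4, t(utils::combn(4, 2)))
  expect_equal(node_degree(complete4)$degree, rep(3, 4))

  star5 <- star_network(5)
  deg <- node_degree(star5)
  expect_equal(deg$degree, c(5, rep(1, 5)))
  expect_equal(attr(deg, "argmax"), star5$nodes$name[1])

  for (s in 1:10) {
    net <- random_network(10, seed = 50 + s)
    expect_equal(sum(node_degree(net)$degree), 2 * nrow(net$links))
  }
})

test_that("power method reproduces analytic eigenpairs", {
  pm <- power_method(matrix(c(2, 1, 1, 2), 2), seed = 1)
  expect_equal(pm$lambda, 3, tolerance = 1e-9)
  expect_equal(abs(unname(pm$vector)), rep(1 / sqrt(2), 2), tolerance = 1e-8)

  pd <- power_method(diag(c(1, 0.5)), seed = 1)
  expect_equal(pd$lambda, 1, tolerance = 1e-9)
  expect_equal(unname(pd$vector), c(1, 0), tolerance = 1e-6)

  expect_error(power_method(matrix(0, 3, 3)),
               class = "sprintnet_error_degenerate_matrix")
  expect_error(power_method(matrix(c(0, 1, 2, 0), 2)),
               class = "sprintnet_error_bad_input")
})

test_that("power method matches a dense eigensolver up to 23x23", {
  for (n in c(5, 9, 14, 23)) {
    for (s in 1:3) {
      set.seed(1000 * n + s)
      M <- matrix(runif(n * n), n)
      M <- (M + t(M)) / 2
      pm <- power_method(M, seed = s)
      dd <- dense_dominant(M)
      expect_lt(abs(pm$lambda - dd$lambda), 1e-8)
      angle <- acos(min(1, abs(sum(pm$vector * dd$vector))))
      expect_lt(angle, 1e-6)
    }
  }
})

test_that("power method is seed-independent for simple dominant eigenvalues", {
  set.seed(42)
  M <- matrix(runif(64), 8)
  M <- (M + t(M)) / 2
  a <- power_method(M, seed = 1)
  b <- power_method(M, seed = 99)
  expect_equal(a$lambda, b$lambda, tolerance = 1e-9)
  expect_equal(a$vector, b$vector, tolerance = 1e-7)
})

test_that("eigen-importance singles out the star center and scales freely", {
  star <- star_network(5)
  eig <- eigen_importance(star, seed = 2)
  expect_equal(attr(eig, "argmax"), star$nodes$name[1])
  expect_gt(eig$eigen_importance[1], max(eig$eigen_importance[-1]))
  expect_equal(sum(eig$eigen_importance^2), 1, tolerance = 1e-10)
  expect_true(all(eig$eigen_importance >= 0))

  # global rescaling of all weights leaves the importance vector unchanged
  net <- random_network(9, seed = 31)
  eig1 <- eigen_importance(net, seed = 4)
  pm_half <- power_method(net$C * 0.5, seed = 4)
  expect_equal(eig1$eigen_importance,
               unname(pm_half$vector[net$nodes$name]), tolerance = 1e-6)

  # connected network: strictly positive everywhere (Perron-Frobenius)
  conn <- edge_network(5, cbind(1:4, 2:5))
  expect_true(all(eigen_importance(conn, seed = 6)$eigen_importance > 0))

  isolated <- build_network(toy_corr(sym_from_upper(3, rep(0.1, 3))))
  expect_error(eigen_importance(isolated), class = "sprintnet_error_no_links")
})

test_that("two disconnected equal pairs get equal within-pair importance", {
  net <- edge_network(4, rbind(c(1, 2), c(3, 4)))
  eig <- eigen_importance(net, seed = 8)
  expect_equal(eig$eigen_importance[1], eig$eigen_importance[2], tolerance = 1e-6)
  expect_equal(eig$eigen_importance[3], eig$eigen_importance[4], tolerance = 1e-6)
})

test_that("betweenness matches closed forms on paths and stars", {
  path3 <- edge_network(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(node_betweenness(path3)$betweenness, c(0, 1, 0))

  for (k in c(3, 5, 8)) {
    star <- star_network(k)
    bc <- node_betweenness(star)$betweenness
    expect_equal(bc[1], k * (k - 1) / 2)
    expect_equal(bc[-1], rep(0, k))
  }
})

test_that("Brandes betweenness equals exhaustive path enumeration", {
  for (s in 1:50) {
    net <- random_network(8, seed = 2000 + s)
    expect_equal(node_betweenness(net)$betweenness,
                 brute_betweenness(net)$betweenness, tolerance = 1e-10)
  }
})

test_that("weighted betweenness uses reciprocal-weight path lengths", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    net <- random_network(8, seed = 3000 + s)
    if (nrow(net$links) == 0) next
    g <- as_igraph(net)
    ours <- node_betweenness(net, weighted = TRUE)
    ref <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                               directed = FALSE)
    expect_equal(ours$betweenness, unname(ref[net$nodes$name]), tolerance = 1e-8)
  }
})

test_that("influence trajectories follow S(t) = C^t S(0)", {
  # diagonal closed form s_i(t) = v_i^t s_i(0)
  traj <- influence_trajectory(diag(c(0.5, 2)), c(1, 1), t_max = 3)
  final <- traj[traj$t == 3, ]
  expect_equal(final$state, c(0.125, 8))
  expect_equal(attr(traj, "regime"), "growth")

  # matrix-power oracle on a real network
  net <- build_network(correlate_athletes(
    generate_athletes(free_model_preset(), n = 8, seed = 21)
  ))
  s0 <- seq_len(18) / 18
  traj <- influence_trajectory(net, s0, t_max = 6)
  Ct <- Reduce(`%*%`, rep(list(net$C), 6))
  expect_equal(traj$state[traj$t == 6], as.vector(Ct %*% s0), tolerance = 1e-10)

  # contraction when the leading eigenvalue is below one
  C <- matrix(c(0, 0.4, 0.4, 0), 2)
  tr <- influence_trajectory(C, c(1, 2), t_max = 12)
  norms <- vapply(0:12, function(t) sqrt(sum(tr$state[tr$t == t]^2)), numeric(1))
  expect_equal(attr(tr, "regime"), "decay")
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[13], 1e-3)

  # null initial state stays null
  z <- influence_trajectory(C, c(0, 0), t_max = 5)
  expect_true(all(z$state == 0))

  expect_error(influence_trajectory(C, c(1, 2, 3), 2),
               class = "sprintnet_error_mismatch")
})

test_that("the metrics report gathers all three metrics with maxima", {
  tab <- generate_athletes(free_model_preset(), n = 8, seed = 33)
  net <- build_network(correlate_athletes(tab))
  rep_ <- network_metrics(net, seed = 1)
  expect_equal(nrow(rep_), 18)
  expect_named(tibble::as_tibble(rep_),
               c("node", "category", "degree", "eigen_importance", "betweenness"))
  mx <- attr(rep_, "maxima")
  expect_equal(mx$node[mx$metric == "degree"],
               attr(node_degree(net), "argmax"))
  g <- glance(rep_)
  expect_equal(g$n_nodes, 18)

  f <- withr::local_tempfile(fileext = ".json")
  write_metric_maxima(rep_, f)
  js <- jsonlite::read_json(f)
  expect_setequal(names(js$maxima), c("degree", "eigen_importance", "betweenness"))
})
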