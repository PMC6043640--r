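# Independent oracles and fixture builders. Everything here is brute force or
# closed form on purpose: it must not share code paths with the package.

# Hand evaluation of the Pearson product-moment formula (centered form).
brute_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# A tiny registry of p anonymous variables for structural tests.
toy_registry <- function(p, prefix = "v") {
  tibble::tibble(
    name = sprintf("%s%02d", prefix, seq_len(p)),
    label = sprintf("Variable %d", seq_len(p)),
    unit = "dimensionless",
    category = "time_limit"
  )
}

# Fabricate a corr_matrix with prescribed coefficients (upper-triangle vector
# or full symmetric matrix), bypassing data so link rules can be pinned down.
toy_corr <- function(r, registry = NULL) {
  if (!is.matrix(r)) stop("r must be a matrix")
  p <- nrow(r)
  if (is.null(registry)) registry <- toy_registry(p)
  dimnames(r) <- list(registry$name, registry$name)
  structure(
    list(variables = registry$name, r = r, method = "pearson",
         registry = registry),
    class = "corr_matrix"
  )
}

# Symmetric coefficient matrix from an upper-triangle vector (row-major over
# pairs (1,2), (1,3), ..., (p-1,p)).
sym_from_upper <- function(p, upper) {
  r <- diag(1, p)
  r[upper.tri(r)] <- NA
  k <- 1
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r[i, j] <- r[j, i] <- upper[k]
      k <- k + 1
    }
  }
  r
}

# Random influence network on p nodes through the real build path: random
# symmetric coefficients, default thresholds.
random_network <- function(p, seed) {
  set.seed(seed)
  upper <- runif(p * (p - 1) / 2, min = -1, max = 1)
  build_network(toy_corr(sym_from_upper(p, upper)))
}

# Network with explicit unit-weight edges given as a 2-column matrix of node
# indices (all links high-class, weight 1 after normalization).
edge_network <- function(p, edges) {
  r <- diag(1, p)
  for (k in seq_len(nrow(edges))) {
    r[edges[k, 1], edges[k, 2]] <- r[edges[k, 2], edges[k, 1]] <- 0.9
  }
  build_network(toy_corr(r))
}

# Exhaustive betweenness: enumerate every simple path between every pair by
# depth-first search, keep the shortest ones, and split credit equally.
brute_betweenness <- function(net) {
  nodes <- net$nodes$name
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(net$links) > 0) {
    ia <- match(net$links$a, nodes)
    ib <- match(net$links$b, nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (u in adj[[v]]) {
        if (!(u %in% path)) walk(c(path, u))
      }
    }
    walk(s)
    out
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (pth in shortest) {
        interior <- setdiff(pth, c(s, t))
        bc[interior] <- bc[interior] + 1 / sigma
      }
    }
  }
  tibble::tibble(node = nodes, betweenness = bc)
}

# Dominant eigenpair by dense eigendecomposition (base eigen), sign-fixed.
dense_dominant <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  i <- which.max(abs(e$values))
  v <- e$vectors[, i]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(lambda = e$values[i], vector = v)
}

# Free-model athlete table with a planted hub, used across recovery checks.
hub_free_table <- function(n, seed, hub = "aerobic_capacity",
                           neighbors = c("c_vo2", "peak_p_vvo2", "peak_p_vo2",
                                         "mean_velocity", "peak_vo2_pct")) {
  st <- structure_hub(sprint_variables("free")$name, hub, neighbors,
                      hub_c = 0.85, base_c = 0)
  generate_athletes(free_model_preset(), structure = st, n = n, seed = seed)
}

# Write an athlete table to CSV the way a user's spreadsheet export would.
write_table_csv <- function(tab, path) {
  readr::write_csv(tibble::as_tibble(tab), path)
  path
}
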