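# Node-importance metrics on the influence network: degree, leading-eigenvector
# importance via the power method, Brandes betweenness centrality, and the
# linear influence-state dynamics S(t) = C^t S(0).

#' Node degree
#'
#' The degree of a node is the count of its connecting links. The node with
#' maximal degree is the network hub (the "most popular" node). Ties in the
#' argmax are broken by the lexicographically smallest variable name.
#'
#' @param net An `influence_network`.
#' @return A tibble with columns `node`, `degree`, carrying the hub name in
#'   attribute `"argmax"`.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "influence_network"))
  counts <- table(factor(c(net$links$a, net$links$b), levels = net$nodes$name))
  out <- tibble(node = net$nodes$name, degree = as.integer(counts))
  attr(out, "argmax") <- argmax_node(out$node, out$degree)
  out
}

#' Dominant eigenpair by power iteration
#'
#' Computes the leading eigenvalue and eigenvector of a symmetric nonnegative
#' matrix by power iteration: repeat z = A q, q = z / ||z|| from a random
#' strictly positive start vector until successive iterates differ by at most
#' `eps`, then return the Rayleigh quotient lambda = q' C q. Iteration runs on
#' the shifted matrix A = C + `shift` I, which has the same eigenvectors and
#' guarantees convergence on bipartite-like graphs (e.g. stars), whose
#' unshifted spectrum is symmetric about zero; lambda is always reported for
#' the original C. The sign convention makes the largest-magnitude component
#' positive, so for a connected nonnegative matrix the returned vector is the
#' nonnegative Perron vector.
#'
#' @param C Symmetric nonnegative matrix, not all-zero.
#' @param eps Convergence tolerance on ||q_k - q_(k-1)|| (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @param seed Optional integer seed for the random start vector; global RNG
#'   state is untouched.
#' @param shift Diagonal shift used during iteration (default 1).
#' @return A list with `lambda`, unit-norm `vector` (named if C has
#'   dimnames), `iterations`, and `converged = TRUE`.
#' @examples
#' pm <- power_method(matrix(c(2, 1, 1, 2), 2), seed = 1)
#' pm$lambda          # 3
#' pm$vector          # (1, 1) / sqrt(2)
#' @export
power_method <- function(C, eps = 1e-10, max_iter = 10000, seed = NULL,
                         shift = 1) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) {
    abort("`C` must be a square matrix.", class = "sprintnet_error_bad_input")
  }
  if (max(abs(C - t(C))) > 1e-10) {
    abort("`C` must be symmetric.", class = "sprintnet_error_bad_input")
  }
  if (any(C < 0)) {
    abort("`C` must be nonnegative.", class = "sprintnet_error_bad_input")
  }
  if (all(C == 0)) {
    abort("degenerate all-zero matrix: dominant eigenpair undefined.",
          class = "sprintnet_error_degenerate_matrix")
  }
  if (!(eps > 0)) {
    abort("`eps` must be positive.", class = "sprintnet_error_bad_input")
  }
  n <- nrow(C)
  A <- C + diag(shift, n)
  q <- with_seed(seed, runif(n, min = 0.1, max = 1))
  q <- q / sqrt(sum(q^2))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    z <- as.vector(A %*% q)
    q_new <- z / sqrt(sum(z^2))
    if (sqrt(sum((q_new - q)^2)) <= eps) {
      q <- q_new
      converged <- TRUE
      break
    }
    q <- q_new
  }
  if (!converged) {
    abort("power method did not converge within max_iter.",
          class = "sprintnet_error_no_convergence",
          last_iterate = q, iterations = iter)
  }
  if (q[which.max(abs(q))] < 0) q <- -q
  lambda <- as.numeric(t(q) %*% C %*% q)
  names(q) <- rownames(C)
  list(lambda = lambda, vector = q, iterations = iter, converged = TRUE)
}

#' Eigen-importance of network nodes
#'
#' A node's importance is its component in the leading eigenvector of the
#' connection matrix C (eigenvector centrality), computed with
#' [power_method()]. The leading eigenvalue lambda also governs the
#' asymptotics of the influence dynamics (see [influence_trajectory()]). On a
#' disconnected network the dominant component carries the mass; other
#' components decay toward zero importance.
#'
#' @inheritParams power_method
#' @param net An `influence_network` with at least one link.
#' @return A tibble with columns `node`, `eigen_importance` (nonnegative,
#'   unit Euclidean norm), with attributes `"lambda"` and `"argmax"`.
#' @export
eigen_importance <- function(net, eps = 1e-10, max_iter = 10000, seed = NULL) {
  stopifnot(inherits(net, "influence_network"))
  if (nrow(net$links) == 0) {
    abort("network has no links: eigen-importance is undefined.",
          class = "sprintnet_error_no_links")
  }
  pm <- power_method(net$C, eps = eps, max_iter = max_iter, seed = seed)
  v <- pmax(pm$vector, 0)
  v <- v / sqrt(sum(v^2))
  out <- tibble(node = net$nodes$name, eigen_importance = unname(v[net$nodes$name]))
  attr(out, "lambda") <- pm$lambda
  attr(out, "argmax") <- argmax_node(out$node, out$eigen_importance)
  out
}

#' Betweenness centrality
#'
#' Credit a node earns for lying on shortest paths between other node pairs:
#' for every unordered pair (s, t) with s != t != v, node v receives
#' sigma_st(v) / sigma_st, where sigma_st counts shortest paths and
#' sigma_st(v) those passing through v. Computed by the Brandes single-source
#' accumulation scheme; endpoints are excluded and unreachable pairs
#' contribute zero. By default paths are hop counts on the unweighted link
#' skeleton; `weighted = TRUE` instead measures path length as the sum of
#' reciprocal link weights (strong links are short), which can change the
#' ranking.
#'
#' @param net An `influence_network`.
#' @param weighted Use reciprocal-weight path lengths instead of hop counts.
#' @return A tibble with columns `node`, `betweenness`, attribute `"argmax"`.
#' @export
node_betweenness <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "influence_network"))
  nodes <- net$nodes$name
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  w <- lapply(seq_len(n), function(i) numeric(0))
  if (nrow(net$links) > 0) {
    ia <- match(net$links$a, nodes)
    ib <- match(net$links$b, nodes)
    len <- if (weighted) 1 / net$links$weight else rep(1, length(ia))
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
      w[[ia[k]]] <- c(w[[ia[k]]], len[k])
      w[[ib[k]]] <- c(w[[ib[k]]], len[k])
    }
  }
  bc <- brandes(adj, w, n, weighted)
  out <- tibble(node = nodes, betweenness = bc)
  attr(out, "argmax") <- argmax_node(out$node, out$betweenness)
  out
}

# Brandes (2001) accumulation. Unweighted sources use BFS; weighted sources a
# simple O(n^2) Dijkstra — ample for networks of a few dozen nodes. Each
# undirected pair is counted once (accumulated twice, halved at the end).
brandes <- function(adj, w, n, weighted) {
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(Inf, n); dist[s] <- 0
    pred <- lapply(seq_len(n), function(i) integer(0))
    order_popped <- integer(0)
    if (!weighted) {
      queue <- c(s)
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        order_popped <- c(order_popped, v)
        for (k in seq_along(adj[[v]])) {
          u <- adj[[v]][k]
          if (is.infinite(dist[u])) {
            dist[u] <- dist[v] + 1
            queue <- c(queue, u)
          }
          if (dist[u] == dist[v] + 1) {
            sigma[u] <- sigma[u] + sigma[v]
            pred[[u]] <- c(pred[[u]], v)
          }
        }
      }
    } else {
      visited <- rep(FALSE, n)
      repeat {
        cand <- which(!visited & is.finite(dist))
        if (length(cand) == 0) break
        v <- cand[which.min(dist[cand])]
        visited[v] <- TRUE
        order_popped <- c(order_popped, v)
        for (k in seq_along(adj[[v]])) {
          u <- adj[[v]][k]
          if (visited[u]) next
          nd <- dist[v] + w[[v]][k]
          if (nd < dist[u] - 1e-12) {
            dist[u] <- nd
            sigma[u] <- sigma[v]
            pred[[u]] <- c(v)
          } else if (abs(nd - dist[u]) <= 1e-12) {
            sigma[u] <- sigma[u] + sigma[v]
            pred[[u]] <- c(pred[[u]], v)
          }
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_popped)) {
      for (p in pred[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc / 2
}

#' Influence-state dynamics on the connection matrix
#'
#' Iterates the linear influence map S(t) = C^t S(0): each step every node's
#' state becomes the weight-summed states of its neighbours. Because C is
#' symmetric, the trajectory's asymptotics are set by the leading eigenvalue
#' lambda: states decay to zero when lambda < 1, grow without bound when
#' lambda > 1, and are marginal when lambda = 1 (within `tol`).
#'
#' @param C Connection matrix (or an `influence_network`).
#' @param s0 Initial state vector, one entry per node.
#' @param t_max Number of steps (>= 0).
#' @param tol Half-width of the marginal band around lambda = 1.
#' @return A tibble with columns `t`, `node`, `state` covering steps
#'   0..`t_max`, with attributes `"lambda"` and `"regime"` (one of
#'   `"decay"`, `"growth"`, `"marginal"`).
#' @export
influence_trajectory <- function(C, s0, t_max, tol = 1e-8) {
  if (inherits(C, "influence_network")) C <- C$C
  if (!is.matrix(C) || nrow(C) != ncol(C)) {
    abort("`C` must be a square matrix.", class = "sprintnet_error_bad_input")
  }
  if (length(s0) != nrow(C)) {
    abort("`s0` length must equal the matrix dimension.",
          class = "sprintnet_error_mismatch")
  }
  if (t_max < 0) {
    abort("`t_max` must be >= 0.", class = "sprintnet_error_bad_input")
  }
  nodes <- rownames(C)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(C)))
  states <- matrix(NA_real_, nrow = t_max + 1, ncol = nrow(C))
  s <- as.numeric(s0)
  states[1, ] <- s
  for (t in seq_len(t_max)) {
    s <- as.vector(C %*% s)
    states[t + 1, ] <- s
  }
  lambda <- if (all(C == 0)) 0 else power_method(C, seed = 1L)$lambda
  regime <- if (abs(lambda - 1) <= tol) "marginal" else if (lambda < 1) "decay" else "growth"
  out <- tibble(
    t = rep(0:t_max, each = nrow(C)),
    node = rep(nodes, times = t_max + 1),
    state = as.vector(t(states))
  )
  attr(out, "lambda") <- lambda
  attr(out, "regime") <- regime
  out
}

#' Full per-node metrics report
#'
#' Computes the three node-importance metrics — degree, eigen-importance and
#' betweenness — for every node and records the per-metric maxima (the hub,
#' the max eigen-importance node, and the max betweenness node).
#'
#' @inheritParams eigen_importance
#' @param weighted_betweenness Use reciprocal-weight path lengths for
#'   betweenness (default hop counts).
#' @return A `metrics_report`: a tibble with columns `node`, `category`,
#'   `degree`, `eigen_importance`, `betweenness`; attributes
#'   `"leading_eigenvalue"` and `"maxima"` (tibble metric/node/value).
#' @export
network_metrics <- function(net, eps = 1e-10, max_iter = 10000, seed = NULL,
                            weighted_betweenness = FALSE) {
  deg <- node_degree(net)
  eig <- eigen_importance(net, eps = eps, max_iter = max_iter, seed = seed)
  btw <- node_betweenness(net, weighted = weighted_betweenness)
  out <- dplyr::left_join(deg, eig, by = "node") |>
    dplyr::left_join(btw, by = "node") |>
    dplyr::left_join(dplyr::select(net$nodes, node = "name", "category"),
                     by = "node") |>
    dplyr::select("node", "category", "degree", "eigen_importance", "betweenness")
  maxima <- tibble(
    metric = c("degree", "eigen_importance", "betweenness"),
    node = c(attr(deg, "argmax"), attr(eig, "argmax"), attr(btw, "argmax")),
    value = c(
      deg$degree[deg$node == attr(deg, "argmax")],
      eig$eigen_importance[eig$node == attr(eig, "argmax")],
      btw$betweenness[btw$node == attr(btw, "argmax")]
    )
  )
  attr(out, "leading_eigenvalue") <- attr(eig, "lambda")
  attr(out, "maxima") <- maxima
  attr(out, "n_links") <- nrow(net$links)
  class(out) <- c("metrics_report", class(out))
  out
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), c("degree", "eigen_importance", "betweenness"),
                      names_to = "metric", values_to = "value")
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  mx <- attr(x, "maxima")
  tibble(
    n_nodes = nrow(x),
    n_links = attr(x, "n_links"),
    leading_eigenvalue = attr(x, "leading_eigenvalue"),
    max_degree_node = mx$node[mx$metric == "degree"],
    max_eigen_node = mx$node[mx$metric == "eigen_importance"],
    max_betweenness_node = mx$node[mx$metric == "betweenness"]
  )
}

#' Export the metrics report
#'
#' `write_metrics()` writes the per-node TSV; `write_metric_maxima()` writes
#' a JSON summary naming the three per-metric maximal nodes.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_metrics <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_metric_maxima <- function(report, path) {
  mx <- attr(report, "maxima")
  payload <- list(
    leading_eigenvalue = attr(report, "leading_eigenvalue"),
    maxima = setNames(
      lapply(seq_len(nrow(mx)), function(i) {
        list(node = mx$node[i], value = mx$value[i])
      }),
      mx$metric
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
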