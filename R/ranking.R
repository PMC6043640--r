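# Composite "performance node" ranking and the end-to-end pipeline bundle.

#' Composite performance-node ranking
#'
#' Aggregates the three node-importance metrics into one ranking by Borda
#' count: within each metric, nodes are ranked by descending value (ties
#' averaged) and receive |N| - rank points; the composite score is the sum of
#' points over degree, eigen-importance and betweenness. Being rank-based,
#' the composite is invariant to any strictly monotone transform of a
#' metric's values. Ties in the composite are ordered by node name.
#'
#' @param report A `metrics_report`.
#' @param k Number of top nodes to return (default 10; truncated to |N| with
#'   a warning if larger).
#' @return A `node_ranking` tibble with columns `rank`, `node`, `category`,
#'   `composite_score` and the three per-metric point columns.
#' @export
rank_nodes <- function(report, k = 10) {
  if (!inherits(report, "metrics_report")) {
    abort("`report` must be a metrics_report.", class = "sprintnet_error_bad_input")
  }
  if (k < 1) {
    abort("`k` must be >= 1.", class = "sprintnet_error_bad_input")
  }
  n <- nrow(report)
  if (k > n) {
    warn(sprintf("k = %d exceeds the %d available nodes; truncating.", k, n))
    k <- n
  }
  borda <- function(v) n - rank(-v, ties.method = "average")
  scored <- tibble(
    node = report$node,
    category = report$category,
    degree_points = borda(report$degree),
    eigen_points = borda(report$eigen_importance),
    betweenness_points = borda(report$betweenness)
  )
  scored$composite_score <- scored$degree_points + scored$eigen_points +
    scored$betweenness_points
  ord <- order(-scored$composite_score, scored$node, method = "radix")
  out <- scored[ord, ]
  out$rank <- seq_len(nrow(out))
  out <- dplyr::select(out, "rank", "node", "category", "composite_score",
                       "degree_points", "eigen_points", "betweenness_points")
  out <- head(out, k)
  attr(out, "k") <- k
  class(out) <- c("node_ranking", class(out))
  out
}

#' @method tidy node_ranking
#' @export
tidy.node_ranking <- function(x, ...) as_tibble(x)

#' Run the full influence-network pipeline
#'
#' Correlate -> classify/threshold -> build network -> metrics -> composite
#' ranking, as one deterministic call. The same table, configuration and seed
#' always yield byte-identical exported bundles.
#'
#' @param table An `athlete_table`.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @param weak,high Link-selection thresholds on |c|.
#' @param k Ranking cutoff.
#' @param seed Seed for the power-method start vector.
#' @param weighted_betweenness Passed to [network_metrics()].
#' @return A `sprint_run` list with elements `correlation`, `network`,
#'   `metrics`, `ranking`, `config`.
#' @export
run_pipeline <- function(table, method = c("pearson", "spearman"),
                         weak = 0.3, high = 0.7, k = 10, seed = 1L,
                         weighted_betweenness = FALSE) {
  method <- match.arg(method)
  corr <- correlate_athletes(table, method = method)
  net <- build_network(corr, weak = weak, high = high)
  metrics <- network_metrics(net, seed = seed,
                             weighted_betweenness = weighted_betweenness)
  ranking <- rank_nodes(metrics, k = k)
  config <- list(
    method = method, weak = weak, high = high, k = k, seed = seed,
    weighted_betweenness = weighted_betweenness,
    n_subjects = nrow(table), n_variables = nrow(attr(table, "registry"))
  )
  structure(
    list(correlation = corr, network = net, metrics = metrics,
         ranking = ranking, config = config, input_hash = table_hash(table)),
    class = "sprint_run"
  )
}

# Canonical md5 of the numeric content of an athlete table (layout- and
# platform-stable: full-precision text rendering hashed via tools::md5sum).
table_hash <- function(table) {
  m <- athlete_matrix(table)
  txt <- paste(
    paste(colnames(m), collapse = ","),
    paste(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")),
          collapse = "\n"),
    sep = "\n"
  )
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' @export
print.sprint_run <- function(x, ...) {
  cat(sprintf("<sprint_run: %d nodes, %d links, method = %s>\n",
              nrow(x$network$nodes), nrow(x$network$links), x$config$method))
  cat("Top nodes:\n")
  print(head(as_tibble(x$ranking), 5))
  invisible(x)
}

#' @method glance sprint_run
#' @export
glance.sprint_run <- function(x, ...) {
  dplyr::bind_cols(glance(x$metrics), tibble(method = x$config$method))
}

#' Write a pipeline run bundle to disk
#'
#' One directory per run: `edges.tsv`, `matrix.csv`, `metrics.tsv`,
#' `ranking.tsv`, `maxima.json` and a machine-readable `manifest.json`
#' (configuration, input hash, package version). Manifests contain no
#' timestamps, so repeated identical runs produce byte-identical payloads.
#'
#' @param run A `sprint_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_bundle <- function(run, dir) {
  stopifnot(inherits(run, "sprint_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(run$network, file.path(dir, "edges.tsv"))
  write_connection_matrix(run$network, file.path(dir, "matrix.csv"))
  write_metrics(run$metrics, file.path(dir, "metrics.tsv"))
  readr::write_tsv(as_tibble(run$ranking), file.path(dir, "ranking.tsv"))
  write_metric_maxima(run$metrics, file.path(dir, "maxima.json"))
  manifest <- list(
    package = "sprintnet",
    version = as.character(utils::packageVersion("sprintnet")),
    input_hash = run$input_hash,
    config = run$config,
    n_links = nrow(run$network$links),
    leading_eigenvalue = attr(run$metrics, "leading_eigenvalue")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
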