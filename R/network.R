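# Turning a classified correlation matrix into the weighted bidirectional
# influence network and its connection matrix C.

#' Build an influence network from a correlation matrix
#'
#' Every variable becomes a node; every moderate or high pair (|c| >= `weak`)
#' becomes one bidirectional link. Link weights are coefficient magnitudes
#' normalized by the maximum |c| over the retained links, so the strongest
#' link has weight exactly 1. The connection matrix C is symmetric with zero
#' diagonal (no self-influence); isolated nodes are kept so the node set
#' always equals the registry. Signed coefficients are preserved on the links
#' (`c_raw`) but weights, classification and C use magnitudes: the network
#' metrics require nonnegative weights, and "influence" reads as strength,
#' not direction.
#'
#' @param corr A `corr_matrix` from [correlate_athletes()].
#' @param registry Variable registry giving node identity/order; defaults to
#'   the registry attached by [correlate_athletes()].
#' @param weak Lower |c| threshold for a link (default 0.3).
#' @param high |c| threshold separating moderate from high (default 0.7).
#' @return An `influence_network`: `nodes` (registry tibble), `links` (tibble
#'   of a, b, c_raw, strength, weight), and the connection matrix `C`.
#' @export
build_network <- function(corr, registry = NULL, weak = 0.3, high = 0.7) {
  if (!inherits(corr, "corr_matrix")) {
    abort("`corr` must be a corr_matrix.", class = "sprintnet_error_bad_input")
  }
  if (is.null(registry)) registry <- corr$registry
  registry <- validate_registry(registry)
  if (!setequal(registry$name, corr$variables) ||
      length(registry$name) != length(corr$variables)) {
    abort("correlation matrix and registry cover different variables.",
          class = "sprintnet_error_mismatch")
  }
  if (!(weak > 0 && weak < high && high <= 1)) {
    abort("need 0 < weak < high <= 1.", class = "sprintnet_error_bad_input")
  }
  pairs <- tidy(corr)
  links <- dplyr::filter(pairs, abs(.data$c) >= weak)
  links <- tibble(
    a = links$var_a,
    b = links$var_b,
    c_raw = links$c,
    strength = factor(ifelse(abs(links$c) >= high, "high", "moderate"),
                      levels = c("moderate", "high"), ordered = TRUE)
  )
  links <- normalize_weights(links)
  new_network(registry, links, weak = weak, high = high)
}

new_network <- function(registry, links, weak = 0.3, high = 0.7) {
  p <- nrow(registry)
  C <- matrix(0, p, p, dimnames = list(registry$name, registry$name))
  if (nrow(links) > 0) {
    ia <- match(links$a, registry$name)
    ib <- match(links$b, registry$name)
    if (anyNA(ia) || anyNA(ib)) {
      abort("link endpoints not present in the registry.",
            class = "sprintnet_error_mismatch")
    }
    if (any(ia == ib)) {
      abort("self-links are not allowed.", class = "sprintnet_error_bad_input")
    }
    C[cbind(ia, ib)] <- links$weight
    C[cbind(ib, ia)] <- links$weight
  }
  structure(
    list(nodes = registry, links = links, C = C,
         thresholds = c(weak = weak, high = high)),
    class = "influence_network"
  )
}

#' Normalize link weights
#'
#' Divides each link's |c| by the maximum |c| over all links present in the
#' network, so weights lie in (0, 1] and the strongest link has weight 1.
#' An empty link set passes through unchanged.
#'
#' @param links A tibble with at least a `c_raw` column.
#' @return The same tibble with a `weight` column (re)computed.
#' @export
normalize_weights <- function(links) {
  links <- as_tibble(links)
  if (nrow(links) == 0) {
    links$weight <- numeric(0)
    return(links)
  }
  links$weight <- abs(links$c_raw) / max(abs(links$c_raw))
  links
}

#' @rdname build_network
#' @param net An `influence_network`.
#' @return `connection_matrix()` returns the symmetric numeric matrix C.
#' @export
connection_matrix <- function(net) {
  stopifnot(inherits(net, "influence_network"))
  net$C
}

#' @export
print.influence_network <- function(x, ...) {
  cat(sprintf(
    "<influence_network: %d nodes, %d links (%d high, %d moderate)>\n",
    nrow(x$nodes), nrow(x$links),
    sum(x$links$strength == "high"), sum(x$links$strength == "moderate")
  ))
  invisible(x)
}

#' @method tidy influence_network
#' @export
tidy.influence_network <- function(x, ...) x$links

#' @method glance influence_network
#' @export
glance.influence_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_links = nrow(x$links),
    n_high = sum(x$links$strength == "high"),
    n_moderate = sum(x$links$strength == "moderate"),
    candidate_pairs = nrow(x$nodes) * (nrow(x$nodes) - 1) / 2
  )
}

#' Export / reimport the influence network
#'
#' The edge list TSV carries `a`, `b`, `c_raw`, `strength`, `weight` with
#' full-precision numerics, so a network rebuilt from its own export has a
#' bit-identical connection matrix. The connection matrix export is a square
#' CSV with a leading `node` column. GraphML export (node category and link
#' weight attributes) requires the igraph package.
#'
#' @param net An `influence_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  e <- net$links
  out <- data.frame(
    a = e$a, b = e$b,
    c_raw = sprintf("%.17g", e$c_raw),
    strength = as.character(e$strength),
    weight = sprintf("%.17g", e$weight),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param registry Registry for the rebuilt network's node set.
#' @export
read_edge_list <- function(path, registry) {
  registry <- validate_registry(registry)
  e <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric",
                                 "character", "numeric"))
  links <- tibble(
    a = e$a, b = e$b, c_raw = e$c_raw,
    strength = factor(e$strength, levels = c("moderate", "high"),
                      ordered = TRUE),
    weight = e$weight
  )
  new_network(registry, links)
}

#' @rdname write_edge_list
#' @export
write_connection_matrix <- function(net, path) {
  df <- as.data.frame(net$C)
  df <- dplyr::bind_cols(tibble(node = rownames(net$C)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("GraphML export requires the igraph package.",
          class = "sprintnet_error_bad_input")
  }
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_list
#' @return `as_igraph()` returns an undirected weighted igraph graph with a
#'   `category` vertex attribute.
#' @export
as_igraph <- function(net) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("as_igraph requires the igraph package.",
          class = "sprintnet_error_bad_input")
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(net$links[, c("a", "b", "c_raw", "strength", "weight")]),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
  g
}
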