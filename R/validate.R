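#' Compound graph of biochemical reaction steps
#'
#' An undirected graph whose nodes are compound accessions and whose edges
#' connect compounds one reaction step apart; used as the reference to
#' evaluate data-derived networks by pathway distance.
#'
#' @param edges data.frame (or 2-column matrix) of accession pairs.
#' @return an undirected, simplified igraph graph.
#' @export
compound_graph <- function(edges) {
  edges <- as.data.frame(edges)[, 1:2]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Read a compound graph from a two-column edge-list file (TSV)
#'
#' @param path file path; two tab-separated accession columns, no header by
#'   default.
#' @param header whether the file has a header row.
#' @export
read_compound_graph <- function(path, header = FALSE) {
  compound_graph(utils::read.delim(path, header = header,
                                   stringsAsFactors = FALSE))
}

#' Pathway distances of network edges
#'
#' For every partial-correlation edge of the network whose endpoints both map
#' to accessions present in the compound graph, computes the unweighted
#' shortest-path (reaction-step) distance. Pairs mapping to the same accession
#' (distance 0) are counted in their own category and excluded from the
#' distance-1 statistic; unreachable pairs are counted as such.
#'
#' @param net a [build_ggm()] network.
#' @param graph a [compound_graph()].
#' @param id_map named character vector, uid -> accession.
#' @return Object of class \code{distance_summary} with \code{n_edges_total},
#'   \code{n_mappable}, the per-edge \code{distances} and \code{counts}
#'   (d0, d1, d2, d3, gt3, unreachable).
#' @export
pathway_distance_profile <- function(net, graph, id_map) {
  e <- net$edges[net$edges$edge_type == "pcor", , drop = FALSE]
  acc_a <- unname(id_map[e$uid_a])
  acc_b <- unname(id_map[e$uid_b])
  vs <- igraph::V(graph)$name
  ok <- !is.na(acc_a) & !is.na(acc_b) & acc_a %in% vs & acc_b %in% vs
  if (!any(ok)) stop("no network edge has both endpoints mappable to the graph")
  acc <- unique(c(acc_a[ok], acc_b[ok]))
  D <- igraph::distances(graph, v = acc, to = acc)
  d <- D[cbind(match(acc_a[ok], acc), match(acc_b[ok], acc))]
  counts <- c(d0 = sum(d == 0), d1 = sum(d == 1), d2 = sum(d == 2),
              d3 = sum(d == 3), gt3 = sum(is.finite(d) & d > 3),
              unreachable = sum(is.infinite(d)))
  structure(list(n_edges_total = nrow(e), n_mappable = sum(ok),
                 distances = d, counts = counts),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("Pathway distances:", x$n_mappable, "of", x$n_edges_total,
      "edges mappable\n")
  print(x$counts)
  invisible(x)
}

#' Node-relabeling bootstrap of pathway proximity
#'
#' Generates \code{n_iter} networks with the same topology but randomized node
#' labeling: the accession assignment is permuted uniformly at random among
#' the mapped nodes only (topology fixed), and the count of edges at pathway
#' distance 1 is recomputed each time. The observed count is compared to this
#' null with the add-one empirical p-value
#' \eqn{(1 + \#\{null \ge observed\}) / (n_{iter} + 1)}.
#'
#' @inheritParams pathway_distance_profile
#' @param n_iter number of relabeled networks (default 1000).
#' @param seed RNG seed.
#' @param permutation_fn test hook: \code{function(n)} returning a
#'   permutation of 1..n (default \code{sample}).
#' @return Object of class \code{bootstrap_result} with \code{observed_count},
#'   \code{null_counts}, \code{max_null}, \code{empirical_p}, \code{n_iter},
#'   \code{seed}.
#' @export
bootstrap_relabel <- function(net, graph, id_map, n_iter = 1000, seed = 1,
                              permutation_fn = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  e <- net$edges[net$edges$edge_type == "pcor", , drop = FALSE]
  vs <- igraph::V(graph)$name
  mapped_uids <- intersect(net$nodes$uid, names(id_map))
  mapped_uids <- mapped_uids[id_map[mapped_uids] %in% vs]
  if (length(mapped_uids) < 2) stop("fewer than 2 mappable nodes")
  acc0 <- unname(id_map[mapped_uids])
  uacc <- unique(acc0)
  D <- igraph::distances(graph, v = uacc, to = uacc)
  ia <- match(e$uid_a, mapped_uids)
  ib <- match(e$uid_b, mapped_uids)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  d1_count <- function(assign) {
    sum(D[cbind(match(assign[ia], uacc), match(assign[ib], uacc))] == 1)
  }
  observed <- d1_count(acc0)
  set.seed(seed)
  if (is.null(permutation_fn)) permutation_fn <- sample
  null_counts <- vapply(seq_len(n_iter), function(i)
    d1_count(acc0[permutation_fn(length(acc0))]), 0L)
  structure(list(observed_count = observed, null_counts = null_counts,
                 max_null = max(null_counts),
                 empirical_p = (1 + sum(null_counts >= observed)) /
                   (n_iter + 1),
                 n_iter = n_iter, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Node-relabeling bootstrap (", x$n_iter, " iterations):\n", sep = "")
  cat("  observed distance-1 edges:", x$observed_count,
      "| max under null:", x$max_null, "\n")
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}
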