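#' Build the pair similarity network from duplication records
#'
#' One node per distinct chain; one undirected edge per unordered pair,
#' keeping the record with the highest rearranged TM-score; the edge flag
#' is `cp`, `indel` or `both` according to the record's classification.
#' Records that are neither CP nor indel are dropped (they carry no
#' detected relationship).
#'
#' @param records data.frame of rows from [run_pairwise()].
#' @return An object of class `pair_graph`: list with `nodes` (character)
#'   and `edges` (data.frame `from`, `to`, `weight`, `flag`).
#' @export
build_pair_graph <- function(records) {
  if (nrow(records) == 0)
    return(structure(list(nodes = character(0),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             weight = numeric(),
                                             flag = character())),
                     class = "pair_graph"))
  rec <- records[records$is_cp | records$is_indel, , drop = FALSE]
  if (nrow(rec)) {
    a <- pmin(rec$query_id, rec$target_id)
    b <- pmax(rec$query_id, rec$target_id)
    keep <- a != b                                   # no self-loops
    rec <- rec[keep, , drop = FALSE]; a <- a[keep]; b <- b[keep]
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -rec$tm_rearranged)
    first <- !duplicated(key[ord])
    rec <- rec[ord, , drop = FALSE][first, , drop = FALSE]
    a <- a[ord][first]; b <- b[ord][first]
    flag <- ifelse(rec$is_cp & rec$is_indel, "both",
                   ifelse(rec$is_cp, "cp", "indel"))
    edges <- data.frame(from = a, to = b, weight = rec$tm_rearranged,
                        flag = flag, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), flag = character())
  }
  nodes <- sort(unique(c(records$query_id, records$target_id)))
  structure(list(nodes = nodes, edges = edges), class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  cat(sprintf("<pair_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Cluster the pair network into communities
#'
#' `method = "leiden"` runs seeded Leiden community detection (modularity
#' objective, unweighted edges by default -- weights are kept for
#' reporting only); `method = "components"` is a deterministic,
#' dependency-free connected-components fallback. Reported alongside the
#' membership are community sizes in descending order and the fraction of
#' members in the 10 largest communities.
#'
#' @param graph a `pair_graph` from [build_pair_graph()].
#' @param method `"leiden"` or `"components"`.
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed RNG seed for the Leiden path (default 42).
#' @param use_weights use TM weights in the Leiden objective
#'   (default FALSE).
#' @return List with `membership` (named integer), `sizes` (descending),
#'   `n_communities`, and `top10_fraction`.
#' @export
cluster_pair_graph <- function(graph, method = c("leiden", "components"),
                               resolution = 1, seed = 42L,
                               use_weights = FALSE) {
  stopifnot(inherits(graph, "pair_graph"))
  method <- match.arg(method)
  if (length(graph$nodes) == 0) stop("empty graph")
  if (method == "leiden") {
    g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                       vertices = graph$nodes)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    cl <- igraph::cluster_leiden(
      g, objective_function = "modularity",
      weights = if (use_weights && nrow(graph$edges)) graph$edges$weight
                else NA,
      resolution = resolution, n_iterations = 5)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    membership <- setNames(as.integer(igraph::membership(cl)),
                           igraph::V(g)$name)
    membership <- membership[graph$nodes]
  } else {
    membership <- components_membership(graph)
  }
  sizes <- sort(table(membership), decreasing = TRUE)
  list(membership = membership,
       sizes = as.integer(sizes),
       n_communities = length(sizes),
       top10_fraction = sum(head(sort(as.integer(sizes),
                                      decreasing = TRUE), 10)) /
         length(membership))
}

# deterministic union-find, invariant to edge insertion order
components_membership <- function(graph) {
  nodes <- sort(graph$nodes)
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(graph$edges)) {
    ed <- graph$edges[order(graph$edges$from, graph$edges$to), ,
                      drop = FALSE]
    for (k in seq_len(nrow(ed))) {
      ra <- find(match(ed$from[k], nodes))
      rb <- find(match(ed$to[k], nodes))
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  setNames(match(roots, sort(unique(roots))), nodes)[graph$nodes]
}

#' Write the edge list and community table
#'
#' @param graph a `pair_graph`.
#' @param clustering result of [cluster_pair_graph()].
#' @param edges_path,communities_path output TSV paths (NULL to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_network_tsv <- function(graph, clustering = NULL,
                              edges_path = NULL, communities_path = NULL) {
  if (!is.null(edges_path))
    write.table(graph$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(communities_path) && !is.null(clustering))
    write.table(data.frame(chain_id = names(clustering$membership),
                           community = clustering$membership),
                communities_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(edges = edges_path, communities = communities_path))
}
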