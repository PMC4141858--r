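#' Build a minimum spanning network from an integer distance matrix
#'
#' Kruskal-style construction in non-decreasing distance order. Before any
#' edge of a given weight is added, every edge of that weight joining two
#' still-separate components is recorded: the first in id order becomes a
#' tree edge, the remainder become *alternative* (reticulation) edges. The
#' retained tree edges form a minimum spanning tree and the alternative
#' edges are exactly the tied edges that belong to some other minimum
#' spanning tree, so the network displays every shortest mutational path
#' while remaining deterministic.
#'
#' @param d symmetric distance matrix with unit ids as dimnames (e.g. from
#'   [distance_matrix()]).
#' @param annotations optional data frame of node attributes with an `id`
#'   column (e.g. MLL assignment, host, haplotype copy number); carried into
#'   exports.
#' @return object of class `spanning_network`: list with
#'   `nodes` (data frame: `id`, `inferred`, annotations) and
#'   `edges` (data frame: `from`, `to`, `length`, `alternative`).
#' @examples
#' d <- distance_matrix(collapse_mlg(load_table1_fixture()))
#' net <- build_msn(d)
#' sum(net$edges$length[!net$edges$alternative])  # MST weight
#' @export
build_msn <- function(d, annotations = NULL) {
  ids <- rownames(d)
  n <- nrow(d)
  if (n < 2) stop_data("need at least 2 nodes")
  if (any(!is.finite(d))) stop_data("distances must be finite")
  ut <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[ut], ids[ut[, 1]], ids[ut[, 2]])
  ut <- ut[ord, , drop = FALSE]
  w <- d[ut]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- vector("list", nrow(ut))
  k <- 0L
  for (lev in unique(w)) {
    at <- which(w == lev)
    # component structure before this weight level is processed
    comp_before <- vapply(seq_len(n), find, 0L)
    joins <- at[comp_before[ut[at, 1]] != comp_before[ut[at, 2]]]
    for (e in joins) {
      i <- ut[e, 1]; j <- ut[e, 2]
      ri <- find(i); rj <- find(j)
      tree <- ri != rj
      if (tree) parent[ri] <- rj
      k <- k + 1L
      edges[[k]] <- data.frame(from = min(ids[i], ids[j]),
                               to = max(ids[i], ids[j]),
                               length = lev, alternative = !tree)
    }
  }
  edges <- do.call(rbind, edges[seq_len(k)])
  if (length(unique(vapply(seq_len(n), find, 0L))) != 1)
    stop_data("distance matrix does not connect all nodes")
  nodes <- data.frame(id = ids, inferred = FALSE)
  if (!is.null(annotations)) {
    if (!"id" %in% names(annotations)) stop_data("annotations need an 'id' column")
    nodes <- merge(nodes, annotations, by = "id", all.x = TRUE, sort = FALSE)
    nodes <- nodes[match(ids, nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "spanning_network")
}

#' @export
print.spanning_network <- function(x, ...) {
  nt <- sum(!x$edges$alternative)
  cat("spanning_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$inferred), "inferred ),", nt, "tree edges of total length",
      sum(x$edges$length[!x$edges$alternative]), "+",
      nrow(x$edges) - nt, "alternative edges\n")
  invisible(x)
}

#' Expand network edges into unit mutational steps
#'
#' Replaces every edge of length `k > 1` by a chain of `k` unit edges
#' through `k - 1` inferred intermediate nodes, so each rendered node
#' represents one allele (or substitution) step. Observed nodes are
#' unchanged and the operation is idempotent on all-unit networks.
#'
#' @param network a [build_msn()] result.
#' @return a `spanning_network` whose edges all have length 1; inferred
#'   nodes are flagged `inferred = TRUE` and named `<from>.<to>.<step>`.
#' @export
expand_step_nodes <- function(network) {
  nodes <- network$nodes
  new_edges <- list()
  new_nodes <- list()
  for (r in seq_len(nrow(network$edges))) {
    e <- network$edges[r, ]
    if (e$length <= 1) { new_edges[[length(new_edges) + 1]] <- e; next }
    chain <- c(e$from, paste(e$from, e$to, seq_len(e$length - 1), sep = "."),
               e$to)
    new_nodes[[r]] <- chain[-c(1, length(chain))]
    for (s in seq_len(e$length)) {
      new_edges[[length(new_edges) + 1]] <-
        data.frame(from = chain[s], to = chain[s + 1], length = 1L,
                   alternative = e$alternative)
    }
  }
  inferred <- unlist(new_nodes)
  if (length(inferred)) {
    extra <- nodes[rep(NA_integer_, length(inferred)), , drop = FALSE]
    extra$id <- inferred
    extra$inferred <- TRUE
    rownames(extra) <- NULL
    nodes <- rbind(nodes, extra)
  }
  structure(list(nodes = nodes, edges = do.call(rbind, new_edges)),
            class = "spanning_network")
}

as_igraph_network <- function(network) {
  # logical attributes as 0/1: the DOT writer has no boolean type
  nodes <- network$nodes
  edges <- network$edges
  nodes[] <- lapply(nodes, function(x) if (is.logical(x)) as.integer(x) else x)
  edges[] <- lapply(edges, function(x) if (is.logical(x)) as.integer(x) else x)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a spanning network
#'
#' `edge_list` writes a TSV with columns `from`, `to`, `length`,
#' `alternative` (nodes are recoverable from the edges; the network is
#' connected by construction). `graphml` and `dot` carry all node and edge
#' attributes via igraph, so graph viewers can colour nodes by lineage or
#' host.
#'
#' @param network a [build_msn()] result.
#' @param path output file.
#' @param format `"edge_list"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @seealso [import_network()] for reading an edge list back.
#' @export
export_network <- function(network, path,
                           format = c("edge_list", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    out <- network$edges
    out$alternative <- as.integer(out$alternative)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph_network(network), path, format = format)
  }
  invisible(path)
}

#' Read a spanning network back from a TSV edge list
#'
#' @param path file written by [export_network()] with `format = "edge_list"`.
#' @return a `spanning_network` (node annotations other than ids are not
#'   stored in the edge-list format).
#' @export
import_network <- function(path) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character",
                                        "integer", "integer"))
  e$alternative <- as.logical(e$alternative)
  ids <- sort(unique(c(e$from, e$to)))
  inferred <- grepl("\\.[0-9]+$", ids)
  structure(list(nodes = data.frame(id = ids, inferred = inferred),
                 edges = e),
            class = "spanning_network")
}
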