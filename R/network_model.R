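#' Flag significant differentially expressed features
#'
#' Sets the `significant` flag by strict comparison `p_adj < alpha` and
#' refreshes `direction = sign(log2fc)`.  The table is otherwise unchanged;
#' non-significant rows are kept (downstream network construction ignores
#' them).
#'
#' @param table A `deg_table`.
#' @param alpha Cutoff in (0, 1); default 0.05.
#' @return The table with `significant` and `direction` set.
#' @export
filter_significant <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "deg_table"), alpha > 0, alpha < 1)
  table$significant <- table$p_adj < alpha
  table$direction <- sign(table$log2fc)
  table
}

#' Build the gene-pathway membership network and its pathway projection
#'
#' The membership graph is bipartite and undirected: nodes are pathways and
#' the significant features they contain; edges connect a gene to each
#' pathway holding it.  No gene-gene or pathway-pathway edges exist in the
#' membership view.  The pathway projection connects two pathways with
#' weight equal to the number of significant genes they share.  Pathways
#' with no retained gene are dropped; significant genes belonging to no
#' retained pathway are dropped (not kept as isolates) and reported in the
#' `dropped_genes` field.
#'
#' A gene id equal to a pathway name is rejected: node names must be unique
#' across the two node kinds.
#'
#' @param pathways A `pathway_collection`; if its `anchor` is set, the
#'   anchor must retain at least one significant gene.
#' @param table A `deg_table` already passed through [filter_significant()].
#' @return A `hetero_network`: list with `membership` and `projection`
#'   igraph objects, `sig_members` (named list of per-pathway retained
#'   genes), `genes`, `pathways`, `anchor` and `dropped_genes`.
#' @export
build_network <- function(pathways, table) {
  stopifnot(inherits(pathways, "pathway_collection"),
            inherits(table, "deg_table"))
  if (anyNA(table$significant)) {
    stop("significance flags not set; run filter_significant() first")
  }
  retained <- table$feature_id[table$significant]
  sig_members <- lapply(pathways$sets, intersect, x = retained)
  sig_members <- Filter(function(x) length(x) > 0, sig_members)
  if (!is.null(pathways$anchor) && !pathways$anchor %in% names(sig_members)) {
    stop("anchor pathway '", pathways$anchor,
         "' retains no significant gene; nothing to analyze")
  }
  pw_names <- names(sig_members)
  gene_names <- unique(unlist(sig_members, use.names = FALSE))
  clash <- intersect(pw_names, gene_names)
  if (length(clash) > 0) {
    stop("identifier used as both gene and pathway name: ",
         paste(clash, collapse = ", "))
  }
  dropped <- setdiff(retained, gene_names)

  edges <- do.call(rbind, lapply(pw_names, function(p) {
    cbind(sig_members[[p]], p)
  }))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(gene_names), name = gene_names,
                            kind = "gene")
  g <- igraph::add_vertices(g, length(pw_names), name = pw_names,
                            kind = "pathway")
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }

  proj <- igraph::make_empty_graph(n = 0, directed = FALSE)
  proj <- igraph::add_vertices(proj, length(pw_names), name = pw_names)
  if (length(pw_names) >= 2) {
    pairs <- utils::combn(pw_names, 2)
    w <- apply(pairs, 2, function(pq) {
      length(intersect(sig_members[[pq[1]]], sig_members[[pq[2]]]))
    })
    keep <- w >= 1
    if (any(keep)) {
      proj <- igraph::add_edges(proj, as.vector(pairs[, keep, drop = FALSE]),
                                weight = w[keep])
    }
  }

  structure(
    list(
      membership = g,
      projection = proj,
      sig_members = sig_members,
      genes = gene_names,
      pathways = pw_names,
      anchor = pathways$anchor,
      dropped_genes = dropped
    ),
    class = "hetero_network"
  )
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("hetero_network:", length(x$genes), "gene nodes,",
      length(x$pathways), "pathway nodes,",
      igraph::ecount(x$membership), "membership edges\n")
  cat("  projection:", igraph::ecount(x$projection), "weighted edges;",
      length(x$dropped_genes), "significant genes outside all pathways\n")
  if (!is.null(x$anchor)) cat("  anchor:", x$anchor, "\n")
  invisible(x)
}

#' Network connectedness as global efficiency
#'
#' Mean of the inverse shortest-path length over all unordered node pairs,
#' with unreachable pairs contributing 0.  Equals 1 on a complete graph, 0
#' on an edgeless, single-node or empty graph, and degrades continuously
#' under fragmentation, which makes it usable for ranking node removals.
#'
#' @param graph An igraph object or a `hetero_network` (its membership view
#'   is used).
#' @return A number in `[0, 1]`.
#' @export
connectedness <- function(graph) {
  if (inherits(graph, "hetero_network")) graph <- graph$membership
  n <- igraph::vcount(graph)
  if (n < 2) return(0)
  d <- igraph::distances(graph, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Dump the membership and projection graphs as an edge-list TSV
#'
#' @param net A `hetero_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network_edges <- function(net, path) {
  memb <- igraph::as_edgelist(net$membership)
  rows <- data.frame(
    node1 = memb[, 1], node2 = memb[, 2],
    kind = "membership", weight = 1,
    stringsAsFactors = FALSE
  )
  if (igraph::ecount(net$projection) > 0) {
    pr <- igraph::as_edgelist(net$projection)
    rows <- rbind(rows, data.frame(
      node1 = pr[, 1], node2 = pr[, 2],
      kind = "projection",
      weight = igraph::E(net$projection)$weight,
      stringsAsFactors = FALSE
    ))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
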