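#' Expression-weighted network impact of each pathway
#'
#' The impact of a pathway is the mean, over its retained significant
#' genes, of the product of the gene's negated removal score and the
#' magnitude of its log2 fold change: genes whose removal damages the
#' network and whose expression shift is large contribute most.
#'
#' @param net A `hetero_network`.
#' @param scores Data frame from [node_removal_centrality()].
#' @param table A filtered `deg_table`.
#' @param pathway Optional single pathway name; default computes all.
#' @return Named numeric vector of impacts (or a single number when
#'   `pathway` is given).
#' @export
pathway_impacts <- function(net, scores, table, pathway = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  sc <- stats::setNames(scores$score, scores$gene)
  fc <- stats::setNames(abs(table$log2fc), table$feature_id)
  one <- function(p) {
    if (!p %in% net$pathways) stop("pathway not in network: ", p)
    g <- net$sig_members[[p]]
    if (length(g) == 0) return(0)
    mean((-sc[g]) * fc[g])
  }
  if (!is.null(pathway)) return(one(pathway))
  stats::setNames(vapply(net$pathways, one, numeric(1)), net$pathways)
}

#' Impact similarity to the anchor pathway
#'
#' The distance-like divergence of a pathway from the anchor is the
#' absolute difference of their impacts; similarity is one minus the
#' min-max normalization of that divergence over the non-anchor pathways.
#' The anchor itself has similarity 1 by convention.  With fewer than two
#' non-anchor pathways, or when all divergences coincide, every similarity
#' is defined as 1.
#'
#' @param impacts Named numeric vector from [pathway_impacts()].
#' @param anchor Anchor pathway name; must be present in `impacts`.
#' @return Named numeric vector of similarities in `[0, 1]`.
#' @export
similarity_to_anchor <- function(impacts, anchor) {
  if (!anchor %in% names(impacts)) stop("anchor not in impacts: ", anchor)
  d_raw <- abs(impacts - impacts[[anchor]])
  others <- setdiff(names(impacts), anchor)
  sim <- stats::setNames(rep(1, length(impacts)), names(impacts))
  if (length(others) >= 2) {
    rng <- range(d_raw[others])
    if (diff(rng) > 0) {
      sim[others] <- 1 - (d_raw[others] - rng[1]) / diff(rng)
    }
  }
  sim[anchor] <- 1
  sim
}

#' Strength of the connection between each pathway and the anchor
#'
#' The raw strength blends gene-set overlap and network proximity:
#' `overlap_weight * Ochiai(sig(p), sig(anchor)) +
#'  (1 - overlap_weight) / (1 + hop(p, anchor))`,
#' where Ochiai is the cosine-like set overlap |A n B| / sqrt(|A||B|) on
#' the retained gene sets, and hop is the shortest membership-graph
#' distance between the two pathway nodes (so 2 via one shared gene;
#' infinite hop contributes 0).  Raw strengths are then min-max normalized
#' over the non-anchor pathways; the anchor is set to 1 by convention.  If
#' all non-anchor raw strengths coincide they normalize to 1 when positive
#' and 0 when zero.
#'
#' @param net A `hetero_network` whose anchor (or the `anchor` argument)
#'   is set.
#' @param anchor Anchor pathway name; defaults to `net$anchor`.
#' @param overlap_weight Weight of the overlap term, in `[0, 1]`;
#'   default 0.5.
#' @param normalize Set `FALSE` to return the raw (unnormalized) blend.
#' @return Named numeric vector of strengths in `[0, 1]`.
#' @export
connection_strength <- function(net, anchor = net$anchor,
                                overlap_weight = 0.5, normalize = TRUE) {
  stopifnot(inherits(net, "hetero_network"), !is.null(anchor),
            overlap_weight >= 0, overlap_weight <= 1)
  if (!anchor %in% net$pathways) stop("anchor not in network: ", anchor)
  a_set <- net$sig_members[[anchor]]
  hops <- igraph::distances(net$membership, v = anchor,
                            to = net$pathways, weights = NA)[1, ]
  raw <- vapply(net$pathways, function(p) {
    p_set <- net$sig_members[[p]]
    och <- length(intersect(p_set, a_set)) /
      sqrt(length(p_set) * length(a_set))
    h <- hops[[p]]
    prox <- if (is.finite(h)) 1 / (1 + h) else 0
    overlap_weight * och + (1 - overlap_weight) * prox
  }, numeric(1))
  names(raw) <- net$pathways
  if (!normalize) return(raw)
  others <- setdiff(net$pathways, anchor)
  out <- raw
  if (length(others) >= 1) {
    rng <- range(raw[others])
    if (diff(rng) > 0) {
      out[others] <- (raw[others] - rng[1]) / diff(rng)
    } else {
      out[others] <- ifelse(raw[others] > 0, 1, 0)
    }
  }
  out[anchor] <- 1
  out
}

#' Key-regulator index of each pathway
#'
#' Eigenvector centrality on the weighted pathway projection (edge weight =
#' number of shared retained genes), which rewards pathways that are both
#' well connected and connected to well-connected neighbours.  Computed by
#' power iteration (convergence 1e-10 in the max norm) independently on
#' each connected component; each component's vector is scaled by the ratio
#' of its dominant eigenvalue to the largest dominant eigenvalue, so the
#' strongest hub overall has index 1 and isolated pathways have index 0.
#'
#' @param net A `hetero_network`.
#' @param tol Power-iteration convergence tolerance; default 1e-10.
#' @return Named numeric vector of indices in `[0, 1]`.
#' @export
key_regulator_index <- function(net, tol = 1e-10) {
  stopifnot(inherits(net, "hetero_network"))
  proj <- net$projection
  idx <- stats::setNames(rep(0, length(net$pathways)), net$pathways)
  if (igraph::ecount(proj) == 0) {
    warning("empty pathway projection: all key-regulator indices are 0")
    return(idx)
  }
  comps <- igraph::components(proj)
  lambdas <- numeric(0)
  vecs <- list()
  for (ci in seq_len(comps$no)) {
    members <- names(comps$membership)[comps$membership == ci]
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(proj, members)
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    # positive diagonal shift: breaks the period-2 oscillation of power
    # iteration on bipartite-like projections without changing the
    # eigenvector (eigenvalues shift by `shift`)
    shift <- max(rowSums(A))
    B <- A + diag(shift, nrow(A))
    v <- rep(1, nrow(A))
    lambda <- 0
    for (it in seq_len(100000)) {
      v_new <- as.vector(B %*% v)
      vmax <- max(v_new)
      if (vmax == 0) break   # no edges in this component
      v_new <- v_new / vmax
      lambda <- vmax - shift
      if (max(abs(v_new - v)) < tol) { v <- v_new; break }
      v <- v_new
    }
    if (lambda > 0) {
      lambdas <- c(lambdas, lambda)
      vecs[[length(lambdas)]] <- stats::setNames(v, rownames(A))
    }
  }
  if (length(lambdas) > 0) {
    lmax <- max(lambdas)
    for (i in seq_along(lambdas)) {
      vi <- vecs[[i]] * (lambdas[i] / lmax)
      idx[names(vecs[[i]])] <- vi
    }
  }
  idx
}

#' Combine the three pathway parameters and rank against the anchor
#'
#' The combined coefficient is the weighted mean of impact similarity,
#' connection strength and key-regulator index.  Pathways are ranked
#' descending by the coefficient (closest to the anchor first), ties broken
#' by similarity then name; the anchor itself is excluded from the ranked
#' list.  A pathway passes the listing threshold only when its coefficient
#' is strictly greater than `config$combined_threshold` (default 0.35).
#'
#' @param similarity,strength,regulator Named numeric vectors in `[0, 1]`
#'   over the same pathways.
#' @param config A `run_config` supplying `weights`, `combined_threshold`
#'   and `anchor_name`.
#' @return A `pathway_priority` data frame with columns `pathway`,
#'   `similarity`, `connection_strength`, `key_regulator`, `combined`,
#'   `rank` and `passes_threshold`.
#' @export
combine_and_rank <- function(similarity, strength, regulator, config) {
  stopifnot(inherits(config, "run_config"))
  pw <- names(similarity)
  stopifnot(setequal(pw, names(strength)), setequal(pw, names(regulator)))
  strength <- strength[pw]
  regulator <- regulator[pw]
  comp <- cbind(similarity, strength, regulator)
  if (any(comp < -1e-12 | comp > 1 + 1e-12)) {
    stop("component outside [0, 1]: normalization bug upstream")
  }
  comp <- pmin(pmax(comp, 0), 1)
  combined <- as.vector(comp %*% config$weights)
  keep <- pw != config$anchor_name
  out <- data.frame(
    pathway = pw[keep],
    similarity = comp[keep, 1],
    connection_strength = comp[keep, 2],
    key_regulator = comp[keep, 3],
    combined = combined[keep],
    stringsAsFactors = FALSE
  )
  ord <- order(-out$combined, -out$similarity, out$pathway)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$passes_threshold <- out$combined > config$combined_threshold
  rownames(out) <- NULL
  class(out) <- c("pathway_priority", "data.frame")
  out
}

#' Prioritize every pathway against the anchor
#'
#' Convenience wrapper running the full prioritization: significance
#' filtering, network construction, node-removal centrality, the three
#' pathway parameters and their combination.
#'
#' @param pathways A `pathway_collection` (anchor taken from
#'   `config$anchor_name` when the collection has none).
#' @param table A `deg_table` (filtered here if flags are unset).
#' @param config A `run_config`.
#' @return List with `records` (the ranked `pathway_priority` table),
#'   `net`, `scores`, `impacts`, and the three component vectors.
#' @export
prioritize_pathways <- function(pathways, table, config = run_config()) {
  if (is.null(pathways$anchor)) {
    pathways <- pathway_collection(pathways$sets, pathways$descriptions,
                                   anchor = config$anchor_name,
                                   query = pathways$query)
  }
  if (anyNA(table$significant)) {
    table <- filter_significant(table, config$alpha_deg)
  }
  net <- build_network(pathways, table)
  scores <- node_removal_centrality(net)
  impacts <- pathway_impacts(net, scores, table)
  sim <- similarity_to_anchor(impacts, net$anchor)
  str_ <- connection_strength(net, overlap_weight = config$overlap_weight)
  reg <- key_regulator_index(net)
  records <- combine_and_rank(sim, str_, reg, config)
  list(records = records, net = net, scores = scores, impacts = impacts,
       similarity = sim, strength = str_, regulator = reg)
}

#' Minimum node distance from a gene set to a target pathway
#'
#' Breadth-first shortest hop count in the membership graph from any source
#' gene node to the target pathway node, in gene-pathway alternating hops
#' (a gene adjacent to the target is at distance 1; two pathways sharing a
#' gene are 2 apart).  One shortest chain is returned, the
#' lexicographically smallest node sequence among the shortest ones.
#'
#' @param source_genes Character vector of gene ids (for example the
#'   primary-cilium set); genes absent from the network are reported in
#'   `missing_sources` and ignored, but all-absent is an error.
#' @param target Target pathway name.
#' @param net A `hetero_network`.
#' @return A `chain_result`: list with `source_genes`, `target`,
#'   `distance`, `chain` (node names, source to target), `kinds`
#'   (gene/pathway per chain node), `reachable` and `missing_sources`.
#' @export
min_node_distance <- function(source_genes, target, net) {
  stopifnot(inherits(net, "hetero_network"))
  if (!target %in% net$pathways) stop("target pathway not in network: ", target)
  source_genes <- unique(as.character(source_genes))
  present <- intersect(source_genes, net$genes)
  missing <- setdiff(source_genes, net$genes)
  if (length(present) == 0) {
    stop("no source gene is present in the network")
  }
  m <- net$membership
  d_from_target <- igraph::distances(m, v = target, weights = NA)[1, ]
  d_src <- d_from_target[present]
  if (all(!is.finite(d_src))) {
    return(structure(
      list(source_genes = source_genes, target = target,
           distance = NA_integer_, chain = character(0),
           kinds = character(0), reachable = FALSE,
           missing_sources = missing),
      class = "chain_result"
    ))
  }
  dist <- min(d_src[is.finite(d_src)])
  starts <- sort(present[which(d_src == dist)])
  cur <- starts[1]
  chain <- cur
  # walk down the BFS distance gradient, smallest neighbour name first,
  # which yields the lexicographically smallest shortest node sequence
  while (d_from_target[[cur]] > 0) {
    nb <- igraph::neighbors(m, cur)$name
    nxt <- sort(nb[d_from_target[nb] == d_from_target[[cur]] - 1])[1]
    chain <- c(chain, nxt)
    cur <- nxt
  }
  kinds <- ifelse(chain %in% net$pathways, "pathway", "gene")
  structure(
    list(source_genes = source_genes, target = target,
         distance = as.integer(dist), chain = chain, kinds = kinds,
         reachable = TRUE, missing_sources = missing),
    class = "chain_result"
  )
}

#' @export
print.chain_result <- function(x, ...) {
  if (!x$reachable) {
    cat("chain_result: target '", x$target, "' unreachable from the source set\n",
        sep = "")
  } else {
    cat("chain_result: distance ", x$distance, " (membership-graph hops)\n",
        "  ", paste(x$chain, collapse = " - "), "\n", sep = "")
  }
  if (length(x$missing_sources) > 0) {
    cat("  source genes absent from network:",
        paste(x$missing_sources, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a chain result as TSV
#'
#' @param chain A `chain_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_chain <- function(chain, path) {
  df <- data.frame(
    step = seq_along(chain$chain),
    node = chain$chain,
    kind = chain$kinds,
    distance = rep(if (chain$reachable) chain$distance else NA_integer_,
                   length(chain$chain)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
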