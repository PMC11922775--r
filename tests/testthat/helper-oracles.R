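# Independent brute-force oracles, deliberately built on plain adjacency
# lists and hand-rolled BFS so they share no code path with the package's
# igraph-based implementations.

# adjacency list (named list of character vectors) from per-pathway member
# lists
oracle_adjacency <- function(sig_members) {
  adj <- list()
  add <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (p in names(sig_members)) {
    if (is.null(adj[[p]])) adj[[p]] <- character(0)
    for (g in sig_members[[p]]) add(g, p)
  }
  adj
}

# single-source BFS hop counts over an adjacency list
oracle_bfs <- function(adj, start) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[start] <- 0
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (!is.finite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

# global efficiency by all-pairs BFS
oracle_efficiency <- function(adj) {
  nodes <- names(adj)
  n <- length(nodes)
  if (n < 2) return(0)
  total <- 0
  for (v in nodes) {
    d <- oracle_bfs(adj, v)
    inv <- 1 / d[setdiff(nodes, v)]
    total <- total + sum(inv[is.finite(inv)])
  }
  total / (n * (n - 1))
}

# node-removal score of one gene by recomputation on the pruned member
# lists; pathway nodes stay in place even when emptied, mirroring deletion
# of the gene node alone
oracle_removal_score <- function(sig_members, gene) {
  base <- oracle_efficiency(oracle_adjacency(sig_members))
  pruned <- lapply(sig_members, setdiff, y = gene)
  oracle_efficiency(oracle_adjacency(pruned)) - base
}

# exact hypergeometric upper tail P(X >= x) by exhaustive enumeration of
# every k-subset of an N-gene universe containing K pathway members
oracle_hyper_tail <- function(N, K, k, x) {
  subsets <- utils::combn(N, k)
  hits <- colSums(subsets <= K)   # members coded 1..K
  mean(hits >= x)
}

# minimum hop distance from a source gene set to a pathway node
oracle_min_distance <- function(sig_members, sources, target) {
  adj <- oracle_adjacency(sig_members)
  sources <- intersect(sources, names(adj))
  if (length(sources) == 0) return(Inf)
  d <- oracle_bfs(adj, target)
  min(d[sources])
}

# a random small pathway universe in which every gene is significant
random_small_universe <- function(n_genes, n_pathways, max_size) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  sets <- lapply(seq_len(n_pathways), function(i) {
    sample(genes, sample(2:max_size, 1))
  })
  names(sets) <- sprintf("P%02d", seq_len(n_pathways))
  pathways <- pathway_collection(sets)
  table <- filter_significant(
    deg_table(genes, rnorm(n_genes, 0, 1.5), runif(n_genes, 1e-6, 0.049)),
    alpha = 0.05
  )
  list(pathways = pathways, table = table, sets = sets)
}
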