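#' Run the full pathway-network analysis
#'
#' End-to-end pipeline: significance filtering, gene-pathway network
#' construction, node-removal centrality, importance ordering, ordered
#' enrichment of the central genes, pathway prioritization against the
#' anchor, the cumulative coordinated-expression scan with zone detection,
#' and per-pathway coordination strengths.  When `out_dir` is given, the
#' standard output tables and a JSON run report are written there.
#'
#' @param pathways A `pathway_collection`.
#' @param table A `deg_table`.
#' @param config A `run_config`.
#' @param out_dir Optional output directory (created if needed).
#' @return List with `net`, `scores`, `ranking` (ordered gene list),
#'   `enrichment`, `priority` (result of [prioritize_pathways()] minus the
#'   recomputed pieces), `records`, `profile`, `zones`, `coordination`
#'   and `report`.
#' @export
run_analysis <- function(pathways, table, config = run_config(),
                         out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  if (is.null(pathways$anchor)) {
    pathways <- pathway_collection(pathways$sets, pathways$descriptions,
                                   anchor = config$anchor_name,
                                   query = pathways$query)
  }
  table <- filter_significant(table, config$alpha_deg)
  net <- build_network(pathways, table)
  tick("network")
  scores <- node_removal_centrality(net)
  ranking <- rank_genes(scores, table)
  tick("centrality")
  enrichment <- NULL
  if (nrow(ranking$central) > 0) {
    enrichment <- ordered_enrichment(ranking$central$gene, pathways,
                                     pathway_universe(pathways))
  }
  tick("enrichment")
  impacts <- pathway_impacts(net, scores, table)
  sim <- similarity_to_anchor(impacts, net$anchor)
  strength <- connection_strength(net, overlap_weight = config$overlap_weight)
  regulator <- key_regulator_index(net)
  records <- combine_and_rank(sim, strength, regulator, config)
  tick("prioritization")
  profile <- NULL
  zones <- NULL
  coordination <- NULL
  if (nrow(ranking$central) > 0) {
    profile <- cumulative_scan(ranking$central$gene, table)
    zones <- detect_zones(profile, config$scan_window, config$scan_slope)
    coordination <- coordination_strengths(ranking$central$gene, pathways,
                                           table)
    tick("scan")
  }
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(out_dir, f)
    write_ranked_pathways(records, pth("ranked_pathways.tsv"))
    gs <- ranking$order
    utils::write.table(gs, pth("gene_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(pth("ranked_pathways.tsv"), pth("gene_scores.tsv"))
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, pth("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, pth("enrichment.tsv"))
    }
    if (!is.null(profile)) {
      write_scan(profile, zones, pth("profile.tsv"), pth("zones.tsv"))
      outputs <- c(outputs, pth("profile.tsv"), pth("zones.tsv"))
    }
  }
  report <- run_report(
    config,
    n_genes = nrow(table), n_pathways = length(pathways$sets),
    n_retained = sum(table$significant),
    timings = timings,
    outputs = if (is.null(out_dir)) character(0)
              else c(outputs, file.path(out_dir, "report.json"))
  )
  if (!is.null(out_dir)) {
    write_run_report(report, file.path(out_dir, "report.json"))
  }
  list(net = net, scores = scores, ranking = ranking,
       enrichment = enrichment, records = records, impacts = impacts,
       similarity = sim, strength = strength, regulator = regulator,
       profile = profile, zones = zones, coordination = coordination,
       report = report)
}
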