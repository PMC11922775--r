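#' Run configuration
#'
#' Central container for the tunable parameters of the pipeline: the
#' significance cutoff applied to the differential-expression table, the
#' combined-coefficient listing threshold, the anchor pathway name, the
#' coordinated-expression scan parameters, and the weights of the combined
#' coefficient.
#'
#' @param alpha_deg Adjusted-p cutoff for retaining differentially expressed
#'   features; strict `p_adj < alpha_deg`. Default 0.05.
#' @param combined_threshold Listing threshold for the combined coefficient;
#'   a pathway passes only when its coefficient is strictly greater.
#'   Default 0.35.
#' @param anchor_name Name of the anchor pathway every other pathway is
#'   scored against (the autophagy pathway in the motivating analysis).
#' @param scan_window Window length (in list positions) for zone detection
#'   along the cumulative expression scan. Default 10.
#' @param scan_slope Minimum absolute windowed slope, in (0, 1], for a
#'   position to belong to a zone. Default 0.6.
#' @param seed Non-negative integer seed recorded in run reports.
#' @param weights Three non-negative weights (impact similarity, connection
#'   strength, key-regulator index) summing to 1. Default `rep(1/3, 3)`.
#' @param overlap_weight Weight in `[0, 1]` of the gene-overlap (Ochiai)
#'   term versus the inverse-hop term inside connection strength.
#'   Default 0.5.
#'
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(alpha_deg = 0.05,
                       combined_threshold = 0.35,
                       anchor_name = "autophagy",
                       scan_window = 10L,
                       scan_slope = 0.6,
                       seed = 0L,
                       weights = rep(1 / 3, 3),
                       overlap_weight = 0.5) {
  stopifnot(
    is.numeric(alpha_deg), length(alpha_deg) == 1,
    alpha_deg > 0, alpha_deg < 1,
    is.numeric(combined_threshold), length(combined_threshold) == 1,
    combined_threshold >= 0, combined_threshold <= 1,
    is.character(anchor_name), length(anchor_name) == 1, nzchar(anchor_name),
    is.numeric(scan_window), length(scan_window) == 1, scan_window >= 2,
    scan_window == as.integer(scan_window),
    is.numeric(scan_slope), length(scan_slope) == 1,
    scan_slope > 0, scan_slope <= 1,
    is.numeric(seed), length(seed) == 1, seed >= 0,
    is.numeric(weights), length(weights) == 3, all(weights >= 0),
    is.numeric(overlap_weight), length(overlap_weight) == 1,
    overlap_weight >= 0, overlap_weight <= 1
  )
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must sum to 1 (within 1e-9), got ", sum(weights))
  }
  structure(
    list(
      alpha_deg = alpha_deg,
      combined_threshold = combined_threshold,
      anchor_name = anchor_name,
      scan_window = as.integer(scan_window),
      scan_slope = scan_slope,
      seed = as.integer(seed),
      weights = weights,
      overlap_weight = overlap_weight
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("degnet run configuration\n")
  cat("  alpha_deg          :", x$alpha_deg, "\n")
  cat("  combined_threshold :", x$combined_threshold, "(strict >)\n")
  cat("  anchor_name        :", x$anchor_name, "\n")
  cat("  scan_window        :", x$scan_window, "\n")
  cat("  scan_slope         :", x$scan_slope, "\n")
  cat("  weights            :", paste(signif(x$weights, 4), collapse = ", "), "\n")
  cat("  overlap_weight     :", x$overlap_weight, "\n")
  cat("  seed               :", x$seed, "\n")
  invisible(x)
}

#' Read pathway gene sets from a GMT file
#'
#' One pathway per line: name, description, then one member per field, all
#' tab-separated.  Member lists are de-duplicated preserving first
#' occurrence; pathway order follows the file.
#'
#' @param path Path to a GMT file.
#' @param anchor_name Optional name of the anchor pathway; stored on the
#'   collection and checked for presence when given.
#' @return A `pathway_collection`: a list with elements `sets` (named list
#'   of character vectors), `descriptions`, `anchor`, and `query`.
#' @export
read_gmt <- function(path, anchor_name = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(pathway_collection(sets = list(), anchor = anchor_name))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop(
      "duplicate pathway name in GMT: ",
      paste(unique(names_[duplicated(names_)]), collapse = ", ")
    )
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- names_
  desc <- vapply(fields, `[[`, character(1), 2)
  names(desc) <- names_
  pathway_collection(sets = sets, descriptions = desc, anchor = anchor_name)
}

#' Construct a pathway collection
#'
#' @param sets Named list of character vectors (gene sets).
#' @param descriptions Optional named character vector of descriptions.
#' @param anchor Optional anchor pathway name; must be present in `sets`
#'   when the collection is non-empty.
#' @param query Optional character vector of query genes (for example a
#'   primary-cilium gene set) used for chain extraction.
#' @return A `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL, anchor = NULL,
                               query = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("all pathway sets must be named")
  }
  if (anyDuplicated(names(sets))) stop("duplicate pathway names")
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  if (!is.null(anchor) && length(sets) > 0 && !anchor %in% names(sets)) {
    stop("anchor pathway '", anchor, "' not present in the collection")
  }
  structure(
    list(sets = sets, descriptions = descriptions, anchor = anchor,
         query = query),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x$sets), "pathways,",
      length(pathway_universe(x)), "distinct genes\n")
  if (!is.null(x$anchor)) cat("  anchor:", x$anchor, "\n")
  if (!is.null(x$query)) cat("  query set:", length(x$query), "genes\n")
  invisible(x)
}

#' Union of all pathway members
#'
#' @param pathways A `pathway_collection`.
#' @return Character vector of all distinct member genes.
#' @export
pathway_universe <- function(pathways) {
  unique(unlist(pathways$sets, use.names = FALSE))
}

#' Write a pathway collection as GMT
#'
#' @param pathways A `pathway_collection`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways$sets), function(nm) {
    paste(c(nm, pathways$descriptions[[nm]], pathways$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with header; required columns `feature_id`, `log2fc`,
#' `p_adj` (extra columns are ignored).  Significance flags are not set
#' here; apply [filter_significant()] with the configured cutoff.
#'
#' @param path Path to a TSV file.
#' @return A `deg_table` data frame with columns `feature_id`, `log2fc`,
#'   `p_adj`, `significant` (NA until filtered) and `direction`
#'   (`sign(log2fc)`).
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("DEG table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "log2fc", "p_adj")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0) {
    stop("DEG table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  deg_table(df$feature_id, df$log2fc, df$p_adj)
}

#' Construct a differential-expression table
#'
#' @param feature_id Character vector of unique feature identifiers
#'   (case-sensitive; symbol harmonization is the caller's job).
#' @param log2fc Numeric log2 fold changes.
#' @param p_adj Adjusted p-values in `[0, 1]`.
#' @return A `deg_table` data frame.
#' @export
deg_table <- function(feature_id, log2fc, p_adj) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "))
  }
  log2fc <- suppressWarnings(as.numeric(log2fc))
  if (anyNA(log2fc)) {
    stop("non-numeric log2fc in row(s): ",
         paste(which(is.na(log2fc)), collapse = ", "))
  }
  p_adj <- suppressWarnings(as.numeric(p_adj))
  bad <- which(is.na(p_adj) | p_adj < 0 | p_adj > 1)
  if (length(bad) > 0) {
    stop("p_adj outside [0, 1] in row(s): ", paste(bad, collapse = ", "))
  }
  structure(
    data.frame(
      feature_id = feature_id,
      log2fc = log2fc,
      p_adj = p_adj,
      significant = rep(NA, length(feature_id)),
      direction = sign(log2fc),
      stringsAsFactors = FALSE
    ),
    class = c("deg_table", "data.frame")
  )
}

#' Write a differential-expression table as TSV
#'
#' @param table A `deg_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(
    table[, c("feature_id", "log2fc", "p_adj")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased on read; positions are 1-based and inclusive
#' downstream.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (any(Biostrings::width(aa) == 0)) {
    stop("empty sequence under header: ",
         paste(names(aa)[Biostrings::width(aa) == 0], collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(toupper(as.character(aa)), ids)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Write ranked pathway records as TSV
#'
#' Columns: pathway, similarity, connection_strength, key_regulator,
#' combined, rank, passes_threshold.  Numeric columns are written with six
#' significant digits; the row order is the rank order, so repeated runs
#' with the same configuration produce byte-identical files.
#'
#' @param records A ranked `pathway_priority` data frame from
#'   [combine_and_rank()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ranked_pathways <- function(records, path) {
  cols <- c("pathway", "similarity", "connection_strength", "key_regulator",
            "combined", "rank", "passes_threshold")
  stopifnot(all(cols %in% colnames(records)))
  out <- records[, cols]
  for (cc in c("similarity", "connection_strength", "key_regulator", "combined")) {
    out[[cc]] <- signif(out[[cc]], 6)
  }
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a run report
#'
#' Records the configuration, input digests (counts of genes, pathways and
#' retained significant features), the seed, per-stage timings and the
#' paths of every file written, for provenance of a pipeline run.
#'
#' @param config A `run_config`.
#' @param n_genes,n_pathways,n_retained Input digests.
#' @param timings Named numeric vector of per-stage elapsed seconds.
#' @param outputs Character vector of output file paths.
#' @return A `run_report` list.
#' @export
run_report <- function(config, n_genes, n_pathways, n_retained,
                       timings = numeric(0), outputs = character(0)) {
  structure(
    list(
      config = unclass(config),
      inputs = list(n_genes = n_genes, n_pathways = n_pathways,
                    n_retained = n_retained),
      seed = config$seed,
      timings = as.list(timings),
      outputs = as.list(outputs),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_report"
  )
}

#' Write a run report as JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
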