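#' Cumulative coordinated-expression scan along an ordered gene list
#'
#' Walks the importance-ordered gene list and accumulates a position
#' score: +1 when the gene is upregulated, -1 when downregulated, 0 when
#' its log2 fold change is exactly zero (such genes stay in the list so the
#' topographic order is preserved; their count is attached as an
#' attribute).  A flat trace indicates directions distributed at random; a
#' sustained slope marks a run of topographically related genes with
#' coordinated expression.
#'
#' @param genes_ordered Character vector of gene ids, most important first
#'   (typically the central sublist from [rank_genes()]).
#' @param table A filtered `deg_table` containing every listed gene.
#' @return A `scan_profile` data frame with columns `rank`, `gene`,
#'   `increment` and `cumulative` (the trace starts implicitly at 0).
#' @export
cumulative_scan <- function(genes_ordered, table) {
  genes_ordered <- as.character(genes_ordered)
  idx <- match(genes_ordered, table$feature_id)
  if (anyNA(idx)) {
    stop("gene(s) missing from the expression table: ",
         paste(genes_ordered[is.na(idx)], collapse = ", "))
  }
  inc <- table$direction[idx]
  out <- data.frame(
    rank = seq_along(genes_ordered),
    gene = genes_ordered,
    increment = inc,
    cumulative = cumsum(inc),
    stringsAsFactors = FALSE
  )
  attr(out, "n_zero_direction") <- sum(inc == 0)
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' Detect sustained-slope zones in a scan profile
#'
#' The windowed slope at trace position i (0-based, trace S with S_0 = 0)
#' is `(S[i + window] - S[i]) / window`.  A zone is a maximal run of
#' positions whose absolute slope reaches `slope_min` with constant sign;
#' same-sign runs separated by fewer than `window / 2` positions are
#' merged.  A zone spanning trace positions `start..end` covers genes at
#' ranks `start + 1` through `end`; its strength is
#' `|S[end] - S[start]| / (end - start)`, at most 1 by construction.
#' Zones are returned sorted by strength descending (the paper-style
#' "zone A" is simply the strongest zone).
#'
#' @param profile A `scan_profile`.
#' @param window Window length, at least 2; default 10.
#' @param slope_min Minimum absolute windowed slope in (0, 1]; default 0.6.
#' @return Data frame with columns `start`, `end` (0-based trace
#'   positions), `sign` (+1/-1) and `strength`; zero rows when nothing
#'   qualifies.
#' @export
detect_zones <- function(profile, window = 10L, slope_min = 0.6) {
  stopifnot(inherits(profile, "scan_profile"),
            window >= 2, slope_min > 0, slope_min <= 1)
  window <- as.integer(window)
  L <- nrow(profile)
  empty <- data.frame(start = integer(0), end = integer(0),
                      sign = integer(0), strength = numeric(0))
  if (window >= L) {
    warning("window (", window, ") >= list length (", L, "): no zones")
    return(empty)
  }
  S <- c(0, profile$cumulative)            # S[i + 1] is trace position i
  i <- 0:(L - window)
  slope <- (S[i + window + 1] - S[i + 1]) / window
  ok <- abs(slope) >= slope_min
  sgn <- sign(slope)
  # maximal runs of qualifying positions with constant sign
  runs <- list()
  r_start <- NA
  for (j in seq_along(i)) {
    if (ok[j]) {
      if (is.na(r_start)) {
        r_start <- j
      } else if (sgn[j] != sgn[r_start]) {
        runs[[length(runs) + 1]] <- c(r_start, j - 1)
        r_start <- j
      }
    } else if (!is.na(r_start)) {
      runs[[length(runs) + 1]] <- c(r_start, j - 1)
      r_start <- NA
    }
  }
  if (!is.na(r_start)) runs[[length(runs) + 1]] <- c(r_start, length(i))
  if (length(runs) == 0) return(empty)
  # merge same-sign runs separated by fewer than window/2 positions
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    gap <- r[1] - last[2] - 1
    if (sgn[r[1]] == sgn[last[1]] && gap < window / 2) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  zones <- do.call(rbind, lapply(merged, function(r) {
    start <- i[r[1]]
    end <- i[r[2]] + window
    data.frame(
      start = start, end = end,
      sign = as.integer(sgn[r[1]]),
      strength = abs(S[end + 1] - S[start + 1]) / (end - start)
    )
  }))
  zones <- zones[zones$end - zones$start >= window, , drop = FALSE]
  zones <- zones[order(-zones$strength, zones$start), , drop = FALSE]
  rownames(zones) <- NULL
  zones
}

#' Coordinated-expression strength of a pathway along the ordered list
#'
#' The absolute net direction of the pathway's genes that appear in the
#' ordered list, divided by the number of those genes with a nonzero
#' direction: 1 when all move the same way, 0 when up and down balance.
#'
#' @param pathway Pathway name.
#' @param genes_ordered Character vector (the scanned ordered list).
#' @param pathways A `pathway_collection`.
#' @param table A filtered `deg_table`.
#' @return A number in `[0, 1]`, or `NA` when the pathway has no listed
#'   gene (reported with a message) or no listed gene with nonzero
#'   direction.
#' @export
coordination_strength <- function(pathway, genes_ordered, pathways, table) {
  stopifnot(inherits(pathways, "pathway_collection"))
  if (!pathway %in% names(pathways$sets)) {
    stop("unknown pathway: ", pathway)
  }
  g <- intersect(pathways$sets[[pathway]], genes_ordered)
  if (length(g) == 0) {
    message("pathway '", pathway, "' has no gene in the ordered list")
    return(NA_real_)
  }
  dirs <- table$direction[match(g, table$feature_id)]
  nz <- sum(dirs != 0, na.rm = TRUE)
  if (nz == 0) return(NA_real_)
  abs(sum(dirs, na.rm = TRUE)) / nz
}

#' Coordination strength for every pathway
#'
#' @inheritParams coordination_strength
#' @return Named numeric vector (NA where undefined), one entry per
#'   pathway in the collection.
#' @export
coordination_strengths <- function(genes_ordered, pathways, table) {
  stats::setNames(
    vapply(names(pathways$sets), function(p) {
      suppressMessages(
        coordination_strength(p, genes_ordered, pathways, table)
      )
    }, numeric(1)),
    names(pathways$sets)
  )
}

#' Write a scan profile and its zones as TSVs
#'
#' @param profile A `scan_profile`.
#' @param zones Zone data frame from [detect_zones()].
#' @param profile_path,zones_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_scan <- function(profile, zones, profile_path, zones_path) {
  utils::write.table(as.data.frame(profile), profile_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(zones, zones_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(profile_path, zones_path))
}
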