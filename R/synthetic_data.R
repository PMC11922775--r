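#' Specification of a synthetic pathway universe
#'
#' Describes a seeded synthetic data set emulating the inputs of the
#' pathway-network analysis: a pathway collection with controlled overlap
#' and a differential-expression table with known significance flags,
#' plus optional planted structure whose recovery downstream stages can be
#' tested against — a pathway sharing genes with the anchor, a pathway
#' sharing none (hence at membership-graph distance at least 4), a
#' high-membership regulator gene, and a contiguous block of
#' same-direction genes in a reference importance ordering.
#'
#' @param seed Non-negative integer seed; the generated universe is a pure
#'   function of the spec including the seed.
#' @param n_genes Number of background genes; default 500.
#' @param n_pathways Total number of pathways including anchor and planted
#'   ones; default 40.
#' @param pathway_size_range Integer pair; each pathway's size is drawn
#'   uniformly in this range. Default c(10, 30).
#' @param overlap_rate Expected fraction of a background pathway's members
#'   copied from a random earlier pathway, in `[0, 1]`; default 0.25.
#' @param frac_significant Fraction of genes flagged significant; default
#'   0.3.
#' @param effect_size_scale Scale of |log2fc| for significant features;
#'   default 1.5.
#' @param alpha Significance cutoff the generator honours: significant
#'   features draw `p_adj` uniformly below it, others uniformly at or
#'   above it. Default 0.05.
#' @param anchor_name Name of the anchor pathway; default "autophagy".
#' @param planted_near_pathway Name of a pathway built to share half its
#'   members with the anchor, or NULL to omit. Default "near_anchor".
#' @param planted_far_pathway Name of a pathway sharing zero members with
#'   the anchor, or NULL. Default "far_island".
#' @param planted_regulator_gene Name of a gene inserted into 70% of the
#'   pathways (never the far pathway), or NULL. Default "regulator".
#' @param planted_zone List `(start, length, direction)` describing a
#'   coordinated block planted at those ranks of the reference ordering of
#'   significant genes, or NULL. Default `list(start = 41, length = 30,
#'   direction = 1)`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 500L,
                           n_pathways = 40L,
                           pathway_size_range = c(10L, 30L),
                           overlap_rate = 0.25,
                           frac_significant = 0.3,
                           effect_size_scale = 1.5,
                           alpha = 0.05,
                           anchor_name = "autophagy",
                           planted_near_pathway = "near_anchor",
                           planted_far_pathway = "far_island",
                           planted_regulator_gene = "regulator",
                           planted_zone = list(start = 41L, length = 30L,
                                               direction = 1L)) {
  stopifnot(
    seed >= 0, n_genes >= 10, n_pathways >= 2,
    length(pathway_size_range) == 2,
    pathway_size_range[1] >= 2,
    pathway_size_range[2] >= pathway_size_range[1],
    pathway_size_range[2] <= n_genes,
    overlap_rate >= 0, overlap_rate <= 1,
    frac_significant >= 0, frac_significant <= 1,
    effect_size_scale > 0,
    alpha > 0, alpha < 1
  )
  if (!is.null(planted_zone)) {
    stopifnot(all(c("start", "length", "direction") %in% names(planted_zone)),
              planted_zone$start >= 1, planted_zone$length >= 1,
              planted_zone$direction %in% c(-1, 1))
    if (planted_zone$length > n_genes) {
      stop("planted zone longer than the gene list")
    }
  }
  n_special <- 1 + (!is.null(planted_near_pathway)) +
    (!is.null(planted_far_pathway))
  if (n_pathways < n_special) {
    stop("n_pathways too small for the planted pathways")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_pathways = as.integer(n_pathways),
         pathway_size_range = as.integer(pathway_size_range),
         overlap_rate = overlap_rate, frac_significant = frac_significant,
         effect_size_scale = effect_size_scale, alpha = alpha,
         anchor_name = anchor_name,
         planted_near_pathway = planted_near_pathway,
         planted_far_pathway = planted_far_pathway,
         planted_regulator_gene = planted_regulator_gene,
         planted_zone = planted_zone),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic pathway universe with planted ground truth
#'
#' Builds, reproducibly for a fixed spec, a `pathway_collection`, a
#' `deg_table` whose significance flags are consistent with the spec's
#' `alpha` (significant features have `p_adj < alpha`, others
#' `p_adj >= alpha`), and a `ground_truth` record of every planted
#' structure.  Background pathways draw members without replacement and
#' induce overlap by copying a fraction of members from a random earlier
#' pathway; the planted near pathway copies half its members from the
#' anchor; the planted far pathway draws only from genes outside the
#' anchor, so its membership-graph distance to the anchor is at least 4
#' (or infinite); the planted regulator gene replaces one member in 70% of
#' the pathways (never the far one) and is forced significant; the planted
#' zone fixes the direction of a contiguous block of the reference
#' ordering of significant genes (recorded in the ground truth), the rest
#' drawing random signs.  The anchor and the planted pathways are
#' guaranteed at least two significant members so they survive network
#' construction.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `pathways` (`pathway_collection`), `table`
#'   (`deg_table`, flags already set) and `truth` (`ground_truth` list:
#'   `anchor`, `near`, `far`, `regulator`, `zone` with
#'   `start`/`length`/`direction`/`genes`/`order`).
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  width <- nchar(as.character(spec$n_genes))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(spec$n_genes))

  # --- significance flags -------------------------------------------------
  n_sig <- round(spec$frac_significant * spec$n_genes)
  sig <- stats::setNames(rep(FALSE, spec$n_genes), genes)
  if (n_sig > 0) sig[sample(genes, n_sig)] <- TRUE

  # --- pathway memberships ------------------------------------------------
  rng <- spec$pathway_size_range
  draw_size <- function() sample(seq(rng[1], rng[2]), 1)
  sets <- list()
  sets[[spec$anchor_name]] <- sample(genes, draw_size())
  n_bg <- spec$n_pathways - 1 - (!is.null(spec$planted_near_pathway)) -
    (!is.null(spec$planted_far_pathway))
  for (i in seq_len(n_bg)) {
    s <- draw_size()
    src <- sets[[sample(length(sets), 1)]]
    n_copy <- min(round(spec$overlap_rate * s), length(src))
    copied <- if (n_copy > 0) sample(src, n_copy) else character(0)
    rest <- sample(setdiff(genes, copied), s - n_copy)
    sets[[sprintf("pw_%02d", i)]] <- c(copied, rest)
  }
  if (!is.null(spec$planted_near_pathway)) {
    s <- draw_size()
    n_copy <- min(ceiling(s / 2), length(sets[[spec$anchor_name]]))
    copied <- sample(sets[[spec$anchor_name]], n_copy)
    rest <- sample(setdiff(genes, copied), s - n_copy)
    sets[[spec$planted_near_pathway]] <- c(copied, rest)
  }
  if (!is.null(spec$planted_far_pathway)) {
    s <- draw_size()
    pool <- setdiff(genes, sets[[spec$anchor_name]])
    sets[[spec$planted_far_pathway]] <- sample(pool, s)
  }

  # --- planted regulator: high membership degree --------------------------
  if (!is.null(spec$planted_regulator_gene)) {
    reg <- spec$planted_regulator_gene
    hosts <- setdiff(names(sets), spec$planted_far_pathway)
    n_hosts <- min(length(hosts), max(2, ceiling(0.7 * length(sets))))
    hosts <- sample(hosts, n_hosts)
    for (p in hosts) {
      if (!reg %in% sets[[p]]) {
        drop_i <- sample(length(sets[[p]]), 1)
        sets[[p]][drop_i] <- reg
      }
    }
    genes <- c(genes, reg)
    sig[reg] <- TRUE
  }

  # --- guarantee the special pathways survive filtering (only when the
  # spec asks for significant features at all) -----------------------------
  specials <- if (n_sig > 0) {
    c(spec$anchor_name, spec$planted_near_pathway, spec$planted_far_pathway)
  } else character(0)
  for (p in specials) {
    members <- sets[[p]]
    n_have <- sum(sig[members])
    if (n_have < 2) {
      promote <- sample(members[!sig[members]], 2 - n_have)
      sig[promote] <- TRUE
    }
  }

  sig_genes <- names(sig)[sig]

  # --- reference ordering and planted coordinated block -------------------
  zone <- NULL
  order_ref <- sample(sig_genes)
  planted_dir <- stats::setNames(integer(0), character(0))
  if (!is.null(spec$planted_zone)) {
    z <- spec$planted_zone
    last <- z$start + z$length - 1
    if (last > length(sig_genes)) {
      stop("planted zone (ranks ", z$start, "-", last,
           ") exceeds the ", length(sig_genes), " significant genes")
    }
    zone_genes <- order_ref[z$start:last]
    planted_dir <- stats::setNames(rep(as.integer(z$direction),
                                       length(zone_genes)), zone_genes)
    zone <- list(start = as.integer(z$start),
                 length = as.integer(z$length),
                 direction = as.integer(z$direction),
                 genes = zone_genes, order = order_ref)
  }

  # --- expression table ---------------------------------------------------
  n <- length(genes)
  is_sig <- unname(sig[genes])
  p_adj <- numeric(n)
  p_adj[is_sig] <- stats::runif(sum(is_sig), 1e-6, spec$alpha * 0.999)
  p_adj[!is_sig] <- stats::runif(sum(!is_sig), spec$alpha, 1)
  magnitude <- numeric(n)
  magnitude[is_sig] <- spec$effect_size_scale * stats::runif(sum(is_sig), 0.5, 1.5)
  direction <- sample(c(-1L, 1L), n, replace = TRUE)
  direction[match(names(planted_dir), genes)] <- planted_dir
  log2fc <- numeric(n)
  log2fc[is_sig] <- direction[is_sig] * magnitude[is_sig]
  log2fc[!is_sig] <- stats::rnorm(sum(!is_sig), 0, 0.2)
  table <- deg_table(genes, log2fc, p_adj)
  table <- filter_significant(table, spec$alpha)

  pathways <- pathway_collection(sets, anchor = spec$anchor_name)
  truth <- structure(
    list(anchor = spec$anchor_name,
         near = spec$planted_near_pathway,
         far = spec$planted_far_pathway,
         regulator = spec$planted_regulator_gene,
         zone = zone),
    class = "ground_truth"
  )
  list(pathways = pathways, table = table, truth = truth)
}

#' Synthetic GPR158 C-terminal motif fixture
#'
#' A 400-residue synthetic protein whose only V.P. tetramers are the five
#' ciliary-targeting instances of the GPR158 C-terminal domain: VCPW at
#' 212-215, 277-280 and 377-380, VLPG at 300-303 and VAPK at 331-334.  The
#' background is drawn from an amino-acid alphabet excluding V and P, so
#' no spurious match can arise and the five-hit count is certain by
#' construction.
#'
#' @param seed Seed for the background draw; default 101.
#' @return Named character vector of length one
#'   (`GPR158_Cterm_synthetic`).
#' @export
generate_motif_fixture <- function(seed = 101L) {
  set.seed(seed)
  background <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "S", "T", "W", "Y")   # 20 AA minus V, P
  chars <- sample(background, 400, replace = TRUE)
  motifs <- list(`212` = "VCPW", `277` = "VCPW", `300` = "VLPG",
                 `331` = "VAPK", `377` = "VCPW")
  for (pos in names(motifs)) {
    i <- as.integer(pos)
    chars[i:(i + 3)] <- strsplit(motifs[[pos]], "")[[1]]
  }
  stats::setNames(paste(chars, collapse = ""), "GPR158_Cterm_synthetic")
}
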