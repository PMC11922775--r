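#' Scan a protein sequence for VxPx ciliary-targeting motifs
#'
#' Reports every tetramer with valine at its first position and proline at
#' its third ("x" is any residue, including V or P), the canonical
#' ciliary-targeting signal of GPCR cytoplasmic tails.  Overlapping matches
#' are all reported; coordinates are 1-based and inclusive.
#'
#' @param seq A single protein sequence (character string; upper-cased
#'   internally).
#' @param id Optional sequence id recorded in the result.
#' @return Data frame with columns `seq_id`, `start`, `end`
#'   (`start + 3`) and `tetramer`, in ascending start order.
#' @export
scan_vxpx <- function(seq, id = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^A-Z]", seq)) stop("non-alphabetic characters in sequence")
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), tetramer = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < 4) {
    warning("sequence shorter than 4 residues: no scan possible")
    return(empty)
  }
  starts <- gregexpr("(?=V.P.)", seq, perl = TRUE)[[1]]
  if (starts[1] == -1) return(empty)
  data.frame(
    seq_id = rep(id, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts) + 3L,
    tetramer = substring(seq, starts, starts + 3L),
    stringsAsFactors = FALSE
  )
}

#' Scan several sequences for VxPx motifs
#'
#' @param seqs Named character vector, e.g. from [read_fasta()].
#' @return Row-bound hit table (see [scan_vxpx()]).
#' @export
scan_vxpx_all <- function(seqs) {
  do.call(rbind, lapply(names(seqs), function(nm) scan_vxpx(seqs[[nm]], nm)))
}

#' Build a motif mutation plan
#'
#' The default ablation replaces the valine (motif position 1) and the
#' proline (motif position 3) with alanine, which destroys the V.P. match
#' while keeping sequence length.  Specific tetramers can be overridden
#' with a full 4-residue replacement (for example `c(VLPG = "ALQG")` to use
#' glutamine at the proline position of that instance).
#'
#' @param v_replacement Residue replacing the motif's valine; default "A".
#' @param p_replacement Residue replacing the motif's proline; default "A".
#' @param overrides Named character vector mapping a tetramer to its full
#'   replacement tetramer; each replacement must be 4 residues and must not
#'   itself match V.P. .
#' @return A `mutation_plan` list.
#' @export
mutation_plan <- function(v_replacement = "A", p_replacement = "A",
                          overrides = character(0)) {
  stopifnot(
    is.character(v_replacement), nchar(v_replacement) == 1,
    is.character(p_replacement), nchar(p_replacement) == 1,
    is.character(overrides)
  )
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(nchar(names(overrides)) != 4)) {
      stop("overrides must be named by 4-residue tetramers")
    }
    if (any(nchar(overrides) != 4)) {
      stop("override replacements must be 4 residues long")
    }
    if (any(grepl("^V.P.$", overrides))) {
      stop("an override replacement still matches V.P.: ",
           paste(overrides[grepl("^V.P.$", overrides)], collapse = ", "))
    }
  }
  structure(
    list(v_replacement = toupper(v_replacement),
         p_replacement = toupper(p_replacement),
         overrides = stats::setNames(toupper(overrides),
                                     toupper(names(overrides)))),
    class = "mutation_plan"
  )
}

#' Apply a mutation plan to ablate motif hits
#'
#' Substitutes residues at each hit according to the plan, leaving the
#' sequence length unchanged, and verifies that no mutated position still
#' starts a V.P. match.  Overlapping hits are allowed as long as their
#' substitutions agree at every shared position; conflicting assignments
#' raise an error.
#'
#' @param seq The protein sequence the hits were found in.
#' @param hits Hit table from [scan_vxpx()] (any subset of rows).
#' @param plan A `mutation_plan`; default ablates V and P to alanine.
#' @return The mutated sequence (character string, same length).
#' @export
design_mutant <- function(seq, hits, plan = mutation_plan()) {
  stopifnot(inherits(plan, "mutation_plan"), is.data.frame(hits))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (nrow(hits) > 0 && (any(hits$start < 1) || any(hits$end > n))) {
    stop("hit outside sequence bounds")
  }
  sub_pos <- integer(0)
  sub_res <- character(0)
  for (r in seq_len(nrow(hits))) {
    tet <- substring(seq, hits$start[r], hits$end[r])
    if (tet %in% names(plan$overrides)) {
      repl <- strsplit(plan$overrides[[tet]], "")[[1]]
      pos <- hits$start[r] + 0:3
      changed <- repl != strsplit(tet, "")[[1]]
      sub_pos <- c(sub_pos, pos[changed])
      sub_res <- c(sub_res, repl[changed])
    } else {
      sub_pos <- c(sub_pos, hits$start[r], hits$start[r] + 2L)
      sub_res <- c(sub_res, plan$v_replacement, plan$p_replacement)
    }
  }
  if (length(sub_pos) > 0) {
    tab <- split(sub_res, sub_pos)
    conflict <- names(tab)[vapply(tab, function(x) length(unique(x)) > 1,
                                  logical(1))]
    if (length(conflict) > 0) {
      stop("conflicting substitutions at position(s): ",
           paste(conflict, collapse = ", "))
    }
    chars <- strsplit(seq, "")[[1]]
    chars[as.integer(names(tab))] <- vapply(tab, `[[`, character(1), 1)
    seq <- paste(chars, collapse = "")
  }
  rescanned <- scan_vxpx(seq)
  bad <- intersect(rescanned$start, hits$start)
  if (length(bad) > 0) {
    stop("mutation failed to ablate hit(s) at position(s): ",
         paste(bad, collapse = ", "))
  }
  seq
}
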