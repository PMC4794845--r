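## Degradation-byproduct detection and quantitation: cross-species
## coordinate mapping by global alignment, exact/partial match
## classification under semi-tryptic terminal rules, percent degradation and
## control-normalized ratios, and the MAG/PLP severity proxy.

strip_markers <- function(x) gsub("#", "", x, fixed = TRUE)

#' Map a byproduct peptide onto a target protein
#'
#' Globally aligns the source protein to the target protein
#' (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 0.5) and projects the
#' source peptide's residue span through the alignment: the aligned columns
#' of the span, gaps removed, give the target-coordinate peptide and its
#' 1-based inclusive span. A trailing `#` on the source peptide marks a
#' modified (citrullinated) terminal residue and is carried through as
#' `terminal_mod`.
#'
#' @param source_peptide Peptide string, optionally with `#` markers (e.g.
#'   `"YLATASTMDHAR#"`); must occur in `source_seq` after marker removal.
#' @param source_seq,target_seq Full protein sequences.
#' @param gap_opening,gap_extension Alignment gap penalties.
#' @return A list of class `byproduct`: `source_sequence` (as given),
#'   `source_bare`, `mapped_sequence`, `start`, `end`, `terminal_mod`.
#' @export
#' @examples
#' map_byproduct("PEPTIDE", "AAKPEPTIDERAA", "AAKPEPTIDERAA")
map_byproduct <- function(source_peptide, source_seq, target_seq,
                          gap_opening = 10, gap_extension = 0.5) {
  bare <- strip_markers(source_peptide)
  terminal_mod <- grepl("#$", source_peptide)
  hit <- regexpr(bare, source_seq, fixed = TRUE)
  if (hit == -1L)
    stop("source peptide '", bare, "' not found in source protein")
  s_start <- as.integer(hit); s_end <- s_start + nchar(bare) - 1L
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(source_seq), Biostrings::AAString(target_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  src_pos <- cumsum(ap != "-")   # source residue index at each column
  tgt_pos <- cumsum(as_ != "-")  # target residue index at each column
  cols <- which(ap != "-" & src_pos >= s_start & src_pos <= s_end)
  keep <- cols[as_[cols] != "-"]
  if (!length(keep))
    stop("source peptide aligns entirely to gaps in the target (mapping failure)")
  mapped <- paste(as_[keep], collapse = "")
  structure(list(source_sequence = source_peptide, source_bare = bare,
                 mapped_sequence = mapped,
                 start = tgt_pos[keep[1]], end = tgt_pos[keep[length(keep)]],
                 terminal_mod = terminal_mod),
            class = "byproduct")
}

#' @export
print.byproduct <- function(x, ...) {
  cat(sprintf("byproduct %s -> %s at %d-%d%s\n", x$source_sequence,
              x$mapped_sequence, x$start, x$end,
              if (x$terminal_mod) " (modified terminal residue)" else ""))
  invisible(x)
}

is_tryptic_nterm <- function(prev_aa) prev_aa %in% c("K", "R", "-")
is_tryptic_cterm <- function(peptide, next_aa) {
  last <- substring(peptide, nchar(peptide), nchar(peptide))
  last %in% c("K", "R") | next_aa == "-"
}

## modified terminal Lys/Arg (any annotated mod on a terminal K/R)
has_modified_terminal_kr <- function(peptide, mods) {
  ml <- parse_mods(mods)
  if (!nrow(ml)) return(FALSE)
  plen <- nchar(peptide)
  any(ml$position %in% c(1L, plen) & ml$residue %in% c("K", "R"))
}

#' Classify a PSM against a degradation byproduct
#'
#' `"exact"`: the bare peptide equals the mapped byproduct sequence *and*
#' the peptide is an in-vivo degradation product - it has at least one
#' non-tryptic terminus given its flanking context, or carries a modified
#' (e.g. citrullinated) terminal Lys/Arg; purely tryptic copies produced by
#' sample processing are rejected. `"partial"`: a fully tryptic peptide that
#' strictly contains the mapped sequence. Anything else is `"none"`. The
#' exact and partial classes are mutually exclusive by construction.
#'
#' @param psm A `psm_table` (rows assumed to belong to the target protein).
#' @param byproduct A `byproduct` from [map_byproduct()].
#' @return Character vector, one of `"exact"`, `"partial"`, `"none"` per row.
#' @export
classify_match <- function(psm, byproduct) {
  vapply(seq_len(nrow(psm)), function(i) {
    pep <- psm$peptide[i]
    if (pep == byproduct$mapped_sequence) {
      nontryp <- !is_tryptic_nterm(psm$prev_aa[i]) ||
                 !is_tryptic_cterm(pep, psm$next_aa[i])
      if (nontryp || has_modified_terminal_kr(pep, psm$mods[i]))
        return("exact")
      return("none")
    }
    if (grepl(byproduct$mapped_sequence, pep, fixed = TRUE) &&
        nchar(pep) > nchar(byproduct$mapped_sequence) &&
        is_tryptic_nterm(psm$prev_aa[i]) &&
        is_tryptic_cterm(pep, psm$next_aa[i]))
      return("partial")
    "none"
  }, "")
}

#' Percent degradation and control-normalized degradation ratio
#'
#' Per group, sums the reporter areas of exact and partial matches of the
#' byproduct and computes
#' pct = exact area x 100 / (exact area + partial area); the degradation
#' ratio divides each group's percentage by the reference group's (which is
#' therefore exactly 1). A reference group with no signal yields `NA` ratios
#' with a warning.
#'
#' @param psm A `psm_table` containing the target protein's PSMs.
#' @param byproduct A `byproduct` from [map_byproduct()].
#' @param design A [group_design()].
#' @param protein_acc Optional accession filter.
#' @param min_conf_pct Confidence filter for contributing PSMs.
#' @return Data frame of class `degradation_quant`, one row per group:
#'   `byproduct`, `group`, `exact_area`, `partial_area`, `pct_degradation`,
#'   `ratio_vs_control`.
#' @export
degradation_ratio <- function(psm, byproduct, design = group_design(),
                              protein_acc = NULL, min_conf_pct = 99) {
  psm <- psm[!psm$is_decoy & psm$confidence_pct >= min_conf_pct, ,
             drop = FALSE]
  if (!is.null(protein_acc))
    psm <- psm[psm$protein_acc %in% protein_acc, , drop = FALSE]
  cls <- classify_match(psm, byproduct)
  grps <- unique(design_groups(design))
  rows <- lapply(grps, function(g) {
    a <- psm[[area_column(design, g)]]
    ex <- sum(a[cls == "exact"]); pa <- sum(a[cls == "partial"])
    pct <- if (ex + pa > 0) ex * 100 / (ex + pa) else NA_real_
    data.frame(byproduct = byproduct$source_sequence, group = g,
               exact_area = ex, partial_area = pa, pct_degradation = pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref_pct <- out$pct_degradation[out$group == design$reference_group]
  if (!length(ref_pct) || is.na(ref_pct) || ref_pct == 0) {
    warning("reference group has no usable byproduct signal; ratios undefined")
    out$ratio_vs_control <- NA_real_
  } else {
    out$ratio_vs_control <- out$pct_degradation / ref_pct
  }
  structure(out, class = c("degradation_quant", "data.frame"))
}

#' Severity proxy from two proteins' group ratios
#'
#' Ratio of two proteins' group-vs-reference abundance ratios, by default
#' MAG over PLP: because MAG degrades readily under ischemia while PLP
#' tracks white-matter pathology, a lower value indicates greater
#' white-matter disease severity.
#'
#' @param quant A `protein_quant` table.
#' @param numerator_acc,denominator_acc Protein accessions (e.g. MAG, PLP).
#' @return Named numeric vector, one severity ratio per group.
#' @export
severity_ratio <- function(quant, numerator_acc, denominator_acc) {
  grps <- unique(quant$group)
  vapply(grps, function(g) {
    num <- quant$ratio[quant$protein_acc == numerator_acc & quant$group == g]
    den <- quant$ratio[quant$protein_acc == denominator_acc & quant$group == g]
    if (!length(num) || !length(den))
      stop("protein missing from group '", g, "' (design error)")
    num / den
  }, 0)
}
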