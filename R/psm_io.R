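## PSM table input, validation and identification qualification.

PSM_REQUIRED_COLS <- c("run_id", "peptide", "mods", "protein_acc", "is_decoy",
                       "confidence_pct", "unused_score", "prev_aa", "next_aa")

#' Experimental design of an isobaric-tag run
#'
#' Describes how reporter channels map to pooled sample groups, which runs
#' are replicates, and which group is the ratio denominator. The default
#' mirrors a 4-plex layout in which channel 114 carries the pooled
#' age-matched controls, 116 the female patients and 117 the male patients;
#' channel 115 may be present in the data but unmapped.
#'
#' @param channel_map Named character vector, channel label -> group label.
#' @param replicates Optional character vector of run identifiers; if `NULL`
#'   the runs observed in the data are used.
#' @param reference_group Group used as the denominator of all ratios.
#' @return An object of class `group_design`.
#' @export
#' @examples
#' group_design()
group_design <- function(channel_map = c("114" = "control",
                                         "116" = "female",
                                         "117" = "male"),
                         replicates = NULL,
                         reference_group = "control") {
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stop("channel_map must be a named character vector (channel -> group)")
  if (anyDuplicated(names(channel_map)))
    stop("each channel must map to exactly one group")
  if (!reference_group %in% channel_map)
    stop("reference_group '", reference_group, "' not among mapped groups")
  structure(list(channel_map = channel_map,
                 replicates = replicates,
                 reference_group = reference_group),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat("Group design:", length(x$channel_map), "mapped channels\n")
  for (ch in names(x$channel_map))
    cat(sprintf("  %s -> %s%s\n", ch, x$channel_map[[ch]],
                if (x$channel_map[[ch]] == x$reference_group) " (reference)" else ""))
  invisible(x)
}

design_groups <- function(design) unname(design$channel_map)

## channel label of a group (first match)
group_channel <- function(design, group) {
  ch <- names(design$channel_map)[design$channel_map == group]
  if (!length(ch)) stop("group '", group, "' not present in design")
  ch[[1]]
}

area_column <- function(design, group) paste0("area_", group_channel(design, group))

mapped_area_columns <- function(design) paste0("area_", names(design$channel_map))

#' Identification qualification criteria
#'
#' Thresholds applied to search-engine identifications before quantitation:
#' the decoy-estimated FDR bound (doubling formula), the minimum protein
#' unused score, and the minimum peptide confidence. The defaults are the
#' conventional FDR < 1 %, unused score >= 2 (99 % protein confidence) and
#' peptide confidence >= 99 %.
#'
#' @param max_fdr_pct Upper bound on retained-set FDR, percent.
#' @param min_unused_score Minimum protein-level unused score.
#' @param min_peptide_conf_pct Minimum peptide confidence, percent.
#' @return An object of class `qualification_criteria`.
#' @export
qualification_criteria <- function(max_fdr_pct = 1.0,
                                   min_unused_score = 2.0,
                                   min_peptide_conf_pct = 99.0) {
  if (max_fdr_pct < 0 || min_unused_score < 0 || min_peptide_conf_pct < 0)
    stop("qualification criteria must be non-negative")
  structure(list(max_fdr_pct = max_fdr_pct,
                 min_unused_score = min_unused_score,
                 min_peptide_conf_pct = min_peptide_conf_pct),
            class = "qualification_criteria")
}

#' Parse a modification annotation string
#'
#' Modifications are encoded per PSM as semicolon-separated
#' `position|residue|name` triples, e.g. `"2|Q|Deamidated;12|R|Citrullination"`,
#' with positions 1-based within the peptide.
#'
#' @param mods Character vector of annotation strings ("" = unmodified).
#' @return For [parse_mods()], a data frame with columns `position`,
#'   `residue`, `mod_name` for a single string.
#' @export
parse_mods <- function(mods) {
  stopifnot(length(mods) == 1L)
  if (is.na(mods) || !nzchar(mods))
    return(data.frame(position = integer(), residue = character(),
                      mod_name = character(), stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed mods string: '", mods, "'")
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             residue = vapply(parts, `[`, "", 2L),
             mod_name = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' @rdname parse_mods
#' @param position,residue,mod_name Vectors of equal length describing one
#'   modification per element.
#' @export
format_mods <- function(position, residue, mod_name) {
  if (!length(position)) return("")
  paste(sprintf("%d|%s|%s", as.integer(position), residue, mod_name),
        collapse = ";")
}

## fast vectorized test: does a PSM carry >=1 mod of mod_name?
has_mod <- function(mods, mod_name) {
  grepl(paste0("\\|", mod_name, "(;|$)"), mods)
}

## expand all mods of a psm table into long form with source row index
mod_long <- function(psm) {
  idx <- which(nzchar(psm$mods) & !is.na(psm$mods))
  if (!length(idx))
    return(data.frame(row = integer(), position = integer(),
                      residue = character(), mod_name = character(),
                      stringsAsFactors = FALSE))
  per <- lapply(idx, function(i) cbind(row = i, parse_mods(psm$mods[i])))
  do.call(rbind, per)
}

validate_psm_table <- function(psm, design) {
  miss <- setdiff(PSM_REQUIRED_COLS, names(psm))
  if (length(miss))
    stop("PSM table lacks required column(s): ", paste(miss, collapse = ", "))
  acol <- mapped_area_columns(design)
  miss <- setdiff(acol, names(psm))
  if (length(miss))
    stop("PSM table lacks reporter area column(s) for mapped channel(s): ",
         paste(miss, collapse = ", "), " (design error)")
  if (any(psm$confidence_pct < 0 | psm$confidence_pct > 100, na.rm = TRUE))
    stop("confidence_pct must lie in [0, 100]")
  ml <- mod_long(psm)
  if (nrow(ml)) {
    plen <- nchar(psm$peptide)[ml$row]
    if (any(ml$position < 1L | ml$position > plen))
      stop("modification position outside peptide length")
    obs <- substr(psm$peptide[ml$row], ml$position, ml$position)
    if (any(obs != ml$residue))
      stop("modification residue does not match peptide sequence")
  }
  invisible(psm)
}

#' Read a tab-separated PSM table
#'
#' Reads the package's documented PSM schema: one row per identified
#' peptide-spectrum match with columns `run_id`, `peptide`, `mods`,
#' `protein_acc`, `is_decoy`, `confidence_pct`, `unused_score`, `prev_aa`,
#' `next_aa` and one `area_<channel>` column per reporter channel. Rows with
#' missing or negative reporter areas in any mapped channel are dropped and
#' counted; the count is attached as attribute `n_dropped` and reported via
#' [message()].
#'
#' @param path Path to a TSV file.
#' @param design A [group_design()]; its mapped channels must have matching
#'   area columns in the header.
#' @return A `data.frame` of class `psm_table`.
#' @export
read_psm_table <- function(path, design = group_design()) {
  psm <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  psm$mods[is.na(psm$mods)] <- ""
  psm$run_id <- as.character(psm$run_id)
  psm$is_decoy <- as.logical(psm$is_decoy)
  validate_psm_table(psm, design)
  acol <- mapped_area_columns(design)
  bad <- rowSums(is.na(psm[acol]) | psm[acol] < 0) > 0
  if (any(bad))
    message("read_psm_table: dropped ", sum(bad),
            " row(s) with missing/negative reporter areas")
  psm <- psm[!bad, , drop = FALSE]
  rownames(psm) <- NULL
  structure(psm, n_dropped = sum(bad),
            class = c("psm_table", "data.frame"))
}

#' Write a PSM table in the package TSV schema
#' @param psm A `psm_table` data frame.
#' @param path Output path.
#' @export
write_psm_table <- function(psm, path) {
  utils::write.table(psm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Decoy-estimated false discovery rate
#'
#' Applies the doubling formula FDR = 2.0 x (decoy hits / total hits) x 100
#' to a concatenated target-decoy identification set.
#'
#' @param x A `psm_table` data frame with an `is_decoy` column, or a logical
#'   vector of decoy flags.
#' @return FDR in percent.
#' @export
#' @examples
#' compute_decoy_fdr(c(rep(FALSE, 995), rep(TRUE, 5)))  # 1 %
compute_decoy_fdr <- function(x) {
  dec <- if (is.data.frame(x)) x$is_decoy else x
  if (!length(dec)) stop("cannot compute an FDR from zero identifications")
  2.0 * (sum(dec) / length(dec)) * 100
}

#' Convert an unused protein score to a confidence percentage
#'
#' The unused score is -log10 of the residual error probability, so a score
#' of 2 corresponds to 99 % confidence: conf = (1 - 10^(-score)) x 100.
#'
#' @param score Non-negative score (vectorized).
#' @return Confidence in percent.
#' @export
unused_score_to_confidence <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("unused score must be >= 0")
  (1 - 10^(-score)) * 100
}

#' Apply identification qualification criteria
#'
#' Gates PSMs on the protein unused score and peptide confidence, then
#' enforces the decoy-estimated FDR bound by a monotone sweep: the
#' confidence cutoff is raised through the observed confidence values until
#' the retained set (targets plus decoys) satisfies
#' `compute_decoy_fdr(retained) <= max_fdr_pct`. Decoys are removed from the
#' returned table; the FDR of the retained set *before* decoy removal and
#' the realized confidence cutoff are attached as attributes
#' `retained_fdr_pct` and `confidence_cutoff`.
#'
#' @param psm A `psm_table` data frame.
#' @param criteria A [qualification_criteria()].
#' @return The qualifying non-decoy subset of `psm`, same class, with
#'   attributes `retained_fdr_pct`, `confidence_cutoff` and `n_dropped`
#'   (named count per filter).
#' @export
qualify_identifications <- function(psm, criteria = qualification_criteria()) {
  stopifnot(is.data.frame(psm), nrow(psm) > 0)
  n0 <- nrow(psm)
  keep_score <- psm$unused_score >= criteria$min_unused_score
  psm1 <- psm[keep_score, , drop = FALSE]
  drops <- c(unused_score = n0 - nrow(psm1))

  cutoff <- criteria$min_peptide_conf_pct
  fdr <- NA_real_
  repeat {
    ret <- psm1$confidence_pct >= cutoff
    if (!any(ret)) { cutoff <- NA_real_; break }
    fdr <- compute_decoy_fdr(psm1$is_decoy[ret])
    if (fdr <= criteria$max_fdr_pct) break
    higher <- psm1$confidence_pct[psm1$confidence_pct > cutoff]
    if (!length(higher)) { cutoff <- NA_real_; break }
    cutoff <- min(higher)
  }
  if (is.na(cutoff)) {
    warning("no confidence cutoff satisfies the FDR bound; returning 0 records")
    out <- psm[0, , drop = FALSE]
    fdr <- NA_real_
  } else {
    ret <- psm1[psm1$confidence_pct >= cutoff, , drop = FALSE]
    drops <- c(drops, confidence_fdr = nrow(psm1) - nrow(ret))
    out <- ret[!ret$is_decoy, , drop = FALSE]
    drops <- c(drops, decoy = nrow(ret) - nrow(out))
  }
  rownames(out) <- NULL
  structure(out, retained_fdr_pct = fdr, confidence_cutoff = cutoff,
            n_dropped = drops, class = c("psm_table", "data.frame"))
}

#' Proteins identified in every replicate
#'
#' Returns the accessions of (non-decoy) proteins having at least one
#' qualifying peptide in every replicate run, the replicate-intersection
#' rule under which only proteins confidently identified in all experiments
#' are carried into quantitation.
#'
#' @param psm A `psm_table` data frame (normally after
#'   [qualify_identifications()]).
#' @param design A [group_design()]; if it names `replicates`, those runs
#'   define the requirement, otherwise the runs present in `psm` do.
#' @return Character vector of accessions (possibly empty).
#' @export
intersect_replicates <- function(psm, design = group_design()) {
  runs <- design$replicates
  if (is.null(runs)) runs <- unique(psm$run_id)
  if (!nrow(psm) || !length(runs)) return(character())
  tgt <- psm[!psm$is_decoy, , drop = FALSE]
  tab <- unique(tgt[c("protein_acc", "run_id")])
  cnt <- table(tab$protein_acc[tab$run_id %in% runs])
  sort(names(cnt)[cnt == length(runs)])
}

#' Read protein reference sequences from FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of upper-case sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1L)
  seqs
}
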