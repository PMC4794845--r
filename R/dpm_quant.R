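## Degenerative-protein-modification quantitation: site mapping,
## peptide-level stoichiometry, per-site group comparison (one-way ANOVA +
## Bonferroni), proteome-wide modification rates by spectral counting, and
## modified amino-acid-pair profiles.

#' Map peptide-local modifications to protein coordinates
#'
#' Locates the peptide in the reference sequence (first occurrence if it
#' occurs more than once, with a warning) and converts each modification's
#' 1-based peptide position to a 1-based protein position, checking the
#' reference residue.
#'
#' @param peptide Upper-case peptide string.
#' @param mods Modification annotation string (see [parse_mods()]).
#' @param reference Protein reference sequence.
#' @return Data frame with `position` (protein coordinate), `residue`,
#'   `mod_name`, `peptide_position`; zero rows for an unmodified peptide.
#' @export
map_peptide_mods_to_protein <- function(peptide, mods, reference) {
  hits <- gregexpr(peptide, reference, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("peptide '", peptide, "' not found in reference sequence")
  if (length(hits) > 1L)
    warning("peptide '", peptide, "' occurs ", length(hits),
            " times in reference; using the first occurrence")
  off <- hits[1]
  ml <- parse_mods(mods)
  if (!nrow(ml))
    return(data.frame(position = integer(), residue = character(),
                      mod_name = character(), peptide_position = integer(),
                      stringsAsFactors = FALSE))
  pos <- off + ml$position - 1L
  ref_res <- substring(reference, pos, pos)
  if (any(ref_res != ml$residue))
    stop("modified residue does not match reference at protein position ",
         paste(pos[ref_res != ml$residue], collapse = ", "))
  data.frame(position = pos, residue = ml$residue, mod_name = ml$mod_name,
             peptide_position = ml$position, stringsAsFactors = FALSE)
}

#' Per-site modification areas by group and replicate
#'
#' Accumulates, for every modified residue of every protein with a supplied
#' reference sequence, the reporter area of each group's channel per
#' replicate run. This is the site-resolution table behind site-distribution
#' plots and the input to [site_group_comparison()].
#'
#' @param psm A `psm_table`.
#' @param design A [group_design()].
#' @param references Named character vector of protein sequences (names =
#'   accessions); proteins without a reference are skipped.
#' @param mod_name Optional filter to one modification type.
#' @return Long data frame of class `mod_sites`: `protein_acc`, `position`,
#'   `residue`, `mod_name`, `group`, `run_id`, `area`, aggregated over PSMs.
#' @export
mod_site_table <- function(psm, design = group_design(), references,
                           mod_name = NULL) {
  psm <- psm[!psm$is_decoy & psm$protein_acc %in% names(references), ,
             drop = FALSE]
  grps <- unique(design_groups(design))
  rows <- vector("list", nrow(psm))
  for (i in seq_len(nrow(psm))) {
    if (!nzchar(psm$mods[i])) next
    mp <- map_peptide_mods_to_protein(psm$peptide[i], psm$mods[i],
                                      references[[psm$protein_acc[i]]])
    if (!is.null(mod_name)) mp <- mp[mp$mod_name %in% mod_name, , drop = FALSE]
    if (!nrow(mp)) next
    per_group <- lapply(grps, function(g) {
      data.frame(protein_acc = psm$protein_acc[i], position = mp$position,
                 residue = mp$residue, mod_name = mp$mod_name, group = g,
                 run_id = psm$run_id[i],
                 area = psm[[area_column(design, g)]][i],
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_group)
  }
  long <- do.call(rbind, rows)
  if (is.null(long))
    long <- data.frame(protein_acc = character(), position = integer(),
                       residue = character(), mod_name = character(),
                       group = character(), run_id = character(),
                       area = numeric(), stringsAsFactors = FALSE)
  agg <- stats::aggregate(area ~ protein_acc + position + residue +
                            mod_name + group + run_id,
                          data = long, FUN = sum)
  agg <- agg[order(agg$protein_acc, agg$position, agg$mod_name,
                   agg$group, agg$run_id), ]
  rownames(agg) <- NULL
  structure(agg, class = c("mod_sites", "data.frame"))
}

#' Relative site levels vs the reference group
#'
#' Summed site areas per group divided by the matched site's area in the
#' reference group; sites with no reference-group signal are returned
#' unnormalized with `no_reference = TRUE`.
#'
#' @param sites A `mod_sites` table.
#' @param reference_group Denominator group label.
#' @return Data frame with one row per site x group: `group_area`,
#'   `rel_level`, `no_reference`.
#' @export
site_relative_levels <- function(sites, reference_group = "control") {
  tot <- stats::aggregate(area ~ protein_acc + position + residue +
                            mod_name + group, data = sites, FUN = sum)
  key <- function(d) paste(d$protein_acc, d$position, d$mod_name, sep = "/")
  ref <- tot[tot$group == reference_group, ]
  ref_area <- ref$area[match(key(tot), key(ref))]
  tot$no_reference <- is.na(ref_area) | ref_area == 0
  tot$rel_level <- ifelse(tot$no_reference, NA_real_, tot$area / ref_area)
  names(tot)[names(tot) == "area"] <- "group_area"
  tot
}

#' Peptide-level modification stoichiometry
#'
#' Percent of a protein's distinct identified peptides - distinct meaning
#' unique (sequence, full modification state) pairs - that carry at least
#' one residue bearing `mod_name`. Duplicated PSMs of an already-counted
#' distinct peptide do not change the value.
#'
#' @param psm A `psm_table` (any subset; decoys excluded internally).
#' @param mod_name Modification to count, e.g. `"Deamidated"`.
#' @param protein_acc Optional accession filter; default uses all rows and
#'   reports per protein.
#' @return Data frame of class `stoichiometry_result`: `protein_acc`,
#'   `mod_name`, `n_modified`, `n_total`, `pct_of_peptides`.
#' @export
#' @examples
#' \dontrun{stoichiometry(psm, "Deamidated", "MBPSYN_HUMAN")}
stoichiometry <- function(psm, mod_name, protein_acc = NULL) {
  psm <- psm[!psm$is_decoy, , drop = FALSE]
  if (!is.null(protein_acc))
    psm <- psm[psm$protein_acc %in% protein_acc, , drop = FALSE]
  if (!nrow(psm)) stop("no PSMs for the requested protein(s)")
  ## canonical mod-state key: sorted triples so annotation order is immaterial
  state <- vapply(psm$mods, function(m) {
    ml <- parse_mods(m)
    if (!nrow(ml)) return("")
    paste(sort(sprintf("%d|%s|%s", ml$position, ml$residue, ml$mod_name)),
          collapse = ";")
  }, "", USE.NAMES = FALSE)
  d <- unique(data.frame(protein_acc = psm$protein_acc,
                         peptide = psm$peptide, state = state,
                         stringsAsFactors = FALSE))
  sp <- split(d, d$protein_acc)
  out <- do.call(rbind, lapply(sp, function(x) {
    nm <- sum(has_mod(x$state, mod_name))
    data.frame(protein_acc = x$protein_acc[1], mod_name = mod_name,
               n_modified = nm, n_total = nrow(x),
               pct_of_peptides = 100 * nm / nrow(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("stoichiometry_result", "data.frame"))
}

#' Per-site group comparison by one-way ANOVA with Bonferroni correction
#'
#' For each modification site, compares the replicate reporter areas across
#' groups by one-way ANOVA (F-test). Sites lacking at least 2 groups with at
#' least 2 replicate areas each are excluded (`p_raw = NA`). Raw p-values
#' are Bonferroni-multiplied by the number of sites actually tested, capped
#' at 1. A site with zero variance everywhere has F = 0, p = 1.
#'
#' @param sites A `mod_sites` table from [mod_site_table()].
#' @return Data frame, one row per site: `protein_acc`, `position`,
#'   `residue`, `mod_name`, `f_value`, `p_raw`, `p_bonf`, `tested`.
#' @export
site_group_comparison <- function(sites) {
  keyed <- split(sites, paste(sites$protein_acc, sites$position,
                              sites$mod_name, sep = "/"))
  rows <- lapply(keyed, function(s) {
    base <- data.frame(protein_acc = s$protein_acc[1],
                       position = s$position[1], residue = s$residue[1],
                       mod_name = s$mod_name[1], stringsAsFactors = FALSE)
    reps <- table(s$group)
    if (sum(reps >= 2) < 2) {
      return(cbind(base, f_value = NA_real_, p_raw = NA_real_,
                   tested = FALSE))
    }
    if (stats::var(s$area) == 0)
      return(cbind(base, f_value = 0, p_raw = 1, tested = TRUE))
    fit <- stats::anova(stats::lm(area ~ group, data = s))
    cbind(base, f_value = fit[["F value"]][1], p_raw = fit[["Pr(>F)"]][1],
          tested = TRUE)
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(out$tested)
  out$p_bonf <- ifelse(out$tested, pmin(out$p_raw * n_tested, 1), NA_real_)
  out <- out[order(out$protein_acc, out$position), ]
  rownames(out) <- NULL
  out
}

#' Proteome-wide modification rate and disease association
#'
#' Spectral counting of modified peaks: per group, the percent of PSMs with
#' signal in that group's channel (area > 0) that carry `mod_name`. Disease
#' association is a 2x2 chi-square (no continuity correction, 1 df) of
#' modified vs unmodified counts, pooled disease groups against the
#' reference group. Counts, not areas, drive the result, so it is invariant
#' to uniform scaling of the reporter areas.
#'
#' @param psm A `psm_table` (confidence-filtered upstream as desired).
#' @param design A [group_design()].
#' @param mod_name Modification to count.
#' @param disease_groups Groups pooled against the reference; default all
#'   non-reference groups.
#' @return List of class `dpm_rate` with `rates` (per-group data frame:
#'   `n_psm`, `n_modified`, `pct`), `table` (2x2 counts), `chi_sq`, `df`,
#'   `p_value`.
#' @export
proteome_dpm_rate <- function(psm, design = group_design(), mod_name,
                              disease_groups = NULL) {
  psm <- psm[!psm$is_decoy, , drop = FALSE]
  grps <- unique(design_groups(design))
  if (is.null(disease_groups))
    disease_groups <- setdiff(grps, design$reference_group)
  modded <- has_mod(psm$mods, mod_name)
  per <- lapply(grps, function(g) {
    present <- psm[[area_column(design, g)]] > 0
    if (!any(present)) stop("group '", g, "' has no PSMs with signal (design error)")
    data.frame(group = g, n_psm = sum(present),
               n_modified = sum(present & modded),
               pct = 100 * sum(present & modded) / sum(present),
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, per)
  dis <- rates[rates$group %in% disease_groups, ]
  ref <- rates[rates$group == design$reference_group, ]
  tab <- rbind(disease = c(modified = sum(dis$n_modified),
                           unmodified = sum(dis$n_psm) - sum(dis$n_modified)),
               reference = c(modified = sum(ref$n_modified),
                             unmodified = sum(ref$n_psm) - sum(ref$n_modified)))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(rates = rates, table = tab,
                 chi_sq = unname(chi$statistic), df = unname(chi$parameter),
                 p_value = unname(chi$p.value), mod_name = mod_name),
            class = "dpm_rate")
}

#' @export
print.dpm_rate <- function(x, ...) {
  cat("Proteome-wide", x$mod_name, "rate (spectral counting):\n")
  for (i in seq_len(nrow(x$rates)))
    cat(sprintf("  %-8s %5.2f %% (%d / %d PSMs)\n", x$rates$group[i],
                x$rates$pct[i], x$rates$n_modified[i], x$rates$n_psm[i]))
  cat(sprintf("  chi-square %.3f (%d df), p = %.3g\n",
              x$chi_sq, x$df, x$p_value))
  invisible(x)
}

#' Modified amino-acid-pair profiles
#'
#' For every modified residue, the pair (modified residue, immediate
#' C-terminal neighbor) accumulates the PSM's reporter area per group. The
#' neighbor is taken from within the peptide, or from `next_aa` when the
#' modification sits at the peptide C-terminus (`"-"` marks the protein
#' terminus). Pairs never observed are simply absent from the table; the
#' companion [pair_matrix()] lays observed pairs against the full neighbor
#' alphabet with `NA` for no identification.
#'
#' @param psm A `psm_table`.
#' @param design A [group_design()].
#' @param mod_name Modification to profile.
#' @return Data frame of class `aa_pair_profile`: `mod_name`, `residue`,
#'   `neighbor`, `group`, `area`.
#' @export
aa_pair_profile <- function(psm, design = group_design(), mod_name) {
  psm <- psm[!psm$is_decoy & has_mod(psm$mods, mod_name), , drop = FALSE]
  grps <- unique(design_groups(design))
  rows <- list()
  for (i in seq_len(nrow(psm))) {
    ml <- parse_mods(psm$mods[i])
    ml <- ml[ml$mod_name == mod_name, , drop = FALSE]
    if (!nrow(ml)) next
    plen <- nchar(psm$peptide[i])
    neighbor <- ifelse(ml$position < plen,
                       substring(psm$peptide[i], ml$position + 1,
                                 ml$position + 1),
                       psm$next_aa[i])
    for (g in grps) {
      rows[[length(rows) + 1L]] <- data.frame(
        mod_name = mod_name, residue = ml$residue, neighbor = neighbor,
        group = g, area = psm[[area_column(design, g)]][i],
        stringsAsFactors = FALSE)
    }
  }
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mod_name = character(), residue = character(),
               neighbor = character(), group = character(), area = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(long)) {
    long <- stats::aggregate(area ~ mod_name + residue + neighbor + group,
                             data = long, FUN = sum)
    long <- long[order(long$residue, long$neighbor, long$group), ]
    rownames(long) <- NULL
  }
  structure(long, class = c("aa_pair_profile", "data.frame"))
}

#' @rdname aa_pair_profile
#' @param profile An `aa_pair_profile` table.
#' @param group Group whose areas fill the matrix.
#' @return For [pair_matrix()], a residue x neighbor matrix over the 20
#'   amino acids plus the terminus marker `"-"`, `NA` where a pair was never
#'   identified (heatmap convention: blank = no identification).
#' @export
pair_matrix <- function(profile, group) {
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  res <- sort(unique(profile$residue))
  m <- matrix(NA_real_, length(res), length(alphabet),
              dimnames = list(res, alphabet))
  sub <- profile[profile$group == group, ]
  for (i in seq_len(nrow(sub)))
    m[sub$residue[i], sub$neighbor[i]] <- sub$area[i]
  m
}
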