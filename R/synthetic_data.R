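## Seeded synthetic PSM generator emulating a pooled 3-group, 4-plex
## labelled, triplicate-run experiment, with known ground truth for every
## downstream stage: fold changes, modification rates, degradation states
## and a target-decoy structure.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
## background residue frequencies with K+R ~ 11 % so tryptic peptide
## lengths are plausible
AA_FREQ <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
             I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 4.0,
             R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)

#' Configuration of the synthetic PSM generator
#'
#' Defines the simulated study conditions: a pooled three-group design
#' (control / female / male on channels 114 / 116 / 117), triplicate runs,
#' log-normal reporter areas with multiplicative ratio noise, per-residue
#' modification probabilities, a degradation-state fixture protein and a
#' concatenated target-decoy structure.
#'
#' @param n_proteins Number of simulated target proteins.
#' @param peptides_per_protein Length-2 integer range; each protein
#'   contributes a number of tryptic peptides drawn uniformly from it.
#' @param true_fold_changes Either `NULL` (per protein and group: fold 1
#'   with probability 0.85, fold 2 or 0.5 with probability 0.075 each - a
#'   mostly-null proteome), a named numeric vector (one constant fold per
#'   comparison group), or a matrix (`n_proteins` x comparison groups).
#' @param dpm_rates Named list, modification -> named per-group per-eligible-
#'   residue probabilities. Eligible residues are Asn/Gln for
#'   `"Deamidated"`, Arg for `"Citrullination"`.
#' @param degradation_state Named list, byproduct source peptide (with
#'   optional terminal `#` marker) -> named per-group target percent
#'   degradation of the fixture protein.
#' @param noise_cv Multiplicative log-normal coefficient of variation of
#'   peptide ratios.
#' @param decoy_fraction Fraction of all PSMs that are decoys.
#' @param n_replicates Number of replicate runs.
#' @param seed Integer RNG seed; generation is deterministic given it.
#' @param global_log_bias Systematic log10 offset multiplied into every
#'   comparison-channel area (what [estimate_log_bias()] should recover).
#' @param area_meanlog,area_sdlog Log-normal parameters of base reporter
#'   areas.
#' @param semi_tryptic_frac Fraction of peptides emitted with a truncated
#'   (semi-tryptic) N-terminus.
#' @param mod_area_scale Abundance of a modified species relative to its
#'   unmodified parent peptide.
#' @param include_mbp Include the shipped synthetic MBP fixture protein and
#'   its degradation byproducts.
#' @param mod_neighbor_restrict Optional named list, modification -> allowed
#'   C-terminal neighbor residues; eligible residues with other neighbors
#'   are never modified (useful for pair-profile truth experiments).
#' @param design A [group_design()].
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 60,
                             peptides_per_protein = c(4, 8),
                             true_fold_changes = NULL,
                             dpm_rates = list(
                               Deamidated = c(control = 0.010,
                                              female = 0.014, male = 0.012),
                               Citrullination = c(control = 0.004,
                                                  female = 0.008,
                                                  male = 0.004)),
                             degradation_state = list(
                               "TQDENPVVHF" = c(control = 30, female = 13.5,
                                                male = 27),
                               "YLATASTMDHAR#" = c(control = 30, female = 31,
                                                   male = 29)),
                             noise_cv = 0.15,
                             decoy_fraction = 0.2,
                             n_replicates = 3,
                             seed = 1,
                             global_log_bias = 0,
                             area_meanlog = log(5000),
                             area_sdlog = 0.9,
                             semi_tryptic_frac = 0.08,
                             mod_area_scale = 0.3,
                             include_mbp = TRUE,
                             mod_neighbor_restrict = NULL,
                             design = group_design()) {
  stopifnot(n_proteins >= 1, length(peptides_per_protein) == 2,
            noise_cv >= 0, n_replicates >= 1,
            decoy_fraction >= 0, decoy_fraction < 1,
            semi_tryptic_frac >= 0, semi_tryptic_frac <= 1)
  for (m in names(dpm_rates))
    if (any(dpm_rates[[m]] < 0 | dpm_rates[[m]] > 1))
      stop("dpm_rates must be probabilities in [0, 1]")
  if (!is.null(degradation_state))
    for (b in names(degradation_state))
      if (any(degradation_state[[b]] < 0 | degradation_state[[b]] > 100))
        stop("degradation_state entries are percentages in [0, 100]")
  structure(as.list(environment()), class = "synthetic_config")
}

random_protein_seq <- function(len) {
  paste(sample(AA20, len, replace = TRUE, prob = AA_FREQ[AA20]),
        collapse = "")
}

## tryptic digest with protein coordinates and flanking residues
digest_tryptic <- function(seq, min_len = 6, max_len = 30) {
  res <- strsplit(seq, "")[[1]]
  cut_after <- which(res %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after, length(res)))
  starts <- utils::head(bounds, -1) + 1L
  ends <- utils::tail(bounds, -1)
  len <- ends - starts + 1L
  keep <- len >= min_len & len <= max_len
  data.frame(peptide = substring(seq, starts, ends)[keep],
             start = starts[keep], end = ends[keep],
             prev_aa = ifelse(starts[keep] == 1L, "-",
                              substring(seq, starts[keep] - 1L,
                                        starts[keep] - 1L)),
             next_aa = ifelse(ends[keep] == nchar(seq), "-",
                              substring(seq, ends[keep] + 1L,
                                        ends[keep] + 1L)),
             stringsAsFactors = FALSE)
}

## eligible (position, mod) table for one peptide under the configured
## residue rules and optional neighbor restriction
eligible_mods <- function(peptide, next_aa, dpm_rates, restrict) {
  res <- strsplit(peptide, "")[[1]]
  out <- list()
  rules <- list(Deamidated = c("N", "Q"), Citrullination = "R")
  for (m in names(dpm_rates)) {
    targets <- rules[[m]]
    if (is.null(targets)) next
    pos <- which(res %in% targets)
    if (!is.null(restrict[[m]]) && length(pos)) {
      nb <- ifelse(pos < length(res), res[pos + 1L], next_aa)
      pos <- pos[nb %in% restrict[[m]]]
    }
    if (length(pos))
      out[[m]] <- data.frame(position = pos, residue = res[pos],
                             mod_name = m, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(), residue = character(),
                      mod_name = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

mbp_fixture_sequence <- function() {
  read_protein_fasta(system.file("extdata", "mbp_human_synthetic.fasta",
                                 package = "dpmquant"))[[1]]
}

#' Generate a synthetic PSM table with ground truth
#'
#' Deterministic given `config$seed`. Per replicate run, every simulated
#' protein yields tryptic (and occasional semi-tryptic) peptides from a
#' generated sequence; reference-channel areas are drawn log-normal and the
#' comparison channels are multiplied by the protein's true fold change,
#' the global bias and log-normal noise. Eligible residues acquire
#' modifications at the configured per-group rates, emitted as separate
#' modified PSM species whose channel areas are zero in groups where the
#' draw failed. The fixture MBP-like protein carries the configured
#' degradation byproducts with exact/partial areas set so that, without
#' noise, the realized percent degradation equals `degradation_state`
#' exactly. Decoy PSMs with shuffled sequences, lower confidences and lower
#' unused scores are appended at `decoy_fraction`.
#'
#' @param config A [synthetic_config()].
#' @return List with `psm` (a `psm_table`) and `truth` (list: `proteins`
#'   with per-group true folds, `eligible` with per-protein eligible-residue
#'   counts for closed-form stoichiometry expectations, `dpm_rates`,
#'   `degradation`, `config`).
#' @export
generate_psm_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  design <- config$design
  grps <- unique(design_groups(design))
  cmp_groups <- setdiff(grps, design$reference_group)
  ref_group <- design$reference_group
  runs <- paste0("run", seq_len(config$n_replicates))
  sdln <- sqrt(log(1 + config$noise_cv^2))
  noise <- function(n) if (sdln == 0) rep(1, n) else exp(stats::rnorm(n, 0, sdln))
  bias_mult <- 10^config$global_log_bias

  ## --- fold-change matrix (reference group fixed at 1) ------------------
  fc <- matrix(1, config$n_proteins, length(grps),
               dimnames = list(NULL, grps))
  tf <- config$true_fold_changes
  if (is.null(tf)) {
    for (g in cmp_groups)
      fc[, g] <- sample(c(1, 2, 0.5), config$n_proteins, replace = TRUE,
                        prob = c(0.85, 0.075, 0.075))
  } else if (is.matrix(tf)) {
    fc[, colnames(tf)] <- tf
  } else {
    for (g in names(tf)) fc[, g] <- tf[[g]]
  }

  accs <- sprintf("PROT%04d", seq_len(config$n_proteins))
  seqs <- vapply(sample(150:500, config$n_proteins, replace = TRUE),
                 random_protein_seq, "")
  names(seqs) <- accs

  ## --- select peptides per protein --------------------------------------
  pep_rows <- list()
  for (i in seq_len(config$n_proteins)) {
    dig <- digest_tryptic(seqs[[i]])
    if (!nrow(dig)) next
    npep_range <- seq(config$peptides_per_protein[1],
                      config$peptides_per_protein[2])
    npep <- npep_range[sample.int(length(npep_range), 1)]
    dig <- dig[sample(nrow(dig), min(npep, nrow(dig))), , drop = FALSE]
    ## occasional semi-tryptic N-terminal truncation
    semi <- stats::runif(nrow(dig)) < config$semi_tryptic_frac
    for (j in which(semi)) {
      cut <- sample(1:3, 1)
      if (nchar(dig$peptide[j]) - cut < 6) next
      dig$prev_aa[j] <- substring(dig$peptide[j], cut, cut)
      dig$peptide[j] <- substring(dig$peptide[j], cut + 1)
      dig$start[j] <- dig$start[j] + cut
    }
    dig$protein_acc <- accs[i]
    dig$fold_idx <- i
    pep_rows[[i]] <- dig
  }
  peps <- do.call(rbind, pep_rows)

  ## --- MBP fixture -------------------------------------------------------
  mbp_acc <- "MBPSYN_HUMAN"
  byproducts <- list()
  if (config$include_mbp) {
    mseq <- mbp_fixture_sequence()
    for (bp in names(config$degradation_state)) {
      bare <- strip_markers(bp)
      pos <- regexpr(bare, mseq, fixed = TRUE)
      if (pos == -1L)
        stop("degradation_state byproduct '", bare,
             "' not present in the fixture sequence (config error)")
      ## enclosing fully tryptic peptide = partial match
      dig <- digest_tryptic(mseq, min_len = 2, max_len = 100)
      span <- c(pos, pos + nchar(bare) - 1L)
      enc <- dig[dig$start <= span[1] & dig$end >= span[2] &
                   nchar(dig$peptide) > nchar(bare), , drop = FALSE]
      if (!nrow(enc))
        stop("no enclosing tryptic peptide for byproduct '", bare,
             "' (config error)")
      byproducts[[bp]] <- list(
        bare = bare, start = span[1], end = span[2],
        prev_aa = if (span[1] == 1) "-" else substring(mseq, span[1] - 1, span[1] - 1),
        next_aa = if (span[2] == nchar(mseq)) "-" else substring(mseq, span[2] + 1, span[2] + 1),
        terminal_mod = grepl("#$", bp),
        partial = enc[1, ])
    }
    mdig <- digest_tryptic(mseq)
    ## keep the byproduct regions free of ordinary digest signal so the
    ## configured degradation state is realized exactly
    for (b in byproducts)
      mdig <- mdig[mdig$end < b$start | mdig$start > b$partial$end, ,
                   drop = FALSE]
    if (nrow(mdig)) {
      mdig$protein_acc <- mbp_acc
      mdig$fold_idx <- NA_integer_  # fold 1 in every group
      peps <- rbind(peps, mdig)
      seqs[mbp_acc] <- mseq
    }
  }

  ## --- base PSMs: one per peptide per run --------------------------------
  n_pep <- nrow(peps)
  psm <- do.call(rbind, lapply(runs, function(r) {
    base <- stats::rlnorm(n_pep, config$area_meanlog, config$area_sdlog)
    d <- data.frame(run_id = r, peptide = peps$peptide, mods = "",
                    protein_acc = peps$protein_acc, is_decoy = FALSE,
                    confidence_pct = unused_score_to_confidence(
                      2 + stats::rexp(n_pep, 0.8)),
                    unused_score = NA_real_,
                    stringsAsFactors = FALSE)
    d$area_114 <- NA_real_; d$area_115 <- 0
    d$area_116 <- NA_real_; d$area_117 <- NA_real_
    d[[area_column(design, ref_group)]] <- base
    for (g in cmp_groups) {
      f <- ifelse(is.na(peps$fold_idx), 1, fc[pmax(peps$fold_idx, 1), g])
      d[[area_column(design, g)]] <- base * f * bias_mult * noise(n_pep)
    }
    d$prev_aa <- peps$prev_aa; d$next_aa <- peps$next_aa
    d$.base <- base
    d
  }))

  ## --- modified species --------------------------------------------------
  mod_rows <- list()
  rates <- config$dpm_rates
  if (length(rates)) {
    elig <- lapply(seq_len(n_pep), function(j)
      eligible_mods(peps$peptide[j], peps$next_aa[j], rates,
                    config$mod_neighbor_restrict))
    for (ri in seq_along(runs)) {
      off <- (ri - 1L) * n_pep
      for (j in seq_len(n_pep)) {
        em <- elig[[j]]
        if (!nrow(em)) next
        parent <- psm[off + j, ]
        for (k in seq_len(nrow(em))) {
          rk <- rates[[em$mod_name[k]]]
          hit <- stats::runif(length(grps)) < rk[grps]
          names(hit) <- grps
          if (!any(hit)) next
          row <- parent
          row$mods <- format_mods(em$position[k], em$residue[k],
                                  em$mod_name[k])
          mb <- parent$.base * config$mod_area_scale
          row[[area_column(design, ref_group)]] <-
            if (hit[[ref_group]]) mb else 0
          for (g in cmp_groups) {
            f <- if (is.na(peps$fold_idx[j])) 1 else fc[peps$fold_idx[j], g]
            row[[area_column(design, g)]] <-
              if (hit[[g]]) mb * f * bias_mult * noise(1) else 0
          }
          mod_rows[[length(mod_rows) + 1L]] <- row
        }
      }
    }
  }
  if (length(mod_rows)) psm <- rbind(psm, do.call(rbind, mod_rows))

  ## --- degradation byproduct PSMs ---------------------------------------
  bp_total <- 20000
  if (length(byproducts)) {
    for (bp in names(byproducts)) {
      b <- byproducts[[bp]]
      d_pct <- config$degradation_state[[bp]]
      for (r in runs) {
        tmpl <- data.frame(run_id = r, peptide = b$bare, mods = "",
                           protein_acc = mbp_acc, is_decoy = FALSE,
                           confidence_pct = unused_score_to_confidence(
                             6 + stats::rexp(1, 1)),
                           unused_score = NA_real_,
                           area_114 = 0, area_115 = 0, area_116 = 0,
                           area_117 = 0, prev_aa = b$prev_aa,
                           next_aa = b$next_aa, .base = bp_total,
                           stringsAsFactors = FALSE)
        exact <- tmpl
        if (b$terminal_mod)
          exact$mods <- format_mods(nchar(b$bare),
                                    substring(b$bare, nchar(b$bare)),
                                    "Citrullination")
        partial <- tmpl
        partial$peptide <- b$partial$peptide
        partial$prev_aa <- b$partial$prev_aa
        partial$next_aa <- b$partial$next_aa
        for (g in grps) {
          dg <- d_pct[[g]]
          exact[[area_column(design, g)]] <- bp_total * dg / 100 * noise(1)
          partial[[area_column(design, g)]] <-
            bp_total * (1 - dg / 100) * noise(1)
        }
        psm <- rbind(psm, exact, partial)
      }
    }
  }

  ## protein-level unused scores (decoys handled below)
  uscore <- stats::setNames(2 + stats::rexp(length(seqs), 0.5), names(seqs))
  psm$unused_score <- uscore[psm$protein_acc]

  ## --- decoys ------------------------------------------------------------
  f <- config$decoy_fraction
  n_target <- nrow(psm)
  n_decoy <- round(f / (1 - f) * n_target)
  if (n_decoy > 0) {
    src <- sample(n_target, n_decoy, replace = TRUE)
    dec <- psm[src, , drop = FALSE]
    dec$peptide <- vapply(dec$peptide, function(p)
      paste(sample(strsplit(p, "")[[1]]), collapse = ""), "")
    dec$mods <- ""
    dec$protein_acc <- paste0("DECOY_", dec$protein_acc)
    dec$is_decoy <- TRUE
    ## mostly low-confidence decoys plus a thin high-scoring component with
    ## a faster-decaying tail than the targets, so the FDR sweep has work
    ## to do but always converges
    hi <- stats::runif(n_decoy) < 0.15
    dec_score <- ifelse(hi, 2 + stats::rexp(n_decoy, 2.5),
                        stats::rexp(n_decoy, 3))
    dec$confidence_pct <- unused_score_to_confidence(dec_score)
    dec$unused_score <- stats::rexp(n_decoy, 0.7)
    psm <- rbind(psm, dec)
  }
  psm$.base <- NULL
  rownames(psm) <- NULL
  psm <- structure(psm, class = c("psm_table", "data.frame"))

  ## --- ground truth ------------------------------------------------------
  truth_prot <- do.call(rbind, lapply(cmp_groups, function(g)
    data.frame(protein_acc = accs, group = g, true_fold = fc[, g],
               stringsAsFactors = FALSE)))
  elig_cnt <- do.call(rbind, lapply(names(rates), function(m) {
    k <- vapply(seq_len(n_pep), function(j)
      nrow(eligible_mods(peps$peptide[j], peps$next_aa[j], rates[m],
                         config$mod_neighbor_restrict)), 0L)
    data.frame(protein_acc = peps$protein_acc, peptide = peps$peptide,
               mod_name = m, n_eligible = k, stringsAsFactors = FALSE)
  }))
  degr <- if (length(byproducts)) {
    do.call(rbind, lapply(names(byproducts), function(bp)
      data.frame(byproduct = bp, group = grps,
                 true_pct = unname(config$degradation_state[[bp]][grps]),
                 stringsAsFactors = FALSE)))
  } else NULL
  list(psm = psm,
       truth = list(proteins = truth_prot, eligible = elig_cnt,
                    dpm_rates = rates, degradation = degr,
                    references = seqs, config = config))
}

#' Compare pipeline output with generator ground truth
#'
#' Scores regulation calls against the simulated fold changes (using the
#' same ratio cutoffs as the calls), and optionally degradation ratios
#' against the configured degradation states.
#'
#' @param calls A `regulation_calls` table from [call_regulation()].
#' @param truth The `truth` element of [generate_psm_data()] output.
#' @param degradation Optional `degradation_quant` table to score against
#'   the configured degradation states.
#' @param up_cut Ratio threshold defining the true labels (down is
#'   round(1/up_cut, 2)).
#' @return List of class `truth_comparison`: per-group confusion matrices
#'   (true label x called label for modulated calls), `sensitivity_up`,
#'   `sensitivity_down`, `false_positive_rate`, and `degradation_error`
#'   (mean absolute ratio error) when supplied.
#' @export
truth_compare <- function(calls, truth, degradation = NULL, up_cut = 1.5) {
  down_cut <- round(1 / up_cut, 2)
  groups <- unique(truth$proteins$group)
  common <- intersect(calls$protein_acc, unique(truth$proteins$protein_acc))
  if (!length(common))
    stop("calls and truth share no proteins; mismatched runs (design error)")
  out <- list()
  for (g in groups) {
    tg <- truth$proteins[truth$proteins$group == g, ]
    tg <- tg[match(common, tg$protein_acc), ]
    true_lab <- ifelse(tg$true_fold > up_cut, "up",
                ifelse(tg$true_fold < down_cut, "down", "unchanged"))
    call_col <- paste0(g, "_call"); mod_col <- paste0(g, "_modulated")
    if (!call_col %in% names(calls)) next
    idx <- match(common, calls$protein_acc)
    called <- ifelse(calls[[mod_col]][idx], calls[[call_col]][idx],
                     "unchanged")
    lv <- c("up", "down", "unchanged")
    out[[g]] <- list(
      confusion = table(true = factor(true_lab, lv),
                        called = factor(called, lv)),
      sensitivity_up = if (any(true_lab == "up"))
        mean(called[true_lab == "up"] == "up") else NA_real_,
      sensitivity_down = if (any(true_lab == "down"))
        mean(called[true_lab == "down"] == "down") else NA_real_,
      false_positive_rate = if (any(true_lab == "unchanged"))
        mean(called[true_lab == "unchanged"] != "unchanged") else NA_real_)
  }
  if (!is.null(degradation) && !is.null(truth$degradation)) {
    td <- truth$degradation
    ref <- unique(degradation$group[
      abs(degradation$ratio_vs_control - 1) < 1e-12])
    err <- merge(degradation, td,
                 by.x = c("byproduct", "group"),
                 by.y = c("byproduct", "group"))
    ctrl_pct <- td$true_pct[match(err$byproduct, td$byproduct)]
    ## true ratio = group pct / control pct
    tc <- td[td$group == "control", ]
    true_ratio <- err$true_pct / tc$true_pct[match(err$byproduct, tc$byproduct)]
    out$degradation_error <- mean(abs(err$ratio_vs_control - true_ratio),
                                  na.rm = TRUE)
  }
  structure(out, class = "truth_comparison")
}

#' @export
print.truth_comparison <- function(x, ...) {
  for (g in setdiff(names(x), "degradation_error")) {
    cat("Group", g, ": sensitivity(up) =",
        format(x[[g]]$sensitivity_up, digits = 3),
        " sensitivity(down) =", format(x[[g]]$sensitivity_down, digits = 3),
        " FPR =", format(x[[g]]$false_positive_rate, digits = 3), "\n")
    print(x[[g]]$confusion)
  }
  if (!is.null(x$degradation_error))
    cat("Mean |degradation ratio error| =",
        format(x$degradation_error, digits = 3), "\n")
  invisible(x)
}
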