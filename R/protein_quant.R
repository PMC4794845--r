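## Protein-level relative quantitation and differential-expression inference:
## weighted log-ratio statistics (error factor, Student t), area-based
## G-tests with Benjamini-Hochberg correction, %CV profiles and
## regulation / gender-difference calls.

#' Global log-ratio bias
#'
#' The systematic offset of an experiment's peptide log10 ratios, estimated
#' as their median, under the usual assumption that the bulk of proteins are
#' unchanged so the ratio distribution should center at 1.
#'
#' @param log_ratios Numeric vector of peptide log10 ratios.
#' @return The median (log10 units).
#' @export
estimate_log_bias <- function(log_ratios) {
  log_ratios <- log_ratios[is.finite(log_ratios)]
  if (!length(log_ratios)) stop("no finite log ratios supplied")
  stats::median(log_ratios)
}

#' Weighted protein log-ratio statistics
#'
#' Aggregates peptide-level reporter ratios into a protein-level weighted
#' average of log10 ratios with its weighted standard deviation S_MW, the
#' Student statistic t = (weighted mean - log_bias) / S_MW referred to
#' n - 1 degrees of freedom, and the multiplicative 95 % uncertainty bound
#' Error factor = 10^(S_MW x t_crit(0.975, n - 1)).
#'
#' With a single contributing peptide the dispersion-based quantities are
#' undefined and returned as `NA`. When all peptide ratios coincide
#' (S_MW = 0), t is 0 (p = 1) at the null and +/-Inf (p = 0) otherwise.
#'
#' @param group_areas,ref_areas Positive reporter areas of each peptide in
#'   the comparison and reference channels.
#' @param weights Peptide weights; default is the summed area of the two
#'   channels, a precision proxy.
#' @param log_bias Systematic log10 offset subtracted in the t statistic
#'   (see [estimate_log_bias()]).
#' @return A list of class `ratio_stats` with elements `weighted_log_ratio`,
#'   `ratio`, `s_mw`, `n_peptides`, `t_stat`, `p_value`, `error_factor`.
#' @export
#' @examples
#' protein_log_ratio(c(200, 210, 190), c(100, 100, 100))
protein_log_ratio <- function(group_areas, ref_areas,
                              weights = group_areas + ref_areas,
                              log_bias = 0) {
  if (any(group_areas <= 0) || any(ref_areas <= 0))
    stop("reporter areas must be positive for ratio estimation")
  if (any(weights <= 0)) stop("weights must be positive")
  r <- log10(group_areas / ref_areas)
  n <- length(r)
  w <- weights / sum(weights)
  m <- sum(w * r)
  if (n == 1L) {
    s <- t_stat <- p <- ef <- NA_real_
  } else {
    s <- sqrt(sum(w * (r - m)^2) * n / (n - 1))
    if (s == 0) {
      t_stat <- if (m == log_bias) 0 else sign(m - log_bias) * Inf
      p <- if (t_stat == 0) 1 else 0
    } else {
      t_stat <- (m - log_bias) / s
      p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    }
    ef <- 10^(s * stats::qt(0.975, df = n - 1))
  }
  structure(list(weighted_log_ratio = m, ratio = 10^m, s_mw = s,
                 n_peptides = n, t_stat = t_stat, p_value = p,
                 error_factor = ef),
            class = "ratio_stats")
}

#' @export
print.ratio_stats <- function(x, ...) {
  cat(sprintf("ratio %.4g (log10 %.4g, n = %d peptides)\n",
              x$ratio, x$weighted_log_ratio, x$n_peptides))
  cat(sprintf("  S_MW %.4g  t %.4g  p %.4g  error factor %.4g\n",
              x$s_mw, x$t_stat, x$p_value, x$error_factor))
  invisible(x)
}

## 0 * ln 0 -> 0 convention
xlnx_ratio <- function(x, e) ifelse(x == 0, 0, x * log(x / e))

#' Two-cell G-test on summed reporter areas
#'
#' Likelihood-ratio statistic comparing a protein's summed reporter area in
#' the reference (control) group against a disease group:
#' G = 2 (Ctrl_A ln\[Ctrl_A / m\] + Dem_A ln\[Dem_A / m\]) with
#' m = (Ctrl_A + Dem_A) / 2, referred to the chi-square distribution with
#' one degree of freedom (upper tail, no continuity correction). The
#' convention 0 ln 0 = 0 applies when one area is zero.
#'
#' @param ctrl_area,dem_area Non-negative areas (vectorized; not both zero).
#' @return A data frame of class `g_test_result` with columns `ctrl_area`,
#'   `dem_area`, `g_value`, `p_raw`.
#' @export
#' @examples
#' g_test(100, 300)  # G ~ 104.65
g_test <- function(ctrl_area, dem_area) {
  if (any(ctrl_area < 0) || any(dem_area < 0))
    stop("areas must be non-negative")
  if (any(ctrl_area == 0 & dem_area == 0))
    stop("G-test undefined when both areas are zero")
  m <- (ctrl_area + dem_area) / 2
  g <- 2 * (xlnx_ratio(ctrl_area, m) + xlnx_ratio(dem_area, m))
  g <- pmax(g, 0)  # guard tiny negative round-off at the null
  structure(data.frame(ctrl_area = ctrl_area, dem_area = dem_area,
                       g_value = g,
                       p_raw = stats::pchisq(g, df = 1, lower.tail = FALSE)),
            class = c("g_test_result", "data.frame"))
}

#' Benjamini-Hochberg correction with a data-driven threshold
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) together with the
#' largest raw p-value still declared significant at level `alpha` - the
#' dataset's realized significance threshold (e.g. a corrected cutoff such
#' as 0.014 arises this way).
#'
#' @param p Raw p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return List with `p_adjusted`, `threshold` (largest significant raw p,
#'   `NA` if no discovery) and `n_signif`.
#' @export
#' @examples
#' bh_correct(c(0.01, 0.02, 0.04, 0.8))
bh_correct <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(adj) & adj <= alpha
  list(p_adjusted = adj,
       threshold = if (any(sig)) max(p[sig]) else NA_real_,
       n_signif = sum(sig))
}

#' Replicate-to-replicate ratio variability
#'
#' Percent coefficient of variation (100 x SD / mean) of each protein's
#' per-replicate ratios, plus the empirical fraction of proteins whose %CV
#' falls under any cutoff (attribute `fraction_under`, a function).
#'
#' @param ratios Data frame with columns `protein_acc`, `run_id`, `ratio`
#'   (one row per protein x replicate; extra columns ignored).
#' @return Data frame with `protein_acc`, `n_reps`, `cv_pct` (`NA` when the
#'   mean is 0 or fewer than 2 replicates are available).
#' @export
ratio_cv_profile <- function(ratios) {
  stopifnot(all(c("protein_acc", "ratio") %in% names(ratios)))
  sp <- split(ratios$ratio, ratios$protein_acc)
  cv <- vapply(sp, function(x) {
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    100 * stats::sd(x) / mean(x)
  }, 0)
  out <- data.frame(protein_acc = names(sp),
                    n_reps = lengths(sp),
                    cv_pct = unname(cv),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fraction_under") <- function(cut) mean(out$cv_pct < cut, na.rm = TRUE)
  out
}

#' Protein-level quantitation across groups
#'
#' The central aggregation step. For every (protein, comparison group):
#' peptide log10 ratios are formed from PSMs with positive areas in both the
#' group and reference channels, normalized by the per-run median log ratio
#' (the log bias), and combined by [protein_log_ratio()]; summed reporter
#' areas (rounded to integer, treating areas as counts) feed [g_test()] with
#' BH correction across proteins within the group; per-replicate protein
#' ratios give the %CV profile.
#'
#' @param psm A qualified `psm_table`.
#' @param design A [group_design()].
#' @param min_conf_pct Peptides below this confidence are excluded from
#'   quantitation (the >= 99 % contributor rule).
#' @param alpha FDR level for the BH correction of G-test p-values.
#' @param bias_correct Subtract the per-run median peptide log ratio before
#'   aggregation (default TRUE).
#' @return Data frame of class `protein_quant`, one row per protein x group,
#'   with columns `protein_acc`, `group`, `n_peptides`, `weighted_log_ratio`,
#'   `ratio`, `s_mw`, `t_stat`, `p_value`, `error_factor`, `ctrl_area`,
#'   `dem_area`, `g_value`, `p_raw`, `p_bh`, `cv_pct`. Attributes:
#'   `bh_threshold` (named per group), `log_bias` (named per run x group).
#' @export
quantify_proteins <- function(psm, design = group_design(),
                              min_conf_pct = 99, alpha = 0.05,
                              bias_correct = TRUE) {
  stopifnot(is.data.frame(psm))
  psm <- psm[!psm$is_decoy & psm$confidence_pct >= min_conf_pct, , drop = FALSE]
  if (!nrow(psm)) stop("no qualifying PSMs to quantify")
  ref_col <- area_column(design, design$reference_group)
  cmp_groups <- setdiff(unique(design_groups(design)), design$reference_group)

  res <- list(); biases <- c()
  for (grp in cmp_groups) {
    gcol <- area_column(design, grp)
    ok <- psm[[gcol]] > 0 & psm[[ref_col]] > 0
    d <- psm[ok, , drop = FALSE]
    if (!nrow(d)) next
    lr <- log10(d[[gcol]] / d[[ref_col]])
    ## per-run global normalization
    bias <- tapply(lr, d$run_id, stats::median)
    if (bias_correct) lr <- lr - bias[d$run_id]
    biases[paste(grp, names(bias), sep = ":")] <- bias
    w <- d[[gcol]] + d[[ref_col]]

    accs <- sort(unique(d$protein_acc))
    rows <- lapply(accs, function(acc) {
      i <- d$protein_acc == acc
      rs <- protein_log_ratio(10^lr[i], rep(1, sum(i)), weights = w[i],
                              log_bias = 0)
      ## per-replicate protein ratios for the %CV profile
      rep_r <- tapply(seq_len(sum(i)), d$run_id[i], function(j) {
        jj <- which(i)[j]
        10^(sum(w[jj] * lr[jj]) / sum(w[jj]))
      })
      cv <- if (length(rep_r) >= 2 && mean(rep_r) != 0)
        100 * stats::sd(rep_r) / mean(rep_r) else NA_real_
      data.frame(protein_acc = acc, group = grp,
                 n_peptides = rs$n_peptides,
                 weighted_log_ratio = rs$weighted_log_ratio,
                 ratio = rs$ratio, s_mw = rs$s_mw, t_stat = rs$t_stat,
                 p_value = rs$p_value, error_factor = rs$error_factor,
                 ctrl_area = round(sum(d[[ref_col]][i])),
                 dem_area = round(sum(d[[gcol]][i])),
                 cv_pct = cv, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    gt <- g_test(tab$ctrl_area, tab$dem_area)
    tab$g_value <- gt$g_value
    tab$p_raw <- gt$p_raw
    bh <- bh_correct(tab$p_raw, alpha = alpha)
    tab$p_bh <- bh$p_adjusted
    attr(tab, "bh_threshold") <- bh$threshold
    res[[grp]] <- tab
  }
  if (!length(res)) stop("no comparison group had quantifiable PSMs")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out,
            bh_threshold = vapply(res, attr, 0, "bh_threshold"),
            log_bias = biases, alpha = alpha,
            class = c("protein_quant", "data.frame"))
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("Protein quantitation:", length(unique(x$protein_acc)), "proteins x",
      length(unique(x$group)), "group(s)\n")
  thr <- attr(x, "bh_threshold")
  for (g in names(thr))
    cat(sprintf("  %s: BH threshold (raw p) %.4g\n", g, thr[[g]]))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Regulation and gender-difference calls
#'
#' Classifies each protein per comparison group as up- (ratio > `up_cut`),
#' down- (ratio < round(1/`up_cut`, 2), i.e. 0.67 at the default 1.5) or
#' unchanged, and reports it as *modulated* only when the BH-corrected
#' G-test p-value also clears `alpha`. Proteins quantified in both the
#' female and male groups get a gender difference |female - male| of the
#' ratios, a female/male quotient, a differential flag at `diff_cut`
#' (>= 0.2) and a significance tier: `"p<0.05 & diff>=0.2"` or the stronger
#' `"p<0.001 & diff>=0.9"`.
#'
#' @param quant A `protein_quant` table from [quantify_proteins()] covering
#'   both groups in `groups`.
#' @param up_cut Up-regulation ratio threshold (down is round(1/up_cut, 2)).
#' @param alpha Significance level on BH-corrected G-test p-values.
#' @param diff_cut Gender-difference call threshold on |female - male|.
#' @param strong_p,strong_diff Thresholds of the stronger significance tier.
#' @param groups Character vector of length 2: the two compared groups.
#' @return Data frame of class `regulation_calls`, one row per protein, with
#'   per-group ratio/call/modulated columns, `gender_difference`,
#'   `gender_quotient`, `is_gender_differential`, `significance_tier`.
#' @export
call_regulation <- function(quant, up_cut = 1.5, alpha = 0.05,
                            diff_cut = 0.2, strong_p = 0.001,
                            strong_diff = 0.9,
                            groups = c("female", "male")) {
  stopifnot(length(groups) == 2)
  down_cut <- round(1 / up_cut, 2)
  g1 <- quant[quant$group == groups[1], , drop = FALSE]
  g2 <- quant[quant$group == groups[2], , drop = FALSE]
  if (!nrow(g1) || !nrow(g2))
    stop("both groups must be present in the quantitation table (design error)")
  accs <- intersect(g1$protein_acc, g2$protein_acc)
  i1 <- match(accs, g1$protein_acc); i2 <- match(accs, g2$protein_acc)
  classify <- function(r) ifelse(r > up_cut, "up",
                          ifelse(r < down_cut, "down", "unchanged"))
  r1 <- g1$ratio[i1]; r2 <- g2$ratio[i2]
  c1 <- classify(r1); c2 <- classify(r2)
  m1 <- c1 != "unchanged" & g1$p_bh[i1] <= alpha
  m2 <- c2 != "unchanged" & g2$p_bh[i2] <= alpha
  diff <- abs(r1 - r2)
  p_min <- pmin(g1$p_bh[i1], g2$p_bh[i2])
  tier <- ifelse(p_min < strong_p & diff >= strong_diff,
                 sprintf("p<%.3g & diff>=%.2g", strong_p, strong_diff),
          ifelse(p_min < alpha & diff >= diff_cut,
                 sprintf("p<%.3g & diff>=%.2g", alpha, diff_cut), "none"))
  out <- data.frame(protein_acc = accs,
                    stringsAsFactors = FALSE)
  out[[paste0(groups[1], "_ratio")]] <- r1
  out[[paste0(groups[2], "_ratio")]] <- r2
  out[[paste0(groups[1], "_call")]] <- c1
  out[[paste0(groups[2], "_call")]] <- c2
  out[[paste0(groups[1], "_modulated")]] <- m1
  out[[paste0(groups[2], "_modulated")]] <- m2
  out$is_modulated <- m1 | m2
  out$gender_difference <- diff
  out$gender_quotient <- r1 / r2
  out$is_gender_differential <- diff >= diff_cut
  out$significance_tier <- tier
  structure(out, up_cut = up_cut, down_cut = down_cut, alpha = alpha,
            class = c("regulation_calls", "data.frame"))
}

#' @export
print.regulation_calls <- function(x, ...) {
  cat("Regulation calls:", nrow(x), "proteins;",
      sum(x$is_modulated), "modulated;",
      sum(x$is_gender_differential), "gender-differential\n")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 3)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Heatmap-ready log-ratio matrix
#'
#' Proteins x groups matrix of log10 ratios with the reference column fixed
#' at 0 (ratio 1), the tabular form behind enrichment/depletion heatmaps.
#'
#' @param quant A `protein_quant` table.
#' @param design A [group_design()].
#' @return Numeric matrix, rownames = accessions.
#' @export
ratio_matrix <- function(quant, design = group_design()) {
  accs <- sort(unique(quant$protein_acc))
  grps <- unique(design_groups(design))
  m <- matrix(NA_real_, length(accs), length(grps),
              dimnames = list(accs, grps))
  m[, design$reference_group] <- 0
  for (g in setdiff(grps, design$reference_group)) {
    sub <- quant[quant$group == g, ]
    m[sub$protein_acc, g] <- sub$weighted_log_ratio
  }
  m
}
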