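test_that("weighted protein log-ratio statistics behave at the null and on the worked example", {
  ## all peptide ratios exactly 1: log ratio 0, t = 0, p = 1
  rs <- protein_log_ratio(c(100, 200, 50), c(100, 200, 50))
  expect_equal(rs$weighted_log_ratio, 0)
  expect_equal(rs$ratio, 1)
  expect_equal(rs$t_stat, 0)
  expect_equal(rs$p_value, 1)

  ## four equally-weighted peptides with log ratios {0.30, 0.28, 0.32, 0.30}
  ## (frozen hand-computed oracle: m = 0.30, S = 0.016329932,
  ##  t = 18.371173, p = 3.5192e-4, EF = 1.1271173)
  x <- c(0.30, 0.28, 0.32, 0.30)
  rs <- protein_log_ratio(10^x, rep(1, 4), weights = rep(1, 4))
  expect_equal(rs$weighted_log_ratio, 0.30)
  expect_equal(rs$s_mw, 0.0163299316186, tolerance = 1e-10)
  expect_equal(rs$t_stat, 18.3711730709, tolerance = 1e-9)
  expect_equal(rs$p_value, 0.000351922396968, tolerance = 1e-9)
  expect_equal(rs$error_factor, 1.12711733834, tolerance = 1e-9)
  expect_lt(rs$p_value, 0.05)
  expect_gte(rs$error_factor, 1)

  ## single peptide: ratio reported, dispersion-based quantities undefined
  rs1 <- protein_log_ratio(300, 100)
  expect_equal(rs1$ratio, 3)
  expect_true(is.na(rs1$p_value) && is.na(rs1$error_factor))

  expect_error(protein_log_ratio(c(100, 0), c(100, 100)), "positive")
})

test_that("log bias is the median peptide log ratio and is recovered from simulated data", {
  expect_equal(estimate_log_bias(c(-0.3, -0.1, 0, 0.1, 0.3)), 0)
  expect_equal(estimate_log_bias(rep(0.3, 5)), 0.3)
  expect_error(estimate_log_bias(numeric()), "no finite")

  ## generator with ~10 % true changes and a known systematic offset
  sim <- generate_psm_data(synthetic_config(
    seed = 31, n_proteins = 80, decoy_fraction = 0, dpm_rates = list(),
    include_mbp = FALSE, global_log_bias = 0.05))
  psm <- sim$psm
  ok <- psm$area_116 > 0 & psm$area_114 > 0
  bias <- estimate_log_bias(log10(psm$area_116[ok] / psm$area_114[ok]))
  expect_lt(abs(bias - 0.05), 0.02)
})

test_that("the two-cell G statistic matches its closed forms and limits", {
  g0 <- g_test(100, 100)
  expect_equal(g0$g_value, 0)
  expect_equal(g0$p_raw, 1)

  g1 <- g_test(100, 300)
  expect_equal(g1$g_value, 104.649628753, tolerance = 1e-9)

  ## 0 * ln 0 convention
  g2 <- g_test(0, 50)
  expect_equal(g2$g_value, 2 * 50 * log(2))

  expect_error(g_test(0, 0), "both areas are zero")
  expect_error(g_test(-1, 10), "non-negative")
})

test_that("BH correction reproduces the step-up oracle and reports the data-driven threshold", {
  ## frozen hand-computed step-up example
  res <- bh_correct(c(0.01, 0.02, 0.04, 0.8), alpha = 0.05)
  expect_equal(res$p_adjusted, c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_equal(res$threshold, 0.02)
  expect_equal(res$n_signif, 2)

  ## m = 1
  res1 <- bh_correct(0.03, alpha = 0.05)
  expect_equal(res1$p_adjusted, 0.03)
  expect_equal(res1$threshold, 0.03)

  ## no discovery
  expect_true(is.na(bh_correct(rep(1, 5))$threshold))
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")

  ## BH discoveries always include Bonferroni discoveries
  set.seed(1)
  for (i in 1:50) {
    p <- runif(30)^2
    bh_sig <- which(bh_correct(p)$p_adjusted <= 0.05)
    bonf_sig <- which(p.adjust(p, "bonferroni") <= 0.05)
    expect_true(all(bonf_sig %in% bh_sig))
  }
})

test_that("regulation calls apply the 1.5 / 0.67 cutoffs and gender-difference rules", {
  ## enriched in women (ratio 2.09), flat in men (0.89)
  q <- make_quant("NADPH1", 2.09, 0.89)
  calls <- call_regulation(q)
  expect_equal(calls$female_call, "up")
  expect_equal(calls$male_call, "unchanged")
  expect_equal(calls$gender_difference, 1.20)
  expect_equal(calls$gender_quotient, 2.09 / 0.89)
  expect_true(calls$is_gender_differential)
  expect_true(calls$female_modulated)
  expect_equal(calls$significance_tier, "p<0.001 & diff>=0.9")

  ## unchanged protein
  flat <- call_regulation(make_quant("FLAT", 1.0, 1.0))
  expect_equal(flat$female_call, "unchanged")
  expect_false(flat$is_gender_differential)
  expect_equal(flat$significance_tier, "none")

  ## down-regulation: ratio 0.5 < 0.67
  gs <- call_regulation(make_quant("GS", 0.5, 0.9))
  expect_equal(gs$female_call, "down")
  expect_true(gs$female_modulated)

  ## ratio cutoff alone is not enough without G-test significance
  ns <- call_regulation(make_quant("NS", 2.0, 1.0, female_p = 0.5))
  expect_equal(ns$female_call, "up")
  expect_false(ns$female_modulated)

  expect_error(call_regulation(q[q$group == "female", ]), "design error")
})

test_that("replicate ratio %CV matches hand computation and recovers simulated noise", {
  r <- data.frame(protein_acc = c("A", "A", "B", "B"),
                  run_id = c("r1", "r2", "r1", "r2"),
                  ratio = c(1.2, 1.2, 1.0, 1.5))
  cv <- ratio_cv_profile(r)
  expect_equal(cv$cv_pct[cv$protein_acc == "A"], 0)
  expect_equal(cv$cv_pct[cv$protein_acc == "B"], 28.28427125, tolerance = 1e-8)
  expect_equal(attr(cv, "fraction_under")(50), 1)

  ## one peptide per protein so the replicate ratio CV tracks noise_cv;
  ## an SD from 3 replicates underestimates by c4(3) ~ 0.886, so the
  ## expected median sits near 17.7 for 20 % simulated noise
  sim <- generate_psm_data(synthetic_config(
    seed = 9, n_proteins = 80, peptides_per_protein = c(1, 1),
    noise_cv = 0.20, decoy_fraction = 0, dpm_rates = list(),
    include_mbp = FALSE, true_fold_changes = c(female = 1, male = 1)))
  psm <- sim$psm
  ok <- psm$area_116 > 0 & psm$area_114 > 0
  r <- data.frame(protein_acc = psm$protein_acc[ok],
                  run_id = psm$run_id[ok],
                  ratio = psm$area_116[ok] / psm$area_114[ok])
  cv <- ratio_cv_profile(r)
  expect_gt(median(cv$cv_pct, na.rm = TRUE), 12)
  expect_lt(median(cv$cv_pct, na.rm = TRUE), 24)
})

test_that("protein quantitation aggregates PSMs into per-group statistics", {
  sim <- generate_psm_data(synthetic_config(
    seed = 13, n_proteins = 25, decoy_fraction = 0,
    true_fold_changes = c(female = 2, male = 0.5),
    dpm_rates = list(), include_mbp = FALSE))
  quant <- quantify_proteins(sim$psm)
  expect_s3_class(quant, "protein_quant")
  expect_setequal(unique(quant$group), c("female", "male"))
  expect_true(all(quant$error_factor >= 1, na.rm = TRUE))
  expect_true(all(quant$p_bh >= quant$p_raw))
  expect_true(all(quant$ratio > 0))
  ## bias correction centres a uniformly-2-fold experiment at ratio 1,
  ## which is exactly what global normalization must do
  expect_equal(median(quant$ratio[quant$group == "female"]), 1,
               tolerance = 0.05)
  ## without bias correction the true fold reappears
  quant2 <- quantify_proteins(sim$psm, bias_correct = FALSE)
  expect_equal(median(quant2$ratio[quant2$group == "female"]), 2,
               tolerance = 0.1)
  expect_equal(median(quant2$ratio[quant2$group == "male"]), 0.5,
               tolerance = 0.05)
})

test_that("the heatmap matrix pins the reference column at log-ratio zero", {
  sim <- generate_psm_data(synthetic_config(
    seed = 17, n_proteins = 10, decoy_fraction = 0, dpm_rates = list(),
    include_mbp = FALSE))
  quant <- quantify_proteins(sim$psm, bias_correct = FALSE)
  m <- ratio_matrix(quant)
  expect_true(all(m[, "control"] == 0))
  expect_setequal(colnames(m), c("control", "female", "male"))
})
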