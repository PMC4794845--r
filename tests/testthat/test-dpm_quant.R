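test_that("peptide-local modification positions map to protein coordinates", {
  ref <- paste0(strrep("G", 80), "WQDENPVVHF", strrep("A", 20))
  ## peptide starts at protein position 81; mod at peptide position 2 -> 82
  mp <- map_peptide_mods_to_protein("WQDENPVVHF", "2|Q|Deamidated", ref)
  expect_equal(mp$position, 82)
  expect_equal(mp$residue, "Q")

  ## multi-occurrence peptides resolve to the first occurrence with a warning
  ref2 <- paste0("AAA", "WQDENPVVHF", "CCC", "WQDENPVVHF", "DDD")
  expect_warning(mp2 <- map_peptide_mods_to_protein("WQDENPVVHF",
                                                    "2|Q|Deamidated", ref2),
                 "first occurrence")
  expect_equal(mp2$position, 5)

  ## absent peptide and mismatching residue are mapping errors
  expect_error(map_peptide_mods_to_protein("NOTTHERE", "", ref), "not found")
  expect_error(map_peptide_mods_to_protein("WQDENPVVHF", "3|Q|Deamidated", ref),
               "does not match")
})

test_that("site areas conserve the contributing peptide areas per group", {
  ref <- c(P1 = paste0(strrep("G", 10), "AQNDER", strrep("A", 10)))
  psm <- bind_psm(
    make_psm(peptide = "AQNDER", mods = "2|Q|Deamidated", area_114 = 10,
             area_116 = 20, area_117 = 5),
    make_psm(peptide = "AQNDER", mods = "2|Q|Deamidated", area_114 = 7,
             area_116 = 13, area_117 = 2),
    make_psm(peptide = "AQNDER", mods = "4|D|Other", area_114 = 100,
             area_116 = 100, area_117 = 100))
  sites <- mod_site_table(psm, references = ref, mod_name = "Deamidated")
  expect_equal(unique(sites$position), 12)
  f <- sites$area[sites$group == "female"]
  expect_equal(sum(f), 33, tolerance = 1e-9)
  expect_equal(sum(sites$area[sites$group == "control"]), 17, tolerance = 1e-9)

  rel <- site_relative_levels(sites)
  expect_equal(rel$rel_level[rel$group == "female"], 33 / 17)
  expect_false(any(rel$no_reference))
})

test_that("stoichiometry counts distinct (sequence, mod-state) peptides", {
  rows <- c(lapply(1:3, function(i)
              make_psm(peptide = sprintf("PEPTIDEQ%dK", i),
                       mods = "8|Q|Deamidated")),
            lapply(4:10, function(i)
              make_psm(peptide = sprintf("PEPTIDEQ%dK", i))))
  psm <- do.call(bind_psm, rows)
  st <- stoichiometry(psm, "Deamidated")
  expect_equal(st$n_modified, 3)
  expect_equal(st$n_total, 10)
  expect_equal(st$pct_of_peptides, 30)

  ## duplicating PSMs of an already-counted distinct peptide changes nothing
  st2 <- stoichiometry(bind_psm(psm, psm[1, ], psm[5, ]), "Deamidated")
  expect_equal(st2$pct_of_peptides, 30)

  ## no modification at all
  st0 <- stoichiometry(psm, "Citrullination")
  expect_equal(st0$pct_of_peptides, 0)
})

test_that("site ANOVA matches the hand-computed F oracle and Bonferroni scales by sites tested", {
  site <- function(pos, areas_by_group) {
    do.call(rbind, lapply(names(areas_by_group), function(g)
      data.frame(protein_acc = "P1", position = pos, residue = "Q",
                 mod_name = "Deamidated", group = g,
                 run_id = paste0("r", seq_along(areas_by_group[[g]])),
                 area = areas_by_group[[g]], stringsAsFactors = FALSE)))
  }
  ## frozen oracle: F = 505.857143, p = 2.0492e-7
  s1 <- site(10, list(control = c(10, 11, 9), female = c(30, 29, 31),
                      male = c(10, 10, 11)))
  s2 <- site(20, list(control = c(5, 6, 5), female = c(5, 5, 6),
                      male = c(6, 5, 5)))
  s3 <- site(30, list(control = c(7, 7, 7), female = c(7, 7, 7),
                      male = c(7, 7, 7)))
  res <- site_group_comparison(rbind(s1, s2, s3))
  r1 <- res[res$position == 10, ]
  expect_equal(r1$f_value, 505.857142857, tolerance = 1e-8)
  expect_equal(r1$p_raw, 2.0491613e-07, tolerance = 1e-6)
  expect_equal(r1$p_bonf, r1$p_raw * 3)
  expect_lt(r1$p_bonf, 0.05)

  ## all-identical areas: F = 0, p = 1
  r3 <- res[res$position == 30, ]
  expect_equal(r3$f_value, 0)
  expect_equal(r3$p_raw, 1)

  ## single replicate per group: excluded, not an error
  s4 <- site(40, list(control = 5, female = 9, male = 7))
  res4 <- site_group_comparison(s4)
  expect_false(res4$tested)
  expect_true(is.na(res4$p_raw))
})

test_that("proteome-wide modification rates use spectral counts and a 2x2 chi-square", {
  design <- group_design(c("114" = "control", "116" = "female"),
                         reference_group = "control")
  n_shared_mod <- 352; n_f_only_mod <- 38
  psm <- bind_psm(
    make_psm(peptide = "AQNDEK")[rep(1, 9610), ],
    make_psm(peptide = "AQNDEK", mods = "2|Q|Deamidated")[rep(1, n_shared_mod), ],
    make_psm(peptide = "AQNDEK", mods = "2|Q|Deamidated",
             area_114 = 0)[rep(1, n_f_only_mod), ],
    make_psm(peptide = "AQNDEK", area_116 = 0)[rep(1, n_f_only_mod), ])
  res <- proteome_dpm_rate(psm, design, "Deamidated")
  rf <- res$rates[res$rates$group == "female", ]
  rc <- res$rates[res$rates$group == "control", ]
  expect_equal(rf$n_psm, 10000); expect_equal(rc$n_psm, 10000)
  expect_equal(rf$pct, 3.90); expect_equal(rc$pct, 3.52)
  ## frozen independent 2x2 oracle for 390/10000 vs 352/10000
  expect_equal(res$chi_sq, 2.02107347, tolerance = 1e-7)
  expect_equal(res$df, 1)

  ## counts, not areas: uniform area scaling changes nothing
  psm2 <- psm
  for (col in c("area_114", "area_116")) psm2[[col]] <- psm2[[col]] * 7.3
  res2 <- proteome_dpm_rate(psm2, design, "Deamidated")
  expect_equal(res2$rates$pct, res$rates$pct)
  expect_equal(res2$chi_sq, res$chi_sq)

  ## equal rates across groups: chi-square at the null
  eq <- bind_psm(make_psm()[rep(1, 100), ],
                 make_psm(mods = "6|Q|Deamidated",
                          peptide = "AAAAAQK")[rep(1, 4), ])
  res_eq <- proteome_dpm_rate(eq, design, "Deamidated")
  expect_equal(res_eq$chi_sq, 0, tolerance = 1e-12)
})

test_that("amino-acid pairs credit the modified residue and its C-terminal neighbor", {
  psm <- bind_psm(
    make_psm(peptide = "AAQDLLK", mods = "3|Q|Deamidated",
             area_114 = 10, area_116 = 30, area_117 = 20),
    ## modification at the peptide C-terminus pairs with next_aa
    make_psm(peptide = "LLVTQAR", mods = "7|R|Citrullination", next_aa = "-",
             area_114 = 5, area_116 = 15, area_117 = 5))
  prof <- aa_pair_profile(psm, mod_name = "Deamidated")
  qd <- prof[prof$residue == "Q" & prof$neighbor == "D", ]
  expect_equal(nrow(qd), 3)
  expect_equal(qd$area[qd$group == "female"], 30)

  cit <- aa_pair_profile(psm, mod_name = "Citrullination")
  expect_equal(unique(cit$neighbor), "-")

  m <- pair_matrix(prof, "female")
  expect_equal(m["Q", "D"], 30)
  expect_true(all(is.na(m["Q", setdiff(colnames(m), "D")])))
})

test_that("restricting the generator to one citrullination pair leaves all other pairs absent", {
  sim <- generate_psm_data(synthetic_config(
    seed = 19, n_proteins = 40, decoy_fraction = 0, include_mbp = FALSE,
    dpm_rates = list(Citrullination = c(control = 0.5, female = 0.5,
                                        male = 0.5)),
    mod_neighbor_restrict = list(Citrullination = "G")))
  prof <- aa_pair_profile(sim$psm, mod_name = "Citrullination")
  expect_gt(nrow(prof), 0)
  expect_equal(unique(prof$residue), "R")
  expect_equal(unique(prof$neighbor), "G")
})
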