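test_that("byproduct mapping is the identity on identical sequences", {
  seqs <- "MKTAESTPEPTIDEGLQRWAANNK"
  b <- map_byproduct("PEPTIDE", seqs, seqs)
  expect_equal(b$mapped_sequence, "PEPTIDE")
  expect_equal(c(b$start, b$end), c(8, 14))
  expect_false(b$terminal_mod)
})

test_that("byproduct mapping projects through substitutions and terminal extensions", {
  src <- "MKTAESTPEPTIDEGLQRWAANNK"
  ## single substitution inside the peptide region: D -> E
  tgt <- sub("PEPTIDE", "PEPTIEE", src)
  b <- map_byproduct("PEPTIDE", src, tgt)
  expect_equal(b$mapped_sequence, "PEPTIEE")
  expect_equal(c(b$start, b$end), c(8, 14))

  ## N-terminal extension of the source shifts coordinates, not content
  b2 <- map_byproduct("PEPTIDE", paste0("GAS", src), src)
  expect_equal(b2$mapped_sequence, "PEPTIDE")
  expect_equal(c(b2$start, b2$end), c(8, 14))

  expect_error(map_byproduct("ABSENT", src, tgt), "not found")
})

test_that("fixture byproducts reproduce the published human coordinates", {
  hum <- mbp_human_seq(); bov <- mbp_bovine_seq()
  b1 <- map_byproduct("TQDENPVVHF", bov, hum)
  expect_equal(b1$mapped_sequence, "TQDENPVVHF")
  expect_equal(c(b1$start, b1$end), c(81, 90))

  ## the cathepsin-susceptible core QDENPVV sits at 82-88
  core <- map_byproduct("QDENPVV", bov, hum)
  expect_equal(c(core$start, core$end), c(82, 88))

  b2 <- map_byproduct("YLATASTMDHAR#", bov, hum)
  expect_equal(b2$mapped_sequence, "YLATASTMDHAR")
  expect_true(b2$terminal_mod)
  expect_equal(substr(hum, b2$start, b2$end), "YLATASTMDHAR")
})

test_that("exact/partial classification follows the semi-tryptic terminal rules", {
  hum <- mbp_human_seq()
  b1 <- map_byproduct("TQDENPVVHF", hum, hum)
  b2 <- map_byproduct("YLATASTMDHAR#", hum, hum)
  container <- substr(hum, 75, 95)

  psm <- bind_psm(
    ## in-vivo byproduct: equals the mapped peptide, non-tryptic N-terminus
    make_psm(peptide = "TQDENPVVHF", prev_aa = substr(hum, 80, 80),
             next_aa = substr(hum, 91, 91), protein_acc = "MBPSYN_HUMAN"),
    ## longer fully tryptic peptide containing it
    make_psm(peptide = container, prev_aa = "K", next_aa = substr(hum, 96, 96),
             protein_acc = "MBPSYN_HUMAN"),
    ## tryptic-looking copy of the byproduct sequence: rejected
    make_psm(peptide = "TQDENPVVHF", prev_aa = "K", next_aa = "-",
             protein_acc = "MBPSYN_HUMAN"),
    ## citrullinated terminal Arg makes a fully tryptic peptide a byproduct
    make_psm(peptide = "YLATASTMDHAR", mods = "12|R|Citrullination",
             prev_aa = "K", next_aa = substr(hum, 160, 160),
             protein_acc = "MBPSYN_HUMAN"),
    ## same sequence without the terminal modification: rejected
    make_psm(peptide = "YLATASTMDHAR", prev_aa = "K",
             next_aa = substr(hum, 160, 160), protein_acc = "MBPSYN_HUMAN"))

  expect_equal(classify_match(psm, b1),
               c("exact", "partial", "none", "none", "none"))
  expect_equal(classify_match(psm, b2),
               c("none", "none", "none", "exact", "none"))

  ## partition: a record is never both exact and partial
  sim <- generate_psm_data(synthetic_config(seed = 23))
  cls1 <- classify_match(sim$psm, b1)
  expect_true(all(cls1 %in% c("exact", "partial", "none")))
  expect_false(any(cls1 == "exact" & cls1 == "partial"))
})

test_that("percent degradation follows the exact/partial area equation", {
  hum <- mbp_human_seq()
  b <- map_byproduct("TQDENPVVHF", hum, hum)
  mk <- function(exact_area, partial_area) bind_psm(
    make_psm(peptide = "TQDENPVVHF", prev_aa = substr(hum, 80, 80),
             next_aa = substr(hum, 91, 91), protein_acc = "MBP",
             area_114 = exact_area[1], area_116 = exact_area[2],
             area_117 = exact_area[3]),
    make_psm(peptide = substr(hum, 75, 95), prev_aa = "K",
             next_aa = substr(hum, 96, 96), protein_acc = "MBP",
             area_114 = partial_area[1], area_116 = partial_area[2],
             area_117 = partial_area[3]))

  ## control applied to itself: ratio exactly 1
  d <- degradation_ratio(mk(c(50, 50, 50), c(50, 50, 50)), b)
  expect_equal(d$pct_degradation, rep(50, 3))
  expect_equal(d$ratio_vs_control[d$group == "control"], 1)

  ## a group with no exact signal: pct 0, ratio 0 against a live control
  d0 <- degradation_ratio(mk(c(50, 0, 0), c(50, 100, 100)), b)
  expect_equal(d0$pct_degradation, c(50, 0, 0))
  expect_equal(d0$ratio_vs_control, c(1, 0, 0))

  ## uniform scaling of all areas leaves the percentages unchanged
  d1 <- degradation_ratio(mk(c(30, 10, 20), c(70, 90, 80)), b)
  d2 <- degradation_ratio(mk(c(30, 10, 20) * 11, c(70, 90, 80) * 11), b)
  expect_equal(d1$pct_degradation, c(30, 10, 20))
  expect_equal(d2$pct_degradation, d1$pct_degradation)
  expect_equal(d1$ratio_vs_control, c(1, 1 / 3, 2 / 3))

  ## dead reference channel: undefined with a warning
  expect_warning(dna <- degradation_ratio(mk(c(0, 10, 20), c(0, 90, 80)), b),
                 "undefined")
  expect_true(all(is.na(dna$ratio_vs_control)))
})

test_that("the severity proxy is the ratio of two proteins' group ratios", {
  quant <- data.frame(
    protein_acc = rep(c("MAG", "PLP"), each = 2),
    group = rep(c("female", "male"), 2),
    ratio = c(1.0, 1.0, 5.0, 2.0))
  sev <- severity_ratio(quant, "MAG", "PLP")
  expect_equal(unname(sev["female"]), 0.2)
  expect_equal(unname(sev["male"]), 0.5)
  expect_equal(unname(severity_ratio(quant, "MAG", "MAG")["female"]), 1.0)
  expect_error(severity_ratio(quant, "MAG", "CNP"), "design error")
})
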