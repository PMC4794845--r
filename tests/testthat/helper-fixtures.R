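## shared fixture builders: all synthetic data is constructed in code

make_psm <- function(peptide = "SAMPLEPK", run_id = "run1", mods = "",
                     protein_acc = "P1", is_decoy = FALSE,
                     confidence_pct = 99.9, unused_score = 5,
                     area_114 = 100, area_115 = 0, area_116 = 100,
                     area_117 = 100, prev_aa = "K", next_aa = "A") {
  structure(data.frame(run_id = run_id, peptide = peptide, mods = mods,
                       protein_acc = protein_acc, is_decoy = is_decoy,
                       confidence_pct = confidence_pct,
                       unused_score = unused_score, area_114 = area_114,
                       area_115 = area_115, area_116 = area_116,
                       area_117 = area_117, prev_aa = prev_aa,
                       next_aa = next_aa, stringsAsFactors = FALSE),
            class = c("psm_table", "data.frame"))
}

bind_psm <- function(...) {
  structure(do.call(rbind, lapply(list(...), as.data.frame)),
            class = c("psm_table", "data.frame"))
}

mbp_human_seq <- function() {
  read_protein_fasta(system.file("extdata", "mbp_human_synthetic.fasta",
                                 package = "dpmquant"))[[1]]
}

mbp_bovine_seq <- function() {
  read_protein_fasta(system.file("extdata", "mbp_bovine_synthetic.fasta",
                                 package = "dpmquant"))[[1]]
}

## minimal quantitation table for regulation-call tests
make_quant <- function(acc, female_ratio, male_ratio,
                       female_p = 1e-6, male_p = 1e-6) {
  data.frame(protein_acc = rep(acc, 2),
             group = c("female", "male"),
             ratio = c(female_ratio, male_ratio),
             p_bh = c(female_p, male_p),
             stringsAsFactors = FALSE)
}
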