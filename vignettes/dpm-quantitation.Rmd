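---
title: "Quantifying degenerative protein modifications and protein regulation from iTRAQ PSM tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying degenerative protein modifications and protein regulation from iTRAQ PSM tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpmquant)
```

## The analytical problem

Isobaric-tag (iTRAQ) shotgun proteomics of pooled tissue compares protein
abundance across sample groups by labelling the groups with different mass
tags and reading, for every identified peptide, the reporter-ion peak area
of each channel. `dpmquant` implements the full downstream analysis for a
pooled three-group brain-tissue design — age-matched controls on channel
114, female patients on 116, male patients on 117, with triplicate runs —
from search-engine PSM export to biological read-outs:

1. **Identification qualification** by target-decoy filtering.
2. **Protein-level relative quantitation** with weighted log-ratio
   statistics and two complementary significance tests.
3. **Degenerative protein modification (DPM) quantitation** — deamidation
   of Asn/Gln and citrullination of Arg — at peptide, site and
   amino-acid-pair resolution.
4. **Degradation-byproduct scoring** for myelin basic protein (MBP), whose
   in-vivo proteolytic fragments are distinguished from in-vitro tryptic
   peptides by their termini.

The package consumes a documented TSV schema (one row per PSM with
sequence, modification annotations, accession, decoy flag, confidence,
unused score, per-channel areas and flanking residues) rather than any
proprietary search-engine export; a thin column mapping adapts real
exports.

## Identification qualification

Search results arrive as a concatenated target-decoy set. The decoy-based
false discovery rate uses the doubling formula

$$\mathrm{FDR} = 2 \times \frac{\text{decoy hits}}{\text{total hits}} \times 100\,\%$$

and the default qualification criteria are FDR < 1 %, protein unused score
≥ 2 and peptide confidence ≥ 99 %. The unused score is $-\log_{10}$ of the
residual error probability, so score 2 corresponds to 99 % confidence via
$\mathrm{conf} = (1 - 10^{-\text{score}}) \times 100$. Because only the
formula and the bound are prescribed, the FDR control itself is
implemented as a monotone sweep: the peptide-confidence cutoff is raised
through the observed confidence values until the retained set satisfies
the bound. This is deterministic, and re-applying the filter to its own
output is a no-op. The peptide-confidence and protein-score gates are both
applied (jointly, with per-filter drop counts logged), since the two
criteria act at different levels and neither implies the other.

Only proteins with at least one qualifying peptide in **every** replicate
run enter quantitation (`intersect_replicates()`), which is the
conservative replicate-intersection rule for a pooled design where
replication exists only at the run level.

## Protein quantitation model

For one protein in one comparison group, let $r_i$ be the $\log_{10}$
ratio of peptide $i$'s group-channel area to its reference-channel area,
and $w_i > 0$ a weight. The protein estimate is the weighted average
$\bar r = \sum w_i r_i / \sum w_i$ with weighted standard deviation

$$S_{MW} = \sqrt{\tfrac{n}{n-1} \textstyle\sum \tilde w_i (r_i - \bar r)^2},
\qquad \tilde w_i = w_i / \textstyle\sum w_j,$$

which reduces to the ordinary $n-1$ sample standard deviation under equal
weights. Significance and uncertainty follow the stated forms

$$t = \frac{\bar r - \text{log bias}}{S_{MW}}, \qquad
\text{Error factor} = 10^{\,S_{MW}\, t_{0.975,\,n-1}},$$

with a two-sided p-value from $t$ on $n - 1$ degrees of freedom. Both
expressions use $S_{MW}$ directly, as written, rather than a standard
error $S_{MW}/\sqrt{n}$; the t-test is therefore conservative for large
$n$. With a single peptide the dispersion quantities are undefined and
reported as `NA`; when all ratios coincide exactly, $t$ is 0 at the null
(p = 1). Two genuinely open choices were fixed as follows:

* **Weights.** The upstream software's weighting is proprietary; we use
  $w_i$ = the peptide's summed area in the two channels, a standard
  precision proxy (brighter peaks have more reliable ratios).
* **Log bias.** Named but not defined upstream; we use the median peptide
  log ratio of the run (global normalization under the assumption that
  most proteins are unchanged), estimated and applied per replicate.
  `quantify_proteins(..., bias_correct = FALSE)` disables it.

### The G-test and multiple-testing correction

Independently of the ratio model, each protein's summed reporter areas in
the reference ($\mathrm{Ctrl}_A$) and disease ($\mathrm{Dem}_A$) groups are
compared by the two-cell likelihood-ratio statistic

$$G = 2\left(\mathrm{Ctrl}_A \ln\!\frac{\mathrm{Ctrl}_A}{m}
      + \mathrm{Dem}_A \ln\!\frac{\mathrm{Dem}_A}{m}\right),
\qquad m = \frac{\mathrm{Ctrl}_A + \mathrm{Dem}_A}{2},$$

referred to $\chi^2_1$ (upper tail, no continuity correction), with the
convention $0 \ln 0 = 0$. Areas are rounded to integers before the formula
since the statistic treats them as counts. Raw p-values are adjusted by
Benjamini–Hochberg step-up at $\alpha = 0.05$; `bh_correct()` also reports
the *data-driven threshold* — the largest raw p-value still declared
significant — which is the dataset-specific "corrected p-value" cutoff
this style of analysis quotes. Note the G-test on summed areas is very
powerful (areas are large), so it functions as a gate in conjunction with
the ratio cutoffs rather than as the sole call criterion.

### Regulation and gender-difference calls

Ratio thresholds derive from the empirical replicate %CV profile of the
data (`ratio_cv_profile()`; most proteins fall under 50 %): up-regulation
requires ratio > 1.5, down-regulation ratio < 0.67 — the reciprocal
deliberately rounded to two decimals so both cutoffs are exact decimal
constants. A protein is reported *modulated* only when the ratio cutoff
holds **and** its BH-corrected G-test p-value clears $\alpha$. For
gender comparison, proteins quantified in both disease groups get the
absolute ratio difference |female − male| (call threshold ≥ 0.2, based on
the between-group %CV < 20 %), the female/male quotient for reporting,
and a two-tier significance annotation (p < 0.05 with difference ≥ 0.2;
p < 0.001 with difference ≥ 0.9).

## DPM quantitation

Modification assignments (deamidation +0.984 Da at Asn/Gln, citrullination
+0.984 Da at Arg) are taken from the input annotations; no spectral
re-localization is attempted. Three complementary summaries:

* **Stoichiometry** (`stoichiometry()`): the percent of a protein's
  distinct peptides carrying the modification, where *distinct* means
  unique (sequence, full modification state) — charge states collapse and
  duplicate PSMs do not inflate the value.
* **Site quantitation** (`mod_site_table()`): peptide-local positions are
  projected to protein coordinates through the reference sequence (first
  occurrence wins for repeated peptides, with a warning), and per-site
  replicate areas are compared across the three groups by one-way ANOVA
  with Bonferroni correction over the number of sites tested. Sites
  without ≥ 2 groups × ≥ 2 replicates are excluded rather than tested.
* **Proteome-wide rates** (`proteome_dpm_rate()`): spectral counting — the
  percent of PSMs with signal in a group's channel that carry the
  modification — with disease association from a 2×2 chi-square (pooled
  disease groups vs controls, 1 df, no continuity correction; pooling is
  what a single degree of freedom implies).
* **Amino-acid pairs** (`aa_pair_profile()`): each modified residue is
  paired with its immediate **C-terminal** neighbor (consistent with
  Arg–X pair naming); pairs never observed are reported absent, and
  `pair_matrix()` lays profiles against the full residue alphabet with
  `NA` for no identification. The alternative N-terminal pairing is noted
  as an open choice; the code reads the neighbor from within the peptide
  or from the flanking `next_aa` at the peptide C-terminus.

## Degradation byproducts

In-vivo proteolysis (e.g. by cathepsin D) produces byproduct peptides
whose termini do not look tryptic. Byproducts are specified as peptides of
a source species (bovine MBP in the motivating study) and projected onto
the human target by global Needleman–Wunsch alignment (BLOSUM62, gap open
10, gap extension 0.5 — EMBOSS Needle defaults, via
`Biostrings::pairwiseAlignment`). A PSM then classifies as:

* **exact** — bare sequence equals the mapped byproduct *and* the peptide
  shows degradation evidence: a non-tryptic terminus given its flanking
  residues, or a modified (e.g. citrullinated) terminal Lys/Arg. This
  operationalizes "modified Lys/Arg at the terminal sites" and rejects
  tryptic copies produced during sample processing.
* **partial** — a fully tryptic peptide strictly containing the mapped
  sequence.

Percent degradation is
$\text{exact area} \times 100 / (\text{exact area} + \text{partial area})$,
and each group's percentage is divided by the control group's, so the
control ratio is exactly 1. The MAG/PLP severity proxy
(`severity_ratio()`) is the ratio of two proteins' group ratios; lower
values indicate more severe white-matter pathology because MAG degrades
readily under ischemia while PLP tracks pathology.

The shipped FASTA fixtures are **synthetic stand-ins** (not database
sequences), engineered so that the published human coordinates hold:
TQDENPVVHF occupies residues 81–90 (hence the cathepsin-susceptible core
QDENPVV at 82–88 and the deamidation-prone Gln 82), YLATASTMDHAR ends at
Arg 159, and Gln 215/236/255/281, Asn 217 and Arg 231/256 are in place.
Users analyzing real data must supply the FASTA matching their search
database; which database isoform's numbering applies is the user's choice
and the coordinates follow the supplied sequence.

## The synthetic-data generator

`generate_psm_data()` emulates the statistical structure the analysis
assumes — it is how every stage is validated without access to raw
instrument data. Per replicate run, each simulated protein (random
sequence with ~11 % Lys/Arg so tryptic peptide lengths are plausible)
contributes tryptic peptides, a configurable fraction with truncated
semi-tryptic N-termini. Base areas are log-normal
(meanlog `log(5000)`, sdlog 0.9); comparison channels are multiplied by
the protein's true fold change and by multiplicative log-normal noise of
coefficient of variation `noise_cv`, so the noiseless limit reproduces
fold changes exactly. Defaults mirror the pooled study conditions: 3
replicates, 15 % ratio noise, a mostly-null proteome (85 % of proteins at
fold 1, the rest split between 2.0 and 0.5), and modification rates on the
order of a percent per eligible residue with female-elevated deamidation
and citrullination. Modified species are emitted as separate PSM rows at
0.3× parent abundance whose channel areas are zero in groups where the
per-group Bernoulli draw failed — this is what makes per-group spectral
counts informative. The fixture MBP protein carries the two byproducts
with exact/partial areas set from the configured per-group degradation
percentages (control 30 %, with the female group strongly reduced for
TQDENPVVHF and essentially unchanged for YLATASTMDHAR, matching the
motivating biology); ordinary digest peptides overlapping the byproduct
regions are suppressed so the configured state is realized exactly.
Decoys are appended with shuffled sequences, mostly low confidences plus
a thin high-scoring tail that decays faster than the target tail, so the
FDR sweep is exercised but always converges.

Ground truth (fold changes, eligible-residue counts, rates, degradation
states) is returned beside the table, and `truth_compare()` scores calls
against it. What the generator does **not** emulate: spectra, retention
times, m/z, interference/ratio compression between co-eluting peptides,
shared peptides between proteins, and missing-value structure beyond the
modification mechanism. Passing recovery tests therefore demonstrates
correctness of the statistical chain under its own assumptions, not
instrument-level fidelity.

## Numerical choices and degenerate inputs

* $0 \ln 0 = 0$ in the G statistic; both areas zero is a domain error.
* Zero or negative areas are invalid for ratio estimation; PSM rows with
  negative or missing areas are dropped (and counted) at read time, while
  zero areas are legal and simply excluded from ratio formation.
* `s_mw = 0` yields $t = 0, p = 1$ at the null and $\pm\infty, p = 0$
  otherwise; single-peptide proteins report `NA` for $p$ and error factor.
* Repeated peptide occurrences in a reference map to the first occurrence
  with a warning; a residue mismatch is an error, not a warning.
* The BH threshold is `NA` when nothing is significant; Bonferroni caps
  at 1; %CV is `NA` for proteins with fewer than 2 replicates or zero
  mean.
* All generator randomness flows from one integer seed, and the caller's
  RNG state is restored afterwards.

## Problem sizes

The test suite validates the chain at sizes chosen to keep a full run in
tens of seconds while leaving Monte-Carlo margins wide: oracle equivalence
on 1,000 random area pairs, BH monotonicity on 1,000 random p-vectors,
qualification on ~3,200-PSM tables with 40 % decoys, parameter recovery
on 200 proteins × 6 peptides × 3 replicates at 15 % noise (≥ 90 %
sensitivity for 2-fold changes; false-positive rate ≤ 0.07 under the
global null), and stoichiometry against its closed-form binomial
expectation over ~500 distinct peptides.

## Known limitations

* No protein inference or grouping: accessions are taken as given, and
  shared peptides count toward every accession they are assigned to.
* The t-statistic convention divides by $S_{MW}$, not $S_{MW}/\sqrt n$;
  treat its p-values as conservative companions to the G-test, which is
  the primary significance gate.
* The G-test treats summed areas as counts; with very large areas it is
  extremely sensitive, which is why calls always also require the ratio
  cutoff.
* Site-level ANOVA assumes run-level replicates are exchangeable and
  areas are approximately normal within groups; with three replicates it
  has limited power and is best read as a screen.
* Deamidation/citrullination assignments are trusted as annotated;
  isotope-pattern or retention-time validation is out of scope.
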