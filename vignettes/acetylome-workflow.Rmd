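---
title: "Quantifying deacetylase targets from a paired knockdown/overexpression acetylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying deacetylase targets from a paired knockdown/overexpression acetylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylscope)
library(dplyr)
```

## The experimental design and the inference it supports

The pipeline analyses a four-sample label-free experiment: an acetyl-enriched
peptide fraction and a total-lysate (global protein) fraction are quantified
in a deacetylase **knockdown** arm (experimental vs. control shRNA) and a
deacetylase **overexpression** arm (enzyme + acetyltransferases vs. vector +
acetyltransferases). Each condition is a single LC-MS/MS run, so there are no
within-condition replicates; all statistical leverage comes from the
*anti-correlation* requirement across the two arms:

* a **direct** target site gains acetylation when the enzyme is depleted
  *and* loses it when the enzyme is overexpressed;
* an **indirect** target shows the reverse pattern (its acetylation follows
  the enzyme level, implying regulation downstream of it);
* everything else is **neither**.

Because a change must exceed the fold threshold in *both* independent arms,
in opposite directions, a single noisy measurement cannot create a direct
call; the built-in false-positive-rate estimator (below) quantifies how
often noise alone does.

## Stages and their assumptions

### Missing values: left-censored imputation

Label-free intensities go missing predominantly because the analyte fell
below the detection limit, so missingness is informative (MNAR). Missing
cells are imputed from a Gaussian **downshifted** from the observed
population: with population mean $\mu$ and standard deviation $\sigma$
computed over the log2 of *all* unimputed measurements of a table, draws
come from $N(\mu - 1.8\sigma,\ \sigma^2)$ truncated to
$\mu - 1.8\sigma \pm 0.3\sigma$. The downshift (1.8 SD) and truncation
half-width (0.3 SD) are the field-standard parameters for LFQ data and are
the package defaults (`impute_downshift()`). Two contracts matter:

* imputation operates in log2 space — a Gaussian downshift is only
  meaningful on log intensities — while fold changes and thresholds are
  reported linear, where the field states them ("1.5-fold");
* a pair with **both** members missing is never imputed; it is excluded
  downstream with an explicit reason (`both_missing`), because imputing an
  entire comparison would fabricate a ratio out of nothing.

Population statistics are computed per table (acetyl and global protein
separately, all four samples pooled). The truncated draws use rejection
sampling; only the distribution, not the random stream, is part of the
contract.

### Normalization to protein abundance

A site's raw fold change confounds acetylation change with protein-abundance
change. For each site-arm pair the parent protein's LFQ ratio in the same
two samples divides the site ratio:
$\text{normalized} = \text{raw}/\text{protein}$. Consequences encoded as
invariants (and tested as such):

* rescaling one sample's intensities by a constant in *both* tables leaves
  every normalized ratio unchanged;
* a protein unquantified in an arm (never measured, or both LFQ values
  imputed) removes **all** of its peptides from that arm's normalized
  analysis (`protein_unquantified`);
* records mapping to several accessions are normalized to the first listed
  accession (a warning is emitted; the upstream search's razor-protein
  assignment is not re-derived here).

### Classification and counting

`call_dex()` applies strict inequalities (`> t` up, `< 1/t` down, default
`t = 1.5`); a ratio exactly at the threshold is `unchanged`. Peptide-level
classification requires the identical peptide — same sequence *and* acetyl
site set — to satisfy both arm conditions; protein level uses the any-site
rule (each arm's condition may be met by a different site), with proteins
consolidated by case-insensitive gene symbol. Site-level margin counts are
global (unique accession x position), and both site- and peptide-level
overlap counts are reported, since a site reached by several distinct
peptides is counted once globally but once per peptide at peptide level.

### The sliding-threshold FPR estimator

Since both arms are controlled against a matched background, a site that
*decreases* beyond the threshold in **both** comparisons is biologically
implausible — enzyme depletion and enzyme excess should not move acetylation
the same way. The estimator counts those (-/-) items as false positives and
all other qualifying two-arm patterns (+/-, -/+, +/+) as potential true
positives, sweeping the threshold over a grid (default 1.0-1.5 by 0.01).
`FPR = FP/TP`, reported as `NA` (never 0) when nothing qualifies as TP.
Retention applies the same at-most-one-imputed-value rule per comparison as
the main analysis.

Two **scrambled-null** schemes calibrate the estimator. Their construction
is genuinely open — "nonsense pairings" under-determines the arithmetic — so
the package implements named interpretations and documents each:

* `scrambled1`: the two controls compared to each other and the two
  experimental samples compared to each other. Neither comparison is a
  treatment contrast.
* `scrambled2` / `scrambled2alt`: two readings of "differences of nonsense
  differences", built as ratio-of-ratio contrasts
  (see `?scrambled_changes`). Both are constructed so that an
  anti-correlated planted effect cancels: they are true nulls.
* `scrambled_cross`: the literal cross-arm re-pairing
  (`exp_kd/ctrl_oe`, `exp_oe/ctrl_kd`). This pairing is provided for
  completeness but is **not** a null: a genuine direct target still shows an
  anti-correlated pattern across the two pseudo-comparisons, so under real
  effects it tracks the real scheme rather than calibrating it. The
  package's null comparisons are the first three schemes.

### Motif extraction

Direct-target windows (the modified K ± 5 residues, trimmed from the stored
± 15 windows) are searched greedily: at each step the (position, residue)
pair with the smallest binomial upper-tail p-value — foreground matches vs.
the position-specific background probability from all K-centered windows of
the proteome — is fixed, provided `p < 0.001` and at least 12 foreground
occurrences; foreground and background are then restricted to matching
windows and the search recurses. A completed motif consumes its windows and
extraction restarts on the remainder, so motifs partition the foreground.
Ties break deterministically (smaller p, larger count, leftmost position,
alphabetical residue). The background is position-specific rather than a
pooled frequency because each step conditions on previously fixed positions.
Padding characters from protein termini never count as occurrences.

The residue heatmap widens the window to ± 10 and replaces the greedy search
with an exhaustive test: per residue and position, a two-sided Fisher exact
test of foreground vs. background counts, displayed as
$\mathrm{sign} \times -\log_{10}(p)$ (positive = over-used, negative =
under-used; the central column, K by construction, is masked).

### Gene-set over-representation

`fisher_enrich()` is a one-sided hypergeometric test of a hit list against
gene sets, with the background defined as **all quantified proteins of the
experiment** — not the proteome — so the question is enrichment beyond what
the observable proteome gives by chance. Set members are intersected with
the background first; Benjamini-Hochberg q-values accompany raw p-values.
Ontology-graph pruning of redundant terms is out of scope (it requires the
ontology DAG); results are flat per-term.

## The synthetic experiment generator

`simulate_acetylome()` produces a full experiment — proteome FASTA, protein
LFQ table, site table, ground-truth labels — with the structure the analysis
assumes:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 400 | proteins; sites per protein ~ 1 + Poisson(1), capped at 5 |
| `log2_intensity_mean` / `_sd` | 25 / 2 | latent log2 intensity population (MaxQuant-like LFQ scale) |
| `frac_direct` / `frac_indirect` | 0.1 / 0.1 | planted site classes |
| `effect_log2` | 1 | planted |log2 fold| (2-fold), +KD/-OE for direct, reversed for indirect |
| `protein_change_sd` | 0.25 | log2 protein-abundance shift per protein x sample, class-independent |
| `noise_sd` | 0.2 | SD of the log2 ratio noise between two samples |
| `missing_midpoint` / `_slope` | 22 / 1 | logistic MNAR dropout on final log2 intensities; slope 0 disables |

Design choices worth stating explicitly:

* **Noise is parameterized at the contrast level.** `noise_sd` is the SD of
  a two-sample log2 ratio; each acetyl measurement draws independent
  $N(0, \texttt{noise\_sd}^2/2)$. Global-protein LFQ values are generated
  noise-free: protein LFQ aggregates evidence over many peptides, so its
  measurement variance is far below that of a single acetyl-peptide
  precursor, and the protein-level sample shifts remain exactly cancellable
  by normalization. Under this parameterization the expected direct-site
  sensitivity at the default conditions (2-fold effect, 1.5-fold threshold,
  `noise_sd = 0.2`, no dropout) is
  $\Phi((1 - \log_2 1.5)/0.2)^2 \approx 0.962$, which is what the recovery
  tests check.
* Intensities are simulated in log2 space and exponentiated on write,
  matching the left-censoring assumption of the imputation step.
* Protein sequences are i.i.d. draws from human amino-acid background
  frequencies with K forced at planted site positions — sufficient for
  window and motif machinery; no homology or domain structure.
* One replicate per condition, exactly as in the study design; the
  generator has no replicate parameter to refuse.
* In `planted_motif_windows()` the planted position carries the residue
  with probability `enrichment` **exactly** (otherwise a non-matching
  residue is drawn), so `enrichment =` background frequency is a true null;
  and background proteins are pure i.i.d. draws — their naturally occurring
  K's supply background windows — because forcing an extra K per background
  protein would bias the background K content and make every other residue
  look foreground-enriched.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: peptide digestion and miscleavage structure, shared
peptides between proteins, correlated (batch/run) intensity error,
match-between-runs artefacts, the global acetylation shift induced by
acetyltransferase co-transfection, or compositional biases of real
proteomes. Tests on synthetic data validate the *arithmetic and the
contracts*, not biological discovery performance.

## Numerical choices and degenerate inputs

* Stored zeros and blank cells both read as missing (LFQ convention that 0
  means "not quantified"); parsing is strict — a cell like `12,345` is a
  row-level error, never a silently coerced NA.
* Imputation refuses tables with fewer than two observed values or zero
  population SD.
* `FPR` with `TP = 0` is `NA`, never 0.
* In motif extraction a residue absent from a finite background cannot
  yield $p_0 = 0$; it is floored at half a count ($0.5/n_{bg}$).
* Fisher heatmap p-values are floored at the smallest double before the
  $-\log_{10}$ transform.
* Thresholds use strict inequalities; an exactly-1.5-fold ratio is not a
  call.

## Problem sizes used by the test suite

The suite validates distributional claims at the smallest sizes where the
statistics are sharp: 10,000 imputation draws against the truncated-normal
integral; ~5,000 sites (10% direct, 10% indirect) for classification
recovery; ~20,000 sites with 20% planted direct targets for the
real-vs-scrambled FPR ordering; 100-seed null simulations for motif
extraction (foreground identical to its 200-window background sample) and
1,000 permuted hit lists for enrichment calibration (background 1,000,
term size 200, hit list 100, where the exact achieved level of the
discrete test at nominal 0.05 is 0.047).

## Known limitations

* With one run per condition the threshold rule has no per-site error
  model; the FPR estimator is an aggregate, not a per-site q-value.
* Gene-symbol consolidation is exact case-insensitive matching; no alias
  resolution.
* The razor-protein question (multi-accession records) is resolved by
  first-listed accession, not by re-deriving protein groups.
* Site coordinates are 1-based protein positions and must land on K when a
  proteome is supplied; isoform coordinate mismatches are skipped with a
  warning rather than remapped.

## A compact end-to-end run

```{r workflow, eval = FALSE}
sim <- simulate_acetylome(sim_config(seed = 1))

sites    <- impute_downshift(sim$sites,    sim$design, seed = 2)
proteins <- impute_downshift(sim$proteins, sim$design, seed = 3)

dex     <- compute_changes(sites, proteins, sim$design) |> call_dex(1.5)
classes <- classify_targets(dex)
venn_summary(dex, classes)

curves <- dplyr::bind_rows(
  fpr_curve(compute_changes(sites, proteins, sim$design)),
  fpr_curve(scrambled_changes(sites, proteins, sim$design, "scrambled1")),
  fpr_curve(scrambled_changes(sites, proteins, sim$design, "scrambled2"))
)
autoplot(curves)

direct <- classes$peptide[classes$peptide$class == "direct", ]
windows <- sim$sites |>
  dplyr::semi_join(direct, by = c("peptide", "sites")) |>
  extract_windows(sim$proteome, half_width = 15)
mx <- motifx(trim_windows(windows$window, 5),
             motif_background(sim$proteome, 5))
hm <- residue_heatmap(trim_windows(windows$window, 10),
                      motif_background(sim$proteome, 10))
autoplot(hm)
```
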