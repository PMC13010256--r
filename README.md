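# splicerescue

Quantification of splicing and expression rescue in myotonic dystrophy
(DM1) cell models.

In DM1, an expanded CUG-repeat RNA sequesters the MBNL family of splicing
regulators, dysregulating hundreds of cassette (skipped-exon) splicing
events and many genes' expression. When a candidate small molecule is
tested in patient-derived cells, the analysis question is always the same:
*how far did treatment move each dysregulated event back toward the
unaffected (control) level?* `splicerescue` implements that quantification
for anyone post-processing rMATS-style skipped-exon output, RT-PCR isoform
tables, qPCR plates, or fluorescence indicator displacement assays from
such screens.

## The statistics at its core

**Percent spliced in** of a cassette exon, from any inclusion/exclusion
signal pair (junction reads or capillary-electrophoresis RFU):

    PSI = 100 * inclusion / (inclusion + exclusion)

**Percent rescue** of a dysregulated splicing event, from the three group
mean PSIs:

    %rescue = 100 * (PSI_affected - PSI_treated) / (PSI_affected - PSI_unaffected)

Scores >= +10% are categorized **Rescue**, <= -10% **MisRescue** (the
treated PSI moved further from control), everything between **NoChange**.
An analogous score on normalized expression handles the gene-expression
side (both the published sign convention and its orientation-corrected
negation are exposed).

Around these, the package provides the full transcriptome-wide procedure:
canonical event IDs (coordinates + gene), cross-contrast matching,
missing-value and SD <= 20 PSI filters, the dysregulation call
(|inclusion-level difference| >= 0.1 and FDR <= 0.05), per-dose response
categorization, off-target flagging, a Dunnett-gated Hill fit for
EC50/ECmax screening tables, delta-delta-Ct qPCR quantification, %FID, and
a synthetic-data generator with planted ground truth that exercises every
step.

## Worked example

```r
library(splicerescue)

# A synthetic three-arm study: control vs affected vs treated at
# 8/32/125 nM, 300 skipped-exon events, 30% planted dysregulated.
cfg <- sim_config(n_events = 300, frac_dysregulated = 0.3,
                  doses = c(8, 32, 125), seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
res$summary
#> # A tibble: 3 × 8
#>   contrast                  dose n_rescue n_misrescue n_nochange n_unscorable
#>   <chr>                    <dbl>    <int>       <int>      <int>        <int>
#> 1 treated_8nM_vs_control       8       84           0          0            0
#> 2 treated_32nM_vs_control     32       84           0          0            0
#> 3 treated_125nM_vs_control   125       84           0          0            0
#>   n_dysregulated n_off_target
#> 1             84            1
#> 2             84            0
#> 3             84            0
```

84 of the 300 events pass the dysregulation call (the planted fraction is
90; the weakest planted shifts fall below the 0.1 inclusion-difference
threshold under read noise). The planted EC50 is 3.5 nM, so even the 8 nM
arm reaches ~70% of the maximal effect — comfortably past the 10% Rescue
threshold for every event, which is why the category counts saturate
across this dose ladder; weaker compounds (higher EC50 or lower `true_emax`)
produce the dose-dependent category shift the summary is designed to
surface. One event is flagged off-target at 8 nM: a null event whose
treated-vs-control contrast crossed both significance thresholds by
chance. Scalar building blocks work directly:

```r
compute_psi(30, 10)                    # 75 : PSI from RFU or read counts
splicing_rescue_score(20, 70, 45)      # value 50, category Rescue
percent_fid(50, 100)                   # 50 : half the indicator displaced
```

## Documentation

The methods vignette (`vignettes/splice-rescue-methods.Rmd`) documents the
models, the generator's assumptions, numerical choices, and known
limitations.
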