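---
title: "Methods: quantifying splicing and expression rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying splicing and expression rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicerescue)
```

## The problem

Myotonic dystrophy type 1 (DM1) is driven by an expanded CUG-repeat RNA
that sequesters MBNL splicing regulators. The downstream molecular
signature is a large set of mis-regulated cassette (skipped-exon, SE)
splicing events and mis-expressed genes. Compound screens in
patient-derived cells therefore need a per-event, per-dose answer to one
question: how far did treatment move each dysregulated event back toward
the unaffected level? This package implements that quantification — the
scoring statistics, the transcriptome-wide post-processing of rMATS-style
SE tables that surrounds them, dose–response summarization, and the two
small assay calculations (qPCR ΔΔCt and %FID) that accompany such
screens — together with a synthetic-data generator that plants known
truth so every step can be validated.

## Scores and categories

Percent spliced in is the bounded ratio
$PSI = 100\,\frac{inc}{inc + exc}$, computed identically from junction
read counts or electropherogram RFU values; it is invariant to any common
positive rescaling of the two channels, which is what makes RFU- and
count-based PSIs comparable.

The splicing rescue score for an event with group mean PSIs $a$
(affected, untreated), $u$ (unaffected control) and $t$ (treated) is

$$\%rescue = 100\,\frac{a - t}{a - u}.$$

It is 0 when treatment did nothing, 100 when the treated mean equals the
control mean, negative when splicing moved the wrong way, and above 100
on overshoot. Scores are deliberately not capped: extreme values carry
information and the categorization absorbs them. Categories are **Rescue**
(score ≥ +10), **MisRescue** (score ≤ −10; the "opposite-direction" label
seen in methods sections is the same category) and **NoChange** for the
open interval between. Both boundaries are inclusive, matching the "≥ 10%"
/ "≤ −10%" phrasing these screens use. The printed definition of
No-change in the source literature ("score < −10% and < 10%") is
internally inconsistent; this package implements No-change as the open
interval complement of the two labelled categories, which is the only
reading under which the three categories partition the line.

The group-level score uses the arithmetic mean of replicate PSIs per
group (missing replicates dropped). Mean rather than median was chosen
because these experiments are reported as mean ± SEM; with 3 replicates
the difference is immaterial.

The expression-side score is the same construction on normalized counts
(not log counts — the score consumes the normalized-count scale its
upstream tools report). The published formula, evaluated exactly as
typeset, algebraically reduces to $-100\,(t - a)/(u - a)$: it assigns
*negative* scores to genes that move toward the control level, which
contradicts the accompanying use of "Rescue" for scores ≥ +10%. Because
the intent cannot be resolved from the text, both behaviours are exposed:
`mode = "symmetric"` (default; positive = toward control, consistent with
the splicing score) and `mode = "as_printed"` (verbatim). They are exact
negations of each other, a property the test suite checks on random
triples.

## The event pipeline

Events are identified by a canonical key — chromosome, strand, upstream
exon, cassette exon and downstream exon coordinates (0-based half-open,
exactly as rMATS emits them; no conversion, to avoid off-by-one drift),
Ensembl gene ID and gene symbol, joined in fixed order. Matching across
contrasts is an inner join on this key; duplicate keys within one table
are a hard error by default (silent collapse would corrupt counts), with
an opt-in keep-first mode.

Two filters precede any call, applied to the baseline untreated groups
(control and affected) only: rows with any missing replicate inclusion
level are removed, and rows whose replicate PSI standard deviation within
either baseline group exceeds 20 are removed. The SD threshold is read in
PSI units (percent), the natural scale of the "≤ 20%" phrasing. Treated
groups are not filtered on SD: the filter's purpose is a stable baseline
against which rescue is measured. Filtering precedes the dysregulation
call, so "dysregulated totals" are post-filter counts.

An event is **dysregulated** when |inclusion-level difference| ≥ 0.1
(0–1 scale) and FDR ≤ 0.05 in the affected-vs-control contrast. FDR and
p-values are consumed as reported in the input tables and never
recomputed — the pipeline post-processes an upstream tool's statistics
rather than replacing them. For each dysregulated event and dose the
rescue score is computed from group means and categorized; events whose
affected and control means coincide have an undefined score and are
counted separately (`n_unscorable`), preserving the invariant
`Rescue + MisRescue + NoChange + unscorable = dysregulated`. Events that
were *not* dysregulated at baseline but crossed both thresholds in a
treated-vs-control contrast are flagged **off-target**.

## Dose–response summarization

Compound screening tables report, per compound and event, an EC50, an
ECmax and a significance call. The gate is a one-way ANOVA across dose
groups followed by Dunnett many-to-one comparisons of each dose against
vehicle. The adjustment uses the exact multivariate-t distribution of the
joint contrasts (via `multcomp`); a max-t permutation oracle in the test
suite confirms the adjusted p-values. When every group has zero
within-group variance the linear model degenerates; that path is handled
explicitly (equal means → p = 1, differing means → p = 0) and tested.

EC50 comes from a least-squares Hill fit
$\Delta PSI(d) = EC_{max}\, d^h / (EC_{50}^h + d^h)$ with the bottom fixed
at 0 (vehicle-anchored ΔPSI), EC50 estimated on the log10 scale, and the
Hill coefficient box-bounded to [0.3, 5] and started at 1 — the screens
report no fitting model, so the minimal-assumption Hill form with a
stabilized exponent was chosen once. A fit is rejected (no EC50) when the
optimizer fails, the fitted plateau is not positive, or the fitted EC50
lands more than 100-fold outside the tested dose range; and an EC50 is
*reported* only when the significance gate passes, reproducing the "–"
entries of screening tables whose ΔPSI never separated from vehicle.
ECmax is reported as the maximum observed group-mean ΔPSI (the literal
"maximum ΔPSI reached"), with the fitted plateau available alongside.

## Assays

ΔΔCt relative expression assumes a doubling amplification efficiency and
no efficiency correction: $\Delta Ct = Ct_{target} - Ct_{reference}$,
$\Delta\Delta Ct$ relative to the mean ΔCt of the vehicle calibrator
group, fold change $2^{-\Delta\Delta Ct}$ — so the calibrator group's
pooled mean fold change is exactly 1. %FID is
$100 - 100\,F/F_0$; values below 0 (fluorescence enhancement) are
reported rather than clipped because they indicate a qualitatively
different binding mode.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: three
biological replicates per group (control, affected, treated at each
dose), ~30% of events dysregulated with planted |ΔPSI| shifts of 10–50
PSI drawn uniformly, treatment doses of 8/32/125 nM, a planted EC50 of
3.5 nM with Hill coefficient 1, and a maximal restored fraction
(`true_emax`) of 0.8 — matching screens in which most but not all
dysregulated events are rescued at the top dose. Junction totals are
Poisson around `mean_coverage` (default 100 reads/event); replicate
inclusion probabilities are beta-distributed around the group PSI with
intraclass correlation `bb_dispersion` (default 0.01), the standard
overdispersion model for splicing counts; and reported inclusion levels
follow the rMATS length normalization for SE events (two inclusion
junctions versus one skipping junction), $I/(I + 2S)$. Doses may include
0, which denotes the vehicle (DMSO) arm — the Hill effect at dose 0 is
exactly zero.

Contrast p-values are produced by a moderated t-test on replicate
inclusion levels (limma's empirical-Bayes variance shrinkage), with
Benjamini–Hochberg correction across events. With three replicates a
plain Welch t-test's four-degree-of-freedom variance estimate is so
unstable that planted 30-PSI shifts at coverage 100 are recovered with
only ~35–60% sensitivity; variance moderation is the field's standard
remedy at this sample size and restores near-complete recovery while the
null simulation stays calibrated (the test suite checks both). Rows where
the moderated statistic is undefined (all replicates identical, as in
noiseless limits) fall back to an exact-separation rule: equal means
give p = 1, different means p = 0.

Features of real data the generator does **not** emulate: correlated
events within a gene, library-size and batch effects, coverage that
varies systematically with expression, rMATS's likelihood-ratio test
(any calibrated monotone test exercises the thresholds equally), and
isoform-specific amplification biases in RT-PCR. Passing tests on
synthetic data therefore demonstrate that the *procedure* is implemented
correctly against planted truth — not that any particular biological
dataset will show a given rescue fraction.

The expression generator plants DE genes at |log2FC| = 3 (comfortably
past the ≥ 2 calling threshold) on a log-normal baseline with 0.25 log2
units of replicate noise; treated groups move back toward control by the
same Hill fraction as splicing. The qPCR generator plants a 2-fold change
with 0.1-cycle Ct noise; the FID generator uses a one-site displacement
isotherm with the half-displacement point at `fid_kd`.

## Numerical choices and degenerate inputs

- PSI is undefined when both signals are 0; this is an error naming the
  offending positions, never a silent NA.
- The rescue score is undefined when affected and control means coincide;
  inside the pipeline such events are excluded and counted, at the scalar
  level it is an error.
- Problem sizes in the tests — 1000–2000 events for recovery and filter
  checks, 100 seeded curves for EC50 recovery, 100 simulated plates for
  ΔΔCt — were chosen as the smallest sizes at which the stochastic
  recovery criteria are stable across seeds.
- Determinism: every generator draws through a single seeded RNG scope
  (`withr::with_seed`), each simulator using a fixed offset of the
  configured seed, so identical configurations are byte-identical after
  serialization and independent of call order.
- JCEC serialization writes replicate inclusion levels at 15 significant
  digits, so write→read round-trips are identities to numerical
  precision.

## Known limitations

- The Dunnett gate assumes the one-way homoscedastic layout; strongly
  unequal variances across dose groups are not modelled.
- The Hill fit fixes the bottom at 0; screens where vehicle itself drifts
  would need a floating-bottom variant.
- `match_events` keeps everything in memory; tables far beyond 10^6
  events would need a keyed on-disk join.
- The simulated p-values exercise thresholds with a calibrated monotone
  test; they are not a reimplementation of rMATS's count-model test, and
  absolute p-value magnitudes should not be compared against rMATS
  output.
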