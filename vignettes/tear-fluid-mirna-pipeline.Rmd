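---
title: "Profiling the tear-fluid miRNAome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the tear-fluid miRNAome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tearmiR)
```

## The problem

Tear fluid (TF) is an easily collected biofluid whose miRNA content may
reflect neurodegenerative disease, because the lacrimal gland is innervated
from brain-stem regions affected early in Parkinson's disease (PD) and the
atypical Parkinsonian syndromes multiple system atrophy (MSA) and
progressive supranuclear palsy (PSP). TF yields are tiny, so a screening
study of this kind pools samples per diagnostic group and profiles them by
RT-qPCR over a fixed panel (1113 miRNAs plus 3 internal controls, technical
duplicates, five pools: control, two PD biological replicates of 19 and 10
subjects, MSA, PSP).

No normalization miRNAs are established for TF, so absolute quantification
is off the table. Instead the raw cycle-threshold (CT) values are reduced to
a three-level categorical call per miRNA and pool, and all downstream
analysis is presence/absence based. `tearmiR` implements that full analysis
chain plus the subject-level clinical statistics, with a synthetic-data
generator that plants known ground truth so every stage is testable without
the (unreleased) raw study data.

## Status calling

For each miRNA and pool the technical duplicate \((CT_a, CT_b)\) is
classified:

* **high** (amplified with high certainty): both replicates numeric, both
  \(CT < 40\), and replicate SD \(< 5\) cycles;
* **none** (not amplified): both replicates undetermined;
* **low** (amplified with low certainty): everything else.

Two points the rule leaves open, and how this package resolves them:

* *SD of a duplicate.* With two values the sample (\(n-1\)) SD is
  \(|a-b|/\sqrt{2}\); the population (\(n\)) SD is \(|a-b|/2\). QC
  conventions use the sample SD, so that is the default; the choice is
  exposed as `sd_denominator` in `status_calling_config()` and only matters
  for replicate differences in \([5, 5\sqrt2)\) cycles.
* *What counts as "amplified".* A numeric CT at or above 40 still means the
  instrument detected a product — late, but detected. Such a pair is
  therefore never **none**; only a missing/"Undetermined" Cq counts as not
  amplified. Cutoff comparisons are strict (`< 40`, `< 5`) as stated.

The PD group is screened as two biological-replicate pools. A miRNA **high**
in at least one pool is **high** for the group (the published merge rule);
the remaining combinations are merged by the maximum under
none < low < high, a convention this package adopts (the source rule only
covers the high case). The merge is commutative, associative and idempotent
with **none** as identity, which the test suite checks exhaustively.

```{r status-demo}
call_status(35.0, 36.0)   # SD 0.71, both < 40
call_status(NA, 35.0)     # one undetermined: in between
merge_biological_replicates("high", "none")
```

Internal-control assays are parsed, excluded from the 1113-miRNA universe
and reported in a QC side table; no normalization is performed.

## Intersections and candidate sets

High-certainty calls are binarized (present iff **high** — low-certainty and
not-amplified are deliberately pooled as absent) and every miRNA is assigned
to exactly one of the \(2^4 = 16\) presence patterns over (control, PD, MSA,
PSP), the tabulation an UpSet plot displays. For a disease \(D\) the two
interesting cells are the *exclusively present* set (present only in
\(D\)) and the *exclusively absent* set (present in exactly the other three
groups); their union is the candidate set for \(D\), each member tagged with
its direction. Patterns are encoded as 4-bit strings in fixed group order so
file output is stable.

## Clinical statistics

The subject-level battery mirrors a standard exploratory cohort analysis:

* **Cumulative wetting length** (WL): sum of the two per-eye Schirmer
  measurements, each in \([0, 35]\) mm per 5 min.
* **Pearson correlations** of miRNA concentration against WL, age and
  disease duration, overall and within groups. Confidence intervals use the
  Fisher z-transform: \(z = \operatorname{atanh} r\) is approximately normal
  with SE \(1/\sqrt{n-3}\), so the 95% bounds are
  \(\tanh(z \mp 1.96/\sqrt{n-3})\). P-values use the usual
  \(t = r\sqrt{n-2}/\sqrt{1-r^2}\) on \(n-2\) df. Recomputing intervals from
  printed two-decimal \(r\) values reproduces most published bounds exactly
  at two decimals; the handful that land one rounding unit away are
  consistent with the original authors having used unrounded coefficients,
  and are not asserted by the tests.
* **Wetting-length regression**: OLS of cumulative WL on group with the
  confounders age and sex (treatment coding, reference levels control and
  F). A flag drops sex for sensitivity analysis, since correcting "for age"
  alone is also a defensible reading of the design.
* **One-way ANOVA with Tukey post hoc** (Tukey–Kramer for unequal group
  sizes) for age, disease duration and concentration, via `aov()` +
  `TukeyHSD()`.
* **Exact tests on categorical tables** (sex and the ophthalmic/medication
  flags): the Freeman–Halton generalisation of Fisher's exact test,
  implemented by full recursive enumeration of tables with the observed
  margins (two-sided: total null probability of tables no more probable
  than the observed one, with a \(10^{-7}\) relative tie tolerance). Beyond
  a configurable table budget the test switches to Monte Carlo sampling
  from the margin-conditional null (Patefield's algorithm) and reports the
  simulation SE. Missing flags are excluded pairwise.

No multiple-testing correction is applied across this battery, matching the
exploratory design it reproduces.

```{r clin-demo}
fisher_ci_from_summary(0.91, 7)   # small-n interval, printed as [0.50, 0.99]
fisher_exact_rxc(matrix(c(2, 0, 0, 2), 2))$p
```

## Annotation

Candidate miRNAs are renamed to current miRBase annotation through a
two-column mapping table; assays with no current annotation are dropped and
reported. Literature evidence is looked up in a packaged table of miRNAs
reported as significantly changed in PD/MSA/PSP in other biofluids (blood,
CSF, brain tissue; 27 miRNAs, one row per citation). That table contains the
spelling `hsa-miR-516a-6p`, which body text elsewhere gives as
`hsa-miR-516a-5p`; both spellings are kept and reconciled through an
explicit alias rather than silently corrected. Brain-tissue presence uses a
read-count table with the strict threshold "expressed iff read count > 1"
in any brain or brain-stem tissue.

## Overrepresentation analysis

Each direction (exclusively present / exclusively absent) is analysed
separately. Target genes are aggregated across the miRNA list by set union
("gene union"), then every term is tested with the upper-tail
hypergeometric probability \(P[X \ge k]\) (population = background,
successes = term genes, draws = query genes) — the standard
overrepresentation tail, equivalent to one-sided Fisher. BH-FDR is applied
within each (category, direction) stratum, matching the per-panel
presentation of GO MF/BP/CC and KEGG results. Retained terms need raw
\(p \le 0.05\), FDR \(< 0.01\) and targets from at least 5 input miRNAs.
The enrichment ratio is the overlap divided by the term size (hence
\(\le 1\)), negated for the absent direction; `top_terms()` keeps the top 5
per stratum by absolute ratio, ties broken by smaller FDR then term id.
The background universe defaults to all genes in the term database and
target map, and is configurable because the original web tool does not
disclose its universe.

## The synthetic-data generator

`generate_cohort()` draws one record per subject. Its defaults are the
study conditions: group sizes 10/29/7/10; per-group means and SDs for age,
disease duration, cumulative WL (37±22, 21±17, 20±21, 18±9 mm/5 min) and
miRNA concentration (22±15, 13±10, 12±13, 17±11 ng/µl); per-group target
correlation between concentration and WL (0.68, 0.58, 0.91, 0.74); sex and
flag frequencies matching the cohort table (including the 20% missing
anticholinergic status among controls). Per group, (concentration, WL) come
from a bivariate normal with the target correlation, truncated at 0 —
truncation slightly attenuates planted correlations for configs with mass
near 0, which is why the recovery tests use moderate parameters (means 4–5
SDs above 0). The cumulative WL is split between eyes by a Beta(5, 5)
fraction constrained so each eye stays within its 35 mm strip while the sum
is preserved. Disease duration is absent for controls; Hoehn & Yahr stage
is drawn for PD only.

`generate_ct_experiment()` realises a planted truth matrix as replicate
CT values. Replicate noise is clamped at ±4 SD, and `ct_noise_config()`
rejects any configuration in which the clamped noise could push a planted
**high** across either cutoff (`max(mean_ct_range) + 4·SD < 40` and
`4·√2·SD < 5`), so status recovery is exact by construction — the
round-trip tests verify 100% recovery. Planted **low** cells are realised
either as a single-dropout pair or as a wide numeric pair (SD ≥ cutoff),
governed by `dropout_prob_low`. CT means are uniform in [20, 34] with
replicate SD 0.3 by default; TF CT distributions are not published, so
these are conventions, not claims about real data. Each generator draws
from its own named substream of the master seed, so adding a generator
never shifts another one's output.

What the generator does *not* emulate: amplification efficiency, melting
curves, per-subject (unpooled) CT values, plate effects, or realistic
correlation between a miRNA's status across pools. Passing tests therefore
demonstrate the correctness of the *analysis logic* under the stated noise
model, not performance on real tear-fluid data.

## Numerical and scale choices

* Presentation rounding is half-away-from-zero at 2 decimals; full
  precision is kept internally and in `stats.json`.
* The Freeman–Halton enumeration budget defaults to 2×10^5 tables
  (comfortably above every table arising from a 56-subject cohort); the
  Monte Carlo fallback uses 10^5 draws and agrees with enumeration within
  3 SE in the tests.
* Test problem sizes — 200-miRNA round trips, 100 coverage replicates at
  n = 200, 500 partition matrices at the full 1113-miRNA panel width,
  100–200 null-calibration databases — were chosen so the whole suite runs
  in well under a minute while keeping Monte Carlo bands narrow enough to
  be meaningful.
* ANOVA on exactly constant data returns F = 0, p = 1 (independence holds
  trivially) instead of `lm`'s numerically unstable 0/0.

## Known limitations

* The three-level call treats CT ≥ 40 as "late amplification"; instruments
  that report artefactual Cq values near the cycle limit will inflate the
  **low** class.
* Pattern-cell candidate sets are sensitive to single miscalls in any
  group: one replicate dropout in the control pool can move a miRNA into a
  disease's exclusive-absent cell. The published design accepts this; so
  does the package.
* The published headline counts (e.g. 286 miRNAs found in all groups, the
  −10.73 mm PD wetting-length estimate) depend on the unreleased raw data
  and are therefore demonstrated qualitatively on synthetic cohorts, not
  reproduced numerically.
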