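# tearmiR

Analysis pipeline for RT-qPCR miRNA profiling of pooled **tear-fluid (TF)**
samples in Parkinson's disease (PD) and the atypical Parkinsonian syndromes
multiple system atrophy (MSA) and progressive supranuclear palsy (PSP).

TF is collected on Schirmer strips and yields too little RNA for per-subject
quantification, so a screen of this kind pools samples per diagnostic group
(control, PD as two biological-replicate pools, MSA, PSP) and profiles a
1113-miRNA panel in technical duplicates. With no established normalization
miRNAs in TF, the analysis is categorical: raw cycle-threshold (CT) values
are reduced to a three-level amplification status, candidate miRNAs are
identified through presence/absence intersections, and their predicted
target genes are tested for pathway overrepresentation.

## What the package implements

**Status calling.** Each technical duplicate (CT<sub>a</sub>, CT<sub>b</sub>)
is classified as

- *high* (amplified with high certainty): both numeric, both CT &lt; 40,
  replicate SD &lt; 5 (sample SD of a duplicate, |a−b|/√2);
- *none* (not amplified): both undetermined;
- *low* (amplified with low certainty): anything in between.

PD's two biological-replicate pools are merged by the maximum under
none &lt; low &lt; high, so *high* in at least one pool is *high* for the
group.

**Intersections.** High-certainty calls are binarized and each miRNA is
assigned to one of the 2⁴ = 16 presence patterns over (control, PD, MSA,
PSP) — the cells of an UpSet plot. The candidate set for a disease D is the
union of its *exclusively present* cell (present only in D) and its
*exclusively absent* cell (present in exactly the other three groups).

**Clinical statistics.** Cumulative Schirmer wetting length (WL, both eyes,
mm/5 min); Pearson correlations with Fisher-z confidence intervals
(z = atanh r, SE 1/√(n−3)) and t-based p-values; OLS regression of WL on
group adjusted for age and sex; one-way ANOVA with Tukey–Kramer post hoc
tests; Freeman–Halton exact tests (full enumeration with a Monte Carlo
fallback) for categorical tables.

**Annotation.** miRBase name normalization, cross-referencing against a
packaged table of miRNAs reported as altered in PD/MSA/PSP in other
biofluids (blood, CSF, brain tissue), and brain-tissue presence lookup
(expressed iff read count &gt; 1).

**Overrepresentation analysis.** Gene-union aggregation of miRNA targets,
upper-tail hypergeometric test per term, BH-FDR within each
(category, direction) stratum, filters FDR &lt; 0.01 and ≥ 5 contributing
miRNAs, and a signed enrichment ratio (overlap / term size, negated for the
exclusively-absent direction) with top-5 reporting per stratum.

**Synthetic data.** Seed-deterministic generators for clinical cohorts
(group sizes 10/29/7/10, published means/SDs, planted concentration~WL
correlations), replicate-level CT experiments with planted truth and
margin-guaranteed recovery, and annotation databases with planted enriched
terms — so every stage is testable without the unreleased raw study data.

## Worked example

Simulate a cohort and screen at study scale, then run the analysis:

```r
library(tearmiR)

clin <- generate_cohort(cohort_config(seed = 42))
correlate(clin$mirna_conc, clin$wl_left + clin$wl_right)
#> Pearson r = 0.58 (n = 56), 95% CI [0.38, 0.73], p = 2.6e-06

truth <- generate_truth_matrix(n_mirnas = 1113, seed = 42)
ct    <- generate_ct_experiment(truth, ct_noise_config(seed = 42))
sm    <- call_status_matrix(ct, default_pool_composition())
sm
#> Amplification status matrix: 1113 miRNAs x 4 groups (control, PD, MSA, PSP)
#>      control  PD MSA PSP
#> none     387 144 393 384
#> low      204 219 225 213
#> high     522 750 495 516
#> 3 internal control assay(s) reported separately

rep <- upset_assignment(binarize_high(sm))
rep
#> Intersection report over 1113 miRNAs, 4 groups ( control, PD, MSA, PSP )
#>   found in all groups: 69  | found in none: 55
#>   control: 51 exclusively present, 82 exclusively absent
#>   PD: 121 exclusively present, 44 exclusively absent
#>   MSA: 48 exclusively present, 93 exclusively absent
#>   PSP: 51 exclusively present, 81 exclusively absent
```

The correlation output reads: across the 56 simulated subjects, miRNA
concentration and cumulative wetting length correlate at r = 0.58 with a
Fisher-z 95% CI of [0.38, 0.73] — the generator planted per-group
correlations, and the pooled estimate recovers them. The status matrix
counts miRNAs per amplification level in each group (PD has more *high*
calls because its two biological replicates are merged by maximum). The
intersection report gives the UpSet cells from which disease candidate sets
are drawn:

```r
head(disease_candidate_set(rep, "PD"), 3)
#>           mirna_id direction
#> 1 hsa-sim-miR-0011   present
#> 2 hsa-sim-miR-0019   present
#> 3 hsa-sim-miR-0021   present
```

The wetting-length regression on the same cohort recovers the planted PD
deficit (control mean 37 vs PD 21 mm/5 min):

```r
clinical_stats_battery(clin)$wl_regression
#> Linear model: wl_cumulative ~ group + age + sex  (n = 56 )
#>         term estimate  ci_low ci_high        p
#>  (Intercept)   47.722  11.736  83.708 0.010400
#>     groupMSA  -18.776 -32.554  -4.997 0.008560
#>      groupPD  -20.767 -31.080 -10.454 0.000181
#>     groupPSP  -17.382 -29.783  -4.980 0.006960
#>          age   -0.148  -0.596   0.300 0.510000
#>         sexM   -0.505  -9.063   8.053 0.906000
```

An end-to-end run over files on disk (`simulate_inputs()` + `run_all()`)
writes the status matrix, UpSet tables, candidate sets, `stats.json`, ORA
tables and a run manifest; `inst/cli/tearmir.R` exposes the same stages as
a command-line tool with `simulate`, `call-status`, `intersect`,
`clin-stats`, `annotate`, `ora` and `run-all` subcommands.

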