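# multiregDE

Per-patient differential expression and prognostic stratification for
multi-region tumour RNA-seq cohorts.

## The problem

Cohort-level ("all-patients") tumour-vs-normal differential expression finds
genes whose dysregulation is shared across most patients. Genes that are
strongly up-regulated in only a *subgroup* of patients — especially genes
with highly variable baseline expression in normal tissue — are
systematically missed, even though they can carry prognostic signal. When
each patient contributes several tumour regions and one adjacent-normal
sample, the tumour regions act as within-patient replicates, so a *paired
per-patient* analysis becomes possible and recovers exactly this
subgroup-specific signal.

`multiregDE` implements that workflow end to end for researchers analysing
multi-region resection cohorts (e.g. hepatocellular carcinoma):

1. **Per-patient DE** — for each patient, the tumour regions are compared
   with the patient's own normal sample by a negative-binomial Wald test
   (log-link GLM with median-of-ratios size-factor offsets; gene-wise
   method-of-moments dispersion shrunk to a parametric trend
   α(μ) = a₀ + a₁/μ). A gene is called up/down when `padj < 0.05` and
   `|log2FC| > 1`.
2. **DEPC aggregation** — the *differentially expressed patient count* of a
   gene is the number of patients calling it up (or down). Genes with DEPC
   at or above `mean + 2·SD` are split into **AP** genes (also found by the
   all-patients analysis, design `~ patient + sample_type`) and **NAP**
   genes (missed by it).
3. **Co-clustering** — the per-patient calls over the NAP genes form a
   categorical matrix with entries −1/0/+1; a categorical latent block
   model fitted by classification EM co-clusters genes and patients,
   yielding patient groups PG0, PG1, … ordered by up-regulation richness.
4. **Survival** — recurrence-free survival of the groups is compared with
   weighted log-rank tests (modified Peto-Peto by default, weight
   S̃(t)·n/(n+1)); clinical covariates are screened Table-1 style
   (Fisher/chi-square/Wilcoxon).
5. **Enrichment** — hypergeometric over-representation of gene lists
   against GMT collections with BH FDR.
6. **Transfer classification** — tumour−normal differences (TND) on
   TMM-CPM-log expression feed a 4-layer MLP trained over many random 7:3
   splits; per-instance predicted-label counts are tested against the
   uniform expectation by a chi-square goodness-of-fit test and assigned to
   the group with the largest standardized residual (BH-controlled),
   otherwise left unassigned.

A synthetic cohort generator (`simulate_cohort()`) plants all of this
structure — cohort-wide up/down genes, subgroup-restricted genes in a
high-variance baseline stratum, latent patient groups with different
recurrence hazards — so every stage can be validated against ground truth.

## Worked example

```r
library(multiregDE)

co     <- simulate_cohort(sim_config(n_patients = 20, n_genes = 1000, seed = 42))
counts <- filter_genes(co$counts)          # >=1 count in >=30% of samples
ap     <- run_all_patients(counts, co$samples)
pp     <- run_per_patient(counts, co$samples)
depc   <- compute_depc(pp)
cls    <- classify_ap_nap(depc, ap, "up")

sum(ap$call == "up")                       # 7   cohort-wide up-genes
attr(cls, "threshold")                     # 4.78 DEPC two-SD threshold
sum(cls$above_threshold)                   # 43  high-DEPC up-genes
sum(cls$above_threshold & cls$class == "NAP")  # 36 missed by the cohort analysis

nap    <- cls$gene_id[cls$class == "NAP" & cls$above_threshold]
fit    <- lbm_cocluster(categorize(pp, nap), seed = 1)
groups <- assign_groups(fit)
attr(groups, "sizes")                      # PG0 3, PG1 8, PG2 9
adjusted_rand_index(groups$group,
                    co$truth$patient_group[groups$patient_id])  # 1

merged <- merge(groups, co$clinical, by = "patient_id")
two    <- merged[merged$group != "PG2", ]
weighted_logrank(two$rfs_days, two$recurrence_event, two$group)
#> weighted logrank (modified_peto)
#>   statistic = 1.3861 (df = 1)
#>   p = 0.23906 (two-sided)
```

The planted patient groups are recovered exactly (ARI 1); the survival
contrast is underpowered at 20 patients (11 in PG0∪PG1), which is expected —
power analyses live in the test suite.

`run_pipeline(pipeline_config(...))` chains all stages under one seed and
writes every stage output as TSV.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full workflow (simulation → filtering → all-patients and
per-patient DE → DEPC/AP-NAP → co-clustering → survival → trial-ensemble
classification) on a scaled synthetic cohort under the given seed, prints a
stage summary, and writes the results JSON.
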