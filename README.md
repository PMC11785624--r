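# organoproteo

Label-free quantitative proteomics of **membrane-bound-organelle fractions**
analysed by spectral counting, packaged as a tested, reusable R pipeline.
The motivating use case is muscle-biopsy proteomics in idiopathic
inflammatory myopathies (IIM): a small cohort (3 controls run as technical
duplicates, 10 IIM patients, 1 mitochondrial-myopathy "disease control")
profiled on an organelle-enriched fraction, quantified by spectral counts,
and screened for differentially expressed proteins and dysregulated
pathways. Because such studies rarely deposit raw data, the package ships a
calibrated synthetic-data generator with known ground truth so every stage
is exercisable, testable, and benchmarkable offline.

## The model

For protein *i* with spectral count SpC and length *L* (amino acids) in one
MS run, the **normalized spectral abundance factor** is

    NSAF_i = (SpC_i / L_i) / Σ_j (SpC_j / L_j)

so each run column sums to 1 over the quantified proteome. The analysis
then proceeds:

1. **Identification filter** — keep proteins with ≥ 2 unique peptides.
2. **Replicate QC** — Pearson r and per-protein RSD (100·sd/mean) across
   the control technical duplicates; duplicates are then averaged.
3. **Presence filter** — keep proteins quantified in ≥ ½ of disease *or*
   ≥ ⅔ of control samples.
4. **Minimum imputation** — zeros replaced by the smallest nonzero NSAF of
   the same sample.
5. **Differential calling** — ratio r = median(disease) / mean(control),
   reported as a signed fold change (+r if r ≥ 1, else −1/r), with a
   two-tailed two-sample t-test. Two profiles:
   *strict* (disease = IIM+MM, p < 0.05 and |FC| ≥ 3) and
   *exploratory* (IIM only, |FC| ≥ 2.83 = 2^1.5, no p filter,
   over/under kept separate).
6. **Structure** — PCA of samples on NSAF; unsupervised clustering
   (per-row z-scores, Euclidean distance, average/UPGMA linkage) of the
   significant proteins.
7. **Enrichment** — hypergeometric over-representation of the over- and
   underexpressed sets against GMT libraries, Benjamini–Hochberg adjusted;
   plus proteomap-style NSAF mass summaries per functional category.

## Worked example

```r
library(organoproteo)
cfg <- pipeline_config(simulate = TRUE, output_dir = "run1", seed = 17)
report <- run_pipeline(cfg)
writeLines(summarize_report(report))
```

```
== membrane-organelle spectral-counting analysis ==
proteins loaded: 700
after identification filter (>= 2 unique peptides): 676
after presence filter: 551
replicate QC: median RSD 27.8%; pair Pearson r: CT1=0.97, CT2=0.98, CT3=0.97
strict profile (p < 0.05, |FC| >= 3): 27 significant proteins
exploratory profile (|FC| >= 2.83, IIM only): 22 over / 80 under (102 total)
top over-enriched sets: planted
top under-enriched sets: planted
config hash: 024263338b58761c97cb65f2454a6b1c
```

Reading it: 700 simulated proteins enter; 676 survive the unique-peptide
filter and 551 the presence filter. The technical duplicates reproduce at a
median RSD of 27.8% with pair correlations ≥ 0.97 — the noise regime the
generator is calibrated to. The default ground truth plants 20 proteins at
+4-fold and 40 at −4-fold: the strict profile calls 27 of them, the
exploratory profile flags 22 over- / 80 underexpressed proteins, and the
planted gene set is the top-enriched set in both directions. All
intermediate tables are written under `output_dir` as TSV.

Real data enter the same way via
`pipeline_config(counts_path = ..., sheet_path = ..., gmt_paths = ...)`;
the expected formats are a TSV count table
(`protein_id  length_aa  unique_peptides  <run...>`), a TSV sample sheet
(`run_id  sample_id  group  replicate_index`, groups in
`{control, IIM, MM}`), and standard GMT gene-set files.

A thin CLI wrapper lives at `inst/cli/organoproteo.R`:

```sh
Rscript inst/cli/organoproteo.R simulate --out simdir --seed 4
Rscript inst/cli/organoproteo.R run --config cfg.json --out rundir
```

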