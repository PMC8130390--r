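# hepsig

Hepatocyte gene signatures and index-based cell classification for liver
tumor / para-carcinoma transcriptomics.

## What it does, and for whom

Analysts of hepatocellular carcinoma (HCC) single-cell and bulk RNA-seq data
repeatedly need to answer: which cells are hepatocytes, how differentiated
are they, and which of them are proliferating? `hepsig` implements a
signature-index pipeline for these questions:

1. **Derive** a hepatocyte-specific gene set from a multi-cell-type atlas:
   per-type fraction-of-cells-expressing profiles, a two-threshold
   specificity filter (fraction < 0.1 in every excluded stem/progenitor
   type, > 0.5 in at least one other type), Euclidean + ward.D2 hierarchical
   clustering with a k-group tree cut, selection of the most target-specific
   cluster, and a 2-group refinement on a Z-scored multi-tissue bulk panel.
2. **Score** units with a signature index. For sample *k* over signature
   genes *1..n* with Z-scored expression *Z<sub>ik</sub>*:
   Hep<sub>k</sub> = median(Z<sub>1k</sub>, ..., Z<sub>nk</sub>) for bulk,
   and the **mean** instead of the median for single cells (sequencing depth
   is too low for a median, which would be zero for most cells). The same
   construction over a stem/progenitor-derived signature gives the
   proliferation ("S1") index.
3. **Call** hepatocytes with a reproducible threshold: the per-cell Hep
   index of mixed tissue fits a two-component mixture
   *w* λe<sup>−λ(v−s)</sup> + (1−*w*) N(v; μ, σ²), fitted by EM; the calling
   threshold is the posterior-0.5 crossover (equal weighted component
   densities). Cells above it are hepatocytes; hepatocytes with S1 index
   above 0.1 are proliferative hepatocytes.
4. **Classify** macrophages (≥ 2 of ITGAM, CD68, CD163, CD14, FCGR3A
   expressed) and stratify them by tissue of origin and ferroportin status
   into N_exp / N_noexp / T_exp / T_noexp, with marker-percentage and
   contingency summaries.
5. **Compare** groups: Wilcoxon rank-sum differential expression with
   Bonferroni control (exact permutation p-values for small groups, normal
   approximation with tie correction otherwise), Pearson index correlation
   with the t-based P, and Welch t-tests with figure-style star annotation.

Seeded synthetic-data generators (`generate_atlas`, `generate_bulk_panel`,
`generate_tumor_para`, `generate_dev_timeseries`) emulate the statistical
structure of the real inputs with ground-truth labels, so the entire pipeline
is testable without downloading any dataset. Supported real-data formats:
10x-style MTX triplets, dense TSV/CSV tables, gene-list files and per-cell
metadata TSVs (`read_matrix`, `read_gene_list`, `read_unit_meta`).

## Worked example

```r
library(hepsig)

## derive a liver signature from a synthetic atlas + bulk panel
atlas <- generate_atlas(seed = 1)
bulk  <- generate_bulk_panel(seed = 2)
profile <- build_celltype_profile(atlas$matrix, atlas$type_labels)
sig <- derive_signature(profile, atlas$truth$excluded_types, "hepatocyte",
                        bulk$matrix, bulk$tissue_labels, "Liver")
sig
#> gene_signature 'hepatocyte_signature': 24 genes
length(intersect(sig$genes, bulk$truth$liver_genes))
#> [1] 24        # all 24 planted liver-specific genes, nothing else

## score a synthetic tumor/para single-cell dataset and call cells
tp  <- generate_tumor_para(seed = 1)
z   <- zscore_by_gene(rp10k_normalize(tp$matrix))
hep <- score_signature(z, tp$hep_signature, "mean")
s1  <- score_signature(z, tp$s1_signature,  "mean")
fit <- fit_exp_normal(hep$scores)
fit
#> mixture_fit (n=6000, converged after 13 EM iterations)
#>   exponential: weight 0.562, rate 2.726, shift -1.1276
#>   normal:      weight 0.438, mu 0.9772, sigma 0.1502
#>   loglik -2686.957, calling threshold 0.5386

ann <- classify_hepatocytes(hep, s1, hep_threshold = fit$threshold,
                            unit_meta = tp$matrix$unit_meta)
ann <- call_macrophages(tp$matrix, ann)
ann <- assign_slc40a1_groups(tp$matrix, ann)
table(ann$cell_class)
#>               hepatocyte               macrophage                    other
#>                     2636                      900                     2443
#> proliferative_hepatocyte
#>                       21
table(ann$slc40a1_group)
#>   N_exp N_noexp   T_exp T_noexp
#>     325     132     192     251

## Kupffer-gene positivity among para-carcinoma macrophages
mac <- ann$unit_id[ann$cell_class == "macrophage"]
round(marker_positive_fraction(tp$matrix,
        mac[ann$tissue[match(mac, ann$unit_id)] == "para"],
        c("CD5L", "CETP", "MARCO", "CFP")), 2)
#>  CD5L  CETP MARCO   CFP
#>  0.74  0.72  0.72  0.68
```

Reading the output: the mixture separates a low, exponential-shaped
non-hepatocyte mode from a normal hepatocyte mode around 0.98 and places the
calling threshold at 0.54 where the weighted densities cross; 21 cells clear
both the hepatocyte and the 0.1 proliferation thresholds; macrophages split
into the four ferroportin strata by tissue, and about 70% of para-carcinoma
macrophages express each Kupffer-cell gene (the generator plants 0.7 in para
versus 0.2 in tumor tissue).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end from the installed package: it derives
the signature from freshly generated atlas + bulk data, scores and
classifies a freshly generated tumor/para dataset (mixture fit, posterior
threshold, hepatocyte / proliferative / macrophage / SLC40A1-group calls),
computes the developmental time-series index correlation, and writes the
results JSON to `--out`. All randomness is driven by `--seed`.
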