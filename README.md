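# qtlallele

Dissecting the QTL-allele constitution of quantitative traits in inbred
germplasm panels — and turning it into breeding decisions.

Bi-allelic SNP markers cannot represent the multi-allelic variation that
accumulates in a germplasm collection: a locus segregating for several
haplotypes looks, SNP by SNP, like a set of weak two-allele signals.
`qtlallele` instead groups tightly linked SNPs into **SNP
linkage-disequilibrium blocks (SNPLDBs)** whose distinct haplotypes act
as the alleles of one multi-allelic marker, then fits a **restricted
two-stage multi-locus association model**: a single-locus F-test scan
(against population-structure eigenvector covariates) shrinks the marker
set, and forward–backward stepwise regression with experiment-wise error
control at a normal significance level (α = 0.02) builds one joint
multi-locus model, so no external multiple-testing correction is applied
and the total explained variance cannot overflow the trait heritability.
The detected loci and their per-allele effects form the **QTL-allele
matrix** — a loci × accessions table of the effects each accession
carries — which the package uses to:

* estimate variance components, heritability and the genetic coefficient
  of variation for multi-environment RCBD trials:
  `h² = σ̂g² / (σ̂g² + σ̂ge²/s + σ̂²/(sr))` (multi-environment) and
  `h² = σ̂g² / (σ̂g² + σ̂²/r)` (single environment), `GCV = 100·σ̂g/μ`;
* test allele-frequency differentiation among subpopulations (ecoregions)
  locus by locus with Pearson chi-square (Monte-Carlo fallback for small
  expected counts) and flag group-specific alleles;
* predict **optimal crosses**: for every parent pair, 2,000 fully inbred
  progeny are simulated under a linkage model (adjacent-locus
  recombination `R = 2r/(1+2r)` with `r` from Haldane's map function) or
  an independent-assortment model, and the cross is scored by the
  nearest-rank 99th percentile (maximize) or 1st percentile (minimize)
  of progeny genotypic value;
* filter **candidate genes**: genes within 100 kb of a detected SNPLDB
  that contain SNPs significantly associated with the marker's alleles;
* generate **synthetic panels** (block-structured genotypes with
  subpopulation drift, planted multi-allelic QTLs, multi-environment
  phenotypes at a target heritability) so the whole pipeline is testable
  end to end.

## Worked example

```r
library(qtlallele)

cfg   <- sim_config(n_accessions = 200, n_groups = 4, n_chromosomes = 2,
                    snps_per_chromosome = 60, n_qtl = 8, seed = 42)
study <- simulate_study(cfg)          # genotypes + planted QTLs + trial

markers <- snpldb_markers(study$pop$genotypes)
#> snpldb_set: 23 markers (18 multi-SNP), alleles per marker 2-6

vc <- fit_variance_components(study$obs)
#> variance components (moments, s = 4 environments, r = 2 replications)
#>   genotypic       var_g  = 1.468
#>   genotype x env  var_ge = 0.09888
#>   error           var    = 0.9912
#>   heritability h2 = 0.9081
gcv(vc)                               # 5.85 (%)

fit <- rtm_gwas(markers, study$obs, trait = "Oil")
summary(fit)
#> Two-stage multi-locus association, trait Oil (n = 200, alpha = 0.02)
#>   stage 1: 23 markers scanned, 8 candidates (p < 0.05)
#>   selected 4 QTL; marker R2 = 60.31%, covariate R2 = 28.62%
#>        qtl                    marker n_alleles neglog10p seq_r2 partial_r2
#>  Oil-a-2-1   Gm02_BLOCK3_92400_93000         5     39.61  24.47      22.66
#>  Oil-a-1-2 Gm01_BLOCK6_245000_246800         6     38.42  19.71      22.26
#>  Oil-a-1-3 Gm01_BLOCK8_338200_339400         6     19.90  11.60       9.04
#>  Oil-a-1-1   Gm01_BLOCK1_60000_60800         5     11.33   4.53       4.53
```

The marker R² (60.3%) stays below the estimated heritability (0.908) —
the joint multi-locus model cannot overflow it. Each selected block is a
QTL named `<Trait>-a-<chromosome>-<serial>`; `neglog10p` is the
partial-F p-value of the allele factor in the joint model, `seq_r2` the
selection-order sum-of-squares contribution (these sum exactly to the
marker R²), `partial_r2` the last-entry contribution.

```r
qam <- build_qam(fit, markers, partition = study$pop$partition)
#> qtl_allele_matrix: 4 loci x 200 accessions (cells = allele effects)
#>   effect range -0.89 to 1.21; population mean 20.34
count_signed_alleles(qam)             # positive/negative alleles per line

map <- build_genetic_map(data.frame(marker = fit$qtl$marker,
                                    chrom = fit$qtl$chrom,
                                    pos_bp = fit$qtl$start_bp))
A <- allele_assignments(markers[fit$selected])
enumerate_and_rank(A[1:25, ], fit, map, study$pop$partition[1:25],
                   n_progeny = 2000, seed = 42, top_k = 3)
#> cross_table: 300 crosses, direction max, ranking model linkage
#>       p1      p2 pred_linkage pred_independent
#>  ACC0006 ACC0011     23.36183         23.36183
#>  ...
```

The best predicted cross (23.36) is transgressive: complementary
positive alleles pyramid beyond either parent's own genotypic value.

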