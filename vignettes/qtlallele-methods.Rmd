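---
title: "Methods: multi-allelic block markers, two-stage multi-locus association, and QTL-allele based cross prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-allelic block markers, two-stage multi-locus association, and QTL-allele based cross prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlallele)
```

## The problem

A germplasm panel of inbred landraces carries, at each functional locus,
not two but several alleles — haplotypes accumulated over the
population's history. A genome-wide scan of bi-allelic SNPs dilutes such
a locus into several partially redundant two-allele tests, and a
single-locus model tested marker by marker either floods the results
with false positives (no correction) or misses most of the genetic
architecture (Bonferroni-style correction). `qtlallele` implements the
alternative: multi-allelic haplotype-block markers analysed jointly in
one multi-locus model, with the detected allele effects organised into a
QTL-allele matrix that downstream tools (differentiation tests, cross
prediction, candidate-gene filtering) consume directly.

## SNPLDB markers

Inbred accessions are homozygous, so each accession's genotype string
over a set of linked SNPs *is* its haplotype; no phasing is involved.
Blocks are called with a Gabriel-style confidence-interval rule on D′:

* For each SNP pair within a physical window, D′ and a two-sided 90%
  interval are computed by profiling the multinomial likelihood of the
  four haplotype counts over D′ ∈ [0, 1] with allele frequencies fixed
  at their observed values (101 grid points; the normalized profile's
  5th and 95th percentiles are the bounds).
* A pair is *strong LD* when the bounds satisfy lower ≥ 0.70 and
  upper ≥ 0.98, and *strong recombination* when upper < 0.90; other
  pairs are uninformative.
* A candidate block is a run of consecutive SNPs on one chromosome,
  spanning at most `max_block_bp` (default 200,000 bp, matching the
  largest spans one sees in dense soybean panels), with at least 95% of
  informative pairs in strong LD. Candidates are accepted greedily
  longest-first; everything left over becomes a singleton block, so the
  blocks partition the SNP set exactly.

Within a block, the distinct genotype strings are candidate alleles.
Strings rarer than `min_allele_freq` (default 0.01, which caps allele
counts near the 2–9 range realistic for a few-hundred-accession panel)
are merged into their Hamming-nearest frequent haplotype; ties go to the
more frequent, then lexicographically smaller, target. Rare-class
handling was a genuinely open choice — collapsing all rare strings into
one synthetic class was the alternative — but Hamming-nearest keeps each
merged accession closest to a real haplotype and never invents an allele
absent from the panel. Monomorphic blocks yield no marker. Marker ids
follow `<chrom>_<pos>` (singleton) and `<chrom>_BLOCK<k>_<start>_<end>`
conventions.

Missing calls are imputed to the per-SNP major allele before block
calling (`impute_major()`), and heterozygous calls are set to missing at
ingestion: the target panels are inbred, so residual heterozygosity is
treated as genotyping noise. Both operations report counts.

## Population structure

The similarity of two accessions is the fraction of markers at which
they carry the same allele. The top k eigenvectors (default k = 10) of
the double-centered similarity matrix enter every association model as
fixed covariates and are never candidates for removal. The reported
cumulative variance fraction is the share of positive eigenvalue mass.

## The two-stage multi-locus model

Association uses one across-environment mean phenotype per accession.

**Stage 1** tests each marker separately: an F-test of the allele-class
factor (allele count − 1 numerator df — one test per locus, not per
contrast, which is what makes the marker genuinely multi-allelic) added
to the covariate-only model. Markers with p < 0.05 (configurable)
proceed, ordered by ascending p.

**Stage 2** builds the joint model by forward–backward stepwise
regression. The forward step takes the candidate with the smallest
partial-F p-value and admits it when its *experiment-wise* p-value is
below α (default 0.02): the partial p is Šidák-adjusted over the m
markers scanned genome-wide in stage 1, `1 − (1 − p)^m`. This is the
model's built-in experiment-wise error control — the smallest p among m
null markers is itself a random variable with distribution
`1 − (1 − p)^m`, so admitting on the adjusted value holds the
probability of any false selection near α per experiment, and no
posterior multiple-testing correction is applied. A naive unadjusted
entry rule at α = 0.02 would select a null marker in essentially every
scan of a few hundred markers; the package's null-calibration tests
(200 accessions, 500 null markers) verify the adjusted rule selects
anything in only a few percent of runs while a planted locus with
R² = 0.3 is recovered essentially always. The backward step removes any
included marker whose joint-model partial-F p is ≥ α, so every retained
locus is significant in the final joint model. Ties on p break by
ascending genome position; the procedure is deterministic and invariant
to candidate input order.

Per-locus contributions are reported two ways, because the choice is
genuinely ambiguous: `seq_r2`, the selection-order sequential
sum-of-squares fraction (these sum *exactly* to the marker share of the
model R², and covariate R² + marker R² + residual fraction = 1), and
`partial_r2`, the last-entry fraction. Sequential is the default
reported column. Allele effects come from zero-sum (deviation) coding of
each allele factor, so each locus's unweighted effect sum is 0 and the
intercept is the population mean term; alleles absent from the
phenotyped accessions get no effect (reported). Since the loci are
jointly fitted, the total detected R² is bounded by the model R² and in
practice stays below the estimated heritability — the key sanity
property asserted in the acceptance tests.

## Variance components, heritability, GCV

Trials are randomized complete block designs replicated in r blocks
within each of s environments, with genotype, environment, replication
within environment, and genotype-by-environment all random. For balanced
data the expected-mean-squares method-of-moments estimators of the
two-way ANOVA are used — `σ̂² = MS_error`, `σ̂ge² = (MS_GE − MS_error)/r`,
`σ̂g² = (MS_G − MS_GE)/(sr)` — which coincide with REML on balanced data
when all estimates are interior; unbalanced data are routed to an
iterative REML fit (`lme4`, bobyqa with a tight convergence radius so
the balanced-data agreement holds to ~1e-6). Negative estimates are
truncated at zero and reported; estimates below 1e-10 of the data's
squared scale are snapped to exact zero so constant data give exact
zeros. Mean squares are exposed so users can audit the ANOVA layout.

Heritability is evaluated on an entry-mean basis,
`σ̂g²/(σ̂g² + σ̂ge²/s + σ̂²/(sr))` (multi-environment) or
`σ̂g²/(σ̂g² + σ̂²/r)` (single environment), clipped to [0, 1]; an
all-zero component set is an error, distinct from h² = 0. The genetic
coefficient of variation is `100·σ̂g/μ̂`.

## Differentiation among subpopulations

For each locus, the allele × group count table is tested for
independence by Pearson chi-square. When any expected count is below 5
the asymptotic p is replaced by a Monte-Carlo permutation p (10,000
resamples, seeded) and flagged. Raw p-values are reported alongside a
Benjamini–Hochberg FDR column — the differentiation literature usually
reports raw significance, so both are exposed and the `significant`
flag follows raw p. Alleles carried by at most two groups are listed as
group-specific. The highest-frequency allele at each locus is labeled
the "original" allele in the QTL-allele matrix metadata; this is
descriptive, not inferential.

## Cross prediction

Only the detected loci matter for prediction, so a genetic map over
them suffices. Map positions default to physical position × 2.5 cM/Mb —
a soybean-scale average, fully overridable by an explicit map — and
adjacent-locus meiotic recombination comes from Haldane's function
`r = (1 − e^(−2d/100))/2`; loci on different chromosomes get r = 0.5.

"Continuously inbred progenies" are modeled at complete homozygosity
(F∞ recombinant inbred lines): between adjacent loci the parental origin
switches with the Haldane–Waddington probability `R = 2r/(1 + 2r)`. The
generation number is not identified by the percentile statistic at the
panel scales involved, so F∞ is the fixed choice. Progeny are simulated
as a two-state Markov chain along each chromosome; the
independent-assortment model forces R = 0.5 everywhere, and the two
models coincide exactly when all adjacent r = 0.5 (a convergence the
tests assert). Genotypic value is additive: μ plus the carried allele's
effect at each locus — dominance cannot appear in fully inbred lines and
epistasis is deliberately out of model.

A cross's predicted value is the nearest-rank percentile (the ⌈qn⌉-th
order statistic — deterministic and platform-independent, unlike
interpolated quantiles) of n = 2,000 simulated progeny: the 99th
percentile when maximizing, the 1st when minimizing. Per-cross seeds are
derived from the global seed and the *sorted* parent pair, so results
are independent of enumeration order and parallelization. An exact
oracle (`exact_small_cross()`) enumerates all 2^L origin vectors with
chain probabilities for ≤ 12 segregating loci; the acceptance tests
require the Monte-Carlo percentile to land within half of the smallest
per-locus effect gap of the exact percentile in ≥ 95% of random
fixtures. `enumerate_and_rank()` scores all C(n, 2) unordered pairs and
summarizes within- and among-group extremes; `multi_trait_select()`
ranks crosses by an equally-weighted (configurable) sum of standardized
per-trait predictions, with minimize-direction traits sign-flipped.

## Candidate genes

Three filters compose: (1) the gene's interval overlaps a detected
marker's block or the gap between intervals — counted in bases strictly
between them, so overlap and abutment are distance 0 — is strictly less
than 100 kb; (2) the gene contains at least one SNP segregating in the
panel; (3) at least one of those SNPs is associated with the marker's
allele classes by chi-square at α_gene (default 0.05; the literature
rarely states this α, so it is exposed rather than inferred). The
candidate list is monotone in the window by construction.

## The synthetic-population generator

The generator exists so every stage is testable without restricted
data. Its defaults emulate the study conditions of a large landrace
panel: 366 accessions in 6 subpopulations, blocks of 1–10 SNPs, pools
of 2–6 haplotypes per block, 50 planted QTLs, 4 environments × 2
replications, target multi-environment h² = 0.90, genotypic-to-
interaction variance ratio 10 (echoing the roughly tenfold ratios such
panels report), σ_env² = σ² (environments are random with error-sized
spread), and a genetic coefficient of variation near 6% of μ = 20.

Block haplotype pools are drawn on a mutation tree under infinite
sites: each new pool haplotype copies an existing one and mutates sites
not yet mutated in the pool. Every informative SNP pair inside a block
therefore passes the four-gamete test (D′ = 1), exactly the signature
of a non-recombined LD block — an earlier design that drew arbitrary
distinct haplotypes produced blocks whose internal D′ could be low,
which no real block-calling criterion would (or should) reconstruct.
Between blocks, draws are independent; subpopulation haplotype
frequencies drift from the ancestral pool frequencies by a
Balding–Nichols Dirichlet with concentration `p(1 − F)/F` (default
F = 0.05), which reproduces significant but modest among-group
differentiation without modeling pedigree history.

Phenotypes are `μ + g + env + g×e + error` with the genotypic values
rescaled so the panel variance of g equals σg² exactly; environment
effects, interactions and plot errors are independent normals with the
configured variances, so the multi-environment h² formula evaluates to
the target in expectation. Everything is deterministic given the seed.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: LD decay within and between blocks (LD
is all-or-nothing), mutation/genotyping error, non-additive gene
action, unbalanced or missing field data (covered only by dedicated
unbalanced-path tests), and ascertainment bias in SNP discovery.

## Numerical choices and problem sizes

All model fitting is QR-based with rank detection at 1e-8; candidates
adding no rank (collinear with covariates or selected loci) are skipped
and reported. The χ² implementation is checked against a direct
Σ(O−E)²/E oracle to 1e-10. Simulation-based test sizes — 20 seeds at
n = 300 for heritability recovery, 100 replicates of (n = 200, 500
markers) for null calibration and power, 100 random fixtures for the
Monte-Carlo/exact percentile comparison, 10,000 progeny for the
Haldane–Waddington closed-form checks — were chosen so each check's
sampling noise is several times smaller than the tolerance it asserts.

## Known limitations

No kinship-based mixed model (the eigenvector covariates are the only
structure correction); no BCF or genotype-likelihood input; no AMOVA;
no within-block phasing beyond the inbred assumption; cross prediction
ignores selection during inbreeding and any non-additive effects; the
block algorithm is greedy, so a different tie-break can produce a
different (equally valid) partition on pathological inputs.
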