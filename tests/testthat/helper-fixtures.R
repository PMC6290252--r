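# Shared in-code fixtures for the suite.

# A bare bi-/multi-allelic marker without going through block calling.
make_marker <- function(id, chrom, pos, allele_of, end = pos) {
  stopifnot(!is.null(names(allele_of)))
  allele_of <- stats::setNames(as.integer(allele_of), names(allele_of))
  K <- max(allele_of)
  structure(list(id = id, chrom = chrom, start_bp = pos, end_bp = end,
                 snp_ids = id, alleles = as.character(seq_len(K)),
                 allele_of = allele_of,
                 freqs = as.numeric(tabulate(allele_of, K)) /
                   length(allele_of)),
            class = "snpldb")
}

# m independent bi-allelic markers on one chromosome (null genotypes).
null_markers <- function(n_acc, m, seed, maf = 0.5) {
  set.seed(seed)
  acc <- sprintf("A%04d", seq_len(n_acc))
  mk <- lapply(seq_len(m), function(j) {
    repeat {
      a <- sample(1:2, n_acc, replace = TRUE, prob = c(maf, 1 - maf))
      if (length(unique(a)) == 2) break
    }
    make_marker(sprintf("Gm01_%d", j * 1000), "Gm01", j * 1000L,
                stats::setNames(a, acc))
  })
  names(mk) <- vapply(mk, `[[`, "", "id")
  mk
}

# Tiny genotype matrix built from an explicit call matrix.
toy_genotypes <- function(calls, chrom = NULL, pos = NULL) {
  if (is.null(chrom)) chrom <- rep("Gm01", ncol(calls))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  genotype_matrix(calls, chrom, pos)
}

# Small simulated study used by several files.
small_study <- function(seed = 1, n = 80, n_qtl = 4) {
  cfg <- sim_config(n_accessions = n, n_groups = 2, n_chromosomes = 2,
                    snps_per_chromosome = 40, n_qtl = n_qtl, seed = seed)
  list(cfg = cfg, st = simulate_study(cfg))
}

# Direct Pearson chi-square oracle, independent of stats::chisq.test.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
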