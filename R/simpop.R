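#' Configuration for the synthetic germplasm panel generator
#'
#' Defines the statistical structure of a simulated inbred landrace panel:
#' haplotype-block genotypes with subpopulation drift, multi-allelic QTLs
#' hosted in blocks, and a multi-environment randomized-complete-block
#' phenotype. Defaults emulate a 366-accession panel from six ecoregions
#' grown in 4 environments x 2 replications with heritability near 0.90
#' and a genotypic-to-interaction variance ratio near 10.
#'
#' Phenotypic variance is partitioned explicitly: if `var_g`, `var_ge` and
#' `var_error` are all supplied they are used as given; otherwise they are
#' derived from `target_h2` and `ge_ratio` with `var_g` fixed so the
#' genetic coefficient of variation is `gcv_pct` of `mu`.
#'
#' @param n_accessions number of inbred accessions.
#' @param n_groups number of subpopulations (ecoregions).
#' @param n_chromosomes,snps_per_chromosome genome dimensions.
#' @param block_snps integer vector sampled for planted-block sizes (SNPs
#'   per LD block; 1 = singleton).
#' @param pool_sizes integer vector sampled for the per-block haplotype
#'   pool size (distinct haplotypes segregating in the panel).
#' @param n_qtl number of planted QTLs (each hosted by one multi-haplotype
#'   block; must not exceed the number of such blocks).
#' @param drift Balding-Nichols-style fixation index controlling how far
#'   subpopulation haplotype frequencies drift from the ancestral pool
#'   frequencies; 0 = no differentiation.
#' @param mu population mean of the trait (trait units).
#' @param target_h2 multi-environment heritability the phenotype model is
#'   calibrated to.
#' @param ge_ratio ratio `var_g / var_ge`.
#' @param gcv_pct genetic coefficient of variation (percent) used to set
#'   `var_g` when variance components are not given explicitly.
#' @param var_g,var_ge,var_error optional explicit variance components
#'   (genotypic, genotype-by-environment, plot error).
#' @param var_env environment main-effect variance; defaults to
#'   `var_error` (environments are random with error-sized spread).
#' @param n_environments,n_replications trial dimensions (s and r).
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 366, n_groups = 6,
                       n_chromosomes = 5, snps_per_chromosome = 400,
                       block_snps = 1:10, pool_sizes = 2:6,
                       n_qtl = 50, drift = 0.05, mu = 20,
                       target_h2 = 0.90, ge_ratio = 10, gcv_pct = 6,
                       var_g = NULL, var_ge = NULL, var_error = NULL,
                       var_env = NULL,
                       n_environments = 4, n_replications = 2,
                       seed = 1) {
  s <- n_environments; r <- n_replications
  if (is.null(var_g) || is.null(var_ge) || is.null(var_error)) {
    if (target_h2 <= 0 || target_h2 > 1)
      stop("target_h2 must be in (0, 1]")
    var_g <- (gcv_pct / 100 * mu)^2
    var_ge <- var_g / ge_ratio
    # solve target_h2 = vg / (vg + vge/s + ve/(s r)) for ve
    var_error <- s * r * (var_g / target_h2 - var_g - var_ge / s)
    if (var_error < 0) stop("target_h2 unreachable with this ge_ratio")
  } else {
    target_h2 <- var_g / (var_g + var_ge / s + var_error / (s * r))
  }
  if (is.null(var_env)) var_env <- var_error
  cfg <- list(n_accessions = n_accessions, n_groups = n_groups,
              n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome,
              block_snps = block_snps, pool_sizes = pool_sizes,
              n_qtl = n_qtl, drift = drift, mu = mu,
              target_h2 = target_h2,
              var_g = var_g, var_ge = var_ge, var_error = var_error,
              var_env = var_env,
              n_environments = s, n_replications = r, seed = seed)
  stopifnot(n_accessions >= 2, n_groups >= 1, n_chromosomes >= 1,
            snps_per_chromosome >= 1, all(block_snps >= 1),
            all(pool_sizes >= 1), n_qtl >= 0, drift >= 0, drift < 1,
            s >= 1, r >= 1, var_g >= 0, var_ge >= 0, var_error >= 0)
  structure(cfg, class = "sim_config")
}

# Dirichlet draw via independent gammas.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (all(x == 0)) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate block-structured genotypes with subpopulation drift
#'
#' Within each planted block, accession genotypes are drawn jointly from a
#' small pool of block haplotypes (producing high within-block LD);
#' different blocks segregate independently. Each subpopulation's
#' haplotype frequencies drift from the ancestral pool frequencies by a
#' Balding-Nichols Dirichlet with concentration `p * (1 - F) / F`
#' (fixation index `F = drift`).
#'
#' @param cfg a [sim_config].
#' @return A list of class `sim_population` with elements
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix]}
#'     \item{blocks}{data.frame of planted blocks (chromosome, SNP index
#'       range, pool size)}
#'     \item{block_haplotypes}{list of per-block pool haplotype matrices
#'       (haplotype x SNP, 0/1)}
#'     \item{hap_of}{accession x block matrix of drawn haplotype indices}
#'     \item{partition}{named factor of group labels}
#'   }
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions
  acc <- sprintf("ACC%04d", seq_len(n))
  grp <- factor(sprintf("G%d", 1 + (seq_len(n) - 1) %% cfg$n_groups),
                levels = sprintf("G%d", seq_len(cfg$n_groups)))
  names(grp) <- acc

  blocks <- list(); haps <- list(); chroms <- character(); starts <- integer()
  # carve each chromosome's SNPs into planted blocks
  for (ch in seq_len(cfg$n_chromosomes)) {
    left <- cfg$snps_per_chromosome
    while (left > 0) {
      len <- sample(cfg$block_snps, 1)
      len <- min(len, left)
      blocks[[length(blocks) + 1]] <- c(ch, len)
      left <- left - len
    }
  }
  nb <- length(blocks)
  block_chr <- vapply(blocks, `[`, 0, 1)
  block_len <- vapply(blocks, `[`, 0, 2)

  # positions: SNPs inside a block ~200 bp apart, ~30 kb between blocks
  chrom <- character(0); pos <- integer(0)
  for (ch in seq_len(cfg$n_chromosomes)) {
    p <- 0L
    for (b in which(block_chr == ch)) {
      p <- p + 30000L
      bp <- p + 200L * (seq_len(block_len[b]) - 1L)
      chrom <- c(chrom, rep(sprintf("Gm%02d", ch), block_len[b]))
      pos <- c(pos, bp)
      p <- bp[length(bp)]
    }
  }

  # pools, group frequencies, accession draws
  hap_of <- matrix(0L, n, nb, dimnames = list(acc, NULL))
  calls <- matrix(0L, n, length(pos))
  pools <- vector("list", nb)
  col0 <- 0L
  gidx <- split(seq_len(n), grp)
  for (b in seq_len(nb)) {
    L <- block_len[b]
    K <- sample(cfg$pool_sizes, 1)
    K <- min(K, L + 1L)
    # haplotypes on a mutation tree (infinite sites, no recombination):
    # each SNP mutates once on one branch, so every informative SNP pair
    # inside the block passes the four-gamete test (D' = 1), as in a real
    # non-recombined LD block
    pool <- matrix(0L, K, L)
    if (K > 1) {
      free <- sample.int(L)  # sites not yet mutated, random order
      # distribute the L sites over the K - 1 branches, >= 1 each
      nmut <- drop(stats::rmultinom(1, L - (K - 1), rep(1, K - 1))) + 1L
      at <- 1L
      for (k in 2:K) {
        parent <- sample.int(k - 1, 1)
        sites <- free[at:(at + nmut[k - 1] - 1L)]
        at <- at + nmut[k - 1]
        pool[k, ] <- pool[parent, ]
        pool[k, sites] <- 1L - pool[k, sites]
      }
    }
    anc <- rdirichlet1(rep(2, K))
    for (g in seq_along(gidx)) {
      f <- if (cfg$drift > 0 && K > 1)
        rdirichlet1(anc * (1 - cfg$drift) / cfg$drift)
      else anc
      draw <- sample.int(K, length(gidx[[g]]), replace = TRUE, prob = f)
      hap_of[gidx[[g]], b] <- draw
    }
    calls[, col0 + seq_len(L)] <- pool[hap_of[, b], , drop = FALSE]
    pools[[b]] <- pool
    col0 <- col0 + L
  }
  snp_ids <- paste0(chrom, "_", pos)
  dimnames(calls) <- list(acc, snp_ids)

  block_tab <- data.frame(
    block = seq_len(nb),
    chrom = sprintf("Gm%02d", block_chr),
    first_snp = c(1L, 1L + cumsum(block_len))[seq_len(nb)],
    n_snps = block_len,
    pool_size = vapply(pools, nrow, 0L))
  block_tab$last_snp <- block_tab$first_snp + block_tab$n_snps - 1L

  structure(list(
    genotypes = genotype_matrix(calls, chrom, pos),
    blocks = block_tab,
    block_haplotypes = pools,
    hap_of = hap_of,
    partition = grp), class = "sim_population")
}

#' Plant multi-allelic QTL effects into simulated blocks
#'
#' Chooses `n_qtl` blocks with at least two pool haplotypes as QTLs and
#' draws an additive effect per haplotype allele, re-centered to an exact
#' unweighted zero sum per locus.
#'
#' @param pop a `sim_population` from [simulate_genotypes()].
#' @param cfg the [sim_config] used to build it.
#' @return A list of class `true_model` with `mu`, `qtl_blocks` (block
#'   indices) and `effects` (list of per-haplotype effect vectors).
#' @export
plant_qtls <- function(pop, cfg) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(cfg$seed + 1000L)
  poly <- which(pop$blocks$pool_size >= 2)
  if (cfg$n_qtl > length(poly))
    stop("more QTLs requested than polymorphic blocks available")
  qtl <- sort(sample(poly, cfg$n_qtl))
  eff <- lapply(qtl, function(b) {
    e <- stats::rnorm(pop$blocks$pool_size[b])
    e - mean(e)
  })
  structure(list(mu = cfg$mu, qtl_blocks = qtl, effects = eff),
            class = "true_model")
}

#' True genotypic values of simulated accessions
#'
#' Sum of planted allele effects over QTLs, rescaled (about its mean) so
#' the panel genotypic variance equals `var_g` exactly, plus `mu`.
#'
#' @param model a `true_model`.
#' @param pop the `sim_population` hosting it.
#' @param cfg the [sim_config].
#' @return Named numeric vector of genotypic values (trait units).
#' @export
genotypic_values_true <- function(model, pop, cfg) {
  n <- nrow(pop$hap_of)
  g <- numeric(n)
  for (k in seq_along(model$qtl_blocks)) {
    b <- model$qtl_blocks[k]
    g <- g + model$effects[[k]][pop$hap_of[, b]]
  }
  v <- stats::var(g)
  if (v > 0) g <- (g - mean(g)) * sqrt(cfg$var_g / v)
  else if (cfg$var_g > 0 && length(model$qtl_blocks) > 0)
    warning("planted QTLs are monomorphic in the panel; genotypic variance 0")
  stats::setNames(model$mu + g, rownames(pop$hap_of))
}

#' Simulate a multi-environment RCBD phenotype
#'
#' `value = mu + genotypic value + environment effect + GxE + plot error`,
#' with environment effects N(0, var_env), interaction N(0, var_ge) and
#' errors N(0, var_error), so the multi-environment heritability formula
#' evaluates to `target_h2` in expectation.
#'
#' @param model a `true_model` from [plant_qtls()].
#' @param pop the `sim_population`.
#' @param cfg the [sim_config].
#' @param seed seed for the trial noise (defaults to `cfg$seed + 2000`).
#' @return A `trait_obs` table with `n_accessions * s * r` records.
#' @export
simulate_trait <- function(model, pop, cfg, seed = cfg$seed + 2000L) {
  if (cfg$target_h2 == 0 && length(model$qtl_blocks) > 0 && cfg$var_g > 0)
    stop("target_h2 = 0 is inconsistent with nonzero QTL effects")
  set.seed(seed)
  g <- genotypic_values_true(model, pop, cfg)
  n <- length(g); s <- cfg$n_environments; r <- cfg$n_replications
  env <- sprintf("E%d", seq_len(s))
  env_eff <- stats::rnorm(s, 0, sqrt(cfg$var_env))
  ge <- matrix(stats::rnorm(n * s, 0, sqrt(cfg$var_ge)), n, s)
  rec <- expand.grid(accession = names(g), environment = env,
                     replication = sprintf("R%d", seq_len(r)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ai <- match(rec$accession, names(g))
  ei <- match(rec$environment, env)
  err <- stats::rnorm(nrow(rec), 0, sqrt(cfg$var_error))
  rec$value <- g[ai] + env_eff[ei] + ge[cbind(ai, ei)] + err
  trait_obs(rec$accession, rec$environment, rec$replication, rec$value)
}

#' One-call synthetic study
#'
#' Convenience wrapper: genotypes, planted QTLs and phenotype in one call.
#' @param cfg a [sim_config].
#' @return List with `pop`, `model`, `obs`, `true_g` (genotypic values).
#' @export
simulate_study <- function(cfg = sim_config()) {
  pop <- simulate_genotypes(cfg)
  model <- plant_qtls(pop, cfg)
  obs <- simulate_trait(model, pop, cfg)
  list(pop = pop, model = model, obs = obs,
       true_g = genotypic_values_true(model, pop, cfg))
}
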