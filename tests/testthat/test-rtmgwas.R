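test_that("stage-1 scan: null, perfect-signal and skip behavior", {
  mk <- null_markers(60, 10, seed = 31)
  acc <- names(mk[[1]]$allele_of)
  # constant phenotype: nothing to explain
  s1 <- stage1_scan(mk, stats::setNames(rep(3, 60), acc))
  expect_true(all(s1$p == 1))
  expect_true(all(s1$r2 == 0))
  # phenotype equal to the allele index of one marker: R2 = 1 there
  y <- stats::setNames(as.numeric(mk[[4]]$allele_of), acc)
  s1 <- stage1_scan(mk, y)
  expect_equal(s1$r2[4], 1, tolerance = 1e-12)
  expect_lt(s1$p[4], 1e-30)
  expect_true(all(s1$r2[-4] < 1))
  # a marker monomorphic among phenotyped accessions is skipped
  mono <- make_marker("Gm01_99", "Gm01", 99L,
                      stats::setNames(rep(1L, 60), acc))
  mono$alleles <- c("1", "2"); mono$freqs <- c(1, 0)
  expect_warning(s1b <- stage1_scan(c(mk, list(Gm01_99 = mono)), y),
                 "skipped")
  expect_true(is.na(s1b$p[11]))
})

test_that("stage-1 p-values are calibrated under the null", {
  fracs <- vapply(1:10, function(s) {
    mk <- null_markers(200, 1000, seed = 500 + s)
    set.seed(600 + s)
    y <- stats::setNames(rnorm(200), names(mk[[1]]$allele_of))
    s1 <- stage1_scan(mk, y)
    mean(s1$p < 0.05)
  }, 0)
  expect_true(abs(mean(fracs) - 0.05) < 0.02)
})

test_that("preselect keeps markers below threshold, ordered by p", {
  s1 <- data.frame(marker = c("a", "b", "c"),
                   p = c(0.2, 0.001, 0.04))
  expect_identical(preselect(s1, 0.05), c("b", "c"))
  expect_identical(preselect(s1, 1.0), c("b", "c", "a"))
  expect_message(out <- preselect(s1, 0), "no candidates")
  expect_length(out, 0)
})

test_that("stepwise recovers planted QTLs with accurate R2", {
  set.seed(41)
  mk <- null_markers(200, 50, seed = 41)
  acc <- names(mk[[1]]$allele_of)
  a1 <- mk[[10]]$allele_of  # two independent bi-allelic loci
  a2 <- mk[[30]]$allele_of
  # scale effects for true R2 near 0.3 and 0.2 at h2 = 1 (no noise beyond
  # the remaining allelic variance)
  z1 <- (a1 - mean(a1)) / stats::sd(a1)
  z2 <- (a2 - mean(a2)) / stats::sd(a2)
  y <- stats::setNames(sqrt(0.3) * z1 + sqrt(0.2) * z2 +
                         sqrt(0.5) * rnorm(200), acc)
  fit <- rtm_gwas(mk, y, k_eigen = 0)
  expect_true(all(c(mk[[10]]$id, mk[[30]]$id) %in% fit$selected))
  r2 <- fit$qtl$seq_r2[match(c(mk[[10]]$id, mk[[30]]$id), fit$qtl$marker)]
  expect_lt(abs(r2[1] - 0.3), 0.05)
  expect_lt(abs(r2[2] - 0.2), 0.05)
})

test_that("selection is invariant to candidate input order", {
  set.seed(43)
  mk <- null_markers(150, 40, seed = 43)
  acc <- names(mk[[1]]$allele_of)
  y <- stats::setNames((mk[[7]]$allele_of == 2) * 1.5 +
                         (mk[[22]]$allele_of == 2) * 1.0 + rnorm(150), acc)
  s1 <- stage1_scan(mk, y)
  cand <- preselect(s1, 0.05)
  sel1 <- stage2_stepwise(cand, mk, y, n_genomewide = 40)
  set.seed(99)
  sel2 <- stage2_stepwise(sample(cand), mk, y, n_genomewide = 40)
  expect_identical(sel1, sel2)
})

test_that("R2 decomposition is exact and consistent", {
  sim <- small_study(seed = 45, n = 100, n_qtl = 4)
  mk <- suppressWarnings(suppressMessages(snpldb_markers(sim$st$pop$genotypes)))
  fit <- suppressMessages(rtm_gwas(mk, sim$st$obs))
  skip_if(length(fit$selected) == 0, "no locus detected in this fixture")
  # sequential R2 sums exactly to the marker share of the model R2
  expect_equal(sum(fit$qtl$seq_r2) + fit$covariate_r2 +
                 sum(fit$residuals^2) / sum((fit$y - mean(fit$y))^2),
               1, tolerance = 1e-8)
  expect_equal(fit$marker_r2 + fit$covariate_r2, fit$model_r2,
               tolerance = 1e-8)
  expect_lte(fit$model_r2, 1)
  # every retained marker is significant at the exit level
  expect_true(all(fit$qtl$partial_p < fit$alpha_exit))
})

test_that("sequential equals marginal R2 for a single-marker model and equals partial on orthogonal designs", {
  # orthogonal two-marker fixture: balanced 2x2 crossing
  acc <- sprintf("A%03d", 1:80)
  a1 <- rep(c(1L, 1L, 2L, 2L), 20)
  a2 <- rep(c(1L, 2L, 1L, 2L), 20)
  mk <- list(make_marker("Gm01_1000", "Gm01", 1000L, setNames(a1, acc)),
             make_marker("Gm01_5000", "Gm01", 5000L, setNames(a2, acc)))
  names(mk) <- c("Gm01_1000", "Gm01_5000")
  set.seed(47)
  y <- stats::setNames(a1 * 1.0 + a2 * 0.7 + rnorm(80, 0, 0.5), acc)
  fit <- rtm_gwas(mk, y, k_eigen = 0, stage1_p = 1)
  expect_setequal(fit$selected, names(mk))
  ix <- match(fit$qtl$marker, names(mk))
  # orthogonality: sequential == partial for both markers
  expect_equal(fit$qtl$seq_r2, fit$qtl$partial_r2, tolerance = 1e-10)
  # single-marker model: sequential equals the stage-1 marginal R2
  fit1 <- rtm_gwas(mk[1], y, k_eigen = 0, stage1_p = 1)
  expect_equal(fit1$qtl$seq_r2, fit1$stage1$r2[1], tolerance = 1e-10)
})

test_that("allele effects are zero-sum deviations recovering class means", {
  acc <- sprintf("A%03d", 1:60)
  a <- rep(c(1L, 2L), 30)
  mk <- list(M = make_marker("Gm02_700", "Gm02", 700L, setNames(a, acc)))
  names(mk) <- "Gm02_700"
  y <- stats::setNames(ifelse(a == 1, 21, 19), acc)
  fit <- rtm_gwas(mk, y, k_eigen = 0, stage1_p = 1)
  eff <- fit$effects[["Gm02_700"]]
  expect_equal(unname(eff["1"]), 1.0, tolerance = 1e-10)
  expect_equal(unname(eff["2"]), -1.0, tolerance = 1e-10)
  expect_equal(fit$mu, 20, tolerance = 1e-10)
  expect_equal(sum(eff), 0, tolerance = 1e-12)
})

test_that("per-locus effect sums are zero on a fitted simulated panel", {
  sim <- small_study(seed = 49, n = 100, n_qtl = 4)
  mk <- suppressWarnings(suppressMessages(snpldb_markers(sim$st$pop$genotypes)))
  fit <- suppressMessages(rtm_gwas(mk, sim$st$obs))
  for (eff in fit$effects)
    expect_equal(sum(eff), 0, tolerance = 1e-8)
})

test_that("a stringent alpha yields a subset of the normal-alpha model", {
  ok <- logical(0)
  for (s in 1:3) {
    cfg <- sim_config(n_accessions = 200, n_groups = 2, n_chromosomes = 2,
                      snps_per_chromosome = 50, n_qtl = 8, target_h2 = 0.9,
                      seed = 700 + s)
    st <- simulate_study(cfg)
    mk <- suppressWarnings(suppressMessages(snpldb_markers(st$pop$genotypes)))
    fit02 <- suppressMessages(rtm_gwas(mk, st$obs, alpha = 0.02))
    fit0002 <- suppressMessages(rtm_gwas(mk, st$obs, alpha = 0.0002))
    ok <- c(ok, all(fit0002$selected %in% fit02$selected))
  }
  expect_true(all(ok))
})

test_that("QTL names follow the trait-chromosome-serial convention", {
  acc <- sprintf("A%03d", 1:80)
  a1 <- rep(c(1L, 2L), 40); a2 <- rep(c(1L, 1L, 2L, 2L), 20)
  mk <- list(make_marker("Gm20_5000", "Gm20", 5000L, setNames(a1, acc)),
             make_marker("Gm20_900000", "Gm20", 900000L, setNames(a2, acc)))
  names(mk) <- c("Gm20_5000", "Gm20_900000")
  set.seed(51)
  y <- stats::setNames(a1 * 2 + a2 * 1.5 + rnorm(80, 0, 0.3), acc)
  fit <- rtm_gwas(mk, y, k_eigen = 0, stage1_p = 1, trait = "Oil")
  tab <- fit$qtl[order(fit$qtl$start_bp), ]
  expect_identical(tab$qtl, c("Oil-a-20-1", "Oil-a-20-2"))
})

test_that("predict() reproduces fitted genotypic values on training data", {
  sim <- small_study(seed = 53, n = 100, n_qtl = 4)
  mk <- suppressWarnings(suppressMessages(snpldb_markers(sim$st$pop$genotypes)))
  fit <- suppressMessages(rtm_gwas(mk, sim$st$obs, k_eigen = 0))
  skip_if(length(fit$selected) == 0, "no locus detected in this fixture")
  A <- allele_assignments(mk[fit$selected])
  pred <- predict(fit, A)
  # without covariates the fit is mu + sum of allele effects
  expect_equal(unname(pred[names(fit$fitted)]), unname(fit$fitted),
               tolerance = 1e-8)
})
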