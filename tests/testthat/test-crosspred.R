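two_locus_setup <- function(r = 0.2, eff1 = c(1, -1), eff2 = c(0.5, -0.5),
                            mu = 20) {
  ids <- c("M1", "M2")
  # choose physical spacing so Haldane gives exactly r
  d_cm <- if (r == 0) 0 else -50 * log(1 - 2 * r)
  map <- build_genetic_map(data.frame(marker = ids, chrom = "Gm01",
                                      pos_bp = c(1e6, 1e6 + d_cm / 2.5 * 1e6)),
                          cm_per_mb = 2.5)
  eff <- list(M1 = stats::setNames(eff1, c("1", "2")),
              M2 = stats::setNames(eff2, c("1", "2")))
  p1 <- stats::setNames(c(1L, 1L), ids)
  p2 <- stats::setNames(c(2L, 2L), ids)
  list(map = map, eff = eff, p1 = p1, p2 = p2, mu = mu)
}

test_that("map functions match their closed forms", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(100), 0.5 * (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(round(haldane_r(100), 4), 0.4323)
  expect_equal(ril_R(0.2), 0.4 / 1.4)
  expect_equal(round(ril_R(0.2), 4), 0.2857)
  expect_equal(ril_R(0), 0)
  expect_equal(ril_R(0.5), 0.5)
})

test_that("loci on different chromosomes assort independently", {
  map <- build_genetic_map(data.frame(marker = c("A", "B"),
                                      chrom = c("Gm01", "Gm02"),
                                      pos_bp = c(100, 100)))
  expect_equal(map$r_next[1], 0.5)
  expect_error(build_genetic_map(data.frame(marker = "A", chrom = "Gm01",
                                            pos_bp = 1), cm_per_mb = -1),
               "non-negative")
})

test_that("identical parents breed true", {
  s <- two_locus_setup()
  prog <- simulate_inbred_progeny(s$p1, s$p1, s$map, n = 50, seed = 3)
  expect_true(all(prog[, "M1"] == 1L & prog[, "M2"] == 1L))
  pc <- predict_cross(s$p1, s$p1, s$eff, s$map, mu = s$mu, n = 200)
  expect_equal(pc$predicted, s$mu + 1 + 0.5)
})

test_that("complete linkage transmits only parental two-locus classes", {
  s <- two_locus_setup(r = 0)
  prog <- simulate_inbred_progeny(s$p1, s$p2, s$map, n = 4000, seed = 5)
  classes <- paste(prog[, 1], prog[, 2])
  expect_setequal(unique(classes), c("1 1", "2 2"))
  expect_equal(mean(classes == "1 1"), 0.5, tolerance = 0.05)
})

test_that("RIL class frequencies follow Haldane-Waddington", {
  # r = 0.2 -> R = 0.2857, parental class frequency (1 - R)/2 = 0.3571
  s <- two_locus_setup(r = 0.2)
  prog <- simulate_inbred_progeny(s$p1, s$p2, s$map, n = 10000, seed = 7)
  classes <- paste(prog[, 1], prog[, 2])
  expect_equal(mean(classes == "1 1"), (1 - ril_R(0.2)) / 2,
               tolerance = 0.02)
  expect_equal(mean(classes == "1 1"), 0.3571, tolerance = 0.02)
  # independent-assortment model forces R = 0.5
  progI <- simulate_inbred_progeny(s$p1, s$p2, s$map,
                                   model = "independent", n = 10000, seed = 7)
  classesI <- paste(progI[, 1], progI[, 2])
  expect_equal(mean(classesI == "1 1"), 0.25, tolerance = 0.02)
})

test_that("genotypic value is mu plus the sum of allele effects", {
  s <- two_locus_setup()
  prog <- matrix(c(1L, 2L), 1, 2, dimnames = list(NULL, c("M1", "M2")))
  expect_equal(genotypic_value(prog, s$eff, mu = 20), 20 + 1 - 0.5)
  eff0 <- list(M1 = c("1" = 0, "2" = 0), M2 = c("1" = 0, "2" = 0))
  expect_equal(genotypic_value(prog, eff0, mu = 20), 20)
})

test_that("progeny mean approaches the midparent value under additivity", {
  s <- two_locus_setup(r = 0.3)
  g1 <- s$mu + sum(vapply(names(s$eff), function(id)
    s$eff[[id]][as.character(s$p1[id])], 0))
  g2 <- s$mu + sum(vapply(names(s$eff), function(id)
    s$eff[[id]][as.character(s$p2[id])], 0))
  prog <- simulate_inbred_progeny(s$p1, s$p2, s$map, n = 2000, seed = 9)
  g <- genotypic_value(prog, s$eff, mu = s$mu)
  se <- stats::sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - (g1 + g2) / 2), 2 * se + 1e-9)
})

test_that("the exact small-cross enumeration is a proper distribution with chain probabilities", {
  s <- two_locus_setup(r = 0.2)
  ex <- exact_small_cross(s$p1, s$p2, s$eff, s$map, mu = s$mu)
  expect_equal(sum(ex$prob), 1, tolerance = 1e-12)
  # classes: parental (1,1) & (2,2) at (1-R)/2, recombinant at R/2
  R <- ril_R(0.2)
  probs <- ex$prob[order(-ex$prob)]
  expect_equal(sort(probs, decreasing = TRUE),
               sort(c((1 - R) / 2, (1 - R) / 2, R / 2, R / 2),
                    decreasing = TRUE), tolerance = 1e-12)
  expect_equal(round((1 - R) / 2, 4), 0.3571)
  # single segregating locus: two classes at 1/2
  ids <- "M1"
  map1 <- build_genetic_map(data.frame(marker = ids, chrom = "Gm01",
                                       pos_bp = 1e6))
  ex1 <- exact_small_cross(stats::setNames(1L, ids), stats::setNames(2L, ids),
                           s$eff["M1"], map1, mu = 0)
  expect_equal(ex1$prob, c(0.5, 0.5))
  expect_error(exact_small_cross(s$p1, s$p2, s$eff, s$map, max_loci = 1,
                                 mu = s$mu), "segregating")
})

test_that("Monte-Carlo percentiles agree with exact enumeration within the effect-gap tolerance", {
  set.seed(71)
  ok <- 0
  for (rep in 1:40) {
    L <- sample(2:8, 1)
    ids <- sprintf("M%02d", seq_len(L))
    map <- build_genetic_map(data.frame(marker = ids, chrom = "Gm01",
                                        pos_bp = sort(sample.int(4e7, L))))
    eff <- lapply(seq_len(L), function(k) {
      e <- rnorm(2, 0, 0.5); stats::setNames(e - mean(e), c("1", "2"))
    })
    names(eff) <- ids
    p1 <- stats::setNames(sample(1:2, L, TRUE), ids)
    p2 <- stats::setNames(sample(1:2, L, TRUE), ids)
    if (all(p1 == p2)) p2[1] <- 3L - p2[1]
    pc <- predict_cross(p1, p2, eff, map, n = 2000, seed = rep, mu = 20)
    ex <- exact_small_cross(p1, p2, eff, map, mu = 20)
    seg <- ids[p1 != p2]
    tol <- min(vapply(seg, function(id)
      abs(eff[[id]]["1"] - eff[[id]]["2"]), 0)) / 2
    ok <- ok + (abs(pc$predicted - exact_percentile(ex, 0.99)) <=
                  tol + 1e-12)
  }
  expect_gte(ok / 40, 0.9)
})

test_that("nearest-rank percentiles and pyramiding bounds hold", {
  s <- two_locus_setup(r = 0.25)
  pc <- predict_cross(s$p1, s$p2, s$eff, s$map, mu = s$mu, n = 2000, seed = 11)
  expect_gte(pc$predicted, pc$mean)          # maximize direction
  expect_lte(pc$predicted, pc$max)
  expect_gte(pc$predicted, pc$min)
  best <- s$mu + sum(vapply(names(s$eff), function(id)
    max(s$eff[[id]][as.character(c(s$p1[id], s$p2[id]))]), 0))
  expect_lte(pc$predicted, best)
  pc_min <- predict_cross(s$p1, s$p2, s$eff, s$map, direction = "min",
                          mu = s$mu, n = 2000, seed = 11)
  expect_lte(pc_min$predicted, pc_min$mean)
  expect_warning(predict_cross(s$p1, s$p2, s$eff, s$map, mu = s$mu, n = 50,
                               seed = 1), "unstable")
})

test_that("per-cross seeds do not depend on enumeration order", {
  s <- two_locus_setup(r = 0.2)
  a <- predict_cross(s$p1, s$p2, s$eff, s$map, mu = s$mu, n = 500, seed = 2,
                     p1_id = "P7", p2_id = "P3")
  b <- predict_cross(s$p2, s$p1, s$eff, s$map, mu = s$mu, n = 500, seed = 2,
                     p1_id = "P3", p2_id = "P7")
  expect_equal(a$seed, b$seed)
})

test_that("cross enumeration covers all pairs with conserved group counts", {
  acc <- c("a", "b", "c", "d", "e")
  ids <- c("M1", "M2")
  A <- matrix(sample(1:2, 10, replace = TRUE), 5, 2,
              dimnames = list(acc, ids))
  map <- build_genetic_map(data.frame(marker = ids, chrom = "Gm01",
                                      pos_bp = c(1e6, 2e6)))
  eff <- list(M1 = c("1" = 1, "2" = -1), M2 = c("1" = 0.5, "2" = -0.5))
  part <- stats::setNames(factor(c("I", "I", "I", "II", "II")), acc)
  ct <- enumerate_and_rank(A, eff, map, part, n_progeny = 200, mu = 20)
  expect_equal(ct$n_crosses, choose(5, 2))
  expect_equal(sum(ct$group_summary$n), choose(5, 2))
  # within + among counts: C(3,2) + C(2,2) + 3*2
  expect_equal(ct$group_summary$n[ct$group_summary$group == "within I"], 3L)
  expect_equal(ct$group_summary$n[ct$group_summary$group == "within II"], 1L)
  expect_equal(ct$group_summary$n[grepl("among", ct$group_summary$group)], 6L)
  expect_error(enumerate_and_rank(A[1, , drop = FALSE], eff, map),
               "at least 2")
})

test_that("linkage and independent models coincide when all r = 0.5", {
  ids <- c("M1", "M2")
  map <- build_genetic_map(data.frame(marker = ids,
                                      chrom = c("Gm01", "Gm02"),
                                      pos_bp = c(1e6, 1e6)))
  eff <- list(M1 = c("1" = 1, "2" = -1), M2 = c("1" = 0.5, "2" = -0.5))
  p1 <- stats::setNames(c(1L, 1L), ids); p2 <- stats::setNames(c(2L, 2L), ids)
  a <- predict_cross(p1, p2, eff, map, "linkage", mu = 20, n = 2000, seed = 4)
  b <- predict_cross(p1, p2, eff, map, "independent", mu = 20, n = 2000,
                     seed = 4)
  expect_equal(a$predicted, b$predicted)
})

test_that("multi-trait selection reduces, cancels and ranks by hand z-scores", {
  fake_ct <- function(vals) {
    structure(list(crosses = data.frame(p1 = c("a", "a", "b"),
                                        p2 = c("b", "c", "c"),
                                        pred_linkage = vals,
                                        stringsAsFactors = FALSE),
                   models = "linkage", direction = "max"),
              class = "cross_table")
  }
  ct1 <- fake_ct(c(10, 12, 14))
  # single trait, unit weight: ordering identical to that trait's ranking
  sel <- multi_trait_select(list(T1 = ct1), c(T1 = "max"))
  expect_identical(paste(sel$p1, sel$p2), c("b c", "a c", "a b"))
  z <- (c(10, 12, 14) - 12) / stats::sd(c(10, 12, 14))
  expect_equal(sel$score, sort(z, decreasing = TRUE))
  # two identical traits with opposite directions cancel
  sel2 <- multi_trait_select(list(T1 = ct1, T2 = ct1),
                             c(T1 = "max", T2 = "min"))
  expect_equal(sel2$score, rep(0, 3), tolerance = 1e-12)
  # mismatched panels are refused
  ct_bad <- fake_ct(c(1, 2, 3))
  ct_bad$crosses$p2 <- c("b", "c", "d")
  expect_error(multi_trait_select(list(T1 = ct1, T2 = ct_bad),
                                  c(T1 = "max", T2 = "max")), "mismatched")
})
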