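#' Genetic map over the detected loci
#'
#' Assigns a map position to every detected locus (from a user map file or
#' a constant cM/Mb rate applied to physical positions) and an adjacent-
#' pair recombination fraction from the Haldane map function
#' `r = (1 - exp(-2 d / 100)) / 2` for distance `d` in cM; loci on
#' different chromosomes recombine freely (`r = 0.5`).
#'
#' @param loci data.frame with columns `marker`, `chrom`, `pos_bp`
#'   (e.g. from an `rtm_gwas` fit's QTL table: `start_bp`), ordered or
#'   not; the map is sorted by (chrom, pos).
#' @param cm_per_mb constant map rate (default 2.5 cM/Mb, a soybean-scale
#'   average); ignored when `cm` is supplied.
#' @param cm optional numeric vector of map positions (cM), one per locus.
#' @return An object of class `genetic_map`: data.frame `marker`, `chrom`,
#'   `pos_bp`, `cm`, `r_next` (recombination fraction to the next locus in
#'   map order; 0.5 across chromosome boundaries, NA for the last locus).
#' @export
build_genetic_map <- function(loci, cm_per_mb = 2.5, cm = NULL) {
  if (cm_per_mb < 0) stop("cm_per_mb must be non-negative")
  ord <- order(loci$chrom, loci$pos_bp)
  loci <- loci[ord, , drop = FALSE]
  if (is.null(cm)) cm <- loci$pos_bp * cm_per_mb / 1e6
  else cm <- cm[ord]
  n <- nrow(loci)
  r_next <- rep(NA_real_, n)
  if (n > 1) {
    d <- diff(cm)
    same <- loci$chrom[-n] == loci$chrom[-1]
    r_next[-n] <- ifelse(same, haldane_r(d), 0.5)
  }
  structure(data.frame(marker = loci$marker, chrom = loci$chrom,
                       pos_bp = loci$pos_bp, cm = cm, r_next = r_next,
                       stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Haldane map function
#' @param d_cm map distance in centimorgans.
#' @return Recombination fraction `(1 - exp(-2 d / 100)) / 2`.
#' @export
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Recombinant-inbred-line recombination fraction
#'
#' For fully inbred (F-infinity selfed) lines the observed recombination
#' between adjacent loci is `R = 2 r / (1 + 2 r)` (Haldane-Waddington).
#' @param r meiotic recombination fraction.
#' @return RIL recombination fraction.
#' @export
ril_R <- function(r) 2 * r / (1 + 2 * r)

# deterministic small-integer hash of a cross, so per-cross seeds do not
# depend on enumeration order
cross_seed <- function(seed, p1, p2) {
  key <- paste(sort(c(p1, p2)), collapse = "\r")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + seed) %% 2147483647)
}

# per-locus R values in map order for a model
ril_R_chain <- function(map, model = c("linkage", "independent")) {
  model <- match.arg(model)
  r <- map$r_next
  if (model == "independent") r[!is.na(r)] <- 0.5
  ril_R(r)
}

#' Simulate fully inbred progeny of a cross
#'
#' Each progeny is a homozygous recombinant inbred line: along each
#' chromosome the parental origin of consecutive loci follows a two-state
#' Markov chain with switch probability `R = 2r/(1+2r)`; chromosomes (and
#' all adjacent pairs under the independent-assortment model, where
#' `r = 0.5` so `R = 0.5`) segregate independently. Loci where the two
#' parents carry the same allele are constant.
#'
#' @param p1,p2 named integer vectors: each parent's allele index at every
#'   locus of `map` (names = marker ids).
#' @param map a [build_genetic_map()] over the loci.
#' @param model `"linkage"` or `"independent"`.
#' @param n number of progeny.
#' @param seed integer seed.
#' @return Integer matrix `n x loci` of allele indices (columns in map
#'   order).
#' @export
simulate_inbred_progeny <- function(p1, p2, map, model = "linkage",
                                    n = 2000, seed = 1) {
  ids <- map$marker
  if (!all(ids %in% names(p1)) || !all(ids %in% names(p2)))
    stop("parent missing an allele at locus ",
         ids[!(ids %in% names(p1) & ids %in% names(p2))][1])
  a1 <- p1[ids]; a2 <- p2[ids]
  L <- length(ids)
  R <- ril_R_chain(map, model)
  set.seed(seed)
  origin <- matrix(0L, n, L)
  origin[, 1] <- stats::rbinom(n, 1, 0.5)
  if (L > 1) for (k in 2:L) {
    sw <- stats::rbinom(n, 1, R[k - 1])
    origin[, k] <- ifelse(sw == 1, 1L - origin[, k - 1], origin[, k - 1])
  }
  out <- matrix(0L, n, L, dimnames = list(NULL, ids))
  for (k in seq_len(L))
    out[, k] <- ifelse(origin[, k] == 0L, a1[k], a2[k])
  out
}

#' Genotypic value of progeny under an additive allele-effect model
#'
#' `mu + sum over loci of the effect of the allele carried`.
#'
#' @param progeny integer allele matrix (rows = lines, columns = marker
#'   ids), e.g. from [simulate_inbred_progeny()].
#' @param effects per-locus allele effects: an `rtm_gwas` fit, or a named
#'   list of named effect vectors with attribute/entry `mu`.
#' @param mu population mean term (taken from `effects` when it is a fit).
#' @return Numeric vector of genotypic values (trait units).
#' @export
genotypic_value <- function(progeny, effects, mu = NULL) {
  if (inherits(effects, "rtm_gwas")) {
    mu <- effects$mu
    effects <- effects$effects
  }
  if (is.null(mu)) stop("mu must be supplied with a plain effect list")
  g <- rep(mu, nrow(progeny))
  for (id in colnames(progeny)) {
    e <- unname(effects[[id]][as.character(progeny[, id])])
    e[is.na(e)] <- 0
    g <- g + e
  }
  g
}

nearest_rank <- function(x, q) unname(sort(x)[max(1L, ceiling(q * length(x)))])

#' Predict the value of one cross
#'
#' Simulates `n` fully inbred progeny of the pair and reports the
#' nearest-rank percentile of their genotypic values: the 99th percentile
#' for a maximize-direction trait, the 1st for minimize.
#'
#' @param p1,p2 named parental allele vectors over the map's loci.
#' @param effects an `rtm_gwas` fit or named effect list (see
#'   [genotypic_value()]).
#' @param map a [build_genetic_map()].
#' @param model `"linkage"` or `"independent"`.
#' @param direction `"max"` (99th percentile) or `"min"` (1st).
#' @param n number of progeny (default 2000).
#' @param seed base seed; the cross's own seed is derived from it and the
#'   sorted parent pair, so results do not depend on enumeration order.
#' @param percentile overrides the direction-implied percentile (in
#'   (0, 100)).
#' @param mu mean term when `effects` is a plain list.
#' @param p1_id,p2_id parent labels (enter the per-cross seed derivation).
#' @return List of class `cross_prediction`: parents, model, direction,
#'   `predicted` (the percentile), `mean`, `min`, `max`, `n`, `seed`.
#' @export
predict_cross <- function(p1, p2, effects, map, model = "linkage",
                          direction = c("max", "min"), n = 2000,
                          seed = 1, percentile = NULL, mu = NULL,
                          p1_id = "P1", p2_id = "P2") {
  direction <- match.arg(direction)
  if (n < 100) warning("n < 100 progeny: percentile estimate is unstable")
  q <- if (!is.null(percentile)) percentile / 100
       else if (direction == "max") 0.99 else 0.01
  sd <- cross_seed(seed, p1_id, p2_id)
  prog <- simulate_inbred_progeny(p1, p2, map, model, n, sd)
  g <- genotypic_value(prog, effects, mu)
  structure(list(p1 = p1_id, p2 = p2_id, model = model,
                 direction = direction, n = n, seed = sd,
                 predicted = nearest_rank(g, q),
                 mean = mean(g), min = min(g), max = max(g)),
            class = "cross_prediction")
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat(sprintf("cross %s x %s (%s model, %s): predicted %.4g [progeny mean %.4g, range %.4g..%.4g]\n",
              x$p1, x$p2, x$model, x$direction, x$predicted, x$mean,
              x$min, x$max))
  invisible(x)
}

#' Exact progeny-value distribution of a small cross
#'
#' Verification oracle for the Monte-Carlo predictor: enumerates all
#' parental-origin vectors over the segregating loci with two-state
#' Markov-chain probabilities (each adjacent pair contributes `R` or
#' `1 - R`), aggregates identical genotypic values, and returns the exact
#' distribution.
#'
#' @inheritParams predict_cross
#' @param max_loci cap on segregating loci (2^L enumeration).
#' @return data.frame `value`, `prob` (sorted by value, probs sum to 1).
#' @export
exact_small_cross <- function(p1, p2, effects, map, model = "linkage",
                              max_loci = 12, mu = NULL) {
  if (inherits(effects, "rtm_gwas")) {
    mu <- effects$mu
    eff <- effects$effects
  } else eff <- effects
  if (is.null(mu)) stop("mu must be supplied with a plain effect list")
  ids <- map$marker
  a1 <- p1[ids]; a2 <- p2[ids]
  seg <- which(a1 != a2)
  base <- mu + sum(vapply(which(a1 == a2), function(k) {
    e <- eff[[ids[k]]][as.character(a1[k])]
    if (is.na(e)) 0 else e
  }, 0))
  if (!length(seg))
    return(data.frame(value = base, prob = 1))
  if (length(seg) > max_loci)
    stop("more than ", max_loci, " segregating loci")
  R <- ril_R_chain(map, model)
  L <- length(ids)
  vals <- NULL; probs <- NULL
  n_orig <- 2^length(seg)
  for (m in seq_len(n_orig) - 1L) {
    o <- rep(0L, L)  # origin at non-segregating loci is irrelevant:
    bits <- as.integer(intToBits(m)[seq_along(seg)])
    # marginalize: chain probability over segregating loci only is exact
    # because intermediate loci contribute factor 1 when summed out --
    # the two-state chain is Markov, so the origin process restricted to
    # any subset of loci is a chain with the composed switch
    # probabilities between consecutive segregating loci.
    o[seg] <- bits
    pr <- 0.5
    if (length(seg) > 1) for (t in 2:length(seg)) {
      Rcomp <- compose_R(R, seg[t - 1], seg[t])
      pr <- pr * if (bits[t] != bits[t - 1]) Rcomp else 1 - Rcomp
    }
    v <- base
    for (t in seq_along(seg)) {
      k <- seg[t]
      al <- if (bits[t] == 0L) a1[k] else a2[k]
      e <- eff[[ids[k]]][as.character(al)]
      v <- v + if (is.na(e)) 0 else e
    }
    vals <- c(vals, v); probs <- c(probs, pr)
  }
  agg <- tapply(probs, round(vals, 12), sum)
  out <- data.frame(value = as.numeric(names(agg)), prob = as.numeric(agg),
                    row.names = NULL)
  out[order(out$value), , drop = FALSE]
}

# switch probability of the two-state origin chain composed across the
# (possibly non-segregating) loci between positions i < j in map order
compose_R <- function(R, i, j) {
  # P(switch over a path) composes as p' = p1(1-p2) + (1-p1)p2 stepwise
  p <- 0
  for (k in i:(j - 1)) {
    Rk <- R[k]
    p <- p * (1 - Rk) + (1 - p) * Rk
  }
  p
}

#' Exact nearest-rank percentile of an exact distribution
#' @param dist data.frame `value`, `prob` from [exact_small_cross()].
#' @param q quantile in (0, 1).
#' @return The smallest value whose cumulative probability is >= q.
#' @export
exact_percentile <- function(dist, q) {
  cw <- cumsum(dist$prob)
  dist$value[which(cw >= q - 1e-12)[1]]
}

#' All unordered parent pairs of a panel
#'
#' The cross enumeration behind [enumerate_and_rank()]: a panel of n
#' accessions yields choose(n, 2) single crosses.
#'
#' @param accessions character vector of parent ids.
#' @return 2 x choose(n, 2) character matrix of unordered pairs.
#' @export
cross_pairs <- function(accessions) {
  if (length(accessions) < 2) stop("need at least 2 accessions")
  if (anyDuplicated(accessions)) stop("duplicate parent ids")
  utils::combn(accessions, 2)
}

#' Enumerate and rank all crosses of a panel
#'
#' Scores every unordered parent pair by simulated-progeny percentile
#' value and summarizes within-group / among-group extremes plus a top-k
#' recommendation list.
#'
#' @param assign accession x marker allele matrix over the detected loci
#'   ([allele_assignments()] restricted to the fit's selected markers).
#' @param effects an `rtm_gwas` fit or effect list.
#' @param map a [build_genetic_map()].
#' @param partition optional named group factor for the group summary.
#' @param direction `"max"` or `"min"`.
#' @param models character vector of recombination models to run; the
#'   first is the ranking model, others are reported alongside.
#' @param n_progeny progeny per cross (default 2000).
#' @param seed base seed.
#' @param top_k rows in the recommendation table.
#' @param mu mean term for a plain effect list.
#' @return List of class `cross_table`: `crosses` (all pairs with
#'   predicted value per model, ranked), `group_summary` (per parent-group
#'   pair: count, mean/min/max predicted), `top` (head of the ranking),
#'   `n_crosses`.
#' @export
enumerate_and_rank <- function(assign, effects, map, partition = NULL,
                               direction = c("max", "min"),
                               models = c("linkage", "independent"),
                               n_progeny = 2000, seed = 1, top_k = 15,
                               mu = NULL) {
  direction <- match.arg(direction)
  acc <- rownames(assign)
  pairs <- cross_pairs(acc)
  np <- ncol(pairs)
  pred <- matrix(NA_real_, np, length(models),
                 dimnames = list(NULL, models))
  for (ix in seq_len(np)) {
    p1 <- assign[pairs[1, ix], ]; p2 <- assign[pairs[2, ix], ]
    for (mo in models)
      pred[ix, mo] <- predict_cross(p1, p2, effects, map, mo, direction,
                                    n = n_progeny, seed = seed, mu = mu,
                                    p1_id = pairs[1, ix],
                                    p2_id = pairs[2, ix])$predicted
  }
  crosses <- data.frame(p1 = pairs[1, ], p2 = pairs[2, ],
                        stringsAsFactors = FALSE)
  for (mo in models) crosses[[paste0("pred_", mo)]] <- pred[, mo]
  main <- pred[, models[1]]
  ord <- if (direction == "max") order(-main) else order(main)
  crosses <- crosses[ord, , drop = FALSE]
  rownames(crosses) <- NULL
  group_summary <- NULL
  if (!is.null(partition)) {
    g1 <- as.character(partition[crosses$p1])
    g2 <- as.character(partition[crosses$p2])
    gp <- ifelse(g1 == g2, paste0("within ", g1),
                 paste("among", pmin(g1, g2), "x", pmax(g1, g2)))
    v <- crosses[[paste0("pred_", models[1])]]
    group_summary <- do.call(rbind, lapply(split(seq_along(v), gp),
      function(ix) data.frame(group = gp[ix[1]], n = length(ix),
                              mean = mean(v[ix]), min = min(v[ix]),
                              max = max(v[ix]), stringsAsFactors = FALSE)))
    rownames(group_summary) <- NULL
  }
  structure(list(crosses = crosses,
                 group_summary = group_summary,
                 top = utils::head(crosses, top_k),
                 n_crosses = np, direction = direction,
                 models = models),
            class = "cross_table")
}

#' @export
print.cross_table <- function(x, ...) {
  cat(sprintf("cross_table: %d crosses, direction %s, ranking model %s\n",
              x$n_crosses, x$direction, x$models[1]))
  print(utils::head(x$top, 5), row.names = FALSE)
  invisible(x)
}

#' Combine per-trait cross predictions into one recommendation
#'
#' Standardizes each trait's predicted values across crosses, flips the
#' sign of minimize-direction traits, and ranks by the weighted sum.
#'
#' @param predictions named list of `cross_table`s over the same panel.
#' @param directions named character vector (`"max"`/`"min"`) per trait.
#' @param weights numeric weights (default equal).
#' @param top_k rows in the output.
#' @return data.frame of crosses with per-trait predicted values, the
#'   combined standardized `score`, ranked descending.
#' @export
multi_trait_select <- function(predictions, directions,
                               weights = NULL, top_k = 15) {
  traits <- names(predictions)
  if (is.null(weights)) weights <- rep(1, length(traits))
  key <- function(ct) paste(pmin(ct$crosses$p1, ct$crosses$p2),
                            pmax(ct$crosses$p1, ct$crosses$p2))
  k0 <- sort(key(predictions[[1]]))
  for (tr in traits)
    if (!identical(sort(key(predictions[[tr]])), k0))
      stop("trait panels mismatched: cross sets differ")
  base <- predictions[[1]]$crosses[order(key(predictions[[1]])),
                                   c("p1", "p2")]
  score <- rep(0, nrow(base))
  for (i in seq_along(traits)) {
    ct <- predictions[[traits[i]]]
    v <- ct$crosses[[paste0("pred_", ct$models[1])]][order(key(ct))]
    z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    if (directions[[traits[i]]] == "min") z <- -z
    base[[traits[i]]] <- v
    score <- score + weights[i] * z
  }
  base$score <- score
  base <- base[order(-base$score), , drop = FALSE]
  rownames(base) <- NULL
  utils::head(base, top_k)
}
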