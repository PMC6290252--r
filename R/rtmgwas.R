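# Internal linear-algebra workhorses ------------------------------------

# F-test for adding columns Z to a model whose fitted subspace is spanned
# by the orthonormal columns of Q0. yres = residual of y on Q0, rss0 its
# RSS, rdf0 its residual df. Returns NULL when Z adds no rank.
ftest_add <- function(Q0, rss0, rdf0, Z, yres) {
  Zr <- Z - Q0 %*% crossprod(Q0, Z)
  qz <- qr(Zr)
  rk <- qz$rank
  if (rk == 0 || max(abs(diag(qr.R(qz))[seq_len(rk)])) < 1e-8) return(NULL)
  rss1 <- sum(qr.resid(qz, yres)^2)
  df2 <- rdf0 - rk
  if (df2 <= 0) return(NULL)
  Fst <- ((rss0 - rss1) / rk) / (rss1 / df2)
  p <- stats::pf(Fst, rk, df2, lower.tail = FALSE)
  list(F = Fst, p = p, df = rk, rss1 = rss1)
}

# zero-sum (deviation) coding for a marker's allele factor on a given
# accession set; levels ordered by allele index (descending frequency).
marker_design <- function(marker, acc) {
  a <- marker$allele_of[acc]
  lev <- sort(unique(a))
  if (length(lev) < 2) return(NULL)
  f <- factor(a, levels = lev)
  stats::contrasts(f) <- stats::contr.sum(length(lev))
  Z <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(Z) <- paste0(marker$id, "..", lev[-length(lev)])
  list(Z = Z, levels = lev, f = f)
}

as_cov_matrix <- function(covariates, acc) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "structure_covariates")) {
    V <- covariates$vectors
    rownames(V) <- rownames(covariates$similarity)
    covariates <- V
  }
  covariates <- as.matrix(covariates)
  if (!is.null(rownames(covariates))) covariates <- covariates[acc, , drop = FALSE]
  covariates
}

#' Stage-1 single-locus scan over SNPLDB markers
#'
#' Tests each multi-allelic marker one at a time: an F-test of the allele
#' factor (allele_count - 1 numerator df) added to the covariate-only
#' linear model of the across-environment accession means. The marginal
#' R-squared is the sum-of-squares the marker explains beyond the
#' covariates, as a fraction of the total phenotypic sum of squares.
#'
#' @param markers a `snpldb_set` (or list of `snpldb`).
#' @param y named numeric vector of accession trait means (see
#'   [trait_means()]).
#' @param covariates `NULL`, a numeric matrix (accessions x q), or a
#'   [similarity_and_eigen()] result.
#' @return data.frame with columns `marker`, `df`, `F`, `p`, `r2`,
#'   ordered as the input markers. Markers with a single allele class
#'   among phenotyped accessions are skipped with a warning.
#' @export
stage1_scan <- function(markers, y, covariates = NULL) {
  acc <- intersect(names(y), names(markers[[1]]$allele_of))
  if (length(acc) < 3) stop("fewer than 3 phenotyped, genotyped accessions")
  y <- stats::setNames(as.numeric(y[acc]), acc)
  C <- as_cov_matrix(covariates, acc)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  q0 <- qr(X0)
  Q0 <- qr.Q(q0)
  yres <- y - Q0 %*% crossprod(Q0, y)
  rss0 <- sum(yres^2)
  rdf0 <- length(y) - q0$rank
  sst <- sum((y - mean(y))^2)
  out <- data.frame(marker = names(markers), df = NA_integer_,
                    F = NA_real_, p = NA_real_, r2 = NA_real_,
                    stringsAsFactors = FALSE)
  if (rss0 <= 1e-12 * max(1, sum(y^2))) {
    # constant (or covariate-saturated) phenotype: nothing to explain
    out$p <- 1; out$r2 <- 0
    return(out)
  }
  skipped <- 0L
  for (k in seq_along(markers)) {
    d <- marker_design(markers[[k]], acc)
    if (is.null(d)) { skipped <- skipped + 1L; next }
    ft <- ftest_add(Q0, rss0, rdf0, d$Z, yres)
    if (is.null(ft)) { skipped <- skipped + 1L; next }
    out$df[k] <- ft$df
    out$F[k] <- ft$F
    out$p[k] <- ft$p
    out$r2[k] <- if (sst > 0) (rss0 - ft$rss1) / sst else 0
  }
  if (skipped > 0)
    warning(skipped, " marker(s) skipped (single allele class or no rank)")
  out
}

#' Preselect candidate markers from the stage-1 scan
#'
#' @param stage1 result of [stage1_scan()].
#' @param threshold stage-1 p-value cut (default 0.05).
#' @return Character vector of marker ids with `p < threshold`, ordered
#'   by ascending p. An empty result is valid (the stage-2 model is then
#'   covariates-only) and is reported.
#' @export
preselect <- function(stage1, threshold = 0.05) {
  keep <- which(!is.na(stage1$p) & stage1$p < threshold)
  keep <- keep[order(stage1$p[keep])]
  if (!length(keep)) message("no candidates pass the stage-1 threshold")
  stage1$marker[keep]
}

#' Stage-2 stepwise multi-locus model
#'
#' Forward-backward stepwise regression of the accession means on
#' multi-allelic markers with the structure covariates always included.
#' Each forward step takes the candidate with the smallest partial-F
#' p-value and admits it when its experiment-wise p-value
#' (Sidak-adjusted over the `n_genomewide` markers scanned in stage 1,
#' `1 - (1 - p)^m`) is below `alpha_enter` — this is the built-in
#' experiment-wise error control of the multi-locus model, so no external
#' multiple-testing correction is applied afterwards. Each backward step
#' removes any included marker whose joint-model partial-F p-value is
#' `>= alpha_exit`. Steps alternate to a fixed point. Ties on p are
#' broken by ascending genome position, making the procedure
#' deterministic and invariant to candidate input order.
#'
#' @param candidates character vector of candidate marker ids (from
#'   [preselect()]).
#' @param markers the full `snpldb_set`.
#' @param y named accession means.
#' @param covariates as in [stage1_scan()]; never dropped.
#' @param alpha_enter,alpha_exit significance levels (default 0.02).
#' @param n_genomewide number of markers tested genome-wide in stage 1
#'   (the multiplicity of the experiment-wise entry control).
#' @return Character vector of selected marker ids in selection order.
#' @export
stage2_stepwise <- function(candidates, markers, y, covariates = NULL,
                            alpha_enter = 0.02, alpha_exit = alpha_enter,
                            n_genomewide = length(markers)) {
  acc <- intersect(names(y), names(markers[[1]]$allele_of))
  y <- stats::setNames(as.numeric(y[acc]), acc)
  C <- as_cov_matrix(covariates, acc)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  designs <- lapply(candidates, function(id) {
    d <- marker_design(markers[[id]], acc)
    if (is.null(d)) NULL else d$Z
  })
  names(designs) <- candidates
  ok <- !vapply(designs, is.null, TRUE)
  if (any(!ok)) message(sum(!ok), " degenerate candidate(s) skipped")
  candidates <- candidates[ok]; designs <- designs[ok]
  pos_of <- vapply(candidates, function(id)
    markers[[id]]$start_bp, 0)
  chr_of <- vapply(candidates, function(id) markers[[id]]$chrom, "")

  selected <- character(0)
  repeat {
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      Xcur <- do.call(cbind, c(list(X0), designs[selected]))
      qc <- qr(Xcur)
      Q <- qr.Q(qc)
      yres <- y - Q %*% crossprod(Q, y)
      rss <- sum(yres^2)
      rdf <- length(y) - qc$rank
      ps <- rep(NA_real_, length(pool))
      for (k in seq_along(pool)) {
        ft <- ftest_add(Q, rss, rdf, designs[[pool[k]]], yres)
        if (!is.null(ft)) ps[k] <- ft$p
      }
      if (any(!is.na(ps))) {
        best <- which(ps == min(ps, na.rm = TRUE))
        if (length(best) > 1) {
          ordk <- order(chr_of[match(pool[best], candidates)],
                        pos_of[match(pool[best], candidates)])
          best <- best[ordk[1]]
        }
        p_exp <- 1 - (1 - ps[best])^n_genomewide
        if (!is.na(p_exp) && p_exp < alpha_enter) {
          selected <- c(selected, pool[best])
          changed <- TRUE
        }
      }
    }
    # backward
    repeat {
      if (length(selected) < 1) break
      drop_p <- vapply(seq_along(selected), function(k) {
        others <- selected[-k]
        Xo <- do.call(cbind, c(list(X0), designs[others]))
        qo <- qr(Xo)
        Qo <- qr.Q(qo)
        yr <- y - Qo %*% crossprod(Qo, y)
        ft <- ftest_add(Qo, sum(yr^2), length(y) - qo$rank,
                        designs[[selected[k]]], yr)
        if (is.null(ft)) 1 else ft$p
      }, 0)
      worst <- which.max(drop_p)
      if (drop_p[worst] >= alpha_exit) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  selected
}

#' Restricted two-stage multi-locus association on SNPLDB markers
#'
#' The central fitting function. Stage 1 screens every marker with a
#' single-locus F-test against the structure-covariate background and
#' keeps candidates with `p < stage1_p`; stage 2 builds the multi-locus
#' model by forward-backward stepwise regression with experiment-wise
#' entry control at `alpha` (see [stage2_stepwise()]). Per-locus
#' contributions are reported both as sequential (selection-order)
#' R-squared, which sums exactly to the marker part of the model
#' R-squared, and as partial (last-entry) R-squared; allele effects are
#' recovered from the zero-sum allele coding so each locus's unweighted
#' effect sum is 0.
#'
#' @param markers a `snpldb_set` from [snpldb_markers()].
#' @param phenotype a `trait_obs` table (means taken across environments)
#'   or a named numeric vector of accession means.
#' @param covariates `NULL` (compute the top-`k_eigen` eigenvectors from
#'   `markers`), a matrix, or a [similarity_and_eigen()] result.
#' @param k_eigen number of structure eigenvectors when `covariates` is
#'   `NULL`; `0` for no structure correction.
#' @param alpha significance level of the multi-locus model (default
#'   0.02; the experiment-wise error control).
#' @param alpha_exit backward-elimination level (default `alpha`).
#' @param stage1_p stage-1 preselection threshold (default 0.05).
#' @param trait trait name used for QTL labels (`<Trait>-a-<chrom#>-<serial>`).
#' @return An object of class `rtm_gwas` with components `stage1`,
#'   `candidates`, `selected`, `qtl` (per-locus table: QTL name, marker,
#'   alleles, -log10 p, sequential and partial R2), `effects` (per-locus
#'   allele effects), `mu`, `model_r2`, `covariate_r2`, `fitted`,
#'   `residuals`, plus bookkeeping. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @export
rtm_gwas <- function(markers, phenotype, covariates = NULL, k_eigen = 10,
                     alpha = 0.02, alpha_exit = alpha, stage1_p = 0.05,
                     trait = "Trait") {
  cl <- match.call()
  y <- if (inherits(phenotype, "trait_obs") ||
           (is.data.frame(phenotype) && "value" %in% names(phenotype)))
    trait_means(phenotype) else phenotype
  if (is.null(names(y))) stop("phenotype means must be named by accession")
  if (is.null(covariates) && k_eigen > 0)
    covariates <- similarity_and_eigen(markers, k = min(k_eigen, length(y) - 1))
  acc <- intersect(names(y), names(markers[[1]]$allele_of))
  y <- y[acc]

  s1 <- stage1_scan(markers, y, covariates)
  cand <- preselect(s1, stage1_p)
  sel <- stage2_stepwise(cand, markers, y, covariates,
                         alpha_enter = alpha, alpha_exit = alpha_exit,
                         n_genomewide = sum(!is.na(s1$p)))

  C <- as_cov_matrix(covariates, acc)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  sst <- sum((y - mean(y))^2)
  q0 <- qr(X0)
  rss_cov <- sum(qr.resid(q0, y)^2)
  cov_r2 <- if (sst > 0) (sst - rss_cov) / sst else 0

  designs <- lapply(sel, function(id) marker_design(markers[[id]], acc))
  names(designs) <- sel
  X <- do.call(cbind, c(list(X0), lapply(designs, `[[`, "Z")))
  qf <- qr(X)
  coefs <- qr.coef(qf, y)
  fitted <- drop(X %*% ifelse(is.na(coefs), 0, coefs))
  names(fitted) <- acc
  resid <- y - fitted
  rss_full <- sum(resid^2)
  rdf <- length(y) - qf$rank

  # sequential R2 in selection order + partial (last-entry) tests
  seq_r2 <- partial_r2 <- partial_p <- part_df <- numeric(length(sel))
  rss_prev <- rss_cov
  for (k in seq_along(sel)) {
    Xk <- do.call(cbind, c(list(X0),
                           lapply(designs[seq_len(k)], `[[`, "Z")))
    rss_k <- sum(qr.resid(qr(Xk), y)^2)
    seq_r2[k] <- if (sst > 0) (rss_prev - rss_k) / sst else 0
    rss_prev <- rss_k
    others <- sel[-k]
    Xo <- do.call(cbind, c(list(X0), lapply(designs[others], `[[`, "Z")))
    qo <- qr(Xo)
    Qo <- qr.Q(qo)
    yr <- y - Qo %*% crossprod(Qo, y)
    ft <- ftest_add(Qo, sum(yr^2), length(y) - qo$rank,
                    designs[[sel[k]]]$Z, yr)
    partial_r2[k] <- if (sst > 0) (sum(yr^2) - ft$rss1) / sst else 0
    partial_p[k] <- ft$p
    part_df[k] <- ft$df
  }

  # allele effects from the zero-sum coding
  effects <- vector("list", length(sel))
  names(effects) <- sel
  for (k in seq_along(sel)) {
    d <- designs[[sel[k]]]
    cc <- coefs[colnames(d$Z)]
    cc[is.na(cc)] <- 0
    eff <- c(cc, -sum(cc))
    names(eff) <- as.character(d$levels)
    all_alleles <- seq_along(markers[[sel[k]]]$alleles)
    absent <- setdiff(all_alleles, d$levels)
    if (length(absent))
      message(sel[k], ": allele(s) ", paste(absent, collapse = ","),
              " absent from phenotyped accessions; no effect estimated")
    effects[[k]] <- eff
  }

  # QTL naming <Trait>-a-<chrom#>-<serial> (serial along the chromosome)
  qtl_name <- rep(NA_character_, length(sel))
  if (length(sel)) {
    chr <- vapply(sel, function(id) markers[[id]]$chrom, "")
    pos <- vapply(sel, function(id) markers[[id]]$start_bp, 0)
    chrn <- as.integer(sub("\\D*(\\d+)$", "\\1", chr))
    for (ch in unique(chrn)) {
      ix <- which(chrn == ch)
      qtl_name[ix[order(pos[ix])]] <- sprintf("%s-a-%d-%d", trait, ch,
                                              seq_along(ix))
    }
  }

  qtl <- data.frame(
    qtl = qtl_name, marker = sel,
    chrom = vapply(sel, function(id) markers[[id]]$chrom, ""),
    start_bp = vapply(sel, function(id) markers[[id]]$start_bp, 0),
    n_alleles = vapply(designs, function(d) length(d$levels), 0L),
    neglog10p = -log10(pmax(partial_p, 1e-300)),
    seq_r2 = seq_r2, partial_r2 = partial_r2, partial_p = partial_p,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(call = cl, trait = trait, n = length(y), y = y,
                 stage1 = s1, candidates = cand, selected = sel,
                 qtl = qtl, effects = effects,
                 mu = unname(coefs["(Intercept)"]),
                 coefficients = coefs,
                 model_r2 = if (sst > 0) (sst - rss_full) / sst else 0,
                 covariate_r2 = cov_r2,
                 marker_r2 = sum(seq_r2),
                 residual_var = rss_full / max(rdf, 1),
                 residual_df = rdf,
                 fitted = fitted, residuals = resid,
                 alpha = alpha, alpha_exit = alpha_exit,
                 stage1_p = stage1_p,
                 marker_meta = lapply(markers[sel], function(m)
                   m[c("id", "chrom", "start_bp", "end_bp")])),
            class = "rtm_gwas")
}

#' @export
print.rtm_gwas <- function(x, ...) {
  cat(sprintf("Two-stage multi-locus association, trait %s (n = %d, alpha = %g)\n",
              x$trait, x$n, x$alpha))
  cat(sprintf("  stage 1: %d markers scanned, %d candidates (p < %g)\n",
              nrow(x$stage1), length(x$candidates), x$stage1_p))
  cat(sprintf("  selected %d QTL; marker R2 = %.2f%%, covariate R2 = %.2f%%\n",
              length(x$selected), 100 * x$marker_r2, 100 * x$covariate_r2))
  invisible(x)
}

#' @export
summary.rtm_gwas <- function(object, ...) {
  structure(list(fit = object), class = "summary.rtm_gwas")
}

#' @export
print.summary.rtm_gwas <- function(x, ...) {
  print(x$fit)
  if (nrow(x$fit$qtl)) {
    tab <- x$fit$qtl
    tab$seq_r2 <- round(100 * tab$seq_r2, 2)
    tab$partial_r2 <- round(100 * tab$partial_r2, 2)
    tab$neglog10p <- round(tab$neglog10p, 2)
    print(tab[, c("qtl", "marker", "n_alleles", "neglog10p",
                  "seq_r2", "partial_r2")], row.names = FALSE)
  }
  invisible(x)
}

#' Allele effects of a fitted multi-locus model
#'
#' @param object an `rtm_gwas` fit.
#' @param ... unused.
#' @return data.frame with columns `marker`, `allele`, `effect`, plus the
#'   population mean as attribute `mu`. Per-locus effects sum to zero.
#' @export
coef.rtm_gwas <- function(object, ...) {
  if (!length(object$effects))
    return(structure(data.frame(marker = character(), allele = integer(),
                                effect = numeric()), mu = object$mu))
  out <- do.call(rbind, lapply(names(object$effects), function(id)
    data.frame(marker = id,
               allele = as.integer(names(object$effects[[id]])),
               effect = unname(object$effects[[id]]),
               stringsAsFactors = FALSE)))
  structure(out, mu = object$mu)
}

#' @export
fitted.rtm_gwas <- function(object, ...) object$fitted

#' @export
residuals.rtm_gwas <- function(object, ...) object$residuals

#' Predict genotypic values from a fitted multi-locus model
#'
#' Sums the population mean and the per-locus effect of the allele each
#' accession carries — the cross-prediction engine uses the same rule on
#' simulated progeny.
#'
#' @param object an `rtm_gwas` fit.
#' @param newdata accession x marker integer allele matrix covering the
#'   selected markers (e.g. [allele_assignments()]); defaults to the
#'   training assignments.
#' @param ... unused.
#' @return Named numeric vector of genotypic values.
#' @export
predict.rtm_gwas <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  sel <- object$selected
  if (!all(sel %in% colnames(newdata)))
    stop("newdata must cover all selected markers")
  g <- rep(object$mu, nrow(newdata))
  names(g) <- rownames(newdata)
  for (id in sel) {
    eff <- object$effects[[id]]
    e <- eff[as.character(newdata[, id])]
    e[is.na(e)] <- 0
    g <- g + e
  }
  g
}

#' Manhattan-style plot of the stage-1 scan
#'
#' @param x an `rtm_gwas` fit.
#' @param markers the `snpldb_set` used in the fit (for positions).
#' @param ... passed to [graphics::plot()].
#' @export
plot.rtm_gwas <- function(x, markers = NULL, ...) {
  s1 <- x$stage1
  if (!is.null(markers)) {
    chr <- vapply(s1$marker, function(id) markers[[id]]$chrom, "")
    pos <- vapply(s1$marker, function(id) markers[[id]]$start_bp, 0)
    off <- c(0, cumsum(tapply(pos, chr, max)))
    xcoord <- pos + off[match(chr, names(sort(unique(chr))))]
  } else xcoord <- seq_len(nrow(s1))
  lp <- -log10(pmax(s1$p, 1e-300))
  graphics::plot(xcoord, lp, pch = 20, col = "grey40",
                 xlab = "genome position", ylab = "-log10 p (stage 1)", ...)
  hit <- s1$marker %in% x$selected
  graphics::points(xcoord[hit], lp[hit], pch = 20, col = "red3")
  invisible(x)
}

#' Sequential and partial R-squared partition of a fitted model
#'
#' @param fit an `rtm_gwas` fit.
#' @return The per-locus QTL table with sequential (selection-order) and
#'   partial (last-entry) R-squared columns; attribute `model_r2` gives
#'   the full-model R-squared and `covariate_r2` the structure share.
#' @export
partition_r2 <- function(fit) {
  stopifnot(inherits(fit, "rtm_gwas"))
  structure(fit$qtl, model_r2 = fit$model_r2,
            covariate_r2 = fit$covariate_r2)
}
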