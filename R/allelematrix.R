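#' Assemble the QTL-allele matrix of a panel
#'
#' The compact representation of a population's genetic constitution:
#' a detected-locus x accession matrix whose cell is the estimated effect
#' of the allele that accession carries at that locus. Rows are ordered
#' by ascending positive-allele frequency (the fraction of accessions
#' whose allele effect is > 0), columns by ascending accession phenotype
#' mean, mirroring the usual graphical display.
#'
#' @param fit an [rtm_gwas()] fit (provides effects and locus set).
#' @param markers the `snpldb_set` used in the fit (provides allele
#'   assignments).
#' @param phenotype named accession means (column ordering metadata);
#'   defaults to the fit's training phenotype.
#' @param partition optional named factor of group (ecoregion) labels.
#' @return An object of class `qtl_allele_matrix`: the effect matrix with
#'   attributes `row_meta` (locus, R2, positive-allele frequency,
#'   original allele = most frequent) and `col_meta` (phenotype, group).
#' @export
build_qam <- function(fit, markers, phenotype = NULL, partition = NULL) {
  stopifnot(inherits(fit, "rtm_gwas"))
  if (is.null(phenotype)) phenotype <- fit$y
  sel <- fit$selected
  if (!length(sel)) stop("no detected loci in the fit")
  acc <- names(phenotype)
  A <- allele_assignments(markers[sel])
  if (!all(acc %in% rownames(A)))
    stop("accessions missing allele assignments: ",
         paste(utils::head(setdiff(acc, rownames(A))), collapse = ", "))
  A <- A[acc, , drop = FALSE]
  M <- matrix(NA_real_, length(sel), length(acc),
              dimnames = list(sel, acc))
  for (id in sel) {
    eff <- fit$effects[[id]]
    e <- eff[as.character(A[, id])]
    if (anyNA(e))
      stop("accession with unestimated allele at locus ", id)
    M[id, ] <- e
  }
  pos_freq <- rowMeans(M > 0)
  row_ord <- order(pos_freq)
  col_ord <- order(phenotype)
  M <- M[row_ord, col_ord, drop = FALSE]
  r2 <- fit$qtl$seq_r2[match(rownames(M), fit$qtl$marker)]
  orig <- vapply(rownames(M), function(id) {
    f <- markers[[id]]$freqs
    which.max(f)  # highest-frequency allele = original allele
  }, 0L)
  row_meta <- data.frame(marker = rownames(M), r2 = r2,
                         positive_freq = pos_freq[row_ord],
                         original_allele = orig,
                         stringsAsFactors = FALSE)
  col_meta <- data.frame(accession = colnames(M),
                         phenotype = as.numeric(phenotype[colnames(M)]),
                         group = if (is.null(partition)) NA
                                 else as.character(partition[colnames(M)]),
                         stringsAsFactors = FALSE)
  structure(M, row_meta = row_meta, col_meta = col_meta,
            mu = fit$mu, class = "qtl_allele_matrix")
}

#' @export
print.qtl_allele_matrix <- function(x, ...) {
  cat(sprintf("qtl_allele_matrix: %d loci x %d accessions (cells = allele effects)\n",
              nrow(x), ncol(x)))
  cat(sprintf("  effect range %.3g to %.3g; population mean %.4g\n",
              min(x), max(x), attr(x, "mu")))
  invisible(x)
}

#' @export
plot.qtl_allele_matrix <- function(x, ...) {
  M <- unclass(x)
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M),
                  xlab = "accessions (rising phenotype)",
                  ylab = "loci (rising positive-allele frequency)",
                  main = "QTL-allele matrix", ...)
  invisible(x)
}

#' Per-accession counts of positive/negative-effect alleles
#'
#' @param qam a [build_qam()] matrix.
#' @return data.frame per accession: `n_positive`, `n_negative`, `n_zero`
#'   (strict signs; counts sum to the number of loci), plus the phenotype
#'   column from the matrix metadata.
#' @export
count_signed_alleles <- function(qam) {
  stopifnot(inherits(qam, "qtl_allele_matrix"))
  M <- unclass(qam)
  cm <- attr(qam, "col_meta")
  data.frame(accession = colnames(M),
             n_positive = colSums(M > 0),
             n_negative = colSums(M < 0),
             n_zero = colSums(M == 0),
             phenotype = cm$phenotype[match(colnames(M), cm$accession)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Allele counts and frequencies per subpopulation
#'
#' @param markers a `snpldb_set` (or list of `snpldb`).
#' @param partition named factor of group labels covering the accessions.
#' @param loci optional character vector restricting to a locus subset
#'   (e.g. the detected QTLs).
#' @return data.frame of class `group_freq_table` with columns `marker`,
#'   `allele`, `group`, `count`, `freq`, plus per-allele `overall` rows
#'   (`group = "(overall)"`). Groups with zero accessions are dropped
#'   with a warning.
#' @export
group_allele_freqs <- function(markers, partition, loci = NULL) {
  if (is.null(loci)) loci <- names(markers)
  acc <- names(markers[[1]]$allele_of)
  part <- partition[acc]
  if (anyNA(part)) {
    acc <- acc[!is.na(part)]
    part <- part[acc]
  }
  part <- droplevels(factor(part))
  empty <- setdiff(levels(factor(partition)), levels(part))
  if (length(empty))
    warning("group(s) with no genotyped accession dropped: ",
            paste(empty, collapse = ", "))
  out <- list()
  for (id in loci) {
    a <- markers[[id]]$allele_of[acc]
    tab <- table(allele = a, group = part)
    for (al in rownames(tab)) {
      cnt <- as.integer(tab[al, ])
      out[[length(out) + 1]] <- data.frame(
        marker = id, allele = as.integer(al),
        group = c(colnames(tab), "(overall)"),
        count = c(cnt, sum(cnt)),
        freq = c(cnt / as.integer(table(part)), sum(cnt) / length(acc)),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("group_freq_table", "data.frame"))
}

group_counts_matrix <- function(table, locus) {
  sub <- table[table$marker == locus & table$group != "(overall)", ]
  if (!nrow(sub)) stop("locus not in table: ", locus)
  stats::xtabs(count ~ allele + group, data = sub)
}

#' Chi-square test of allele-frequency independence among groups
#'
#' Pearson chi-square on the allele x group contingency table of one
#' locus, testing whether the allele frequency distribution differs
#' among subpopulations. When any expected count is below 5 the
#' asymptotic p-value is replaced by a Monte-Carlo permutation p (10,000
#' resamples, seeded) and flagged.
#'
#' @param table a [group_allele_freqs()] result.
#' @param locus marker id to test.
#' @param n_mc Monte-Carlo resamples for the small-count fallback.
#' @param seed seed for the Monte-Carlo fallback.
#' @return List with `chisq`, `df`, `p`, `monte_carlo` flag.
#' @export
chisq_differentiation <- function(table, locus, n_mc = 10000, seed = 1) {
  cm <- group_counts_matrix(table, locus)
  cm <- cm[rowSums(cm) > 0, colSums(cm) > 0, drop = FALSE]
  if (nrow(cm) < 2 || ncol(cm) < 2)
    stop("degenerate table for ", locus, ": need >= 2 alleles and 2 groups")
  suppressWarnings(ct <- stats::chisq.test(cm, correct = FALSE))
  mc <- any(ct$expected < 5)
  p <- if (mc) {
    set.seed(seed)
    stats::chisq.test(cm, correct = FALSE, simulate.p.value = TRUE,
                      B = n_mc)$p.value
  } else ct$p.value
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = p, monte_carlo = mc)
}

#' Differentiation scan over all loci of a frequency table
#'
#' @param table a [group_freq_table].
#' @param alpha significance level for the `significant` flag (raw p).
#' @param seed Monte-Carlo seed passed to [chisq_differentiation()].
#' @return data.frame per locus: `chisq`, `df`, `p`, `fdr`
#'   (Benjamini-Hochberg across loci), `monte_carlo`, `significant`.
#' @export
differentiation_scan <- function(table, alpha = 0.05, seed = 1) {
  loci <- unique(table$marker)
  res <- lapply(seq_along(loci), function(i)
    chisq_differentiation(table, loci[i], seed = seed + i))
  out <- data.frame(marker = loci,
                    chisq = vapply(res, `[[`, 0, "chisq"),
                    df = vapply(res, `[[`, 0, "df"),
                    p = vapply(res, `[[`, 0, "p"),
                    monte_carlo = vapply(res, `[[`, TRUE, "monte_carlo"),
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < alpha
  out
}

#' Group-specific alleles
#'
#' Alleles carried by at most `max_groups` subpopulations (nonzero count),
#' the "specific ecoregion alleles" of a panel.
#'
#' @param table a [group_freq_table].
#' @param max_groups maximum number of carrier groups (default 2).
#' @return data.frame: `marker`, `allele`, `n_groups`, `groups`
#'   (comma-separated carrier labels), `count`.
#' @export
specific_alleles <- function(table, max_groups = 2) {
  sub <- table[table$group != "(overall)", ]
  key <- paste(sub$marker, sub$allele, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- sub[key == k, ]
    carriers <- rows$group[rows$count > 0]
    if (length(carriers) >= 1 && length(carriers) <= max_groups)
      out[[length(out) + 1]] <- data.frame(
        marker = rows$marker[1], allele = rows$allele[1],
        n_groups = length(carriers),
        groups = paste(carriers, collapse = ","),
        count = sum(rows$count), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker = character(), allele = integer(),
                      n_groups = integer(), groups = character(),
                      count = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
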