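#' Two-locus D' with a likelihood-based confidence interval
#'
#' For inbred homozygous accessions the genotype at each SNP is the
#' haplotype, so two-locus haplotype counts are read directly off the
#' call matrix. D' is the normalized disequilibrium coefficient
#' |D| / Dmax; the confidence interval comes from profiling the
#' multinomial likelihood of the four haplotype counts over D' in [0, 1]
#' with allele frequencies fixed at their observed values (the
#' Wall-Pritchard construction used for block calling), taking the 5th
#' and 95th percentiles of the normalized profile.
#'
#' @param n11,n10,n01,n00 haplotype counts for allele pairs (A,B), (A,b),
#'   (a,B), (a,b).
#' @param grid number of D' grid points for the likelihood profile.
#' @return List with `D`, `dprime`, `r2`, `ci_lo`, `ci_hi`, or `NULL` if
#'   either locus is monomorphic.
#' @export
ld_pair <- function(n11, n10, n01, n00, grid = 101L) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NULL)
  D <- n11 / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (dmax == 0) 0 else abs(D) / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  sgn <- if (D >= 0) 1 else -1
  dgrid <- seq(0, 1, length.out = grid)
  eps <- 1e-12
  ll <- vapply(dgrid, function(d) {
    Dd <- sgn * d * dmax
    p <- c(pA * pB + Dd, pA * (1 - pB) - Dd,
           (1 - pA) * pB - Dd, (1 - pA) * (1 - pB) + Dd)
    p <- pmax(p, eps)
    n11 * log(p[1]) + n10 * log(p[2]) + n01 * log(p[3]) + n00 * log(p[4])
  }, 0)
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  ci_lo <- dgrid[which(cw >= 0.05)[1]]
  ci_hi <- dgrid[which(cw >= 0.95)[1]]
  list(D = D, dprime = dp, r2 = r2, ci_lo = ci_lo, ci_hi = ci_hi)
}

#' Pairwise D' estimates within a physical window
#'
#' @param g a [genotype_matrix] without missing calls (see
#'   [impute_major()]).
#' @param max_window_bp pairs farther apart are skipped.
#' @return data.frame with columns `i`, `j` (SNP column indices), `snp_i`,
#'   `snp_j`, `dprime`, `ci_lo`, `ci_hi`, `r2`. Pairs with a monomorphic
#'   member are skipped with one summary warning.
#' @export
pairwise_ld <- function(g, max_window_bp = 200000) {
  chrom <- snp_chrom(g); pos <- snp_pos(g)
  m <- unclass(g)
  if (anyNA(m)) stop("impute missing calls before LD estimation")
  p <- ncol(m)
  mono <- colSums(m) %in% c(0L, nrow(m))
  out <- vector("list", 256); nout <- 0L
  skipped <- 0L
  for (i in seq_len(p - 1)) {
    j <- i + 1L
    while (j <= p && chrom[j] == chrom[i] &&
           pos[j] - pos[i] <= max_window_bp) {
      if (mono[i] || mono[j]) {
        skipped <- skipped + 1L
      } else {
        xi <- m[, i]; xj <- m[, j]
        est <- ld_pair(sum(xi == 1 & xj == 1), sum(xi == 1 & xj == 0),
                       sum(xi == 0 & xj == 1), sum(xi == 0 & xj == 0))
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- c(i, j, est$dprime, est$ci_lo, est$ci_hi, est$r2)
      }
      j <- j + 1L
    }
  }
  if (skipped > 0)
    warning(skipped, " pair(s) with a monomorphic SNP skipped")
  tab <- as.data.frame(do.call(rbind, out[seq_len(nout)]))
  if (nout == 0L)
    tab <- data.frame(i = integer(), j = integer(), dprime = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), r2 = numeric())
  names(tab) <- c("i", "j", "dprime", "ci_lo", "ci_hi", "r2")
  tab$snp_i <- colnames(m)[tab$i]
  tab$snp_j <- colnames(m)[tab$j]
  tab
}

#' Partition SNPs into haplotype blocks (Gabriel-style)
#'
#' A pair is in "strong LD" when its D' confidence bounds satisfy
#' `ci_lo >= ld_lower` and `ci_hi >= ld_upper`; it shows "strong
#' recombination" when `ci_hi < recomb_hi`; other pairs are
#' uninformative. A candidate block is a run of consecutive SNPs on one
#' chromosome, spanning at most `max_block_bp`, in which at least
#' `frac_strong` of informative pairs are in strong LD (and at least one
#' pair is informative). Candidates are accepted greedily longest-first;
#' remaining SNPs become singleton blocks, so every SNP belongs to
#' exactly one block.
#'
#' @param g a [genotype_matrix].
#' @param ld output of [pairwise_ld()] on `g`.
#' @param max_block_bp maximum physical span of a block.
#' @param ld_lower,ld_upper strong-LD bounds on the D' CI.
#' @param recomb_hi CI upper bound below which a pair counts as strong
#'   recombination.
#' @param frac_strong minimum fraction of informative pairs in strong LD.
#' @return data.frame with one row per block: `first`, `last` (SNP column
#'   index range), `chrom`, `start_bp`, `end_bp`, `n_snps`.
#' @export
build_blocks <- function(g, ld, max_block_bp = 200000,
                         ld_lower = 0.70, ld_upper = 0.98,
                         recomb_hi = 0.90, frac_strong = 0.95) {
  chrom <- snp_chrom(g); pos <- snp_pos(g)
  p <- ncol(g)
  strong <- ld$ci_lo >= ld_lower & ld$ci_hi >= ld_upper
  recomb <- ld$ci_hi < recomb_hi
  info <- strong | recomb
  # windowed 2D cumulative counts: nS[i0,j0] / nI[i0,j0] = strong /
  # informative pairs fully inside [i0, j0], built bottom-up over i0
  cand <- list()
  if (nrow(ld)) {
    for (cset in split(seq_len(p), chrom)) {
      lo <- min(cset); hi <- max(cset); nc <- hi - lo + 1
      rows <- which(ld$i >= lo & ld$j <= hi)
      if (!length(rows)) next
      Srow <- matrix(0L, nc, nc); Irow <- matrix(0L, nc, nc)
      ii <- ld$i[rows] - lo + 1L; jj <- ld$j[rows] - lo + 1L
      Srow[cbind(ii, jj)] <- as.integer(strong[rows])
      Irow[cbind(ii, jj)] <- as.integer(info[rows])
      nS <- numeric(nc); nI <- numeric(nc)  # running vectors over j0
      for (i0 in nc:1) {
        rS <- cumsum(Srow[i0, ]); rI <- cumsum(Irow[i0, ])
        nS <- nS + rS; nI <- nI + rI
        if (i0 < nc) {
          jmax <- i0
          for (j0 in (i0 + 1):nc) {
            if (pos[lo + j0 - 1] - pos[lo + i0 - 1] > max_block_bp) break
            jmax <- j0
            if (nI[j0] > 0 && nS[j0] / nI[j0] >= frac_strong)
              cand[[length(cand) + 1]] <- c(lo + i0 - 1, lo + j0 - 1)
          }
        }
      }
    }
  }
  taken <- rep(FALSE, p)
  blocks <- list()
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    ord <- order(-(cm[, 2] - cm[, 1]), cm[, 1])
    for (r in ord) {
      a <- cm[r, 1]; b <- cm[r, 2]
      if (any(taken[a:b])) next
      taken[a:b] <- TRUE
      blocks[[length(blocks) + 1]] <- c(a, b)
    }
  }
  for (i in which(!taken)) blocks[[length(blocks) + 1]] <- c(i, i)
  bm <- do.call(rbind, blocks)
  bm <- bm[order(bm[, 1]), , drop = FALSE]
  data.frame(first = bm[, 1], last = bm[, 2],
             chrom = chrom[bm[, 1]],
             start_bp = pos[bm[, 1]], end_bp = pos[bm[, 2]],
             n_snps = bm[, 2] - bm[, 1] + 1L,
             stringsAsFactors = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Call haplotype alleles for one block
#'
#' Enumerates the distinct within-block genotype strings of the panel as
#' candidate alleles. Strings rarer than `min_allele_freq` are merged into
#' their Hamming-nearest frequent haplotype (ties broken toward the more
#' frequent, then lexicographically smaller, haplotype). Allele indices
#' are assigned by descending final frequency. Marker ids follow the
#' convention `<chrom>_<pos>` for single-SNP blocks and
#' `<chrom>_BLOCK<k>_<start>_<end>` for multi-SNP blocks.
#'
#' @param g a [genotype_matrix] without missing calls.
#' @param snp_idx column indices of the block's member SNPs.
#' @param min_allele_freq frequency below which haplotypes are merged.
#' @param serial block serial number used in the id of multi-SNP blocks.
#' @return An object of class `snpldb` (list with `id`, `chrom`,
#'   `start_bp`, `end_bp`, `snp_ids`, `alleles`, `allele_of`, `freqs`),
#'   or `NULL` for a monomorphic block.
#' @export
call_haplotype_alleles <- function(g, snp_idx, min_allele_freq = 0.01,
                                   serial = 1L) {
  m <- unclass(g)[, snp_idx, drop = FALSE]
  if (anyNA(m)) stop("impute missing calls before allele calling")
  strings <- apply(m, 1, paste, collapse = "")
  cnt <- table(strings)
  n <- length(strings)
  if (length(cnt) < 2) return(NULL)
  freq <- as.numeric(cnt) / n
  hapstr <- names(cnt)
  frequent <- freq >= min_allele_freq
  if (!any(frequent)) frequent[which.max(freq)] <- TRUE
  map <- stats::setNames(hapstr, hapstr)
  for (hs in hapstr[!frequent]) {
    targets <- hapstr[frequent]
    d <- vapply(targets, hamming, 0, a = hs)
    best <- targets[d == min(d)]
    if (length(best) > 1) {
      f <- freq[match(best, hapstr)]
      best <- best[f == max(f)]
      best <- sort(best)[1]
    }
    map[hs] <- best
  }
  merged <- map[strings]
  cnt2 <- table(merged)
  if (length(cnt2) < 2) return(NULL)
  ord <- order(-as.numeric(cnt2), names(cnt2))
  alleles <- names(cnt2)[ord]
  allele_of <- match(merged, alleles)
  names(allele_of) <- rownames(m)
  chrom <- snp_chrom(g)[snp_idx[1]]
  start <- snp_pos(g)[snp_idx[1]]
  end <- snp_pos(g)[snp_idx[length(snp_idx)]]
  id <- if (length(snp_idx) == 1) paste0(chrom, "_", start)
        else sprintf("%s_BLOCK%d_%d_%d", chrom, serial, start, end)
  structure(list(id = id, chrom = chrom, start_bp = start, end_bp = end,
                 snp_ids = colnames(g)[snp_idx],
                 alleles = alleles,
                 allele_of = allele_of,
                 freqs = as.numeric(cnt2)[ord] / n),
            class = "snpldb")
}

#' @export
print.snpldb <- function(x, ...) {
  cat(sprintf("snpldb %s: %d SNP(s), %d allele(s); freqs %s\n", x$id,
              length(x$snp_ids), length(x$alleles),
              paste(sprintf("%.3f", x$freqs), collapse = "/")))
  invisible(x)
}

#' Build the SNPLDB marker set of a panel
#'
#' End-to-end wrapper: impute missing calls, estimate pairwise D' within
#' the window, call blocks, and derive one multi-allelic marker per
#' polymorphic block. Monomorphic blocks yield no marker (reported).
#'
#' @param g a [genotype_matrix].
#' @param max_block_bp,ld_lower,ld_upper,recomb_hi,frac_strong block
#'   calling parameters, see [build_blocks()].
#' @param min_allele_freq rare-haplotype merge threshold, see
#'   [call_haplotype_alleles()].
#' @return A list of class `snpldb_set` of [call_haplotype_alleles()]
#'   markers, with the block table as attribute `blocks`.
#' @export
snpldb_markers <- function(g, max_block_bp = 200000, min_allele_freq = 0.01,
                           ld_lower = 0.70, ld_upper = 0.98,
                           recomb_hi = 0.90, frac_strong = 0.95) {
  g <- impute_major(g)
  ld <- pairwise_ld(g, max_window_bp = max_block_bp)
  blocks <- build_blocks(g, ld, max_block_bp, ld_lower, ld_upper,
                         recomb_hi, frac_strong)
  serial <- stats::ave(seq_len(nrow(blocks)), blocks$chrom,
                       FUN = function(ix) cumsum(blocks$n_snps[ix] > 1))
  markers <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks)))
    markers[[b]] <- call_haplotype_alleles(
      g, blocks$first[b]:blocks$last[b], min_allele_freq, serial[b])
  dropped <- vapply(markers, is.null, TRUE)
  if (any(dropped))
    message(sum(dropped), " monomorphic block(s) yielded no marker")
  markers <- markers[!dropped]
  names(markers) <- vapply(markers, `[[`, "", "id")
  structure(markers, blocks = blocks, class = "snpldb_set")
}

#' @export
print.snpldb_set <- function(x, ...) {
  na <- vapply(x, function(m) length(m$alleles), 0L)
  cat(sprintf("snpldb_set: %d markers (%d multi-SNP), alleles per marker %d-%d\n",
              length(x), sum(vapply(x, function(m) length(m$snp_ids), 0L) > 1),
              min(na), max(na)))
  invisible(x)
}

#' Accession x marker allele-index matrix
#' @param markers a `snpldb_set` or list of `snpldb` markers.
#' @return Integer matrix, rows = accessions, columns = marker ids.
#' @export
allele_assignments <- function(markers) {
  acc <- names(markers[[1]]$allele_of)
  out <- vapply(markers, function(m) m$allele_of[acc], integer(length(acc)))
  rownames(out) <- acc
  out
}

#' Marker summary table
#' @param markers a `snpldb_set`.
#' @return data.frame: id, chrom, start/end, n_snps, n_alleles, freqs.
#' @export
marker_table <- function(markers) {
  data.frame(
    id = vapply(markers, `[[`, "", "id"),
    chrom = vapply(markers, `[[`, "", "chrom"),
    start_bp = vapply(markers, `[[`, 0, "start_bp"),
    end_bp = vapply(markers, `[[`, 0, "end_bp"),
    n_snps = vapply(markers, function(m) length(m$snp_ids), 0L),
    n_alleles = vapply(markers, function(m) length(m$alleles), 0L),
    freqs = vapply(markers, function(m)
      paste(sprintf("%.4f", m$freqs), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Genetic-similarity matrix and eigenvector covariates
#'
#' Similarity between two accessions is the fraction of markers at which
#' they carry the same allele (1 on the diagonal). The matrix is
#' double-centered (Gower) and eigen-decomposed; the top-k eigenvectors
#' serve as population-structure covariates in association scans, and the
#' cumulative variance fraction is the share of the positive eigenvalue
#' mass they carry.
#'
#' @param markers a `snpldb_set`.
#' @param k number of eigenvectors to keep (default 10).
#' @return An object of class `structure_covariates`: list with
#'   `similarity`, `eigenvalues`, `vectors` (accession x k), `k`,
#'   `cum_var_fraction`.
#' @export
similarity_and_eigen <- function(markers, k = 10) {
  A <- allele_assignments(markers)
  n <- nrow(A); M <- ncol(A)
  if (k > n) stop("k exceeds the number of accessions")
  S <- matrix(0, n, n, dimnames = list(rownames(A), rownames(A)))
  for (j in seq_len(M)) {
    a <- A[, j]
    S <- S + (outer(a, a, "=="))
  }
  S <- S / M
  rm <- rowMeans(S)
  C <- S - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(S)
  e <- eigen(C, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  structure(list(similarity = S,
                 eigenvalues = e$values,
                 vectors = e$vectors[, seq_len(k), drop = FALSE],
                 k = k,
                 cum_var_fraction = sum(pos[seq_len(k)]) / sum(pos)),
            class = "structure_covariates")
}

#' @export
print.structure_covariates <- function(x, ...) {
  cat(sprintf("structure_covariates: top %d eigenvectors of %d accessions (%.1f%% of variation)\n",
              x$k, nrow(x$similarity), 100 * x$cum_var_fraction))
  invisible(x)
}
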