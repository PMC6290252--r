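#' Genes within a physical window of detected markers
#'
#' A gene qualifies for a marker when its interval overlaps the marker's
#' block interval (distance 0) or the gap between the two intervals is
#' strictly smaller than `window` bp.
#'
#' @param markers a `snpldb_set` (or subset list) of detected markers.
#' @param genes a [read_gff()] gene table.
#' @param window proximity window in bp (default 100,000).
#' @return data.frame: `marker`, `gene_id`, `distance_bp`.
#' @export
genes_near <- function(markers, genes, window = 100000) {
  mtab <- marker_table(markers)
  if (!any(genes$chrom %in% mtab$chrom) && nrow(genes) > 0)
    stop("chromosome names do not match between markers and genes: ",
         paste(utils::head(unique(genes$chrom)), collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(mtab))) {
    g <- genes[genes$chrom == mtab$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    # distance = bases strictly between the two intervals (0 on overlap)
    gap <- pmax(0, pmax(mtab$start_bp[i] - g$end, g$start - mtab$end_bp[i]) - 1)
    keep <- gap < window
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(
        marker = mtab$id[i], gene_id = g$gene_id[keep],
        distance_bp = gap[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker = character(), gene_id = character(),
                      distance_bp = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Chi-square association of a gene's SNPs with a marker's alleles
#'
#' For each SNP whose position falls inside the gene interval, tests
#' independence of the SNP genotype class and the marker allele class by
#' Pearson chi-square (Monte-Carlo p when any expected count is below 5).
#' A gene passes when it contains at least one SNP and the smallest SNP
#' p-value is below `alpha_gene`.
#'
#' @param gene one row of a [read_gff()] table (or a list with
#'   `gene_id`, `chrom`, `start`, `end`).
#' @param g a [genotype_matrix].
#' @param marker a `snpldb` marker.
#' @param alpha_gene significance level (default 0.05).
#' @param seed Monte-Carlo seed.
#' @return List: `gene_id`, `n_snps`, `min_p`, `passes`, `note`.
#' @export
gene_marker_association <- function(gene, g, marker, alpha_gene = 0.05,
                                    seed = 1) {
  chrom <- snp_chrom(g); pos <- snp_pos(g)
  in_gene <- which(chrom == gene$chrom & pos >= gene$start &
                     pos <= gene$end)
  if (!length(in_gene))
    return(list(gene_id = gene$gene_id, n_snps = 0L, min_p = NA_real_,
                passes = FALSE, note = "no SNP"))
  acc <- names(marker$allele_of)
  m <- unclass(g)[acc, , drop = FALSE]
  ps <- rep(NA_real_, length(in_gene))
  for (k in seq_along(in_gene)) {
    snp <- m[, in_gene[k]]
    keep <- !is.na(snp)
    tab <- table(snp[keep], marker$allele_of[acc][keep])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 5)) {
      set.seed(seed + k)
      ps[k] <- stats::chisq.test(tab, correct = FALSE,
                                 simulate.p.value = TRUE,
                                 B = 10000)$p.value
    } else ps[k] <- ct$p.value
  }
  if (all(is.na(ps)))
    return(list(gene_id = gene$gene_id, n_snps = length(in_gene),
                min_p = NA_real_, passes = FALSE,
                note = "no polymorphic SNP"))
  minp <- min(ps, na.rm = TRUE)
  list(gene_id = gene$gene_id, n_snps = length(in_gene), min_p = minp,
       passes = minp < alpha_gene, note = "")
}

#' Candidate genes around detected markers
#'
#' The three-step filter: (1) genes within `window` bp of a detected
#' marker, (2) genes containing at least one SNP segregating in the
#' panel, (3) genes whose SNPs are significantly associated with the
#' marker's allele classes by chi-square at `alpha_gene`.
#'
#' @param markers detected markers (a `snpldb_set` or subset list).
#' @param genes a [read_gff()] table.
#' @param g the [genotype_matrix] of the panel.
#' @param window proximity window in bp (default 100,000).
#' @param alpha_gene chi-square significance level (default 0.05).
#' @param seed Monte-Carlo seed.
#' @return data.frame: `marker`, `gene_id`, `distance_bp`, `n_snps`,
#'   `min_p`, `passes`, `note`.
#' @export
candidate_genes <- function(markers, genes, g, window = 100000,
                            alpha_gene = 0.05, seed = 1) {
  near <- genes_near(markers, genes, window)
  if (!nrow(near))
    return(cbind(near, n_snps = integer(), min_p = numeric(),
                 passes = logical(), note = character()))
  res <- lapply(seq_len(nrow(near)), function(i) {
    gene <- genes[genes$gene_id == near$gene_id[i], ]
    gene_marker_association(as.list(gene), g, markers[[near$marker[i]]],
                            alpha_gene, seed = seed + i)
  })
  near$n_snps <- vapply(res, `[[`, 0L, "n_snps")
  near$min_p <- vapply(res, `[[`, 0, "min_p")
  near$passes <- vapply(res, `[[`, TRUE, "passes")
  near$note <- vapply(res, `[[`, "", "note")
  near
}
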