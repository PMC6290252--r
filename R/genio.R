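#' Genotype matrix for an inbred panel
#'
#' Container for homozygous bi-allelic genotype calls of an inbred panel:
#' an accession x SNP integer matrix with per-SNP chromosome and 1-based
#' physical position. Calls are coded 0 (reference homozygote), 1
#' (alternate homozygote) or `NA` (missing). Heterozygous calls are not
#' representable: the ingestion functions set them to `NA` (the panels this
#' package targets are inbred lines, where residual heterozygosity is
#' treated as missing data).
#'
#' @param calls integer matrix, accessions in rows (rownames required),
#'   SNPs in columns (colnames required), values in `{0, 1, NA}`.
#' @param chrom character vector of chromosome names, one per SNP.
#' @param pos integer vector of 1-based positions, one per SNP.
#' @param sort logical; reorder SNPs by (chromosome, position) if needed.
#' @return An object of class `genotype_matrix`: the call matrix with
#'   `chrom` and `pos` attributes.
#' @export
genotype_matrix <- function(calls, chrom, pos, sort = TRUE) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have accession rownames and SNP colnames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate accession ids")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate SNP ids")
  if (length(chrom) != ncol(calls) || length(pos) != ncol(calls))
    stop("chrom/pos length must equal the number of SNPs")
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, NA_integer_)))
    stop("calls must be coded 0, 1 or NA")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  key <- order(chrom, pos)
  if (!identical(key, seq_along(pos))) {
    if (!sort) stop("SNPs are not sorted by (chromosome, position)")
    calls <- calls[, key, drop = FALSE]
    chrom <- chrom[key]
    pos <- pos[key]
  }
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicate (chromosome, position) pairs")
  if (any(rowSums(!is.na(calls)) == 0))
    stop("some accessions are missing at every SNP")
  structure(calls, chrom = chrom, pos = pos, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x), ncol(x), length(unique(attr(x, "chrom")))))
  miss <- mean(is.na(x))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  chrom <- attr(x, "chrom"); pos <- attr(x, "pos")
  m <- unclass(x)
  attr(m, "chrom") <- NULL; attr(m, "pos") <- NULL
  if (missing(j)) j <- seq_along(chrom)
  out <- m[i, j, drop = FALSE]
  structure(out, chrom = chrom[j], pos = pos[j], class = "genotype_matrix")
}

snp_chrom <- function(g) attr(g, "chrom")
snp_pos <- function(g) attr(g, "pos")

#' Read genotypes from VCF or HapMap text
#'
#' Ingests bi-allelic SNP genotypes of an inbred panel. Multi-allelic
#' records are dropped, heterozygous calls are set to missing, and SNPs
#' that end up all-missing or where every retained call is identical after
#' this cleaning are kept (monomorphic handling is left to downstream
#' steps) unless all calls are missing, in which case the SNP is dropped
#' with a warning. Counts of dropped records and recoded calls are
#' reported via `message()`.
#'
#' @param path path to the genotype file.
#' @param format `"vcf"` (v4.x text) or `"hapmap"` (tab-separated HapMap
#'   text with 11 metadata columns and two-letter genotype codes).
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, vcf = read_vcf_genotypes(path),
         hapmap = read_hapmap_genotypes(path))
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multi-allelic record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow(code), ncol(code),
                  dimnames = dimnames(code))
  calls[code %in% c("0/0", "0")] <- 0L
  calls[code %in% c("1/1", "1")] <- 1L
  het <- code %in% c("0/1", "1/0")
  if (any(het)) message(sum(het), " heterozygous call(s) set to missing")
  calls <- t(calls)  # accessions x SNPs
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  colnames(calls) <- ids
  keep <- colSums(!is.na(calls)) > 0
  if (!all(keep))
    warning(sum(!keep), " all-missing SNP(s) dropped")
  genotype_matrix(calls[, keep, drop = FALSE],
                  chrom = fix[keep, "CHROM"],
                  pos = as.integer(fix[keep, "POS"]))
}

read_hapmap_genotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("rs#", "alleles", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("not a HapMap table: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (ncol(tab) < 12) stop("HapMap table has no genotype columns")
  acc <- names(tab)[-(1:11)]
  al <- strsplit(tab$alleles, "/", fixed = TRUE)
  bad <- lengths(al) != 2
  if (any(bad)) message(sum(bad), " non-bi-allelic record(s) dropped")
  tab <- tab[!bad, , drop = FALSE]; al <- al[!bad]
  raw <- as.matrix(tab[, acc, drop = FALSE])
  ref2 <- vapply(al, function(a) paste0(a[1], a[1]), "")
  alt2 <- vapply(al, function(a) paste0(a[2], a[2]), "")
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw))
  calls[raw == ref2] <- 0L
  calls[raw == alt2] <- 1L
  het <- !is.na(raw) & raw != ref2 & raw != alt2 &
    !(raw %in% c("NN", "N", "--", "..", "//"))
  if (any(het)) message(sum(het), " heterozygous call(s) set to missing")
  calls <- t(calls)
  rownames(calls) <- acc
  colnames(calls) <- tab[["rs#"]]
  keep <- colSums(!is.na(calls)) > 0
  if (!all(keep)) warning(sum(!keep), " all-missing SNP(s) dropped")
  genotype_matrix(calls[, keep, drop = FALSE],
                  chrom = tab$chrom[keep], pos = as.integer(tab$pos[keep]))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Inverse of [read_genotypes()] for the `vcf` format; calls become
#' homozygous diploid GT fields (`0/0`, `1/1`, `./.`).
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  chrom <- snp_chrom(g); pos <- snp_pos(g)
  gt <- matrix("./.", ncol(g), nrow(g))
  m <- t(unclass(g))
  gt[!is.na(m) & m == 0L] <- "0/0"
  gt[!is.na(m) & m == 1L] <- "1/1"
  body <- cbind(chrom, pos, colnames(g), "A", "C", ".", "PASS", ".", "GT", gt)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Impute missing calls to the per-SNP major allele
#'
#' Haplotype-block calling needs fully defined genotype strings; missing
#' calls are filled with each SNP's most frequent allele (ties go to the
#' reference allele 0). The number of imputed calls is reported.
#'
#' @param g a [genotype_matrix].
#' @return A [genotype_matrix] without missing calls.
#' @export
impute_major <- function(g) {
  m <- unclass(g)
  nmiss <- sum(is.na(m))
  if (nmiss > 0) {
    maj <- ifelse(colMeans(m, na.rm = TRUE) > 0.5, 1L, 0L)
    maj[is.na(maj)] <- 0L
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- maj[idx[, 2]]
    message(nmiss, " missing call(s) imputed to the major allele")
  }
  genotype_matrix(m, snp_chrom(g), snp_pos(g))
}

#' Read multi-environment trial phenotypes
#'
#' Reads a delimited table with columns `accession`, `environment`,
#' `replication`, `value` (extra columns ignored; comma or tab delimited,
#' autodetected from the header line).
#'
#' @param path path to the table.
#' @return A data.frame of class `trait_obs` with the four columns above.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("accession", "environment", "replication", "value")
  if (!all(need %in% names(tab)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "))
  val <- suppressWarnings(as.numeric(tab$value))
  bad <- which(is.na(val) & !is.na(tab$value) & tab$value != "" &
                 tolower(tab$value) != "na")
  if (length(bad))
    stop("non-numeric value(s) at data line(s): ",
         paste(bad, collapse = ", "))
  trait_obs(tab$accession, tab$environment, tab$replication, val)
}

#' Construct trait observations
#'
#' @param accession,environment,replication identifier vectors.
#' @param value numeric trait values (trait units, e.g. % oil).
#' @return A data.frame of class `trait_obs`.
#' @export
trait_obs <- function(accession, environment, replication, value) {
  obs <- data.frame(accession = as.character(accession),
                    environment = as.character(environment),
                    replication = as.character(replication),
                    value = as.numeric(value),
                    stringsAsFactors = FALSE)
  key <- paste(obs$accession, obs$environment, obs$replication, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (accession, environment, replication) key: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  if (any(!is.finite(obs$value)))
    stop("trait values must be finite")
  class(obs) <- c("trait_obs", "data.frame")
  obs
}

#' Write trait observations to a delimited file
#' @param obs a `trait_obs` table.
#' @param path output path.
#' @export
write_phenotypes <- function(obs, path) {
  utils::write.table(as.data.frame(obs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Across-environment accession means
#'
#' Association scans use one mean phenotype per accession across all
#' environments and replications.
#'
#' @param obs a `trait_obs` table.
#' @return Named numeric vector of per-accession means.
#' @export
trait_means <- function(obs) {
  m <- tapply(obs$value, obs$accession, mean)
  stats::setNames(as.numeric(m), names(m))[unique(obs$accession)]
}

#' Read a two-column accession-to-group table
#'
#' @param path delimited file with columns `accession` and `group`.
#' @return A named factor (names = accession ids) of group labels.
#' @export
read_groups <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("accession", "group") %in% names(tab)))
    stop("group table must have columns accession, group")
  if (anyDuplicated(tab$accession)) stop("duplicate accession in group table")
  stats::setNames(factor(tab$group), tab$accession)
}

#' Read gene models from GFF3
#'
#' Extracts features of type `gene` with 1-based inclusive coordinates;
#' all other feature types (mRNA, exon, CDS, ...) are ignored.
#'
#' @param path path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gff <- ape::read.gff(path)
  gff <- gff[gff$type == "gene", , drop = FALSE]
  if (any(gff$end < gff$start))
    stop("gene with end < start in ", path)
  id <- sub(".*ID=([^;]+).*", "\\1", gff$attributes)
  noid <- !grepl("ID=", gff$attributes)
  id[noid] <- paste0("gene", which(noid))
  if (anyDuplicated(id)) stop("duplicate gene ids in ", path)
  data.frame(gene_id = id, chrom = as.character(gff$seqid),
             start = as.integer(gff$start), end = as.integer(gff$end),
             strand = as.character(gff$strand), stringsAsFactors = FALSE)
}
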