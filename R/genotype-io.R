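#' Genotype matrix container
#'
#' @param dosages n x p numeric matrix of allele dosages on the 0-2 scale;
#'   `NA` marks missing genotypes.
#' @param snps data frame of per-SNP metadata with columns `id`,
#'   `chromosome`, `position`, `allele1`, `allele2`. Dosages count copies of
#'   `allele1` (recorded in the `dosage_allele` attribute).
#' @param sample_ids character vector of individual identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps = NULL, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); p <- ncol(dosages)
  if (is.null(snps))
    snps <- data.frame(id = paste0("snp", seq_len(p)),
                       chromosome = "0", position = seq_len(p),
                       allele1 = "A", allele2 = "B",
                       stringsAsFactors = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(n))
  if (nrow(snps) != p) stop("nrow(snps) must equal ncol(dosages)")
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal nrow(dosages)")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  structure(list(dosages = dosages, snps = snps, sample_ids = sample_ids),
            class = "genotype_matrix", dosage_allele = "allele1")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' Per-SNP summary statistics
#'
#' Computes minor allele frequency, call rate and the Hardy-Weinberg
#' chi-square p-value for each SNP. The HWE test uses hard genotype calls
#' (dosages rounded to 0/1/2).
#'
#' @param gm a [genotype_matrix()].
#' @return Data frame with columns `id`, `maf`, `call_rate`, `hwe_p`.
#' @export
genotype_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  D <- gm$dosages
  n <- nrow(D)
  obs <- colSums(!is.na(D))
  freq <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hwe <- vapply(seq_len(ncol(D)), function(j) {
    g <- round(D[!is.na(D[, j]), j])
    if (length(g) == 0) return(1)  # fully missing; caught by call-rate filter
    hwe_test(c(sum(g == 2), sum(g == 1), sum(g == 0)))
  }, 0)
  data.frame(id = gm$snps$id, maf = maf, call_rate = obs / n, hwe_p = hwe,
             stringsAsFactors = FALSE)
}

# 256-entry lookup: PLINK bed byte -> 4 dosages (counting allele1)
# 2-bit codes: 00 hom allele1 (2), 01 missing (NA), 10 het (1), 11 hom allele2 (0)
.bed_decode_table <- function() {
  codes <- c(2, NA, 1, 0)
  t(vapply(0:255, function(b) {
    codes[c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
            bitwAnd(bitwShiftR(b, 4L), 3L),
            bitwAnd(bitwShiftR(b, 6L), 3L)) + 1L]
  }, numeric(4)))
}

#' Read PLINK binary genotypes
#'
#' Reads a `.bed`/`.bim`/`.fam` file set (SNP-major bed layout). Dosages
#' count copies of the `.bim` first allele; missing genotypes are `NA`.
#'
#' @param prefix path prefix (without extension).
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bimd <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("chromosome", "id", "cm", "position",
                                   "allele1", "allele2"),
                     colClasses = c("character", "character", "numeric",
                                    "integer", "character", "character"))
  famd <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famd); p <- nrow(bimd)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error in ", bed, ": bad magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("format error in ", bed, ": not in SNP-major mode")
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) != 3 + bytes_per_snp * p)
    stop("format error in ", bed, ": truncated or inconsistent with bim/fam")
  tab <- .bed_decode_table()
  body <- as.integer(raw[-(1:3)]) + 1L
  # decode all bytes at once: (4*bytes_per_snp) x p, then trim padding rows
  vals <- matrix(t(tab)[, body], nrow = 4 * bytes_per_snp)
  D <- vals[seq_len(n), , drop = FALSE]
  snps <- bimd[, c("id", "chromosome", "position", "allele1", "allele2")]
  genotype_matrix(D, snps, sample_ids = as.character(famd[[2]]))
}

#' Write PLINK binary genotypes
#'
#' Inverse of [read_plink()]. Dosages must be integral (0/1/2 or `NA`).
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  D <- gm$dosages
  if (any(abs(D - round(D)) > 1e-9, na.rm = TRUE))
    stop("PLINK bed stores hard calls; dosages must be integers 0/1/2")
  n <- nrow(D); p <- ncol(D)
  # dosage -> 2-bit code (counting allele1): 2->00, NA->01, 1->10, 0->11
  code <- matrix(3L, n, p)
  code[!is.na(D) & D == 2] <- 0L
  code[is.na(D)] <- 1L
  code[!is.na(D) & D == 1] <- 2L
  pad <- 4 * ceiling(n / 4) - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  idx <- seq(1, nrow(code), by = 4)
  bytes <- code[idx, , drop = FALSE] +
    code[idx + 1, , drop = FALSE] * 4L +
    code[idx + 2, , drop = FALSE] * 16L +
    code[idx + 3, , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  close(con)
  s <- gm$snps
  write.table(data.frame(s$chromosome, s$id, 0, s$position,
                         s$allele1, s$allele2),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(gm$sample_ids, gm$sample_ids, 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read BIMBAM mean-genotype text format
#'
#' One SNP per row: id, allele1, allele2, then n dosages (possibly
#' fractional posterior mean genotypes); `NA` marks missing.
#'
#' @param path path to the mean-genotype file.
#' @param sample_ids optional individual identifiers.
#' @return A [genotype_matrix()].
#' @export
read_bimbam <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  len <- lengths(parts)
  if (length(unique(len)) != 1)
    stop("format error in ", path, ": rows have inconsistent field counts")
  if (len[1] < 4)
    stop("format error in ", path, ": need id, two alleles and dosages")
  ids <- vapply(parts, `[`, "", 1)
  a1 <- vapply(parts, `[`, "", 2)
  a2 <- vapply(parts, `[`, "", 3)
  D <- t(vapply(parts, function(x)
    suppressWarnings(as.numeric(x[-(1:3)])), numeric(len[1] - 3)))
  if (nrow(D) == 1 && length(ids) > 1) D <- t(D)
  snps <- data.frame(id = ids, chromosome = "0",
                     position = seq_along(ids), allele1 = a1, allele2 = a2,
                     stringsAsFactors = FALSE)
  genotype_matrix(t(D), snps, sample_ids = sample_ids)
}

#' Write BIMBAM mean-genotype text format
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bimbam <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  D <- t(gm$dosages)  # SNP per row
  rows <- vapply(seq_len(nrow(D)), function(j) {
    paste(c(gm$snps$id[j], gm$snps$allele1[j], gm$snps$allele2[j],
            ifelse(is.na(D[j, ]), "NA", format(D[j, ], trim = TRUE))),
          collapse = " ")
  }, "")
  writeLines(rows, path)
  invisible(path)
}
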