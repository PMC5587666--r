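#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of the observed
#' genotype counts against the Hardy-Weinberg proportions implied by the
#' sample allele frequency. Monomorphic SNPs return p = 1 by convention.
#'
#' @param genotype_counts integer vector `(n_AA, n_Aa, n_aa)`.
#' @return The p-value.
#' @examples
#' hwe_test(c(25, 50, 25)) # exact HWE proportions -> 1
#' hwe_test(c(0, 100, 0))  # all heterozygous -> ~1.5e-23
#' @export
hwe_test <- function(genotype_counts) {
  ct <- as.numeric(genotype_counts)
  if (length(ct) != 3 || any(!is.finite(ct)) || any(ct < 0))
    stop("genotype_counts must be three nonnegative counts (n_AA, n_Aa, n_aa)")
  n <- sum(ct)
  if (n < 1) stop("total genotype count must be >= 1")
  pa <- (2 * ct[1] + ct[2]) / (2 * n)
  if (pa == 0 || pa == 1) return(1)
  expd <- n * c(pa^2, 2 * pa * (1 - pa), (1 - pa)^2)
  stat <- sum((ct - expd)^2 / expd)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Quality-control filter for a genotype panel
#'
#' Removes SNPs with a Hardy-Weinberg p-value below `hwe_thresh`, a call
#' rate below `call_thresh`, or a minor allele frequency below `maf_thresh`
#' (all strict `<` comparisons). The defaults are the standard GWAS filter
#' (HWE p < 1e-4, call rate < 95%, MAF < 1%).
#'
#' @param gm a [genotype_matrix()]; missing genotypes allowed.
#' @param hwe_thresh,call_thresh,maf_thresh filter thresholds.
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (data frame of removed SNPs with the first failing rule, in
#'   the order HWE, call rate, MAF).
#' @export
apply_qc <- function(gm, hwe_thresh = 1e-4, call_thresh = 0.95,
                     maf_thresh = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stats <- genotype_stats(gm)
  rule <- rep(NA_character_, nrow(stats))
  rule[which(stats$maf < maf_thresh)] <- "maf"
  rule[which(stats$call_rate < call_thresh)] <- "call_rate"
  rule[which(stats$hwe_p < hwe_thresh)] <- "hwe"
  drop <- !is.na(rule)
  if (all(drop)) stop("empty panel: all SNPs removed by QC")
  report <- data.frame(id = stats$id[drop], rule = rule[drop],
                       maf = stats$maf[drop],
                       call_rate = stats$call_rate[drop],
                       hwe_p = stats$hwe_p[drop],
                       stringsAsFactors = FALSE)
  out <- genotype_matrix(gm$dosages[, !drop, drop = FALSE],
                         gm$snps[!drop, , drop = FALSE],
                         gm$sample_ids)
  list(genotypes = out, report = report)
}

#' Mean imputation of missing genotypes
#'
#' Replaces each missing dosage by the mean observed dosage of that SNP.
#'
#' @param gm a [genotype_matrix()].
#' @return A [genotype_matrix()] without missing values.
#' @export
mean_impute <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  D <- gm$dosages
  miss <- is.na(D)
  if (any(colSums(!miss) == 0))
    stop("fully missing SNP; it should have been removed by call-rate QC")
  if (any(miss)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  genotype_matrix(D, gm$snps, gm$sample_ids)
}

#' Quantile normalization to a standard normal distribution
#'
#' Maps the value with (average, 1-based) rank r among n values to
#' \eqn{\Phi^{-1}((r - 0.5) / n)}; output order matches input order.
#'
#' @param values numeric vector with at least two distinct values.
#' @return Normalized values.
#' @export
quantile_normalize <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2) stop("need at least two values")
  if (length(unique(v)) < 2) stop("rank degenerate: all values identical")
  r <- rank(v, ties.method = "average")
  qnorm((r - 0.5) / length(v))
}

#' Center genotype columns
#'
#' Subtracts per-SNP means. When `means` is supplied (e.g., training means
#' applied to test data) those values are used verbatim; otherwise column
#' means are computed and returned for later reuse.
#'
#' @param gm a [genotype_matrix()] or plain numeric matrix, without missing
#'   values.
#' @param means optional numeric vector of column means to subtract.
#' @return A list with `X` (the centered matrix) and `means`.
#' @export
center_genotypes <- function(gm, means = NULL) {
  X <- if (inherits(gm, "genotype_matrix")) gm$dosages else as.matrix(gm)
  if (anyNA(X)) stop("X contains missing values; impute first")
  if (is.null(means)) means <- colMeans(X)
  if (length(means) != ncol(X))
    stop("means must have one entry per SNP column")
  list(X = sweep(X, 2, means), means = means)
}
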