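# SNP quality control, allele-frequency summaries, genotype distances and
# phenotype pre-correction.
#
# Editing rules operate on the combined multi-line data: a SNP is dropped if
# its call rate is below 95%, its minor allele frequency below 2%, it shows
# no homozygous genotype at all, or its Hardy-Weinberg goodness-of-fit
# chi-square exceeds 600.

#' Per-SNP summary statistics
#'
#' Computes, for every SNP column, the call rate, reference-allele frequency,
#' minor allele frequency, the three genotype counts, and the 3-class
#' Hardy-Weinberg goodness-of-fit chi-square with expectations derived from
#' the observed allele frequency (classes with zero expectation are skipped;
#' SNPs without any non-missing call are flagged undefined via `NA`).
#'
#' @param geno Individuals x SNPs matrix coded 0/1/2 with `NA` for missing.
#' @return Data frame with one row per SNP: `snp`, `n_called`, `call_rate`,
#'   `freq`, `maf`, `n0`, `n1`, `n2`, `hwe_chisq`.
#' @export
snp_stats <- function(geno) {
  if (!is.matrix(geno) || nrow(geno) == 0 || ncol(geno) == 0)
    stop("empty genotype matrix")
  bad <- geno[!is.na(geno)]
  if (!all(bad %in% c(0, 1, 2))) stop("genotype codes must be 0, 1, 2 or NA")
  n <- nrow(geno)
  n0 <- colSums(geno == 0, na.rm = TRUE)
  n1 <- colSums(geno == 1, na.rm = TRUE)
  n2 <- colSums(geno == 2, na.rm = TRUE)
  called <- n0 + n1 + n2
  freq <- ifelse(called > 0, (2 * n2 + n1) / (2 * called), NA_real_)
  maf <- pmin(freq, 1 - freq)
  # 3-class goodness-of-fit chi-square against HWE proportions
  q <- 1 - freq
  e0 <- called * q^2
  e1 <- called * 2 * freq * q
  e2 <- called * freq^2
  term <- function(o, e) ifelse(is.na(e) | e == 0, 0, (o - e)^2 / e)
  hwe <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  hwe[called == 0] <- NA_real_
  data.frame(snp = colnames(geno) %||% paste0("snp", seq_len(ncol(geno))),
             n_called = called, call_rate = called / n, freq = freq,
             maf = maf, n0 = n0, n1 = n1, n2 = n2, hwe_chisq = hwe,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SNP editing thresholds
#'
#' @param min_call_rate Minimum call rate; SNPs strictly below are removed.
#' @param min_maf Minimum minor allele frequency; strictly below removed
#'   (a MAF of exactly `min_maf` is retained).
#' @param require_homozygote Remove SNPs with no observed homozygous genotype.
#' @param max_hwe_chisq Maximum Hardy-Weinberg chi-square; strictly above
#'   removed (a value of exactly `max_hwe_chisq` is retained).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_call_rate = 0.95, min_maf = 0.02,
                              require_homozygote = TRUE, max_hwe_chisq = 600) {
  if (min_call_rate < 0 || min_call_rate > 1 || min_maf < 0 || min_maf > 1)
    stop("rate thresholds must lie in [0, 1]")
  if (max_hwe_chisq < 0) stop("max_hwe_chisq must be non-negative")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 require_homozygote = isTRUE(require_homozygote),
                 max_hwe_chisq = max_hwe_chisq),
            class = "filter_thresholds")
}

#' Apply the SNP editing rules
#'
#' All four rules are evaluated for every SNP and all failed-rule tags are
#' recorded, so per-rule counts do not depend on any rule ordering. Editing is
#' intended to be run on the combined multi-line data.
#'
#' @param geno Individuals x SNPs matrix coded 0/1/2 with `NA` for missing.
#' @param thresholds A [filter_thresholds()] object.
#' @param stats Optional precomputed [snp_stats()] table.
#' @return An object of class `snp_filter`: `genotypes` (retained columns),
#'   `report` (per-SNP logical columns `call_rate`, `maf`, `no_homozygote`,
#'   `hwe` and `retained`), `counts` (removed per rule and retained) and the
#'   thresholds used.
#' @export
filter_snps <- function(geno, thresholds = filter_thresholds(), stats = NULL) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (is.null(stats)) stats <- snp_stats(geno)
  fail_cr <- stats$call_rate < thresholds$min_call_rate
  fail_maf <- is.na(stats$maf) | stats$maf < thresholds$min_maf
  fail_hom <- if (thresholds$require_homozygote)
    (stats$n0 + stats$n2) == 0 else rep(FALSE, nrow(stats))
  fail_hwe <- is.na(stats$hwe_chisq) | stats$hwe_chisq > thresholds$max_hwe_chisq
  retained <- !(fail_cr | fail_maf | fail_hom | fail_hwe)
  report <- data.frame(snp = stats$snp, call_rate = fail_cr, maf = fail_maf,
                       no_homozygote = fail_hom, hwe = fail_hwe,
                       retained = retained, stringsAsFactors = FALSE)
  structure(list(genotypes = geno[, retained, drop = FALSE],
                 report = report,
                 counts = c(call_rate = sum(fail_cr), maf = sum(fail_maf),
                            no_homozygote = sum(fail_hom), hwe = sum(fail_hwe),
                            removed = sum(!retained), retained = sum(retained)),
                 thresholds = thresholds),
            class = "snp_filter")
}

#' @export
print.snp_filter <- function(x, ...) {
  cat("SNP filter report\n")
  cat(sprintf("  retained %d of %d SNPs\n", x$counts["retained"],
              nrow(x$report)))
  cat(sprintf("  failed: call rate %d, MAF %d, no homozygote %d, HWE %d\n",
              x$counts["call_rate"], x$counts["maf"],
              x$counts["no_homozygote"], x$counts["hwe"]))
  invisible(x)
}

#' SNPs segregating within a set of training lines
#'
#' Returns the indices of SNPs whose minor allele frequency is greater than
#' zero among the selected individuals (the union of the training lines, or an
#' explicit id set). SNPs fixed in the whole training set carry no information
#' for that scenario and are excluded from its design matrices.
#'
#' @param geno Individuals x SNPs matrix, rownames = ids.
#' @param line Line label per row of `geno`.
#' @param lines Character vector of training line names.
#' @param ids Optional explicit individual ids; overrides `lines`.
#' @return Integer vector of SNP column indices.
#' @export
segregating_subset <- function(geno, line, lines = NULL, ids = NULL) {
  if (is.null(ids)) {
    if (is.null(lines)) stop("provide lines or ids")
    if (!all(lines %in% unique(as.character(line))))
      stop("unknown line name")
    rows <- as.character(line) %in% lines
  } else {
    rows <- rownames(geno) %in% ids
    if (sum(rows) != length(unique(ids))) stop("unknown individual ids")
  }
  sub <- geno[rows, , drop = FALSE]
  f <- colMeans(sub, na.rm = TRUE) / 2
  which(f > 0 & f < 1)
}

#' Fixed-allele summary per line and per line pair
#'
#' A SNP is fixed in a line when one allele has frequency 1 among non-missing
#' genotypes. For every pair of lines, SNPs fixed in both are tallied as fixed
#' for the same or for opposite alleles.
#'
#' @param geno Individuals x SNPs matrix coded 0/1/2 with `NA` for missing.
#' @param line Line label per row of `geno`.
#' @return List with `per_line` (named count of fixed SNPs), `same_allele` and
#'   `opposite_allele` (symmetric matrices of pairwise counts).
#' @export
fixed_allele_summary <- function(geno, line) {
  line <- as.character(line)
  lns <- unique(line)
  if (length(lns) < 2) stop("at least two lines required")
  freq <- sapply(lns, function(ln)
    colMeans(geno[line == ln, , drop = FALSE], na.rm = TRUE) / 2)
  fixed0 <- freq == 0
  fixed1 <- freq == 1
  per_line <- colSums(fixed0 | fixed1, na.rm = TRUE)
  k <- length(lns)
  same <- opp <- matrix(0L, k, k, dimnames = list(lns, lns))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- sum((fixed0[, i] & fixed0[, j]) | (fixed1[, i] & fixed1[, j]),
             na.rm = TRUE)
    o <- sum((fixed0[, i] & fixed1[, j]) | (fixed1[, i] & fixed0[, j]),
             na.rm = TRUE)
    same[i, j] <- same[j, i] <- s
    opp[i, j] <- opp[j, i] <- o
  }
  list(per_line = per_line, same_allele = same, opposite_allele = opp)
}

#' Correlation of per-line minor allele frequencies
#'
#' Pearson correlation over SNPs of the minor allele frequency computed within
#' each of two lines (each line folded at its own minor allele).
#'
#' @param geno Individuals x SNPs matrix.
#' @param line Line label per row of `geno`.
#' @param line_a,line_b The two line names to compare.
#' @return Pearson correlation coefficient.
#' @export
allele_freq_correlation <- function(geno, line, line_a, line_b) {
  line <- as.character(line)
  if (!all(c(line_a, line_b) %in% line)) stop("unknown line name")
  maf_of <- function(ln) {
    f <- colMeans(geno[line == ln, , drop = FALSE], na.rm = TRUE) / 2
    pmin(f, 1 - f)
  }
  a <- maf_of(line_a)
  b <- maf_of(line_b)
  keep <- !is.na(a) & !is.na(b)
  if (stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0)
    stop("zero variance in per-line allele frequencies")
  stats::cor(a[keep], b[keep])
}

#' Euclidean distance matrix between genotypes
#'
#' Entry (j, k) is `sqrt(sum_i (x_ij - x_ik)^2)` over SNPs i. Genotypes must
#' be complete; impute or restrict the panel first.
#'
#' @param geno Individuals x SNPs numeric matrix without missing values.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(geno) {
  if (anyNA(geno)) stop("missing genotypes present; impute first")
  d <- as.matrix(stats::dist(geno, method = "euclidean"))
  dimnames(d) <- list(rownames(geno), rownames(geno))
  d
}

#' Mean-impute missing genotypes
#'
#' Replaces missing codes by the per-SNP mean genotype of the supplied data
#' (the combined multi-line set), leaving observed codes untouched.
#'
#' @param geno Individuals x SNPs matrix with `NA` for missing.
#' @return Numeric matrix without missing values.
#' @export
impute_genotypes <- function(geno) {
  if (!anyNA(geno)) {
    storage.mode(geno) <- "double"
    return(geno)
  }
  m <- colMeans(geno, na.rm = TRUE)
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- m[idx[, 2]]
  storage.mode(geno) <- "double"
  geno
}

#' Pre-correct phenotypes for hatch-week fixed effects
#'
#' Fits a one-way fixed-effect model of phenotype on hatch week by least
#' squares on the fitting set (training individuals, to avoid leakage) and
#' subtracts the estimated hatch-week means from all records, leaving
#' residuals with mean zero on the fitting set. Applying the correction twice
#' changes nothing.
#'
#' @param pheno Data frame with columns `id`, `y` and `hatch_week`.
#' @param fit_ids Ids used to estimate the hatch-week means (default: all).
#' @return `pheno` with a `y_corrected` column appended.
#' @export
precorrect_phenotypes <- function(pheno, fit_ids = NULL) {
  stopifnot(all(c("id", "y", "hatch_week") %in% colnames(pheno)))
  if (is.null(fit_ids)) fit_ids <- pheno$id
  fit <- pheno$id %in% fit_ids
  if (!any(fit)) stop("no fitting records")
  means <- tapply(pheno$y[fit], pheno$hatch_week[fit], mean)
  wk <- as.character(pheno$hatch_week)
  if (!all(wk %in% names(means)))
    stop("hatch week without fitting records: ",
         paste(setdiff(wk, names(means)), collapse = ", "))
  pheno$y_corrected <- pheno$y - as.numeric(means[wk])
  pheno
}
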