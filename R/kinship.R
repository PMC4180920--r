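# Relationship matrices: the pedigree numerator relationship matrix A and
# three genomic relationship matrices (VanRaden method 1, fraction of shared
# SNP alleles, and excess of identical homozygotes over Hardy-Weinberg
# expectation).

.relmat <- function(M, ids, kind, ...) {
  dimnames(M) <- list(ids, ids)
  attr(M, "kind") <- kind
  extra <- list(...)
  for (nm in names(extra)) attr(M, nm) <- extra[[nm]]
  class(M) <- c("relmat", class(M))
  M
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d individuals\n", attr(x, "kind"),
              nrow(x)))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x)), mean(x[upper.tri(x)])))
  invisible(x)
}

#' Keep ancestors of a set of individuals, optionally depth-limited
#'
#' Utility for building A on the relevant part of a deep pedigree: retains the
#' requested ids plus their ancestors up to `max_generations` parent steps
#' (unlimited by default), in parents-before-offspring order.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (NA = unknown).
#' @param ids Ids whose ancestry to keep.
#' @param max_generations Maximum number of parent generations to climb.
#' @return The pruned pedigree data frame.
#' @export
prune_pedigree <- function(ped, ids, max_generations = Inf) {
  keep <- unique(ids)
  frontier <- keep
  g <- 0
  while (length(frontier) > 0 && g < max_generations) {
    rows <- ped[ped$id %in% frontier, , drop = FALSE]
    parents <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), keep)
    keep <- c(keep, parents)
    frontier <- parents
    g <- g + 1
  }
  sub <- ped[ped$id %in% keep, , drop = FALSE]
  # unknown-ify parents that fell outside the pruned set
  sub$sire[!(sub$sire %in% sub$id)] <- NA
  sub$dam[!(sub$dam %in% sub$id)] <- NA
  sub[order(match(sub$id, ped$id)), , drop = FALSE]
}

#' Numerator relationship matrix from a pedigree
#'
#' Recursive tabular method: founders are taken as unrelated and non-inbred;
#' for individual i with parents s and d, `A[j, i] = (A[j, s] + A[j, d]) / 2`
#' for previous individuals j and `A[i, i] = 1 + A[s, d] / 2`.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (NA = unknown
#'   parent), sorted parents before offspring (checked; a topological sort is
#'   attempted when the check fails).
#' @param ids Optional subset of ids for the returned matrix (ancestors are
#'   still used internally).
#' @return A `relmat` of kind `"pedigree_A"`.
#' @export
build_A <- function(ped, ids = NULL) {
  stopifnot(all(c("id", "sire", "dam") %in% colnames(ped)))
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(!is.na(ped$sire) & is.na(si)) || any(!is.na(ped$dam) & is.na(di)))
    stop("parent not present in pedigree; prune_pedigree() first")
  bad <- which(si >= seq_len(n) | di >= seq_len(n))
  if (length(bad) > 0) {
    ord <- .topo_order(si, di, n)
    ped <- ped[ord, , drop = FALSE]
    si <- match(ped$sire, ped$id)
    di <- match(ped$dam, ped$id)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(s)) rel <- rel + 0.5 * A[j, s]
      if (!is.na(d)) rel <- rel + 0.5 * A[j, d]
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  out <- .relmat(A, ped$id, "pedigree_A")
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped$id)
    if (length(miss) > 0) stop("ids not in pedigree: ", paste(miss, collapse = ", "))
    out <- out[ids, ids]
    out <- .relmat(unclass(out), ids, "pedigree_A")
  }
  out
}

# Kahn topological sort; errors on cyclic pedigrees.
.topo_order <- function(si, di, n) {
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n) stop("cyclic pedigree")
  ord
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' `G = M M' / (2 * sum(p_i * (1 - p_i)))` where column i of `M` is the
#' genotype column centred by twice the allele frequency `p_i`. Frequencies
#' default to those of the supplied (combined multi-line) data; the matrix is
#' intended to be built once on all lines and reused across training sets.
#'
#' @param geno Individuals x SNPs numeric matrix, no missing values.
#' @param freq Allele frequencies per SNP, strictly inside (0, 1).
#' @return A `relmat` of kind `"G_vanraden"`.
#' @export
build_G_vanraden <- function(geno, freq = NULL) {
  if (anyNA(geno)) stop("missing genotypes present; impute first")
  if (is.null(freq)) freq <- colMeans(geno) / 2
  if (length(freq) != ncol(geno)) stop("one frequency per SNP required")
  if (any(freq <= 0 | freq >= 1))
    stop("allele frequency of exactly 0 or 1 among included SNPs")
  M <- sweep(geno, 2, 2 * freq)
  G <- tcrossprod(M) / (2 * sum(freq * (1 - freq)))
  .relmat(G, rownames(geno), "G_vanraden")
}

#' Genomic relationship as the fraction of identical SNP alleles
#'
#' Per SNP, a pair scores 1 when both individuals are identical homozygotes,
#' 0 when they are opposite homozygotes, and 0.5 otherwise (any genotype pair
#' involving a heterozygote); the relationship is the mean score over SNPs.
#'
#' @param geno Individuals x SNPs matrix with integer codes 0/1/2, no missing
#'   values (mean-imputed values must be rounded back to integers first).
#' @return A `relmat` of kind `"G_identity_fraction"` with entries in [0, 1].
#' @export
build_G_identity_fraction <- function(geno) {
  if (anyNA(geno)) stop("missing genotypes present; impute first")
  if (!all(geno %in% c(0, 1, 2)))
    stop("integer genotype codes 0/1/2 required (round imputed values)")
  p <- ncol(geno)
  H0 <- (geno == 0) + 0
  H2 <- (geno == 2) + 0
  ident <- tcrossprod(H0) + tcrossprod(H2)
  opp <- tcrossprod(H0, H2)
  opp <- opp + t(opp)
  G <- (ident + 0.5 * (p - ident - opp)) / p
  .relmat(G, rownames(geno), "G_identity_fraction")
}

#' Genomic relationship as excess of identical homozygotes
#'
#' `([O(H_identical) - O(H_opposite)] - E(H)) / (p - E(H))`, where the
#' observed counts are tallied over SNPs for each pair and `E(H)` is the
#' expected value of that difference under whole-population allele
#' frequencies. Two definitions of `E(H)` are available: `"pairwise"`
#' (default) takes the expectation for two independent Hardy-Weinberg
#' individuals, `sum(p^4 + q^4 - 2 p^2 q^2)`; `"individual"` uses the simpler
#' expected homozygosity of a single individual, `sum(1 - 2 p q)`. The choice
#' is recorded in the matrix metadata.
#'
#' @param geno Individuals x SNPs matrix with integer codes 0/1/2, no missing.
#' @param freq Allele frequencies per SNP (default: from `geno`).
#' @param eh_method `"pairwise"` or `"individual"`.
#' @return A `relmat` of kind `"G_excess_hom"`.
#' @export
build_G_excess_hom <- function(geno, freq = NULL,
                               eh_method = c("pairwise", "individual")) {
  eh_method <- match.arg(eh_method)
  if (anyNA(geno)) stop("missing genotypes present; impute first")
  if (!all(geno %in% c(0, 1, 2)))
    stop("integer genotype codes 0/1/2 required (round imputed values)")
  if (is.null(freq)) freq <- colMeans(geno) / 2
  p <- ncol(geno)
  q <- 1 - freq
  EH <- if (eh_method == "pairwise")
    sum(freq^4 + q^4 - 2 * freq^2 * q^2) else sum(1 - 2 * freq * q)
  if (EH >= p) stop("expected homozygosity equals the SNP count (all fixed)")
  H0 <- (geno == 0) + 0
  H2 <- (geno == 2) + 0
  O_id <- tcrossprod(H0) + tcrossprod(H2)
  O_op <- tcrossprod(H0, H2)
  O_op <- O_op + t(O_op)
  G <- (O_id - O_op - EH) / (p - EH)
  .relmat(G, rownames(geno), "G_excess_hom", eh_method = eh_method)
}

#' Add a ridge to a relationship matrix diagonal
#'
#' Small diagonal inflation used when a solver needs strict positive
#' definiteness; the amount used is recorded in the matrix metadata.
#'
#' @param K A relationship matrix.
#' @param ridge Value added to the diagonal (default 1e-6).
#' @return The inflated matrix.
#' @export
add_ridge <- function(K, ridge = 1e-6) {
  K2 <- K + diag(ridge, nrow(K))
  attributes(K2) <- attributes(K)
  attr(K2, "ridge") <- ridge
  K2
}
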