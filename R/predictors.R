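# Frequentist predictors: centring/scaling of genotype designs, ridge
# regression on markers (RRBLUP), the animal-model mixed-model solver used
# for pedigree BLUP and GBLUP, and principal-component ridge regression
# (RRPCA) with its PC sweep.

#' Variance components for the prediction models
#'
#' Holds the additive genetic variance, the residual variance, and the derived
#' quantities used by the predictors: heritability `h2 = sigma_a2 /
#' (sigma_a2 + sigma_e2)`, the per-SNP variance `sigma_w2 = sigma_a2 / n_snps`
#' (genotypes being centred and scaled to unit variance), and the ridge
#' coefficient `alpha = sigma_e2 / sigma_w2`.
#'
#' @param sigma_a2 Additive genetic variance (trait units squared).
#' @param sigma_e2 Residual variance (trait units squared).
#' @param n_snps Number of SNPs in the design (needed for `sigma_w2`/`alpha`).
#' @return A `variance_components` list.
#' @export
variance_components <- function(sigma_a2, sigma_e2, n_snps = NULL) {
  if (sigma_a2 < 0 || sigma_e2 < 0) stop("variances must be non-negative")
  if (sigma_a2 + sigma_e2 == 0) stop("total variance must be positive")
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)
  sw2 <- if (!is.null(n_snps)) sigma_a2 / n_snps else NA_real_
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2,
                 sigma_w2 = sw2,
                 alpha = if (!is.null(n_snps) && sw2 > 0) sigma_e2 / sw2
                         else NA_real_,
                 lambda = if (sigma_a2 > 0) sigma_e2 / sigma_a2 else Inf,
                 n_snps = n_snps),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma_a2=%.4g sigma_e2=%.4g h2=%.3f",
              x$sigma_a2, x$sigma_e2, x$h2))
  if (!is.na(x$sigma_w2))
    cat(sprintf(" sigma_w2=%.4g alpha=%.4g (p=%d)", x$sigma_w2, x$alpha,
                x$n_snps))
  cat("\n")
  invisible(x)
}

## ---- centring and scaling -------------------------------------------------

#' Centre and scale a genotype design matrix
#'
#' Each SNP column is centred by its mean and scaled to unit empirical
#' variance over the reference individuals. The constants are returned so the
#' identical transform (training constants, not validation moments) can be
#' re-applied to validation genotypes with [apply_scaling()].
#'
#' @param geno Individuals x SNPs numeric matrix (reference individuals).
#' @return List with `Z` (transformed matrix), `center`, `scale`.
#' @export
center_scale <- function(geno) {
  m <- colMeans(geno)
  v <- (colSums(geno^2) - nrow(geno) * m^2) / (nrow(geno) - 1)
  if (any(v <= 0))
    stop("zero-variance column(s): exclude monomorphic SNPs first (",
         paste(utils::head(which(v <= 0), 5), collapse = ", "), ")")
  s <- sqrt(v)
  Z <- sweep(sweep(geno, 2, m), 2, s, "/")
  list(Z = Z, center = m, scale = s)
}

#' Apply stored centring/scaling constants to new genotypes
#'
#' @param geno Individuals x SNPs matrix on the same SNP panel.
#' @param scaling Output of [center_scale()].
#' @return The transformed matrix.
#' @export
apply_scaling <- function(geno, scaling) {
  if (ncol(geno) != length(scaling$center)) stop("SNP panel mismatch")
  sweep(sweep(geno, 2, scaling$center), 2, scaling$scale, "/")
}

## ---- ridge regression (RRBLUP) --------------------------------------------

#' Ridge-regression solution for marker effects
#'
#' Minimizes `||y - Z w||^2 + alpha ||w||^2` after removing the phenotype
#' mean; the mean is restored at prediction. For `alpha = 0` this is ordinary
#' least squares and requires `Z'Z` to be invertible. When `p > n` and
#' `alpha > 0` the dual identity `w = Z'(Z Z' + alpha I)^{-1} y` is used.
#'
#' @param Z Training design matrix (usually centred/scaled genotypes).
#' @param y Training phenotypes.
#' @param alpha Non-negative ridge coefficient, `sigma_e2 / sigma_w2` for
#'   RRBLUP.
#' @param scaling Optional [center_scale()] constants stored with the result.
#' @return An object of class `marker_effects`: `weights`, `intercept`,
#'   `alpha`, and the scaling constants if given.
#' @export
ridge_solve <- function(Z, y, alpha, scaling = NULL) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (nrow(Z) != length(y)) stop("dimension mismatch between Z and y")
  mu <- mean(y)
  yc <- y - mu
  n <- nrow(Z); p <- ncol(Z)
  if (alpha == 0) {
    C <- crossprod(Z)
    w <- tryCatch(solve(C, crossprod(Z, yc)),
                  error = function(e) stop("singular system at alpha = 0"))
  } else if (p > n) {
    K <- tcrossprod(Z)
    diag(K) <- diag(K) + alpha
    w <- crossprod(Z, solve(K, yc))
  } else {
    C <- crossprod(Z)
    diag(C) <- diag(C) + alpha
    w <- solve(C, crossprod(Z, yc))
  }
  structure(list(weights = as.numeric(w), intercept = mu, alpha = alpha,
                 snp_ids = colnames(Z), scaling = scaling),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("marker effects: %d SNPs, alpha=%.4g, intercept=%.4g\n",
              length(x$weights), x$alpha, x$intercept))
  invisible(x)
}

#' Predict breeding values from marker effects
#'
#' Applies the stored training centring/scaling constants to the validation
#' genotypes and returns `Z_val w + intercept`.
#'
#' @param effects A `marker_effects` object carrying scaling constants.
#' @param geno Validation genotypes on the training SNP panel (raw 0/1/2
#'   codes if `effects` carries scaling; already-transformed otherwise).
#' @return Named numeric vector of predictions.
#' @export
predict_validation <- function(effects, geno) {
  stopifnot(inherits(effects, "marker_effects"))
  if (ncol(geno) != length(effects$weights)) stop("SNP panel mismatch")
  Z <- if (!is.null(effects$scaling)) apply_scaling(geno, effects$scaling)
       else geno
  ebv <- as.numeric(Z %*% effects$weights) + effects$intercept
  names(ebv) <- rownames(geno)
  ebv
}

## ---- animal-model mixed model (BLUP / GBLUP) ------------------------------

#' Solve the animal model for a given relationship matrix
#'
#' Fits `y = 1 mu + u + e`, `u ~ N(0, K sigma_a2)`, `e ~ N(0, I sigma_e2)`,
#' with the overall mean as the only fixed effect (phenotypes are assumed
#' pre-corrected for other fixed effects). The mean is the GLS estimate and
#' breeding values for all individuals covered by `K` (validation phenotypes
#' treated as missing) are obtained jointly:
#' `u = sigma_a2 K[., t] V^{-1} (y - mu)` with `V = sigma_a2 K[t, t] +
#' sigma_e2 I`.
#'
#' @param K Relationship matrix covering training and prediction individuals
#'   (rownames = ids).
#' @param y Named vector of training phenotypes (names must appear in `K`).
#' @param vc A [variance_components()] object.
#' @param ridge Diagonal inflation tried on `K[t, t]` when the plain Cholesky
#'   factorization fails.
#' @return List with `ebv` (named vector over all individuals in `K`), `mu`,
#'   the training ids, and `conditioning` (`"none"`, `"ridge"` or `"bent"`).
#' @details An indefinite similarity matrix (possible for the
#'   excess-homozygosity G, whose entries are shifted by a whole-population
#'   expectation) cannot serve as a covariance directly. If a small ridge
#'   does not restore positive definiteness, the training block is bent:
#'   eigenvalues below a small positive floor are raised to it, the standard
#'   conditioning treatment for estimated relationship matrices.
#' @export
solve_mixed_model <- function(K, y, vc, ridge = 1e-6) {
  stopifnot(inherits(vc, "variance_components"))
  ids <- rownames(K)
  if (is.null(ids)) stop("K must carry individual ids as dimnames")
  if (is.null(names(y))) stop("y must be named by individual id")
  if (!all(names(y) %in% ids)) stop("training ids missing from K")
  t_idx <- match(names(y), ids)
  Ktt <- K[t_idx, t_idx, drop = FALSE]
  conditioning <- "none"
  V <- vc$sigma_a2 * Ktt
  diag(V) <- diag(V) + vc$sigma_e2
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V2 <- V
    diag(V2) <- diag(V2) + vc$sigma_a2 * ridge
    ch <- tryCatch(chol(V2), error = function(e) NULL)
    conditioning <- "ridge"
  }
  if (is.null(ch)) {
    ev <- eigen(Ktt, symmetric = TRUE)
    floor_ev <- 1e-8 * max(abs(ev$values))
    lam <- pmax(ev$values, floor_ev)
    Ktt <- ev$vectors %*% (lam * t(ev$vectors))
    K[t_idx, t_idx] <- Ktt
    V <- vc$sigma_a2 * Ktt
    diag(V) <- diag(V) + vc$sigma_e2
    ch <- chol(V)
    conditioning <- "bent"
  }
  ones <- rep(1, length(y))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  mu <- sum(ones * Vi_y) / sum(ones * Vi_1)
  Vi_r <- Vi_y - mu * Vi_1
  ebv <- vc$sigma_a2 * as.numeric(K[, t_idx, drop = FALSE] %*% Vi_r)
  names(ebv) <- ids
  list(ebv = ebv, mu = mu, train_ids = names(y), conditioning = conditioning)
}

## ---- principal component regression ----------------------------------------

#' Principal components of a genotype design
#'
#' Singular value decomposition of the (already centred, possibly scaled)
#' reference design; the projection rows are the leading eigenvectors of the
#' genotype covariance. With a variance threshold `t`, the retained dimension
#' `d` is the smallest number of components whose cumulative eigenvalue
#' fraction reaches `t` (default 0.97).
#'
#' @param Z Reference design matrix (individuals x SNPs, centred).
#' @param d Number of components to retain; overrides `threshold`.
#' @param threshold Cumulative variance-explained cutoff in (0, 1].
#' @return An object of class `gp_pca`: `rotation` (SNPs x rank matrix of
#'   eigenvectors), `eigenvalues` (nonincreasing), `cum_fraction`, `d`, and
#'   `rank`.
#' @export
pca_fit <- function(Z, d = NULL, threshold = 0.97) {
  if (nrow(Z) == 0) stop("empty reference set")
  if (!is.null(threshold) && (threshold <= 0 || threshold > 1))
    stop("threshold must lie in (0, 1]")
  sv <- svd(Z, nu = 0)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  ev <- sv$d[seq_len(rank)]^2
  cf <- cumsum(ev) / sum(ev)
  if (is.null(d)) {
    d <- which(cf >= threshold)[1]
  } else {
    if (d < 1) stop("d must be at least 1")
    d <- min(d, rank)
  }
  structure(list(rotation = sv$v[, seq_len(rank), drop = FALSE],
                 eigenvalues = ev, cum_fraction = cf, d = d, rank = rank,
                 threshold = threshold),
            class = "gp_pca")
}

#' @export
print.gp_pca <- function(x, ...) {
  cat(sprintf("genotype PCA: rank %d, d = %d (cumulative fraction %.3f)\n",
              x$rank, x$d, x$cum_fraction[x$d]))
  invisible(x)
}

#' Ridge regression on principal component scores (RRPCA)
#'
#' Projects training and validation designs onto the leading `d` components
#' and applies [ridge_solve()] in the reduced space. At `d = rank` and equal
#' `alpha` the predictions coincide with RRBLUP (ridge is invariant to an
#' orthonormal basis of the design row space).
#'
#' @param pca A [pca_fit()] object.
#' @param Z_train Training design (same columns as the PCA reference).
#' @param y Training phenotypes.
#' @param Z_val Validation design, or `NULL`.
#' @param alpha Ridge coefficient on the scores.
#' @param d Number of components (default: the PCA's `d`).
#' @return List with `ebv_val`, `ebv_train`, `beta` (effects in PC space),
#'   `intercept`, `d`.
#' @export
rrpca_solve <- function(pca, Z_train, y, Z_val = NULL, alpha, d = pca$d) {
  stopifnot(inherits(pca, "gp_pca"))
  if (d < 1) stop("d must be at least 1")
  d <- min(d, pca$rank)
  V <- pca$rotation[, seq_len(d), drop = FALSE]
  S <- Z_train %*% V
  fit <- ridge_solve(S, y, alpha)
  ebv_train <- as.numeric(S %*% fit$weights) + fit$intercept
  names(ebv_train) <- rownames(Z_train)
  ebv_val <- NULL
  if (!is.null(Z_val)) {
    ebv_val <- as.numeric(Z_val %*% V %*% fit$weights) + fit$intercept
    names(ebv_val) <- rownames(Z_val)
  }
  list(ebv_val = ebv_val, ebv_train = ebv_train, beta = fit$weights,
       intercept = fit$intercept, d = d)
}

#' Prediction accuracy across the number of retained components
#'
#' Evaluates RRPCA over a grid of `d`, returning the validation accuracy for
#' each dimension. The grid must not exceed the PCA rank (the number of
#' components is always smaller than the number of reference individuals).
#'
#' @param pca A [pca_fit()] object (reference set chosen by the caller: the
#'   scenario's training lines or all lines).
#' @param Z_train,y Training design and phenotypes.
#' @param Z_val Validation design.
#' @param pheno_val Validation phenotypes (for accuracy).
#' @param h2 Heritability used in the accuracy denominator.
#' @param alpha Ridge coefficient.
#' @param d_grid Integer vector of dimensions to evaluate (default: a spread
#'   across `1..rank`).
#' @return Data frame of class `gp_pc_sweep` with columns `d` and `accuracy`.
#' @export
pc_sweep <- function(pca, Z_train, y, Z_val, pheno_val, h2, alpha,
                     d_grid = NULL) {
  stopifnot(inherits(pca, "gp_pca"))
  if (is.null(d_grid))
    d_grid <- unique(round(seq(1, pca$rank, length.out = min(40, pca$rank))))
  if (any(d_grid < 1) || any(d_grid > pca$rank))
    stop("d grid exceeds available components")
  S_tr <- Z_train %*% pca$rotation
  S_va <- Z_val %*% pca$rotation
  acc <- vapply(d_grid, function(d) {
    cols <- seq_len(d)
    fit <- ridge_solve(S_tr[, cols, drop = FALSE], y, alpha)
    ebv <- as.numeric(S_va[, cols, drop = FALSE] %*% fit$weights)
    accuracy(ebv, pheno_val, h2)$accuracy
  }, numeric(1))
  structure(data.frame(d = d_grid, accuracy = acc),
            class = c("gp_pc_sweep", "data.frame"))
}

#' Plot an accuracy-versus-components curve
#'
#' @param x A [pc_sweep()] result (or several rbind-ed together with a
#'   `curve` column).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gp_pc_sweep <- function(x, ...) {
  if (!is.null(x$curve)) {
    curves <- unique(x$curve)
    graphics::plot(range(x$d), range(x$accuracy), type = "n",
                   xlab = "number of principal components",
                   ylab = "prediction accuracy", ...)
    for (i in seq_along(curves)) {
      sub <- x[x$curve == curves[i], ]
      graphics::lines(sub$d, sub$accuracy, col = i, lwd = 2)
    }
    graphics::legend("bottomright", legend = curves, col = seq_along(curves),
                     lwd = 2, bty = "n", cex = 0.8)
  } else {
    graphics::plot(x$d, x$accuracy, type = "l", lwd = 2,
                   xlab = "number of principal components",
                   ylab = "prediction accuracy", ...)
  }
  invisible(x)
}
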