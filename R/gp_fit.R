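# Unified fitting front-end: one function, one classed result, the usual
# print / summary / coef / predict / fitted / residuals methods. Dispatches
# to the pedigree/genomic mixed-model solver, marker ridge regression, PC
# ridge regression, or the Gibbs samplers.

#' Fit a genomic (or pedigree) prediction model
#'
#' Single entry point for the prediction models compared in this package:
#'
#' * `"blup"` — animal model with a pedigree numerator relationship matrix
#'   (supply `kinship` built by [build_A()]).
#' * `"gblup"` — animal model with a genomic relationship matrix (supply
#'   `kinship` from one of the G builders).
#' * `"rrblup"` — ridge regression on centred/scaled SNP genotypes with
#'   `alpha = sigma_e2 / sigma_w2`.
#' * `"rrpca"` — ridge regression on the leading principal components of the
#'   genotypes.
#' * `"bayesc"`, `"bssvs"` — Gibbs-sampling variable-selection models.
#'
#' For the marker-based methods, genotypes are centred and scaled to unit
#' variance using constants estimated on the training rows and re-applied to
#' the validation rows. For the kinship methods, `kinship` must cover training
#' and validation individuals; validation phenotypes are treated as missing
#' and their breeding values obtained jointly.
#'
#' @param y Named numeric vector of training phenotypes (pre-corrected);
#'   names are individual ids.
#' @param vc A [variance_components()] object; `n_snps` is filled in from the
#'   design when missing.
#' @param method One of `"blup"`, `"gblup"`, `"rrblup"`, `"rrpca"`,
#'   `"bayesc"`, `"bssvs"`.
#' @param geno Individuals x SNPs matrix (0/1/2, complete) covering at least
#'   the training ids; required for marker-based methods.
#' @param validation_ids Ids to predict. For kinship methods they must appear
#'   in `kinship`; for marker methods in `geno`.
#' @param kinship Relationship matrix (kinship methods only).
#' @param pca Optional precomputed [pca_fit()] for `"rrpca"`; by default the
#'   PCA is fitted on the training design. `n_pc` overrides its dimension.
#' @param n_pc Number of components for `"rrpca"` (default: the PCA's
#'   97%-variance dimension).
#' @param alpha Ridge coefficient override (default `vc$alpha`).
#' @param gibbs A [gibbs_config()] for the Bayesian methods.
#' @return An object of class `gp_fit` with elements `method`, `ebv`
#'   (named vector for training + validation individuals), `mu`, `vc`,
#'   `effects` (marker methods), `posterior` (Bayesian methods), `pca`
#'   (`"rrpca"`), `train_ids`, `validation_ids`.
#' @export
gp_fit <- function(y, vc,
                   method = c("rrblup", "gblup", "blup", "rrpca", "bayesc",
                              "bssvs"),
                   geno = NULL, validation_ids = NULL, kinship = NULL,
                   pca = NULL, n_pc = NULL, alpha = NULL,
                   gibbs = gibbs_config()) {
  method <- match.arg(method)
  stopifnot(inherits(vc, "variance_components"))
  if (is.null(names(y))) stop("y must be named by individual id")
  train_ids <- names(y)
  validation_ids <- validation_ids %||% character(0)

  if (method %in% c("blup", "gblup")) {
    if (is.null(kinship)) stop(method, " requires a kinship matrix")
    need <- c(train_ids, validation_ids)
    miss <- setdiff(need, rownames(kinship))
    if (length(miss) > 0) stop("ids missing from kinship: ",
                               paste(utils::head(miss, 5), collapse = ", "))
    K <- kinship[need, need, drop = FALSE]
    sol <- solve_mixed_model(K, y, vc)
    out <- list(method = method, ebv = sol$ebv, mu = sol$mu, vc = vc,
                effects = NULL, posterior = NULL, pca = NULL,
                kinship_kind = attr(kinship, "kind"))
  } else {
    if (is.null(geno)) stop(method, " requires a genotype matrix")
    miss <- setdiff(c(train_ids, validation_ids), rownames(geno))
    if (length(miss) > 0) stop("ids missing from geno: ",
                               paste(utils::head(miss, 5), collapse = ", "))
    Xt <- geno[train_ids, , drop = FALSE]
    sc <- center_scale(Xt)
    Zt <- sc$Z
    Zv <- if (length(validation_ids) > 0)
      apply_scaling(geno[validation_ids, , drop = FALSE], sc) else NULL
    if (is.na(vc$sigma_w2))
      vc <- variance_components(vc$sigma_a2, vc$sigma_e2, ncol(Zt))
    a <- alpha %||% vc$alpha
    if (method == "rrblup") {
      eff <- ridge_solve(Zt, y, a, scaling = sc)
      ebv_t <- as.numeric(Zt %*% eff$weights) + eff$intercept
      ebv_v <- if (!is.null(Zv))
        as.numeric(Zv %*% eff$weights) + eff$intercept else numeric(0)
      out <- list(method = method,
                  ebv = stats::setNames(c(ebv_t, ebv_v),
                                        c(train_ids, validation_ids)),
                  mu = eff$intercept, vc = vc, effects = eff,
                  posterior = NULL, pca = NULL)
    } else if (method == "rrpca") {
      pc <- pca %||% pca_fit(Zt)
      d <- n_pc %||% pc$d
      fit <- rrpca_solve(pc, Zt, y, Zv, alpha = a, d = d)
      out <- list(method = method,
                  ebv = stats::setNames(c(fit$ebv_train, fit$ebv_val %||% numeric(0)),
                                        c(train_ids, validation_ids)),
                  mu = fit$intercept, vc = vc, effects = NULL,
                  posterior = NULL, pca = pc, d = fit$d)
    } else {
      chain <- if (method == "bayesc") gibbs_bayesc(Zt, y, gibbs, vc)
               else gibbs_bssvs(Zt, y, gibbs, vc)
      post <- posterior_summaries(chain)
      mu <- unname(post$mu["mean"])
      ebv_t <- as.numeric(Zt %*% post$effects) + mu
      ebv_v <- if (!is.null(Zv))
        as.numeric(Zv %*% post$effects) + mu else numeric(0)
      eff <- structure(list(weights = unname(post$effects), intercept = mu,
                            alpha = NA_real_, snp_ids = colnames(Zt),
                            scaling = sc),
                       class = "marker_effects")
      out <- list(method = method,
                  ebv = stats::setNames(c(ebv_t, ebv_v),
                                        c(train_ids, validation_ids)),
                  mu = mu, vc = vc, effects = eff, posterior = post,
                  pca = NULL, chain = chain)
    }
  }
  out$y <- y
  out$train_ids <- train_ids
  out$validation_ids <- validation_ids
  class(out) <- "gp_fit"
  out
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit: %s, %d training / %d validation individuals\n",
              x$method, length(x$train_ids), length(x$validation_ids)))
  cat(sprintf("  mu = %.4g, h2 = %.3f, sd(EBV) = %.4g\n", x$mu, x$vc$h2,
              stats::sd(x$ebv)))
  invisible(x)
}

#' @export
summary.gp_fit <- function(object, pheno = NULL, h2 = object$vc$h2, ...) {
  res <- list(method = object$method, n_train = length(object$train_ids),
              n_val = length(object$validation_ids), mu = object$mu,
              vc = object$vc)
  if (!is.null(pheno) && length(object$validation_ids) > 0) {
    ebv_v <- object$ebv[object$validation_ids]
    ph <- if (!is.null(names(pheno))) pheno[object$validation_ids] else pheno
    res$accuracy <- accuracy(ebv_v, ph, h2)
    res$bias <- bias_regression(ph, ebv_v, n_boot = 1000L, seed = 1L)
  }
  class(res) <- "summary.gp_fit"
  res
}

#' @export
print.summary.gp_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d training, %d validation individuals, mu = %.4g\n",
              x$method, x$n_train, x$n_val, x$mu))
  print(x$vc)
  if (!is.null(x$accuracy)) print(x$accuracy)
  if (!is.null(x$bias)) print(x$bias)
  invisible(x)
}

#' @export
coef.gp_fit <- function(object, ...) {
  if (is.null(object$effects)) return(NULL)
  stats::setNames(object$effects$weights,
                  object$effects$snp_ids %||%
                    seq_along(object$effects$weights))
}

#' Predict breeding values for new genotyped individuals
#'
#' Marker-based fits predict from new genotypes on the training SNP panel;
#' kinship-based fits return the jointly estimated breeding values for the
#' requested ids.
#'
#' @param object A `gp_fit`.
#' @param newdata Genotype matrix (marker methods) or character ids already
#'   covered by the fit (kinship methods). `NULL` returns validation EBV.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.gp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (length(object$validation_ids) == 0) return(object$ebv)
    return(object$ebv[object$validation_ids])
  }
  if (is.character(newdata)) {
    miss <- setdiff(newdata, names(object$ebv))
    if (length(miss) > 0) stop("ids not covered by the fit: ",
                               paste(utils::head(miss, 5), collapse = ", "))
    return(object$ebv[newdata])
  }
  if (object$method == "rrpca") {
    sc <- attr(object$pca, "scaling")
    stop("predict with a genotype matrix is not supported for rrpca fits; ",
         "pass validation_ids to gp_fit()")
  }
  if (is.null(object$effects))
    stop("kinship-based fits predict by id; pass a character vector")
  predict_validation(object$effects, newdata)
}

#' @export
fitted.gp_fit <- function(object, ...) object$ebv[object$train_ids]

#' @export
residuals.gp_fit <- function(object, ...) {
  object$y - object$mu - object$ebv[object$train_ids]
}
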