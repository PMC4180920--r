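# Gibbs-sampling variable-selection models: BayesC (spike at zero) and BSSVS
# (small-variance component instead of a spike). The single-site samplers are
# implemented in compiled code (src/gibbs.cpp); these wrappers handle
# configuration, seeding and posterior summaries.

#' Configuration for the Gibbs samplers
#'
#' @param n_iter Total chain length (default 10 000).
#' @param burn_in Iterations discarded before summarising (default 2 000).
#' @param thin Keep every `thin`-th post-burn-in iteration (default 10).
#' @param pi Prior fraction of SNPs without a large effect; defaults to 0.9
#'   for BayesC and 0.999 for BSSVS when left `NULL`.
#' @param c Ratio of the large to the small effect variance (BSSVS only,
#'   must exceed 1; default 100).
#' @param nu Prior degrees of freedom of the scaled-inverse-chi-square
#'   variance priors (default 4.2, weakly informative).
#' @param seed Optional integer seed applied before the chain starts.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(n_iter = 10000L, burn_in = 2000L, thin = 10L,
                         pi = NULL, c = 100, nu = 4.2, seed = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be at least 1")
  if (!is.null(pi) && (pi < 0 || pi >= 1)) stop("pi must lie in [0, 1)")
  if (c <= 1) stop("c must exceed 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), pi = pi, c = c, nu = nu,
                 seed = seed),
            class = "gibbs_config")
}

.gibbs_run <- function(Z, y, cfg, vc, mode, default_pi) {
  stopifnot(inherits(cfg, "gibbs_config"), inherits(vc, "variance_components"))
  pi <- cfg$pi %||% default_pi
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  s2w0 <- if (!is.na(vc$sigma_w2)) vc$sigma_w2 else vc$sigma_a2 / ncol(Z)
  res <- .gibbs_mixture_cpp(Z, y, cfg$n_iter, cfg$burn_in, cfg$thin, pi,
                            cfg$c, mode, cfg$nu, s2w0, cfg$nu, vc$sigma_e2)
  structure(list(chain = res,
                 model = if (mode == 0) "bayesc" else "bssvs",
                 pi = pi, c = if (mode == 1) cfg$c else NA_real_,
                 config = cfg, snp_ids = colnames(Z)),
            class = "gibbs_chain")
}

#' BayesC Gibbs sampler
#'
#' Two-component mixture per SNP: with prior probability `pi` the effect is
#' exactly zero in an iteration of the chain; otherwise it is normal with the
#' common variance `sigma_w2`, whose prior scale is initialised as the total
#' genetic variance divided by the number of SNPs. Genotypes are expected
#' centred and scaled.
#'
#' @param Z Centred/scaled training design matrix.
#' @param y Training phenotypes.
#' @param cfg A [gibbs_config()] (default `pi` = 0.9 for BayesC).
#' @param vc A [variance_components()] object supplying the prior scales.
#' @return A `gibbs_chain` object; summarise with [posterior_summaries()].
#' @export
gibbs_bayesc <- function(Z, y, cfg = gibbs_config(), vc) {
  .gibbs_run(Z, y, cfg, vc, mode = 0L, default_pi = 0.9)
}

#' BSSVS Gibbs sampler
#'
#' Stochastic search variable selection: every SNP always contributes, with
#' its effect drawn from a large-variance normal (`sigma_w2`, prior mass
#' `1 - pi`) or a small-variance normal (`sigma_w2 / c`, prior mass `pi`).
#'
#' @inheritParams gibbs_bayesc
#' @param cfg A [gibbs_config()] (default `pi` = 0.999 and `c` = 100).
#' @return A `gibbs_chain` object.
#' @export
gibbs_bssvs <- function(Z, y, cfg = gibbs_config(), vc) {
  .gibbs_run(Z, y, cfg, vc, mode = 1L, default_pi = 0.999)
}

#' @export
print.gibbs_chain <- function(x, ...) {
  cat(sprintf("%s chain: %d kept samples (%d iterations, burn-in %d, thin %d), pi = %g\n",
              toupper(x$model), x$chain$n_kept, x$config$n_iter,
              x$config$burn_in, x$config$thin, x$pi))
  invisible(x)
}

# effective sample size from the initial positive sequence of autocorrelations
.ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Posterior summaries of a Gibbs chain
#'
#' Means over the kept (post-burn-in, thinned) iterations: posterior-mean
#' marker effects, per-SNP inclusion probability (fraction of kept iterations
#' in the large-effect state), posterior means and SDs of the variance
#' components and the mean, plus an effective-sample-size diagnostic for the
#' residual variance (flagged degenerate for constant chains).
#'
#' @param fit A `gibbs_chain` from [gibbs_bayesc()] or [gibbs_bssvs()].
#' @return An object of class `posterior_summary` with elements `effects`,
#'   `inclusion_prob`, `mu`, `sigma_e2`, `sigma_w2` (each a `mean`/`sd` pair
#'   for the scalars), `ess_sigma_e2`, `n_kept`, `model`, `pi`.
#' @export
posterior_summaries <- function(fit) {
  stopifnot(inherits(fit, "gibbs_chain"))
  ch <- fit$chain
  if (ch$n_kept < 1) stop("no kept iterations")
  eff <- colMeans(ch$w)
  names(eff) <- fit$snp_ids
  incl <- colMeans(ch$delta)
  names(incl) <- fit$snp_ids
  structure(list(effects = eff, inclusion_prob = incl,
                 mu = c(mean = mean(ch$mu), sd = stats::sd(ch$mu)),
                 sigma_e2 = c(mean = mean(ch$sigma_e2),
                              sd = stats::sd(ch$sigma_e2)),
                 sigma_w2 = c(mean = mean(ch$sigma_w2),
                              sd = stats::sd(ch$sigma_w2)),
                 ess_sigma_e2 = .ess(ch$sigma_e2),
                 n_kept = ch$n_kept, model = fit$model, pi = fit$pi),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s posterior (%d kept samples, pi = %g)\n", toupper(x$model),
              x$n_kept, x$pi))
  cat(sprintf("  sigma_e2 %.4g (sd %.3g, ESS %.0f), sigma_w2 %.4g (sd %.3g)\n",
              x$sigma_e2["mean"], x$sigma_e2["sd"],
              if (is.na(x$ess_sigma_e2)) 0 else x$ess_sigma_e2,
              x$sigma_w2["mean"], x$sigma_w2["sd"]))
  cat(sprintf("  max |posterior mean effect| %.4g, max inclusion %.3f\n",
              max(abs(x$effects)), max(x$inclusion_prob)))
  invisible(x)
}
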