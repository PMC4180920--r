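# Centring/scaling, ridge regression, the animal-model solver, PCA and the
# RRBLUP / GBLUP / RRPCA equivalences.

test_that("center_scale produces unit-variance columns and reusable constants", {
  set.seed(61)
  X <- hwe_genotypes(80, runif(50, 0.1, 0.5))
  sc <- center_scale(X)
  expect_lt(max(abs(colMeans(sc$Z))), 1e-10)
  expect_lt(max(abs(apply(sc$Z, 2, var) - 1)), 1e-10)
  # training constants are re-applied verbatim to new data
  Xv <- hwe_genotypes(20, runif(50, 0.1, 0.5))
  Zv <- apply_scaling(Xv, sc)
  expect_equal(Zv, sweep(sweep(Xv, 2, sc$center), 2, sc$scale, "/"))
  expect_false(isTRUE(all.equal(colMeans(Zv), rep(0, 50))))
  # monomorphic column is rejected
  X2 <- cbind(X, mono = rep(1L, 80))
  expect_error(center_scale(X2), "zero-variance")
})

test_that("ridge_solve matches OLS at alpha 0 and a hand-solved 2x2 system", {
  Z <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  y <- c(1, 2, 3)
  # alpha = 0 equals ordinary least squares
  w0 <- ridge_solve(Z, y, 0)
  expect_equal(w0$weights, unname(coef(lm(I(y - mean(y)) ~ Z - 1))),
               tolerance = 1e-10)
  # hand inversion of (Z'Z + I): Z'Z = [[2,1],[1,2]], rhs = (0, 1)
  w1 <- ridge_solve(Z, y, 1)
  expect_equal(w1$weights, c(-1 / 8, 3 / 8), tolerance = 1e-12)
  expect_equal(w1$intercept, 2)
  # huge alpha shrinks the solution away
  wbig <- ridge_solve(Z, y, 1e12)
  expect_lt(sqrt(sum(wbig$weights^2)),
            1e-6 * sqrt(sum(w1$weights^2)))
  # shrinkage monotonicity of the norm
  norms <- vapply(c(0, 0.5, 2, 10, 100),
                  function(a) sqrt(sum(ridge_solve(Z, y, a)$weights^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  # primal and dual paths agree when p > n
  set.seed(62)
  Zp <- matrix(rnorm(5 * 9), 5, 9)
  yp <- rnorm(5)
  wd <- ridge_solve(Zp, yp, 3)$weights           # dual branch
  C <- crossprod(Zp) + diag(3, 9)
  wp <- solve(C, crossprod(Zp, yp - mean(yp)))
  expect_equal(wd, as.numeric(wp), tolerance = 1e-8)
  expect_error(ridge_solve(Zp, yp, 0), "singular")
})

test_that("the animal-model solver reduces to the closed form for K = I", {
  set.seed(63)
  y <- setNames(rnorm(30), paste0("t", 1:30))
  ids <- c(names(y), paste0("v", 1:5))
  K <- diag(35); dimnames(K) <- list(ids, ids)
  vc <- variance_components(2, 3)
  sol <- solve_mixed_model(K, y, vc)
  expect_equal(sol$mu, mean(y), tolerance = 1e-10)
  expect_equal(sol$ebv[names(y)], vc$h2 * (y - mean(y)), tolerance = 1e-10)
  expect_equal(unname(sol$ebv[paste0("v", 1:5)]), rep(0, 5))
  # infinite shrinkage: lambda -> Inf sends every EBV to zero
  vc2 <- variance_components(1e-10, 1)
  sol2 <- solve_mixed_model(K, y, vc2)
  expect_lt(max(abs(sol2$ebv)), 1e-9)
})

test_that("GBLUP with K = ZZ'/p reproduces RRBLUP validation EBV", {
  set.seed(64)
  n_tr <- 120L; n_va <- 40L; p <- 400L
  geno <- hwe_genotypes(n_tr + n_va, runif(p, 0.1, 0.5))
  tr <- rownames(geno)[1:n_tr]; va <- rownames(geno)[-(1:n_tr)]
  trait <- polygenic_trait(geno, 80L, 0.4, seed = 64)
  y <- trait$y[tr]
  sc <- center_scale(geno[tr, ])
  Zt <- sc$Z; Zv <- apply_scaling(geno[va, ], sc)
  vc <- variance_components(trait$sigma_a2, trait$sigma_e2, p)
  # RRBLUP route
  eff <- ridge_solve(Zt, y, vc$alpha, scaling = sc)
  ebv_rr <- predict_validation(eff, geno[va, ])
  # GBLUP route with the matched kinship and per-SNP variance
  Zall <- rbind(Zt, Zv)
  K <- tcrossprod(Zall) / p
  dimnames(K) <- list(rownames(Zall), rownames(Zall))
  vk <- variance_components(vc$sigma_a2, vc$sigma_e2)
  sol <- solve_mixed_model(K, y, vk)
  ebv_gb <- sol$ebv[va] + sol$mu
  expect_lt(max(abs(ebv_gb - ebv_rr)) / max(abs(ebv_rr)), 1e-8)
  # predict_validation agrees with direct multiplication and duplicates
  dupe <- geno[c(va[1], va[1]), ]
  pr <- predict_validation(eff, dupe)
  expect_equal(pr[1], pr[2])
  eff0 <- eff; eff0$weights <- rep(0, p)
  expect_equal(unname(predict_validation(eff0, geno[va, ])),
               rep(eff$intercept, n_va))
})

test_that("predictions are invariant to SNP column permutation", {
  set.seed(65)
  geno <- hwe_genotypes(100, runif(150, 0.1, 0.5))
  trait <- polygenic_trait(geno, 40L, 0.4, seed = 65)
  tr <- rownames(geno)[1:70]; va <- rownames(geno)[71:100]
  vc <- variance_components(trait$sigma_a2, trait$sigma_e2, 150)
  fit1 <- gp_fit(trait$y[tr], vc, method = "rrblup", geno = geno,
                 validation_ids = va)
  perm <- sample(150)
  fit2 <- gp_fit(trait$y[tr], vc, method = "rrblup", geno = geno[, perm],
                 validation_ids = va)
  expect_equal(fit1$ebv, fit2$ebv, tolerance = 1e-8)
})

test_that("pca_fit recovers a known eigenstructure and honours the threshold", {
  # rank-2 toy with singular values 2 and 1: eigenvalues 4 and 1
  Z <- diag(c(2, 1, 0))
  pc <- pca_fit(Z, threshold = 0.97)
  expect_equal(pc$rank, 2)
  expect_equal(pc$eigenvalues, c(4, 1))
  expect_equal(pc$cum_fraction, c(0.8, 1))
  expect_equal(pc$d, 2)                      # 0.8 < 0.97 at d = 1
  expect_equal(abs(pc$rotation[, 1]), c(1, 0, 0))
  # threshold 1 keeps the full rank; eigenvalues are nonincreasing
  set.seed(66)
  Zr <- scale(matrix(rnorm(30 * 12), 30, 12), scale = FALSE)
  pr <- pca_fit(Zr, threshold = 1)
  expect_equal(pr$d, pr$rank)
  expect_true(all(diff(pr$eigenvalues) <= 1e-10))
  expect_true(all(diff(pr$cum_fraction) >= -1e-12))
  d97 <- pca_fit(Zr, threshold = 0.97)$d
  expect_gte(pr$cum_fraction[d97], 0.97)
  if (d97 > 1) expect_lt(pr$cum_fraction[d97 - 1], 0.97)
  expect_error(pca_fit(Zr, threshold = 1.2), "threshold")
})

test_that("RRPCA equals RRBLUP at full rank and tracks PC1 at d = 1", {
  set.seed(67)
  geno <- hwe_genotypes(90, runif(200, 0.1, 0.5))
  trait <- polygenic_trait(geno, 50L, 0.4, seed = 67)
  tr <- rownames(geno)[1:60]; va <- rownames(geno)[61:90]
  sc <- center_scale(geno[tr, ])
  Zt <- sc$Z; Zv <- apply_scaling(geno[va, ], sc)
  vc <- variance_components(trait$sigma_a2, trait$sigma_e2, 200)
  pc <- pca_fit(Zt, threshold = 1)
  full <- rrpca_solve(pc, Zt, trait$y[tr], Zv, alpha = vc$alpha, d = pc$rank)
  eff <- ridge_solve(Zt, trait$y[tr], vc$alpha)
  ebv_rr <- as.numeric(Zv %*% eff$weights) + eff$intercept
  expect_lt(max(abs(full$ebv_val - ebv_rr)) / max(abs(ebv_rr)), 1e-8)
  # d = 1: predictions perfectly correlated with the first PC score
  one <- rrpca_solve(pc, Zt, trait$y[tr], Zv, alpha = vc$alpha, d = 1)
  s1 <- as.numeric(Zv %*% pc$rotation[, 1])
  expect_equal(abs(cor(one$ebv_val, s1)), 1, tolerance = 1e-10)
})

test_that("the PC sweep is deterministic, spans to RRBLUP, and widens with lines", {
  cfg <- tiny_config(seed = 68L, n_train = 120L, n_val = 40L, n_snps = 400L,
                     n_qtl = 80L)
  sim <- simulate_multiline(cfg)
  data <- prepare_analysis(sim, matrices = character(0))
  scens <- build_training_sets(data, target_lines = "A")
  own <- Filter(function(s) s$own_line, scens)[[1]]
  both <- Filter(function(s) s$name == "A+B", scens)[[1]]
  ph <- data$phenotypes
  y <- setNames(ph$y_corrected[match(own$train_ids, ph$id)], own$train_ids)
  yv <- ph$y_corrected[match(own$validation_ids, ph$id)]
  X <- data$genotypes[, own$snp_subset, drop = FALSE]
  sc <- center_scale(X[own$train_ids, ])
  Zt <- sc$Z
  Zv <- apply_scaling(X[own$validation_ids, ], sc)
  pc_own <- pca_fit(Zt)
  vc <- own$vc
  sw <- pc_sweep(pc_own, Zt, y, Zv, yv, own$h2_target, vc$alpha,
                 d_grid = c(1, 5, 20, pc_own$rank))
  sw2 <- pc_sweep(pc_own, Zt, y, Zv, yv, own$h2_target, vc$alpha,
                  d_grid = c(1, 5, 20, pc_own$rank))
  expect_identical(sw, sw2)                          # no randomness
  # endpoint at full rank reproduces the RRBLUP accuracy
  eff <- ridge_solve(Zt, y, vc$alpha)
  acc_rr <- accuracy(as.numeric(Zv %*% eff$weights), yv, own$h2_target)
  expect_equal(sw$accuracy[4], acc_rr$accuracy, tolerance = 1e-8)
  # PCA reference with both lines reaches larger d than the one-line PCA
  Xb <- data$genotypes[, both$snp_subset, drop = FALSE]
  scb <- center_scale(Xb[both$train_ids, ])
  pc_all <- pca_fit(scb$Z)
  expect_gt(pc_all$rank, pc_own$rank)
  expect_error(pc_sweep(pc_own, Zt, y, Zv, yv, own$h2_target, vc$alpha,
                        d_grid = pc_own$rank + 1), "exceeds")
})

test_that("variance-component bookkeeping matches its definitions", {
  vc <- variance_components(2, 6, n_snps = 100)
  expect_equal(vc$h2, 0.25)
  expect_equal(vc$sigma_w2, 0.02)
  expect_equal(vc$alpha, 300)
  expect_equal(vc$lambda, 3)
  expect_error(variance_components(-1, 1), "non-negative")
})
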