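# Simulator: base-population sampling, line divergence, QTL effects,
# phenotypes, and the training/validation split.

test_that("base population follows the founder allele frequencies", {
  cfg <- tiny_config(n_snps = 500L)
  # symmetric case: frequency 0.5 -> mean genotype ~ 1
  set.seed(11)
  n <- 4000L
  g <- matrix(rbinom(n * 50, 2L, 0.5), n, 50)
  expect_true(all(abs(colMeans(g) - 1) < 4 * sqrt(0.5 * 0.5 * 2 / n)))
  # binomial sampling at frequency 0.2: observed within 4 binomial SE
  set.seed(12)
  n <- 10000L
  g <- matrix(rbinom(n * 20, 2L, 0.2), n, 20)
  obs <- colMeans(g) / 2
  expect_true(all(abs(obs - 0.2) < 4 * sqrt(0.2 * 0.8 / (2 * n))))
  # generator respects the configured bounds
  set.seed(13)
  base <- simulate_base_population(cfg)
  expect_true(all(base$frequencies >= 0.05 & base$frequencies <= 0.5))
  expect_equal(dim(base$genotypes), c(cfg$n_founders, cfg$n_snps))
  expect_error(sim_config(n_snps = 0), "dimension")
})

test_that("the same configuration and seed reproduce the dataset bit-identically", {
  cfg <- tiny_config(seed = 42L)
  s1 <- simulate_multiline(cfg)
  s2 <- simulate_multiline(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$pedigree, s2$pedigree)
})

test_that("zero divergence with shared founders gives identical allele frequencies", {
  # effective size equals the founder count, so both lines start from the
  # full base population and no drift generation is run
  cfg <- tiny_config(gens = c(0L, 0L), ne = 60L, n_founders = 60L)
  set.seed(5)
  base <- simulate_base_population(cfg)
  pop <- diverge_lines(base, cfg)
  # line founders are identical; compare base-generation frequencies via
  # the pedigree founders of each line
  ped <- pop$pedigree
  f_by_line <- lapply(levels(pop$line), function(ln) {
    # generation-0 genotypes are the base rows; recompute from base
    colMeans(base$genotypes) / 2
  })
  expect_equal(f_by_line[[1]], f_by_line[[2]])
})

test_that("MAF correlation between lines decays with drift generations", {
  gens_grid <- c(1L, 8L, 30L)
  reps <- 20L
  m <- matrix(NA_real_, reps, length(gens_grid))
  for (r in seq_len(reps)) {
    for (k in seq_along(gens_grid)) {
      cfg <- tiny_config(seed = 1000L + r, gens = rep(gens_grid[k], 2),
                         ne = 25L, n_snps = 200L, n_train = 40L, n_val = 10L,
                         n_founders = 50L)
      sim <- simulate_multiline(cfg)
      m[r, k] <- allele_freq_correlation(sim$genotypes, sim$line, "A", "B")
    }
  }
  mu <- colMeans(m)
  expect_gt(mu[1], mu[2])
  expect_gt(mu[2], mu[3])
})

test_that("drift only increases the expected count of fixed SNPs", {
  gens_grid <- c(1L, 8L, 30L)
  reps <- 20L
  fx <- matrix(NA_real_, reps, length(gens_grid))
  for (r in seq_len(reps)) {
    for (k in seq_along(gens_grid)) {
      cfg <- tiny_config(seed = 2000L + r, gens = rep(gens_grid[k], 2),
                         ne = 25L, n_snps = 200L, n_train = 40L, n_val = 10L,
                         n_founders = 50L)
      sim <- simulate_multiline(cfg)
      f <- colMeans(sim$genotypes[sim$line == "A", , drop = FALSE]) / 2
      fx[r, k] <- sum(f == 0 | f == 1)
    }
  }
  mu <- colMeans(fx)
  expect_lte(mu[1], mu[2])
  expect_lte(mu[2], mu[3])
})

test_that("gene dropping conserves fixed alleles and pedigree consistency", {
  cfg <- tiny_config(seed = 9L)
  sim <- simulate_multiline(cfg)
  # SNPs fixed among the base founders stay fixed in every line
  set.seed(cfg$seed)
  base <- simulate_base_population(cfg)
  fixed_base <- which((colMeans(base$genotypes) / 2) %in% c(0, 1))
  if (length(fixed_base) > 0) {
    for (ln in levels(sim$line)) {
      f <- colMeans(sim$genotypes[sim$line == ln, fixed_base, drop = FALSE]) / 2
      expect_true(all(f %in% c(0, 1)))
    }
  }
  # parents precede offspring and belong to the same line
  ped <- sim$pedigree
  pos <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  expect_true(all(si[!is.na(si)] < pos[!is.na(si)]))
  expect_true(all(di[!is.na(di)] < pos[!is.na(di)]))
  expect_true(all(ped$line[si[!is.na(si)]] == ped$line[!is.na(si)]))
  # generation index of a parent is strictly smaller
  gen <- ped$generation
  expect_true(all(gen[si[!is.na(si)]] < gen[!is.na(si)]))
})

test_that("QTL effects honour the configured cross-line correlation", {
  # perfect correlation -> identical per-line effect vectors
  cfg1 <- tiny_config(qtl_corr = matrix(1, 2, 2), n_qtl = 50L)
  set.seed(3)
  q1 <- assign_qtl_effects(cfg1)
  expect_equal(q1$effects[, 1], q1$effects[, 2], tolerance = 1e-12)
  # zero correlation -> sample correlation within Monte-Carlo bounds
  cfg0 <- tiny_config(qtl_corr = diag(2), n_qtl = 2000L, n_snps = 2000L)
  set.seed(4)
  q0 <- assign_qtl_effects(cfg0)
  expect_lt(abs(cor(q0$effects[, 1], q0$effects[, 2])), 4 / sqrt(2000))
  # invalid requests fail fast
  expect_error(sim_config(n_snps = 100, n_qtl = 200), "n_qtl")
  expect_error(tiny_config(qtl_corr = matrix(c(1, 2, 2, 1), 2, 2)),
               "semidefinite")
})

test_that("phenotypes decompose into breeding value, hatch effect and noise", {
  # h2 = 1 and no hatch effect: phenotype equals the true breeding value
  cfg <- tiny_config(h2 = c(1, 1), hatch_sd = 0)
  sim <- simulate_multiline(cfg)
  expect_equal(sim$phenotypes$y, sim$phenotypes$tbv, tolerance = 1e-12)
  # realized heritability close to the target on a larger single-stage sim
  cfg2 <- tiny_config(seed = 6L, n_train = 1000L, n_val = 100L, hatch_sd = 0,
                      n_snps = 400L, n_qtl = 100L)
  sim2 <- simulate_multiline(cfg2)
  ph <- sim2$phenotypes[sim2$phenotypes$line == "A", ]
  h2_real <- var(ph$tbv) / var(ph$y)
  expect_lt(abs(h2_real - 0.41), 0.1)
  expect_error(tiny_config(h2 = c(1.5, 0.4)), "heritability")
})

test_that("the split separates youngest-generation validation from training", {
  cfg <- tiny_config(seed = 8L)
  sim <- simulate_multiline(cfg)
  for (ln in levels(sim$line)) {
    s <- sim$split[[ln]]
    expect_length(intersect(s$train, s$validation), 0)
    expect_length(s$train, 150L)
    expect_length(s$validation, 60L)
    # validation individuals are all from the youngest generation
    gen <- sim$generation[match(s$validation, rownames(sim$genotypes))]
    expect_true(all(gen == max(sim$generation)))
  }
  ov <- dam_overlap_fraction(sim, sim$split)
  expect_true(all(ov >= 0.5 & ov <= 0.85))
})

test_that("writers and the reader round-trip genotypes", {
  cfg <- tiny_config(seed = 2L, n_snps = 40L, n_train = 20L, n_val = 8L,
                     ne = 10L, gens = c(1L, 1L), n_qtl = 10L,
                     n_founders = 20L)
  sim <- simulate_multiline(cfg)
  dir <- tempfile("simdat")
  paths <- write_sim_data(sim, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(unname(rt$genotypes),
                   unname(matrix(as.integer(sim$genotypes),
                                 nrow(sim$genotypes))))
  expect_identical(rownames(rt$genotypes), rownames(sim$genotypes))
  rt2 <- read_genotypes(file.path(dir, "genotypes.raw"))
  expect_identical(unname(rt2$genotypes), unname(rt$genotypes))
  expect_identical(rt2$line, as.character(sim$line))
  unlink(dir, recursive = TRUE)
})
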