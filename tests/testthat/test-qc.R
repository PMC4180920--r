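# SNP editing rules, allele-frequency summaries, genotype distances and
# hatch-week pre-correction.

test_that("snp_stats reproduces hand-computed call rate, frequency and HWE chi-square", {
  geno <- cbind(a = geno_column(25, 50, 25),          # exact HWE proportions
                b = geno_column(0, 100, 0),           # all heterozygous
                c = geno_column(40, 40, 15, 5))       # 5 missing of 100
  st <- snp_stats(geno)
  expect_equal(st$hwe_chisq[1], 0)
  expect_equal(st$freq[2], 0.5)
  expect_equal(st$hwe_chisq[2], 100)                  # 25 + 50 + 25
  expect_equal(st$call_rate[3], 0.95)
  expect_equal(st$freq[1] + (1 - st$freq[1]), 1)
  expect_error(snp_stats(matrix(numeric(0), 0, 0)), "empty")
})

test_that("filter_snps removes exactly the planted violations with their tags", {
  geno <- qc_toy()
  flt <- filter_snps(geno)
  rep <- flt$report
  expect_equal(sum(!rep$retained), 4)
  expect_identical(rep$snp[!rep$retained],
                   c("call_rate", "maf", "no_homozygote", "hwe"))
  for (rule in c("call_rate", "maf", "no_homozygote", "hwe")) {
    expect_true(rep[[rule]][rep$snp == rule])
    expect_equal(sum(rep[[rule]]), 1)                 # one violation per rule
  }
  # partition: every SNP is retained or carries at least one tag
  tagged <- rep$call_rate | rep$maf | rep$no_homozygote | rep$hwe
  expect_true(all(xor(rep$retained, tagged)))
  expect_equal(flt$counts[["retained"]] + flt$counts[["removed"]], nrow(rep))
})

test_that("boundary behaviour of the MAF and HWE thresholds", {
  # MAF strictly below 2% is removed; exactly 2% is kept
  n <- 1000L
  below <- geno_column(962, 38, 0)    # freq 0.019
  at <- geno_column(960, 40, 0)       # freq 0.020
  geno <- cbind(below = below, at = at)
  rep <- filter_snps(geno)$report
  expect_true(rep$maf[rep$snp == "below"])
  expect_false(rep$maf[rep$snp == "at"])
  # chi-square exactly at the threshold is retained, just above removed
  st <- data.frame(snp = c("x", "y"), n_called = 10, call_rate = 1,
                   freq = 0.5, maf = 0.5, n0 = 3, n1 = 4, n2 = 3,
                   hwe_chisq = c(600, 600.01))
  rep2 <- filter_snps(matrix(0L, 1, 2), stats = st)$report
  expect_false(rep2$hwe[1])
  expect_true(rep2$hwe[2])
})

test_that("segregating_subset returns SNPs polymorphic in the training lines", {
  geno <- rbind(ind1 = c(0L, 2L, 2L), ind2 = c(1L, 2L, 0L),
                ind3 = c(2L, 2L, 0L), ind4 = c(0L, 2L, 1L))
  colnames(geno) <- paste0("s", 1:3)
  line <- c("A", "A", "B", "B")
  # SNP 2 fixed in both training lines -> dropped from the union subset
  expect_identical(unname(segregating_subset(geno, line, lines = c("A", "B"))),
                   c(1L, 3L))
  expect_identical(unname(segregating_subset(geno, line, lines = "A")),
                   c(1L, 3L))
  # monotonicity: superset of lines segregates a superset of SNPs
  expect_true(all(segregating_subset(geno, line, lines = "A") %in%
                    segregating_subset(geno, line, lines = c("A", "B"))))
  expect_error(segregating_subset(geno, line, lines = "C"), "unknown")
})

test_that("fixed_allele_summary tallies same- and opposite-allele fixation", {
  # line A fixed ref at s1 and alt at s2; line B fixed ref at both
  geno <- rbind(a1 = c(0L, 2L, 1L), a2 = c(0L, 2L, 0L),
                b1 = c(0L, 0L, 2L), b2 = c(0L, 0L, 1L))
  colnames(geno) <- paste0("s", 1:3)
  fx <- fixed_allele_summary(geno, c("A", "A", "B", "B"))
  expect_equal(unname(fx$per_line), c(2, 2))
  expect_equal(fx$same_allele["A", "B"], 1)
  expect_equal(fx$opposite_allele["A", "B"], 1)
  expect_true(all(fx$per_line <= ncol(geno)))
  # identical lines share no opposite fixation
  fx2 <- fixed_allele_summary(rbind(geno[1:2, ], geno[1:2, ]),
                              c("A", "A", "B", "B"))
  expect_equal(fx2$opposite_allele["A", "B"], 0)
  expect_error(fixed_allele_summary(geno, rep("A", 4)), "two lines")
})

test_that("allele-frequency correlation behaves like a correlation", {
  set.seed(21)
  geno <- hwe_genotypes(60, runif(120, 0.1, 0.5))
  line <- rep(c("A", "B"), each = 30)
  dup <- rbind(geno[1:30, ], geno[1:30, ])
  rownames(dup) <- paste0("i", 1:60)
  expect_equal(allele_freq_correlation(dup, line, "A", "B"), 1)
  # invariant to SNP ordering
  r1 <- allele_freq_correlation(geno, line, "A", "B")
  perm <- sample(ncol(geno))
  r2 <- allele_freq_correlation(geno[, perm], line, "A", "B")
  expect_equal(r1, r2)
  # independently shuffled frequencies decorrelate
  set.seed(22)
  reps <- vapply(1:10, function(i) {
    gA <- hwe_genotypes(40, runif(400, 0.1, 0.5))
    gB <- hwe_genotypes(40, runif(400, 0.1, 0.5))
    allele_freq_correlation(rbind(gA, gB), rep(c("A", "B"), each = 40),
                            "A", "B")
  }, numeric(1))
  expect_lt(mean(abs(reps)), 4 / sqrt(400))
})

test_that("euclidean distances match the definition and the metric axioms", {
  g <- rbind(x = c(0, 1, 2), y = c(2, 1, 0), z = c(0, 1, 2))
  d <- euclidean_distance_matrix(g)
  expect_equal(d["x", "y"], sqrt(8))
  expect_equal(d["x", "z"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # oracle: brute-force double loop on a random instance
  set.seed(31)
  G <- hwe_genotypes(15, runif(40, 0.1, 0.5))
  D <- euclidean_distance_matrix(G)
  for (j in 1:15) for (k in 1:15)
    expect_equal(D[j, k], sqrt(sum((G[j, ] - G[k, ])^2)), tolerance = 1e-12)
  # triangle inequality on sampled triples
  for (t in 1:50) {
    ijk <- sample(15, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
  G[1, 1] <- NA
  expect_error(euclidean_distance_matrix(G), "missing")
})

test_that("hatch-week pre-correction is an idempotent within-week centring", {
  set.seed(41)
  ph <- data.frame(id = paste0("i", 1:60), y = rnorm(60),
                   hatch_week = rep(0:2, each = 20))
  # two hatches offset by a constant end with equal group means
  ph2 <- ph
  ph2$y <- ph2$y + 5 * (ph2$hatch_week == 1)
  out <- precorrect_phenotypes(ph2)
  gm <- tapply(out$y_corrected, out$hatch_week, mean)
  expect_lt(max(abs(gm - gm[1])), 1e-10)
  # single hatch week reduces to mean-centring
  one <- precorrect_phenotypes(ph[ph$hatch_week == 0, ])
  expect_equal(one$y_corrected, ph$y[ph$hatch_week == 0] -
                 mean(ph$y[ph$hatch_week == 0]))
  # idempotence
  again <- out
  again$y <- out$y_corrected
  expect_equal(precorrect_phenotypes(again)$y_corrected, out$y_corrected,
               tolerance = 1e-12)
  # residuals orthogonal to hatch-week indicators
  X <- model.matrix(~ 0 + factor(out$hatch_week))
  expect_lt(max(abs(crossprod(X, out$y_corrected))), 1e-10)
  # training-only fitting applies training means to held-out records
  fit_ids <- ph$id[c(1:10, 21:30, 41:50)]
  out2 <- precorrect_phenotypes(ph, fit_ids = fit_ids)
  m0 <- mean(ph$y[ph$hatch_week == 0 & ph$id %in% fit_ids])
  expect_equal(out2$y_corrected[ph$hatch_week == 0],
               ph$y[ph$hatch_week == 0] - m0)
  # a hatch week absent from the fitting set cannot be corrected
  expect_error(precorrect_phenotypes(ph, fit_ids = ph$id[1:40]),
               "hatch week")
})

test_that("mean imputation fills missing codes with per-SNP means", {
  g <- cbind(a = c(0L, 2L, NA), b = c(1L, 1L, 1L))
  out <- impute_genotypes(g)
  expect_equal(unname(out[3, "a"]), 1)
  expect_equal(out[, "b"], c(1, 1, 1))
  expect_false(anyNA(out))
})
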