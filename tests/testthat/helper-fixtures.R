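# Small fixtures shared across the test files. Everything is generated in
# code; sizes are kept small so single files run in seconds.

# two-line configuration for fast structural tests
tiny_config <- function(seed = 1L, gens = c(4L, 4L), ne = 30L,
                        n_snps = 300L, n_train = 150L, n_val = 60L,
                        n_qtl = 60L, h2 = c(0.41, 0.41),
                        qtl_corr = matrix(c(1, 0.8, 0.8, 1), 2, 2),
                        hatch_sd = 0.25, n_founders = 60L,
                        dam_overlap = 2 / 3) {
  sim_config(n_snps = n_snps, n_founders = n_founders,
             lines = list(line_spec("A", gens[1], ne, n_train, n_val),
                          line_spec("B", gens[2], ne, n_train, n_val)),
             n_qtl = n_qtl, qtl_effect_correlation = qtl_corr,
             heritability = h2, n_hatch_weeks = 3L, hatch_effect_sd = hatch_sd,
             n_study_generations = 2L, dam_overlap = dam_overlap, seed = seed)
}

# HWE genotypes for n individuals at given allele frequencies
hwe_genotypes <- function(n, freq, ids = paste0("ind", seq_len(n))) {
  p <- length(freq)
  matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), nrow = n,
         dimnames = list(ids, paste0("snp", seq_len(p))))
}

# genotype column with exact genotype counts (n0 x 0, n1 x 1, n2 x 2, nm x NA)
geno_column <- function(n0, n1, n2, nm = 0) {
  c(rep(0L, n0), rep(1L, n1), rep(2L, n2), rep(NA_integer_, nm))
}

# 10-SNP editing toy: one planted violation per rule among SNPs 1-4, six
# clean SNPs. n = 620 so the all-heterozygote SNP (590 called, chi-square
# 590) stays under the Hardy-Weinberg threshold of 600 that SNP 4 (620
# called, chi-square 620) exceeds.
qc_toy <- function() {
  n <- 620L
  cols <- list(
    call_rate = geno_column(145, 290, 145, 40),         # call rate 580/620 < 0.95
    maf = geno_column(612, 8, 0),                       # freq 8/1240 < 0.02
    no_homozygote = geno_column(0, 590, 0, 30),         # all het, chisq 590
    hwe = geno_column(310, 0, 310),                     # chisq 620 > 600
    clean1 = geno_column(155, 310, 155),
    clean2 = geno_column(349, 248, 23),                 # ~HWE at p ~ 0.24
    clean3 = geno_column(96, 300, 224),
    clean4 = geno_column(250, 300, 70),
    clean5 = geno_column(400, 200, 20),
    clean6 = geno_column(140, 320, 160))
  geno <- do.call(cbind, cols)
  rownames(geno) <- paste0("ind", seq_len(n))
  geno
}

# deterministic polygenic trait from genotypes: first n_qtl SNPs carry
# N(0, 1) effects; residual variance tuned to the target h2
polygenic_trait <- function(geno, n_qtl, h2, seed = 1L) {
  set.seed(seed)
  b <- stats::rnorm(n_qtl)
  g <- as.numeric(geno[, seq_len(n_qtl), drop = FALSE] %*% b)
  ve <- stats::var(g) * (1 - h2) / h2
  y <- g + stats::rnorm(nrow(geno), 0, sqrt(ve))
  list(y = stats::setNames(y, rownames(geno)), g = g,
       sigma_a2 = stats::var(g), sigma_e2 = ve)
}
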