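# Multi-line genotype / pedigree / phenotype simulator.
#
# Emulates the data structure of a three-line layer breeding program: two
# closely related lines plus one distant line, diverged by drift (gene
# dropping without linkage), a pedigreed study phase of ~1000 training birds
# per line, and a youngest validation generation of ~240 birds whose dams
# only partly overlap the training set.

#' Describe one breeding line for the simulator
#'
#' @param name Line label (e.g. `"B1"`).
#' @param generations_since_split Number of discrete drift generations between
#'   the common base population and the start of the line's study phase. More
#'   generations mean lower allele-frequency correlation with the other lines.
#' @param effective_size Number of breeding individuals per drift generation
#'   (must be at least 2).
#' @param n_train Number of phenotyped training individuals in the study phase.
#' @param n_validation Size of the youngest (validation) generation.
#' @return A `line_spec` list.
#' @export
line_spec <- function(name, generations_since_split, effective_size = 50L,
                      n_train = 1000L, n_validation = 240L) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (effective_size < 2) stop("effective_size must be >= 2")
  if (generations_since_split < 0) stop("generations_since_split must be >= 0")
  if (n_train < 1 || n_validation < 1) stop("line sizes must be positive")
  structure(list(name = name,
                 generations_since_split = as.integer(generations_since_split),
                 effective_size = as.integer(effective_size),
                 n_train = as.integer(n_train),
                 n_validation = as.integer(n_validation)),
            class = "line_spec")
}

#' Configuration for the multi-line simulator
#'
#' Defaults describe the calibrated three-line design used throughout the
#' package: two sibling lines whose minor-allele-frequency (MAF) correlation
#' is around 0.35, one heavily drifted distant line with MAF correlation near
#' 0.1, roughly 1000 training and 240 validation birds per line, a polygenic
#' trait with heritabilities 0.41/0.41/0.51, and hatch-week fixed effects.
#'
#' @param n_snps Number of biallelic SNPs simulated (all unlinked).
#' @param n_founders Size of the common base population.
#' @param lines List of [line_spec()] objects (one per line).
#' @param n_qtl Number of SNPs carrying trait effects (`n_qtl <= n_snps`).
#' @param qtl_effect_correlation Symmetric positive semidefinite matrix of
#'   cross-line correlations of allele-substitution effects, unit diagonal.
#' @param heritability Per-line narrow-sense heritability in (0, 1].
#' @param n_hatch_weeks Number of hatch-week classes.
#' @param hatch_effect_sd Standard deviation of hatch-week effects, trait units.
#' @param n_study_generations Number of pedigreed training generations per line.
#' @param dam_overlap Probability that a validation individual's dam belongs to
#'   the training set (the remainder are bred from unphenotyped contemporaries).
#' @param founder_maf_range Range of the uniform founder allele-frequency
#'   sampler; bounded away from 0 and 1.
#' @param seed Integer seed; the same configuration and seed reproduce all
#'   outputs bit-identically.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 1500L,
                       n_founders = 100L,
                       lines = list(
                         line_spec("B1", generations_since_split = 14L),
                         line_spec("B2", generations_since_split = 14L),
                         line_spec("W1", generations_since_split = 150L)),
                       n_qtl = 300L,
                       qtl_effect_correlation = matrix(c(1, 0.8, 0.2,
                                                         0.8, 1, 0.2,
                                                         0.2, 0.2, 1), 3, 3),
                       heritability = c(0.41, 0.41, 0.51),
                       n_hatch_weeks = 6L,
                       hatch_effect_sd = 0.25,
                       n_study_generations = 3L,
                       dam_overlap = 2 / 3,
                       founder_maf_range = c(0.05, 0.5),
                       seed = 1L) {
  if (n_snps < 1 || n_founders < 2) stop("non-positive dimensions")
  if (n_qtl > n_snps) stop("n_qtl must not exceed n_snps")
  if (n_qtl < 1) stop("n_qtl must be positive")
  nl <- length(lines)
  if (nl < 1) stop("at least one line required")
  if (!all(vapply(lines, inherits, logical(1), "line_spec")))
    stop("lines must be a list of line_spec objects")
  nms <- vapply(lines, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("line names must be unique")
  C <- qtl_effect_correlation
  if (!is.matrix(C) || nrow(C) != nl || ncol(C) != nl)
    stop("qtl_effect_correlation must be a square matrix matching the lines")
  if (max(abs(C - t(C))) > 1e-12) stop("qtl_effect_correlation must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-12) stop("qtl_effect_correlation needs unit diagonal")
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("qtl_effect_correlation must be positive semidefinite")
  h2 <- rep_len(heritability, nl)
  if (any(h2 <= 0 | h2 > 1)) stop("heritability must lie in (0, 1]")
  if (n_hatch_weeks < 1) stop("n_hatch_weeks must be positive")
  if (hatch_effect_sd < 0) stop("hatch_effect_sd must be non-negative")
  if (dam_overlap < 0 || dam_overlap > 1) stop("dam_overlap must lie in [0, 1]")
  if (length(founder_maf_range) != 2 || founder_maf_range[1] <= 0 ||
      founder_maf_range[2] >= 1 || founder_maf_range[1] > founder_maf_range[2])
    stop("founder_maf_range must lie strictly inside (0, 1)")
  structure(list(n_snps = as.integer(n_snps),
                 n_founders = as.integer(n_founders),
                 lines = lines,
                 n_qtl = as.integer(n_qtl),
                 qtl_effect_correlation = C,
                 heritability = stats::setNames(h2, nms),
                 n_hatch_weeks = as.integer(n_hatch_weeks),
                 hatch_effect_sd = hatch_effect_sd,
                 n_study_generations = as.integer(n_study_generations),
                 dam_overlap = dam_overlap,
                 founder_maf_range = founder_maf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Multi-line simulation configuration\n")
  cat(sprintf("  SNPs: %d (QTL: %d), founders: %d, seed: %d\n",
              x$n_snps, x$n_qtl, x$n_founders, x$seed))
  for (i in seq_along(x$lines)) {
    l <- x$lines[[i]]
    cat(sprintf("  line %-4s gens=%3d Ne=%3d train=%4d val=%3d h2=%.2f\n",
                l$name, l$generations_since_split, l$effective_size,
                l$n_train, l$n_validation, x$heritability[i]))
  }
  invisible(x)
}

## ---- base population ------------------------------------------------------

#' Simulate the unstructured base population
#'
#' Genotypes are drawn as two independent alleles per SNP at a founder
#' frequency (Hardy-Weinberg proportions); founder frequencies are uniform on
#' `config$founder_maf_range`.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (founders x SNPs integer matrix, 0/1/2) and
#'   `frequencies` (founder allele frequencies).
#' @export
simulate_base_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_founders
  p <- config$n_snps
  freq <- stats::runif(p, config$founder_maf_range[1], config$founder_maf_range[2])
  geno <- matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), nrow = n,
                 dimnames = list(paste0("base_", seq_len(n)),
                                 paste0("snp", seq_len(p))))
  list(genotypes = geno, frequencies = freq)
}

# One generation of random-mating gene dropping: each child receives one
# allele sampled from each parent's genotype, independently per SNP.
.drop_generation <- function(parents, n_off) {
  np <- nrow(parents)
  p <- ncol(parents)
  sire <- sample.int(np, n_off, replace = TRUE)
  dam <- sample.int(np, n_off, replace = TRUE)
  clash <- which(dam == sire)
  while (length(clash) > 0) {
    dam[clash] <- sample.int(np, length(clash), replace = TRUE)
    clash <- clash[dam[clash] == sire[clash]]
  }
  a1 <- matrix(stats::rbinom(n_off * p, 1L, parents[sire, , drop = FALSE] / 2),
               n_off, p)
  a2 <- matrix(stats::rbinom(n_off * p, 1L, parents[dam, , drop = FALSE] / 2),
               n_off, p)
  list(genotypes = a1 + a2, sire = sire, dam = dam)
}

## ---- line divergence ------------------------------------------------------

#' Diverge lines from a common base by gene dropping
#'
#' Each line samples `effective_size` founders from the base population, then
#' drifts through `generations_since_split` discrete generations of random
#' mating. A pedigreed study phase follows: `n_study_generations` training
#' generations holding `n_train` phenotyped individuals, an unphenotyped
#' contemporary pool, and a final validation generation of `n_validation`
#' individuals whose dams are drawn from the training set with probability
#' `dam_overlap`.
#'
#' @param base Output of [simulate_base_population()].
#' @param config A [sim_config()].
#' @return List with `genotypes` (study-phase individuals of all lines x SNPs),
#'   `line` (factor of line labels, one per row), `role` (`"training"`,
#'   `"unphenotyped"` or `"validation"`), `generation` (study generation index)
#'   and `pedigree` (id, sire, dam, generation, line for every simulated
#'   individual including the drift phase).
#' @export
diverge_lines <- function(base, config) {
  stopifnot(inherits(config, "sim_config"))
  geno_list <- list()
  ped_list <- list()
  line_lab <- character(0)
  role_lab <- character(0)
  gen_lab <- integer(0)

  for (li in seq_along(config$lines)) {
    spec <- config$lines[[li]]
    ne <- spec$effective_size
    if (ne > config$n_founders)
      stop("effective_size exceeds the number of base founders")
    idx <- sample.int(config$n_founders, ne)
    cur <- base$genotypes[idx, , drop = FALSE]
    cur_ids <- sprintf("%s_g0_%d", spec$name, seq_len(ne))
    ped <- data.frame(id = cur_ids, sire = NA_character_, dam = NA_character_,
                      generation = 0L, line = spec$name,
                      stringsAsFactors = FALSE)

    # drift phase at constant size
    g <- 0L
    if (spec$generations_since_split > 0) {
      for (g in seq_len(spec$generations_since_split)) {
        off <- .drop_generation(cur, ne)
        ids <- sprintf("%s_g%d_%d", spec$name, g, seq_len(ne))
        ped <- rbind(ped, data.frame(id = ids, sire = cur_ids[off$sire],
                                     dam = cur_ids[off$dam], generation = g,
                                     line = spec$name, stringsAsFactors = FALSE))
        cur <- off$genotypes
        cur_ids <- ids
      }
    }

    # study phase: expanded, pedigreed, phenotyped generations
    sizes <- rep(ceiling(spec$n_train / config$n_study_generations),
                 config$n_study_generations)
    sizes[config$n_study_generations] <-
      spec$n_train - sum(sizes[-config$n_study_generations])
    n_extra <- max(ceiling(spec$n_validation * (1 - config$dam_overlap)) + 5L, 5L)
    study_geno <- list()
    study_role <- character(0)
    study_gen <- integer(0)
    study_ids_all <- character(0)
    for (sg in seq_len(config$n_study_generations)) {
      g <- g + 1L
      n_this <- sizes[sg] +
        if (sg == config$n_study_generations) n_extra else 0L
      off <- .drop_generation(cur, n_this)
      ids <- sprintf("%s_g%d_%d", spec$name, g, seq_len(n_this))
      ped <- rbind(ped, data.frame(id = ids, sire = cur_ids[off$sire],
                                   dam = cur_ids[off$dam], generation = g,
                                   line = spec$name, stringsAsFactors = FALSE))
      role <- rep("training", n_this)
      if (sg == config$n_study_generations && n_extra > 0)
        role[sizes[sg] + seq_len(n_extra)] <- "unphenotyped"
      study_geno[[sg]] <- off$genotypes
      study_role <- c(study_role, role)
      study_gen <- c(study_gen, rep(g, n_this))
      study_ids_all <- c(study_ids_all, ids)
      cur <- off$genotypes
      cur_ids <- ids
    }

    # validation generation: dam from training parents with prob dam_overlap
    last_role <- study_role[study_gen == g]
    train_par <- which(last_role == "training")
    extra_par <- which(last_role == "unphenotyped")
    nv <- spec$n_validation
    from_train <- stats::runif(nv) < config$dam_overlap
    if (length(extra_par) == 0) from_train[] <- TRUE
    dam <- integer(nv)
    dam[from_train] <- sample(train_par, sum(from_train), replace = TRUE)
    dam[!from_train] <- sample(extra_par, sum(!from_train), replace = TRUE)
    sire <- sample.int(nrow(cur), nv, replace = TRUE)
    clash <- which(sire == dam)
    while (length(clash) > 0) {
      sire[clash] <- sample.int(nrow(cur), length(clash), replace = TRUE)
      clash <- clash[sire[clash] == dam[clash]]
    }
    p <- ncol(cur)
    a1 <- matrix(stats::rbinom(nv * p, 1L, cur[sire, , drop = FALSE] / 2), nv, p)
    a2 <- matrix(stats::rbinom(nv * p, 1L, cur[dam, , drop = FALSE] / 2), nv, p)
    g <- g + 1L
    val_ids <- sprintf("%s_g%d_%d", spec$name, g, seq_len(nv))
    ped <- rbind(ped, data.frame(id = val_ids, sire = cur_ids[sire],
                                 dam = cur_ids[dam], generation = g,
                                 line = spec$name, stringsAsFactors = FALSE))

    geno <- rbind(do.call(rbind, study_geno), a1 + a2)
    rownames(geno) <- c(study_ids_all, val_ids)
    geno_list[[li]] <- geno
    ped_list[[li]] <- ped
    line_lab <- c(line_lab, rep(spec$name, nrow(geno)))
    role_lab <- c(role_lab, study_role, rep("validation", nv))
    gen_lab <- c(gen_lab, study_gen, rep(g, nv))
  }

  geno <- do.call(rbind, geno_list)
  colnames(geno) <- colnames(base$genotypes)
  list(genotypes = geno,
       line = factor(line_lab, levels = vapply(config$lines, `[[`,
                                               character(1), "name")),
       role = role_lab,
       generation = gen_lab,
       pedigree = do.call(rbind, ped_list))
}

## ---- genetic architecture -------------------------------------------------

#' Sample QTL positions and per-line allele-substitution effects
#'
#' QTL positions are sampled without replacement among the SNPs; for each QTL
#' the vector of per-line effects is multivariate normal with the configured
#' cross-line correlation, so `qtl_effect_correlation = 1` everywhere yields
#' identical genetic architectures and lower values let effects diverge.
#'
#' @param config A [sim_config()].
#' @return List with `qtl_indices` and `effects` (n_qtl x n_lines matrix).
#' @export
assign_qtl_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_qtl > config$n_snps) stop("n_qtl must not exceed n_snps")
  C <- config$qtl_effect_correlation
  ev <- eigen(C, symmetric = TRUE)
  M <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  idx <- sort(sample.int(config$n_snps, config$n_qtl))
  Zr <- matrix(stats::rnorm(config$n_qtl * ncol(C)), config$n_qtl)
  eff <- Zr %*% M
  colnames(eff) <- vapply(config$lines, `[[`, character(1), "name")
  list(qtl_indices = idx, effects = eff)
}

#' Simulate phenotypes from genotypes and QTL effects
#'
#' The true breeding value of an individual is the sum of its QTL allele
#' counts times its line's effects. Residual variance is set per line so that
#' realized genetic variance over total variance equals the configured
#' heritability; a hatch-week effect (common normal shift per week class) is
#' added on top.
#'
#' @param pop Output of [diverge_lines()].
#' @param qtl Output of [assign_qtl_effects()].
#' @param config A [sim_config()].
#' @return List with `phenotypes` (data.frame: id, line, hatch_week, y, tbv)
#'   and `vc` (per-line data.frame of realized sigma_a2, sigma_e2, h2).
#' @export
simulate_phenotypes <- function(pop, qtl, config) {
  stopifnot(inherits(config, "sim_config"))
  h2 <- config$heritability
  if (any(h2 <= 0 | h2 > 1)) stop("heritability must lie in (0, 1]")
  geno <- pop$genotypes
  if (max(qtl$qtl_indices) > ncol(geno)) stop("QTL index outside SNP panel")
  n <- nrow(geno)
  tbv <- numeric(n)
  sig_a <- sig_e <- numeric(length(config$lines))
  names(sig_a) <- names(sig_e) <- levels(pop$line)
  Xq <- geno[, qtl$qtl_indices, drop = FALSE]
  for (ln in levels(pop$line)) {
    rows <- which(pop$line == ln)
    tbv[rows] <- as.numeric(Xq[rows, , drop = FALSE] %*% qtl$effects[, ln])
    vg <- stats::var(tbv[rows])
    sig_a[ln] <- vg
    sig_e[ln] <- vg * (1 - h2[ln]) / h2[ln]
  }
  week <- sample.int(config$n_hatch_weeks, n, replace = TRUE) - 1L
  week_eff <- stats::rnorm(config$n_hatch_weeks, 0, config$hatch_effect_sd)
  e <- stats::rnorm(n, 0, sqrt(sig_e[as.character(pop$line)]))
  y <- tbv + week_eff[week + 1L] + e
  list(phenotypes = data.frame(id = rownames(geno),
                               line = as.character(pop$line),
                               hatch_week = week, y = y, tbv = tbv,
                               stringsAsFactors = FALSE),
       vc = data.frame(line = names(sig_a), sigma_a2 = sig_a,
                       sigma_e2 = sig_e, h2 = sig_a / (sig_a + sig_e),
                       row.names = NULL, stringsAsFactors = FALSE))
}

## ---- scenario split -------------------------------------------------------

#' Training/validation id sets per line
#'
#' Validation individuals are the youngest generation of each line; training
#' individuals are the phenotyped members of the older study generations. The
#' two sets are disjoint by construction, and the fraction of validation dams
#' present in the training set follows the configured `dam_overlap`.
#'
#' @param pop Output of [diverge_lines()].
#' @param config A [sim_config()].
#' @return Named list (per line) of lists with `train` and `validation` ids.
#' @export
make_scenario_split <- function(pop, config) {
  out <- list()
  for (ln in levels(pop$line)) {
    rows <- pop$line == ln
    out[[ln]] <- list(train = rownames(pop$genotypes)[rows & pop$role == "training"],
                      validation = rownames(pop$genotypes)[rows & pop$role == "validation"])
  }
  out
}

#' Fraction of validation individuals whose dam is in the training set
#'
#' @param pop Output of [diverge_lines()].
#' @param split Output of [make_scenario_split()].
#' @return Named numeric vector, one fraction per line.
#' @export
dam_overlap_fraction <- function(pop, split) {
  ped <- pop$pedigree
  vapply(names(split), function(ln) {
    dams <- ped$dam[match(split[[ln]]$validation, ped$id)]
    mean(dams %in% split[[ln]]$train)
  }, numeric(1))
}

## ---- one-call simulator ---------------------------------------------------

#' Simulate a complete multi-line dataset
#'
#' Runs the full generator: base population, line divergence, QTL effects,
#' phenotypes and the training/validation split, with per-stage seeds derived
#' deterministically from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `ml_sim`: genotypes, line labels, roles,
#'   pedigree, phenotypes, true breeding values, per-line variance components,
#'   the QTL model, the train/validation split, and founder frequencies.
#' @export
simulate_multiline <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base <- simulate_base_population(config)
  set.seed(config$seed + 1L)
  pop <- diverge_lines(base, config)
  set.seed(config$seed + 2L)
  qtl <- assign_qtl_effects(config)
  set.seed(config$seed + 3L)
  ph <- simulate_phenotypes(pop, qtl, config)
  split <- make_scenario_split(pop, config)
  structure(list(genotypes = pop$genotypes,
                 line = pop$line,
                 role = pop$role,
                 generation = pop$generation,
                 pedigree = pop$pedigree,
                 phenotypes = ph$phenotypes,
                 vc = ph$vc,
                 qtl = qtl,
                 split = split,
                 founder_frequencies = base$frequencies,
                 config = config),
            class = "ml_sim")
}

#' @export
print.ml_sim <- function(x, ...) {
  cat("Simulated multi-line dataset\n")
  cat(sprintf("  %d individuals x %d SNPs, %d lines\n",
              nrow(x$genotypes), ncol(x$genotypes), nlevels(x$line)))
  for (ln in levels(x$line)) {
    s <- x$split[[ln]]
    cat(sprintf("  line %-4s train=%4d validation=%3d h2=%.3f\n", ln,
                length(s$train), length(s$validation),
                x$vc$h2[x$vc$line == ln]))
  }
  invisible(x)
}

## ---- writers / readers ----------------------------------------------------

#' Write a simulated dataset as plain-text tables
#'
#' Writes `genotypes.raw` (PLINK .raw-style additive coding), `genotypes.tsv`,
#' `pedigree.tsv` (id, sire, dam, generation, line) and `phenotypes.tsv`.
#'
#' @param sim An `ml_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "ml_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genotypes.raw", "genotypes.tsv", "pedigree.tsv",
                            "phenotypes.tsv"))
  raw <- data.frame(FID = as.character(sim$line), IID = rownames(sim$genotypes),
                    PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9,
                    stringsAsFactors = FALSE)
  raw <- cbind(raw, as.data.frame(sim$genotypes))
  utils::write.table(raw, paths[1], sep = " ", quote = FALSE, row.names = FALSE)
  gt <- data.frame(id = rownames(sim$genotypes), line = as.character(sim$line),
                   as.data.frame(sim$genotypes), stringsAsFactors = FALSE)
  utils::write.table(gt, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$pedigree, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$phenotypes, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read genotypes from a PLINK .raw or plain TSV file
#'
#' `.raw` files are expected to carry the usual six leading columns
#' (FID IID PAT MAT SEX PHENOTYPE); TSV files an `id` column, optionally a
#' `line` column, then one column per SNP. Missing genotypes may be encoded
#' as `NA`.
#'
#' @param path File path.
#' @param format `"raw"` or `"tsv"`; guessed from the extension by default.
#' @return List with `genotypes` (individuals x SNPs matrix, rownames = ids)
#'   and `line` (character vector or `NULL`).
#' @export
read_genotypes <- function(path, format = c("auto", "raw", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.raw$", path)) "raw" else "tsv"
  if (format == "raw") {
    df <- utils::read.table(path, header = TRUE, sep = "",
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df$IID)
    line <- as.character(df$FID)
    gcols <- setdiff(colnames(df), c("FID", "IID", "PAT", "MAT", "SEX",
                                     "PHENOTYPE"))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df$id)
    line <- if ("line" %in% colnames(df)) as.character(df$line) else NULL
    gcols <- setdiff(colnames(df), c("id", "line"))
  }
  geno <- as.matrix(df[, gcols, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- ids
  list(genotypes = geno, line = line)
}
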