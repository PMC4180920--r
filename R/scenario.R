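# Scenario runner: crosses each target line with every non-empty subset of
# lines as training set (7 scenarios per target for 3 lines), restricts each
# scenario to SNPs segregating in its training data, averages variance
# components over member lines, fits the configured models, and evaluates
# accuracy, bias and cross-model correlations.

#' Average variance components over training lines
#'
#' Arithmetic means of the additive and residual variances across the member
#' lines; heritability and the ridge coefficient are re-derived from the
#' means (not averaged), and the per-SNP variance is the mean additive
#' variance divided by the scenario's SNP count.
#'
#' @param vc_list List of [variance_components()] objects (one per line).
#' @param n_snps SNP count of the scenario's segregating subset.
#' @return A [variance_components()] object.
#' @export
average_vc <- function(vc_list, n_snps = NULL) {
  if (length(vc_list) == 0) stop("empty variance-component list")
  stopifnot(all(vapply(vc_list, inherits, logical(1), "variance_components")))
  sa <- mean(vapply(vc_list, `[[`, numeric(1), "sigma_a2"))
  se <- mean(vapply(vc_list, `[[`, numeric(1), "sigma_e2"))
  variance_components(sa, se, n_snps)
}

#' Build all training scenarios for each target line
#'
#' For `k` lines, each target line is crossed with every non-empty subset of
#' lines as training set (`2^k - 1` scenarios per target; 7 for three lines):
#' its own line, each other line alone, each pair, and all lines. Each
#' scenario records the training ids (union of the member lines' training
#' sets), the target line's validation ids, the SNP subset segregating in the
#' training data, and the averaged variance components. Pedigree BLUP is only
#' applicable to the own-line scenario (there are no pedigree relationships
#' between lines), which is flagged on the scenario.
#'
#' @param data An `ml_data` object from [prepare_analysis()] (scenario SNP
#'   subsets are taken within its QC-retained panel); an `ml_sim` is also
#'   accepted, in which case no SNP editing is assumed.
#' @param target_lines Lines to evaluate (default: all).
#' @return List of `training_scenario` objects.
#' @export
build_training_sets <- function(data, target_lines = NULL) {
  if (inherits(data, "ml_data")) {
    sim <- data$sim
    geno <- data$genotypes
  } else {
    sim <- data
    geno <- sim$genotypes
  }
  lines <- levels(sim$line)
  target_lines <- target_lines %||% lines
  if (!all(target_lines %in% lines)) stop("unknown line name")
  k <- length(lines)
  subsets <- list()
  for (m in seq_len(k))
    subsets <- c(subsets, utils::combn(lines, m, simplify = FALSE))
  vc_by_line <- lapply(stats::setNames(lines, lines), function(ln) {
    row <- sim$vc[sim$vc$line == ln, ]
    variance_components(row$sigma_a2, row$sigma_e2)
  })
  out <- list()
  for (tg in target_lines) {
    for (ss in subsets) {
      train_ids <- unlist(lapply(ss, function(ln) sim$split[[ln]]$train),
                          use.names = FALSE)
      snp_subset <- segregating_subset(geno, sim$line, ids = train_ids)
      vc <- average_vc(vc_by_line[ss], n_snps = length(snp_subset))
      sc <- structure(list(target = tg,
                           train_lines = ss,
                           name = paste(ss, collapse = "+"),
                           train_ids = train_ids,
                           validation_ids = sim$split[[tg]]$validation,
                           snp_subset = snp_subset,
                           vc = vc,
                           h2_target = vc_by_line[[tg]]$h2,
                           own_line = identical(ss, tg)),
                      class = "training_scenario")
      out[[length(out) + 1L]] <- sc
    }
  }
  out
}

#' @export
print.training_scenario <- function(x, ...) {
  cat(sprintf("scenario: target %s, training %s (%d ids, %d SNPs)%s\n",
              x$target, x$name, length(x$train_ids), length(x$snp_subset),
              if (x$own_line) " [own line]" else ""))
  invisible(x)
}

#' Prepare a simulated dataset for the scenario runner
#'
#' Runs the standard pipeline once: SNP editing on the combined lines,
#' mean imputation, hatch-week pre-correction fitted on training individuals
#' only, the genomic relationship matrices built once on all lines
#' (VanRaden G on combined frequencies, plus the identity-fraction and
#' excess-homozygosity matrices), and per-line truncated pedigrees for BLUP.
#'
#' @param sim An `ml_sim` object.
#' @param thresholds A [filter_thresholds()] object.
#' @param pedigree_depth Parent generations climbed from the study phase when
#'   truncating the pedigree for the A matrix (default 6).
#' @param matrices Which relationship matrices to build: any of `"vr"`,
#'   `"id"`, `"eh"` (genomic, built once on all lines) and `"A"` (per-line
#'   pedigree matrices). Default: all.
#' @return A list of class `ml_data` with prepared inputs for
#'   [run_scenario()].
#' @export
prepare_analysis <- function(sim, thresholds = filter_thresholds(),
                             pedigree_depth = 6,
                             matrices = c("vr", "id", "eh", "A")) {
  stopifnot(inherits(sim, "ml_sim"))
  flt <- filter_snps(sim$genotypes, thresholds)
  geno <- impute_genotypes(flt$genotypes)
  geno_int <- round(geno)
  storage.mode(geno_int) <- "integer"
  train_all <- unlist(lapply(sim$split, `[[`, "train"), use.names = FALSE)
  pheno <- precorrect_phenotypes(sim$phenotypes, fit_ids = train_all)
  freq <- colMeans(geno) / 2
  seg <- which(freq > 0 & freq < 1)
  G_vr <- if ("vr" %in% matrices)
    build_G_vanraden(geno[, seg, drop = FALSE], freq[seg]) else NULL
  G_id <- if ("id" %in% matrices)
    build_G_identity_fraction(geno_int[, seg, drop = FALSE]) else NULL
  G_eh <- if ("eh" %in% matrices)
    build_G_excess_hom(geno_int[, seg, drop = FALSE], freq[seg]) else NULL
  A_by_line <- if ("A" %in% matrices)
    lapply(stats::setNames(levels(sim$line), levels(sim$line)), function(ln) {
      ids <- c(sim$split[[ln]]$train, sim$split[[ln]]$validation)
      ped <- prune_pedigree(sim$pedigree, ids, max_generations = pedigree_depth)
      build_A(ped)
    }) else NULL
  structure(list(sim = sim, filter = flt, genotypes = geno,
                 genotypes_int = geno_int, phenotypes = pheno,
                 G_vr = G_vr, G_id = G_id, G_eh = G_eh,
                 A_by_line = A_by_line),
            class = "ml_data")
}

#' @export
print.ml_data <- function(x, ...) {
  cat("Prepared multi-line analysis data\n")
  print(x$filter)
  built <- c(vr = !is.null(x$G_vr), id = !is.null(x$G_id),
             eh = !is.null(x$G_eh), A = !is.null(x$A_by_line))
  cat(sprintf("  matrices built: %s (%d individuals)\n",
              paste(names(built)[built], collapse = ", "),
              nrow(x$genotypes)))
  invisible(x)
}

#' Run all configured models on one training scenario
#'
#' Fits each requested model on the scenario's training data, predicts the
#' target line's validation individuals, and evaluates accuracy (with the
#' target line's heritability), dispersion bias and cross-model EBV
#' correlations. A numerical failure of one model is recorded with its error
#' message and does not abort the remaining models.
#'
#' @param data An `ml_data` object from [prepare_analysis()].
#' @param scenario A `training_scenario` from [build_training_sets()].
#' @param models Character vector among `"blup"`, `"gblup_vr"`, `"gblup_id"`,
#'   `"gblup_eh"`, `"rrblup"`, `"rrpca"`, `"bayesc"`, `"bssvs"`. `"blup"` is
#'   silently dropped for non-own-line scenarios.
#' @param gibbs A [gibbs_config()] for the Bayesian models.
#' @param n_boot Bootstrap samples for the bias SE.
#' @param seed Seed applied before each stochastic model / the bootstrap.
#' @return An object of class `scenario_result`: per-model `ebv`
#'   (validation), `accuracy`, `bias`, `failed` (named error messages),
#'   `correlations`, and the scenario.
#' @export
run_scenario <- function(data, scenario,
                         models = c("blup", "gblup_vr", "gblup_id", "gblup_eh",
                                    "rrblup", "rrpca", "bayesc", "bssvs"),
                         gibbs = gibbs_config(), n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(data, "ml_data"), inherits(scenario, "training_scenario"))
  sim <- data$sim
  tr <- scenario$train_ids
  va <- scenario$validation_ids
  ph <- data$phenotypes
  y <- stats::setNames(ph$y_corrected[match(tr, ph$id)], tr)
  y_val <- stats::setNames(ph$y_corrected[match(va, ph$id)], va)
  snp <- scenario$snp_subset
  vc <- scenario$vc
  h2 <- scenario$h2_target
  if (!scenario$own_line) models <- setdiff(models, "blup")

  ebv <- list()
  failed <- character(0)
  for (m in models) {
    res <- tryCatch({
      if (m == "blup") {
        A <- data$A_by_line[[scenario$target]]
        fit <- gp_fit(y, vc, method = "blup", kinship = A,
                      validation_ids = va)
      } else if (m %in% c("gblup_vr", "gblup_id", "gblup_eh")) {
        K <- switch(m, gblup_vr = data$G_vr, gblup_id = data$G_id,
                    gblup_eh = data$G_eh)
        fit <- gp_fit(y, vc, method = "gblup", kinship = K,
                      validation_ids = va)
      } else if (m %in% c("bayesc", "bssvs")) {
        set.seed(seed)
        fit <- gp_fit(y, vc, method = m,
                      geno = data$genotypes[, snp, drop = FALSE],
                      validation_ids = va, gibbs = gibbs)
      } else {
        fit <- gp_fit(y, vc, method = m,
                      geno = data$genotypes[, snp, drop = FALSE],
                      validation_ids = va)
      }
      fit$ebv[va]
    }, error = function(e) e)
    if (inherits(res, "error")) failed[m] <- conditionMessage(res)
    else ebv[[m]] <- res
  }

  acc <- lapply(ebv, function(v) accuracy(v, y_val, h2))
  bias <- lapply(ebv, function(v)
    bias_regression(y_val, v, n_boot = n_boot, seed = seed))
  corr <- if (length(ebv) >= 2) method_correlation_matrix(ebv) else NULL
  structure(list(scenario = scenario, ebv = ebv, accuracy = acc, bias = bias,
                 correlations = corr, failed = failed,
                 n_snps = length(snp), n_train = length(tr),
                 n_validation = length(va), seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  for (m in names(x$accuracy))
    cat(sprintf("  %-9s accuracy %6.3f  b1 %6.3f\n", m,
                x$accuracy[[m]]$accuracy, x$bias[[m]]$b1))
  if (length(x$failed) > 0)
    cat("  failed:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}

#' Run every scenario for every target line
#'
#' @param data An `ml_data` object.
#' @param models,gibbs,n_boot,seed Passed to [run_scenario()].
#' @param target_lines Lines to evaluate (default: all).
#' @return List of `scenario_result` objects.
#' @export
run_all_scenarios <- function(data, models = c("blup", "gblup_vr", "gblup_id",
                                               "gblup_eh", "rrblup", "rrpca",
                                               "bayesc", "bssvs"),
                              gibbs = gibbs_config(), n_boot = 1000L,
                              seed = 1L, target_lines = NULL) {
  scens <- build_training_sets(data, target_lines)
  lapply(scens, function(sc)
    run_scenario(data, sc, models = models, gibbs = gibbs, n_boot = n_boot,
                 seed = seed))
}

#' Tabulate scenario results
#'
#' Collects a list of [run_scenario()] results into the standard report
#' tables: an accuracy grid (one row per model, one column per training set,
#' one table per target line), matching bias grids, and the per-target
#' cross-model correlation matrices of the all-lines training set.
#'
#' @param results List of `scenario_result` objects.
#' @return List of class `gp_report` with `accuracy` (named list of matrices),
#'   `bias`, `correlations`, and `counts` (data frame of scenario sizes).
#' @export
report_scenarios <- function(results) {
  if (length(results) == 0) stop("no scenario results")
  targets <- unique(vapply(results, function(r) r$scenario$target, character(1)))
  models <- unique(unlist(lapply(results, function(r) names(r$accuracy))))
  acc <- bias <- list()
  corr <- list()
  counts <- data.frame()
  for (tg in targets) {
    rs <- Filter(function(r) r$scenario$target == tg, results)
    sets <- vapply(rs, function(r) r$scenario$name, character(1))
    A <- B <- matrix(NA_real_, length(models), length(sets),
                     dimnames = list(models, sets))
    for (j in seq_along(rs)) {
      for (m in names(rs[[j]]$accuracy)) {
        A[m, j] <- rs[[j]]$accuracy[[m]]$accuracy
        B[m, j] <- rs[[j]]$bias[[m]]$b1
      }
      counts <- rbind(counts, data.frame(
        target = tg, training = sets[j], n_train = rs[[j]]$n_train,
        n_snps = rs[[j]]$n_snps, n_validation = rs[[j]]$n_validation))
    }
    acc[[tg]] <- A
    bias[[tg]] <- B
    all_set <- which(vapply(rs, function(r)
      length(r$scenario$train_lines), integer(1)) ==
        max(vapply(rs, function(r) length(r$scenario$train_lines), integer(1))))
    corr[[tg]] <- rs[[all_set[1]]]$correlations
  }
  structure(list(accuracy = acc, bias = bias, correlations = corr,
                 counts = unique(counts)),
            class = "gp_report")
}

#' @export
print.gp_report <- function(x, digits = 3, ...) {
  for (tg in names(x$accuracy)) {
    cat(sprintf("== target line %s: accuracy ==\n", tg))
    print(round(x$accuracy[[tg]], digits))
  }
  invisible(x)
}

#' Replicate experiment for the qualitative multi-line conclusions
#'
#' Runs the calibrated three-line simulation for a set of seeds and, per
#' replicate, evaluates with GBLUP (VanRaden) and pedigree BLUP the three
#' contrasts the multi-line design is about: own-line genomic versus pedigree
#' prediction, prediction from the distant line only, and the change in
#' own-line accuracy when the sibling line is added to training.
#'
#' @param seeds Integer vector; one simulation replicate per seed.
#' @param config Base [sim_config()]; its `seed` is replaced per replicate.
#' @param sibling_pair,distant Line names: the two sibling lines and the
#'   distant line (defaults match the default configuration).
#' @return Data frame with one row per replicate: mean own-line GBLUP and
#'   BLUP accuracies, mean distant-line-only accuracy, and the mean change in
#'   own-line accuracy from adding the sibling line.
#' @export
evaluate_multiline_pattern <- function(seeds, config = sim_config(),
                                       sibling_pair = c("B1", "B2"),
                                       distant = "W1") {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- simulate_multiline(cfg)
    data <- prepare_analysis(sim, matrices = c("vr", "A"))
    scens <- build_training_sets(data)
    pick <- function(tg, nm)
      Filter(function(x) x$target == tg && x$name == nm, scens)[[1]]
    acc <- function(sc, models) {
      r <- run_scenario(data, sc, models = models, n_boot = 10, seed = s)
      vapply(r$accuracy, `[[`, numeric(1), "accuracy")
    }
    lines <- levels(sim$line)
    own <- vapply(lines, function(ln)
      acc(pick(ln, ln), c("blup", "gblup_vr")), numeric(2))
    dist_only <- c(
      acc(pick(sibling_pair[1], distant), "gblup_vr"),
      acc(pick(distant, sibling_pair[1]), "gblup_vr"))
    sib_name <- paste(sort(sibling_pair), collapse = "+")
    sib_delta <- vapply(sibling_pair, function(ln)
      acc(pick(ln, sib_name), "gblup_vr") - own["gblup_vr", ln], numeric(1))
    data.frame(seed = s,
               own_gblup = mean(own["gblup_vr", ]),
               own_blup = mean(own["blup", ]),
               distant_only = mean(dist_only),
               sibling_delta = mean(sib_delta))
  })
  do.call(rbind, rows)
}
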