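#' Configuration for the synthetic multi-omics generator
#'
#' Defines a multi-cohort methylation + expression study with planted
#' causal genes. Defaults mirror the desk-scale study conditions used
#' throughout the package's validation: four cohorts of 250 samples,
#' 500 genes with on average 5 CpGs each, 5 causal genes, cohort-specific
#' phenotype shifts emulating the age heterogeneity of real population
#' cohorts, and a sex-linked feature block for activation-pattern
#' analyses.
#'
#' @param n_cohorts number of cohorts.
#' @param n_per_cohort samples per cohort.
#' @param n_genes number of genes.
#' @param cpgs_per_gene mean CpGs per gene (Poisson, minimum 1).
#' @param n_causal number of causal genes.
#' @param me_beta,ge_beta phenotype effect (outcome units per SD of the
#'   gene-level signal) of the methylation / expression arm of each
#'   causal gene.
#' @param omic_specificity fraction of causal genes whose signal exists
#'   in only one omic (alternating methylation-only / expression-only).
#' @param shared_latent if TRUE, each causal gene's expression reflects
#'   the same latent factor as its methylation, making the causal signal
#'   redundant between the omics (either omic suffices for prediction);
#'   if FALSE (default) the two omic arms carry independent information.
#' @param cohort_shift per-cohort additive phenotype shift (recycled);
#'   default emulates the between-cohort mean age spread of population
#'   biobanks for regression and no shift for classification.
#' @param intercept phenotype baseline (regression).
#' @param noise_sd residual SD of the continuous phenotype.
#' @param sex_block_size number of (non-causal) genes carrying a sex
#'   main effect in both omics.
#' @param sex_feature_effect latent shift (in SD units) the binary
#'   covariate adds to the sex-block genes' features.
#' @param sex_pheno_effect direct phenotype effect of the covariate.
#' @param prevalence target case fraction (classification).
#' @param link_scale logistic signal scale (classification); larger
#'   values raise the generator's Bayes-optimal AUC.
#' @param me_noise_sd per-CpG noise SD on the logit scale.
#' @param seed RNG seed; same seed, bit-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 4L, n_per_cohort = 250L, n_genes = 500L,
                       cpgs_per_gene = 5, n_causal = 5L,
                       me_beta = 1, ge_beta = 1, omic_specificity = 0,
                       shared_latent = FALSE,
                       cohort_shift = NULL, intercept = 51, noise_sd = 1,
                       sex_block_size = 20L, sex_feature_effect = 2,
                       sex_pheno_effect = 0, prevalence = 0.25,
                       link_scale = 6, me_noise_sd = 0.5, seed = 1L) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts), n_per_cohort = as.integer(n_per_cohort),
    n_genes = as.integer(n_genes), cpgs_per_gene = cpgs_per_gene,
    n_causal = as.integer(n_causal), me_beta = me_beta, ge_beta = ge_beta,
    omic_specificity = omic_specificity, shared_latent = isTRUE(shared_latent),
    cohort_shift = cohort_shift,
    intercept = intercept, noise_sd = noise_sd,
    sex_block_size = as.integer(sex_block_size),
    sex_feature_effect = sex_feature_effect,
    sex_pheno_effect = sex_pheno_effect, prevalence = prevalence,
    link_scale = link_scale, me_noise_sd = me_noise_sd, seed = as.integer(seed)
  )
  if (cfg$n_cohorts < 1 || cfg$n_per_cohort < 1 || cfg$n_genes < 1) {
    stop("counts must be positive")
  }
  if (cfg$n_causal > cfg$n_genes) stop("more causal genes than genes")
  if (cfg$sex_block_size > cfg$n_genes - cfg$n_causal) {
    stop("sex block does not fit beside the causal genes")
  }
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) stop("prevalence must be in (0,1)")
  structure(cfg, class = "sim_config")
}

simulate_features <- function(config) {
  n <- config$n_cohorts * config$n_per_cohort
  g_ids <- sprintf("G%04d", seq_len(config$n_genes))
  cohort <- rep(paste0("C", seq_len(config$n_cohorts)), each = config$n_per_cohort)
  sample_ids <- sprintf("s%05d", seq_len(n))

  # gene layout on one chromosome: TSS spacing 10 kb, CpGs within +-2 kb of
  # their gene's TSS, so the nearest-TSS rule recovers the planted map exactly
  spacing <- 10000L
  tss <- spacing * seq_len(config$n_genes)
  genes <- data.frame(
    gene_id = g_ids, chrom = "chr1", tss = tss,
    strand = rep(c("+", "-"), length.out = config$n_genes),
    stringsAsFactors = FALSE
  )
  n_cpg_per_gene <- pmax(1L, stats::rpois(config$n_genes, config$cpgs_per_gene))
  cpg_gene <- rep(seq_len(config$n_genes), times = n_cpg_per_gene)
  offsets <- unlist(lapply(n_cpg_per_gene, function(k) sample(-2000:2000, k)))
  cpgs <- data.frame(
    cpg_id = sprintf("cg%06d", seq_along(cpg_gene)),
    chrom = "chr1",
    pos = tss[cpg_gene] + offsets,
    stringsAsFactors = FALSE
  )

  causal_idx <- sort(sample.int(config$n_genes, config$n_causal))
  block_pool <- setdiff(seq_len(config$n_genes), causal_idx)
  sex_block_idx <- sort(sample(block_pool, config$sex_block_size))
  sex <- stats::rbinom(n, 1, 0.5)

  Z <- matrix(stats::rnorm(n * config$n_genes), n, config$n_genes)  # methylation latent
  V <- matrix(stats::rnorm(n * config$n_genes), n, config$n_genes)  # expression latent
  if (isTRUE(config$shared_latent)) {
    # redundant causal signal: expression mirrors the methylation latent
    V[, causal_idx] <- Z[, causal_idx]
  }
  if (length(sex_block_idx)) {
    shift <- config$sex_feature_effect * sex
    Z[, sex_block_idx] <- Z[, sex_block_idx] + shift
    V[, sex_block_idx] <- V[, sex_block_idx] + shift
  }

  b0 <- stats::rnorm(length(cpg_gene), 0, 1)
  me <- stats::plogis(
    matrix(b0, n, length(cpg_gene), byrow = TRUE) +
      Z[, cpg_gene, drop = FALSE] +
      matrix(stats::rnorm(n * length(cpg_gene), 0, config$me_noise_sd),
             n, length(cpg_gene))
  )
  dimnames(me) <- list(sample_ids, cpgs$cpg_id)

  mu_g <- stats::runif(config$n_genes, 2, 6)
  ge <- exp(matrix(mu_g, n, config$n_genes, byrow = TRUE) + 0.5 * V)
  dimnames(ge) <- list(sample_ids, g_ids)

  # per-omic causal coefficients; omic-exclusive genes alternate ME-only /
  # GE-only to probe omic-specific information
  me_coef <- rep(config$me_beta, config$n_causal)
  ge_coef <- rep(config$ge_beta, config$n_causal)
  n_spec <- round(config$omic_specificity * config$n_causal)
  if (n_spec > 0) {
    for (i in seq_len(n_spec)) {
      if (i %% 2 == 1) ge_coef[i] <- 0 else me_coef[i] <- 0
    }
  }
  signal <- numeric(n)
  s_me <- s_ge <- matrix(0, n, config$n_causal)
  for (i in seq_along(causal_idx)) {
    g <- causal_idx[i]
    s_me[, i] <- as.vector(scale(rowMeans(me[, cpg_gene == g, drop = FALSE])))
    s_ge[, i] <- as.vector(scale(log1p(ge[, g])))
    signal <- signal + me_coef[i] * s_me[, i] + ge_coef[i] * s_ge[, i]
  }

  list(
    n = n, sample_ids = sample_ids, cohort = cohort, sex = sex,
    genes = genes, cpgs = cpgs, cpg_gene = cpg_gene,
    me = me, ge = ge, signal = signal,
    causal = data.frame(gene = g_ids[causal_idx], me_coef = me_coef,
                        ge_coef = ge_coef, stringsAsFactors = FALSE),
    sex_block = g_ids[sex_block_idx]
  )
}

finish_simulation <- function(fx, config, phenotype, extra_truth) {
  dataset <- omics_dataset(
    me = fx$me, ge = fx$ge, phenotype = phenotype, cohort = fx$cohort,
    covariates = data.frame(sex = fx$sex, row.names = fx$sample_ids)
  )
  annotations <- list(cpgs = fx$cpgs, genes = fx$genes)
  truth <- c(
    list(
      causal_genes = fx$causal,
      sex_block = fx$sex_block,
      cpg_map = stats::setNames(fx$genes$gene_id[fx$cpg_gene], fx$cpgs$cpg_id),
      signal = stats::setNames(fx$signal, fx$sample_ids),
      config = config
    ),
    extra_truth
  )
  list(dataset = dataset, annotations = annotations, truth = truth)
}

#' Simulate a multi-cohort multi-omics dataset (continuous phenotype)
#'
#' Methylation betas arise from a logistic-transformed Gaussian model
#' with a shared gene-level latent factor per gene (so the mean beta of
#' a gene's CpGs is informative); expression is log-normal and passes a
#' 1-CPM-average inclusion filter by construction. The continuous
#' phenotype is a linear combination of the causal genes' standardized
#' gene-level methylation summaries and log-expression values, plus
#' covariate effect, cohort shift and Gaussian noise. CpG positions are
#' laid out so nearest-TSS annotation reproduces the planted CpG-to-gene
#' map exactly.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an `omics_dataset`), `annotations`
#'   (CpG and gene tables) and `truth` (causal genes with per-omic
#'   coefficients, sex block, planted CpG map, generator signal,
#'   formula).
#' @export
simulate_omics <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fx <- simulate_features(config)
  shift <- config$cohort_shift %||% c(16, -6, 7, -13)
  shift <- rep(shift, length.out = config$n_cohorts)
  cohort_idx <- match(fx$cohort, paste0("C", seq_len(config$n_cohorts)))
  y <- config$intercept + fx$signal + config$sex_pheno_effect * fx$sex +
    shift[cohort_idx] + stats::rnorm(fx$n, 0, config$noise_sd)
  finish_simulation(fx, config, y, list(
    task = "regression",
    cohort_means = config$intercept + shift,
    formula = "y = intercept + sum_causal(me_coef*scale(mean_beta) + ge_coef*scale(log_ge)) + sex_effect*sex + cohort_shift + N(0, noise_sd)"
  ))
}

#' Simulate a multi-cohort multi-omics dataset (binary phenotype)
#'
#' Features as in [simulate_omics()]; the binary outcome follows a
#' logistic model on the standardized causal signal, with the intercept
#' solved so the expected prevalence matches the target. The generator's
#' Bayes-optimal AUC (empirical AUC of the true linear score against
#' the sampled labels) is reported in the truth manifest.
#'
#' @param config a [sim_config()].
#' @return as [simulate_omics()], with `truth$bayes_auc` and
#'   `truth$eta` (true logistic score).
#' @export
simulate_classification <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fx <- simulate_features(config)
  shift <- rep(config$cohort_shift %||% 0, length.out = config$n_cohorts)
  cohort_idx <- match(fx$cohort, paste0("C", seq_len(config$n_cohorts)))
  eta_raw <- fx$signal + config$sex_pheno_effect * fx$sex + shift[cohort_idx]
  if (stats::sd(eta_raw) > 0) {
    eta <- config$link_scale * as.vector(scale(eta_raw))
  } else {
    eta <- numeric(fx$n)
  }
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - config$prevalence,
    interval = c(-30, 30)
  )$root
  y <- stats::rbinom(fx$n, 1, stats::plogis(alpha + eta))
  bayes_auc <- if (length(unique(y)) == 2) {
    as.numeric(pROC::auc(response = y, predictor = eta,
                         levels = c(0, 1), direction = "<", quiet = TRUE))
  } else NA_real_
  finish_simulation(fx, config, y, list(
    task = "classification", eta = stats::setNames(eta, fx$sample_ids),
    alpha = alpha, bayes_auc = bayes_auc,
    formula = "y ~ Bernoulli(plogis(alpha + link_scale*scale(signal + sex_effect*sex + cohort_shift)))"
  ))
}

#' Generate a random pathway hierarchy fixture
#'
#' Builds a three-level hierarchy (local, mid, global) by annotating a
#' fraction of the genes to 1-3 random local pathways, then assigning
#' each local pathway a mid parent and each mid a global parent.
#'
#' @param gene_ids character vector of genes.
#' @param n_local,n_mid,n_global level widths (default the 321/44/6
#'   KEGG-style shape).
#' @param annotated_frac fraction of genes with at least one local
#'   pathway (default 0.6).
#' @param seed RNG seed.
#' @return list with `membership` (gene -> local pathways) and `parent`
#'   (child -> parent), as consumed by [build_pathway_masks()].
#' @export
make_pathway_hierarchy <- function(gene_ids, n_local = 321L, n_mid = 44L,
                                   n_global = 6L, annotated_frac = 0.6,
                                   seed = 1L) {
  set.seed(seed)
  gene_ids <- as.character(gene_ids)
  local_ids <- sprintf("pwL%03d", seq_len(n_local))
  mid_ids <- sprintf("pwM%03d", seq_len(n_mid))
  global_ids <- sprintf("pwG%01d", seq_len(n_global))
  n_ann <- round(annotated_frac * length(gene_ids))
  annotated <- sample(gene_ids, n_ann)
  membership <- stats::setNames(
    lapply(seq_len(n_ann), function(i) sample(local_ids, sample(1:3, 1))),
    annotated
  )
  # every local pathway needs >= 1 member so the fixture keeps its widths
  used <- unique(unlist(membership, use.names = FALSE))
  missing <- setdiff(local_ids, used)
  if (length(missing) && n_ann > 0) {
    extra_host <- sample(annotated, length(missing), replace = TRUE)
    for (i in seq_along(missing)) {
      g <- extra_host[i]
      membership[[g]] <- unique(c(membership[[g]], missing[i]))
    }
  }
  if (n_local < n_mid || n_mid < n_global) {
    stop("level widths must be non-increasing (local >= mid >= global)")
  }
  # the first n_mid locals cover each mid once (and likewise for globals),
  # so every mid/global node stays reachable; the rest draw random parents
  local_parents <- c(mid_ids,
                     sample(mid_ids, n_local - n_mid, replace = TRUE))
  mid_parents <- c(global_ids,
                   sample(global_ids, n_mid - n_global, replace = TRUE))
  parent <- c(
    stats::setNames(sample(local_parents), local_ids),
    stats::setNames(sample(mid_parents), mid_ids)
  )
  list(membership = membership, parent = parent,
       levels = c("local", "mid", "global"))
}
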