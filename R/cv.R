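#' Bundle aligned multi-omics matrices into a dataset
#'
#' @param me sample-by-CpG methylation beta matrix (rownames = sample
#'   ids, values in [0,1]).
#' @param ge sample-by-gene expression matrix (same row order as `me`).
#' @param phenotype numeric outcome vector ({0,1} for classification).
#' @param cohort character/factor cohort label per sample.
#' @param covariates optional data.frame of numeric covariates.
#' @return an `omics_dataset`.
#' @export
omics_dataset <- function(me, ge, phenotype, cohort, covariates = NULL) {
  me <- as.matrix(me); ge <- as.matrix(ge)
  n <- nrow(me)
  if (nrow(ge) != n) stop("me and ge have different sample counts")
  if (!is.null(rownames(me)) && !is.null(rownames(ge)) &&
      !identical(rownames(me), rownames(ge))) {
    stop("me and ge sample ids disagree; align them first (see align_samples)")
  }
  if (length(phenotype) != n) stop("phenotype length mismatch")
  if (length(cohort) != n) stop("cohort length mismatch")
  if (anyNA(me) || anyNA(ge) || anyNA(phenotype)) {
    stop("missing values are not supported; the method assumes complete data")
  }
  sample_ids <- rownames(me) %||% paste0("s", seq_len(n))
  structure(
    list(me = me, ge = ge, phenotype = as.numeric(phenotype),
         cohort = as.character(cohort), covariates = covariates,
         sample_ids = sample_ids),
    class = "omics_dataset"
  )
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d samples, %d CpGs, %d genes, %d cohort(s)\n",
              length(x$sample_ids), ncol(x$me), ncol(x$ge),
              length(unique(x$cohort))))
  invisible(x)
}

#' Prepare network input matrices from a dataset
#'
#' Expression is log-transformed (`log1p`) and z-scored per gene, and
#' methylation betas are z-scored per CpG, both using statistics from
#' the training rows only, so no information leaks from validation or
#' test samples (zero-mean, unit-scale inputs keep the masked layers in
#' their trainable range). Covariates pass through unchanged; switches
#' restore raw betas / raw expression.
#'
#' @param dataset an `omics_dataset`.
#' @param train_idx row indices defining the training set (source of the
#'   scaling statistics).
#' @param scale_expression z-score expression per gene (default TRUE).
#' @param log_expression apply `log1p` to expression first (default
#'   TRUE).
#' @param scale_methylation z-score methylation per CpG (default TRUE;
#'   FALSE feeds raw beta values).
#' @return named list of full-dataset input matrices (`me`, `ge`, and
#'   `cov` when covariates exist); subset rows for each split.
#' @export
prepare_inputs <- function(dataset, train_idx, scale_expression = TRUE,
                           log_expression = TRUE, scale_methylation = TRUE) {
  zscore <- function(m) {
    mu <- colMeans(m[train_idx, , drop = FALSE])
    sdv <- apply(m[train_idx, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    sweep(sweep(m, 2, mu), 2, sdv, `/`)
  }
  ge <- dataset$ge
  if (log_expression) ge <- log1p(ge)
  if (scale_expression) ge <- zscore(ge)
  me <- dataset$me
  if (scale_methylation) me <- zscore(me)
  out <- list(me = me, ge = ge)
  if (!is.null(dataset$covariates)) {
    cv <- as.matrix(dataset$covariates)
    rownames(cv) <- dataset$sample_ids
    out$cov <- cv
  }
  out
}

#' Default hyperparameter search grid
#'
#' Learning rates 0.01, 0.001, 0.005, 0.0001 crossed with L1 penalties
#' 0.01, 0.001, 0.0001 on the regularized layers.
#'
#' @return data.frame with columns `learning_rate`, `l1_lambda`.
#' @export
default_hyperparameter_grid <- function() {
  expand.grid(
    learning_rate = c(0.01, 0.001, 0.005, 0.0001),
    l1_lambda = c(0.01, 0.001, 0.0001),
    KEEP.OUT.ATTRS = FALSE
  )
}

metric_of <- function(ev, task) if (task == "classification") ev$auc else ev$rmse

better_than <- function(a, b, task) {
  if (task == "classification") a > b else a < b
}

#' Cohort-wise (leave-one-cohort-out) cross-validation
#'
#' For each cohort: hold it out as the test set, pool the remaining
#' cohorts and split them 75%/25% into training and validation sets
#' (seeded), grid-search the hyperparameters on the validation set, then
#' retrain the best combination `n_seeds` times with different random
#' seeds and evaluate each replicate on the held-out cohort. Metric
#' means are aggregated over folds with a normal-approximation 95%
#' confidence interval (mean +/- 1.96 sd/sqrt(k)).
#'
#' @param spec a `network_spec` (built once; masks do not depend on the
#'   split). Alternatively a function `function() spec`.
#' @param dataset an `omics_dataset` with >= 2 cohorts.
#' @param grid hyperparameter data.frame (default
#'   [default_hyperparameter_grid()]).
#' @param n_seeds replicate seeds for the best hyperparameters (default
#'   10; seeds are `base_seed + 0..n_seeds-1`).
#' @param base_seed integer base seed.
#' @param hp baseline [hyperparams()] supplying epochs, batch size,
#'   patience and any omic-specific penalty.
#' @param train_frac training fraction of the pooled cohorts (default
#'   0.75).
#' @param scale_expression,log_expression,scale_methylation passed to
#'   [prepare_inputs()].
#' @param contributions also compute a per-seed contribution report
#'   (default TRUE).
#' @param verbose print progress.
#' @return a `cv_results` list: `folds` (per-fold results incl. per-seed
#'   validation/test metrics and contribution reports) and `summary`
#'   (mean and 95% CI per metric over folds).
#' @export
cohort_cv <- function(spec, dataset, grid = default_hyperparameter_grid(),
                      n_seeds = 10L, base_seed = 1L, hp = hyperparams(),
                      train_frac = 0.75, scale_expression = TRUE,
                      log_expression = TRUE, scale_methylation = TRUE,
                      contributions = TRUE, select_tolerance = NULL,
                      verbose = FALSE) {
  if (is.function(spec)) spec <- spec()
  task <- spec$task
  cohorts <- sort(unique(dataset$cohort))
  if (length(cohorts) < 2) stop("cohort-wise CV needs at least 2 cohorts")
  folds <- list()

  for (f in seq_along(cohorts)) {
    test_cohort <- cohorts[f]
    test_idx <- which(dataset$cohort == test_cohort)
    pool_idx <- which(dataset$cohort != test_cohort)
    if (length(test_idx) < 2 || length(pool_idx) < 4) {
      warning(sprintf("fold '%s' skipped: too few samples", test_cohort))
      next
    }
    set.seed(base_seed * 1000L + f)
    n_tr <- round(train_frac * length(pool_idx))
    train_idx <- sort(sample(pool_idx, n_tr))
    val_idx <- setdiff(pool_idx, train_idx)

    inputs <- prepare_inputs(dataset, train_idx,
                             scale_expression = scale_expression,
                             log_expression = log_expression,
                             scale_methylation = scale_methylation)
    take <- function(idx) lapply(inputs, function(m) m[idx, , drop = FALSE])
    x_tr <- take(train_idx); x_va <- take(val_idx); x_te <- take(test_idx)
    y_tr <- dataset$phenotype[train_idx]
    y_va <- dataset$phenotype[val_idx]
    y_te <- dataset$phenotype[test_idx]

    grid_runs <- vector("list", nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      hp_i <- hp
      hp_i$learning_rate <- grid$learning_rate[gi]
      hp_i$l1_lambda <- grid$l1_lambda[gi]
      model <- train_vnn(spec, x_tr, y_tr, x_va, y_va, hp = hp_i,
                         seed = base_seed)
      m_val <- metric_of(evaluate(y_va, predict_vnn(model, spec, x_va), task), task)
      if (verbose) {
        message(sprintf("fold %s  lr=%g l1=%g  val %s=%.4f", test_cohort,
                        hp_i$learning_rate, hp_i$l1_lambda,
                        if (task == "classification") "AUC" else "RMSE", m_val))
      }
      grid_runs[[gi]] <- list(hp = hp_i, metric = m_val,
                              epoch = model$meta$best_epoch)
    }
    vals <- vapply(grid_runs, `[[`, 0, "metric")
    best_val <- if (task == "classification") max(vals) else min(vals)
    tol <- select_tolerance %||%
      (if (task == "classification") 0.005 else 0.01 * abs(best_val))
    tied <- if (task == "classification") {
      which(vals >= best_val - tol)
    } else {
      which(vals <= best_val + tol)
    }
    # one-standard-error-style tie break: prefer the more regularized,
    # then the shorter-trained, model among validation ties
    l1s <- vapply(grid_runs[tied], function(r) r$hp$l1_lambda, 0)
    tied <- tied[l1s == max(l1s)]
    eps <- vapply(grid_runs[tied], `[[`, 0L, "epoch")
    best <- grid_runs[[tied[which.min(eps)]]]

    seeds <- base_seed + seq_len(n_seeds) - 1L
    seed_rows <- list()
    reports <- list()
    for (s in seeds) {
      model <- train_vnn(spec, x_tr, y_tr, x_va, y_va, hp = best$hp, seed = s)
      ev_va <- evaluate(y_va, predict_vnn(model, spec, x_va), task)
      ev_te <- evaluate(y_te, predict_vnn(model, spec, x_te), task)
      row <- data.frame(seed = s)
      for (nm in names(ev_va)) row[[paste0("val_", nm)]] <- ev_va[[nm]]
      for (nm in names(ev_te)) row[[paste0("test_", nm)]] <- ev_te[[nm]]
      seed_rows[[length(seed_rows) + 1L]] <- row
      if (contributions) {
        reports[[as.character(s)]] <- contribution_report(model, spec)
      }
    }
    folds[[test_cohort]] <- list(
      test_cohort = test_cohort,
      best_hp = best$hp,
      val_metric_grid_best = best$metric,
      seed_metrics = do.call(rbind, seed_rows),
      reports = if (contributions) reports else NULL,
      n_train = length(train_idx), n_val = length(val_idx),
      n_test = length(test_idx),
      train_ids = dataset$sample_ids[train_idx],
      val_ids = dataset$sample_ids[val_idx],
      test_ids = dataset$sample_ids[test_idx]
    )
    if (verbose) {
      message(sprintf("fold %s done: mean test %s = %.4f", test_cohort,
                      if (task == "classification") "AUC" else "RMSE",
                      mean(folds[[test_cohort]]$seed_metrics[[
                        if (task == "classification") "test_auc" else "test_rmse"]])))
    }
  }
  if (length(folds) == 0) stop("no usable folds")

  metric_cols <- setdiff(names(folds[[1]]$seed_metrics), "seed")
  fold_means <- sapply(metric_cols, function(cn) {
    vapply(folds, function(fd) mean(fd$seed_metrics[[cn]]), 0)
  })
  fold_means <- matrix(fold_means, nrow = length(folds),
                       dimnames = list(names(folds), metric_cols))
  k <- nrow(fold_means)
  summary <- data.frame(
    metric = metric_cols,
    mean = colMeans(fold_means),
    sd = apply(fold_means, 2, stats::sd),
    row.names = NULL
  )
  summary$ci_lo <- summary$mean - 1.96 * summary$sd / sqrt(k)
  summary$ci_hi <- summary$mean + 1.96 * summary$sd / sqrt(k)
  structure(list(folds = folds, summary = summary, task = task,
                 base_seed = base_seed, n_seeds = n_seeds),
            class = "cv_results")
}

#' @export
print.cv_results <- function(x, ...) {
  cat(sprintf("cohort-wise CV (%s), %d fold(s), %d seed(s)\n",
              x$task, length(x$folds), x$n_seeds))
  print(x$summary, digits = 4)
  invisible(x)
}
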