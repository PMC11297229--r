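test_that("weighted binary cross-entropy matches its closed forms", {
  # balanced classes: weights are 1 and the p=0.5 loss is ln 2
  y <- c(1, 1, 0, 0)
  expect_equal(weighted_bce(y, rep(0.5, 4)), log(2), tolerance = 1e-12)
  cw <- class_weights(y)
  expect_equal(unname(cw), c(1, 1))
  # perfect predictions drive the loss to (clipped) zero
  expect_lt(weighted_bce(y, c(1, 1, 0, 0)), 1e-6)
  # imbalanced hand-evaluated case: n1=1, n0=3, all p=0.5
  y2 <- c(1, 0, 0, 0)
  w1 <- 4 / (2 * 1); w0 <- 4 / (2 * 3)
  manual <- mean(-(w1 * y2 * log(0.5) + w0 * (1 - y2) * log(0.5)))
  expect_equal(weighted_bce(y2, rep(0.5, 4)), manual, tolerance = 1e-12)
  expect_error(class_weights(c(1, 1)), "single class")
})

test_that("weighted BCE equals unweighted BCE when classes are balanced", {
  set.seed(11)
  y <- rep(c(0, 1), each = 25)
  p <- runif(50, 0.05, 0.95)
  unweighted <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(weighted_bce(y, p), unweighted, tolerance = 1e-12)
})

test_that("mean squared error matches direct computation", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, -1)), 1)
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(mse_loss(a, b), sum((a - b)^2) / 40, tolerance = 1e-12)
})

test_that("L1 term sums selected weights only", {
  mask <- connectivity_mask(c("x:a", "x:b"), "y", c(1L, 2L), c(1L, 1L))
  spec <- new_network_spec(
    list(new_masked_layer("output", mask, "relu", l1 = TRUE)),
    "regression", list(x = c("a", "b"))
  )
  st <- init_model(spec, 1)
  st$layers[[1]]$W <- c(1, -2)
  expect_equal(l1_term(st, spec, 0.1, "all"), 0.3)
  # selector matching nothing contributes zero
  expect_equal(l1_term(st, spec, 0.1, "ge"), 0)
  # omic-tagged selector sums only that omic's edges
  fx <- tiny_me_ge_model()
  stf <- fx$state
  gl <- fx$spec$layers[[2]]$mask
  lam <- 0.5
  want <- lam * sum(abs(stf$layers[[2]]$W[gl$tags == "ge"]))
  expect_equal(l1_term(stf, fx$spec, lam, "ge"), want)
})

test_that("evaluation metrics agree with independent oracles", {
  y <- c(0, 0, 1, 1)
  expect_equal(evaluate(y, c(0.1, 0.2, 0.8, 0.9), "classification")$auc, 1)
  ev <- evaluate(c(1, 2, 3), c(1, 2, 3), "regression")
  expect_equal(ev$rmse, 0)
  expect_equal(ev$explained_variance, 1)
  set.seed(5)
  yy <- rbinom(50, 1, 0.4); ss <- rnorm(50)
  expect_equal(evaluate(yy, ss, "classification")$auc, rank_auc(yy, ss),
               tolerance = 1e-12)
  yt <- rnorm(50); yp <- yt + rnorm(50, 0, 0.5)
  evr <- evaluate(yt, yp, "regression")
  expect_equal(evr$rmse, sqrt(mean((yt - yp)^2)), tolerance = 1e-12)
  expect_equal(evr$explained_variance, 1 - var(yt - yp) / var(yt),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cpgs <- paste0("cg", 1:6); genes <- paste0("G", 1:3)
  gm <- connectivity_mask(cpgs, genes, 1:6, c(1, 1, 2, 2, 3, 3), tags = rep("me", 6))
  for (task in c("classification", "regression")) {
    spec <- build_me_ge_network(gm, genes, task = task,
                                hidden = if (task == "classification") "tanh" else "relu")
    n <- 9
    inputs <- list(
      me = matrix(runif(n * 6), n, 6, dimnames = list(NULL, cpgs)),
      ge = matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, genes))
    )
    y <- if (task == "classification") rbinom(n, 1, 0.5) else rnorm(n, 2)
    if (task == "classification" && length(unique(y)) == 1) y[1] <- 1 - y[1]
    cw <- if (task == "classification") class_weights(y) else NULL
    plans <- vnnomics:::compile_network(spec, lapply(inputs, colnames))
    state <- init_model(spec, seed = 3)
    state$layers[[3]]$b <- 0.3   # keep relu output active
    lossfun <- function(st) {
      p <- vnnomics:::forward_pass(st, spec, inputs, plans)$output
      vnnomics:::data_loss(y, p, task, cw)
    }
    fw <- vnnomics:::forward_pass(state, spec, inputs, plans, keep_cache = TRUE)
    d_out <- matrix(vnnomics:::loss_grad(y, fw$output, task, cw), ncol = 1)
    grads <- vnnomics:::backward_pass(state, spec, plans, fw$caches, d_out)
    h <- 1e-6
    for (k in seq_along(state$layers)) {
      idx <- seq_len(min(5, length(state$layers[[k]]$W)))
      for (i in idx) {
        up <- state; up$layers[[k]]$W[i] <- up$layers[[k]]$W[i] + h
        dn <- state; dn$layers[[k]]$W[i] <- dn$layers[[k]]$W[i] - h
        num <- (lossfun(up) - lossfun(dn)) / (2 * h)
        expect_equal(unname(grads[[k]]$W[i]), num, tolerance = 1e-5)
      }
    }
  }
})

test_that("training solves a linearly separable toy problem", {
  set.seed(1)
  n <- 80
  genes <- c("A", "B")
  ge <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, genes))
  y <- as.integer(ge[, 1] - ge[, 2] > 0)
  spec <- build_ge_network(genes, "classification")
  inputs <- list(ge = ge)
  m <- train_vnn(spec, inputs, y, inputs, y,
                 hp = hyperparams(learning_rate = 0.05, l1_lambda = 1e-4,
                                  epochs = 200, patience = 50, batch_size = 16),
                 seed = 1)
  auc <- evaluate(y, predict_vnn(m, spec, inputs), "classification")$auc
  expect_gte(auc, 0.999)
})

test_that("constant targets collapse to the bias under L1", {
  set.seed(2)
  n <- 60
  genes <- c("A", "B", "C")
  ge <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, genes))
  y <- rep(5, n)
  spec <- build_ge_network(genes, "regression")
  inputs <- list(ge = ge)
  m <- train_vnn(spec, inputs, y, inputs, y,
                 hp = hyperparams(learning_rate = 0.01, l1_lambda = 0.01,
                                  epochs = 150, patience = 150), seed = 1)
  p <- predict_vnn(m, spec, inputs)
  expect_equal(mean(p), 5, tolerance = 0.05)
  expect_lt(max(abs(m$layers[[1]]$W)), 0.05)
})

test_that("noise-free linear generator is fit below a tenth of the outcome spread", {
  sim <- simulate_omics(sim_config(
    n_cohorts = 1, n_per_cohort = 300, n_genes = 20, n_causal = 2,
    noise_sd = 0, cohort_shift = 0, sex_block_size = 0,
    sex_feature_effect = 0, seed = 5
  ))
  ds <- sim$dataset
  map <- map_cpgs_to_genes(sim$annotations$cpgs, sim$annotations$genes)
  go <- intersect_gene_sets(unique(map$pairs), colnames(ds$ge))
  gm <- build_gene_mask(map, go, colnames(ds$me))
  spec <- build_me_ge_network(gm, go, "regression")
  set.seed(2)
  tr <- sort(sample(300, 225)); va <- setdiff(1:300, tr)
  inp <- prepare_inputs(ds, tr)
  g <- function(i) lapply(inp, function(m) m[i, , drop = FALSE])
  y <- ds$phenotype
  m <- train_vnn(spec, g(tr), y[tr], g(va), y[va],
                 hp = hyperparams(learning_rate = 0.01, l1_lambda = 1e-4,
                                  epochs = 600, patience = 60), seed = 1)
  rmse <- evaluate(y[va], predict_vnn(m, spec, g(va)), "regression")$rmse
  expect_lte(rmse, 0.1 * sd(y))
})

test_that("stronger L1 never densifies the penalized layer", {
  set.seed(3)
  n <- 120
  genes <- paste0("G", 1:30)
  ge <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, genes))
  y <- as.integer(ge[, 1] + ge[, 2] + rnorm(n, 0, 0.3) > 0)
  spec <- build_ge_network(genes, "classification")
  inputs <- list(ge = ge)
  nnz <- sapply(c(1e-4, 1e-3, 1e-2), function(lam) {
    m <- train_vnn(spec, inputs, y, inputs, y,
                   hp = hyperparams(learning_rate = 0.01, l1_lambda = lam,
                                    epochs = 120, patience = 120), seed = 1)
    sum(abs(m$layers[[1]]$W) > 1e-3)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("training aborts on single-class labels", {
  spec <- build_ge_network(c("A", "B"), "classification")
  x <- list(ge = matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("A", "B"))))
  expect_error(train_vnn(spec, x, rep(1, 5), x, rep(1, 5)), "single class")
})
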