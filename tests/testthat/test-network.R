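test_that("masked affine forward matches hand calculations", {
  mask <- connectivity_mask(c("a", "b"), "o", c(1L, 2L), c(1L, 1L))
  out <- masked_affine_forward(matrix(c(3, 4), 1), c(1, 1), 0, mask, "linear")
  expect_equal(as.numeric(out), 7)
  # relu clamps negatives to zero
  m3 <- connectivity_mask("x", paste0("o", 1:3), rep(1L, 3), 1:3)
  out3 <- masked_affine_forward(matrix(1), c(-2, 0, 5), c(0, 0, 0), m3, "relu")
  expect_equal(as.numeric(out3), c(0, 0, 5))
  expect_error(masked_affine_forward(matrix(1, 1, 3), c(1, 1), 0, mask), "3 columns")
  expect_error(masked_affine_forward(matrix(NA_real_, 1, 2), c(1, 1), 0, mask),
               "missing")
})

test_that("masked forward equals a dense matrix with explicit zeros", {
  for (seed in 1:10) {
    set.seed(seed)
    n_in <- sample(2:20, 1); n_out <- sample(1:20, 1); n <- 5
    mask <- random_mask(n_in, n_out, density = 0.4, seed = seed)
    w <- stats::rnorm(n_edges(mask))
    b <- stats::rnorm(n_out)
    x <- matrix(stats::rnorm(n * n_in), n)
    dense <- matrix(0, n_in, n_out)
    dense[cbind(mask$in_idx, mask$out_idx)] <- w
    for (act in c("linear", "relu", "tanh", "sigmoid")) {
      got <- masked_affine_forward(x, w, b, mask, act)
      want <- act_forward(sweep(x %*% dense, 2, b, `+`), act)
      expect_equal(unname(got), unname(want), tolerance = 1e-6)
    }
  }
})

test_that("arctanh activation is clipped, odd, and monotone", {
  expect_equal(arctanh_activation(0), 0)
  expect_equal(arctanh_activation(0.5), atanh(0.5))
  expect_equal(arctanh_activation(0.5), 0.5493, tolerance = 1e-4)
  # out-of-domain input is clipped to a finite value
  expect_equal(arctanh_activation(1.7), atanh(1 - 1e-5))
  expect_true(is.finite(arctanh_activation(100)))
  expect_equal(arctanh_activation(-0.3), -arctanh_activation(0.3))
  z <- seq(-0.99, 0.99, length.out = 50)
  expect_true(all(diff(arctanh_activation(z)) > 0))
})

test_that("expression-only network is a single all-to-output layer", {
  spec <- build_ge_network(paste0("G", 1:10), "classification")
  expect_length(spec$layers, 1)
  expect_equal(n_edges(spec$layers[[1]]$mask), 10L)
  expect_equal(spec$layers[[1]]$activation, "sigmoid")
  reg <- build_ge_network(paste0("G", 1:10), "regression")
  expect_equal(reg$layers[[1]]$activation, "relu")
})

test_that("methylation network chains CpGs -> genes -> output", {
  spec <- build_me_network(tiny_gene_mask(), "classification")
  dims <- vapply(spec$layers, function(l) length(layer_out_ids(l)), 0L)
  expect_equal(unname(dims), c(3L, 1L))
  expect_equal(length(spec$input_blocks$me), 6L)
  # total edges: one per CpG plus one per gene
  expect_equal(sum(vapply(spec$layers, function(l) n_edges(l$mask), 0L)), 6L + 3L)
  # the inverse-tanh formulation is available as an option
  spec2 <- build_me_network(tiny_gene_mask(), "classification", hidden = "arctanh")
  expect_equal(spec2$layers[[1]]$activation, "arctanh")
  reg <- build_me_network(tiny_gene_mask(), "regression")
  expect_equal(vapply(reg$layers, `[[`, "", "activation"), c("relu", "relu"))
})

test_that("combined network has one tagged edge pair per gene", {
  spec <- build_me_ge_network(tiny_gene_mask(), paste0("G", 1:3), "classification")
  gene_layer <- spec$layers[[2]]
  expect_equal(gene_layer$name, "gene")
  deg <- tabulate(gene_layer$mask$out_idx, 3)
  expect_true(all(deg == 2))
  expect_equal(sort(unique(gene_layer$mask$tags)), c("ge", "me"))
  expect_equal(sum(gene_layer$mask$tags == "me"), 3L)
  expect_equal(sum(gene_layer$mask$tags == "ge"), 3L)
  # trainable weights: n_cpgs + 2*n_genes + n_genes
  n_w <- sum(vapply(spec$layers, function(l) n_edges(l$mask), 0L))
  expect_equal(n_w, 6L + 2L * 3L + 3L)
  # gene order must match the mask
  expect_error(build_me_ge_network(tiny_gene_mask(), c("G1", "G2"), "classification"),
               "gene_order")
})

test_that("pathway network stacks 321/44/6 layers and skip edges", {
  genes <- paste0("G", sprintf("%04d", 1:800))
  set.seed(1)
  map <- list(pairs = stats::setNames(sample(genes, 2400, replace = TRUE),
                                      paste0("cg", 1:2400)))
  covered <- intersect_gene_sets(unique(map$pairs), genes)
  gm <- build_gene_mask(map, covered, names(map$pairs))
  base <- build_me_ge_network(gm, covered, "classification")
  h <- make_pathway_hierarchy(covered, 321, 44, 6, annotated_frac = 0.55, seed = 4)
  pm <- build_pathway_masks(h, covered)
  spec <- build_pathway_network(base, pm)
  nm <- vapply(spec$layers, `[[`, "", "name")
  dims <- vapply(spec$layers, function(l) length(layer_out_ids(l)), 0L)
  expect_equal(dims[match(c("pw_local", "pw_mid", "pw_global", "output"), nm)],
               c(321L, 44L, 6L, 1L))
  # output in-degree = global pathways + unannotated genes
  out_mask <- spec$layers[[length(spec$layers)]]$mask
  expect_equal(n_edges(out_mask), 6L + length(pm$skip_genes))
})

test_that("pathway network with no annotated genes degenerates to the base", {
  genes <- paste0("G", 1:4)
  gm <- connectivity_mask(paste0("cg", 1:4), genes, 1:4, 1:4, tags = rep("me", 4))
  base <- build_me_ge_network(gm, genes, "classification")
  pm <- suppressWarnings(tryCatch(
    build_pathway_masks(list(membership = list(), parent = character()), genes),
    error = function(e) NULL
  ))
  # empty membership is a configuration error from the mask builder;
  # the network-level degenerate path is all-skip
  h <- list(membership = list(G1 = "p1"), parent = c(p1 = "m1", m1 = "t1"))
  pm2 <- build_pathway_masks(h, genes)
  spec <- build_pathway_network(base, pm2)
  out_mask <- spec$layers[[length(spec$layers)]]$mask
  expect_equal(n_edges(out_mask), 1L + 3L)  # 1 global + 3 skip genes
})

test_that("dense comparison network mirrors the pathway widths", {
  genes <- paste0("G", 1:50)
  gm <- connectivity_mask(paste0("cg", 1:50), genes, 1:50, 1:50, tags = rep("me", 50))
  base <- build_me_ge_network(gm, genes, "classification")
  spec <- build_dense_equivalent(base, dims = c(321L, 44L, 6L))
  nm <- vapply(spec$layers, `[[`, "", "name")
  dense <- spec$layers[nm %in% c("dense1", "dense2", "dense3")]
  expect_equal(vapply(dense, `[[`, 0L, "width"), c(321L, 44L, 6L))
  # dense parameter count: n_genes*321 + 321*44 + 44*6 + 6
  n_par <- sum(vapply(dense, function(l) length(l$in_ids) * l$width, 0L)) +
    n_edges(spec$layers[[length(spec$layers)]]$mask)
  expect_equal(n_par, 50L * 321L + 321L * 44L + 44L * 6L + 6L)
})

test_that("pathway net with complete bipartite masks predicts like its dense twin", {
  genes <- paste0("G", 1:6)
  gm <- connectivity_mask(paste0("cg", 1:6), genes, 1:6, 1:6, tags = rep("me", 6))
  base <- build_me_ge_network(gm, genes, "classification")
  # complete-bipartite "pathway" masks with the dense twin's widths
  mk_complete <- function(ins, outs) {
    connectivity_mask(ins, outs,
                      rep(seq_along(ins), times = length(outs)),
                      rep(seq_along(outs), each = length(ins)))
  }
  dims <- c(4L, 3L, 2L)
  pm <- list(
    gene_local = mk_complete(genes, paste0("u", 1:4)),
    local_mid = mk_complete(paste0("u", 1:4), paste0("v", 1:3)),
    mid_global = mk_complete(paste0("v", 1:3), paste0("w", 1:2)),
    skip = connectivity_mask(character(), "y", integer(), integer()[0]),
    annotated_genes = genes, skip_genes = character()
  )
  # skip mask with zero edges is invalid at assembly; the all-annotated case
  # wires output solely from the global layer
  pw <- build_pathway_network(base, pm)
  dn <- build_dense_equivalent(base, dims = dims)
  # same neuron counts -> weights can be mapped 1:1; copy weights across
  st <- init_model(pw, seed = 8)
  std <- init_model(dn, seed = 8)
  for (k in seq_along(pw$layers)) {
    lp <- pw$layers[[k]]
    if (lp$kind != "masked") next
    kd <- dn$layers[[k]]
    if (!is.null(kd) && kd$kind == "dense") {
      W <- matrix(0, length(lp$mask$in_ids), length(lp$mask$out_ids))
      W[cbind(lp$mask$in_idx, lp$mask$out_idx)] <- st$layers[[k]]$W
      std$layers[[k]]$W <- W
      std$layers[[k]]$b <- st$layers[[k]]$b
    } else {
      std$layers[[k]]$W <- st$layers[[k]]$W
      std$layers[[k]]$b <- st$layers[[k]]$b
    }
  }
  set.seed(9)
  inputs <- list(
    me = matrix(runif(5 * 6), 5, 6, dimnames = list(NULL, paste0("cg", 1:6))),
    ge = matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, genes))
  )
  expect_equal(predict_vnn(st, pw, inputs), predict_vnn(std, dn, inputs),
               tolerance = 1e-12)
})

test_that("covariates wire into the output node or into every gene node", {
  spec <- build_me_ge_network(tiny_gene_mask(), paste0("G", 1:3), "classification")
  last <- add_covariates(spec, c("sex", "age"), "last_layer")
  out_mask <- last$layers[[length(last$layers)]]$mask
  expect_equal(n_edges(out_mask), 3L + 2L)
  expect_equal(sum(out_mask$tags == "covariate", na.rm = TRUE), 2L)
  per <- add_covariates(spec, "sex", "per_gene")
  gl <- per$layers[[2]]$mask
  expect_equal(n_edges(gl), 6L + 3L)  # 2 omic edges + 1 covariate edge per gene
  expect_equal(sum(gl$tags == "covariate"), 3L)
  per2 <- add_covariates(spec, c("sex", "age"), "per_gene")
  expect_equal(sum(per2$layers[[2]]$mask$tags == "covariate"), 2L * 3L)
})

test_that("locally connected baseline windows the concatenated input", {
  ids <- paste0("f", 1:100)
  spec <- build_locally_connected_baseline(ids, window = 10, stride = 10,
                                           dense_dims = c(8L, 4L),
                                           task = "classification")
  lc <- spec$layers[[1]]
  expect_length(layer_out_ids(lc), 10L)
  expect_equal(n_edges(lc$mask), 10L * 10L)
  # degenerate window covering everything collapses to one unit
  one <- build_locally_connected_baseline(ids, window = 100, stride = 100,
                                          dense_dims = c(4L), task = "regression")
  expect_length(layer_out_ids(one$layers[[1]]), 1L)
  expect_error(build_locally_connected_baseline(ids, 0, 1, task = "regression"),
               "window")
})

test_that("output bias initializes to the training outcome mean", {
  spec <- build_ge_network(paste0("G", 1:4), "regression")
  st <- init_model(spec, seed = 1)
  expect_equal(init_output_bias(st, c(2, 4, 6))$layers[[1]]$b, 4)
  expect_equal(init_output_bias(st, rep(3.3, 10))$layers[[1]]$b, 3.3)
  set.seed(1); y <- rnorm(100)
  expect_equal(init_output_bias(st, y)$layers[[1]]$b, mean(y))
})

test_that("task constrains the output range", {
  sim <- simulate_classification(sim_config(n_cohorts = 2, n_per_cohort = 30,
                                            n_genes = 10, n_causal = 2,
                                            sex_block_size = 2, seed = 3))
  ds <- sim$dataset
  map <- map_cpgs_to_genes(sim$annotations$cpgs, sim$annotations$genes)
  go <- intersect_gene_sets(unique(map$pairs), colnames(ds$ge))
  gm <- build_gene_mask(map, go, colnames(ds$me))
  inputs <- prepare_inputs(ds, seq_len(30))[c("me", "ge")]
  cls <- build_me_ge_network(gm, go, "classification")
  p <- predict_vnn(init_model(cls, 1), cls, inputs)
  expect_true(all(p > 0 & p < 1))
  reg <- build_me_ge_network(gm, go, "regression")
  pr <- predict_vnn(init_model(reg, 1), reg, inputs)
  expect_true(all(pr >= 0))
})

test_that("weights off any output path leave predictions unchanged", {
  # gene G3's expression edge is zeroed at the combined layer; the CpG
  # weights feeding G3's methylation node upstream of a zeroed combined
  # edge then cannot influence the output
  fx <- tiny_me_ge_model()
  spec <- fx$spec; st <- fx$state
  gl <- spec$layers[[2]]$mask
  me_edge_g3 <- which(gl$tags == "me" & gl$out_idx == 3L)
  st$layers[[2]]$W[me_edge_g3] <- 0
  set.seed(4)
  inputs <- list(
    me = matrix(runif(8 * 6), 8, 6, dimnames = list(NULL, paste0("cg", 1:6))),
    ge = matrix(rnorm(8 * 3), 8, 3, dimnames = list(NULL, paste0("G", 1:3)))
  )
  p0 <- predict_vnn(st, spec, inputs)
  # perturb the now-disconnected CpG weights (CpGs 5,6 feed gene 3)
  st2 <- st
  cpg_edges_g3 <- which(spec$layers[[1]]$mask$out_idx == 3L)
  st2$layers[[1]]$W[cpg_edges_g3] <- st2$layers[[1]]$W[cpg_edges_g3] + 5
  expect_equal(predict_vnn(st2, spec, inputs), p0, tolerance = 1e-12)
})
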