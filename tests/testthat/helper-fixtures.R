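# Shared fixtures and independent oracles for the test suite.

# A small CpG->gene mask: 6 CpGs over 3 genes (2 each).
tiny_gene_mask <- function() {
  connectivity_mask(
    in_ids = paste0("cg", 1:6), out_ids = paste0("G", 1:3),
    in_idx = 1:6, out_idx = c(1, 1, 2, 2, 3, 3),
    tags = rep("me", 6)
  )
}

# Random sparse mask with every output unit connected: one guaranteed edge
# per output, plus random extras at the requested density.
random_mask <- function(n_in, n_out, density = 0.3, seed = 1) {
  set.seed(seed)
  base <- cbind(sample.int(n_in, n_out, replace = TRUE), seq_len(n_out))
  extra_sel <- which(stats::runif(n_in * n_out) < density)
  extra <- cbind(((extra_sel - 1L) %% n_in) + 1L,
                 ((extra_sel - 1L) %/% n_in) + 1L)
  edges <- unique(rbind(base, extra))
  connectivity_mask(paste0("i", seq_len(n_in)), paste0("o", seq_len(n_out)),
                    edges[, 1], edges[, 2])
}

# Random feed-forward network over a couple of masked layers, ending in one
# output unit; returns spec + state with random weights.
random_dag_network <- function(widths, density = 0.5, seed = 1,
                               task = "regression") {
  set.seed(seed)
  layers <- list()
  prev_block <- "in"
  prev_ids <- paste0("f", seq_len(widths[1]))
  for (k in seq_along(widths)[-1]) {
    m <- random_mask(widths[k - 1], widths[k], density, seed = seed + 17 * k)
    mask <- connectivity_mask(
      paste0(prev_block, ":", prev_ids), paste0("n", seq_len(widths[k])),
      m$in_idx, m$out_idx
    )
    nm <- paste0("L", k - 1)
    layers[[nm]] <- new_masked_layer(nm, mask, "linear")
    prev_block <- nm
    prev_ids <- mask$out_ids
  }
  out_mask <- connectivity_mask(
    paste0(prev_block, ":", prev_ids), "y",
    seq_along(prev_ids), rep(1L, length(prev_ids))
  )
  layers[["output"]] <- new_masked_layer("output", out_mask, "relu")
  spec <- new_network_spec(unname(layers), task,
                           input_blocks = list(`in` = paste0("f", seq_len(widths[1]))))
  state <- init_model(spec, seed = seed)
  for (k in seq_along(state$layers)) {
    state$layers[[k]]$W <- stats::rnorm(length(state$layers[[k]]$W))
  }
  list(spec = spec, state = state)
}

# Brute-force path enumeration oracle: raw contribution of every input =
# sum over all input->output paths of the product of |w|; also returns the
# raw mass per node. Independent of the package's DP implementation.
enumerate_path_products <- function(spec, state) {
  # collect the full edge list over global node ids
  edges <- list()
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    if (layer$kind == "masked") {
      m <- layer$mask
      from <- m$in_ids[m$in_idx]
      to <- paste0(layer$name, ":", m$out_ids[m$out_idx])
      w <- abs(state$layers[[k]]$W)
    } else {
      from <- rep(layer$in_ids, times = layer$width)
      to <- paste0(layer$name, ":", rep(layer$out_ids, each = length(layer$in_ids)))
      w <- abs(as.vector(state$layers[[k]]$W))
    }
    edges[[k]] <- data.frame(from = from, to = to, w = w,
                             stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edges)
  out_node <- paste0(spec$layers[[length(spec$layers)]]$name, ":",
                     layer_out_ids(spec$layers[[length(spec$layers)]]))
  inputs <- unlist(lapply(names(spec$input_blocks), function(b) {
    paste0(b, ":", spec$input_blocks[[b]])
  }))
  node_mass <- new.env()
  input_mass <- stats::setNames(numeric(length(inputs)), inputs)
  walk <- function(node, prod) {
    prev <- get0(node, envir = node_mass, ifnotfound = 0)
    assign(node, prev + prod, envir = node_mass)
    if (node %in% inputs) {
      input_mass[node] <<- input_mass[node] + prod
      return(invisible())
    }
    back <- ed[ed$to == node, , drop = FALSE]
    for (i in seq_len(nrow(back))) {
      walk(back$from[i], prod * back$w[i])
    }
  }
  walk(out_node, 1)
  nodes <- ls(node_mass)
  list(
    input_raw = input_mass,
    node_raw = stats::setNames(vapply(nodes, function(n) get(n, node_mass), 0), nodes)
  )
}

# Rank-statistic AUC (Mann-Whitney), independent of pROC.
rank_auc <- function(y, score) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Tiny fully-specified ME+GE model with hand-set weights, used by the
# interpretation examples. Weight layout per layer follows canonical mask
# edge order (by output, then input).
tiny_me_ge_model <- function(task = "classification") {
  gm <- tiny_gene_mask()
  spec <- build_me_ge_network(gm, paste0("G", 1:3), task = task)
  state <- init_model(spec, seed = 1)
  state
  list(spec = spec, state = state)
}
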