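# Network specification: ordered masked/dense layers over named node ids.
# Node ids are global strings "<source>:<unit>", where <source> is either an
# input block ("me", "ge", "cov", "x") or the name of an earlier layer.

VNN_ACTIVATIONS <- c("arctanh", "tanh", "relu", "sigmoid", "linear")

#' Clipped inverse hyperbolic tangent activation
#'
#' `atanh` has domain (-1, 1) but network pre-activations are unbounded,
#' so inputs are clipped to `(-1 + eps, 1 - eps)` before the transform.
#' The result is always finite; the function is odd and monotone on the
#' unclipped range.
#'
#' @param z numeric vector/matrix of pre-activations.
#' @param eps clipping margin (default 1e-5).
#' @return `atanh(clip(z))`, same shape as `z`.
#' @export
arctanh_activation <- function(z, eps = 1e-5) {
  atanh(pmin(pmax(z, -1 + eps), 1 - eps))
}

act_forward <- function(z, activation, eps = 1e-5) {
  switch(activation,
    arctanh = arctanh_activation(z, eps),
    tanh = tanh(z),
    relu = pmax(z, 0),
    sigmoid = stats::plogis(z),
    linear = z,
    stop("unknown activation: ", activation)
  )
}

# derivative wrt pre-activation z; `a` is the stored forward output.
# arctanh's true derivative 1/(1-z^2) is unbounded near +-1 and zero outside
# the clipped domain; both break optimization (exploding then dead units).
# Training uses a capped pseudo-derivative: min(1/(1-z^2), cap) inside the
# domain and cap outside, so saturated units keep a finite, bounded gradient.
act_grad <- function(z, a, activation, eps = 1e-5, cap = 10) {
  switch(activation,
    arctanh = ifelse(abs(z) < 1, pmin(1 / (1 - z^2), cap), cap),
    tanh = 1 - a^2,
    relu = (z > 0) * 1,
    sigmoid = a * (1 - a),
    linear = array(1, dim = dim(z) %||% length(z)),
    stop("unknown activation: ", activation)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default hidden activation: tanh for classification (bounded, trainable;
# the clipped arctanh form is available as an option but saturates and dies
# at realistic scales), relu for regression (relu for all layers there).
hidden_activation <- function(task, hidden = NULL) {
  if (!is.null(hidden)) {
    if (!hidden %in% VNN_ACTIVATIONS) stop("unknown activation: ", hidden)
    return(hidden)
  }
  if (task == "classification") "tanh" else "relu"
}
output_activation <- function(task) if (task == "classification") "sigmoid" else "relu"

new_masked_layer <- function(name, mask, activation, l1 = FALSE) {
  stopifnot(inherits(mask, "connectivity_mask"))
  if (!activation %in% VNN_ACTIVATIONS) stop("unknown activation: ", activation)
  list(name = name, kind = "masked", mask = mask, activation = activation, l1 = l1)
}

new_dense_layer <- function(name, in_ids, width, activation, l1 = FALSE) {
  if (!activation %in% VNN_ACTIVATIONS) stop("unknown activation: ", activation)
  list(
    name = name, kind = "dense", in_ids = as.character(in_ids),
    width = as.integer(width),
    out_ids = paste0("u", seq_len(width)),
    activation = activation, l1 = l1
  )
}

layer_out_ids <- function(layer) {
  if (layer$kind == "masked") layer$mask$out_ids else layer$out_ids
}

layer_in_ids <- function(layer) {
  if (layer$kind == "masked") layer$mask$in_ids else layer$in_ids
}

new_network_spec <- function(layers, task, input_blocks, gene_layer = NULL,
                             gene_order = NULL) {
  task <- match.arg(task, c("classification", "regression"))
  spec <- structure(
    list(
      layers = layers, task = task, input_blocks = input_blocks,
      gene_layer = gene_layer, gene_order = gene_order
    ),
    class = "network_spec"
  )
  validate_network_spec(spec)
  spec
}

#' Validate a network specification
#'
#' Checks that every layer input resolves to an input-block feature or an
#' earlier layer's output, that every layer output has at least one
#' incoming edge, that the network ends in exactly one output unit, and
#' that the output activation matches the task (sigmoid for
#' classification, relu for regression).
#'
#' @param spec a `network_spec`.
#' @return `spec`, invisibly; errors describe the offending layer.
#' @export
validate_network_spec <- function(spec) {
  known <- unlist(lapply(names(spec$input_blocks), function(b) {
    paste0(b, ":", spec$input_blocks[[b]])
  }))
  for (layer in spec$layers) {
    ins <- layer_in_ids(layer)
    missing <- setdiff(ins, known)
    if (length(missing)) {
      stop(sprintf("layer '%s': unresolved input unit '%s'", layer$name, missing[1]))
    }
    if (layer$kind == "masked") {
      deg <- tabulate(layer$mask$out_idx, nbins = length(layer$mask$out_ids))
      if (any(deg == 0)) {
        stop(sprintf("layer '%s': output unit '%s' has no incoming edge",
                     layer$name, layer$mask$out_ids[which(deg == 0)[1]]))
      }
    }
    known <- c(known, paste0(layer$name, ":", layer_out_ids(layer)))
  }
  last <- spec$layers[[length(spec$layers)]]
  if (length(layer_out_ids(last)) != 1L) {
    stop("network must end in exactly one output unit")
  }
  expected <- output_activation(spec$task)
  if (last$activation != expected) {
    stop(sprintf("%s networks must end in a %s output", spec$task, expected))
  }
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec (%s), %d layer(s):\n", x$task, length(x$layers)))
  for (l in x$layers) {
    np <- if (l$kind == "masked") n_edges(l$mask) else length(l$in_ids) * l$width
    cat(sprintf("  %-12s %-6s %5d -> %5d  %-8s %d weights%s\n",
                l$name, l$kind, length(layer_in_ids(l)), length(layer_out_ids(l)),
                l$activation, np, if (isTRUE(l$l1)) "  [L1]" else ""))
  }
  invisible(x)
}

complete_mask <- function(in_ids, out_ids, tags = NULL) {
  n_in <- length(in_ids); n_out <- length(out_ids)
  connectivity_mask(
    in_ids, out_ids,
    in_idx = rep(seq_len(n_in), times = n_out),
    out_idx = rep(seq_len(n_out), each = n_in),
    tags = if (is.null(tags)) NULL else rep(tags, length.out = n_in * n_out)
  )
}

#' Gene-expression-only network
#'
#' The simplest visible network: every gene's expression value is wired
#' straight to the output node, as in a LASSO regression.
#'
#' @param gene_order character vector of gene ids (canonical order).
#' @param task `"classification"` or `"regression"`.
#' @return a `network_spec`.
#' @export
build_ge_network <- function(gene_order, task = c("classification", "regression")) {
  task <- match.arg(task)
  gene_order <- as.character(gene_order)
  out_mask <- complete_mask(paste0("ge:", gene_order), "y", tags = "ge")
  new_network_spec(
    layers = list(new_masked_layer("output", out_mask, output_activation(task), l1 = TRUE)),
    task = task,
    input_blocks = list(ge = gene_order),
    gene_order = gene_order
  )
}

#' Methylation-only network
#'
#' CpG inputs are grouped into one node per gene using the CpG-to-gene
#' mask; gene nodes connect to the output node.
#'
#' @param gene_mask `connectivity_mask` from [build_gene_mask()]
#'   (CpGs -> genes).
#' @param task `"classification"` or `"regression"`.
#' @param hidden optional hidden activation override (default tanh for
#'   classification, relu for regression; `"arctanh"` selects the
#'   clipped inverse-tanh form).
#' @return a `network_spec`.
#' @export
build_me_network <- function(gene_mask, task = c("classification", "regression"),
                             hidden = NULL) {
  task <- match.arg(task)
  genes <- gene_mask$out_ids
  me_mask <- connectivity_mask(
    paste0("me:", gene_mask$in_ids), genes,
    gene_mask$in_idx, gene_mask$out_idx, tags = gene_mask$tags
  )
  out_mask <- complete_mask(paste0("gene_me:", genes), "y")
  new_network_spec(
    layers = list(
      new_masked_layer("gene_me", me_mask, hidden_activation(task, hidden), l1 = TRUE),
      new_masked_layer("output", out_mask, output_activation(task))
    ),
    task = task,
    input_blocks = list(me = gene_mask$in_ids),
    gene_layer = "gene_me",
    gene_order = genes
  )
}

#' Combined methylation + expression network
#'
#' CpGs are reduced to one methylation node per gene; each gene then has
#' a combined node that merges its methylation node and its expression
#' input (one scalar edge per omic, tagged `"me"` / `"ge"`); combined
#' gene nodes connect to the output node. The gene order must be the
#' omics intersection: every gene needs both a methylation route and an
#' expression input.
#'
#' @param gene_mask `connectivity_mask` from [build_gene_mask()], whose
#'   `out_ids` equal `gene_order`.
#' @param gene_order character vector of shared genes (canonical order).
#' @param task `"classification"` or `"regression"`.
#' @param hidden optional hidden activation override (see
#'   [build_me_network()]).
#' @param l1_layers which layers the L1 penalty targets: `"gene"` (the
#'   combined gene layer, default), `"gene_me"` (the CpG aggregation
#'   layer), or both. Sparsifying the merge edges performs gene
#'   selection; penalizing the aggregation layer as well also shrinks
#'   the methylation representation itself.
#' @return a `network_spec` with `gene_layer = "gene"`.
#' @export
build_me_ge_network <- function(gene_mask, gene_order,
                                task = c("classification", "regression"),
                                hidden = NULL, l1_layers = "gene") {
  task <- match.arg(task)
  if (!all(l1_layers %in% c("gene", "gene_me"))) {
    stop("l1_layers must be a subset of c(\"gene\", \"gene_me\")")
  }
  gene_order <- as.character(gene_order)
  if (!identical(gene_mask$out_ids, gene_order)) {
    stop("gene_mask out_ids must equal gene_order (use the intersected gene set)")
  }
  n_g <- length(gene_order)
  me_mask <- connectivity_mask(
    paste0("me:", gene_mask$in_ids), gene_order,
    gene_mask$in_idx, gene_mask$out_idx, tags = gene_mask$tags
  )
  combined <- connectivity_mask(
    in_ids = c(paste0("gene_me:", gene_order), paste0("ge:", gene_order)),
    out_ids = gene_order,
    in_idx = c(seq_len(n_g), n_g + seq_len(n_g)),
    out_idx = c(seq_len(n_g), seq_len(n_g)),
    tags = c(rep("me", n_g), rep("ge", n_g))
  )
  out_mask <- complete_mask(paste0("gene:", gene_order), "y")
  new_network_spec(
    layers = list(
      new_masked_layer("gene_me", me_mask, hidden_activation(task, hidden),
                       l1 = "gene_me" %in% l1_layers),
      new_masked_layer("gene", combined, hidden_activation(task, hidden),
                       l1 = "gene" %in% l1_layers),
      new_masked_layer("output", out_mask, output_activation(task))
    ),
    task = task,
    input_blocks = list(me = gene_mask$in_ids, ge = gene_order),
    gene_layer = "gene",
    gene_order = gene_order
  )
}

#' Add a pathway hierarchy on top of a combined network
#'
#' Replaces the direct gene-to-output wiring of a combined (ME+GE)
#' network with three pathway layers (local, mid, global). Genes without
#' any pathway annotation keep a skip connection straight to the output
#' node, so the output receives the global pathway nodes plus one edge
#' per unannotated gene.
#'
#' @param me_ge_spec `network_spec` from [build_me_ge_network()].
#' @param pathway_masks list from [build_pathway_masks()].
#' @return a `network_spec` with layers `pw_local`, `pw_mid`, `pw_global`.
#' @export
build_pathway_network <- function(me_ge_spec, pathway_masks) {
  pm <- pathway_masks
  task <- me_ge_spec$task
  gene_layer <- me_ge_spec$gene_layer
  base <- me_ge_spec$layers[seq_len(length(me_ge_spec$layers) - 1L)]
  if (length(pm$annotated_genes) == 0) {
    return(me_ge_spec)  # no pathway routes: topology degenerates to the base
  }
  hact <- me_ge_spec$layers[[1]]$activation
  gl <- pm$gene_local
  gene_local <- connectivity_mask(
    paste0(gene_layer, ":", gl$in_ids), gl$out_ids, gl$in_idx, gl$out_idx
  )
  lm <- pm$local_mid
  local_mid <- connectivity_mask(
    paste0("pw_local:", lm$in_ids), lm$out_ids, lm$in_idx, lm$out_idx
  )
  mg <- pm$mid_global
  mid_global <- connectivity_mask(
    paste0("pw_mid:", mg$in_ids), mg$out_ids, mg$in_idx, mg$out_idx
  )
  out_in <- c(paste0("pw_global:", mg$out_ids),
              if (length(pm$skip_genes)) paste0(gene_layer, ":", pm$skip_genes))
  out_mask <- connectivity_mask(
    out_in, "y", seq_along(out_in), rep(1L, length(out_in)),
    tags = c(rep("pathway", length(mg$out_ids)), rep("skip", length(pm$skip_genes)))
  )
  new_network_spec(
    layers = c(base, list(
      new_masked_layer("pw_local", gene_local, hact),
      new_masked_layer("pw_mid", local_mid, hact),
      new_masked_layer("pw_global", mid_global, hact),
      new_masked_layer("output", out_mask, output_activation(task))
    )),
    task = task,
    input_blocks = me_ge_spec$input_blocks,
    gene_layer = gene_layer,
    gene_order = me_ge_spec$gene_order
  )
}

#' Dense comparison network with the pathway layer widths
#'
#' Same neuron counts as the pathway network (default 321/44/6) but fully
#' connected between the gene layer and the output, carrying no prior
#' knowledge.
#'
#' @param me_ge_spec `network_spec` from [build_me_ge_network()].
#' @param dims integer widths of the dense layers (default
#'   `c(321, 44, 6)`).
#' @return a `network_spec`.
#' @export
build_dense_equivalent <- function(me_ge_spec, dims = c(321L, 44L, 6L)) {
  task <- me_ge_spec$task
  gene_layer <- me_ge_spec$gene_layer
  base <- me_ge_spec$layers[seq_len(length(me_ge_spec$layers) - 1L)]
  hact <- me_ge_spec$layers[[1]]$activation
  prev_ids <- paste0(gene_layer, ":", me_ge_spec$gene_order)
  dense <- list()
  for (k in seq_along(dims)) {
    nm <- paste0("dense", k)
    dense[[k]] <- new_dense_layer(nm, prev_ids, dims[k], hact)
    prev_ids <- paste0(nm, ":", dense[[k]]$out_ids)
  }
  out_mask <- complete_mask(prev_ids, "y")
  new_network_spec(
    layers = c(base, dense, list(
      new_masked_layer("output", out_mask, output_activation(task))
    )),
    task = task,
    input_blocks = me_ge_spec$input_blocks,
    gene_layer = gene_layer,
    gene_order = me_ge_spec$gene_order
  )
}

extend_masked_layer <- function(layer, extra_in_ids, extra_in_idx, extra_out_idx,
                                extra_tags) {
  m <- layer$mask
  tags_old <- m$tags %||% rep(NA_character_, n_edges(m))
  mask <- connectivity_mask(
    in_ids = c(m$in_ids, extra_in_ids),
    out_ids = m$out_ids,
    in_idx = c(m$in_idx, length(m$in_ids) + extra_in_idx),
    out_idx = c(m$out_idx, extra_out_idx),
    tags = c(tags_old, extra_tags)
  )
  layer$mask <- mask
  layer
}

#' Add covariates to a network
#'
#' Either wires covariates straight into the output node
#' (`mode = "last_layer"`) or feeds every covariate into every combined
#' gene node (`mode = "per_gene"`), exposing gene-specific covariate
#' weights. Covariate edges are tagged `"covariate"`.
#'
#' @param spec a `network_spec`.
#' @param covariate_ids character vector of covariate names.
#' @param mode `"last_layer"` or `"per_gene"`.
#' @return a `network_spec` with an additional `cov` input block.
#' @export
add_covariates <- function(spec, covariate_ids, mode = c("last_layer", "per_gene")) {
  mode <- match.arg(mode)
  covariate_ids <- as.character(covariate_ids)
  n_c <- length(covariate_ids)
  if (n_c == 0) stop("covariate_ids is empty")
  if (!is.null(spec$input_blocks$cov)) stop("network already has covariates")
  layers <- spec$layers
  cov_ids <- paste0("cov:", covariate_ids)
  if (mode == "last_layer") {
    k <- length(layers)
    layers[[k]] <- extend_masked_layer(
      layers[[k]], cov_ids, seq_len(n_c), rep(1L, n_c),
      rep("covariate", n_c)
    )
  } else {
    if (is.null(spec$gene_layer)) stop("per_gene covariates need a gene layer")
    k <- which(vapply(layers, function(l) l$name, "") == spec$gene_layer)
    n_g <- length(layer_out_ids(layers[[k]]))
    layers[[k]] <- extend_masked_layer(
      layers[[k]], cov_ids,
      rep(seq_len(n_c), each = n_g),
      rep(seq_len(n_g), times = n_c),
      rep("covariate", n_c * n_g)
    )
  }
  new_network_spec(
    layers = layers, task = spec$task,
    input_blocks = c(spec$input_blocks, list(cov = covariate_ids)),
    gene_layer = spec$gene_layer, gene_order = spec$gene_order
  )
}

#' Locally connected baseline network
#'
#' A conventional comparison network: an unshared-weight 1D locally
#' connected layer slides a window over the concatenated input features,
#' followed by dense layers and the output node. Carries no biological
#' annotation.
#'
#' @param input_ids character vector of concatenated feature names
#'   (methylation then expression, in input order).
#' @param window window length in features.
#' @param stride step between windows.
#' @param dense_dims widths of the following dense layers (default
#'   `c(64, 16)`).
#' @param task `"classification"` or `"regression"`.
#' @param hidden optional hidden activation override (see
#'   [build_me_network()]).
#' @return a `network_spec`.
#' @export
build_locally_connected_baseline <- function(input_ids, window, stride,
                                             dense_dims = c(64L, 16L),
                                             task = c("classification", "regression"),
                                             hidden = NULL) {
  task <- match.arg(task)
  input_ids <- as.character(input_ids)
  n <- length(input_ids)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 1 || window > n) stop("window must be in [1, n_inputs]")
  if (stride < 1) stop("stride must be >= 1")
  n_win <- (n - window) %/% stride + 1L
  starts <- (seq_len(n_win) - 1L) * stride + 1L
  in_idx <- as.integer(outer(seq_len(window) - 1L, starts, `+`))
  out_idx <- rep(seq_len(n_win), each = window)
  lc_mask <- connectivity_mask(
    paste0("x:", input_ids), paste0("w", seq_len(n_win)), in_idx, out_idx
  )
  hact <- hidden_activation(task, hidden)
  layers <- list(new_masked_layer("lc", lc_mask, hact))
  prev_ids <- paste0("lc:", lc_mask$out_ids)
  for (k in seq_along(dense_dims)) {
    nm <- paste0("dense", k)
    layers <- c(layers, list(new_dense_layer(nm, prev_ids, dense_dims[k], hact)))
    prev_ids <- paste0(nm, ":u", seq_len(dense_dims[k]))
  }
  layers <- c(layers, list(
    new_masked_layer("output", complete_mask(prev_ids, "y"), output_activation(task))
  ))
  new_network_spec(
    layers = layers, task = task,
    input_blocks = list(x = input_ids)
  )
}
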