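# Contribution scores: for every path from an input to the output, the
# product of the absolute edge weights along the path; an entity's raw score
# sums these products over all output-reaching paths through it. Computed by
# dynamic programming over the layer DAG (equivalent to explicit path
# enumeration); biases are ignored.

interpret_plans <- function(spec) {
  compile_network(spec, lapply(spec$input_blocks, identity))
}

layer_abs_matrix <- function(layer, st, plan) {
  if (layer$kind == "masked") {
    W <- plan$template
    W@x <- abs(st$W)
    W
  } else {
    abs(st$W)
  }
}

# backward accumulation: mass[output] = 1; mass flows against the edges,
# multiplied by |w|. Returns per-source vectors incl. the input blocks.
dp_backward_abs <- function(state, spec, plans) {
  mass <- list()
  for (b in names(spec$input_blocks)) {
    mass[[b]] <- stats::setNames(numeric(length(spec$input_blocks[[b]])),
                                 spec$input_blocks[[b]])
  }
  for (layer in spec$layers) {
    mass[[layer$name]] <- stats::setNames(numeric(length(layer_out_ids(layer))),
                                          layer_out_ids(layer))
  }
  last <- spec$layers[[length(spec$layers)]]$name
  mass[[last]][] <- 1
  for (k in rev(seq_along(spec$layers))) {
    layer <- spec$layers[[k]]
    mo <- mass[[layer$name]]
    if (all(mo == 0)) next
    Wabs <- layer_abs_matrix(layer, state$layers[[k]], plans[[k]])
    mi <- as.vector(Wabs %*% mo)
    for (seg in plans[[k]]$segments) {
      mass[[seg$src]][seg$cols] <- mass[[seg$src]][seg$cols] + mi[seg$dest]
    }
  }
  mass
}

# forward accumulation from per-input seed values f0 (named list per block).
dp_forward_abs <- function(state, spec, plans, f0) {
  f <- f0
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    fin <- numeric(plans[[k]]$n_in)
    for (seg in plans[[k]]$segments) {
      fin[seg$dest] <- f[[seg$src]][seg$cols]
    }
    Wabs <- layer_abs_matrix(layer, state$layers[[k]], plans[[k]])
    fout <- as.vector(Matrix::crossprod(Wabs, fin))
    f[[layer$name]] <- stats::setNames(fout, layer_out_ids(layer))
  }
  f
}

#' Input contribution scores
#'
#' For each input feature, sums the product of absolute weights over all
#' paths from that input to the output node, then normalizes so the
#' scores over all inputs sum to one. Computed by backward dynamic
#' programming; identical to explicit path enumeration.
#'
#' @param state a trained `vnn_model`.
#' @param spec the matching `network_spec`.
#' @return named numeric vector of proportions, names
#'   `"<block>:<feature>"` (e.g. `"me:cg0001"`, `"ge:G12"`).
#' @export
input_contributions <- function(state, spec) {
  plans <- interpret_plans(spec)
  mass <- dp_backward_abs(state, spec, plans)
  raw <- unlist(lapply(names(spec$input_blocks), function(b) {
    stats::setNames(mass[[b]], paste0(b, ":", names(mass[[b]])))
  }))
  total <- sum(raw)
  if (total <= 0) {
    stop("all contribution mass is zero (all-zero weights?); inspect the trained model")
  }
  raw / total
}

#' Hidden-node contribution scores within one layer
#'
#' Each input's final contribution proportion is propagated forward,
#' multiplied by the absolute weights along every path from the input to
#' the node; node scores are normalized within the layer.
#'
#' @param state a trained `vnn_model`.
#' @param spec the matching `network_spec`.
#' @param layer name of a hidden layer (e.g. the gene layer or a pathway
#'   layer).
#' @return named numeric vector of per-node proportions summing to one.
#' @export
node_contributions <- function(state, spec, layer = spec$gene_layer) {
  lname <- layer
  if (is.null(lname)) stop("no layer given and the network has no gene layer")
  if (!lname %in% vapply(spec$layers, `[[`, "", "name")) {
    stop("unknown layer: ", lname)
  }
  plans <- interpret_plans(spec)
  p <- input_contributions(state, spec)
  f0 <- lapply(names(spec$input_blocks), function(b) {
    ids <- spec$input_blocks[[b]]
    stats::setNames(unname(p[paste0(b, ":", ids)]), ids)
  })
  names(f0) <- names(spec$input_blocks)
  f <- dp_forward_abs(state, spec, plans, f0)
  v <- f[[lname]]
  total <- sum(v)
  if (total <= 0) stop("layer '", lname, "' receives zero contribution mass")
  v / total
}

#' Per-gene split of contribution mass by omic
#'
#' For each combined gene node, the path-product mass arriving over each
#' incoming edge (upstream absolute-weight path sums times the edge's
#' absolute weight) is grouped by the edge's omic tag; per gene the
#' fractions sum to one. Genes receiving zero mass get `NA` fractions
#' and are listed in the `zero_mass_genes` attribute.
#'
#' @param state a trained `vnn_model`.
#' @param spec a `network_spec` with a tagged combined gene layer.
#' @return data.frame with columns `gene` and one fraction column per
#'   omic tag (`me`, `ge`, and `covariate` if present).
#' @export
gene_omic_split <- function(state, spec) {
  lname <- spec$gene_layer
  if (is.null(lname)) stop("network has no combined gene layer")
  k <- match(lname, vapply(spec$layers, `[[`, "", "name"))
  layer <- spec$layers[[k]]
  if (layer$kind != "masked" || is.null(layer$mask$tags)) {
    stop("gene layer has no omic-tagged edges")
  }
  plans <- interpret_plans(spec)
  ones <- lapply(spec$input_blocks, function(ids) {
    stats::setNames(rep(1, length(ids)), ids)
  })
  up <- dp_forward_abs(state, spec, plans, ones)
  # upstream mass at this layer's input units
  uin <- numeric(plans[[k]]$n_in)
  for (seg in plans[[k]]$segments) {
    uin[seg$dest] <- up[[seg$src]][seg$cols]
  }
  m <- layer$mask
  edge_mass <- uin[m$in_idx] * abs(state$layers[[k]]$W)
  genes <- m$out_ids
  tags <- sort(unique(m$tags))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (tg in tags) {
    v <- numeric(length(genes))
    sel <- m$tags == tg
    agg <- tapply(edge_mass[sel], m$out_idx[sel], sum)
    v[as.integer(names(agg))] <- agg
    out[[tg]] <- v
  }
  tot <- rowSums(out[, tags, drop = FALSE])
  zero <- tot == 0
  for (tg in tags) out[[tg]] <- ifelse(zero, NA_real_, out[[tg]] / tot)
  attr(out, "zero_mass_genes") <- genes[zero]
  out
}

#' Overall contribution share per omic
#'
#' Sums the input contribution proportions over each input block,
#' answering "what fraction of the network's decision mass comes from
#' methylation vs expression (vs covariates)".
#'
#' @param state a trained `vnn_model`.
#' @param spec the matching `network_spec`.
#' @return named numeric vector (one entry per input block) summing to 1.
#' @export
omic_contributions <- function(state, spec) {
  p <- input_contributions(state, spec)
  blk <- sub(":.*$", "", names(p))
  vapply(split(p, blk), sum, 0)[names(spec$input_blocks)]
}

#' Full contribution report for one trained model
#'
#' @param state a trained `vnn_model`.
#' @param spec the matching `network_spec`.
#' @return a `contribution_report`: `input_scores`, `gene_scores` (node
#'   contributions at the gene layer, when present), `gene_omic_split`
#'   (for tagged combined layers), `omic_shares`, and metadata.
#' @export
contribution_report <- function(state, spec) {
  rep <- list(
    input_scores = input_contributions(state, spec),
    omic_shares = omic_contributions(state, spec),
    metadata = list(seed = state$meta$seed)
  )
  if (!is.null(spec$gene_layer)) {
    rep$gene_scores <- node_contributions(state, spec, spec$gene_layer)
    k <- match(spec$gene_layer, vapply(spec$layers, `[[`, "", "name"))
    if (!is.null(spec$layers[[k]]$mask$tags)) {
      rep$gene_omic_split <- gene_omic_split(state, spec)
    }
  }
  structure(rep, class = "contribution_report")
}

#' Aggregate contribution reports over replicate seeds
#'
#' @param reports list of `contribution_report`s from models trained
#'   with different random seeds.
#' @param what which score set to aggregate: `"gene_scores"` (default)
#'   or `"input_scores"`.
#' @return data.frame with columns `id`, `mean`, `sd`, sorted by
#'   decreasing mean contribution.
#' @export
aggregate_over_seeds <- function(reports, what = c("gene_scores", "input_scores")) {
  what <- match.arg(what)
  if (length(reports) == 0) stop("no reports to aggregate")
  mats <- lapply(reports, function(r) r[[what]])
  ids <- names(mats[[1]])
  if (any(!vapply(mats, function(v) identical(names(v), ids), TRUE))) {
    stop("reports have inconsistent score names")
  }
  m <- do.call(rbind, mats)
  out <- data.frame(
    id = ids,
    mean = colMeans(m),
    sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, length(ids)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$mean), ]
}

#' Principal components of gene-level activation patterns
#'
#' Runs every sample through the network, collects the post-activation
#' values of the gene-level nodes, centers them and computes the top-k
#' principal components. Clusters in this embedding expose groups of
#' individuals for which the network uses a similar activation pattern
#' (e.g. the sexes, via X-linked genes).
#'
#' @param state a trained `vnn_model`.
#' @param spec the matching `network_spec`.
#' @param inputs named list of input matrices (as in [predict_vnn()]).
#' @param k number of components (default 2).
#' @param layer layer whose activations to embed (default the gene
#'   layer).
#' @return an `activation_embedding`: `scores` (sample x k),
#'   `var_ratio` (per component, of total variance), `loadings`
#'   (node x k), `sample_ids`.
#' @export
activation_pca <- function(state, spec, inputs, k = 2L,
                           layer = spec$gene_layer) {
  A <- layer_activations(state, spec, inputs, layer)
  vars <- apply(A, 2, stats::var)
  if (all(vars < 1e-12)) {
    stop("activations are constant across samples; PCA is undefined")
  }
  k <- min(as.integer(k), nrow(A) - 1L, ncol(A))
  pc <- stats::prcomp(A, center = TRUE, scale. = FALSE)
  structure(
    list(
      scores = pc$x[, seq_len(k), drop = FALSE],
      var_ratio = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      sample_ids = rownames(A) %||% rownames(inputs[[1]])
    ),
    class = "activation_embedding"
  )
}
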