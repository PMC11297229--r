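# Forward/backward engine for masked networks.
#
# Values flow through a pool of named sources: input blocks first, then each
# layer's outputs. A compiled plan resolves every layer's input units to
# (source, column) pairs once, so the per-step work is sparse matrix algebra
# plus per-edge gradient accumulation.

split_node_ids <- function(ids) {
  src <- sub(":.*$", "", ids)
  unit <- sub("^[^:]*:", "", ids)
  list(src = src, unit = unit)
}

compile_network <- function(spec, input_colnames) {
  universe <- lapply(spec$input_blocks, as.character)
  for (b in names(universe)) {
    cols <- input_colnames[[b]]
    if (is.null(cols)) stop("missing input block: ", b)
    if (!all(universe[[b]] %in% cols)) {
      miss <- setdiff(universe[[b]], cols)[1]
      stop(sprintf("input block '%s' lacks feature '%s'", b, miss))
    }
  }
  plans <- vector("list", length(spec$layers))
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    ids <- split_node_ids(layer_in_ids(layer))
    cols <- integer(length(ids$unit))
    for (s in unique(ids$src)) {
      sel <- ids$src == s
      if (s %in% names(universe)) {
        cols[sel] <- match(ids$unit[sel], input_colnames[[s]])
      } else {
        li <- match(s, vapply(spec$layers, `[[`, "", "name"))
        if (is.na(li) || li >= k) {
          stop(sprintf("layer '%s': input source '%s' not available", layer$name, s))
        }
        cols[sel] <- match(ids$unit[sel], layer_out_ids(spec$layers[[li]]))
      }
      if (anyNA(cols[sel])) {
        stop(sprintf("layer '%s': could not resolve some inputs from '%s'", layer$name, s))
      }
    }
    # contiguous runs over the same source, gathered/scattered as blocks
    r <- rle(ids$src)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segments <- lapply(seq_along(r$values), function(i) {
      list(src = r$values[[i]], dest = starts[i]:ends[i], cols = cols[starts[i]:ends[i]])
    })
    src_width <- function(s) {
      if (s %in% names(universe)) length(input_colnames[[s]])
      else length(layer_out_ids(spec$layers[[match(s, vapply(spec$layers, `[[`, "", "name"))]]))
    }
    # a layer consuming exactly one whole source in order needs no copy
    whole <- length(segments) == 1L &&
      identical(segments[[1]]$cols, seq_len(src_width(segments[[1]]$src)))
    Wt <- if (layer$kind == "masked") mask_matrix(layer$mask) else NULL
    plans[[k]] <- list(segments = segments, n_in = length(ids$unit),
                       template = Wt, whole_source = whole)
  }
  plans
}

gather_layer_input <- function(plan, values) {
  if (isTRUE(plan$whole_source)) {
    return(values[[plan$segments[[1]]$src]])
  }
  n <- nrow(values[[plan$segments[[1]]$src]])
  X <- matrix(0, n, plan$n_in)
  for (seg in plan$segments) {
    X[, seg$dest] <- values[[seg$src]][, seg$cols, drop = FALSE]
  }
  X
}

forward_pass <- function(state, spec, inputs, plans, keep_cache = FALSE) {
  values <- inputs
  caches <- if (keep_cache) vector("list", length(spec$layers)) else NULL
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    st <- state$layers[[k]]
    X <- gather_layer_input(plans[[k]], values)
    if (layer$kind == "masked") {
      W <- plans[[k]]$template
      W@x <- st$W
      Z <- as.matrix(X %*% W)
    } else {
      Z <- X %*% st$W
    }
    Z <- Z + rep(st$b, each = nrow(Z))
    A <- act_forward(Z, layer$activation)
    colnames(A) <- layer_out_ids(layer)
    values[[layer$name]] <- A
    if (keep_cache) caches[[k]] <- list(X = X, Z = Z, A = A)
  }
  list(values = values, caches = caches,
       output = values[[spec$layers[[length(spec$layers)]]$name]][, 1])
}

backward_pass <- function(state, spec, plans, caches, d_out) {
  n_layers <- length(spec$layers)
  grads <- vector("list", n_layers)
  dacc <- list()
  dacc[[spec$layers[[n_layers]]$name]] <- d_out
  for (k in rev(seq_len(n_layers))) {
    layer <- spec$layers[[k]]
    st <- state$layers[[k]]
    cache <- caches[[k]]
    dA <- dacc[[layer$name]]
    if (is.null(dA)) {  # layer feeds nothing downstream (should not happen)
      grads[[k]] <- list(W = 0 * st$W, b = 0 * st$b)
      next
    }
    dZ <- dA * act_grad(cache$Z, cache$A, layer$activation)
    gb <- colSums(dZ)
    if (layer$kind == "masked") {
      m <- layer$mask
      gW <- unname(colSums(cache$X[, m$in_idx, drop = FALSE] *
                             dZ[, m$out_idx, drop = FALSE]))
      W <- plans[[k]]$template
      W@x <- st$W
      dX <- as.matrix(dZ %*% Matrix::t(W))
    } else {
      gW <- crossprod(cache$X, dZ)
      dX <- tcrossprod(dZ, st$W)
    }
    grads[[k]] <- list(W = gW, b = gb)
    for (seg in plans[[k]]$segments) {
      if (seg$src %in% names(spec$input_blocks)) next
      cur <- dacc[[seg$src]]
      if (is.null(cur)) {
        li <- match(seg$src, vapply(spec$layers, `[[`, "", "name"))
        cur <- matrix(0, nrow(dX), length(layer_out_ids(spec$layers[[li]])))
      }
      cur[, seg$cols] <- cur[, seg$cols, drop = FALSE] + dX[, seg$dest, drop = FALSE]
      dacc[[seg$src]] <- cur
    }
  }
  grads
}

#' Initialize model weights for a network
#'
#' Glorot-uniform initialization restricted to mask edges: for masked
#' layers the fan terms use the mask's mean in/out degree rather than the
#' full layer dimensions, so very sparse layers keep a usable weight
#' scale. Biases start at zero. Fully seeded for reproducibility.
#'
#' @param spec a `network_spec`.
#' @param seed integer RNG seed.
#' @return a `vnn_model` state (weights, biases, metadata).
#' @export
init_model <- function(spec, seed = 1L) {
  set.seed(seed)
  layers <- vector("list", length(spec$layers))
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    if (layer$kind == "masked") {
      m <- layer$mask
      ne <- n_edges(m)
      fan_in <- ne / length(m$out_ids)
      fan_out <- ne / length(m$in_ids)
      lim <- sqrt(6 / (fan_in + fan_out))
      layers[[k]] <- list(
        W = stats::runif(ne, -lim, lim),
        b = numeric(length(m$out_ids))
      )
    } else {
      n_in <- length(layer$in_ids)
      lim <- sqrt(6 / (n_in + layer$width))
      layers[[k]] <- list(
        W = matrix(stats::runif(n_in * layer$width, -lim, lim), n_in, layer$width),
        b = numeric(layer$width)
      )
    }
  }
  structure(
    list(layers = layers, meta = list(seed = seed)),
    class = "vnn_model"
  )
}

#' Initialize the output bias to the training outcome mean
#'
#' Sets the bias of the last (output) neuron to the arithmetic mean of
#' the training-set outcome, giving the network a calibrated starting
#' point.
#'
#' @param state a `vnn_model`.
#' @param y_train numeric training outcomes.
#' @return the updated `vnn_model`.
#' @export
init_output_bias <- function(state, y_train) {
  k <- length(state$layers)
  state$layers[[k]]$b[] <- mean(y_train)
  state$meta$y_mean <- mean(y_train)
  state
}

#' Forward pass through a masked affine layer
#'
#' Computes `activation(x W + b)` where `W` is the sparse matrix whose
#' nonzeros sit on the mask edges (zeros elsewhere); only mask edges
#' carry weights and therefore gradient.
#'
#' @param x sample-by-input matrix, columns ordered as `mask$in_ids`.
#' @param weights numeric vector, one weight per mask edge (canonical
#'   edge order).
#' @param bias numeric vector, one per output unit.
#' @param mask a `connectivity_mask`.
#' @param activation activation name.
#' @return sample-by-output matrix.
#' @export
masked_affine_forward <- function(x, weights, bias, mask,
                                  activation = "linear") {
  x <- as.matrix(x)
  if (ncol(x) != length(mask$in_ids)) {
    stop(sprintf("input has %d columns but mask expects %d", ncol(x), length(mask$in_ids)))
  }
  if (anyNA(x)) stop("input contains missing values")
  W <- mask_matrix(mask, weights)
  Z <- sweep(as.matrix(x %*% W), 2, bias, `+`)
  A <- act_forward(Z, activation)
  colnames(A) <- mask$out_ids
  A
}

#' Predict with a trained visible network
#'
#' @param state a `vnn_model`.
#' @param spec the matching `network_spec`.
#' @param inputs named list of sample-by-feature matrices, one per input
#'   block (column names are feature ids).
#' @return numeric vector of predictions, one per sample.
#' @export
predict_vnn <- function(state, spec, inputs) {
  plans <- compile_network(spec, lapply(inputs, colnames))
  forward_pass(state, spec, inputs, plans)$output
}

#' Collect a layer's activations for every sample
#'
#' @param state a `vnn_model`.
#' @param spec the matching `network_spec`.
#' @param inputs named list of input matrices (as in [predict_vnn()]).
#' @param layer layer name; default the network's gene layer.
#' @return sample-by-node matrix of post-activation values.
#' @export
layer_activations <- function(state, spec, inputs, layer = spec$gene_layer) {
  if (is.null(layer)) stop("no layer given and the network has no gene layer")
  if (!layer %in% vapply(spec$layers, `[[`, "", "name")) {
    stop("unknown layer: ", layer)
  }
  plans <- compile_network(spec, lapply(inputs, colnames))
  forward_pass(state, spec, inputs, plans)$values[[layer]]
}

adam_new <- function(state) {
  lapply(state$layers, function(l) list(
    mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b
  ))
}

adam_step <- function(state, opt, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (k in seq_along(state$layers)) {
    g <- grads[[k]]
    o <- opt[[k]]
    o$mW <- beta1 * o$mW + (1 - beta1) * g$W
    o$vW <- beta2 * o$vW + (1 - beta2) * g$W^2
    o$mb <- beta1 * o$mb + (1 - beta1) * g$b
    o$vb <- beta2 * o$vb + (1 - beta2) * g$b^2
    state$layers[[k]]$W <- state$layers[[k]]$W - lr * (o$mW / c1) / (sqrt(o$vW / c2) + eps)
    state$layers[[k]]$b <- state$layers[[k]]$b - lr * (o$mb / c1) / (sqrt(o$vb / c2) + eps)
    opt[[k]] <- o
  }
  list(state = state, opt = opt)
}

#' Hyperparameter settings for training
#'
#' @param learning_rate Adam step size.
#' @param l1_lambda L1 penalty on the weights of the layers flagged for
#'   regularization (the combined gene layer in ME+GE networks, the
#'   methylation gene layer in ME-only networks, the output layer in the
#'   LASSO-like GE network).
#' @param omic_l1 optional `list(tag = , lambda = )` adding an extra L1
#'   penalty only to edges carrying one omic tag (`"me"` or `"ge"`),
#'   used to probe omic-specific information.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param patience epochs without validation-loss improvement before
#'   early stopping.
#' @param finetune_epochs optional settle phase run after the main loop
#'   at a tenth of the learning rate, damping optimizer oscillations
#'   around the L1 shrinkage equilibrium; adopted only if it improves
#'   the validation loss (default 0, disabled).
#' @return a `vnn_hyperparams` list.
#' @export
hyperparams <- function(learning_rate = 0.001, l1_lambda = 0.001,
                        omic_l1 = NULL, epochs = 100L, batch_size = 64L,
                        patience = 10L, finetune_epochs = 0L) {
  if (!is.null(omic_l1) && (is.null(omic_l1$tag) || is.null(omic_l1$lambda))) {
    stop("omic_l1 must be list(tag=, lambda=)")
  }
  structure(
    list(learning_rate = learning_rate, l1_lambda = l1_lambda,
         omic_l1 = omic_l1, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         finetune_epochs = as.integer(finetune_epochs)),
    class = "vnn_hyperparams"
  )
}

data_loss <- function(y, p, task, class_weights = NULL) {
  if (task == "classification") {
    weighted_bce(y, p, class_weights)
  } else {
    mse_loss(y, p)
  }
}

loss_grad <- function(y, p, task, class_weights = NULL) {
  n <- length(y)
  if (task == "classification") {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    w1 <- class_weights[["w1"]]; w0 <- class_weights[["w0"]]
    -(w1 * y / p - w0 * (1 - y) / (1 - p)) / n
  } else {
    2 * (p - y) / n
  }
}

# All L1 penalties enter the update as subgradients (lambda * sign(w)), the
# standard formulation for L1-regularized network training: the base penalty
# on the layers flagged for regularization, plus the optional omic-specific
# penalty on edges carrying one omic tag.
add_penalty_grads <- function(grads, state, spec, hp) {
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    w <- state$layers[[k]]$W
    if (isTRUE(layer$l1) && hp$l1_lambda > 0) {
      grads[[k]]$W <- grads[[k]]$W + hp$l1_lambda * sign(w)
    }
    if (!is.null(hp$omic_l1) && layer$kind == "masked" &&
        !is.null(layer$mask$tags)) {
      sel <- layer$mask$tags == hp$omic_l1$tag
      if (any(sel)) {
        grads[[k]]$W[sel] <- grads[[k]]$W[sel] +
          hp$omic_l1$lambda * sign(w[sel])
      }
    }
  }
  grads
}

#' Train a visible network
#'
#' Minibatch Adam on the task loss (weighted binary cross-entropy for
#' classification, mean squared error for regression) plus the L1
#' penalties in `hp`. The output bias starts at the training outcome
#' mean. Early stopping monitors the validation data loss with the given
#' patience and restores the best-validation-epoch weights.
#'
#' @param spec a `network_spec`.
#' @param inputs_train,inputs_val named lists of input matrices.
#' @param y_train,y_val outcome vectors ({0,1} for classification).
#' @param hp a [hyperparams()] object.
#' @param seed integer seed controlling initialization and batching.
#' @param verbose print per-epoch losses.
#' @return a `vnn_model` with `$history` (per-epoch train/validation
#'   loss) and training metadata.
#' @export
train_vnn <- function(spec, inputs_train, y_train, inputs_val, y_val,
                      hp = hyperparams(), seed = 1L, verbose = FALSE) {
  task <- spec$task
  cw <- NULL
  if (task == "classification") {
    if (length(unique(y_train)) < 2) {
      stop("training labels contain a single class; cannot fit a classifier")
    }
    cw <- class_weights(y_train)
  }
  plans <- compile_network(spec, lapply(inputs_train, colnames))
  plans_val <- compile_network(spec, lapply(inputs_val, colnames))
  state <- init_model(spec, seed = seed)
  state <- init_output_bias(state, y_train)
  n <- length(y_train)
  history <- data.frame(epoch = integer(), phase = integer(),
                        train_loss = numeric(), val_loss = numeric())

  run_phase <- function(state, lr, n_epochs, phase) {
    opt <- adam_new(state)
    step <- 0L
    best_val <- Inf
    best_layers <- state$layers
    best_epoch <- 0L
    wait <- 0L
    for (epoch in seq_len(n_epochs)) {
      idx <- sample.int(n)
      nb <- ceiling(n / hp$batch_size)
      batch_losses <- numeric(nb)
      for (bi in seq_len(nb)) {
        rows <- idx[((bi - 1L) * hp$batch_size + 1L):min(bi * hp$batch_size, n)]
        xb <- lapply(inputs_train, function(m) m[rows, , drop = FALSE])
        fw <- forward_pass(state, spec, xb, plans, keep_cache = TRUE)
        p <- fw$output
        if (anyNA(p) || any(!is.finite(p))) {
          stop(sprintf("non-finite predictions at epoch %d (layer '%s'); try a lower learning rate",
                       epoch, spec$layers[[length(spec$layers)]]$name))
        }
        batch_losses[bi] <- data_loss(y_train[rows], p, task, cw)
        d_out <- matrix(loss_grad(y_train[rows], p, task, cw), ncol = 1)
        grads <- backward_pass(state, spec, plans, fw$caches, d_out)
        grads <- add_penalty_grads(grads, state, spec, hp)
        step <- step + 1L
        upd <- adam_step(state, opt, grads, lr, step)
        state <- upd$state
        opt <- upd$opt
      }
      # training loss tracked as the running minibatch average; one full
      # forward per epoch on the validation set only
      p_va <- forward_pass(state, spec, inputs_val, plans_val)$output
      tr_loss <- mean(batch_losses)
      va_loss <- data_loss(y_val, p_va, task, cw)
      if (!is.finite(tr_loss) || !is.finite(va_loss)) {
        stop(sprintf("non-finite loss at epoch %d; training diverged", epoch))
      }
      history <<- rbind(history, data.frame(epoch = epoch, phase = phase,
                                            train_loss = tr_loss,
                                            val_loss = va_loss))
      if (verbose) {
        message(sprintf("phase %d epoch %3d  train %.5f  val %.5f",
                        phase, epoch, tr_loss, va_loss))
      }
      if (va_loss < best_val - 1e-9) {
        best_val <- va_loss
        best_layers <- state$layers
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hp$patience) break
      }
    }
    list(layers = best_layers, val = best_val, epoch = best_epoch)
  }

  main <- run_phase(state, hp$learning_rate, hp$epochs, phase = 1L)
  state$layers <- main$layers
  best <- main
  if (hp$finetune_epochs > 0) {
    # settle phase: restart from the best weights at a tenth of the
    # learning rate, so optimizer oscillations (in particular around the
    # L1 shrinkage equilibrium near zero) damp out
    fine <- run_phase(state, hp$learning_rate / 10, hp$finetune_epochs,
                      phase = 2L)
    if (fine$val < best$val) {
      state$layers <- fine$layers
      best <- fine
    }
  }
  state$meta$hp <- hp
  state$meta$best_epoch <- main$epoch
  state$meta$best_val_loss <- best$val
  state$history <- history
  state
}
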