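#' Class weights inverse to the class imbalance
#'
#' For labels with `n1` positives and `n0` negatives out of `n`, returns
#' `w1 = n/(2 n1)` and `w0 = n/(2 n0)`: each class's weight is inversely
#' proportional to its prevalence, normalized so the two weights average
#' to one (balanced data gives `w0 = w1 = 1`).
#'
#' @param y {0,1} label vector.
#' @return named numeric `c(w0=, w1=)`.
#' @export
class_weights <- function(y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("labels contain a single class")
  n <- n1 + n0
  c(w0 = n / (2 * n0), w1 = n / (2 * n1))
}

#' Weighted binary cross-entropy
#'
#' Mean over samples of `-(w1 y log p + w0 (1-y) log(1-p))`, with class
#' weights inverse to the class imbalance (see [class_weights()]).
#' Predictions are clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param y_true {0,1} labels.
#' @param y_pred predicted probabilities in (0,1).
#' @param weights named `c(w0=, w1=)`; derived from `y_true` when `NULL`.
#' @return scalar loss.
#' @export
weighted_bce <- function(y_true, y_pred, weights = NULL) {
  if (is.null(weights)) weights <- class_weights(y_true)
  p <- pmin(pmax(y_pred, 1e-7), 1 - 1e-7)
  mean(-(weights[["w1"]] * y_true * log(p) +
           weights[["w0"]] * (1 - y_true) * log(1 - p)))
}

#' Mean squared error loss
#' @param y_true,y_pred numeric vectors.
#' @return scalar mean of squared residuals.
#' @export
mse_loss <- function(y_true, y_pred) mean((y_true - y_pred)^2)

#' L1 penalty over selected network weights
#'
#' `lambda * sum(|w|)` over the selected edges: `selector = "all"` sums
#' the weights of every layer flagged for L1 regularization (the
#' combined gene layer in ME+GE networks); an omic tag (`"me"`, `"ge"`,
#' `"covariate"`) sums only the edges carrying that tag, in any layer.
#'
#' @param state a `vnn_model`.
#' @param spec the matching `network_spec`.
#' @param lambda penalty strength.
#' @param selector `"all"` or an edge tag.
#' @return scalar penalty value (0 if nothing matches).
#' @export
l1_term <- function(state, spec, lambda, selector = "all") {
  total <- 0
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    w <- state$layers[[k]]$W
    if (identical(selector, "all")) {
      if (isTRUE(layer$l1)) total <- total + sum(abs(w))
    } else if (layer$kind == "masked" && !is.null(layer$mask$tags)) {
      sel <- layer$mask$tags == selector
      if (any(sel)) total <- total + sum(abs(w[sel]))
    }
  }
  lambda * total
}

#' Evaluate predictions with the task's reported metrics
#'
#' Classification: area under the ROC curve. Regression: root mean
#' squared error and explained variance
#' (`1 - Var(y - pred) / Var(y)`).
#'
#' @param y_true observed outcomes.
#' @param y_pred predictions (probabilities or values).
#' @param task `"classification"` or `"regression"`.
#' @return named list: `auc`, or `rmse` and `explained_variance`.
#' @export
evaluate <- function(y_true, y_pred, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") {
    auc <- as.numeric(pROC::auc(
      response = y_true, predictor = y_pred,
      levels = c(0, 1), direction = "<", quiet = TRUE
    ))
    list(auc = auc)
  } else {
    list(
      rmse = sqrt(mean((y_true - y_pred)^2)),
      explained_variance = 1 - stats::var(y_true - y_pred) / stats::var(y_true)
    )
  }
}
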