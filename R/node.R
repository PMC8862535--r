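# One node of the hierarchy: a multi-class probabilistic classifier built
# from one-vs-rest binaries in the node's own PCA feature space.

#' Node training parameters
#'
#' @param model Classifier family: `"svm_rbf"` (radial-kernel SVM, default),
#'   `"logistic"` (ridge-logistic on the PC scores) or `"mlp"` (single
#'   hidden-layer network via nnet).
#' @param n_pcs Feature-space dimensionality (capped at `n_cells - 1`).
#' @param n_hvg Variable genes selected before PCA.
#' @param cost,gamma RBF-SVM hyperparameters; `gamma = NULL` uses
#'   `1 / (n_pcs * mean score variance)`.
#' @param min_cells Minimum cells per class.
#' @param cv_folds Cross-validation folds used both for Platt calibration and
#'   the held-out metrics; `0` disables CV (calibration then uses training
#'   decision values).
#' @param seed Base seed; every stochastic step derives from it.
#' @export
node_params <- function(model = c("svm_rbf", "logistic", "mlp"),
                        n_pcs = 100, n_hvg = 10000, cost = 1, gamma = NULL,
                        min_cells = 20, cv_folds = 3, seed = 1) {
  list(model = match.arg(model), n_pcs = n_pcs, n_hvg = n_hvg, cost = cost,
       gamma = gamma, min_cells = min_cells, cv_folds = cv_folds, seed = seed)
}

# Platt scaling: fit P(y=1|d) = 1/(1+exp(a*d+b)) by Newton iterations on the
# smoothed targets of Platt (1999) / Lin et al. (2007). Robust to perfectly
# separable decision values, where a plain logistic fit diverges.
platt_fit <- function(decision, y) {
  prior1 <- sum(y); prior0 <- sum(!y)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y, hi, lo)
  a <- 0; b <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(a, b) {
    fApB <- decision * a + b
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(a, b)
  for (it in 1:100) {
    fApB <- decision * a + b
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(decision * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(decision^2 * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(decision * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    stepsize <- 1
    while (stepsize >= 1e-10) {
      na <- a + stepsize * dA; nb <- b + stepsize * dB
      nf <- fval(na, nb)
      if (nf < fv + 1e-4 * stepsize * (g1 * dA + g2 * dB) || nf <= fv) {
        a <- na; b <- nb; fv <- nf; break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < 1e-10) break
  }
  c(a = a, b = b)
}

platt_apply <- function(decision, ab) {
  p <- 1 / (1 + exp(ab["a"] * decision + ab["b"]))
  pmin(pmax(unname(p), 0), 1)
}

# Fit one binary classifier on scores; returns list(fit, decision(scores)).
fit_binary <- function(scores, y, params, seed) {
  if (params$model == "svm_rbf") {
    gamma <- params$gamma %||% (1 / (ncol(scores) * mean(apply(scores, 2, stats::var))))
    set.seed(seed)
    fit <- e1071::svm(x = scores, y = factor(y, levels = c(FALSE, TRUE)),
                      kernel = "radial", gamma = gamma, cost = params$cost,
                      scale = FALSE, probability = FALSE)
    dec <- function(s) {
      d <- attr(stats::predict(fit, s, decision.values = TRUE), "decision.values")[, 1]
      d
    }
    # orient decision values so positives score high
    d0 <- dec(scores)
    flip <- mean(d0[y]) < mean(d0[!y])
    list(predictor = fit, decision = function(s) {
      d <- attr(stats::predict(fit, s, decision.values = TRUE), "decision.values")[, 1]
      if (flip) -d else d
    }, flip = flip)
  } else if (params$model == "logistic") {
    set.seed(seed)
    # small ridge via quasi-Newton on the penalized likelihood keeps separable
    # nodes finite; implemented with glm + tiny jitter-free L2 through offsetted
    # iteration is overkill here, nnet's logistic with decay does the job.
    fit <- nnet::nnet(x = scores, y = as.numeric(y), size = 0, skip = TRUE,
                      entropy = TRUE, decay = 1e-3, maxit = 200, trace = FALSE)
    list(predictor = fit,
         decision = function(s) stats::qlogis(pmin(pmax(
           as.numeric(stats::predict(fit, s)), 1e-12), 1 - 1e-12)))
  } else {
    set.seed(seed)
    fit <- nnet::nnet(x = scores, y = as.numeric(y), size = 8, decay = 0.01,
                      entropy = TRUE, maxit = 200, trace = FALSE,
                      MaxNWts = 20000)
    list(predictor = fit,
         decision = function(s) stats::qlogis(pmin(pmax(
           as.numeric(stats::predict(fit, s)), 1e-12), 1 - 1e-12)))
  }
}

#' Train one node's classifier
#'
#' Fits the node's feature space (HVG selection, PCA, one optional
#' harmonization round) on the node's own cells, then one calibrated
#' one-vs-rest binary per class: cross-validated decision values feed a Platt
#' sigmoid and the held-out AUROC/sensitivity/specificity stored in
#' `cv_metrics`. Training rows are sorted by cell id first, so the result is
#' invariant to the order cells arrive in.
#'
#' @param ds A [kc_dataset()] of the node's cells (lognorm computed if absent).
#' @param labels Per-cell class label at this node (child identities).
#' @param classes Class order (default: order of appearance).
#' @param params See [node_params()].
#' @param batch Optional per-cell batch factor for harmonization.
#' @param node_name Stored name of the node.
#' @param verbose Log dimensionality reductions.
#' @return An object of class `node_model`.
#' @export
train_node <- function(ds, labels, classes = NULL, params = node_params(),
                       batch = NULL, node_name = "node", verbose = FALSE) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(ds$counts))
  ord <- order(ds$cell_ids, method = "radix")  # byte order: locale-independent
  ds <- subset_cells(ds, ord)
  labels <- labels[ord]
  if (!is.null(batch)) batch <- as.character(batch)[ord]
  classes <- classes %||% unique(labels)
  classes <- classes[classes %in% labels]
  if (length(classes) < 2)
    kc_abort(sprintf("node '%s' has a single class; nothing to train", node_name),
             "single_class_error")
  tab <- table(factor(labels, levels = classes))
  small <- names(tab)[tab < params$min_cells]
  if (length(small))
    kc_abort(sprintf("node '%s': class(es) below %d cells: %s",
                     node_name, params$min_cells, paste(small, collapse = ", ")),
             "small_class_error")
  n <- nrow(ds$counts)
  n_pcs <- min(params$n_pcs, n - 1)
  genes <- select_hvg(ds, n_hvg = params$n_hvg)
  n_pcs <- min(n_pcs, length(genes))
  if (verbose && n_pcs < params$n_pcs)
    message(sprintf("train_node[%s]: n_pcs reduced to %d", node_name, n_pcs))
  space <- fit_feature_space(ds, genes = genes, n_pcs = n_pcs, batch = batch,
                             seed = params$seed)
  scores <- space$scores
  folds <- NULL
  if (params$cv_folds >= 2) {
    set.seed(params$seed + 7L)
    folds <- sample(rep_len(seq_len(params$cv_folds), n))
  }
  binaries <- list()
  cv_metrics <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    y <- labels == cls
    seed_c <- params$seed + 1000L * ci
    if (!is.null(folds)) {
      dec_cv <- numeric(n)
      ok <- TRUE
      for (f in seq_len(params$cv_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) { ok <- FALSE; break }
        bf <- fit_binary(scores[tr, , drop = FALSE], y[tr], params, seed_c + f)
        dec_cv[!tr] <- bf$decision(scores[!tr, , drop = FALSE])
      }
      if (!ok) dec_cv <- NULL
    } else dec_cv <- NULL
    full <- fit_binary(scores, y, params, seed_c)
    dec_cal <- dec_cv %||% full$decision(scores)
    ab <- platt_fit(dec_cal, y)
    if (!is.null(dec_cv)) {
      p_cv <- platt_apply(dec_cv, ab)
      pred <- p_cv >= 0.5
      cv_metrics[[cls]] <- c(
        auroc = auroc(dec_cv, y),
        sensitivity = if (sum(y)) mean(pred[y]) else NA_real_,
        specificity = if (sum(!y)) mean(!pred[!y]) else NA_real_)
    }
    binaries[[cls]] <- list(fit = full, platt = ab)
  }
  structure(list(node_name = node_name, classes = classes, space = space,
                 binaries = binaries,
                 cv_metrics = if (length(cv_metrics))
                   do.call(rbind, cv_metrics) else NULL,
                 params = params),
            class = "node_model")
}

#' Predict class probabilities at one node
#'
#' @param model A `node_model`.
#' @param newdata A [kc_dataset()] or a precomputed score matrix in the
#'   node's feature space.
#' @param batch Optional query batch factor (used only when the node's space
#'   carries harmonization state).
#' @return Cells x classes matrix of calibrated one-vs-rest probabilities in
#'   \[0, 1\] (rows are not renormalized; see Details).
#' @details One-vs-rest Platt scores are deliberately not renormalized to sum
#'   to 1: the rejection rule compares the maximum score to an absolute
#'   threshold, and renormalization would mask uniformly-low rows — exactly
#'   the cells the threshold exists to reject.
#' @export
predict_node <- function(model, newdata, batch = NULL) {
  scores <- if (inherits(newdata, "kc_dataset"))
    project_query(newdata, model$space, batch = batch) else as.matrix(newdata)
  p <- vapply(model$classes, function(cls) {
    b <- model$binaries[[cls]]
    platt_apply(b$fit$decision(scores), b$platt)
  }, numeric(nrow(scores)))
  p <- matrix(p, nrow = nrow(scores), ncol = length(model$classes),
              dimnames = list(rownames(scores), model$classes))
  p
}

#' @export
#' @method print node_model
print.node_model <- function(x, ...) {
  cat(sprintf("<node_model> '%s': %s | %d PCs, %s\n", x$node_name,
              paste(x$classes, collapse = ", "), ncol(x$space$loadings),
              x$params$model))
  if (!is.null(x$cv_metrics)) {
    cat("held-out CV metrics:\n")
    print(round(x$cv_metrics, 3))
  }
  invisible(x)
}
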