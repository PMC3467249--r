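# Soft-margin linear SVM via dual coordinate descent (the liblinear L1-loss
# algorithm): minimize (1/2)||w||^2 + C * sum_i max(0, 1 - y_i w'x_i) over
# the augmented weight vector w (a constant feature of 1 carries the,
# regularized, intercept). Updates are cyclic and deterministic, so label
# flips negate the solution exactly and repeated fits are identical.

.svm_dual_cd <- function(X, y, cost, max_pass = 2000L, tol = 1e-9) {
  n <- nrow(X)
  Xa <- cbind(X, intercept = 1)
  Q <- rowSums(Xa ^ 2)          # diag of the Gram matrix
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  for (pass in seq_len(max_pass)) {
    max_viol <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * Xa[i, ]) - 1          # gradient of dual coordinate
      pg <- if (alpha[i] <= 0) min(g, 0) else if (alpha[i] >= cost) max(g, 0) else g
      if (abs(pg) > 1e-14) {
        a_new <- min(max(alpha[i] - g / Q[i], 0), cost)
        d <- a_new - alpha[i]
        if (d != 0) {
          w <- w + d * y[i] * Xa[i, ]
          alpha[i] <- a_new
        }
      }
      max_viol <- max(max_viol, abs(pg))
    }
    if (max_viol < tol) break
  }
  p <- length(w)
  list(weights = w[-p], intercept = w[p], alpha = alpha, passes = pass)
}

#' Train a linear support vector machine
#'
#' Features are standardized (center/scale) on the training data; the model
#' stores the weights on the standardized scale together with the
#' standardization so it can score raw feature matrices. The positive class
#' (positive decision score) is NR.
#'
#' @param X Sample x gene numeric matrix, no missing values.
#' @param y Class labels in \{"NR", "CCR"\}.
#' @param cost Soft-margin cost C (default 1).
#' @return A `signature_model`: genes, weights, intercept, standardization
#'   (center, scale), positive_class, cost.
#' @export
train_linear_svm <- function(X, y, cost = 1.0) {
  X <- as.matrix(X)
  if (anyNA(X)) cs_stop("X contains missing values",
                        class = "chemosig_domain_error")
  y <- as.character(y)
  if (length(unique(y)) < 2L) cs_stop("labels are single-class",
                                      class = "chemosig_degenerate_label_error")
  stopifnot(all(y %in% c("NR", "CCR")), nrow(X) == length(y),
            min(table(y)) >= 2)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  zero_var <- scale == 0 | !is.finite(scale)
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance feature(s): scale set to 1, weight 0",
                    sum(zero_var)))
    scale[zero_var] <- 1
  }
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  ynum <- ifelse(y == "NR", 1, -1)
  fit <- .svm_dual_cd(Z, ynum, cost)
  genes <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  structure(list(genes = genes,
                 weights = stats::setNames(fit$weights, genes),
                 intercept = fit$intercept,
                 center = stats::setNames(center, genes),
                 scale = stats::setNames(scale, genes),
                 positive_class = "NR", cost = cost,
                 passes = fit$passes),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model: %d genes, positive class %s, cost %g>\n",
              length(x$genes), x$positive_class, x$cost))
  invisible(x)
}

#' Decision scores of a signature model
#'
#' `s(x) = sum_i w_i * (x_i - center_i)/scale_i + intercept`; positive
#' scores predict the positive class (NR).
#'
#' @param model A `signature_model`.
#' @param X Sample x gene matrix containing the model's genes as columns.
#' @return Numeric vector of decision scores, one per row of `X`.
#' @export
decision_score <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$genes, colnames(X))
  if (length(missing)) cs_stop("feature(s) absent from X: %s",
                               paste(missing, collapse = ", "),
                               class = "chemosig_key_error")
  Z <- sweep(sweep(X[, model$genes, drop = FALSE], 2, model$center),
             2, model$scale, "/")
  drop(Z %*% model$weights) + model$intercept
}

#' Predict classes from a signature model
#'
#' @param object A `signature_model`.
#' @param X Sample x gene matrix.
#' @param ... Unused.
#' @return Character vector over \{"NR", "CCR"\} (threshold: score > 0 -> NR).
#' @export
predict.signature_model <- function(object, X, ...) {
  s <- decision_score(object, X)
  ifelse(s > 0, object$positive_class, "CCR")
}
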