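#' Train a multiclass linear SVM
#'
#' L2-regularized hinge-loss linear SVM solved by dual coordinate descent
#' (the standard solver for linear SVMs), with multiclass handled by
#' one-vs-one voting. A bias term is included as an augmented constant
#' feature. Features are expected to be standardized by the caller; this
#' function does no scaling.
#'
#' @param X numeric n x p feature matrix.
#' @param y factor (or coercible) of class labels.
#' @param C soft-margin cost parameter.
#' @param tol dual projected-gradient stopping tolerance.
#' @param max_epochs cap on coordinate-descent epochs.
#' @param seed seed for the solver's internal coordinate-shuffling PRNG.
#' @return object of class `linear_svm` with the per-pair weight vectors.
#' @export
linear_svm <- function(X, y, C = 1, tol = 0.01, max_epochs = 200L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), C > 0)
  classes <- levels(droplevels(y))
  if (length(classes) < 2L) stop("need at least two classes to train an SVM")
  Xa <- cbind(X, 1)                          # bias as augmented feature
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  models <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    sel <- y %in% pr
    yy <- ifelse(y[sel] == pr[1L], 1L, -1L)
    w <- svm_dcd_cpp(Xa[sel, , drop = FALSE], as.integer(yy), C = C,
                     tol = tol, max_epochs = as.integer(max_epochs),
                     seed = as.integer(seed) + i)
    list(pair = pr, w = w)
  })
  structure(list(models = models, classes = classes, p = ncol(X), C = C),
            class = "linear_svm")
}

#' Predict movement classes with a trained linear SVM
#'
#' One-vs-one voting; ties are broken by the summed signed decision values
#' of the tied classes, then by class order (deterministic).
#'
#' @param object a [linear_svm()] model.
#' @param newdata numeric matrix with the same feature layout as training.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  X <- cbind(as.matrix(newdata), 1)
  stopifnot(ncol(X) == object$p + 1L)
  n <- nrow(X)
  votes <- matrix(0L, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  margin <- matrix(0, n, length(object$classes),
                   dimnames = list(NULL, object$classes))
  for (m in object$models) {
    d <- as.numeric(X %*% m$w)
    i1 <- match(m$pair[1L], object$classes)
    i2 <- match(m$pair[2L], object$classes)
    pos <- d > 0
    votes[pos, i1] <- votes[pos, i1] + 1L
    votes[!pos, i2] <- votes[!pos, i2] + 1L
    margin[, i1] <- margin[, i1] + d
    margin[, i2] <- margin[, i2] - d
  }
  pick <- vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) top <- top[which.max(margin[i, top])]
    top[1L]
  }, integer(1))
  factor(object$classes[pick], levels = object$classes)
}
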