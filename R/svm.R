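#' Polynomial-kernel SVM on fused CNN features
#'
#' Thin wrapper around [e1071::svm()] fixing the classifier used after
#' feature fusion: polynomial kernel (default degree 3, `coef0 = 1`,
#' cost `C = 1`) on standardized inputs. Standardization parameters are
#' learned on the training rows only and reapplied at prediction time;
#' constant columns are left unscaled.
#'
#' @param X numeric feature matrix (e.g. a [fuse_feature_blocks()] result).
#' @param y 2-class labels.
#' @param degree polynomial degree (>= 1).
#' @param C regularization cost (> 0).
#' @param coef0 kernel offset.
#' @param standardize center/scale the columns.
#' @return A `holo_svm` classifier.
#' @export
train_svm <- function(X, y, degree = 3, C = 1, coef0 = 1,
                      standardize = TRUE) {
  stopifnot(degree >= 1, C > 0)
  y <- factor(y)
  if (nlevels(y) < 2) stop("single-class fit")
  X <- as.matrix(X)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
    X <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }
  model <- e1071::svm(X, y, kernel = "polynomial", degree = degree,
                      cost = C, coef0 = coef0, scale = FALSE)
  out <- list(model = model, center = center, scale = scale,
              levels = levels(y))
  class(out) <- "holo_svm"
  out
}

#' @rdname train_svm
#' @param clf a `holo_svm`.
#' @param newdata feature matrix with the training columns.
#' @return `predict_svm`: factor of predicted labels.
#' @export
predict_svm <- function(clf, newdata) {
  stopifnot(inherits(clf, "holo_svm"))
  X <- sweep(sweep(as.matrix(newdata), 2, clf$center, "-"), 2, clf$scale, "/")
  stats::predict(clf$model, X)
}
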