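#' Specify a classifier
#'
#' Three model families, mirroring the comparison the analysis runs:
#' \describe{
#'   \item{`lda`}{Gaussian discriminant with one pooled full covariance
#'     matrix, class priors from training frequencies, and a diagonal ridge
#'     (`1e-6`) for invertibility.}
#'   \item{`svm_quadratic`}{Soft-margin SVM with a degree-2 polynomial
#'     kernel; the kernel scale is set automatically to the median pairwise
#'     training distance; multiclass by one-vs-one majority vote.}
#'   \item{`nn`}{Feed-forward network with one hidden layer of 100 ReLU
#'     units and a softmax output, trained full-batch by L-BFGS on the
#'     cross-entropy loss with an L2 weight penalty.}
#' }
#' All families z-score the features with training-fold statistics before
#' fitting (amplitude, frequency and phase columns live on very different
#' scales).
#'
#' @param family `"lda"`, `"svm_quadratic"` or `"nn"`.
#' @param seed Seed for stochastic training (NN weight initialization).
#' @param cost Soft-margin penalty for the SVM (default 1).
#' @param ridge Diagonal ridge added to the pooled LDA covariance.
#' @param hidden NN hidden-layer width (default 100).
#' @param max_iter NN optimizer iteration cap (default 1000).
#' @param l2 NN L2 weight penalty (default 1e-4).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("lda", "svm_quadratic", "nn"), seed = 0,
                       cost = 1, ridge = 1e-6, hidden = 100L,
                       max_iter = 1000L, l2 = 1e-4) {
  family <- match.arg(family)
  assert_scalar_number(seed, "seed")
  spec <- list(family = family, seed = as.integer(seed))
  if (family == "svm_quadratic") {
    assert_scalar_number(cost, "cost", min = 1e-12)
    spec$cost <- cost
  }
  if (family == "lda") {
    assert_scalar_number(ridge, "ridge", min = 0)
    spec$ridge <- ridge
  }
  if (family == "nn") {
    assert_scalar_number(hidden, "hidden", min = 1)
    assert_scalar_number(max_iter, "max_iter", min = 1)
    assert_scalar_number(l2, "l2", min = 0)
    spec$hidden <- as.integer(hidden)
    spec$max_iter <- as.integer(max_iter)
    spec$l2 <- l2
  }
  structure(spec, class = "model_spec")
}

#' Stratified k-fold assignment
#'
#' Partitions sample indices into `k` disjoint, exhaustive folds with
#' per-class counts differing by at most one across folds, deterministically
#' for a given seed.
#'
#' @param labels Class label per sample.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..k) per sample, with
#'   attribute `k`, class `fold_assignment`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 0) {
  labels <- as.character(labels)
  k <- as.integer(k)
  counts <- table(labels)
  if (any(counts < k)) {
    small <- names(counts)[counts < k][1]
    stop(sprintf("class '%s' has %d samples, fewer than k = %d folds",
                 small, counts[[small]], k), call. = FALSE)
  }
  fold <- integer(length(labels))
  with_rng_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      # deal round-robin from a random starting fold so remainders spread
      start <- sample.int(k, 1)
      fold[idx] <- 1L + (seq_along(idx) + start - 2L) %% k
    }
  })
  structure(fold, k = k, class = "fold_assignment")
}

# ---- in-package pooled-covariance Gaussian discriminant ---------------------

lda_train <- function(X, y, ridge = 1e-6) {
  classes <- sort(unique(y))
  n <- nrow(X); p <- ncol(X)
  means <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(p)))
  pooled <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    Xc <- sweep(Xc, 2, means[match(cl, classes), ])
    pooled <- pooled + crossprod(Xc)
  }
  pooled <- pooled / (n - length(classes)) + diag(ridge, p)
  Sinv <- tryCatch(solve(pooled), error = function(e) {
    stop("pooled covariance singular even after ridge; features may be duplicated",
         call. = FALSE)
  })
  list(classes = classes, means = means, Sinv = Sinv,
       log_prior = log(as.vector(table(y)[classes]) / n))
}

lda_predict <- function(model, X) {
  # discriminant: x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log prior_c
  W <- model$Sinv %*% t(model$means) # p x C
  b <- -0.5 * colSums(t(model$means) * W) + model$log_prior
  scores <- X %*% W + rep(b, each = nrow(X))
  model$classes[max.col(scores, ties.method = "first")]
}

# ---- ReLU MLP trained by full-batch L-BFGS ----------------------------------

mlp_unpack <- function(par, p, h, C) {
  i <- 0
  W1 <- matrix(par[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * C)], h, C); i <- i + h * C
  b2 <- par[i + seq_len(C)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(w, X) {
  H <- pmax(X %*% w$W1 + rep(w$b1, each = nrow(X)), 0)
  logits <- H %*% w$W2 + rep(w$b2, each = nrow(X))
  list(H = H, logits = logits)
}

mlp_train <- function(X, y, hidden = 100L, max_iter = 1000L, l2 = 1e-4,
                      seed = 0) {
  classes <- sort(unique(y))
  C <- length(classes); p <- ncol(X); n <- nrow(X)
  Yind <- outer(y, classes, `==`) * 1
  npar <- p * hidden + hidden + hidden * C + C
  par0 <- with_rng_seed(seed, {
    c(stats::rnorm(p * hidden, 0, sqrt(2 / p)), rep(0, hidden),
      stats::rnorm(hidden * C, 0, sqrt(2 / hidden)), rep(0, C))
  })
  loss_grad <- function(par) {
    w <- mlp_unpack(par, p, hidden, C)
    fw <- mlp_forward(w, X)
    z <- fw$logits - apply(fw$logits, 1, max)
    P <- exp(z); P <- P / rowSums(P)
    loss <- -sum(Yind * log(pmax(P, 1e-300))) / n +
      l2 * (sum(w$W1^2) + sum(w$W2^2))
    dlogits <- (P - Yind) / n
    dW2 <- crossprod(fw$H, dlogits) + 2 * l2 * w$W2
    db2 <- colSums(dlogits)
    dH <- dlogits %*% t(w$W2)
    dH[fw$H <= 0] <- 0
    dW1 <- crossprod(X, dH) + 2 * l2 * w$W1
    db1 <- colSums(dH)
    list(loss = loss, grad = c(as.vector(dW1), db1, as.vector(dW2), db2))
  }
  fit <- stats::optim(par0,
                      fn = function(par) loss_grad(par)$loss,
                      gr = function(par) loss_grad(par)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter))
  list(par = fit$par, p = p, hidden = hidden, classes = classes)
}

mlp_predict <- function(model, X) {
  w <- mlp_unpack(model$par, model$p, model$hidden, length(model$classes))
  logits <- mlp_forward(w, X)$logits
  model$classes[max.col(logits, ties.method = "first")]
}

# ---- shared surface ---------------------------------------------------------

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(z, X) sweep(sweep(X, 2, z$mu), 2, z$sd, `/`)

#' Train a classifier and predict test labels
#'
#' Fits the model named by `spec` on the training rows and predicts the test
#' rows. Everything data-dependent — the z-scoring statistics, the SVM
#' kernel scale — is fitted on the training data only, so the function can
#' sit inside a cross-validation loop without leakage.
#'
#' @param spec A [model_spec()].
#' @param features_train,features_test Numeric feature matrices.
#' @param labels_train Class label per training row; at least two classes.
#' @return Character vector of predicted labels for the test rows.
#' @export
train_predict <- function(spec, features_train, labels_train, features_test) {
  stopifnot(inherits(spec, "model_spec"))
  features_train <- as.matrix(features_train)
  features_test <- as.matrix(features_test)
  labels_train <- as.character(labels_train)
  if (length(unique(labels_train)) < 2L) {
    stop("training labels must contain at least two classes", call. = FALSE)
  }
  if (any(!is.finite(features_train)) || any(!is.finite(features_test))) {
    stop("features must be finite", call. = FALSE)
  }
  z <- zscore_fit(features_train)
  Xtr <- zscore_apply(z, features_train)
  Xte <- zscore_apply(z, features_test)

  if (spec$family == "lda") {
    model <- lda_train(Xtr, labels_train, ridge = spec$ridge)
    return(lda_predict(model, Xte))
  }
  if (spec$family == "svm_quadratic") {
    s <- stats::median(stats::dist(Xtr))
    if (!is.finite(s) || s <= 0) s <- 1
    model <- e1071::svm(Xtr, factor(labels_train), type = "C-classification",
                        kernel = "polynomial", degree = 2,
                        gamma = 1 / s^2, coef0 = 1, cost = spec$cost,
                        scale = FALSE)
    return(as.character(stats::predict(model, Xte)))
  }
  model <- mlp_train(Xtr, labels_train, hidden = spec$hidden,
                     max_iter = spec$max_iter, l2 = spec$l2, seed = spec$seed)
  mlp_predict(model, Xte)
}

#' Cross-validate a classifier over a fold assignment
#'
#' For each fold, trains on the complement and predicts the fold, so every
#' sample is predicted exactly once by a model that never saw it. All
#' data-dependent preprocessing happens inside [train_predict()] on the
#' training fold only.
#'
#' @param spec A [model_spec()].
#' @param features A `feature_matrix` or a plain numeric matrix.
#' @param folds A [stratified_folds()] assignment (or integer vector).
#' @param labels Class labels; taken from `features$labels` when `features`
#'   is a `feature_matrix`.
#' @return Object of class `prediction_set`: `data.frame` with columns
#'   `sample_id`, `fold`, `true_label`, `predicted_label`, plus the model
#'   spec as attribute.
#' @export
cross_validate <- function(spec, features, folds, labels = NULL) {
  if (inherits(features, "feature_matrix")) {
    labels <- labels %||% features$labels
    X <- features$values
  } else {
    X <- as.matrix(features)
  }
  labels <- as.character(labels)
  fold <- as.integer(folds)
  if (length(fold) != nrow(X) || length(labels) != nrow(X)) {
    stop("folds and labels must match the feature rows", call. = FALSE)
  }
  pred <- character(nrow(X))
  for (f in sort(unique(fold))) {
    test <- fold == f
    pred[test] <- tryCatch(
      train_predict(spec, X[!test, , drop = FALSE], labels[!test],
                    X[test, , drop = FALSE]),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
  }
  out <- data.frame(sample_id = seq_len(nrow(X)), fold = fold,
                    true_label = labels, predicted_label = pred,
                    stringsAsFactors = FALSE)
  structure(out, class = c("prediction_set", "data.frame"),
            model = unclass(spec))
}

#' Write a prediction set as CSV (with the model spec as JSON sidecar)
#'
#' @param predictions A `prediction_set`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(as.data.frame(predictions), path, row.names = FALSE,
                   quote = FALSE)
  model <- attr(predictions, "model")
  if (!is.null(model)) {
    jsonlite::write_json(model, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(true_label = "character",
                                       predicted_label = "character"))
  structure(df, class = c("prediction_set", "data.frame"))
}
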