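#' Classifier configuration
#'
#' Hyperparameters of the three recognition algorithms: linear discriminant
#' analysis in a one-vs-rest arrangement, k-nearest neighbours with
#' inverse-distance-weighted voting (`k = 3`, Euclidean metric), and a
#' soft-margin SVM with Gaussian radial-basis kernel
#' `exp(-||u - v||^2 / (2 sigma^2))`, regularisation `C = 5` and kernel
#' width `sigma = 2.58`, also one-vs-rest. KNN and SVM standardise features
#' to zero mean and unit variance (fitted on training rows). An optional
#' grid search selects `(C, sigma)` by stratified cross-validation, ties
#' broken toward smaller `C` then larger `sigma`.
#'
#' @param kind `"lda"`, `"knn"` or `"svm"`.
#' @param knn_k Number of neighbours.
#' @param svm_c Soft-margin regularisation.
#' @param svm_sigma RBF kernel width (the sigma in the exponent).
#' @param grid_search If `TRUE`, search `grid_c` x `grid_sigma` by CV.
#' @param grid_c,grid_sigma Grid-search candidate values.
#' @param cv_folds Stratified folds for the grid search.
#' @param seed Seed for the grid-search fold assignment.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kind = c("lda", "knn", "svm"),
                              knn_k = 3L,
                              svm_c = 5,
                              svm_sigma = 2.58,
                              grid_search = FALSE,
                              grid_c = c(0.1, 1, 5, 10, 100),
                              grid_sigma = c(0.5, 1, 2.58, 5, 10),
                              cv_folds = 5L,
                              seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(knn_k >= 1, svm_c > 0, svm_sigma > 0, cv_folds >= 2)
  structure(list(kind = kind, knn_k = as.integer(knn_k), svm_c = svm_c,
                 svm_sigma = svm_sigma, grid_search = isTRUE(grid_search),
                 grid_c = grid_c, grid_sigma = grid_sigma,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train a pain-intensity classifier
#'
#' @param x Numeric matrix or tibble of feature rows (training set).
#' @param y Class labels, one per row.
#' @param config A [classifier_config()], or a kind string (`"lda"`,
#'   `"knn"`, `"svm"`) to use that kind's defaults.
#' @param ... Passed to [classifier_config()] when `config` is a string.
#' @return A `pain_classifier` object usable with [predict()].
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' m <- train_classifier(x, rep(c("a", "b"), each = 20), "lda")
#' predict(m, x[1:2, , drop = FALSE])
#' @export
train_classifier <- function(x, y, config = classifier_config(), ...) {
  if (is.character(config)) config <- classifier_config(kind = config, ...)
  x <- feature_block(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("training data must contain >= 2 classes")
  fit <- switch(config$kind,
    lda = fit_lda_ovr(x, y, classes),
    knn = fit_knn(x, y, config),
    svm = fit_svm(x, y, classes, config)
  )
  structure(list(kind = config$kind, config = config, classes = classes,
                 n_features = ncol(x), feature_names = colnames(x),
                 fit = fit),
            class = "pain_classifier")
}

#' One-vs-rest linear discriminant training
#'
#' Fits one binary linear discriminant per class (that class against the
#' pooled rest), each using the pooled within-group covariance
#' (ridge-regularised by `1e-6 x mean diagonal` -- the 36 statistical
#' features are partly collinear by construction). Prediction takes the
#' class whose discriminant score is highest.
#'
#' @inheritParams train_classifier
#' @return A `pain_classifier` of kind `"lda"`.
#' @export
train_lda_ovr <- function(x, y) {
  train_classifier(x, y, classifier_config("lda"))
}

fit_lda_ovr <- function(x, y, classes) {
  d <- ncol(x)
  disc <- lapply(classes, function(cl) {
    in1 <- y == cl
    x1 <- x[in1, , drop = FALSE]
    x0 <- x[!in1, , drop = FALSE]
    if (nrow(x1) < 2 || nrow(x0) < 2) {
      abort(sprintf("class '%s' needs >= 2 samples on each side", cl))
    }
    mu1 <- colMeans(x1)
    mu0 <- colMeans(x0)
    s1 <- crossprod(sweep(x1, 2, mu1))
    s0 <- crossprod(sweep(x0, 2, mu0))
    S <- (s1 + s0) / (nrow(x) - 2)
    eps <- 1e-6 * mean(diag(S))
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
    S <- S + diag(eps, d)
    w <- tryCatch(solve(S, mu1 - mu0),
                  error = function(e) abort(
                    "within-class covariance is singular even after regularisation"))
    list(w = w,
         b = -sum(w * (mu1 + mu0)) / 2 + log(nrow(x1) / nrow(x0)))
  })
  names(disc) <- classes
  list(discriminants = disc)
}

lda_scores <- function(fit, x, classes) {
  sc <- vapply(classes,
               function(cl) as.numeric(x %*% fit$discriminants[[cl]]$w +
                                         fit$discriminants[[cl]]$b),
               numeric(nrow(x)))
  matrix(sc, nrow = nrow(x))  # vapply drops to a vector for 1-row input
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mean), 2, st$sd, "/")
}

fit_knn <- function(x, y, config) {
  if (config$knn_k > nrow(x)) abort("knn_k exceeds the number of training rows")
  st <- standardize_fit(x)
  list(std = st, xs = standardize_apply(x, st), y = y, k = config$knn_k)
}

#' Distance-weighted k-nearest-neighbour vote
#'
#' Finds the `k` nearest training rows by Euclidean distance on
#' standardised features; each neighbour votes for its label with weight
#' `1/d`. A zero-distance neighbour decides the query outright. Weighted
#' ties break by smaller mean neighbour distance, then by label order.
#'
#' @param model A `pain_classifier` of kind `"knn"`.
#' @param query Feature row(s), matrix or tibble.
#' @return Character vector of predicted labels.
#' @export
knn_classify <- function(model, query) {
  stopifnot(inherits(model, "pain_classifier"), model$kind == "knn")
  predict(model, query)
}

knn_predict <- function(fit, xq) {
  d2 <- cpp_sqdist(xq, fit$xs)
  apply_rows(d2, function(drow) {
    nn <- order(drow)[seq_len(fit$k)]
    dn <- sqrt(drow[nn])
    if (any(dn == 0)) return(fit$y[nn[which(dn == 0)[1]]])
    w <- tapply(1 / dn, fit$y[nn], sum)
    best <- names(w)[w == max(w)]
    if (length(best) > 1) {
      md <- tapply(dn, fit$y[nn], mean)[best]
      best <- sort(best[md == min(md)])[1]
    }
    best
  })
}

apply_rows <- function(m, f) vapply(seq_len(nrow(m)), function(i) f(m[i, ]), character(1))

fit_svm <- function(x, y, classes, config) {
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  pars <- list(C = config$svm_c, sigma = config$svm_sigma)
  if (config$grid_search) {
    pars <- svm_grid_search(xs, y, config)
  }
  K <- exp(-cpp_sqdist(xs, xs) / (2 * pars$sigma^2))
  machines <- lapply(classes, function(cl) {
    yy <- ifelse(y == cl, 1, -1)
    sol <- cpp_svm_smo(K, yy, pars$C)
    keep <- which(sol$alpha > 1e-8)
    list(coef = sol$alpha[keep] * yy[keep], sv = keep, b = sol$b)
  })
  names(machines) <- classes
  list(std = st, xs = xs, machines = machines, C = pars$C,
       sigma = pars$sigma)
}

svm_grid_search <- function(xs, y, config) {
  folds <- with_seed(config$seed, stratified_folds(y, config$cv_folds))
  grid <- expand.grid(C = sort(config$grid_c),
                      sigma = sort(config$grid_sigma, decreasing = TRUE))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      cfg <- classifier_config("svm", svm_c = grid$C[g],
                               svm_sigma = grid$sigma[g])
      m <- train_classifier(xs[tr, , drop = FALSE], y[tr], cfg)
      mean(predict(m, xs[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  # ties toward smaller C then larger sigma: grid is ordered that way
  best <- which(acc >= max(acc) - 1e-12)[1]
  list(C = grid$C[best], sigma = grid$sigma[best])
}

svm_scores <- function(fit, xq, classes) {
  sc <- vapply(classes, function(cl) {
    m <- fit$machines[[cl]]
    Kq <- exp(-cpp_sqdist(xq, fit$xs[m$sv, , drop = FALSE]) /
                (2 * fit$sigma^2))
    as.numeric(Kq %*% m$coef + m$b)
  }, numeric(nrow(xq)))
  matrix(sc, nrow = nrow(xq))
}

#' Grid-searched RBF-SVM training
#'
#' Convenience wrapper: [train_classifier()] with kind `"svm"`. With
#' `grid_search = FALSE` (default) the model uses `(C, sigma) = (5, 2.58)`
#' directly; otherwise the configured grid is searched by stratified CV.
#'
#' @inheritParams train_classifier
#' @param config A [classifier_config()] with `kind = "svm"`.
#' @export
train_svm_grid <- function(x, y, config = classifier_config("svm")) {
  stopifnot(config$kind == "svm")
  train_classifier(x, y, config)
}

#' Predict pain levels for new feature rows
#'
#' Applies the stored standardisation (KNN/SVM) and the model's decision
#' rule. Rows must have the training width.
#'
#' @param object A `pain_classifier`.
#' @param newdata Feature matrix or tibble.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.pain_classifier <- function(object, newdata, ...) {
  x <- feature_block(newdata,
                     if (is.data.frame(newdata)) object$feature_names)
  if (ncol(x) != object$n_features) {
    abort(sprintf("feature width %d does not match training width %d",
                  ncol(x), object$n_features))
  }
  switch(object$kind,
    lda = {
      sc <- lda_scores(object$fit, x, object$classes)
      object$classes[max.col(sc, ties.method = "first")]
    },
    knn = knn_predict(object$fit, standardize_apply(x, object$fit$std)),
    svm = {
      sc <- svm_scores(object$fit, standardize_apply(x, object$fit$std),
                       object$classes)
      object$classes[max.col(sc, ties.method = "first")]
    }
  )
}

#' @export
print.pain_classifier <- function(x, ...) {
  cat(sprintf("<pain_classifier: %s, %d classes, %d features>\n",
              toupper(x$kind), length(x$classes), x$n_features))
  if (x$kind == "svm") {
    cat(sprintf("  C = %g, sigma = %g, support vectors: %s\n",
                x$fit$C, x$fit$sigma,
                paste(vapply(x$fit$machines, function(m) length(m$sv), 0L),
                      collapse = "/")))
  }
  invisible(x)
}

#' @export
glance.pain_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_classes = length(x$classes),
                 n_features = x$n_features)
}
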