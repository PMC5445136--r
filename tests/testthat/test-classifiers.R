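test_that("OvR-LDA separates blobs and matches a direct evaluation of the discriminants", {
  d <- make_blobs(30, centers = 4, d = 3, spacing = 6, sd = 0.8, seed = 4)
  m <- train_classifier(d$x, d$y, "lda")
  expect_equal(mean(predict(m, d$x) == d$y), 1.0)
  # direct one-vs-rest discriminant computation, written out in the test
  classes <- sort(unique(d$y))
  scores <- sapply(classes, function(cl) {
    x1 <- d$x[d$y == cl, ]; x0 <- d$x[d$y != cl, ]
    mu1 <- colMeans(x1); mu0 <- colMeans(x0)
    S <- ((nrow(x1) - 1) * cov(x1) + (nrow(x0) - 1) * cov(x0)) /
      (nrow(d$x) - 2)
    S <- S + diag(1e-6 * mean(diag(S)), ncol(S))
    w <- solve(S, mu1 - mu0)
    d$x %*% w - sum(w * (mu1 + mu0)) / 2 + log(nrow(x1) / nrow(x0))
  })
  expect_equal(predict(m, d$x), classes[max.col(scores)])
  # a training point deep inside a class keeps its label
  expect_equal(predict(m, d$x[1, , drop = FALSE]), d$y[1])
})

test_that("binary LDA direction agrees with MASS on separated blobs", {
  skip_if_not_installed("MASS")
  d <- make_blobs(40, centers = 2, d = 4, spacing = 4, sd = 1, seed = 9)
  m <- train_classifier(d$x, d$y, "lda")
  ref <- MASS::lda(d$x, grouping = d$y)
  q <- make_blobs(30, centers = 2, d = 4, spacing = 4, sd = 1.5, seed = 10)
  expect_equal(predict(m, q$x),
               as.character(predict(ref, q$x)$class))
})

test_that("weighted KNN vote follows the hand-computed example and zero-distance rule", {
  x <- matrix(c(0, 0.1, 1), ncol = 1)
  y <- c("A", "A", "B")
  m <- train_classifier(x, y, "knn", knn_k = 3)
  # query 0.05: weights ~ 20 + 20 for A vs ~ 1.05 for B
  expect_equal(predict(m, matrix(0.05)), "A")
  # query on a training point takes that label outright
  expect_equal(predict(m, matrix(1)), "B")
  # k = 1 reduces to the nearest neighbour
  m1 <- train_classifier(x, y, "knn", knn_k = 1)
  expect_equal(predict(m1, matrix(0.6)), "B")
  expect_error(train_classifier(x, y, "knn", knn_k = 9), "exceeds")
})

test_that("KNN matches an exhaustive brute-force search on a 200-row fixture", {
  d <- make_blobs(50, centers = 4, d = 5, spacing = 1.2, sd = 1, seed = 12)
  q <- make_blobs(20, centers = 4, d = 5, spacing = 1.2, sd = 1.3, seed = 13)
  m <- train_classifier(d$x, d$y, "knn")
  got <- predict(m, q$x)
  # oracle: plain loops on the standardised training set
  mu <- colMeans(d$x); sdv <- apply(d$x, 2, sd)
  xs <- sweep(sweep(d$x, 2, mu), 2, sdv, "/")
  qs <- sweep(sweep(q$x, 2, mu), 2, sdv, "/")
  oracle <- character(nrow(qs))
  for (i in seq_len(nrow(qs))) {
    dv <- numeric(nrow(xs))
    for (j in seq_len(nrow(xs))) dv[j] <- sqrt(sum((qs[i, ] - xs[j, ])^2))
    nn <- order(dv)[1:3]
    if (any(dv[nn] == 0)) {
      oracle[i] <- d$y[nn[dv[nn] == 0][1]]
    } else {
      w <- tapply(1 / dv[nn], d$y[nn], sum)
      oracle[i] <- names(w)[which.max(w)]
    }
  }
  expect_equal(got, oracle)
})

test_that("RBF-SVM solves XOR with the default hyperparameters", {
  set.seed(1)
  x <- rbind(matrix(rnorm(100, 0, 0.3), ncol = 2),
             matrix(rnorm(100, 3, 0.3), ncol = 2),
             cbind(rnorm(50, 0, 0.3), rnorm(50, 3, 0.3)),
             cbind(rnorm(50, 3, 0.3), rnorm(50, 0, 0.3)))
  y <- rep(c("a", "a", "b", "b"), each = 50)
  m <- train_classifier(x, y, "svm")
  expect_equal(mean(predict(m, x) == y), 1.0)
  # grid search disabled: the printed hyperparameters are used verbatim
  expect_equal(m$fit$C, 5)
  expect_equal(m$fit$sigma, 2.58)
})

test_that("SMO solution matches the quadprog dual optimum on a small fixture", {
  skip_if_not_installed("quadprog")
  d <- make_blobs(20, centers = 2, d = 2, spacing = 2.5, sd = 1, seed = 2)
  ys <- ifelse(d$y == "L0", 1, -1)
  xs <- scale(d$x)
  K <- exp(-as.matrix(dist(xs))^2 / (2 * 2.58^2))
  C <- 5
  sol <- painsense:::cpp_svm_smo(K, ys, C)
  n <- length(ys)
  Q <- (ys %o% ys) * K
  qp <- quadprog::solve.QP(Dmat = Q + diag(1e-8, n), dvec = rep(1, n),
                           Amat = cbind(ys, diag(n), -diag(n)),
                           bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  obj <- function(a) sum(a) - 0.5 * as.numeric(t(a) %*% Q %*% a)
  expect_equal(obj(sol$alpha), obj(qp$solution), tolerance = 1e-6)
  # alphas agree to the KKT tolerance of the SMO stopping rule
  expect_equal(as.numeric(sol$alpha), qp$solution, tolerance = 1e-2)
})

test_that("SVM and LDA agree on points far from a linear boundary", {
  d <- make_blobs(40, centers = 2, d = 2, spacing = 8, sd = 0.7, seed = 6)
  q <- make_blobs(25, centers = 2, d = 2, spacing = 8, sd = 0.7, seed = 7)
  ml <- train_classifier(d$x, d$y, "lda")
  ms <- train_classifier(d$x, d$y, "svm")
  expect_equal(predict(ms, q$x), predict(ml, q$x))
})

test_that("prediction is vectorised, deterministic, and checks the feature width", {
  d <- make_blobs(25, centers = 4, d = 3, spacing = 5, sd = 1, seed = 20)
  q <- make_blobs(10, centers = 4, d = 3, spacing = 5, sd = 1, seed = 21)
  for (kind in c("lda", "knn", "svm")) {
    m <- train_classifier(d$x, d$y, kind)
    p1 <- predict(m, q$x)
    expect_identical(p1, predict(m, q$x))
    perm <- sample(nrow(q$x))
    expect_identical(predict(m, q$x[perm, ]), p1[perm])
    expect_error(predict(m, q$x[, 1:2]), "width")
  }
  expect_error(train_classifier(d$x[1:25, ], d$y[1:25], "lda"), "2 classes")
})
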