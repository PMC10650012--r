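# Model wrappers. Each spec is a small list (name, hyperparameters, seed);
# fit/predict dispatch on the name. Features arrive already standardised by
# the cross-validation layer, so all wrappers disable internal scaling.

#' Classifier specification
#'
#' The five classifiers of the evaluation protocol: radial-kernel support
#' vector classifier (C = 1), random forest (100 trees), 1-nearest-neighbour,
#' linear and quadratic discriminant analysis. Hyperparameters are fixed
#' documented defaults; no tuning is performed.
#'
#' @param name one of `"SVC"`, `"RF"`, `"KNN1"`, `"LDA"`, `"QDA"`.
#' @param seed integer seed for stochastic learners (RF).
#' @param ntree random-forest tree count.
#' @param cost SVC cost parameter.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("SVC", "RF", "KNN1", "LDA", "QDA"),
                            seed = 1L, ntree = 100L, cost = 1) {
  name <- match.arg(name)
  structure(list(name = name, seed = as.integer(seed),
                 ntree = as.integer(ntree), cost = cost),
            class = "classifier_spec")
}

#' Regressor specification
#'
#' The eight regressors of the evaluation protocol: radial support vector
#' regression, random forest, 1-nearest-neighbour, linear regression,
#' decision tree, lasso, ridge, and a feed-forward neural network with two
#' hidden layers of 36 and 16 units.
#'
#' @param name one of `"SVR"`, `"RF"`, `"KNN1"`, `"LR"`, `"DT"`, `"Lasso"`,
#'   `"Ridge"`, `"ANN"`.
#' @param seed integer seed for stochastic learners (RF, ANN init).
#' @param ntree random-forest tree count.
#' @param cost SVR cost parameter.
#' @param lambda penalty for lasso/ridge (on standardised features).
#' @param hidden ANN hidden-layer sizes; fixed at `c(36, 16)`.
#' @param maxit ANN optimisation iteration cap.
#' @param weight_decay ANN L2 penalty; the default 0.01 is sized for the
#'   ~50-sample training folds of this protocol, where an unregularised
#'   36+16-unit network overfits badly.
#' @return an object of class `regressor_spec`.
#' @export
regressor_spec <- function(name = c("SVR", "RF", "KNN1", "LR", "DT",
                                    "Lasso", "Ridge", "ANN"),
                           seed = 1L, ntree = 100L, cost = 1,
                           lambda = 0.05, hidden = c(36L, 16L),
                           maxit = 2000L, weight_decay = 1e-2) {
  name <- match.arg(name)
  if (name == "ANN" && !identical(as.integer(hidden), c(36L, 16L)))
    stop("the ANN topology is fixed at two hidden layers of 36 and 16 units",
         call. = FALSE)
  structure(list(name = name, seed = as.integer(seed),
                 ntree = as.integer(ntree), cost = cost, lambda = lambda,
                 hidden = as.integer(hidden), maxit = as.integer(maxit),
                 weight_decay = weight_decay),
            class = "regressor_spec")
}

#' Default model sets
#'
#' @return list of all five [classifier_spec()]s or all eight
#'   [regressor_spec()]s, keyed by name.
#' @param seed seed passed to each spec.
#' @export
default_classifiers <- function(seed = 1L) {
  nm <- c("SVC", "RF", "KNN1", "LDA", "QDA")
  setNames(lapply(nm, classifier_spec, seed = seed), nm)
}

#' @rdname default_classifiers
#' @export
default_regressors <- function(seed = 1L) {
  nm <- c("SVR", "RF", "KNN1", "LR", "DT", "Lasso", "Ridge", "ANN")
  setNames(lapply(nm, regressor_spec, seed = seed), nm)
}

# ---- classification ------------------------------------------------------

fit_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  switch(spec$name,
    SVC = e1071::svm(X, y, kernel = "radial", cost = spec$cost, scale = FALSE),
    RF = with_seed(spec$seed,
                   randomForest::randomForest(X, y, ntree = spec$ntree)),
    KNN1 = list(X = X, y = y),
    LDA = MASS::lda(X, grouping = y),
    QDA = MASS::qda(X, grouping = y),
    stop("unknown classifier ", spec$name))
}

predict_classifier <- function(spec, fit, X) {
  X <- as.matrix(X)
  switch(spec$name,
    SVC = predict(fit, X),
    RF = predict(fit, X),
    KNN1 = fit$y[nn1_index(fit$X, X)],
    LDA = predict(fit, X)$class,
    QDA = predict(fit, X)$class,
    stop("unknown classifier ", spec$name))
}

# ---- regression ----------------------------------------------------------

fit_regressor <- function(spec, X, y) {
  X <- as.matrix(X)
  switch(spec$name,
    SVR = e1071::svm(X, y, kernel = "radial", cost = spec$cost, scale = FALSE),
    RF = with_seed(spec$seed,
                   randomForest::randomForest(X, y, ntree = spec$ntree)),
    KNN1 = list(X = X, y = y),
    LR = {
      df <- data.frame(y = y, X)
      lm(y ~ ., data = df)
    },
    DT = {
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df, method = "anova")
    },
    Lasso = fit_lasso(X, y, spec$lambda),
    Ridge = fit_ridge(X, y, spec$lambda),
    ANN = mlp_fit(X, y, hidden = spec$hidden, seed = spec$seed,
                  maxit = spec$maxit, weight_decay = spec$weight_decay),
    stop("unknown regressor ", spec$name))
}

predict_regressor <- function(spec, fit, X) {
  X <- as.matrix(X)
  switch(spec$name,
    SVR = as.numeric(predict(fit, X)),
    RF = as.numeric(predict(fit, X)),
    KNN1 = as.numeric(fit$y[nn1_index(fit$X, X)]),
    LR = as.numeric(predict(fit, data.frame(X))),
    DT = as.numeric(predict(fit, data.frame(X))),
    Lasso = ,
    Ridge = as.numeric(fit$intercept + X %*% fit$beta),
    ANN = mlp_predict(fit, X),
    stop("unknown regressor ", spec$name))
}

# Deterministic 1-nearest-neighbour lookup: index of the closest training
# row for each query row, ties broken towards the earliest training row.
nn1_index <- function(Xtr, Xq) {
  apply(Xq, 1, function(r) which.min(colSums((t(Xtr) - r)^2)))
}

# Ridge regression in closed form (glmnet-style objective
# 1/(2n) RSS + lambda/2 |beta|^2 on centred data).
fit_ridge <- function(X, y, lambda) {
  n <- nrow(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  beta <- solve(crossprod(Xc) / n + diag(lambda, ncol(X)),
                crossprod(Xc, y - ym) / n)
  list(beta = as.numeric(beta), intercept = ym - sum(xm * beta))
}

# Lasso: coordinate-descent soft-thresholding for p >= 2, closed form for
# p = 1 (objective 1/(2n) RSS + lambda |beta|_1 on centred data).
fit_lasso <- function(X, y, lambda, tol = 1e-9, maxit = 10000L) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  ssq <- colSums(Xc^2) / n
  beta <- numeric(p)
  r <- yc
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      zj <- sum(Xc[, j] * r) / n + ssq[j] * beta[j]
      bj <- if (ssq[j] > 0) soft(zj, lambda) / ssq[j] else 0
      if (bj != beta[j]) {
        r <- r - Xc[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
  }
  list(beta = beta, intercept = ym - sum(xm * beta))
}

# ---- two-hidden-layer perceptron -----------------------------------------
# Feed-forward network p -> 36 -> 16 -> 1 with tanh hidden units and a linear
# output, trained full-batch by BFGS on mean squared error with a small L2
# penalty. Inputs and targets are expected pre-standardised.

mlp_unpack <- function(theta, p, h) {
  i <- 0
  take <- function(n) { v <- theta[(i + 1):(i + n)]; i <<- i + n; v }
  W1 <- matrix(take(p * h[1]), p, h[1]); b1 <- take(h[1])
  W2 <- matrix(take(h[1] * h[2]), h[1], h[2]); b2 <- take(h[2])
  W3 <- matrix(take(h[2]), h[2], 1); b3 <- take(1)
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
}

mlp_fit <- function(X, y, hidden = c(36L, 16L), seed = 1L, maxit = 2000L,
                    weight_decay = 1e-2) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X); h <- hidden
  npar <- p * h[1] + h[1] + h[1] * h[2] + h[2] + h[2] + 1
  theta0 <- with_seed(seed, rnorm(npar, 0, 0.5) /
                        rep(c(sqrt(p), 1, sqrt(h[1]), 1, sqrt(h[2]), 1),
                            c(p * h[1], h[1], h[1] * h[2], h[2], h[2], 1)))
  fwd <- function(th) {
    w <- mlp_unpack(th, p, h)
    A1 <- tanh(sweep(X %*% w$W1, 2, w$b1, `+`))
    A2 <- tanh(sweep(A1 %*% w$W2, 2, w$b2, `+`))
    yhat <- as.numeric(A2 %*% w$W3 + w$b3)
    list(w = w, A1 = A1, A2 = A2, yhat = yhat)
  }
  fn <- function(th) {
    fw <- fwd(th)
    mean((fw$yhat - y)^2) / 2 + weight_decay * sum(th^2) / 2
  }
  gr <- function(th) {
    fw <- fwd(th)
    w <- fw$w
    d3 <- matrix((fw$yhat - y) / n, n, 1)
    gW3 <- crossprod(fw$A2, d3); gb3 <- sum(d3)
    d2 <- (d3 %*% t(w$W3)) * (1 - fw$A2^2)
    gW2 <- crossprod(fw$A1, d2); gb2 <- colSums(d2)
    d1 <- (d2 %*% t(w$W2)) * (1 - fw$A1^2)
    gW1 <- crossprod(X, d1); gb1 <- colSums(d1)
    c(as.numeric(gW1), gb1, as.numeric(gW2), gb2, as.numeric(gW3), gb3) +
      weight_decay * th
  }
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  structure(list(theta = opt$par, p = p, h = h), class = "sipemg_mlp")
}

mlp_predict <- function(fit, X) {
  X <- as.matrix(X)
  w <- mlp_unpack(fit$theta, fit$p, fit$h)
  A1 <- tanh(sweep(X %*% w$W1, 2, w$b1, `+`))
  A2 <- tanh(sweep(A1 %*% w$W2, 2, w$b2, `+`))
  as.numeric(A2 %*% w$W3 + w$b3)
}
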