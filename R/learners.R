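# The seven classifier families behind the model grid, under one interface:
# fit_learner() returns an object whose predict_learner() yields a
# probability of the NPD (responder) class. Features are z-scaled with
# statistics learned at fit time. Margin-type outputs (SVM, AdaBoost,
# nearest centroid) are mapped to [0, 1] by a logistic link fit on the
# training decision values.

#' @useDynLib immunosig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Names of the supported classifier algorithms
#' @return Character vector in the declared (tie-break) order.
#' @export
learner_algorithms <- function() {
  c("svm", "nb", "rf", "knn", "adaboost", "logitboost", "centroid")
}

scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

platt_fit <- function(dec, y01) {
  if (stats::sd(dec) == 0) return(c(a = 0, b = 2 * mean(y01) - 1))
  fit <- suppressWarnings(stats::glm(y01 ~ dec, family = stats::binomial()))
  co <- stats::coef(fit)
  if (any(!is.finite(co))) co <- c(0, 1)
  c(a = unname(co[1]), b = unname(co[2]))
}

platt_apply <- function(coefs, dec) {
  1 / (1 + exp(-(coefs["a"] + coefs["b"] * dec)))
}

svm_objective <- function(par, X, ysign, C) {
  w <- par[-1]; b <- par[1]
  f <- as.vector(X %*% w) + b
  xi <- pmax(0, 1 - ysign * f)
  0.5 * sum(w^2) + C * sum(xi^2)
}

svm_gradient <- function(par, X, ysign, C) {
  w <- par[-1]; b <- par[1]
  f <- as.vector(X %*% w) + b
  xi <- pmax(0, 1 - ysign * f)
  gb <- -2 * C * sum(xi * ysign)
  gw <- w - 2 * C * as.vector(crossprod(X, xi * ysign))
  c(gb, gw)
}

#' Fit one classifier
#'
#' @param algorithm One of [learner_algorithms()]: `"svm"` (linear
#'   maximum-margin classifier, squared hinge loss), `"nb"` (Gaussian naive
#'   Bayes), `"rf"` (bagged gini decision trees with random feature
#'   subsampling), `"knn"` (k-nearest-neighbor vote), `"adaboost"` (discrete
#'   AdaBoost over decision stumps), `"logitboost"` (boosted logistic
#'   regression stumps), `"centroid"` (nearest-centroid on standardized
#'   features, correlation-to-centroid score; the parameter-free learner).
#' @param X Numeric feature matrix (samples x features).
#' @param y01 Integer 0/1 labels (1 = NPD).
#' @param params Named list of hyperparameters for the algorithm (see
#'   [default_grids()]).
#' @return A `Learner` object for [predict_learner()].
#' @export
fit_learner <- function(algorithm, X, y01, params = list()) {
  algorithm <- match.arg(algorithm, learner_algorithms())
  stopifnot(is.matrix(X), length(y01) == nrow(X), all(y01 %in% c(0, 1)))
  sc <- scale_fit(X)
  Z <- scale_apply(X, sc)
  model <- switch(algorithm,
    svm = {
      C <- if (is.null(params$C)) 1 else params$C
      ysign <- ifelse(y01 == 1, 1, -1)
      opt <- stats::optim(rep(0, ncol(Z) + 1), svm_objective, svm_gradient,
                          X = Z, ysign = ysign, C = C, method = "BFGS",
                          control = list(maxit = 200))
      dec <- as.vector(Z %*% opt$par[-1]) + opt$par[1]
      list(w = opt$par[-1], b = opt$par[1], platt = platt_fit(dec, y01))
    },
    nb = {
      eps <- if (is.null(params$eps)) 1e-9 else params$eps
      fit_nb <- function(rows) {
        list(mu = colMeans(Z[rows, , drop = FALSE]),
             var = apply(Z[rows, , drop = FALSE], 2, stats::var))
      }
      cls <- list(`0` = fit_nb(y01 == 0), `1` = fit_nb(y01 == 1))
      vmax <- max(c(cls$`0`$var, cls$`1`$var, 1))
      for (k in names(cls)) cls[[k]]$var <- cls[[k]]$var + eps * vmax
      list(classes = cls, prior1 = mean(y01))
    },
    rf = {
      ntree <- if (is.null(params$ntree)) 500 else params$ntree
      depth <- if (is.null(params$max_depth)) 0 else params$max_depth
      mtry <- max(1L, floor(sqrt(ncol(Z))))
      list(forest = cpp_build_forest(Z, as.integer(y01), as.integer(ntree),
                                     mtry, as.integer(depth), 2L))
    },
    knn = {
      k <- if (is.null(params$k)) 5 else params$k
      list(train = Z, y = y01, k = as.integer(k))
    },
    adaboost = {
      rounds <- if (is.null(params$rounds)) 100 else params$rounds
      m <- cpp_adaboost(Z, as.integer(y01), as.integer(rounds))
      dec <- cpp_predict_adaboost(m, Z)
      list(stumps = m, platt = platt_fit(dec, y01))
    },
    logitboost = {
      rounds <- if (is.null(params$rounds)) 100 else params$rounds
      list(stumps = cpp_logitboost(Z, as.integer(y01), as.integer(rounds)))
    },
    centroid = {
      cen0 <- colMeans(Z[y01 == 0, , drop = FALSE])
      cen1 <- colMeans(Z[y01 == 1, , drop = FALSE])
      dec <- centroid_decision(Z, cen0, cen1)
      list(cen0 = cen0, cen1 = cen1, platt = platt_fit(dec, y01))
    })
  structure(list(algorithm = algorithm, params = params, scaler = sc,
                 model = model, features = colnames(X)),
            class = "Learner")
}

# Nearest-centroid decision value: difference of Euclidean distances to the
# standardized class centroids (positive favors class 1). A
# correlation-to-centroid score was considered but degenerates whenever the
# class centroids are near-constant across features (uniform signature
# shifts), so the distance form is used.
centroid_decision <- function(Z, cen0, cen1) {
  d0 <- sqrt(rowSums(sweep(Z, 2, cen0)^2))
  d1 <- sqrt(rowSums(sweep(Z, 2, cen1)^2))
  d0 - d1
}

#' Predict NPD probabilities from a fitted learner
#'
#' @param learner A `Learner` from [fit_learner()].
#' @param X Feature matrix with the same columns used at fit time.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_learner <- function(learner, X) {
  stopifnot(inherits(learner, "Learner"))
  Z <- scale_apply(X, learner$scaler)
  m <- learner$model
  p <- switch(learner$algorithm,
    svm = platt_apply(m$platt, as.vector(Z %*% m$w) + m$b),
    nb = {
      loglik <- function(cls) {
        rowSums(sweep(-0.5 * sweep(Z, 2, cls$mu)^2, 2, cls$var, "/") -
                  matrix(0.5 * log(2 * pi * cls$var), nrow(Z), ncol(Z), byrow = TRUE))
      }
      l1 <- loglik(m$classes$`1`) + log(max(m$prior1, 1e-12))
      l0 <- loglik(m$classes$`0`) + log(max(1 - m$prior1, 1e-12))
      1 / (1 + exp(l0 - l1))
    },
    rf = cpp_predict_forest(m$forest, Z),
    knn = {
      apply(Z, 1, function(x) {
        d <- sqrt(colSums((t(m$train) - x)^2))
        mean(m$y[order(d)[seq_len(m$k)]])
      })
    },
    adaboost = platt_apply(m$platt, cpp_predict_adaboost(m$stumps, Z)),
    logitboost = cpp_predict_logitboost(m$stumps, Z),
    centroid = platt_apply(m$platt, centroid_decision(Z, m$cen0, m$cen1)))
  pmin(1, pmax(0, as.numeric(p)))
}
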