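# L2-regularised linear classifiers fitted by BFGS on a smooth loss.
# Deterministic (zero start, fixed regularisation): no solver randomness,
# so feature-elimination orders and permutation p-values are reproducible.
#
# kind = "logistic": mean log(1 + exp(-y f)) + lambda/2 ||w||^2
# kind = "svm":      mean max(0, 1 - y f)^2  + lambda/2 ||w||^2
#   (squared hinge: differentiable, same large-margin geometry as the
#    usual linear SVM; the intercept is unpenalised)
fit_linear_classifier <- function(X, y, kind = c("logistic", "svm"),
                                  lambda = 0.01, maxit = 500L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- ifelse(as_binary_labels(y) == 1, 1, -1)
  assert_that(length(unique(y)) == 2, "need both classes to fit a classifier")
  n <- nrow(X); p <- ncol(X)

  objective <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    f <- drop(X %*% w) + b
    m <- y * f
    if (kind == "logistic") {
      # numerically stable log(1 + exp(-m))
      loss <- mean(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m))))
    } else {
      loss <- mean(pmax(0, 1 - m)^2)
    }
    loss + lambda / 2 * sum(w^2)
  }
  gradient <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    f <- drop(X %*% w) + b
    m <- y * f
    if (kind == "logistic") {
      g <- -y * plogis(-m) / n
    } else {
      g <- -2 * y * pmax(0, 1 - m) / n
    }
    c(drop(crossprod(X, g)) + lambda * w, sum(g))
  }

  fit <- optim(rep(0, p + 1), objective, gradient, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  if (fit$convergence != 0) {
    # retry under stronger regularisation (non-convergence safeguard)
    message(sprintf("classifier (%s) did not converge; refitting with lambda=%g",
                    kind, lambda * 10))
    fit <- optim(rep(0, p + 1), objective, gradient, method = "BFGS",
                 control = list(maxit = maxit * 2L, reltol = 1e-12))
  }
  structure(list(weights = fit$par[seq_len(p)], intercept = fit$par[p + 1],
                 kind = kind, lambda = lambda, value = fit$value,
                 feature_names = colnames(X)),
            class = "linear_classifier")
}

# Decision values (and class-1 probabilities for the logistic model).
predict_linear <- function(model, X) {
  X <- as.matrix(X)
  f <- drop(X %*% model$weights) + model$intercept
  list(decision = f,
       prob = if (model$kind == "logistic") plogis(f) else plogis(f))
}
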