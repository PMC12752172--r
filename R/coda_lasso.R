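# zero-sum elastic net via pairwise coordinate descent (C++ kernel,
# src/zerosum.cpp); pair moves preserve sum(beta) = 0 exactly
zerosum_enet <- function(Z, y, lambda, alpha_mix, weights = NULL,
                         beta = NULL, beta0 = NULL, tol = 1e-9,
                         max_sweeps = 500) {
  n <- nrow(Z)
  w <- weights %||% rep(1, n)
  beta <- beta %||% numeric(ncol(Z))
  beta0 <- beta0 %||% sum(w * y) / sum(w)
  zerosum_enet_cpp(Z, y, lambda, alpha_mix, w, beta, beta0, tol,
                   max_sweeps)
}

coda_design <- function(t, pseudo_prop) {
  q <- sweep(t, 2, colSums(t), "/")
  base::t(log(q + pseudo_prop))         # samples x taxa
}

#' Sparse zero-sum log-contrast regression (CODA-LASSO)
#'
#' Regresses a response on the log of total-sum-scaled taxon proportions
#' under the compositional constraint that the coefficients sum to zero,
#' with an elastic-net penalty (`alpha_mix = 1` is the pure lasso). The
#' zero-sum constraint makes the fitted linear predictor invariant to
#' per-sample rescaling of the log-composition, and the lasso part yields a
#' sparse signed taxon signature. The penalty weight is chosen by k-fold
#' cross-validation at the minimum mean error.
#'
#' @param t count table (OTUs x samples)
#' @param y continuous response (`family = "gaussian"`) or binary 0/1 or
#'   two-level factor (`family = "binomial"`)
#' @param alpha_mix elastic-net mixing in [0, 1]; 1 = lasso
#' @param n_lambda,lambda_min_ratio geometric penalty grid controls
#' @param lambda optional explicit penalty grid (descending)
#' @param cv_folds number of cross-validation folds
#' @param pseudocount count-scale pseudocount; converted to the proportion
#'   scale by dividing by the mean library size before the log
#' @param family loss: squared error or logistic deviance
#' @param seed integer seed for fold assignment
#' @return object of class `coda_lasso`: `beta` (selected-lambda
#'   coefficients, zero-sum), `beta0`, `lambda`, `lambda_opt`, `cv_error`,
#'   `path` (taxa x lambda), `selected` (nonzero taxa split by sign)
#' @export
fit_coda_lasso <- function(t, y, alpha_mix = 1, n_lambda = 50,
                           lambda_min_ratio = 1e-3, lambda = NULL,
                           cv_folds = 5, pseudocount = 0.5,
                           family = c("gaussian", "binomial"), seed = 1L) {
  family <- match.arg(family)
  t <- count_table(t)
  n <- ncol(t)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2) stop("binary response must have 2 levels")
    y <- as.numeric(y) - 1
  }
  stopifnot(length(y) == n, all(is.finite(y)))
  if (family == "gaussian" && var(y) == 0) stop("constant response")
  if (n < cv_folds) stop("need >= cv_folds samples")
  pseudo_prop <- pseudocount / mean(colSums(t))
  Z <- coda_design(t, pseudo_prop)

  if (is.null(lambda)) {
    Zc <- scale(Z, scale = FALSE)
    yc <- y - mean(y)
    lmax <- max(abs(crossprod(Zc, yc)) / n) / max(alpha_mix, 0.05) * 1.05
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = n_lambda))
  }
  if (!length(lambda)) stop("empty lambda grid")
  lambda <- sort(lambda, decreasing = TRUE)

  fit_path <- function(Ztr, ytr) {
    p <- ncol(Ztr)
    path <- matrix(0, p, length(lambda))
    b0s <- numeric(length(lambda))
    b <- numeric(p); b0 <- NULL
    for (li in seq_along(lambda)) {
      if (family == "gaussian") {
        f <- zerosum_enet(Ztr, ytr, lambda[li], alpha_mix, beta = b,
                          beta0 = b0)
        b <- f$beta; b0 <- f$beta0
      } else {
        # IRLS around the weighted zero-sum elastic net
        b0 <- b0 %||% stats::qlogis(pmin(pmax(mean(ytr), 0.01), 0.99))
        for (irls in 1:25) {
          eta <- b0 + drop(Ztr %*% b)
          pr <- stats::plogis(eta)
          w <- pmax(pr * (1 - pr), 1e-5)
          zwork <- eta + (ytr - pr) / w
          f <- zerosum_enet(Ztr, zwork, lambda[li], alpha_mix,
                            weights = w, beta = b, beta0 = b0)
          if (max(abs(f$beta - b)) < 1e-7 && abs(f$beta0 - b0) < 1e-7) {
            b <- f$beta; b0 <- f$beta0
            break
          }
          b <- f$beta; b0 <- f$beta0
        }
      }
      path[, li] <- b
      b0s[li] <- b0
    }
    list(path = path, beta0 = b0s)
  }

  full <- fit_path(Z, y)

  set.seed(child_seed(seed, "cvfolds"))
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  cv_err <- matrix(NA_real_, cv_folds, length(lambda))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    pf <- fit_path(Z[tr, , drop = FALSE], y[tr])
    eta <- matrix(pf$beta0, sum(!tr), length(lambda), byrow = TRUE) +
      Z[!tr, , drop = FALSE] %*% pf$path
    if (family == "gaussian") {
      cv_err[f, ] <- colMeans((y[!tr] - eta)^2)
    } else {
      pr <- stats::plogis(eta)
      pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
      cv_err[f, ] <- colMeans(-2 * (y[!tr] * log(pr) +
                                      (1 - y[!tr]) * log(1 - pr)))
    }
  }
  cvm <- colMeans(cv_err)
  opt <- which.min(cvm)
  beta <- setNames(full$path[, opt], rownames(t))
  nz <- beta[beta != 0]
  structure(list(
    beta = beta, beta0 = full$beta0[opt], lambda = lambda,
    lambda_opt = lambda[opt], cv_error = cvm,
    path = `dimnames<-`(full$path, list(rownames(t), NULL)),
    path_beta0 = full$beta0,
    selected = list(positive = names(nz)[nz > 0],
                    negative = names(nz)[nz < 0]),
    alpha_mix = alpha_mix, family = family,
    pseudo_prop = pseudo_prop, seed = seed),
    class = "coda_lasso")
}

#' @export
print.coda_lasso <- function(x, ...) {
  cat(sprintf("CODA-LASSO (%s, alpha = %g): lambda_opt = %.4g, %d taxa selected (sum beta = %.1e)\n",
              x$family, x$alpha_mix, x$lambda_opt, sum(x$beta != 0),
              sum(x$beta)))
  if (length(x$selected$positive))
    cat("  positive:", paste(x$selected$positive, collapse = ", "), "\n")
  if (length(x$selected$negative))
    cat("  negative:", paste(x$selected$negative, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.coda_lasso <- function(object, ...) {
  c(`(Intercept)` = object$beta0, object$beta)
}

#' @export
plot.coda_lasso <- function(x, ...) {
  plot(log(x$lambda), x$cv_error, type = "b", pch = 16,
       xlab = "log lambda", ylab = "mean CV error", ...)
  abline(v = log(x$lambda_opt), lty = 2)
  invisible(x)
}

#' Predict from a CODA-LASSO fit
#' @param object a `coda_lasso`
#' @param t_new count table containing the fitted taxa
#' @param type `"response"` (probabilities for logistic loss) or `"link"`
#' @param ... unused
#' @export
predict.coda_lasso <- function(object, t_new, type = c("response", "link"),
                               ...) {
  type <- match.arg(type)
  miss <- setdiff(names(object$beta), rownames(t_new))
  if (length(miss)) stop("taxa missing from new table: ", miss[1])
  Z <- coda_design(t_new[names(object$beta), , drop = FALSE],
                   object$pseudo_prop)
  eta <- drop(object$beta0 + Z %*% object$beta)
  if (object$family == "binomial" && type == "response") stats::plogis(eta)
  else eta
}
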