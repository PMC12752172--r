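test_that("design matrices use treatment coding against declared references", {
  md <- data.frame(
    amendment = factor(c("None", "FYM", "Digestate", "Slurry", "None",
                         "FYM"),
                       levels = c("None", "FYM", "Digestate", "Slurry")),
    LOI = c(5, 6, 9, 8, 5.5, 6.5),
    row.names = paste0("S", 1:6))
  X <- build_design(md, c("amendment", "LOI"),
                    references = list(amendment = "None"))
  expect_identical(colnames(X), c("amendment_FYM", "amendment_Digestate",
                                  "amendment_Slurry", "LOI"))
  expect_equal(unname(X[1, 1:3]), c(0, 0, 0))   # reference rows all zero
  expect_equal(mean(X[, "LOI"]), 0, tolerance = 1e-12)
  expect_equal(sd(X[, "LOI"]), 1, tolerance = 1e-12)
  expect_error(build_design(md, c("amendment"),
                            references = list(amendment = "Compost")),
               "Compost")
  expect_error(build_design(transform(md, k = 1), c("k")), "constant")
})

test_that("with no latent variables the model collapses to independent GLMs", {
  set.seed(51)
  n <- 60; p <- 8
  x <- rbinom(n, 1, 0.5)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  b0 <- runif(p, 0, 2); b1 <- runif(p, -1, 1)
  Y <- sapply(seq_len(p), function(j) rpois(n, exp(b0[j] + b1[j] * x)))
  tt <- t(Y)
  dimnames(tt) <- list(paste0("OTU_", 1:p), paste0("S", 1:n))
  fit <- fit_gllvm(tt, X, family = "poisson", d = 0)
  ref <- sapply(seq_len(p), function(j)
    coef(stats::glm(Y[, j] ~ x, family = stats::poisson())))
  expect_equal(unname(fit$intercepts), unname(ref[1, ]), tolerance = 1e-4)
  expect_equal(unname(fit$coef[, 1]), unname(ref[2, ]), tolerance = 1e-4)
})

test_that("the negative binomial fit matches glm.nb without latent variables", {
  skip_if_not_installed("MASS")
  set.seed(52)
  n <- 80
  x <- rnorm(n)
  mu <- exp(1.5 + 0.8 * x)
  y <- rnbinom(n, size = 2, mu = mu)
  tt <- matrix(y, 1, n, dimnames = list("OTU_1", paste0("S", 1:n)))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- suppressWarnings(fit_gllvm(tt, X, family = "nb", d = 0))
  ref <- suppressWarnings(MASS::glm.nb(y ~ x))
  expect_equal(unname(fit$coef[1, 1]), unname(coef(ref)[2]),
               tolerance = 1e-3)
  expect_equal(unname(fit$dispersion), ref$theta, tolerance = 0.05)
})

test_that("fits are reproducible and high-zero taxa are excluded", {
  set.seed(53)
  n <- 40; p <- 6
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  tt <- matrix(rpois(p * n, 4), p, n,
               dimnames = list(paste0("OTU_", 1:p), paste0("S", 1:n)))
  tt[6, ] <- 0L; tt[6, 1] <- 1L     # 97.5% zeros
  expect_warning(f1 <- fit_gllvm(tt, X, family = "poisson", d = 1,
                                 seed = 4),
                 "excluding 1 taxa")
  f2 <- suppressWarnings(fit_gllvm(tt, X, family = "poisson", d = 1,
                                   seed = 4))
  expect_identical(f1$coef, f2$coef)
  expect_identical(nrow(f1$coef), 5L)
  expect_error(fit_gllvm(tt[1:5, ], X, d = 40), "d must be")
})

test_that("latent loadings satisfy the triangular identifiability convention", {
  set.seed(54)
  n <- 50; p <- 10; d <- 2
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  U <- matrix(rnorm(n * d), n, d)
  Th <- matrix(rnorm(p * d, sd = 0.5), p, d)
  Y <- matrix(rpois(n * p, as.vector(exp(1 + U %*% t(Th)))), n, p)
  tt <- t(Y)
  dimnames(tt) <- list(paste0("OTU_", 1:p), paste0("S", 1:n))
  fit <- suppressWarnings(fit_gllvm(tt, X, family = "poisson", d = 2,
                                    seed = 5))
  L <- fit$loadings
  expect_equal(L[1, 2], 0, tolerance = 1e-10)
  expect_gte(L[1, 1], 0)
  expect_gte(L[2, 2], 0)
})

test_that("directional labels follow the confidence intervals", {
  fit <- structure(list(
    coef = matrix(c(0.65, -0.05, -0.8), 3, 1,
                  dimnames = list(paste0("t", 1:3), "x")),
    se = matrix(c(0.23, 0.23, 0.2), 3, 1,
                dimnames = list(paste0("t", 1:3), "x"))),
    class = "gllvm_fit")
  lab <- directional_associations(fit)
  expect_identical(unname(lab[, 1]), c("positive", "none", "negative"))
  # wider level flips a borderline case to none
  lab99 <- directional_associations(fit, level = 0.999)
  expect_identical(unname(lab99[1, 1]), "none")
})
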