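make_perm_fixture <- function(n = 24, seed = 2) {
  p <- simulate_metacommunity(100, 0, 1, seed = seed)
  cnt <- simulate_neutral_counts(p, 0.3, rep(5000L, n), seed = seed + 1)
  set.seed(seed + 2)
  meta <- data.frame(g = factor(rep(c("a", "b", "c"),
                                    length.out = n)),
                     x = rnorm(n), row.names = colnames(cnt))
  list(d = bray_curtis(cnt), meta = meta)
}

test_that("sequential partitioning agrees with vegan's adonis2", {
  fx <- make_perm_fixture()
  fit <- permanova(fx$d, fx$meta, c("g", "x"), n_perm = 99, seed = 5)
  ref <- vegan::adonis2(stats::as.dist(fx$d) ~ g + x, data = fx$meta,
                        permutations = 99, by = "terms")
  expect_equal(fit$table$sum_sq[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(fit$table$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(fit$table$r_squared[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(sum(fit$table$r_squared), 1, tolerance = 1e-10)
})

test_that("p-values respect the permutation lower bound and R2 sums to one", {
  fx <- make_perm_fixture(seed = 9)
  fit <- permanova(fx$d, fx$meta, c("g", "x"), n_perm = 49, seed = 1)
  p <- fit$table$p_value[1:2]
  expect_true(all(p >= 1 / 50 & p <= 1))
  expect_equal(sum(fit$table$r_squared), 1, tolerance = 1e-10)
  expect_error(permanova(fx$d, transform(fx$meta, g = factor("a")), "g"),
               "constant term")
})

test_that("perfect two-cluster separation reaches the minimal p-value", {
  n <- 12
  d <- matrix(1, n, n)
  d[1:6, 1:6] <- 0.01; d[7:12, 7:12] <- 0.01
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  meta <- data.frame(g = factor(rep(c("a", "b"), each = 6)),
                     row.names = rownames(d))
  fit <- permanova(d, meta, "g", n_perm = 199, seed = 3)
  expect_equal(fit$table$p_value[1], 1 / 200, tolerance = 1e-12)
})

test_that("exhaustive enumeration reproduces the brute-force p-value", {
  fx <- make_perm_fixture(n = 6, seed = 13)
  fit <- permanova(fx$d, fx$meta, "g", exhaustive = TRUE)
  G <- microcore:::gower_centre(fx$d)
  X <- stats::model.matrix(~g, fx$meta)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  H0 <- matrix(1 / 6, 6, 6)
  fstat <- function(Gp) {
    ssm <- sum(H * Gp) - sum(H0 * Gp)
    ssr <- sum(diag(Gp)) - sum(H * Gp)
    (ssm / 2) / (ssr / 3)
  }
  perms <- microcore:::all_permutations(6)
  f_obs <- fstat(G)
  p_bf <- mean(apply(perms, 1, function(pp) fstat(G[pp, pp]) >= f_obs - 1e-12))
  expect_equal(fit$table$p_value[1], p_bf, tolerance = 1e-12)
  expect_identical(fit$n_perm, 720L)
})

test_that("samples without metadata are dropped with a warning", {
  fx <- make_perm_fixture(seed = 21)
  meta <- fx$meta[-1, , drop = FALSE]
  expect_warning(fit <- permanova(fx$d, meta, "g", n_perm = 19, seed = 1),
                 "without metadata")
  expect_identical(fit$n, nrow(fx$meta) - 1L)
})

test_that("stepwise db-RDA recovers an injected driver and allows empty selection", {
  hits_first <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    p <- simulate_metacommunity(120, 0, 1, seed = 100 + r)
    md <- data.frame(Ca = rnorm(30), noise1 = rnorm(30), noise2 = rnorm(30),
                     row.names = paste0("S", 1:30))
    eff <- matrix(2.5, 20, 1,
                  dimnames = list(names(p)[1:20], "Ca"))
    tilted <- apply_environmental_filter(p, md, eff)
    cnt <- simulate_neutral_counts(tilted, 0.5, rep(5000L, 30),
                                   seed = 200 + r)
    colnames(cnt) <- rownames(md)
    sel <- stepwise_dbrda(bray_curtis(cnt), md,
                          c("Ca", "noise1", "noise2"),
                          n_perm = 99, seed = 300 + r)
    if (length(sel$selected) && sel$selected[1] == "Ca")
      hits_first <- hits_first + 1
  }
  expect_gte(hits_first, round(0.9 * reps))

  # pure noise: empty selection is allowed and common
  p <- simulate_metacommunity(80, 0, 1, seed = 999)
  cnt <- simulate_neutral_counts(p, 0.5, rep(4000L, 20), seed = 998)
  md <- data.frame(noise1 = rnorm(20), noise2 = rnorm(20),
                   row.names = colnames(cnt))
  sel <- stepwise_dbrda(bray_curtis(cnt), md, c("noise1", "noise2"),
                        n_perm = 99, seed = 997)
  expect_true(length(sel$selected) <= 1)
  expect_warning(stepwise_dbrda(bray_curtis(cnt),
                                transform(md, k = 1),
                                c("noise1", "k"), n_perm = 19, seed = 1),
                 "constant")
})
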