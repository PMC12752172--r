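test_that("Bray-Curtis hits its boundary and hand-computed cases", {
  m <- matrix(c(2L, 1L, 0L,
                2L, 1L, 0L,
                0L, 1L, 2L), 3, 3,
              dimnames = list(paste0("o", 1:3), c("a", "b", "c")))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2 / 3, tolerance = 1e-12)
  disj <- matrix(c(3L, 0L, 0L, 4L), 2, 2,
                 dimnames = list(c("o1", "o2"), c("a", "b")))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
})

test_that("unweighted UniFrac matches exhaustive edge enumeration", {
  # star tree with unit branches, disjoint tip sets -> 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- matrix(0L, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  m[c("A", "B"), "s1"] <- 1L
  m[c("C", "D"), "s2"] <- 1L
  expect_equal(unweighted_unifrac(m, star)["s1", "s2"], 1)
  m2 <- m; m2[, 2] <- m2[, 1]
  expect_equal(unweighted_unifrac(m2, star)["s1", "s2"], 0)

  # balanced 4-tip tree, overlapping samples, vs brute force
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m3 <- matrix(0L, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                         c("s1", "s2")))
  m3[c("A", "B"), "s1"] <- 3L
  m3[c("A", "C"), "s2"] <- 2L
  got <- unweighted_unifrac(m3, tr)["s1", "s2"]
  expect_equal(got, bf_unifrac(tr, c("A", "B"), c("A", "C")),
               tolerance = 1e-12)

  miss <- rbind(m3, OTU_X = c(1L, 0L))
  expect_error(unweighted_unifrac(miss, tr), "OTU_X")
})

test_that("UniFrac agrees with brute force on random trees and tables", {
  for (s in 1:4) {
    tr <- simulate_tree(12, seed = 20 + s)
    m <- random_fixture(12, 4, seed = 30 + s, lambda = 1)
    rownames(m) <- tr$tip.label
    d <- unweighted_unifrac(m, tr)
    for (j in 1:3) for (k in (j + 1):4) {
      expect_equal(d[j, k],
                   bf_unifrac(tr, rownames(m)[m[, j] > 0],
                              rownames(m)[m[, k] > 0]),
                   tolerance = 1e-10)
    }
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(11)
  pts <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  fit <- pcoa(d)
  rec <- as.matrix(dist(fit$points[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  expect_true(all(diff(fit$eig) <= 1e-8))
  expect_true(all(fit$prop_explained >= 0 & fit$prop_explained <= 1))

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(max(abs(pcoa(z)$points)), 0)
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(pcoa(dna), "NA")
})

test_that("distance matrices round-trip through TSV", {
  m <- random_fixture(8, 5, seed = 40)
  d <- bray_curtis(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance(d, path)
  expect_equal(read_distance(path), d, tolerance = 1e-12)
})

test_that("distance regression returns the resilience slope", {
  m <- random_fixture(20, 8, seed = 50)
  d1 <- bray_curtis(m)
  # exact linear relations make summary.lm warn about a perfect fit
  expect_equal(suppressWarnings(distance_regression(d1, d1))$slope, 1,
               tolerance = 1e-10)
  half <- suppressWarnings(distance_regression(d1, 0.5 * d1))
  expect_equal(half$slope, 0.5, tolerance = 1e-10)
  expect_equal(half$intercept, 0, tolerance = 1e-10)
  # permuted pairs decouple the matrices: slope within 2 SE of zero
  set.seed(6)
  perm <- sample(nrow(d1))
  d2 <- d1[perm, perm]
  dimnames(d2) <- dimnames(d1)
  fit <- distance_regression(d1, d2)
  expect_lt(abs(fit$slope), 2.5 * fit$slope_se + 0.2)
  expect_error(distance_regression(d1[1:2, 1:2], d1[1:2, 1:2]), ">= 3")
})
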