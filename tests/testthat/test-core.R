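test_that("the occupancy index averages site occupancy and replication consistency", {
  cnt <- matrix(c(5L, 5L, 3L, 0L,
                  1L, 1L, 1L, 1L,
                  0L, 0L, 0L, 0L), nrow = 3, byrow = TRUE,
                dimnames = list(c("X", "Y", "Z"),
                                c("a1", "a2", "b1", "b2")))
  oi <- occupancy_index(cnt, c("A", "A", "B", "B"))
  expect_equal(oi["Y", "index"], 1)          # present everywhere
  expect_equal(oi["Z", "index"], 0)          # absent everywhere
  expect_equal(oi["X", "site_occupancy"], (1 + 0.5) / 2)
  expect_equal(oi["X", "replication_consistency"], (1 + 0) / 2)
  expect_equal(oi["X", "index"], 0.625)
  expect_error(occupancy_index(cnt, c("A", "A", NA, "B")), "empty group")
})

test_that("the index is presence-based, with abundance only breaking ties", {
  m <- random_fixture(12, 6, seed = 41)
  g <- rep(c("u", "v"), each = 3)
  oi1 <- occupancy_index(m, g)
  scaled <- m
  scaled[, 1] <- scaled[, 1] * 7L
  oi2 <- occupancy_index(count_table(scaled), g)
  expect_equal(oi1[rownames(oi2), "index"], oi2$index, tolerance = 1e-12)
})

test_that("the contribution curve is a normalised cumulative decomposition", {
  m <- random_fixture(15, 6, seed = 42, lambda = 20)
  ranking <- rownames(m)[order(rowSums(m), decreasing = TRUE)]
  curve <- bc_contribution_curve(m, ranking)
  expect_true(all(diff(curve$E) >= -1e-12))
  expect_equal(curve$E[nrow(curve)], 1, tolerance = 1e-10)
  expect_equal(curve$C, 1 - curve$E, tolerance = 1e-12)
  # E(k) against a direct mean-pairwise computation at k = 5
  libs <- colSums(m)
  k <- 5
  top <- ranking[1:k]
  num <- 0; den <- 0; cnt_pairs <- 0
  for (j in 1:5) for (l in (j + 1):6) {
    num <- num + sum(abs(m[top, j] - m[top, l])) / (libs[j] + libs[l])
    den <- den + sum(abs(m[, j] - m[, l])) / (libs[j] + libs[l])
  }
  expect_equal(curve$E[k], unname(num / den), tolerance = 1e-10)
})

test_that("the stopping rule reads increments of the explanatory value", {
  curve <- data.frame(otu = paste0("o", 1:5),
                      E = c(0.50, 0.80, 0.95, 0.96, 0.97),
                      C = 1 - c(0.50, 0.80, 0.95, 0.96, 0.97))
  core <- select_core(curve, delta = 0.02)
  expect_identical(core$k, 3L)
  expect_identical(core$core, paste0("o", 1:3))

  # every increment clears delta: all taxa are core
  curve2 <- data.frame(otu = paste0("o", 1:4),
                       E = c(0.25, 0.50, 0.75, 1.0), C = NA)
  expect_identical(select_core(curve2, delta = 0.02)$k, 4L)

  # k >= 1 even when the first increment is tiny
  curve3 <- data.frame(otu = paste0("o", 1:3),
                       E = c(0.001, 0.002, 0.003), C = NA)
  expect_identical(select_core(curve3, delta = 0.02)$k, 1L)

  bad <- data.frame(otu = paste0("o", 1:3), E = c(0.5, 0.4, 1), C = NA)
  expect_error(select_core(bad), "decreases")
})

test_that("a dominant structured subset is recovered exactly", {
  set.seed(43)
  n <- 12; p <- 20
  m <- matrix(rpois(p * n, 40), p, n,
              dimnames = list(paste0("OTU_", 1:p), paste0("S", 1:n)))
  m[1:3, ] <- matrix(rpois(3 * n, 400), 3, n) *
    rep(sample(c(1L, 9L), n, replace = TRUE), each = 3)
  m <- count_table(m)
  ranking <- c(paste0("OTU_", 1:3),
               sample(paste0("OTU_", 4:p)))
  core <- select_core(bc_contribution_curve(m, ranking), delta = 0.02)
  expect_identical(sort(core$core), sort(paste0("OTU_", 1:3)))
})

test_that("per-level occupancy models run within levels and pool", {
  ds <- simulate_dataset(sim_config(n_taxa = 60, n_samples = 24,
                                    depth_range = c(1000L, 2000L),
                                    amendment_freq = c(None = 0.5,
                                                       FYM = 0.5,
                                                       Digestate = 0,
                                                       Slurry = 0),
                                    seed = 44))
  cores <- occupancy_models(ds$counts, ds$metadata,
                            model_var = "amendment", site_var = "farm_id")
  expect_true("all" %in% names(cores))
  expect_true(all(vapply(cores, function(x) x$k >= 1, logical(1))))
  expect_true(all(vapply(cores, function(x)
    is.numeric(x$min_occupancy) && x$min_occupancy > 0, logical(1))))

  md1 <- ds$metadata
  md1$amendment[1] <- "Slurry"   # a level with a single sample
  expect_warning(occupancy_models(ds$counts, md1), "skipping level")
})

test_that("core overlap computes Venn counts and sharing percentages", {
  ov <- core_overlap(list(x = c("A", "B", "C"), y = c("B", "C", "D")))
  expect_equal(unname(ov$pairwise_sharing), 50)
  expect_equal(ov$total_sharing, 50)
  expect_equal(sum(ov$venn_counts), 4)

  same <- core_overlap(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(same$total_sharing, 100)
  none <- core_overlap(list(x = "A", y = "B"))
  expect_equal(none$total_sharing, 0)
  expect_error(core_overlap(list(x = "A")), ">= 2")
})

test_that("neutral overlay joins partition labels onto the core", {
  p <- simulate_metacommunity(100, 0, 1.5, seed = 45)
  cnt <- simulate_neutral_counts(p, 0.2, rep(3000L, 20), seed = 46)
  fit <- fit_sloan_neutral(cnt)
  stats <- occupancy_index(cnt, rep(c("a", "b"), each = 10))
  curve <- bc_contribution_curve(cnt, rownames(stats))
  core <- select_core(curve, ranking_stats = stats)
  ov <- neutral_overlay(core, fit)
  expect_equal(sum(ov$counts), core$k)
  fake <- core
  fake$core <- c(fake$core, "OTU_NOT_THERE")
  expect_error(neutral_overlay(fake, fit), "OTU_NOT_THERE")
})
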