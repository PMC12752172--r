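test_that("simulated trees are reproducible with positive branch lengths", {
  t1 <- simulate_tree(2, seed = 5)
  expect_identical(ape::Ntip(t1), 2L)
  a <- ape::write.tree(simulate_tree(100, seed = 7))
  b <- ape::write.tree(simulate_tree(100, seed = 7))
  expect_identical(a, b)
  tr <- simulate_tree(100, seed = 8)
  expect_true(all(tr$edge.length > 0))
  expect_error(simulate_tree(1), "n_tips")
})

test_that("metacommunity proportions are normalised and reproducible", {
  p <- simulate_metacommunity(200, 0, 1.5, seed = 2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_identical(p, simulate_metacommunity(200, 0, 1.5, seed = 2))
  # rank-abundance curve decreasing, concave-ish on the log scale
  sorted <- sort(p, decreasing = TRUE)
  expect_true(all(diff(log(sorted)) <= 0))
})

test_that("neutral sampling tracks the source at high migration and is seeded", {
  p <- simulate_metacommunity(50, 0, 1, seed = 3)
  cnt <- simulate_neutral_counts(p, 1e6, rep(50000L, 4), seed = 4)
  props <- sweep(cnt, 2, colSums(cnt), "/")
  expect_lt(max(abs(props - p)), 0.01)
  expect_identical(cnt, simulate_neutral_counts(p, 1e6, rep(50000L, 4),
                                                seed = 4))
  expect_error(simulate_neutral_counts(p, 0, rep(100L, 2)), "m must be")
})

test_that("occupancy increases with metacommunity abundance under neutral sampling", {
  p <- simulate_metacommunity(500, 0, 1.5, seed = 6)
  cnt <- simulate_neutral_counts(p, 0.1, rep(8000L, 40), seed = 7)
  occ <- rowMeans(cnt > 0)
  expect_gt(cor(p, occ, method = "spearman"), 0.9)
})

test_that("environmental filtering tilts proportions as specified", {
  p <- simulate_metacommunity(40, 0, 1, seed = 8)
  md <- data.frame(Ca = rnorm(25, 2500, 300),
                   row.names = paste0("S", 1:25))
  eff0 <- matrix(0, 3, 1, dimnames = list(names(p)[1:3], "Ca"))
  flat <- apply_environmental_filter(p, md, eff0)
  expect_equal(max(apply(flat, 1, sd)), 0, tolerance = 1e-15)

  eff <- matrix(2, 1, 1, dimnames = list("OTU_1", "Ca"))
  tilted <- apply_environmental_filter(p, md, eff)
  expect_gt(cor(tilted["OTU_1", ], md$Ca, method = "spearman"), 0.9)
  expect_equal(colSums(tilted), setNames(rep(1, 25), rownames(md)),
               tolerance = 1e-12)

  md_bad <- md; md_bad$Ca[1] <- NA
  expect_error(apply_environmental_filter(p, md_bad, eff), "non-finite")
})

test_that("clade-confined effects make clade members co-vary", {
  tr <- simulate_tree(100, seed = 9)
  clade <- compact_clade_tips(tr, 15)
  expect_gt(length(clade), 2)
  p <- simulate_metacommunity(100, 0, 1, seed = 10)
  md <- data.frame(Ca = rnorm(40, 0, 1), row.names = paste0("S", 1:40))
  eff <- matrix(2, length(clade), 1, dimnames = list(clade, "Ca"))
  tilted <- apply_environmental_filter(p, md, eff)
  lt <- log(tilted)
  cors <- cor(t(lt))
  in_clade <- rownames(tilted) %in% clade
  within <- mean(cors[in_clade, in_clade][upper.tri(cors[in_clade, in_clade])])
  background <- mean(cors[in_clade, !in_clade])
  expect_gt(within, background)
})

test_that("the default dataset matches the survey design envelope", {
  ds <- simulate_dataset(sim_config(seed = 11))
  expect_identical(dim(ds$counts), c(300L, 116L))
  libs <- library_sizes(ds$counts)
  expect_true(all(libs >= 5079 & libs <= 41827))
  expect_identical(levels(ds$metadata$amendment),
                   c("None", "FYM", "Digestate", "Slurry"))
  expect_identical(length(levels(ds$metadata$texture)), 4L)
  expect_true(all(ds$truth$filtered_taxa %in% rownames(ds$counts)))
  expect_identical(ds$truth$m_true, 0.1)

  ds2 <- simulate_dataset(sim_config(seed = 11))
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(ape::write.tree(ds$tree), ape::write.tree(ds2$tree))
})

test_that("a zero-effect configuration is purely neutral", {
  cfg <- sim_config(n_taxa = 80, n_samples = 20, effect_size = 0,
                    depth_range = c(2000L, 4000L), seed = 12)
  ds <- simulate_dataset(cfg)
  # all samples share one source distribution: per-taxon proportions differ
  # only by sampling noise, so group means agree within Monte Carlo error
  props <- sweep(ds$counts, 2, colSums(ds$counts), "/")
  hi <- ds$metadata$Ca > stats::median(ds$metadata$Ca)
  diffs <- abs(rowMeans(props[, hi]) - rowMeans(props[, !hi]))
  expect_lt(max(diffs), 0.05)
})
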