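#' Simulation configuration for the synthetic community generator
#'
#' The defaults emulate the survey design the package's analyses target: 116
#' soil samples drawn from 14 farms, four organic-amendment groups with the
#' observed imbalance (None 0.55, FYM 0.38, Digestate 0.035, Slurry 0.035 —
#' the two rare groups land near n = 4), four soil textures, library sizes
#' uniform on [5079, 41827] reads, a lognormal metacommunity, Sloan-type
#' neutral sampling with migration parameter `m_true`, and deterministic
#' environmental filtering: a phylogenetically clustered subset of taxa whose
#' local relative abundances respond to the continuous covariates Ca and LOI.
#'
#' @param n_taxa number of OTUs in the metacommunity
#' @param n_samples number of samples
#' @param n_farms number of farm labels
#' @param amendment_freq named probabilities for the amendment groups
#' @param textures soil texture level names
#' @param log_mean,log_sd lognormal parameters of metacommunity abundances
#' @param m_true Sloan migration parameter used by the neutral sampler
#' @param depth_range min/max library size (reads), sampled uniformly
#' @param n_filtered number of environmentally filtered taxa (confined to
#'   one clade when `phylo_signal` is TRUE)
#' @param effect_size log-scale response per standard deviation of covariate
#' @param phylo_signal confine filtered taxa to a single clade
#' @param seed integer seed recorded in the output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_taxa = 300, n_samples = 116, n_farms = 14,
                       amendment_freq = c(None = 0.55, FYM = 0.38,
                                          Digestate = 0.035, Slurry = 0.035),
                       textures = c("Sandy Silt Loam", "Sandy Loam",
                                    "Silty Clay Loam", "Clay Loam"),
                       log_mean = 0, log_sd = 1.5,
                       m_true = 0.1,
                       depth_range = c(5079L, 41827L),
                       n_filtered = 30, effect_size = 1.0,
                       phylo_signal = TRUE, seed = 1L) {
  stopifnot(n_taxa >= 2, n_samples >= 2, log_sd > 0, m_true > 0,
            all(depth_range >= 1), abs(sum(amendment_freq) - 1) < 1e-8)
  structure(list(n_taxa = n_taxa, n_samples = n_samples, n_farms = n_farms,
                 amendment_freq = amendment_freq, textures = textures,
                 log_mean = log_mean, log_sd = log_sd, m_true = m_true,
                 depth_range = depth_range, n_filtered = n_filtered,
                 effect_size = effect_size, phylo_signal = phylo_signal,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a rooted phylogeny
#'
#' Pure-birth (Yule) topology with independent exponential branch lengths;
#' tips are labelled `OTU_1 ... OTU_n`.
#'
#' @param n_tips number of tips (>= 2)
#' @param seed integer seed
#' @param rate rate of the exponential branch-length distribution
#' @return an [ape::phylo] tree
#' @export
simulate_tree <- function(n_tips, seed = 1L, rate = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- rexp(nrow(tree$edge), rate = rate)
  tree$tip.label <- paste0("OTU_", seq_len(n_tips))
  tree
}

#' Simulate lognormal metacommunity relative abundances
#'
#' @param n_taxa number of taxa
#' @param log_mean,log_sd parameters of the log-abundance normal
#' @param seed integer seed
#' @return proportions summing to one, named `OTU_1 ... OTU_n`
#' @export
simulate_metacommunity <- function(n_taxa, log_mean = 0, log_sd = 1.5,
                                   seed = 1L) {
  stopifnot(log_sd > 0)
  set.seed(seed)
  a <- rlnorm(n_taxa, meanlog = log_mean, sdlog = log_sd)
  setNames(a / sum(a), paste0("OTU_", seq_len(n_taxa)))
}

#' Sample counts under the Sloan neutral community model
#'
#' For sample j with library size `N_j` and (possibly sample-specific)
#' source proportions p, local relative abundances are drawn
#' Dirichlet(N_j * m * p) — so each taxon's marginal is the Sloan
#' Beta(N_j m p_i, N_j m (1 - p_i)) — and counts are then multinomial at
#' depth N_j.
#'
#' @param meta metacommunity proportions, or a taxa x samples matrix of
#'   per-sample source proportions (e.g. after environmental filtering)
#' @param m migration parameter (> 0); large m means local communities track
#'   the source closely
#' @param depths integer library sizes, one per sample
#' @param seed integer seed
#' @return integer count table (taxa x samples)
#' @export
simulate_neutral_counts <- function(meta, m, depths, seed = 1L) {
  if (m <= 0) stop("m must be > 0")
  stopifnot(all(depths >= 1))
  if (is.matrix(meta)) {
    p <- meta
    stopifnot(ncol(p) == length(depths))
  } else {
    p <- matrix(meta, nrow = length(meta), ncol = length(depths),
                dimnames = list(names(meta), NULL))
  }
  set.seed(seed)
  n_s <- length(depths)
  counts <- matrix(0L, nrow = nrow(p), ncol = n_s)
  for (j in seq_len(n_s)) {
    local <- rdirichlet1(depths[j] * m * p[, j])
    counts[, j] <- as.integer(rmultinom(1, size = depths[j], prob = local))
  }
  rownames(counts) <- rownames(p) %||% paste0("OTU_", seq_len(nrow(p)))
  colnames(counts) <- paste0("S", seq_len(n_s))
  counts
}

#' Tips of the phylogenetically most compact clade of roughly a given size
#'
#' Scans internal nodes whose descendant clade holds between `k/2` and `2k`
#' tips and returns (up to `k` of) the tips of the clade with the smallest
#' mean within-clade patristic distance. Used to confine simulated
#' environmental effects to a phylogenetically coherent group.
#'
#' @param tree an [ape::phylo] tree
#' @param k target clade size
#' @return character vector of tip labels (length <= k)
#' @export
compact_clade_tips <- function(tree, k) {
  D <- ape::cophenetic.phylo(tree)
  pp <- ape::prop.part(tree)
  sizes <- lengths(pp)
  cand <- which(sizes >= max(2, floor(k / 2)) & sizes <= 2 * k)
  if (!length(cand)) cand <- which.min(abs(sizes - k))
  within <- vapply(cand, function(i) {
    tips <- tree$tip.label[pp[[i]]]
    mean(D[tips, tips])
  }, numeric(1))
  tips <- tree$tip.label[pp[[cand[which.min(within)]]]]
  if (length(tips) > k) {
    # keep the k tips closest to the clade centroid
    tips <- tips[order(rowMeans(D[tips, tips]))][seq_len(k)]
  }
  tips
}

#' Apply deterministic environmental filtering to source proportions
#'
#' Each sample's source proportions are tilted multiplicatively:
#' `p_ij` is proportional to `p_i * exp(sum_k effects[i,k] * z[j,k])` with z
#' the standardized continuous covariates, then renormalized per sample.
#' Taxa without a row in `effects` are unaffected (effect 0).
#'
#' @param meta metacommunity proportions (named)
#' @param metadata sample metadata holding the covariate columns
#' @param effects matrix (taxa x covariates) of log-scale responses;
#'   rownames are taxon ids, colnames are metadata covariate names
#' @return taxa x samples matrix of per-sample source proportions
#' @export
apply_environmental_filter <- function(meta, metadata, effects) {
  stopifnot(!is.null(rownames(effects)), !is.null(colnames(effects)))
  miss <- setdiff(rownames(effects), names(meta))
  if (length(miss)) stop("effect rows not in metacommunity: ", miss[1])
  z <- sapply(colnames(effects), function(v) {
    x <- metadata[[v]]
    if (is.null(x) || !is.numeric(x)) stop("covariate not numeric: ", v)
    if (any(!is.finite(x))) stop("non-finite covariate: ", v)
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  z <- matrix(z, nrow = nrow(metadata),
              dimnames = list(rownames(metadata), colnames(effects)))
  eff_full <- matrix(0, nrow = length(meta), ncol = ncol(effects),
                     dimnames = list(names(meta), colnames(effects)))
  eff_full[rownames(effects), ] <- effects
  tilt <- exp(eff_full %*% t(z))      # taxa x samples
  p <- meta * tilt
  sweep(p, 2, colSums(p), "/")
}

#' Simulate a complete synthetic survey with known ground truth
#'
#' Composes tree, metacommunity, design metadata, environmental filtering
#' and neutral sampling into one dataset. The returned `truth` element
#' records the migration parameter, the filtered taxa, their effect matrix
#' and the metacommunity proportions for recovery tests.
#'
#' Continuous covariates mirror the qualitative field patterns the analyses
#' probe: Ca is higher in silty clay loam soils, LOI is higher under
#' digestate and slurry; pH, P, K, Mg and Na are uninformative noise.
#'
#' @param config a [sim_config()] list
#' @return list with elements `counts`, `metadata`, `tree`, `taxonomy`,
#'   `truth`, `config`
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  n_t <- config$n_taxa
  n_s <- config$n_samples

  tree <- simulate_tree(n_t, seed = child_seed(seed, "tree"))
  meta_p <- simulate_metacommunity(n_t, config$log_mean, config$log_sd,
                                   seed = child_seed(seed, "metacommunity"))

  # design: farms, amendments, textures, continuous soil chemistry
  set.seed(child_seed(seed, "design"))
  farm <- sample(paste0("Farm_", sprintf("%02d", seq_len(config$n_farms))),
                 n_s, replace = TRUE)
  amendment <- sample(names(config$amendment_freq), n_s, replace = TRUE,
                      prob = config$amendment_freq)
  texture <- sample(config$textures, n_s, replace = TRUE)
  ca <- rnorm(n_s, mean = ifelse(texture == "Silty Clay Loam", 2800, 2200),
              sd = 400)
  loi <- rnorm(n_s,
               mean = ifelse(amendment %in% c("Digestate", "Slurry"), 9, 6),
               sd = 1.2)
  metadata <- data.frame(
    farm_id = factor(farm),
    amendment = factor(amendment, levels = names(config$amendment_freq)),
    texture = factor(texture, levels = config$textures),
    pH = rnorm(n_s, 6.3, 0.4),
    P = rnorm(n_s, 45, 12),
    K = rnorm(n_s, 180, 40),
    Mg = rnorm(n_s, 150, 35),
    Ca = ca,
    Na = rnorm(n_s, 30, 8),
    LOI = loi,
    row.names = paste0("S", seq_len(n_s)),
    check.names = FALSE
  )

  # filtered taxa: one clade when phylogenetic signal is requested
  set.seed(child_seed(seed, "effects"))
  k <- min(config$n_filtered, n_t)
  if (k > 0) {
    if (config$phylo_signal && k > 1) {
      filtered <- compact_clade_tips(tree, k)
    } else {
      filtered <- sample(names(meta_p), k)
    }
    k <- length(filtered)
    effects <- matrix(0, nrow = k, ncol = 2,
                      dimnames = list(filtered, c("Ca", "LOI")))
    half <- seq_len(ceiling(k / 2))
    effects[half, "Ca"] <- config$effect_size
    effects[setdiff(seq_len(k), half), "LOI"] <- config$effect_size
  } else {
    filtered <- character(0)
    effects <- matrix(0, 0, 2, dimnames = list(NULL, c("Ca", "LOI")))
  }

  p_local <- if (k > 0 && config$effect_size != 0) {
    apply_environmental_filter(meta_p, metadata, effects)
  } else {
    matrix(meta_p, nrow = n_t, ncol = n_s,
           dimnames = list(names(meta_p), rownames(metadata)))
  }

  set.seed(child_seed(seed, "depths"))
  depths <- sample(seq(config$depth_range[1], config$depth_range[2]), n_s,
                   replace = TRUE)
  counts <- simulate_neutral_counts(p_local, config$m_true, depths,
                                    seed = child_seed(seed, "counts"))
  colnames(counts) <- rownames(metadata)

  phyla <- paste0("Phylum_", 1 + (seq_len(n_t) - 1) %% 8)
  taxonomy <- data.frame(
    domain = "Bacteria", phylum = phyla,
    class = paste0("Class_", seq_len(n_t)),
    order = "", family = "", genus = paste0("Genus_", seq_len(n_t)),
    row.names = names(meta_p), stringsAsFactors = FALSE
  )

  list(counts = counts, metadata = metadata, tree = tree,
       taxonomy = taxonomy,
       truth = list(m_true = config$m_true, filtered_taxa = filtered,
                    effects = effects, metacommunity = meta_p),
       config = config)
}

#' Write a synthetic dataset bundle to a directory
#'
#' Emits `otu_table.tsv`, `metadata.tsv`, `tree.nwk`, `taxonomy.tsv` and
#' `truth.json`.
#'
#' @param dataset output of [simulate_dataset()]
#' @param dir output directory (created if absent)
#' @return the directory, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(dataset$counts, file.path(dir, "otu_table.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  truth <- dataset$truth
  truth$effects <- list(taxa = rownames(truth$effects),
                        covariates = colnames(truth$effects),
                        values = unname(as.data.frame(truth$effects)))
  truth$metacommunity <- as.list(truth$metacommunity)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
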