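#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' For each pair of samples, the average over taxa present in one sample of
#' the patristic distance to the nearest taxon present in the other,
#' averaged over both directions. Weights are relative abundances
#' (abundance-weighted, the default) or equal weights over present taxa.
#' A taxon present in both samples has nearest-taxon distance zero.
#'
#' @param t count table whose OTUs are tips of `tree`
#' @param tree rooted phylogeny with branch lengths
#' @param weighted abundance-weight the per-taxon terms
#' @param dist_mat optional precomputed patristic distance matrix (taxa
#'   ordered as `rownames(t)`)
#' @return symmetric sample x sample matrix
#' @export
beta_mntd <- function(t, tree = NULL, weighted = TRUE, dist_mat = NULL) {
  if (is.null(dist_mat)) {
    tree <- validate_tree(tree)
    miss <- setdiff(rownames(t), tree$tip.label)
    if (length(miss)) stop("OTU missing from tree: ", miss[1])
    dist_mat <- ape::cophenetic.phylo(tree)[rownames(t), rownames(t)]
  }
  if (any(colSums(t) == 0))
    stop("empty sample: ", colnames(t)[colSums(t) == 0][1])
  P <- t > 0
  W <- if (weighted) sweep(t, 2, colSums(t), "/")
       else sweep(P * 1, 2, colSums(P), "/")
  M <- min_dist_to_sample(dist_mat, P)
  B <- crossprod(W, M)                  # B[j,k] = sum_i w_ij * mindist(i,k)
  out <- 0.5 * (B + base::t(B))
  dimnames(out) <- list(colnames(t), colnames(t))
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD against a null in which tip labels are
#' shuffled across the patristic distance matrix (taxa-label null: richness
#' and abundances are preserved, phylogenetic positions randomised). The
#' standard z-score sign convention is used: betaNTI < 0 means the observed
#' communities are phylogenetically *more* similar than chance
#' (clustering / homogeneous selection), betaNTI > 0 means overdispersion
#' (variable selection); |betaNTI| > 2 is the usual threshold for
#' deterministic assembly.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip-shuffle null draws
#' @param seed integer seed
#' @return object of class `bnti_result`: `bnti`, `observed`, `null_mean`,
#'   `null_sd` matrices plus settings
#' @export
beta_nti <- function(t, tree, n_null = 999, seed = 1L, weighted = TRUE) {
  tree <- validate_tree(tree)
  miss <- setdiff(rownames(t), tree$tip.label)
  if (length(miss)) stop("OTU missing from tree: ", miss[1])
  D <- ape::cophenetic.phylo(tree)[rownames(t), rownames(t)]
  obs <- beta_mntd(t, weighted = weighted, dist_mat = D)
  n_t <- nrow(t)
  set.seed(seed)
  s1 <- matrix(0, nrow(obs), ncol(obs))
  s2 <- matrix(0, nrow(obs), ncol(obs))
  for (r in seq_len(n_null)) {
    perm <- sample.int(n_t)
    b <- beta_mntd(t, weighted = weighted,
                   dist_mat = D[perm, perm, drop = FALSE])
    s1 <- s1 + b
    s2 <- s2 + b * b
  }
  null_mean <- s1 / n_null
  null_sd <- sqrt(pmax(s2 / n_null - null_mean^2, 0) * n_null / (n_null - 1))
  bnti <- (obs - null_mean) / null_sd
  zero_sd <- null_sd == 0 & upper.tri(null_sd)
  if (any(zero_sd)) {
    warning("null SD is zero for ", sum(zero_sd), " sample pairs; ",
            "betaNTI set to NaN")
    bnti[null_sd == 0] <- NaN
  }
  diag(bnti) <- NaN
  structure(list(bnti = bnti, observed = obs, null_mean = null_mean,
                 null_sd = null_sd, n_null = n_null, seed = seed,
                 weighted = weighted),
            class = "bnti_result")
}

#' @export
print.bnti_result <- function(x, ...) {
  v <- x$bnti[upper.tri(x$bnti)]
  v <- v[is.finite(v)]
  cat(sprintf("betaNTI over %d sample pairs (%d tip-shuffle nulls, %s)\n",
              length(v), x$n_null,
              if (x$weighted) "abundance-weighted" else "unweighted"))
  cat(sprintf("  mean %.2f | %.1f%% pairs < -2 | %.1f%% pairs > +2\n",
              mean(v), 100 * mean(v < -2), 100 * mean(v > 2)))
  invisible(x)
}

#' Pairwise betaNTI values in long format
#' @param x a `bnti_result`
#' @return data.frame with one row per unordered sample pair
#' @export
bnti_pairs <- function(x) {
  ut <- which(upper.tri(x$bnti), arr.ind = TRUE)
  data.frame(sample_1 = rownames(x$bnti)[ut[, 1]],
             sample_2 = colnames(x$bnti)[ut[, 2]],
             beta_mntd = x$observed[ut],
             null_mean = x$null_mean[ut],
             null_sd = x$null_sd[ut],
             bnti = x$bnti[ut])
}
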