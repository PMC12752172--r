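# brute-force oracles, written independently of the package internals

bf_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  total <- 0
  for (pi in p) total <- total - pi * log(pi)
  total
}

bf_chao1 <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

bf_bray <- function(a, b) sum(abs(a - b)) / sum(a + b)

# tips descending from a node, by direct recursion over the edge list
bf_tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, bf_tips_below, tree = tree))
}

# unweighted UniFrac by exhaustive edge enumeration
bf_unifrac <- function(tree, set_a, set_b) {
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- bf_tips_below(tree, tree$edge[e, 2])
    in_a <- any(tips %in% set_a)
    in_b <- any(tips %in% set_b)
    if (in_a || in_b) {
      den <- den + tree$edge.length[e]
      if (xor(in_a, in_b)) num <- num + tree$edge.length[e]
    }
  }
  if (den == 0) 0 else num / den
}

# abundance-weighted betaMNTD by exhaustive tip enumeration
bf_bmntd <- function(counts_j, counts_k, D, weighted = TRUE) {
  pres_j <- which(counts_j > 0)
  pres_k <- which(counts_k > 0)
  w_j <- if (weighted) counts_j[pres_j] / sum(counts_j)
         else rep(1 / length(pres_j), length(pres_j))
  w_k <- if (weighted) counts_k[pres_k] / sum(counts_k)
         else rep(1 / length(pres_k), length(pres_k))
  s1 <- 0
  for (h in seq_along(pres_j)) {
    dmin <- Inf
    for (i2 in pres_k) dmin <- min(dmin, D[pres_j[h], i2])
    s1 <- s1 + w_j[h] * dmin
  }
  s2 <- 0
  for (h in seq_along(pres_k)) {
    dmin <- Inf
    for (i2 in pres_j) dmin <- min(dmin, D[pres_k[h], i2])
    s2 <- s2 + w_k[h] * dmin
  }
  as.numeric(0.5 * (s1 + s2))
}

# small random community fixture
random_fixture <- function(n_taxa = 10, n_samples = 6, seed = 1,
                           lambda = 8) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(paste0("OTU_", seq_len(n_taxa)),
                              paste0("S", seq_len(n_samples))))
  # ensure no empty samples/taxa
  m[1, ] <- m[1, ] + 1L
  storage.mode(m) <- "integer"
  m
}
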