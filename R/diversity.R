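#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via [vegan::rrarefy()]). Samples shallower than `depth` are dropped with
#' a warning when `drop_short = TRUE`, otherwise an error is raised.
#'
#' @param t count table
#' @param depth target depth; default = minimum library size
#' @param seed integer seed (subsampling is stochastic)
#' @param drop_short drop samples with fewer than `depth` reads
#' @return rarefied count table with all column sums equal to `depth`
#' @export
rarefy_counts <- function(t, depth = min(library_sizes(t)), seed = 1L,
                          drop_short = FALSE) {
  t <- count_table(t)
  if (depth < 1) stop("depth must be >= 1")
  short <- library_sizes(t) < depth
  if (any(short)) {
    if (!drop_short)
      stop("samples below rarefaction depth: ",
           paste(colnames(t)[short], collapse = ", "))
    warning("dropping ", sum(short), " samples below depth ", depth)
    t <- t[, !short, drop = FALSE]
  }
  set.seed(seed)
  # rrarefy emits a heuristic "observed counts" warning whenever the
  # smallest nonzero count exceeds 1; irrelevant here, counts are validated
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(t), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

#' Shannon entropy of a count vector (nats)
#'
#' @param counts non-negative counts with positive total
#' @return H = -sum p_i log p_i over taxa with nonzero counts
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("Shannon entropy needs a positive total")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1/F2 the singleton and
#' doubleton counts.
#'
#' @param counts integer count vector
#' @return estimated richness (taxa)
#' @export
chao1 <- function(counts) {
  if (any(counts != round(counts))) stop("chao1 needs integer counts")
  unname(vegan::estimateR(as.integer(counts))["S.chao1"])
}

#' Per-sample alpha diversity on rarefied counts
#'
#' @param t count table
#' @param depth rarefaction depth (default minimum library size)
#' @param seed rarefaction seed
#' @return data.frame with `shannon` and `chao1` per sample
#' @export
alpha_diversity <- function(t, depth = min(library_sizes(t)), seed = 1L) {
  r <- rarefy_counts(t, depth = depth, seed = seed)
  data.frame(
    shannon = apply(r, 2, shannon),
    chao1 = apply(r, 2, chao1),
    row.names = colnames(r)
  )
}
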