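#' Bray-Curtis dissimilarity between samples
#'
#' `d(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` on the counts as
#' given (apply [tss_clr()] proportions or rarefaction upstream if wanted).
#'
#' @param t count table (>= 2 samples)
#' @return symmetric sample x sample matrix in [0, 1]
#' @export
bray_curtis <- function(t) {
  if (ncol(t) < 2) stop("need >= 2 samples")
  zero <- colSums(t) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(t)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(base::t(t), method = "bray"))
}

#' Unweighted UniFrac distance
#'
#' Fraction of total branch length leading exclusively to tips present in
#' only one of the two samples, over the branch length leading to tips
#' present in either. Presence means count > 0. Tips absent from both
#' samples contribute to neither numerator nor denominator.
#'
#' @param t count table whose OTU ids are tips of `tree`
#' @param tree rooted phylogeny with branch lengths
#' @return symmetric sample x sample matrix in [0, 1]
#' @export
unweighted_unifrac <- function(t, tree) {
  tree <- validate_tree(tree)
  miss <- setdiff(rownames(t), tree$tip.label)
  if (length(miss)) stop("OTU missing from tree: ", miss[1])
  keep <- intersect(tree$tip.label, rownames(t))
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  pres <- t[tree$tip.label, , drop = FALSE] > 0
  n_s <- ncol(pres)
  # postorder accumulation: tip-descendant presence per edge child node
  post <- ape::reorder.phylo(tree, "postorder")
  node_pres <- matrix(FALSE, nrow = n_node, ncol = n_s)
  node_pres[seq_len(n_tip), ] <- pres
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chl <- post$edge[e, 2]
    node_pres[par, ] <- node_pres[par, ] | node_pres[chl, ]
  }
  child <- post$edge[, 2]
  blen <- post$edge.length
  P <- node_pres[child, , drop = FALSE]   # edge x sample presence-below
  d <- matrix(0, n_s, n_s, dimnames = list(colnames(t), colnames(t)))
  for (j in seq_len(n_s - 1)) {
    for (k in (j + 1):n_s) {
      either <- P[, j] | P[, k]
      uniq <- xor(P[, j], P[, k])
      denom <- sum(blen[either])
      d[j, k] <- d[k, j] <- if (denom == 0) 0 else sum(blen[uniq]) / denom
    }
  }
  d
}

#' Write / read a square distance matrix as TSV
#' @param d symmetric matrix with sample dimnames
#' @param path TSV path
#' @export
write_distance <- function(d, path) write_tsv(d, path, row_label = "sample_id")

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!isTRUE(all.equal(m, base::t(m), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  m
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres -D^2/2 and eigendecomposes it. Negative eigenvalues are
#' reported but excluded from the variance-explained denominator; no
#' correction is applied (the convention is recorded in the result).
#'
#' @param d symmetric distance matrix
#' @param k number of axes to keep (default all positive-eigenvalue axes)
#' @return object of class `mc_pcoa` with `points` (samples x axes),
#'   `eig`, `prop_explained`, `correction`
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA")
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(abs(eig)) * 1e-12)
  if (!length(pos)) {
    # degenerate configuration (all distances zero): one null axis
    pts <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
    return(structure(list(points = pts, eig = eig, prop_explained = 0,
                          correction = "none (degenerate input)"),
                     class = "mc_pcoa"))
  }
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eig = eig,
                 prop_explained = pmax(eig, 0)[seq_len(k)] /
                   sum(eig[eig > 0]),
                 correction = "none (negative eigenvalues excluded)"),
            class = "mc_pcoa")
}

#' @export
print.mc_pcoa <- function(x, ...) {
  cat("Principal coordinate analysis:", nrow(x$points), "samples,",
      ncol(x$points), "axes\n")
  cat("Proportion explained (positive inertia):",
      paste(sprintf("%.1f%%", 100 * head(x$prop_explained, 5)),
            collapse = " "), "\n")
  if (any(x$eig < 0))
    cat("Negative eigenvalues present (min", format(min(x$eig)), "),",
        x$correction, "\n")
  invisible(x)
}

#' @export
plot.mc_pcoa <- function(x, axes = c(1, 2), col = 1, pch = 1, ...) {
  p <- x$prop_explained
  plot(x$points[, axes[1]], x$points[, axes[2]],
       xlab = sprintf("Axis %d (%.1f%%)", axes[1], 100 * p[axes[1]]),
       ylab = sprintf("Axis %d (%.1f%%)", axes[2], 100 * p[axes[2]]),
       col = col, pch = pch, ...)
  invisible(x)
}

#' Regression of one distance matrix on another
#'
#' Ordinary least squares of the secondary distances on the taxonomic
#' distances over the unique sample pairs. The slope is a resilience proxy:
#' a lower slope means the secondary (e.g. functional) distances respond
#' less to taxonomic turnover. Pairs are not independent, so the standard
#' errors are descriptive only.
#'
#' @param d_taxonomic,d_secondary matched symmetric distance matrices
#' @return list with `slope`, `intercept`, `r_squared`, `slope_se`, `n_pairs`
#' @export
distance_regression <- function(d_taxonomic, d_secondary) {
  d1 <- as.matrix(d_taxonomic); d2 <- as.matrix(d_secondary)
  if (nrow(d1) < 3) stop("need >= 3 samples")
  stopifnot(all(dim(d1) == dim(d2)))
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)))
    d2 <- d2[rownames(d1), rownames(d1)]
  lo <- lower.tri(d1)
  fit <- lm(d2[lo] ~ d1[lo])
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, slope_se = s$coefficients[2, 2],
       n_pairs = sum(lo))
}
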