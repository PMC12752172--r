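#' Abundance-occupancy ranking index
#'
#' For each OTU over S sample groups ("sites"), the index averages two
#' quantities in [0, 1]: the group-averaged occupancy (mean over groups of
#' the fraction of that group's samples in which the OTU is detected) and
#' the group-averaged replication consistency (mean over groups of the
#' indicator that the OTU is present in *all* of the group's samples).
#' Detection means count > 0. Ties are broken by total abundance (larger
#' first), then by OTU id.
#'
#' @param t count table
#' @param groups factor/character of group ("site") labels, one per sample
#' @return data.frame ordered by decreasing index with columns `index`,
#'   `site_occupancy`, `replication_consistency`, `occupancy`,
#'   `total_abundance`, `rank`
#' @export
occupancy_index <- function(t, groups) {
  t <- count_table(t)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(t))
  if (any(table(groups) == 0) || anyNA(groups)) stop("empty group")
  pres <- t > 0
  g_occ <- sapply(levels(groups), function(g)
    rowMeans(pres[, groups == g, drop = FALSE]))
  site_occ <- rowMeans(g_occ)
  rep_cons <- rowMeans(g_occ == 1)
  idx <- (site_occ + rep_cons) / 2
  tot <- rowSums(t)
  ord <- order(-idx, -tot, rownames(t))
  out <- data.frame(index = idx, site_occupancy = site_occ,
                    replication_consistency = rep_cons,
                    occupancy = rowMeans(pres), total_abundance = tot,
                    row.names = rownames(t))[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Cumulative Bray-Curtis contribution of ranked taxa
#'
#' `BC_all` is the mean pairwise Bray-Curtis dissimilarity of the full
#' table. `BC_core(k)` replaces each pair's numerator by the sum over the
#' top-k ranked taxa only, keeping the full-table denominators, so the
#' explanatory value `E(k) = BC_core(k) / BC_all` grows from 0 to 1 as taxa
#' are added. The complementary form `C(k) = 1 - E(k)` is reported
#' alongside.
#'
#' @param t count table
#' @param ranking ordered OTU ids (a permutation or prefix of the rows)
#' @return data.frame with one row per rank: `otu`, `E`, `C`
#' @export
bc_contribution_curve <- function(t, ranking) {
  t <- count_table(t)
  stopifnot(all(ranking %in% rownames(t)), !anyDuplicated(ranking))
  libs <- library_sizes(t)
  n_s <- ncol(t)
  if (n_s < 2) stop("need >= 2 samples")
  # per-OTU mean pair contribution |x_ij - x_il| / (N_j + N_l)
  contrib <- numeric(nrow(t))
  for (j in seq_len(n_s - 1)) {
    for (l in (j + 1):n_s) {
      denom <- libs[j] + libs[l]
      if (denom == 0) stop("pair of all-zero samples")
      contrib <- contrib + abs(t[, j] - t[, l]) / denom
    }
  }
  contrib <- contrib / (n_s * (n_s - 1) / 2)
  names(contrib) <- rownames(t)
  bc_all <- sum(contrib)
  if (bc_all == 0) stop("all samples identical: Bray-Curtis is zero")
  E <- cumsum(contrib[ranking]) / bc_all
  data.frame(otu = ranking, E = unname(E), C = 1 - unname(E),
             stringsAsFactors = FALSE)
}

#' Select the core set by the 2% explanatory-increment stopping rule
#'
#' Taxa are added in rank order until the next taxon raises the explanatory
#' value E by less than `delta` (absolute increase on the [0, 1] scale; the
#' default 0.02 is the "2%" rule). At least one taxon is always selected;
#' when every increment clears `delta`, all taxa are core.
#'
#' @param curve a [bc_contribution_curve()] data.frame
#' @param delta minimum absolute increment to keep adding taxa
#' @param ranking_stats optional [occupancy_index()] table to carry along
#' @param label optional occupancy-model label (e.g. an amendment level)
#' @return object of class `core_result` with `core` (OTU ids), `k`,
#'   `curve`, `delta`, `label`, and `stats` when supplied
#' @export
select_core <- function(curve, delta = 0.02, ranking_stats = NULL,
                        label = "all") {
  E <- curve$E
  inc <- diff(c(0, E))
  if (any(inc < -1e-8))
    stop("explanatory curve decreases: ranking/curve mismatch")
  P <- length(E)
  k <- P
  if (P > 1) {
    below <- which(inc[-1] < delta)   # increment from k to k+1
    if (length(below)) k <- below[1]
  }
  k <- max(k, 1L)
  structure(list(core = curve$otu[seq_len(k)], k = k, curve = curve,
                 delta = delta, label = label, stats = ranking_stats),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("Core microbiome ('%s' occupancy model): %d of %d taxa, E(k) = %.3f (delta = %g)\n",
              x$label, x$k, nrow(x$curve), x$curve$E[x$k], x$delta))
  invisible(x)
}

#' @export
plot.core_result <- function(x, ...) {
  plot(seq_len(nrow(x$curve)), x$curve$E, type = "l",
       xlab = "ranked taxa added", ylab = "explanatory value E(k)", ...)
  abline(v = x$k, col = "goldenrod", lwd = 2)
  invisible(x)
}

#' Per-level core microbiomes ("occupancy models")
#'
#' Runs the ranking / contribution-curve / stopping-rule pipeline within
#' each level of a categorical variable (e.g. organic amendment) and on all
#' samples pooled. Within a level, Eq.-style site grouping uses `site_var`
#' when available, else each sample is its own site. Levels with fewer than
#' 2 samples are skipped with a warning.
#'
#' @param t count table
#' @param meta metadata (rownames = sample ids)
#' @param model_var categorical metadata column defining the models
#' @param site_var metadata column defining sites/groups within a model
#' @param delta stopping increment for [select_core()]
#' @return list of `core_result` objects, one per usable level plus
#'   `"all"`; each carries `min_occupancy`, the minimum within-level
#'   occupancy among its core taxa
#' @export
occupancy_models <- function(t, meta, model_var = "amendment",
                             site_var = "farm_id", delta = 0.02) {
  t <- count_table(t)
  meta <- meta[colnames(t), , drop = FALSE]
  lv <- as.character(meta[[model_var]])
  run_one <- function(sub, label) {
    sites <- if (!is.null(meta[[site_var]]))
      droplevels(as.factor(meta[colnames(sub), site_var]))
    else factor(colnames(sub))
    keep <- rowSums(sub) > 0
    sub <- sub[keep, , drop = FALSE]
    stats <- occupancy_index(sub, sites)
    curve <- bc_contribution_curve(sub, rownames(stats))
    res <- select_core(curve, delta = delta, ranking_stats = stats,
                       label = label)
    res$min_occupancy <- min(stats[res$core, "occupancy"])
    res
  }
  out <- list()
  for (g in unique(lv)) {
    cols <- which(lv == g)
    if (length(cols) < 2) {
      warning("skipping level with < 2 samples: ", g)
      next
    }
    out[[g]] <- run_one(t[, cols, drop = FALSE], g)
  }
  out[["all"]] <- run_one(t, "all")
  out
}

#' Overlap between core sets
#'
#' Each core is first restricted to taxa with within-model occupancy at
#' least `prevalence_filter` (default 1: the fully prevalent core). Emits
#' Venn-style counts for every membership pattern and Jaccard sharing
#' percentages for each pair and overall.
#'
#' @param cores list of `core_result` objects (e.g. from
#'   [occupancy_models()]), or a named list of OTU id vectors
#' @param prevalence_filter minimum occupancy within the model's samples
#' @return list with `sets`, `venn_counts`, `pairwise_sharing`,
#'   `total_sharing` (percent)
#' @export
core_overlap <- function(cores, prevalence_filter = 1.0) {
  if (length(cores) < 2) stop("need >= 2 core sets")
  sets <- lapply(cores, function(x) {
    if (inherits(x, "core_result")) {
      if (!is.null(x$stats))
        x$core[x$stats[x$core, "occupancy"] >= prevalence_filter]
      else x$core
    } else as.character(x)
  })
  if (any(lengths(sets) == 0))
    warning("empty core set after prevalence filter: ",
            paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) memb <- matrix(memb, nrow = 1,
                                        dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1, function(r) paste(names(sets)[r],
                                              collapse = "&"))
  venn <- table(pattern)
  pairs <- combn(names(sets), 2)
  pw <- apply(pairs, 2, function(pr) {
    a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
    u <- length(union(a, b))
    if (u == 0) 0 else 100 * length(intersect(a, b)) / u
  })
  names(pw) <- apply(pairs, 2, paste, collapse = " vs ")
  inter_all <- Reduce(intersect, sets)
  total <- if (length(univ) == 0) 0 else 100 * length(inter_all) /
    length(univ)
  list(sets = sets, venn_counts = venn, pairwise_sharing = pw,
       total_sharing = total)
}

#' Overlay neutral-model partition labels on a core set
#'
#' @param core a `core_result`
#' @param fit a [fit_sloan_neutral()] result on the same table
#' @return list with `labels` (per core OTU) and `counts`
#'   (above/neutral/below)
#' @export
neutral_overlay <- function(core, fit) {
  stopifnot(inherits(core, "core_result"), inherits(fit, "sloan_fit"))
  lab <- classify_partition(fit)
  miss <- setdiff(core$core, names(lab))
  if (length(miss)) stop("core OTU missing from neutral fit: ", miss[1])
  labels <- lab[core$core]
  counts <- table(factor(labels, levels = c("above", "neutral", "below")))
  list(labels = labels, counts = counts)
}
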