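# Gower-centred inner-product matrix of squared distances:
# G = -(I - 11'/n) (D^2/2) (I - 11'/n); tr(H G) gives the SS explained by
# the subspace projected by H (McArdle & Anderson partitioning)
gower_centre <- function(d) {
  d <- as.matrix(d)
  a <- -0.5 * d^2
  n <- nrow(d)
  rm <- rowMeans(a); gm <- mean(a)
  a - outer(rm, rm, "+") + gm
}

hat_matrix <- function(m) {
  q <- qr(m)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Sequential (type-I) partitioning of the squared-distance inner-product
#' matrix over an ordered list of metadata terms, with pseudo-F per term and
#' permutation p-values from free permutation of sample labels. The p-value
#' estimator is (1 + #\{permuted F >= observed F\}) / (1 + n_perm); with
#' `exhaustive = TRUE` all n! label permutations are enumerated instead and
#' the p-value is the exact proportion (identity included).
#'
#' @param d sample distance matrix
#' @param meta metadata data.frame (rownames = sample ids)
#' @param terms ordered character vector of metadata column names
#' @param n_perm number of permutations (ignored when exhaustive)
#' @param seed integer seed for the permutation stream
#' @param exhaustive enumerate all permutations (n <= 8 enforced)
#' @return object of class `mc_permanova`: per-term df, SS, R2, pseudo-F and
#'   p-value, plus the residual row
#' @export
permanova <- function(d, meta, terms, n_perm = 999, seed = 1L,
                      exhaustive = FALSE) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (!is.null(ids) && !is.null(rownames(meta))) {
    miss <- setdiff(ids, rownames(meta))
    if (length(miss)) {
      warning("dropping samples without metadata: ",
              paste(miss, collapse = ", "))
      ids <- setdiff(ids, miss)
      d <- d[ids, ids]
    }
    meta <- meta[ids, , drop = FALSE]
  }
  stopifnot(all(terms %in% colnames(meta)))
  n <- nrow(d)
  for (tm in terms) {
    x <- meta[[tm]]
    if (is.factor(x)) x <- droplevels(x)
    if (length(unique(x)) < 2) stop("constant term: ", tm)
    meta[[tm]] <- x
  }
  G <- gower_centre(d)
  ss_total <- sum(diag(G))

  # cumulative hat matrices H_0 (intercept) .. H_k (full model)
  H <- vector("list", length(terms) + 1)
  M <- matrix(1, n, 1)
  H[[1]] <- hat_matrix(M)
  dfs <- integer(length(terms))
  for (i in seq_along(terms)) {
    Xi <- model.matrix(stats::as.formula(paste("~", paste(terms[seq_len(i)],
                                                          collapse = "+"))),
                       data = meta)
    H[[i + 1]] <- hat_matrix(Xi)
    dfs[i] <- qr(Xi)$rank - qr(M)$rank
    M <- Xi
  }
  df_res <- n - qr(M)$rank
  if (df_res < 1) stop("no residual degrees of freedom")

  stat_fun <- function(Gp) {
    tr <- vapply(H, function(h) sum(h * Gp), numeric(1))
    ss <- diff(tr)                       # per-term sequential SS
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    (ss / dfs) / (ss_res / df_res)
  }
  F_obs <- stat_fun(G)
  ss_tr <- vapply(H, function(h) sum(h * G), numeric(1))
  ss_terms <- diff(ss_tr)
  ss_res <- ss_total - ss_tr[length(ss_tr)]

  if (exhaustive) {
    if (n > 8) stop("exhaustive permutation only for n <= 8")
    perms <- all_permutations(n)
    hits <- rep(0L, length(terms))
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      Fp <- stat_fun(G[p, p])
      hits <- hits + (Fp >= F_obs - 1e-12)
    }
    pval <- hits / nrow(perms)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    hits <- rep(0L, length(terms))
    for (r in seq_len(n_perm)) {
      p <- sample.int(n)
      Fp <- stat_fun(G[p, p])
      hits <- hits + (Fp >= F_obs)
    }
    pval <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }

  tab <- data.frame(
    df = c(dfs, df_res),
    sum_sq = c(ss_terms, ss_res),
    r_squared = c(ss_terms, ss_res) / ss_total,
    pseudo_F = c(F_obs, NA),
    p_value = c(pval, NA),
    row.names = c(terms, "Residual")
  )
  structure(list(table = tab, n_perm = n_used, seed = seed,
                 exhaustive = exhaustive, n = n),
            class = "mc_permanova")
}

#' @export
print.mc_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %s permutations, n = %d)\n",
              if (x$exhaustive) paste0("all ", x$n_perm) else x$n_perm, x$n))
  printCoefmat(as.matrix(x$table), na.print = "", tst.ind = 4,
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Stepwise distance-based RDA variable selection
#'
#' Forward steps add the candidate with the smallest permutation p-value for
#' its conditional (added-last) pseudo-F given the current model, when that
#' p-value is at most `alpha_enter`; after each addition a backward pass
#' removes terms whose conditional p-value exceeds `alpha_drop`. Terminates
#' when no term enters or leaves.
#'
#' @param d sample distance matrix
#' @param meta metadata data.frame
#' @param candidates character vector of candidate covariate names
#' @param alpha_enter,alpha_drop entry / retention thresholds
#' @param n_perm permutations per test
#' @param seed integer seed
#' @return list with `selected` (ordered names) and `trace` data.frame
#' @export
stepwise_dbrda <- function(d, meta, candidates, alpha_enter = 0.05,
                           alpha_drop = 0.10, n_perm = 199, seed = 1L) {
  stopifnot(length(candidates) > 0)
  usable <- character(0)
  for (cand in candidates) {
    x <- meta[[cand]]
    ok <- !is.null(x) &&
      length(unique(if (is.factor(x)) droplevels(x) else x)) >= 2
    if (!ok) warning("skipping constant/absent candidate: ", cand)
    else usable <- c(usable, cand)
  }
  selected <- character(0)
  trace <- data.frame(step = integer(), action = character(),
                      term = character(), pseudo_F = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  step_i <- 0L
  cond_test <- function(model_terms, term, sd2) {
    fit <- tryCatch(
      permanova(d, meta, c(model_terms, term), n_perm = n_perm, seed = sd2),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    k <- length(model_terms) + 1
    list(F = fit$table$pseudo_F[k], p = fit$table$p_value[k])
  }
  repeat {
    step_i <- step_i + 1L
    changed <- FALSE
    pool <- setdiff(usable, selected)
    if (length(pool)) {
      res <- lapply(pool, function(cand)
        cond_test(selected, cand, child_seed(seed, paste0("fwd", step_i,
                                                          cand))))
      ok <- !vapply(res, is.null, logical(1))
      pool <- pool[ok]; res <- res[ok]
      if (length(pool)) {
        ps <- vapply(res, `[[`, numeric(1), "p")
        fs <- vapply(res, `[[`, numeric(1), "F")
        best <- order(ps, -fs)[1]
        if (ps[best] <= alpha_enter) {
          selected <- c(selected, pool[best])
          trace <- rbind(trace, data.frame(step = step_i, action = "add",
                                           term = pool[best],
                                           pseudo_F = fs[best],
                                           p_value = ps[best]))
          changed <- TRUE
        }
      }
    }
    # backward pass: test each selected term as if added last
    if (length(selected) > 1) {
      repeat {
        ps <- vapply(selected, function(tm) {
          r <- cond_test(setdiff(selected, tm), tm,
                         child_seed(seed, paste0("bwd", step_i, tm)))
          if (is.null(r)) 0 else r$p
        }, numeric(1))
        worst <- which.max(ps)
        if (ps[worst] > alpha_drop) {
          trace <- rbind(trace, data.frame(step = step_i, action = "drop",
                                           term = selected[worst],
                                           pseudo_F = NA,
                                           p_value = ps[worst]))
          selected <- selected[-worst]
          changed <- TRUE
        } else break
        if (length(selected) <= 1) break
      }
    }
    if (!changed) break
  }
  list(selected = selected, trace = trace)
}
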