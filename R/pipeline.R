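#' Pipeline configuration
#'
#' Assembles (and validates) the settings for [run_pipeline()]. Unknown
#' names are rejected. Pass either individual overrides or a YAML file via
#' [read_pipeline_config()].
#'
#' @param ... overrides of the defaults listed below
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_reads = 5000,
    exclude = c("mitochondria", "chloroplast"),
    drop_unassigned = FALSE,
    rarefy_depth = NULL,           # NULL = minimum library size
    permanova_terms = c("amendment", "texture", "Ca", "LOI"),
    dbrda_candidates = c("amendment", "texture", "farm_id", "pH", "P", "K",
                         "Mg", "Ca", "Na", "LOI"),
    n_perm = 999,
    bnti_nulls = 999,
    bnti_weighted = TRUE,
    core_model_var = "amendment",
    core_site_var = "farm_id",
    core_delta = 0.02,
    gllvm_covariates = c("farm_id", "amendment", "LOI", "Ca"),
    gllvm_family = "nb",
    gllvm_d = 2,
    gllvm_top_taxa = 100,
    coda_response = "LOI",
    coda_alpha = 1,
    coda_folds = 5,
    pseudocount = 0.5,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file of overrides
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Cross-check the consistency of a dataset bundle
#'
#' Report-only: lists samples without metadata, OTUs missing from the tree,
#' and all-zero rows/columns. Never raises an error.
#'
#' @param t count table
#' @param meta metadata
#' @param tree phylogeny (optional)
#' @param tax taxonomy (optional)
#' @return list of character vectors; all empty when consistent
#' @export
validate_inputs <- function(t, meta, tree = NULL, tax = NULL) {
  rep <- list(
    samples_without_metadata = setdiff(colnames(t), rownames(meta)),
    metadata_without_samples = setdiff(rownames(meta), colnames(t)),
    otus_missing_from_tree = if (!is.null(tree))
      setdiff(rownames(t), tree$tip.label) else character(0),
    otus_missing_from_taxonomy = if (!is.null(tax))
      setdiff(rownames(t), rownames(tax)) else character(0),
    zero_count_otus = rownames(t)[rowSums(t) == 0],
    zero_count_samples = colnames(t)[colSums(t) == 0]
  )
  rep
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing filters, rarefied alpha diversity,
#' Bray-Curtis and unweighted UniFrac distances with PCoA, PERMANOVA and
#' stepwise db-RDA selection, betaNTI, the Sloan neutral fit with
#' partitioning, per-level core microbiomes with overlap and neutral
#' overlay, the GLLVM on the most abundant taxa, and CODA-LASSO. Every
#' stochastic stage is seeded deterministically from the global seed, so a
#' rerun with the same inputs and config reproduces the outputs exactly.
#'
#' @param t count table
#' @param meta sample metadata
#' @param tree rooted phylogeny covering the OTUs
#' @param tax taxonomy table (optional; enables contaminant screening)
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, all stage outputs are
#'   written as TSV/JSON together with the resolved config
#' @return named list of stage results
#' @export
run_pipeline <- function(t, meta, tree, tax = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- validate_inputs(t, meta, tree, tax)
  if (length(report$samples_without_metadata))
    stop("inconsistent inputs: samples without metadata: ",
         paste(report$samples_without_metadata, collapse = ", "))

  res <- list(config = config, validation = report)
  res$filtered <- stage("filter",
    filter_dataset(t, tax, min_reads = config$min_reads,
                   exclude = config$exclude,
                   drop_unassigned = config$drop_unassigned, quiet = TRUE))
  tt <- res$filtered
  meta <- meta[colnames(tt), , drop = FALSE]

  res$alpha <- stage("alpha_diversity",
    alpha_diversity(tt, depth = config$rarefy_depth %||%
                      min(library_sizes(tt)),
                    seed = child_seed(seed, "rarefy")))
  res$bray <- stage("bray_curtis", bray_curtis(tt))
  res$unifrac <- stage("unifrac", unweighted_unifrac(tt, tree))
  res$pcoa_bray <- stage("pcoa", pcoa(res$bray, k = 10))
  res$pcoa_unifrac <- stage("pcoa", pcoa(res$unifrac, k = 10))

  terms <- intersect(config$permanova_terms, colnames(meta))
  res$permanova <- stage("permanova",
    permanova(res$bray, meta, terms, n_perm = config$n_perm,
              seed = child_seed(seed, "permanova")))
  cands <- intersect(config$dbrda_candidates, colnames(meta))
  res$dbrda <- stage("dbrda",
    stepwise_dbrda(res$bray, meta, cands, n_perm = min(config$n_perm, 199),
                   seed = child_seed(seed, "dbrda")))

  res$bnti <- stage("bnti",
    beta_nti(tt, tree, n_null = config$bnti_nulls,
             seed = child_seed(seed, "bnti"),
             weighted = config$bnti_weighted))
  res$sloan <- stage("sloan", fit_sloan_neutral(tt))
  res$cores <- stage("core",
    occupancy_models(tt, meta, model_var = config$core_model_var,
                     site_var = config$core_site_var,
                     delta = config$core_delta))
  res$core_overlap <- if (length(res$cores) > 2)
    stage("core_overlap",
          core_overlap(res$cores[setdiff(names(res$cores), "all")]))
  res$core_neutral <- stage("core_neutral",
    neutral_overlay(res$cores[["all"]], res$sloan))

  top <- order(rowSums(tt), decreasing = TRUE)[
    seq_len(min(config$gllvm_top_taxa, nrow(tt)))]
  X <- stage("design", build_design(meta, intersect(config$gllvm_covariates,
                                                    colnames(meta))))
  res$gllvm <- stage("gllvm",
    fit_gllvm(tt[top, , drop = FALSE], X, family = config$gllvm_family,
              d = config$gllvm_d, seed = child_seed(seed, "gllvm")))
  res$associations <- directional_associations(res$gllvm)

  yv <- meta[[config$coda_response]]
  res$coda <- stage("coda_lasso",
    fit_coda_lasso(tt[top, , drop = FALSE], yv,
                   alpha_mix = config$coda_alpha,
                   cv_folds = config$coda_folds,
                   pseudocount = config$pseudocount,
                   seed = child_seed(seed, "coda")))

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(res$config)
  cfg$rarefy_depth <- cfg$rarefy_depth %||% "min"
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  write_count_table(res$filtered, file.path(out_dir, "filtered_counts.tsv"))
  write_tsv(res$alpha, file.path(out_dir, "alpha_diversity.tsv"),
            row_label = "sample_id")
  write_distance(res$bray, file.path(out_dir, "bray_curtis.tsv"))
  write_distance(res$unifrac, file.path(out_dir, "unifrac.tsv"))
  write_tsv(res$pcoa_bray$points, file.path(out_dir, "pcoa_bray.tsv"),
            row_label = "sample_id")
  write_tsv(res$permanova$table, file.path(out_dir, "permanova.tsv"),
            row_label = "term")
  utils::write.table(bnti_pairs(res$bnti), file.path(out_dir, "bnti.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(res$sloan$otu, file.path(out_dir, "sloan_fit.tsv"),
            row_label = "otu_id")
  core_tab <- do.call(rbind, lapply(names(res$cores), function(nm) {
    cr <- res$cores[[nm]]
    data.frame(model = nm, otu = cr$core, rank = seq_along(cr$core))
  }))
  utils::write.table(core_tab, file.path(out_dir, "core_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary(res$gllvm),
                     file.path(out_dir, "gllvm_coefficients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  coda_tab <- data.frame(otu = names(res$coda$beta),
                         coefficient = unname(res$coda$beta))
  utils::write.table(coda_tab, file.path(out_dir, "coda_lasso.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(
    sloan = list(m = res$sloan$m, r_squared = res$sloan$r_squared),
    permanova_r2 = as.list(setNames(res$permanova$table$r_squared,
                                    rownames(res$permanova$table))),
    dbrda_selected = res$dbrda$selected,
    core_sizes = lapply(res$cores, `[[`, "k"),
    core_min_occupancy = lapply(res$cores, `[[`, "min_occupancy"),
    core_neutral_counts = as.list(res$core_neutral$counts),
    coda_lambda = res$coda$lambda_opt,
    seed = res$config$seed
  )
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
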