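#' Validate an OTU count table
#'
#' A count table is an integer matrix with OTUs as rows and samples as
#' columns, both uniquely named. All downstream functions index counts as
#' (OTU, sample).
#'
#' @param counts matrix of non-negative integers with rownames (OTU ids) and
#'   colnames (sample ids).
#' @return the validated integer matrix, invisibly classed as a plain matrix.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs OTU rownames and sample colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicate OTU id: ", dup[1])
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop("duplicate sample id: ", dup[1])
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at OTU '%s', sample '%s'",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Library sizes (per-sample read totals)
#' @param t count table (OTUs x samples)
#' @return named integer vector of column sums
#' @export
library_sizes <- function(t) colSums(t)

#' Read / write an OTU count table as TSV
#'
#' The file has OTU rows and sample columns; the first column holds OTU ids
#' and the header row holds sample ids.
#'
#' @param path TSV file path
#' @return integer count matrix (OTUs x samples)
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column and >=1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric cells in sample column '", colnames(df)[-1][bad], "'")
  }
  rownames(m) <- ids
  count_table(m)
}

#' @rdname read_count_table
#' @param t count table to write
#' @export
write_count_table <- function(t, path) write_tsv(t, path, row_label = "otu_id")

#' Read a taxonomy table
#'
#' TSV keyed by OTU id with one column per rank (domain ... genus). Empty
#' strings mark ranks with no assignment.
#'
#' @param path TSV path
#' @return data.frame with rownames = OTU ids and character rank columns
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = NULL)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate OTU id in taxonomy: ",
                               ids[duplicated(ids)][1])
  out <- df[, -1, drop = FALSE]
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  rownames(out) <- ids
  out
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame
#' @export
write_taxonomy <- function(tax, path) write_tsv(tax, path, row_label = "otu_id")

# declared categorical structure of the study design; reference level first
default_metadata_levels <- function() {
  list(
    amendment = c("None", "FYM", "Digestate", "Slurry"),
    texture = c("Sandy Silt Loam", "Sandy Loam", "Silty Clay Loam",
                "Clay Loam")
  )
}

#' Read sample metadata
#'
#' TSV keyed by sample id. Columns named in `levels` are validated against
#' the declared level sets (first level = reference) and converted to
#' factors; remaining character columns become unordered factors and numeric
#' columns are checked finite.
#'
#' @param path TSV path
#' @param levels named list of declared level vectors for categorical
#'   covariates; the first element of each is the reference level.
#' @return data.frame with rownames = sample ids
#' @export
read_metadata <- function(path, levels = default_metadata_levels()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample id in metadata: ",
                               ids[duplicated(ids)][1])
  out <- df[, -1, drop = FALSE]
  rownames(out) <- ids
  validate_metadata(out, levels)
}

validate_metadata <- function(meta, levels = default_metadata_levels()) {
  for (v in names(levels)) {
    if (!v %in% colnames(meta)) next
    x <- as.character(meta[[v]])
    bad <- setdiff(unique(x), levels[[v]])
    if (length(bad))
      stop(sprintf("unknown level '%s' for covariate '%s'", bad[1], v))
    meta[[v]] <- factor(x, levels = levels[[v]])
  }
  for (v in colnames(meta)) {
    if (is.character(meta[[v]])) meta[[v]] <- factor(meta[[v]])
    if (is.numeric(meta[[v]]) && any(!is.finite(meta[[v]])))
      stop("non-finite values in continuous covariate '", v, "'")
  }
  meta
}

#' @rdname read_metadata
#' @param meta metadata data.frame
#' @export
write_metadata <- function(meta, path) write_tsv(meta, path,
                                                 row_label = "sample_id")

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that enforces what the phylogenetic
#' metrics need: unique tip labels and non-negative branch lengths on every
#' edge.
#'
#' @param path Newick file
#' @return an [ape::phylo] tree
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("tree is missing branch lengths (required by UniFrac and betaMNTD)")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  tree
}

#' Filter an OTU table the way shallow samples and contaminant lineages are
#' screened out of amplicon surveys
#'
#' Drops samples whose library size is not strictly greater than `min_reads`,
#' OTUs whose taxonomy lineage contains any of the `exclude` substrings
#' (case-insensitive match over the concatenated lineage), and, optionally,
#' OTUs with no assignment at any rank.
#'
#' @param t count table
#' @param tax taxonomy data.frame covering the OTUs of `t` (may be NULL to
#'   skip lineage screening)
#' @param min_reads library-size threshold; samples kept only if strictly
#'   greater (default 5000)
#' @param exclude character vector of contaminant substrings
#' @param drop_unassigned drop OTUs unassigned at every rank
#' @param quiet suppress the removal report message
#' @return filtered count table
#' @export
filter_dataset <- function(t, tax = NULL, min_reads = 5000,
                           exclude = c("mitochondria", "chloroplast"),
                           drop_unassigned = FALSE, quiet = FALSE) {
  t <- count_table(t)
  drop_otu <- logical(nrow(t))
  if (!is.null(tax) && nrow(t)) {
    miss <- setdiff(rownames(t), rownames(tax))
    if (length(miss)) stop("taxonomy missing OTU: ", miss[1])
    tx <- tax[rownames(t), , drop = FALSE]
    lineage <- tolower(apply(tx, 1, paste, collapse = ";"))
    for (pat in exclude)
      drop_otu <- drop_otu | grepl(tolower(pat), lineage, fixed = TRUE)
    if (drop_unassigned) {
      unass <- apply(tx, 1, function(r) all(trimws(r) == ""))
      drop_otu <- drop_otu | unass
    }
  }
  # contaminants are removed first so the library-size threshold applies to
  # the cleaned table (and filtering is idempotent)
  clean <- t[!drop_otu, , drop = FALSE]
  keep_s <- colSums(clean) > min_reads
  out <- clean[, keep_s, drop = FALSE]
  if (ncol(out) == 0) stop("no samples survive filtering")
  if (!quiet)
    message(sprintf("filter_dataset: removed %d/%d samples, %d/%d OTUs",
                    sum(!keep_s), ncol(t), sum(drop_otu), nrow(t)))
  out
}

#' Total-sum scaling followed by the centred log-ratio transform
#'
#' Per sample, counts are shifted by a pseudocount, scaled to proportions,
#' and log-transformed relative to the sample's geometric mean, so each
#' sample's transformed values sum to zero.
#'
#' @param t count table
#' @param pseudocount positive shift added to every count before scaling
#'   (default 0.5, the half-count convention)
#' @return real matrix (OTUs x samples) of CLR values
#' @export
tss_clr <- function(t, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  t <- count_table(t)
  if (any(colSums(t) == 0)) {
    bad <- colnames(t)[colSums(t) == 0][1]
    stop("all-zero sample: ", bad)
  }
  x <- t + pseudocount
  p <- sweep(x, 2, colSums(x), "/")
  lp <- log(p)
  sweep(lp, 2, colMeans(lp), "-")
}
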