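#' Read a taxa-by-samples community count table
#'
#' Reads an integer count matrix (taxa as rows, samples as columns) from a
#' tab-separated file whose first column, `taxon_id`, holds the taxon
#' identifiers, or from a BIOM 2.x file when the `biomformat` package is
#' available. Row and column order of the file is preserved.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return An integer matrix with taxa as rows and samples as columns,
#'   dimnames set to the taxon and sample identifiers.
#' @examples
#' tab <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'               dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' f <- tempfile(fileext = ".tsv")
#' write_community_table(tab, f)
#' identical(read_community_table(f), tab)
#' @export
read_community_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "integer"
    return(validate_community_table(m))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("count table needs a taxon_id column and >= 1 sample column")
  taxa <- df[[1L]]
  samples <- colnames(df)[-1L]
  m <- matrix(NA_integer_, nrow = nrow(df), ncol = length(samples),
              dimnames = list(taxa, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]) | is.na(df[[j + 1L]]))
    if (length(bad)) {
      stop(sprintf("non-numeric count at row '%s', column '%s'",
                   taxa[bad[1L]], samples[j]))
    }
    if (any(v != round(v))) {
      k <- which(v != round(v))[1L]
      stop(sprintf("non-integer count at row '%s', column '%s'",
                   taxa[k], samples[j]))
    }
    if (any(v < 0)) {
      k <- which(v < 0)[1L]
      stop(sprintf("negative count at row '%s', column '%s'",
                   taxa[k], samples[j]))
    }
    m[, j] <- as.integer(v)
  }
  validate_community_table(m)
}

#' Write a community table to TSV
#'
#' Mirrors [read_community_table()] bit-exactly for integer tables: taxa as
#' rows, a leading `taxon_id` column, tab separation, no quoting.
#'
#' @param table Integer taxa-by-samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path) {
  table <- validate_community_table(table)
  df <- data.frame(taxon_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared invariants for count matrices: integer, >= 0, unique dimnames.
validate_community_table <- function(table) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop("community table must carry taxon (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(table))) {
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(table)[duplicated(rownames(table))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(table))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(table)[duplicated(colnames(table))]), collapse = ", "))
  }
  if (any(is.na(table))) stop("community table contains missing values")
  if (any(table < 0)) stop("community table contains negative counts")
  if (any(table != round(table))) stop("community table contains non-integer counts")
  storage.mode(table) <- "integer"
  table
}

#' Read a rooted phylogeny from a newick file
#'
#' Wraps [ape::read.tree()] and enforces the invariants the phylogenetic
#' metrics rely on: the tree is rooted, every tip is labeled and unique, and
#' every branch carries a non-negative length.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  validate_phylogeny(tree)
}

#' @rdname read_phylogeny
#' @param tree An [ape::phylo] object.
#' @export
write_phylogeny <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!nzchar(tree$tip.label)) || any(is.na(tree$tip.label))) {
    stop("tree contains unlabeled tips")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("tree has missing or negative branch lengths")
  }
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; root it (e.g. with ape::root) before analysis")
  }
  tree
}

#' Read sample metadata from CSV
#'
#' Expects a header with at least `sample_id` and `date` (ISO-8601,
#' `YYYY-MM-DD`); `station` and any numeric environmental columns (e.g.
#' temperature, salinity, nutrients) are carried through. A `month` column
#' (1-12) is derived from the date.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `sample_id`, `date` (`Date`), `month`,
#'   `station` (if present) and the environmental variables.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "date") %in% colnames(df))) {
    stop("metadata must contain 'sample_id' and 'date' columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stop("unparseable dates in metadata (expect YYYY-MM-DD)")
  df$month <- as.integer(format(df$date, "%m"))
  env_cols <- setdiff(colnames(df), c("sample_id", "date", "month", "station"))
  for (v in env_cols) {
    df[[v]] <- as.numeric(df[[v]])
    if (any(is.infinite(df[[v]]), na.rm = TRUE)) {
      stop("non-finite values in metadata variable '", v, "'")
    }
  }
  df
}

#' @rdname read_sample_metadata
#' @param metadata A metadata data.frame as returned by [read_sample_metadata()].
#' @export
write_sample_metadata <- function(metadata, path) {
  out <- metadata
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a community table, tree and metadata
#'
#' Report-only consistency check run before any phylogenetic stage: every
#' taxon must be a tip of the tree and every sample must have metadata.
#'
#' @param table Taxa-by-samples count matrix.
#' @param tree An [ape::phylo] object.
#' @param metadata Optional metadata data.frame with a `sample_id` column;
#'   `NULL` means metadata checks are skipped.
#' @return A list of class `"validation_report"` with elements `shared_taxa`,
#'   `taxa_missing_from_tree`, `samples_missing_metadata` and `is_valid`.
#'   `is_valid` is `TRUE` iff both missing lists are empty.
#' @export
validate_consistency <- function(table, tree, metadata = NULL) {
  table <- validate_community_table(table)
  validate_phylogeny(tree)
  missing_taxa <- setdiff(rownames(table), tree$tip.label)
  if (is.null(metadata)) {
    missing_samples <- character(0)
  } else {
    missing_samples <- setdiff(colnames(table), metadata$sample_id)
  }
  structure(list(
    shared_taxa = length(intersect(rownames(table), tree$tip.label)),
    taxa_missing_from_tree = missing_taxa,
    samples_missing_metadata = missing_samples,
    is_valid = length(missing_taxa) == 0L && length(missing_samples) == 0L
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Consistency report\n")
  cat("  shared taxa:            ", x$shared_taxa, "\n")
  cat("  taxa missing from tree: ", length(x$taxa_missing_from_tree), "\n")
  cat("  samples w/o metadata:   ", length(x$samples_missing_metadata), "\n")
  cat("  valid:                  ", x$is_valid, "\n")
  invisible(x)
}

#' Rarefy a community table to uniform depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to a common depth. Samples with
#' fewer reads than `depth` are dropped, as are taxa left with all-zero
#' counts; both drops are reported via `message()` and recorded in
#' attributes.
#'
#' @param table Taxa-by-samples integer count matrix.
#' @param depth Target reads per sample (positive integer), the common
#'   sequencing depth after rarefaction.
#' @param seed Integer seed; identical `(table, depth, seed)` gives an
#'   identical result.
#' @return The rarefied count matrix, every column summing exactly to
#'   `depth`, with attributes `rarefied_depth`, `dropped_samples` and
#'   `dropped_taxa`.
#' @examples
#' tab <- matrix(c(500L, 520L, 0L, 900L, 80L, 40L), nrow = 3,
#'               dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' r <- rarefy_table(tab, depth = 100, seed = 1)
#' colSums(r)  # all exactly 100
#' @export
rarefy_table <- function(table, depth, seed = NULL) {
  table <- validate_community_table(table)
  if (length(depth) != 1L || !is.finite(depth) || depth < 1) {
    stop("depth must be a positive integer")
  }
  depth <- as.integer(depth)
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  dropped_samples <- colnames(table)[!keep]
  if (length(dropped_samples)) {
    message("rarefy_table: dropping ", length(dropped_samples),
            " sample(s) below depth ", depth, ": ",
            paste(dropped_samples, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  # vegan's "observed counts" advisory is redundant here: counts are already
  # validated as integers and under-depth samples have been dropped
  sub <- withCallingHandlers(
    t(vegan::rrarefy(t(table[, keep, drop = FALSE]), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(sub) <- "integer"
  zero <- rowSums(sub) == 0L
  dropped_taxa <- rownames(sub)[zero]
  if (length(dropped_taxa)) {
    message("rarefy_table: dropping ", length(dropped_taxa),
            " taxa with zero counts after rarefaction")
  }
  out <- sub[!zero, , drop = FALSE]
  attr(out, "rarefied_depth") <- depth
  attr(out, "dropped_samples") <- dropped_samples
  attr(out, "dropped_taxa") <- dropped_taxa
  out
}
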