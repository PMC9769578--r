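#' Environmental niche values per taxon
#'
#' The niche value of a taxon for an environmental variable is its
#' abundance-weighted mean of that variable over samples:
#' `niche_i = sum_s a_is * env_s / sum_s a_is`. Taxa with zero total
#' abundance are excluded (and reported via `message()`).
#'
#' @param table Taxa-by-samples count matrix.
#' @param env Either a named numeric vector (`sample_id -> value`) or a
#'   metadata data.frame with `sample_id`, in which case `variable` names
#'   the column to use.
#' @param variable Column of `env` holding the variable (when `env` is a
#'   data.frame).
#' @return Named numeric vector of niche values over taxa with nonzero
#'   abundance, with attribute `"variable"`.
#' @export
niche_values <- function(table, env, variable = NULL) {
  table <- validate_community_table(table)
  if (is.data.frame(env)) {
    if (is.null(variable)) stop("supply 'variable' when env is a data.frame")
    if (!variable %in% colnames(env)) stop("variable '", variable,
                                           "' not in metadata")
    env <- stats::setNames(env[[variable]], env$sample_id)
  }
  miss <- setdiff(colnames(table), names(env))
  if (length(miss)) stop("samples without environmental values: ",
                         paste(miss, collapse = ", "))
  e <- env[colnames(table)]
  if (any(!is.finite(e))) stop("environmental values must be finite")
  tot <- rowSums(table)
  zero <- tot == 0
  if (any(zero)) {
    message("niche_values: excluding ", sum(zero), " taxa with zero abundance")
  }
  tab <- table[!zero, , drop = FALSE]
  out <- as.numeric(tab %*% e) / rowSums(tab)
  names(out) <- rownames(tab)
  attr(out, "variable") <- if (is.null(variable)) "env" else variable
  out
}

#' Mantel correlogram of niche distance against phylogenetic distance
#'
#' Tests for phylogenetic signal in a niche: for each of a set of contiguous
#' equal-width phylogenetic distance classes, the Mantel statistic is the
#' Pearson correlation between the class-membership indicator and the niche
#' distances over all unordered tip pairs. Significance is assessed by
#' jointly permuting the taxon order of the niche-distance matrix
#' (two-tailed), with progressive Holm correction across classes (class k is
#' corrected for the k tests up to and including it).
#'
#' Sign convention: the raw correlation is negative when within-class pairs
#' are ecologically more similar than average, so the reported `r` is the
#' sign-flipped statistic — positive `r` in a short-distance class means
#' close relatives have more similar niches than chance, i.e. phylogenetic
#' signal. The raw value is kept in `r_raw`.
#'
#' @param phylo_dist Symmetric tip-distance matrix with zero diagonal (e.g.
#'   [cophenetic_matrix()]), restricted to the taxa of interest.
#' @param niche_dist Symmetric matrix of absolute niche differences over the
#'   same taxa, in the same order (see [niche_values()]).
#' @param n_classes Number of distance classes; default Sturges' rule on the
#'   number of pairs.
#' @param n_permutations Permutations for the per-class tests (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return data.frame of class `"mantel_correlogram"`, one row per class:
#'   `class`, `lower`, `upper`, `midpoint`, `n_pairs`, `r`, `r_raw`,
#'   `p_raw`, `p_corrected`, `n_permutations`. Classes with fewer than 2
#'   pairs get `NA` statistics.
#' @export
mantel_correlogram <- function(phylo_dist, niche_dist, n_classes = NULL,
                               n_permutations = 999L, seed = NULL) {
  phylo_dist <- as.matrix(phylo_dist)
  niche_dist <- as.matrix(niche_dist)
  if (!isTRUE(all.equal(dim(phylo_dist), dim(niche_dist)))) {
    stop("distance matrices must have the same dimensions")
  }
  if (any(abs(phylo_dist - t(phylo_dist)) > 1e-8) ||
      any(abs(niche_dist - t(niche_dist)) > 1e-8)) {
    stop("distance matrices must be symmetric")
  }
  if (any(diag(phylo_dist) != 0) || any(diag(niche_dist) != 0)) {
    stop("distance matrices must have zero diagonals")
  }
  n <- nrow(phylo_dist)
  lt <- lower.tri(phylo_dist)
  pd <- phylo_dist[lt]
  n_pairs_tot <- length(pd)
  if (is.null(n_classes)) n_classes <- ceiling(log2(n_pairs_tot) + 1)
  breaks <- seq(min(pd), max(pd), length.out = n_classes + 1L)
  cls <- cut(pd, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  A <- vapply(seq_len(n_classes), function(k) as.numeric(cls == k),
              numeric(n_pairs_tot))
  npk <- colSums(A)
  usable <- npk >= 2 & npk < n_pairs_tot  # indicator needs variance
  nd <- niche_dist[lt]
  if (stats::sd(nd) == 0) {
    warning("niche distances are constant; Mantel statistics undefined")
    usable[] <- FALSE
  }
  r_raw <- rep(NA_real_, n_classes)
  r_raw[usable] <- suppressWarnings(
    as.numeric(stats::cor(A[, usable, drop = FALSE], nd)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  exceed <- rep(0L, n_classes)
  for (p in seq_len(n_permutations)) {
    idx <- sample.int(n)
    ndp <- niche_dist[idx, idx][lt]
    rp <- suppressWarnings(
      as.numeric(stats::cor(A[, usable, drop = FALSE], ndp)))
    exceed[usable] <- exceed[usable] + (abs(rp) >= abs(r_raw[usable]))
  }
  p_raw <- rep(NA_real_, n_classes)
  p_raw[usable] <- (exceed[usable] + 1) / (n_permutations + 1)
  # progressive correction: class k adjusted for the k tests up to it
  p_corr <- rep(NA_real_, n_classes)
  for (k in which(usable & !is.na(p_raw))) {
    upto <- p_raw[seq_len(k)]
    upto <- upto[!is.na(upto)]
    p_corr[k] <- stats::p.adjust(upto, method = "holm")[length(upto)]
  }
  out <- data.frame(class = seq_len(n_classes),
                    lower = breaks[-length(breaks)],
                    upper = breaks[-1L],
                    midpoint = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                    n_pairs = as.integer(npk),
                    r = -r_raw,
                    r_raw = r_raw,
                    p_raw = p_raw,
                    p_corrected = p_corr,
                    n_permutations = as.integer(n_permutations))
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat("Mantel correlogram (", x$n_permutations[1], "permutations )\n")
  print.data.frame(x[c("class", "midpoint", "n_pairs", "r", "p_raw",
                       "p_corrected")], digits = 4, row.names = FALSE)
  invisible(x)
}
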