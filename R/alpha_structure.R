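#' Non-phylogenetic alpha diversity indices
#'
#' Per-sample richness, Shannon entropy (natural log) and the Simpson
#' diversity index 1-D, computed on relative abundances within each sample.
#' All-zero samples get `NA` for every index (undefined, not zero).
#'
#' @param table Taxa-by-samples count matrix.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson_1d`.
#' @examples
#' tab <- matrix(c(25L, 25L, 25L, 25L), ncol = 1,
#'               dimnames = list(paste0("t", 1:4), "s1"))
#' alpha_diversity(tab)  # richness 4, shannon log(4), simpson 0.75
#' @export
alpha_diversity <- function(table) {
  table <- validate_community_table(table)
  comm <- t(table)
  totals <- rowSums(comm)
  sh <- vegan::diversity(comm, index = "shannon")
  si <- vegan::diversity(comm, index = "simpson")
  out <- data.frame(sample_id = colnames(table),
                    richness = as.integer(rowSums(comm > 0)),
                    shannon = as.numeric(sh),
                    simpson_1d = as.numeric(si),
                    stringsAsFactors = FALSE)
  empty <- totals == 0
  out$shannon[empty] <- NA_real_
  out$simpson_1d[empty] <- NA_real_
  out
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting each sample's
#' occupied taxa and the tree root (rooted PD, via [picante::pd()]).
#'
#' @param table Taxa-by-samples count matrix; every occupied taxon must be a
#'   tip of `tree`.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @return Named numeric vector of PD per sample (`NA` for empty samples).
#' @export
faith_pd <- function(table, tree) {
  table <- validate_community_table(table)
  validate_phylogeny(tree)
  occupied <- rownames(table)[rowSums(table) > 0]
  missing <- setdiff(occupied, tree$tip.label)
  if (length(missing)) {
    stop("occupied taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  comm <- t(table[intersect(rownames(table), tree$tip.label), , drop = FALSE])
  pd <- picante::pd(comm, tree, include.root = TRUE)
  res <- stats::setNames(pd$PD, rownames(pd))
  res[rowSums(comm) == 0] <- NA_real_
  res[colnames(table)]
}

#' Mean pairwise phylogenetic distance within one community
#'
#' Unweighted: the mean cophenetic distance over all unordered pairs of
#' occupied taxa. Weighted: the abundance-weighted mean,
#' `sum(d_ij a_i a_j) / sum(a_i a_j)` over `i != j`.
#'
#' @param taxa Character vector of occupied taxa (length >= 2 for a defined
#'   value).
#' @param dist Cophenetic distance matrix with these taxa among its
#'   rows/columns (see [cophenetic_matrix()]).
#' @param weighted Use abundance weighting (default `FALSE`).
#' @param abundances Named abundance vector, required when `weighted = TRUE`.
#' @return The MPD, or `NA` when fewer than 2 taxa are occupied.
#' @export
mpd_community <- function(taxa, dist, weighted = FALSE, abundances = NULL) {
  taxa <- unique(taxa)
  if (length(taxa) < 2L) return(NA_real_)
  if (!all(taxa %in% rownames(dist))) {
    stop("taxa absent from distance matrix")
  }
  d <- dist[taxa, taxa]
  if (!weighted) {
    return(mean(d[upper.tri(d)]))
  }
  if (is.null(abundances)) stop("weighted MPD requires abundances")
  a <- abundances[taxa]
  num <- as.numeric(t(a) %*% d %*% a)          # diagonal of d is zero
  den <- sum(a)^2 - sum(a^2)
  if (den <= 0) return(NA_real_)
  num / den
}

# Presence/abundance matrix over the FULL set of tree tips (tip order), so
# the tip-label-shuffling null permutes the whole tree, not just observed taxa.
tip_indicator_matrix <- function(table, tree, weighted = FALSE) {
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing)) {
    stop("table taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  P <- matrix(0, nrow = ntip, ncol = ncol(table),
              dimnames = list(tree$tip.label, colnames(table)))
  idx <- match(rownames(table), tree$tip.label)
  P[idx, ] <- if (weighted) table else (table > 0) * 1
  P
}

# Per-sample MPD for every column of indicator matrix P against distances D.
# Unweighted: v'Dv counts each unordered pair twice, so divide by n(n-1).
mpd_all_samples <- function(P, D, weighted = FALSE) {
  if (!weighted) {
    quad <- colSums(P * (D %*% P))
    n <- colSums(P > 0)
    out <- quad / (n * (n - 1))
    out[n < 2] <- NA_real_
    return(out)
  }
  tot <- colSums(P)
  A <- sweep(P, 2, pmax(tot, 1), "/")
  quad <- colSums(A * (D %*% A))
  den <- 1 - colSums(A^2)
  out <- quad / den
  out[colSums(P > 0) < 2 | den <= 0] <- NA_real_
  out
}

#' Net relatedness index under a tip-label-shuffling null
#'
#' For each sample, the observed MPD is compared with its null distribution
#' obtained by uniformly permuting all tip labels of the phylogeny
#' (membership and abundances untouched), and the z-score is sign-flipped:
#' `NRI = -(MPD_obs - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. Positive NRI indicates phylogenetic clustering (environmental
#' filtering), negative NRI overdispersion. Samples with fewer than 2
#' occupied taxa, or degenerate nulls (`sd = 0`), are reported as `NA`.
#'
#' @param table Taxa-by-samples count matrix; taxa must be tips of `tree`.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param n_reps Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param weighted Abundance-weighted MPD instead of presence-based
#'   (default `FALSE`).
#' @return data.frame with columns `sample_id`, `richness`, `mpd_obs`,
#'   `null_mean`, `null_sd`, `nri`, `n_reps`.
#' @export
nri <- function(table, tree, n_reps = 999L, seed = NULL, weighted = FALSE) {
  table <- validate_community_table(table)
  validate_phylogeny(tree)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  D <- cophenetic_matrix(tree)
  P <- tip_indicator_matrix(table, tree, weighted = weighted)
  obs <- mpd_all_samples(P, D, weighted = weighted)
  ntip <- nrow(D)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nulls <- matrix(NA_real_, nrow = ncol(P), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(ntip)
    nulls[, r] <- mpd_all_samples(P, D[perm, perm], weighted = weighted)
  }
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1, stats::sd)
  z <- -(obs - null_mean) / null_sd
  z[!is.finite(z)] <- NA_real_
  data.frame(sample_id = colnames(table),
             richness = as.integer(colSums(table > 0)),
             mpd_obs = as.numeric(obs),
             null_mean = null_mean,
             null_sd = null_sd,
             nri = z,
             n_reps = as.integer(n_reps),
             stringsAsFactors = FALSE)
}
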