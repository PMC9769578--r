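#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' Pairwise tip-to-tip distances, each the sum of branch lengths on the path
#' between the two tips, with rows and columns in `tree$tip.label` order.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  validate_phylogeny(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Between-community mean pairwise phylogenetic distance
#'
#' Unweighted betaMPD for one pair of communities: the mean cophenetic
#' distance over all ordered cross pairs (i in a, j in b), including the
#' zero distances contributed by taxa shared between the two communities.
#'
#' @param taxa_a,taxa_b Character vectors of occupied taxa in each community.
#' @param dist Cophenetic distance matrix covering all those taxa.
#' @return The betaMPD, or `NA` if either community is empty.
#' @export
beta_mpd_pair <- function(taxa_a, taxa_b, dist) {
  taxa_a <- unique(taxa_a); taxa_b <- unique(taxa_b)
  if (length(taxa_a) == 0L || length(taxa_b) == 0L) return(NA_real_)
  if (!all(c(taxa_a, taxa_b) %in% rownames(dist))) {
    stop("taxa absent from distance matrix")
  }
  mean(dist[taxa_a, taxa_b])
}

# All-pairs betaMPD matrix from a presence indicator P (tips x samples):
# cross-pair distance sums are t(P) D P, scaled by the richness product.
beta_mpd_all_pairs <- function(P, D) {
  S <- crossprod(P, D %*% P)
  n <- colSums(P > 0)
  B <- S / outer(n, n)
  B[n < 1, ] <- NA_real_
  B[, n < 1] <- NA_real_
  B
}

#' Phylogenetic turnover z-scores (betaNRI) under a tip-shuffling null
#'
#' For every unordered sample pair the observed betaMPD is compared with the
#' null distribution obtained by uniformly permuting all tip labels of the
#' phylogeny:
#' `betaNRI = (betaMPD_obs - mean(null)) / sd(null)` (sample sd, *not*
#' sign-flipped, unlike [nri()]). betaNRI < -2 indicates less phylogenetic
#' turnover than expected (homogeneous selection), betaNRI > +2 more
#' (heterogeneous selection). One permutation stream is shared across all
#' pairs, so the statistic is exactly symmetric in the pair.
#'
#' @inheritParams nri
#' @return data.frame with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `beta_mpd_obs`, `null_mean`, `null_sd`, `beta_nri`,
#'   `n_reps`.
#' @export
beta_nri <- function(table, tree, n_reps = 999L, seed = NULL) {
  table <- validate_community_table(table)
  validate_phylogeny(tree)
  if (ncol(table) < 2L) stop("need at least 2 samples")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  D <- cophenetic_matrix(tree)
  P <- tip_indicator_matrix(table, tree)
  obs <- beta_mpd_all_pairs(P, D)
  ntip <- nrow(D)
  ns <- ncol(P)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sum1 <- matrix(0, ns, ns)
  sum2 <- matrix(0, ns, ns)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(ntip)
    B <- beta_mpd_all_pairs(P, D[perm, perm])
    sum1 <- sum1 + B
    sum2 <- sum2 + B^2
  }
  null_mean <- sum1 / n_reps
  null_sd <- sqrt(pmax(sum2 - n_reps * null_mean^2, 0) / (n_reps - 1))
  z <- (obs - null_mean) / null_sd
  ij <- which(upper.tri(obs), arr.ind = TRUE)
  res <- data.frame(sample_a = colnames(table)[ij[, 1]],
                    sample_b = colnames(table)[ij[, 2]],
                    beta_mpd_obs = obs[ij],
                    null_mean = null_mean[ij],
                    null_sd = null_sd[ij],
                    beta_nri = z[ij],
                    n_reps = as.integer(n_reps),
                    stringsAsFactors = FALSE)
  res$beta_nri[!is.finite(res$beta_nri)] <- NA_real_
  res
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC = sum(|x - y|) / sum(x + y)`, in \[0, 1\]. Undefined (`NA`) when both
#' vectors are all-zero.
#'
#' @param x,y Non-negative abundance vectors on the same taxon indexing.
#' @return The Bray-Curtis dissimilarity.
#' @examples
#' bray_curtis(c(10, 0, 5), c(2, 8, 5))  # 16/30
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must share taxon indexing")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) return(NA_real_)
  sum(abs(x - y)) / tot
}

# One null community per sample under the abundance Raup-Crick model:
# observed richness taxa drawn without replacement with probability
# proportional to occupancy frequency; reads = 1 each + a multinomial of the
# remaining total with probabilities proportional to dataset-wide relative
# abundance. Marginals (richness, total reads) match the template exactly.
rc_null_sample <- function(richness, total, occ_freq, rel_ab) {
  n <- length(occ_freq)
  members <- sample.int(n, richness, replace = FALSE, prob = occ_freq)
  reads <- rep(1L, richness)
  extra <- total - richness
  if (extra > 0) {
    p <- rel_ab[members]
    if (sum(p) == 0) p <- rep(1, richness)
    reads <- reads + stats::rmultinom(1, extra, p)[, 1]
  }
  out <- integer(n)
  out[members] <- reads
  out
}

#' Raup-Crick turnover on Bray-Curtis dissimilarity (RC_bray)
#'
#' Compares each pair's observed Bray-Curtis dissimilarity with a null
#' distribution in which community membership is randomized proportionally
#' to taxon occupancy frequency (holding each sample's richness fixed) and
#' reads are reallocated proportionally to dataset-wide relative abundance
#' (holding each sample's total fixed, every drawn taxon receiving at least
#' one read). With `F` the fraction of null values below the observed value
#' (ties counted half),
#' `RC_bray = 2 * (F - 0.5)` in \[-1, 1\]. RC_bray > 0.95 indicates more
#' compositional turnover than chance (dispersal limitation),
#' RC_bray < -0.95 less (homogenizing dispersal).
#'
#' A rarefied table (equal column sums) is recommended. One null community
#' is built per sample per replicate and shared across the pairs of that
#' replicate; null draws for the two members of a pair are independent.
#'
#' @inheritParams nri
#' @return data.frame with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bray_curtis_obs`, `rc_bray`, `n_reps`.
#' @export
raup_crick_bray <- function(table, n_reps = 999L, seed = NULL) {
  table <- validate_community_table(table)
  if (ncol(table) < 2L) stop("need at least 2 samples")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ns <- ncol(table)
  richness <- colSums(table > 0)
  totals <- colSums(table)
  if (any(richness == 0)) {
    warning("samples with zero richness are flagged NA: ",
            paste(colnames(table)[richness == 0], collapse = ", "))
  }
  occ_freq <- rowSums(table > 0)
  rel_ab <- rowSums(table) / sum(table)
  obs <- as.matrix(vegan::vegdist(t(table), method = "bray"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  below <- matrix(0, ns, ns)
  ties <- matrix(0, ns, ns)
  null_tab <- matrix(0L, nrow(table), ns)
  eps <- 1e-10
  for (r in seq_len(n_reps)) {
    for (s in seq_len(ns)) {
      null_tab[, s] <- rc_null_sample(richness[s], totals[s], occ_freq, rel_ab)
    }
    # null marginals must equal the template's by construction
    stopifnot(all(colSums(null_tab > 0) == richness),
              all(colSums(null_tab) == totals))
    nb <- as.matrix(vegan::vegdist(t(null_tab), method = "bray"))
    below <- below + (nb < obs - eps)
    ties <- ties + (abs(nb - obs) <= eps)
  }
  rc <- 2 * ((below + 0.5 * ties) / n_reps - 0.5)
  ij <- which(upper.tri(obs), arr.ind = TRUE)
  res <- data.frame(sample_a = colnames(table)[ij[, 1]],
                    sample_b = colnames(table)[ij[, 2]],
                    bray_curtis_obs = obs[ij],
                    rc_bray = rc[ij],
                    n_reps = as.integer(n_reps),
                    stringsAsFactors = FALSE)
  bad <- richness == 0
  if (any(bad)) {
    flag <- colnames(table)[bad]
    hit <- res$sample_a %in% flag | res$sample_b %in% flag
    res$rc_bray[hit] <- NA_real_
    res$bray_curtis_obs[hit] <- NA_real_
  }
  res
}

#' Full pairwise turnover records
#'
#' Convenience wrapper combining [beta_nri()] and [raup_crick_bray()] into
#' one record per sample pair — the input the process classifier consumes.
#' Independent permutation streams are used for the two null models
#' (`seed` and `seed + 1`).
#'
#' @inheritParams nri
#' @return data.frame with columns `sample_a`, `sample_b`, `beta_mpd_obs`,
#'   `beta_nri`, `bray_curtis_obs`, `rc_bray`, `n_reps`.
#' @export
turnover_records <- function(table, tree, n_reps = 999L, seed = NULL) {
  bn <- beta_nri(table, tree, n_reps = n_reps, seed = seed)
  rc <- raup_crick_bray(table, n_reps = n_reps,
                        seed = if (is.null(seed)) NULL else as.integer(seed) + 1L)
  stopifnot(identical(bn$sample_a, rc$sample_a),
            identical(bn$sample_b, rc$sample_b))
  data.frame(bn[c("sample_a", "sample_b", "beta_mpd_obs", "beta_nri")],
             rc[c("bray_curtis_obs", "rc_bray")],
             n_reps = as.integer(n_reps),
             stringsAsFactors = FALSE)
}
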