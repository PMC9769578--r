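# Independent brute-force oracles and tiny fixtures shared across tests.

# the worked 4-tip balanced tree: d(A,B) = d(C,D) = 2, all cross-clade = 4
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# MPD by explicit double loop over unordered pairs
brute_mpd <- function(taxa, D) {
  taxa <- unique(taxa)
  if (length(taxa) < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (i < j) { tot <- tot + D[taxa[i], taxa[j]]; np <- np + 1 }
    }
  }
  tot / np
}

# abundance-weighted MPD by explicit double loop over ordered pairs i != j
brute_mpd_weighted <- function(abund, D) {
  taxa <- names(abund)[abund > 0]
  a <- abund[taxa] / sum(abund[taxa])
  num <- 0; den <- 0
  for (i in taxa) for (j in taxa) {
    if (i != j) { num <- num + a[i] * a[j] * D[i, j]; den <- den + a[i] * a[j] }
  }
  unname(num / den)
}

# betaMPD by explicit double loop over ALL ordered cross pairs (shared taxa
# contribute their zero self-distances)
brute_beta_mpd <- function(taxa_a, taxa_b, D) {
  tot <- 0; np <- 0
  for (i in taxa_a) for (j in taxa_b) { tot <- tot + D[i, j]; np <- np + 1 }
  tot / np
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# exhaustive tip-label-shuffle null for one community's NRI: every label
# permutation is equally likely, so the null mean/sd are population moments
# over all n! relabelings
exhaustive_nri <- function(taxa, tree) {
  D <- cophenetic_matrix(tree)
  obs <- brute_mpd(taxa, D)
  nulls <- vapply(all_perms(seq_len(nrow(D))), function(perm) {
    Dp <- D[perm, perm]
    dimnames(Dp) <- dimnames(D)
    brute_mpd(taxa, Dp)
  }, numeric(1))
  m <- mean(nulls)
  s <- sqrt(mean((nulls - m)^2))  # population sd: the full null is enumerated
  list(obs = obs, null_mean = m, null_sd = s, nri = -(obs - m) / s,
       nulls = nulls)
}

# same exhaustive null for a pair's betaNRI (not sign-flipped)
exhaustive_beta_nri <- function(taxa_a, taxa_b, tree) {
  D <- cophenetic_matrix(tree)
  obs <- brute_beta_mpd(taxa_a, taxa_b, D)
  nulls <- vapply(all_perms(seq_len(nrow(D))), function(perm) {
    Dp <- D[perm, perm]
    dimnames(Dp) <- dimnames(D)
    brute_beta_mpd(taxa_a, taxa_b, Dp)
  }, numeric(1))
  m <- mean(nulls)
  s <- sqrt(mean((nulls - m)^2))
  list(obs = obs, null_mean = m, null_sd = s, z = (obs - m) / s)
}

# random (tree, community) instance for oracle-equivalence scans
random_instance <- function(seed, max_tips = 12L) {
  set.seed(seed)
  n <- sample(4:max_tips, 1)
  tree <- ecoassembly::simulate_tree(n, seed = seed)
  k <- sample(2:n, 1)
  taxa <- sample(tree$tip.label, k)
  list(tree = tree, taxa = taxa, D = cophenetic_matrix(tree))
}

random_count_table <- function(seed, n_taxa = 8L, n_samples = 4L,
                               depth = 60L) {
  set.seed(seed)
  m <- matrix(0L, n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", 1:n_taxa),
                              sprintf("s%02d", 1:n_samples)))
  for (s in seq_len(n_samples)) {
    p <- stats::rlnorm(n_taxa)
    m[, s] <- stats::rmultinom(1, depth, p)[, 1]
  }
  m
}
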