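test_that("cophenetic distances equal hand-summed path lengths", {
  D <- cophenetic_matrix(toy_tree())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # birth-death trees are ultrametric: equal tip-to-root depths
  tr <- simulate_tree(30, seed = 8)
  depths <- ape::node.depth.edgelength(tr)[seq_len(30)]
  expect_lt(max(depths) - min(depths), 1e-9)
})

test_that("betaMPD matches cross-pair enumeration including shared taxa", {
  D <- cophenetic_matrix(toy_tree())
  expect_equal(beta_mpd_pair(c("A", "B"), c("C", "D"), D), 4)
  expect_equal(beta_mpd_pair(c("A", "B"), c("A", "C"), D), 2.5)
  # identical communities: 2 * sum of unordered pair distances / |X|^2
  expect_equal(beta_mpd_pair(c("A", "B"), c("A", "B"), D), 2 * 2 / 4)
  expect_true(is.na(beta_mpd_pair(character(0), "A", D)))
})

test_that("betaMPD agrees with brute force and picante on random instances", {
  for (s in 1:100) {
    inst <- random_instance(s)
    set.seed(s + 1000)
    other <- sample(rownames(inst$D), sample(2:nrow(inst$D), 1))
    expect_equal(beta_mpd_pair(inst$taxa, other, inst$D),
                 brute_beta_mpd(inst$taxa, other, inst$D), tolerance = 1e-10)
  }
  inst <- random_instance(17)
  other <- setdiff(rownames(inst$D), inst$taxa)[1:2]
  comm <- matrix(0, 2, nrow(inst$D),
                 dimnames = list(c("x", "y"), rownames(inst$D)))
  comm["x", inst$taxa] <- 1; comm["y", other] <- 1
  expect_equal(beta_mpd_pair(inst$taxa, other, inst$D),
               as.numeric(picante::comdist(comm, inst$D)), tolerance = 1e-10)
})

test_that("betaNRI signs match the exhaustive label-permutation oracle", {
  tr <- toy_tree()
  # identical single-clade communities: observed turnover below the null
  ex_same <- exhaustive_beta_nri(c("A", "B"), c("A", "B"), tr)
  expect_lt(ex_same$z, 0)
  # opposite deepest clades: observed turnover above the null
  ex_opp <- exhaustive_beta_nri(c("A", "B"), c("C", "D"), tr)
  expect_gt(ex_opp$z, 0)
  tab <- cbind(p = c(1L, 1L, 0L, 0L), q = c(1L, 1L, 0L, 0L),
               r = c(0L, 0L, 1L, 1L))
  rownames(tab) <- c("A", "B", "C", "D")
  res <- beta_nri(tab, tr, n_reps = 999, seed = 5)
  expect_lt(res$beta_nri[res$sample_a == "p" & res$sample_b == "q"], 0)
  expect_gt(res$beta_nri[res$sample_a == "p" & res$sample_b == "r"], 0)
  expect_equal(res$null_mean[1], ex_same$null_mean, tolerance = 0.1)
})

test_that("betaNRI is exactly symmetric under sample order", {
  tab <- random_count_table(21, n_taxa = 15, n_samples = 5)
  tr <- simulate_tree(15, seed = 21)
  rownames(tab) <- tr$tip.label
  a <- beta_nri(tab, tr, n_reps = 99, seed = 4)
  b <- beta_nri(tab[, rev(colnames(tab))], tr, n_reps = 99, seed = 4)
  key_a <- paste(pmin(a$sample_a, a$sample_b), pmax(a$sample_a, a$sample_b))
  key_b <- paste(pmin(b$sample_a, b$sample_b), pmax(b$sample_a, b$sample_b))
  expect_equal(a$beta_nri[order(key_a)], b$beta_nri[order(key_b)],
               tolerance = 1e-12)
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  expect_equal(bray_curtis(c(10, 0, 5), c(2, 8, 5)), 16 / 30)
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))
  tab <- random_count_table(31, n_taxa = 10, n_samples = 4)
  mine <- outer(seq_len(4), seq_len(4),
                Vectorize(function(i, j) bray_curtis(tab[, i], tab[, j])))
  expect_equal(unname(as.matrix(vegan::vegdist(t(tab), "bray"))), mine,
               tolerance = 1e-12)
})

test_that("Raup-Crick nulls preserve each sample's richness and total reads", {
  tab <- random_count_table(41, n_taxa = 12, n_samples = 4, depth = 80)
  occ <- rowSums(tab > 0); rel <- rowSums(tab) / sum(tab)
  for (i in 1:100) {
    set.seed(i)
    s <- sample(4, 1)
    nul <- ecoassembly:::rc_null_sample(sum(tab[, s] > 0), sum(tab[, s]),
                                        occ, rel)
    expect_equal(sum(nul > 0), sum(tab[, s] > 0))
    expect_equal(sum(nul), sum(tab[, s]))
    expect_true(all(nul[nul > 0] >= 1))
  }
})

test_that("RC_bray hits its limits on designed communities", {
  # two samples holding both of two taxa: null membership is forced, null
  # BC concentrates near 0, so strongly divergent counts give RC = +1 exactly
  tab <- cbind(s1 = c(90L, 10L), s2 = c(10L, 90L),
               s3 = c(50L, 50L), s4 = c(55L, 45L))
  rownames(tab) <- c("t1", "t2")
  rc <- raup_crick_bray(tab, n_reps = 199, seed = 1)
  expect_equal(rc$rc_bray[rc$sample_a == "s1" & rc$sample_b == "s2"], 1)
  # identical samples among diverse ones: observed BC = 0 beats nearly every
  # null, so RC approaches -1
  tab2 <- random_count_table(52, n_taxa = 20, n_samples = 4, depth = 300)
  tab2 <- cbind(tab2, dup1 = tab2[, 1], dup2 = tab2[, 1])
  colnames(tab2)[1] <- "orig"
  rc2 <- raup_crick_bray(tab2, n_reps = 199, seed = 2)
  expect_lt(rc2$rc_bray[rc2$sample_a == "dup1" & rc2$sample_b == "dup2"], -0.9)
})

test_that("RC_bray stays within [-1, 1] and is symmetric across random tables", {
  for (s in 1:200) {
    tab <- random_count_table(s, n_taxa = 8, n_samples = 4, depth = 40)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    rc <- raup_crick_bray(tab, n_reps = 19, seed = s)
    expect_true(all(rc$rc_bray >= -1 & rc$rc_bray <= 1))
  }
  tab <- random_count_table(9, n_taxa = 12, n_samples = 5, depth = 100)
  a <- raup_crick_bray(tab, n_reps = 99, seed = 3)
  b <- raup_crick_bray(tab, n_reps = 99, seed = 3)
  expect_identical(a, b)
})

test_that("stronger synthetic selection drives mean betaNRI down", {
  # narrowing the niche filter strengthens phylogenetic clustering; the
  # response saturates between the two strongest settings because the
  # per-sample richness quota bounds how clustered a community can get, so
  # the assertion is that every stronger filter sits below the weakest one
  for (seed in c(1, 123)) {
    means <- vapply(c(0.3, 0.1, 0.05), function(fw) {
      cfg <- scenario_config("homogeneous_selection", n_samples = 12,
                             filter_width = fw, seed = seed)
      ds <- assemble_communities(cfg)
      bn <- beta_nri(ds$table, ds$tree, n_reps = 99, seed = seed)
      mean(bn$beta_nri, na.rm = TRUE)
    }, numeric(1))
    expect_lt(means[2], means[1])
    expect_lt(means[3], means[1])
  }
})
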