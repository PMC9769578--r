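test_that("community table TSV round-trips bit-exactly and validates", {
  tab <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
                dimnames = list(c("tx1", "tx2", "tx3"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(tab, f)
  back <- read_community_table(f)
  expect_identical(back, tab)
  # second round trip is the identity
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("BIOM tables read to the same matrix as TSV", {
  tab <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
                dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(tab), f)
  expect_identical(read_community_table(f, format = "biom"), tab)
})

test_that("malformed count tables are rejected with the offending cell named", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "tx1\t5\t-2", "tx2\t1\t0"), f)
  expect_error(read_community_table(f), "tx1.*s2")
  writeLines(c("taxon_id\ts1", "tx1\tfoo", "tx2\t1"), f)
  expect_error(read_community_table(f), "tx1.*s1")
  writeLines(c("taxon_id\ts1", "tx1\t1.5", "tx2\t1"), f)
  expect_error(read_community_table(f), "non-integer")
  writeLines(c("taxon_id\ts1", "tx1\t1", "tx1\t2"), f)
  expect_error(read_community_table(f), "duplicate")
})

test_that("newick reading enforces tree invariants and preserves distances", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", f)
  tr <- read_phylogeny(f)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(sum(tr$edge.length), 6)
  # duplicate tip label
  writeLines("((A:1,A:1):1,(C:1,D:1):1);", f)
  expect_error(read_phylogeny(f), "duplicate")
  # unrooted (basal trifurcation)
  writeLines("(A:1,B:1,C:1);", f)
  expect_error(read_phylogeny(f), "unrooted")
  # round trip preserves the cophenetic matrix
  tr2 <- simulate_tree(15, seed = 7)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_phylogeny(tr2, f2)
  d_ref <- cophenetic_matrix(tr2)
  d_back <- cophenetic_matrix(read_phylogeny(f2))[rownames(d_ref),
                                                  colnames(d_ref)]
  expect_equal(d_back, d_ref, tolerance = 1e-12)
})

test_that("metadata round-trips and derives month from the date", {
  md <- data.frame(sample_id = c("s1", "s2"),
                   date = c("2020-01-15", "2020-07-02"),
                   station = "ST1", temperature = c(8.1, 17.3),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(md, f, row.names = FALSE, quote = FALSE)
  back <- read_sample_metadata(f)
  expect_equal(back$month, c(1L, 7L))
  expect_s3_class(back$date, "Date")
  expect_equal(back$temperature, md$temperature)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sample_metadata(back, f2)
  expect_equal(read_sample_metadata(f2), back)
})

test_that("consistency validation reports missing taxa and samples", {
  tr <- toy_tree()
  tab <- matrix(c(3L, 1L, 2L, 5L), nrow = 2,
                dimnames = list(c("A", "B"), c("s1", "s2")))
  md <- data.frame(sample_id = c("s1", "s2"), month = c(1L, 2L))
  rep1 <- validate_consistency(tab, tr, md)
  expect_true(rep1$is_valid)
  expect_equal(rep1$shared_taxa, 2L)

  rownames(tab) <- c("A", "X")
  rep2 <- validate_consistency(tab, tr, md)
  expect_false(rep2$is_valid)
  expect_equal(rep2$taxa_missing_from_tree, "X")

  rep3 <- validate_consistency(tab, tr, data.frame(sample_id = character(0)))
  expect_false(rep3$is_valid)
  expect_setequal(rep3$samples_missing_metadata, c("s1", "s2"))
})

test_that("rarefaction conserves depth, is a sub-multiset, and drops as documented", {
  tab <- random_count_table(42, n_taxa = 30, n_samples = 5, depth = 2000)
  r <- suppressMessages(rarefy_table(tab, depth = 500, seed = 1))
  expect_true(all(colSums(r) == 500L))
  expect_true(all(r <= tab[rownames(r), colnames(r)]))

  # single occupied taxon: forced outcome
  one <- matrix(c(4L, 0L, 0L), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(suppressMessages(rarefy_table(one, 2, seed = 1))[1, 1]), 2L)

  # samples below depth are dropped, others kept at exactly the depth
  tab3 <- random_count_table(7, n_taxa = 40, n_samples = 3, depth = 900)
  extra <- random_count_table(8, n_taxa = 40, n_samples = 2, depth = 1020)
  extra[, 2] <- extra[, 2] + random_count_table(9, 40, 1, 980)[, 1]  # 2000 reads
  tab3 <- cbind(extra, tab3[, 1, drop = FALSE])
  colnames(tab3) <- c("deep1", "deep2", "shallow")
  expect_message(r3 <- rarefy_table(tab3, 1020, seed = 3), "shallow")
  expect_equal(colnames(r3), c("deep1", "deep2"))
  expect_true(all(colSums(r3) == 1020L))
  expect_equal(attr(r3, "dropped_samples"), "shallow")
})

test_that("rarefaction is deterministic under a seed and errors on bad depth", {
  tab <- random_count_table(11, n_taxa = 50, n_samples = 4, depth = 3000)
  a <- suppressMessages(rarefy_table(tab, 800, seed = 99))
  b <- suppressMessages(rarefy_table(tab, 800, seed = 99))
  expect_identical(a, b)
  c_ <- suppressMessages(rarefy_table(tab, 800, seed = 100))
  expect_false(identical(a, c_))
  expect_error(rarefy_table(tab, 0), "positive")
  expect_error(rarefy_table(tab, 10000), "fewer than")
})
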