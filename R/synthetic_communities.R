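#' Assembly process vocabulary
#'
#' The five ecological processes the pairwise classifier can assign:
#' homogeneous selection, heterogeneous selection, dispersal limitation,
#' homogenizing dispersal and drift.
#'
#' @return Character vector of the five process labels.
#' @export
assembly_processes <- function() {
  c("homogeneous_selection", "heterogeneous_selection",
    "dispersal_limitation", "homogenizing_dispersal", "drift")
}

#' Configure a synthetic community scenario
#'
#' Bundles the recipe for one synthetic dataset: a birth-death tree,
#' Brownian niche traits on its tips, a (possibly structured) environment,
#' and communities assembled under one of the five processes. The defaults
#' describe the standard validation conditions used throughout the package:
#' 200 taxa, 20 samples, 1,000 reads per sample, a birth-death tree with
#' high relative extinction (death/birth = 0.8, so deep branches carry much
#' of the trait variance and niche optima are conserved within clades),
#' unit-rate Brownian trait evolution and a narrow Gaussian niche filter
#' (`filter_width = 0.05` on the \[0, 1\] environment axis) so that
#' selection scenarios produce strong phylogenetic clustering.
#'
#' @param scenario One of [assembly_processes()].
#' @param n_taxa Number of tips/taxa (>= 4).
#' @param n_samples Number of samples (>= 4).
#' @param depth Reads per sample (>= 100).
#' @param birth_rate,death_rate Birth-death rates of the tree simulation;
#'   `birth_rate > death_rate >= 0`.
#' @param brownian_sigma2 Brownian-motion rate of niche-trait evolution
#'   (variance per unit branch length, > 0 unless degenerate traits wanted).
#' @param filter_width Gaussian niche-filter width (sd) on the \[0, 1\]
#'   environment axis; only used by selection scenarios.
#' @param migration Mixing weight in \[0, 1\] between the shared
#'   metacommunity and a per-sample perturbation; defaults to 0 for
#'   `dispersal_limitation` (fully limited) and 1 for
#'   `homogenizing_dispersal` (fully mixed), unused otherwise.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario,
                            n_taxa = 200L,
                            n_samples = 20L,
                            depth = 1000L,
                            birth_rate = 1,
                            death_rate = 0.8,
                            brownian_sigma2 = 1,
                            filter_width = 0.05,
                            migration = NULL,
                            seed = 1L) {
  scenario <- match.arg(scenario, assembly_processes())
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (depth < 100L) stop("depth must be >= 100")
  if (!(birth_rate > death_rate && death_rate >= 0)) {
    stop("need birth_rate > death_rate >= 0")
  }
  selection <- scenario %in% c("homogeneous_selection", "heterogeneous_selection")
  if (selection && (!is.finite(filter_width) || filter_width <= 0)) {
    stop("filter_width must be > 0 for selection scenarios")
  }
  if (is.null(migration)) {
    migration <- switch(scenario,
                        dispersal_limitation = 0,
                        homogenizing_dispersal = 1,
                        NA_real_)
  }
  if (!is.na(migration) && (migration < 0 || migration > 1)) {
    stop("migration must lie in [0, 1]")
  }
  structure(list(scenario = scenario,
                 n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples),
                 depth = as.integer(depth),
                 birth_rate = birth_rate, death_rate = death_rate,
                 brownian_sigma2 = brownian_sigma2,
                 filter_width = filter_width,
                 migration = migration,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a birth-death phylogeny
#'
#' Thin seed-controlled wrapper around [ape::rphylo()]: a rooted birth-death
#' tree conditioned on exactly `n_taxa` extant tips, labeled `t1..tn`, with
#' strictly positive branch lengths.
#'
#' @inheritParams scenario_config
#' @return An [ape::phylo] object with `n_taxa` tips.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, death_rate = 0, seed = NULL) {
  if (!(birth_rate > death_rate && death_rate >= 0)) {
    stop("need birth_rate > death_rate >= 0")
  }
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = death_rate)
  # zero-length branches would collapse cophenetic distances; nudge them
  tree$edge.length[tree$edge.length <= 0] <- .Machine$double.eps
  validate_phylogeny(tree)
}

#' Evolve a continuous niche trait by Brownian motion
#'
#' One trait value per tip, with independent Gaussian increments along each
#' branch of variance `brownian_sigma2 * branch length` (via
#' [ape::rTraitCont()]). This is the mechanism that puts phylogenetic signal
#' into the synthetic niches: close relatives end up with similar optima.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param brownian_sigma2 Brownian rate (variance per unit branch length, >= 0).
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
evolve_niche_trait <- function(tree, brownian_sigma2 = 1, root_value = 0,
                               seed = NULL) {
  validate_phylogeny(tree)
  if (brownian_sigma2 < 0) stop("brownian_sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(brownian_sigma2),
                  root.value = root_value)
}

#' Simulate seasonally structured sample metadata
#'
#' Samples are spread evenly over one synthetic year at a single station.
#' The active environmental axis `env` lives on \[0, 1\]: all samples share
#' one value (0.5) except under `heterogeneous_selection`, where two distinct
#' levels (0.25 and 0.75) are assigned alternately, half the samples each.
#' Two decoy variables with no influence on assembly are added so signal
#' detection can be tested for false positives: a seasonal `temperature`
#' cycle and white-noise `salinity`.
#'
#' @inheritParams scenario_config
#' @return Metadata data.frame (`sample_id`, `date`, `month`, `station`,
#'   `env`, `temperature`, `salinity`).
#' @export
simulate_environment <- function(n_samples, scenario, seed = NULL) {
  scenario <- match.arg(scenario, assembly_processes())
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  doy <- round(seq(1, 360, length.out = n_samples))
  date <- as.Date("2020-01-01") + (doy - 1)
  if (scenario == "heterogeneous_selection") {
    env <- rep(c(0.1, 0.9), length.out = n_samples)
  } else {
    # one shared level at an extreme of the niche axis: an interior trait
    # window can capture one representative of every clade (each clade's
    # Brownian trajectory passes through interior values), whereas extreme
    # trait values belong to the lineages that evolved them, so filtering
    # at an extreme is what yields detectable phylogenetic clustering —
    # ecologically, the harsh end of the gradient
    env <- rep(0.1, n_samples)
  }
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    date = date,
    month = as.integer(format(date, "%m")),
    station = "ST1",
    env = env,
    temperature = 12 + 6 * sin(2 * pi * (doy - 105) / 365) +
      stats::rnorm(n_samples, 0, 0.5),
    salinity = 34 + stats::rnorm(n_samples, 0, 0.2),
    stringsAsFactors = FALSE
  )
}

# Gaussian niche-filter weights: selection probability of taxon i in sample s
# is proportional to exp(-(opt_i - env_s)^2 / (2 fw^2)) times its
# metacommunity relative abundance. As fw -> Inf this tends to meta_p alone.
selection_weights <- function(opt, env, filter_width, meta_p) {
  w <- exp(-(opt - env)^2 / (2 * filter_width^2)) * meta_p
  if (sum(w) == 0) w <- meta_p  # filter too narrow for any taxon: fall back
  w / sum(w)
}

#' Assemble synthetic communities under a known process
#'
#' Generates a full synthetic dataset — tree, Brownian niche traits,
#' metadata, count table and per-pair ground-truth labels — under the
#' mechanics of one assembly process:
#'
#' * **selection** (`homogeneous_selection`, `heterogeneous_selection`):
#'   taxa enter each sample with probability proportional to a Gaussian
#'   niche filter around the sample's environment times their metacommunity
#'   abundance; per-sample richness is drawn uniformly from
#'   `[0.2, 0.5] * n_taxa` and reads are multinomial to `depth` with the same
#'   filtered weights. Homogeneous selection uses one shared environment,
#'   heterogeneous two divergent levels.
#' * **drift**: each sample's abundances fluctuate by chance around the
#'   shared log-normal metacommunity (an independent per-sample log-normal
#'   jitter of the metacommunity abundances, sd 0.25 on the log scale, a
#'   quarter of the among-taxon spread) before multinomial sampling; no
#'   trait dependence. The magnitude is the generator's design calibration:
#'   large enough that chance alone moves communities apart, small enough
#'   that the shared abundance hierarchy is not erased, so that turnover
#'   under drift is statistically indistinguishable from the null
#'   expectation — the defining signature of drift in this framework.
#'   (Zero jitter would collapse onto homogenizing dispersal; a jitter as
#'   large as the spread itself onto dispersal limitation.)
#' * **dispersal_limitation**: each sample draws from an independently
#'   perturbed metacommunity (per-sample log-normal re-draw, mixed with the
#'   shared metacommunity by weight `migration`, default 0).
#' * **homogenizing_dispersal**: all samples are multinomial resamples of a
#'   single realized community, so they differ only by sampling noise.
#'
#' Ground truth: all pairs carry the scenario label, except under
#' heterogeneous selection where same-environment pairs are expected to show
#' homogeneous selection and cross-environment pairs heterogeneous selection.
#'
#' @param config A [scenario_config()].
#' @return A list of class `"synthetic_dataset"`: `table` (taxa x samples
#'   integer matrix), `tree`, `metadata`, `traits` (raw Brownian values),
#'   `niche_optima` (traits rescaled to \[0, 1\]), `truth` (data.frame
#'   `sample_a`, `sample_b`, `expected_process`) and `config`.
#' @export
assemble_communities <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  tree <- simulate_tree(cfg$n_taxa, cfg$birth_rate, cfg$death_rate,
                        seed = cfg$seed)
  traits <- evolve_niche_trait(tree, cfg$brownian_sigma2, root_value = 0,
                               seed = cfg$seed + 1L)
  metadata <- simulate_environment(cfg$n_samples, cfg$scenario,
                                   seed = cfg$seed + 2L)
  # map traits onto the [0,1] environment axis by rank (empirical CDF):
  # niche optima then cover the gradient uniformly, so a filter of width
  # sigma_w admits the same number of taxa wherever it sits, while the
  # phylogenetic ordering of the optima is preserved
  n_tr <- length(traits)
  opt <- if (stats::sd(traits) > 0) {
    (rank(traits, ties.method = "first") - 0.5) / n_tr
  } else rep(0.5, n_tr)
  names(opt) <- names(traits)
  set.seed(cfg$seed + 3L)
  n <- cfg$n_taxa
  meta_ab <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  meta_p <- meta_ab / sum(meta_ab)
  counts <- matrix(0L, nrow = n, ncol = cfg$n_samples,
                   dimnames = list(tree$tip.label, metadata$sample_id))
  selection <- cfg$scenario %in% c("homogeneous_selection",
                                   "heterogeneous_selection")
  if (selection) {
    for (s in seq_len(cfg$n_samples)) {
      w <- selection_weights(opt, metadata$env[s], cfg$filter_width, meta_p)
      rich <- max(2L, round(stats::runif(1, 0.2, 0.5) * n))
      members <- sample.int(n, rich, replace = FALSE, prob = w)
      counts[members, s] <- stats::rmultinom(1, cfg$depth,
                                             w[members] / sum(w[members]))
    }
  } else if (cfg$scenario == "drift") {
    # chance fluctuations of population sizes: per-sample log-normal jitter
    # of the shared metacommunity at a quarter of the among-taxon spread,
    # the magnitude at which chance turnover matches the null expectation
    for (s in seq_len(cfg$n_samples)) {
      drift_ab <- meta_ab * stats::rlnorm(n, meanlog = 0, sdlog = 0.25)
      counts[, s] <- stats::rmultinom(1, cfg$depth, drift_ab / sum(drift_ab))
    }
  } else if (cfg$scenario == "dispersal_limitation") {
    m <- if (is.na(cfg$migration)) 0 else cfg$migration
    for (s in seq_len(cfg$n_samples)) {
      local_ab <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
      p_s <- m * meta_p + (1 - m) * local_ab / sum(local_ab)
      counts[, s] <- stats::rmultinom(1, cfg$depth, p_s)
    }
  } else { # homogenizing_dispersal
    # one fixed realized community; every sample is that community with a
    # small fraction (5%) of its reads exchanged — mass effects keep the
    # same individuals nearly everywhere, so noise stays well below a fresh
    # full-depth multinomial draw
    realized <- stats::rmultinom(1, cfg$depth, meta_p)[, 1]
    p0 <- realized / sum(realized)
    m <- max(1L, as.integer(round(0.05 * cfg$depth)))
    for (s in seq_len(cfg$n_samples)) {
      kept <- tabulate(sample(rep.int(seq_len(n), realized),
                              cfg$depth - m), nbins = n)
      counts[, s] <- as.integer(kept) + stats::rmultinom(1, m, p0)[, 1]
    }
  }
  pairs <- utils::combn(metadata$sample_id, 2)
  expected <- rep(cfg$scenario, ncol(pairs))
  if (cfg$scenario == "heterogeneous_selection") {
    env <- stats::setNames(metadata$env, metadata$sample_id)
    same <- env[pairs[1, ]] == env[pairs[2, ]]
    expected[same] <- "homogeneous_selection"
  }
  truth <- data.frame(sample_a = pairs[1, ], sample_b = pairs[2, ],
                      expected_process = expected, stringsAsFactors = FALSE)
  structure(list(table = counts, tree = tree, metadata = metadata,
                 traits = traits, niche_optima = opt, truth = truth,
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset —", x$config$scenario, "\n")
  cat("  ", nrow(x$table), "taxa x", ncol(x$table), "samples, depth",
      x$config$depth, "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same files the readers consume: count table TSV, newick tree,
#' metadata CSV and a `truth.tsv` with the expected process per sample pair.
#'
#' @param dataset A `"synthetic_dataset"` from [assemble_communities()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "counts.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_community_table(dataset$table, paths["table"])
  write_phylogeny(dataset$tree, paths["tree"])
  write_sample_metadata(dataset$metadata, paths["metadata"])
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
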