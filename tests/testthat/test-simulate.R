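test_that("Yule species trees are reproducible and well-formed", {
  t1 <- simulate_species_tree(5, 0.3, seed = 11)
  t2 <- simulate_species_tree(5, 0.3, seed = 11)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  k1 <- simulate_species_tree(1, 0.3, seed = 1)
  expect_equal(ape::Ntip(k1), 1L)
  expect_gt(k1$edge.length, 0)
  # conditioning places every split at least min_stem before the present
  t3 <- simulate_species_tree(6, 0.3, min_stem = 2, seed = 5)
  expect_gte(min(node_times(t3)[7:11]), 2)
})

test_that("lineage growth matches the pure-birth expectation", {
  # from the root (2 lineages) the pure-birth expectation is 2 exp(rate * t);
  # Monte Carlo within 3 SE, with K large enough that truncation is rare
  set.seed(101)
  rate <- 1; t_at <- 1.5
  counts <- replicate(1000, {
    tr <- simulate_species_tree(25, rate)
    root_age <- max(node_times(tr)) - node_times(tr)  # time since the root
    1 + sum(root_age[26:(25 + tr$Nnode)] <= t_at)     # root split included
  })
  expect_lt(abs(mean(counts) - 2 * exp(rate * t_at)),
            3 * sd(counts) / sqrt(length(counts)))
})

test_that("coalescent gene trees match Kingman expectations", {
  # two samples in one species: pairwise distance has mean theta
  set.seed(55)
  theta <- 0.02
  sp1 <- simulate_species_tree(1, 0.5, min_stem = 100, seed = 55)
  dists <- replicate(2000, {
    gt <- simulate_gene_tree(sp1, theta, 2)
    sum(gt$edge.length)
  })
  expect_lt(abs(mean(dists) - theta), 3 * sd(dists) / sqrt(length(dists)))
  expect_error(simulate_gene_tree(sp1, theta, 0))
})

test_that("gene trees track the species tree when divergences dwarf theta", {
  set.seed(77)
  theta <- 0.01
  hits <- replicate(40, {
    sp <- simulate_species_tree(4, 0.5, min_stem = 20 * theta)
    gt <- simulate_gene_tree(sp, theta, 1)
    gt$tip.label <- id_clade(gt$tip.label)
    ape::dist.topo(ape::unroot(gt), ape::unroot(sp)) == 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("sequence evolution follows the substitution model", {
  # zero branch lengths give identical sequences
  tr <- ape::read.tree(text = "(a_1:0,b_1:0);")
  a0 <- evolve_sequences(tr, 100, seed = 1)
  expect_equal(a0$mat[1, ], a0$mat[2, ], ignore_attr = TRUE)
  # JC closed form at d = 0.1: E[p] = 3/4 (1 - exp(-4 d / 3))
  set.seed(20)
  d <- 0.1
  tr2 <- ape::read.tree(text = sprintf("(a_1:%f,b_1:%f);", d / 2, d / 2))
  ps <- replicate(500, {
    al <- evolve_sequences(tr2, 300)
    p_distance(al$mat[1, ], al$mat[2, ])
  })
  expect_lt(abs(mean(ps) - 0.75 * (1 - exp(-4 * d / 3))),
            3 * sd(ps) / sqrt(length(ps)))
  # the indel process is off for the mitochondrial-like marker
  expect_false("-" %in% evolve_sequences(tr2, 200, indel_rate = 0,
                                         seed = 3)$mat)
  withgaps <- evolve_sequences(ape::rcoal(6, br = function(n) runif(n, .05, .2)),
                               200, indel_rate = 0.5, seed = 4)
  expect_true("-" %in% withgaps$mat)
  expect_equal(alignment_length(withgaps), 200L)
})

test_that("full data sets are deterministic and internally consistent", {
  d1 <- simulate_dataset(sim_config(K = 4, seed = 31, n_per_species = 5))
  d2 <- simulate_dataset(sim_config(K = 4, seed = 31, n_per_species = 5))
  expect_identical(d1$alignments$coi$mat, d2$alignments$coi$mat)
  expect_identical(d1$sites, d2$sites)
  expect_equal(ape::write.tree(d1$gene_trees$its2),
               ape::write.tree(d2$gene_trees$its2))
  # partition is consistent across markers and the site table adds up
  expect_setequal(d1$alignments$coi$ids, d1$alignments$its2$ids)
  expect_equal(sum(d1$sites$sample_size), length(d1$alignments$coi$ids))
  expect_setequal(unlist(d1$true_partition$blocks), d1$alignments$coi$ids)
  expect_true(all(d1$sites$region %in% biogeographic_regions()))
  expect_true(all(d1$sites$depth_min >= 8 & d1$sites$depth_max <= 4380))
  # written files are parseable by the upstream modules
  td <- tempfile(); write_dataset(d1, td)
  back <- read_alignment(file.path(td, "coi.fasta"), marker = "COI")
  expect_identical(back$mat, d1$alignments$coi$mat)
  sites <- load_site_table(file.path(td, "sites.csv"))
  expect_equal(registry_totals(sites)$n_specimens,
               length(d1$alignments$coi$ids))
  tr <- read_tree(file.path(td, "gene_tree_coi.nwk"))
  expect_equal(ape::Ntip(tr), length(d1$alignments$coi$ids))
})

test_that("within-species diversity tracks the coalescent theta", {
  means <- unlist(lapply(1:8, function(s) {
    ds <- simulate_dataset(sim_config(K = 4, seed = 400 + s,
                                      n_per_species = 6))
    d <- p_distance_matrix(ds$alignments$coi)
    lab <- id_clade(ds$alignments$coi$ids)
    vapply(unique(lab), function(cl) {
      i <- lab == cl
      mean(d[i, i][upper.tri(d[i, i])])
    }, numeric(1))
  }))
  theta_mito <- 0.04 * 0.25
  # the JC map from expected substitutions to observed p-distance is mildly
  # concave; compare on the substitution scale
  p_expected <- 0.75 * (1 - exp(-4 * theta_mito / 3))
  expect_lt(abs(mean(means) - p_expected),
            3 * sd(means) / sqrt(length(means)) + 0.1 * p_expected)
})

test_that("pipeline recovery improves with species divergence", {
  depths <- c(0.5, 2, 6)
  err <- vapply(depths, function(ms) {
    mean(vapply(1:6, function(s) {
      ds <- simulate_dataset(sim_config(K = 4, seed = 600 + s, min_stem = ms,
                                        n_per_species = 6, theta = 0.012))
      abs(n_networks(build_networks(collapse_identical(ds$alignments$coi))) - 4)
    }, numeric(1)))
  }, numeric(1))
  expect_true(err[3] <= err[2] + 1e-9 && err[2] <= err[1] + 1e-9)
})
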