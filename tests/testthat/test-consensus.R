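test_that("species partitions validate their blocks", {
  expect_error(species_partition(list(c("a", "b"), c("b", "c"))),
               "not disjoint")
  expect_error(species_partition(list(character(0))), "empty")
  p <- species_partition(list(g1 = c("a", "b"), g2 = "c"))
  expect_equal(n_blocks(p), 2L)
  expect_equal(p$universe, c("a", "b", "c"))
})

test_that("agreement coding distinguishes identical, finer and coarser", {
  ref <- species_partition(list(A = c("a", "b"), B = c("c", "d"), C = "e"))
  expect_true(all(agreement_code(ref, ref)$code == "identical"))
  finer <- species_partition(list(c("a"), c("b"), c("c", "d"), "e"))
  expect_equal(agreement_code(ref, finer)$code, c("finer", "identical",
                                                  "identical"))
  coarser <- species_partition(list(c("a", "b", "c", "d"), "e"))
  expect_equal(agreement_code(ref, coarser)$code, c("coarser", "coarser",
                                                    "identical"))
  expect_error(agreement_code(ref, species_partition(list("zz"))),
               "no shared")
  # randomized brute-force check: a reference block is identical iff it is
  # literally a block of the other partition
  set.seed(4)
  for (rep in 1:10) {
    ids <- letters[1:10]
    refp <- species_partition(split(ids, sample(1:3, 10, replace = TRUE)))
    othp <- species_partition(split(ids, sample(1:4, 10, replace = TRUE)))
    codes <- agreement_code(refp, othp)
    okeys <- vapply(othp$blocks, function(b) paste(sort(b), collapse = ","),
                    character(1))
    for (i in seq_len(nrow(codes))) {
      b <- refp$blocks[[codes$block[i]]]
      expect_equal(codes$code[i] == "identical",
                   paste(sort(b), collapse = ",") %in% okeys)
    }
  }
})

test_that("posterior partition frequencies are canonical and order-free", {
  samples <- c(replicate(988, list(c("a", "b"), "c"), simplify = FALSE),
               replicate(12, list(c("a", "b", "c")), simplify = FALSE))
  fr <- posterior_partition_frequencies(samples)
  expect_equal(fr$frequency, c(0.988, 0.012))
  expect_equal(sum(fr$frequency), 1, tolerance = 1e-12)
  shuffled <- posterior_partition_frequencies(sample(samples))
  expect_equal(shuffled$frequency, fr$frequency)
  expect_equal(shuffled$partition, fr$partition)
  same <- posterior_partition_frequencies(replicate(5, list("x", "y"),
                                                    simplify = FALSE))
  expect_equal(same$frequency, 1)
  expect_error(posterior_partition_frequencies(list()), "no samples")
})

test_that("partition logs parse into summarizable samples", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("s1 s2 s3", "1 1 2", "1 1 2", "1 2 3"), f)
  samples <- read_partition_log(f)
  fr <- posterior_partition_frequencies(samples)
  expect_equal(fr$count, c(2L, 1L))
  expect_equal(fr$n_blocks, c(2L, 3L))
})

test_that("rule engine decisions replay into the final partition", {
  expect_error(reconciliation_rules(lump_if_shared_nuclear_and_coi_below = 9),
               "below")
  # hand-traced synthetic case: one lumpable pair, one keeper, one flag
  ref <- species_partition(list(A = sprintf("a%d_1", 1:2),
                                B = sprintf("b%d_2", 1:5),
                                C = sprintf("c%d_3", 1:12),
                                D = sprintf("d%d_4", 1:2)))
  ev <- data.frame(a = c("A", "C"), b = c("B", "D"),
                   shares_nuclear_haplotype = c(TRUE, FALSE),
                   coi_min_inter = c(2.5, 9.5),
                   indel_support = c(FALSE, FALSE),
                   n_a = c(2L, 12L), n_b = c(5L, 2L))
  res <- reconcile(ref, list(), ev)
  expect_equal(res$n_species, 3L)                      # A+B lumped
  expect_true("A/B" %in% names(res$final_partition$blocks))
  expect_equal(res$decisions$action[res$decisions$pair == "A+B"], "lump")
  expect_equal(res$decisions$rule[res$decisions$pair == "A+B"], "R2")
  # C+D kept (COI above threshold) but flagged for the under-sampled side
  acts <- res$decisions[res$decisions$pair == "C+D", ]
  expect_setequal(acts$action, c("keep", "flag-uncertain"))
  expect_equal(res$upper_bound, 3L)
  expect_equal(res$lower_bound, 2L)
  # audit completeness: replaying the log reconstructs the final partition
  replay <- replay_decisions(ref, res$decisions)
  expect_equal(lapply(replay$blocks, sort),
               lapply(res$final_partition$blocks, sort))
})

test_that("all-identical inputs collapse the bounds onto the reference", {
  ref <- species_partition(list(A = c("a", "b"), B = c("c", "d")))
  res <- reconcile(ref, list(ref), data.frame())
  expect_equal(res$n_species, 2L)
  expect_equal(res$lower_bound, 2L)
  expect_equal(res$upper_bound, 2L)
  expect_equal(lapply(res$final_partition$blocks, sort),
               lapply(ref$blocks, sort))
})

test_that("the printed-table evidence reproduces the published consensus", {
  res <- study_consensus()
  expect_equal(res$n_species, 27L)
  expect_equal(res$lower_bound, 25L)
  expect_equal(res$upper_bound, 27L)
  expect_true("20/28" %in% names(res$final_partition$blocks))
  expect_equal(res$decisions$rule[res$decisions$pair == "20+28"], "R2")
  expect_equal(res$decisions$action[res$decisions$pair == "8"],
               "reject-split")
  # the nuclear GMYC merge of 21 with 20/28 codes the affected clades coarser
  oth <- study_other_partitions()
  codes <- agreement_code(study_reference_partition(), oth$gmyc_its2s)
  expect_equal(codes$code[codes$block %in% c("20", "21", "28")],
               rep("coarser", 3))
  expect_equal(codes$code[codes$block == "1"], "identical")
  # raising the lump threshold cannot split the lumped pair back
  replay <- replay_decisions(study_reference_partition(), res$decisions)
  expect_equal(n_blocks(replay), 27L)
})
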