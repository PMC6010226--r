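test_that("FASTA reading normalizes and validates", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a_1", "acgu", ">b_1", "ACGT", ">c_2", "ACG-"), f)
  a <- read_alignment(f)
  expect_equal(alignment_length(a), 4L)
  expect_equal(n_sequences(a), 3L)
  expect_equal(paste(a$mat[1, ], collapse = ""), "ACGT")  # u -> T, upper
  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), ragged)
  expect_error(read_alignment(ragged), "ragged")
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_alignment(dup), "duplicate")
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGX"), bad)
  expect_error(read_alignment(bad), "non-IUPAC")
})

test_that("interleaved NEXUS equals its sequential form", {
  seqs <- c(a_1 = "ACGTACGTAC", b_1 = "ACGTTCGTAA", c_2 = "ACG-TCGTAT")
  seq_file <- tempfile(fileext = ".nex")
  write_nexus(alignment_from_strings(seqs), seq_file)
  inter <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=3 NCHAR=10;",
               "FORMAT DATATYPE=DNA MISSING=? GAP=- INTERLEAVE=YES;",
               "MATRIX",
               "a_1 ACGTA", "b_1 ACGTT", "c_2 ACG-T", "",
               "a_1 CGTAC", "b_1 CGTAA", "c_2 CGTAT",
               ";", "END;"), inter)
  expect_identical(read_alignment(seq_file)$mat, read_alignment(inter)$mat)
  # and the writer round-trips through the reader
  expect_identical(read_alignment(seq_file)$mat,
                   alignment_from_strings(seqs)$mat)
})

test_that("clade extraction matches a string-suffix filter", {
  a <- toy_alignment(c(a_1 = "ACGT", b_1 = "ACGA", c_2 = "ACGC"))
  expect_equal(extract_clade(a, "1")$ids, c("a_1", "b_1"))
  expect_warning(e <- extract_clade(a, "99"), "no sequences")
  expect_equal(n_sequences(e), 0L)
  set.seed(7)
  ids <- sprintf("s%d_%d", 1:40, sample(1:5, 40, replace = TRUE))
  seqs <- setNames(replicate(40, paste(sample(c("A", "C", "G", "T"), 8,
                                              replace = TRUE),
                                       collapse = "")), ids)
  big <- toy_alignment(seqs)
  for (cl in as.character(1:5))
    expect_equal(extract_clade(big, cl)$ids,
                 ids[sub("^.*_", "", ids) == cl])
})

test_that("flank pruning trims exactly the terminal-missing window", {
  a <- toy_alignment(c(a_1 = "??ACGTAC--", b_1 = "-GACGTACGT",
                       c_1 = "TTACGTACG?"))
  expect_equal(alignment_length(prune_to_full_coverage(a)),
               prune_oracle_length(c("??ACGTAC--", "-GACGTACGT",
                                     "TTACGTACG?")))
  clean <- toy_alignment(c(a_1 = "ACGT", b_1 = "AC-T"))
  expect_identical(prune_to_full_coverage(clean)$mat, clean$mat)
  # randomized staggered terminal gaps against the independent column scan
  set.seed(11)
  for (rep in 1:15) {
    L <- sample(10:25, 1)
    strings <- replicate(4, {
      core <- paste(sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                           prob = c(rep(0.23, 4), 0.08)), collapse = "")
      lead <- strrep("?", sample(0:3, 1)); tail <- strrep("-", sample(0:3, 1))
      paste0(lead, substr(core, 1, L - nchar(lead) - nchar(tail)), tail)
    })
    names(strings) <- paste0("s", 1:4, "_1")
    want <- prune_oracle_length(strings)
    if (want == 0L) {
      expect_error(prune_to_full_coverage(toy_alignment(strings)))
    } else {
      pr <- prune_to_full_coverage(toy_alignment(strings))
      expect_equal(alignment_length(pr), want)
      # idempotence: re-pruning changes nothing
      expect_identical(prune_to_full_coverage(pr)$mat, pr$mat)
    }
  }
  expect_error(prune_to_full_coverage(a, removed_ids = "zzz"), "not in")
  expect_error(prune_to_full_coverage(
    toy_alignment(c(a_1 = "??", b_1 = "GG"))), "every column")
})

test_that("haplotype collapsing follows the exact-identity rule", {
  a <- toy_alignment(c(x_1 = "ACGT", y_1 = "ACGT", z_1 = "ACGN"))
  h <- collapse_identical(a)
  expect_equal(n_haplotypes(h), 2L)
  expect_setequal(h$members[[1]], c("x_1", "y_1"))
  # with the wildcard flag, missing symbols match anything
  hw <- collapse_identical(a, treat_missing_as_wildcard = TRUE)
  expect_equal(n_haplotypes(hw), 1L)
  # membership partitions the input and collapse is idempotent
  set.seed(3)
  seqs <- setNames(replicate(30, paste(sample(c("A", "C"), 5, replace = TRUE),
                                       collapse = "")),
                   sprintf("q%d_1", 1:30))
  hh <- collapse_identical(toy_alignment(seqs))
  expect_equal(sort(unlist(hh$members)), sort(names(seqs)))
  again <- collapse_identical(hh$representatives)
  expect_equal(n_haplotypes(again), n_haplotypes(hh))
  # permutation invariance up to representative choice
  perm <- sample(length(seqs))
  hp <- collapse_identical(toy_alignment(seqs[perm]))
  expect_setequal(vapply(hp$members, function(m) paste(sort(m), collapse = ","),
                         character(1)),
                  vapply(hh$members, function(m) paste(sort(m), collapse = ","),
                         character(1)))
})

test_that("per-clade haplotype report counts haplotypes on the pruned window", {
  set.seed(5)
  ds <- simulate_dataset(sim_config(K = 3, seed = 5, n_per_species = 6))
  rep <- clade_haplotype_report(ds$alignments$coi)
  expect_equal(nrow(rep), 3L)
  expect_equal(sum(rep$n_specimens), 18L)
  # counting a clade of identical sequences
  mono <- toy_alignment(c(a_1 = "ACGT", b_1 = "ACGT", c_1 = "ACGT"))
  expect_equal(clade_haplotype_report(mono)$n_haplotypes, 1L)
  # haplotype count equals brute-force distinct-row count on the window
  for (cl in rep$clade) {
    pr <- prune_to_full_coverage(extract_clade(ds$alignments$coi, cl))
    expect_equal(rep$n_haplotypes[rep$clade == cl],
                 length(unique(apply(pr$mat, 1, paste, collapse = ""))))
  }
  # merged species are pruned jointly
  joint <- clade_haplotype_report(ds$alignments$coi, clades = "1/2")
  expect_equal(joint$n_specimens, 12L)
})
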