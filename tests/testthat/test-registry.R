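test_that("site table loads with typed fields and missing-value handling", {
  s <- sites_fixture()
  ka1 <- s[s$site_id == "KA1", ]
  expect_equal(ka1$region, "Kattegat")
  expect_equal(ka1$sample_size, 11L)
  expect_equal(ka1$clades[[1]], "4")
  expect_equal(c(ka1$depth_min, ka1$depth_max), c(18, 20))
  ncs3 <- s[s$site_id == "NCS3", ]
  expect_true(is.na(ncs3$habitat))
  expect_setequal(ncs3$clades[[1]], c("8", "13"))
  # single-value depth becomes a degenerate range
  sk10 <- s[s$site_id == "SK10", ]
  expect_equal(sk10$depth_min, sk10$depth_max)
})

test_that("malformed site tables are rejected with informative errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines("site_id,region,sample_size,clades,latitude,longitude,depth",
             empty)
  expect_error(load_site_table(empty), "no records")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("site_id,region,sample_size,clades,latitude,longitude,depth",
               "X1,Atlantis,3,1,50,0,100"), bad)
  expect_error(load_site_table(bad), "unknown region")
  baddepth <- tempfile(fileext = ".csv")
  writeLines(c("site_id,region,sample_size,clades,latitude,longitude,depth",
               "X1,Kattegat,3,1,50,0,deep"), baddepth)
  expect_error(load_site_table(baddepth), "non-numeric depth")
})

test_that("registry totals add up across trivial and packaged inputs", {
  s <- sites_fixture()
  tot <- registry_totals(s)
  expect_equal(tot$n_specimens, sum(s$sample_size))
  one <- s[1, ]; one$sample_size <- 1L; one$depth_min <- 10; one$depth_max <- 10
  expect_equal(registry_totals(one),
               list(n_sites = 1L, n_specimens = 1L,
                    depth_min = 10, depth_max = 10))
  two <- s[1:2, ]; two$sample_size <- c(2L, 3L)
  expect_equal(registry_totals(two)$n_specimens, 5L)
  # regional specimen counts partition the total
  expect_equal(sum(regional_summary(s)$n_specimens), tot$n_specimens)
})

test_that("regional species sets use the merged species concept", {
  s <- sites_fixture()
  rs <- regional_summary(s)
  expect_setequal(rs$species[[which(rs$region == "Skagerrak")]],
                  c("1", "2", "3", "4", "5", "6", "7", "8", "12", "13"))
  # merging clades can only reduce or preserve regional species counts
  clade_level <- regional_summary(s, identity_merge_map(unique(unlist(s$clades))))
  expect_true(all(rs$n_species <= clade_level$n_species))
  # degenerate single-clade region
  mono <- s[s$region == "Arctic Ocean", ]
  expect_equal(regional_summary(mono)$n_species, 1L)
})

test_that("shared-species and most-similar-region queries work", {
  rs <- regional_summary(sites_fixture())
  gb <- shared_species("Greenland Sea", "Barents Sea", rs)
  expect_equal(c(gb$n_shared, gb$n_in_a), c(4L, 4L))
  expect_true("Barents Sea" %in% gb$most_similar)
  expect_error(shared_species("Kattegat", "Baltic Sea", rs), "absent")
  # disjoint synthetic regions share nothing
  rs2 <- data.frame(region = c("A", "B"))
  rs2$species <- list(c("x", "y"), c("z"))
  d <- shared_species("A", "B", rs2)
  expect_equal(c(d$n_shared, d$n_in_a), c(0L, 2L))
})

test_that("co-occurrence accounting matches site structure", {
  s <- sites_fixture()
  co <- cooccurrence_stats(s)
  expect_equal(co$max_species_per_site, 5L)     # site NCS24
  expect_lte(co$n_multispecies_sites, co$n_multispecimen_sites)
  singletons <- s[s$sample_size == 1 & lengths(s$clades) == 1, ]
  co1 <- cooccurrence_stats(singletons)
  expect_equal(co1[c("n_multispecimen_sites", "n_multispecies_sites",
                     "max_species_per_site")],
               list(n_multispecimen_sites = 0L, n_multispecies_sites = 0L,
                    max_species_per_site = 1L))
})

test_that("analytic rarefaction equals exhaustive enumeration", {
  expect_equal(rarefaction_curve(c("A", "A", "B"), 2)$expected_species,
               rarefaction_enum(c("A", "A", "B"), 2))
  set.seed(42)
  for (rep in 1:10) {
    N <- sample(3:8, 1)
    labels <- sample(letters[1:4], N, replace = TRUE)
    rc <- rarefaction_curve(labels)
    for (n in seq_len(N))
      expect_equal(rc$expected_species[n], rarefaction_enum(labels, n),
                   tolerance = 1e-12)
    expect_equal(rc$expected_species[1], 1)
    expect_equal(rc$expected_species[N], length(unique(labels)))
    expect_true(all(diff(rc$expected_species) >= -1e-12))
  }
  expect_error(rarefaction_curve(c("A", "B"), 3), "exceeds")
})

test_that("depth profiles aggregate site ranges per species", {
  s <- sites_fixture()
  dp <- depth_profile(s)
  s24 <- dp[dp$species == "24", ]
  expect_setequal(setdiff(s24$region, "all"), "Arctic Ocean")
  expect_equal(s24$depth_min[s24$region == "all"], 4038)
  expect_equal(s24$depth_max[s24$region == "all"], 4380)
  # a species found at a single site inherits that site's range
  s9 <- dp[dp$species == "9" & dp$region == "all", ]
  expect_equal(c(s9$depth_min, s9$depth_max), c(48, 111))
})

test_that("marker-coverage rule selects concatenation-eligible specimens", {
  spx <- data.frame(specimen_id = c("a", "b", "c"),
                    coi = c(TRUE, TRUE, FALSE), its2 = c(TRUE, TRUE, TRUE),
                    rdna16s = c(TRUE, FALSE, FALSE),
                    rdna28s = c(FALSE, FALSE, FALSE))
  expect_equal(concat_eligible(spx, 3), "a")
  expect_setequal(concat_eligible(spx, 1), c("a", "b", "c"))
  expect_error(concat_eligible(spx, 5), "out of range")
  cov <- read.csv(system.file("extdata", "terebellides_marker_coverage.csv",
                              package = "haplodelim"))
  expect_equal(sum(cov$concat), 91L)
  expect_equal(sum(cov$n_specimens), 513L)
})

test_that("rarefaction agrees with the community-ecology reference", {
  set.seed(99)
  labels <- sample(letters[1:12], 60, replace = TRUE)
  rc <- rarefaction_curve(labels, sizes = c(1, 5, 20, 40, 60))
  counts <- as.numeric(table(labels))
  ref <- vapply(c(1, 5, 20, 40, 60), function(n)
    as.numeric(suppressWarnings(vegan::rarefy(counts, n))), numeric(1))
  expect_equal(rc$expected_species, ref, tolerance = 1e-8)
})
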