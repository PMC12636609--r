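test_that("overlap counting respects the half-open convention", {
  q <- genomic_intervals("chr1", 10, 40)
  expect_equal(count_overlaps(q, genomic_intervals("chr1", 39, 60))$n_overlaps,
               1L)  # one shared base
  expect_equal(count_overlaps(q, genomic_intervals("chr1", 40, 60))$n_overlaps,
               0L)  # abutting
  expect_equal(count_overlaps(q, genomic_intervals("chrX", 10, 40))$n_overlaps,
               0L)  # unknown chromosome: no overlap, no error
  # min_bp raises the bar
  expect_equal(count_overlaps(q, genomic_intervals("chr1", 35, 60),
                              min_bp = 6)$n_overlaps, 0L)
  expect_equal(count_overlaps(q, genomic_intervals("chr1", 34, 60),
                              min_bp = 6)$n_overlaps, 1L)
})

test_that("overlap counts equal the brute-force pairwise oracle", {
  withr::local_seed(101)
  g <- test_genome()
  a <- random_intervals(200, g)
  b <- random_intervals(200, g)
  for (mb in c(1, 25)) {
    expect_equal(count_overlaps(a, b, min_bp = mb)$n_overlaps,
                 as.integer(brute_force_overlap_counts(a, b, mb)))
  }
  # total pair count is symmetric at min_bp = 1
  expect_equal(sum(count_overlaps(a, b)$n_overlaps),
               sum(count_overlaps(b, a)$n_overlaps))
})

test_that("tertile stratification follows the size and order rules", {
  r3 <- tibble::tibble(g4_probability = c(0.1, 0.5, 0.9))
  expect_equal(as.character(stratify_by_probability(r3)$stratum),
               c("low", "medium", "high"))
  r7 <- tibble::tibble(g4_probability = seq(0.1, 0.7, by = 0.1))
  expect_equal(as.vector(table(stratify_by_probability(r7)$stratum)),
               c(3, 2, 2))  # extra member goes to low
  withr::local_seed(5)
  r300 <- tibble::tibble(g4_probability = runif(300))
  s <- stratify_by_probability(r300)
  expect_equal(as.vector(table(s$stratum)), c(100, 100, 100))
  expect_lte(max(s$g4_probability[s$stratum == "low"]),
             min(s$g4_probability[s$stratum == "high"]))
  expect_error(stratify_by_probability(r3[1:2, ]), "at least 3")
})

test_that("phase enrichment labels exclusivity and computes the ratio", {
  regions <- genomic_intervals(c("c", "c"), c(0, 100), c(30, 130),
                               name = c("ex", "sh"))
  soluble <- genomic_intervals(rep("c", 7),
                               c(0, 5, 10, 100, 100, 105, 110),
                               c(30, 35, 40, 130, 120, 135, 140))
  droplet <- genomic_intervals(rep("c", 2), c(100, 105), c(130, 135))
  pe <- phase_enrichment(regions, soluble, droplet)
  expect_equal(as.character(pe$exclusivity), c("soluble_only", "shared"))
  expect_true(is.na(pe$enrichment[1]))      # (3, 0): undefined
  expect_equal(pe$count_soluble, c(3L, 4L))
  expect_equal(pe$enrichment[2], 2.0)       # (4, 2)
})

test_that("high stratum is more soluble-enriched than low on planted data", {
  sim <- simulate_enrichment_dataset(n_g4 = 150, seed = 21)
  pe <- phase_enrichment(sim$regions, sim$soluble, sim$droplet)
  sol_rate <- tapply(pe$count_soluble > 0, pe$stratum, mean)
  expect_gt(sol_rate[["high"]], sol_rate[["low"]])
  shared <- pe[pe$exclusivity == "shared", ]
  if (any(shared$stratum == "high") && any(shared$stratum == "low")) {
    expect_gte(mean(shared$enrichment[shared$stratum == "high"]),
               mean(shared$enrichment[shared$stratum == "low"]) * 0.8)
  }
})

test_that("candidate ranking puts exclusives first, then by enrichment", {
  rec <- tibble::tibble(
    region_id = c("a", "b", "c", "d"),
    exclusivity = factor(c("shared", "soluble_only", "shared", "droplet_only"),
                         levels = c("soluble_only", "droplet_only", "shared",
                                    "neither")),
    enrichment = c(1.2, NA, 3.0, NA))
  out <- select_candidates(rec, strata_filter = NULL)
  expect_equal(out$region_id, c("b", "c", "a"))
  all_drop <- rec[rec$exclusivity == "droplet_only", ]
  expect_equal(nrow(select_candidates(all_drop, strata_filter = NULL)), 0)
})

test_that("the planted soluble-exclusive region ranks first", {
  # with every non-exclusive region given a droplet overlap, the region
  # planted with droplet probability 0 is the only soluble-exclusive one
  sim <- simulate_enrichment_dataset(n_g4 = 60, p_droplet = 1,
                                     n_exclusive = 1, seed = 31)
  pe <- phase_enrichment(sim$regions, sim$soluble, sim$droplet)
  top <- select_candidates(pe, strata_filter = "high")$region_id[1]
  expect_equal(top, sim$truth$name[sim$truth$is_exclusive])
})

test_that("shuffling preserves lengths and places uniformly by length", {
  g1 <- genome_table("chrA", 100)
  iv <- genomic_intervals("chrZ", 50, 150)  # length 100, must go to (0, 100)
  sh <- shuffle_intervals(iv, g1, seed = 1)
  expect_equal(sh$chrom, "chrA")
  expect_equal(sh$start, 0)
  expect_equal(sh$end, 100)

  g <- genome_table(c("chrA", "chrB"), c(50, 150))
  withr::local_seed(9)
  iv10 <- genomic_intervals(rep("chrA", 40), seq(0, 39), seq(10, 49))
  sh <- do.call(rbind, lapply(1:50, function(i) shuffle_intervals(iv10, g)))
  expect_equal(sort(sh$end - sh$start), rep(10, 2000))  # length multiset kept
  # binomial oracle: P(chrB) = 150/200 = 0.75
  frac_b <- mean(sh$chrom == "chrB")
  se <- sqrt(0.75 * 0.25 / 2000)
  expect_lt(abs(frac_b - 0.75), 3 * se)
  # starts stay within bounds
  expect_true(all(sh$start >= 0))
  expect_true(all(sh$end <= g$length[match(sh$chrom, g$chrom)]))
  # an interval longer than every chromosome is impossible
  expect_error(shuffle_intervals(genomic_intervals("chrA", 0, 500), g),
               "longer than every chromosome")
})

test_that("permutation p-values use the pseudocount form and the right tail", {
  g <- genome_table("chr1", 1e6)
  # set A fully nested in set B on a genome 1000x larger: shuffles almost
  # never reproduce the observed full overlap
  a <- genomic_intervals(rep("chr1", 5), 100 + 0:4 * 10, 105 + 0:4 * 10)
  b <- genomic_intervals("chr1", 90, 160)
  pt <- permutation_test(a, b, g, n_shuffles = 100, direction = "a", seed = 3)
  expect_equal(pt$observed, 5)
  expect_equal(pt$empirical_p, 1 / 101)
  expect_equal(length(pt$null_counts), 100)

  # n_shuffles = 1 with null >= observed gives exactly 1
  tiny <- genome_table("c", 10)
  a1 <- genomic_intervals("c", 0, 10)
  pt1 <- permutation_test(a1, a1, tiny, n_shuffles = 1, direction = "b",
                          seed = 4)
  expect_equal(pt1$empirical_p, 1.0)

  expect_error(permutation_test(a[0, ], b, g), "non-empty")
  # p can never be zero
  expect_gte(pt$empirical_p, 1 / (pt$n_shuffles + 1))
})

test_that("the fast any-overlap path agrees with the GenomicRanges route", {
  withr::local_seed(303)
  g <- test_genome()
  for (i in 1:10) {
    a <- random_intervals(sample(5:60, 1), g, max_len = 1000)
    b <- random_intervals(sample(5:60, 1), g, max_len = 1000)
    fast <- rg4llps:::n_overlapping_any(a, rg4llps:::merge_interval_blocks(b))
    slow <- sum(count_overlaps(a, b)$n_overlaps > 0)
    expect_equal(fast, slow)
  }
})

test_that("permutation test is deterministic given a seed", {
  g <- test_genome()
  withr::local_seed(77)
  a <- random_intervals(20, g)
  b <- random_intervals(20, g)
  p1 <- permutation_test(a, b, g, n_shuffles = 20, direction = "b", seed = 8)
  p2 <- permutation_test(a, b, g, n_shuffles = 20, direction = "b", seed = 8)
  expect_identical(p1$null_counts, p2$null_counts)
  expect_equal(nrow(glance(p1)), 1)
  expect_equal(nrow(tidy(p1)), 20)
})
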