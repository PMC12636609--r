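test_that("segmentation recovers planted disks with accurate areas", {
  sim <- simulate_droplet_image(shape = c(128, 128), n_droplets = 7,
                                radius_range = c(4, 8), noise_sd = 1,
                                seed = 1)
  seg <- segment_droplets(sim$image)
  expect_equal(nrow(seg$records), 7)
  # areas within 10% of the planted pixel counts, matched by position
  got <- sort(seg$records$area)
  want <- sort(sim$truth$area)
  expect_true(all(abs(got - want) / want < 0.10))
  expect_equal(tidy(seg), seg$records)
})

test_that("degenerate thresholding yields zero droplets with a warning", {
  flat <- matrix(5, 32, 32)
  expect_warning(seg <- segment_droplets(flat, threshold = 1), "zero droplets")
  expect_equal(nrow(seg$records), 0)
  expect_warning(seg2 <- segment_droplets(flat + matrix(rnorm(1024, sd = 1e-6),
                                                        32, 32)),
                 "zero droplets|min_area")
})

test_that("components bridged by one pixel merge under 8-connectivity", {
  img <- matrix(0, 32, 32)
  img[5:9, 5:9] <- 10       # square A
  img[11:15, 11:15] <- 10   # square B, diagonal from A
  img[10, 10] <- 10         # 1-px bridge touching both diagonally
  seg <- segment_droplets(img, threshold = 5, min_area = 4)
  expect_equal(nrow(seg$records), 1)
  # without the bridge the corners (9,9)-(11,11) are two apart: disconnected
  img[10, 10] <- 0
  seg2 <- segment_droplets(img, threshold = 5, min_area = 4)
  expect_equal(nrow(seg2$records), 2)
})

test_that("purely diagonal adjacency connects, separated blocks do not", {
  img <- matrix(0, 32, 32)
  img[5:8, 5:8] <- 10
  img[9:12, 9:12] <- 10     # corner (8,8) diagonally adjacent to (9,9)
  expect_equal(nrow(segment_droplets(img, threshold = 5)$records), 1)
  img2 <- matrix(0, 32, 32)
  img2[5:8, 5:8] <- 10
  img2[10:13, 10:13] <- 10  # gap of one empty diagonal
  expect_equal(nrow(segment_droplets(img2, threshold = 5)$records), 2)
})

test_that("enrichment scores are partition ratios, invariant to rescaling", {
  sim <- simulate_droplet_image(shape = c(128, 128), n_droplets = 5,
                                intensity_inside = 200,
                                intensity_background = 100, noise_sd = 0.5,
                                seed = 2)
  seg <- segment_droplets(sim$image)
  es <- enrichment_scores(sim$image, seg)
  expect_equal(nrow(es), 5)
  expect_true(all(abs(es$enrichment - 2.0) < 0.1))
  # doubling intensities leaves enrichment unchanged
  es2 <- enrichment_scores(2 * sim$image, seg)
  expect_equal(es2$enrichment, es$enrichment, tolerance = 1e-12)
  # a disk equal to the background scores 1.0 (manual threshold)
  img <- matrix(100, 64, 64)
  lbl <- matrix(0L, 64, 64); lbl[20:28, 20:28] <- 1L
  expect_equal(enrichment_scores(img, lbl)$enrichment, 1.0)
})

test_that("background mean excludes the halo around droplets", {
  img <- matrix(100, 64, 64)
  img[30:34, 30:34] <- 200
  lbl <- matrix(0L, 64, 64); lbl[30:34, 30:34] <- 1L
  # sentinel intensity on the 2-px halo ring: must not contaminate background
  halo <- matrix(FALSE, 64, 64); halo[28:36, 28:36] <- TRUE
  halo[30:34, 30:34] <- FALSE
  img[halo] <- 1e6
  es <- enrichment_scores(img, lbl, halo_px = 2)
  expect_equal(es$background_mean, 100)
  expect_equal(es$enrichment, 2.0)
})

test_that("phase diagrams average counts per image and pool enrichment", {
  droplets <- tidyr::expand_grid(condition = "S1_1uM", time = 30,
                                 image = 1:10, d = 1:3)
  droplets$enrichment <- 2
  pd <- phase_diagram(droplets)
  expect_equal(pd$mean_count, 3)
  expect_equal(pd$mean_enrichment, 2)
  # zero-droplet images pull the mean down when the inventory is supplied
  images <- tidyr::expand_grid(condition = "S1_1uM", time = 30, image = 1:12)
  pd2 <- phase_diagram(droplets, images)
  expect_equal(pd2$mean_count, 30 / 12)
  # an empty cell has count 0 and undefined enrichment
  images2 <- dplyr::bind_rows(images,
                              tibble::tibble(condition = "S1_32uM", time = 30,
                                             image = 1))
  pd3 <- phase_diagram(droplets, images2)
  empty <- pd3[pd3$condition == "S1_32uM", ]
  expect_equal(empty$mean_count, 0)
  expect_true(is.na(empty$mean_enrichment))
})

test_that("planted decreasing droplet numbers give a monotone count column", {
  counts <- c(9, 6, 3)
  rows <- purrr::imap_dfr(counts, function(n, i) {
    sim <- simulate_droplet_image(shape = c(128, 128), n_droplets = n,
                                  radius_range = c(3, 5), seed = 100 + i)
    seg <- segment_droplets(sim$image)
    es <- enrichment_scores(sim$image, seg)
    tibble::tibble(condition = sprintf("conc_%d", i), time = 30, image = 1,
                   enrichment = es$enrichment)
  })
  pd <- phase_diagram(rows)
  expect_equal(pd$mean_count, counts)
  expect_true(all(diff(pd$mean_count) < 0))
})

test_that("speckle enhancement keeps dots and removes flat or sloped bases", {
  flat <- matrix(7, 64, 64)
  expect_equal(enhance_speckles(flat), matrix(0, 64, 64))
  # a small bright dot survives, its surround goes to ~0
  img <- matrix(10, 64, 64); img[30:32, 30:32] <- 100
  en <- enhance_speckles(img)
  expect_gt(en[31, 31], 80)
  expect_lt(max(en[1:10, 1:10]), 1e-6)
  # broad gradient suppressed > 90%, dots dominate the output
  grad <- outer(seq(0, 50, length.out = 96), seq(0, 50, length.out = 96), "+")
  dots <- matrix(0, 96, 96)
  for (ctr in list(c(20, 70), c(50, 30), c(80, 80))) {
    dots[ctr[1] + (-1:1), ctr[2] + (-1:1)] <- 120
  }
  en2 <- enhance_speckles(grad + dots)
  expect_lt(max(en2[dots == 0 & row(dots) > 12 & col(dots) > 12 &
                      row(dots) < 84 & col(dots) < 84]),
            0.1 * max(grad))
  expect_gt(min(en2[dots > 0]), 50)
})

test_that("cytoplasmic masking removes nuclear foci and honours shrinkage", {
  # all foci inside the shrunken nuclei: empty mask
  nuclei <- matrix(0, 64, 64); nuclei[20:50, 20:50] <- 100
  foci <- matrix(10, 64, 64); foci[33:35, 33:35] <- 200
  m <- cytoplasmic_foci_mask(foci, nuclei, shrink_px = 5, feature_size = 10)
  expect_false(any(m))
  # no nuclei: the mask is the thresholded enhanced foci
  none <- matrix(0, 64, 64)
  m2 <- cytoplasmic_foci_mask(foci, none, shrink_px = 5, feature_size = 10)
  expect_true(any(m2[33:35, 33:35]))
  expect_error(cytoplasmic_foci_mask(foci, matrix(0, 32, 32)), "shape")
})

test_that("planted cytoplasmic foci are recovered with Jaccard >= 0.7", {
  sim <- simulate_cell_image(shape = c(192, 192), n_foci = 20,
                             shared_fraction = 0.5, seed = 9)
  m <- cytoplasmic_foci_mask(sim$channel_a, sim$nuclei)
  jac <- sum(m & sim$truth$mask_a) / sum(m | sim$truth$mask_a)
  expect_gte(jac, 0.7)
})

test_that("Pearson colocalization behaves at its algebraic anchors", {
  withr::local_seed(14)
  a <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(TRUE, 32, 32)
  expect_equal(pearson_colocalization(a, a, mask), 1.0)
  expect_equal(pearson_colocalization(a, 2 - a, mask), -1.0)
  # affine invariance
  b <- matrix(runif(32 * 32), 32, 32)
  expect_equal(pearson_colocalization(a, b, mask),
               pearson_colocalization(3 * a + 1, 0.5 * b - 2, mask),
               tolerance = 1e-12)
  expect_error(pearson_colocalization(a, matrix(1, 32, 32), mask), "variance")
  small <- matrix(FALSE, 32, 32); small[1, 1:5] <- TRUE
  expect_error(pearson_colocalization(a, b, small), "10 pixels")
})

test_that("colocalization r increases with the planted shared fraction", {
  r <- vapply(c(0, 0.5, 1), function(f) {
    sim <- simulate_cell_image(shape = c(192, 192), shared_fraction = f,
                               seed = 5)
    colocalize_cytoplasmic_foci(sim$channel_a, sim$channel_b, sim$nuclei)$r
  }, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_gt(r[3], 0.8)
})

test_that("assembly counting averages component counts per image", {
  zeros <- matrix(0L, 20, 20)
  expect_equal(count_assemblies(list(zeros, zeros, zeros)), 0)
  two <- matrix(0L, 20, 20); two[2:4, 2:4] <- 1L; two[10:12, 10:12] <- 2L
  four <- matrix(0L, 20, 20)
  four[cbind(c(2, 8, 14, 18), c(2, 8, 14, 18))] <- 1:4
  expect_equal(count_assemblies(list(two, four)), 3)
  # planted recovery on noiseless well-separated disks is exact
  segs <- lapply(1:3, function(i) {
    sim <- simulate_droplet_image(shape = c(128, 128), n_droplets = 5,
                                  radius_range = c(3, 5), noise_sd = 0,
                                  seed = 40 + i)
    segment_droplets(sim$image, threshold = 150)
  })
  expect_equal(count_assemblies(segs), 5)
})
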