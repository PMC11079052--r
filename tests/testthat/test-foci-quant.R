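test_that("noise-free segmentation recovers the ground-truth nuclei exactly", {
  sc <- simulate_scene(scene_params(nucleus_count = 5, noise_sd = 0, seed = 17))
  gt <- sc$ground_truth$nucleus_label_mask
  m <- segment_nuclei(sc$channels$dna, segmentation_config(), 0.1)
  expect_identical(attr(m, "n_nuclei"), 5L)
  # pixel sets equal up to label permutation
  expect_true(all(per_nucleus_jaccard(m, gt) == 1))
})

test_that("an all-zero raster yields an explicit empty segmentation", {
  m <- segment_nuclei(matrix(0, 50, 50), segmentation_config(), 0.1)
  expect_identical(attr(m, "n_nuclei"), 0L)
  expect_true(all(m == 0L))
})

test_that("segmentation overlap stays high at moderate noise and degrades monotonically", {
  noise_levels <- c(0, 15, 45, 90)
  mean_j <- vapply(noise_levels, function(ns) {
    js <- vapply(c(1, 2, 3), function(seed) {
      sc <- simulate_scene(scene_params(nucleus_count = 4, noise_sd = ns,
                                        seed = seed))
      m <- segment_nuclei(sc$channels$dna, segmentation_config(), 0.1)
      mean(per_nucleus_jaccard(m, sc$ground_truth$nucleus_label_mask))
    }, numeric(1))
    mean(js)
  }, numeric(1))
  # noise_sd = 0.05 x contrast x nucleoplasm level = 15 a.u. here
  expect_gte(mean_j[2], 0.95)
  expect_true(all(diff(mean_j) <= 1e-6))
})

test_that("external masks are validated and relabeled, not recomputed", {
  sc <- simulate_scene(scene_params(nucleus_count = 3, seed = 6))
  gt <- sc$ground_truth$nucleus_label_mask
  shifted <- gt
  shifted[shifted > 0] <- shifted[shifted > 0] * 10L  # ids 10, 20, 30
  m <- segment_nuclei(sc$channels$dna,
                      segmentation_config(method = "external_mask"),
                      0.1, mask = shifted)
  expect_identical(sort(unique(as.vector(m))), 0:3)
  expect_true(all(per_nucleus_jaccard(m, gt) == 1))
  expect_error(segment_nuclei(sc$channels$dna,
                              segmentation_config(method = "external_mask"), 0.1),
               "requires a mask")
})

test_that("per-nucleus foci detection recovers ground truth and is brightness invariant", {
  sc <- simulate_scene(scene_params(nucleus_count = 2, noise_sd = 0, seed = 12))
  gt <- sc$ground_truth
  f <- detect_foci(sc$channels$dna, gt$nucleus_label_mask, foci_config(), 0.1)
  expect_identical(unname(f[, ]), unname(gt$foci_mask[, ]))

  # two nuclei, same internal contrast, 5x different absolute brightness
  img <- matrix(0, 40, 80)
  mask <- matrix(0L, 40, 80)
  mask[10:30, 10:30] <- 1L; mask[10:30, 50:70] <- 2L
  img[mask == 1L] <- 100; img[15:20, 15:20] <- 300
  img[mask == 2L] <- 500; img[15:20, 55:60] <- 1500
  f2 <- detect_foci(img, mask, foci_config(), 0.1)
  counts <- vapply(1:2, function(id) {
    sum(EBImage::bwlabel((f2 & mask == id) * 1) > 0) > 0
  }, logical(1))
  expect_true(all(counts))
  expect_identical(sum(f2 & mask == 1L), sum(f2 & mask == 2L))
})

test_that("uniform and constant nuclei yield no foci", {
  img <- matrix(0, 30, 30)
  mask <- matrix(0L, 30, 30)
  mask[5:25, 5:25] <- 1L
  img[mask == 1L] <- 100
  f <- detect_foci(img, mask, foci_config(), 0.1)
  expect_false(any(f))
  expect_identical(attr(f, "skipped_nuclei"), 1L)
})

test_that("measurements satisfy the sum decomposition and unit conversion", {
  sc <- simulate_scene(scene_params(nucleus_count = 3, noise_sd = 4, seed = 9))
  gt <- sc$ground_truth
  meas <- measure_nuclei(sc$channels, gt$nucleus_label_mask, gt$foci_mask, 0.1)
  px2 <- 0.1^2
  for (i in seq_len(nrow(meas))) {
    for (ch in c("dna", "reporter")) {
      mf <- meas[[paste0("mean_foci_", ch)]][i]
      mn <- meas[[paste0("mean_nucleoplasm_", ch)]][i]
      tot <- meas[[paste0("total_nuclear_", ch)]][i]
      fa <- meas$foci_area_um2[i] / px2
      na <- meas$nucleus_area_um2[i] / px2 - fa
      expect_equal(tot, (if (fa > 0) mf * fa else 0) + mn * na,
                   tolerance = 1e-9)
    }
  }
  # areas are pixel counts times pixel_size^2
  expect_equal(meas$nucleus_area_um2,
               as.vector(table(gt$nucleus_label_mask[gt$nucleus_label_mask > 0])) * px2)
})

test_that("ratios follow from the channel means and scale equivariance holds", {
  img <- matrix(0, 20, 20)
  mask <- matrix(0L, 20, 20); mask[3:18, 3:18] <- 1L
  foci <- matrix(FALSE, 20, 20); foci[5:8, 5:8] <- TRUE
  img[mask == 1L] <- 80; img[foci] <- 200
  meas <- measure_nuclei(list(dna = img), mask, foci, 0.1)
  expect_equal(meas$ratio_dna, 2.5)
  meas2 <- measure_nuclei(list(dna = img * 7.3), mask, foci, 0.1)
  expect_equal(meas2$ratio_dna, meas$ratio_dna)
  expect_equal(meas2$nucleus_area_um2, meas$nucleus_area_um2)
  # 10,000 px at 0.1 um/px -> 100 um^2
  big <- matrix(1, 120, 120)
  bmask <- matrix(0L, 120, 120); bmask[1:100, 1:100] <- 1L
  bm <- measure_nuclei(list(dna = big), bmask, matrix(FALSE, 120, 120), 0.1)
  expect_equal(bm$nucleus_area_um2, 100)
  expect_identical(bm$foci_count, 0L)
  expect_true(is.na(bm$ratio_dna))
})

test_that("foci pixels outside any nucleus are a mask inconsistency error", {
  mask <- matrix(0L, 10, 10); mask[3:8, 3:8] <- 1L
  foci <- matrix(FALSE, 10, 10); foci[1, 1] <- TRUE
  expect_error(measure_nuclei(list(dna = matrix(1, 10, 10)), mask, foci, 0.1),
               "inconsistency")
})

test_that("the noise-free pipeline reproduces generator parameters end to end", {
  sc <- simulate_scene(scene_params(nucleus_count = 4, noise_sd = 0, seed = 23,
                                    reporter_foci_ratio = 2))
  m <- segment_nuclei(sc$channels$dna, segmentation_config(), 0.1)
  f <- detect_foci(sc$channels$dna, m, foci_config(), 0.1)
  meas <- measure_nuclei(sc$channels, m, f, 0.1)
  truth <- sc$ground_truth$per_nucleus
  # match segmented labels to ground-truth ids via overlap
  for (id in truth$nucleus_id) {
    t_mask <- sc$ground_truth$nucleus_label_mask == id
    lab <- unique(m[t_mask]); lab <- lab[lab > 0]
    row <- meas[meas$nucleus_id == lab, ]
    expect_identical(row$foci_count, truth$foci_count[id])
    expect_equal(row$foci_area_um2, truth$foci_area_px[id] * 0.01)
    if (truth$foci_count[id] > 0) {
      expect_equal(row$mean_foci_dna, truth$dna_foci_mean[id])
      expect_equal(row$ratio_reporter, 2)
    }
  }
})

test_that("distribution classification follows the threshold rule", {
  meas <- data.frame(nucleus_id = 1:4, foci_count = c(0L, 3L, 2L, 1L),
                     ratio_reporter = c(NA, 3, 1.3, 1.05))
  calls <- classify_distribution(meas, "reporter", 1.5, 1.1)
  expect_identical(as.character(calls$label),
                   c("diffuse", "spotty", "mixed", "diffuse"))
  expect_identical(calls$t_spotty, rep(1.5, 4))
  expect_error(classify_distribution(meas, "reporter", 1.1, 1.5), "t_spotty")
  expect_error(classify_distribution(meas, "dna"), "not present")
})

test_that("call summaries tally fractions per replicate then average", {
  one <- data.frame(label = rep("spotty", 4), group = "g1", replicate = 1L)
  s1 <- summarize_calls(one)
  expect_equal(s1$mean_fraction[s1$label == "spotty"], 1)
  expect_true(all(is.na(s1$sd_fraction)))
  expect_true(all(s1$single_replicate))

  two <- data.frame(
    label = c(rep("spotty", 2), rep("diffuse", 3),  # rep 1: 0.4 spotty
              rep("spotty", 3), rep("diffuse", 2)), # rep 2: 0.6 spotty
    group = "g1", replicate = rep(1:2, each = 5))
  s2 <- summarize_calls(two)
  expect_equal(s2$mean_fraction[s2$label == "spotty"], 0.5)
  expect_equal(sum(s2$mean_fraction), 1)

  # random labels: cross-check against a hand tally
  labs <- withr::with_seed(5, sample(c("spotty", "mixed", "diffuse"), 60, TRUE))
  rand <- data.frame(label = labs, group = "g",
                     replicate = rep(1:3, each = 20))
  s3 <- summarize_calls(rand)
  for (lv in c("spotty", "mixed", "diffuse")) {
    manual <- mean(vapply(1:3, function(r) {
      sum(labs[rand$replicate == r] == lv) / 20
    }, numeric(1)))
    expect_equal(s3$mean_fraction[s3$label == lv], manual)
  }
})
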