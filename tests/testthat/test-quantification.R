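test_that("segmentation applies the intensity and 200 px^2 size rules", {
  set.seed(1)
  img <- simulate_puncta_image(10, radius_px = 10, image_shape = c(300, 300))
  # disks of ~314 px^2 pass the 200 px^2 threshold
  ps <- segment_puncta(img$channels$munc13, min_area_px = 200)
  expect_equal(nrow(ps), 10)
  expect_true(all(ps$area_px >= 200))
  # area conversion: 6 nm pixels make 200 px^2 about 7,200 nm^2
  expect_equal(ps$area_nm2, ps$area_px * 36)
  # a 150 px^2 object is rejected at the 200 px^2 cut
  small <- matrix(0, 60, 60)
  small[cbind(rep(20:34, each = 10), rep(20:29, times = 15))] <- 1
  expect_equal(sum(small), 150)
  expect_equal(nrow(segment_puncta(small, min_area_px = 200)), 0)
  expect_equal(nrow(segment_puncta(small, min_area_px = 150)), 1)
  expect_error(segment_puncta("x"), "matrix")
  # absolute-threshold alternative
  ps2 <- segment_puncta(img$channels$munc13, method = "absolute",
                        threshold = 0.5, min_area_px = 200)
  expect_equal(nrow(ps2), 10)
})

test_that("colocalization follows the >5% smaller-punctum overlap rule", {
  # identical masks: overlap fraction 1, matched
  m <- matrix(0, 50, 50); m[20:30, 20:30] <- 1
  a <- segment_puncta(m, min_area_px = 50)
  pairs <- colocalize(a, a)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$overlap_fraction, 1)
  # disjoint masks: unmatched
  m2 <- matrix(0, 50, 50); m2[1:8, 1:8] <- 1
  b <- segment_puncta(m2, min_area_px = 50)
  expect_equal(nrow(colocalize(a, b)), 0)
  # matching is symmetric under the smaller-punctum denominator
  set.seed(2)
  img <- simulate_puncta_image(15, radius_px = 9, image_shape = c(300, 300),
                               coloc_fraction = 0.8)
  pa <- segment_puncta(img$channels$munc13, min_area_px = 150)
  pb <- segment_puncta(img$channels$psd95, min_area_px = 150)
  ab <- colocalize(pa, pb)
  ba <- colocalize(pb, pa)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$label_a, ab$label_b),
                  paste(ba$label_b, ba$label_a))
})

test_that("planned co-placement is recovered by the analyzer", {
  set.seed(3)
  img <- simulate_puncta_image(40, radius_px = 8, image_shape = c(460, 460),
                               coloc_fraction = 0.9)
  pa <- segment_puncta(img$channels$munc13, min_area_px = 120)
  pb <- segment_puncta(img$channels$psd95, min_area_px = 120)
  n_matched <- nrow(colocalize(pa, pb))
  planned <- sum(img$truth$coloc[img$truth$channel == "psd95"])
  expect_equal(n_matched, planned)
})

test_that("synapse density is count over imaged volume", {
  # 20 synapses in a 10.13 um x 10.13 um x 0.5 um volume
  expect_equal(synapse_density(20, 10.13^2, 500), 20 / (10.13^2 * 0.5))
  expect_equal(round(synapse_density(20, 10.13^2, 500), 2), 0.39)
  expect_equal(synapse_density(0, 100, 500), 0)
  # doubling thickness halves density
  expect_equal(synapse_density(20, 100, 1000),
               synapse_density(20, 100, 500) / 2)
  expect_error(synapse_density(5, 0, 500), "positive")
})

test_that("blot normalization is per-blot, per-protein, control-anchored", {
  bt <- data.frame(
    protein = rep("PSD95", 6),
    sample_id = 1:6,
    group = c("control", "control", "ko", "control", "control", "ko"),
    band_intensity = c(2, 4, 6, 10, 30, 40),
    blot_id = rep(c("b1", "b2"), each = 3))
  res <- normalize_blot(bt, "control")
  expect_equal(res$table$relative_amount,
               c(2 / 3, 4 / 3, 2, 0.5, 1.5, 2))
  # control mean is 1 on every blot by construction
  ctrl <- res$table[res$table$group == "control", ]
  expect_equal(as.numeric(tapply(ctrl$relative_amount, ctrl$blot_id, mean)),
               c(1, 1))
  # invariance to a per-blot gain
  bt2 <- bt; bt2$band_intensity[bt2$blot_id == "b2"] <-
    bt2$band_intensity[bt2$blot_id == "b2"] * 13
  expect_equal(normalize_blot(bt2, "control")$table$relative_amount,
               res$table$relative_amount)
  # rows without a control are flagged and excluded
  bt3 <- rbind(bt, data.frame(protein = "PSD93", sample_id = 7, group = "ko",
                              band_intensity = 5, blot_id = "b1"))
  res3 <- normalize_blot(bt3, "control")
  expect_equal(res3$excluded$protein, "PSD93")
  expect_match(res3$excluded$reason, "no control")
})

test_that("puncta generator bookkeeping matches its rendered channels", {
  expect_error(simulate_puncta_image(5, radius_px = 40,
                                     image_shape = c(50, 50)), "larger")
  set.seed(4)
  img <- simulate_puncta_image(12, radius_px = 10, image_shape = c(300, 300),
                               coloc_fraction = 1)
  expect_equal(sum(img$truth$channel == "munc13"), 12)
  expect_true(all(img$truth$coloc[img$truth$channel == "psd95"]))
  expect_equal(img$image_area_um2, (300 * 6 / 1000)^2)
  # psd93 channel stays empty under a psd95 plan
  expect_true(all(img$channels$psd93 == 0))
})
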