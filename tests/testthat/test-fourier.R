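test_that("temporal binning averages non-overlapping frame quadruples", {
  gt <- flat_gt(2, 1, c(4, 4), phase = 0.7, stim_freq = 0.125,
                frame_rate = 30, n_frames = 1248)
  mv <- simulate_movie(gt, "contra")
  tb <- temporal_bin(mv)
  expect_equal(dim(tb$frames)[1], 312)
  expect_equal(tb$frame_rate, 7.5)
  # constant movie is unchanged
  cm <- mv; cm$frames[] <- 3.3
  expect_true(all(temporal_bin(cm)$frames == 3.3))
  # remainder rule: 7 frames at factor 4 -> 1 frame, 3 dropped, logged
  sm <- mv; sm$frames <- mv$frames[1:7, , , drop = FALSE]
  expect_message(out <- temporal_bin(sm), "dropping 3")
  expect_equal(dim(out$frames)[1], 1)
  expect_error(temporal_bin(list()), "response_movie")
})

test_that("boxcar binning attenuates a sinusoid by the Dirichlet factor", {
  f <- 1; fr <- 30; k <- 4
  gt <- flat_gt(5, 1, c(4, 4), phase = 1.1, stim_freq = f, frame_rate = fr,
                n_frames = 1200)
  amp <- fourier_extract(temporal_bin(simulate_movie(gt, "contra")))$amplitude
  atten <- abs(sin(pi * f * k / fr) / (k * sin(pi * f / fr)))
  expect_equal(mean(amp), 5 * atten, tolerance = 1e-3)
})

test_that("fourier_extract recovers a noiseless sinusoid exactly", {
  gt <- flat_gt(2.5, 1, c(4, 4), phase = 1.2, stim_freq = 0.125,
                frame_rate = 7.5, n_frames = 300)
  maps <- fourier_extract(simulate_movie(gt, "contra"))
  expect_equal(max(abs(maps$amplitude - 2.5)), 0, tolerance = 1e-10)
  expect_equal(max(abs(maps$phase - 1.2)), 0, tolerance = 1e-10)
  # a linear phase ramp is reproduced modulo 2 pi
  ramp <- matrix(rep(seq(0, 2 * pi, length.out = 16), each = 8), 8, 16)
  gt2 <- imaging_ground_truth(matrix(2, 8, 16), matrix(1, 8, 16), ramp,
                              0.125, 7.5, 300)
  ph <- fourier_extract(simulate_movie(gt2, "contra"))$phase
  expect_lt(max(abs(circ_err <- atan2(sin(ph - ramp), cos(ph - ramp)))),
            1e-10)
  expect_error(fourier_extract(simulate_movie(gt, "contra")[c(1, 2)]),
               "response_movie")
})

test_that("amplitude is invariant and phase equivariant under time shift", {
  gt <- flat_gt(2, 1, c(4, 4), phase = 0.4, stim_freq = 0.125,
                frame_rate = 7.5, n_frames = 360)
  mv <- simulate_movie(gt, "contra")
  m1 <- fourier_extract(mv)
  shift <- 12  # frames
  mv2 <- mv
  mv2$frames <- mv$frames[c((shift + 1):360, 1:shift), , , drop = FALSE]
  m2 <- fourier_extract(mv2)
  expect_equal(m2$amplitude, m1$amplitude, tolerance = 1e-8)
  # advancing the movie by dt lowers the recovered phase by 2 pi f dt
  dphi <- 2 * pi * 0.125 * shift / 7.5
  expect_equal(as.numeric((m1$phase - m2$phase) %% (2 * pi)),
               rep(dphi %% (2 * pi), 16), tolerance = 1e-8)
})

test_that("noise-only amplitude falls as 1/sqrt(T)", {
  set.seed(1)
  mk <- function(n_frames) {
    gt <- flat_gt(0, 0, c(16, 16), stim_freq = 0.125, frame_rate = 7.5,
                  n_frames = n_frames, noise_sd = 1)
    mean(fourier_extract(simulate_movie(gt, "contra"))$amplitude)
  }
  ratio <- mk(1200) / mk(300)
  expect_lt(abs(ratio - 0.5), 0.1)
})

test_that("OD score and ODI obey the (C-I)/(C+I) algebra", {
  c_amp <- matrix(2, 8, 8); i_amp <- matrix(2, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  expect_equal(od_analysis(c_amp, i_amp, mask)$odi, 0)
  # ipsi silent: score 1 at every responsive pixel
  od1 <- od_analysis(c_amp, i_amp * 0, mask)
  expect_true(all(od1$od_score[od1$responsive_mask] == 1))
  expect_equal(od1$odi, 1)
  # eye swap negates exactly
  set.seed(2)
  ca <- matrix(runif(64, 1, 3), 8, 8); ia <- matrix(runif(64, 1, 3), 8, 8)
  expect_equal(od_analysis(ca, ia, mask)$odi,
               -od_analysis(ia, ca, mask)$odi)
  # global gain on both eyes leaves the ODI unchanged
  expect_equal(od_analysis(5 * ca, 5 * ia, mask)$odi,
               od_analysis(ca, ia, mask)$odi)
  # zero-total pixels are excluded from the mask
  od0 <- od_analysis(ca * 0, ia * 0, mask)
  expect_false(any(od0$responsive_mask))
  expect_error(od_analysis(ca, matrix(1, 4, 4)), "co-registered")
})

test_that("run ODIs are block-averaged with the exclusion rule", {
  # 8 runs -> 2 block ODIs -> animal discarded
  b8 <- odi_blocks(rnorm(8, 0.3, 0.01))
  expect_true(b8$excluded)
  expect_length(b8$block_odis, 2)
  expect_true(is.na(b8$odi))
  # 21 runs -> 5 blocks, 1 dropped run logged
  expect_message(b21 <- odi_blocks(rep(0.25, 21)), "dropping 1")
  expect_length(b21$block_odis, 5)
  expect_equal(b21$n_dropped_runs, 1)
  expect_false(b21$excluded)
  # identical runs: animal ODI equals the run ODI
  b20 <- odi_blocks(rep(0.31, 20))
  expect_equal(b20$odi, 0.31)
})

test_that("map scatter separates smooth from scrambled retinotopy", {
  ramp <- matrix(rep(seq(0, 2 * pi, length.out = 32), each = 32), 32, 32)
  expect_lt(map_scatter(ramp), 0.05)
  set.seed(3)
  unif <- matrix(runif(64 * 64, 0, 2 * pi), 64, 64)
  expect_lt(abs(map_scatter(unif) - pi / 2), 0.05)
  # scatter grows monotonically with phase noise
  set.seed(4)
  sc <- vapply(c(0.1, 0.4, 1.0), function(s)
    map_scatter((ramp + matrix(rnorm(1024, 0, s), 32, 32)) %% (2 * pi)),
    numeric(1))
  expect_true(all(diff(sc) > 0))
  expect_error(map_scatter(ramp, neighborhood = 33), "larger than")
  expect_error(map_scatter(ramp, mask = matrix(FALSE, 32, 32)), "empty")
})
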