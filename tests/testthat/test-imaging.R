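grid_positions <- function(n_side, spacing, offset) {
  g <- expand.grid(row = offset + spacing * (seq_len(n_side) - 1),
                   col = offset + spacing * (seq_len(n_side) - 1))
  as.matrix(g)
}

test_that("noiseless rendering makes ROI sums proportional to trace values", {
  amp <- matrix(c(10, 20, 40, 80, 160), ncol = 1)
  stack <- simulate_image_stack(amp, dim_px = c(31, 31),
                                positions = matrix(c(15, 15), 1, 2),
                                psf_sigma_px = 1.2)
  sums <- apply(stack$frames, 1, sum)
  expect_equal(sums / sums[1], amp[, 1] / amp[1, 1], tolerance = 1e-10)
})

test_that("a single static spot is localised within half a pixel", {
  amp <- matrix(rep(100, 6), ncol = 1)
  pos <- matrix(c(14.3, 16.7), 1, 2)
  stack <- simulate_image_stack(amp, dim_px = c(31, 31), positions = pos,
                                psf_sigma_px = 1.5)
  det <- detect_spots(stack$frames[1, , ], spot_diameter_px = 4,
                      quality_threshold = 1)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$row_px - 14.3), 0.5)
  expect_lt(abs(det$col_px - 16.7), 0.5)
})

test_that("a 5x5 grid of spots yields exactly 25 detections near truth", {
  pos <- grid_positions(5, 12, 8)
  amp <- matrix(100, nrow = 6, ncol = 25)
  stack <- simulate_image_stack(amp, dim_px = c(64, 64), positions = pos,
                                psf_sigma_px = 1.2)
  det <- detect_spots(stack$frames[1, , ], 4, quality_threshold = 1)
  expect_equal(nrow(det), 25)
  for (i in seq_len(25)) {
    d2 <- (det$row_px - pos[i, 1])^2 + (det$col_px - pos[i, 2])^2
    expect_lt(min(d2), 0.5^2)
  }
})

test_that("blank noisy frames produce no detections at the default threshold", {
  set.seed(19)
  fp <- vapply(1:20, function(i) {
    nrow(detect_spots(matrix(rnorm(64 * 64, 100, 5), 64, 64), 4))
  }, 0)
  # false-positive rate below one spot per 10 frames
  expect_lt(mean(fp), 0.1)
})

test_that("two spots closer than the diameter collapse to one detection", {
  pos <- matrix(c(20, 20, 20, 22.5), 2, 2, byrow = TRUE)
  amp <- matrix(100, 1, 2)
  expect_warning(
    stack <- simulate_image_stack(amp, dim_px = c(41, 41), positions = pos,
                                  psf_sigma_px = 1.2),
    "flagged")
  det <- detect_spots(stack$frames[1, , ], 4, quality_threshold = 1)
  expect_equal(nrow(det), 1)
})

test_that("spot diameter below 2 px is rejected", {
  expect_error(detect_spots(matrix(0, 8, 8), spot_diameter_px = 1), "at least 2")
})

test_that("frame-multiplicative drift is removed by normalisation", {
  set.seed(2)
  amp <- matrix(100, nrow = 30, ncol = 4)
  pos <- grid_positions(2, 20, 12)
  stack <- simulate_image_stack(amp, dim_px = c(48, 48), positions = pos,
                                psf_sigma_px = 1.2)
  drift <- 1 + 0.2 * sin(seq_len(30))
  for (f in 1:30) stack$frames[f, , ] <- (50 + stack$frames[f, , ]) * drift[f]
  norm <- normalize_stack(stack)
  frame_means <- apply(norm$frames, 1, mean)
  expect_lt(diff(range(frame_means)) / mean(frame_means), 0.01)
})

test_that("normalisation is idempotent and preserves an already-flat stack", {
  set.seed(3)
  frames <- array(100 + rnorm(10 * 32 * 32, 0, 2), dim = c(10, 32, 32))
  once <- normalize_stack(frames)
  twice <- normalize_stack(once$frames)
  expect_lt(max(abs(twice$frames - once$frames)), 1e-6 * mean(once$frames))
  # flat input: unchanged up to a global scale
  ratio <- once$frames / frames
  expect_lt(diff(range(ratio)), 0.05)
})

test_that("Gaussian illumination is flattened so spot amplitudes equalise", {
  pos <- grid_positions(3, 16, 8)
  amp <- matrix(100, nrow = 12, ncol = 9)
  stack <- simulate_image_stack(amp, dim_px = c(48, 48), positions = pos,
                                psf_sigma_px = 1.2,
                                illumination_sigma_px = 30)
  stack$frames <- stack$frames + 20 * array(
    rep(stack$illumination, each = 12), dim = dim(stack$frames))
  norm <- normalize_stack(stack)
  peak <- vapply(seq_len(9), function(i)
    max(norm$frames[1, pos[i, 1] + 1 + (-2:2), pos[i, 2] + 1 + (-2:2)]), 0)
  expect_lt((max(peak) - min(peak)) / mean(peak), 0.05)
})

test_that("all-zero frames and short stacks are rejected", {
  frames <- array(1, dim = c(10, 16, 16))
  frames[3, , ] <- 0
  expect_error(normalize_stack(frames), "all zero")
  expect_error(normalize_stack(array(1, dim = c(4, 16, 16))), "at least 8")
})

test_that("noiseless extraction returns traces proportional to amplitudes", {
  amp <- matrix(c(50, 100, 25, 75), ncol = 1)
  pos <- matrix(c(15, 15), 1, 2)
  stack <- simulate_image_stack(amp, dim_px = c(31, 31), positions = pos,
                                psf_sigma_px = 1.2)
  ex <- extract_traces(stack, data.frame(row_px = 15, col_px = 15, quality = 1))
  expect_equal(ex$traces[, 1] / ex$traces[2, 1], amp[, 1] / amp[2, 1],
               tolerance = 1e-10)
})

test_that("an ROI over empty background reports the background level", {
  frames <- array(100, dim = c(8, 31, 31))
  ex <- extract_traces(frames, data.frame(row_px = 5, col_px = 25, quality = 1))
  expect_equal(unname(ex$traces[, 1]), rep(100, 8))
})

test_that("border-crossing ROIs are skipped with a message", {
  frames <- array(100, dim = c(8, 31, 31))
  det <- data.frame(row_px = c(0, 15), col_px = c(0, 15), quality = c(1, 1))
  expect_message(ex <- extract_traces(frames, det), "skipped")
  expect_equal(ncol(ex$traces), 1)
})

test_that("the imaging chain recovers event calls that match ground truth", {
  sim <- simulate_traces(trace_sim_params(
    10, n_frames = 250, tau_bleach_s = 8, i_on = 120, mu_bg = 20,
    sigma_bg = 2, sigma_on = 4, seed = 47))
  pos <- grid_positions(4, 15, 9)[1:10, ]
  stack <- simulate_image_stack(sim, dim_px = c(64, 64), positions = pos,
                                psf_sigma_px = 1.2)
  ex <- extract_traces(stack, detections = data.frame(
    row_px = pos[, 1], col_px = pos[, 2], quality = 1))
  ev <- call_events_all(ex$traces, exposure_s = 0.06)
  for (m in 1:10) {
    # molecules that never photobleach in-window have no background segment,
    # so per-trace thresholding is undefined for them; compare the rest
    if (sim$truth$censored[m]) next
    truth <- truth_events(sim$truth$on_intervals[[m]], 15L)
    called <- ev[[m]]$events
    expect_equal(nrow(called), nrow(truth))
    if (nrow(truth) > 0) {
      expect_true(all(abs(called[, "start"] - truth[, "start"]) <= 2))
      expect_true(all(abs(called[, "end"] - truth[, "end"]) <= 2))
    }
  }
})

test_that("stacks round-trip through 16-bit TIFF", {
  amp <- matrix(c(100, 50, 25), ncol = 1)
  stack <- simulate_image_stack(amp, dim_px = c(16, 16),
                                positions = matrix(c(8, 8), 1, 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(stack, path, scale = 200)
  back <- read_stack_tiff(path, exposure_s = 0.06)
  expect_equal(dim(back$frames), dim(stack$frames))
  expect_equal(back$frames * 200, stack$frames, tolerance = 200 / 65535)
})
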