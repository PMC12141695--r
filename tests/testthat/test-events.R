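test_that("a single on-period gives one event with the expected lifetime", {
  # on for frames [0, 200), then photobleached background
  x <- c(rep(200, 200), rep(100, 300))
  ev <- call_events(x, mu_bg = 100, sigma_bg = 5, k_sigma = 10,
                    exposure_s = 0.06)
  expect_equal(ev$n_blinks, 1)
  expect_equal(unname(ev$events[1, ]), c(0, 200))
  expect_equal(ev$bleach_lifetime_s, 12.0)
  expect_equal(ev$cumulative_on_s, 12.0)
})

test_that("gaps below the 15-frame window merge events; larger gaps do not", {
  on <- function(n) rep(200, n); off <- function(n) rep(100, n)
  x10 <- c(on(30), off(10), on(30), off(100))
  x20 <- c(on(30), off(20), on(30), off(100))
  e10 <- call_events(x10, 100, 5)
  e20 <- call_events(x20, 100, 5)
  expect_equal(e10$n_blinks, 1)
  expect_equal(unname(e10$events[1, ]), c(0, 70))  # gap absorbed
  expect_equal(e20$n_blinks, 2)
  expect_equal(unname(e20$events[, "start"]), c(0, 50))
  # a 15-frame gap is not below the window: two events
  e15 <- call_events(c(on(30), off(15), on(30), off(100)), 100, 5)
  expect_equal(e15$n_blinks, 2)
})

test_that("events shorter than the window are discarded after merging", {
  x <- c(rep(200, 10), rep(100, 400))  # 10-frame blip only
  ev <- call_events(x, 100, 5)
  expect_equal(ev$n_blinks, 0)
  expect_equal(ev$bleach_lifetime_s, 0)
  expect_equal(ev$cumulative_on_s, 0)
})

test_that("event calling is invariant to affine intensity rescaling", {
  sim <- simulate_traces(trace_sim_params(5, n_frames = 600,
                                          tau_bleach_s = 15, seed = 13))
  for (m in 1:5) {
    x <- sim$intensities[, m]
    y <- 3.7 * x + 50
    bx <- background_stats(segment_trace(x))
    by <- background_stats(segment_trace(y))
    ex <- call_events(x, bx$mu_bg, bx$sigma_bg)
    ey <- call_events(y, by$mu_bg, by$sigma_bg)
    expect_identical(ex$events, ey$events)
  }
})

test_that("cumulative on-time never exceeds lifetime nor the span", {
  sim <- simulate_traces(trace_sim_params(40, n_frames = 800,
                                          tau_bleach_s = 20, seed = 29))
  ev <- call_events_all(sim)
  span <- 800 * 0.06
  for (e in ev) {
    expect_lte(e$cumulative_on_s, e$bleach_lifetime_s + 1e-12)
    expect_lte(e$bleach_lifetime_s, span + 1e-12)
    if (e$n_blinks > 1) {
      expect_true(all(diff(e$events[, "start"]) > 0))
      expect_true(all(e$events[-1, "start"] >= e$events[-nrow(e$events), "end"]))
    }
  }
})

test_that("called event boundaries match ground truth at high SNR", {
  sim <- simulate_traces(trace_sim_params(
    120, n_frames = 600, tau_bleach_s = 15, k_on_per_s = 0.5,
    k_off_per_s = 0.2, i_on = 100, mu_bg = 100, sigma_bg = 5, sigma_on = 10,
    seed = 41))
  ev <- call_events_all(sim)
  n_match <- 0L; n_total <- 0L
  for (m in seq_along(ev)) {
    truth <- truth_events(sim$truth$on_intervals[[m]], 15L)
    called <- ev[[m]]$events
    for (r in seq_len(nrow(truth))) {
      n_total <- n_total + 1L
      ok <- any(abs(called[, "start"] - truth[r, "start"]) <= 2 &
                  abs(called[, "end"] - truth[r, "end"]) <= 2)
      if (isTRUE(ok)) n_match <- n_match + 1L
    }
  }
  expect_gt(n_total, 100)
  expect_gte(n_match / n_total, 0.95)
})

test_that("thresholding the CK-filtered trace is available as an option", {
  x <- c(rep(200, 100), rep(100, 200)) + rnorm(300, 0, 3)
  set.seed(2)
  bg <- background_stats(segment_trace(x))
  raw <- call_events(x, bg$mu_bg, bg$sigma_bg)
  filt <- call_events(x, bg$mu_bg, bg$sigma_bg, use_filtered = TRUE)
  expect_equal(raw$n_blinks, 1)
  expect_equal(filt$n_blinks, 1)
})

test_that("event sets survive a JSON round-trip", {
  sim <- simulate_traces(trace_sim_params(4, n_frames = 300,
                                          tau_bleach_s = 8, seed = 55))
  ev <- call_events_all(sim)
  path <- withr::local_tempfile(fileext = ".json")
  write_event_sets(ev, path)
  back <- read_event_sets(path)
  expect_equal(length(back), 4)
  for (i in 1:4) {
    expect_equal(unname(back[[i]]$events), unname(ev[[i]]$events),
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$bleach_lifetime_s, ev[[i]]$bleach_lifetime_s)
    expect_equal(back[[i]]$cumulative_on_s, ev[[i]]$cumulative_on_s)
  }
})
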