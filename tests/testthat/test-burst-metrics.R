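test_that("Lorentzian width recovers a known Cauchy scale and matches an MLE oracle", {
  set.seed(1)
  s <- rcauchy(4000, location = 100, scale = 12)
  fit <- fit_lorentzian_width(s)
  expect_lt(abs(fit$width - 12) / 12, 0.10)
  oracle <- MASS::fitdistr(s, "cauchy")
  expect_lt(abs(fit$scale - oracle$estimate[["scale"]]), 0.05)
  expect_lt(abs(fit$location - oracle$estimate[["location"]]), 0.05)
})

test_that("Gaussian background yields the documented HWHM-matched width", {
  set.seed(2)
  g <- rnorm(4000, 0, 10)
  fit <- fit_lorentzian_width(g)
  oracle <- suppressWarnings(MASS::fitdistr(g, "cauchy"))
  expect_lt(abs(fit$scale - oracle$estimate[["scale"]]), 0.05)
  # Cauchy MLE scale on a Gaussian sample sits near 0.61-0.63 sigma (~6.3 for sigma 10)
  expect_gt(fit$scale, 5.5)
  expect_lt(fit$scale, 7.0)
  # sigma mode converts through the common HWHM
  expect_equal(fit_lorentzian_width(g, mode = "sigma")$width,
               fit$scale / sqrt(2 * log(2)), tolerance = 1e-6)
  # constant background collapses to width 0
  expect_equal(fit_lorentzian_width(rep(5, 100))$width, 0)
})

test_that("background estimation pools four ring points and falls back when starved", {
  set.seed(3)
  st <- array(rnorm(40 * 40 * 30, 100, 8), c(40, 40, 30))
  trace <- structure(list(cell_id = 1, intensity = rep(1, 30),
                          x = rep(20, 30), y = rep(20, 30),
                          tier = factor(rep("primary", 30),
                                        levels = c("primary", "fallback", "carried-over")),
                          end_frame = 30L, no_ts = FALSE, frame_interval = 15),
                     class = "intensity_trace")
  w <- estimate_background_sd(st, trace, ring_distance = 5)
  expect_gt(as.numeric(w), 3); expect_lt(as.numeric(w), 8)  # ~0.61 * 8
  expect_equal(attr(w, "fit")$n, 120)
  # positions missing everywhere -> too few samples -> global sd fallback
  trace$x <- rep(NA_real_, 30); trace$y <- rep(NA_real_, 30)
  expect_warning(w2 <- estimate_background_sd(st, trace), "global image s.d.")
  expect_equal(as.numeric(w2), sd(as.vector(st)), tolerance = 1e-9)
})

test_that("binarization applies threshold then the two cleanup rules in order", {
  x <- c(0, 1, 0, 0, 1, 1, 0, 1, 1, 0) * 10
  b <- binarize(structure(x, frame_interval = 15), bg_width = 1)
  expect_equal(as.logical(b), as.logical(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0)))
  # all sub-threshold -> inactive
  expect_false(any(binarize(structure(rep(0.1, 10), frame_interval = 15), 1)))
  # alternating frames: deletion precedes merging, so everything dies
  expect_false(any(binarize(structure(rep(c(10, 0), 5), frame_interval = 15), 1)))
  # merge-first order would instead keep the alternating run
  expect_true(any(binarize(structure(rep(c(10, 0), 5), frame_interval = 15), 1,
                           cleanup_order = "merge_first")))
})

test_that("cleanup is idempotent over random traces", {
  set.seed(4)
  for (i in 1:50) {
    v <- runif(60) > 0.6
    once <- burstepi:::merge_single_gaps(burstepi:::delete_single_frame_bursts(v))
    twice <- burstepi:::merge_single_gaps(burstepi:::delete_single_frame_bursts(once))
    expect_identical(once, twice)
  }
})

test_that("burst records compute induction, durations and inter-burst times", {
  on <- rep(FALSE, 40); on[13:20] <- TRUE     # frame 13 at t = 3 min, 8 frames ON
  r <- extract_burst_record(as_binary(on), as.numeric(on) * 100)
  expect_equal(r$induction_time, 3.0)
  expect_equal(r$burst_durations, 2.0)
  expect_equal(r$burst_intensity, 100)
  # dead-time offset shifts induction only
  r_off <- extract_burst_record(as_binary(on), as.numeric(on), t_acquisition_offset = 5)
  expect_equal(r_off$induction_time, 8.0)
  # two bursts separated by 8 OFF frames -> inter-burst 2 min
  on2 <- rep(FALSE, 40); on2[5:8] <- TRUE; on2[17:20] <- TRUE
  r2 <- extract_burst_record(as_binary(on2), as.numeric(on2))
  expect_equal(r2$inter_burst_times, 2.0)
  expect_equal(length(r2$burst_durations), 2L)
  # trailing burst is right-censored and excluded from durations
  on3 <- rep(FALSE, 20); on3[15:20] <- TRUE
  r3 <- extract_burst_record(as_binary(on3), as.numeric(on3))
  expect_equal(r3$n_censored, 1L)
  expect_length(r3$burst_durations, 0)
  # inactive cell
  r0 <- extract_burst_record(as_binary(rep(FALSE, 10)), rep(0, 10))
  expect_false(r0$active)
  expect_length(r0$inter_burst_times, 0)
})

test_that("population bootstrap has the right degenerate and CLT behaviour", {
  mk <- function(ind) structure(list(cell_id = 1, active = TRUE, induction_time = ind,
                                     burst_durations = numeric(0),
                                     inter_burst_times = numeric(0),
                                     burst_intensity = NA_real_, n_censored = 0L),
                                class = "burst_record")
  # identical values: bootstrap mean equals the value, sd 0
  s <- summarize_population(lapply(1:20, function(i) mk(5)), n_boot = 200, seed = 1,
                            parameters = "induction_time")
  expect_equal(s$parameters$induction_time$mean, 5)
  expect_equal(s$parameters$induction_time$sd, 0)
  # exponential sample: bootstrap sd ~ sample sd / sqrt(n) within 15%
  set.seed(5)
  v <- rexp(200, 1 / 8)
  s2 <- summarize_population(lapply(v, mk), n_boot = 1000, seed = 2,
                             parameters = "induction_time")
  expect_lt(abs(s2$parameters$induction_time$sd - sd(v) / sqrt(200)) /
              (sd(v) / sqrt(200)), 0.15)
  # counts and sqrt(n) errors on the active fraction
  recs <- c(lapply(rep(5, 40), mk),
            lapply(1:60, function(i) {
              r <- mk(NA_real_); r$active <- FALSE; r
            }))
  s3 <- summarize_population(recs, n_boot = 50, seed = 3)
  expect_equal(s3$n_active, 40); expect_equal(s3$n_inactive, 60)
  expect_equal(s3$active_fraction, 0.40)
  expect_equal(s3$active_fraction_sd,
               sqrt(60^2 * 40 + 40^2 * 60) / 100^2, tolerance = 1e-12)
})

test_that("bursting parameters are recovered on simulated populations", {
  p <- burst_sim_params(n_steps = 3, step_rate = 0.5, mean_on = 2, mean_off = 8,
                        frame_interval = 15, movie_length = 60, active_prob = 1,
                        mean_intensity = 1000, bg_sd = 20, seed = 101)
  sim <- simulate_traces(p, 300)
  recs <- burst_records(sim$traces, bg_width = p$bg_sd)
  s <- summarize_population(recs, n_boot = 1000, seed = 5)
  truth <- summarize_population(discretize_truth(sim$truth, p$frame_interval),
                                n_boot = 1000, seed = 6)
  for (par in c("induction_time", "burst_duration", "inter_burst_time")) {
    expect_lt(abs(s$parameters[[par]]$mean - truth$parameters[[par]]$mean) /
                truth$parameters[[par]]$mean, 0.10)
  }
})
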