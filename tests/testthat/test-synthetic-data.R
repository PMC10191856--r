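test_that("parameter validation rejects inconsistent bursting parameters", {
  expect_error(burst_sim_params(mean_on = -1), "mean_on")
  expect_error(burst_sim_params(active_prob = 1.2), "active_prob")
  expect_error(burst_sim_params(frame_interval = 17), "divide")
  expect_s3_class(burst_sim_params(), "burst_sim_params")
})

test_that("simulated traces are byte-identical under a fixed seed", {
  p <- burst_sim_params(seed = 42)
  expect_identical(simulate_traces(p, 25), simulate_traces(p, 25))
  p2 <- burst_sim_params(seed = 43)
  expect_false(identical(simulate_traces(p, 25)$traces$intensity,
                         simulate_traces(p2, 25)$traces$intensity))
})

test_that("induction times follow the Gamma of sequential activation steps", {
  # single step: exponential with mean 1/rate = 2 min
  p <- burst_sim_params(n_steps = 1, step_rate = 0.5, active_prob = 1,
                        movie_length = 60, seed = 7)
  sim <- simulate_traces(p, 10000)
  ind <- sim$truth$induction_time
  se <- 2 / sqrt(10000)
  expect_lt(abs(mean(ind) - 2), 3 * se)
  # multi-step: Gamma moments (mean k/rate, var k/rate^2, skewness 2/sqrt(k))
  p3 <- burst_sim_params(n_steps = 4, step_rate = 0.5, active_prob = 1, seed = 8)
  ind3 <- simulate_traces(p3, 10000)$truth$induction_time
  expect_lt(abs(mean(ind3) - 8), 4 * sqrt(4 / 0.25 / 10000))
  expect_lt(abs(var(ind3) - 16), 0.1 * 16)
  skew <- mean((ind3 - mean(ind3))^3) / sd(ind3)^3
  expect_lt(abs(skew - 1), 0.15)
})

test_that("dwell times in the ground truth match the generative means", {
  p <- burst_sim_params(mean_on = 2, mean_off = 8, movie_length = 480,
                        frame_interval = 30, active_prob = 1, seed = 11)
  sim <- simulate_traces(p, 150)
  drop_last <- function(iv, which_cens, state) {
    # exclude the movie-end-truncated interval from the mean
    unlist(lapply(seq_along(iv), function(i) {
      v <- iv[[i]]
      if (isTRUE(which_cens[i]) && identical(state[i], TRUE) && length(v) > 0)
        v <- v[-length(v)]
      v
    }))
  }
  tr <- sim$truth
  on <- drop_last(tr$on_intervals, tr$last_interval_censored,
                  tr$censored_state == "on")
  off <- drop_last(tr$off_intervals, tr$last_interval_censored,
                   tr$censored_state == "off")
  expect_gt(length(on), 5000)
  expect_lt(abs(mean(on) - 2) / 2, 0.05)
  expect_lt(abs(mean(off) - 8) / 8, 0.05)
})

test_that("ground-truth intervals tile the movie", {
  p <- burst_sim_params(active_prob = 1, seed = 3)
  sim <- simulate_traces(p, 50)
  tr <- sim$truth
  for (i in seq_len(50)) {
    if (!tr$active[i] || tr$induction_time[i] >= p$movie_length) next
    tot <- tr$induction_time[i] + sum(tr$on_intervals[[i]]) +
      sum(tr$off_intervals[[i]])
    expect_lt(abs(tot - p$movie_length), p$frame_interval / 60 + 1e-9)
  }
  # state series consistent with intervals: ON time = sum of ON dwells +/- frame
  dt <- p$frame_interval / 60
  for (i in which(tr$active & tr$induction_time < p$movie_length)) {
    expect_lt(abs(sum(tr$state[, i]) * dt - sum(tr$on_intervals[[i]])),
              (1 + length(tr$on_intervals[[i]])) * dt)
  }
})

test_that("inactive populations generate background-only traces", {
  p <- burst_sim_params(active_prob = 0, bg_sd = 5, seed = 2)
  sim <- simulate_traces(p, 30)
  expect_false(any(sim$truth$active))
  expect_true(all(sim$traces$spot_intensity == 0))
  recs <- burst_records(sim$traces, bg_width = 5)
  s <- summarize_population(recs, n_boot = 50, seed = 1)
  expect_equal(s$active_fraction, 0)
})

test_that("rendered movies carry one quantifiable spot per ON cell", {
  # near-instant induction guarantees ON frames inside the short fixture
  p <- burst_sim_params(n_steps = 1, step_rate = 50, mean_on = 5,
                        active_prob = 1, intensity_cv = 0, movie_length = 2,
                        seed = 21)
  sim <- simulate_traces(p, 2)
  mv <- render_movie(sim$traces, psf_sigma = 1.3, noise_sd = 0, bg_level = 10,
                     seed = 4)
  k <- which(sim$traces$spot_intensity[, 1] > 0)[1]
  expect_false(is.na(k))
  fit <- gaussian_mask_fit(mv$data[, , k], mv$spot_xy[1, 1], mv$spot_xy[1, 2])
  expect_lt(abs(fit$intensity - sim$traces$spot_intensity[k, 1]) /
              sim$traces$spot_intensity[k, 1], 0.01)
  # OFF frames have no pixel above background + 6 x noise floor
  k0 <- which(sim$traces$spot_intensity[, 1] == 0)[1]
  if (!is.na(k0)) {
    tile <- mv$data[, , k0][unclass(mv$masks) == 1]
    expect_true(all(tile <= 10 + 1e-9))
  }
})

test_that("smFISH simulator produces the stated cell-table structure", {
  sm <- simulate_smfish(500, ts_nascent = 7, seed = 31)
  expect_equal(nrow(sm$cells), 500)
  # one nuclear TS per cell at nascent x unit
  nuc <- sm$spots[sm$spots$compartment == "nuclear", ]
  expect_equal(nrow(nuc), 500)
  expect_equal(nuc$intensity, sm$cells$nascent_true * sm$unit_intensity)
  # cytoplasmic intensities scatter around a unit median
  cyto <- sm$spots$intensity[sm$spots$compartment == "cytoplasmic"]
  expect_lt(abs(median(cyto) / sm$unit_intensity - 1), 0.05)
  expect_warning(simulate_smfish(50, dapi_model = list(means = c(1e5, 1e5),
                                                       sds = c(5e3, 5e3))),
                 "degenerate")
  expect_identical(simulate_smfish(100, seed = 5), simulate_smfish(100, seed = 5))
})

test_that("MNase simulator plants recoverable nucleosomes", {
  mod <- nuc_sim_model(c(chrT = 2000),
                       data.frame(chrom = "chrT", center = 1000, occupancy = 1),
                       n_fragments = 10000, seed = 17)
  fr <- simulate_mnase(mod)
  expect_identical(fr, simulate_mnase(mod))
  cov <- make_coverage(fr, c(chrT = 2000))
  sm <- smooth_gaussian(cov$norm$chrT, fwhm = 40)
  expect_lt(abs(which.max(sm) - 1 - 1000), 10)
  # lengths respect the truncation bounds
  len <- fr$end - fr$start
  expect_true(all(len >= 50 & len <= 301))
  expect_error(nuc_sim_model(c(chrT = 2000),
                             data.frame(chrom = "chrT", center = 1000,
                                        occupancy = 0)), "occupancy")
  expect_error(nuc_sim_model(c(chrT = 2000),
                             data.frame(chrom = "chrT", center = 5000,
                                        occupancy = 1)), "bounds")
})
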