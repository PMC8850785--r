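# Synthetic population, threshold law, and raw-trial simulators.

test_that("population sampling honors counts, boundaries and determinism", {
  pop <- sample_population(40, 0.6, seed = 1)
  expect_equal(sum(pop$gender_code == 1), 24)
  expect_equal(sum(pop$gender_code == 0), 16)

  all_female <- sample_population(41, 0, seed = 7)
  expect_equal(sum(all_female$gender_code), 0)
  expect_equal(nrow(all_female), 41)

  expect_identical(sample_population(20, 0.5, seed = 3),
                   sample_population(20, 0.5, seed = 3))

  expect_error(sample_population(0, 0.5, seed = 1),
               class = "painlimits_invalid_argument")
  expect_error(sample_population(10, 1.5, seed = 1),
               class = "painlimits_invalid_argument")
})

test_that("threshold quantile function matches closed forms", {
  expect_equal(loglogistic_quantile(0.5, 4.22, 0, 0.46), exp(4.22),
               tolerance = 1e-12)
  expect_equal(loglogistic_quantile(0.75, 4.22, 0, 0.46),
               112.77, tolerance = 1e-4)
  expect_error(loglogistic_quantile(0, 4, 0, 0.3),
               class = "painlimits_domain_error")
  expect_error(loglogistic_quantile(0.5, 4, 0, -0.1),
               class = "painlimits_invalid_argument")
})

test_that("threshold draws follow the expanded log-logistic law", {
  y <- draw_threshold(1e5, 3.0, 0.5, 0.3, gender_code = 1, seed = 42)
  expect_equal(median(y), exp(3.5), tolerance = 0.3 / exp(3.5))

  # probability integral transform of 1e4 draws is uniform (KS distance)
  y2 <- draw_threshold(1e4, 4.0, 0, 0.3, gender_code = 0, seed = 43)
  u <- expanded_cdf(y2, x_G = 0, beta0 = 4.0, beta1 = 0, alpha = 0.3)
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 0.02)

  expect_identical(draw_threshold(50, 4, 0.3, 0.2, gender_code = 1, seed = 9),
                   draw_threshold(50, 4, 0.3, 0.2, gender_code = 1, seed = 9))
})

test_that("algometer trial fires the event at threshold/slope", {
  proto <- make_protocol(c_H = 50000, noise_sd = 0)
  tr <- simulate_algometer_trial(50, proto, baseline = 1)
  # slope = 50 N/s, so the event is 1.0 s after contact, 2.0 s absolute
  expect_equal(tr$data$time_s[tr$event_index], 2.0, tolerance = 1e-9)
  expect_equal(tr$data$f_N[tr$event_index], 50, tolerance = 1e-9)

  # sensor offset shifts the raw baseline but not the processed observation
  tr2 <- simulate_algometer_trial(50, make_protocol(50000, offset = 2))
  baseline <- tr2$data$f_N[tr2$data$time_s < 1]
  expect_equal(mean(baseline), 2, tolerance = 1e-9)
  cleaned <- eliminate_offset(as_force_signal(tr2))
  expect_equal(max_contact_force(cleaned, "algometer"), 50, tolerance = 1e-6)

  expect_error(simulate_algometer_trial(1e6, proto, max_duration = 5),
               class = "painlimits_simulation_limit")
})

test_that("noisy algometer force-at-event stays near threshold", {
  proto <- make_protocol(c_H = 50000, noise_sd = 0.5)
  vals <- vapply(1:100, function(s) {
    tr <- simulate_algometer_trial(50, proto, seed = 1000 + s)
    sig <- eliminate_offset(as_force_signal(tr))
    max_contact_force(sig, "algometer")
  }, numeric(1))
  expect_true(all(abs(vals - 50) < 2))
})

test_that("pendulum staircase brackets the threshold", {
  # peak = sqrt(16.5 * 1.19e6) * v = 4431 * v; pain at the second trial
  proto <- make_protocol(c_H = 1.19e6, noise_sd = 0, step = 0.05,
                         start = 0.005)
  st <- simulate_pendulum_staircase(140, proto, masses = 16.5)
  expect_equal(nrow(st), 2)
  expect_equal(st$pain, c(FALSE, TRUE))
  iv <- intervals_from_staircase(
    tibble::tibble(peak = st$peak_true, pain = st$pain))
  expect_equal(iv$censor_type, "interval")
  expect_equal(iv$L, 22.2, tolerance = 0.01)
  expect_equal(iv$R, 243.7, tolerance = 0.001)

  # threshold below the first-trial peak: single painful trial (left-censored)
  st_lo <- simulate_pendulum_staircase(10, proto, masses = 16.5)
  expect_equal(nrow(st_lo), 1)
  expect_true(st_lo$pain)

  # threshold above the peak at the 1.25 m/s cap: no pain (right-censored)
  st_hi <- simulate_pendulum_staircase(6000, proto, masses = 16.5)
  expect_false(any(st_hi$pain))
  expect_equal(max(st_hi$velocity), 1.205, tolerance = 1e-9)

  expect_error(simulate_pendulum_staircase(-1, proto),
               class = "painlimits_invalid_argument")
})

test_that("noiseless staircases always bracket the true threshold", {
  proto <- make_protocol(c_H = 5e5, noise_sd = 0)
  thresholds <- seq(30, 900, length.out = 25)
  for (thr in thresholds) {
    st <- simulate_pendulum_staircase(thr, proto, masses = 16.5)
    iv <- intervals_from_staircase(
      tibble::tibble(peak = st$peak_true, pain = st$pain))
    if (iv$censor_type == "interval") {
      expect_lt(iv$L, thr)
      expect_gte(iv$R, thr)
    } else if (iv$censor_type == "left") {
      expect_gte(iv$R, thr)
    } else {
      expect_lt(iv$L, thr)
    }
  }
})

test_that("staircases are bit-reproducible for a fixed seed", {
  proto <- make_protocol(c_H = 5e5, noise_sd = 0.5)
  expect_identical(simulate_pendulum_staircase(140, proto, seed = 7),
                   simulate_pendulum_staircase(140, proto, seed = 7))
})

test_that("pressure frames integrate to the contact force before masking", {
  geom <- film_geometry()
  stk <- simulate_pressure_frames(100, geom, profile = "uniform",
                                  quantize = FALSE)
  covered <- stk$frames[[1]][geom$coverage]
  expect_equal(mean(covered), 100 / 1.96, tolerance = 1e-9)
  # blind spots are zeroed, so the masked integral falls short of the force
  expect_lt(sum(stk$frames[[1]]) * geom$sensel_area_cm2, 100)

  expect_error(simulate_pressure_frames(c(10, 20), geom, times = 0),
               class = "painlimits_invalid_argument")
})
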