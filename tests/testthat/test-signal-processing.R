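# Channel-class filtering, offset elimination, inertia compensation,
# maximum contact force.

make_signal <- function(f, fs = 1e4, event_index = NA, m_B = NA, m_I = NA) {
  force_signal(tibble::tibble(time_s = (seq_along(f) - 1) / fs, f_N = f),
               sampling_rate = fs, event_index = event_index,
               m_B = m_B, m_I = m_I)
}

test_that("channel-class filter has unity DC gain and zero phase", {
  sig <- make_signal(rep(50, 2000))
  out <- cfc_filter(sig, "CFC100")
  expect_equal(out$data$f_N, rep(50, 2000), tolerance = 1e-6)
  # away from the edges the startup transient has fully decayed
  expect_equal(out$data$f_N[500:1500], rep(50, 1001), tolerance = 1e-10)

  # symmetric pulse keeps its peak sample under the zero-phase filter
  tri <- c(rep(0, 900), seq(0, 100, length.out = 101),
           seq(100, 0, length.out = 101)[-1], rep(0, 900))
  ftri <- cfc_filter(make_signal(tri), "CFC100")
  expect_equal(which.max(ftri$data$f_N), which.max(tri))
})

test_that("filter attenuation at the cutoff matches the two-pass design", {
  fs <- 1e4
  t <- (0:(2 * fs)) / fs
  x <- sin(2 * pi * 165 * t)
  out <- cfc_filter(make_signal(x, fs), "CFC100")
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  amp <- sqrt(2) * sd(out$data$f_N[mid])
  # net |H|^2 = 1/2 at the -3 dB cutoff of each pass
  expect_equal(amp, 0.5, tolerance = 0.01)
})

test_that("filtering is linear", {
  set.seed(5)
  a <- rnorm(1500)
  b <- cumsum(rnorm(1500)) / 10
  fa <- cfc_filter(make_signal(a), "CFC100")$data$f_N
  fb <- cfc_filter(make_signal(b), "CFC100")$data$f_N
  fab <- cfc_filter(make_signal(a + b), "CFC100")$data$f_N
  expect_equal(fab, fa + fb, tolerance = 1e-9)
})

test_that("filter rejects invalid inputs", {
  expect_error(cfc_filter(make_signal(rep(1, 30), fs = 100), "CFC100"),
               class = "painlimits_invalid_argument") # cutoff above Nyquist
  expect_error(cfc_filter(make_signal(rep(1, 10)), "CFC100"),
               class = "painlimits_invalid_argument") # too short
})

test_that("offset elimination zeroes the baseline and finds the onset", {
  proto <- make_protocol(c_H = 5e5, noise_sd = 0, offset = 2)
  tr <- simulate_algometer_trial(50, proto, baseline = 1)
  sig <- eliminate_offset(as_force_signal(tr))
  pre <- sig$data$f_N[sig$data$time_s < 0.5]
  expect_lt(mean(abs(pre)), 0.01)
  expect_true(sig$offset_removed)

  flat <- make_signal(rep(0, 3000))
  expect_error(eliminate_offset(flat), class = "painlimits_no_contact")
})

test_that("onset detection is accurate under baseline noise", {
  proto <- make_protocol(c_H = 5e5, noise_sd = 0.5)
  onsets <- vapply(1:100, function(s) {
    tr <- simulate_algometer_trial(50, proto, baseline = 1, seed = 2000 + s)
    sig <- eliminate_offset(as_force_signal(tr))
    tr$data$time_s[sig$onset_index]
  }, numeric(1))
  expect_true(all(abs(onsets - 1.0) <= 0.05))
})

test_that("inertia compensation applies V_f = 1 + m_I/m_B exactly once", {
  sig <- make_signal(rep(100, 100), m_B = 2, m_I = 0.5)
  out <- compensate_inertia(sig)
  expect_equal(out$data$f_N, rep(125, 100))
  expect_error(compensate_inertia(out),
               class = "painlimits_invalid_argument")

  ident <- compensate_inertia(make_signal(rep(100, 100), m_B = 2, m_I = 0))
  expect_equal(ident$data$f_N, rep(100, 100))

  expect_error(compensate_inertia(make_signal(rep(1, 10))),
               class = "painlimits_invalid_argument") # missing masses
})

test_that("maximum contact force is the norm maximum, truncated for ramps", {
  tri <- force_signal(
    tibble::tibble(time_s = (0:99) / 100, fx_N = rep(3, 100),
                   fy_N = rep(4, 100), fz_N = rep(0, 100)),
    sampling_rate = 100)
  expect_equal(max_contact_force(tri, "impact"), 5)

  ramp <- make_signal(seq(0, 100, length.out = 101), fs = 100,
                      event_index = 81)
  expect_equal(max_contact_force(ramp, "algometer"), 80)
  expect_equal(max_contact_force(ramp, "impact"), 100)
  ramp$event_index <- NA
  expect_error(max_contact_force(ramp, "algometer"),
               class = "painlimits_missing_event")
})

test_that("impact conditioning recovers the tip peak force", {
  proto <- make_protocol(c_H = 2e5, noise_sd = 0.5)
  peaks <- vapply(1:100, function(s) {
    tr <- simulate_impact_trial(140, proto, mass = 16.5, m_I = 0.3,
                                seed = 3000 + s)
    sig <- as_force_signal(tr)
    sig <- cfc_filter(sig, "CFC100")
    sig <- eliminate_offset(sig)
    sig <- compensate_inertia(sig)
    max_contact_force(sig, "impact")
  }, numeric(1))
  expect_true(all(abs(peaks - 140) < 1.5))
})

test_that("force norm is invariant under axis rotation", {
  proto <- make_protocol(c_H = 2e5, noise_sd = 0)
  tr <- simulate_impact_trial(140, proto)
  sig <- as_force_signal(tr)
  th <- 0.7
  rot <- sig
  rot$data$fx_N <- cos(th) * sig$data$fx_N - sin(th) * sig$data$fy_N
  rot$data$fy_N <- sin(th) * sig$data$fx_N + cos(th) * sig$data$fy_N
  expect_equal(max_contact_force(rot, "impact"),
               max_contact_force(sig, "impact"), tolerance = 1e-9)
})
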