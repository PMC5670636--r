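flat_trace <- function(n = 200, level = 9, dt = 0.005, do_sat = 9.08) {
  respirogram_trace(seq(0, by = dt, length.out = n), rep(level, n),
                    do_sat = do_sat)
}

test_that("smoothing preserves constants and interior linear ramps", {
  tr <- flat_trace()
  for (m in c("moving-average", "polynomial-filter"))
    expect_equal(smooth_trace(tr, 5, m)$do_signal, tr$do_signal)

  ramp <- respirogram_trace(seq(0, 1, by = 0.01), seq(9, 7, length.out = 101),
                            do_sat = 9.08)
  sm <- smooth_trace(ramp, 7, "moving-average")
  expect_equal(sm$do_signal[4:98], ramp$do_signal[4:98], tolerance = 1e-12)

  # as the window approaches the trace length, pure noise shrinks to its mean
  set.seed(1)
  y <- 5 + stats::rnorm(301, 0, 0.3)
  noisy <- respirogram_trace(seq(0, 3, by = 0.01), pmax(y, 0), do_sat = 9.08)
  sm2 <- smooth_trace(noisy, 299, "moving-average")
  mid <- sm2$do_signal[150]
  expect_equal(mid, mean(noisy$do_signal), tolerance = 0.01)

  expect_error(smooth_trace(tr, 4), "odd")
  expect_error(smooth_trace(tr, 1), "odd")
  expect_error(smooth_trace(tr, 9999), "odd|smaller")
})

test_that("segmentation finds one recovering segment per addition", {
  tr <- piecewise_trace()
  segs <- segment_events(tr, addition_times = tr$additions)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$t_start, tr$additions, tolerance = 0.01)
  expect_true(all(segs$t_end > segs$t_start))
  expect_true(all(segs$t_end[1:2] < tr$additions[2:3]))
  expect_equal(segs$baseline_do, rep(9, 3), tolerance = 1e-6)

  # detection mode on the same trace recovers the same starts
  det <- segment_events(tr, delta = 0.3)
  expect_equal(nrow(det), 3)
  expect_equal(det$t_start, segs$t_start, tolerance = 0.03)

  # a flat trace contains no events
  expect_equal(nrow(segment_events(flat_trace(), delta = 0.3)), 0)

  # a drop that never comes back up is reported as unterminated
  n <- 200
  sink <- respirogram_trace(seq(0, by = 0.005, length.out = n),
                            c(rep(9, 20), seq(9, 4, length.out = n - 20)),
                            do_sat = 9.08)
  expect_error(segment_events(sink, addition_times = 0.1), "restabilize")
})

test_that("detected pulse times on simulated traces match the schedule", {
  sc <- substrate_scenario("peptone")
  sim <- simulate_respirogram(sc)
  det <- segment_events(smooth_trace(sim$trace, 21, "polynomial-filter"),
                        addition_times = NULL, delta = 0.3)
  expect_equal(nrow(det), 3)
  expect_equal(det$t_start, sim$truth$t_pulse, tolerance = 0.02)
})

test_that("R_S modes agree with closed-form segments", {
  const <- reactor_constants(kla = 10)
  # DO declining linearly at 3 mg/L/h: derivative mode reads the slope
  n <- 61
  tt <- seq(0, 0.3, length.out = n)
  tr <- respirogram_trace(tt, 9 - 3 * tt, do_sat = 9.08)
  rs <- compute_rs(tr, 0, 0.3, baseline_do = 9, const, mode = "derivative")
  expect_equal(rs$rs, rep(3, n), tolerance = 1e-9)

  # constant DO at baseline: both modes report zero uptake
  tr0 <- flat_trace(level = 9)
  for (m in c("derivative", "mass-balance")) {
    rs0 <- compute_rs(tr0, 0, 1, baseline_do = 9, const, mode = m)
    expect_equal(rs0$rs, rep(0, nrow(rs0)))
  }

  expect_error(compute_rs(tr, 0, 0.3, 9, reactor_constants(), "mass-balance"),
               "kla")
})

test_that("mass-balance R_S recovers the simulator's uptake at the peak", {
  sc <- substrate_scenario("sodium_acetate", noise_sd = 0)
  sim <- simulate_respirogram(sc)
  ev <- process_trace(sim$trace, sc$pulse_schedule,
                      constants = reactor_constants(kla = sc$kla),
                      mode = "mass-balance", x_t = sim$truth$x0)
  q <- 1 - sc$f_cv * sc$y_tss_true
  true_peak <- q * sim$truth$mu_true * sim$truth$x0 / sc$y_tss_true
  expect_equal(vapply(ev, `[[`, numeric(1), "rs_peak"), true_peak,
               tolerance = 0.05)
})

test_that("OC integrates R_S: rectangle, triangle, and the COD balance", {
  expect_equal(compute_oc(data.frame(time = c(0, 1.5, 3), rs = c(2, 2, 2))), 6)
  tt <- seq(0, 2, length.out = 2001)
  tri <- data.frame(time = tt, rs = 2 * tt) # rises 0 -> 4 over 2 h
  expect_equal(compute_oc(tri), 4, tolerance = 1e-5)
  expect_error(compute_oc(data.frame(time = 0, rs = 1)), "fewer than 2")

  # a full event's OC matches (1 - Y_O2) * S from the COD balance
  sc <- substrate_scenario("glucose", noise_sd = 0)
  sim <- simulate_respirogram(sc)
  ev <- process_trace(sim$trace, sc$pulse_schedule,
                      constants = reactor_constants(kla = sc$kla),
                      mode = "mass-balance", x_t = sim$truth$x0)
  oc <- vapply(ev, `[[`, numeric(1), "oc")
  expect_equal(oc, sim$truth$oc_true, tolerance = 0.02)
})

test_that("OC is stable under sampling-rate doubling and scales linearly", {
  rs_fun <- function(t) 4 * exp(-((t - 0.5) / 0.15)^2)
  t1 <- seq(0, 1.5, by = 0.01)
  t2 <- seq(0, 1.5, by = 0.005)
  oc1 <- compute_oc(data.frame(time = t1, rs = rs_fun(t1)))
  oc2 <- compute_oc(data.frame(time = t2, rs = rs_fun(t2)))
  expect_equal(oc1, oc2, tolerance = 0.01)
  # linearity: scaling the uptake profile scales OC
  oc_c <- compute_oc(data.frame(time = t1, rs = 3.7 * rs_fun(t1)))
  expect_equal(oc_c, 3.7 * oc1, tolerance = 1e-3)
  # monotone in event length: extending the segment never decreases OC
  ocs <- vapply(c(50, 100, 151), function(n)
    compute_oc(data.frame(time = t1[1:n], rs = rs_fun(t1[1:n]))), numeric(1))
  expect_true(all(diff(ocs) >= 0))
})

test_that("R_S is nonnegative and derivative-mode OC never exceeds
           mass-balance OC under reaeration", {
  sc <- substrate_scenario("tween80")
  sim <- simulate_respirogram(sc)
  ev_mb <- process_trace(sim$trace, sc$pulse_schedule,
                         constants = reactor_constants(kla = sc$kla),
                         mode = "mass-balance", x_t = sim$truth$x0)
  ev_dv <- process_trace(sim$trace, sc$pulse_schedule,
                         constants = reactor_constants(kla = sc$kla),
                         mode = "derivative", x_t = sim$truth$x0)
  for (e in c(ev_mb, ev_dv)) expect_true(all(e$rs_series$rs >= 0))
  oc_mb <- vapply(ev_mb, `[[`, numeric(1), "oc")
  oc_dv <- vapply(ev_dv, `[[`, numeric(1), "oc")
  expect_true(all(oc_dv <= oc_mb))
})

test_that("kla is recovered from exponential recovery tails", {
  tt <- seq(0, 0.5, by = 0.005)
  do <- 9 - (9 - 5) * exp(-12 * tt)
  est <- estimate_kla(tt, do, baseline = 9)
  expect_equal(est$kla, 12, tolerance = 0.1 / 12)

  set.seed(7)
  do_noisy <- 9 - (9 - 5) * exp(-8 * tt) + stats::rnorm(length(tt), 0, 0.05)
  est2 <- estimate_kla(tt, do_noisy, baseline = 9)
  expect_equal(est2$kla, 8, tolerance = 0.05)

  expect_error(estimate_kla(tt, rep(9, length(tt)), baseline = 9),
               "no DO deficit")
})
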