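# Reference sequential-addition design used across the tests: four substrate
# stocks dosed at 35/70/100% strength, 10 mL pulses into 1.010 L. The
# expected in-reactor S values were frozen from the dose/volume bookkeeping
# computed by hand (dose / (1.010 + 0.010 * k)).

reference_design <- function() {
  data.frame(
    substrate = rep(c("sodium_acetate", "glucose", "tween80", "peptone"),
                    each = 3),
    stock_cod = rep(c(1800, 3400, 1100, 2400), each = 3),
    fraction = rep(c(0.35, 0.70, 1.00), times = 4),
    event = rep(1:3, times = 4),
    cod = c(630, 1260, 1800, 1190, 2380, 3400,
            385, 770, 1100, 840, 1680, 2400),
    s = c(6.1765, 12.2330, 17.3077, 11.6667, 23.1068, 32.6923,
          3.7745, 7.4757, 10.5769, 8.2353, 16.3107, 23.0769),
    x_t = c(306.2, 323.3, 443.1, 351.1, 374.7, 500.9,
            146.6, 178.7, 239.8, 175.6, 265.5, 284.8))
}

design_schedule <- function(substrate) {
  d <- reference_design()
  d <- d[d$substrate == substrate, ]
  addition_schedule(stock_cod = d$stock_cod[1],
                    dilution_fractions = d$fraction,
                    addition_volume = 0.010, initial_volume = 1.010,
                    substrate_label = substrate)
}

# dense LSE grid search: the independent oracle for fit_model. Every model
# is linear in mu_m, so for each k on the grid the predictions are mu_m
# times a shape vector, evaluated across the whole mu_m grid at once.
grid_lse <- function(model_name, points, mu_m_bounds = c(1e-3, 10),
                     k_bounds = c(1e-4, 1e3), n_grid = 200) {
  mu_grid <- exp(seq(log(mu_m_bounds[1]), log(mu_m_bounds[2]),
                     length.out = n_grid))
  k_grid <- exp(seq(log(k_bounds[1]), log(k_bounds[2]), length.out = n_grid))
  best <- Inf
  for (k in k_grid) {
    shape <- model_mu(model_name, c(1, k), points$s, points$x_t)
    pred <- outer(mu_grid, shape)
    lse <- rowSums(sweep(pred, 2, points$mu_empirical)^2)
    best <- min(best, lse)
  }
  best
}

# a clean three-pulse respirogram built directly from line segments (no ODE):
# baseline, linear drop, exponential-ish recovery, per pulse
piecewise_trace <- function(dt = 0.005, do_sat = 9.08, baseline = 9.0,
                            depth = 2, drop_h = 0.1, recover_h = 0.4,
                            quiet_h = 0.3, n_pulses = 3) {
  seg_t <- list()
  seg_y <- list()
  t0 <- 0
  add <- numeric(0)
  for (p in seq_len(n_pulses + 1)) {
    tq <- seq(t0, t0 + quiet_h, by = dt)
    seg_t <- c(seg_t, list(tq)); seg_y <- c(seg_y, list(rep(baseline, length(tq))))
    t0 <- t0 + quiet_h
    if (p > n_pulses) break
    add <- c(add, t0)
    td <- seq(t0, t0 + drop_h, by = dt)
    seg_t <- c(seg_t, list(td))
    seg_y <- c(seg_y, list(baseline - depth * (td - t0) / drop_h))
    t0 <- t0 + drop_h
    tr <- seq(t0, t0 + recover_h, by = dt)
    seg_t <- c(seg_t, list(tr))
    seg_y <- c(seg_y, list(baseline - depth * exp(-12 * (tr - t0))))
    t0 <- t0 + recover_h
  }
  tt <- unlist(seg_t); yy <- unlist(seg_y)
  keep <- !duplicated(tt)
  respirogram_trace(tt[keep], yy[keep], do_sat = do_sat, additions = add)
}
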