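# Mechanistic simulator of a sequential-addition respirometric assay in an
# aerated stirred batch reactor, with known kinetic ground truth. Serves as
# the test bed for the whole processing/fitting pipeline.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Define a simulation scenario
#'
#' Ground-truth kinetics plus reactor physics and a pulse schedule. The
#' defaults describe a 1 L working-volume stirred tank at 20 C, aerated so
#' that kLa = 10 h-1, holding ~300 mg TSS L-1 of heterotrophic biomass with
#' a true biomass yield of 0.47 mg TSS per mg COD (an oxygen yield around
#' 0.7, typical for aerobic heterotrophs and large enough that each pulse
#' leaves a clearly measurable oxygen footprint).
#'
#' @param model_name Growth model generating the data (see [model_mu()]).
#' @param params True parameters `c(mu_m, k)` (plus `n` for Moser).
#' @param pulse_schedule An [addition_schedule()].
#' @param y_tss_true True biomass yield, mg TSS mg COD-1; `f_cv *
#'   y_tss_true` must stay below 1 so oxygen demand is positive.
#' @param f_cv COD content of biomass, mg COD mg TSS-1.
#' @param x0 Initial biomass, mg TSS L-1.
#' @param do_sat Saturation DO, mg O2 L-1.
#' @param kla Oxygen transfer coefficient, h-1.
#' @param endog_rate Endogenous respiration, mg O2 per mg TSS per h.
#' @param sampling_dt Probe sampling interval, hours.
#' @param noise_sd SD of Gaussian probe noise on sampled DO, mg O2 L-1.
#' @param seed Integer seed for the probe noise; `NULL` leaves the RNG
#'   state alone.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(model_name, params, pulse_schedule,
                                y_tss_true = 0.47, f_cv = 1.48, x0 = 300,
                                do_sat = 9.08, kla = 10, endog_rate = 0.002,
                                sampling_dt = 0.005, noise_sd = 0.05,
                                seed = 1L) {
  model_name <- match.arg(model_name, GROWTH_MODELS)
  stopifnot(inherits(pulse_schedule, "addition_schedule"))
  if (any(c(params[1], params[2], y_tss_true, f_cv, x0, do_sat, kla,
            sampling_dt) <= 0))
    stop("rates, volumes and parameters must be positive", call. = FALSE)
  if (endog_rate < 0 || noise_sd < 0)
    stop("`endog_rate` and `noise_sd` must be nonnegative", call. = FALSE)
  if (f_cv * y_tss_true >= 1)
    stop("f_cv * y_tss_true must be < 1 (oxygen demand must be positive)",
         call. = FALSE)
  structure(
    list(model_name = model_name, params = as.numeric(params),
         pulse_schedule = pulse_schedule, y_tss_true = y_tss_true,
         f_cv = f_cv, x0 = x0, do_sat = do_sat, kla = kla,
         endog_rate = endog_rate, sampling_dt = sampling_dt,
         noise_sd = noise_sd, seed = seed),
    class = "simulation_scenario")
}

#' Built-in scenarios for four reference substrates
#'
#' Four substrates spanning the principal heterotrophic metabolisms —
#' sodium acetate (carboxylic acid), glucose (carbohydrate), tween 80
#' (lipid/surfactant) and peptone (protein hydrolysate) — with stock CODs
#' of 1800, 3400, 1100 and 2400 mg O2 L-1, three sequential pulses at 35,
#' 70 and 100% of the stock (10 mL each into 1.010 L), and true kinetics of
#' the magnitude reported for a cold-adapted marine heterotroph growing on
#' these substrates: Monod for acetate and tween 80, Contois for glucose
#' and peptone.
#'
#' @param substrate_label One of `"sodium_acetate"`, `"glucose"`,
#'   `"tween80"`, `"peptone"`.
#' @param ... Overrides passed to [simulation_scenario()].
#' @return A [simulation_scenario()].
#' @export
substrate_scenario <- function(substrate_label, ...) {
  designs <- list(
    sodium_acetate = list(stock = 1800, model = "monod",
                          params = c(0.1163, 4.9267), x0 = 306.2),
    glucose = list(stock = 3400, model = "contois",
                   params = c(0.0886, 0.0071), x0 = 351.1),
    tween80 = list(stock = 1100, model = "monod",
                   params = c(0.1162, 0.5780), x0 = 146.6),
    peptone = list(stock = 2400, model = "contois",
                   params = c(0.2062, 0.0039), x0 = 175.6))
  if (!substrate_label %in% names(designs))
    stop("unknown substrate '", substrate_label, "'; expected one of: ",
         paste(names(designs), collapse = ", "), call. = FALSE)
  d <- designs[[substrate_label]]
  sched <- addition_schedule(stock_cod = d$stock,
                             dilution_fractions = c(0.35, 0.70, 1.00),
                             addition_volume = 0.010, initial_volume = 1.010,
                             substrate_label = substrate_label)
  simulation_scenario(model_name = d$model, params = d$params,
                      pulse_schedule = sched, x0 = d$x0, ...)
}

#' Simulate a respirogram with known ground truth
#'
#' Integrates the batch-reactor balances
#' \deqn{dX/dt = \mu(S, X) X, \quad dS/dt = -\mu X / Y_{TSS},}
#' \deqn{dDO/dt = k_La (DO_{sat} - DO) - (1 - f_{cv} Y_{TSS}) \mu X / Y_{TSS}
#'   - b X}
#' with a fixed-step classical Runge-Kutta scheme at `sampling_dt /
#' substeps`. Each pulse instantaneously raises S by its dose over the
#' post-addition volume and dilutes X and DO by the volume ratio. Pulses
#' fire once the previous one is consumed: S below 2% of its dose and DO
#' back within `epsilon` of the (endogenous) baseline for
#' `stability_window` consecutive samples — the simulated operator reads
#' the true DO, so pulse timing is deterministic. The observed trace is the
#' true DO sampled at `sampling_dt` plus seeded Gaussian probe noise,
#' clipped at 0.
#'
#' @param scenario A [simulation_scenario()].
#' @param substeps Integration substeps per sampling interval (>= 10 keeps
#'   the step at or below `sampling_dt / 10`).
#' @param t_stabilize Aeration-only period before the first pulse, hours.
#' @param max_event_hours Abort horizon per pulse.
#' @param epsilon,stability_window Recovery criterion (mg O2 L-1, samples).
#' @param hold Plateau time held after recovery before the next pulse,
#'   hours; gives downstream baseline/stability detection a clean window,
#'   as an operator waiting for a visibly flat trace would.
#' @param o2_limit_horizon DO below 0.05 mg O2 L-1 for longer than this
#'   (hours) flags oxygen limitation on the result.
#' @return A list with `trace` (a [respirogram_trace()] whose `additions`
#'   record the true pulse times), `truth` (data.frame per event:
#'   `event_index`, `t_pulse`, `t_stable`, `s0`, `x0`, `mu_true`,
#'   `oc_true`, `uptake`), `trajectory` (noise-free sampled states) and
#'   `oxygen_limited` (logical).
#' @export
simulate_respirogram <- function(scenario, substeps = 10, t_stabilize = 0.25,
                                 max_event_hours = 6,
                                 epsilon = 0.02, stability_window = 6,
                                 hold = 0.15, o2_limit_horizon = 0.05) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  sched <- sc$pulse_schedule
  n_pulse <- length(sched$dilution_fractions)
  dt <- sc$sampling_dt
  h <- dt / substeps
  q <- 1 - sc$f_cv * sc$y_tss_true      # oxygen demand per unit COD consumed

  deriv <- function(t, y, p) {
    s <- max(y[["S"]], 0)
    mu <- if (s > 0)
      model_mu(sc$model_name, sc$params, s, y[["X"]]) else 0
    growth <- mu * y[["X"]]
    exo <- q * growth / sc$y_tss_true
    list(c(X = growth,
           S = -growth / sc$y_tss_true,
           DO = sc$kla * (sc$do_sat - y[["DO"]]) - exo -
             sc$endog_rate * y[["X"]],
           U = exo))
  }

  baseline_at <- function(x) sc$do_sat - sc$endog_rate * x / sc$kla

  state <- c(X = sc$x0, S = 0, DO = baseline_at(sc$x0), U = 0)
  vol <- sched$initial_volume
  t_cur <- 0
  samp_t <- 0
  samp_state <- matrix(state, nrow = 1,
                       dimnames = list(NULL, names(state)))

  integrate_until <- function(state, t_cur, stop_fn, horizon) {
    # advance in chunks; return first sample where stop_fn says stop
    t_kept <- numeric(0); kept <- NULL
    stable_run <- 0L
    chunk <- 50L * dt
    t0 <- t_cur
    repeat {
      tt <- seq(t_cur, min(t_cur + chunk, t0 + horizon), by = h)
      if (length(tt) < 2) break
      sol <- deSolve::ode(y = state, times = tt, func = deriv, parms = NULL,
                          method = "rk4")
      idx <- seq(1L + substeps, nrow(sol), by = substeps)
      for (i in idx) {
        row <- sol[i, -1]
        t_kept <- c(t_kept, sol[i, 1]); kept <- rbind(kept, row)
        if (!is.null(stop_fn)) {
          if (stop_fn(row)) stable_run <- stable_run + 1L else stable_run <- 0L
          if (stable_run >= stability_window)
            return(list(t = t_kept, states = kept,
                        state = row, t_cur = sol[i, 1], stopped = TRUE))
        }
      }
      state <- sol[nrow(sol), -1]
      t_cur <- sol[nrow(sol), 1]
      if (t_cur >= t0 + horizon - h / 2)
        return(list(t = t_kept, states = kept, state = state, t_cur = t_cur,
                    stopped = is.null(stop_fn)))
    }
    list(t = t_kept, states = kept, state = state, t_cur = t_cur,
         stopped = is.null(stop_fn))
  }

  # aeration-only stabilization before the first pulse
  pre <- integrate_until(state, t_cur, NULL, t_stabilize)
  samp_t <- c(samp_t, pre$t)
  samp_state <- rbind(samp_state, pre$states)
  state <- pre$state; t_cur <- pre$t_cur

  truth <- NULL
  pulse_times <- numeric(0)
  for (k in seq_len(n_pulse)) {
    d <- vol / (vol + sched$addition_volume)
    dose <- dilution_cod(sched$stock_cod, sched$dilution_fractions[k]) *
      sched$addition_volume
    vol <- vol + sched$addition_volume
    state[["X"]] <- state[["X"]] * d
    state[["DO"]] <- state[["DO"]] * d
    state[["S"]] <- state[["S"]] * d + dose / vol
    state[["U"]] <- 0
    s0 <- state[["S"]]; x0 <- state[["X"]]
    pulse_times <- c(pulse_times, t_cur)

    stop_fn <- function(row)
      row[["S"]] <= 0.02 * s0 + 1e-12 &&
        abs(row[["DO"]] - baseline_at(row[["X"]])) < epsilon
    ev <- integrate_until(state, t_cur, stop_fn, max_event_hours)
    if (!ev$stopped)
      stop(sprintf("event %d did not restabilize within %g h", k,
                   max_event_hours), call. = FALSE)
    samp_t <- c(samp_t, ev$t)
    samp_state <- rbind(samp_state, ev$states)
    truth <- rbind(truth, data.frame(
      event_index = k, t_pulse = t_cur, t_stable = ev$t_cur,
      s0 = s0, x0 = x0,
      mu_true = model_mu(sc$model_name, sc$params, s0, x0),
      oc_true = q * s0, uptake = ev$state[["U"]]))
    state <- ev$state; t_cur <- ev$t_cur
    if (hold > 0) {                    # plateau before the next pulse
      hd <- integrate_until(state, t_cur, NULL, hold)
      samp_t <- c(samp_t, hd$t)
      samp_state <- rbind(samp_state, hd$states)
      state <- hd$state; t_cur <- hd$t_cur
    }
  }

  # short quiet tail so the last event's recovery window is fully observed
  tail_run <- integrate_until(state, t_cur, NULL, stability_window * 2 * dt)
  samp_t <- c(samp_t, tail_run$t)
  samp_state <- rbind(samp_state, tail_run$states)

  do_true <- samp_state[, "DO"]
  o2_limited <- any_run_exceeds(do_true < 0.05, ceiling(o2_limit_horizon / dt))
  do_obs <- with_seed(sc$seed,
    do_true + stats::rnorm(length(do_true), 0, sc$noise_sd))
  do_obs <- pmin(pmax(do_obs, 0), sc$do_sat * 1.05)

  trace <- respirogram_trace(
    time = samp_t, do_signal = do_obs, do_sat = sc$do_sat,
    substrate_label = sched$substrate_label, additions = pulse_times)
  list(trace = trace, truth = truth,
       trajectory = data.frame(time = samp_t, samp_state,
                               check.names = FALSE),
       oxygen_limited = o2_limited, final_state = state)
}

any_run_exceeds <- function(flag, len) {
  if (!any(flag)) return(FALSE)
  r <- rle(flag)
  any(r$values & r$lengths > len)
}

#' Generate empirical kinetics points directly from a growth model
#'
#' Bypasses the reactor: draws the true specific growth rate from
#' [model_mu()], applies multiplicative lognormal noise, and packages each
#' point with internally consistent R_S, OC and yields (fixed oxygen yield
#' `y_o2`) so that the stored `mu_empirical` is exactly the noisy rate.
#'
#' @param model_name,params Generating model and true parameters.
#' @param s_values,x_t_values Substrate and biomass per point (equal
#'   length).
#' @param noise_sd SD of the log of the multiplicative noise (0.05 = 5%).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param y_o2 Oxygen yield used for the consistent OC/rs bookkeeping.
#' @param f_cv COD content of biomass.
#' @return A `kinetics_points` data.frame with attribute `"mu_true"`.
#' @export
make_points <- function(model_name, params, s_values, x_t_values,
                        noise_sd = 0, seed = NULL, y_o2 = 0.7, f_cv = 1.48) {
  if (length(s_values) != length(x_t_values))
    stop("`s_values` and `x_t_values` must have equal length", call. = FALSE)
  mu_true <- model_mu(model_name, params, s_values, x_t_values)
  mu_obs <- if (noise_sd > 0)
    with_seed(seed, mu_true * exp(stats::rnorm(length(mu_true), 0, noise_sd)))
  else mu_true
  y_tss <- y_o2 / f_cv
  df <- data.frame(
    s = s_values, x_t = x_t_values,
    rs = mu_obs * (1 - y_o2) * x_t_values / y_tss,
    oc = (1 - y_o2) * s_values,
    y_o2 = y_o2, y_tss = y_tss, mu_empirical = mu_obs)
  class(df) <- c("kinetics_points", "data.frame")
  attr(df, "mu_true") <- mu_true
  df
}
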