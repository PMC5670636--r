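# Growth-kinetics core: yields and empirical specific growth rates from
# addition events, the four unstructured growth models (Monod, Moser,
# Contois, Tessier), least-squared-error fitting, model selection and rate
# curves.

#' Supported growth models, in tie-break preference order
#' @export
GROWTH_MODELS <- c("monod", "tessier", "moser", "contois")

#' Yield coefficients from the COD balance of one event
#'
#' The oxygen yield is the fraction of the dosed substrate COD that was not
#' oxidized, `Y_O2 = (S - OC) / S`; dividing by the COD content of biomass
#' `f_cv` gives the biomass yield `Y_TSS = Y_O2 / f_cv` (mg TSS per mg COD).
#'
#' @param s In-reactor substrate concentration of the pulse, mg O2 L-1 (COD).
#' @param oc Oxygen consumed over the event, mg O2 L-1.
#' @param f_cv COD per unit biomass, mg COD mg TSS-1 (default 1.48).
#' @return A list `y_o2`, `y_tss`.
#' @export
compute_yields <- function(s, oc, f_cv = 1.48) {
  if (s <= 0) stop("substrate concentration must be positive", call. = FALSE)
  if (oc < 0) stop("oxygen consumption must be nonnegative", call. = FALSE)
  if (oc > s)
    stop(sprintf(
      "COD balance violated: OC (%.4g) exceeds dosed substrate (%.4g)",
      oc, s), call. = FALSE)
  y_o2 <- (s - oc) / s
  list(y_o2 = y_o2, y_tss = y_o2 / f_cv)
}

#' Empirical specific growth rate of one event
#'
#' `mu = Y_TSS * R_S / ((1 - Y_O2) * X_T)`: the oxygen uptake rate is scaled
#' to a substrate consumption rate by `1 - Y_O2`, to a biomass production
#' rate by `Y_TSS`, and normalized by the standing biomass.
#'
#' @param y_tss Biomass yield, mg TSS mg COD-1.
#' @param rs Representative dynamic oxygen uptake rate, mg O2 L-1 h-1.
#' @param y_o2 Oxygen yield (must be < 1: some oxygen was consumed).
#' @param x_t Biomass concentration, mg TSS L-1.
#' @return Specific growth rate, h-1.
#' @export
mu_empirical <- function(y_tss, rs, y_o2, x_t) {
  if (x_t <= 0) stop("biomass concentration must be positive", call. = FALSE)
  if (y_o2 >= 1)
    stop("y_o2 >= 1: no net oxygen consumption, growth rate undefined",
         call. = FALSE)
  y_tss * rs / ((1 - y_o2) * x_t)
}

#' Specific growth rate under an unstructured growth model
#'
#' Saturation laws relating the specific growth rate to the substrate
#' concentration (and, for Contois, the biomass concentration):
#' \describe{
#'   \item{monod}{`mu_m * S / (K_S + S)`}
#'   \item{moser}{`mu_m * S^n / (K_S + S^n)` with exponent `n` (here 2), so
#'     `K_S` has units (mg O2 L-1)^n}
#'   \item{contois}{`mu_m * S / (K_C * X_T + S)` — the apparent
#'     half-saturation grows with biomass; `K_C` in mg O2 mg TSS-1}
#'   \item{tessier}{`mu_m * (1 - exp(-S / K_S))`}
#' }
#' All four vanish at `S = 0` and approach `mu_m` as `S` grows.
#'
#' @param model_name One of `"monod"`, `"moser"`, `"contois"`, `"tessier"`.
#' @param params Numeric: `mu_m` (h-1), `k` (model-specific units), and for
#'   Moser an optional third element `n` (default 2).
#' @param s Substrate concentration(s), mg O2 L-1 (COD); vectorized.
#' @param x_t Biomass concentration(s), mg TSS L-1; required for Contois.
#' @return Specific growth rate(s), h-1.
#' @export
model_mu <- function(model_name, params, s, x_t = NULL) {
  model_name <- match.arg(model_name, GROWTH_MODELS)
  mu_m <- params[[1]]
  k <- params[[2]]
  if (mu_m <= 0 || k <= 0)
    stop("model parameters must be positive", call. = FALSE)
  if (any(s < 0)) stop("substrate concentration must be >= 0", call. = FALSE)
  switch(model_name,
    monod = mu_m * s / (k + s),
    moser = {
      n <- if (length(params) >= 3) params[[3]] else 2
      mu_m * s^n / (k + s^n)
    },
    contois = {
      if (is.null(x_t))
        stop("the Contois model requires `x_t`", call. = FALSE)
      if (any(x_t <= 0)) stop("`x_t` must be positive", call. = FALSE)
      mu_m * s / (k * x_t + s)
    },
    tessier = mu_m * (1 - exp(-s / k)))
}

#' Build empirical kinetics points from processed events
#'
#' Converts addition events into (S, X_T, R_S, OC, yields, mu_empirical)
#' points for model fitting. Three modes:
#' \describe{
#'   \item{`"resolved"` (default)}{Several points per event, sampled along
#'     the event at interior times. The substrate remaining at time t is
#'     reconstructed from the cumulative-uptake fraction,
#'     `S(t) = S_added * (1 - U(t)/OC)`, and paired with the locally
#'     smoothed R_S(t). Interior samples avoid the bias of differentiating
#'     across the pulse discontinuity, so this mode is the most accurate
#'     input for fitting.}
#'   \item{`"peak"`}{One point per event at the event's peak uptake rate,
#'     which occurs right after the pulse while S is still at its dosed
#'     value — the classical single-mu-per-concentration summary.}
#'   \item{`"mean"`}{One point per event at the mean R_S (diagnostics).}
#' }
#'
#' @param events List of `addition_event` objects from [process_trace()],
#'   or a data.frame with columns `s`, `x_t`, `rs`, `oc` (then used as-is,
#'   one point per row).
#' @param constants A [reactor_constants()] (supplies `f_cv`).
#' @param rs_mode `"resolved"`, `"peak"` or `"mean"`.
#' @param n_resolved Points sampled per event in resolved mode.
#' @param edge_skip Time after the pulse excluded in resolved mode (hours);
#'   `NULL` skips 12 sampling intervals, the support of the default
#'   smoothing stencils.
#' @return A data.frame of class `kinetics_points` with columns `s`, `x_t`,
#'   `rs`, `oc`, `y_o2`, `y_tss`, `mu_empirical`.
#' @export
build_points <- function(events, constants = reactor_constants(),
                         rs_mode = c("resolved", "peak", "mean"),
                         n_resolved = 8, edge_skip = NULL) {
  rs_mode <- match.arg(rs_mode)
  if (is.data.frame(events)) {
    df <- events[, c("s", "x_t", "rs", "oc")]
  } else if (rs_mode == "resolved") {
    df <- do.call(rbind, lapply(events, resolved_event_points,
                                n_resolved = n_resolved,
                                edge_skip = edge_skip))
  } else {
    df <- data.frame(
      s = vapply(events, `[[`, numeric(1), "s_added"),
      x_t = vapply(events, `[[`, numeric(1), "x_t"),
      rs = vapply(events, function(e)
        if (rs_mode == "peak") e$rs_peak else mean(e$rs_series$rs), numeric(1)),
      oc = vapply(events, `[[`, numeric(1), "oc"))
  }
  # yields come from the event-level COD balance (dosed S vs total OC);
  # in resolved mode the row's s is the reconstructed instantaneous S
  if (is.null(df$s_event)) df$s_event <- df$s
  ys <- mapply(function(s, oc) unlist(compute_yields(s, oc, constants$f_cv)),
               df$s_event, pmin(df$oc, df$s_event * (1 - 1e-9)))
  df$y_o2 <- ys["y_o2", ]
  df$y_tss <- ys["y_tss", ]
  df$mu_empirical <- mapply(mu_empirical, df$y_tss, df$rs, df$y_o2, df$x_t)
  rownames(df) <- NULL
  class(df) <- c("kinetics_points", "data.frame")
  df
}

resolved_event_points <- function(e, n_resolved = 8, edge_skip = NULL) {
  tt <- e$rs_series$time
  rs <- e$rs_series$rs
  dt <- stats::median(diff(tt))
  if (is.null(edge_skip)) edge_skip <- 12 * dt
  U <- pracma::cumtrapz(tt, rs)[, 1]
  u_tot <- U[length(U)]
  w <- min(11L, 2L * (length(rs) %/% 4L) + 1L)
  rs_sm <- as.numeric(stats::filter(rs, rep(1 / w, w)))
  usable <- which(tt - e$t_start >= edge_skip & U <= 0.9 * u_tot &
                    !is.na(rs_sm))
  if (length(usable) < 2)   # event too short to resolve; fall back to peak
    return(data.frame(s = e$s_added, s_event = e$s_added, x_t = e$x_t,
                      rs = e$rs_peak, oc = e$oc))
  idx <- unique(round(seq(usable[1], usable[length(usable)],
                          length.out = n_resolved)))
  data.frame(s = e$s_added * (1 - U[idx] / u_tot), s_event = e$s_added,
             x_t = e$x_t, rs = rs_sm[idx], oc = e$oc)
}

lse_objective <- function(model_name, points, weights) {
  force(points)
  function(theta) {
    mu_hat <- model_mu(model_name, exp(theta), points$s, points$x_t)
    sum(weights * (mu_hat - points$mu_empirical)^2)
  }
}

#' Fit a growth model to empirical kinetics points
#'
#' Minimizes the least-squared error `LSE = sum((mu_theoretical -
#' mu_empirical)^2)` (optionally weighted) over positive `(mu_m, k)`. The
#' Moser exponent is fixed at `n = 2`. Optimization runs bounded
#' quasi-Newton searches in log-parameter space from a log-spaced
#' multi-start grid, so the returned LSE is never above the best grid
#' point's.
#'
#' @param model_name One of [GROWTH_MODELS].
#' @param points A `kinetics_points` data.frame (needs `s`, `mu_empirical`,
#'   and `x_t` for Contois); at least 2 points with distinct `s`.
#' @param weights Optional per-point weights (default unit weights).
#' @param mu_m_bounds,k_bounds Search box for the parameters.
#' @param n_starts Grid resolution per parameter for the multi-start.
#' @return An object of class `kinetic_fit`: `model_name`, `mu_m`, `k`, `n`,
#'   `lse`, `mu_theoretical`, `points`, `converged`.
#' @export
fit_model <- function(model_name, points, weights = NULL,
                      mu_m_bounds = c(1e-3, 10), k_bounds = c(1e-4, 1e3),
                      n_starts = 5) {
  model_name <- match.arg(model_name, GROWTH_MODELS)
  if (length(unique(points$s)) < 2)
    stop("underdetermined fit: need >= 2 points with distinct substrate levels",
         call. = FALSE)
  if (any(!is.finite(points$mu_empirical)))
    stop("mu_empirical must be finite for all points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  obj <- lse_objective(model_name, points, weights)
  lo <- log(c(mu_m_bounds[1], k_bounds[1]))
  hi <- log(c(mu_m_bounds[2], k_bounds[2]))
  starts <- expand.grid(
    mu = seq(lo[1], hi[1], length.out = n_starts),
    k = seq(lo[2], hi[2], length.out = n_starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- as.numeric(starts[i, ])
    res <- try(stats::nlminb(th0, obj, lower = lo, upper = hi,
                             control = list(eval.max = 1000, iter.max = 500,
                                            rel.tol = 1e-14, x.tol = 1e-12)),
               silent = TRUE)
    cand <- if (inherits(res, "try-error"))
      list(par = th0, objective = obj(th0), convergence = 1L) else res
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }
  if (is.null(best))
    stop("fit failed to converge from every start", call. = FALSE)
  pars <- exp(best$par)
  mu_hat <- model_mu(model_name, pars, points$s, points$x_t)
  structure(
    list(model_name = model_name, mu_m = pars[1], k = pars[2],
         n = if (model_name == "moser") 2 else NA_real_,
         lse = best$objective, mu_theoretical = mu_hat,
         points = points, converged = best$convergence == 0L),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  kn <- switch(x$model_name, contois = "K_C", "K_S")
  cat(sprintf("<kinetic_fit> %s: mu_m = %.4f h-1, %s = %.4f, LSE = %.4g h-2\n",
              x$model_name, x$mu_m, kn, x$k, x$lse))
  invisible(x)
}

#' Select the best-fitting growth model
#'
#' Lowest least-squared error wins; exact ties fall back to the simpler
#' model in the order Monod, Tessier, Moser, Contois.
#'
#' @param fits A list of `kinetic_fit` objects.
#' @return A list `best` (the winning fit) and `ranking` (data.frame of
#'   model, mu_m, k, lse ordered by the selection rule).
#' @export
select_best_model <- function(fits) {
  fits <- Filter(function(f) inherits(f, "kinetic_fit"), fits)
  if (!length(fits)) stop("no successful fits to select from", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model_name"),
    mu_m = vapply(fits, `[[`, numeric(1), "mu_m"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    lse = vapply(fits, `[[`, numeric(1), "lse"),
    stringsAsFactors = FALSE)
  ord <- order(tab$lse, match(tab$model, GROWTH_MODELS))
  list(best = fits[[ord[1]]], ranking = tab[ord, , drop = FALSE])
}

#' Substrate-degradation and cell-growth rate curves
#'
#' From a fitted model, `r_su(S) = mu(S) * X_T / Y_TSS` (reported as a
#' magnitude; the underlying substrate balance carries a minus sign) and
#' `r_x(S) = mu(S) * X_T`, so `r_x / r_su = Y_TSS` pointwise.
#'
#' @param fit A `kinetic_fit`.
#' @param x_t Biomass concentration, mg TSS L-1.
#' @param y_tss Biomass yield, mg TSS mg COD-1.
#' @param s_grid Substrate concentrations to evaluate, mg O2 L-1.
#' @return A data.frame `s`, `mu`, `r_su` (mg O2 L-1 h-1), `r_x`
#'   (mg TSS L-1 h-1).
#' @export
rate_curves <- function(fit, x_t, y_tss, s_grid) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (x_t <= 0 || y_tss <= 0)
    stop("`x_t` and `y_tss` must be positive", call. = FALSE)
  mu <- model_mu(fit$model_name, c(fit$mu_m, fit$k, fit$n), s_grid, x_t)
  data.frame(s = s_grid, mu = mu, r_su = mu * x_t / y_tss, r_x = mu * x_t)
}

#' Full kinetic analysis of one substrate
#'
#' Builds empirical kinetics points from the substrate's addition events,
#' fits the requested growth models, selects the best by lowest LSE, and
#' evaluates rate curves at the highest tested substrate concentration's
#' biomass. With replicate event sets, models are fitted per replicate and
#' parameters reported as mean and SD across replicates (a pooled fit over
#' all points is also returned).
#'
#' @param events A list of `addition_event` objects (single replicate) or a
#'   named list of such lists (one element per replicate).
#' @param constants A [reactor_constants()].
#' @param models Character vector of models to fit (default all four).
#' @param substrate_label Label carried into the report.
#' @param s_grid Substrate grid for rate curves (default 100 points spanning
#'   0 to the largest tested S).
#' @param rs_mode Passed to [build_points()].
#' @return A list of class `substrate_report`: `substrate`, `points`,
#'   `fits` (pooled, one per model), `parameter_table` (per model: mu_m, k,
#'   y_tss, lse, with `mu_m_sd`/`k_sd` across replicates when present),
#'   `best_model`, `rate_curves`, `n_replicates`.
#' @export
analyze_substrate <- function(events, constants = reactor_constants(),
                              models = GROWTH_MODELS,
                              substrate_label = NA_character_,
                              s_grid = NULL, rs_mode = "resolved") {
  models <- vapply(models, match.arg, character(1), choices = GROWTH_MODELS)
  is_replicated <- length(events) > 0 && is.list(events[[1]]) &&
    !inherits(events[[1]], "addition_event")
  reps <- if (is_replicated) events else list(events)
  if (any(vapply(reps, length, integer(1)) < 2))
    stop("underdetermined: need >= 2 events per replicate", call. = FALSE)

  pts_by_rep <- lapply(reps, build_points, constants = constants,
                       rs_mode = rs_mode)
  pooled <- do.call(rbind, pts_by_rep)

  fits <- lapply(models, function(m) fit_model(m, pooled))
  names(fits) <- models
  rep_fits <- if (length(reps) > 1)
    lapply(pts_by_rep, function(p) lapply(models, function(m) fit_model(m, p)))
  else NULL

  param_table <- do.call(rbind, lapply(seq_along(models), function(i) {
    m <- models[i]
    row <- data.frame(
      substrate = substrate_label, model = m,
      mu_m = fits[[m]]$mu_m, k = fits[[m]]$k,
      k_units = switch(m, moser = "(mg O2 L-1)^2",
                       contois = "mg O2 mg TSS-1", "mg O2 L-1"),
      y_tss = mean(pooled$y_tss), lse = fits[[m]]$lse,
      mu_m_sd = NA_real_, k_sd = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(rep_fits)) {
      mus <- vapply(rep_fits, function(fl) fl[[i]]$mu_m, numeric(1))
      ks <- vapply(rep_fits, function(fl) fl[[i]]$k, numeric(1))
      row$mu_m <- mean(mus); row$mu_m_sd <- stats::sd(mus)
      row$k <- mean(ks); row$k_sd <- stats::sd(ks)
    }
    row
  }))

  sel <- select_best_model(fits)
  s_max <- if (!is.null(pooled$s_event)) max(pooled$s_event) else max(pooled$s)
  if (is.null(s_grid)) s_grid <- seq(0, s_max, length.out = 100)
  i_top <- which.max(pooled$s)
  rc <- rate_curves(sel$best, x_t = pooled$x_t[i_top],
                    y_tss = mean(pooled$y_tss), s_grid = s_grid)

  structure(
    list(substrate = substrate_label, points = pooled, fits = fits,
         parameter_table = param_table, best_model = sel$best$model_name,
         ranking = sel$ranking, rate_curves = rc,
         n_replicates = length(reps)),
    class = "substrate_report")
}

#' @export
print.substrate_report <- function(x, ...) {
  cat(sprintf("<substrate_report> %s (%d replicate%s, %d points)\n",
              x$substrate, x$n_replicates,
              if (x$n_replicates > 1) "s" else "", nrow(x$points)))
  cat(sprintf("  best model: %s\n", x$best_model))
  print(x$parameter_table[, c("model", "mu_m", "k", "lse")], row.names = FALSE)
  invisible(x)
}
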