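test_that("yield coefficients follow the COD balance", {
  y <- compute_yields(10, 3, 1.48)
  expect_equal(y$y_o2, 0.7)
  expect_equal(y$y_tss, 0.7 / 1.48) # 0.47297
  y0 <- compute_yields(25, 0, 1.48)
  expect_equal(y0$y_o2, 1)
  expect_equal(y0$y_tss, 1 / 1.48)
  # inverting the biomass-yield relation: y_tss = 0.6695 with f_cv = 1.48
  # corresponds to an oxygen yield of 0.99086
  expect_equal(0.6695 * 1.48, 0.99086, tolerance = 1e-6)
  expect_error(compute_yields(10, 11), "COD balance")
  expect_error(compute_yields(0, 0), "positive")
})

test_that("the empirical specific growth rate is Y_TSS Rs / ((1-Y_O2) X_T)", {
  expect_equal(mu_empirical(0.47297, 2, 0.3, 100),
               0.47297 * 2 / (0.7 * 100)) # 0.013513 h-1
  expect_equal(mu_empirical(0.5, 0, 0.3, 100), 0)
  # homogeneity: doubling rs and x_t together leaves mu unchanged
  expect_equal(mu_empirical(0.5, 4, 0.3, 200), mu_empirical(0.5, 2, 0.3, 100))
  expect_error(mu_empirical(0.5, 2, 1, 100), "undefined")
  expect_error(mu_empirical(0.5, 2, 0.3, 0), "positive")
})

test_that("model_mu reproduces hand-computed reference values", {
  # values computed by hand from the model formulas with reported
  # parameter magnitudes for a marine heterotroph
  expect_equal(model_mu("monod", c(0.1163, 4.9267), 17.3077),
               0.1163 * 17.3077 / (4.9267 + 17.3077)) # 0.09053
  expect_equal(round(model_mu("monod", c(0.1163, 4.9267), 17.3077), 5),
               0.09053)
  expect_equal(round(model_mu("moser", c(0.0946, 17.8571), 17.3077), 5),
               0.08928)
  expect_equal(round(model_mu("contois", c(0.2062, 0.0039), 23.0769,
                              x_t = 284.8), 5), 0.19673)
  mu_m <- 0.13; ks <- 3.7
  expect_equal(model_mu("tessier", c(mu_m, ks), ks), mu_m * (1 - exp(-1)))
  expect_error(model_mu("contois", c(0.1, 0.01), 5), "x_t")
  expect_error(model_mu("gompertz", c(0.1, 1), 5))
})

test_that("all four models vanish at S=0, increase with S, saturate at mu_m", {
  s <- seq(0, 500, length.out = 400)
  for (m in GROWTH_MODELS) {
    for (p in list(c(0.1, 0.5), c(0.2062, 0.0039), c(1, 20))) {
      mu <- model_mu(m, p, s, x_t = 280)
      expect_equal(mu[1], 0)
      expect_true(all(diff(mu) >= 0))
      expect_true(all(mu <= p[1] + 1e-12))
      expect_gt(model_mu(m, p, 1e7, x_t = 280), 0.99 * p[1])
    }
  }
})

test_that("Contois collapses to Monod when K_C X_T is held fixed", {
  s <- c(0.5, 3, 12, 40)
  x_t <- 284.8
  k_c <- 0.0039
  expect_equal(model_mu("contois", c(0.2, k_c), s, x_t),
               model_mu("monod", c(0.2, k_c * x_t), s))
})

test_that("noiseless points are interpolated back to the generating
           parameters for every model", {
  s <- c(6.18, 12.23, 17.31)
  x_t <- c(306, 323, 443)
  truth <- list(monod = c(0.12, 5), moser = c(0.0946, 17.8571),
                contois = c(0.2062, 0.0039), tessier = c(0.0934, 5.3119))
  for (m in names(truth)) {
    pts <- make_points(m, truth[[m]], s, x_t)
    fit <- fit_model(m, pts)
    expect_equal(fit$mu_m, truth[[m]][1], tolerance = 1e-4)
    expect_equal(fit$k, truth[[m]][2], tolerance = 1e-4)
    expect_lt(fit$lse, 1e-10)
    # stored lse must equal the objective recomputed from stored values
    expect_equal(fit$lse,
                 sum((fit$mu_theoretical - pts$mu_empirical)^2),
                 tolerance = 1e-12)
  }
})

test_that("a saturated flat profile drives Monod's mu_m to the plateau", {
  pts <- make_points("monod", c(0.1, 1e-3), c(50, 100, 200), rep(300, 3))
  pts$mu_empirical <- 0.1 # exactly flat
  fit <- fit_model("monod", pts)
  expect_equal(fit$mu_m, 0.1, tolerance = 1e-3)
  expect_lt(fit$lse, 1e-10)
})

test_that("fitting the wrong model leaves a strictly positive LSE", {
  pts <- make_points("monod", c(0.12, 5), c(2, 6.18, 12.23, 17.31),
                     rep(306, 4))
  fit <- fit_model("tessier", pts)
  expect_gt(fit$lse, 1e-8)
  # the optimizer's minimum agrees with a dense grid-search oracle
  expect_lte(fit$lse, grid_lse("tessier", pts) + 1e-12)
})

test_that("the optimizer never loses to a 200x200 log-spaced grid search", {
  set.seed(42)
  cases <- list(
    list(m = "monod", p = c(0.1163, 4.9267)),
    list(m = "moser", p = c(0.0946, 17.8571)),
    list(m = "contois", p = c(0.2062, 0.0039)),
    list(m = "tessier", p = c(0.0934, 5.3119)))
  for (cs in cases) {
    s <- sort(stats::runif(5, 1, 35))
    pts <- make_points(cs$m, cs$p, s, rep(300, 5), noise_sd = 0.08, seed = 99)
    for (fit_m in GROWTH_MODELS) {
      fit <- fit_model(fit_m, pts)
      expect_lte(fit$lse, grid_lse(fit_m, pts) + 1e-12)
    }
  }
})

test_that("underdetermined or degenerate inputs raise errors", {
  pts <- make_points("monod", c(0.1, 2), c(5, 5), c(300, 300))
  expect_error(fit_model("monod", pts), "distinct")
  pts2 <- make_points("monod", c(0.1, 2), c(5, 10), c(300, 300))
  pts2$mu_empirical[1] <- NaN
  expect_error(fit_model("monod", pts2), "finite")
})

test_that("model selection takes the lowest LSE with a simplicity tie-break", {
  mk <- function(m, lse) structure(list(model_name = m, mu_m = 0.1, k = 1,
                                        lse = lse), class = "kinetic_fit")
  # LSE ordering of a four-model comparison on an acetate-like dataset
  fits <- list(mk("monod", 1.0661e-6), mk("moser", 9.4331e-6),
               mk("contois", 3.1754e-5), mk("tessier", 6.1539e-6))
  sel <- select_best_model(fits)
  expect_equal(sel$best$model_name, "monod")
  expect_equal(sel$ranking$model, c("monod", "tessier", "moser", "contois"))

  expect_equal(select_best_model(list(mk("moser", 1)))$best$model_name,
               "moser")
  tie <- select_best_model(list(mk("contois", 2e-6), mk("tessier", 2e-6)))
  expect_equal(tie$best$model_name, "tessier") # simpler model wins ties
  expect_error(select_best_model(list()), "no successful fits")
})

test_that("rate curves satisfy r_x / r_su = Y_TSS and match hand values", {
  fit <- structure(list(model_name = "contois", mu_m = 0.2062, k = 0.0039,
                        n = NA_real_), class = "kinetic_fit")
  rc <- rate_curves(fit, x_t = 284.8, y_tss = 0.6687,
                    s_grid = c(0, 5, 23.0769))
  expect_equal(rc$r_su[1], 0)
  expect_equal(rc$r_x[1], 0)
  expect_equal(rc$r_x[-1] / rc$r_su[-1], rep(0.6687, 2),
               tolerance = 1e-12)
  # highest-concentration point: mu = 0.19673, r_su = mu * X_T / Y_TSS
  expect_equal(rc$r_su[3], 0.19673 * 284.8 / 0.6687, tolerance = 1e-4)
  expect_gt(rc$r_su[3], 60)
  expect_true(all(rc$r_su >= 0 & rc$r_x >= 0))
})

test_that("analyze_substrate aggregates replicates as mean and SD", {
  s <- c(6.18, 12.23, 17.31)
  reps <- lapply(1:3, function(r)
    make_points("monod", c(0.12, 5), s, rep(306, 3), noise_sd = 0.05,
                seed = r))
  rep_report <- analyze_substrate(reps, models = c("monod", "tessier"),
                                  substrate_label = "synthetic")
  expect_equal(rep_report$n_replicates, 3)
  tab <- rep_report$parameter_table
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$mu_m_sd)))
  expect_true(all(tab$mu_m_sd > 0))
  expect_equal(tab$mu_m[tab$model == "monod"], 0.12, tolerance = 0.15)

  expect_error(analyze_substrate(reps[[1]][1, , drop = FALSE]),
               "underdetermined|>= 2")
})
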