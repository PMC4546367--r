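test_that("growth curves evaluate their closed forms", {
  # logistic at t = ln(B)/k sits exactly at half the asymptote
  expect_equal(growth_curve("logistic", log(9) / 0.1, A = 100, B = 9, k = 0.1),
               50)
  # gompertz at t = 0 is A * exp(-B)
  expect_equal(growth_curve("gompertz", 0, A = 100, B = 1, k = 0.05),
               100 * exp(-1))
  # von Bertalanffy at t = 0: signed cube, no clamping
  expect_equal(growth_curve("von_bertalanffy", 0, A = 211.3, B = 0.8514,
                            k = 0.004849),
               211.3 * (1 - 0.8514)^3, tolerance = 1e-12)
  vb_neg <- growth_curve("von_bertalanffy", 0, A = 100, B = 1.5, k = 0.01)
  expect_equal(vb_neg, 100 * (1 - 1.5)^3)
  expect_lt(vb_neg, 0)
  expect_error(growth_curve("richards", 1, 1, 1, 1), "unknown growth model")
})

test_that("every model increases monotonically to its asymptote", {
  draws <- expand.grid(model = growth_models(),
                       A = c(50, 211.3), k = c(0.005, 0.05),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(draws))) {
    m <- draws$model[i]
    B <- switch(m, logistic = 9, gompertz = 4, von_bertalanffy = 0.85)
    # strictly increasing until the curve saturates at float resolution
    t <- seq(0, 15 / draws$k[i], length.out = 500)
    w <- growth_curve(m, t, draws$A[i], B, draws$k[i])
    expect_true(all(diff(w) > 0), info = m)
    expect_equal(growth_curve(m, 100 / draws$k[i], draws$A[i], B, draws$k[i]),
                 draws$A[i], tolerance = 1e-6)
  }
})

test_that("noiseless data recovers generating parameters exactly", {
  for (m in growth_models()) {
    truth <- switch(m,
      logistic = c(A = 100, B = 9, k = 0.1),
      gompertz = c(A = 100, B = 4, k = 0.03),
      von_bertalanffy = params_from_inflection(m, 193.40, 62.61, 0.45543))
    obs <- tibble::tibble(
      age_days = seq(0, 250, length.out = 20),
      weight_kg = growth_curve(m, seq(0, 250, length.out = 20),
                               truth[["A"]], truth[["B"]], truth[["k"]]))
    fit <- fit_growth_model(obs, m)
    expect_equal(fit$coefficients, truth, tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
    expect_lt(fit$rse, 1e-8)
  }
})

test_that("fit is invariant to observation order and guards bad input", {
  obs <- simulate_growth(growth_sim_config(noise_sd = 1, seed = 5))
  fit1 <- fit_growth_model(obs, "von_bertalanffy")
  fit2 <- fit_growth_model(obs[sample.int(nrow(obs)), ], "von_bertalanffy")
  expect_equal(fit1$coefficients, fit2$coefficients)
  expect_error(fit_growth_model(obs[1:3, ], "logistic"), "at least 4")
  flat <- tibble::tibble(age_days = 1:10, weight_kg = rep(5, 10))
  expect_error(fit_growth_model(flat, "logistic"), "degenerate")
})

test_that("noisy Gompertz fit agrees with an exhaustive grid-search oracle", {
  cfg <- growth_sim_config(model = "gompertz", A = 100, B = 4, k = 0.03,
                           noise_sd = 1, seed = 42)
  obs <- simulate_growth(cfg)
  fit <- fit_growth_model(obs, "gompertz")
  expect_equal(unname(fit$coefficients / c(100, 4, 0.03)), rep(1, 3),
               tolerance = 0.05)
  oracle <- oracle_grid_fit(obs, "gompertz",
                            A_grid = seq(80, 130, by = 2.5),
                            B_grid = exp(seq(log(1), log(12), length.out = 20)),
                            k_grid = seq(0.01, 0.06, length.out = 20))
  expect_lte(fit$rse, oracle$rss * (1 + 1e-6))
  expect_equal(unname(fit$coefficients / oracle$par), rep(1, 3),
               tolerance = 0.02)
})

test_that("R2 is 1 for perfect fits and decreases under added noise", {
  obs <- simulate_growth(growth_sim_config(noise_sd = 0))
  fit <- fit_growth_model(obs, "von_bertalanffy")
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  noisy <- simulate_growth(growth_sim_config(noise_sd = 2, seed = 3))
  fit_n <- fit_growth_model(noisy, "von_bertalanffy")
  expect_lt(fit_n$r2, 1)
  expect_equal(fit_n$r2, 1 - fit_n$rse / fit_n$rst)
})

test_that("closed-form inflection analytics match the printed identities", {
  ip <- inflection_point("logistic", A = 100, B = 9, k = 0.1)
  expect_equal(ip$t_star_days, log(9) / 0.1, tolerance = 1e-9)
  expect_equal(ip$w_star_kg, 50)
  expect_equal(ip$g_max_kg_day, 2.5)

  ip <- inflection_point("gompertz", A = 100, B = 1, k = 0.05)
  expect_equal(ip$t_star_days, 0)
  expect_equal(ip$w_star_kg, 100 / exp(1), tolerance = 1e-9)
  expect_equal(ip$g_max_kg_day, 0.05 * 100 / exp(1), tolerance = 1e-9)

  # G_max relations to W*: kW*/2, kW*, 3kW*/2
  for (m in growth_models()) {
    ip <- suppressWarnings(inflection_point(m, A = 80, B = 2, k = 0.02))
    mult <- switch(m, logistic = 0.5, gompertz = 1, von_bertalanffy = 1.5)
    expect_equal(ip$g_max_kg_day, 0.02 * ip$w_star_kg * mult,
                 tolerance = 1e-12, info = m)
    expect_gt(ip$w_star_kg, 0)
    expect_lt(ip$w_star_kg, 80)
  }
})

test_that("inflection before birth is returned as-is with a warning", {
  expect_warning(ip <- inflection_point("logistic", A = 100, B = 0.5, k = 0.1),
                 "before birth")
  expect_lt(ip$t_star_days, 0)
  expect_true(ip$before_birth)
})

test_that("numeric inflection search agrees with closed forms", {
  set.seed(101)
  for (m in growth_models()) {
    for (rep in 1:5) {
      A <- runif(1, 50, 300)
      B <- switch(m, logistic = runif(1, 2, 50), gompertz = runif(1, 1.2, 20),
                  von_bertalanffy = runif(1, 0.4, 1))
      k <- runif(1, 0.005, 0.1)
      closed <- inflection_point(m, A = A, B = B, k = k)
      numeric <- inflection_point_numeric(m, A = A, B = B, k = k,
                                          grid_step = 0.001)
      expect_lt(abs(closed$t_star_days - numeric$t_star_days), 0.001)
      expect_equal(numeric$g_max_kg_day, closed$g_max_kg_day,
                   tolerance = 1e-4)
    }
  }
})

test_that("model comparison ranks the generating model first at zero noise", {
  obs <- simulate_growth(growth_sim_config(noise_sd = 0))
  cmp <- compare_models(obs)
  expect_identical(cmp$model[1], "von_bertalanffy")
  expect_equal(cmp$r2[1], 1, tolerance = 1e-9)
  expect_true(all(diff(ifelse(cmp$ok, cmp$r2, -Inf)) <= 1e-6))
  expect_s3_class(attr(cmp, "fits")$logistic, "growth_fit")
})

test_that("tidy and glance return broom-shaped tibbles; predict round-trips", {
  obs <- simulate_growth(growth_sim_config(noise_sd = 0))
  fit <- fit_growth_model(obs, "von_bertalanffy")
  td <- tidy(fit)
  expect_identical(td$term, c("A", "B", "k"))
  gl <- glance(fit)
  expect_identical(names(gl), c("model", "rse", "rst", "r2", "n_obs"))
  expect_equal(predict(fit), obs$weight_kg, tolerance = 1e-6)
  expect_equal(predict(fit, t = 0),
               growth_curve("von_bertalanffy", 0, fit$coefficients[["A"]],
                            fit$coefficients[["B"]], fit$coefficients[["k"]]))
})

test_that("inflection triple inverts through params_from_inflection", {
  for (m in growth_models()) {
    p <- switch(m, logistic = c(A = 120, B = 15, k = 0.03),
                gompertz = c(A = 90, B = 5, k = 0.02),
                von_bertalanffy = c(A = 211.3, B = 0.8514, k = 0.004849))
    ip <- inflection_point(m, A = p[["A"]], B = p[["B"]], k = p[["k"]])
    back <- params_from_inflection(m, ip$t_star_days, ip$w_star_kg,
                                   ip$g_max_kg_day)
    expect_equal(back, p, tolerance = 1e-10)
  }
})
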