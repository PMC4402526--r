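test_that("single-force Michaelis-Menten fit recovers exact parameters", {
  D <- c(2, 5, 10, 50, 100, 200, 500)
  d <- fv_dataset(force = 0, dntp = D, velocity = 112 * D / (31 + D),
                  sem = 0, n = 1L)
  fit <- fit_mm_at_force(d)
  expect_true(fit$converged)
  expect_equal(fit$vmax, 112, tolerance = 1e-6)
  expect_equal(fit$km, 31, tolerance = 1e-6)

  # noiseless ratchet data at zero load: V_max = 1/(a+b), K_M = (r+s)/(a+b)
  d3 <- synthesize_fv_dataset(rel_noise = 0, forces = 0, dntps = D)
  fit3 <- fit_mm_at_force(d3)
  expect_equal(fit3$vmax, 101.01, tolerance = 1e-4)
  expect_equal(fit3$km, 31.3131, tolerance = 1e-4)
  expect_lt(abs(fit3$km - 31), 3)   # within the measured 31 +/- 3 uM
  expect_error(fit_mm_at_force(d3[1:2, ]), "3 dNTP levels")
})

test_that("global fit is exact on noiseless data from each model", {
  forces <- seq(-30, 20, by = 5)
  dntps <- c(5, 10, 50, 100, 200, 500)
  grid <- expand.grid(force = forces, dntp = dntps)

  # model 3
  d3 <- synthesize_fv_dataset(rel_noise = 0, forces = forces, dntps = dntps)
  f3 <- ratchet_fit(d3, model = 3, seed = 1)
  expect_lt(max(abs(coef(f3) - phi29_coefficients()) /
                  as.numeric(phi29_coefficients())), 1e-6)

  # model 1 truth: a = 1/k_cat, s = 1/k_on0, d_s = d_on
  m1 <- model1_rates(k_on0 = 5, k_off0 = 0, k_cat = 120, d_on = 0.35)
  d1 <- fv_dataset(grid$force, grid$dntp,
                   velocity_model1(grid$force, grid$dntp, m1), sem = 0)
  f1 <- ratchet_fit(d1, model = 1, seed = 1)
  expect_equal(coef(f1)[["a"]], 1 / 120, tolerance = 1e-6)
  expect_equal(coef(f1)[["s"]], 1 / 5, tolerance = 1e-6)
  expect_equal(coef(f1)[["d_s"]], 0.35, tolerance = 1e-5)

  # model 2 truth: a = 1/k_cat, b = (1 + k_mcat/k_cat)/k_ppi0, r = 1/k_on
  m2 <- model2_rates(k_on = 5, k_off = 0, k_cat = 120, k_mcat = 10,
                     k_ppi0 = 1e3, d_ppi = 0.35)
  d2 <- fv_dataset(grid$force, grid$dntp,
                   velocity_model2(grid$force, grid$dntp, m2), sem = 0)
  f2 <- ratchet_fit(d2, model = 2, seed = 1)
  expect_equal(coef(f2)[["a"]], 1 / 120, tolerance = 1e-5)
  expect_equal(coef(f2)[["b"]], (1 + 10 / 120) / 1e3, tolerance = 1e-4)
  expect_equal(coef(f2)[["r"]], 1 / 5, tolerance = 1e-6)
  expect_equal(coef(f2)[["d_b"]], 0.35, tolerance = 1e-4)
})

test_that("derived rates satisfy the algebraic closure exactly", {
  d <- synthesize_fv_dataset(rel_noise = 0.08, seed = 5,
                             forces = c(-30, -20, -15, -10, -5, 5, 20))
  fit <- ratchet_fit(d, model = 3, seed = 5)
  co <- coef(fit)
  dr <- fit$derived
  expect_equal(dr$rates$k_cat, 1 / co[["a"]], tolerance = 1e-12)
  expect_equal(dr$rates$k_T0, 1 / co[["b"]], tolerance = 1e-12)
  expect_equal(dr$rates$k_mT0 / dr$rates$k_T0, co[["s"]] / co[["r"]],
               tolerance = 1e-12)
  expect_equal(dr$rates$d_T, co[["d_b"]], tolerance = 1e-12)
  expect_equal(dr$rates$d_T + dr$rates$d_mT, co[["d_s"]], tolerance = 1e-12)
  expect_equal(dr$K_delta0, co[["r"]] / co[["s"]], tolerance = 1e-12)
  expect_equal(dr$dG_trans, -log(co[["r"]] / co[["s"]]), tolerance = 1e-12)
})

test_that("noisy parameter recovery lands near the generating truth", {
  d <- synthesize_fv_dataset(forces = c(-30, -20, -15, -10, -5, 5, 20),
                             rel_noise = 0.08, n_replicates = 8, seed = 11)
  fit <- ratchet_fit(d, model = 3, seed = 11)
  rel <- abs(coef(fit) - phi29_coefficients()) /
    as.numeric(phi29_coefficients())
  expect_lt(max(rel), 0.25)
})

test_that("bootstrap intervals behave like 90%-plus confidence sets", {
  truth <- as.numeric(phi29_coefficients())
  names(truth) <- names(unclass(phi29_coefficients()))
  n_seeds <- 20
  covered <- matrix(FALSE, n_seeds, 6, dimnames = list(NULL, names(truth)))
  for (i in seq_len(n_seeds)) {
    d <- synthesize_fv_dataset(forces = c(-30, -20, -15, -10, -5, 5, 20),
                               rel_noise = 0.08, n_replicates = 8,
                               seed = 2000 + i)
    fit <- ratchet_fit(d, model = 3, n_boot = 100, seed = 2000 + i,
                       n_starts = 4)
    ci <- confint(fit, level = 0.9)
    covered[i, ] <- ci[, 1] <= truth & truth <= ci[, 2]
  }
  # with 20 seeds, a true 90% coverage fails a >= 0.75 observed bound with
  # probability < 3%; this guards the claim without flaking
  expect_gte(mean(covered), 0.75)
})

test_that("fit object methods are coherent", {
  d <- synthesize_fv_dataset(rel_noise = 0.05, seed = 3)
  fit <- ratchet_fit(d, model = 3, n_boot = 30, seed = 3)
  expect_s3_class(fit, "ratchet_fit")
  expect_named(coef(fit), c("a", "b", "r", "s", "d_b", "d_s"))
  expect_length(fitted(fit), nrow(d))
  expect_equal(residuals(fit, "raw"), fitted(fit) - d$velocity)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_equal(AIC(fit), fit$aic, tolerance = 1e-9)

  # predict: velocity at the data equals fitted values
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-9)
  kmv <- predict(fit, data.frame(force = 0), type = "km_over_vmax")
  expect_equal(kmv, coef(fit)[["r"]] + coef(fit)[["s"]], tolerance = 1e-9)
  rup <- predict(fit, data.frame(dntp = 500), type = "rupture")
  expect_gt(rup, 40); expect_lt(rup, 60)

  # simulate: reproducible and mean-centred on the fitted values
  s1 <- simulate(fit, nsim = 2, seed = 8)
  s2 <- simulate(fit, nsim = 2, seed = 8)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(nrow(d), 2L))

  sm <- summary(fit)
  expect_s3_class(sm, "summary.ratchet_fit")
  expect_true(all(c("ci_lo", "ci_hi") %in% names(sm$table)))
  expect_output(print(fit), "Brownian ratchet")

  expect_error(ratchet_fit(d[d$force %in% c(-30, -25), ]), "unidentifiable")
})

test_that("prediction curves reproduce the closed-form decompositions", {
  co <- phi29_coefficients()
  pred <- model_predictions(co, forces = c(-20, 0, 20), dntps = c(2, 10, 500))
  expect_equal(pred$mm$inv_vmax[2], 0.0099, tolerance = 1e-9)
  expect_equal(pred$mm$km_over_vmax[2], 0.31, tolerance = 1e-9)
  expect_equal(pred$mm$km[2], 31.31, tolerance = 1e-3)
  expect_true(is.na(pred$rupture$force[1]))       # 2 uM: below criterion
  expect_equal(pred$rupture$force[3], 49.32, tolerance = 1e-3)

  # model-1 preset: flat 1/V_max; model-2 preset: flat K_M/V_max
  m1co <- mm_coefficients(a = 1 / 120, b = 1e-12, r = 1e-12, s = 0.2,
                          d_b = 0, d_s = 0.35)
  iv <- inv_vmax_curve <- vapply(c(-25, 0, 25), function(F) {
    1 / velocity_model3(F, 1e12, m1co)
  }, numeric(1))
  expect_lt(diff(range(iv)) / mean(iv), 1e-6)
})

test_that("model discrimination recovers each generating scheme", {
  forces <- c(-30, -20, -15, -10, -5, 5, 20)
  d3 <- synthesize_fv_dataset(forces = forces, rel_noise = 0.08, seed = 41)
  disc <- discriminate_models(d3, n_boot = 60, seed = 41)
  expect_equal(disc$best, 3)
  expect_true(disc$slopes$vmax_force_dependent)
  expect_true(disc$slopes$kb_force_dependent)

  # model-1 data: 1/V_max slope CI contains zero
  grid <- expand.grid(force = forces, dntp = c(5, 10, 50, 100, 200, 500))
  m1 <- model1_rates()
  v1 <- velocity_model1(grid$force, grid$dntp, m1)
  set.seed(42)
  d1 <- fv_dataset(grid$force, grid$dntp,
                   stats::rnorm(nrow(grid), v1, 0.08 * v1 / sqrt(8)),
                   sem = 0.08 * v1 / sqrt(8), n = 8)
  disc1 <- discriminate_models(d1, n_boot = 60, seed = 42)
  expect_false(disc1$slopes$vmax_force_dependent)
  expect_true(disc1$slopes$kb_force_dependent)
  expect_true(disc1$table$model[1] %in% c(1, 3))
})
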