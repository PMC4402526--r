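test_that("Bell rates match direct exponential evaluation", {
  expect_identical(bell_rate(670, 0.35, 0), 670)
  # frozen scalar evaluations of k0 * exp(F d / kBT), checked in log space
  expect_equal(bell_rate(670, 0.35, -20, kBT = 4.075), 120.23959, tolerance = 1e-6)
  expect_equal(log(bell_rate(670, 0.35, -20, kBT = 4.075)),
               log(670) - 20 * 0.35 / 4.075, tolerance = 1e-12)
  expect_equal(bell_rate(420, -0.05, -20, kBT = 4.075), 536.8154, tolerance = 1e-6)
  # monotone in F for fixed positive d
  F <- seq(-30, 30, by = 1)
  expect_true(all(diff(bell_rate(100, 0.4, F)) > 0))
  expect_error(bell_rate(-1, 0.3, 0), "k0")
  expect_error(bell_rate(1, 0.3, 0, kBT = 0), "kBT")
})

test_that("ratchet closed form reproduces hand-evaluated velocities", {
  co <- phi29_coefficients()
  # 1/v = a + b + (r + s)/500 at zero load
  expect_equal(velocity_model3(0, 500, co), 1 / (0.0099 + 0.31 / 500),
               tolerance = 1e-12)
  expect_equal(velocity_model3(0, 500, co), 95.057, tolerance = 1e-4)
  expect_equal(velocity_model3(-10, 500, co), 77.153, tolerance = 1e-4)
  # consistent with the measured positive peak 79 +/- 6 bp/s at -10 pN
  expect_lt(abs(velocity_model3(-10, 500, co) - 79), 6)
  # saturating limit 1/(a+b)
  expect_equal(velocity_model3(0, 1e12, co), 101.01, tolerance = 1e-3)
  expect_identical(velocity_model3(-10, 0, co), 0)
  expect_error(velocity_model3(0, -1, co), "dntp")
})

test_that("power-stroke closed forms have their defining signatures", {
  m1 <- model1_rates(k_on0 = 5, k_off0 = 0, k_cat = 120, d_on = 0.35)
  # frozen: 1/v = 1/120 + 1/(5*31)
  expect_equal(velocity_model1(0, 31, m1), 67.6364, tolerance = 1e-5)
  # V_max is force independent by construction
  expect_equal(velocity_model1(-20, 1e16, m1), velocity_model1(20, 1e16, m1),
               tolerance = 1e-12)
  expect_equal(velocity_model1(0, 1e16, m1), 120, tolerance = 1e-9)
  expect_lt(velocity_model1(-20, 500, m1), velocity_model1(0, 500, m1))

  m2 <- model2_rates(k_on = 5, k_off = 0, k_cat = 120, k_mcat = 10,
                     k_ppi0 = 1e4, d_ppi = 0.35)
  # frozen: 1/v = 1e-4 + (1/120)(1 + 1e-3)
  expect_equal(velocity_model2(0, 1e14, m2), 118.46, tolerance = 1e-4)
  # K_M/V_max varies < 5% over |F| <= 25 pN when k_mcat/k_ppi << 1, even
  # with substantial unbinding feeding the force-dependent correction
  m2b <- model2_rates(k_on = 5, k_off = 100, k_cat = 120, k_mcat = 10,
                      k_ppi0 = 1e4, d_ppi = 0.35)
  kb_inv <- function(F) {
    vs <- velocity_model2(F, c(1e7, 10), m2b)
    (1 / vs[2] - 1 / vs[1]) * 10   # (1/v - 1/Vmax) * D
  }
  vals <- vapply(seq(-25, 25, by = 5), kb_inv, numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 0.05)
  # strong hindering load stalls the PPi-coupled cycle
  expect_lt(velocity_model2(-200, 500, m2), 1e-3)
})

test_that("unicyclic solver handles symmetry and rate-limiting cases", {
  ss <- unicycle_steady_state(c(1, 1), c(1, 1))
  expect_equal(ss$occupancy, c(0.5, 0.5))
  expect_equal(ss$velocity, 0)
  # one rate 1000x slower than the rest limits the flux
  ss <- unicycle_steady_state(c(1000, 1000, 1), c(0, 0, 0))
  expect_equal(ss$velocity, 1, tolerance = 3e-3)
  expect_error(unicycle_steady_state(c(0, 0), c(1, 1)), "degenerate")
  expect_error(unicycle_steady_state(1, numeric(0)), "length")
})

test_that("unicyclic solver agrees with matrix-exponential propagation", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  for (i in 1:5) {
    n <- sample(2:5, 1)
    fw <- 10^runif(n, 0, 2)
    bw <- 10^runif(n, -1, 2) * rbinom(n, 1, 0.7)
    ss <- unicycle_steady_state(fw, bw)
    ref <- expm_cycle_steady_state(fw, bw)
    expect_equal(ss$occupancy, ref$occupancy, tolerance = 1e-6)
    expect_equal(ss$velocity, ref$velocity, tolerance = 1e-6)
  }
})

test_that("closed forms equal the master-equation flux on random parameters", {
  set.seed(7)
  for (i in 1:30) {
    F <- runif(1, -30, 20); D <- 10^runif(1, 0, 3); kBT <- kbt()
    rr <- random_ratchet_rates()
    ss <- unicycle_steady_state(
      c(bell_rate(rr$k_T0, rr$d_T, F), rr$k_on * D, rr$k_cat),
      c(bell_rate(rr$k_mT0, -rr$d_mT, F), rr$k_off, 0))
    expect_equal(velocity_from_rates(rr, F, D), ss$velocity, tolerance = 1e-8)

    m1 <- random_model1_rates()
    ss1 <- unicycle_steady_state(
      c(bell_rate(m1$k_on0, m1$d_on, F) * D, m1$k_cat),
      c(if (m1$k_off0 > 0) bell_rate(m1$k_off0, -m1$d_off, F) else 0, 0))
    expect_equal(velocity_model1(F, D, m1), ss1$velocity, tolerance = 1e-8)

    m2 <- random_model2_rates()
    ss2 <- unicycle_steady_state(
      c(m2$k_on * D, m2$k_cat, bell_rate(m2$k_ppi0, m2$d_ppi, F)),
      c(m2$k_off, m2$k_mcat, 0))
    expect_equal(velocity_model2(F, D, m2), ss2$velocity, tolerance = 1e-8)
  }
})

test_that("coefficient-rate mapping reproduces the printed relations", {
  # k_cat ~ 1/a, k_T(0) = 1/b, K_delta(0) = r/s
  co <- phi29_coefficients()
  rr <- rates_from_coefficients(co)
  expect_equal(rr$k_cat, 1 / 0.0084, tolerance = 1e-12)   # ~119, printed 120
  expect_lt(abs(rr$k_cat - 120) / 120, 0.01)
  expect_equal(rr$k_T0, 1 / 0.0015, tolerance = 1e-12)    # ~667, printed 670
  expect_lt(abs(rr$k_T0 - 670) / 670, 0.01)
  expect_equal(0.19 / 0.12, rr$k_T0 / rr$k_mT0, tolerance = 1e-12)  # K_delta
  expect_lt(abs(0.19 / 0.12 - 1.59) / 1.59, 0.01)
  expect_equal(rr$d_T, 0.35)
  expect_equal(rr$d_mT, 0.05, tolerance = 1e-12)
  expect_error(rates_from_coefficients(
    mm_coefficients(0.01, 0.001, 0.2, 0.1, 0.5, 0.3)), "d_s < d_b")
})

test_that("coefficient-rate round trip is the identity", {
  set.seed(11)
  for (i in 1:20) {
    rr <- random_ratchet_rates()
    co <- coefficients_from_rates(rr)
    back <- rates_from_coefficients(co,
                                    k_off_over_kcat = rr$k_off / rr$k_cat,
                                    k_ppi = rr$k_ppi)
    for (nm in names(unclass(rr))) {
      expect_equal(back[[nm]], rr[[nm]], tolerance = 1e-12)
    }
    # forward again
    co2 <- coefficients_from_rates(back)
    expect_equal(as.numeric(co2), as.numeric(co), tolerance = 1e-12)
  }
})

test_that("occupancies are a distribution obeying M_bound = v / k_cat", {
  set.seed(13)
  for (i in 1:15) {
    rr <- random_ratchet_rates()
    oc <- occupancy(rr, runif(1, -30, 20), 10^runif(1, 0, 3))
    expect_equal(sum(oc$per_state), 1, tolerance = 1e-12)
    expect_equal(oc$M_free + oc$M_bound, 1, tolerance = 1e-12)
    expect_equal(oc$M_bound, oc$velocity / rr$k_cat, tolerance = 1e-9)
  }
  # extreme hindering load empties the post and bound states
  oc <- occupancy(phi29_rates(), -500, 500)
  expect_lt(oc$M_bound, 1e-6)
  expect_gt(oc$per_state[["pre_free"]], 1 - 1e-5)
  # saturating dNTP: M_bound = V_max / k_cat
  oc <- occupancy(phi29_rates(), 0, 1e9)
  expect_equal(oc$M_bound, 0.848, tolerance = 1e-3)
})

test_that("translocation landscape matches the fitted energetics", {
  rr <- phi29_rates()
  l0 <- translocation_landscape(rr, 0)
  expect_equal(l0$K_delta, 670 / 420, tolerance = 1e-12)
  expect_equal(l0$dG_trans, -0.467, tolerance = 1e-3)  # printed -0.46 kBT
  expect_equal(l0$delta, 0.40, tolerance = 1e-12)
  # symmetric landscape has zero free-energy change
  sym <- ratchet_rates(k_T0 = 500, k_mT0 = 500)
  expect_equal(translocation_landscape(sym, 0)$dG_trans, 0)
  # hindering load disfavors the post state: dG(F) = dG(0) - F delta / kBT
  l10 <- translocation_landscape(rr, -10, kBT = 4.075)
  expect_equal(l10$dG_trans, l0$dG_trans + 10 * 0.40 / 4.075, tolerance = 1e-6)
  expect_equal(l10$dG_trans, 0.515, tolerance = 1e-2)
  expect_equal(l10$barrier_shift, 10 * 0.35 / 4.075, tolerance = 1e-12)
})

test_that("translocation equilibrium is thermodynamically consistent", {
  set.seed(17)
  for (i in 1:10) {
    rr <- random_ratchet_rates()
    F <- runif(1, -40, 25)
    K0 <- translocation_landscape(rr, 0)$K_delta
    KF <- translocation_landscape(rr, F)$K_delta
    expect_equal(KF / K0, exp(F * (rr$d_T + rr$d_mT) / kbt()),
                 tolerance = 1e-12)
  }
})

test_that("rupture load prediction is monotone and handles no-root input", {
  co <- phi29_coefficients()
  expect_equal(rupture_force(co, 500), 49.318, tolerance = 1e-4)
  expect_equal(rupture_force(co, 10), 22.137, tolerance = 1e-4)
  # at 2 uM the zero-load velocity is already below 7 nt/s: no root
  expect_true(is.na(rupture_force(co, 2)))
  expect_lt(rupture_force(co, 200), rupture_force(co, 500))
  # the solved root actually satisfies the detachment criterion
  f500 <- rupture_force(co, 500)
  expect_equal(velocity_model3(-f500, 500, co), 7, tolerance = 1e-5)
})

test_that("ratchet velocity is monotone in load and substrate and bounded", {
  co <- phi29_coefficients()
  F <- seq(-45, 20, by = 1)
  for (D in c(5, 50, 500)) {
    expect_true(all(diff(velocity_model3(F, D, co)) > 0))
  }
  D <- c(1, 2, 5, 10, 50, 100, 200, 500, 1000)
  for (f in c(-25, -10, 0, 15)) {
    v <- velocity_model3(f, D, co)
    expect_true(all(diff(v) > 0))
    rr <- rates_from_coefficients(co)
    expect_true(all(v <= min(rr$k_cat, bell_rate(rr$k_T0, rr$d_T, f)) + 1e-9))
  }
})
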