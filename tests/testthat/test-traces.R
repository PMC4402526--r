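test_that("sliding-window velocity is exact on linear signals", {
  nt <- 50 * (0:299) / 60
  v <- instantaneous_velocity(nt, 60, 50)
  expect_length(v, 300 - 50 + 1)
  expect_equal(as.numeric(v), rep(50, 251), tolerance = 1e-9)
  # window centers map back into the time base
  expect_equal(attr(v, "centers")[1], (1 + 50) / 2)
  expect_error(instantaneous_velocity(nt[1:40], 60, 50), "insufficient")
})

test_that("a velocity step is resolved within one window", {
  nt <- c(rep(0, 150), 100 * (1:150) / 60)
  v <- as.numeric(instantaneous_velocity(nt, 60, 50))
  expect_equal(v[1:90], rep(0, 90), tolerance = 1e-9)
  expect_equal(v[length(v)], 100, tolerance = 1e-9)
  trans <- v[91:170]
  expect_true(all(diff(trans) > -1e-9))   # monotone transition
  expect_lt(sum(v > 1 & v < 99), 51)      # completed within one window
})

test_that("window-average velocity matches the closed form on synthetic traces", {
  cfg <- sim_config(dntp = 500, schedule = constant_force(-10),
                    pause_entry_rate = 0, seed = 42)
  tr <- synthesize_trace(cfg)
  nt <- nucleotides_from_distance(tr)
  v <- instantaneous_velocity(nt, 60, 50)
  v_true <- velocity_from_rates(phi29_rates(), -10, 500)
  se <- stats::sd(v) / sqrt(3487)  # >= SE of the mean over ~3487 cycles
  expect_lt(abs(mean(v) - v_true), 3 * max(se, v_true / sqrt(3487)))
})

test_that("velocity histogram mixture separates active and paused states", {
  set.seed(1)
  # constructed mixture: paused samples near 0, active near 80
  v <- c(rnorm(2000, 0, 4), rnorm(6000, 80, 9))
  d <- velocity_distribution(v)
  expect_false(d$fallback)
  expect_equal(d$components["zero", "mean"], 0, tolerance = 0.5)
  expect_equal(d$components["positive", "mean"], 80, tolerance = 0.02)
  expect_equal(d$components["positive", "weight"], 0.75, tolerance = 0.1)
  expect_equal(sum(d$components$weight), 1, tolerance = 1e-9)
  # pure noise around zero: no positive component
  d0 <- velocity_distribution(rnorm(3000, 0, 3))
  expect_equal(d0$components["positive", "weight"], 0)
  expect_equal(d0$components["zero", "mean"], 0, tolerance = 0.5)
})

test_that("positive-peak means track the closed form across loads", {
  peaks <- vapply(c(-10, -15, -25), function(F) {
    v_all <- unlist(lapply(1:2, function(i) {
      tr <- synthesize_trace(sim_config(dntp = 500,
                                        schedule = constant_force(F),
                                        seed = 100 + 10 * abs(F) + i))
      nt <- nucleotides_from_distance(tr)
      as.numeric(instantaneous_velocity(nt, 60, 50))
    }))
    velocity_distribution(v_all)$components["positive", "mean"]
  }, numeric(1))
  truth <- velocity_from_rates(phi29_rates(), c(-10, -15, -25), 500)
  # 3-SE criterion with the peak SE dominated by trace-to-trace scatter
  expect_lt(max(abs(peaks - truth)), 5)
  expect_true(all(diff(peaks) < 0))
})

test_that("pause detector flags injected pauses and only them", {
  # noiseless constructed trace: 80 nt/s with one 1-s pause at t = 5 s
  sr <- 60
  t <- (0:899) / sr
  active <- !(t >= 5 & t < 6)
  nt <- cumsum(active * 80 / sr)
  ps <- detect_pauses(nt, sr, v_threshold = 40)
  expect_equal(nrow(ps$intervals), 1L)
  ov <- min(ps$intervals[1, 2], 6) - max(ps$intervals[1, 1], 5)
  expect_gt(ov / 1, 0.8)   # >= 80% overlap with the injected pause
  # pause-free noiseless ramp yields an empty pause set
  ps0 <- detect_pauses(cumsum(rep(80 / sr, 900)), sr, v_threshold = 40)
  expect_equal(nrow(ps0$intervals), 0L)
  expect_equal(ps0$with_pauses_rate, ps0$without_pauses_rate, tolerance = 1e-9)
})

test_that("a half-paused trace halves the with-pauses rate", {
  sr <- 60
  t <- (0:7199) / sr
  active <- (t %/% 10) %% 2 == 0   # 10 s on, 10 s off
  nt <- cumsum(active * 80 / sr)
  ps <- detect_pauses(nt, sr, v_threshold = 40)
  expect_equal(ps$with_pauses_rate, 40, tolerance = 0.05)
  expect_equal(ps$without_pauses_rate, 80, tolerance = 0.05)
})

test_that("detector sensitivity and precision reach 0.9 on long pauses", {
  hits <- 0L; n_true <- 0L; matched_det <- 0L; n_det <- 0L
  for (i in 1:12) {
    tr <- synthesize_trace(sim_config(dntp = 500,
                                      schedule = constant_force(-10),
                                      pause_entry_rate = 0.08,
                                      pause_mean_duration = 1.2,
                                      seed = 600 + i))
    truth <- attr(tr, "pauses")
    nt <- nucleotides_from_distance(tr)
    det <- detect_pauses(nt, 60)$intervals
    overlap <- function(a, b) {
      max(0, min(a[2], b[2]) - max(a[1], b[1]))
    }
    if (nrow(truth) > 0) {
      long <- truth[truth[, 2] - truth[, 1] >= 0.8, , drop = FALSE]
      n_true <- n_true + nrow(long)
      for (j in seq_len(nrow(long))) {
        ovs <- if (nrow(det) > 0) {
          vapply(seq_len(nrow(det)),
                 function(k) overlap(long[j, ], det[k, ]), numeric(1))
        } else 0
        if (max(ovs) >= 0.5 * (long[j, 2] - long[j, 1])) hits <- hits + 1L
      }
    }
    n_det <- n_det + nrow(det)
    for (k in seq_len(nrow(det))) {
      ovs <- if (nrow(truth) > 0) {
        vapply(seq_len(nrow(truth)),
               function(j) overlap(truth[j, ], det[k, ]), numeric(1))
      } else 0
      if (max(ovs) > 0) matched_det <- matched_det + 1L
    }
  }
  expect_gt(n_true, 10)
  expect_gte(hits / n_true, 0.9)
  expect_gte(matched_det / n_det, 0.9)
})

test_that("average rates follow the line-fit definitions", {
  # exact staircase: 100 nt in 2 s
  sr <- 60
  nt <- seq(0, 100, length.out = 121)
  expect_equal(average_rate(nt, sr), 50, tolerance = 1e-9)
  expect_error(average_rate(numeric(1)), "at least 2")

  # excising ground-truth pauses recovers the pause-free velocity
  cfg <- sim_config(dntp = 500, schedule = constant_force(-10),
                    pause_entry_rate = 0.08, seed = 77)
  tr <- synthesize_trace(cfg)
  nt <- nucleotides_from_distance(tr)
  truth_ps <- structure(list(intervals = attr(tr, "pauses")),
                        class = "pause_set")
  v_ex <- average_rate(nt, 60, exclude = truth_ps)
  v_true <- velocity_from_rates(phi29_rates(), -10, 500)
  expect_lt(abs(v_ex - v_true), 3 * v_true / sqrt(3487) + 1)
})

test_that("per-force pooling follows the +/- 2.5 pN rule", {
  forces <- c(-9, -10.4, -11, -20, -19.2)
  rates <- c(80, 78, 82, 40, 44)
  pooled <- pool_rates_by_force(forces, rates, centers = c(-10, -20))
  expect_equal(pooled$velocity[pooled$force == -10], 80)
  expect_equal(pooled$velocity[pooled$force == -20], 42)
  expect_equal(pooled$n, c(3, 2))
  expect_true(all(pooled$sem > 0))
})

test_that("analyze_trace composes the per-trace pipeline", {
  cfg <- sim_config(dntp = 500, schedule = constant_force(-10), seed = 9)
  rep <- analyze_trace(synthesize_trace(cfg))
  expect_s3_class(rep, "trace_report")
  expect_false(rep$distribution$fallback)
  v_true <- velocity_from_rates(phi29_rates(), -10, 500)
  expect_lt(abs(rep$rates$without_pauses - v_true), 0.1 * v_true)
  expect_lte(rep$rates$with_pauses, rep$rates$without_pauses + 1e-9)
})
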