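make_record <- function(tris, total, dur = 3, temp = 39, amend = "none",
                        rep = 1L, ct = 10) {
  tibble::tibble(temperature_C = temp, amendment = amend, replicate = rep,
                 duration_d = dur, tris_cpm = tris, total_cpm = total,
                 counting_time_min = ct)
}

test_that("the rate equation reproduces hand arithmetic", {
  # 26.2 mM sulfate, TRIS/TOT = 1e-5, 3 d:
  # 26200 * 1.06 * 1e-5 / 3 = 0.0925733 nmol/ml/d
  r <- compute_srr(make_record(tris = 100, total = 1e7), sulfate_mM = 26.2)
  expect_equal(r$rate_nmol_ml_d, 26200 * 1.06 * 1e-5 / 3)
  expect_equal(r$rate_nmol_ml_d, 0.0925733, tolerance = 1e-6)

  # TRIS equal to the background sum -> rate clamps to zero
  bg <- background_model(counter = 30, distillation = 50, tracer = 20)
  r0 <- compute_srr(make_record(tris = 100, total = 1e7), 26.2,
                    background = bg)
  expect_equal(r0$rate_nmol_ml_d, 0)
  expect_false(r0$above_detection)
})

test_that("rate is linear in TRIS counts and inverse in duration and total", {
  base <- compute_srr(make_record(50, 1e6), 26.2)$rate_nmol_ml_d
  expect_equal(compute_srr(make_record(100, 1e6), 26.2)$rate_nmol_ml_d,
               2 * base)
  expect_equal(compute_srr(make_record(50, 2e6), 26.2)$rate_nmol_ml_d,
               base / 2)
  expect_equal(compute_srr(make_record(50, 1e6, dur = 6), 26.2)$rate_nmol_ml_d,
               base / 2)
  expect_equal(compute_srr(make_record(50, 1e6), 52.4)$rate_nmol_ml_d,
               2 * base)
})

test_that("degenerate tracer accounting is rejected", {
  bg <- background_model(counter = 200)
  expect_error(compute_srr(make_record(10, 100), 26.2, background = bg),
               "tracer accounting")
  expect_error(compute_srr(make_record(10, 100, dur = -1), 26.2), "duration")
  expect_error(compute_srr(make_record(10, 100), -5), "sulfate")
})

test_that("time-course mode recovers the rate from the fraction slope", {
  times <- 1:5
  true_rate <- 0.05
  frac <- true_rate * times / (26200 * 1.06)
  inc <- tibble::tibble(temperature_C = 39, amendment = "none",
                        replicate = 1L, duration_d = times,
                        tris_cpm = frac * 1e7, total_cpm = 1e7,
                        counting_time_min = 10)
  r <- compute_srr(inc, 26.2, mode = "timecourse")
  expect_equal(r$rate_nmol_ml_d, true_rate, tolerance = 1e-10)
  # endpoint mode on the same series uses the final point only
  r2 <- compute_srr(inc, 26.2, mode = "endpoint")
  expect_equal(r2$rate_nmol_ml_d, true_rate, tolerance = 1e-10)
})

test_that("detection limit matches hand arithmetic and is monotone", {
  # B = 100 cpm, k = 3, 10 min: 26200*1.06*(100 + 3*sqrt(10)) / (1e7*3)
  bg <- background_model(counter = 100)
  mdl <- detection_limit(bg, 26.2, 3, 1e7, 10)
  expect_equal(mdl, 26200 * 1.06 * (100 + 3 * sqrt(10)) / (1e7 * 3))
  expect_equal(mdl, 0.1013556, tolerance = 1e-6)

  expect_equal(detection_limit(background_model(), 26.2, 3, 1e7, 10), 0)

  # monotone increasing in every background term
  base_bg <- list(counter = 5, distillation = 4, tracer = 3, seawater = 2)
  mdl0 <- detection_limit(do.call(background_model, base_bg), 26.2, 3, 1e7, 10)
  for (term in names(base_bg)) {
    bumped <- base_bg
    bumped[[term]] <- bumped[[term]] * 2
    expect_gt(detection_limit(do.call(background_model, bumped),
                              26.2, 3, 1e7, 10), mdl0)
  }

  # mdl scales as 1/(a_TOT * t): doubling duration halves it
  expect_equal(detection_limit(bg, 26.2, 6, 1e7, 10), mdl / 2)
  expect_equal(detection_limit(bg, 26.2, 3, 2e7, 10), mdl / 2)

  expect_error(detection_limit(bg, 26.2, 3, 1e7, 0), "counting time")

  # k -> 0 collapses the threshold to the background-equivalent rate
  expect_equal(detection_limit(bg, 26.2, 3, 1e7, 10, k = 0),
               26200 * 1.06 * 100 / (1e7 * 3))
})

test_that("replicates aggregate to mean and range", {
  rates <- tibble::tibble(temperature_C = c(39, 39), amendment = "none",
                          rate_nmol_ml_d = c(0.04, 0.06),
                          mdl_nmol_ml_d = 0.001)
  agg <- aggregate_replicates(rates)
  expect_equal(agg$rate_nmol_ml_d, 0.05)
  expect_equal(agg$rate_min, 0.04)
  expect_equal(agg$rate_max, 0.06)
  expect_equal(agg$n_replicates, 2L)
  expect_true(agg$above_detection)

  single <- aggregate_replicates(rates[1, ])
  expect_equal(single$rate_min, single$rate_max)
  expect_equal(single$rate_nmol_ml_d, 0.04)

  expect_error(aggregate_replicates(rates[0, ]), "no replicate")

  # mixed conditions stay separate rows
  mixed <- tibble::tibble(temperature_C = c(39, 63), amendment = "none",
                          rate_nmol_ml_d = c(0.05, 0.01),
                          mdl_nmol_ml_d = 0)
  expect_equal(nrow(aggregate_replicates(mixed)), 2L)
})

test_that("temperature optima are detected with the plateau and endpoint rules", {
  curve <- sim_thermal_profile(data.frame(t_opt = 44, width = 6,
                                          peak_rate = 0.14))
  opt <- find_topt(curve)
  expect_equal(nrow(opt), 1L)
  grid <- default_temperature_grid()
  expect_equal(opt$temperature_C, grid[which.min(abs(grid - 44))])
  expect_true(opt$global)

  # monotonically increasing curve: single optimum at the top endpoint
  mono <- tibble::tibble(temperature_C = c(10, 20, 30, 40),
                         rate = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(find_topt(mono)$temperature_C, 40)

  # plateau reports its lowest temperature
  plat <- tibble::tibble(temperature_C = c(10, 20, 30, 40, 50),
                         rate = c(0.01, 0.05, 0.05, 0.05, 0.02))
  expect_equal(find_topt(plat)$temperature_C, 20)

  expect_error(find_topt(mono[1:2, ]), "at least 3")

  # three-population profile yields three optima near the planted t_opts
  tri <- sim_thermal_profile(three_populations())
  opt3 <- find_topt(tri)
  expect_equal(nrow(opt3), 3L)
  step <- diff(default_temperature_grid())[1]
  expect_true(all(abs(opt3$temperature_C - c(33, 50, 74)) <= step))
  expect_equal(sum(opt3$global), 1L)
})

test_that("below-detection points are excluded from optima", {
  cv <- tibble::tibble(temperature_C = c(10, 20, 30, 40, 50),
                       rate_nmol_ml_d = c(0.01, 0.05, 0.01, 0.03, 0.01),
                       above_detection = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(find_topt(cv)$temperature_C, 20)
})

test_that("amendment ratios compare curves pointwise", {
  a <- tibble::tibble(temperature_C = c(10, 20, 30),
                      rate_nmol_ml_d = c(0.02, 0.04, 0.08))
  expect_equal(amendment_ratio(a, a)$ratio, rep(1, 3))
  b <- dplyr::mutate(a, rate_nmol_ml_d = rate_nmol_ml_d * 10)
  expect_equal(amendment_ratio(a, b)$ratio, rep(0.1, 3))

  # 8x boost planted at 77 degC
  grid <- tibble::tibble(temperature_C = c(65, 71, 77, 83),
                         rate_nmol_ml_d = c(0.01, 0.01, 0.01, 0.01))
  boosted <- dplyr::mutate(grid, rate_nmol_ml_d =
                             ifelse(temperature_C == 77, 0.08, 0.015))
  rr <- amendment_ratio(boosted, grid)
  expect_equal(rr$ratio[rr$temperature_C == 77], 8)

  disjoint <- dplyr::mutate(a, temperature_C = temperature_C + 5)
  expect_error(amendment_ratio(a, disjoint), "share no temperature")

  # below-detection points are omitted
  bdet <- dplyr::mutate(a, above_detection = c(TRUE, FALSE, TRUE))
  expect_equal(nrow(amendment_ratio(bdet, a)), 2L)
})

test_that("simulated incubations round-trip through compute_srr without bias", {
  # modest-n version of the estimator-recovery property
  rates <- vapply(1:25, function(s) {
    inc <- sim_incubations(true_rate = 0.05, seed = s)
    mean(compute_srr(inc, 26.2, background_model(counter = 1,
                                                 distillation = 1))$rate_nmol_ml_d)
  }, numeric(1))
  expect_equal(mean(rates), 0.05, tolerance = 0.02)
})
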