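test_that("cohort generation is deterministic for a fixed config and seed", {
  cfg <- cohort_config(n_cells = 3, seed = 17)
  a <- simulate_pn_cohort(cfg)
  b <- simulate_pn_cohort(cfg)
  expect_identical(a$sweeps$vm, b$sweeps$vm)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_pn_cohort(cohort_config(n_cells = 3, seed = 18))
  expect_false(identical(a$sweeps$vm, c2$sweeps$vm))
})

test_that("zero-noise spiking patterns equal the fate labels exactly", {
  coh <- simulate_pn_cohort(cohort_config(n_cells = 24, seed = 5, noise_sd = 0))
  pat <- coh$truth_by_temp |>
    dplyr::arrange(.data$cell_id, .data$temperature) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(pat = paste(ifelse(.data$spikes, "T", "F"), collapse = ""),
                     .groups = "drop")
  want <- c(never = "FFF", stay = "TTT", stop = "TTF", start = "FFT")
  expect_identical(pat$pat, unname(want[coh$truth$fate]))
  # detection agrees with the generator's inserted spikes on every sweep
  f <- sweep_features(coh$sweeps)
  bycell <- f |>
    dplyr::group_by(.data$cell_id, .data$temperature) |>
    dplyr::summarise(spk = any(.data$spike_count > 0), .groups = "drop")
  merged <- dplyr::inner_join(bycell, coh$truth_by_temp,
                              by = c("cell_id", "temperature"))
  expect_identical(merged$spk, merged$spikes)
})

test_that("single forced STAY and NEVER cells behave as constructed", {
  stay <- simulate_pn_cohort(cohort_config(
    n_cells = 1, fate_mix = c(0, 1, 0, 0), noise_sd = 0, seed = 2))
  expect_true(all(stay$truth_by_temp$spikes))
  never <- simulate_pn_cohort(cohort_config(
    n_cells = 1, fate_mix = c(1, 0, 0, 0), noise_sd = 0, seed = 2))
  expect_false(any(never$truth_by_temp$spikes))
})

test_that("F-I spike counts are nondecreasing in current at zero noise", {
  set.seed(4)
  for (rep in 1:5) {
    rin <- runif(1, 80, 250)
    theta <- runif(1, -45, -38)
    fi <- simulate_fi_sweeps(rin, theta, current_steps = seq(10, 300, by = 10))
    rf <- rheobase_and_fi(fi)
    expect_true(all(diff(rf$fi_curve$n_spikes) >= 0))
    expect_equal(rf$rheobase_pa,
                 fi_analytic_rheobase(rin, theta, seq(10, 300, by = 10))$grid_pa)
  }
})

test_that("PSP amplitude and threshold are positively coupled in STAY cells", {
  coh <- simulate_pn_cohort(cohort_config(
    n_cells = 40, fate_mix = c(0, 1, 0, 0), seed = 1))
  top <- max(coh$config$temperatures)
  at39 <- dplyr::filter(coh$truth_by_temp, .data$temperature == top)
  res <- pearson_test(at39$theta, at39$epsp_amp)
  expect_gt(res$estimate, 0)
  expect_lt(res$p.value, 0.05)
})

test_that("unit durations follow the planted bimodal mixture", {
  u <- simulate_unit_population(n_units = 633, interneuron_frac = 0.221, seed = 7)
  frac <- mean(u$true_class == "interneuron")
  expect_lt(abs(frac - 0.221), 0.03 + 1e-12)
  narrow <- mean(u$true_duration_ms < 0.6)
  expect_lt(abs(narrow - 0.221), 0.03 + 1e-12)
  # inverted mixture means are rejected
  expect_error(simulate_unit_population(
    n_units = 10, duration_mixture = list(narrow = c(mean = 1, sd = 0.1),
                                          wide = c(mean = 0.4, sd = 0.1))),
    "narrow")
})

test_that("spike trains realise the nominal rates with a refractory floor", {
  set.seed(12)
  tr <- feverspike:::dead_time_train(0, 8700, 2)
  expect_gt(min(diff(tr)), 0.002 - 1e-12)
  expect_lt(abs(length(tr) - 17400), 4 * sqrt(17400))
  # gain = 1 leaves the period rates equal within sampling error
  u <- simulate_unit_population(n_units = 12, fever_gain = c(mean = 1, sd = 0),
                                base_rate = c(meanlog = log(3), sdlog = 0), seed = 3)
  pr <- unit_period_rates(u)
  spread <- pr |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(rel = diff(range(.data$rate_hz)) / mean(.data$rate_hz))
  expect_lt(mean(spread$rel), 0.1)
})

test_that("body-temperature series sampling and bouts", {
  tb0 <- simulate_body_temperature(6, fluct = 0, n_fever_bouts = 0, seed = 1)
  expect_equal(nrow(tb0), 72)              # 6 h at 5-min sampling
  expect_true(all(tb0$tb_c == 36.5))
  tb2 <- simulate_body_temperature(6, n_fever_bouts = 2, seed = 9)
  expect_equal(summarize_tb(tb2)$n_bouts, 2)
  expect_true(all(tb2$tb_c >= 30 & tb2$tb_c <= 43))
  ir <- simulate_body_temperature(6, condition = "infrared", seed = 2)
  late <- ir$tb_c[ir$time_s > max(ir$time_s) * 0.5]
  expect_true(all(late > 38))              # sustained elevation
  expect_identical(tb2$tb_c,
                   simulate_body_temperature(6, n_fever_bouts = 2, seed = 9)$tb_c)
})
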