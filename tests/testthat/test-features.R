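make_sweep <- function(deflection, fs = 20000, pre = 0.05, post = 0.2,
                       holding = -50, noise = 0) {
  n_post <- round(post * fs)
  tt <- (seq_len(n_post) - 1) / fs
  vm <- c(rep(holding, round(pre * fs)), holding + deflection(tt))
  vm + rnorm(length(vm), 0, noise)
}

test_that("spike detection finds template peaks and nothing in flat traces", {
  fs <- 20000
  expect_equal(nrow(detect_spikes(rep(-50, 1000), fs)), 0)
  vm <- rep(-50, 2000)
  tpl <- feverspike:::spike_template(80, -40, -50, fs)
  vm[1001:1080] <- tpl
  pk <- detect_spikes(vm, fs)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_vm, 30)
  expect_equal(pk$peak_index, 1000 + which.max(tpl))
})

test_that("spike threshold matches the exhaustive-scan oracle on fuzz sweeps", {
  set.seed(5)
  fs <- 20000
  for (rep in 1:100) {
    theta <- runif(1, -45, -38)
    amp <- runif(1, theta + 51, 18)
    vm <- make_sweep(function(t) amp * feverspike:::dual_exp(t - 0.003, 0.002, 0.02),
                     noise = runif(1, 0.05, 0.4))
    stim <- round(0.05 * fs) + 1L
    det <- make_sweep(function(t) amp * feverspike:::dual_exp(t - 0.003, 0.002, 0.02))
    ins <- feverspike:::insert_spikes(det, stim - 1L, theta, fs, FALSE)
    if (!length(ins$onsets)) next
    vm2 <- ins$trace + rnorm(length(det), 0, 0.2)
    pk <- detect_spikes(vm2, fs)
    if (!nrow(pk)) next
    pre <- seq_len(stim - 1L)
    got <- spike_threshold(vm2, fs, stim, pk$peak_index[1], pre_window = pre)
    want <- oracle_threshold(vm2, fs, stim, pk$peak_index[1], pre)
    expect_identical(got$threshold_index, want$index)
    if (!is.na(want$vm)) expect_identical(got$threshold_vm, want$vm)
  }
})

test_that("spike threshold recovers a known template onset", {
  set.seed(8)
  fs <- 20000
  theta <- -41.2
  det <- make_sweep(function(t) 14 * feverspike:::dual_exp(t - 0.003, 0.002, 0.02))
  stim <- round(0.05 * fs) + 1L
  ins <- feverspike:::insert_spikes(det, stim - 1L, theta, fs, FALSE)
  vm <- ins$trace + rnorm(length(det), 0, 0.2)
  pk <- detect_spikes(vm, fs)
  th <- spike_threshold(vm, fs, stim, pk$peak_index[1])
  expect_lt(abs(th$threshold_vm - theta), 1)
  # degenerate noiseless baseline is an explicit error
  expect_error(spike_threshold(ins$trace, fs, stim, pk$peak_index[1]),
               "zero variance")
})

test_that("PSP features measure signed window maxima after spike excision", {
  fs <- 20000
  stim <- round(0.05 * fs) + 1L
  # plateau +5 mV over 10-40 ms
  vm <- make_sweep(function(t) 5 * (t >= 0.010 & t <= 0.040))
  ps <- psp_features(vm, fs, stim)
  expect_equal(ps$psp_peak, 5)
  expect_equal(ps$late_psp, 0)
  # sustained -3 mV hyperpolarisation across the late window
  vm2 <- make_sweep(function(t) -3 * (t >= 0.045 & t <= 0.155))
  ps2 <- psp_features(vm2, fs, stim)
  expect_equal(ps2$late_psp, -3)
  # dual-exponential peak matches the closed-form extremum within 1%
  tr <- 0.002; td <- 0.02; A <- 6
  vm3 <- make_sweep(function(t) A * (exp(-t / td) - exp(-t / tr)))
  tpk <- log(td / tr) * tr * td / (td - tr)
  peak <- A * (exp(-tpk / td) - exp(-tpk / tr))
  ps3 <- psp_features(vm3, fs, stim)
  expect_equal(ps3$psp_peak, peak, tolerance = 0.01)
  expect_error(psp_features(vm3, fs, stim, late_window = c(50, 500)), "window")
})

test_that("evoked spike counting respects the analysis window", {
  fs <- 20000
  mk <- function(lat_ms) {
    vm <- rep(-50, round(0.25 * fs))
    stim <- round(0.05 * fs)
    for (l in lat_ms) {
      i <- stim + round(l / 1000 * fs)
      vm[i:(i + 79)] <- feverspike:::spike_template(80, -40, -50, fs)
    }
    tibble::tibble(vm = list(vm), sampling_rate = fs, stim_onset = 0.05)
  }
  expect_warning(r <- count_evoked_spikes(mk(c(5, 100)), expected_sweeps = 11))
  expect_equal(r$per_sweep, 2L)
  expect_warning(r0 <- count_evoked_spikes(mk(0.9), expected_sweeps = 11))
  expect_equal(r0$per_sweep, 0L)  # precedes the window
  sweeps <- dplyr::bind_rows(lapply(c(rep(5, 6), rep(-100, 5)),
                                    function(l) mk(if (l > 0) l else numeric(0))))
  r11 <- count_evoked_spikes(sweeps)
  expect_equal(r11$mean_count, 6 / 11, tolerance = 1e-12)
})

test_that("E-theta applies the more-than-3-of-5 rule", {
  expect_equal(e_theta(c(`10` = 2, `20` = 4, `30` = 5)), 20)
  expect_true(is.na(e_theta(c(`10` = 3, `20` = 3))))   # 3 is not more than 3
  expect_equal(e_theta(c(`10` = 5)), 10)
  # monotone: adding detections never increases the result
  set.seed(2)
  for (rep in 1:20) {
    hits <- sample(0:5, 6, replace = TRUE)
    base <- e_theta(setNames(hits, seq(10, 60, 10)))
    j <- sample(6, 1)
    more <- hits; more[j] <- min(5, more[j] + 1)
    upd <- e_theta(setNames(more, seq(10, 60, 10)))
    expect_true(is.na(upd) && is.na(base) || isTRUE(upd <= base) ||
                  (is.na(base) && !is.na(upd)))
  }
  expect_error(e_theta(c(`10` = 6)), "block")
})

test_that("rheobase, F-I curve, and the analytic minimal step agree", {
  fi <- simulate_fi_sweeps(150, -42, current_steps = seq(20, 200, by = 20))
  rf <- rheobase_and_fi(fi)
  ana <- fi_analytic_rheobase(150, -42, seq(20, 200, by = 20))
  expect_equal(rf$rheobase_pa, ana$grid_pa)
  expect_true(all(diff(rf$fi_curve$n_spikes) >= 0))  # monotone at zero noise
  # all-subthreshold protocol
  fi0 <- simulate_fi_sweeps(150, -42, current_steps = c(5, 10))
  expect_true(is.na(rheobase_and_fi(fi0)$rheobase_pa))
  expect_error(simulate_fi_sweeps(150, -42, numeric(0)), "empty")
})

test_that("input resistance is dV/dI and scale invariant", {
  fs <- 20000
  mk_step <- function(dv) c(rep(-50, 1000), rep(-50 + dv, round(0.5 * fs)))
  expect_equal(input_resistance(mk_step(-5), fs, 1001L, -50), 100)
  expect_equal(input_resistance(mk_step(-10), fs, 1001L, -50), 200)
  expect_equal(input_resistance(mk_step(-10), fs, 1001L, -100),
               input_resistance(mk_step(-5), fs, 1001L, -50))
  expect_error(input_resistance(mk_step(-5), fs, 1001L, 0), "nonzero")
  # synthetic passive cell, zero noise
  cfg <- cohort_config(n_cells = 1, noise_sd = 0, seed = 1)
  vm <- feverspike:::step_response(cfg, 150, -50)
  expect_equal(input_resistance(vm, cfg$sampling_rate,
                                round(cfg$pre_stim * cfg$sampling_rate) + 1L, -50),
               150, tolerance = 1 / 150)
})

test_that("net I-V subtraction recovers a planted component", {
  ag <- tibble::tibble(voltage_mv = c(-80, 0, 80), current_density = c(-2, 0, 4))
  bl <- tibble::tibble(voltage_mv = c(-80, 0, 80), current_density = c(-1, 0, 1))
  net <- net_current_iv(ag, bl)
  expect_equal(net$current_density, c(-1, 0, 3))
  expect_equal(net$condition, rep("net", 3))
  expect_equal(net_current_iv(ag, ag)$current_density, c(0, 0, 0))
  # planted warmth-current component on top of a shared baseline
  v <- seq(-100, 100, by = 20)
  planted <- 0.04 * v + 0.0005 * v^2
  base <- -0.01 * v
  net2 <- net_current_iv(
    tibble::tibble(voltage_mv = v, current_density = base + planted),
    tibble::tibble(voltage_mv = v, current_density = base))
  expect_equal(net2$current_density, planted, tolerance = 1e-12)
  bad <- tibble::tibble(voltage_mv = v + 1, current_density = base)
  expect_error(net_current_iv(tibble::tibble(voltage_mv = v, current_density = base),
                              bad), "grids")
})
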