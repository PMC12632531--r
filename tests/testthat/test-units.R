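test_that("trough-to-peak duration from sample geometry", {
  fs <- 30000
  w <- rep(0, 200)
  w[91] <- -100; w[109] <- 60        # trough at 90 (0-based), peak 18 samples on
  w <- stats::filter(c(w), rep(1 / 3, 3), sides = 2)
  w[is.na(w)] <- 0
  d <- mean_waveform_duration(as.numeric(w), fs, band = NULL)
  expect_equal(d, 18 / fs * 1000, tolerance = 1e-9)  # 0.6 ms
  # amplitude scaling leaves the duration unchanged
  expect_equal(mean_waveform_duration(5 * as.numeric(w), fs, band = NULL), d)
  # time reversal changes the measurement (trough-then-peak asymmetry)
  expect_false(isTRUE(all.equal(
    mean_waveform_duration(rev(as.numeric(w)), fs, band = NULL), d)))
  expect_error(mean_waveform_duration(c(rep(0, 50), seq(0, -1, length.out = 50)),
                                      fs, band = NULL), "monotone")
})

test_that("planted waveform durations are recovered within one sample", {
  u <- simulate_unit_population(n_units = 30, seed = 7)
  for (i in seq_len(nrow(u))) {
    d <- mean_waveform_duration(u$waveform[[i]], u$waveform_sampling_rate[i])
    expect_lt(abs(d - u$true_duration_ms[i]), 1000 / u$waveform_sampling_rate[i])
  }
})

test_that("inclusion filter enforces count, refractory and presence", {
  sess <- 8700
  good <- seq(0.5, sess - 0.5, length.out = 900)
  expect_true(inclusion_filter(good, sess)$included)
  few <- good[-1]                      # 899 spikes
  expect_equal(inclusion_filter(few, sess)$reason, "min_spikes")
  # >1% of ISIs violating the 2-ms refractory
  burst <- sort(c(good, good[1:20] + 0.001))
  expect_equal(inclusion_filter(burst, sess)$reason, "refractory")
  # silent final bin
  silent <- seq(0.5, sess * 0.85, length.out = 900)
  expect_equal(inclusion_filter(silent, sess)$reason, "presence")
})

test_that("1-D 2-means equals the contiguous brute force and labels narrow units", {
  d6 <- c(0.3, 0.35, 0.4, 0.85, 0.9, 0.95)
  km <- feverspike:::kmeans_1d_2(d6)
  expect_equal(km$split, 3)
  expect_equal(km$boundary, 0.625)
  dup <- c(rep(0.3, 5), rep(0.9, 5))
  expect_equal(feverspike:::kmeans_1d_2(dup)$boundary, 0.6)
  set.seed(13)
  for (rep in 1:25) {
    x <- rnorm(sample(10:60, 1), sample(c(0, 3), 1))
    km <- feverspike:::kmeans_1d_2(x)
    bf <- oracle_kmeans2(x)
    expect_equal(km$split, bf$split)
    expect_equal(sort(km$means), sort(bf$means), tolerance = 1e-12)
    # the contiguous optimum is the k-means optimum in 1-D
    ref <- stats::kmeans(x, centers = 2, nstart = 25)
    expect_equal(sum(sort(km$means) - sort(as.numeric(ref$centers))), 0,
                 tolerance = 1e-8)
  }
})

test_that("unit classification is order invariant and records the dip test", {
  set.seed(3)
  null200 <- dip_null(100, 300)
  d <- c(rnorm(30, 0.35, 0.05), rnorm(70, 0.9, 0.1))
  cl <- classify_units(d, null_dips = null200)
  perm <- sample(length(d))
  cl2 <- classify_units(d[perm], null_dips = null200)
  expect_identical(cl$units$label[perm], cl2$units$label)
  expect_equal(cl$boundary_ms, cl2$boundary_ms)
  expect_equal(cl$n_interneuron, 30)
  g <- glance(cl)
  expect_true(all(c("boundary_ms", "dip", "dip_p") %in% names(g)))
  expect_error(classify_units(rep(0.5, 20)), "identical")
  expect_error(classify_units(c(0.3, 0.9)), "at least")
})

test_that("period rates count spikes in the last 25 minutes of each period", {
  periods <- default_periods()
  # 3000 uniform spikes in the baseline analysis window -> 2 Hz
  st <- seq(periods$analysis_start_s[1], periods$analysis_end_s[1],
            length.out = 3001)[-3001]
  r <- period_firing_rates(st, periods)
  expect_equal(r$rate_hz[r$period == "baseline"], 2, tolerance = 1e-9)
  expect_equal(r$rate_hz[r$period != "baseline"], c(0, 0))
  expect_equal(period_firing_rates(numeric(0), periods)$rate_hz, c(0, 0, 0))
  # conservation: count = rate x window length exactly
  set.seed(6)
  st2 <- sort(runif(5000, 0, 8700))
  r2 <- period_firing_rates(st2, periods)
  for (i in 1:3) {
    cnt <- sum(st2 >= periods$analysis_start_s[i] & st2 < periods$analysis_end_s[i])
    expect_equal(r2$rate_hz[i] * 1500, cnt)
  }
})

test_that("normalisation divides by baseline and averages per animal", {
  rates <- tibble::tibble(
    unit_id = rep(c("u1", "u2"), each = 3),
    animal_id = "a1",
    label = "principal",
    period = rep(c("baseline", "fever", "recovery"), 2),
    rate_hz = c(2, 3, 2, 4, 4, 4))
  nr <- normalize_rates(rates)
  expect_equal(nr$unit$norm_rate[nr$unit$unit_id == "u1"], c(1, 1.5, 1))
  expect_equal(nr$unit$norm_rate[nr$unit$unit_id == "u2"], c(1, 1, 1))
  fever <- nr$animal[nr$animal$period == "fever", ]
  expect_equal(fever$norm_rate, 1.25)
  # zero-baseline units are dropped with a warning
  rates0 <- dplyr::mutate(rates, rate_hz = ifelse(.data$unit_id == "u2" &
    .data$period == "baseline", 0, .data$rate_hz))
  expect_warning(nr0 <- normalize_rates(rates0), "zero baseline")
  expect_false("u2" %in% nr0$unit$unit_id)
})

test_that("planted fever gain is recovered from normalised rates", {
  u <- simulate_unit_population(n_units = 60, fever_gain = c(mean = 1.5, sd = 0),
                                seed = 21)
  pr <- unit_period_rates(u)
  nr <- normalize_rates(dplyr::filter(pr, .data$included))
  fever <- dplyr::filter(nr$unit, .data$period == "fever")
  expect_lt(abs(mean(fever$norm_rate) - 1.5) / 1.5, 0.05)
})
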