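#' Simulate an extracellular single-unit population
#'
#' Emulates a curated in vivo recording session spanning baseline, thermal
#' fever and recovery periods (45 min each, separated by 5-min temperature
#' ramps; 145 min in total). Each unit draws a trough-to-peak waveform
#' duration from a two-component Gaussian mixture (narrow putative
#' interneurons, wide putative principal cells), a baseline firing rate,
#' and a fever gain applied multiplicatively to its rate during the fever
#' period. Spike trains are dead-time renewal processes (exponential
#' inter-spike intervals shifted by the 2-ms refractory floor, with the
#' exponential rate corrected so the realized rate equals the nominal
#' rate). Mean waveforms are zero-net-area biphasic templates stretched so
#' the trough-to-peak interval equals the drawn duration.
#'
#' @param n_units number of units.
#' @param interneuron_frac mixture weight of the narrow (interneuron)
#'   component.
#' @param duration_mixture list with `narrow = c(mean, sd)` and
#'   `wide = c(mean, sd)` in ms; the narrow mean must be smaller.
#' @param base_rate `c(meanlog, sdlog)` of the lognormal baseline rate, Hz.
#' @param fever_gain `c(mean, sd)` of the per-unit fever gain (truncated
#'   at 0.2).
#' @param n_animals units are assigned to this many animals (round-robin)
#'   for per-animal averaging.
#' @param periods period layout, see [default_periods()].
#' @param waveform_sampling_rate Hz for the mean waveform.
#' @param seed integer seed.
#' @return tibble of class `"unit_population"`, one row per unit:
#'   `unit_id`, `animal_id`, `true_class`, `true_duration_ms`,
#'   `true_rate_hz`, `true_fever_gain`, `waveform_sampling_rate`,
#'   `spike_times` (list, s), `waveform` (list, uV).
#' @examples
#' units <- simulate_unit_population(n_units = 5, seed = 7)
#' @export
simulate_unit_population <- function(n_units = 633,
                                     interneuron_frac = 0.221,
                                     duration_mixture = list(
                                       narrow = c(mean = 0.35, sd = 0.05),
                                       wide = c(mean = 0.90, sd = 0.10)),
                                     base_rate = c(meanlog = log(2), sdlog = 0.6),
                                     fever_gain = c(mean = 1.5, sd = 0.15),
                                     n_animals = 5,
                                     periods = default_periods(),
                                     waveform_sampling_rate = 30000,
                                     seed = 7) {
  if (interneuron_frac < 0 || interneuron_frac > 1)
    stop("`interneuron_frac` must be in [0, 1]", call. = FALSE)
  if (duration_mixture$narrow[["mean"]] >= duration_mixture$wide[["mean"]])
    stop("narrow mixture mean must be below the wide mean", call. = FALSE)
  withr::local_seed(seed)
  session_end <- max(periods$end_s)
  cls <- ifelse(runif(n_units) < interneuron_frac, "interneuron", "principal")
  dur <- ifelse(cls == "interneuron",
                rnorm(n_units, duration_mixture$narrow[["mean"]],
                      duration_mixture$narrow[["sd"]]),
                rnorm(n_units, duration_mixture$wide[["mean"]],
                      duration_mixture$wide[["sd"]]))
  dur <- pmax(dur, 0.12)
  rate <- stats::rlnorm(n_units, base_rate[["meanlog"]], base_rate[["sdlog"]])
  gain <- pmax(rnorm(n_units, fever_gain[["mean"]], fever_gain[["sd"]]), 0.2)
  # rate switches at the ramp midpoints
  ramp_mid <- ramp_midpoints(periods)
  spikes <- lapply(seq_len(n_units), function(i) {
    segs <- rbind(c(0, ramp_mid[1], rate[i]),
                  c(ramp_mid[1], ramp_mid[2], rate[i] * gain[i]),
                  c(ramp_mid[2], session_end, rate[i]))
    unlist(lapply(seq_len(nrow(segs)), function(s)
      dead_time_train(segs[s, 1], segs[s, 2], segs[s, 3])))
  })
  wf <- lapply(dur, function(d) unit_waveform(d, waveform_sampling_rate))
  out <- tibble::tibble(
    unit_id = sprintf("unit_%04d", seq_len(n_units)),
    animal_id = sprintf("animal_%d", (seq_len(n_units) - 1L) %% n_animals + 1L),
    true_class = cls,
    true_duration_ms = dur,
    true_rate_hz = rate,
    true_fever_gain = gain,
    waveform_sampling_rate = waveform_sampling_rate,
    spike_times = spikes,
    waveform = wf
  )
  class(out) <- c("unit_population", class(out))
  out
}

# renewal train with 2-ms dead time on [t0, t1); exponential part rate
# corrected so the realized rate equals `rate`
dead_time_train <- function(t0, t1, rate, refractory = 0.002) {
  if (rate <= 0) return(numeric(0))
  if (rate >= 1 / refractory) stop("rate exceeds the refractory limit", call. = FALSE)
  r_exp <- rate / (1 - rate * refractory)
  expect <- (t1 - t0) * rate
  draw <- function(n) refractory + rexp(n, r_exp)
  isi <- draw(ceiling(expect + 4 * sqrt(expect) + 20))
  tt <- t0 + cumsum(isi)
  while (length(tt) && tt[length(tt)] < t1) {
    isi2 <- draw(ceiling(20 + expect / 10))
    tt <- c(tt, tt[length(tt)] + cumsum(isi2))
  }
  tt[tt < t1]
}

# biphasic extracellular template: negative trough then positive peak,
# zero net area (robust to the 300-Hz highpass), trough-to-peak = dur_ms
unit_waveform <- function(dur_ms, fs, trough_uv = 100) {
  dur_s <- dur_ms / 1000
  sig <- max(dur_s / 5, 6e-5)   # narrow lobes keep the extrema where planted
  half <- 0.002
  t <- seq(-half, half + dur_s, by = 1 / fs)
  -trough_uv * exp(-0.5 * (t / sig)^2) +
    trough_uv * exp(-0.5 * ((t - dur_s) / sig)^2)
}

#' Default baseline/fever/recovery period layout
#'
#' Three 45-minute periods separated by 5-minute temperature ramps; the
#' analysis window of each period is its last 25 minutes, avoiding the
#' transients that follow each temperature change.
#'
#' @param period_min,ramp_min,analysis_min durations in minutes.
#' @return tibble `name`, `start_s`, `end_s`, `analysis_start_s`,
#'   `analysis_end_s`.
#' @export
default_periods <- function(period_min = 45, ramp_min = 5, analysis_min = 25) {
  start <- c(0, period_min + ramp_min, 2 * (period_min + ramp_min)) * 60
  end <- start + period_min * 60
  tibble::tibble(
    name = c("baseline", "fever", "recovery"),
    start_s = start, end_s = end,
    analysis_start_s = end - analysis_min * 60,
    analysis_end_s = end
  )
}

ramp_midpoints <- function(periods) {
  p <- dplyr::arrange(periods, .data$start_s)
  (p$end_s[-nrow(p)] + p$start_s[-1]) / 2
}

#' Simulate a body-temperature series
#'
#' Readings every 5 minutes: mean-reverting noise around the baseline,
#' hard-bounded at +/- `fluct`, with optional planted fever bouts (room
#' condition) or a sustained infrared-driven elevation above 38 C that
#' ramps up within minutes and persists for hours.
#'
#' @param duration_h recording length, hours.
#' @param baseline degrees C.
#' @param fluct bound on baseline fluctuation, degrees C.
#' @param n_fever_bouts planted bouts (room condition).
#' @param condition `"room"` or `"infrared"`.
#' @param sample_min sampling interval, minutes.
#' @param seed integer seed.
#' @return tibble `time_s`, `tb_c`, `condition` of class `"tb_series"`.
#' @examples
#' tb <- simulate_body_temperature(6, n_fever_bouts = 2, seed = 1)
#' summarize_tb(tb)$n_bouts
#' @export
simulate_body_temperature <- function(duration_h, baseline = 36.5, fluct = 0.5,
                                      n_fever_bouts = 0,
                                      condition = c("room", "infrared"),
                                      sample_min = 5, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(duration_h > 0, fluct >= 0)
  withr::local_seed(seed)
  n <- floor(duration_h * 60 / sample_min)
  x <- numeric(n)
  phi <- 0.8
  innov_sd <- fluct / 2
  for (i in seq_len(n)) {
    prev <- if (i == 1) 0 else x[i - 1]
    x[i] <- max(-fluct, min(fluct, phi * prev + rnorm(1, 0, innov_sd)))
  }
  tb <- baseline + x
  time_s <- (seq_len(n) - 1) * sample_min * 60
  if (condition == "infrared") {
    onset <- max(2L, round(n * 0.1))
    ramp_len <- max(1L, round(15 / sample_min))     # reaches fever in ~15 min
    plateau <- 38.6 + x * 0.4
    w <- pmin(pmax((seq_len(n) - onset) / ramp_len, 0), 1)
    tb <- (1 - w) * tb + w * plateau
  } else if (n_fever_bouts > 0) {
    len <- pmax(2L, round(runif(n_fever_bouts, 15, 30) / sample_min))
    gap <- 2L  # readings below threshold required between bouts
    avail <- seq_len(max(1L, n - max(len) - 1L))
    starts <- integer(0)
    for (b in seq_len(n_fever_bouts)) {
      ok <- avail[vapply(avail, function(s) {
        all(abs(s - starts) > max(len) + gap)
      }, logical(1))]
      if (!length(ok)) stop("series too short for the requested bouts", call. = FALSE)
      starts <- c(starts, sample(ok, 1))
    }
    for (b in seq_len(n_fever_bouts)) {
      idx <- starts[b]:min(n, starts[b] + len[b] - 1L)
      tb[idx] <- runif(length(idx), 38.2, 38.8)
    }
  }
  tb <- pmin(pmax(tb, 30), 43)
  structure(
    tibble::tibble(time_s = time_s, tb_c = tb, condition = condition),
    class = c("tb_series", "tbl_df", "tbl", "data.frame")
  )
}
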