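#' Trough-to-peak duration of a mean waveform
#'
#' Bandpass-filters the mean waveform (zero-phase 3rd-order Butterworth,
#' 300-6000 Hz by default, preserving trough/peak timing) and returns the
#' time from the global trough to the subsequent maximum, in ms.
#'
#' @param waveform numeric vector, uV.
#' @param sampling_rate Hz.
#' @param band bandpass edges, Hz; `NULL` skips filtering.
#' @return duration in ms.
#' @export
mean_waveform_duration <- function(waveform, sampling_rate, band = c(300, 6000)) {
  w <- as.numeric(waveform)
  if (!is.null(band)) {
    ny <- sampling_rate / 2
    bf <- signal::butter(3, band / ny, type = "pass")
    w <- as.numeric(signal::filtfilt(bf, w))
  }
  trough <- which.min(w)
  if (trough >= length(w) - 1L)
    stop("no waveform peak after the trough (monotone tail)", call. = FALSE)
  post <- w[(trough + 1L):length(w)]
  peak <- trough + which.max(post)
  (peak - trough) / sampling_rate * 1000
}

#' Single-unit inclusion filter
#'
#' Applies the curation criteria for session-long single units: at least
#' `min_spikes` spikes, a clear refractory period (at most
#' `max_violation_frac` of inter-spike intervals shorter than
#' `refractory_ms`), and presence throughout the session (every one of
#' `presence_bins` equal bins contains a spike).
#'
#' @param spike_times sorted spike times, s.
#' @param session_s session length, s.
#' @param min_spikes minimum spike count (about 0.1 Hz over 145 min).
#' @param refractory_ms refractory bound, ms.
#' @param max_violation_frac tolerated fraction of refractory violations.
#' @param presence_bins number of equal session bins that must be occupied.
#' @return list with `included` (logical) and `reason` ("" when included).
#' @export
inclusion_filter <- function(spike_times, session_s,
                             min_spikes = 900, refractory_ms = 2,
                             max_violation_frac = 0.01, presence_bins = 10) {
  st <- sort(spike_times)
  if (length(st) < min_spikes)
    return(list(included = FALSE, reason = "min_spikes"))
  isi <- diff(st)
  if (length(isi) && mean(isi < refractory_ms / 1000) > max_violation_frac)
    return(list(included = FALSE, reason = "refractory"))
  bins <- findInterval(st, seq(0, session_s, length.out = presence_bins + 1L),
                       rightmost.closed = TRUE)
  if (length(unique(bins[bins >= 1 & bins <= presence_bins])) < presence_bins)
    return(list(included = FALSE, reason = "presence"))
  list(included = TRUE, reason = "")
}

#' Classify units by waveform duration
#'
#' Records Hartigan's dip test of the duration distribution, then splits
#' the durations by exact one-dimensional 2-means (full search over
#' contiguous partitions of the sorted values, which contains the optimal
#' 2-means solution in 1-D). The cluster with the smaller mean is labelled
#' putative interneuron; the boundary is the midpoint of the two cluster
#' means.
#'
#' @param durations trough-to-peak durations, ms (n >= 10, not all equal).
#' @param n_boot bootstrap replicates for the dip test.
#' @param null_dips optional precomputed dip null (see [dip_null()]).
#' @return object of class `"unit_classification"`: list with `units`
#'   (tibble `duration_ms`, `label`), `boundary_ms`, `dip` (a
#'   [dip_test()] result), `n_interneuron`, `n_principal`,
#'   `interneuron_frac`.
#' @examples
#' cl <- classify_units(c(0.3, 0.35, 0.4, 0.85, 0.9, 0.95,
#'                        0.32, 0.88, 0.91, 0.37), n_boot = 200)
#' cl$boundary_ms
#' @export
classify_units <- function(durations, n_boot = 2000, null_dips = NULL) {
  d <- as.numeric(durations)
  if (length(d) < 10) stop("need at least 10 units", call. = FALSE)
  if (length(unique(d)) == 1) stop("all durations identical", call. = FALSE)
  dip <- dip_test(d, n_boot = n_boot, null_dips = null_dips)
  km <- kmeans_1d_2(d)
  lab <- ifelse(km$assign == km$narrow_cluster, "interneuron", "principal")
  structure(
    list(units = tibble::tibble(duration_ms = d, label = lab),
         boundary_ms = km$boundary,
         dip = dip,
         n_interneuron = sum(lab == "interneuron"),
         n_principal = sum(lab == "principal"),
         interneuron_frac = mean(lab == "interneuron")),
    class = "unit_classification"
  )
}

# exact 1-D 2-means via prefix sums over all contiguous splits of the
# sorted values
kmeans_1d_2 <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ss <- function(a, b) { # within-SS of xs[a..b]
    s <- cs[b] - if (a > 1) cs[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    s2 - s^2 / (b - a + 1)
  }
  k <- seq_len(n - 1)
  cost <- vapply(k, function(j) ss(1, j) + ss(j + 1, n), numeric(1))
  j <- k[which.min(cost)]
  m1 <- mean(xs[1:j]); m2 <- mean(xs[(j + 1):n])
  assign_sorted <- rep(c(1L, 2L), c(j, n - j))
  assign <- integer(n); assign[o] <- assign_sorted
  list(assign = assign,
       narrow_cluster = if (m1 <= m2) 1L else 2L,
       boundary = (m1 + m2) / 2,
       means = c(m1, m2), split = j)
}

#' @export
print.unit_classification <- function(x, ...) {
  cat(sprintf(
    "<unit_classification> %d interneurons / %d principal cells (%.1f%% - %.1f%%)\n",
    x$n_interneuron, x$n_principal, 100 * x$interneuron_frac,
    100 * (1 - x$interneuron_frac)))
  cat(sprintf("  boundary %.3f ms; dip = %.4f, p = %.3g\n",
              x$boundary_ms, x$dip$statistic, x$dip$p_value))
  invisible(x)
}

#' @rdname classify_units
#' @param x a `unit_classification`.
#' @param ... unused.
#' @export
tidy.unit_classification <- function(x, ...) x$units

#' @rdname classify_units
#' @export
glance.unit_classification <- function(x, ...) {
  tibble::tibble(n_interneuron = x$n_interneuron, n_principal = x$n_principal,
                 interneuron_frac = x$interneuron_frac,
                 boundary_ms = x$boundary_ms,
                 dip = x$dip$statistic, dip_p = x$dip$p_value)
}

#' Firing rate per analysis period
#'
#' Spike count inside each period's analysis window divided by the window
#' length; by default the windows are the last 25 minutes of each 45-min
#' period.
#'
#' @param spike_times spike times, s.
#' @param periods tibble from [default_periods()].
#' @return tibble `period`, `rate_hz`.
#' @export
period_firing_rates <- function(spike_times, periods = default_periods()) {
  if (any(periods$analysis_end_s <= periods$analysis_start_s))
    stop("zero-length analysis window", call. = FALSE)
  p <- dplyr::arrange(periods, .data$start_s)
  if (any(p$start_s[-1] < p$end_s[-nrow(p)]))
    stop("periods overlap", call. = FALSE)
  tibble::tibble(
    period = periods$name,
    rate_hz = vapply(seq_len(nrow(periods)), function(i) {
      w0 <- periods$analysis_start_s[i]; w1 <- periods$analysis_end_s[i]
      sum(spike_times >= w0 & spike_times < w1) / (w1 - w0)
    }, numeric(1))
  )
}

#' Period rates for a unit population
#'
#' Applies [inclusion_filter()], [mean_waveform_duration()] and
#' [period_firing_rates()] across a unit table.
#'
#' @param units tibble from [simulate_unit_population()] (or the reader).
#' @param periods tibble from [default_periods()].
#' @param band waveform bandpass, Hz.
#' @param ... passed to [inclusion_filter()].
#' @return tibble, one row per unit x period, with `duration_ms`,
#'   `included`, `reason`, `period`, `rate_hz`.
#' @export
unit_period_rates <- function(units, periods = default_periods(),
                              band = c(300, 6000), ...) {
  session_s <- max(periods$end_s)
  per_unit <- lapply(seq_len(nrow(units)), function(i) {
    dur <- mean_waveform_duration(units$waveform[[i]],
                                  units$waveform_sampling_rate[i], band = band)
    inc <- inclusion_filter(units$spike_times[[i]], session_s, ...)
    rates <- period_firing_rates(units$spike_times[[i]], periods)
    tibble::tibble(unit_id = units$unit_id[i],
                   animal_id = units$animal_id[i],
                   duration_ms = dur,
                   included = inc$included, reason = inc$reason,
                   period = rates$period, rate_hz = rates$rate_hz)
  })
  dplyr::bind_rows(per_unit)
}

#' Baseline-normalised firing rates
#'
#' Divides each unit's per-period rate by its own baseline rate, then
#' averages within animal (and unit class when present). Units with a
#' zero baseline rate are dropped with a warning.
#'
#' @param rates tibble with `unit_id`, `animal_id`, `period`, `rate_hz`
#'   and optionally `label`.
#' @param baseline_period name of the reference period.
#' @return list with `unit` (per-unit normalised rates) and `animal`
#'   (per-animal means).
#' @export
normalize_rates <- function(rates, baseline_period = "baseline") {
  base <- rates |>
    dplyr::filter(.data$period == baseline_period) |>
    dplyr::select("unit_id", base_rate = "rate_hz")
  zero <- base$unit_id[base$base_rate <= 0]
  if (length(zero))
    warning(sprintf("dropping %d unit(s) with zero baseline rate", length(zero)),
            call. = FALSE)
  unit <- rates |>
    dplyr::inner_join(dplyr::filter(base, .data$base_rate > 0), by = "unit_id") |>
    dplyr::mutate(norm_rate = .data$rate_hz / .data$base_rate)
  grp <- intersect(c("animal_id", "label", "period"), names(unit))
  animal <- unit |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(norm_rate = mean(.data$norm_rate), n_units = dplyr::n(),
                     .groups = "drop")
  list(unit = unit, animal = animal)
}
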