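#' Detect action potentials in a voltage sweep
#'
#' Spikes are local maxima of the membrane potential above `peak_cutoff`,
#' separated by at least `min_separation` ms.
#'
#' @param vm numeric vector of membrane potential samples, mV.
#' @param sampling_rate Hz.
#' @param peak_cutoff minimal peak potential, mV.
#' @param min_separation minimal distance between accepted peaks, ms.
#' @return tibble with `peak_index` (1-based sample) and `peak_vm`.
#' @examples
#' detect_spikes(rep(-50, 1000), 20000)   # empty
#' @export
detect_spikes <- function(vm, sampling_rate, peak_cutoff = 0, min_separation = 1) {
  stopifnot(is.numeric(vm), sampling_rate > 0)
  n <- length(vm)
  if (n < 3) return(tibble::tibble(peak_index = integer(0), peak_vm = numeric(0)))
  cand <- which(vm[2:(n - 1)] >= peak_cutoff &
                vm[2:(n - 1)] >= vm[1:(n - 2)] &
                vm[2:(n - 1)] > vm[3:n]) + 1L
  if (!length(cand)) return(tibble::tibble(peak_index = integer(0), peak_vm = numeric(0)))
  min_gap <- round(min_separation / 1000 * sampling_rate)
  keep <- integer(0); last <- -Inf
  for (i in cand) {
    if (i - last >= min_gap) { keep <- c(keep, i); last <- i }
  }
  tibble::tibble(peak_index = keep, peak_vm = vm[keep])
}

#' Spike threshold by the second-derivative criterion
#'
#' The spike threshold is the membrane potential at the first sample after
#' the stimulus (and not after the spike peak) where the second derivative
#' of Vm exceeds `sd_multiplier` standard deviations of the pre-stimulus
#' second derivative. The second derivative is computed by central finite
#' differences over the whole trace (optional 3-point smoothing for noisy
#' recordings).
#'
#' @param vm membrane potential samples, mV.
#' @param sampling_rate Hz.
#' @param stim_index first sample at/after the stimulus.
#' @param peak_index sample index of the spike peak.
#' @param pre_window integer indices of the pre-stimulus window (>= 50
#'   samples with nonzero second-derivative variance).
#' @param sd_multiplier criterion multiple, default 5.
#' @param smooth apply a 3-point moving average to the second derivative.
#' @return list with `threshold_vm`, `threshold_index`,
#'   `depolarization_to_threshold` (threshold minus mean pre-stimulus Vm);
#'   `threshold_vm` is `NA` (with a warning) when no sample meets the
#'   criterion.
#' @export
spike_threshold <- function(vm, sampling_rate, stim_index, peak_index,
                            pre_window = seq_len(stim_index - 1L),
                            sd_multiplier = 5, smooth = FALSE) {
  n <- length(vm)
  stopifnot(peak_index <= n, stim_index >= 2, peak_index > stim_index)
  if (length(pre_window) < 50)
    stop("pre-stimulus window must contain at least 50 samples", call. = FALSE)
  d2 <- second_derivative(vm, sampling_rate)
  if (smooth) d2 <- stats::filter(d2, rep(1 / 3, 3), sides = 2)
  pre <- d2[intersect(pre_window, 2:(n - 1))]
  sigma <- sd(pre, na.rm = TRUE)
  if (!is.finite(sigma) || sigma == 0)
    stop(paste("pre-stimulus second derivative has zero variance;",
               "add jitter or supply a noisy baseline"), call. = FALSE)
  idx <- (stim_index + 1L):peak_index
  hit <- idx[which(d2[idx] > sd_multiplier * sigma)[1]]
  base <- mean(vm[pre_window])
  if (is.na(hit)) {
    warning("no sample exceeded the second-derivative criterion", call. = FALSE)
    return(list(threshold_vm = NA_real_, threshold_index = NA_integer_,
                depolarization_to_threshold = NA_real_))
  }
  list(threshold_vm = vm[hit], threshold_index = hit,
       depolarization_to_threshold = vm[hit] - base)
}

second_derivative <- function(vm, sampling_rate) {
  n <- length(vm)
  dt <- 1 / sampling_rate
  d2 <- rep(NA_real_, n)
  d2[2:(n - 1)] <- (vm[3:n] - 2 * vm[2:(n - 1)] + vm[1:(n - 2)]) / dt^2
  d2
}

#' PSP component amplitudes
#'
#' Measures the early (excitation-dominated) and late (inhibition-
#' dominated) postsynaptic-potential components of a sweep: the signed
#' maximal deflection from the pre-stimulus baseline within each window.
#' Spikes are excised first by linear interpolation across +/- `excise_ms`
#' around each detected peak.
#'
#' @inheritParams spike_threshold
#' @param early_window,late_window windows in ms post-stimulus.
#' @param spike_peaks integer sample indices of spike peaks to excise.
#' @param excise_ms half-width of the excision window, ms.
#' @return list with `psp_peak`, `late_psp` (mV above baseline, signed)
#'   and `baseline_vm`.
#' @export
psp_features <- function(vm, sampling_rate, stim_index,
                         pre_window = seq_len(stim_index - 1L),
                         early_window = c(2.5, 50), late_window = c(50, 150),
                         spike_peaks = integer(0), excise_ms = 2) {
  n <- length(vm)
  w_idx <- function(w) {
    i0 <- stim_index + round(w[1] / 1000 * sampling_rate)
    i1 <- stim_index + round(w[2] / 1000 * sampling_rate)
    if (i1 > n) stop("measurement window extends past the trace", call. = FALSE)
    i0:i1
  }
  vmx <- excise_spikes(vm, spike_peaks, round(excise_ms / 1000 * sampling_rate))
  base <- mean(vmx[pre_window])
  list(psp_peak = max(vmx[w_idx(early_window)] - base),
       late_psp = max(vmx[w_idx(late_window)] - base),
       baseline_vm = base)
}

excise_spikes <- function(vm, peaks, half_width) {
  if (!length(peaks)) return(vm)
  n <- length(vm)
  out <- vm
  for (p in peaks) {
    a <- max(1L, p - half_width); b <- min(n, p + half_width)
    va <- vm[max(1L, a - 1L)]; vb <- vm[min(n, b + 1L)]
    out[a:b] <- va + (vb - va) * (seq_len(b - a + 1L)) / (b - a + 2L)
  }
  out
}

#' Evoked spikes within the analysis window
#'
#' Counts detected spike peaks with post-stimulus latency inside
#' `[window_start, window_start + window_len]` ms, per sweep, and their
#' mean over sweeps.
#'
#' @param sweeps tibble with columns `vm` (list), `sampling_rate`,
#'   `stim_onset` (s); typically 11 evoked sweeps of one cell at one
#'   temperature.
#' @param window_start window start, ms post-stimulus.
#' @param window_len window length, ms.
#' @param expected_sweeps declared sweep count; fewer triggers a warning.
#' @param peak_cutoff passed to [detect_spikes()].
#' @return list with `mean_count` and integer vector `per_sweep`.
#' @export
count_evoked_spikes <- function(sweeps, window_start = 2.5, window_len = 150,
                                expected_sweeps = 11, peak_cutoff = 0) {
  if (nrow(sweeps) < expected_sweeps)
    warning(sprintf("only %d of %d declared sweeps present", nrow(sweeps),
                    expected_sweeps), call. = FALSE)
  per <- vapply(seq_len(nrow(sweeps)), function(i) {
    fs <- sweeps$sampling_rate[i]
    stim <- round(sweeps$stim_onset[i] * fs) + 1L
    pk <- detect_spikes(sweeps$vm[[i]], fs, peak_cutoff = peak_cutoff)$peak_index
    lat <- (pk - stim) / fs * 1000
    sum(lat >= window_start & lat <= window_start + window_len)
  }, integer(1))
  list(mean_count = mean(per), per_sweep = per)
}

#' Minimal effective stimulation intensity (E-theta)
#'
#' The smallest stimulation intensity that evokes an EPSC in more than 3
#' of 5 consecutive sweeps, i.e. at least `min_hits` = 4 detections in the
#' 5-sweep block.
#'
#' @param detections data frame with columns `intensity` and `hits`
#'   (detections out of `block_size` consecutive sweeps), or a named
#'   vector of hit counts with intensities as names.
#' @param block_size sweeps per intensity block.
#' @param min_hits detections required ("more than 3 of 5" = 4).
#' @return the minimal qualifying intensity, or `NA` if none qualifies.
#' @examples
#' e_theta(c(`10` = 2, `20` = 4, `30` = 5))  # 20
#' @export
e_theta <- function(detections, block_size = 5, min_hits = 4) {
  if (!is.data.frame(detections)) {
    detections <- tibble::tibble(intensity = as.numeric(names(detections)),
                                 hits = as.numeric(detections))
  }
  stopifnot(all(c("intensity", "hits") %in% names(detections)))
  if (any(detections$hits > block_size))
    stop("more detections than sweeps in a block", call. = FALSE)
  d <- dplyr::arrange(detections, .data$intensity)
  ok <- d$intensity[d$hits >= min_hits]
  if (length(ok)) min(ok) else NA_real_
}

#' Rheobase and F-I curve
#'
#' Rheobase is the smallest injected current that elicits at least one
#' detected spike; the F-I curve pairs each current with its spike count.
#'
#' @param fi_sweeps tibble from [simulate_fi_sweeps()] (columns `step_pa`,
#'   `vm`, `sampling_rate`, `stim_onset`).
#' @param step_duration step length, s (spikes counted within the step).
#' @param peak_cutoff passed to [detect_spikes()].
#' @return list with `rheobase_pa` (NA when nothing spikes) and `fi_curve`
#'   (tibble `current_pa`, `n_spikes`).
#' @export
rheobase_and_fi <- function(fi_sweeps, step_duration = 0.5, peak_cutoff = 0) {
  counts <- vapply(seq_len(nrow(fi_sweeps)), function(i) {
    fs <- fi_sweeps$sampling_rate[i]
    stim <- round(fi_sweeps$stim_onset[i] * fs) + 1L
    pk <- detect_spikes(fi_sweeps$vm[[i]], fs, peak_cutoff = peak_cutoff)$peak_index
    sum(pk >= stim & pk <= stim + round(step_duration * fs))
  }, integer(1))
  fi <- tibble::tibble(current_pa = fi_sweeps$step_pa, n_spikes = counts)
  fi <- dplyr::arrange(fi, .data$current_pa)
  spiking <- fi$current_pa[fi$n_spikes >= 1]
  list(rheobase_pa = if (length(spiking)) min(spiking) else NA_real_,
       fi_curve = fi)
}

#' Input resistance from a current-step sweep
#'
#' `Rin = dV_steady / dI`, with the steady-state voltage taken as the mean
#' over the last `steady_ms` of the step and the baseline over the
#' pre-stimulus window.
#'
#' @param vm samples, mV.
#' @param sampling_rate Hz.
#' @param stim_index first sample of the step.
#' @param step_pa injected current, pA (nonzero).
#' @param step_duration s.
#' @param steady_ms steady-state window at the end of the step, ms.
#' @return input resistance, MOhm.
#' @examples
#' # -5 mV at -50 pA -> 100 MOhm
#' @export
input_resistance <- function(vm, sampling_rate, stim_index, step_pa,
                             step_duration = 0.5, steady_ms = 100) {
  if (step_pa == 0) stop("`step_pa` must be nonzero", call. = FALSE)
  end <- stim_index + round(step_duration * sampling_rate) - 1L
  i0 <- end - round(steady_ms / 1000 * sampling_rate) + 1L
  base <- mean(vm[seq_len(stim_index - 1L)])
  dv <- mean(vm[i0:end]) - base
  1000 * dv / step_pa
}

#' Net agonist-minus-blocker I-V curve
#'
#' Pointwise difference of two current-density-voltage relationships
#' measured on the same voltage grid (channel agonist alone minus agonist
#' plus blocker), isolating the blocker-sensitive current.
#'
#' @param agonist,agonist_plus_blocker tibbles/data frames with columns
#'   `voltage_mv` and `current_density` (pA/pF), identical voltage grids.
#' @return tibble `voltage_mv`, `current_density`, `condition = "net"`.
#' @export
net_current_iv <- function(agonist, agonist_plus_blocker) {
  if (!isTRUE(all.equal(agonist$voltage_mv, agonist_plus_blocker$voltage_mv)))
    stop("voltage grids differ between conditions", call. = FALSE)
  if (is.unsorted(agonist$voltage_mv, strictly = TRUE))
    stop("voltages must be strictly increasing", call. = FALSE)
  tibble::tibble(
    voltage_mv = agonist$voltage_mv,
    current_density = agonist$current_density - agonist_plus_blocker$current_density,
    condition = "net"
  )
}

#' Per-sweep feature table
#'
#' Runs spike detection, threshold estimation and PSP measurement on every
#' evoked sweep of a cohort, returning one row per sweep. Step-protocol
#' sweeps yield the per-cell, per-temperature input resistance instead.
#'
#' @param sweeps sweep tibble (see [simulate_pn_cohort()]).
#' @param evoked_window_start,evoked_window_len evoked-spike window, ms.
#' @param early_window,late_window PSP windows, ms post-stimulus.
#' @param sd_multiplier threshold criterion.
#' @return tibble: `cell_id`, `temperature`, `sweep_index`, `spike_count`,
#'   `first_spike_ms`, `spike_threshold_vm`, `depolarization_to_threshold`,
#'   `spike_height`, `ahp`, `psp_peak`, `late_psp`, `baseline_vm`.
#' @export
sweep_features <- function(sweeps,
                           evoked_window_start = 2.5, evoked_window_len = 150,
                           early_window = c(2.5, 50), late_window = c(50, 150),
                           sd_multiplier = 5) {
  ev <- dplyr::filter(sweeps, .data$protocol == "evoked")
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    vm <- ev$vm[[i]]
    fs <- ev$sampling_rate[i]
    stim <- round(ev$stim_onset[i] * fs) + 1L
    pre <- seq_len(stim - 1L)
    pk_all <- detect_spikes(vm, fs)
    lat <- (pk_all$peak_index - stim) / fs * 1000
    in_win <- lat >= evoked_window_start & lat <= evoked_window_start + evoked_window_len
    pk <- pk_all[in_win, , drop = FALSE]
    thr_vm <- dep <- height <- ahp <- NA_real_
    if (nrow(pk) > 0) {
      # noiseless baselines make the criterion undefined; record NA rather
      # than abort the batch
      th <- tryCatch(
        spike_threshold(vm, fs, stim, pk$peak_index[1],
                        pre_window = pre, sd_multiplier = sd_multiplier),
        error = function(e) list(threshold_vm = NA_real_,
                                 threshold_index = NA_integer_,
                                 depolarization_to_threshold = NA_real_))
      thr_vm <- th$threshold_vm
      dep <- th$depolarization_to_threshold
      if (!is.na(thr_vm)) {
        height <- pk$peak_vm[1] - thr_vm
        post <- vm[pk$peak_index[1]:min(length(vm), pk$peak_index[1] + round(0.004 * fs))]
        ahp <- min(post) - thr_vm
      }
    }
    ps <- psp_features(vm, fs, stim, pre_window = pre,
                       early_window = early_window, late_window = late_window,
                       spike_peaks = pk_all$peak_index)
    tibble::tibble(
      cell_id = ev$cell_id[i], temperature = ev$temperature[i],
      sweep_index = ev$sweep_index[i],
      spike_count = nrow(pk),
      first_spike_ms = if (nrow(pk)) lat[in_win][1] else NA_real_,
      spike_threshold_vm = thr_vm, depolarization_to_threshold = dep,
      spike_height = height, ahp = ahp,
      psp_peak = ps$psp_peak, late_psp = ps$late_psp,
      baseline_vm = ps$baseline_vm
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-cell, per-temperature summaries
#'
#' Means of every sweep feature over the sweeps of each cell at each
#' temperature, the fraction of sweeps with at least one evoked spike, and
#' the input resistance from the step-protocol sweep when present.
#'
#' @param features tibble from [sweep_features()].
#' @param sweeps optional sweep tibble containing step-protocol sweeps for
#'   input resistance.
#' @return tibble, one row per cell x temperature.
#' @export
cell_summaries <- function(features, sweeps = NULL) {
  out <- features |>
    dplyr::group_by(.data$cell_id, .data$temperature) |>
    dplyr::summarise(
      n_sweeps = dplyr::n(),
      mean_spike_count = mean(.data$spike_count),
      frac_sweeps_spiking = mean(.data$spike_count >= 1),
      spike_threshold_vm = mean(.data$spike_threshold_vm, na.rm = TRUE),
      depolarization_to_threshold = mean(.data$depolarization_to_threshold, na.rm = TRUE),
      spike_height = mean(.data$spike_height, na.rm = TRUE),
      ahp = mean(.data$ahp, na.rm = TRUE),
      psp_peak = mean(.data$psp_peak),
      late_psp = mean(.data$late_psp),
      baseline_vm = mean(.data$baseline_vm),
      .groups = "drop"
    )
  if (!is.null(sweeps)) {
    st <- dplyr::filter(sweeps, .data$protocol == "step")
    if (nrow(st) > 0) {
      rin <- st |>
        dplyr::mutate(rin = vapply(seq_len(nrow(st)), function(i) {
          fs <- st$sampling_rate[i]
          input_resistance(st$vm[[i]], fs, round(st$stim_onset[i] * fs) + 1L,
                           st$step_pa[i])
        }, numeric(1))) |>
        dplyr::select("cell_id", "temperature", "rin")
      out <- dplyr::left_join(out, rin, by = c("cell_id", "temperature"))
    }
  }
  out
}
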