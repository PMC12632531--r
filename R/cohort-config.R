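#' Configuration for a synthetic pyramidal-neuron cohort
#'
#' Collects every parameter of the intracellular sweep generator. The
#' generator emulates L4-evoked responses in L2/3 pyramidal neurons
#' recorded at three bath temperatures from a just-subthreshold holding
#' potential: each sweep is a stimulus-locked PSP (early excitatory minus
#' delayed inhibitory dual-exponential components) on top of baseline
#' noise, with a stereotyped action-potential template inserted where the
#' deterministic trace crosses the cell's spike threshold.
#'
#' Temperature acts through four channels: the spike threshold
#' depolarises by `theta_slope` mV/degree; input resistance falls by the
#' factor `rin_q10` per 10 degrees (scaling the excitatory amplitude);
#' cells fated to keep (or start) spiking receive an extra multiplicative
#' excitatory gain `(1 + stay_gain)^(T - 30)` (the TRPV3-like warmth
#' current); and the inhibitory amplitude shrinks by
#' `(1 - ipsp_temp_factor)^(T - 30)` (loss of inhibition at temperature).
#'
#' Per-cell excitatory amplitudes are drawn from the `epsp_amp`
#' distribution and then clamped into the amplitude interval consistent
#' with the cell's drawn fate, so that at `noise_sd = 0` the realized
#' spiking pattern across temperatures equals the fate label exactly.
#'
#' @param n_cells number of cells.
#' @param fate_mix probabilities for the NEVER/STAY/STOP/START fates (in
#'   that order; must sum to 1).
#' @param temperatures ordered bath temperatures, degrees C.
#' @param sweeps_per_temperature evoked sweeps recorded per temperature.
#' @param sampling_rate Hz.
#' @param holding_vm holding potential, mV.
#' @param theta30 `c(mean, sd)` of the spike threshold at 30 C, mV.
#' @param theta_slope threshold depolarisation, mV per degree C.
#' @param rin30 `c(mean, sd)` of input resistance at 30 C, MOhm.
#' @param rin_q10 multiplicative change in input resistance per 10 C
#'   (below 1: resistance falls as channels open).
#' @param epsp_amp,ipsp_amp `c(mean, sd)` of the excitatory / inhibitory
#'   component amplitudes, mV.
#' @param epsp_delay synaptic latency of the excitatory component after the
#'   stimulus, ms.
#' @param ipsp_delay inhibitory onset delay after the stimulus, ms (must
#'   exceed `epsp_delay`).
#' @param tau_rise,tau_decay `c(epsp, ipsp)` kernel time constants, ms.
#' @param stay_gain per-degree multiplicative excitatory gain applied to
#'   STAY and START cells.
#' @param ipsp_temp_factor per-degree multiplicative reduction of the
#'   inhibitory amplitude.
#' @param noise_sd baseline noise, mV.
#' @param membrane_cap membrane capacitance, pF (sets the membrane time
#'   constant together with the input resistance).
#' @param pre_stim pre-stimulus baseline duration, s.
#' @param post_stim post-stimulus duration, s (must exceed 0.16).
#' @param burst allow more than one spike per evoked sweep.
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @return a validated list of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_cells = 4, seed = 1)
#' @export
cohort_config <- function(n_cells = 200,
                          fate_mix = c(never = 0.30, stay = 0.27,
                                       stop = 0.28, start = 0.15),
                          temperatures = c(30, 36, 39),
                          sweeps_per_temperature = 11,
                          sampling_rate = 20000,
                          holding_vm = -50,
                          theta30 = c(mean = -42, sd = 1.5),
                          theta_slope = 0.32,
                          rin30 = c(mean = 150, sd = 25),
                          rin_q10 = 0.8,
                          epsp_amp = c(mean = 10, sd = 2.5),
                          ipsp_amp = c(mean = 3, sd = 0.8),
                          epsp_delay = 3,
                          ipsp_delay = 10,
                          tau_rise = c(epsp = 2, ipsp = 6),
                          tau_decay = c(epsp = 20, ipsp = 60),
                          stay_gain = 0.10,
                          ipsp_temp_factor = 0.05,
                          noise_sd = 0.2,
                          membrane_cap = 150,
                          pre_stim = 0.05,
                          post_stim = 0.2,
                          burst = FALSE,
                          seed = 1) {
  if (length(fate_mix) != 4) stop("`fate_mix` needs 4 probabilities", call. = FALSE)
  if (is.null(names(fate_mix))) names(fate_mix) <- c("never", "stay", "stop", "start")
  if (abs(sum(fate_mix) - 1) > 1e-9) stop("`fate_mix` must sum to 1", call. = FALSE)
  if (any(fate_mix < 0)) stop("`fate_mix` must be nonnegative", call. = FALSE)
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("`temperatures` must be strictly increasing", call. = FALSE)
  if (sampling_rate < 10000) stop("`sampling_rate` must be >= 10 kHz", call. = FALSE)
  if (post_stim < 0.16) stop("trace must extend >= 160 ms past the stimulus", call. = FALSE)
  stopifnot(n_cells >= 1, sweeps_per_temperature >= 1,
            theta30[["sd"]] >= 0, rin30[["mean"]] > 0,
            rin_q10 > 0, rin_q10 < 1,
            epsp_amp[["mean"]] > 0, ipsp_amp[["mean"]] >= 0,
            all(tau_rise > 0), all(tau_decay > 0),
            tau_rise[[1]] < tau_decay[[1]], tau_rise[[2]] < tau_decay[[2]],
            epsp_delay >= 0, ipsp_delay > epsp_delay,
            stay_gain >= 0, ipsp_temp_factor >= 0, ipsp_temp_factor < 1,
            noise_sd >= 0, membrane_cap > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d cells at %s C, %d sweeps/temperature, seed %d\n",
              x$n_cells, paste(x$temperatures, collapse = "/"),
              x$sweeps_per_temperature, x$seed))
  cat(sprintf("  fate mix: %s\n",
              paste(sprintf("%s %.0f%%", names(x$fate_mix), 100 * x$fate_mix),
                    collapse = ", ")))
  invisible(x)
}
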