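#' Simulate an intracellular pyramidal-neuron cohort
#'
#' Generates the evoked-sweep recordings described by a [cohort_config()]:
#' for every cell and bath temperature, `sweeps_per_temperature` stimulus-
#' locked voltage sweeps plus one hyperpolarising current-step sweep (for
#' input-resistance measurement). Spikes are inserted as stereotyped
#' templates where the deterministic (noise-free) trace crosses the
#' cell's temperature-dependent threshold, so each cell's spiking pattern
#' across temperatures equals its drawn fate label exactly at zero noise,
#' and remains recoverable under noise because insertion does not depend
#' on the noise draw.
#'
#' @param config a [cohort_config()].
#' @return a list of class `"pn_cohort"`:
#' \describe{
#'   \item{sweeps}{tibble, one row per sweep: `cell_id`, `temperature`,
#'     `sweep_index`, `protocol` ("evoked" or "step"), `step_pa`,
#'     `sampling_rate`, `stim_onset`, `holding_vm`, and `vm` (list-column
#'     of mV samples).}
#'   \item{truth}{per-cell tibble: fate label and drawn parameters.}
#'   \item{truth_by_temp}{per cell x temperature tibble: realized
#'     threshold, input resistance, component amplitudes, whether a spike
#'     was inserted and at what time.}
#'   \item{config}{the input configuration.}
#' }
#' @examples
#' coh <- simulate_pn_cohort(cohort_config(n_cells = 2, seed = 42))
#' dplyr::count(coh$sweeps, protocol)
#' @export
simulate_pn_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  withr::local_seed(cfg$seed)

  fates <- c("never", "stay", "stop", "start")
  fate <- sample(fates, cfg$n_cells, replace = TRUE, prob = cfg$fate_mix)
  theta30 <- pmax(rnorm(cfg$n_cells, cfg$theta30[["mean"]], cfg$theta30[["sd"]]),
                  cfg$holding_vm + 3.5)
  rin30 <- pmax(rnorm(cfg$n_cells, cfg$rin30[["mean"]], cfg$rin30[["sd"]]), 20)
  ipsp0 <- pmax(rnorm(cfg$n_cells, cfg$ipsp_amp[["mean"]], cfg$ipsp_amp[["sd"]]), 0)
  epsp_draw <- rnorm(cfg$n_cells, cfg$epsp_amp[["mean"]], cfg$epsp_amp[["sd"]])

  temps <- cfg$temperatures
  nt <- length(temps)
  if (nt < 2) stop("need at least two temperatures for fate structure", call. = FALSE)
  target <- switch_pattern(fate, nt)

  # per-cell calibration of the excitatory amplitude against the critical
  # amplitude A*(T) at which the deterministic deflection reaches threshold
  cells <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    gained <- fate[i] %in% c("stay", "start")
    acrit <- vapply(seq_len(nt), function(k) {
      critical_amplitude(cfg, temps[k], theta30[i], rin30[i], ipsp0[i], gained)
    }, numeric(1))
    intv <- fate_amplitude_interval(fate[i], acrit, target[i, ])
    if (!is.finite(intv[1]) || intv[1] >= intv[2])
      stop(sprintf(
        "fate '%s' infeasible for cell %d under these parameters; adjust stay_gain/theta_slope",
        fate[i], i), call. = FALSE)
    amp <- clamp_margin(epsp_draw[i], intv)
    cells[[i]] <- list(fate = fate[i], theta30 = theta30[i], rin30 = rin30[i],
                       ipsp0 = ipsp0[i], amp = amp, gained = gained)
  }

  dt <- 1 / cfg$sampling_rate
  n_pre <- round(cfg$pre_stim / dt)
  n_post <- round(cfg$post_stim / dt)
  tt <- (seq_len(n_post) - 1) * dt          # time past stimulus, s
  rows <- list(); tbt <- list(); ridx <- 1L

  for (i in seq_len(cfg$n_cells)) {
    ci <- cells[[i]]
    id <- sprintf("cell_%03d", i)
    for (k in seq_len(nt)) {
      Tk <- temps[k]
      par <- temp_params(cfg, Tk, ci$theta30, ci$rin30, ci$ipsp0, ci$gained)
      defl <- ci$amp * par$e_scale * dual_exp(tt - cfg$epsp_delay / 1000,
                                              cfg$tau_rise[[1]] / 1000,
                                              cfg$tau_decay[[1]] / 1000) -
              par$ipsp_amp * dual_exp(tt - cfg$ipsp_delay / 1000,
                                      cfg$tau_rise[[2]] / 1000,
                                      cfg$tau_decay[[2]] / 1000)
      det <- c(rep(cfg$holding_vm, n_pre), cfg$holding_vm + defl)
      ins <- insert_spikes(det, n_pre, par$theta, cfg$sampling_rate, cfg$burst)
      spike_time <- if (length(ins$onsets)) (ins$onsets[1] - n_pre - 1) * dt else NA_real_
      tbt[[length(tbt) + 1L]] <- tibble::tibble(
        cell_id = id, temperature = Tk, theta = par$theta, rin = par$rin,
        epsp_amp = ci$amp * par$e_scale, ipsp_amp = par$ipsp_amp,
        spikes = length(ins$onsets) > 0, spike_time = spike_time
      )
      for (s in seq_len(cfg$sweeps_per_temperature)) {
        vm <- ins$trace + rnorm(length(det), 0, cfg$noise_sd)
        rows[[ridx]] <- tibble::tibble(
          cell_id = id, temperature = Tk, sweep_index = s, protocol = "evoked",
          step_pa = NA_real_, sampling_rate = cfg$sampling_rate,
          stim_onset = cfg$pre_stim, holding_vm = cfg$holding_vm, vm = list(vm)
        )
        ridx <- ridx + 1L
      }
      # hyperpolarising step sweep for Rin
      vm_step <- step_response(cfg, par$rin, -50) +
        rnorm(n_pre + round(0.6 / dt), 0, cfg$noise_sd)
      rows[[ridx]] <- tibble::tibble(
        cell_id = id, temperature = Tk, sweep_index = 1L, protocol = "step",
        step_pa = -50, sampling_rate = cfg$sampling_rate,
        stim_onset = cfg$pre_stim, holding_vm = cfg$holding_vm, vm = list(vm_step)
      )
      ridx <- ridx + 1L
    }
  }

  truth <- tibble::tibble(
    cell_id = sprintf("cell_%03d", seq_len(cfg$n_cells)),
    fate = fate,
    theta30 = theta30, rin30 = rin30,
    epsp_amp = vapply(cells, `[[`, numeric(1), "amp"),
    ipsp_amp = ipsp0
  )
  structure(
    list(sweeps = dplyr::bind_rows(rows), truth = truth,
         truth_by_temp = dplyr::bind_rows(tbt), config = cfg),
    class = "pn_cohort"
  )
}

#' @export
print.pn_cohort <- function(x, ...) {
  cat(sprintf("<pn_cohort> %d cells, %d sweeps (%s C), seed %d\n",
              nrow(x$truth), nrow(x$sweeps),
              paste(x$config$temperatures, collapse = "/"), x$config$seed))
  print(table(x$truth$fate))
  invisible(x)
}

# target spiking pattern per fate over nt ordered temperatures
switch_pattern <- function(fate, nt) {
  t(vapply(fate, function(f) {
    switch(f,
           never = rep(FALSE, nt),
           stay = rep(TRUE, nt),
           stop = c(rep(TRUE, nt - 1), FALSE),
           start = c(rep(FALSE, nt - 1), TRUE))
  }, logical(nt)))
}

# dual-exponential kernel normalised to unit peak; zero before onset
dual_exp <- function(t, tau_r, tau_d) {
  tpk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  pk <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  out <- ifelse(t >= 0, (exp(-t / tau_d) - exp(-t / tau_r)) / pk, 0)
  out
}

temp_params <- function(cfg, Tk, theta30, rin30, ipsp0, gained) {
  dT <- Tk - cfg$temperatures[1]
  rin <- rin30 * cfg$rin_q10^(dT / 10)
  e_scale <- (rin / rin30) * if (gained) (1 + cfg$stay_gain)^dT else 1
  list(theta = theta30 + cfg$theta_slope * dT,
       rin = rin,
       e_scale = e_scale,
       ipsp_amp = ipsp0 * (1 - cfg$ipsp_temp_factor)^dT)
}

# smallest excitatory amplitude whose deterministic deflection reaches
# threshold at temperature Tk (bisection on a 0.25-ms grid)
critical_amplitude <- function(cfg, Tk, theta30, rin30, ipsp0, gained) {
  par <- temp_params(cfg, Tk, theta30, rin30, ipsp0, gained)
  need <- par$theta - cfg$holding_vm
  tg <- seq(0, cfg$post_stim, by = 2.5e-4)
  ke <- par$e_scale * dual_exp(tg - cfg$epsp_delay / 1000,
                               cfg$tau_rise[[1]] / 1000, cfg$tau_decay[[1]] / 1000)
  ki <- par$ipsp_amp * dual_exp(tg - cfg$ipsp_delay / 1000,
                                cfg$tau_rise[[2]] / 1000, cfg$tau_decay[[2]] / 1000)
  lo <- 0; hi <- 10 * abs(need) + 100
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (max(mid * ke - ki) >= need) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# amplitude interval consistent with a fate's target pattern
fate_amplitude_interval <- function(fate, acrit, pattern) {
  lo_need <- acrit[pattern]      # must reach threshold at these temperatures
  hi_need <- acrit[!pattern]     # must stay below at these
  lower <- if (length(lo_need)) max(lo_need) else 0
  upper <- if (length(hi_need)) min(hi_need) else Inf
  c(lower, upper)
}

clamp_margin <- function(a, intv, frac = 0.08) {
  lo <- intv[1]; hi <- intv[2]
  if (is.finite(hi) && lo > 0) {
    w <- hi - lo
    min(max(a, lo + frac * w), hi - frac * w)
  } else if (is.finite(hi)) {            # NEVER: (0, hi)
    min(max(a, 0.35 * hi), (1 - frac) * hi)
  } else {                               # STAY: (lo, Inf)
    # drive scales with the critical amplitude (depolarisation adjusts to
    # meet threshold); only a compressed share of the draw's excess
    # survives, which plants the threshold-PSP coupling
    base <- (1 + 2 * frac) * lo
    base + 0.3 * max(a - base, 0)
  }
}

# insert 4-ms spike templates at deterministic threshold crossings within
# the evoked window; returns modified trace and onset indices
insert_spikes <- function(det, n_pre, theta, fs, burst) {
  trace <- det
  onsets <- integer(0)
  i <- n_pre + 1L
  n <- length(det)
  tpl_len <- round(0.004 * fs)
  while (i <= n) {
    if (trace[i] >= theta && det[i] >= theta) {
      end <- min(i + tpl_len - 1L, n)
      v_end <- det[min(end + 1L, n)]
      trace[i:end] <- spike_template(tpl_len, theta, v_end, fs)[seq_len(end - i + 1L)]
      onsets <- c(onsets, i)
      if (!burst) break
      i <- end + 1L
    } else i <- i + 1L
  }
  list(trace = trace, onsets = onsets)
}

# stereotyped action potential: kinked linear upstroke to +30 mV (the
# abrupt slope change at onset is what the second-derivative criterion
# keys on), cosine repolarisation, AHP recovery
spike_template <- function(tpl_len, theta, v_end, fs) {
  n_rise <- max(2L, round(0.0005 * fs))
  n_fall <- max(2L, round(0.001 * fs))
  n_ahp <- max(2L, tpl_len - n_rise - n_fall)
  peak <- 30
  ahp <- theta - 12
  rise <- seq(theta, peak, length.out = n_rise)
  fall <- peak + (ahp - peak) * (1 - cos(seq(0, pi, length.out = n_fall + 1)))[-1] / 2
  rec <- ahp + (v_end - ahp) * (1 - cos(seq(0, pi, length.out = n_ahp + 1)))[-1] / 2
  c(rise, fall, rec)[seq_len(tpl_len)]
}

# passive response to a current step (step_pa) from holding, 500-ms step
step_response <- function(cfg, rin, step_pa) {
  dt <- 1 / cfg$sampling_rate
  n_pre <- round(cfg$pre_stim / dt)
  n_step <- round(0.5 / dt)
  n_tail <- round(0.1 / dt)
  tau <- rin * cfg$membrane_cap * 1e-6     # MOhm * pF -> seconds
  dv <- step_pa * rin / 1000               # pA * MOhm -> mV
  t_step <- (seq_len(n_step) - 1) * dt
  t_tail <- seq_len(n_tail) * dt
  v_end <- dv * (1 - exp(-0.5 / tau))
  c(rep(cfg$holding_vm, n_pre),
    cfg$holding_vm + dv * (1 - exp(-t_step / tau)),
    cfg$holding_vm + v_end * exp(-t_tail / tau))
}

#' Simulate an F-I (frequency-current) protocol
#'
#' Leaky integrate-and-fire sweeps from a hyperpolarised holding potential:
#' for each injected current step the membrane charges passively toward
#' `holding + I * Rin` with the membrane time constant; a spike template is
#' inserted whenever the trace reaches threshold, after which the membrane
#' restarts from the post-spike reset. At zero noise the spike count is
#' nondecreasing in the injected current.
#'
#' @param rin input resistance, MOhm.
#' @param theta spike threshold, mV.
#' @param current_steps injected currents, pA, sorted ascending.
#' @param holding_vm holding potential, mV (the protocol holds cells well
#'   below threshold).
#' @param step_duration current step duration, s.
#' @param membrane_cap membrane capacitance, pF.
#' @param sampling_rate Hz.
#' @param noise_sd mV.
#' @param pre_stim baseline before the step, s.
#' @return tibble, one row per step: `step_pa`, `sampling_rate`,
#'   `stim_onset`, `holding_vm`, `vm` (list-column).
#' @examples
#' fi <- simulate_fi_sweeps(150, -42, current_steps = seq(25, 250, by = 25))
#' @export
simulate_fi_sweeps <- function(rin, theta, current_steps,
                               holding_vm = -80, step_duration = 0.5,
                               membrane_cap = 150, sampling_rate = 20000,
                               noise_sd = 0, pre_stim = 0.05) {
  if (length(current_steps) == 0) stop("empty `current_steps`", call. = FALSE)
  if (is.unsorted(current_steps)) stop("`current_steps` must be ascending", call. = FALSE)
  dt <- 1 / sampling_rate
  n_pre <- round(pre_stim / dt)
  n_step <- round(step_duration / dt)
  tau <- rin * membrane_cap * 1e-6
  rows <- lapply(current_steps, function(I) {
    v_inf <- holding_vm + I * rin / 1000
    vm <- numeric(n_step)
    v0 <- holding_vm; i <- 1L
    tpl_len <- round(0.004 * sampling_rate)
    while (i <= n_step) {
      v <- v_inf + (v0 - v_inf) * exp(-(seq_len(n_step - i + 1L) - 1) * dt / tau)
      cross <- which(v >= theta)[1]
      if (is.na(cross)) { vm[i:n_step] <- v; break }
      if (cross > 1) vm[i:(i + cross - 2L)] <- v[seq_len(cross - 1L)]
      end <- min(i + cross - 1L + tpl_len - 1L, n_step)
      tpl <- spike_template(tpl_len, theta, theta - 10, sampling_rate)
      vm[(i + cross - 1L):end] <- tpl[seq_len(end - (i + cross - 1L) + 1L)]
      v0 <- theta - 10
      i <- end + 1L
    }
    trace <- c(rep(holding_vm, n_pre), vm, rep(holding_vm, round(0.05 / dt)))
    if (noise_sd > 0) trace <- trace + rnorm(length(trace), 0, noise_sd)
    tibble::tibble(step_pa = I, sampling_rate = sampling_rate,
                   stim_onset = pre_stim, holding_vm = holding_vm,
                   vm = list(trace))
  })
  dplyr::bind_rows(rows)
}

#' Analytic rheobase of the passive model
#'
#' Closed-form minimal current reaching threshold within the step, snapped
#' up to the protocol's current grid: `I = 1000 (theta - holding) /
#' (Rin (1 - exp(-T/tau)))`.
#'
#' @inheritParams simulate_fi_sweeps
#' @return list with `exact_pa` and `grid_pa` (NA if no step suffices).
#' @export
fi_analytic_rheobase <- function(rin, theta, current_steps,
                                 holding_vm = -80, step_duration = 0.5,
                                 membrane_cap = 150) {
  tau <- rin * membrane_cap * 1e-6
  exact <- 1000 * (theta - holding_vm) / (rin * (1 - exp(-step_duration / tau)))
  grid <- current_steps[current_steps >= exact - 1e-9]
  list(exact_pa = exact,
       grid_pa = if (length(grid)) min(grid) else NA_real_)
}
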