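#' Pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()]. Unknown names in
#' `...` are rejected so typos cannot silently fall back to defaults.
#'
#' @param cohort a [cohort_config()] for the intracellular stage.
#' @param n_units,interneuron_frac,unit_seed extracellular stage.
#' @param tb_duration_h,tb_bouts,tb_seed body-temperature stage.
#' @param fate_mode `"three_temp"` or `"two_temp"` (the latter classifies
#'   on the last two temperatures, as in the 36-to-39-degree analyses).
#' @param dip_n_boot bootstrap replicates for the duration dip test.
#' @param out_dir artifact directory, or `NULL` to skip writing.
#' @param ... must be empty.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            n_units = 633, interneuron_frac = 0.221,
                            unit_seed = 7,
                            tb_duration_h = 6, tb_bouts = 2, tb_seed = 11,
                            fate_mode = "three_temp",
                            dip_n_boot = 2000,
                            out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown pipeline_config fields: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  structure(as.list(environment())[setdiff(names(formals()), "...")],
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or consumes) a cohort of intracellular sweeps, an
#' extracellular unit population and a body-temperature series, then runs
#' feature extraction, fate classification, unit classification, period
#' firing-rate analysis, and the summary statistics, optionally writing
#' every tabular artifact to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-built cohort (e.g. from
#'   [read_sweep_bundle()]); when `NULL` the simulate stage runs.
#' @param units optionally, a pre-built unit tibble.
#' @return a list of class `"run_report"` with elements `config_echo`,
#'   `features`, `cells`, `fates`, `unit_rates`, `classification`,
#'   `tb_summary`, and `paper_analog` (fate percentages, unit counts and
#'   ratio, dip result, correlation table).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL, units = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- simulate_pn_cohort(config$cohort)
  if (is.null(units))
    units <- simulate_unit_population(n_units = config$n_units,
                                      interneuron_frac = config$interneuron_frac,
                                      seed = config$unit_seed)
  tb <- simulate_body_temperature(config$tb_duration_h,
                                  n_fever_bouts = config$tb_bouts,
                                  seed = config$tb_seed)

  feats <- sweep_features(cohort$sweeps)
  cells <- cell_summaries(feats, cohort$sweeps)

  flags <- spiking_flags(feats)
  if (config$fate_mode == "two_temp") {
    temps <- sort(unique(flags$temperature))
    flags <- dplyr::filter(flags, .data$temperature %in% utils::tail(temps, 2))
  }
  fates <- fate_table(flags, mode = config$fate_mode)

  rates <- unit_period_rates(units)
  kept <- dplyr::filter(rates, .data$included)
  durations <- kept |> dplyr::distinct(.data$unit_id, .data$duration_ms)
  cl <- classify_units(durations$duration_ms, n_boot = config$dip_n_boot)
  kept <- dplyr::left_join(
    kept,
    tibble::tibble(unit_id = durations$unit_id, label = cl$units$label),
    by = "unit_id")
  norm <- normalize_rates(kept)
  tbs <- summarize_tb(tb)

  # spike threshold vs PSP coupling among spiking cells at the top
  # temperature (the mechanism readout)
  top <- max(cells$temperature)
  spiking_cells <- cells |>
    dplyr::filter(.data$temperature == top, .data$frac_sweeps_spiking > 0,
                  is.finite(.data$spike_threshold_vm))
  cor_tab <- if (nrow(spiking_cells) >= 3 &&
                 sd(spiking_cells$psp_peak) > 0 &&
                 sd(spiking_cells$spike_threshold_vm) > 0) {
    dplyr::bind_cols(
      pearson_test(spiking_cells$spike_threshold_vm, spiking_cells$psp_peak),
      tidy(deming_fit(spiking_cells$spike_threshold_vm,
                      spiking_cells$psp_peak)) |>
        tidyr::pivot_wider(names_from = "term", values_from = "estimate") |>
        dplyr::rename(deming_intercept = "(Intercept)", deming_slope = "slope")
    )
  } else tibble::tibble()

  report <- structure(list(
    config_echo = config,
    features = feats, cells = cells, fates = fates,
    unit_rates = kept, classification = cl,
    normalized = norm, tb = tb, tb_summary = tbs,
    paper_analog = list(
      fate_percent = fate_proportions(fates),
      n_units_included = length(unique(kept$unit_id)),
      unit_counts = c(interneuron = cl$n_interneuron,
                      principal = cl$n_principal),
      interneuron_percent = 100 * cl$interneuron_frac,
      boundary_ms = cl$boundary_ms,
      dip = tidy(cl$dip),
      correlation = cor_tab,
      tb_median = tbs$median_c
    )
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report_artifacts(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$fates)
  print(x$classification)
  cat(sprintf("  Tb median %.1f C, %d fever bout(s)\n",
              x$tb_summary$median_c, x$tb_summary$n_bouts))
  invisible(x)
}

write_report_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(report$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  fates_flat <- report$fates$cells |>
    dplyr::mutate(flags = vapply(.data$flags, function(f)
      paste(ifelse(f, "T", "F"), collapse = ""), character(1)))
  utils::write.csv(fates_flat, file.path(dir, "fates.csv"), row.names = FALSE)
  utils::write.csv(report$unit_rates, file.path(dir, "units.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    counts = as.list(table(report$fates$cells$fate)),
    percent = report$paper_analog$fate_percent
  ), file.path(dir, "fate_summary.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
  jsonlite::write_json(list(
    dip = unclass(tidy(report$classification$dip)),
    boundary_ms = report$classification$boundary_ms,
    n_interneuron = report$classification$n_interneuron,
    n_principal = report$classification$n_principal,
    interneuron_percent = 100 * report$classification$interneuron_frac
  ), file.path(dir, "classification_summary.json"), auto_unbox = TRUE,
  digits = NA, dataframe = "columns")
  jsonlite::write_json(report$tb_summary[c("median_c", "max_c", "min_c", "n_bouts")],
                       file.path(dir, "tb_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
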