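#' Write / read a sweep bundle
#'
#' A sweep bundle is a directory holding `manifest.json` (sweep metadata,
#' sampling rate, stimulus onset, holding potential, and optionally the
#' generator truth block) plus one two-column CSV per sweep with header
#' `time_s,vm_mV`. Writing then reading reproduces the voltage samples to
#' full float precision.
#'
#' @param cohort a `"pn_cohort"` (see [simulate_pn_cohort()]) or a list
#'   with at least `sweeps`.
#' @param dir target directory (created if needed).
#' @return `write_sweep_bundle` returns `dir` invisibly;
#'   `read_sweep_bundle` returns a list with `sweeps` (tibble) and
#'   `truth`/`truth_by_temp` when present in the manifest.
#' @export
write_sweep_bundle <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sw <- cohort$sweeps
  files <- sprintf("%s_T%g_%s_%02d.csv", sw$cell_id, sw$temperature,
                   sw$protocol, sw$sweep_index)
  for (i in seq_len(nrow(sw))) {
    fs <- sw$sampling_rate[i]
    vm <- sw$vm[[i]]
    df <- data.frame(time_s = sprintf("%.17g", (seq_along(vm) - 1) / fs),
                     vm_mV = sprintf("%.17g", vm))
    utils::write.csv(df, file.path(dir, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- list(
    format = "sweep_bundle",
    sweeps = dplyr::mutate(dplyr::select(sw, -"vm"), file = files)
  )
  if (!is.null(cohort$truth)) manifest$truth <- cohort$truth
  if (!is.null(cohort$truth_by_temp)) manifest$truth_by_temp <- cohort$truth_by_temp
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_sweep_bundle
#' @export
read_sweep_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  sw <- tibble::as_tibble(manifest$sweeps)
  need <- c("cell_id", "temperature", "sweep_index", "protocol",
            "sampling_rate", "stim_onset", "holding_vm", "file")
  miss <- setdiff(need, names(sw))
  if (length(miss))
    stop("manifest lacks fields: ", paste(miss, collapse = ", "), call. = FALSE)
  vm <- lapply(sw$file, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing sweep file: ", f, call. = FALSE)
    df <- utils::read.csv(path)
    if (!identical(names(df), c("time_s", "vm_mV")))
      stop("bad sweep CSV header in ", f, " (expect time_s,vm_mV)", call. = FALSE)
    df$vm_mV
  })
  sw$vm <- vm
  sw$file <- NULL
  out <- list(sweeps = sw)
  if (!is.null(manifest$truth)) out$truth <- tibble::as_tibble(manifest$truth)
  if (!is.null(manifest$truth_by_temp))
    out$truth_by_temp <- tibble::as_tibble(manifest$truth_by_temp)
  out
}

#' Write / read a unit bundle
#'
#' A unit bundle is a directory with `units_manifest.json`, one spike-time
#' text file per unit (one float second per line) and one waveform CSV
#' (`sample_idx,uV`).
#'
#' @param units a unit tibble (see [simulate_unit_population()]).
#' @param dir target directory.
#' @return `write_unit_bundle` returns `dir` invisibly; `read_unit_bundle`
#'   returns the unit tibble.
#' @export
write_unit_bundle <- function(units, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spike_files <- paste0(units$unit_id, "_spikes.txt")
  wf_files <- paste0(units$unit_id, "_waveform.csv")
  for (i in seq_len(nrow(units))) {
    writeLines(format(units$spike_times[[i]], digits = 17, scientific = FALSE,
                      trim = TRUE),
               file.path(dir, spike_files[i]))
    wf <- units$waveform[[i]]
    utils::write.csv(data.frame(sample_idx = seq_along(wf) - 1L,
                                uV = sprintf("%.17g", wf)),
                     file.path(dir, wf_files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  meta <- dplyr::select(units, -"spike_times", -"waveform")
  meta$spike_file <- spike_files
  meta$waveform_file <- wf_files
  jsonlite::write_json(list(format = "unit_bundle", units = meta),
                       file.path(dir, "units_manifest.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_unit_bundle
#' @export
read_unit_bundle <- function(dir) {
  mf <- file.path(dir, "units_manifest.json")
  if (!file.exists(mf)) stop("no units_manifest.json in ", dir, call. = FALSE)
  meta <- tibble::as_tibble(jsonlite::read_json(mf, simplifyVector = TRUE)$units)
  meta$spike_times <- lapply(meta$spike_file, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing spike file: ", f, call. = FALSE)
    as.numeric(readLines(path))
  })
  meta$waveform <- lapply(meta$waveform_file, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing waveform file: ", f, call. = FALSE)
    df <- utils::read.csv(path)
    if (!identical(names(df), c("sample_idx", "uV")))
      stop("bad waveform CSV header in ", f, call. = FALSE)
    df$uV
  })
  meta$spike_file <- NULL
  meta$waveform_file <- NULL
  meta
}

#' Write / read a body-temperature CSV
#'
#' Plain CSV with header `time_s,tb_c`.
#'
#' @param tb a `tb_series` tibble.
#' @param path file path.
#' @export
write_tb_csv <- function(tb, path) {
  utils::write.csv(tb[, c("time_s", "tb_c")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tb_csv
#' @export
read_tb_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df)[1:2], c("time_s", "tb_c")))
    stop("bad Tb CSV header (expect time_s,tb_c)", call. = FALSE)
  tibble::as_tibble(df)
}
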