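#' Per-temperature spiking flags
#'
#' A cell counts as spiking at a temperature when at least one of its
#' sweeps there carries `min_spikes` or more evoked spikes.
#'
#' @param features per-sweep feature tibble ([sweep_features()]) or any
#'   tibble with `cell_id`, `temperature`, `spike_count`.
#' @param min_spikes spikes per sweep required, default 1.
#' @return tibble `cell_id`, `temperature`, `spiking` (logical), ordered
#'   by temperature within cell.
#' @export
spiking_flags <- function(features, min_spikes = 1) {
  features |>
    dplyr::group_by(.data$cell_id, .data$temperature) |>
    dplyr::summarise(spiking = any(.data$spike_count >= min_spikes),
                     .groups = "drop") |>
    dplyr::arrange(.data$cell_id, .data$temperature)
}

#' Classify a spiking-fate label
#'
#' Maps the ordered per-temperature spiking flags of one cell onto the
#' STAY/STOP/START/NEVER labels: cells spiking nowhere are NEVER; cells
#' spiking at the first temperature are STAY if they keep spiking at every
#' later temperature and STOP otherwise; cells silent at the first
#' temperature that spike later are START. The two-temperature variant
#' (e.g. 36 to 39 degrees) is the same rule on two flags.
#'
#' @param flags logical vector of length 3 (`mode = "three_temp"`) or 2
#'   (`"two_temp"`), ordered by increasing temperature.
#' @param mode `"three_temp"` or `"two_temp"`.
#' @return one of `"NEVER"`, `"STAY"`, `"STOP"`, `"START"`.
#' @examples
#' classify_fate(c(TRUE, TRUE, TRUE))    # STAY
#' classify_fate(c(TRUE, FALSE, TRUE))   # STOP (lost spiking on a transition)
#' classify_fate(c(FALSE, TRUE), mode = "two_temp")  # START
#' @export
classify_fate <- function(flags, mode = c("three_temp", "two_temp")) {
  mode <- match.arg(mode)
  need <- if (mode == "three_temp") 3L else 2L
  if (length(flags) != need || anyNA(flags))
    stop(sprintf("`flags` must be %d non-missing logicals", need), call. = FALSE)
  if (!any(flags)) return("NEVER")
  if (flags[1]) {
    if (all(flags)) "STAY" else "STOP"
  } else "START"
}

#' Fate table for a cohort
#'
#' Applies [classify_fate()] to every cell's flags and tabulates cohort
#' counts and percentages.
#'
#' @param flags tibble from [spiking_flags()].
#' @param mode passed to [classify_fate()]; for `"two_temp"` supply flags
#'   at exactly two temperatures (e.g. filter to 36 and 39).
#' @return object of class `"fate_table"`: list with `cells` (tibble
#'   `cell_id`, flag columns, `fate`) and `cohort` (tibble `fate`, `n`,
#'   `percent`), plus `n_cells`.
#' @export
fate_table <- function(flags, mode = c("three_temp", "two_temp")) {
  mode <- match.arg(mode)
  wide <- flags |>
    dplyr::arrange(.data$cell_id, .data$temperature) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(fate = classify_fate(.data$spiking, mode = mode),
                     flags = list(setNames(.data$spiking,
                                           paste0("T", .data$temperature))),
                     .groups = "drop")
  lev <- c("NEVER", "STAY", "STOP", "START")
  cohort <- wide |>
    dplyr::count(fate = factor(.data$fate, levels = lev), .drop = FALSE,
                 name = "n") |>
    dplyr::mutate(fate = as.character(.data$fate),
                  percent = 100 * .data$n / sum(.data$n))
  structure(list(cells = wide, cohort = cohort, n_cells = nrow(wide)),
            class = "fate_table")
}

#' @export
print.fate_table <- function(x, ...) {
  cat(sprintf("<fate_table> %d cells\n", x$n_cells))
  print(as.data.frame(x$cohort), row.names = FALSE)
  invisible(x)
}

#' @rdname fate_table
#' @param x a `fate_table`.
#' @param ... unused.
#' @export
tidy.fate_table <- function(x, ...) x$cohort

#' Fate proportions
#'
#' Percentages per fate label, reported at full precision together with
#' the one-decimal and integer renderings used in cohort summaries
#' (3 STAY of 27 cells prints as 11.1).
#'
#' @param x a [fate_table()] or a named count vector.
#' @param n_cells total cells when `x` is a count vector.
#' @return tibble `fate`, `n`, `percent`, `percent_1dp`, `percent_int`.
#' @examples
#' fate_proportions(c(STAY = 3), n_cells = 27)$percent_1dp  # 11.1
#' @export
fate_proportions <- function(x, n_cells = NULL) {
  if (inherits(x, "fate_table")) {
    tab <- x$cohort
  } else {
    if (is.null(n_cells) || n_cells < 1) stop("supply `n_cells` >= 1", call. = FALSE)
    tab <- tibble::tibble(fate = names(x), n = as.numeric(x),
                          percent = 100 * as.numeric(x) / n_cells)
  }
  dplyr::mutate(tab,
                percent_1dp = round(.data$percent, 1),
                percent_int = round(.data$percent))
}

#' Compare a cohort proportion against a reference (exact binomial)
#'
#' Two-tailed exact binomial test of `k` successes in `n` trials against
#' the reference proportion `p0`; delegates to [binomial_two_tailed()].
#'
#' @param k,n successes and trials.
#' @param p0 reference proportion in (0, 1).
#' @param method `"small_p"` (default) or `"doubling"`.
#' @return tibble `k`, `n`, `p0`, `estimate`, `p.value`.
#' @export
compare_proportions_binomial <- function(k, n, p0, method = "small_p") {
  tibble::tibble(k = k, n = n, p0 = p0, estimate = k / n,
                 p.value = binomial_two_tailed(k, n, p0, method = method))
}

#' Summarise a body-temperature series
#'
#' Median and extremes of the series plus fever bouts: maximal runs of
#' consecutive readings at or above `fever_threshold`.
#'
#' @param tb tibble with columns `time_s` and `tb_c` (see
#'   [simulate_body_temperature()]).
#' @param fever_threshold degrees C, default 38.
#' @return list with `median_c`, `max_c`, `min_c`, `n_bouts` and `bouts`
#'   (tibble `start_s`, `end_s`, `peak_tb`).
#' @examples
#' tb <- tibble::tibble(time_s = seq(0, 1200, 300),
#'                      tb_c = c(36.5, 36.5, 38.2, 38.4, 36.6))
#' summarize_tb(tb)$n_bouts  # 1
#' @export
summarize_tb <- function(tb, fever_threshold = 38) {
  stopifnot(nrow(tb) > 0, all(c("time_s", "tb_c") %in% names(tb)))
  hot <- tb$tb_c >= fever_threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  bouts <- tibble::tibble(
    start_s = tb$time_s[starts[keep]],
    end_s = tb$time_s[ends[keep]],
    peak_tb = vapply(keep, function(j) max(tb$tb_c[starts[j]:ends[j]]), numeric(1))
  )
  list(median_c = median(tb$tb_c), max_c = max(tb$tb_c), min_c = min(tb$tb_c),
       n_bouts = nrow(bouts), bouts = bouts)
}
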