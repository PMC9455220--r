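#' Published beamline processing statistics
#'
#' The production job statistics of the online analysis stack over 20
#' months of operation (number of pipeline calls, frames processed and
#' run time per job), shipped as a plain-text table. These counts are the
#' input of the bookkeeping worked example in [hplc_share()].
#'
#' @return A tibble with columns `pipeline`, `n_calls`,
#'   `frames_thousands`, `runtime_s`.
#' @export
beamline_run_statistics <- function() {
  path <- system.file("extdata", "run_statistics.tsv", package = "biosas")
  tibble::as_tibble(utils::read.delim(path, sep = "\t"))
}

#' HPLC share of measurements and of measurement time
#'
#' Recomputes, from the processing-call bookkeeping, what fraction of the
#' beamline's measurements ran in inline-chromatography (HPLC) mode and
#' what fraction of the acquisition time they consumed. A measurement is
#' one sample analysis: one subtract-and-analyse job in sample-changer
#' mode, or one HPLC-analysis job. Acquisition time is proportional to the
#' frames collected on samples (the multi-frame integration calls are
#' preprocessing shared by both modes): HPLC acquires 100 frames per file
#' against 10 in sample-changer mode, which is exactly why its time share
#' dwarfs its measurement share.
#'
#' @param stats Statistics table, default [beamline_run_statistics()].
#' @return List with `measurements_pct` and `time_pct` (percent).
#' @examples
#' hplc_share()  # ~6% of measurements, ~73% of measurement time
#' @export
hplc_share <- function(stats = beamline_run_statistics()) {
  hplc <- stats[stats$pipeline == "hplc_analysis", ]
  sc <- stats[stats$pipeline == "subtract_sas_analysis", ]
  list(
    measurements_pct = 100 * hplc$n_calls / (hplc$n_calls + sc$n_calls),
    time_pct = 100 * hplc$frames_thousands /
      (hplc$frames_thousands + sc$frames_thousands))
}
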