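# Readers and writers for the supported on-disk formats.

#' Read a smartphone PPG record (Time/R/G/B/RR layout)
#'
#' One record per file, either JSON with arrays `Time` (capture times in
#' ms from start), `R`, `G`, `B` (per-frame mean colour intensities) and
#' optionally `RR` (reference intervals in ms), or a CSV with those column
#' names (the `RR` column, being shorter, may be padded with empty
#' fields).
#'
#' @param path file path (`.json` or `.csv`).
#' @return list with `Time`, the present channels among `R`, `G`, `B`,
#'   and `RR` (NULL if absent).
#' @export
read_welltory_record <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path)
  } else {
    d <- utils::read.csv(path, check.names = FALSE)
    rec <- lapply(d, function(col) col[!is.na(col)])
  }
  if (is.null(rec$Time)) stop("record has no Time array", call. = FALSE)
  out <- list(Time = as.numeric(rec$Time))
  for (ch in c("R", "G", "B")) {
    if (!is.null(rec[[ch]])) out[[ch]] <- as.numeric(rec[[ch]])
  }
  out$RR <- if (!is.null(rec$RR)) as.numeric(rec$RR) else NULL
  out
}

#' Read a generic single-channel PPG CSV
#'
#' Two columns with header `time_ms,value`.
#'
#' @param path file path.
#' @return list with `Time` (ms) and `value`.
#' @export
read_ppg_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "value") %in% names(d))) {
    stop("CSV must have columns time_ms,value", call. = FALSE)
  }
  list(Time = as.numeric(d$time_ms), value = as.numeric(d$value))
}

#' Write the per-interval quality table as CSV
#'
#' @param result an `rr_analysis`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(result, path) {
  d <- result$intervals[, c("peak_time_ms", "rr_ms", "q_sim", "q_cwt",
                            "q", "kept", "outlier")]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
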