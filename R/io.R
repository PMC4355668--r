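#' Read length-versus-time traces from CSV
#'
#' Expects the long format `fibril_id,time_min,length_um`. Traces are grouped
#' by fibril, sorted by time, and validated: numeric cells, strictly
#' increasing and uniform frame spacing per fibril. Errors name the offending
#' row or fibril.
#'
#' @param path CSV path.
#' @return Tibble with `fibril_id`, `time_min`, `length_um`.
#' @export
read_traces <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty trace file: ", path)
    return(tibble::tibble(fibril_id = character(0), time_min = numeric(0),
                          length_um = numeric(0)))
  }
  need <- c("fibril_id", "time_min", "length_um")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  for (col in c("time_min", "length_um")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' at data row %d of %s",
                   col, bad[1], path))
    }
    raw[[col]] <- v
  }
  raw <- raw[order(raw$fibril_id, raw$time_min), need, drop = FALSE]
  for (fid in unique(raw$fibril_id)) {
    tt <- raw$time_min[raw$fibril_id == fid]
    if (length(tt) >= 2) {
      dts <- diff(tt)
      if (any(dts <= 0)) stop("duplicate or non-increasing times for fibril ", fid)
      if (diff(range(dts)) > 1e-6) stop("non-uniform frame spacing for fibril ", fid)
    }
  }
  tibble::as_tibble(raw)
}

#' Write traces to CSV
#'
#' @param traces Long-format trace table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Emits `"<prefix>_rates.csv"` (one row per [stopgo_rates()] summary, 6
#' significant digits), `"<prefix>_segments.csv"`, optionally
#' `"<prefix>_fit.json"` (full precision), and `"<prefix>_summary.txt"`
#' recording every analysis setting that stands in for an unstated
#' experimental choice, so runs are auditable and byte-reproducible.
#'
#' @param rates A `rate_summary` (or row-bound tibble of them).
#' @param prefix Output path prefix.
#' @param fit Optional `rate_fit` to serialize as JSON.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(rates, prefix, fit = NULL) {
  files <- character(0)
  f_rates <- paste0(prefix, "_rates.csv")
  num <- vapply(rates, is.numeric, logical(1))
  rates_out <- as.data.frame(rates)
  rates_out[num] <- lapply(rates_out[num], signif, digits = 6)
  utils::write.csv(rates_out, f_rates, row.names = FALSE, quote = FALSE)
  files <- c(files, f_rates)

  seg <- attr(rates, "segments")
  if (!is.null(seg)) {
    f_seg <- paste0(prefix, "_segments.csv")
    seg_out <- as.data.frame(seg)
    numc <- vapply(seg_out, is.numeric, logical(1))
    seg_out[numc] <- lapply(seg_out[numc], signif, digits = 6)
    utils::write.csv(seg_out, f_seg, row.names = FALSE, quote = FALSE)
    files <- c(files, f_seg)
  }
  if (!is.null(fit)) {
    f_fit <- paste0(prefix, "_fit.json")
    jsonlite::write_json(
      list(rate_constants = unclass(fit$rc), chi2 = fit$chi2,
           residuals = fit$residuals, k0 = fit$k0,
           gauge = "k13 = kr_twisted = kr_nontwisted = 1 min^-1",
           n_starts = fit$n_starts_used),
      f_fit, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f_fit)
  }
  st <- attr(rates, "settings")
  if (!is.null(st)) {
    f_sum <- paste0(prefix, "_summary.txt")
    writeLines(c(
      "stop-go analysis settings",
      sprintf("  segmentation threshold : %.6g nm/min", st$v_thresh),
      sprintf("  smoothing window       : %d intervals", st$smooth_window),
      sprintf("  minimum run            : %d intervals", st$min_run),
      sprintf("  frame interval         : %.6g min", st$frame_dt),
      sprintf("  stop-duration censor   : %.6g min", st$stop_censor),
      sprintf("  missed-event correction: %s", st$correct_missed)
    ), f_sum)
    files <- c(files, f_sum)
  }
  invisible(files)
}
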