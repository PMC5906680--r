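#' Read and write localization tables as CSV
#'
#' The on-disk dialect is fixed: comma-separated, '.' decimal, header
#' `frame,x_um,y_um,photons,background,channel` (extra columns such as
#' `traj_id`, `fit_sigma`, `precision_est` are preserved when present).
#'
#' @param locs Localization (or trajectory) tibble.
#' @param path CSV file path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_localizations <- function(locs, path) {
  lead <- intersect(c("frame", "x_um", "y_um", "photons", "background", "channel"),
                    names(locs))
  locs <- locs[c(lead, setdiff(names(locs), lead))]
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(df)))
    abort(sprintf("%s lacks required columns %s", path,
                  paste(setdiff(need, names(df)), collapse = ", ")))
  as_tibble(df)
}

#' Read and write intensity traces as CSV
#'
#' Dialect: header `trace_id,frame,photons`.
#'
#' @param traces Tibble (`trace_id`, `frame`, `photons`).
#' @param path CSV file path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces[c("trace_id", "frame", "photons")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "photons") %in% names(df)))
    abort(sprintf("%s lacks required columns frame, photons", path))
  if (!"trace_id" %in% names(df)) df$trace_id <- 1L
  as_tibble(df)
}
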