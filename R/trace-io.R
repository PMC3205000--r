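#' Write and read simulation traces
#'
#' `write_trace()` writes the trajectory as CSV with header
#' `t_ms,V_mV,m,h,n` plus a JSON sidecar (`<path>.json`) holding the full
#' parameter set and protocol, so a trace file is self-describing and
#' `read_trace()` can rebuild an equivalent `hh_trace` (spike times are
#' re-detected, not stored).
#'
#' @param trace An `hh_trace` from [hh_simulate()].
#' @param path CSV output path; the sidecar is written next to it.
#' @return `write_trace()`: the CSV path, invisibly. `read_trace()`: an
#'   `hh_trace` object.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hh_trace"))
  df <- data.frame(t_ms = trace$t, V_mV = trace$V,
                   m = trace$m, h = trace$h, n = trace$n)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(parameters = unclass(trace$parameters),
               protocol = unclass(trace$protocol),
               V0 = trace$V0, clamp_hits = trace$clamp_hits,
               voltage_method = trace$voltage_method)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  need <- c("t_ms", "V_mV", "m", "h", "n")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing trace sidecar: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  p <- do.call(hh_parameters, as.list(side$parameters))
  proto <- do.call(stimulus_protocol, as.list(side$protocol))
  trace <- structure(
    list(t = df$t_ms, V = df$V_mV, m = df$m, h = df$h, n = df$n,
         spike_times = numeric(0), clamp_hits = as.integer(side$clamp_hits),
         parameters = p, protocol = proto, V0 = side$V0,
         voltage_method = side$voltage_method),
    class = "hh_trace")
  trace$spike_times <- detect_spikes(trace)
  trace
}
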