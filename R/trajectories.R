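#' Plot per-simulation parameter trajectories
#'
#' The fitting history of a session: one line per touched parameter, raw
#' control value (0-127) against the simulation index. The abscissa is the
#' rerun count, not wall-clock time, so the plot shows *which* parameters the
#' user worked on and in what order, independent of how fast they turned the
#' knobs.
#'
#' @param log A `session_log`.
#' @return A ggplot object (an annotated empty plot, with a warning, for a
#'   log with no applied events).
#' @importFrom rlang .data
#' @export
plot_trajectories <- function(log) {
  stopifnot(inherits(log, "session_log"))
  rec <- log$records
  if (!nrow(rec)) {
    warning("session log contains no applied events; plotting empty axes")
    return(ggplot2::ggplot() +
             ggplot2::scale_y_continuous(limits = c(0, 127)) +
             ggplot2::labs(x = "simulation index", y = "raw control value"))
  }
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$sim_index, y = .data$raw_value,
                                    colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 127)) +
    ggplot2::labs(x = "simulation index", y = "raw control value (0-127)",
                  colour = "parameter") +
    ggplot2::theme_minimal()
}

#' Export / import the trajectory table as CSV
#'
#' Columns `sim_index,element_id,parameter,raw_value,mapped_value`; the CSV
#' round-trips through `read_trajectory_csv()`.
#'
#' @param log A `session_log`.
#' @param path CSV path.
#' @return `read_trajectory_csv()`: the trajectory data frame.
#' @export
write_trajectory_csv <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  df <- log$records[, c("sim_index", "element_id", "parameter",
                        "raw_value", "mapped_value")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sim_index", "element_id", "parameter", "raw_value", "mapped_value")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df[need]
}
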