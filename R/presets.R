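#' Bundled firing-regime presets
#'
#' Three frozen parameter sets demonstrating the model's qualitative regimes
#' under the default step-current protocol:
#'
#' \describe{
#'   \item{`regular_spiking`}{Tonic firing throughout the stimulus.}
#'   \item{`subthreshold_oscillations`}{No spikes, but damped membrane
#'     oscillations after stimulus onset (sodium is too weak to reach
#'     threshold; the interplay of the fast activation and slower potassium
#'     gate still produces a resonance).}
#'   \item{`transient_spiking`}{Spiking at stimulus onset only; sodium
#'     inactivation builds up and is not recovered while the stimulus is on,
#'     silencing the cell.}
#' }
#'
#' Each preset file also declares the classification criteria it is expected
#' to satisfy (see [classify_regime()]). The sets were found interactively
#' with this package's own tuning loop and then frozen.
#'
#' @param name Preset name; see `hh_presets()` for the available names.
#' @return `hh_preset()`: a list with `name`, `parameters`
#'   ([hh_parameters()]), `protocol` ([stimulus_protocol()]) and
#'   `expected_features` (named list of classifier criteria).
#'   `hh_presets()`: character vector of preset names.
#' @examples
#' hh_presets()
#' @export
hh_presets <- function() {
  files <- list.files(system.file("presets", package = "hhtune"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' @rdname hh_presets
#' @export
hh_preset <- function(name) {
  path <- system.file("presets", paste0(name, ".yaml"), package = "hhtune")
  if (path == "")
    stop("unknown preset '", name, "'; available: ",
         paste(hh_presets(), collapse = ", "), call. = FALSE)
  raw <- yaml::read_yaml(path)
  list(name = raw$name,
       parameters = do.call(hh_parameters, raw$parameters),
       protocol = do.call(stimulus_protocol, raw$protocol),
       expected_features = raw$expected_features)
}

#' Default criteria for regime classification
#'
#' Thresholds used by [classify_regime()]; every preset file can override
#' them via its `expected_features` block.
#'
#' @return Named list: `min_spikes_regular` (spike count for tonic firing),
#'   `transient_window_ms` (all spikes within this window after onset count
#'   as transient), `osc_min_peaks` and `osc_min_amplitude_mV` (subthreshold
#'   oscillation detection), `spike_threshold_mV`.
#' @export
regime_criteria <- function() {
  list(min_spikes_regular = 5,
       transient_window_ms = 50,
       osc_min_peaks = 2,
       osc_min_amplitude_mV = 1,
       spike_threshold_mV = 0)
}

#' Classify the firing regime of a trace
#'
#' Qualitative classification of the response to a step current:
#' \itemize{
#'   \item `regular_spiking` -- at least `min_spikes_regular` spikes in the
#'     stimulus window, spread across it (the last spike falls in the final
#'     third of the window);
#'   \item `transient_spiking` -- at least one spike, all within
#'     `transient_window_ms` of stimulus onset;
#'   \item `subthreshold_oscillations` -- no spikes, but at least
#'     `osc_min_peaks` post-onset local voltage maxima rising
#'     `osc_min_amplitude_mV` above the post-transient mean (the mean over
#'     the second half of the stimulus window, after onset dynamics settle);
#'   \item `other` -- anything else, including flat traces.
#' }
#'
#' @param trace An `hh_trace`.
#' @param proto The [stimulus_protocol()] the trace was run under; defaults
#'   to the one stored on the trace.
#' @param criteria Classification thresholds, see [regime_criteria()].
#' @return A single string: the regime label.
#' @export
classify_regime <- function(trace, proto = trace$protocol,
                            criteria = regime_criteria()) {
  stopifnot(inherits(trace, "hh_trace"))
  crit <- modifyList(regime_criteria(), as.list(criteria))
  spikes <- detect_spikes(trace, threshold = crit$spike_threshold_mV)
  in_win <- spikes[spikes >= proto$t_on & spikes <= proto$t_off]

  if (length(in_win) >= crit$min_spikes_regular) {
    final_third <- proto$t_off - (proto$t_off - proto$t_on) / 3
    if (max(in_win) >= final_third) return("regular_spiking")
  }
  if (length(spikes) >= 1 &&
      all(spikes >= proto$t_on &
          spikes <= proto$t_on + crit$transient_window_ms))
    return("transient_spiking")
  if (length(spikes) == 0) {
    win <- trace$t > proto$t_on & trace$t <= proto$t_off
    if (any(win)) {
      V <- trace$V[win]; t <- trace$t[win]
      settle <- t >= (proto$t_on + proto$t_off) / 2
      if (any(settle)) {
        base <- mean(V[settle])
        n_pk <- count_peaks(V, base + crit$osc_min_amplitude_mV)
        if (n_pk >= crit$osc_min_peaks) return("subthreshold_oscillations")
      }
    }
  }
  "other"
}

# strict local maxima above a floor value
count_peaks <- function(V, floor_value) {
  if (length(V) < 3) return(0L)
  mid <- 2:(length(V) - 1)
  sum(V[mid] > V[mid - 1] & V[mid] >= V[mid + 1] & V[mid] >= floor_value)
}
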