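RAW_MAX <- 127L  # 7-bit control-change data byte

#' Bind a control element to a model parameter
#'
#' A binding maps one continuous control element's raw value (an integer in
#' 0-127) onto one tunable model parameter over the interval `[low, high]`,
#' either linearly or exponentially (the latter for scale-type parameters such
#' as conductances and time constants; it requires `low > 0`). Optionally, a
#' meta element may be attached that reshapes the interval live
#' (see [apply_meta()]).
#'
#' @param element_id Integer id of the primary control element.
#' @param parameter Name of the bound parameter; one of
#'   [tunable_parameters()].
#' @param map_kind `"linear"` or `"exponential"`.
#' @param low,high Interval bounds in the parameter's units; `low < high`.
#' @param meta_low_id,meta_high_id Optional element ids whose events reshape
#'   the interval via the meta law ([apply_meta()]). Either (or both, usually
#'   the same id) may be given; both trigger the same symmetric width
#'   rescaling about the interval centre.
#' @return An object of class `parameter_binding`. Carries the base interval
#'   (`low0`, `high0`) used as the meta law's reference, the current interval
#'   (`low`, `high`) and the element's last seen raw value (`last_raw`).
#' @examples
#' parameter_binding(3, "gNa_max", "exponential", low = 1, high = 300)
#' @export
parameter_binding <- function(element_id, parameter,
                              map_kind = c("linear", "exponential"),
                              low, high,
                              meta_low_id = NA, meta_high_id = NA) {
  map_kind <- match.arg(map_kind)
  element_id <- as.integer(element_id)
  if (!parameter %in% tunable_parameters())
    stop("'", parameter, "' is not a tunable parameter; valid: ",
         paste(tunable_parameters(), collapse = ", "), call. = FALSE)
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("binding requires finite low < high", call. = FALSE)
  if (map_kind == "exponential" && low <= 0)
    stop("exponential mapping requires low > 0", call. = FALSE)
  structure(list(element_id = element_id, parameter = parameter,
                 map_kind = map_kind,
                 low = low, high = high, low0 = low, high0 = high,
                 meta_low_id = as.integer(meta_low_id),
                 meta_high_id = as.integer(meta_high_id),
                 last_raw = NA_integer_),
            class = "parameter_binding")
}

#' @export
print.parameter_binding <- function(x, ...) {
  meta <- unique(stats::na.omit(c(x$meta_low_id, x$meta_high_id)))
  cat(sprintf("<parameter_binding> element %d -> %s, %s over [%g, %g]%s\n",
              x$element_id, x$parameter, x$map_kind, x$low, x$high,
              if (length(meta)) sprintf(" (meta element %s)",
                                        paste(meta, collapse = "/")) else ""))
  invisible(x)
}

check_raw <- function(raw_value) {
  if (length(raw_value) != 1 || is.na(raw_value) ||
      raw_value != as.integer(raw_value) ||
      raw_value < 0 || raw_value > RAW_MAX)
    stop("raw_value must be an integer in [0, 127]", call. = FALSE)
  as.integer(raw_value)
}

#' Map a raw control value onto a parameter value
#'
#' Linear: `low + (raw/127) * (high - low)`. Exponential:
#' `low * (high/low)^(raw/127)`. In both modes raw 0 and raw 127 hit `low`
#' and `high` exactly (the endpoints are assigned, not computed, so no
#' floating-point slop can accumulate there), and the map is strictly
#' increasing in the raw value.
#'
#' @param raw_value Integer in 0-127.
#' @param binding A [parameter_binding()].
#' @param low,high Override the binding's current interval (used internally
#'   by the meta machinery); default is the binding's interval.
#' @return The mapped parameter value, in the parameter's units.
#' @examples
#' b <- parameter_binding(0, "mu_m", "linear", low = -80, high = -20)
#' map_raw(64, b)
#' @export
map_raw <- function(raw_value, binding, low = binding$low,
                    high = binding$high) {
  raw_value <- check_raw(raw_value)
  if (raw_value == 0L) return(low)
  if (raw_value == RAW_MAX) return(high)
  f <- raw_value / RAW_MAX
  if (binding$map_kind == "linear") {
    low + f * (high - low)
  } else {
    if (low <= 0) stop("exponential mapping requires low > 0", call. = FALSE)
    low * (high / low)^f
  }
}

#' Invert a parameter value back to the nearest raw control value
#'
#' The inverse of [map_raw()], rounded to the nearest integer raw step; the
#' round trip `unmap_raw(map_raw(r))` is the identity for every raw value
#' 0-127. Values outside `[low, high]` are clamped to the nearest endpoint
#' and flagged via the `"clamped"` attribute.
#'
#' @param value A parameter value in the binding's units.
#' @param binding A [parameter_binding()].
#' @return Integer raw value in 0-127, with attribute `clamped` (logical).
#' @export
unmap_raw <- function(value, binding) {
  low <- binding$low; high <- binding$high
  clamped <- FALSE
  if (value < low) { value <- low; clamped <- TRUE }
  if (value > high) { value <- high; clamped <- TRUE }
  f <- if (binding$map_kind == "linear") {
    (value - low) / (high - low)
  } else {
    log(value / low) / log(high / low)
  }
  raw <- as.integer(round(f * RAW_MAX))
  raw <- max(0L, min(RAW_MAX, raw))
  structure(raw, clamped = clamped)
}

#' Reshape a binding's interval from a meta element
#'
#' Meta elements solve the "knob too coarse / range too narrow" problem: a
#' second element rescales the primary element's interval on an exponential
#' scale, about the interval centre, relative to the binding's base interval.
#' The scale is 1 at the centre detent (raw 64, interval unchanged), exactly
#' 1/4 at raw 0 and exactly 4 at raw 127:
#' `scale = 4^((raw - 64)/64)` below the detent and `4^((raw - 64)/63)`
#' above it. After rescaling, the primary parameter is re-derived from the
#' primary element's last raw value under the new interval by the caller
#' (see [run_session()]).
#'
#' @param binding A [parameter_binding()] with a meta element configured.
#' @param meta_raw Raw value 0-127 of the meta element.
#' @return The binding with updated `low`/`high`. For exponential bindings
#'   the lower bound is kept positive (floored at a tiny fraction of the base
#'   lower bound) so the mapping stays valid.
#' @examples
#' b <- parameter_binding(0, "mu_m", "linear", low = 0, high = 10,
#'                        meta_low_id = 20, meta_high_id = 20)
#' apply_meta(b, 127)[c("low", "high")]  # width 40 about centre 5
#' @export
apply_meta <- function(binding, meta_raw) {
  meta_raw <- check_raw(meta_raw)
  if (is.na(binding$meta_low_id) && is.na(binding$meta_high_id))
    stop("binding for '", binding$parameter, "' has no meta element",
         call. = FALSE)
  scale <- meta_width_scale(meta_raw)
  centre <- (binding$low0 + binding$high0) / 2
  half <- (binding$high0 - binding$low0) / 2 * scale
  low <- centre - half
  high <- centre + half
  if (binding$map_kind == "exponential" && low <= 0)
    low <- binding$low0 * 1e-6  # keep the exponential map well defined
  binding$low <- low
  binding$high <- high
  binding
}

# Exponential width law: 1/4 at 0, identity at the centre detent 64, 4 at 127.
meta_width_scale <- function(meta_raw) {
  d <- meta_raw - 64
  if (d <= 0) 4^(d / 64) else 4^(d / 63)
}

#' The default bindings of the Hodgkin-Huxley session
#'
#' Twelve continuous elements drive the eleven kinetic parameters plus the
#' stimulus amplitude. Scale-type parameters (time constants, conductances)
#' use exponential mappings; midpoints, slopes and the current use linear
#' ones. Every binding gets a meta element on the knob 12 rows up (ids
#' 12-23) for live range reshaping.
#'
#' @param with_meta Attach meta elements (default `TRUE`).
#' @return A list of [parameter_binding()] objects, one per entry of
#'   [tunable_parameters()].
#' @export
default_bindings <- function(with_meta = TRUE) {
  spec <- list(
    list(0,  "I_amp",   "linear",      0,    30),
    list(1,  "gNa_max", "exponential", 1,    500),
    list(2,  "gK_max",  "exponential", 1,    200),
    list(3,  "tau_m",   "exponential", 0.05, 20),
    list(4,  "tau_h",   "exponential", 0.1,  100),
    list(5,  "tau_n",   "exponential", 0.1,  100),
    list(6,  "mu_m",    "linear",      -80,  0),
    list(7,  "mu_h",    "linear",      -90,  -20),
    list(8,  "mu_n",    "linear",      -80,  0),
    list(9,  "s_m",     "linear",      1,    20),
    list(10, "s_h",     "linear",      -20,  -1),
    list(11, "s_n",     "linear",      1,    20))
  lapply(spec, function(s) {
    meta <- if (with_meta) s[[1]] + 12L else NA
    parameter_binding(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]],
                      meta_low_id = meta, meta_high_id = meta)
  })
}

#' Read and write binding configuration files
#'
#' YAML, one entry per binding with keys `element_id`, `parameter`,
#' `map_kind`, `low`, `high` and optional `meta_low_id` / `meta_high_id`.
#'
#' @param path YAML file path.
#' @param bindings List of [parameter_binding()] objects.
#' @return `read_bindings()`: a list of bindings.
#' @export
read_bindings <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(b) {
    parameter_binding(b$element_id, b$parameter, b$map_kind, b$low, b$high,
                      meta_low_id = b$meta_low_id %||% NA,
                      meta_high_id = b$meta_high_id %||% NA)
  })
}

#' @rdname read_bindings
#' @export
write_bindings <- function(bindings, path) {
  out <- lapply(bindings, function(b) {
    e <- list(element_id = b$element_id, parameter = b$parameter,
              map_kind = b$map_kind, low = b$low0, high = b$high0)
    if (!is.na(b$meta_low_id)) e$meta_low_id <- b$meta_low_id
    if (!is.na(b$meta_high_id)) e$meta_high_id <- b$meta_high_id
    e
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
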