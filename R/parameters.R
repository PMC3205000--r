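#' Model parameters for the modified Hodgkin-Huxley neuron
#'
#' Constructs the full parameter set of the model: eleven tunable kinetic
#' parameters (three time constants, three activation-curve midpoints, three
#' slope factors, two maximum conductances) plus fixed biophysical constants
#' (membrane capacitance, reversal potentials, leak conductance). The slope
#' factors carry the gate's direction in their sign: positive slopes give
#' activation curves that increase with voltage (m, n), a negative slope gives
#' the decreasing inactivation curve (h).
#'
#' Defaults are the classic squid-axon values with sigmoidal fits to the
#' original steady-state curves; they produce tonic spiking under the default
#' step-current protocol.
#'
#' @param tau_m,tau_h,tau_n Gating time constants, ms. Must be positive.
#' @param mu_m,mu_h,mu_n Activation-curve midpoints, mV.
#' @param s_m,s_h,s_n Activation-curve slope factors, mV; sign encodes
#'   direction (positive = activating, negative = inactivating). Must be
#'   nonzero.
#' @param gNa_max,gK_max Maximum sodium / potassium conductances, mS/cm^2.
#' @param C_m Membrane capacitance, uF/cm^2.
#' @param E_Na,E_K,E_L Reversal potentials, mV.
#' @param gL Leak conductance, mS/cm^2.
#' @return An object of class `hh_parameters` (a named list).
#' @examples
#' p <- hh_parameters()
#' p$gNa_max
#' @export
hh_parameters <- function(tau_m = 0.3, tau_h = 5, tau_n = 4,
                          mu_m = -40, mu_h = -62, mu_n = -53,
                          s_m = 9, s_h = -7, s_n = 15,
                          gNa_max = 120, gK_max = 36,
                          C_m = 1, E_Na = 50, E_K = -77, E_L = -54.4,
                          gL = 0.3) {
  p <- list(tau_m = tau_m, tau_h = tau_h, tau_n = tau_n,
            mu_m = mu_m, mu_h = mu_h, mu_n = mu_n,
            s_m = s_m, s_h = s_h, s_n = s_n,
            gNa_max = gNa_max, gK_max = gK_max,
            C_m = C_m, E_Na = E_Na, E_K = E_K, E_L = E_L, gL = gL)
  p <- lapply(p, as.numeric)
  class(p) <- "hh_parameters"
  validate_hh_parameters(p)
  p
}

#' Names of the tunable model parameters
#'
#' The eleven kinetic parameters a controller may be bound to, plus the
#' stimulus amplitude `I_amp` (bound controllers may drive the injected
#' current as well as the model kinetics).
#'
#' @return Character vector of valid binding targets.
#' @export
tunable_parameters <- function() {
  c("tau_m", "tau_h", "tau_n", "mu_m", "mu_h", "mu_n",
    "s_m", "s_h", "s_n", "gNa_max", "gK_max", "I_amp")
}

validate_hh_parameters <- function(p) {
  stopifnot(inherits(p, "hh_parameters"))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in names(p)) {
    if (!num1(p[[f]])) {
      stop("hh_parameters field '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$tau_m <= 0 || p$tau_h <= 0 || p$tau_n <= 0)
    stop("time constants tau_m, tau_h, tau_n must be > 0", call. = FALSE)
  if (p$gNa_max < 0 || p$gK_max < 0 || p$gL < 0)
    stop("conductances gNa_max, gK_max, gL must be >= 0", call. = FALSE)
  if (p$C_m <= 0) stop("membrane capacitance C_m must be > 0", call. = FALSE)
  if (p$s_m == 0 || p$s_h == 0 || p$s_n == 0)
    stop("slope factors s_m, s_h, s_n must be nonzero", call. = FALSE)
  invisible(p)
}

#' @export
print.hh_parameters <- function(x, ...) {
  cat("<hh_parameters>\n")
  cat(sprintf("  kinetics : tau_m=%.4g tau_h=%.4g tau_n=%.4g ms\n",
              x$tau_m, x$tau_h, x$tau_n))
  cat(sprintf("  midpoints: mu_m=%.4g mu_h=%.4g mu_n=%.4g mV\n",
              x$mu_m, x$mu_h, x$mu_n))
  cat(sprintf("  slopes   : s_m=%.4g s_h=%.4g s_n=%.4g mV\n",
              x$s_m, x$s_h, x$s_n))
  cat(sprintf("  conduct. : gNa_max=%.4g gK_max=%.4g gL=%.4g mS/cm^2\n",
              x$gNa_max, x$gK_max, x$gL))
  cat(sprintf("  constants: C_m=%.4g uF/cm^2, E_Na=%.4g E_K=%.4g E_L=%.4g mV\n",
              x$C_m, x$E_Na, x$E_K, x$E_L))
  invisible(x)
}

#' Step-current stimulus protocol
#'
#' Time discretisation and stimulus description for a single simulation run:
#' a current step of amplitude `I_amp` is injected on the half-open window
#' `[t_on, t_off)`. The defaults are the protocol used throughout the package:
#' a 0.1 ms time step, 300 ms of simulated time and a stimulus lasting from
#' 50 ms to 250 ms.
#'
#' The injected current is interpreted as a current density (uA/cm^2),
#' consistent with a membrane capacitance in uF/cm^2; for this scale-free
#' single-compartment model only the ratio `I/C_m` matters.
#'
#' @param dt Time step, ms.
#' @param duration Total simulated time, ms.
#' @param I_amp Step amplitude, uA/cm^2.
#' @param t_on,t_off Stimulus window bounds, ms (half-open: `t_on <= t < t_off`).
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol()
#' @export
stimulus_protocol <- function(dt = 0.1, duration = 300, I_amp = 10,
                              t_on = 50, t_off = 250) {
  proto <- list(dt = as.numeric(dt), duration = as.numeric(duration),
                I_amp = as.numeric(I_amp), t_on = as.numeric(t_on),
                t_off = as.numeric(t_off))
  class(proto) <- "stimulus_protocol"
  validate_protocol(proto)
  proto
}

validate_protocol <- function(proto) {
  stopifnot(inherits(proto, "stimulus_protocol"))
  with(proto, {
    if (!is.finite(dt) || dt <= 0 || dt > duration)
      stop("need 0 < dt <= duration", call. = FALSE)
    if (!is.finite(I_amp)) stop("I_amp must be finite", call. = FALSE)
    if (t_on < 0 || t_on > t_off || t_off > duration)
      stop("need 0 <= t_on <= t_off <= duration", call. = FALSE)
  })
  invisible(proto)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> dt=%g ms, duration=%g ms, I_amp=%g uA/cm^2, step [%g, %g) ms\n",
    x$dt, x$duration, x$I_amp, x$t_on, x$t_off))
  invisible(x)
}

#' Read and write parameter/protocol configuration files
#'
#' Flat key-value YAML files holding an [hh_parameters()] set and, optionally,
#' a [stimulus_protocol()]. Keys are named exactly as the constructor
#' arguments; unknown keys are an error. `write_hh_config()` and
#' `read_hh_config()` round-trip.
#'
#' @param path File path of the YAML config.
#' @param parameters An `hh_parameters` object.
#' @param protocol A `stimulus_protocol` object, or `NULL` to omit.
#' @return `read_hh_config()`: a list with elements `parameters` and
#'   `protocol` (the latter `NULL` when absent from the file).
#' @export
read_hh_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  param_keys <- names(formals(hh_parameters))
  proto_keys <- names(formals(stimulus_protocol))
  flat <- raw
  # accept either flat or sectioned ('parameters:' / 'protocol:') layout
  if (!is.null(raw$parameters) || !is.null(raw$protocol)) {
    flat <- c(raw$parameters, raw$protocol)
  }
  unknown <- setdiff(names(flat), c(param_keys, proto_keys))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- do.call(hh_parameters, flat[intersect(names(flat), param_keys)])
  proto <- NULL
  if (any(names(flat) %in% proto_keys))
    proto <- do.call(stimulus_protocol, flat[intersect(names(flat), proto_keys)])
  list(parameters = p, protocol = proto)
}

#' @rdname read_hh_config
#' @export
write_hh_config <- function(parameters, protocol = NULL, path) {
  validate_hh_parameters(parameters)
  out <- list(parameters = unclass(parameters))
  if (!is.null(protocol)) {
    validate_protocol(protocol)
    out$protocol <- unclass(protocol)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

# Set one tunable parameter on a (parameters, protocol) pair; 'I_amp' routes
# to the protocol, everything else to the kinetic parameter set.
set_tunable <- function(parameters, protocol, name, value) {
  if (!name %in% tunable_parameters())
    stop("not a tunable parameter: '", name, "'", call. = FALSE)
  if (name == "I_amp") {
    protocol$I_amp <- as.numeric(value)
    validate_protocol(protocol)
  } else {
    parameters[[name]] <- as.numeric(value)
    validate_hh_parameters(parameters)
  }
  list(parameters = parameters, protocol = protocol)
}

get_tunable <- function(parameters, protocol, name) {
  if (!name %in% tunable_parameters())
    stop("not a tunable parameter: '", name, "'", call. = FALSE)
  if (name == "I_amp") protocol$I_amp else parameters[[name]]
}
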