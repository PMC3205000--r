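#' Sigmoidal steady-state activation curve
#'
#' Equilibrium value of a gating variable at a fixed voltage,
#' `1 / (1 + exp(-(V - mu)/s))`. The slope factor's sign sets the direction:
#' `s > 0` gives a curve increasing with voltage (activation), `s < 0` a
#' decreasing one (inactivation). Symmetric about the midpoint:
#' `sigmoid_inf(mu + d) + sigmoid_inf(mu - d) = 1`.
#'
#' @param V Membrane voltage, mV (vectorised).
#' @param mu Midpoint, mV.
#' @param s Slope factor, mV; must be finite and nonzero.
#' @return Values in (0, 1), same length as `V`.
#' @examples
#' sigmoid_inf(-40, mu = -40, s = 5)   # 0.5 at the midpoint
#' sigmoid_inf(-35, mu = -40, s = -5)  # inactivation: decreasing in V
#' @export
sigmoid_inf <- function(V, mu, s) {
  if (!all(is.finite(V)) || !is.finite(mu) || !is.finite(s))
    stop("sigmoid_inf: V, mu and s must all be finite", call. = FALSE)
  if (s == 0) stop("sigmoid_inf: slope factor s must be nonzero", call. = FALSE)
  1 / (1 + exp(-(V - mu) / s))
}

#' One explicit-Euler update of a gating variable
#'
#' Advances a gating variable one step toward its steady state:
#' `x + dt * (x_inf - x) / tau`, clamped to `[0, 1]`. The clamp only engages
#' when `dt > tau` (the explicit scheme overshoots); for `dt <= tau` the
#' update is a convex combination of `x` and `x_inf` and stays in bounds by
#' itself. `x = x_inf` is a fixed point.
#'
#' @param x Current gating value, dimensionless in `[0, 1]`.
#' @param x_inf Steady-state target, dimensionless.
#' @param tau Time constant, ms; must be positive.
#' @param dt Time step, ms; must be positive.
#' @return Updated gating value in `[0, 1]`.
#' @examples
#' gating_step(0, x_inf = 1, tau = 10, dt = 0.1)  # 0.01
#' @export
gating_step <- function(x, x_inf, tau, dt) {
  if (!is.finite(tau) || tau <= 0) stop("gating_step: tau must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("gating_step: dt must be > 0", call. = FALSE)
  if (any(x < 0) || any(x > 1))
    stop("gating_step: x must lie in [0, 1]", call. = FALSE)
  pmin(pmax(x + dt * (x_inf - x) / tau, 0), 1)
}

#' One implicit-Euler update of the membrane voltage
#'
#' Backward-Euler update of the current-balance equation with the ionic
#' conductances held at their freshly updated values:
#' \deqn{V' = \frac{C_m V/dt + g_{Na} E_{Na} + g_K E_K + g_L E_L + I}
#'            {C_m/dt + g_{Na} + g_K + g_L}}
#' Because the new voltage is a convex combination of the old voltage and the
#' conductance-weighted reversal potential (shifted by the injected current),
#' the update is unconditionally stable: no time step can make it diverge.
#'
#' @param V Membrane voltage at the current step, mV.
#' @param gNa,gK Instantaneous sodium / potassium conductances
#'   (`gNa_max * m^3 * h` and `gK_max * n^4`), mS/cm^2; must be `>= 0`.
#' @param I Injected current density, uA/cm^2.
#' @param p An [hh_parameters()] object (supplies `C_m`, reversal potentials
#'   and `gL`).
#' @param dt Time step, ms; must be positive.
#' @return The voltage at the next step, mV.
#' @export
voltage_step <- function(V, gNa, gK, I, p, dt) {
  if (!is.finite(dt) || dt <= 0) stop("voltage_step: dt must be > 0", call. = FALSE)
  if (gNa < 0 || gK < 0) stop("voltage_step: conductances must be >= 0", call. = FALSE)
  (p$C_m * V / dt + gNa * p$E_Na + gK * p$E_K + p$gL * p$E_L + I) /
    (p$C_m / dt + gNa + gK + p$gL)
}

#' Resting potential of the model at zero injected current
#'
#' Finds the fixed point of the full system (gating at steady state, zero net
#' current) by damped iteration on the conductance-weighted reversal
#' potential. Falls back to `E_L` if the iteration does not converge (for
#' example in bistable corners of parameter space).
#'
#' @param p An [hh_parameters()] object.
#' @param tol Convergence tolerance on the voltage, mV.
#' @param max_iter Iteration cap.
#' @return Resting voltage, mV.
#' @export
resting_potential <- function(p, tol = 1e-10, max_iter = 2000) {
  validate_hh_parameters(p)
  V <- p$E_L
  for (k in seq_len(max_iter)) {
    m <- sigmoid_inf(V, p$mu_m, p$s_m)
    h <- sigmoid_inf(V, p$mu_h, p$s_h)
    n <- sigmoid_inf(V, p$mu_n, p$s_n)
    gNa <- p$gNa_max * m^3 * h
    gK <- p$gK_max * n^4
    V_inf <- (gNa * p$E_Na + gK * p$E_K + p$gL * p$E_L) / (gNa + gK + p$gL)
    V_new <- V + 0.2 * (V_inf - V)
    if (abs(V_new - V) < tol) return(V_new)
    V <- V_new
  }
  p$E_L
}

#' Simulate the modified Hodgkin-Huxley model
#'
#' Integrates the model over the protocol's time grid. Per step: (1) the three
#' gating variables advance by explicit Euler ([gating_step()]) toward their
#' sigmoidal steady states evaluated at the old voltage; (2) the instantaneous
#' conductances `gNa_max * m^3 * h` and `gK_max * n^4` are formed from the new
#' gating values; (3) the voltage advances by the implicit update
#' ([voltage_step()]) with the injected current `I_amp` on the half-open
#' window `[t_on, t_off)`. The run is fully deterministic.
#'
#' Gating starts at steady state for the initial voltage `V0`, which defaults
#' to the model's [resting_potential()]. Gating values are clamped to `[0, 1]`
#' whenever a user-chosen time constant drops below the time step; the number
#' of clamp engagements is reported on the trace rather than raised as an
#' error, so an interactive session survives extreme knob positions.
#'
#' @param p An [hh_parameters()] object.
#' @param proto A [stimulus_protocol()] object.
#' @param V0 Initial voltage, mV; `NULL` (default) for the resting potential.
#' @param voltage_method `"implicit"` (default, unconditionally stable) or
#'   `"explicit"` (forward Euler on the voltage too; provided for stability
#'   comparisons, diverges for stiff settings).
#' @param use_lut If `TRUE`, evaluate the three steady-state sigmoids through
#'   precomputed lookup tables ([sigmoid_lut()], 2048 points over
#'   [-100, 50] mV) instead of `exp()`; a speed/accuracy trade documented to
#'   stay within 1e-4 of the direct evaluation inside the table range.
#' @return An object of class `hh_trace`: a list with the time grid `t` (ms),
#'   voltage `V` (mV), gating vectors `m`, `h`, `n`, detected `spike_times`
#'   (upward 0 mV crossings, ms), `clamp_hits`, and the `parameters` and
#'   `protocol` used. All vectors have length `floor(duration/dt) + 1`.
#' @examples
#' tr <- hh_simulate(hh_parameters(), stimulus_protocol(duration = 100))
#' length(tr$spike_times)
#' @export
hh_simulate <- function(p, proto, V0 = NULL,
                        voltage_method = c("implicit", "explicit"),
                        use_lut = FALSE) {
  validate_hh_parameters(p)
  validate_protocol(proto)
  voltage_method <- match.arg(voltage_method)

  dt <- proto$dt
  n_steps <- floor(proto$duration / dt + 1e-9)
  t <- dt * (0:n_steps)

  if (is.null(V0)) V0 <- resting_potential(p)
  if (!is.finite(V0)) stop("V0 must be finite", call. = FALSE)

  # hoisted scalars: the loop below is the hot path
  tau_m <- p$tau_m; tau_h <- p$tau_h; tau_n <- p$tau_n
  mu_m <- p$mu_m; mu_h <- p$mu_h; mu_n <- p$mu_n
  s_m <- p$s_m; s_h <- p$s_h; s_n <- p$s_n
  gNa_max <- p$gNa_max; gK_max <- p$gK_max
  C_m <- p$C_m; E_Na <- p$E_Na; E_K <- p$E_K; E_L <- p$E_L; gL <- p$gL
  I_amp <- proto$I_amp; t_on <- proto$t_on; t_off <- proto$t_off

  if (use_lut) {
    lut_m <- sigmoid_lut(mu_m, s_m); lut_h <- sigmoid_lut(mu_h, s_h)
    lut_n <- sigmoid_lut(mu_n, s_n)
    inf_m <- lut_m$fun; inf_h <- lut_h$fun; inf_n <- lut_n$fun
  } else {
    inf_m <- function(V) 1 / (1 + exp(-(V - mu_m) / s_m))
    inf_h <- function(V) 1 / (1 + exp(-(V - mu_h) / s_h))
    inf_n <- function(V) 1 / (1 + exp(-(V - mu_n) / s_n))
  }

  V <- numeric(n_steps + 1)
  m <- numeric(n_steps + 1); h <- numeric(n_steps + 1); nn <- numeric(n_steps + 1)
  V[1] <- V0
  m[1] <- inf_m(V0); h[1] <- inf_h(V0); nn[1] <- inf_n(V0)
  clamp_hits <- 0L

  am <- dt / tau_m; ah <- dt / tau_h; an <- dt / tau_n
  for (i in seq_len(n_steps)) {
    Vi <- V[i]
    mi <- m[i] + am * (inf_m(Vi) - m[i])
    hi <- h[i] + ah * (inf_h(Vi) - h[i])
    ni <- nn[i] + an * (inf_n(Vi) - nn[i])
    if (mi < 0) { mi <- 0; clamp_hits <- clamp_hits + 1L }
    else if (mi > 1) { mi <- 1; clamp_hits <- clamp_hits + 1L }
    if (hi < 0) { hi <- 0; clamp_hits <- clamp_hits + 1L }
    else if (hi > 1) { hi <- 1; clamp_hits <- clamp_hits + 1L }
    if (ni < 0) { ni <- 0; clamp_hits <- clamp_hits + 1L }
    else if (ni > 1) { ni <- 1; clamp_hits <- clamp_hits + 1L }

    gNa <- gNa_max * mi * mi * mi * hi
    gK <- gK_max * ni * ni * ni * ni
    ti <- t[i]
    I <- if (ti >= t_on && ti < t_off) I_amp else 0

    Vn <- if (voltage_method == "implicit") {
      (C_m * Vi / dt + gNa * E_Na + gK * E_K + gL * E_L + I) /
        (C_m / dt + gNa + gK + gL)
    } else {
      Vi + (dt / C_m) *
        (-gNa * (Vi - E_Na) - gK * (Vi - E_K) - gL * (Vi - E_L) + I)
    }
    if (!is.finite(Vn)) {
      stop(structure(
        class = c("hhtune_nonfinite", "error", "condition"),
        list(message = sprintf(
          "non-finite membrane voltage at step %d (t = %g ms); aborting", i, t[i + 1]),
          call = NULL, step = i)))
    }
    m[i + 1] <- mi; h[i + 1] <- hi; nn[i + 1] <- ni
    V[i + 1] <- Vn
  }

  trace <- structure(
    list(t = t, V = V, m = m, h = h, n = nn,
         spike_times = numeric(0), clamp_hits = clamp_hits,
         parameters = p, protocol = proto, V0 = V0,
         voltage_method = voltage_method),
    class = "hh_trace")
  trace$spike_times <- detect_spikes(trace)
  trace
}

#' @export
print.hh_trace <- function(x, ...) {
  cat(sprintf(
    "<hh_trace> %d samples over %g ms (dt = %g ms); %d spike(s); V in [%.2f, %.2f] mV\n",
    length(x$t), max(x$t), x$protocol$dt, length(x$spike_times),
    min(x$V), max(x$V)))
  if (x$clamp_hits > 0)
    cat(sprintf("  gating clamp engaged %d time(s) (dt exceeds a time constant)\n",
                x$clamp_hits))
  invisible(x)
}

#' Detect spikes as upward threshold crossings
#'
#' A spike is recorded at sample `i` whenever `V[i-1] < threshold <= V[i]`.
#' No refractory window is applied; with the default 0 mV threshold and
#' action-potential-sized excursions this is unambiguous.
#'
#' @param trace An `hh_trace` from [hh_simulate()].
#' @param threshold Crossing threshold, mV.
#' @return Numeric vector of spike times, ms (possibly empty).
#' @export
detect_spikes <- function(trace, threshold = 0) {
  stopifnot(inherits(trace, "hh_trace"))
  V <- trace$V
  if (length(V) < 2) return(numeric(0))
  i <- which(V[-length(V)] < threshold & V[-1] >= threshold) + 1
  trace$t[i]
}

#' Tabulated sigmoid with linear interpolation
#'
#' Precomputes a steady-state activation curve on a regular voltage grid for
#' table lookup during simulation (a classic speed optimisation for
#' conductance-based models). Inside the table range the linear interpolant
#' deviates from [sigmoid_inf()] by at most about `(dV)^2 / (8 * s^2) / 6.2`;
#' with the default 2048 points over [-100, 50] mV and slopes of a few mV the
#' error is below 1e-4. Outside the range the table clamps to its edge values.
#'
#' @param mu Midpoint, mV.
#' @param s Slope factor, mV (nonzero).
#' @param V_range Length-2 numeric, the tabulated voltage interval, mV.
#' @param n_points Number of grid points, at least 2.
#' @return An object of class `sigmoid_lut`: list with the grid `V`, values
#'   `y`, and `fun`, a vectorised evaluator (linear interpolation, edge
#'   clamping).
#' @examples
#' lut <- sigmoid_lut(mu = -40, s = 9)
#' lut$fun(-40)  # 0.5
#' @export
sigmoid_lut <- function(mu, s, V_range = c(-100, 50), n_points = 2048) {
  if (length(V_range) != 2 || !all(is.finite(V_range)) || diff(V_range) <= 0)
    stop("V_range must be a finite, non-degenerate interval", call. = FALSE)
  if (!is.numeric(n_points) || n_points < 2)
    stop("n_points must be >= 2", call. = FALSE)
  V <- seq(V_range[1], V_range[2], length.out = n_points)
  y <- sigmoid_inf(V, mu, s)
  structure(list(V = V, y = y, mu = mu, s = s,
                 fun = approxfun(V, y, method = "linear", rule = 2)),
            class = "sigmoid_lut")
}
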