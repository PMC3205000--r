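# Independent high-accuracy reference solution of the model ODEs.
#
# Brute-force right-hand side handed to deSolve's adaptive lsoda solver;
# shares nothing with the package's fixed-step semi-implicit integrator.
# The step current is handled by integrating each constant-current segment
# separately so the discontinuity never crosses an adaptive step.
oracle_solve <- function(p, proto, V0 = NULL, out_dt = 0.01,
                         rtol = 1e-10, atol = 1e-10) {
  sig <- function(V, mu, s) 1 / (1 + exp(-(V - mu) / s))
  rhs <- function(t, y, parms) {
    V <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    gNa <- p$gNa_max * m^3 * h
    gK <- p$gK_max * n^4
    I <- parms$I
    dV <- (-gNa * (V - p$E_Na) - gK * (V - p$E_K) - p$gL * (V - p$E_L) + I) / p$C_m
    dm <- (sig(V, p$mu_m, p$s_m) - m) / p$tau_m
    dh <- (sig(V, p$mu_h, p$s_h) - h) / p$tau_h
    dn <- (sig(V, p$mu_n, p$s_n) - n) / p$tau_n
    list(c(dV, dm, dh, dn))
  }
  if (is.null(V0)) V0 <- resting_potential(p)
  y <- c(V = V0, m = sig(V0, p$mu_m, p$s_m), h = sig(V0, p$mu_h, p$s_h),
         n = sig(V0, p$mu_n, p$s_n))
  bounds <- sort(unique(c(0, proto$t_on, proto$t_off, proto$duration)))
  bounds <- bounds[bounds <= proto$duration]
  out <- NULL
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    I <- if (a >= proto$t_on && a < proto$t_off) proto$I_amp else 0
    times <- unique(c(seq(a, b, by = out_dt), b))
    seg <- deSolve::lsoda(y, times, rhs, parms = list(I = I),
                          rtol = rtol, atol = atol)
    y <- c(V = seg[nrow(seg), "V"], m = seg[nrow(seg), "m"],
           h = seg[nrow(seg), "h"], n = seg[nrow(seg), "n"])
    names(y) <- c("V", "m", "h", "n")
    out <- rbind(out, if (is.null(out)) seg else seg[-1, , drop = FALSE])
  }
  as.data.frame(out)
}

oracle_spikes <- function(sol, threshold = 0) {
  V <- sol$V
  i <- which(V[-length(V)] < threshold & V[-1] >= threshold) + 1
  sol$time[i]
}
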