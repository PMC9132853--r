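#' Hodgkin-Huxley gating rate coefficients
#'
#' Opening (`alpha`) and closing (`beta`) rates of the m, h and n gates in
#' 1/ms as functions of the membrane potential in mV (physiological
#' convention, rest near -75 mV). The removable singularities of `alpha_m`
#' (at -50 mV) and `alpha_n` (at -65 mV) are replaced by their analytic
#' limits.
#'
#' @param V membrane potential, mV (vectorised).
#' @return A list with numeric vectors `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @export
hh_rates <- function(V) {
  xm <- V + 50
  alpha_m <- ifelse(abs(xm) < 1e-7, 1.0, -0.1 * xm / expm1(-xm / 10))
  beta_m <- 4 * exp(-(V + 75) / 18)
  alpha_h <- 0.07 * exp(-(V + 75) / 20)
  beta_h <- 1 / (exp(-(V + 45) / 10) + 1)
  xn <- V + 65
  alpha_n <- ifelse(abs(xn) < 1e-7, 0.1, -0.01 * xn / expm1(-xn / 10))
  beta_n <- 0.125 * exp(-(V + 75) / 80)
  list(alpha_m = alpha_m, beta_m = beta_m, alpha_h = alpha_h,
       beta_h = beta_h, alpha_n = alpha_n, beta_n = beta_n)
}

#' Steady-state gate values
#'
#' @param V membrane potential, mV.
#' @return A list with `m`, `h`, `n` (each `alpha / (alpha + beta)`).
#' @export
hh_steady_gates <- function(V) {
  r <- hh_rates(V)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h),
       n = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' Total ionic membrane current density
#'
#' `I_ion = g_Na m^3 h (V - E_Na) + g_K n^4 (V - E_K) + g_L (V - E_L) -
#' I_stim` in uA/cm^2. Positive values are outward (hyperpolarising);
#' a positive stimulus depolarises.
#'
#' @param V membrane potential, mV.
#' @param gates a list with `m`, `h`, `n` in `[0, 1]`.
#' @param I_stim stimulus current density, uA/cm^2.
#' @param params an [hh_parameters()] list.
#' @return Ionic current density, uA/cm^2.
#' @export
hh_ionic_current <- function(V, gates, I_stim = 0, params = hh_parameters()) {
  params$g_Na * gates$m^3 * gates$h * (V - params$E_Na) +
    params$g_K * gates$n^4 * (V - params$E_K) +
    params$g_L * (V - params$E_L) - I_stim
}

#' Resting equilibrium of the membrane model
#'
#' Solves `I_ion(V, y_inf(V)) = 0` for the resting potential and returns the
#' corresponding steady gates. Used as the initial condition of every
#' simulation, so an unstimulated run stays exactly at rest (up to solver
#' tolerance).
#'
#' @param params an [hh_parameters()] list.
#' @return A list with `V` (mV) and `m`, `h`, `n`.
#' @export
hh_rest_state <- function(params = hh_parameters()) {
  f <- function(V) {
    y <- hh_steady_gates(V)
    hh_ionic_current(V, y, 0, params)
  }
  V0 <- uniroot(f, c(-90, -60), tol = 1e-13)$root
  c(list(V = V0), hh_steady_gates(V0))
}

#' Stimulus protocol
#'
#' A single rectangular current pulse applied to the membrane of the
#' recruited motor unit at its neuromuscular-junction nodes. The reference
#' amplitude is 700 mA/cm^2 (= 7e5 uA/cm^2) for 0.1 ms; any suprathreshold
#' amplitude elicits the same propagating action potential away from the
#' stimulation site.
#'
#' @param amplitude pulse amplitude in uA/cm^2.
#' @param duration pulse length, ms.
#' @param onset pulse onset time, ms.
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = 7e5, duration = 0.1, onset = 1) {
  stopifnot(duration > 0, onset >= 0)
  structure(list(amplitude = amplitude, duration = duration, onset = onset),
            class = "stimulus_protocol")
}

# amplitude of the stimulus during [t, t + dt), sampled at substep midpoints
stimulus_amplitudes <- function(stim, t, dt, n_sub) {
  if (is.null(stim)) return(numeric(n_sub))
  tm <- t + (seq_len(n_sub) - 0.5) * dt / n_sub
  ifelse(tm >= stim$onset & tm < stim$onset + stim$duration,
         stim$amplitude, 0)
}

#' Advance the membrane reaction terms
#'
#' Integrates the local (reaction) part of the membrane dynamics over
#' `n_sub` substeps of length `dt`: gating variables with the Rush-Larsen
#' exponential update, the membrane potential with forward Euler on
#' `dV/dt = -I_ion / C_m`. Stable for `dt <= 0.02` ms.
#'
#' @param V membrane potential vector, mV.
#' @param gates list with gate vectors `m`, `h`, `n`.
#' @param I_stim either a single number or a vector of per-substep stimulus
#'   amplitudes (uA/cm^2), applied at the nodes in `stim_nodes`.
#' @param dt substep length, ms.
#' @param n_sub number of substeps.
#' @param stim_nodes indices (into `V`) receiving the stimulus.
#' @param params an [hh_parameters()] list.
#' @return A list with updated `V` and `gates`.
#' @export
integrate_reaction <- function(V, gates, I_stim = 0, dt = 0.01, n_sub = 1,
                               stim_nodes = integer(0),
                               params = hh_parameters()) {
  if (dt > 0.02 + 1e-12)
    stop("reaction substep dt must be <= 0.02 ms for stability")
  amps <- rep_len(I_stim, n_sub)
  out <- hh_react_cpp(V, gates$m, gates$h, gates$n,
                      as.integer(stim_nodes), amps, dt, as.integer(n_sub),
                      params$g_Na, params$g_K, params$g_L,
                      params$E_Na, params$E_K, params$E_L, params$C_m)
  if (anyNA(out$V) || any(!is.finite(out$V))) {
    bad <- which(!is.finite(out$V))[1]
    stop(sprintf("membrane integration diverged at node %d", bad))
  }
  list(V = out$V, gates = list(m = out$m, h = out$h, n = out$n))
}
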