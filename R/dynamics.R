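#' One forward-Euler step of an adaptive exponential IF neuron
#'
#' Integrates the charge-balance equation
#' \deqn{C dV/dt = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
#'       - w + I_{syn} + I_{ext}}
#' together with the adaptation current
#' \deqn{\tau_w dw/dt = a (V - E_L) - w.}
#' When `V` reaches the emission threshold the neuron spikes: `V` is reset,
#' `w` is incremented by `b`, and integration of `V` is suspended for the
#' absolute refractory period, during which `V` stays clamped at the reset
#' potential. The exponential argument is capped (at 16) so a single coarse
#' Euler step cannot overflow between threshold and detection.
#'
#' @param state list with `V` (mV), `w_adapt` (nA), `refractory_time_remaining`
#'   (ms) and optionally `last_spike_time` (ms)
#' @param params a [neuron_params()] object
#' @param I_syn,I_ext synaptic and external input currents (pA)
#' @param dt integration step (ms)
#' @param t current time (ms), only used to record the spike time
#' @return list with the updated `state` and the logical `spiked`
#' @export
adex_step <- function(state, params, I_syn = 0, I_ext = 0, dt = 0.1, t = NA) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is.finite(I_syn) || !is.finite(I_ext) || !is.finite(state$V) ||
      !is.finite(state$w_adapt))
    stop("non-finite input to adex_step")
  if (dt <= 0) stop("dt must be > 0")
  p <- params
  V <- state$V
  wad <- state$w_adapt * 1000 # nA -> pA
  refr <- state$refractory_time_remaining
  spiked <- FALSE
  if (refr > 0) {
    refr <- refr - dt
    V <- p$reset_potential
    wad <- wad + dt * (p$adaptation_voltage_coeff *
                         (p$reset_potential - p$resting_potential) - wad) /
      p$adaptation_time_constant
  } else {
    ex <- min((V - p$threshold_voltage) / p$spike_steepness, 16)
    dV <- dt * (-p$leak_conductance * (V - p$resting_potential) +
                  p$leak_conductance * p$spike_steepness * exp(ex) -
                  wad + I_syn + I_ext) / p$capacitance
    wad <- wad + dt * (p$adaptation_voltage_coeff *
                         (V - p$resting_potential) - wad) /
      p$adaptation_time_constant
    V <- V + dV
    if (V >= p$emission_threshold) {
      spiked <- TRUE
      V <- p$reset_potential
      wad <- wad + p$adaptation_spike_increment * 1000
      refr <- p$refractory_period
      state$last_spike_time <- t
    }
  }
  state$V <- V
  state$w_adapt <- wad / 1000
  state$refractory_time_remaining <- max(refr, 0)
  list(state = state, spiked = spiked)
}

#' One step of postsynaptic-current kinetics
#'
#' PSCs have instantaneous rise and exponential decay: over `dt` the
#' current decays by `exp(-dt / tau_syn)`, and each presynaptic spike adds
#' its amplitude instantaneously.
#'
#' @param psc current value (pA)
#' @param tau_syn decay time constant (ms)
#' @param dt elapsed time (ms)
#' @param spike_amplitudes amplitudes (pA) of spikes arriving in this step
#' @return updated current (pA)
#' @export
psc_step <- function(psc, tau_syn, dt, spike_amplitudes = numeric()) {
  if (tau_syn <= 0) stop("tau_syn must be > 0")
  psc * exp(-dt / tau_syn) + sum(spike_amplitudes)
}

#' One step of Tsodyks-Markram short-term synaptic dynamics
#'
#' Between presynaptic spikes the utilisation `u` relaxes to its resting
#' value `U` with time constant `tau_facil` and the resource fraction `x`
#' recovers to 1 with `tau_rec`. At a presynaptic spike, facilitation is
#' applied first, `u <- u + U (1 - u)`, and depression then consumes
#' resources using the updated utilisation: the released fraction is
#' `u * x` and `x <- x (1 - u)`. The released fraction scales the PSC
#' amplitude `J = w * A * u * x`.
#'
#' @param state list with `u` and `x`, both in `[0, 1]`
#' @param params an [sd_params()] object
#' @param dt elapsed time since the last update (ms)
#' @param pre_spiked did a presynaptic spike occur at the end of the step?
#' @return list with updated `state` and `release_fraction` (0 if no spike)
#' @export
sd_step <- function(state, params, dt, pre_spiked = FALSE) {
  stopifnot(inherits(params, "sd_params"))
  if (dt < 0) stop("dt must be >= 0")
  u <- params$U + (state$u - params$U) * exp(-dt / params$tau_facil)
  x <- 1 + (state$x - 1) * exp(-dt / params$tau_rec)
  release <- 0
  if (pre_spiked) {
    u <- u + params$U * (1 - u)
    release <- u * x
    x <- x - release
  }
  list(state = list(u = u, x = x), release_fraction = release)
}

#' Stationary short-term dynamics under Poisson presynaptic firing
#'
#' Mean-field steady state of the resource model at presynaptic rate
#' `rate`:
#' \deqn{u_\infty = U (1 + \tau_f \nu) / (1 + U \tau_f \nu), \qquad
#'       x_\infty = 1 / (1 + u_\infty \tau_r \nu)}
#' so that the mean efficacy factor `u_inf * x_inf * rate` saturates at
#' `1 / tau_rec` for large rates, the bound that limits reverberating
#' activity in depressing networks.
#'
#' @param rate presynaptic firing rate (Hz)
#' @param params an [sd_params()] object
#' @return list with `u_inf`, `x_inf` and `mean_efficacy_factor = u_inf * x_inf`
#' @export
sd_stationary <- function(rate, params) {
  stopifnot(inherits(params, "sd_params"))
  if (any(rate < 0)) stop("rate must be >= 0")
  tf <- params$tau_facil / 1000
  tr <- params$tau_rec / 1000
  u_inf <- params$U * (1 + tf * rate) / (1 + params$U * tf * rate)
  x_inf <- 1 / (1 + u_inf * tr * rate)
  list(u_inf = u_inf, x_inf = x_inf,
       mean_efficacy_factor = u_inf * x_inf)
}
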