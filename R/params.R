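#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Defaults are the standard adaptive exponential model constants of
#' Brette & Gerstner (2005), the parameter set commonly used for cortical
#' regular-spiking pyramidal cells.
#'
#' @param capacitance membrane capacitance (pF)
#' @param leak_conductance leak conductance (nS)
#' @param resting_potential leak reversal / resting potential (mV)
#' @param reset_potential after-spike reset potential (mV)
#' @param spike_steepness exponential spike steepness Delta_T (mV)
#' @param emission_threshold voltage at which a spike is emitted (mV); acts
#'   as a numerical ceiling on the exponential upstroke
#' @param threshold_voltage soft threshold V_T of the exponential term (mV)
#' @param refractory_period absolute refractory period (ms), during which
#'   the membrane potential stays clamped at the reset value
#' @param adaptation_voltage_coeff subthreshold adaptation coupling a (nS)
#' @param adaptation_spike_increment spike-triggered adaptation increment b (nA)
#' @param adaptation_time_constant adaptation time constant tau_w (ms)
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(capacitance = 281, leak_conductance = 30,
                          resting_potential = -70.6, reset_potential = -70.6,
                          spike_steepness = 2, emission_threshold = 0,
                          threshold_voltage = -50.4, refractory_period = 2,
                          adaptation_voltage_coeff = 4,
                          adaptation_spike_increment = 0.0805,
                          adaptation_time_constant = 144) {
  p <- list(capacitance = capacitance, leak_conductance = leak_conductance,
            resting_potential = resting_potential,
            reset_potential = reset_potential,
            spike_steepness = spike_steepness,
            emission_threshold = emission_threshold,
            threshold_voltage = threshold_voltage,
            refractory_period = refractory_period,
            adaptation_voltage_coeff = adaptation_voltage_coeff,
            adaptation_spike_increment = adaptation_spike_increment,
            adaptation_time_constant = adaptation_time_constant)
  stopifnot(all(vapply(p, is.numeric, TRUE)), all(is.finite(unlist(p))))
  if (capacitance <= 0 || adaptation_time_constant <= 0 ||
      refractory_period < 0)
    stop("capacitance and time constants must be strictly positive")
  if (spike_steepness <= 0) stop("spike_steepness Delta_T must be > 0")
  if (reset_potential >= emission_threshold)
    stop("reset_potential must lie below the emission threshold")
  structure(p, class = "neuron_params")
}

#' Tsodyks-Markram short-term synaptic dynamics parameters
#'
#' The two stock parameterisations are the canonical depressing and
#' facilitating classes of the phenomenological resource model: a
#' depressing synapse has a high release probability and a slow recovery
#' from depression, a facilitating synapse a low release probability and a
#' slow decay of facilitation.
#'
#' @param kind `"depressing"` or `"facilitating"`; selects the default set
#' @param U utilisation of synaptic resources (release probability), in (0, 1]
#' @param tau_rec recovery time from depression (ms)
#' @param tau_facil decay time of facilitation (ms)
#' @param tau_syn decay time constant of the postsynaptic current (ms)
#' @return an object of class `sd_params`
#' @export
sd_params <- function(kind = c("depressing", "facilitating"), U = NULL,
                      tau_rec = NULL, tau_facil = NULL, tau_syn = 5) {
  kind <- match.arg(kind)
  def <- if (kind == "depressing") {
    list(U = 0.5, tau_rec = 800, tau_facil = 20)
  } else {
    list(U = 0.05, tau_rec = 130, tau_facil = 530)
  }
  p <- list(kind = kind,
            U = if (is.null(U)) def$U else U,
            tau_rec = if (is.null(tau_rec)) def$tau_rec else tau_rec,
            tau_facil = if (is.null(tau_facil)) def$tau_facil else tau_facil,
            tau_syn = tau_syn)
  if (p$U <= 0 || p$U > 1) stop("U must be in (0, 1]")
  if (p$tau_rec <= 0 || p$tau_facil <= 0 || p$tau_syn <= 0)
    stop("all time constants must be strictly positive")
  structure(p, class = "sd_params")
}

#' Triplet STDP rule parameters
#'
#' Defaults are the minimal all-to-all triplet model fitted to visual
#' cortex pairing data (Pfister & Gerstner 2006): pair potentiation and
#' triplet depression amplitudes are zero, depression is pair-based and
#' potentiation is carried by the pre-post-post triplet term, which is what
#' produces the LTD-to-LTP reversal above a critical pairing frequency.
#'
#' @param A2_plus,A2_minus pair LTP / LTD amplitudes (dimensionless)
#' @param A3_plus,A3_minus triplet LTP / LTD amplitudes (dimensionless)
#' @param tau_plus,tau_x decay times of the presynaptic detectors r1, r2 (ms)
#' @param tau_minus,tau_y decay times of the postsynaptic detectors o1, o2 (ms)
#' @param lambda plasticity rate; scales every weight update
#' @param w_max upper bound of the dimensionless scaling factor w
#' @param variant one of `"triplet"`, `"pair"`, `"anti"`; see
#'   [configure_rule()] for how the control variants are derived
#' @param pair_match_rate pairing rate (Hz) at which the pair-based control
#'   is tuned to reproduce the triplet timing window exactly
#' @param sign_pre,sign_post signs of the pre-triggered (depression-side)
#'   and post-triggered (potentiation-side) updates; flipped by the anti
#'   variant, not meant to be set directly
#' @return an object of class `triplet_params`
#' @export
triplet_params <- function(A2_plus = 0, A2_minus = 7.1e-3, A3_plus = 6.5e-3,
                           A3_minus = 0, tau_plus = 16.8, tau_minus = 33.7,
                           tau_x = 101, tau_y = 114, lambda = 1, w_max = 1,
                           variant = "triplet", pair_match_rate = 1,
                           sign_pre = -1, sign_post = 1) {
  p <- list(A2_plus = A2_plus, A2_minus = A2_minus, A3_plus = A3_plus,
            A3_minus = A3_minus, tau_plus = tau_plus, tau_minus = tau_minus,
            tau_x = tau_x, tau_y = tau_y, lambda = lambda, w_max = w_max,
            variant = variant, pair_match_rate = pair_match_rate,
            sign_pre = sign_pre, sign_post = sign_post)
  if (any(c(tau_plus, tau_minus, tau_x, tau_y) <= 0))
    stop("all detector time constants must be strictly positive")
  if (w_max <= 0) stop("w_max must be > 0")
  if (!variant %in% c("triplet", "pair", "anti"))
    stop("unknown variant: ", variant)
  if (variant == "pair" && (A3_plus != 0 || A3_minus != 0))
    stop("variant 'pair' requires zero triplet-term amplitudes")
  structure(p, class = "triplet_params")
}

#' Derive a control variant of the plasticity rule
#'
#' `"pair"` zeroes both triplet amplitudes and re-tunes the pair LTP
#' amplitude so that the timing window at `pair_match_rate` Hz matches the
#' triplet rule's window exactly (the steady-state value of the slow
#' postsynaptic detector just before a spike is folded into the amplitude).
#' `"anti"` is the exact pre/post role mirror of the rule: amplitude pairs
#' and detector time constants are swapped and the update signs inverted,
#' so the timing window is mirrored about `delta_t = 0` (post-before-pre
#' now potentiates) while the frequency dependence (and its LTD-to-LTP
#' reversal) is retained.
#'
#' @param variant `"triplet"`, `"pair"` or `"anti"`
#' @param params a [triplet_params()] object to derive the variant from
#' @return a [triplet_params()] object implementing the variant
#' @export
configure_rule <- function(variant = c("triplet", "pair", "anti"),
                           params = triplet_params()) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "triplet_params"))
  if (variant == "triplet") return(params)
  if (variant == "pair") {
    Tms <- 1000 / params$pair_match_rate
    o2bar <- exp(-Tms / params$tau_y) / (1 - exp(-Tms / params$tau_y))
    return(triplet_params(
      A2_plus = params$A2_plus + params$A3_plus * o2bar,
      A2_minus = params$A2_minus, A3_plus = 0, A3_minus = 0,
      tau_plus = params$tau_plus, tau_minus = params$tau_minus,
      tau_x = params$tau_x, tau_y = params$tau_y, lambda = params$lambda,
      w_max = params$w_max, variant = "pair",
      pair_match_rate = params$pair_match_rate))
  }
  # anti: swap amplitude pairs and detector time constants, invert signs
  triplet_params(
    A2_plus = params$A2_minus, A2_minus = params$A2_plus,
    A3_plus = params$A3_minus, A3_minus = params$A3_plus,
    tau_plus = params$tau_minus, tau_minus = params$tau_plus,
    tau_x = params$tau_y, tau_y = params$tau_x, lambda = params$lambda,
    w_max = params$w_max, variant = "anti",
    pair_match_rate = params$pair_match_rate,
    sign_pre = -params$sign_pre, sign_post = -params$sign_post)
}

# named vector handed to the C++ engines
rule_vector <- function(params) {
  c(a2p = params$A2_plus, a2m = params$A2_minus, a3p = params$A3_plus,
    a3m = params$A3_minus, tau_p = params$tau_plus, tau_m = params$tau_minus,
    tau_x = params$tau_x, tau_y = params$tau_y, sign_pre = params$sign_pre,
    sign_post = params$sign_post, lambda = params$lambda,
    wmax = params$w_max)
}

neuron_vector <- function(p) {
  c(Cm = p$capacitance, gL = p$leak_conductance, EL = p$resting_potential,
    Vr = p$reset_potential, DT = p$spike_steepness,
    VT = p$threshold_voltage, Vceil = p$emission_threshold,
    tref = p$refractory_period, a = p$adaptation_voltage_coeff,
    b = p$adaptation_spike_increment * 1000, # nA -> pA
    tauw = p$adaptation_time_constant)
}

#' Critical postsynaptic frequency of the plasticity rule
#'
#' Under independent Poisson pre- and postsynaptic trains the mean drift of
#' the minimal triplet rule is proportional to
#' `nu_pre * nu_post * (nu_post - nu_theta)`; this returns `nu_theta`, the
#' postsynaptic rate above which the drift turns potentiating regardless of
#' spike timing.
#'
#' @param rule a [triplet_params()] object
#' @return critical frequency (Hz)
#' @export
critical_frequency <- function(rule = triplet_params()) {
  (rule$A2_minus * rule$tau_minus / 1000) /
    (rule$A3_plus * (rule$tau_plus / 1000) * (rule$tau_y / 1000))
}
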