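#' Parameters of the conductance-based LIF neuron
#'
#' Constructs the parameter set of a leaky integrate-and-fire neuron with
#' conductance-based glutamatergic and GABAergic synapses. Sub-threshold
#' dynamics follow
#' \deqn{\tau \frac{dv}{dt} = -(v - E_L) - g_{GABA}(v - E_{GABA})
#'   - g_{Glu}(v - E_{Glu}),}
#' with a spike emitted whenever \eqn{v} reaches `E_thr`, after which the
#' voltage is reset instantaneously to `E_reset` (no refractory period).
#' Synaptic conductances are dimensionless, normalized by the leak conductance.
#' Defaults are standard values for a striatal projection neuron.
#'
#' @param tau Membrane time constant, ms.
#' @param E_L Leak reversal potential, mV.
#' @param E_thr Spike threshold, mV.
#' @param E_reset Reset potential, mV. Must lie below `E_thr`.
#' @param E_Glu Glutamate reversal potential, mV. Must lie above `E_thr`.
#'
#' @return An object of class `lif_params`.
#' @examples
#' p <- lif_params()
#' deterministic_rate(p, synaptic_drive(g_Glu = 0.4, E_GABA = -63))
#' @export
lif_params <- function(tau = 20, E_L = -80, E_thr = -60, E_reset = -70,
                       E_Glu = 0) {
  stopifnot(tau > 0, E_reset < E_thr, E_Glu > E_thr)
  structure(list(tau = tau, E_L = E_L, E_thr = E_thr, E_reset = E_reset,
                 E_Glu = E_Glu),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat("Conductance-based LIF neuron\n")
  cat(sprintf("  tau = %g ms, E_L = %g mV, E_thr = %g mV, E_reset = %g mV, E_Glu = %g mV\n",
              x$tau, x$E_L, x$E_thr, x$E_reset, x$E_Glu))
  invisible(x)
}

#' Parameters of the EIF-Kir neuron
#'
#' Extends the LIF neuron with an exponential spike-generating current
#' \eqn{\Delta_T \exp((v - V_T)/\Delta_T)} and an inward-rectifier potassium
#' (Kir) current \eqn{-g_K\,f(v)\,(v - E_K)} with sigmoidal activation
#' \eqn{f(v) = 1/(1 + \exp((v - V_P)/K))}, so the Kir conductance shuts off
#' with depolarization. There is no hard threshold: the exponential term makes
#' the voltage diverge, and a spike is registered at a numeric cutoff `V_cut`
#' (see [sim_config()]), after which the voltage resets to `E_reset`. Constant
#' current injections are expressed as \eqn{I/g_L} with the absolute leak
#' conductance `g_L_nS`.
#'
#' Defaults reproduce the sub- and supra-threshold behavior of a typical spiny
#' projection neuron. The reset potential is inherited from the LIF parameter
#' set.
#'
#' @param base An object from [lif_params()]; supplies `tau`, `E_L`, `E_reset`
#'   and `E_Glu` (its hard threshold `E_thr` is unused here).
#' @param Delta_T Spike slope factor, mV.
#' @param V_T Exponential-term threshold, mV.
#' @param g_K Kir conductance, dimensionless (normalized by leak).
#' @param K Kir inactivation slope factor, mV.
#' @param V_P Kir half-conductance potential, mV.
#' @param E_K Kir reversal potential, mV.
#' @param g_L_nS Absolute leak conductance, nS, used to convert injected
#'   currents in pA into mV drive.
#'
#' @return An object of class `eif_kir_params`.
#' @seealso [simulate_eif_kir()], [vi_curve()], [fi_curve()]
#' @export
eif_kir_params <- function(base = lif_params(), Delta_T = 2, V_T = -60,
                           g_K = 5, K = 16, V_P = -80, E_K = -80,
                           g_L_nS = 5) {
  stopifnot(inherits(base, "lif_params"), Delta_T > 0, K > 0, g_K >= 0,
            g_L_nS > 0)
  structure(c(base,
              list(Delta_T = Delta_T, V_T = V_T, g_K = g_K, K = K, V_P = V_P,
                   E_K = E_K, g_L_nS = g_L_nS)),
            class = c("eif_kir_params", "lif_params"))
}

#' @export
print.eif_kir_params <- function(x, ...) {
  cat("EIF-Kir neuron\n")
  cat(sprintf("  tau = %g ms, E_L = %g mV, E_reset = %g mV, E_Glu = %g mV\n",
              x$tau, x$E_L, x$E_reset, x$E_Glu))
  cat(sprintf("  Delta_T = %g mV, V_T = %g mV, g_K = %g, K = %g mV, V_P = %g mV, E_K = %g mV\n",
              x$Delta_T, x$V_T, x$g_K, x$K, x$V_P, x$E_K))
  invisible(x)
}

#' Synaptic operating point
#'
#' The constant-conductance synaptic drive of a neuron: glutamatergic and
#' GABAergic conductances (dimensionless, normalized by leak) and the GABA
#' reversal potential. Fields may be vectors (recycled), which vectorizes the
#' analytic operations over drive points.
#'
#' @param g_Glu Glutamatergic conductance, `>= 0`.
#' @param g_GABA GABAergic conductance, `>= 0`.
#' @param E_GABA GABA reversal potential, mV.
#' @return An object of class `synaptic_drive`.
#' @export
synaptic_drive <- function(g_Glu, g_GABA = 0, E_GABA = -70) {
  stopifnot(all(g_Glu >= 0), all(g_GABA >= 0))
  structure(list(g_Glu = g_Glu, g_GABA = g_GABA, E_GABA = E_GABA),
            class = "synaptic_drive")
}

#' @export
print.synaptic_drive <- function(x, ...) {
  cat(sprintf("Synaptic drive: g_Glu = %s, g_GABA = %s, E_GABA = %s mV\n",
              paste(signif(x$g_Glu, 4), collapse = ","),
              paste(signif(x$g_GABA, 4), collapse = ","),
              paste(signif(x$E_GABA, 4), collapse = ",")))
  invisible(x)
}

#' Input-noise models
#'
#' Three models for the stochastic component of the input current
#' \eqn{I_{noise} = \sigma \sqrt{\tau}\, \zeta(t)} with unit-variance Gaussian
#' white noise \eqn{\zeta}:
#'
#' * `noise_none()` — deterministic dynamics (\eqn{\sigma = 0}).
#' * `noise_constant(sigma)` — additive noise of fixed amplitude `sigma` (mV),
#'   independent of membrane potential and conductances.
#' * `noise_conductance(a_Glu, a_GABA)` — multiplicative noise from the
#'   diffusion approximation of Poisson presynaptic firing, with unitary
#'   synaptic strengths `a_Glu`, `a_GABA` (dimensionless). Its amplitude is
#'   \eqn{\sigma^2 = \sum_s a_s g_s (E_{eff} - E_s)^2} evaluated at the
#'   effective reversal potential (see [conductance_noise_sigma()]).
#'
#' @param sigma Noise amplitude, mV, `>= 0`.
#' @param a_Glu,a_GABA Unitary synaptic strengths, `>= 0`. By default both
#'   synapse types share a single strength `a`.
#' @return A `noise_model` object.
#' @name noise_model
NULL

#' @rdname noise_model
#' @export
noise_none <- function() {
  structure(list(kind = "none"), class = c("noise_none", "noise_model"))
}

#' @rdname noise_model
#' @export
noise_constant <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  structure(list(kind = "constant", sigma = sigma),
            class = c("noise_constant", "noise_model"))
}

#' @rdname noise_model
#' @export
noise_conductance <- function(a_Glu, a_GABA = a_Glu) {
  stopifnot(a_Glu >= 0, a_GABA >= 0)
  structure(list(kind = "conductance", a_Glu = a_Glu, a_GABA = a_GABA),
            class = c("noise_conductance", "noise_model"))
}

#' @export
print.noise_model <- function(x, ...) {
  switch(x$kind,
         none = cat("No input noise\n"),
         constant = cat(sprintf("Constant input noise: sigma = %g mV\n", x$sigma)),
         conductance = cat(sprintf(
           "Conductance-dependent input noise: a_Glu = %g, a_GABA = %g\n",
           x$a_Glu, x$a_GABA)))
  invisible(x)
}

#' Integration configuration for time-stepped simulations
#'
#' @param dt Integration step, ms. Euler-Maruyama integration is used
#'   throughout; 0.05 ms is adequate for LIF dynamics, while the stiff
#'   exponential term of the EIF-Kir model calls for 0.01 ms.
#' @param duration Total simulated time, ms.
#' @param transient Initial window discarded from all analyses, ms.
#' @param seed Integer seed, or `NULL` to leave the RNG state untouched.
#' @param v_cut Numeric spike-detection ceiling for the EIF-Kir model, mV.
#'   Beyond roughly -30 mV the exponential current dominates and the spike
#'   time becomes insensitive (sub-dt) to the exact cutoff.
#' @param v_init Initial voltage, mV, or `NULL` for the leak reversal.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.05, duration = 1000, transient = 100,
                       seed = NULL, v_cut = -30, v_init = NULL) {
  stopifnot(dt > 0, duration > transient, transient >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(dt = dt, duration = duration, transient = transient,
                 seed = seed, v_cut = v_cut, v_init = v_init),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: dt = %g ms, duration = %g ms, transient = %g ms, seed = %s\n",
              x$dt, x$duration, x$transient,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
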