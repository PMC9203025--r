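# Overflow-safe scaled complementary error function erfcx(z) = exp(z^2) erfc(z).
# pracma::erfcx loses accuracy/overflows for z > ~26; beyond z = 15 the
# asymptotic series is already accurate to machine precision.
.erfcx <- function(z) {
  out <- numeric(length(z))
  big <- z > 15
  if (any(!big)) out[!big] <- pracma::erfcx(z[!big])
  if (any(big)) {
    zz <- z[big]; iz2 <- 1 / (2 * zz^2)
    out[big] <- (1 - iz2 + 3 * iz2^2 - 15 * iz2^3 + 105 * iz2^4) /
      (zz * sqrt(pi))
  }
  out
}

# Integrand of the first-passage-time integral, exp(x^2)(1 + erf(x)) = erfcx(-x),
# evaluated without overflow for x << 0.
.fpt_integrand <- function(x) .erfcx(-x)

# Antiderivative (in z = -x) of the asymptotic expansion of erfcx(z), used to
# integrate the deep sub-reset tail x < -10 analytically.
.fpt_tail_antideriv <- function(z) {
  (log(z) + 1 / (4 * z^2) - 3 / (16 * z^4)) / sqrt(pi)
}

# \int_a^b erfcx(-x) dx over a segment with b <= -10, via the asymptotic series.
.fpt_tail_integral <- function(a, b) {
  .fpt_tail_antideriv(-a) - .fpt_tail_antideriv(-b)
}

# Core scalar evaluation of the noisy rate (ms^-1) from effective quantities.
.ric_rate_ms <- function(g_eff, E_eff, sigma, tau, E_thr, E_reset) {
  sigma_eff <- sigma / sqrt(g_eff)
  tau_eff <- tau / g_eff
  x_min <- (E_reset - E_eff) / sigma_eff
  x_max <- (E_thr - E_eff) / sigma_eff
  if (x_max > 26) {
    # deep sub-threshold: integral dominated by exp(x_max^2)/x_max; work in logs
    lognu <- -(log(tau_eff * sqrt(pi)) + x_max^2 - log(x_max))
    return(exp(lognu))  # underflows to 0 for strongly sub-threshold points
  }
  I <- 0
  a <- x_min
  if (a < -10) {
    b_tail <- min(x_max, -10)
    I <- I + .fpt_tail_integral(a, b_tail)
    a <- b_tail
  }
  if (x_max > a) {
    I <- I + integrate(.fpt_integrand, a, x_max, rel.tol = 1e-10,
                       abs.tol = 1e-12, subdivisions = 500L)$value
  }
  1 / (tau_eff * sqrt(pi) * I)
}

# Effective sigma (mV) of a noise model at a drive point; 0 for noise_none.
.noise_sigma <- function(params, drive, noise) {
  switch(noise$kind,
         none = 0,
         constant = noise$sigma,
         conductance = conductance_noise_sigma(params, drive, noise$a_Glu,
                                               noise$a_GABA),
         stop("invalid noise kind: ", noise$kind))
}

.noise_is_none <- function(noise) {
  noise$kind == "none" || (noise$kind == "constant" && noise$sigma == 0)
}

#' Firing rate of the LIF neuron under white input noise
#'
#' Mean first-passage-time (Ricciardi) firing rate of the conductance-based
#' LIF neuron driven by Gaussian white noise:
#' \deqn{\nu = \left[\tau_{eff}\sqrt{\pi}
#'   \int_{x_{min}}^{x_{max}} e^{x^2}(1 + \mathrm{erf}(x))\,dx\right]^{-1},}
#' \deqn{x_{min} = \frac{E_{reset} - E_{eff}}{\sigma_{eff}}, \quad
#'   x_{max} = \frac{E_{thr} - E_{eff}}{\sigma_{eff}}, \quad
#'   \tau_{eff} = \tau / g_{eff}, \quad \sigma_{eff} = \sigma / \sqrt{g_{eff}}.}
#'
#' The integrand is evaluated through the scaled complementary error function
#' to avoid overflow, the deep tail \eqn{x < -10} is integrated with its
#' asymptotic expansion, and strongly sub-threshold points
#' (\eqn{x_{max} > 26}) are handled in log space, so the evaluation is finite
#' and continuous over the whole parameter range. With a `noise_conductance`
#' model, \eqn{\sigma} is first computed from the drive via
#' [conductance_noise_sigma()]. Zero noise dispatches to
#' [deterministic_rate()].
#'
#' @inheritParams effective_input
#' @param noise A [noise_model].
#' @return Firing rate in Hz (vectorized over the drive).
#' @examples
#' p <- lif_params()
#' ricciardi_rate(p, synaptic_drive(g_Glu = 0.25, E_GABA = -65),
#'                noise_constant(3))
#' @export
ricciardi_rate <- function(params, drive, noise) {
  stopifnot(inherits(params, "lif_params"), inherits(drive, "synaptic_drive"),
            inherits(noise, "noise_model"))
  if (.noise_is_none(noise)) return(deterministic_rate(params, drive))
  eff <- effective_input(params, drive)
  n <- max(lengths(eff))
  g <- rep_len(eff$g_eff, n); E <- rep_len(eff$E_eff, n)
  sig <- rep_len(.noise_sigma(params, drive, noise), n)
  vapply(seq_len(n), function(i) {
    if (sig[i] == 0)
      return(1000 * .det_rate_ms(g[i], E[i], params$tau, params$E_thr,
                                 params$E_reset))
    1000 * .ric_rate_ms(g[i], E[i], sig[i], params$tau, params$E_thr,
                        params$E_reset)
  }, numeric(1))
}

#' High-noise limit of the noisy firing rate
#'
#' When the noise amplitude is large compared with the distance of the
#' integration bounds, the first-passage integrand is approximately 1 and the
#' rate reduces to the closed form
#' \deqn{\nu \approx \frac{\sigma \sqrt{g_{eff}}}
#'   {\tau \sqrt{\pi} (E_{thr} - E_{reset})},}
#' i.e. \eqn{\sigma\sqrt{1 + g_{GABA}}} up to the (small) glutamatergic
#' contribution to \eqn{g_{eff}}. In this limit the rate increases with
#' `g_GABA`: strong noise makes small GABA conductances excitatory for any
#' reversal potential below threshold, which is why noise expands the
#' non-monotonic regime.
#'
#' @inheritParams effective_input
#' @param noise A `noise_constant` model.
#' @return Firing rate in Hz (vectorized).
#' @export
high_noise_rate <- function(params, drive, noise) {
  stopifnot(inherits(noise, "noise_constant"))
  g_eff <- 1 + drive$g_GABA + drive$g_Glu
  1000 * noise$sigma * sqrt(g_eff) /
    (params$tau * sqrt(pi) * (params$E_thr - params$E_reset))
}

#' Noise amplitude of conductance-dependent (synaptic) noise
#'
#' In the diffusion approximation of independent Poisson presynaptic firing,
#' the fluctuating part of the synaptic input yields a multiplicative noise
#' with variance \eqn{\sigma^2(v) = \sum_{s \in \{Glu, GABA\}} a_s g_s (v -
#' E_s)^2}, where \eqn{a_s} are unitary synaptic strengths and \eqn{g_s} the
#' mean conductances. Substituting the effective reversal potential for the
#' membrane potential, \eqn{\sigma(v) \approx \sigma(E_{eff})}, makes the
#' amplitude state-independent; since \eqn{E_{eff}} does not depend on
#' \eqn{\sigma}, no self-consistent iteration is needed. The noise vanishes
#' with the conductances, so it has little effect at low drive.
#'
#' @inheritParams effective_input
#' @param a_Glu,a_GABA Unitary synaptic strengths, dimensionless.
#' @return Noise amplitude \eqn{\sigma} in mV (vectorized).
#' @export
conductance_noise_sigma <- function(params, drive, a_Glu, a_GABA = a_Glu) {
  stopifnot(a_Glu >= 0, a_GABA >= 0)
  E <- effective_input(params, drive)$E_eff
  # pmax guards the tiny negative g_GABA used by centered difference stencils
  sqrt(pmax(a_Glu * drive$g_Glu * (E - params$E_Glu)^2 +
              a_GABA * drive$g_GABA * (E - drive$E_GABA)^2, 0))
}

# Initial slope (Hz per unit conductance) of the noisy rate at g_GABA = 0,
# by central finite difference with step h (the Ricciardi integral has no
# printed closed-form derivative). The formulas extend smoothly to the small
# negative g_GABA used by the centered stencil.
.noisy_slope0 <- function(params, g_Glu, E_GABA, noise, h = 1e-4) {
  r <- function(g) {
    d <- structure(list(g_Glu = g_Glu, g_GABA = g, E_GABA = E_GABA),
                   class = "synaptic_drive")
    sig <- .noise_sigma(params, d, noise)
    eff <- effective_input(params, d)
    if (sig == 0)
      return(1000 * .det_rate_ms(eff$g_eff, eff$E_eff, params$tau,
                                 params$E_thr, params$E_reset))
    1000 * .ric_rate_ms(eff$g_eff, eff$E_eff, sig, params$tau, params$E_thr,
                        params$E_reset)
  }
  (r(h) - r(-h)) / (2 * h)
}

#' Boundary between the inhibitory and non-monotonic regimes under noise
#'
#' The GABA reversal potential at which the initial slope
#' \eqn{\partial\nu/\partial g_{GABA}|_{g_{GABA}=0}} of the noisy rate changes
#' sign, located by bisection to a stated tolerance. The deterministic theory
#' bounds this boundary between \eqn{(E_{reset} + E_{thr})/2} and
#' \eqn{E_{thr}}; noise only lowers it, so the search bracket is
#' `[E_reset, E_thr]` and an error is signalled if the slope does not change
#' sign over the bracket. As the noise amplitude grows the boundary moves to
#' lower `E_GABA`, i.e. the non-monotonic region expands.
#'
#' @param params [lif_params()].
#' @param g_Glu Glutamatergic conductance (scalar).
#' @param noise A `noise_constant` or `noise_conductance` model.
#' @param tol Bisection tolerance on `E_GABA`, mV.
#' @return Boundary \eqn{E_{GABA}} in mV.
#' @export
boundary_egaba <- function(params, g_Glu, noise, tol = 0.01) {
  stopifnot(inherits(noise, "noise_model"), noise$kind != "none",
            length(g_Glu) == 1)
  f <- function(E) .noisy_slope0(params, g_Glu, E, noise)
  lo <- params$E_reset
  hi <- params$E_thr - 1e-6
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("initial slope does not change sign over [E_reset, E_thr]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm * fhi <= 0) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  (lo + hi) / 2
}
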