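#' Effective input of the conductance-based LIF neuron
#'
#' With constant synaptic conductances the sub-threshold dynamics collapse to
#' relaxation towards an effective reversal potential,
#' \deqn{\tau \frac{dv}{dt} = -g_{eff}(v - E_{eff}),}
#' with
#' \deqn{g_{eff} = 1 + g_{GABA} + g_{Glu}, \qquad
#'  E_{eff} = \frac{E_L + g_{GABA} E_{GABA} + g_{Glu} E_{Glu}}{1 + g_{GABA} + g_{Glu}},}
#' and effective time constant \eqn{\tau_{eff} = \tau / g_{eff}}.
#' `E_eff` is the conductance-weighted mean of the reversal potentials and
#' always lies between their extremes.
#'
#' @param params [lif_params()].
#' @param drive [synaptic_drive()]; vector fields are recycled.
#' @return An object of class `effective_input` with components `g_eff`
#'   (dimensionless), `E_eff` (mV) and `tau_eff` (ms), each as long as the
#'   recycled drive.
#' @examples
#' effective_input(lif_params(), synaptic_drive(g_Glu = 0.4, E_GABA = -63))
#' @export
effective_input <- function(params, drive) {
  stopifnot(inherits(params, "lif_params"), inherits(drive, "synaptic_drive"))
  g_eff <- 1 + drive$g_GABA + drive$g_Glu
  E_eff <- (params$E_L + drive$g_GABA * drive$E_GABA +
              drive$g_Glu * params$E_Glu) / g_eff
  structure(list(g_eff = g_eff, E_eff = E_eff, tau_eff = params$tau / g_eff),
            class = "effective_input")
}

#' @export
print.effective_input <- function(x, ...) {
  cat(sprintf("Effective input: g_eff = %s, E_eff = %s mV, tau_eff = %s ms\n",
              paste(signif(x$g_eff, 5), collapse = ","),
              paste(signif(x$E_eff, 5), collapse = ","),
              paste(signif(x$tau_eff, 5), collapse = ",")))
  invisible(x)
}

# internal: deterministic rate in ms^-1 from effective quantities
.det_rate_ms <- function(g_eff, E_eff, tau, E_thr, E_reset) {
  out <- numeric(length(E_eff))
  firing <- E_eff > E_thr
  if (any(firing)) {
    out[firing] <- (g_eff[firing] / tau) /
      log((E_eff[firing] - E_reset) / (E_eff[firing] - E_thr))
  }
  out
}

#' Firing rate of the deterministic LIF neuron
#'
#' Closed-form firing rate with constant conductances and no noise:
#' \deqn{\nu = \frac{g_{eff}}{\tau\,
#'   \ln\!\left(\frac{E_{eff} - E_{reset}}{E_{eff} - E_{thr}}\right)}}
#' when \eqn{E_{eff} > E_{thr}}, and 0 otherwise (the rate vanishes
#' continuously at the onset because the logarithm diverges). There is no
#' refractory period.
#'
#' @inheritParams effective_input
#' @return Firing rate in Hz (vectorized over the drive).
#' @examples
#' # ~46.5 Hz at g_Glu = 0.4, no GABA
#' deterministic_rate(lif_params(), synaptic_drive(g_Glu = 0.4, E_GABA = -63))
#' @export
deterministic_rate <- function(params, drive) {
  eff <- effective_input(params, drive)
  g <- rep_len(eff$g_eff, max(length(eff$g_eff), length(eff$E_eff)))
  E <- rep_len(eff$E_eff, length(g))
  1000 * .det_rate_ms(g, E, params$tau, params$E_thr, params$E_reset)
}

#' Glutamatergic conductance at the deterministic firing onset
#'
#' The minimal `g_Glu` (at `g_GABA = 0`) for which the deterministic neuron
#' fires, obtained from \eqn{E_{eff} = E_{thr}}:
#' \deqn{g_{Glu}^{onset} = \frac{E_{thr} - E_L}{E_{Glu} - E_{thr}}.}
#' Equals 1/3 for the default parameters.
#'
#' @param params [lif_params()].
#' @return Dimensionless conductance.
#' @export
glu_firing_onset <- function(params) {
  stopifnot(inherits(params, "lif_params"))
  (params$E_thr - params$E_L) / (params$E_Glu - params$E_thr)
}

#' Silencing GABA conductance
#'
#' For `E_GABA < E_thr` the GABAergic conductance at which firing stops,
#' from the condition \eqn{E_{eff} = E_{thr}}:
#' \deqn{g^{s}_{GABA} = \frac{(E_{thr} - E_L) + g_{Glu}(E_{thr} - E_{Glu})}
#'   {E_{GABA} - E_{thr}},}
#' clamped below at 0 (a neuron that is already silent at `g_GABA = 0` has
#' \eqn{g^s = 0}). For `E_GABA >= E_thr` no finite conductance silences the
#' neuron and `Inf` is returned; the silencing conductance diverges as
#' `E_GABA` approaches `E_thr` from below.
#'
#' @param params [lif_params()].
#' @param g_Glu Glutamatergic conductance (vectorized).
#' @param E_GABA GABA reversal potential, mV (vectorized).
#' @return Dimensionless conductance, possibly `Inf`.
#' @export
silencing_conductance <- function(params, g_Glu, E_GABA) {
  stopifnot(inherits(params, "lif_params"), all(g_Glu >= 0))
  n <- max(length(g_Glu), length(E_GABA))
  g_Glu <- rep_len(g_Glu, n); E_GABA <- rep_len(E_GABA, n)
  num <- (params$E_thr - params$E_L) + g_Glu * (params$E_thr - params$E_Glu)
  out <- ifelse(E_GABA < params$E_thr,
                pmax(num / (E_GABA - params$E_thr), 0), Inf)
  if (any(E_GABA == params$E_thr))
    warning("E_GABA equals E_thr: silencing conductance diverges (Inf)")
  out
}

#' Derivative of the deterministic rate with respect to the GABA conductance
#'
#' The competition between the conductance effect (shorter effective time
#' constant, excitatory) and the reversal-potential effect (lower
#' \eqn{E_{eff}}, sign set by \eqn{E_{GABA} - E_{eff}}) is summarized by
#' \deqn{\frac{d\nu}{dg_{GABA}} = \frac{\nu}{g_{eff}}\left(1 +
#'  \frac{(E_{GABA} - E_{eff})(E_{thr} - E_{reset})}
#'       {(E_{eff} - E_{reset})(E_{eff} - E_{thr})}\,
#'  \frac{\tau \nu}{g_{eff}}\right),}
#' with \eqn{\nu} in ms\eqn{^{-1}}. The sign of the derivative determines
#' whether GABA acts locally as excitatory (+) or inhibitory (-).
#'
#' @inheritParams effective_input
#' @return Derivative in Hz per unit (dimensionless) conductance, vectorized.
#'   `NA` at non-firing points (where the deterministic rate is 0).
#' @export
rate_slope_ggaba <- function(params, drive) {
  eff <- effective_input(params, drive)
  n <- max(lengths(eff))
  g <- rep_len(eff$g_eff, n); E <- rep_len(eff$E_eff, n)
  EG <- rep_len(drive$E_GABA, n)
  nu <- .det_rate_ms(g, E, params$tau, params$E_thr, params$E_reset)
  out <- rep(NA_real_, n)
  f <- E > params$E_thr
  if (any(f)) {
    corr <- (EG[f] - E[f]) * (params$E_thr - params$E_reset) /
      ((E[f] - params$E_reset) * (E[f] - params$E_thr)) *
      params$tau * nu[f] / g[f]
    out[f] <- 1000 * nu[f] / g[f] * (1 + corr)
  }
  out
}

#' Critical GABA reversal potential
#'
#' The value \eqn{E^*_{GABA}} separating the inhibitory from the non-monotonic
#' regime, obtained by setting \eqn{d\nu/dg_{GABA} = 0} at \eqn{g_{GABA} = 0}:
#' \deqn{E^*_{GABA} = E_{eff} -
#'   \frac{(E_{eff} - E_{reset})(E_{eff} - E_{thr})}{E_{thr} - E_{reset}}
#'   \ln\!\left(\frac{E_{eff} - E_{reset}}{E_{eff} - E_{thr}}\right),}
#' with \eqn{E_{eff}} evaluated at `g_GABA = 0`. As `g_Glu` approaches the
#' firing onset from above, \eqn{E^*_{GABA} \to E_{thr}}; for large `g_Glu` it
#' converges to \eqn{(E_{reset} + E_{thr})/2}, which bounds the non-monotonic
#' window to `(E_reset + E_thr)/2 < E_GABA < E_thr` (a 5 mV band below
#' threshold at default parameters).
#'
#' @param params [lif_params()].
#' @param g_Glu Glutamatergic conductance above the firing onset (vectorized).
#' @return \eqn{E^*_{GABA}} in mV.
#' @export
critical_egaba <- function(params, g_Glu) {
  stopifnot(inherits(params, "lif_params"))
  eff <- effective_input(params, synaptic_drive(g_Glu = g_Glu, g_GABA = 0,
                                                E_GABA = params$E_L))
  E <- eff$E_eff
  if (any(E <= params$E_thr))
    stop("g_Glu below the deterministic firing onset: E_eff <= E_thr")
  E - (E - params$E_reset) * (E - params$E_thr) /
    (params$E_thr - params$E_reset) *
    log((E - params$E_reset) / (E - params$E_thr))
}

#' Classify the regime of GABAergic action
#'
#' Deterministic classification of a point in the (`E_GABA`, `g_Glu`) plane:
#' * `SILENT` — `g_Glu` at or below the firing onset and `E_GABA <= E_thr`:
#'   no GABA conductance can make the neuron fire.
#' * `GABA_ACTIVATED` — `g_Glu` sub-threshold but `E_GABA > E_thr`: the neuron
#'   starts firing beyond a critical GABA conductance.
#' * `EXCITATORY` — firing with `E_GABA >= E_thr`: rate increases with
#'   `g_GABA` without bound.
#' * `NON_MONOTONIC` — firing with `E_GABA < E_thr` and positive initial
#'   slope: small GABA conductances raise the rate, large ones silence it.
#' * `INHIBITORY` — firing with non-positive initial slope.
#'
#' Under input noise (`noise` not `noise_none()`), the silent region
#' disappears (the rate is positive for any drive), the boundary to the
#' excitatory region stays at `E_GABA = E_thr`, and the initial slope is
#' measured numerically on the noisy rate; only `EXCITATORY`, `NON_MONOTONIC`
#' and `INHIBITORY` occur.
#'
#' Boundary ties are resolved deterministically: `E_GABA = E_thr` in the
#' firing region is `EXCITATORY`; an initial slope within `1e-9` Hz of zero is
#' `INHIBITORY`.
#'
#' @param params [lif_params()].
#' @param g_Glu,E_GABA Coordinates of the point(s), recycled.
#' @param noise A [noise_model] object.
#' @return Character vector of regime labels.
#' @export
classify_regime <- function(params, g_Glu, E_GABA, noise = noise_none()) {
  stopifnot(inherits(params, "lif_params"), inherits(noise, "noise_model"))
  n <- max(length(g_Glu), length(E_GABA))
  g_Glu <- rep_len(g_Glu, n); E_GABA <- rep_len(E_GABA, n)
  tie <- 1e-9
  if (.noise_is_none(noise)) {
    E0 <- effective_input(params, synaptic_drive(g_Glu, 0, E_GABA))$E_eff
    firing <- E0 > params$E_thr
    slope0 <- rep(NA_real_, n)
    if (any(firing))
      slope0[firing] <- rate_slope_ggaba(
        params, synaptic_drive(g_Glu[firing], 0, E_GABA[firing]))
    out <- ifelse(firing,
                  ifelse(E_GABA >= params$E_thr, "EXCITATORY",
                         ifelse(slope0 > tie, "NON_MONOTONIC", "INHIBITORY")),
                  ifelse(E_GABA > params$E_thr, "GABA_ACTIVATED", "SILENT"))
  } else {
    slope0 <- vapply(seq_len(n), function(i)
      .noisy_slope0(params, g_Glu[i], E_GABA[i], noise), numeric(1))
    out <- ifelse(E_GABA >= params$E_thr, "EXCITATORY",
                  ifelse(slope0 > tie, "NON_MONOTONIC", "INHIBITORY"))
  }
  out
}

#' Summary of the rate-vs-GABA-conductance curve
#'
#' Characterizes the firing-rate curve \eqn{\nu(g_{GABA})} at a fixed
#' (`g_Glu`, `E_GABA`) point: the initial rate \eqn{\nu_{init} =
#' \nu(g_{GABA}=0)}, the maximal rate \eqn{\nu_{max}}, the conductance
#' \eqn{g^*_{GABA}} attaining it, the silencing conductance, and the
#' non-monotonicity strength \eqn{\nu_{max}/\nu_{init}} (reported as `Inf`
#' when the neuron is silent without GABA but activated by it). The maximum is
#' located by evaluating the rate on a coarse grid (512 points, log-spaced
#' above `1e-3`) followed by bounded local refinement to a tolerance of
#' `1e-6` on the conductance; the rate curve is smooth and unimodal in the
#' regimes of interest.
#'
#' @param params [lif_params()].
#' @param g_Glu,E_GABA Scalars defining the point.
#' @param g_GABA_max Upper end of the search interval. Defaults to twice the
#'   silencing conductance when finite, else 50, which guarantees an interior
#'   maximum in the non-monotonic regime.
#' @param noise A [noise_model]; with noise the Ricciardi rate is used.
#' @return An object of class `regime_summary` with fields `nu_init`,
#'   `nu_max` (Hz), `g_star`, `g_silence` (dimensionless), `strength_ratio`
#'   and `label`.
#' @export
regime_summary <- function(params, g_Glu, E_GABA, g_GABA_max = NULL,
                           noise = noise_none()) {
  stopifnot(length(g_Glu) == 1, length(E_GABA) == 1)
  g_sil <- suppressWarnings(silencing_conductance(params, g_Glu, E_GABA))
  if (is.null(g_GABA_max))
    g_GABA_max <- if (is.finite(g_sil)) max(2 * g_sil, 1e-2) else 50
  stopifnot(g_GABA_max > 0)
  ratefun <- if (.noise_is_none(noise)) {
    function(g) deterministic_rate(params, synaptic_drive(g_Glu, g, E_GABA))
  } else {
    function(g) vapply(g, function(gi) ricciardi_rate(
      params, synaptic_drive(g_Glu, gi, E_GABA), noise), numeric(1))
  }
  grid <- c(0, exp(seq(log(1e-3), log(g_GABA_max), length.out = 512)))
  vals <- ratefun(grid)
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  if (hi > lo) {
    opt <- optimize(ratefun, c(lo, hi), maximum = TRUE, tol = 1e-6)
    g_star <- opt$maximum; nu_max <- opt$objective
  } else {
    g_star <- grid[i]; nu_max <- vals[i]
  }
  nu_init <- vals[1]
  if (nu_init >= nu_max) { g_star <- 0; nu_max <- nu_init }
  ratio <- if (nu_init > 0) nu_max / nu_init else if (nu_max > 0) Inf else NA_real_
  structure(list(nu_init = nu_init, nu_max = nu_max, g_star = g_star,
                 g_silence = g_sil, strength_ratio = ratio,
                 label = classify_regime(params, g_Glu, E_GABA, noise),
                 g_Glu = g_Glu, E_GABA = E_GABA),
            class = "regime_summary")
}

#' @export
print.regime_summary <- function(x, ...) {
  cat(sprintf("Regime %s at (g_Glu = %g, E_GABA = %g mV)\n",
              x$label, x$g_Glu, x$E_GABA))
  cat(sprintf("  nu_init = %.4g Hz, nu_max = %.4g Hz at g*_GABA = %.4g\n",
              x$nu_init, x$nu_max, x$g_star))
  cat(sprintf("  g_silence = %.4g, strength ratio nu_max/nu_init = %.4g\n",
              x$g_silence, x$strength_ratio))
  invisible(x)
}
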