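# Shared fixtures: default neuron parameters and a few drive points used
# across test files.

default_lif <- lif_params()
default_eif <- eif_kir_params()

# deterministic rate computed independently of the package, directly from the
# effective-input reduction (used as a closed-form oracle in several places)
oracle_det_rate <- function(p, g_Glu, g_GABA, E_GABA) {
  g_eff <- 1 + g_GABA + g_Glu
  E_eff <- (p$E_L + g_GABA * E_GABA + g_Glu * p$E_Glu) / g_eff
  if (E_eff <= p$E_thr) return(0)
  1000 * (g_eff / p$tau) / log((E_eff - p$E_reset) / (E_eff - p$E_thr))
}

# high-resolution trapezoid quadrature of the first-passage integral; the
# integration method (dense trapezoid) is independent of the package's
# adaptive quadrature + tail expansion. The integrand uses the scaled
# complementary error function where the naive form exp(x^2)(1 + erf(x))
# would cancel catastrophically (x < -4).
oracle_ricciardi <- function(p, g_Glu, g_GABA, E_GABA, sigma, n_grid = 4e5) {
  g_eff <- 1 + g_GABA + g_Glu
  E_eff <- (p$E_L + g_GABA * E_GABA + g_Glu * p$E_Glu) / g_eff
  s_eff <- sigma / sqrt(g_eff)
  t_eff <- p$tau / g_eff
  x <- seq((p$E_reset - E_eff) / s_eff, (p$E_thr - E_eff) / s_eff,
           length.out = n_grid)
  y <- ifelse(x > -4, exp(x^2) * (1 + pracma::erf(x)), pracma::erfcx(-x))
  I <- pracma::trapz(x, y)
  1000 / (t_eff * sqrt(pi) * I)
}
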