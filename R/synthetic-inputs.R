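#' Poisson cortical drive specification
#'
#' Specification of the glutamatergic drive a network neuron receives: an
#' independent Poisson event stream (one stream per neuron) filtered by a
#' single-exponential kernel. Each event increments the conductance by
#' `amplitude`; the conductance then decays with time constant `tau_kernel`.
#' By Campbell's theorem the stationary mean is
#' `amplitude * rate * tau_kernel` and the stationary variance
#' `amplitude^2 * rate * tau_kernel / 2` (rate in events/ms). The defaults
#' approximate the total cortical input to a striatal neuron: 1000 Hz events
#' with a 5.6 ms decay.
#'
#' @param amplitude Per-event conductance jump, dimensionless (normalized by
#'   leak). Usually set by [calibrate_drive()].
#' @param rate Event rate, Hz.
#' @param tau_kernel Exponential decay time constant, ms.
#' @return An object of class `poisson_drive`.
#' @export
poisson_drive <- function(amplitude, rate = 1000, tau_kernel = 5.6) {
  stopifnot(rate > 0, tau_kernel > 0, amplitude >= 0)
  structure(list(rate = rate, tau_kernel = tau_kernel, amplitude = amplitude),
            class = "poisson_drive")
}

#' @export
print.poisson_drive <- function(x, ...) {
  cat(sprintf("Poisson drive: %g Hz, tau = %g ms, amplitude = %g (mean g = %.4g)\n",
              x$rate, x$tau_kernel, x$amplitude,
              x$amplitude * x$rate / 1000 * x$tau_kernel))
  invisible(x)
}

#' Generate a filtered-Poisson conductance trace
#'
#' Realizes the drive of a [poisson_drive()] specification on a regular time
#' grid: per-bin event counts are Poisson with mean `rate * dt`, and the
#' conductance follows the exact discrete update
#' \eqn{g_{t+dt} = g_t e^{-dt/\tau} + A\,n_t}. In the high-rate limit the
#' trace converges to a Gaussian (shot-noise) process with the Campbell mean
#' and variance.
#'
#' @param spec [poisson_drive()].
#' @param duration Trace length, ms.
#' @param dt Time step, ms.
#' @param seed Integer seed or `NULL`. Given a seed, the trace is
#'   bit-reproducible.
#' @return Numeric vector of conductance samples at `dt, 2dt, ...`.
#' @export
generate_poisson_drive <- function(spec, duration, dt = 0.05, seed = NULL) {
  stopifnot(inherits(spec, "poisson_drive"), duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  counts <- rpois(n, spec$rate / 1000 * dt)
  as.numeric(stats::filter(spec$amplitude * counts,
                           exp(-dt / spec$tau_kernel), method = "recursive"))
}

#' GABAergic post-synaptic conductance kernel
#'
#' The difference-of-exponentials conductance time course triggered by one
#' presynaptic spike,
#' \deqn{g_{GABA}(t) = g_0\,(e^{-t/\tau_1} - e^{-t/\tau_2}),}
#' with decay `tau1` and rise `tau2` (`tau1 > tau2`). The kernel is causal
#' (zero for `t < 0`), starts at zero, peaks at
#' \eqn{t^* = \frac{\tau_1\tau_2}{\tau_1-\tau_2}\ln(\tau_1/\tau_2)} and
#' integrates to \eqn{g_0(\tau_1 - \tau_2)}. `g0` is identified with the
#' connection-strength matrix entry in the network model (no peak
#' normalization), which makes the mean total conductance formula of
#' [expected_total_conductance()] exact.
#'
#' @param g0 Amplitude scale, dimensionless.
#' @param tau1 Decay time constant, ms.
#' @param tau2 Rise time constant, ms.
#' @return An object of class `psc_kernel`.
#' @export
psc_kernel <- function(g0 = 1, tau1 = 20, tau2 = 1.5) {
  stopifnot(tau1 > tau2, tau2 > 0, g0 >= 0)
  structure(list(g0 = g0, tau1 = tau1, tau2 = tau2), class = "psc_kernel")
}

#' @rdname psc_kernel
#' @param kernel A `psc_kernel`.
#' @param t Time(s) since the presynaptic spike, ms.
#' @export
psc_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "psc_kernel"))
  ifelse(t >= 0,
         kernel$g0 * (exp(-t / kernel$tau1) - exp(-t / kernel$tau2)), 0)
}

#' @rdname psc_kernel
#' @export
psc_integral <- function(kernel) kernel$g0 * (kernel$tau1 - kernel$tau2)

#' @rdname psc_kernel
#' @export
psc_peak_time <- function(kernel) {
  with(kernel, tau1 * tau2 / (tau1 - tau2) * log(tau1 / tau2))
}

#' @export
print.psc_kernel <- function(x, ...) {
  cat(sprintf("PSC kernel: g0 = %g, tau1 = %g ms (decay), tau2 = %g ms (rise); peak at %.3g ms\n",
              x$g0, x$tau1, x$tau2, psc_peak_time(x)))
  invisible(x)
}

#' @export
plot.psc_kernel <- function(x, t_max = 5 * x$tau1, ...) {
  t <- seq(0, t_max, length.out = 400)
  plot(t, psc_eval(x, t), type = "l", xlab = "time (ms)",
       ylab = "conductance", ...)
  invisible(x)
}

#' Default striatal connectivity matrices
#'
#' Connection probabilities `P` and strengths `G` between the three striatal
#' populations, from population `j` (column) to population `i` (row), with
#' order FSI, dSPN, iSPN. SPNs do not project to FSIs; FSI projections onto
#' dSPNs are both more probable and stronger than onto iSPNs, which is the
#' source of the asymmetric modulation of the two pathways.
#'
#' @return A 3x3 matrix with dimnames.
#' @name striatal_connectivity
NULL

#' @rdname striatal_connectivity
#' @export
striatal_P <- function() {
  matrix(c(0.58, 0,    0,
           0.53, 0.26, 0.27,
           0.36, 0.06, 0.36),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("FSI", "dSPN", "iSPN"), c("FSI", "dSPN", "iSPN")))
}

#' @rdname striatal_connectivity
#' @export
striatal_G <- function() {
  matrix(c(0.06, 0,    0,
           0.5,  0.04, 0.13,
           0.5,  0.11, 0.11),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("FSI", "dSPN", "iSPN"), c("FSI", "dSPN", "iSPN")))
}

#' Sample a Bernoulli connectivity realization
#'
#' Draws a directed connectivity graph between populations: an edge from
#' neuron `j` (population `q`) to neuron `i` (population `p`) is present
#' independently with probability `P[p, q]` and, when present, carries
#' strength `G[p, q]`. Self-connections are excluded. Given a seed the
#' realization is bit-reproducible.
#'
#' @param pop_sizes Named integer vector of population sizes (names define
#'   the population order and must match the matrices).
#' @param P Connection-probability matrix (target row, source column).
#' @param G Strength matrix, same shape as `P`.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `connectivity`: `edges` (data.frame with
#'   columns `pre`, `post`, `w`), `population` (factor over neurons),
#'   `pop_sizes`, `P`, `G`.
#' @examples
#' conn <- sample_connectivity(c(FSI = 20, dSPN = 490, iSPN = 490),
#'                             striatal_P(), striatal_G(), seed = 1)
#' nrow(conn$edges)
#' @export
sample_connectivity <- function(pop_sizes, P, G, seed = NULL) {
  stopifnot(all(P >= 0), all(P <= 1), all(dim(P) == dim(G)),
            length(pop_sizes) == nrow(P), all(pop_sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  k <- length(pop_sizes)
  nm <- names(pop_sizes)
  if (is.null(nm)) nm <- paste0("pop", seq_len(k))
  idx_end <- cumsum(pop_sizes)
  idx_start <- idx_end - pop_sizes + 1
  pre_l <- list(); post_l <- list(); w_l <- list()
  b <- 0L
  for (p in seq_len(k)) {        # target population
    for (q in seq_len(k)) {      # source population
      if (P[p, q] <= 0) next
      pre_ids <- idx_start[q]:idx_end[q]
      post_ids <- idx_start[p]:idx_end[p]
      pairs <- expand.grid(post = post_ids, pre = pre_ids,
                           KEEP.OUT.ATTRS = FALSE)
      keep <- runif(nrow(pairs)) < P[p, q]
      if (p == q) keep <- keep & (pairs$pre != pairs$post)
      if (!any(keep)) next
      b <- b + 1L
      pre_l[[b]] <- pairs$pre[keep]
      post_l[[b]] <- pairs$post[keep]
      w_l[[b]] <- rep(G[p, q], sum(keep))
    }
  }
  edges <- data.frame(pre = unlist(pre_l), post = unlist(post_l),
                      w = unlist(w_l))
  population <- factor(rep(nm, pop_sizes), levels = nm)
  structure(list(edges = edges, population = population,
                 pop_sizes = pop_sizes, P = P, G = G,
                 N = sum(pop_sizes)),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("Connectivity realization: %d neurons (%s), %d edges\n",
              x$N, paste(names(x$pop_sizes), x$pop_sizes, sep = "=",
                         collapse = ", "), nrow(x$edges)))
  invisible(x)
}

#' In-degree from one population
#'
#' Number of afferent connections each neuron of `to` receives from
#' population `from` in a realization.
#'
#' @param conn A [sample_connectivity()] realization.
#' @param from,to Population names.
#' @return Named integer vector over the neurons of `to`.
#' @export
in_degree <- function(conn, from, to) {
  stopifnot(inherits(conn, "connectivity"))
  pre_pop <- conn$population[conn$edges$pre]
  post_pop <- conn$population[conn$edges$post]
  sel <- pre_pop == from & post_pop == to
  ids <- which(conn$population == to)
  counts <- tabulate(conn$edges$post[sel], nbins = conn$N)[ids]
  names(counts) <- ids
  counts
}

#' Mean total recurrent conductance from a population
#'
#' The average total normalized GABAergic conductance a neuron of the target
#' population receives from population `j` with `N_j` neurons firing at mean
#' rate \eqn{\nu_j}:
#' \deqn{\bar g = G_{ij} P_{ij} N_j \nu_j (\tau_1 - \tau_2),}
#' with \eqn{\nu_j} in events/ms. This is Campbell's theorem applied to the
#' difference-of-exponentials kernel, and matches the time-averaged summed
#' synaptic conductance in network simulations.
#'
#' @param G_ij,P_ij Strength and probability of the block.
#' @param N_j Source-population size.
#' @param nu_Hz Source mean firing rate, Hz.
#' @param kernel [psc_kernel()] supplying `tau1`, `tau2` (its `g0` is not
#'   used: the strength is `G_ij`).
#' @return Dimensionless mean conductance (vectorized).
#' @export
expected_total_conductance <- function(G_ij, P_ij, N_j, nu_Hz,
                                       kernel = psc_kernel()) {
  stopifnot(all(nu_Hz >= 0))
  G_ij * P_ij * N_j * (nu_Hz / 1000) * (kernel$tau1 - kernel$tau2)
}
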