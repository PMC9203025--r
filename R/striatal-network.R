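#' Striatal microcircuit specification
#'
#' A recurrent network of conductance-based LIF neurons representing a small
#' volume of striatum: fast-spiking interneurons (FSI, 2%) and direct- and
#' indirect-pathway spiny projection neurons (dSPN, iSPN, 49% each). All
#' neurons receive independent filtered-Poisson glutamatergic drive
#' (approximating total cortical input) and are connected by GABAergic
#' synapses with a difference-of-exponentials conductance kernel. The GABA
#' reversal potential is a property of the postsynaptic cell: hyperpolarizing
#' in FSIs (-80 mV) and, reflecting the depolarized chloride reversal of
#' SPNs, close to threshold in both SPN populations.
#'
#' @param N Total number of neurons.
#' @param fractions Named per-population proportions (must sum to 1).
#' @param P,G Connection probability and strength matrices
#'   ([striatal_P()], [striatal_G()]).
#' @param E_GABA_FSI GABA reversal of FSIs, mV.
#' @param E_GABA_SPN GABA reversal of both SPN populations, mV (default 1 mV
#'   below threshold).
#' @param neuron [lif_params()] shared by all neurons.
#' @param kernel [psc_kernel()] of the GABAergic synapses.
#' @param drive_rate Poisson event rate of the cortical drive, Hz.
#' @param drive_tau Decay of the drive's exponential kernel, ms.
#' @return An object of class `striatal_network`.
#' @examples
#' net <- striatal_network(N = 200)
#' net$pop_sizes
#' @export
striatal_network <- function(N = 1000,
                             fractions = c(FSI = 0.02, dSPN = 0.49,
                                           iSPN = 0.49),
                             P = striatal_P(), G = striatal_G(),
                             E_GABA_FSI = -80, E_GABA_SPN = -61,
                             neuron = lif_params(), kernel = psc_kernel(),
                             drive_rate = 1000, drive_tau = 5.6) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, N >= length(fractions),
            inherits(neuron, "lif_params"), inherits(kernel, "psc_kernel"),
            E_GABA_FSI >= -90, E_GABA_FSI <= -50,
             E_GABA_SPN >= -90, E_GABA_SPN <= -50)
  pop_sizes <- round(N * fractions)
  pop_sizes[1] <- N - sum(pop_sizes[-1])  # keep the exact total
  stopifnot(all(pop_sizes >= 1))
  structure(list(N = N, fractions = fractions, pop_sizes = pop_sizes,
                 P = P, G = G, E_GABA_FSI = E_GABA_FSI,
                 E_GABA_SPN = E_GABA_SPN, neuron = neuron, kernel = kernel,
                 drive_rate = drive_rate, drive_tau = drive_tau),
            class = "striatal_network")
}

#' @export
print.striatal_network <- function(x, ...) {
  cat(sprintf("Striatal network: N = %d (%s)\n", x$N,
              paste(names(x$pop_sizes), x$pop_sizes, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  E_GABA: FSI %g mV, SPN %g mV; drive %g Hz (tau %g ms); PSC tau1/tau2 %g/%g ms\n",
              x$E_GABA_FSI, x$E_GABA_SPN, x$drive_rate, x$drive_tau,
              x$kernel$tau1, x$kernel$tau2))
  invisible(x)
}

# per-neuron GABA reversal according to the postsynaptic population
.net_egaba <- function(net, population) {
  ifelse(population == "FSI", net$E_GABA_FSI, net$E_GABA_SPN)
}

# CSR adjacency (0-based) by presynaptic neuron
.net_csr <- function(conn) {
  o <- order(conn$edges$pre)
  pre <- conn$edges$pre[o]
  ptr <- cumsum(c(0L, tabulate(pre, nbins = conn$N)))
  list(ptr = as.integer(ptr), tgt = as.integer(conn$edges$post[o] - 1L),
       w = conn$edges$w[o])
}

#' Simulate the striatal network
#'
#' Time-stepped (Euler) integration of every neuron's membrane equation with
#' its own filtered-Poisson cortical drive and the recurrent GABAergic
#' conductances produced by network spikes; the GABA reversal potential of a
#' synapse is that of the postsynaptic cell. Initial voltages are drawn
#' uniformly on `[E_L, E_thr]` to avoid spurious synchrony; the initial
#' transient (`config$transient`) is discarded from all rates and samples.
#' Given `config$seed`, spike trains are bit-reproducible.
#'
#' @param net [striatal_network()].
#' @param amplitudes Named per-population drive amplitudes (per-event
#'   conductance jumps), as returned by [calibrate_drive()].
#' @param config [sim_config()].
#' @param conn A [sample_connectivity()] realization, or `NULL` to sample one
#'   (from the same seed).
#' @param record_vm Record membrane-potential samples? Samples are taken
#'   every `vm_dt` ms from the neurons of `vm_populations`.
#' @param vm_dt Membrane-potential sampling interval, ms.
#' @param vm_populations Populations to sample.
#' @return An object of class `network_sim`: per-neuron `rates` (Hz,
#'   post-transient), population mean rates `pop_rates`, the spike table
#'   `spikes` (columns `neuron`, `time_ms`), mean synaptic conductances per
#'   neuron, and (optionally) the `vm` sample matrix (neurons x samples).
#' @export
simulate_network <- function(net, amplitudes, config = sim_config(),
                             conn = NULL, record_vm = FALSE, vm_dt = 1,
                             vm_populations = c("dSPN", "iSPN")) {
  stopifnot(inherits(net, "striatal_network"), inherits(config, "sim_config"),
            all(names(net$pop_sizes) %in% names(amplitudes)))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(conn))
    conn <- sample_connectivity(net$pop_sizes, net$P, net$G, seed = NULL)
  stopifnot(inherits(conn, "connectivity"), conn$N == net$N)
  pop <- conn$population
  p <- net$neuron
  egaba <- .net_egaba(net, pop)
  amp <- as.numeric(amplitudes[as.character(pop)])
  lambda <- rep(net$drive_rate / 1000 * config$dt, net$N)
  lambda[amp <= 0] <- 0
  csr <- .net_csr(conn)
  n_steps <- round(config$duration / config$dt)
  v0 <- runif(net$N, p$E_L, p$E_thr)
  rec_idx <- if (record_vm) which(pop %in% vm_populations) else integer(0)
  vm_stride <- if (record_vm) max(1L, round(vm_dt / config$dt)) else 0L
  res <- cpp_simulate_network(net$N, p$tau, p$E_L, p$E_thr, p$E_reset,
                              p$E_Glu, egaba, amp, lambda, net$drive_tau,
                              net$kernel$tau1, net$kernel$tau2,
                              csr$ptr, csr$tgt, csr$w,
                              config$dt, n_steps, v0,
                              as.integer(rec_idx - 1L), as.integer(vm_stride))
  post <- res$spike_t > config$transient
  counts <- tabulate(res$spike_id[post], nbins = net$N)
  rates <- 1000 * counts / (config$duration - config$transient)
  pop_rates <- tapply(rates, pop, mean)
  out <- list(spikes = data.frame(neuron = res$spike_id,
                                  time_ms = res$spike_t),
              rates = rates, pop_rates = pop_rates, population = pop,
              mean_gGABA = res$mean_gGABA, mean_gGlu = res$mean_gGlu,
              amplitudes = amplitudes, config = config, conn = conn,
              net = net)
  if (record_vm) {
    out$vm <- res$vm
    out$vm_times <- seq_len(ncol(res$vm)) * vm_stride * config$dt
    out$vm_neurons <- rec_idx
  }
  structure(out, class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("Network simulation: N = %d, %g ms (transient %g ms), %d spikes\n",
              x$net$N, x$config$duration, x$config$transient,
              nrow(x$spikes)))
  r <- x$pop_rates
  cat("  population rates (Hz):",
      paste(names(r), sprintf("%.3g", r), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.network_sim <- function(x, max_neurons = 100, ...) {
  ids <- sort(sample(x$net$N, min(max_neurons, x$net$N)))
  s <- x$spikes[x$spikes$neuron %in% ids, ]
  plot(s$time_ms, match(s$neuron, ids), pch = ".", cex = 2,
       xlab = "time (ms)", ylab = "neuron", ...)
  invisible(x)
}

#' @param object A `striatal_network`.
#' @param nsim Number of independent realizations to simulate.
#' @param seed Integer seed.
#' @param ... Passed on to [simulate_network()] (at least `amplitudes`).
#' @rdname simulate_network
#' @export
simulate.striatal_network <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  sims <- lapply(seeds, function(s) {
    args <- list(...)
    cfg <- if (!is.null(args$config)) args$config else sim_config()
    cfg$seed <- s
    args$config <- cfg
    do.call(simulate_network, c(list(net = object), args))
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Calibrate cortical drive amplitudes to target rates
#'
#' Finds per-population Poisson-drive amplitudes such that the simulated
#' population mean rates match given targets, mimicking the tuning of
#' cortical input to in-vivo firing rates (about 10 Hz for FSIs and 1 Hz for
#' SPNs). Each population's transfer is monotone in its amplitude and the
#' recurrent coupling at these rates is weak, so a per-population bisection,
#' applied sequentially and repeated over a few outer sweeps, converges. All
#' evaluation runs reuse the same connectivity realization and RNG seed, so
#' the calibration is deterministic.
#'
#' @param net [striatal_network()].
#' @param targets Named per-population target mean rates, Hz (a target of 0
#'   maps to amplitude 0).
#' @param config [sim_config()] for the evaluation runs; its `duration` sets
#'   the calibration accuracy/cost trade-off (default 10 s).
#' @param conn Connectivity realization; `NULL` samples one from the seed.
#' @param tol Relative tolerance on achieved rates.
#' @param amp_upper Initial upper bracket for the amplitudes.
#' @param max_bisect Bisection steps per population and sweep.
#' @param outer Number of sequential sweeps over the populations.
#' @param fixed Populations whose amplitudes are held at their initial values
#'   (their targets are not enforced), e.g. to re-tune the FSI drive with the
#'   SPN drive frozen.
#' @param amplitudes Optional named starting amplitudes (required for any
#'   `fixed` population).
#' @param verbose Print progress?
#' @return An object of class `drive_calibration`: `amplitudes`, `achieved`
#'   rates, `targets`, the `conn` realization used, and `converged`.
#' @export
calibrate_drive <- function(net, targets = c(FSI = 10, dSPN = 1, iSPN = 1),
                            config = sim_config(duration = 10000),
                            conn = NULL, tol = 0.05, amp_upper = 0.2,
                            max_bisect = 12, outer = 3, fixed = character(0),
                            amplitudes = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "striatal_network"),
            all(names(net$pop_sizes) %in% names(targets)),
            all(targets >= 0), all(targets < 100),
            all(fixed %in% names(net$pop_sizes)))
  seed <- if (!is.null(config$seed)) config$seed else 20220606
  if (is.null(conn)) {
    set.seed(seed)
    conn <- sample_connectivity(net$pop_sizes, net$P, net$G, seed = NULL)
  }
  pops <- names(net$pop_sizes)
  free <- setdiff(pops, fixed)
  amps <- vapply(pops, function(p) if (targets[[p]] > 0) amp_upper / 4 else 0,
                 numeric(1))
  names(amps) <- pops
  if (!is.null(amplitudes)) amps[names(amplitudes)] <- amplitudes
  eval_rates <- function(a) {
    cfg <- config; cfg$seed <- seed
    simulate_network(net, a, cfg, conn = conn)$pop_rates
  }
  achieved <- eval_rates(amps)
  for (sweep in seq_len(outer)) {
    if (all(abs(achieved[free] - targets[free]) <=
              pmax(tol * targets[free], 1e-9))) break
    for (p in free) {
      tgt <- targets[[p]]
      if (tgt == 0) { amps[[p]] <- 0; next }
      lo <- 0; hi <- amp_upper
      r_hi <- NULL
      for (tries in 1:3) {  # ensure the upper bracket overshoots the target
        a <- amps; a[[p]] <- hi
        r_hi <- eval_rates(a)
        if (r_hi[[p]] >= tgt) break
        hi <- hi * 2
      }
      if (r_hi[[p]] < tgt)
        stop("calibration failed: target rate for ", p,
             " unreachable below amplitude ", hi)
      for (it in seq_len(max_bisect)) {
        mid <- (lo + hi) / 2
        a <- amps; a[[p]] <- mid
        r <- eval_rates(a)
        if (abs(r[[p]] - tgt) <= tol * tgt) { lo <- mid; hi <- mid; break }
        if (r[[p]] > tgt) hi <- mid else lo <- mid
      }
      amps[[p]] <- (lo + hi) / 2
      achieved <- eval_rates(amps)
      if (verbose)
        message(sprintf("sweep %d, %s: amp = %.5f, rates = %s", sweep, p,
                        amps[[p]],
                        paste(sprintf("%.2f", achieved), collapse = "/")))
    }
  }
  converged <- all(abs(achieved[free] - targets[free]) <=
                     pmax(2 * tol * targets[free], 1e-9))
  if (!converged)
    warning("calibration did not reach all targets within tolerance")
  structure(list(amplitudes = amps, achieved = achieved, targets = targets,
                 conn = conn, config = config, seed = seed,
                 converged = converged),
            class = "drive_calibration")
}

#' @export
print.drive_calibration <- function(x, ...) {
  cat("Drive calibration\n")
  for (p in names(x$amplitudes))
    cat(sprintf("  %-5s amplitude = %.5f, achieved = %.3g Hz (target %g Hz)\n",
                p, x$amplitudes[[p]], x$achieved[[p]], x$targets[[p]]))
  invisible(x)
}

#' Sweep the FSI population rate
#'
#' Emulates bidirectional manipulation of FSI activity by re-calibrating only
#' the FSI cortical drive to a list of target mean rates (0 = silenced) while
#' the SPN drive stays at its baseline calibration — drive scaling is the
#' minimal model of optogenetic gain modulation and preserves FSI spike
#' statistics. For each target, `n_realizations` independent network
#' realizations (fresh connectivity and noise) are simulated, which feeds the
#' SPN-vs-FSI population curve of [spn_vs_fsi_curve()].
#'
#' @param net [striatal_network()].
#' @param calibration Baseline [calibrate_drive()] result.
#' @param fsi_targets FSI target mean rates, Hz.
#' @param config [sim_config()] for the production runs.
#' @param n_realizations Independent realizations per target.
#' @param calib_config Optional [sim_config()] for the re-calibration runs
#'   (defaults to the calibration's own config).
#' @return An object of class `fsi_sweep`: per-target FSI amplitudes and a
#'   list of `network_sim` lists.
#' @export
fsi_rate_sweep <- function(net, calibration, fsi_targets,
                           config = sim_config(duration = 10000),
                           n_realizations = 1, calib_config = NULL) {
  stopifnot(inherits(calibration, "drive_calibration"))
  if (is.null(calib_config)) calib_config <- calibration$config
  base_amps <- calibration$amplitudes
  fsi_amp <- vapply(fsi_targets, function(tgt) {
    if (tgt == 0) return(0)
    if (abs(tgt - calibration$targets[["FSI"]]) < 1e-9)
      return(base_amps[["FSI"]])
    tgts <- calibration$targets
    tgts[["FSI"]] <- tgt
    cal <- calibrate_drive(net, tgts, calib_config, conn = calibration$conn,
                           fixed = setdiff(names(base_amps), "FSI"),
                           amplitudes = base_amps, outer = 1)
    cal$amplitudes[["FSI"]]
  }, numeric(1))
  seed0 <- if (!is.null(config$seed)) config$seed else calibration$seed
  sims <- lapply(seq_along(fsi_targets), function(i) {
    amps <- base_amps
    amps[["FSI"]] <- fsi_amp[i]
    lapply(seq_len(n_realizations), function(r) {
      cfg <- config
      cfg$seed <- (seed0 + 1000 * r + i) %% 2147483647  # integer-range safe
      simulate_network(net, amps, cfg, conn = NULL)
    })
  })
  structure(list(fsi_targets = fsi_targets, fsi_amplitudes = fsi_amp,
                 sims = sims, net = net, calibration = calibration,
                 n_realizations = n_realizations),
            class = "fsi_sweep")
}

#' @export
print.fsi_sweep <- function(x, ...) {
  cat(sprintf("FSI rate sweep: targets %s Hz, %d realization(s) each\n",
              paste(x$fsi_targets, collapse = ", "), x$n_realizations))
  invisible(x)
}
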