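#' Gaussian width of the pooled SPN membrane-potential distribution
#'
#' Fits a Gaussian (maximum likelihood: sample mean and SD) to the pooled
#' sub-threshold membrane-potential samples of the SPN populations of a
#' network simulation. Samples taken within `exclude_ms` after a spike
#' (reset transient) or within `exclude_ms` before a spike (threshold
#' approach) are excluded, so the fit targets the sub-threshold fluctuation
#' distribution rather than spike/reset artifacts. At the calibrated
#' operating point the distribution is close to Gaussian with a width of
#' about 1 mV.
#'
#' @param sim A [simulate_network()] result with `record_vm = TRUE`.
#' @param populations Populations to pool (default both SPN types).
#' @param exclude_ms Peri-spike exclusion window, ms.
#' @param min_samples Minimal number of retained samples.
#' @return The fitted SD in mV, with the fitted mean and the number of
#'   samples as attributes.
#' @export
vm_distribution_sd <- function(sim, populations = c("dSPN", "iSPN"),
                               exclude_ms = 1, min_samples = 100) {
  stopifnot(inherits(sim, "network_sim"))
  if (is.null(sim$vm))
    stop("no membrane-potential samples: rerun with record_vm = TRUE")
  keep_row <- sim$population[sim$vm_neurons] %in% populations
  tr <- sim$config$transient
  keep_col <- sim$vm_times > tr
  vm <- sim$vm[keep_row, keep_col, drop = FALSE]
  tt <- sim$vm_times[keep_col]
  neurons <- sim$vm_neurons[keep_row]
  # drop samples around each spike of the sampled neuron
  sp <- sim$spikes[sim$spikes$neuron %in% neurons, ]
  if (nrow(sp) > 0) {
    row_of <- match(sp$neuron, neurons)
    for (k in seq_len(nrow(sp))) {
      bad <- which(abs(tt - sp$time_ms[k]) <= exclude_ms)
      if (length(bad)) vm[row_of[k], bad] <- NA
    }
  }
  x <- vm[!is.na(vm)]
  if (length(x) < min_samples)
    stop("too few membrane-potential samples (", length(x), ")")
  structure(sd(x), mean = mean(x), n = length(x))
}

#' Width of the per-neuron firing-rate distribution
#'
#' Sample standard deviation of the post-transient per-neuron rates of one
#' population (or pooled SPNs). In the calibrated network this width grows
#' with FSI activity even while the population mean barely moves — the
#' signature of heterogeneous, non-monotonic GABAergic modulation.
#'
#' @param sim A [simulate_network()] result.
#' @param populations Population name(s) to pool.
#' @return SD of per-neuron rates, Hz, with the mean rate as attribute.
#' @export
rate_distribution_sd <- function(sim, populations = c("dSPN", "iSPN")) {
  stopifnot(inherits(sim, "network_sim"))
  r <- sim$rates[sim$population %in% populations]
  structure(sd(r), mean = mean(r), n = length(r))
}

#' Per-SPN rate change versus FSI in-degree
#'
#' Pairs the change in firing rate of each SPN between two FSI conditions
#' (`delta = rate1 - rate0`) with its number of afferent FSI connections,
#' and reports Pearson (and Spearman) correlations. Because the FSI
#' operating point sits near the peak of the rate-vs-GABA-conductance curve,
#' SPNs with few FSI afferents tend to be excited and heavily innervated
#' SPNs inhibited when FSI activity rises, producing a strong negative
#' correlation. The two simulations must share the connectivity realization
#' and SPN drive.
#'
#' @param sim0,sim1 Two [simulate_network()] results on the same realization
#'   (e.g. FSI silenced vs FSI at 25 Hz).
#' @param populations SPN populations to include.
#' @return An object of class `delta_rate_indegree`: a data.frame
#'   (`neuron`, `population`, `indegree_fsi`, `delta_rate_Hz`) plus
#'   `pearson` and `spearman` correlations.
#' @export
delta_rate_vs_indegree <- function(sim0, sim1,
                                   populations = c("dSPN", "iSPN")) {
  stopifnot(inherits(sim0, "network_sim"), inherits(sim1, "network_sim"))
  if (!identical(sim0$conn$edges, sim1$conn$edges))
    stop("simulations do not share a connectivity realization")
  sel <- sim0$population %in% populations
  ids <- which(sel)
  delta <- sim1$rates[ids] - sim0$rates[ids]
  indeg <- unlist(lapply(populations, function(p)
    in_degree(sim0$conn, from = "FSI", to = p)))
  indeg <- indeg[match(ids, as.integer(names(indeg)))]
  if (sd(delta) == 0)
    stop("rate change is identically zero; correlation undefined")
  df <- data.frame(neuron = ids,
                   population = as.character(sim0$population[ids]),
                   indegree_fsi = indeg, delta_rate_Hz = delta)
  structure(list(data = df,
                 pearson = cor(df$indegree_fsi, df$delta_rate_Hz),
                 spearman = cor(df$indegree_fsi, df$delta_rate_Hz,
                                method = "spearman")),
            class = "delta_rate_indegree")
}

#' @export
print.delta_rate_indegree <- function(x, ...) {
  cat(sprintf("Rate change vs FSI in-degree over %d SPNs: Pearson r = %.3f, Spearman rho = %.3f\n",
              nrow(x$data), x$pearson, x$spearman))
  invisible(x)
}

#' @export
plot.delta_rate_indegree <- function(x, ...) {
  plot(x$data$indegree_fsi, x$data$delta_rate_Hz,
       xlab = "afferent FSI connections", ylab = "rate change (Hz)", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}

#' SPN population rate as a function of FSI rate
#'
#' Aggregates an [fsi_rate_sweep()]: for every FSI target rate, the mean SPN
#' population rate over realizations and the standard deviation of that mean,
#' separately for dSPNs, iSPNs and pooled SPNs, together with the realized
#' FSI rates. With the SPN GABA reversal close to threshold the curve has an
#' interior maximum — both silencing and over-driving the FSIs lowers SPN
#' activity — and dSPNs are modulated more strongly than iSPNs.
#'
#' @param sweep An [fsi_rate_sweep()] result.
#' @return An object of class `fsi_curve`: a data.frame with one row per FSI
#'   target (`fsi_target_Hz`, `fsi_rate_Hz`, mean and SD-of-mean columns per
#'   SPN grouping, `n_realizations`). With a single realization the SD
#'   columns are `NA`.
#' @export
spn_vs_fsi_curve <- function(sweep) {
  stopifnot(inherits(sweep, "fsi_sweep"))
  rows <- lapply(seq_along(sweep$fsi_targets), function(i) {
    sims <- sweep$sims[[i]]
    per <- function(pops) vapply(sims, function(s)
      mean(s$rates[s$population %in% pops]), numeric(1))
    fsi <- vapply(sims, function(s) s$pop_rates[["FSI"]], numeric(1))
    d <- per("dSPN"); ip <- per("iSPN"); sp <- per(c("dSPN", "iSPN"))
    R <- length(sims)
    sdm <- function(x) if (R > 1) sd(x) / sqrt(R) else NA_real_
    data.frame(fsi_target_Hz = sweep$fsi_targets[i],
               fsi_rate_Hz = mean(fsi),
               dSPN_Hz = mean(d), dSPN_sd = sdm(d),
               iSPN_Hz = mean(ip), iSPN_sd = sdm(ip),
               SPN_Hz = mean(sp), SPN_sd = sdm(sp),
               n_realizations = R)
  })
  structure(list(curve = do.call(rbind, rows)), class = "fsi_curve")
}

#' @export
print.fsi_curve <- function(x, ...) {
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fsi_curve <- function(x, ...) {
  cv <- x$curve
  rng <- range(c(cv$dSPN_Hz, cv$iSPN_Hz), na.rm = TRUE)
  plot(cv$fsi_rate_Hz, cv$dSPN_Hz, type = "b", ylim = rng,
       xlab = "FSI rate (Hz)", ylab = "SPN rate (Hz)", col = 2, ...)
  lines(cv$fsi_rate_Hz, cv$iSPN_Hz, type = "b", col = 4)
  legend("bottomleft", col = c(2, 4), lty = 1, legend = c("dSPN", "iSPN"))
  invisible(x)
}

#' Pooled per-neuron rate distribution over short realizations
#'
#' Realizes the rate-distribution measurement of the network study: per-neuron
#' rates are estimated in a short analysis window (after the transient) in
#' each of many independent network realizations (fresh connectivity and
#' input noise), and pooled into one distribution. The width of the pooled
#' distribution mixes quenched heterogeneity (connectivity in-degrees) with
#' finite-window counting noise of order \eqn{\sqrt{\nu\,CV^2/T}}; a single
#' long run would isolate the (much smaller) quenched component instead.
#'
#' @param net [striatal_network()].
#' @param amplitudes Named per-population drive amplitudes.
#' @param n_realizations Number of independent realizations.
#' @param config [sim_config()] for each realization; its `duration` minus
#'   `transient` is the analysis window (default 1 s after a 100 ms
#'   transient) and its `seed` anchors the realization seeds.
#' @param populations Populations whose neurons are pooled.
#' @return Numeric vector of pooled per-neuron rates (Hz), of length
#'   `n_realizations` times the population size.
#' @export
pooled_rate_distribution <- function(net, amplitudes, n_realizations = 100,
                                     config = sim_config(duration = 1100,
                                                         transient = 100),
                                     populations = c("dSPN", "iSPN")) {
  stopifnot(inherits(net, "striatal_network"), n_realizations >= 1)
  seed0 <- if (!is.null(config$seed)) config$seed else 1L
  unlist(lapply(seq_len(n_realizations), function(r) {
    cfg <- config
    cfg$seed <- (seed0 + r) %% 2147483647  # keep derived seeds in integer range
    s <- simulate_network(net, amplitudes, cfg, conn = NULL)
    s$rates[s$population %in% populations]
  }))
}
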