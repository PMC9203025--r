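#' Phase diagram of GABAergic regimes
#'
#' Classifies every point of an (`E_GABA`, `g_Glu`) grid and records the
#' initial slope of the rate-vs-\eqn{g_{GABA}} curve, producing the phase
#' diagram that separates the plane into inhibitory, non-monotonic,
#' excitatory (and, without noise, silent and GABA-activated) regions. The
#' label boundaries are consistent with the critical reversal potential
#' [critical_egaba()] and with the vertical line `E_GABA = E_thr`; with noise
#' the silent region disappears and the inhibitory/non-monotonic boundary
#' moves to lower `E_GABA` (see [boundary_egaba()]).
#'
#' @param params [lif_params()].
#' @param E_GABA,g_Glu Strictly increasing grid axes. Defaults cover
#'   `[-80, -50]` mV in 0.1 mV steps and `[0, 2]` in steps of 0.01.
#' @param noise A [noise_model]; the deterministic closed form is used without
#'   noise, the Ricciardi rate (with a centered-difference initial slope)
#'   otherwise.
#' @param summaries If `TRUE`, also compute a [regime_summary()] per grid
#'   point (`g_star`, `nu_init`, `nu_max`, `strength_ratio`). Off by default:
#'   the per-point maximization is much more expensive than labelling.
#' @return An object of class `phase_diagram`: a list with `points` (a
#'   data.frame with one row per grid point), the axes, `params` and `noise`.
#' @examples
#' pd <- build_phase_diagram(lif_params(), E_GABA = seq(-70, -55, 0.5),
#'                           g_Glu = seq(0, 1, 0.05))
#' table(pd$points$label)
#' @export
build_phase_diagram <- function(params,
                                E_GABA = seq(-80, -50, by = 0.1),
                                g_Glu = seq(0, 2, by = 0.01),
                                noise = noise_none(),
                                summaries = FALSE) {
  stopifnot(inherits(params, "lif_params"),
            !is.unsorted(E_GABA, strictly = TRUE),
            !is.unsorted(g_Glu, strictly = TRUE))
  grid <- expand.grid(E_GABA = E_GABA, g_Glu = g_Glu,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  if (.noise_is_none(noise)) {
    drive0 <- synaptic_drive(grid$g_Glu, 0, grid$E_GABA)
    slope0 <- rate_slope_ggaba(params, drive0)
    slope0[is.na(slope0)] <- 0  # silent at g_GABA = 0
  } else {
    slope0 <- vapply(seq_len(n), function(i)
      .noisy_slope0(params, grid$g_Glu[i], grid$E_GABA[i], noise), numeric(1))
  }
  label <- classify_regime(params, grid$g_Glu, grid$E_GABA, noise)
  pts <- data.frame(E_GABA_mV = grid$E_GABA, g_Glu = grid$g_Glu,
                    label = label, slope0_Hz = slope0,
                    g_star = NA_real_, nu_init_Hz = NA_real_,
                    nu_max_Hz = NA_real_, strength_ratio = NA_real_)
  if (summaries) {
    for (i in seq_len(n)) {
      s <- regime_summary(params, grid$g_Glu[i], grid$E_GABA[i], noise = noise)
      pts$g_star[i] <- s$g_star
      pts$nu_init_Hz[i] <- s$nu_init
      pts$nu_max_Hz[i] <- s$nu_max
      pts$strength_ratio[i] <- s$strength_ratio
    }
  }
  structure(list(points = pts, E_GABA_axis = E_GABA, g_Glu_axis = g_Glu,
                 params = params, noise = noise, summaries = summaries),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: %d x %d grid (E_GABA in [%g, %g] mV, g_Glu in [%g, %g])\n",
              length(x$E_GABA_axis), length(x$g_Glu_axis),
              min(x$E_GABA_axis), max(x$E_GABA_axis),
              min(x$g_Glu_axis), max(x$g_Glu_axis)))
  print(x$noise)
  tab <- table(x$points$label)
  cat("Regions (grid points):\n")
  for (nm in names(tab)) cat(sprintf("  %-15s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @param x A `phase_diagram`.
#' @param what Either `"label"` (regime map) or `"slope0"` (initial slope
#'   heat map).
#' @param ... Passed to [graphics::image()].
#' @rdname build_phase_diagram
#' @export
plot.phase_diagram <- function(x, what = c("label", "slope0"), ...) {
  what <- match.arg(what)
  nE <- length(x$E_GABA_axis); ng <- length(x$g_Glu_axis)
  if (what == "label") {
    lev <- c("SILENT", "INHIBITORY", "NON_MONOTONIC", "EXCITATORY",
             "GABA_ACTIVATED")
    z <- matrix(match(x$points$label, lev), nE, ng)
    image(x$E_GABA_axis, x$g_Glu_axis, z, zlim = c(1, 5),
          col = hcl.colors(5, "Spectral"),
          xlab = "E_GABA (mV)", ylab = "g_Glu", ...)
    legend("topleft", fill = hcl.colors(5, "Spectral"), legend = lev,
           bg = "white", cex = 0.7)
  } else {
    z <- matrix(x$points$slope0_Hz, nE, ng)
    image(x$E_GABA_axis, x$g_Glu_axis, z, col = hcl.colors(64, "Blue-Red 3"),
          xlab = "E_GABA (mV)", ylab = "g_Glu", ...)
  }
  abline(v = x$params$E_thr, lty = 2)
  invisible(x)
}

#' Export a phase diagram to CSV with JSON metadata
#'
#' Writes the per-point table (columns `E_GABA_mV`, `g_Glu`, `label`,
#' `slope0_Hz`, `g_star`, `nu_init_Hz`, `nu_max_Hz`, `strength_ratio`) as CSV
#' and a JSON sidecar recording the neuron parameters, grid, noise model and
#' package version.
#'
#' @param pd A `phase_diagram`.
#' @param csv_path,json_path Output file paths; the JSON sidecar defaults to
#'   the CSV path with extension `.json`.
#' @return Invisibly, the CSV path.
#' @export
write_phase_diagram <- function(pd, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(pd, "phase_diagram"))
  write.csv(pd$points, csv_path, row.names = FALSE)
  meta <- list(
    package = "gabaregimes",
    version = as.character(packageVersion("gabaregimes")),
    params = unclass(pd$params),
    grid = list(E_GABA_mV = range(pd$E_GABA_axis),
                E_GABA_n = length(pd$E_GABA_axis),
                g_Glu = range(pd$g_Glu_axis),
                g_Glu_n = length(pd$g_Glu_axis)),
    noise = unclass(pd$noise),
    summaries = pd$summaries)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}
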