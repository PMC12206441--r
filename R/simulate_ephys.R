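#' Parameters for synthetic whole-cell ramp recordings
#'
#' Describes one experimental group of voltage-clamped cells whose
#' Ba2+-sensitive inward-rectifier conductance is simulated under a
#' +150 to -150 mV voltage ramp.
#'
#' The current model per cell is
#' \deqn{I(V) = [g_{kir} r(V) (V - E_{rev}) + g_{leak} V] \cdot C_m + \epsilon}
#' with the Boltzmann rectification factor
#' \eqn{r(V) = 1 / (1 + e^{(V - V_{1/2})/k})}. Currents are in pA for
#' conductance densities in nS/pF, voltages in mV and capacitance in pF.
#' In the Ba2+ condition \eqn{g_{kir}} is scaled by `1 - ba_block_frac`.
#'
#' Group calibration: when `cd_mean_pa_pf` is supplied, per-cell Kir
#' conductance densities are back-computed from per-cell target current
#' densities at -150 mV drawn as a normal sample standardised to have sample
#' mean exactly `cd_mean_pa_pf` and sample SD exactly `cd_sd_pa_pf`, so the
#' group's true statistics equal the stated values at any seed.
#'
#' @param g_kir Kir chord conductance density (nS/pF); ignored when
#'   `cd_mean_pa_pf` is given.
#' @param e_rev Reversal potential of the Kir component (mV). The default,
#'   -5 mV, is the K+ Nernst potential for 140 mM internal / 115 mM external
#'   K+ at 22 C.
#' @param rect_vhalf,rect_slope Boltzmann rectification midpoint and slope
#'   (mV). Set `rect_slope = NA` (or `Inf`) to disable rectification
#'   (r(V) = 1, an ohmic conductor).
#' @param g_leak Ohmic leak conductance density (nS/pF), reversing at 0 mV
#'   (near-symmetrical K+ solutions).
#' @param ba_block_frac Fraction of the Kir conductance blocked by 200 uM
#'   Ba2+, in \[0, 1\].
#' @param capacitance_pf Mean cell capacitance (pF); `capacitance_sd_pf`
#'   adds between-cell jitter (truncated at 1 pF).
#' @param capacitance_sd_pf Between-cell SD of capacitance (pF).
#' @param noise_sd_pa SD of additive Gaussian current noise (pA).
#' @param n_cells Number of cells in the group.
#' @param seed RNG seed for reproducible groups.
#' @param cd_mean_pa_pf,cd_sd_pa_pf Optional target mean/SD of the true
#'   Ba2+-sensitive current density at -150 mV (pA/pF, inward negative).
#' @param group Group label (e.g. "WT", "MT", "WT+MT").
#' @return An object of class `ephys_sim_params`.
#' @seealso [ephys_preset()], [simulate_ramp_pair()]
#' @export
ephys_sim_params <- function(g_kir = 1, e_rev = -5, rect_vhalf = -20,
                             rect_slope = 20, g_leak = 0.05,
                             ba_block_frac = 0.95, capacitance_pf = 15,
                             capacitance_sd_pf = 0, noise_sd_pa = 20,
                             n_cells = 5, seed = 1,
                             cd_mean_pa_pf = NULL, cd_sd_pa_pf = 0,
                             group = "other") {
  stopifnot_pos(g_kir, "g_kir", strict = FALSE)
  stopifnot_scalar(e_rev, "e_rev")
  stopifnot_pos(g_leak, "g_leak", strict = FALSE)
  stopifnot_frac(ba_block_frac, "ba_block_frac")
  stopifnot_pos(capacitance_pf, "capacitance_pf")
  stopifnot_pos(noise_sd_pa, "noise_sd_pa", strict = FALSE)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("'n_cells' must be >= 1", call. = FALSE)
  if (!is.null(cd_mean_pa_pf)) {
    stopifnot_scalar(cd_mean_pa_pf, "cd_mean_pa_pf")
    stopifnot_pos(cd_sd_pa_pf, "cd_sd_pa_pf", strict = FALSE)
    if (ba_block_frac <= 0)
      stop("calibrating to a target current density requires ba_block_frac > 0",
           call. = FALSE)
  }
  structure(list(
    g_kir = g_kir, e_rev = e_rev, rect_vhalf = rect_vhalf,
    rect_slope = rect_slope, g_leak = g_leak,
    ba_block_frac = ba_block_frac, capacitance_pf = capacitance_pf,
    capacitance_sd_pf = capacitance_sd_pf, noise_sd_pa = noise_sd_pa,
    n_cells = as.integer(n_cells), seed = seed,
    cd_mean_pa_pf = cd_mean_pa_pf, cd_sd_pa_pf = cd_sd_pa_pf,
    group = group
  ), class = "ephys_sim_params")
}

#' Boltzmann inward-rectification factor
#'
#' @param v Voltage (mV), vectorised.
#' @param vhalf,slope Midpoint and slope (mV); `NA` or infinite slope
#'   disables rectification (returns 1).
#' @return Open fraction r(V) in (0, 1\].
#' @export
kir_rectification <- function(v, vhalf, slope) {
  if (is.na(vhalf) || is.na(slope) || !is.finite(slope)) return(rep(1, length(v)))
  1 / (1 + exp((v - vhalf) / slope))
}

#' Preset ramp-simulation parameter sets for the three expression groups
#'
#' Returns [ephys_sim_params()] calibrated so the group's true
#' Ba2+-sensitive current densities at -150 mV have mean and SD equal to the
#' reported group values: WT -147.7 +/- 23.1 pA/pF (N = 5), homomeric mutant
#' (MT) -8.4 +/- 2.3 pA/pF (N = 7), and equimolar co-expression (WT+MT)
#' -19.1 +/- 3.2 pA/pF (N = 5).
#'
#' @param name One of "WT", "MT", "WT+MT".
#' @param seed RNG seed.
#' @param n_cells Group size; default is the reported N.
#' @return An `ephys_sim_params` object.
#' @export
ephys_preset <- function(name = c("WT", "MT", "WT+MT"), seed = 1,
                         n_cells = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    "WT"    = list(mean = -147.7, sd = 23.1, n = 5L),
    "MT"    = list(mean = -8.4,   sd = 2.3,  n = 7L),
    "WT+MT" = list(mean = -19.1,  sd = 3.2,  n = 5L))
  ephys_sim_params(
    cd_mean_pa_pf = spec$mean, cd_sd_pa_pf = spec$sd,
    n_cells = n_cells %||% spec$n, seed = seed, group = name,
    capacitance_pf = 15, capacitance_sd_pf = 2, noise_sd_pa = 20)
}

#' Voltage-ramp command waveform
#'
#' A 400 ms linear ramp from +150 to -150 mV sampled at 10 kHz, flanked by
#' holding segments at 0 mV.
#'
#' @param ramp_ms Ramp duration (ms).
#' @param sampling_hz Sampling rate (Hz).
#' @param v_start,v_end Ramp start/end voltages (mV).
#' @param hold_mV Holding potential (mV).
#' @param hold_ms Duration of each holding segment (ms).
#' @return A data frame with columns `time_s` and `v_mV`.
#' @export
ramp_command <- function(ramp_ms = 400, sampling_hz = 10000,
                         v_start = 150, v_end = -150,
                         hold_mV = 0, hold_ms = 20) {
  n_hold <- round(hold_ms / 1000 * sampling_hz)
  n_ramp <- round(ramp_ms / 1000 * sampling_hz)
  v <- c(rep(hold_mV, n_hold),
         seq(v_start, v_end, length.out = n_ramp),
         rep(hold_mV, n_hold))
  data.frame(time_s = (seq_along(v) - 1L) / sampling_hz, v_mV = v)
}

new_ramp_recording <- function(time, v_cmd, i, capacitance_pf, condition,
                               cell_id, sampling_hz, group = "other") {
  structure(list(time = time, v_cmd = v_cmd, i = i,
                 capacitance_pf = capacitance_pf, condition = condition,
                 cell_id = cell_id, sampling_hz = sampling_hz, group = group),
            class = "ramp_recording")
}

#' @export
print.ramp_recording <- function(x, ...) {
  cat(sprintf("<ramp_recording> cell %s [%s], %d samples @ %g kHz, Cm = %.1f pF\n",
              x$cell_id, x$condition, length(x$i), x$sampling_hz / 1000,
              x$capacitance_pf))
  invisible(x)
}

#' Simulate paired control / Ba2+ voltage-ramp recordings for a cell group
#'
#' For each cell, generates a control sweep and a sweep in 200 uM Ba2+ under
#' the same command waveform; Ba2+ scales the Kir conductance by
#' `1 - ba_block_frac` while the leak is untouched. Ground truth records each
#' cell's conductance and its true Ba2+-sensitive current density at -150 mV,
#' \eqn{g_{kir} \cdot f_{block} \cdot r(-150) \cdot (-150 - E_{rev})} (pA/pF).
#'
#' @param params An [ephys_sim_params()] object.
#' @param command Optional command waveform from [ramp_command()].
#' @return An object of class `ramp_sim`: list with `recordings` (per cell, a
#'   list with `$control` and `$ba` [ramp_recording]s), `truth` (data frame:
#'   cell_id, group, g_kir, capacitance_pf, cd_true_pa_pf, e_rev) and
#'   `params`.
#' @examples
#' sim <- simulate_ramp_pair(ephys_preset("WT", seed = 1))
#' sim$truth$cd_true_pa_pf
#' @export
simulate_ramp_pair <- function(params, command = ramp_command()) {
  stopifnot(inherits(params, "ephys_sim_params"))
  p <- params
  v <- command$v_mV
  r <- kir_rectification(v, p$rect_vhalf, p$rect_slope)
  r150 <- kir_rectification(-150, p$rect_vhalf, p$rect_slope)
  with_seed(p$seed, {
    if (!is.null(p$cd_mean_pa_pf)) {
      cd <- rnorm_exact(p$n_cells, p$cd_mean_pa_pf, p$cd_sd_pa_pf)
      g_kir <- cd / (p$ba_block_frac * r150 * (-150 - p$e_rev))
    } else {
      g_kir <- rep(p$g_kir, p$n_cells)
      cd <- g_kir * p$ba_block_frac * r150 * (-150 - p$e_rev)
    }
    if (any(g_kir < 0))
      stop("calibration produced a negative conductance; check presets",
           call. = FALSE)
    cm <- pmax(1, p$capacitance_pf +
                 if (p$capacitance_sd_pf > 0)
                   stats::rnorm(p$n_cells, 0, p$capacitance_sd_pf) else 0)
    recs <- vector("list", p$n_cells)
    for (k in seq_len(p$n_cells)) {
      id <- sprintf("%s_cell%02d", p$group, k)
      i_kir <- g_kir[k] * r * (v - p$e_rev)
      i_leak <- p$g_leak * v
      noise <- function() if (p$noise_sd_pa > 0)
        stats::rnorm(length(v), 0, p$noise_sd_pa) else 0
      i_ctl <- (i_kir + i_leak) * cm[k] + noise()
      i_ba <- (i_kir * (1 - p$ba_block_frac) + i_leak) * cm[k] + noise()
      recs[[k]] <- list(
        control = new_ramp_recording(command$time_s, v, i_ctl, cm[k],
                                     "control", id, 10000, p$group),
        ba = new_ramp_recording(command$time_s, v, i_ba, cm[k],
                                "ba2+", id, 10000, p$group))
    }
    truth <- data.frame(
      cell_id = vapply(recs, function(r) r$control$cell_id, ""),
      group = p$group, g_kir = g_kir, capacitance_pf = cm,
      cd_true_pa_pf = cd, e_rev = p$e_rev, stringsAsFactors = FALSE)
    structure(list(recordings = recs, truth = truth, params = p),
              class = "ramp_sim")
  })
}

#' @export
print.ramp_sim <- function(x, ...) {
  cat(sprintf("<ramp_sim> group %s: %d paired control/Ba2+ sweeps\n",
              x$params$group, length(x$recordings)))
  cat(sprintf("  true CD at -150 mV: mean %.1f, SD %.1f pA/pF\n",
              mean(x$truth$cd_true_pa_pf), stats::sd(x$truth$cd_true_pa_pf)))
  invisible(x)
}
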