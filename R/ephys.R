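#' Locate the ramp segment of a recording from the command waveform
#'
#' Finds the longest contiguous run of strictly decreasing command voltage,
#' so ramp extraction tolerates different holding-segment layouts between
#' acquisition dialects.
#'
#' @param rec A `ramp_recording`.
#' @return Integer index vector into the recording's samples.
#' @keywords internal
ramp_segment <- function(rec) {
  dv <- diff(rec$v_cmd)
  dec <- dv < 0
  if (!any(dec)) stop("no ramp segment found in command waveform", call. = FALSE)
  r <- rle(dec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  seq.int(starts[best], ends[best] + 1L)
}

#' Ba2+-sensitive difference current
#'
#' Subtracts the sweep recorded in 200 uM Ba2+ from the paired control sweep,
#' sample-wise over the ramp segment, isolating the Kir-channel-mediated
#' (Ba2+-sensitive) current.
#'
#' @param control,ba Paired [ramp_recording]s from the same cell, sharing the
#'   command waveform sample-for-sample.
#' @return An object of class `difference_trace`: list with `v` (mV), `i_diff`
#'   (pA, control minus Ba2+), `capacitance_pf`, `cell_id`, `group`.
#' @export
ba_sensitive_current <- function(control, ba) {
  stopifnot(inherits(control, "ramp_recording"), inherits(ba, "ramp_recording"))
  if (length(control$i) != length(ba$i))
    stop("control and Ba2+ sweeps differ in length", call. = FALSE)
  if (!isTRUE(all.equal(control$v_cmd, ba$v_cmd, tolerance = 1e-9)))
    stop("control and Ba2+ sweeps have different command voltages", call. = FALSE)
  if (!identical(control$cell_id, ba$cell_id))
    warning("pairing sweeps from different cell_ids")
  idx <- ramp_segment(control)
  structure(list(v = control$v_cmd[idx],
                 i_diff = control$i[idx] - ba$i[idx],
                 capacitance_pf = control$capacitance_pf,
                 cell_id = control$cell_id,
                 group = control$group),
            class = "difference_trace")
}

#' @export
print.difference_trace <- function(x, ...) {
  cat(sprintf("<difference_trace> cell %s: %d samples, V in [%g, %g] mV\n",
              x$cell_id, length(x$v), min(x$v), max(x$v)))
  invisible(x)
}

#' Current density at a readout voltage
#'
#' Reads the Ba2+-sensitive current at the target voltage by a local linear
#' fit over samples within +/- `window_mV`, evaluated at `at_mV`, and
#' normalises by cell capacitance, giving pA/pF with inward current negative.
#' The local fit averages noise like a windowed median but stays unbiased
#' when the readout voltage sits at the end of the ramp, where the window is
#' one-sided.
#'
#' @param diff A [ba_sensitive_current()] trace.
#' @param capacitance_pf Cell capacitance (pF); defaults to the trace's own.
#' @param at_mV Readout voltage (mV), default -150.
#' @param window_mV Half-width of the local fit window (mV).
#' @return Current density (pA/pF), scalar.
#' @export
current_density <- function(diff, capacitance_pf = diff$capacitance_pf,
                            at_mV = -150, window_mV = 1) {
  stopifnot(inherits(diff, "difference_trace"))
  stopifnot_pos(capacitance_pf, "capacitance_pf")
  if (at_mV < min(diff$v) - window_mV || at_mV > max(diff$v) + window_mV)
    stop(sprintf("readout voltage %g mV outside the ramp span", at_mV),
         call. = FALSE)
  sel <- abs(diff$v - at_mV) <= window_mV
  i_at <- if (sum(sel) >= 3) {
    fit <- stats::lm.fit(cbind(1, diff$v[sel] - at_mV), diff$i_diff[sel])
    unname(fit$coefficients[1])
  } else if (any(sel)) {
    stats::median(diff$i_diff[sel])
  } else diff$i_diff[which.min(abs(diff$v - at_mV))]
  i_at / capacitance_pf
}

#' K+ Nernst potential
#'
#' @param k_in,k_out Internal/external K+ activities (mM).
#' @param temp_c Temperature (deg C).
#' @return Equilibrium potential (mV).
#' @export
nernst_k <- function(k_in = 140, k_out = 115, temp_c = 22) {
  1000 * 8.314462618 * (273.15 + temp_c) / 96485.332 * log(k_out / k_in)
}

#' Reversal potential of a difference current
#'
#' Zero crossing of the Ba2+-sensitive current versus voltage, by local
#' linear interpolation after running-mean smoothing. With several crossings
#' (noise), the one nearest `prior_mV` — by default the K+ Nernst potential
#' for the recording solutions (about -5 mV) — is returned.
#'
#' @param diff A [ba_sensitive_current()] trace.
#' @param prior_mV Proximity prior for multiple crossings (mV).
#' @param smooth_n Running-mean window (samples, odd).
#' @return Reversal potential (mV).
#' @export
reversal_potential <- function(diff, prior_mV = nernst_k(), smooth_n = 21) {
  stopifnot(inherits(diff, "difference_trace"))
  ord <- order(diff$v)
  v <- diff$v[ord]
  i <- diff$i_diff[ord]
  if (smooth_n > 1 && length(i) > smooth_n) {
    k <- rep(1 / smooth_n, smooth_n)
    i <- stats::filter(i, k, sides = 2)
    keep <- !is.na(i)
    v <- v[keep]; i <- as.numeric(i[keep])
  }
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(i == 0)
  cand <- c(v[exact],
            vapply(cross, function(j) {
              v[j] + (0 - i[j]) * (v[j + 1] - v[j]) / (i[j + 1] - i[j])
            }, 0))
  if (!length(cand))
    stop(sprintf(
      "difference current does not change sign (range %.3g..%.3g pA); no reversal potential",
      min(i), max(i)), call. = FALSE)
  cand[which.min(abs(cand - prior_mV))]
}

#' Chord conductance curve of the Ba2+-sensitive current
#'
#' Evaluates G(V) = I_diff(V) / (V - V_rev) on a regular voltage grid
#' restricted to -140..-20 mV, the span over which the chord conductance of
#' the Ba2+-sensitive component is defined. Grid points within
#' `exclusion_mV` of the reversal potential are dropped to avoid 0/0
#' amplification. pA/mV gives nS.
#'
#' @param diff A [ba_sensitive_current()] trace.
#' @param v_rev Reversal potential (mV), e.g. from [reversal_potential()].
#' @param v_range Evaluation window (mV), default c(-140, -20).
#' @param grid_mV Grid spacing (mV).
#' @param exclusion_mV Half-width of the exclusion window around `v_rev`.
#' @return Object of class `chord_conductance_curve`: list with `v` (mV),
#'   `g` (nS), `v_rev`, `cell_id`.
#' @export
chord_conductance <- function(diff, v_rev, v_range = c(-140, -20),
                              grid_mV = 2, exclusion_mV = 5) {
  stopifnot(inherits(diff, "difference_trace"))
  stopifnot_scalar(v_rev, "v_rev")
  grid <- seq(v_range[1], v_range[2], by = grid_mV)
  grid <- grid[abs(grid - v_rev) >= exclusion_mV]
  if (!length(grid))
    stop("empty chord-conductance evaluation window", call. = FALSE)
  ord <- order(diff$v)
  i_grid <- stats::approx(diff$v[ord], diff$i_diff[ord], xout = grid,
                          ties = mean)$y
  structure(list(v = grid, g = i_grid / (grid - v_rev), v_rev = v_rev,
                 cell_id = diff$cell_id),
            class = "chord_conductance_curve")
}

#' @export
print.chord_conductance_curve <- function(x, ...) {
  cat(sprintf("<chord_conductance_curve> cell %s: %d points, V_rev = %.2f mV, median G = %.3g nS\n",
              x$cell_id %||% "?", length(x$v), x$v_rev, stats::median(x$g)))
  invisible(x)
}

#' Per-cell ramp analysis
#'
#' Runs the full single-cell pipeline — Ba2+ subtraction, reversal potential,
#' current density at -150 mV — over the paired recordings of a [ramp_sim]
#' (or a plain list of `list(control=, ba=)` pairs).
#'
#' @param pairs A `ramp_sim` or list of control/Ba2+ pairs.
#' @return Data frame with columns cell_id, group, capacitance_pf,
#'   cd_pa_per_pf, v_rev.
#' @export
summarize_ramp_cells <- function(pairs) {
  recs <- if (inherits(pairs, "ramp_sim")) pairs$recordings else pairs
  rows <- lapply(recs, function(pr) {
    d <- ba_sensitive_current(pr$control, pr$ba)
    data.frame(cell_id = d$cell_id, group = d$group %||% "other",
               capacitance_pf = d$capacitance_pf,
               cd_pa_per_pf = current_density(d),
               v_rev = reversal_potential(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group summary of current densities
#'
#' Means and SDs are computed over cells (not sweeps); groups are ordered
#' WT, MT, WT+MT, then any others.
#'
#' @param cells Data frame from [summarize_ramp_cells()] (needs columns
#'   `group` and `cd_pa_per_pf`).
#' @return Object of class `ephys_group_summary`: data frame with group,
#'   n, mean_cd, sd_cd, sem_cd. Single-cell groups report `sd_cd = 0`.
#' @export
summarize_groups <- function(cells) {
  if (!is.data.frame(cells) || nrow(cells) == 0)
    stop("no cells to summarise", call. = FALSE)
  canonical <- c("WT", "MT", "WT+MT")
  groups <- unique(cells$group)
  groups <- c(intersect(canonical, groups), setdiff(groups, canonical))
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- cells$cd_pa_per_pf[cells$group == g]
    data.frame(group = g, n = length(x), mean_cd = mean(x),
               sd_cd = if (length(x) > 1) stats::sd(x) else 0,
               sem_cd = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("ephys_group_summary", class(out))
  out
}

#' @export
print.ephys_group_summary <- function(x, ...) {
  cat("Ba2+-sensitive current density at -150 mV (pA/pF)\n")
  for (k in seq_len(nrow(x)))
    cat(sprintf("  %-6s %8.1f +/- %5.1f  (n = %d)\n",
                x$group[k], x$mean_cd[k], x$sd_cd[k], x$n[k]))
  invisible(x)
}
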