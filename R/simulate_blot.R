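#' Molecular-weight calibration for a simulated gel
#'
#' Monotone piecewise-linear map between log10(MW) and migration position
#' (pixels from the top of the gel), anchored at ladder band positions.
#'
#' @param mw_kda Ladder molecular weights (kDa), decreasing down the gel.
#' @param px Pixel positions of the ladder bands; by default spread so that a
#'   70 kDa band sits at 40 px and a 25 kDa band at 360 px of a 400 px lane.
#' @return Object of class `mw_calibration` with functions `mw_to_px()` and
#'   `px_to_mw()`.
#' @export
mw_ladder <- function(mw_kda = c(70, 55, 45, 35, 25), px = NULL) {
  stopifnot(all(diff(mw_kda) < 0))
  lmw <- log10(mw_kda)
  if (is.null(px)) {
    px <- 40 + (lmw[1] - lmw) / (lmw[1] - lmw[length(lmw)]) * 320
  }
  stopifnot(length(px) == length(mw_kda), all(diff(px) > 0))
  mw_to_px <- function(mw) stats::approx(rev(lmw), rev(px), xout = log10(mw),
                                         rule = 2, ties = mean)$y
  px_to_mw <- function(p) 10^stats::approx(px, lmw, xout = p, rule = 2,
                                           ties = mean)$y
  structure(list(mw_kda = mw_kda, px = px,
                 mw_to_px = mw_to_px, px_to_mw = px_to_mw),
            class = "mw_calibration")
}

#' Parameters for one synthetic blot lane
#'
#' A lane carries three Gaussian bands on a tilted baseline: the mature
#' (further-glycosylated, ~45 kDa) and immature (~43 kDa) forms of the target
#' channel, and an alpha-tubulin loading control (~50 kDa).
#'
#' @param abundance Total target amount in the lane (arbitrary units);
#'   `upper_frac` of it goes to the mature band.
#' @param upper_frac Fraction of target signal in the mature band, \[0, 1\].
#' @param tubulin_amount Loading-control amount (a.u.).
#' @param background_level Additive baseline (a.u. per pixel).
#' @param background_tilt Linear baseline slope (a.u. per pixel of migration).
#' @param band_sigma_px Gaussian band SD along the migration axis (px).
#' @param noise_sd Pixel noise SD (a.u.).
#' @param seed RNG seed (per lane; `NULL` = caller's stream).
#' @param group Lane group label ("NT", "WT", "MT").
#' @param treatment Treatment label ("none", "PNGaseF", "EndoH",
#'   "tunicamycin_2h", "tunicamycin_6h", "MG132_8h", "BafA1_3h", "BafA1_6h").
#' @param lane_id Lane identifier.
#' @return Object of class `blot_sim_params`.
#' @export
blot_sim_params <- function(abundance = 300, upper_frac = 0.7,
                            tubulin_amount = 200, background_level = 5,
                            background_tilt = 0.01, band_sigma_px = 4,
                            noise_sd = 0.05, seed = NULL,
                            group = "WT", treatment = "none",
                            lane_id = NULL) {
  stopifnot_pos(abundance, "abundance", strict = FALSE)
  stopifnot_frac(upper_frac, "upper_frac")
  stopifnot_pos(tubulin_amount, "tubulin_amount", strict = FALSE)
  stopifnot_pos(band_sigma_px, "band_sigma_px")
  stopifnot_pos(noise_sd, "noise_sd", strict = FALSE)
  structure(list(abundance = abundance, upper_frac = upper_frac,
                 tubulin_amount = tubulin_amount,
                 background_level = background_level,
                 background_tilt = background_tilt,
                 band_sigma_px = band_sigma_px, noise_sd = noise_sd,
                 seed = seed, group = group, treatment = treatment,
                 lane_id = lane_id),
            class = "blot_sim_params")
}

#' Preset lane parameter sets
#'
#' "WT" is the untreated wild-type lane (mature/immature ratio 0.7/0.3 =
#' 2.33, consistent with the reported untreated ratio above 2). "MT" is the
#' homomeric mutant at 0.40 x the WT abundance, matching the reported
#' total-expression deficit (below 50% of WT). "PNGaseF" collapses the signal
#' into the deglycosylated lower band (upper_frac = 0.05, ratio ~0.053,
#' consistent with the reported post-deglycosylation ratio below 0.5).
#' "NT" is a non-transfected lane (loading control only).
#'
#' @param name One of "WT", "MT", "PNGaseF", "NT".
#' @param seed RNG seed.
#' @param lane_id Lane identifier.
#' @return A `blot_sim_params` object.
#' @export
blot_preset <- function(name = c("WT", "MT", "PNGaseF", "NT"), seed = NULL,
                        lane_id = name) {
  name <- match.arg(name)
  switch(name,
    WT = blot_sim_params(abundance = 300, upper_frac = 0.7, seed = seed,
                         group = "WT", treatment = "none", lane_id = lane_id),
    MT = blot_sim_params(abundance = 0.40 * 300, upper_frac = 0.7,
                         seed = seed, group = "MT", treatment = "none",
                         lane_id = lane_id),
    PNGaseF = blot_sim_params(abundance = 300, upper_frac = 0.05, seed = seed,
                              group = "WT", treatment = "PNGaseF",
                              lane_id = lane_id),
    NT = blot_sim_params(abundance = 0, upper_frac = 0.7, seed = seed,
                         group = "NT", treatment = "none", lane_id = lane_id))
}

#' Apparent molecular weights of the simulated bands (kDa)
#' @keywords internal
blot_band_mws <- function() c(upper = 45, lower = 43, loading = 50)

#' Render synthetic blot lanes
#'
#' Each lane is a 2D intensity patch (migration axis along rows) with three
#' Gaussian bands — mature target, immature target, loading control — on a
#' tilted additive baseline plus Gaussian pixel noise. Band centres come from
#' the monotone MW-to-position calibration. True integrated band amounts are
#' recorded as ground truth.
#'
#' @param params_per_lane List of [blot_sim_params()] (or a single one).
#' @param ladder A [mw_ladder()] calibration.
#' @param lane_px Lane length along the migration axis (px).
#' @param lane_width_px Lane width (px).
#' @param gap_px Blank gap between lanes in the assembled image (px).
#' @return Object of class `blot_sim`: list with `image` (matrix,
#'   rows = migration position, columns = lanes side by side), `lane_bounds`
#'   (list of column ranges per lane), `ladder`, `band_sigma_px`, and `truth`
#'   (data frame: lane_id, group, treatment, upper_true, lower_true,
#'   loading_true).
#' @export
simulate_blot <- function(params_per_lane, ladder = mw_ladder(),
                          lane_px = 400, lane_width_px = 40, gap_px = 10) {
  if (inherits(params_per_lane, "blot_sim_params"))
    params_per_lane <- list(params_per_lane)
  stopifnot(length(params_per_lane) >= 1,
            all(vapply(params_per_lane, inherits, TRUE, "blot_sim_params")))
  mws <- blot_band_mws()
  centers <- stats::setNames(ladder$mw_to_px(mws), names(mws))
  sig <- vapply(params_per_lane, `[[`, 0, "band_sigma_px")
  dmin <- min(dist(centers))
  if (any(dmin < 3 * sig))
    stop(sprintf(
      "degenerate design: band centres %.1f px apart but 3*band_sigma = %.1f px",
      dmin, max(3 * sig)), call. = FALSE)

  n_lane <- length(params_per_lane)
  width_total <- n_lane * lane_width_px + (n_lane - 1) * gap_px
  img <- matrix(0, nrow = lane_px, ncol = width_total)
  pos <- seq_len(lane_px)
  bounds <- vector("list", n_lane)
  truth <- vector("list", n_lane)

  for (k in seq_len(n_lane)) {
    p <- params_per_lane[[k]]
    c0 <- (k - 1) * (lane_width_px + gap_px)
    bounds[[k]] <- c(c0 + 1L, c0 + lane_width_px)
    amounts <- c(upper = p$abundance * p$upper_frac,
                 lower = p$abundance * (1 - p$upper_frac),
                 loading = p$tubulin_amount)
    # per-column intensity: the lane-mean profile integrates to the amount
    prof <- p$background_level + p$background_tilt * pos
    for (b in names(amounts))
      prof <- prof + amounts[[b]] *
        stats::dnorm(pos, centers[[b]], p$band_sigma_px)
    patch <- matrix(rep(prof, lane_width_px), nrow = lane_px)
    if (p$noise_sd > 0)
      patch <- patch + with_seed(p$seed,
        matrix(stats::rnorm(length(patch), 0, p$noise_sd), nrow = lane_px))
    img[, bounds[[k]][1]:bounds[[k]][2]] <- patch
    truth[[k]] <- data.frame(
      lane_id = p$lane_id %||% sprintf("lane%02d", k),
      group = p$group, treatment = p$treatment,
      upper_true = amounts[["upper"]], lower_true = amounts[["lower"]],
      loading_true = amounts[["loading"]], stringsAsFactors = FALSE)
  }
  structure(list(image = img, lane_bounds = bounds, ladder = ladder,
                 band_sigma_px = max(sig), truth = do.call(rbind, truth)),
            class = "blot_sim")
}

#' @export
print.blot_sim <- function(x, ...) {
  cat(sprintf("<blot_sim> %d lanes, %d x %d px image\n",
              length(x$lane_bounds), nrow(x$image), ncol(x$image)))
  print(x$truth)
  invisible(x)
}
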