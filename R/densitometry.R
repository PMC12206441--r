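#' Extract a lane intensity profile from a blot image
#'
#' Column-wise mean intensity across the lane width, as a function of
#' migration position (rows).
#'
#' @param image Matrix (rows = migration axis) or a [blot_sim] object.
#' @param lane_bounds Length-2 integer vector of lane column range, or the
#'   lane index when `image` is a `blot_sim`.
#' @param lane_id Lane identifier.
#' @param calibration A [mw_ladder()] calibration (taken from the `blot_sim`
#'   when available).
#' @return Object of class `lane_profile`: list with `position` (px),
#'   `intensity` (mean a.u.), `lane_width_px`, `lane_id`, `calibration`,
#'   `background_corrected` flag.
#' @export
extract_lane_profile <- function(image, lane_bounds, lane_id = NULL,
                                 calibration = NULL) {
  if (inherits(image, "blot_sim")) {
    sim <- image
    k <- if (length(lane_bounds) == 1) lane_bounds else
      stop("give a lane index when extracting from a blot_sim", call. = FALSE)
    lane_id <- lane_id %||% sim$truth$lane_id[k]
    calibration <- calibration %||% sim$ladder
    lane_bounds <- sim$lane_bounds[[k]]
    image <- sim$image
  }
  stopifnot(is.matrix(image), length(lane_bounds) == 2)
  if (lane_bounds[1] < 1 || lane_bounds[2] > ncol(image) ||
      lane_bounds[1] > lane_bounds[2])
    stop("lane bounds fall outside the image", call. = FALSE)
  cols <- lane_bounds[1]:lane_bounds[2]
  structure(list(position = seq_len(nrow(image)),
                 intensity = rowMeans(image[, cols, drop = FALSE]),
                 lane_width_px = length(cols),
                 lane_id = lane_id %||% "lane",
                 calibration = calibration,
                 background_corrected = FALSE),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> %s: %d px, intensity %.3g..%.3g%s\n",
              x$lane_id, length(x$position), min(x$intensity),
              max(x$intensity),
              if (x$background_corrected) " (background-corrected)" else ""))
  invisible(x)
}

roll_stat <- function(x, half, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    fun(x[max(1, i - half):min(n, i + half)]), 0)
}

#' Subtract the lane background
#'
#' Estimates the baseline by a rolling minimum followed by a rolling maximum
#' over the same window (a morphological opening: the "rolling-minimum
#' baseline"), which follows a constant or tilted baseline exactly. Because
#' the opening can bulge upwards beneath clusters of overlapping bands wider
#' than the window, the baseline is then re-interpolated linearly across band
#' regions through anchor points where the profile sits on the baseline.
#' The corrected profile is clipped at zero.
#'
#' @param profile A [extract_lane_profile()] result.
#' @param band_sigma_px Expected band SD (px); the per-side half-window is
#'   4 x this value, so features up to ~8 sigma wide are treated as bands.
#' @param protect_px Optional integer positions never used as baseline
#'   anchors (the expected band regions). When the profile carries a ladder
#'   calibration this defaults to the expected band centres +/- 5 sigma, so
#'   that band tails are not absorbed into the baseline.
#' @return The background-corrected `lane_profile`, with a `noise_sd` field
#'   (robust pixel-noise estimate from successive differences, computed
#'   before zero-clipping) used downstream as the band-detection floor.
#' @export
subtract_background <- function(profile, band_sigma_px = 4,
                                protect_px = NULL) {
  stopifnot(inherits(profile, "lane_profile"))
  y <- profile$intensity
  half <- max(1L, round(4 * band_sigma_px))
  if (length(y) < 3 * 2 * band_sigma_px)
    stop("profile too short relative to band width", call. = FALSE)
  if (is.null(protect_px) && !is.null(profile$calibration)) {
    ctr <- profile$calibration$mw_to_px(blot_band_mws())
    protect_px <- unlist(lapply(ctr, function(cc)
      seq(floor(cc - 5 * band_sigma_px), ceiling(cc + 5 * band_sigma_px))))
  }
  lo <- roll_stat(y, half, min)
  opening <- roll_stat(lo, half, max)
  # anchor where the profile touches the opening (off-band); interpolate the
  # baseline across band regions between anchors, extrapolating linearly
  # beyond the outermost anchors (the opening is edge-biased over the final
  # half-window, so constant extrapolation would leave a tilt residual there)
  noise_sd <- stats::mad(diff(y)) / sqrt(2)
  tol <- 3 * noise_sd + 1e-6 * max(abs(y))
  anchor <- which(y - opening <= tol)
  if (!is.null(protect_px)) anchor <- setdiff(anchor, protect_px)
  baseline <- if (length(anchor) >= 2) {
    b <- stats::approx(anchor, opening[anchor], xout = seq_along(y),
                       rule = 2)$y
    a1 <- anchor[1]; a2 <- anchor[length(anchor)]
    if (a1 > 1) {
      s <- (opening[anchor[2]] - opening[a1]) / (anchor[2] - a1)
      b[1:(a1 - 1)] <- opening[a1] + s * ((1:(a1 - 1)) - a1)
    }
    if (a2 < length(y)) {
      k <- anchor[length(anchor) - 1]
      s <- (opening[a2] - opening[k]) / (a2 - k)
      b[(a2 + 1):length(y)] <- opening[a2] + s * (((a2 + 1):length(y)) - a2)
    }
    b
  } else opening
  profile$intensity <- pmax(y - baseline, 0)
  profile$background_corrected <- TRUE
  profile$noise_sd <- noise_sd
  profile
}

#' Detect and integrate the expected bands of a lane profile
#'
#' For each expected molecular weight, searches the calibrated window
#' (expected MW +/- `mw_tol_kda`) for a local maximum; a band whose peak
#' falls below the detection floor (3 x the robust noise SD of the corrected
#' profile) is flagged absent with intensity 0. Detected bands are quantified
#' either by a joint Gaussian least-squares unmixing with fixed centres and
#' width (default — the 43 and 45 kDa glycoforms overlap at their tails), or
#' by direct summation over centre +/- 3 sigma truncated at the midpoint
#' between adjacent bands (`method = "sum"`). Intensities integrate the
#' lane-mean profile (a.u. px).
#'
#' @param profile A background-corrected [lane_profile].
#' @param expected_mws Named numeric vector of expected MWs (kDa); defaults
#'   to upper = 45, lower = 43, loading = 50.
#' @param mw_tol_kda Search half-window (kDa).
#' @param band_sigma_px Band SD used for integration (px).
#' @param method "fit" (Gaussian unmixing) or "sum".
#' @return Data frame of class `band_table`: label, expected_mw_kda,
#'   center_px, apparent_mw_kda, integrated_intensity, present, flag.
#' @export
detect_and_integrate_bands <- function(profile,
                                       expected_mws = blot_band_mws(),
                                       mw_tol_kda = 2, band_sigma_px = 4,
                                       method = c("fit", "sum")) {
  stopifnot(inherits(profile, "lane_profile"))
  method <- match.arg(method)
  cal <- profile$calibration
  if (is.null(cal)) stop("ladder calibration required", call. = FALSE)
  y <- profile$intensity
  pos <- profile$position

  # robust noise floor: carried over from background subtraction when
  # available (estimated before zero-clipping, which halves the apparent
  # noise of an empty lane), else re-estimated from successive differences
  noise_sd <- profile$noise_sd %||% (stats::mad(diff(y)) / sqrt(2))
  floor_level <- 3 * noise_sd

  res <- lapply(names(expected_mws), function(lab) {
    mw <- expected_mws[[lab]]
    lo <- cal$mw_to_px(mw + mw_tol_kda)  # heavier migrates less (smaller px)
    hi <- cal$mw_to_px(mw - mw_tol_kda)
    win <- which(pos >= lo & pos <= hi)
    if (!length(win))
      return(data.frame(label = lab, expected_mw_kda = mw, center_px = NA,
                        apparent_mw_kda = NA, integrated_intensity = 0,
                        present = FALSE, flag = "window_outside_profile",
                        stringsAsFactors = FALSE))
    yw <- y[win]
    # local maxima inside the window
    locmax <- win[which(diff(sign(diff(c(-Inf, yw, -Inf)))) < 0)]
    flag <- ""
    if (length(locmax) > 1) {
      flag <- "ambiguous_peak"
      locmax <- locmax[which.min(abs(pos[locmax] - cal$mw_to_px(mw)))]
    }
    peak_height <- if (length(locmax)) y[locmax[1]] else NA
    center <- if (length(locmax)) {
      # sub-pixel refinement by parabolic interpolation around the peak
      j <- locmax[1]
      if (j > 1 && j < length(y) && y[j - 1] - 2 * y[j] + y[j + 1] < 0)
        pos[j] + 0.5 * (y[j - 1] - y[j + 1]) /
          (y[j - 1] - 2 * y[j] + y[j + 1])
      else pos[j]
    } else NA
    present <- !is.na(center) && peak_height > floor_level
    if (!present)
      return(data.frame(label = lab, expected_mw_kda = mw, center_px = center,
                        apparent_mw_kda = if (is.na(center)) NA else
                          cal$px_to_mw(center),
                        integrated_intensity = 0, present = FALSE,
                        flag = if (nzchar(flag)) flag else "absent",
                        stringsAsFactors = FALSE))
    data.frame(label = lab, expected_mw_kda = mw, center_px = center,
               apparent_mw_kda = cal$px_to_mw(center),
               integrated_intensity = NA_real_, present = TRUE, flag = flag,
               stringsAsFactors = FALSE)
  })
  bands <- do.call(rbind, res)

  # two labels collapsing onto (nearly) the same peak: keep the one whose
  # expected position is closer, flag the other absent (e.g. a fully
  # deglycosylated lane where the mature band merges into the immature one)
  det <- which(bands$present)
  if (length(det) > 1) {
    expected_px <- cal$mw_to_px(bands$expected_mw_kda[det])
    drop <- rep(FALSE, length(det))
    for (a in seq_along(det)) for (b in seq_along(det)) {
      if (a >= b || drop[a] || drop[b]) next
      if (abs(bands$center_px[det[a]] - bands$center_px[det[b]]) <
          band_sigma_px) {
        worse <- if (abs(bands$center_px[det[a]] - expected_px[a]) >
                     abs(bands$center_px[det[b]] - expected_px[b])) a else b
        drop[worse] <- TRUE
      }
    }
    if (any(drop)) {
      j <- det[drop]
      bands$present[j] <- FALSE
      bands$integrated_intensity[j] <- 0
      bands$flag[j] <- "collapsed_into_neighbor"
    }
  }

  det <- which(bands$present)
  if (length(det)) {
    if (method == "fit") {
      # cluster bands whose +/- 4 sigma windows overlap, then per cluster fit
      # unit-area Gaussians with fixed centres/width plus a local constant
      # (absorbs residual baseline left between overlapping bands)
      cen <- bands$center_px[det]
      ord <- order(cen)
      cl <- cumsum(c(1, diff(cen[ord]) > 8 * band_sigma_px))
      for (g in unique(cl)) {
        j <- det[ord[cl == g]]
        sel <- which(rowSums(vapply(j, function(b)
          abs(pos - bands$center_px[b]) <= 4 * band_sigma_px,
          logical(length(pos)))) > 0)
        X <- cbind(1, vapply(j, function(b)
          stats::dnorm(pos[sel], bands$center_px[b], band_sigma_px),
          numeric(length(sel))))
        amp <- stats::lm.fit(X, y[sel])$coefficients[-1]
        bands$integrated_intensity[j] <- pmax(amp, 0)
      }
    } else {
      cen <- bands$center_px[det]
      for (idx in seq_along(det)) {
        j <- det[idx]
        lo <- bands$center_px[j] - 3 * band_sigma_px
        hi <- bands$center_px[j] + 3 * band_sigma_px
        others <- cen[-idx]
        for (o in others) {  # truncate at midpoints toward neighbours
          mid <- (bands$center_px[j] + o) / 2
          if (o > bands$center_px[j]) hi <- min(hi, mid) else lo <- max(lo, mid)
        }
        sel <- pos >= lo & pos <= hi
        bands$integrated_intensity[j] <- sum(y[sel])
      }
    }
  }
  class(bands) <- c("band_table", class(bands))
  bands
}

#' Quantify every lane of a blot
#'
#' Full densitometry chain per lane: profile extraction, background
#' subtraction, band detection/integration, loading normalisation and
#' mature/immature ratio.
#'
#' @param blot A [blot_sim] object, or a matrix with `lane_bounds`,
#'   `lane_info` and `calibration` supplied.
#' @param lane_bounds,lane_info,calibration Used when `blot` is a plain
#'   matrix: list of column ranges, data frame (lane_id, group, treatment),
#'   and [mw_ladder()].
#' @param band_sigma_px Band SD (px).
#' @param method Integration method, see [detect_and_integrate_bands()].
#' @return Data frame of class `lane_quant`: lane_id, group, treatment,
#'   upper, lower, total_target, loading, norm_expression,
#'   ratio_upper_lower (NA with `ratio_flag` when the lower band is at or
#'   below the detection floor), flags.
#' @export
quantify_lanes <- function(blot, lane_bounds = NULL, lane_info = NULL,
                           calibration = NULL, band_sigma_px = 4,
                           method = "fit") {
  if (inherits(blot, "blot_sim")) {
    lane_bounds <- blot$lane_bounds
    lane_info <- blot$truth[, c("lane_id", "group", "treatment")]
    calibration <- blot$ladder
    band_sigma_px <- blot$band_sigma_px
    image <- blot$image
  } else image <- blot
  stopifnot(is.matrix(image), !is.null(lane_bounds), !is.null(calibration))
  rows <- lapply(seq_along(lane_bounds), function(k) {
    prof <- extract_lane_profile(image, lane_bounds[[k]],
                                 lane_id = lane_info$lane_id[k],
                                 calibration = calibration)
    prof <- subtract_background(prof, band_sigma_px)
    bands <- detect_and_integrate_bands(prof, band_sigma_px = band_sigma_px,
                                        method = method)
    get <- function(lab) bands$integrated_intensity[bands$label == lab]
    present <- function(lab) bands$present[bands$label == lab]
    upper <- get("upper"); lower <- get("lower"); loading <- get("loading")
    ratio <- if (present("lower") && lower > 0) upper / lower else NA_real_
    data.frame(lane_id = lane_info$lane_id[k], group = lane_info$group[k],
               treatment = lane_info$treatment[k],
               upper = upper, lower = lower,
               total_target = upper + lower, loading = loading,
               norm_expression = if (loading > 0)
                 (upper + lower) / loading else NA_real_,
               ratio_upper_lower = ratio,
               ratio_flag = if (is.na(ratio)) "lower_band_below_floor" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lane_quant", class(out))
  out
}

#' Mature/immature band ratio of a quantified lane
#'
#' @param lane One row of a [quantify_lanes()] table (or any list with
#'   `upper` and `lower`).
#' @return upper/lower, or `NA` with a warning when the lower band is absent
#'   or at zero (never infinity).
#' @export
band_ratio <- function(lane) {
  if (is.na(lane$lower) || lane$lower <= 0) {
    warning("lower band at or below the detection floor; ratio undefined")
    return(NA_real_)
  }
  lane$upper / lane$lower
}

#' Normalise lane expression to a reference condition
#'
#' Divides each lane's loading-normalised expression by the mean
#' loading-normalised expression of the reference lanes (non-transfected
#' lanes are never used as reference).
#'
#' @param lanes A [quantify_lanes()] table.
#' @param reference Logical vector selecting reference lanes, or a function
#'   of the table returning one. Default: untreated WT lanes.
#' @return The table with a `fold_change` column appended.
#' @export
normalize_to_reference <- function(lanes,
                                   reference = function(df)
                                     df$group == "WT" & df$treatment == "none") {
  stopifnot(is.data.frame(lanes))
  sel <- if (is.function(reference)) reference(lanes) else reference
  sel <- sel & lanes$group != "NT"
  if (!any(sel)) stop("no reference lanes found", call. = FALSE)
  ref <- mean(lanes$norm_expression[sel], na.rm = TRUE)
  lanes$fold_change <- lanes$norm_expression / ref
  lanes
}
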