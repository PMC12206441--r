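#' @importFrom EBImage gblur otsu fillHull distmap watershed propagate erode
#'   dilate makeBrush bwlabel Image imageData
NULL

as_ebimage <- function(m) EBImage::Image(t(m))          # matrix (row=y) -> Image (x,y)
as_matrix <- function(img) t(EBImage::imageData(img))

norm01 <- function(m) {
  r <- range(m, finite = TRUE)
  if (r[2] <= r[1]) return(list(img = m * 0, flat = TRUE, range = r))
  list(img = (m - r[1]) / (r[2] - r[1]), flat = FALSE, range = r)
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Pipeline: Gaussian smoothing, global (Otsu) threshold, hole filling —
#' which removes dark intra-nuclear features such as nucleoli — then a
#' watershed split of touching nuclei seeded by distance-transform maxima,
#' and a size filter.
#'
#' @param nuclei_channel Matrix (rows = y) of nuclear-stain intensities.
#' @param sigma Smoothing SD (px).
#' @param threshold Absolute threshold on the normalised (0-1) smoothed
#'   image; default Otsu.
#' @param min_area,max_area Object size filter (px^2).
#' @param watershed_tol Watershed tolerance on the distance map.
#' @return Integer label matrix (0 = background). An empty image yields an
#'   all-zero mask.
#' @export
segment_nuclei <- function(nuclei_channel, sigma = 2, threshold = NULL,
                           min_area = 50, max_area = Inf,
                           watershed_tol = 2) {
  stopifnot(is.matrix(nuclei_channel), length(nuclei_channel) > 0)
  nm <- norm01(nuclei_channel)
  if (nm$flat) return(matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)))
  img <- as_ebimage(nm$img)
  sm <- if (sigma > 0) EBImage::gblur(img, sigma = sigma) else img
  th <- threshold %||% EBImage::otsu(sm, range = c(0, 1))
  bw <- sm > th
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = watershed_tol)
  lab <- as_matrix(lab)
  # size filter, then relabel compactly
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area & tab <= max_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

label_centroids <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(id = i, y = mean(w[, 1]), x = mean(w[, 2]))
  }, c(id = 0, y = 0, x = 0)))
}

#' Expand cell bodies from nuclear seeds
#'
#' Cell positions are taken as the nuclei; the cell extent is grown from each
#' nucleus by seeded Voronoi propagation over the cell foreground (threshold
#' on the supplied marker/target channel), capped at `cap_factor` times the
#' median cell radius estimated from the foreground area per nucleus. When
#' the channel carries (almost) no foreground the cells degrade to dilated
#' nuclei and the result is flagged.
#'
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param foreground_channel Matrix used to delimit cell extent (sum of
#'   membrane-marker and target channels works well).
#' @param cap_factor Multiplier on the median cell radius bounding the
#'   expansion.
#' @param fg_threshold Absolute threshold on the normalised (0-1) smoothed
#'   channel. The default separates any cell signal from background:
#'   background median + 3 x MAD (the dim cytoplasm must be kept, so the
#'   bimodal Otsu split — which lands between cytoplasm and the bright
#'   membrane ring — is not appropriate here).
#' @param sigma Smoothing SD before thresholding (px).
#' @param lambda Propagation regularisation (EBImage::propagate).
#' @return List: `cell_labels` (integer matrix; label k contains nucleus k),
#'   `median_cell_radius_px`, `flags` (character).
#' @export
segment_cells <- function(nucleus_labels, foreground_channel,
                          cap_factor = 1.5, fg_threshold = NULL,
                          sigma = 1, lambda = 1e-4) {
  n_nuc <- max(nucleus_labels)
  if (n_nuc < 1)
    stop("no nuclei found upstream; cannot seed cell segmentation",
         call. = FALSE)
  flags <- character(0)
  nm <- norm01(foreground_channel)
  if (nm$flat) {
    fg <- matrix(FALSE, nrow(nucleus_labels), ncol(nucleus_labels))
  } else {
    sm <- if (sigma > 0)
      as_matrix(EBImage::gblur(as_ebimage(nm$img), sigma = sigma))
    else nm$img
    th <- fg_threshold %||%
      (stats::median(sm) + 3 * stats::mad(sm) + 0.005)
    fg <- sm > th
  }
  fg <- fg | nucleus_labels > 0
  # median radius from an equivalent-disc area per nucleus
  med_r <- stats::median(rep(sqrt(sum(fg) / n_nuc / pi), n_nuc))
  if (sum(fg) <= 1.05 * sum(nucleus_labels > 0)) {
    flags <- c(flags, "low_foreground")
    fg <- as_matrix(EBImage::dilate(as_ebimage(nucleus_labels > 0),
                                    EBImage::makeBrush(7, "disc"))) > 0
    med_r <- sqrt(sum(fg) / n_nuc / pi)
  }
  seeds <- as_ebimage(nucleus_labels)
  x <- as_ebimage(if (nm$flat) fg * 1 else nm$img)
  cells <- EBImage::propagate(x, seeds = seeds, mask = as_ebimage(fg),
                              lambda = lambda)
  cells <- as_matrix(cells)
  storage.mode(cells) <- "integer"

  # cap the expansion at cap_factor * median radius from each seed centroid
  cen <- label_centroids(nucleus_labels)
  cap <- cap_factor * med_r
  yy <- row(cells); xx <- col(cells)
  for (i in seq_len(nrow(cen))) {
    id <- cen[i, "id"]
    sel <- cells == id
    far <- sel & sqrt((yy - cen[i, "y"])^2 + (xx - cen[i, "x"])^2) > cap
    cells[far] <- 0L
    # keep only the connected component containing the nucleus
    comp <- as_matrix(EBImage::bwlabel(as_ebimage(cells == id)))
    seed_comp <- unique(comp[nucleus_labels == id & comp > 0])
    if (length(seed_comp)) cells[cells == id & !(comp %in% seed_comp)] <- 0L
  }
  list(cell_labels = cells, median_cell_radius_px = med_r, flags = flags)
}

#' Extract the membrane ring of each cell
#'
#' The candidate ring is the band just inside each cell's boundary, of width
#' `membrane_width_px` plus a small slack absorbing the boundary uncertainty
#' of the cell segmentation; it is intersected with the marker-positive
#' pixels so that cytoplasmic regions (including out-of-plane membrane
#' signal) are excluded. Cells touching the image border get a
#' `partial_ring` flag.
#'
#' @param marker_channel Membrane-marker intensity matrix.
#' @param cell_labels Integer label matrix from [segment_cells()].
#' @param membrane_width_px Ring width (px).
#' @param boundary_slack_px Extra inward width of the candidate band (px),
#'   absorbing the outward bias of intensity-thresholded cell boundaries.
#' @param marker_threshold Absolute threshold on the normalised marker;
#'   default Otsu. If the marker channel is empty the mask is empty and all
#'   cells are flagged.
#' @return List: `membrane_labels` (integer matrix), `flags` (named character
#'   vector per cell id).
#' @export
segment_membrane <- function(marker_channel, cell_labels,
                             membrane_width_px = 3, boundary_slack_px = 3,
                             marker_threshold = NULL) {
  if (max(cell_labels) < 1) stop("no cell labels supplied", call. = FALSE)
  bw <- cell_labels > 0
  r <- membrane_width_px + boundary_slack_px
  brush <- EBImage::makeBrush(2 * r + 1, "disc")
  interior <- as_matrix(EBImage::erode(as_ebimage(bw), brush)) > 0
  band <- bw & !interior

  nm <- norm01(marker_channel)
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  flags <- stats::setNames(rep("", length(ids)), ids)
  if (nm$flat) {
    mem <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
    flags[] <- "no_marker_signal"
  } else {
    th <- marker_threshold %||%
      EBImage::otsu(as_ebimage(nm$img), range = c(0, 1))
    mem <- ifelse(band & nm$img > th, cell_labels, 0L)
    empty <- ids[!ids %in% unique(mem[mem > 0])]
    flags[as.character(empty)] <- "no_marker_signal"
  }
  # border-touching cells
  border_ids <- unique(c(cell_labels[1, ], cell_labels[nrow(cell_labels), ],
                         cell_labels[, 1], cell_labels[, ncol(cell_labels)]))
  border_ids <- border_ids[border_ids > 0]
  flags[as.character(border_ids)] <-
    paste0(flags[as.character(border_ids)], ";partial_ring")
  list(membrane_labels = mem, flags = flags)
}

#' Run the full segmentation chain on a three-channel field
#'
#' Convenience wrapper: [segment_nuclei()] on the nuclear channel,
#' [segment_cells()] seeded by the nuclei on marker + target,
#' [segment_membrane()] on the marker.
#'
#' @param field A [simulate_cell_field()] result or a named list of channel
#'   matrices (`nuclei`, `marker`, `target`).
#' @param sigma,cap_factor,membrane_width_px,min_area Tuning parameters
#'   passed through.
#' @return Object of class `segmentation_result`: nucleus_labels,
#'   cell_labels, membrane_labels, median_cell_radius_px, flags.
#' @export
segment_field <- function(field, sigma = 2, cap_factor = 1.5,
                          membrane_width_px = 3, min_area = 50) {
  ch <- if (inherits(field, "cell_field")) field$channels else field
  nuc <- segment_nuclei(ch$nuclei, sigma = sigma, min_area = min_area)
  cells <- segment_cells(nuc, ch$marker + ch$target, cap_factor = cap_factor)
  mem <- segment_membrane(ch$marker, cells$cell_labels,
                          membrane_width_px = membrane_width_px)
  structure(list(nucleus_labels = nuc, cell_labels = cells$cell_labels,
                 membrane_labels = mem$membrane_labels,
                 median_cell_radius_px = cells$median_cell_radius_px,
                 flags = list(cells = cells$flags, membrane = mem$flags)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d cells (median radius %.1f px)\n",
              max(x$cell_labels), x$median_cell_radius_px))
  invisible(x)
}

#' Per-cell membrane-trafficking metrics
#'
#' The target channel is first background-corrected by subtracting the median
#' intensity of non-cell pixels (clipped at zero). Per cell,
#' `mem_signal_per_area` is the target signal inside the membrane ring
#' divided by the ring area (a.u./px), and `mem_fraction_of_total` is the
#' ring signal divided by the whole-cell target signal.
#'
#' @param target_channel Target-protein intensity matrix.
#' @param seg A [segment_field()] result (or compatible list).
#' @return Data frame: cell_id, total_target, mem_signal_per_area,
#'   mem_fraction_of_total, ring_area_px, flag. Cells with zero total target
#'   get an undefined-fraction flag.
#' @export
quantify_membrane <- function(target_channel, seg) {
  stopifnot(is.matrix(target_channel))
  bgpix <- target_channel[seg$cell_labels == 0]
  bg <- if (length(bgpix)) stats::median(bgpix) else 0
  tc <- pmax(target_channel - bg, 0)
  ids <- sort(unique(seg$cell_labels[seg$cell_labels > 0]))
  rows <- lapply(ids, function(i) {
    cellpx <- seg$cell_labels == i
    ringpx <- seg$membrane_labels == i
    total <- sum(tc[cellpx])
    ring_area <- sum(ringpx)
    ring_sig <- if (ring_area) sum(tc[ringpx]) else 0
    data.frame(cell_id = i,
               total_target = total,
               mem_signal_per_area = if (ring_area) ring_sig / ring_area
                                     else NA_real_,
               mem_fraction_of_total = if (total > 0) ring_sig / total
                                       else NA_real_,
               ring_area_px = ring_area,
               flag = paste0(c(if (total <= 0) "zero_total_target",
                               if (!ring_area) "empty_ring"), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pool per-cell metrics across groups with a positivity filter
#'
#' Mirrors the "positively transfected" selection: cells whose
#' background-corrected total target falls below `positivity_threshold` are
#' excluded before group comparison.
#'
#' @param quants Named list of per-group [quantify_membrane()] tables, or a
#'   single data frame with a `group` column.
#' @param positivity_threshold Minimum total target (a.u.).
#' @return Data frame of retained per-cell rows with `group`.
#' @export
aggregate_cells <- function(quants, positivity_threshold = 0) {
  df <- if (is.data.frame(quants)) quants else
    do.call(rbind, lapply(names(quants), function(g)
      cbind(quants[[g]], group = g, stringsAsFactors = FALSE)))
  if (length(unique(df$group)) < 2)
    stop("need at least two groups", call. = FALSE)
  out <- df[df$total_target >= positivity_threshold, , drop = FALSE]
  empty <- setdiff(unique(df$group), unique(out$group))
  if (length(empty))
    stop(sprintf("group(s) %s empty after positivity filtering",
                 paste(empty, collapse = ", ")), call. = FALSE)
  out
}

#' Intersection-over-union of two masks
#'
#' @param a,b Logical matrices (or coercible).
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
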