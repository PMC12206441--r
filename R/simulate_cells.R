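#' Parameters for a synthetic multichannel cell field
#'
#' Describes a field of round adherent cells imaged in three channels:
#' a nuclear stain (with dark nucleoli), a plasma-membrane marker decorating
#' a ring at each cell's edge, and a target channel whose per-cell signal is
#' split between the membrane ring (fraction `membrane_fraction`) and the
#' cytoplasm.
#'
#' @param n_cells Number of cells to place.
#' @param image_shape Image size in pixels, c(rows, cols).
#' @param nucleus_radius_px,nucleus_radius_jitter Mean nuclear radius and
#'   uniform jitter (px); nuclei are drawn as ellipses (axis ratio ~0.85)
#'   strictly inside their cell.
#' @param cell_radius_px,cell_radius_jitter Mean cell radius and jitter (px).
#' @param membrane_width_px Membrane ring thickness (px).
#' @param total_expression Mean per-cell target intensity (a.u., summed over
#'   the cell); `expression_cv` adds between-cell lognormal-ish variation.
#' @param expression_cv Coefficient of variation of per-cell expression.
#' @param membrane_fraction Fraction of each cell's target signal on its
#'   membrane ring, in \[0, 1\].
#' @param nuclear_intensity Nuclear-stain intensity (a.u./px).
#' @param marker_intensity Membrane-marker ring intensity (a.u./px).
#' @param n_nucleoli,nucleoli_contrast,nucleoli_radius_px Count, fractional
#'   darkening and radius of the dark intra-nuclear spots.
#' @param noise_sd Additive Gaussian noise SD per pixel (a.u.).
#' @param poisson_scale If > 0, photon-counting noise: each channel is
#'   replaced by rpois(pixel * scale) / scale.
#' @param non_overlap Require cells (rings included) not to overlap.
#' @param seed RNG seed.
#' @param group Group label.
#' @return Object of class `cell_field_sim_params`.
#' @export
cell_field_sim_params <- function(n_cells = 10, image_shape = c(384, 384),
                                  nucleus_radius_px = 10,
                                  nucleus_radius_jitter = 1.5,
                                  cell_radius_px = 26,
                                  cell_radius_jitter = 3,
                                  membrane_width_px = 3,
                                  total_expression = 5e4,
                                  expression_cv = 0.2,
                                  membrane_fraction = 0.5,
                                  nuclear_intensity = 100,
                                  marker_intensity = 80,
                                  n_nucleoli = 2, nucleoli_contrast = 0.6,
                                  nucleoli_radius_px = 2.5,
                                  noise_sd = 0, poisson_scale = 0,
                                  non_overlap = TRUE, seed = 1,
                                  group = "other") {
  stopifnot_frac(membrane_fraction, "membrane_fraction")
  stopifnot_pos(n_cells, "n_cells")
  stopifnot_pos(cell_radius_px, "cell_radius_px")
  stopifnot_pos(nucleus_radius_px, "nucleus_radius_px")
  stopifnot_pos(membrane_width_px, "membrane_width_px")
  stopifnot_pos(total_expression, "total_expression", strict = FALSE)
  if (nucleus_radius_px + nucleus_radius_jitter >=
      cell_radius_px - cell_radius_jitter - membrane_width_px)
    stop("nucleus cannot fit strictly inside the cell", call. = FALSE)
  structure(as.list(environment()), class = "cell_field_sim_params")
}

#' Simulate a three-channel field of cells with ground truth
#'
#' Channel 1 holds the nuclear stain (filled ellipses with dark nucleoli
#' spots), channel 2 the membrane-marker rings, channel 3 the target protein:
#' `membrane_fraction` of each cell's total intensity spread uniformly over
#' its ring and the remainder uniformly over its cytoplasm (interior
#' excluding nucleus and ring). Per-cell label masks (nucleus, whole cell,
#' membrane ring) and true per-cell quantities are returned as ground truth.
#'
#' @param params A [cell_field_sim_params()] object.
#' @param max_attempts Placement attempts per cell before a packing error.
#' @return Object of class `cell_field`: list with `channels`
#'   (list nuclei/marker/target of matrices), `masks` (nucleus_labels,
#'   cell_labels, membrane_labels; integer matrices, background 0), `truth`
#'   (data frame: cell_id, cx, cy, r_cell, r_nucleus, total_expression,
#'   membrane_fraction), and `params`.
#' @examples
#' f <- simulate_cell_field(cell_field_sim_params(n_cells = 3, seed = 2))
#' sum(f$channels$target) / sum(f$truth$total_expression)
#' @export
simulate_cell_field <- function(params, max_attempts = 200) {
  stopifnot(inherits(params, "cell_field_sim_params"))
  p <- params
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  with_seed(p$seed, {
    r_cell <- p$cell_radius_px +
      stats::runif(p$n_cells, -p$cell_radius_jitter, p$cell_radius_jitter)
    r_nuc <- p$nucleus_radius_px +
      stats::runif(p$n_cells, -p$nucleus_radius_jitter, p$nucleus_radius_jitter)
    expr <- p$total_expression *
      pmax(0.05, 1 + stats::rnorm(p$n_cells, 0, p$expression_cv))

    # rejection-sample non-overlapping centres
    margin <- r_cell + 2
    cx <- cy <- numeric(p$n_cells)
    for (k in seq_len(p$n_cells)) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        x <- stats::runif(1, margin[k], nc - margin[k])
        y <- stats::runif(1, margin[k], nr - margin[k])
        if (!p$non_overlap || k == 1 ||
            all(sqrt((cx[seq_len(k - 1)] - x)^2 +
                     (cy[seq_len(k - 1)] - y)^2) >
                r_cell[seq_len(k - 1)] + r_cell[k] + 3)) {
          cx[k] <- x; cy[k] <- y; ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf("could not place cell %d without overlap after %d attempts; enlarge the image or reduce n_cells",
                     k, max_attempts), call. = FALSE)
    }

    chan <- list(nuclei = matrix(0, nr, nc), marker = matrix(0, nr, nc),
                 target = matrix(0, nr, nc))
    masks <- list(nucleus_labels = matrix(0L, nr, nc),
                  cell_labels = matrix(0L, nr, nc),
                  membrane_labels = matrix(0L, nr, nc))

    for (k in seq_len(p$n_cells)) {
      # local bounding box
      rr <- max(1, floor(cy[k] - r_cell[k] - 1)):min(nr, ceiling(cy[k] + r_cell[k] + 1))
      cc <- max(1, floor(cx[k] - r_cell[k] - 1)):min(nc, ceiling(cx[k] + r_cell[k] + 1))
      d <- sqrt(outer((rr - cy[k])^2, (cc - cx[k])^2, `+`))
      cell <- d <= r_cell[k]
      ring <- cell & d > r_cell[k] - p$membrane_width_px

      # nucleus: ellipse strictly inside the cell, small random offset
      max_off <- max(0, r_cell[k] - p$membrane_width_px - r_nuc[k] - 2)
      off <- stats::runif(2, -1, 1) * min(max_off, 3)
      th <- stats::runif(1, 0, pi)
      a_ax <- r_nuc[k]; b_ax <- 0.85 * r_nuc[k]
      dy <- outer(rr - (cy[k] + off[2]), rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - (cx[k] + off[1]))
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      nucleus <- (u / a_ax)^2 + (v / b_ax)^2 <= 1
      cyto <- cell & !ring & !nucleus

      nuc_img <- ifelse(nucleus, p$nuclear_intensity, 0)
      if (p$n_nucleoli > 0) {
        for (s in seq_len(p$n_nucleoli)) {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, 0.5 * b_ax)
          sx <- cx[k] + off[1] + rad * cos(ang)
          sy <- cy[k] + off[2] + rad * sin(ang)
          ds <- sqrt(outer((rr - sy)^2, (cc - sx)^2, `+`))
          spot <- nucleus & ds <= p$nucleoli_radius_px
          nuc_img[spot] <- nuc_img[spot] * (1 - p$nucleoli_contrast)
        }
      }

      n_ring <- sum(ring); n_cyto <- sum(cyto)
      tgt <- matrix(0, length(rr), length(cc))
      if (n_ring > 0) tgt[ring] <- p$membrane_fraction * expr[k] / n_ring
      if (n_cyto > 0) tgt[cyto] <- (1 - p$membrane_fraction) * expr[k] / n_cyto

      chan$nuclei[rr, cc] <- chan$nuclei[rr, cc] + nuc_img
      chan$marker[rr, cc][ring] <- p$marker_intensity
      chan$target[rr, cc] <- chan$target[rr, cc] + tgt
      masks$nucleus_labels[rr, cc][nucleus] <- k
      masks$cell_labels[rr, cc][cell] <- k
      masks$membrane_labels[rr, cc][ring] <- k
    }

    if (p$poisson_scale > 0)
      chan <- lapply(chan, function(m)
        matrix(stats::rpois(length(m), pmax(m, 0) * p$poisson_scale) /
                 p$poisson_scale, nr, nc))
    if (p$noise_sd > 0)
      chan <- lapply(chan, function(m)
        m + matrix(stats::rnorm(length(m), 0, p$noise_sd), nr, nc))

    truth <- data.frame(cell_id = seq_len(p$n_cells), cx = cx, cy = cy,
                        r_cell = r_cell, r_nucleus = r_nuc,
                        total_expression = expr,
                        membrane_fraction = p$membrane_fraction)
    structure(list(channels = chan, masks = masks, truth = truth, params = p),
              class = "cell_field")
  })
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> %d cells in a %d x %d px field (group %s)\n",
              nrow(x$truth), x$params$image_shape[1], x$params$image_shape[2],
              x$params$group))
  invisible(x)
}
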