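#' Write / read a ramp recording as CSV
#'
#' Traces use the plain-text exchange format `time_s, v_mV, i_pA`; cell
#' metadata (cell_id, capacitance_pf, condition, group, sampling_hz) travel
#' in a sidecar CSV next to the traces.
#'
#' @param rec A `ramp_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ramp_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ramp_recording"))
  utils::write.csv(data.frame(time_s = rec$time, v_mV = rec$v_cmd,
                              i_pA = rec$i),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ramp_csv
#' @param capacitance_pf,condition,cell_id,sampling_hz,group Metadata for the
#'   recording being read (e.g. from a sidecar table).
#' @export
read_ramp_csv <- function(path, capacitance_pf, condition = "control",
                          cell_id = basename(path), sampling_hz = NULL,
                          group = "other") {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "v_mV", "i_pA") %in% names(df)))
  if (is.null(sampling_hz))
    sampling_hz <- 1 / stats::median(diff(df$time_s))
  new_ramp_recording(df$time_s, df$v_mV, df$i_pA, capacitance_pf, condition,
                     cell_id, sampling_hz, group)
}

#' Write a sidecar metadata table for a set of ramp recordings
#'
#' @param sim A `ramp_sim`.
#' @param dir Output directory; traces go to `<cell_id>_<condition>.csv`.
#' @return The metadata data frame, invisibly.
#' @export
write_ramp_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ramp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(sim$recordings, function(pr) {
    rows <- lapply(pr, function(r) {
      f <- sprintf("%s_%s.csv", r$cell_id, sub("2\\+", "", r$condition))
      write_ramp_csv(r, file.path(dir, f))
      data.frame(file = f, cell_id = r$cell_id, condition = r$condition,
                 capacitance_pf = r$capacitance_pf, group = r$group,
                 sampling_hz = r$sampling_hz, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  meta <- do.call(rbind, meta)
  utils::write.csv(meta, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read paired ramp recordings from a directory with a `cells.csv` sidecar
#'
#' @param dir Directory written by [write_ramp_sim()] (or hand-assembled with
#'   the same layout).
#' @return A list of per-cell `list(control=, ba=)` pairs, usable by
#'   [summarize_ramp_cells()].
#' @export
read_ramp_dir <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "cells.csv"))
  ids <- unique(meta$cell_id)
  lapply(ids, function(id) {
    m <- meta[meta$cell_id == id, ]
    get <- function(cond) {
      r <- m[m$condition == cond, ]
      if (nrow(r) != 1)
        stop(sprintf("cell %s: missing or duplicated %s sweep", id, cond),
             call. = FALSE)
      read_ramp_csv(file.path(dir, r$file), r$capacitance_pf, cond, id,
                    r$sampling_hz, r$group)
    }
    list(control = get("control"), ba = get("ba2+"))
  })
}

#' Write / read a multichannel field as multi-page TIFF
#'
#' Channel order: nuclei, marker, target (one 32-bit float page each).
#'
#' @param field A `cell_field` or named list of channel matrices.
#' @param path TIFF path.
#' @return `path` invisibly; `read_field_tiff()` returns a named channel list.
#' @export
write_field_tiff <- function(field, path) {
  ch <- if (inherits(field, "cell_field")) field$channels else field
  scale <- max(1, max(unlist(lapply(ch, max))))
  tiff::writeTIFF(lapply(ch[c("nuclei", "marker", "target")],
                         function(m) m / scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stats::setNames(lapply(pages, function(p)
    if (length(dim(p)) == 3) p[, , 1] else p),
    c("nuclei", "marker", "target")[seq_along(pages)])
}

#' Write labelled masks as 16-bit TIFF
#'
#' @param masks Named list of integer label matrices.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_mask_tiffs <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(masks), function(nm) {
    p <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(masks[[nm]] / 65535, p, bits.per.sample = 16L)
    p
  }, "")
  invisible(paths)
}

#' Read a simulation preset list from YAML
#'
#' Presets are named lists of arguments for [ephys_sim_params()],
#' [blot_sim_params()] or [cell_field_sim_params()], keyed by preset name
#' under the top-level keys `ephys`, `blot`, `cells`.
#'
#' @param path YAML file path.
#' @return Nested list of presets.
#' @export
read_presets_yaml <- function(path) yaml::read_yaml(path)
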