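#' Significance stars at the conventional cutoffs
#'
#' Strict-inequality thresholding: `*` for p < 0.05, `**` for p < 0.01,
#' `***` for p < 0.001, `****` for p < 0.0001, otherwise `"ns"` (so exactly
#' p = 0.05 is not significant).
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of star annotations.
#' @export
star_annotation <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  vapply(p, function(x) {
    if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else "ns"
  }, "")
}

new_group_comparison <- function(groups, n, statistic, stat_name, p, test) {
  structure(list(groups = groups, n_per_group = n, statistic = statistic,
                 stat_name = stat_name, p_value = p,
                 stars = star_annotation(p), test = test),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s  %s = %.4g, p = %.4g (%s)\n", x$test,
              paste(x$groups, collapse = " vs "), x$stat_name, x$statistic,
              x$p_value, x$stars))
  invisible(x)
}

#' Unpaired two-sample t test
#'
#' Classical two-sided Student t test with pooled variance (the default);
#' `var_equal = FALSE` gives the Welch form. Degenerate zero-variance data
#' are handled by contract (matching [anova_oneway()]): identical constant
#' groups give t = 0, p = 1; distinct constant groups give t = +/-Inf, p = 0.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param labels Group labels for reporting.
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @return A `group_comparison` object (statistic, p_value, stars).
#' @export
t_unpaired <- function(a, b, labels = c("a", "b"), var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  test <- if (var_equal) "t_unpaired" else "t_welch"
  if (stats::var(a) + stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    return(new_group_comparison(labels, c(length(a), length(b)),
                                if (d == 0) 0 else sign(d) * Inf, "t",
                                if (d == 0) 1 else 0, test))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  new_group_comparison(labels, c(length(a), length(b)),
                       unname(ht$statistic), "t", ht$p.value, test)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from between/within mean squares.
#' Computed directly so that degenerate data are handled by contract:
#' all observations identical gives F = 0, p = 1 (rather than NaN), and
#' groups with zero internal variance are allowed.
#'
#' @param groups A list of numeric samples (>= 2 groups, each n >= 2), or a
#'   numeric vector when `labels` gives the group of each value.
#' @param labels Optional group membership vector.
#' @return A `group_comparison` object with the F statistic.
#' @export
anova_oneway <- function(groups, labels = NULL) {
  if (!is.list(groups)) {
    stopifnot(!is.null(labels), length(labels) == length(groups))
    groups <- split(groups, labels)
  }
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  n <- vapply(groups, length, 0L)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  gm <- mean(x)
  means <- vapply(groups, mean, 0)
  ss_b <- sum(n * (means - gm)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1L
  df_w <- length(x) - length(groups)
  if (ss_b == 0) {
    f <- 0; p <- 1
  } else if (ss_w == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  new_group_comparison(names(groups) %||% paste0("g", seq_along(groups)),
                       n, f, "F", p, "anova_oneway")
}

#' Per-voltage multiple t tests on chord-conductance curves
#'
#' Compares two groups of [chord_conductance()] curves voltage-by-voltage
#' with unpaired t tests (no multiple-testing correction, by design). A
#' two-factor (group x voltage) ANOVA on the pooled curve data is available
#' via `method = "anova_twoway"`.
#'
#' @param curves_a,curves_b Lists of `chord_conductance_curve` objects.
#' @param labels Group labels.
#' @param method "t_multiple" (default) or "anova_twoway".
#' @return For "t_multiple": data frame (v, t, p, stars). For
#'   "anova_twoway": a `group_comparison` for the group main effect.
#' @export
compare_conductance <- function(curves_a, curves_b, labels = c("a", "b"),
                                method = c("t_multiple", "anova_twoway")) {
  method <- match.arg(method)
  va <- curves_a[[1]]$v
  stopifnot(all(vapply(c(curves_a, curves_b),
                       function(cc) identical(cc$v, va), TRUE)))
  ga <- vapply(curves_a, `[[`, numeric(length(va)), "g")
  gb <- vapply(curves_b, `[[`, numeric(length(va)), "g")
  if (method == "t_multiple") {
    res <- lapply(seq_along(va), function(j) {
      ht <- stats::t.test(ga[j, ], gb[j, ], var.equal = TRUE)
      data.frame(v = va[j], t = unname(ht$statistic), p = ht$p.value)
    })
    out <- do.call(rbind, res)
    out$stars <- star_annotation(out$p)
    out
  } else {
    long <- data.frame(
      g = c(as.vector(ga), as.vector(gb)),
      v = factor(c(rep(va, ncol(ga)), rep(va, ncol(gb)))),
      grp = factor(rep(labels, c(length(ga), length(gb)))))
    fit <- stats::aov(g ~ grp + v, data = long)
    tab <- summary(fit)[[1]]
    new_group_comparison(labels, c(ncol(ga), ncol(gb)),
                         tab["grp", "F value"], "F", tab["grp", "Pr(>F)"],
                         "anova_twoway")
  }
}

comparison_row <- function(cmp, arm, metric) {
  data.frame(arm = arm, metric = metric,
             groups = paste(cmp$groups, collapse = " vs "),
             n = paste(cmp$n_per_group, collapse = "/"),
             test = cmp$test, statistic = cmp$statistic,
             p_value = cmp$p_value, stars = cmp$stars,
             stringsAsFactors = FALSE)
}

#' Assemble the pipeline's summary report
#'
#' Writes one CSV per analysis arm present (ephys group summary, blot
#' fold-change table, per-cell trafficking metrics) plus a combined
#' group-comparisons CSV, with deterministic column and row order; the seed
#' and configuration are echoed into `run_info.csv` for provenance. Reruns
#' with the same inputs are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param ephys Optional per-cell table from [summarize_ramp_cells()].
#' @param blot Optional [normalize_to_reference()] table.
#' @param cells Optional [aggregate_cells()] table.
#' @param seed,config Echoed into `run_info.csv`.
#' @return Invisibly, a named list of the tables written (including
#'   `comparisons`).
#' @export
build_report <- function(out_dir, ephys = NULL, blot = NULL, cells = NULL,
                         seed = NULL, config = list()) {
  if (is.null(ephys) && is.null(blot) && is.null(cells))
    stop("at least one analysis arm required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    df
  }
  out <- list()
  cmps <- list()
  two_groups <- function(df, col) {
    gs <- intersect(c("WT", "MT"), unique(df$group))
    if (length(gs) == 2)
      list(a = df[[col]][df$group == "WT"], b = df[[col]][df$group == "MT"])
  }
  if (!is.null(ephys)) {
    ephys <- ephys[order(ephys$group, ephys$cell_id), , drop = FALSE]
    out$ephys_cells <- wr(ephys, "ephys_cells.csv")
    out$ephys_groups <- wr(as.data.frame(summarize_groups(ephys)),
                           "ephys_groups.csv")
    tg <- two_groups(ephys, "cd_pa_per_pf")
    if (!is.null(tg))
      cmps$ephys <- comparison_row(
        t_unpaired(tg$a, tg$b, c("WT", "MT")), "ephys", "cd_pa_per_pf")
  }
  if (!is.null(blot)) {
    blot <- blot[order(blot$group, blot$lane_id), , drop = FALSE]
    out$blot_lanes <- wr(blot, "blot_lanes.csv")
    tg <- two_groups(blot, "fold_change")
    if (!is.null(tg))
      cmps$blot <- comparison_row(
        t_unpaired(tg$a, tg$b, c("WT", "MT")), "blot", "fold_change")
  }
  if (!is.null(cells)) {
    cells <- cells[order(cells$group, cells$cell_id), , drop = FALSE]
    out$trafficking_cells <- wr(cells, "trafficking_cells.csv")
    for (metric in c("mem_signal_per_area", "mem_fraction_of_total")) {
      tg <- two_groups(cells[is.finite(cells[[metric]]), ], metric)
      if (!is.null(tg))
        cmps[[paste0("cells_", metric)]] <- comparison_row(
          t_unpaired(tg$a, tg$b, c("WT", "MT")), "imaging", metric)
    }
  }
  if (length(cmps))
    out$comparisons <- wr(do.call(rbind, cmps), "comparisons.csv")
  info <- data.frame(key = c("seed", names(config)),
                     value = c(if (is.null(seed)) "" else as.character(seed),
                               vapply(config, function(v)
                                 paste(format(v), collapse = ";"), "")),
                     stringsAsFactors = FALSE)
  wr(info, "run_info.csv")
  invisible(out)
}
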