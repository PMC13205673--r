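#' Per-axis difference records from a manifest and measurements
#'
#' Joins ground truth and measured migrations on \code{followup_id} and
#' unrolls them into one record per (follow-up, axis), with the signed
#' difference defined as ground truth minus measurement.
#'
#' @param manifest manifest data.frame ([build_manifest()] /
#'   [read_manifest()]).
#' @param measured data.frame with columns \code{followup_id, mx_mm, my_mm,
#'   mz_mm} (as from [measure_followups()]).
#' @param quantity "translation" (default) or "rotation_deg" for externally
#'   supplied rotation differences.
#' @return data.frame with columns \code{followup_id, axis, truth_mm,
#'   measured_mm, diff_mm, generating_axes, quantity}.
#' @export
difference_records <- function(manifest, measured, quantity = "translation") {
  missing_ids <- setdiff(manifest$followup_id, measured$followup_id)
  extra_ids <- setdiff(measured$followup_id, manifest$followup_id)
  if (length(missing_ids) || length(extra_ids))
    stop("manifest/measured ids do not match; unmatched: ",
         paste(c(missing_ids, extra_ids), collapse = ", "))
  m <- merge(manifest, measured, by = "followup_id", sort = FALSE)
  truth_cols <- c("truth_x_mm", "truth_y_mm", "truth_z_mm")
  meas_cols <- c("mx_mm", "my_mm", "mz_mm")
  out <- do.call(rbind, lapply(1:3, function(a) {
    data.frame(followup_id = m$followup_id, axis = .AXES[a],
               truth_mm = m[[truth_cols[a]]], measured_mm = m[[meas_cols[a]]],
               diff_mm = m[[truth_cols[a]]] - m[[meas_cols[a]]],
               generating_axes = m$generating_axes, quantity = quantity,
               stringsAsFactors = FALSE)
  }))
  out[order(match(out$followup_id, manifest$followup_id)), ]
}

#' Summary statistics of migration differences
#'
#' Mean, sample SD (n - 1 denominator), min and max of the differences over
#' a selection of records.  With a single record the SD is undefined and
#' reported as 0 with \code{flagged = TRUE}.
#'
#' @param records data.frame from [difference_records()].
#' @param axis optional axis filter ("x", "y" or "z").
#' @param subset optional logical vector over rows of \code{records}.
#' @return List of class \code{summary_stats}: \code{n, mean, sd, min, max,
#'   flagged}.
#' @export
summarize_differences <- function(records, axis = NULL, subset = NULL) {
  sel <- records
  if (!is.null(subset)) sel <- sel[subset, , drop = FALSE]
  if (!is.null(axis)) sel <- sel[sel$axis == axis, , drop = FALSE]
  if (nrow(sel) == 0L) stop("empty selection")
  d <- sel$diff_mm
  flagged <- length(d) == 1L
  structure(list(n = length(d), mean = mean(d),
                 sd = if (flagged) 0 else sd(d),
                 min = min(d), max = max(d), flagged = flagged),
            class = "summary_stats")
}

#' Zero-migration precision (1.96 x SD)
#'
#' Precision of the measurement on an axis with no true migration, defined
#' as 1.96 times the sample SD of the differences - the half-width of the
#' 95% interval.  Every selected record must have zero ground truth on the
#' axis.
#'
#' @param records data.frame of difference records for one axis, typically
#'   built from one pool of [zero_migration_pool()].
#' @param axis the axis being evaluated.
#' @return List of class \code{precision_result}: \code{n, mean, sd, min,
#'   max, precision}.
#' @export
precision_zero <- function(records, axis) {
  sel <- records[records$axis == axis, , drop = FALSE]
  if (nrow(sel) == 0L) stop("empty selection")
  if (any(sel$truth_mm != 0))
    stop("contract violation: nonzero ground truth on axis ", axis,
         " in the zero-migration pool")
  s <- summarize_differences(sel)
  structure(list(n = s$n, mean = s$mean, sd = s$sd, min = s$min, max = s$max,
                 precision = 1.96 * s$sd),
            class = "precision_result")
}

#' Bland-Altman agreement between ground truth and measurement
#'
#' Differences are ground truth minus measurement.  Limits of agreement are
#' mean difference +/- 1.96 x SD.  The 95% CI of the mean difference uses
#' SD/sqrt(n); the CI of each limit uses the standard Bland-Altman
#' approximation SD x sqrt(3/n).  The returned plot-ready arrays put the
#' amount of migration (ground truth) on the abscissa.
#'
#' @param truth,measured equal-length numeric vectors (n >= 2).
#' @return List of class \code{bland_altman_result}: \code{n, mean_diff,
#'   sd_diff, loa_low, loa_high, ci_mean, ci_loa_low, ci_loa_high, plot}
#'   (data.frame with \code{migration}, \code{difference}).
#' @export
bland_altman <- function(truth, measured) {
  if (length(truth) != length(measured))
    stop("truth and measured must have equal length")
  n <- length(truth)
  if (n < 2L) stop("need at least 2 paired values")
  d <- truth - measured
  m <- mean(d)
  s <- sd(d)
  half_mean <- 1.96 * s / sqrt(n)
  half_loa <- 1.96 * s * sqrt(3 / n)
  structure(list(n = n, mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 ci_mean = c(m - half_mean, m + half_mean),
                 ci_loa_low = c(m - 1.96 * s - half_loa,
                                m - 1.96 * s + half_loa),
                 ci_loa_high = c(m + 1.96 * s - half_loa,
                                 m + 1.96 * s + half_loa),
                 plot = data.frame(migration = truth, difference = d)),
            class = "bland_altman_result")
}

#' Q-Q plot data for normality assessment
#'
#' Theoretical normal quantiles at probability points (i - 0.5)/n, scaled by
#' the sample mean and SD, paired with the ordered sample.
#'
#' @param diffs numeric vector, n >= 3.
#' @return List with \code{theoretical}, \code{sample} (both sorted
#'   ascending) and \code{degenerate} (TRUE when the sample SD is zero).
#' @export
qq_data <- function(diffs) {
  n <- length(diffs)
  if (n < 3L) stop("need at least 3 values for a Q-Q plot")
  s <- sort(diffs)
  mu <- mean(diffs)
  sdv <- sd(diffs)
  p <- (seq_len(n) - 0.5) / n
  list(theoretical = mu + sdv * qnorm(p), sample = s,
       degenerate = sdv == 0)
}

.stats_row <- function(label, axis, s, precision = NULL) {
  row <- data.frame(value = label, axis = axis, n = s$n, mean = s$mean,
                    sd = s$sd, min = s$min, max = s$max,
                    stringsAsFactors = FALSE)
  if (!is.null(precision)) row$precision <- precision
  row
}

#' Study-style report tables
#'
#' Builds the full evaluation table set from a manifest and measured
#' migrations: per-axis difference summaries for each one-axis family, the
#' two-axis family, all data combined, the zero-migration precision table
#' (with the per-axis pool sizes), and - when rotation differences are
#' supplied - the zero-rotation precision table.
#'
#' @param manifest manifest data.frame.
#' @param measured measured data.frame (see [difference_records()]).
#' @param rotation optional data.frame of externally supplied rotation
#'   differences with columns \code{followup_id, axis, diff_deg}.
#' @return Named list of data.frames: \code{one_axis_x, one_axis_y,
#'   one_axis_z, two_axis, combined, zero_precision} and optionally
#'   \code{rotation_precision}.  All values at full precision; see
#'   [write_report_tables()] for 3-decimal display output.
#' @export
report_tables <- function(manifest, measured, rotation = NULL) {
  rec <- difference_records(manifest, measured)
  fam <- function(ids) rec[rec$followup_id %in% ids, , drop = FALSE]
  tables <- list()
  for (a in .AXES) {
    ids <- manifest$followup_id[manifest$generating_axes == a]
    if (!length(ids)) next
    sub <- fam(ids)
    tables[[paste0("one_axis_", a)]] <- do.call(rbind, lapply(.AXES, function(q)
      .stats_row(sprintf("%d follow-up CTs, one-axis %s family", length(ids), a),
                 q, summarize_differences(sub, axis = q))))
  }
  two_ids <- manifest$followup_id[nchar(manifest$generating_axes) != 1L]
  if (length(two_ids)) {
    sub <- fam(two_ids)
    tables$two_axis <- do.call(rbind, lapply(.AXES, function(q)
      .stats_row(sprintf("%d follow-up CTs, two-axis family", length(two_ids)),
                 q, summarize_differences(sub, axis = q))))
  }
  tables$combined <- do.call(rbind, lapply(.AXES, function(q)
    .stats_row(sprintf("%d follow-up CTs, all synthetic migration",
                       nrow(manifest)),
               q, summarize_differences(rec, axis = q))))
  pools <- zero_migration_pool(manifest)
  n_zero <- length(unique(unlist(lapply(pools, `[[`, "followup_id"))))
  tables$zero_precision <- do.call(rbind, lapply(.AXES, function(q) {
    sub <- rec[rec$followup_id %in% pools[[q]]$followup_id & rec$axis == q, ,
               drop = FALSE]
    p <- precision_zero(sub, q)
    .stats_row(sprintf("%d follow-up CTs with zero migration", n_zero),
               q, p, precision = p$precision)
  }))
  if (!is.null(rotation)) {
    stopifnot(all(c("followup_id", "axis", "diff_deg") %in% names(rotation)))
    tables$rotation_precision <- do.call(rbind, lapply(.AXES, function(q) {
      d <- rotation$diff_deg[rotation$axis == q]
      if (!length(d)) stop("no rotation differences for axis ", q)
      s <- list(n = length(d), mean = mean(d),
                sd = if (length(d) > 1) sd(d) else 0, min = min(d),
                max = max(d))
      .stats_row(sprintf("%d follow-up CTs with zero rotation", length(d)),
                 q, s, precision = 1.96 * s$sd)
    }))
  }
  tables
}

#' Write report tables as CSV with 3-decimal display rounding
#'
#' @param tables list from [report_tables()].
#' @param dir output directory (created if missing).
#' @param digits display rounding for mm/degree columns.
#' @return Character vector of written paths, invisibly.
#' @export
write_report_tables <- function(tables, dir, digits = 3) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    for (cc in c("mean", "sd", "min", "max", "precision"))
      if (cc %in% names(tab)) tab[[cc]] <- round(tab[[cc]], digits)
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
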