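#' Shift protocol configuration
#'
#' The default protocol takes one-voxel steps from -4 to +4 along x and z,
#' -5 to +5 along y (the stem axis, where the voxel spacing is smallest),
#' and diagonal two-axis steps (a, +/-a) up to +/-4 on the three axis pairs.
#'
#' @param max_xz maximum one-axis step along x and z (voxels).
#' @param max_y maximum one-axis step along y (voxels).
#' @param two_axis_max maximum step magnitude in the two-axis families.
#' @param axis_pairs list of axis pairs for the two-axis families.
#' @param include_zero_per_axis include the zero shift in each one-axis
#'   family.
#' @param include_two_axis_zero include one all-zero shift in the two-axis
#'   family.
#' @return An object of class \code{protocol_config}.
#' @export
protocol_config <- function(max_xz = 4L, max_y = 5L, two_axis_max = 4L,
                            axis_pairs = list(c("x", "y"), c("x", "z"),
                                              c("y", "z")),
                            include_zero_per_axis = TRUE,
                            include_two_axis_zero = TRUE) {
  stopifnot(max_xz >= 1, max_y >= 1, two_axis_max >= 1)
  for (p in axis_pairs) .axis_index(p)
  structure(list(max_xz = as.integer(max_xz), max_y = as.integer(max_y),
                 two_axis_max = as.integer(two_axis_max),
                 axis_pairs = axis_pairs,
                 include_zero_per_axis = isTRUE(include_zero_per_axis),
                 include_two_axis_zero = isTRUE(include_two_axis_zero)),
            class = "protocol_config")
}

.shift_df <- function(generating_axes, dx, dy, dz) {
  data.frame(generating_axes = generating_axes, dx = as.integer(dx),
             dy = as.integer(dy), dz = as.integer(dz),
             stringsAsFactors = FALSE)
}

#' Enumerate the one-axis shift families
#'
#' For each axis, every integer step from -max to +max (including zero when
#' configured), tagged with the generating axis.  The default yields
#' 9 + 11 + 9 = 29 shifts.
#'
#' @param cfg a [protocol_config()].
#' @return data.frame with columns \code{generating_axes, dx, dy, dz}.
#' @export
one_axis_shifts <- function(cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  out <- list()
  for (a in .AXES) {
    m <- if (a == "y") cfg$max_y else cfg$max_xz
    steps <- seq.int(-m, m)
    if (!cfg$include_zero_per_axis) steps <- steps[steps != 0L]
    d <- matrix(0L, nrow = length(steps), ncol = 3)
    d[, .axis_index(a)] <- steps
    out[[a]] <- .shift_df(a, d[, 1], d[, 2], d[, 3])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Enumerate the two-axis shift family
#'
#' For each axis pair (a, b): all shifts (a_val, b_val) with a_val in
#' -max..max excluding 0 and b_val in {a_val, -a_val} (16 per pair), plus
#' one all-zero shift when configured.  The default yields 3 x 16 + 1 = 49.
#'
#' @param cfg a [protocol_config()].
#' @return data.frame with columns \code{generating_axes, dx, dy, dz}.
#' @export
two_axis_shifts <- function(cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  out <- list()
  for (p in cfg$axis_pairs) {
    ia <- .axis_index(p[1]); ib <- .axis_index(p[2])
    avals <- setdiff(seq.int(-cfg$two_axis_max, cfg$two_axis_max), 0L)
    rows <- expand.grid(a = avals, s = c(1L, -1L))
    d <- matrix(0L, nrow = nrow(rows), ncol = 3)
    d[, ia] <- rows$a
    d[, ib] <- rows$a * rows$s
    out[[paste0(p[1], p[2])]] <- .shift_df(paste0(p[1], p[2]),
                                           d[, 1], d[, 2], d[, 3])
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (cfg$include_two_axis_zero)
    res <- rbind(res, .shift_df("", 0L, 0L, 0L))
  res
}

#' Full shift protocol
#'
#' Concatenation of the one-axis and two-axis families; 29 + 49 = 78 shifts
#' per baseline under the default configuration.
#'
#' @param cfg a [protocol_config()].
#' @return data.frame with columns \code{generating_axes, dx, dy, dz}.
#' @export
full_protocol <- function(cfg = protocol_config()) {
  rbind(one_axis_shifts(cfg), two_axis_shifts(cfg))
}

#' Build a multi-baseline manifest from a shift protocol
#'
#' @param baseline_ids character vector of baseline identifiers.
#' @param shifts shift data.frame from [full_protocol()] (or a sub-family).
#' @param frame_spacing_mm either a single numeric length-3 spacing used for
#'   all baselines, or a list/matrix of per-baseline spacings.
#' @return Manifest data.frame, one row per (baseline, shift), with
#'   follow-up ids of the form \code{baseline_fu001}.
#' @export
build_manifest <- function(baseline_ids, shifts = full_protocol(),
                           frame_spacing_mm = c(1, 1, 1)) {
  if (is.numeric(frame_spacing_mm) && length(frame_spacing_mm) == 3L)
    frame_spacing_mm <- rep(list(frame_spacing_mm), length(baseline_ids))
  stopifnot(length(frame_spacing_mm) == length(baseline_ids))
  ns <- nrow(shifts)
  per <- lapply(seq_along(baseline_ids), function(b) {
    sp <- as.numeric(frame_spacing_mm[[b]])
    data.frame(baseline_id = baseline_ids[b],
               followup_id = sprintf("%s_fu%03d", baseline_ids[b],
                                     seq_len(ns)),
               generating_axes = shifts$generating_axes,
               dx = shifts$dx, dy = shifts$dy, dz = shifts$dz,
               truth_x_mm = shifts$dx * sp[1], truth_y_mm = shifts$dy * sp[2],
               truth_z_mm = shifts$dz * sp[3],
               frame_sx_mm = sp[1], frame_sy_mm = sp[2], frame_sz_mm = sp[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(per, list(make.row.names = FALSE)))
}

#' Zero-migration record pools per axis
#'
#' Precision on an axis is evaluated on follow-ups whose true migration on
#' that axis is zero.  Following the study design, only the one-axis
#' families contribute: the pool for axis q consists of every one-axis
#' record generated along the other two axes (all of which, including their
#' zero shifts, have zero truth on q).  With 10 baselines and the default
#' protocol the pools have sizes x: 200, y: 180, z: 200, drawn from 290
#' distinct zero-migration follow-ups.
#'
#' @param manifest manifest data.frame; two-axis rows are ignored.
#' @return Named list of manifest subsets, one per axis.
#' @export
zero_migration_pool <- function(manifest) {
  one <- manifest[nchar(manifest$generating_axes) == 1L, , drop = FALSE]
  setNames(lapply(.AXES, function(q) {
    one[one$generating_axes != q, , drop = FALSE]
  }), .AXES)
}
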