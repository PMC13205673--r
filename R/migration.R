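#' Integer-voxel shift specification
#'
#' A signed integer translation of the implant in the stem-aligned grid.
#' The protocol bounds (|dx| <= 4, |dy| <= 5, |dz| <= 4 by default) reflect
#' the larger admissible step count along the stem axis, whose voxel spacing
#' is the smallest.
#'
#' @param dx,dy,dz signed integer voxel steps along the stem x, y, z axes.
#' @param generating_axes string recording the protocol family ("x", "y",
#'   "z", a two-letter pair, or "" for the two-axis zero shift).
#' @param max_xz,max_y protocol bounds used for validation.
#' @return An object of class \code{shift_spec}.
#' @export
shift_spec <- function(dx, dy, dz, generating_axes = "",
                       max_xz = 4L, max_y = 5L) {
  d <- as.integer(c(dx, dy, dz))
  if (anyNA(d)) stop("shift components must be integers")
  if (abs(d[1]) > max_xz || abs(d[3]) > max_xz || abs(d[2]) > max_y)
    stop("shift outside protocol bounds (|dx|,|dz| <= ", max_xz,
         ", |dy| <= ", max_y, ")")
  axs <- strsplit(generating_axes, "")[[1]]
  if (length(axs)) .axis_index(axs)
  structure(list(dx = d[1], dy = d[2], dz = d[3],
                 generating_axes = generating_axes),
            class = "shift_spec")
}

#' Vacated-voxel fill configuration
#'
#' After the implant voxels move, the voxels they vacated are filled with the
#' HU of the nearest (Euclidean, mm-scaled) voxel from the donor label set,
#' then smoothed with a mean filter applied to the vacated voxels only.
#'
#' @param fill_source_labels character vector of donor label names
#'   (default soft tissue only; bone never donates by default).
#' @param smoothing_radius_voxels half-width of the cubic mean window
#'   (0 disables smoothing).
#' @param fallback donor fallback when no source-label voxel exists:
#'   "nearest_any_nonimplant".
#' @return An object of class \code{fill_config}.
#' @export
fill_config <- function(fill_source_labels = "SoftTissue",
                        smoothing_radius_voxels = 1L,
                        fallback = "nearest_any_nonimplant") {
  stopifnot(smoothing_radius_voxels >= 0)
  fallback <- match.arg(fallback)
  structure(list(fill_source_labels = fill_source_labels,
                 smoothing_radius_voxels = as.integer(smoothing_radius_voxels),
                 fallback = fallback),
            class = "fill_config")
}

.implant_mask <- function(lab, implant_labels) {
  array(lab$labels %in% as.integer(implant_labels), dim = dim(lab$labels))
}

#' Shift the implant voxels in the stem-aligned grid
#'
#' Moves every implant voxel's HU and label by exactly (dx, dy, dz) voxels;
#' all other voxels keep their values except destination voxels, which are
#' overwritten by the arriving implant (a physical implant displaces
#' tissue).  Vacated voxels (source minus destination) keep their stale HU
#' until [fill_vacated()] runs; their label becomes soft tissue.
#'
#' @param ct_frame [ct_volume()] on the stem-aligned grid.
#' @param lab_frame congruent [label_volume()].
#' @param implant_labels integer label codes of the implant.
#' @param shift a [shift_spec()].
#' @param warn_overlap emit a message when the overlap fraction (overwritten
#'   non-implant voxels / implant voxels) exceeds this value.
#' @return List with \code{ct}, \code{labels}, \code{vacated} (logical
#'   array) and \code{overlap_fraction}.
#' @export
apply_shift <- function(ct_frame, lab_frame, implant_labels, shift,
                        warn_overlap = 0.01) {
  stopifnot(inherits(shift, "shift_spec"))
  if (!check_congruent(ct_frame, lab_frame))
    stop("image and labels are not congruent")
  dims <- dim(ct_frame$voxels)
  mask <- .implant_mask(lab_frame, implant_labels)
  src <- which(mask)
  if (length(src) == 0L) stop("implant mask is empty")
  d <- c(shift$dx, shift$dy, shift$dz)
  idx <- arrayInd(src, dims)
  for (a in 1:3) {
    rng <- range(idx[, a]) + d[a]
    if (rng[1] < 1L || rng[2] > dims[a])
      stop("shift pushes implant out of bounds along ", .AXES[a], " axis")
  }
  dlin <- d[1] + dims[1] * (d[2] + dims[2] * d[3])
  dst <- src + dlin
  ct2 <- ct_frame$voxels
  lab2 <- lab_frame$labels
  hu_src <- ct2[src]
  lab_src <- lab2[src]
  vac <- setdiff(src, dst)
  overwritten <- setdiff(dst, src)
  soft_code <- as.integer(lab_frame$codes[["SoftTissue"]])
  lab2[vac] <- soft_code
  ct2[dst] <- hu_src
  lab2[dst] <- lab_src
  overlap <- length(overwritten) / length(src)
  if (overlap > warn_overlap)
    message(sprintf("implant overwrote %.1f%% of its volume in other tissue",
                    100 * overlap))
  vac_mask <- array(FALSE, dim = dims)
  vac_mask[vac] <- TRUE
  out_ct <- ct_frame; out_ct$voxels <- ct2
  out_lab <- lab_frame; out_lab$labels <- lab2
  list(ct = out_ct, labels = out_lab, vacated = vac_mask,
       overlap_fraction = overlap)
}

#' Fill vacated implant voxels with nearby soft-tissue HU
#'
#' Each vacated voxel receives the HU of its nearest (Euclidean, mm-scaled)
#' donor voxel - a voxel whose label is in the donor set and which is
#' neither vacated nor implant.  If the donor set is empty anywhere in the
#' volume, the nearest non-implant voxel donates instead.  A mean filter of
#' the configured radius is then applied to the vacated voxels only, using
#' the already-filled values and surrounding donor-class voxels (bone and
#' implant HU never bleed into the fill).
#'
#' @param ct [ct_volume()] after [apply_shift()].
#' @param vacated logical array (vacated mask).
#' @param lab [label_volume()] after [apply_shift()].
#' @param cfg a [fill_config()].
#' @return A new [ct_volume()] with non-vacated voxels unchanged.
#' @export
fill_vacated <- function(ct, vacated, lab, cfg = fill_config()) {
  stopifnot(inherits(cfg, "fill_config"))
  if (!check_congruent(ct, lab)) stop("image and labels are not congruent")
  vac <- which(vacated)
  if (length(vac) == 0L) return(ct)
  dims <- dim(ct$voxels)
  imp <- .implant_mask(lab, implant_codes(lab$codes))
  if (any(imp[vac])) stop("vacated mask overlaps the current implant mask")
  donor_codes <- lab$codes[cfg$fill_source_labels]
  if (anyNA(donor_codes)) stop("unknown donor label name")
  donor <- array(lab$labels %in% as.integer(donor_codes), dim = dims)
  donor[vacated] <- FALSE
  if (!any(donor)) {  # fallback: nearest non-implant voxel
    donor <- !imp
    donor[vacated] <- FALSE
  }
  vals <- as.numeric(ct$voxels)
  filled <- cpp_nearest_donor(vals, as.logical(donor), dims, ct$spacing,
                              vac - 1L)
  vals[vac] <- filled
  if (cfg$smoothing_radius_voxels > 0) {
    # smooth over already-filled vacated voxels and surrounding donor-class
    # tissue; bone and implant never bleed into the fill
    include <- donor
    include[vacated] <- TRUE
    sm <- cpp_box_mean(vals, as.logical(include), dims, vac - 1L,
                       cfg$smoothing_radius_voxels)
    vals[vac] <- sm
  }
  out <- ct
  out$voxels <- array(vals, dim = dims)
  out
}

#' Generate one synthetic follow-up CT
#'
#' Full pipeline for a single shift: resample the baseline CT and labels to
#' the stem-aligned grid, translate the implant voxels by the integer shift,
#' fill the vacated voxels, and resample back onto the baseline grid.  The
#' ground-truth migration is the shift times the stem-aligned grid spacing.
#'
#' @param baseline [ct_volume()].
#' @param labels congruent [label_volume()].
#' @param frame [build_stem_frame()] result.
#' @param shift a [shift_spec()].
#' @param fill a [fill_config()].
#' @param spec a [resample_spec()].
#' @param baseline_id,followup_id identifiers for the manifest record.
#' @return List with \code{followup} ([ct_volume()] on the baseline grid)
#'   and \code{record} (one-row manifest data.frame).
#' @export
generate_followup <- function(baseline, labels, frame, shift,
                              fill = fill_config(), spec = resample_spec(),
                              baseline_id = "baseline",
                              followup_id = "followup") {
  if (!check_congruent(baseline, labels))
    stop("baseline image and labels are not congruent")
  rf <- resample_to_frame(baseline, frame, spec)
  rl <- resample_to_frame(labels, frame, spec)
  sh <- apply_shift(rf$volume, rl$volume, implant_codes(labels$codes), shift)
  ct_filled <- fill_vacated(sh$ct, sh$vacated, sh$labels, fill)
  followup <- resample_from_frame(ct_filled, rf$transform, baseline,
                                  interpolation = spec$interpolation)
  rec <- manifest_record(baseline_id, followup_id, shift$generating_axes,
                         c(shift$dx, shift$dy, shift$dz),
                         rf$transform$dst$spacing)
  list(followup = followup, record = rec)
}
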