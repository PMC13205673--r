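#' Measurement stand-in configuration
#'
#' Settings for the transparent migration measurement shipped with the
#' package: threshold segmentation of the metal implant followed by either
#' an HU-weighted centroid comparison or a normalized cross-correlation
#' (NCC) translation search.  This is a deliberately simple, fully open
#' method intended to exercise the evaluation layer; it measures
#' translations only.
#'
#' @param hu_threshold HU above which a voxel counts as metal; must sit
#'   above the soft-tissue and bone HU of the data at hand.
#' @param method "centroid" or "xcorr".
#' @param xcorr_search_mm half-width (mm) of the NCC search window, centred
#'   on an initial centroid estimate of the translation.
#' @param subvoxel logical; parabolic refinement of the NCC peak.
#' @return An object of class \code{measurement_config}.
#' @export
measurement_config <- function(hu_threshold = 2500,
                               method = c("centroid", "xcorr"),
                               xcorr_search_mm = 2, subvoxel = TRUE) {
  method <- match.arg(method)
  stopifnot(xcorr_search_mm > 0)
  structure(list(hu_threshold = hu_threshold, method = method,
                 xcorr_search_mm = xcorr_search_mm,
                 subvoxel = isTRUE(subvoxel)),
            class = "measurement_config")
}

#' Threshold segmentation of the metal implant
#'
#' Voxels with HU at or above the threshold, reduced to the largest
#' 26-connected component (small disconnected metal specks and streak
#' maxima are discarded).
#'
#' @param ct a [ct_volume()].
#' @param cfg a [measurement_config()].
#' @return Logical 3D array.
#' @export
segment_metal <- function(ct, cfg = measurement_config()) {
  mask <- ct$voxels >= cfg$hu_threshold
  if (!any(mask))
    stop("no implant found: no voxel reaches ", cfg$hu_threshold, " HU")
  array(cpp_largest_component(as.logical(mask), dim(ct$voxels)),
        dim = dim(ct$voxels))
}

.mask_centroid_world <- function(ct, mask) {
  idx <- which(mask, arr.ind = TRUE) - 1  # 0-based
  w <- ct$voxels[mask]
  cv <- colSums(idx * w) / sum(w)
  .index_to_world(.grid_of(ct), cv)
}

#' Measure implant translation between two CT volumes
#'
#' Stand-in migration measurement: both volumes are segmented with
#' [segment_metal()]; the translation is estimated either as the difference
#' of HU-weighted centroids or as the offset maximizing NCC of the
#' metal-masked HU, and expressed in the baseline stem frame (positive =
#' medial, superior, anterior; left-sided frames already encode the
#' right-sided reporting convention).
#'
#' @param baseline,followup [ct_volume()]s on congruent grids.
#' @param frame the baseline [build_stem_frame()] result.
#' @param cfg a [measurement_config()].
#' @return List of class \code{measured_migration} with
#'   \code{translation_mm} (length-3, stem frame) and \code{method_tag}.
#' @export
measure_translation <- function(baseline, followup, frame,
                                cfg = measurement_config()) {
  if (!check_congruent(baseline, followup))
    stop("baseline and follow-up are not on congruent grids")
  stopifnot(inherits(frame, "stem_frame"))
  if (cfg$method == "centroid") {
    mb <- segment_metal(baseline, cfg)
    mf <- segment_metal(followup, cfg)
    dw <- .mask_centroid_world(followup, mf) - .mask_centroid_world(baseline, mb)
  } else {
    mb <- segment_metal(baseline, cfg)
    mf <- segment_metal(followup, cfg)
    dims <- dim(baseline$voxels)
    halfw <- pmax(1L, as.integer(ceiling(cfg$xcorr_search_mm / baseline$spacing)))
    # initial integer-voxel estimate from the mask centroids
    dw0 <- .mask_centroid_world(followup, mf) - .mask_centroid_world(baseline, mb)
    center <- as.integer(round(as.vector(crossprod(baseline$direction, dw0)) /
                                 baseline$spacing))
    # correlate over the implant dilated by 2 voxels: the metal interior is
    # nearly constant, so the signal lives on the implant boundary
    ai <- which(mb, arr.ind = TRUE)
    offs <- as.matrix(expand.grid(i = -2:2, j = -2:2, k = -2:2))
    big <- ai[rep(seq_len(nrow(ai)), each = nrow(offs)), , drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), times = nrow(ai)), , drop = FALSE]
    ok <- big[, 1] >= 1 & big[, 1] <= dims[1] & big[, 2] >= 1 &
      big[, 2] <= dims[2] & big[, 3] >= 1 & big[, 3] <= dims[3]
    big <- big[ok, , drop = FALSE]
    region <- unique(big[, 1] + dims[1] * (big[, 2] - 1) +
                       dims[1] * dims[2] * (big[, 3] - 1))
    scores <- cpp_ncc_search(as.numeric(baseline$voxels),
                             as.numeric(followup$voxels),
                             dims, region - 1L, halfw, center)
    if (all(is.na(scores)))
      stop("cross-correlation search degenerate: no HU contrast around the implant")
    best <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
    off <- center + as.numeric(best) - (halfw + 1)  # voxel offset at the peak
    peak <- scores[best[1], best[2], best[3]]
    # a perfect correlation peak is an exact integer-voxel match; parabolic
    # refinement could only perturb it
    if (cfg$subvoxel && peak < 1 - 1e-12) {
      for (a in 1:3) {
        i <- best
        if (best[a] > 1 && best[a] < dim(scores)[a]) {
          im <- i; im[a] <- i[a] - 1L
          ip <- i; ip[a] <- i[a] + 1L
          ym <- scores[im[1], im[2], im[3]]
          y0 <- scores[i[1], i[2], i[3]]
          yp <- scores[ip[1], ip[2], ip[3]]
          den <- ym - 2 * y0 + yp
          if (is.finite(den) && den < 0)
            off[a] <- off[a] + 0.5 * (ym - yp) / den
        }
      }
    }
    dw <- as.vector(baseline$direction %*% (off * baseline$spacing))
  }
  tf <- as.vector(crossprod(frame$rotation, dw))
  structure(list(translation_mm = tf, method_tag = cfg$method),
            class = "measured_migration")
}

#' Measure a set of follow-ups against one baseline
#'
#' @param baseline [ct_volume()].
#' @param followups named list of [ct_volume()]s (names become follow-up
#'   ids) or character vector of file paths.
#' @param frame the baseline stem frame.
#' @param cfg a [measurement_config()].
#' @return data.frame with columns \code{followup_id, mx_mm, my_mm, mz_mm,
#'   method}.
#' @export
measure_followups <- function(baseline, followups, frame,
                              cfg = measurement_config()) {
  if (is.character(followups)) {
    ids <- sub("\\.nii(\\.gz)?$", "", basename(followups))
    followups <- setNames(lapply(followups, read_volume), ids)
  }
  stopifnot(length(followups) >= 1, !is.null(names(followups)))
  rows <- lapply(names(followups), function(id) {
    m <- measure_translation(baseline, followups[[id]], frame, cfg)
    data.frame(followup_id = id, mx_mm = m$translation_mm[1],
               my_mm = m$translation_mm[2], mz_mm = m$translation_mm[3],
               method = m$method_tag, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
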