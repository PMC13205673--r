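#' Build the stem coordinate system from landmarks
#'
#' The stem frame has its y axis along the stem centerline (unit vector from
#' tip to center, so positive is superior/proximal), its x axis along the
#' component of the neckline orthogonal to y (positive medial), and z
#' completing a right-handed frame (positive anterior for a right-sided
#' frame).  For left hips the x axis is negated so that reported positive x
#' is medial under the "as if all hips were right-sided" convention.
#'
#' @param landmarks a [stem_landmarks()].
#' @param side "right" or "left"; defaults to the landmarks' side.
#' @return An object of class \code{stem_frame}: list with \code{origin_mm},
#'   3x3 \code{rotation} (columns = x, y, z axes in world coordinates) and
#'   \code{side}.
#' @export
build_stem_frame <- function(landmarks, side = landmarks$side) {
  stopifnot(inherits(landmarks, "stem_landmarks"))
  side <- match.arg(side, c("right", "left"))
  yv <- landmarks$center_mm - landmarks$tip_mm
  ny <- sqrt(sum(yv^2))
  if (ny < 1e-9) stop("degenerate frame: center and tip coincide")
  yhat <- yv / ny
  neck <- landmarks$neck_point_mm - landmarks$center_mm
  xr <- neck - sum(neck * yhat) * yhat
  nx <- sqrt(sum(xr^2))
  if (nx < sqrt(sum(neck^2)) * sin(1 * pi / 180))
    stop("degenerate frame: neck point collinear with stem axis")
  xhat <- xr / nx
  if (side == "left") xhat <- -xhat
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])
  rot <- cbind(xhat, yhat, zhat, deparse.level = 0)
  stopifnot(abs(det(rot) - 1) < 1e-9)
  structure(list(origin_mm = landmarks$center_mm, rotation = rot, side = side),
            class = "stem_frame")
}

#' @export
print.stem_frame <- function(x, ...) {
  cat("<stem_frame> side:", x$side, "\n origin (mm):",
      paste(signif(x$origin_mm, 6), collapse = ", "), "\n")
  print(signif(x$rotation, 6))
  invisible(x)
}

#' Resampling specification
#'
#' @param interpolation "linear" (default, HU images) or "nearest".  Label
#'   volumes always resample with nearest neighbor regardless of this value.
#' @param output_spacing_mm spacing of the stem-aligned grid, or NULL to
#'   inherit the source CT spacing permuted to the closest-aligned axes (so
#'   one-voxel shifts stay commensurate with the scanner spacing).
#' @param padding_value HU assigned outside the source volume (default air).
#' @return An object of class \code{resample_spec}.
#' @export
resample_spec <- function(interpolation = c("linear", "nearest"),
                          output_spacing_mm = NULL, padding_value = -1024) {
  interpolation <- match.arg(interpolation)
  if (!is.null(output_spacing_mm)) {
    output_spacing_mm <- as.numeric(output_spacing_mm)
    stopifnot(length(output_spacing_mm) == 3L, all(output_spacing_mm > 0))
  }
  structure(list(interpolation = interpolation,
                 output_spacing_mm = output_spacing_mm,
                 padding_value = padding_value),
            class = "resample_spec")
}

#' Stem-aligned grid spacing inherited from a CT volume
#'
#' For each stem-frame axis, picks the spacing of the CT world axis it is
#' most closely aligned with.  This keeps "1 voxel" steps in the
#' stem-aligned grid comparable to the scanner's own spacing.
#'
#' @param frame a [build_stem_frame()] result.
#' @param vol the source [ct_volume()].
#' @return Numeric length-3 spacing in mm.
#' @export
frame_spacing <- function(frame, vol) {
  # alignment between frame axes (columns of rotation) and CT voxel axes
  # (columns of direction): |direction^T rotation|
  align <- abs(crossprod(vol$direction, frame$rotation))
  vapply(1:3, function(a) vol$spacing[which.max(align[, a])], numeric(1))
}

# 0-based voxel index -> world mm
.index_to_world <- function(grid, idx) {
  grid$origin + as.vector(grid$direction %*% (idx * grid$spacing))
}

# affine (A, b) mapping 0-based indices of `from` grid to continuous
# 0-based indices of `to` grid
.grid_affine <- function(from, to) {
  Rt <- t(to$direction)
  A <- diag(1 / to$spacing) %*% Rt %*% from$direction %*% diag(from$spacing)
  b <- as.vector(diag(1 / to$spacing) %*% Rt %*% (from$origin - to$origin))
  list(A = A, b = b)
}

.resample_onto <- function(vol, out_grid, interpolation, padding_value) {
  src_grid <- .grid_of(vol)
  is_lab <- inherits(vol, "label_volume")
  arr <- if (is_lab) vol$labels else vol$voxels
  method <- if (is_lab || interpolation == "nearest") 0L else 1L
  pad <- if (is_lab) 0 else padding_value
  aff <- .grid_affine(out_grid, src_grid)
  res <- cpp_resample_affine(as.numeric(arr), dim(arr), out_grid$dim,
                             aff$A, aff$b, method, pad)
  res <- array(res, dim = out_grid$dim)
  if (is_lab)
    label_volume(array(as.integer(round(res)), dim = out_grid$dim),
                 spacing = out_grid$spacing, origin = out_grid$origin,
                 direction = out_grid$direction, codes = vol$codes)
  else
    ct_volume(res, spacing = out_grid$spacing, origin = out_grid$origin,
              direction = out_grid$direction)
}

#' Resample a volume onto the stem-aligned grid
#'
#' Produces a volume whose grid axes are parallel to the stem frame axes
#' (the "rotation" of the baseline CT), with a field of view covering the
#' input volume, and records the exact rigid relation between the two grids
#' for later inversion by [resample_from_frame()].
#'
#' @param vol a [ct_volume()] or [label_volume()].
#' @param frame a [build_stem_frame()] result.
#' @param spec a [resample_spec()].
#' @return List with \code{volume} (resampled, same class as input) and
#'   \code{transform} (class \code{frame_transform}), which records both
#'   grids and the frame.
#' @export
resample_to_frame <- function(vol, frame, spec = resample_spec()) {
  stopifnot(inherits(frame, "stem_frame"), inherits(spec, "resample_spec"))
  src <- .grid_of(vol)
  out_sp <- spec$output_spacing_mm
  if (is.null(out_sp)) out_sp <- frame_spacing(frame, vol)
  # frame-coordinates of the 8 corners of the voxel-center bounding box
  corners <- as.matrix(expand.grid(c(0, src$dim[1] - 1), c(0, src$dim[2] - 1),
                                   c(0, src$dim[3] - 1)))
  wc <- t(apply(corners, 1, function(v) .index_to_world(src, v)))
  fc <- sweep(wc, 2, frame$origin_mm) %*% frame$rotation
  cmin <- apply(fc, 2, min); cmax <- apply(fc, 2, max)
  n <- as.integer(ceiling((cmax - cmin) / out_sp - 1e-7)) + 1L
  out_grid <- list(dim = n, spacing = out_sp,
                   origin = frame$origin_mm + as.vector(frame$rotation %*% cmin),
                   direction = frame$rotation)
  volume <- .resample_onto(vol, out_grid, spec$interpolation,
                           spec$padding_value)
  transform <- structure(list(src = src, dst = out_grid, frame = frame,
                              padding_value = spec$padding_value),
                         class = "frame_transform")
  list(volume = volume, transform = transform)
}

#' Resample a stem-aligned volume back to the reference CT grid
#'
#' Applies the exact inverse of the rigid relation recorded by
#' [resample_to_frame()], producing a volume on the reference grid (the
#' "inverse rotation" back to scanner coordinates).
#'
#' @param vol volume on the stem-aligned grid.
#' @param transform the \code{frame_transform} from [resample_to_frame()].
#' @param reference a volume on the original grid (geometry reference).
#' @param interpolation "linear" or "nearest"; labels always use nearest.
#' @return Volume on the reference grid, same class as \code{vol}.
#' @export
resample_from_frame <- function(vol, transform, reference,
                                interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(transform, "frame_transform"))
  if (!.same_grid(.grid_of(vol), transform$dst))
    stop("volume grid does not match the recorded stem-aligned grid")
  if (!.same_grid(.grid_of(reference), transform$src))
    stop("reference grid does not match the recorded source grid")
  .resample_onto(vol, transform$src, interpolation, transform$padding_value)
}

#' Write / read stem landmarks as JSON
#'
#' @param landmarks a [stem_landmarks()].
#' @param path JSON path.
#' @return \code{write_landmarks}: the path invisibly;
#'   \code{read_landmarks}: a [stem_landmarks()].
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(list(center_mm = landmarks$center_mm,
                            tip_mm = landmarks$tip_mm,
                            neck_point_mm = landmarks$neck_point_mm,
                            side = landmarks$side),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stem_landmarks(x$center_mm, x$tip_mm, x$neck_point_mm, side = x$side)
}
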