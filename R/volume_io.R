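#' CT volume container
#'
#' A minimal in-memory representation of a 3D CT scan: a voxel array of
#' Hounsfield units plus the geometric metadata needed to place every voxel
#' in world (scanner) space.  World position of 0-based voxel index
#' \code{v} is \code{origin + direction \%*\% (v * spacing)}.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix mapping voxel axes to world axes.
#' @return An object of class \code{ct_volume}.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-9)
    stop("direction matrix must be orthonormal")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 6), collapse = ", "),
      ") mm, HU range [", round(min(x$voxels), 1), ", ",
      round(max(x$voxels), 1), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Default label codes
#'
#' Fixed small-integer codes for the semantic labels used throughout the
#' package.  The stem shaft and prosthetic head carry separate codes; both
#' together form the implant.
#' @return Named integer vector.
#' @export
default_label_codes <- function() {
  c(Background = 0L, SoftTissue = 1L, FemurLeft = 2L, FemurRight = 3L,
    HipLeft = 4L, HipRight = 5L, Stem = 6L, Head = 7L)
}

#' Label codes of the implant (stem shaft + head)
#' @param codes named label-code vector.
#' @return Integer vector of implant codes.
#' @export
implant_codes <- function(codes = default_label_codes()) {
  unname(codes[names(codes) %in% c("Stem", "Head")])
}

#' Label volume container
#'
#' Integer segmentation congruent with a [ct_volume()]: same shape, spacing,
#' origin and direction.  Every voxel must hold a declared label code.
#'
#' @param labels 3D integer array.
#' @param spacing,origin,direction grid metadata, as in [ct_volume()].
#' @param codes named integer vector of the declared label codes.
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3), codes = default_label_codes()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), as.integer(codes))
  if (length(bad))
    stop("undeclared label codes present: ", paste(bad, collapse = ", "))
  geo <- ct_volume(array(0, dim = dim(labels)), spacing, origin, direction)
  structure(list(labels = labels, spacing = geo$spacing, origin = geo$origin,
                 direction = geo$direction, codes = codes),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = as.integer(x$codes),
                      labels = names(x$codes)))
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "), " voxels\n",
      sep = "")
  print(tab[tab > 0])
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

.grid_of <- function(x) {
  arr <- if (inherits(x, "label_volume")) x$labels else x$voxels
  list(dim = dim(arr), spacing = x$spacing, origin = x$origin,
       direction = x$direction)
}

.same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Check image/label grid congruence
#'
#' TRUE iff the two volumes share shape and have spacing, origin and
#' direction equal within 1e-6 mm.  Symmetric in its arguments.
#'
#' @param vol,lab a [ct_volume()] or [label_volume()] each.
#' @return Logical scalar.
#' @export
check_congruent <- function(vol, lab) {
  .same_grid(.grid_of(vol), .grid_of(lab))
}

#' Read a CT or label volume from NIfTI
#'
#' Reads a 3D NIfTI file (.nii or .nii.gz); spacing, origin and direction are
#' taken from the header xform.  HU values are returned unmodified.
#'
#' @param path file path.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("unreadable volume file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(img)) != 3L)
    stop("not a 3D image (", length(dim(img)), "D): ", path)
  x <- RNifti::xform(img, useQuaternionFirst = FALSE)
  m <- x[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  direction <- sweep(m, 2, spacing, "/")
  vox <- array(as.numeric(img), dim = dim(img))
  ct_volume(vox, spacing = spacing, origin = x[1:3, 4], direction = direction)
}

#' Read a label volume from NIfTI
#'
#' @param path file path.
#' @param codes named label-code vector the file must conform to.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, codes = default_label_codes()) {
  v <- read_volume(path)
  if (max(abs(v$voxels - round(v$voxels))) > 0)
    stop("label file contains non-integer values: ", path)
  label_volume(array(as.integer(round(v$voxels)), dim = dim(v$voxels)),
               spacing = v$spacing, origin = v$origin,
               direction = v$direction, codes = codes)
}

#' Write a CT or label volume to NIfTI
#'
#' Integer-valued volumes are stored as 16-bit signed integers (lossless for
#' the HU range), real-valued volumes as 32-bit float.  Label volumes always
#' store as int16.
#'
#' @param vol a [ct_volume()] or [label_volume()].
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @param datatype "auto" (default), "int16" or "float".
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  if (!dir.exists(dirname(path))) stop("parent directory missing: ", path)
  arr <- if (inherits(vol, "label_volume")) vol$labels else vol$voxels
  if (datatype == "auto") {
    is_int <- is.integer(arr) ||
      (max(abs(arr - round(arr))) == 0 && min(arr) >= -32768 && max(arr) <= 32767)
    datatype <- if (is_int) "int16" else "float"
  }
  img <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
  RNifti::pixdim(img) <- vol$spacing
  m <- rbind(cbind(vol$direction %*% diag(vol$spacing), vol$origin),
             c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = datatype); TRUE },
                 error = function(e) stop("failed to write volume: ", path,
                                          " (", conditionMessage(e), ")"))
  invisible(path)
}

#' Build a one-row migration manifest record
#'
#' The ground-truth migration is defined as the integer voxel shift times the
#' spacing of the stem-aligned grid, axis by axis; this identity is enforced
#' exactly.
#'
#' @param baseline_id,followup_id identifiers.
#' @param generating_axes string naming the protocol family axes, e.g. "y",
#'   "xz", or "" for the two-axis zero shift.
#' @param shift_voxels integer length-3 (dx, dy, dz).
#' @param frame_spacing_mm numeric length-3 spacing of the stem-aligned grid.
#' @return One-row data.frame with the manifest columns.
#' @export
manifest_record <- function(baseline_id, followup_id, generating_axes,
                            shift_voxels, frame_spacing_mm) {
  shift_voxels <- as.integer(shift_voxels)
  stopifnot(length(shift_voxels) == 3L, length(frame_spacing_mm) == 3L)
  axs <- strsplit(generating_axes, "")[[1]]
  if (length(axs)) .axis_index(axs)
  truth <- shift_voxels * as.numeric(frame_spacing_mm)
  data.frame(baseline_id = as.character(baseline_id),
             followup_id = as.character(followup_id),
             generating_axes = as.character(generating_axes),
             dx = shift_voxels[1], dy = shift_voxels[2], dz = shift_voxels[3],
             truth_x_mm = truth[1], truth_y_mm = truth[2], truth_z_mm = truth[3],
             frame_sx_mm = frame_spacing_mm[1],
             frame_sy_mm = frame_spacing_mm[2],
             frame_sz_mm = frame_spacing_mm[3],
             stringsAsFactors = FALSE)
}

.manifest_cols <- c("baseline_id", "followup_id", "generating_axes",
                    "dx", "dy", "dz", "truth_x_mm", "truth_y_mm", "truth_z_mm",
                    "frame_sx_mm", "frame_sy_mm", "frame_sz_mm")

#' Write / read the migration manifest CSV
#'
#' One row per follow-up.  Numeric columns are written with 17 significant
#' digits so the round trip is lossless at double precision.
#'
#' @param records manifest data.frame (rows from [manifest_record()]).
#' @param path CSV path.
#' @return \code{write_manifest}: the path, invisibly.
#' @export
write_manifest <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- manifest_record("b", "f", "x", c(0L, 0L, 0L), c(1, 1, 1))[0, ]
  }
  stopifnot(all(.manifest_cols %in% names(records)))
  out <- records[, .manifest_cols]
  for (cc in names(out))
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]]))
      out[[cc]] <- sprintf("%.17g", out[[cc]])
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @return \code{read_manifest}: manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- tryCatch(suppressWarnings(
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(baseline_id = "character",
                            followup_id = "character",
                            generating_axes = "character"))),
    error = function(e) stop("malformed manifest CSV: ", path,
                             " (", conditionMessage(e), ")"))
  missing_cols <- setdiff(.manifest_cols, names(df))
  if (length(missing_cols))
    stop("malformed manifest CSV ", path, ": missing columns ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.manifest_cols, c("baseline_id", "followup_id",
                                        "generating_axes"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (nrow(df) && anyNA(v))
      stop("malformed manifest CSV ", path, ": non-numeric value in column ",
           cc, " at row ", which(is.na(v))[1])
    df[[cc]] <- v
  }
  df$generating_axes[is.na(df$generating_axes)] <- ""
  for (cc in c("dx", "dy", "dz")) df[[cc]] <- as.integer(df[[cc]])
  df
}
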