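#' Digital hip phantom configuration
#'
#' Parameters of the synthetic baseline CT used to exercise the migration
#' simulator without patient data: a tapered-cylinder metal stem with a
#' spherical prosthetic head, embedded in a coaxial bone cylinder, inside a
#' soft-tissue ellipsoid, surrounded by air.
#'
#' Default spacing mirrors a common clinical protocol for hip CT
#' (0.7812 x 0.7812 mm in-plane, 0.45 mm axial); HU levels are typical
#' clinical values (air -1000, soft tissue 40, cortical-like bone 1200,
#' metal 3000).
#'
#' @param shape integer length-3 voxel counts per axis.
#' @param spacing_mm numeric length-3 voxel size in mm.
#' @param side "right" or "left"; left phantoms are mirror images of right
#'   ones across the sagittal mid-plane.
#' @param hu_air,hu_soft,hu_bone,hu_metal HU levels (must be increasing).
#' @param stem_length_mm stem centerline length (tip to stem center).
#' @param stem_radius_mm stem radius at the proximal end; the tip tapers to
#'   one third of this value.
#' @param head_radius_mm radius of the prosthetic head sphere.
#' @param neck_length_mm distance from stem center to head center.
#' @param stem_tilt_deg tilt of the stem centerline from the image z axis,
#'   in the medial direction.
#' @param noise_sd_hu SD of additive Gaussian image noise (0 = noise free).
#' @param artifact_streaks logical; add cosmetic metal-artifact streaks.
#' @param seed integer seed making the phantom fully reproducible.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(shape = c(96L, 96L, 128L),
                           spacing_mm = c(0.7812, 0.7812, 0.45),
                           side = c("right", "left"),
                           hu_air = -1000, hu_soft = 40, hu_bone = 1200,
                           hu_metal = 3000,
                           stem_length_mm = 26, stem_radius_mm = 4.5,
                           head_radius_mm = 5.5, neck_length_mm = 11,
                           stem_tilt_deg = 8,
                           noise_sd_hu = 20, artifact_streaks = FALSE,
                           seed = 1L) {
  side <- match.arg(side)
  if (!(hu_air < hu_soft && hu_soft < hu_bone && hu_bone < hu_metal))
    stop("HU levels must satisfy hu_air < hu_soft < hu_bone < hu_metal")
  stopifnot(length(shape) == 3L, all(shape >= 16),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            stem_length_mm > 0, stem_radius_mm > 0, head_radius_mm > 0,
            neck_length_mm > 0, noise_sd_hu >= 0)
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 side = side, hu_air = hu_air, hu_soft = hu_soft,
                 hu_bone = hu_bone, hu_metal = hu_metal,
                 stem_length_mm = stem_length_mm,
                 stem_radius_mm = stem_radius_mm,
                 head_radius_mm = head_radius_mm,
                 neck_length_mm = neck_length_mm,
                 stem_tilt_deg = stem_tilt_deg,
                 noise_sd_hu = noise_sd_hu,
                 artifact_streaks = isTRUE(artifact_streaks),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Stem landmarks
#'
#' World-coordinate (mm) landmarks defining the stem coordinate system:
#' stem center (proximal end of the centerline), stem tip, and a point on
#' the neck/head axis.
#'
#' @param center_mm,tip_mm,neck_point_mm numeric length-3 world points.
#' @param side "right" or "left".
#' @return An object of class \code{stem_landmarks}.
#' @export
stem_landmarks <- function(center_mm, tip_mm, neck_point_mm,
                           side = c("right", "left")) {
  side <- match.arg(side)
  center_mm <- as.numeric(center_mm); tip_mm <- as.numeric(tip_mm)
  neck_point_mm <- as.numeric(neck_point_mm)
  stopifnot(length(center_mm) == 3L, length(tip_mm) == 3L,
            length(neck_point_mm) == 3L)
  axis <- center_mm - tip_mm
  if (sqrt(sum(axis^2)) < 1e-9) stop("center and tip coincide")
  neck <- neck_point_mm - center_mm
  nn <- sqrt(sum(neck^2))
  if (nn < 1e-9) stop("neck point coincides with stem center")
  cosang <- abs(sum(axis * neck)) / (sqrt(sum(axis^2)) * nn)
  if (cosang > cos(1 * pi / 180))
    stop("neck point collinear with stem axis (within 1 degree)")
  structure(list(center_mm = center_mm, tip_mm = tip_mm,
                 neck_point_mm = neck_point_mm, side = side),
            class = "stem_landmarks")
}

# run expr with a private RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# analytic implant geometry (world mm) for a given config
.phantom_geometry <- function(cfg) {
  extent <- (cfg$shape - 1) * cfg$spacing_mm
  ctr <- extent / 2
  med <- if (cfg$side == "right") 1 else -1  # medial = +x for right hips
  t <- cfg$stem_tilt_deg * pi / 180
  axis <- c(med * sin(t), 0, cos(t))               # distal -> proximal
  mdir <- c(med * cos(t), 0, -sin(t))              # medial, perp to axis
  center <- ctr + (cfg$stem_length_mm / 2) * axis
  tip <- ctr - (cfg$stem_length_mm / 2) * axis
  elev <- 35 * pi / 180                            # neck elevation above medial
  neck_dir <- cos(elev) * mdir + sin(elev) * axis
  neck_dir <- neck_dir / sqrt(sum(neck_dir^2))
  head_center <- center + cfg$neck_length_mm * neck_dir
  list(center = center, tip = tip, head_center = head_center,
       axis = axis, mdir = mdir, ctr = ctr, extent = extent,
       r_tip = cfg$stem_radius_mm / 3, r_top = cfg$stem_radius_mm)
}

#' Generate a synthetic baseline hip CT
#'
#' Builds the phantom image, its congruent label volume and the stem
#' landmarks.  Stem and head voxels are set to \code{hu_metal} and labeled
#' \code{Stem}/\code{Head}; a coaxial bone cylinder is labeled
#' \code{FemurLeft}/\code{FemurRight} by side; an enclosing ellipsoid is
#' \code{SoftTissue}; the remainder is \code{Background} at \code{hu_air}.
#' Additive Gaussian noise (seeded) is applied to the image only.
#'
#' @param cfg a [phantom_config()].
#' @return List with elements \code{ct} ([ct_volume()]), \code{labels}
#'   ([label_volume()]) and \code{landmarks} ([stem_landmarks()]).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  g <- .phantom_geometry(cfg)
  dims <- cfg$shape
  sp <- cfg$spacing_mm
  # voxel-center world coordinates per axis
  xs <- (seq_len(dims[1]) - 1) * sp[1]
  ys <- (seq_len(dims[2]) - 1) * sp[2]
  zs <- (seq_len(dims[3]) - 1) * sp[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dim = dims)

  # stem frustum: axial parameter s in [0, L], radius tapering r_tip -> r_top
  dxv <- X - g$tip[1]; dyv <- Y - g$tip[2]; dzv <- Z - g$tip[3]
  s <- dxv * g$axis[1] + dyv * g$axis[2] + dzv * g$axis[3]
  perp2 <- pmax(dxv^2 + dyv^2 + dzv^2 - s^2, 0)
  L <- cfg$stem_length_mm
  rad <- g$r_tip + (g$r_top - g$r_tip) * pmin(pmax(s / L, 0), 1)
  stem <- s >= 0 & s <= L & perp2 <= rad^2

  # metal neck connecting the stem shoulder to the head (so the implant is
  # one connected metal component, as for a real monoblock prosthesis)
  ndir <- (g$head_center - g$center) / cfg$neck_length_mm
  nxv <- X - g$center[1]; nyv <- Y - g$center[2]; nzv <- Z - g$center[3]
  u <- nxv * ndir[1] + nyv * ndir[2] + nzv * ndir[3]
  nperp2 <- pmax(nxv^2 + nyv^2 + nzv^2 - u^2, 0)
  # neck radius half the stem radius: thick enough to stay 26-connected
  # after resampling at every clinical spacing in use
  neck <- u >= 0 & u <= cfg$neck_length_mm & nperp2 <= (g$r_top / 2)^2
  stem <- stem | neck

  # prosthetic head sphere
  head <- (X - g$head_center[1])^2 + (Y - g$head_center[2])^2 +
    (Z - g$head_center[3])^2 <= cfg$head_radius_mm^2

  # bone: coaxial cylinder around the stem axis, distal 90% of the stem span
  bone_r <- cfg$stem_radius_mm * 2
  bone <- s >= -0.1 * L & s <= 0.95 * L & perp2 <= bone_r^2 & !stem & !head

  # soft tissue ellipsoid centered in the volume
  semi <- 0.47 * g$extent
  soft <- ((X - g$ctr[1]) / semi[1])^2 + ((Y - g$ctr[2]) / semi[2])^2 +
    ((Z - g$ctr[3]) / semi[3])^2 <= 1

  codes <- default_label_codes()
  lab <- array(codes[["Background"]], dim = dims)
  lab[soft] <- codes[["SoftTissue"]]
  femur_code <- if (cfg$side == "right") codes[["FemurRight"]] else codes[["FemurLeft"]]
  lab[bone] <- femur_code
  lab[stem] <- codes[["Stem"]]
  lab[head] <- codes[["Head"]]

  # implant must keep >= 6 voxels margin on every axis so that every
  # protocol shift (up to 5 voxels) stays inside the grid
  implant <- stem | head
  idx <- which(implant, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("configuration error: implant voxelizes to nothing")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  if (any(lo < 7L) || any(dims - hi < 6L))
    stop("configuration error: implant margin below 6 voxels on axis ",
         paste(.AXES[lo < 7L | dims - hi < 6L], collapse = ","))

  hu <- array(cfg$hu_air, dim = dims)
  hu[soft] <- cfg$hu_soft
  hu[bone] <- cfg$hu_bone
  hu[implant] <- cfg$hu_metal
  if (cfg$noise_sd_hu > 0) {
    noise <- .with_seed(cfg$seed,
                        array(rnorm(prod(dims), 0, cfg$noise_sd_hu), dim = dims))
    hu <- hu + noise
  }

  ct <- ct_volume(hu, spacing = sp)
  labels <- label_volume(lab, spacing = sp, codes = codes)
  lm <- stem_landmarks(center_mm = g$center,
                       tip_mm = g$tip + 1.5 * g$axis,  # inset: inside the taper
                       neck_point_mm = g$head_center,
                       side = cfg$side)
  if (cfg$artifact_streaks)
    ct <- add_streak_artifacts(ct, labels, amplitude_hu = 80, n_streaks = 8,
                               seed = cfg$seed + 1L)
  list(ct = ct, labels = labels, landmarks = lm)
}

#' Add cosmetic metal-artifact streaks
#'
#' Adds radial high/low-HU rays emanating from the implant centroid into
#' non-implant voxels, as a cosmetic emulation of beam-hardening streaks.
#' Implant voxels are never modified.  Deterministic for a fixed seed.
#'
#' @param vol a [ct_volume()].
#' @param lab congruent [label_volume()].
#' @param amplitude_hu peak streak amplitude in HU (>= 0).
#' @param n_streaks number of rays.
#' @param seed integer seed.
#' @return A new [ct_volume()].
#' @export
add_streak_artifacts <- function(vol, lab, amplitude_hu, n_streaks = 8L,
                                 seed = 1L) {
  stopifnot(amplitude_hu >= 0, n_streaks >= 1)
  if (!check_congruent(vol, lab)) stop("image and labels are not congruent")
  if (amplitude_hu == 0) return(vol)
  dims <- dim(vol$voxels)
  implant <- array(lab$labels %in% implant_codes(lab$codes), dim = dims)
  idx <- which(implant, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no implant voxels to anchor streaks")
  c0 <- colMeans(idx)  # centroid in voxel index space
  sp <- vol$spacing
  xs <- ((seq_len(dims[1]) - c0[1]) * sp[1])
  ys <- ((seq_len(dims[2]) - c0[2]) * sp[2])
  zs <- ((seq_len(dims[3]) - c0[3]) * sp[3])
  X <- array(rep(xs, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dim = dims)
  rr <- sqrt(X^2 + Y^2 + Z^2)
  rr[rr == 0] <- 1e-9
  dirs <- .with_seed(seed, {
    u <- matrix(rnorm(3 * n_streaks), ncol = 3)
    u / sqrt(rowSums(u^2))
  })
  add <- array(0, dim = dims)
  sig <- 0.06  # angular half-width (radians-ish, on |cos| scale)
  for (q in seq_len(nrow(dirs))) {
    d <- dirs[q, ]
    cosang <- abs(X * d[1] + Y * d[2] + Z * d[3]) / rr
    ang <- acos(pmin(cosang, 1))
    sgn <- if (q %% 2 == 0) 1 else -1
    add <- add + sgn * amplitude_hu * exp(-(ang / sig)^2)
  }
  add[implant] <- 0
  out <- vol
  out$voxels <- vol$voxels + add
  out
}

#' Baseline scanner voxel spacings
#'
#' Per-baseline voxel spacings (xct, yct, zct in mm) of the ten hip CT
#' protocols the simulation study conditions are modeled on: five Siemens
#' and five Philips acquisitions with in-plane spacing 0.72-0.86 mm and
#' axial spacing 0.45-0.6 mm.
#'
#' @return data.frame with columns \code{baseline_id}, \code{manufacturer},
#'   \code{sx}, \code{sy}, \code{sz}.
#' @export
scanner_spacing_table <- function() {
  data.frame(
    baseline_id = sprintf("P%02d", 1:10),
    manufacturer = c(rep("Siemens", 5), rep("Philips", 5)),
    sx = c(0.8594, 0.7871, 0.8203, 0.7207, 0.7871, rep(0.7812, 5)),
    sy = c(0.8594, 0.7871, 0.8203, 0.7207, 0.7871, rep(0.7812, 5)),
    sz = c(0.5, 0.5, 0.6, 0.5, 0.5, rep(0.45, 5)),
    stringsAsFactors = FALSE
  )
}
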