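test_that("axis-aligned landmarks give the canonical frame", {
  lm <- stem_landmarks(center_mm = c(0, 0, 100), tip_mm = c(0, 0, 0),
                       neck_point_mm = c(20, 0, 100), side = "right")
  fr <- build_stem_frame(lm)
  expect_equal(fr$rotation[, 2], c(0, 0, 1))        # y along centerline
  expect_equal(fr$rotation[, 1], c(1, 0, 0))        # x along neckline
  expect_equal(fr$rotation[, 3], c(0, -1, 0))       # z = x cross y
  expect_equal(fr$origin_mm, c(0, 0, 100))
})

test_that("mirrored left-side landmarks report the same right-sided frame axes", {
  mirror <- function(p) c(-p[1], p[2], p[3])
  # canonical in-plane landmarks: the left-side negation cancels the mirror
  # and the reported x axis is identical to the right-sided one
  lmr0 <- stem_landmarks(c(0, 0, 100), c(0, 0, 0), c(20, 0, 100), "right")
  lml0 <- stem_landmarks(mirror(c(0, 0, 100)), mirror(c(0, 0, 0)),
                         mirror(c(20, 0, 100)), side = "left")
  expect_equal(build_stem_frame(lml0)$rotation[, 1],
               build_stem_frame(lmr0)$rotation[, 1], tolerance = 1e-12)
  # generic landmarks: the medial component of the x axis keeps its sign,
  # the y axis mirrors with the anatomy, and the frame stays right-handed
  lmr <- stem_landmarks(c(5, 2, 100), c(1, 3, 0), c(25, 6, 104), "right")
  lml <- stem_landmarks(mirror(c(5, 2, 100)), mirror(c(1, 3, 0)),
                        mirror(c(25, 6, 104)), side = "left")
  fr <- build_stem_frame(lmr)
  fl <- build_stem_frame(lml)
  expect_equal(fl$rotation[1, 1], fr$rotation[1, 1], tolerance = 1e-12)
  expect_equal(fl$rotation[, 2], mirror(fr$rotation[, 2]), tolerance = 1e-12)
  expect_equal(det(fl$rotation), 1, tolerance = 1e-12)
})

test_that("frames are orthonormal right-handed and scale invariant", {
  set.seed(42)
  for (i in 1:25) {
    tip <- rnorm(3, sd = 30)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    center <- tip + runif(1, 40, 120) * axis
    neck <- center + rnorm(3, sd = 15)
    ok <- tryCatch({ lm <- stem_landmarks(center, tip, neck); TRUE },
                   error = function(e) FALSE)
    if (!ok) next
    fr <- build_stem_frame(lm)
    expect_lt(max(abs(crossprod(fr$rotation) - diag(3))), 1e-9)
    expect_lt(abs(det(fr$rotation) - 1), 1e-9)
    # direction-only: scaling all landmark distances about the center
    lm2 <- stem_landmarks(center, center + 3.7 * (tip - center),
                          center + 3.7 * (neck - center))
    expect_equal(build_stem_frame(lm2)$rotation, fr$rotation,
                 tolerance = 1e-12)
  }
})

test_that("superior stems give y axes pointing superior", {
  ph <- small_phantom()  # stem proximal end toward +z (superior)
  fr <- build_stem_frame(ph$landmarks)
  expect_gt(sum(fr$rotation[, 2] * c(0, 0, 1)), 0.9)
})

test_that("identity-permutation resampling is exact and invertible", {
  ph <- aligned_phantom()
  fr <- build_stem_frame(ph$landmarks)
  spec <- resample_spec("nearest")
  rf <- resample_to_frame(ph$ct, fr, spec)
  # grid axes parallel to the frame, spacing inherited (permuted)
  expect_equal(abs(crossprod(rf$volume$direction, fr$rotation)), diag(3),
               tolerance = 1e-12)
  expect_equal(sort(rf$volume$spacing), sort(ph$ct$spacing))
  back <- resample_from_frame(rf$volume, rf$transform, ph$ct, "nearest")
  expect_identical(back$voxels, ph$ct$voxels)
})

test_that("label masks survive frame resampling within tolerance", {
  ph <- small_phantom()  # tilted stem: genuine interpolation
  fr <- build_stem_frame(ph$landmarks)
  rl <- resample_to_frame(ph$labels, fr, resample_spec())
  n0 <- sum(implant_mask_of(ph$labels))
  n1 <- sum(implant_mask_of(rl$volume))
  expect_lt(abs(n1 - n0) / n0, 0.02)
  back <- resample_from_frame(rl$volume, rl$transform, ph$labels)
  n2 <- sum(implant_mask_of(back))
  expect_lt(abs(n2 - n0) / n0, 0.05)
})

test_that("linear interpolation output stays within the input HU hull", {
  ph <- small_phantom()
  fr <- build_stem_frame(ph$landmarks)
  rf <- resample_to_frame(ph$ct, fr, resample_spec("linear"))
  lo <- min(min(ph$ct$voxels), -1024)  # padding joins the hull
  expect_gte(min(rf$volume$voxels), lo - 1e-9)
  expect_lte(max(rf$volume$voxels), max(ph$ct$voxels) + 1e-9)
})

test_that("tilted-frame HU round trip stays close on the noise-free phantom", {
  ph <- small_phantom()
  fr <- build_stem_frame(ph$landmarks)
  rf <- resample_to_frame(ph$ct, fr, resample_spec("linear"))
  back <- resample_from_frame(rf$volume, rf$transform, ph$ct, "linear")
  soft <- ph$labels$labels == ph$labels$codes[["SoftTissue"]]
  # inside soft tissue (eroded so tissue-boundary smearing is excluded) the
  # field is constant and interpolation must not disturb it
  interior <- soft
  for (sh in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    for (sgn in c(-2L, -1L, 1L, 2L)) {
      d <- sh * sgn
      interior <- interior & .shift_logical(soft, d)
    }
  }
  expect_gt(sum(interior), 1000)
  expect_lt(mean(abs(back$voxels[interior] - ph$ct$voxels[interior])), 20)
})

test_that("mismatched grids are refused on the inverse resample", {
  ph <- aligned_phantom()
  fr <- build_stem_frame(ph$landmarks)
  rf <- resample_to_frame(ph$ct, fr, resample_spec("nearest"))
  wrong <- ct_volume(ph$ct$voxels, spacing = ph$ct$spacing * 2)
  expect_error(resample_from_frame(rf$volume, rf$transform, wrong),
               "reference grid")
  expect_error(resample_from_frame(ph$ct, rf$transform, ph$ct),
               "stem-aligned grid")
})

test_that("landmarks round-trip through JSON", {
  ph <- small_phantom()
  f <- file.path(withr::local_tempdir(), "landmarks.json")
  write_landmarks(ph$landmarks, f)
  expect_equal(read_landmarks(f), ph$landmarks)
})
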