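# frame-space fixtures shared by the shift tests
frame_fixture <- function() {
  cached("frame_fixture", {
    ph <- aligned_phantom()
    fr <- build_stem_frame(ph$landmarks)
    spec <- resample_spec("nearest")
    list(ph = ph, fr = fr,
         ct = resample_to_frame(ph$ct, fr, spec)$volume,
         lab = resample_to_frame(ph$labels, fr, spec)$volume)
  })
}

test_that("the zero shift is a strict no-op", {
  fx <- frame_fixture()
  res <- apply_shift(fx$ct, fx$lab, implant_codes(), shift_spec(0, 0, 0))
  expect_identical(res$ct$voxels, fx$ct$voxels)
  expect_identical(res$labels$labels, fx$lab$labels)
  expect_false(any(res$vacated))
  expect_identical(res$overlap_fraction, 0)
})

test_that("a one-voxel shift moves the implant centroid by exactly one voxel", {
  fx <- frame_fixture()
  res <- suppressMessages(
    apply_shift(fx$ct, fx$lab, implant_codes(), shift_spec(0, 1, 0, "y")))
  c0 <- colMeans(which(implant_mask_of(fx$lab), arr.ind = TRUE))
  c1 <- colMeans(which(implant_mask_of(res$labels), arr.ind = TRUE))
  expect_equal(c1 - c0, c(0, 1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("implant voxel count is conserved and locality holds for every shift", {
  fx <- frame_fixture()
  n0 <- sum(implant_mask_of(fx$lab))
  shifts <- full_protocol()
  src <- implant_mask_of(fx$lab)
  for (s in sample(seq_len(nrow(shifts)), 12)) {
    sh <- shift_spec(shifts$dx[s], shifts$dy[s], shifts$dz[s])
    res <- suppressMessages(apply_shift(fx$ct, fx$lab, implant_codes(), sh))
    expect_identical(sum(implant_mask_of(res$labels)), n0)
    # voxels outside source, destination and vacated are bit-identical
    dst <- implant_mask_of(res$labels)
    untouched <- !(src | dst | res$vacated)
    expect_identical(res$ct$voxels[untouched], fx$ct$voxels[untouched])
    expect_identical(res$labels$labels[untouched], fx$lab$labels[untouched])
  }
})

test_that("out-of-bounds shifts fail naming the offending axis", {
  codes <- default_label_codes()
  lab <- array(codes[["SoftTissue"]], dim = c(8, 8, 8))
  lab[6:8, 4, 4] <- codes[["Stem"]]
  lv <- label_volume(lab)
  cv <- ct_volume(array(0, dim = c(8, 8, 8)))
  expect_error(apply_shift(cv, lv, implant_codes(), shift_spec(1, 0, 0)),
               "out of bounds along x axis")
  expect_error(apply_shift(cv, lv, implant_codes(), shift_spec(0, -4, 0)),
               "y axis")
  res <- suppressMessages(
    apply_shift(cv, lv, implant_codes(), shift_spec(-2, 0, 0)))
  expect_identical(sum(res$labels$labels == codes[["Stem"]]), 3L)
})

test_that("an empty implant mask is rejected", {
  cv <- ct_volume(array(0, dim = c(4, 4, 4)))
  lv <- label_volume(array(1L, dim = c(4, 4, 4)))
  expect_error(apply_shift(cv, lv, implant_codes(), shift_spec(1, 0, 0)),
               "implant mask is empty")
})

test_that("filling in a uniform soft-tissue field reproduces the field", {
  fx <- frame_fixture()
  res <- suppressMessages(
    apply_shift(fx$ct, fx$lab, implant_codes(), shift_spec(0, 3, 0, "y")))
  expect_gt(sum(res$vacated), 0)
  for (r in c(0L, 1L, 2L)) {
    filled <- fill_vacated(res$ct, res$vacated, res$labels,
                           fill_config(smoothing_radius_voxels = r))
    expect_true(all(filled$voxels[res$vacated] == 40))
    expect_identical(filled$voxels[!res$vacated], res$ct$voxels[!res$vacated])
  }
})

test_that("an empty vacated mask leaves the image untouched", {
  fx <- frame_fixture()
  empty <- array(FALSE, dim = dim(fx$ct$voxels))
  expect_identical(fill_vacated(fx$ct, empty, fx$lab), fx$ct)
})

test_that("nearest-donor filling matches the brute-force oracle on 32^3", {
  set.seed(99)
  dims <- c(32L, 32L, 32L)
  codes <- default_label_codes()
  lab <- array(codes[["SoftTissue"]], dim = dims)
  lab[12:20, 12:20, 8:24] <- codes[["Stem"]]
  lab[1:4, , ] <- codes[["Background"]]
  lab[, 28:32, ] <- codes[["FemurRight"]]
  lv <- label_volume(lab, spacing = c(0.8, 0.7, 0.5))
  hu <- array(rnorm(prod(dims), 40, 15), dim = dims)
  hu[lab == codes[["Stem"]]] <- 3000
  hu[lab == codes[["FemurRight"]]] <- 1200
  hu[lab == codes[["Background"]]] <- -1000
  cv <- ct_volume(hu, spacing = c(0.8, 0.7, 0.5))
  res <- suppressMessages(
    apply_shift(cv, lv, implant_codes(), shift_spec(0, 2, 1)))
  filled <- fill_vacated(res$ct, res$vacated, res$labels,
                         fill_config(smoothing_radius_voxels = 0L))
  donor <- res$labels$labels == codes[["SoftTissue"]] & !res$vacated
  cands <- brute_force_nearest_candidates(res$ct$voxels, donor, cv$spacing,
                                          which(res$vacated, arr.ind = TRUE))
  got <- filled$voxels[res$vacated]
  expect_true(all(vapply(seq_along(got),
                         function(q) any(abs(got[q] - cands[[q]]) < 1e-12),
                         logical(1))))
  # with smoothing, filled values stay inside the donor-region HU hull
  sm <- fill_vacated(res$ct, res$vacated, res$labels,
                     fill_config(smoothing_radius_voxels = 1L))
  rng <- range(res$ct$voxels[donor])
  expect_true(all(sm$voxels[res$vacated] >= rng[1] &
                    sm$voxels[res$vacated] <= rng[2]))
})

test_that("ground truth is linear in the shift", {
  sp <- c(0.8594, 0.5, 0.8594)
  t1 <- unlist(manifest_record("b", "f", "x", c(1L, 2L, -1L), sp)[, 7:9])
  t2 <- unlist(manifest_record("b", "f", "x", c(3L, -2L, 0L), sp)[, 7:9])
  t12 <- unlist(manifest_record("b", "f", "x", c(4L, 0L, -1L), sp)[, 7:9])
  expect_identical(t12, t1 + t2)
})

test_that("a shift followed by its inverse restores the implant exactly", {
  fx <- frame_fixture()
  res <- suppressMessages(
    apply_shift(fx$ct, fx$lab, implant_codes(), shift_spec(2, -3, 1)))
  back <- suppressMessages(
    apply_shift(res$ct, res$labels, implant_codes(), shift_spec(-2, 3, -1)))
  expect_identical(implant_mask_of(back$labels), implant_mask_of(fx$lab))
  imp <- implant_mask_of(fx$lab)
  expect_identical(back$ct$voxels[imp], fx$ct$voxels[imp])
})

test_that("generate_followup produces the documented ground truth", {
  ph <- aligned_phantom()
  fr <- build_stem_frame(ph$landmarks)
  g <- suppressMessages(
    generate_followup(ph$ct, ph$labels, fr, shift_spec(0, 1, 0, "y"),
                      spec = resample_spec("nearest")))
  expect_equal(g$record$truth_y_mm, 0.5)  # frame y inherits the 0.5 mm axial spacing
  expect_equal(g$record$truth_x_mm, 0)
  expect_true(check_congruent(g$followup, ph$ct))
})
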