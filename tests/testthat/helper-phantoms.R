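# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# compact phantom used by most unit tests (noise free unless overridden)
small_phantom_config <- function(...) {
  args <- list(shape = c(48L, 48L, 80L), spacing_mm = c(0.78, 0.78, 0.5),
               stem_length_mm = 14, stem_radius_mm = 3,
               head_radius_mm = 3.5, neck_length_mm = 7.5,
               stem_tilt_deg = 8, noise_sd_hu = 0, seed = 7L)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

small_phantom <- function() cached("small", generate_phantom(small_phantom_config()))

# axis-aligned variant: stem exactly along the image z axis
aligned_phantom <- function() {
  cached("aligned",
         generate_phantom(small_phantom_config(stem_tilt_deg = 0)))
}

# full-size noise-free, axis-aligned phantom for the end-to-end suite
protocol_phantom <- function() {
  cached("protocol",
         generate_phantom(phantom_config(noise_sd_hu = 0, stem_tilt_deg = 0)))
}

# translate a logical array by integer voxel offset d, FALSE outside
.shift_logical <- function(m, d) {
  dims <- dim(m)
  out <- array(FALSE, dims)
  src <- vector("list", 3); dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      src[[a]] <- seq_len(dims[a] - d[a]); dst[[a]] <- src[[a]] + d[a]
    } else {
      dst[[a]] <- seq_len(dims[a] + d[a]); src[[a]] <- dst[[a]] - d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

implant_mask_of <- function(lab) {
  array(lab$labels %in% implant_codes(lab$codes), dim = dim(lab$labels))
}

# brute-force exact nearest-donor oracle (mm-scaled Euclidean metric);
# returns, per vacated voxel, every donor value at the minimal distance so
# that equidistant ties are accepted whichever donor the implementation picks
brute_force_nearest_candidates <- function(vals, donor, spacing, vac_idx) {
  didx <- which(donor, arr.ind = TRUE)
  dval <- vals[donor]
  lapply(seq_len(nrow(vac_idx)), function(q) {
    dd <- sweep(didx, 2, vac_idx[q, ])
    d2 <- (dd[, 1] * spacing[1])^2 + (dd[, 2] * spacing[2])^2 +
      (dd[, 3] * spacing[3])^2
    dval[d2 <= min(d2) + 1e-9]
  })
}
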