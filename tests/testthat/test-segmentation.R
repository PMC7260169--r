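test_that("saturation clips at linear-interpolation percentiles", {
  two <- grey_volume(array(rep(c(0, 1), 500), c(10, 10, 10)))
  s <- saturate(two)
  expect_identical(s$volume$data, two$data * 1)
  expect_equal(s$scale$clip_min, 0)
  expect_equal(s$scale$clip_max, 1)

  const <- grey_volume(array(5, c(5, 5, 5)))
  sc <- saturate(const)
  expect_true(all(sc$volume$data == 5))
  expect_equal(sc$scale$clip_min, sc$scale$clip_max)

  ramp <- grey_volume(array(as.numeric(1:1000), c(10, 10, 10)))
  sr <- saturate(ramp)
  # sort-and-interpolate percentile oracle (linear interpolation, type 7)
  oq <- function(p) {
    h <- (1000 - 1) * p + 1
    sort(1:1000)[floor(h)] + (h - floor(h)) *
      (sort(1:1000)[ceiling(h)] - sort(1:1000)[floor(h)])
  }
  expect_equal(sr$scale$clip_min, oq(0.005))
  expect_equal(sr$scale$clip_max, oq(0.995))
  expect_equal(min(sr$volume$data), oq(0.005))
  expect_equal(max(sr$volume$data), oq(0.995))
  expect_error(saturate(ramp, 99, 1), "low_pct")
})

test_that("normalization maps the clip window onto the unit interval", {
  sc <- structure(list(clip_min = 10, clip_max = 30),
                  class = "intensity_scale")
  v <- grey_volume(array(c(10, 20, 30), c(3, 1, 1)))
  n <- normalize_intensity(v, sc)
  expect_equal(as.vector(n$data), c(0, 0.5, 1))
  # constant scale maps to zero
  n0 <- normalize_intensity(v, structure(list(clip_min = 7, clip_max = 7),
                                         class = "intensity_scale"))
  expect_true(all(n0$data == 0))
  # full 0-254 volume with negligible clipping: 102 sits near the 0.4 cutoff
  full <- grey_volume(array(as.integer(rep(0:254, length.out = 8000)),
                            c(20, 20, 20)))
  s <- saturate(full)
  nf <- normalize_intensity(s$volume, s$scale)
  expect_equal(nf$data[which(full$data == 102L)[1]], 0.4, tolerance = 0.01)
})

test_that("the adaptive-threshold sigma follows the region-size formula", {
  expect_equal(gaussian_sigma(60), 59 / 6)
  expect_equal(gaussian_sigma(60), 9.8333, tolerance = 1e-4)
  expect_equal(gaussian_sigma(7), 1)
  expect_warning(s0 <- gaussian_sigma(1), "degenerate")
  expect_equal(s0, 0)
})

test_that("adaptive thresholding matches a brute-force kernel-sum oracle", {
  set.seed(21)
  v <- array(runif(16^3), c(16, 16, 16))
  region <- 9; offset <- 0.06
  m <- adaptive_gaussian_threshold(v, region, offset)
  om <- oracle_gaussian_mean(v, (region - 1) / 6)
  oracle <- array(1L, dim(v))
  oracle[as.vector(v) < om - offset] <- 0L
  expect_identical(m$data, oracle)
  # spot-check the published region size on a larger volume
  set.seed(22)
  v2 <- array(runif(48^3), c(48, 48, 48))
  m2 <- adaptive_gaussian_threshold(v2, 60, 0.06)
  pts <- cbind(sample(48, 25, TRUE), sample(48, 25, TRUE),
               sample(48, 25, TRUE))
  om2 <- oracle_gaussian_mean(v2, 59 / 6, voxels = pts)
  dec <- ifelse(v2[pts] < om2 - 0.06, 0L, 1L)
  expect_identical(m2$data[pts], dec)
})

test_that("flat fields are all air; an isolated dark voxel is material", {
  const <- grey_volume(array(0.5, c(20, 20, 20)))
  expect_true(all(adaptive_gaussian_threshold(const, 60, 0.06)$data == 1L))
  v <- array(0.8, c(121, 121, 121))
  v[61, 61, 61] <- 0
  m <- adaptive_gaussian_threshold(v, 60, 0.06)
  expect_identical(m$data[61, 61, 61], 0L)
  expect_identical(m$data[5, 5, 5], 1L)
  expect_equal(sum(m$data == 0L), 1)
})

test_that("the global threshold is strictly below the cutoff", {
  v <- grey_volume(array(c(0.39, 0.40, 0.41), c(3, 1, 1)))
  m <- global_threshold(v, 0.4)
  expect_identical(as.vector(m$data), c(0L, 1L, 1L))
  expect_true(all(global_threshold(array(1, c(2, 2, 2)), 0.4)$data == 1L))
  set.seed(2)
  u <- array(runif(64, max = 0.999), c(4, 4, 4))
  expect_true(all(global_threshold(u, 1.0)$data == 0L))
})

test_that("mask combination is the union of material sets", {
  a <- binary_volume(array(c(0L, 0L, 1L, 1L), c(4, 1, 1)))
  g <- binary_volume(array(c(0L, 1L, 0L, 1L), c(4, 1, 1)))
  cm <- combine_masks(a, g)
  expect_identical(as.vector(cm$data), c(0L, 0L, 0L, 1L))
  expect_identical(combine_masks(a, a)$data, a$data)
  set.seed(13)
  r1 <- binary_volume(array(rbinom(512, 1, 0.6), c(8, 8, 8)))
  r2 <- binary_volume(array(rbinom(512, 1, 0.6), c(8, 8, 8)))
  expect_gte(fill_fraction(combine_masks(r1, r2)),
             max(fill_fraction(r1), fill_fraction(r2)))
  expect_error(combine_masks(r1, binary_volume(array(0L, c(2, 2, 2)))),
               "shape")
})

test_that("non-local means preserves flat fields and the zero-strength limit", {
  const <- grey_volume(array(0.37, c(12, 12, 12)))
  d <- nlm_denoise(const, 3, 3, h = 0.1, sigma = 0)
  expect_lt(max(abs(d$data - const$data)), 1e-5)
  set.seed(31)
  v <- array(runif(12^3), c(12, 12, 12))
  d0 <- nlm_denoise(v, 3, 3, h = 1e-6, sigma = 0)
  expect_equal(d0$data, v, tolerance = 1e-5)
  expect_error(nlm_denoise(v, 4, 3), "odd")
})

test_that("non-local means agrees with a literal double-precision oracle", {
  set.seed(33)
  v <- array(runif(7 * 7 * 7), c(7, 7, 7))
  d <- nlm_denoise(v, patch_size = 3, patch_distance = 2, h = 0.15,
                   sigma = 0.05)
  o <- oracle_nlm(v, 1, 2, 0.15, 0.05)
  expect_equal(d$data, o, tolerance = 1e-4)
})

test_that("denoising shrinks per-phase variance and preserves phase means", {
  cfg <- synthetic_scale_config(shape = c(32, 32, 64),
                                cuticle_thickness_voxels = 0, seed = 12)
  tr <- generate_truth(cfg)
  base <- ifelse(tr$data == 0, 0.2, 0.8)
  set.seed(5)
  v <- base + rnorm(length(base), 0, 0.08)
  v <- pmin(pmax(v, 0), 1); dim(v) <- dim(base)
  d <- nlm_denoise(v, 5, 5)
  for (lev in c(0.2, 0.8)) {
    sel <- base == lev
    expect_lt(sd(d$data[sel]), sd(v[sel]))
    expect_lt(abs(mean(d$data[sel]) - mean(v[sel])), 0.01)
  }
  expect_lt(abs(attr(d, "nlm_sigma") - 0.08), 0.015)
})

test_that("chunked application equals monolithic wherever the halo covers", {
  set.seed(51)
  v <- array(runif(32^3), c(32, 32, 32))
  op <- nlm_operator(3, 3, h = 0.1, sigma = 0.05)  # support 4
  mono <- grey_volume(array(op$fn(v), dim(v)))
  one <- chunked_apply(v, op, chunk_shape = 64, halo = 10)
  expect_identical(one$data, mono$data)
  split <- chunked_apply(v, op, chunk_shape = 16, halo = 5)
  expect_identical(split$data, mono$data)
  par2 <- chunked_apply(v, op, chunk_shape = 16, halo = 5, workers = 2)
  expect_identical(par2$data, mono$data)
  expect_error(chunked_apply(v, op, chunk_shape = 16, halo = 3),
               "support")
  op57 <- nlm_operator(5, 7, h = 0.1, sigma = 0.05)  # support 9
  expect_error(chunked_apply(v, op57, chunk_shape = 16, halo = 5),
               "support")
})

test_that("thresholds are monotone in their parameters", {
  set.seed(61)
  v <- array(runif(16^3), c(16, 16, 16))
  g1 <- global_threshold(v, 0.3)$data
  g2 <- global_threshold(v, 0.5)$data
  expect_true(all(g2[g1 == 0] == 0))  # larger cutoff never shrinks material
  a1 <- adaptive_gaussian_threshold(v, 9, 0.02)$data
  a2 <- adaptive_gaussian_threshold(v, 9, 0.10)$data
  expect_true(all(a1[a2 == 0] == 0))  # larger offset never grows material
})

test_that("the full chain reproduces a noiseless two-level truth exactly", {
  sc <- make_scale(c(48, 48, 96), seed = 2, noise_sigma = 0,
                   ring_amplitude = 0)
  m <- segment(sc$grey)
  expect_identical(m$data, sc$truth$data)
  # output is valid binary and survives the packed round trip
  expect_setequal(unique(as.vector(m$data)), c(0L, 1L))
  expect_identical(unpack_binary(pack_binary(m))$data, m$data)
})

test_that("identical configurations yield identical recorded parameters", {
  cfg <- segmentation_config()
  m1 <- segment(make_scale(c(32, 32, 48), seed = 1,
                           cuticle_thickness_voxels = 6)$grey, cfg)
  m2 <- segment(make_scale(c(32, 32, 48), seed = 2,
                           cuticle_thickness_voxels = 6)$grey, cfg)
  fields <- names(unclass(cfg))
  fields <- fields[!vapply(unclass(cfg), is.null, logical(1))]
  p1 <- attr(m1, "provenance"); p2 <- attr(m2, "provenance")
  expect_identical(serialize(p1[fields], NULL), serialize(p2[fields], NULL))
  # derived quantities are recorded alongside
  expect_true(all(c("nlm_sigma_derived", "nlm_h_used", "clip_min",
                    "clip_max") %in% names(p1)))
  expect_error(segmentation_config(halo = 5), "halo")
})
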