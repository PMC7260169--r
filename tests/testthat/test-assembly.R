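test_that("nominal overlap frame counts come from the pitch", {
  expect_identical(nominal_overlap_frames(10, 25), 400L)
  expect_identical(nominal_overlap_frames(0, 25), 0L)
  expect_identical(nominal_overlap_frames(1, 25), 40L)
  expect_error(nominal_overlap_frames(1, 30), "not an integer")
})

test_that("a volume matches itself with zero offset and perfect score", {
  sc <- make_scale(c(24, 24, 60), seed = 4, cuticle_thickness_voxels = 4)
  m <- find_overlap(sc$grey, sc$grey, nominal_frames = 0,
                    search_window = 5, lateral_window = 2)
  expect_identical(m$z_offset, 0L)
  expect_identical(unname(m$lateral_shift), c(0L, 0L))
  expect_equal(m$score, 1, tolerance = 1e-12)
  flat <- grey_volume(array(7L, c(8, 8, 20)))
  expect_error(find_overlap(flat, flat, 0, 2, 1), "texture")
})

test_that("true offsets and shifts are recovered on jittered scan sets", {
  sc <- make_scale(c(48, 48, 300), seed = 6)
  ss <- split_into_scans(sc$grey, 120, 40, lateral_jitter = 2, seed = 8)
  run_match <- function(ss_obs) {
    ms <- lapply(seq_len(length(ss_obs$scans) - 1), function(k)
      find_overlap(ss_obs$scans[[k]], ss_obs$scans[[k + 1]], 40,
                   search_window = 10, lateral_window = 4))
    list(off = cumsum(c(0L, vapply(ms, `[[`, integer(1), "z_offset"))),
         sh = apply(rbind(c(0L, 0L),
                          t(vapply(ms, `[[`, integer(2), "lateral_shift"))),
                    2, cumsum),
         matches = ms)
  }
  r <- run_match(ss)
  expect_identical(as.integer(r$off), ss$z_offsets)
  # the aligning shift undoes the applied one
  expect_identical(unname(r$sh), -1L * unname(ss$lateral_shifts))
  # independent per-scan noise at sigma = 5 grey levels: still exact
  ssn <- perturb_scans(ss, sd = 5, seed = 99)
  rn <- run_match(ssn)
  expect_identical(as.integer(rn$off), ss$z_offsets)
  expect_identical(unname(rn$sh), -1L * unname(ss$lateral_shifts))
})

test_that("match scores are invariant to affine intensity rescaling", {
  sc <- make_scale(c(24, 24, 120), seed = 9, cuticle_thickness_voxels = 4)
  ss <- split_into_scans(sc$grey, 60, 20, lateral_jitter = 1, seed = 3)
  a <- ss$scans[[1]]; b <- ss$scans[[2]]
  m1 <- find_overlap(a, b, 20, search_window = 6, lateral_window = 2)
  b2 <- grey_volume(array(as.numeric(b$data) * 1.7 + 11, dim(b$data)))
  m2 <- find_overlap(a, b2, 20, search_window = 6, lateral_window = 2)
  expect_identical(m2$z_offset, m1$z_offset)
  expect_identical(m2$lateral_shift, m1$lateral_shift)
  expect_equal(m2$score, m1$score, tolerance = 1e-9)
})

test_that("stitching inverts splitting bit-exactly and places seams centrally", {
  sc <- make_scale(c(48, 48, 300), seed = 6)
  for (jit in c(0, 2)) {
    ss <- split_into_scans(sc$grey, 120, 40, lateral_jitter = jit, seed = 8)
    ms <- lapply(seq_len(length(ss$scans) - 1), function(k)
      find_overlap(ss$scans[[k]], ss$scans[[k + 1]], 40,
                   search_window = 10, lateral_window = 4))
    st <- stitch(ss, ms)
    if (jit == 0) {
      expect_identical(st$data, sc$grey$data)
    } else {
      # jittered scans lose shifted-out edge columns; the interior is exact
      expect_identical(st$data[3:46, 3:46, ], sc$grey$data[3:46, 3:46, ])
    }
    plan <- attr(st, "stitch_plan")
    expect_equal(plan$seams[seq_along(ms)],
                 plan$z_offsets[-1] + 20L)  # centre of the 40-frame overlap
  }
})

test_that("stitched extent equals offsets plus field of view", {
  v <- grey_volume(array(as.integer(sample(0:254, 8 * 8 * 3920, TRUE)),
                         c(8, 8, 3920)))
  ss <- split_into_scans(v, 2160, 400, lateral_jitter = 0, seed = 1)
  expect_length(ss$scans, 2L)
  ms <- list(find_overlap(ss$scans[[1]], ss$scans[[2]], 400,
                          search_window = 5, lateral_window = 0))
  st <- stitch(ss, ms)
  expect_equal(dim(st), c(8, 8, 3920))  # 2 * 2160 - 400
})

test_that("known small tilts are recovered from principal axes", {
  sc <- make_scale(c(48, 64, 160), seed = 1, correlation_length_nm = 100,
                   cuticle_thickness_voxels = 4)
  vol <- embed_in_air(sc$grey, c(80, 100, 220))
  est0 <- estimate_tilt(vol)
  expect_true(all(abs(est0) < 0.5))
  est3 <- estimate_tilt(rotate_volume(vol, c(3, 0, 0)))
  expect_equal(unname(est3[["theta_x"]]), -3, tolerance = 0.5 / 3)
  esty <- estimate_tilt(rotate_volume(vol, c(0, -2, 0)))
  expect_equal(unname(esty[["theta_y"]]), 2, tolerance = 0.5 / 2)
  set.seed(4)
  u <- grey_volume(array(as.integer(sample(0:254, 40^3, TRUE)),
                         c(40, 40, 40)))
  expect_error(estimate_tilt(u), "dominant object")
})

test_that("rotation is exact on lattice symmetries and near-invertible", {
  sv <- smooth_volume(c(48, 48, 96), seed = 8)
  expect_identical(rotate_volume(sv, c(0, 0, 0))$data, sv$data)

  set.seed(12)
  cube <- grey_volume(array(as.integer(sample(0:254, 20^3, TRUE)),
                            c(20, 20, 20)))
  r90 <- rotate_volume(cube, c(0, 0, 90), order = "nearest")
  man <- array(0L, c(20, 20, 20))
  for (x in 1:20) for (y in 1:20) man[x, y, ] <- cube$data[y, 21 - x, ]
  expect_identical(r90$data, man)

  fw <- rotate_volume(sv, c(2, 0, 0))
  bk <- rotate_volume(fw, c(-2, 0, 0))
  i <- 5:44; k <- 5:92
  rms <- sqrt(mean((bk$data[i, i, k] - sv$data[i, i, k])^2))
  expect_lt(rms, 2)
  expect_error(rotate_volume(sv, c(NA, 0, 0)), "finite")
})
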